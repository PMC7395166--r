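#' Construct a coloured point cloud
#'
#' Builds a \code{\linkS4class{ColouredPointCloud}} from a coordinate matrix
#' and an RGB matrix. Rows with non-finite coordinates are dropped and
#' counted, mirroring what [readPLY()] does on file input.
#'
#' @param coords numeric N x 3 matrix of (x, y, z) coordinates.
#' @param rgb numeric or integer N x 3 matrix with values in [0, 255].
#' @param sourceId character identifier attached to the cloud.
#' @param extra optional data.frame of additional per-point attributes.
#' @param extraTypes named character vector of PLY type names for `extra`.
#' @return A \code{\linkS4class{ColouredPointCloud}}.
#' @examples
#' cl <- newPointCloud(matrix(runif(30), ncol = 3),
#'                     matrix(200L, nrow = 10, ncol = 3))
#' nPoints(cl)
#' @export
newPointCloud <- function(coords, rgb, sourceId = NA_character_,
                          extra = data.frame(), extraTypes = character(0)) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  rgb <- as.matrix(rgb)
  storage.mode(rgb) <- "integer"
  keep <- is.finite(coords[, 1L]) & is.finite(coords[, 2L]) &
    is.finite(coords[, 3L])
  nDropped <- sum(!keep)
  if (nDropped > 0L) {
    coords <- coords[keep, , drop = FALSE]
    rgb <- rgb[keep, , drop = FALSE]
    if (nrow(extra) > 0L) extra <- extra[keep, , drop = FALSE]
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  dimnames(rgb) <- list(NULL, c("r", "g", "b"))
  new("ColouredPointCloud", coords = coords, rgb = rgb,
      extra = extra, extraTypes = extraTypes,
      sourceId = sourceId, nDropped = as.integer(nDropped))
}

.ply_type_size <- c(
  char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
  short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
  int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
  float = 4L, float32 = 4L, double = 8L, float64 = 8L
)

.ply_read_column <- function(data, offsets, type) {
  # offsets: 0-based byte offsets of the first byte of each value
  size <- .ply_type_size[[type]]
  idx <- as.vector(outer(seq_len(size), offsets, `+`))  # 1-based
  bytes <- data[idx]
  n <- length(offsets)
  switch(type,
    float = , float32 = readBin(bytes, "numeric", n = n, size = 4L,
                                endian = "little"),
    double = , float64 = readBin(bytes, "numeric", n = n, size = 8L,
                                 endian = "little"),
    char = , int8 = readBin(bytes, "integer", n = n, size = 1L,
                            signed = TRUE, endian = "little"),
    uchar = , uint8 = readBin(bytes, "integer", n = n, size = 1L,
                              signed = FALSE, endian = "little"),
    short = , int16 = readBin(bytes, "integer", n = n, size = 2L,
                              signed = TRUE, endian = "little"),
    ushort = , uint16 = readBin(bytes, "integer", n = n, size = 2L,
                                signed = FALSE, endian = "little"),
    int = , int32 = readBin(bytes, "integer", n = n, size = 4L,
                            endian = "little"),
    uint = , uint32 = {
      v <- readBin(bytes, "integer", n = n, size = 4L, endian = "little")
      v <- as.numeric(v)
      v[v < 0] <- v[v < 0] + 2^32
      v
    },
    stop("unsupported PLY property type: ", type, call. = FALSE)
  )
}

.ply_parse_header <- function(raw) {
  # locate "end_header" + newline by raw byte search (the binary payload
  # may contain nul bytes, so the file must not pass through rawToChar)
  probe_len <- min(length(raw), 65536L)
  m <- grepRaw("end_header", raw[seq_len(probe_len)], fixed = TRUE)
  if (length(m) == 0L) {
    stop("not a valid PLY file: no end_header found in the first ",
         probe_len, " bytes", call. = FALSE)
  }
  m <- m[1L]
  header_end <- m + 9L                    # last byte of "end_header"
  if (header_end < length(raw) && raw[header_end + 1L] == as.raw(13L)) {
    header_end <- header_end + 1L         # optional \r
  }
  if (header_end >= length(raw) || raw[header_end + 1L] != as.raw(10L)) {
    stop("not a valid PLY file: end_header not terminated by newline",
         call. = FALSE)
  }
  header_end <- header_end + 1L           # the newline itself
  lines <- strsplit(rawToChar(raw[seq_len(m - 1L)]), "\r?\n")[[1]]
  if (length(lines) == 0L || trimws(lines[1]) != "ply") {
    stop("not a valid PLY file: missing 'ply' magic", call. = FALSE)
  }
  format <- NULL
  elements <- list()
  cur <- NULL
  for (ln in lines[-1]) {
    tok <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment" || tok[1] == "obj_info") next
    if (tok[1] == "format") {
      format <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("PLY property outside element", call. = FALSE)
      if (tok[2] == "list") {
        cur$props[[tok[5]]] <- list(name = tok[5], list = TRUE,
                                    count_type = tok[3], item_type = tok[4])
      } else {
        cur$props[[tok[3]]] <- list(name = tok[3], list = FALSE,
                                    type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(format) || !format %in% c("ascii", "binary_little_endian")) {
    stop("unsupported PLY format: ",
         if (is.null(format)) "<missing>" else format,
         " (ascii and binary_little_endian are supported)", call. = FALSE)
  }
  list(format = format, elements = elements, data_start = header_end + 1L)
}

#' Read a coloured point cloud from a PLY file
#'
#' Parses ASCII or binary-little-endian PLY. The vertex element must carry
#' `x`, `y`, `z` coordinates and `red`, `green`, `blue` colours; any further
#' scalar vertex properties are preserved and re-emitted by [writePLY()].
#' Faces and other elements are ignored. Vertex rows with non-finite
#' coordinates are dropped and counted in the returned object.
#'
#' @param path path to a `.ply` file.
#' @return A \code{\linkS4class{ColouredPointCloud}} whose `sourceId` is the
#'   file's base name.
#' @seealso [writePLY()]
#' @export
readPLY <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  hdr <- .ply_parse_header(raw)
  elements <- hdr$elements
  if (!"vertex" %in% names(elements)) {
    stop("PLY file has no vertex element: ", path, call. = FALSE)
  }
  vertex <- elements[["vertex"]]
  needed <- c("x", "y", "z", "red", "green", "blue")
  missing <- setdiff(needed, names(vertex$props))
  if (length(missing)) {
    stop("PLY vertex element lacks required propert",
         if (length(missing) > 1) "ies: " else "y: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(vapply(vertex$props, `[[`, TRUE, "list"))) {
    stop("list-typed vertex properties are not supported", call. = FALSE)
  }

  if (hdr$format == "ascii") {
    vals <- .ply_read_ascii(raw, hdr, vertex)
  } else {
    vals <- .ply_read_binary(raw, hdr, vertex, path)
  }
  pnames <- names(vertex$props)
  co <- cbind(vals[["x"]], vals[["y"]], vals[["z"]])
  rgbm <- cbind(vals[["red"]], vals[["green"]], vals[["blue"]])
  extra_names <- setdiff(pnames, needed)
  extra <- if (length(extra_names)) {
    as.data.frame(vals[extra_names], optional = TRUE)
  } else {
    data.frame()
  }
  extraTypes <- vapply(vertex$props[extra_names], `[[`, "", "type")
  newPointCloud(co, rgbm, sourceId = basename(path),
                extra = extra, extraTypes = extraTypes)
}

.ply_read_ascii <- function(raw, hdr, vertex) {
  txt <- rawToChar(raw[hdr$data_start:length(raw)])
  lines <- strsplit(txt, "\r?\n")[[1]]
  lines <- lines[nzchar(trimws(lines))]
  offset <- 0L
  for (el in hdr$elements) {
    if (el$name == "vertex") break
    offset <- offset + el$count
  }
  if (length(lines) < offset + vertex$count) {
    stop("truncated ASCII PLY: expected ", offset + vertex$count,
         " data rows, found ", length(lines), call. = FALSE)
  }
  vlines <- lines[(offset + 1L):(offset + vertex$count)]
  tok <- strsplit(trimws(vlines), "[ \t]+")
  np <- length(vertex$props)
  bad <- vapply(tok, length, 1L) < np
  if (any(bad)) {
    stop("malformed ASCII PLY vertex row ", which(bad)[1], call. = FALSE)
  }
  mat <- matrix(as.numeric(unlist(lapply(tok, `[`, seq_len(np)))),
                ncol = np, byrow = TRUE)
  stats::setNames(lapply(seq_len(np), function(j) mat[, j]),
                  names(vertex$props))
}

.ply_read_binary <- function(raw, hdr, vertex, path) {
  pos <- hdr$data_start  # 1-based index of first data byte
  for (el in hdr$elements) {
    if (el$name == "vertex") break
    has_list <- any(vapply(el$props, `[[`, TRUE, "list"))
    if (!has_list) {
      rowsize <- sum(vapply(el$props, function(p) .ply_type_size[[p$type]], 1L))
      pos <- pos + el$count * rowsize
    } else {
      # walk variable-length rows one by one
      for (i in seq_len(el$count)) {
        for (p in el$props) {
          if (!p$list) {
            pos <- pos + .ply_type_size[[p$type]]
          } else {
            cnt <- .ply_read_column(raw, pos - 1L, p$count_type)
            pos <- pos + .ply_type_size[[p$count_type]] +
              cnt * .ply_type_size[[p$item_type]]
          }
        }
      }
    }
  }
  types <- vapply(vertex$props, `[[`, "", "type")
  sizes <- .ply_type_size[types]
  rowsize <- sum(sizes)
  need <- pos + vertex$count * rowsize - 1L
  if (need > length(raw)) {
    stop("truncated binary PLY: need ", need, " bytes, file has ",
         length(raw), " (vertex data starts at byte offset ", pos - 1L, ")",
         call. = FALSE)
  }
  within <- c(0L, cumsum(sizes))[seq_along(sizes)]
  base <- (pos - 1L) + (seq_len(vertex$count) - 1L) * rowsize
  out <- lapply(seq_along(types), function(j) {
    .ply_read_column(raw, base + within[j], types[[j]])
  })
  stats::setNames(out, names(vertex$props))
}

.ply_write_column <- function(values, type) {
  switch(type,
    float = , float32 = writeBin(as.numeric(values), raw(), size = 4L,
                                 endian = "little"),
    double = , float64 = writeBin(as.numeric(values), raw(), size = 8L,
                                  endian = "little"),
    uchar = , uint8 = , char = , int8 =
      writeBin(as.integer(values), raw(), size = 1L, endian = "little"),
    short = , int16 = , ushort = , uint16 =
      writeBin(as.integer(values), raw(), size = 2L, endian = "little"),
    int = , int32 = , uint = , uint32 =
      writeBin(as.integer(values), raw(), size = 4L, endian = "little"),
    stop("unsupported PLY property type: ", type, call. = FALSE)
  )
}

#' Write a coloured point cloud to a PLY file
#'
#' Emits a vertex-only PLY with `x`, `y`, `z` as 32-bit floats and
#' `red`, `green`, `blue` as 8-bit unsigned integers, plus any pass-through
#' properties carried by the cloud, in ASCII or binary-little-endian
#' encoding. The output is readable by [readPLY()] and standard viewers.
#'
#' @param cloud a non-empty \code{\linkS4class{ColouredPointCloud}}.
#' @param path output file path.
#' @param encoding `"ascii"` or `"binary_le"`.
#' @return Invisibly, `path`.
#' @seealso [readPLY()]
#' @export
writePLY <- function(cloud, path, encoding = c("binary_le", "ascii")) {
  stopifnot(is(cloud, "ColouredPointCloud"))
  encoding <- match.arg(encoding)
  n <- nPoints(cloud)
  extra_names <- colnames(cloud@extra)
  extra_types <- vapply(extra_names, function(nm) {
    tp <- cloud@extraTypes[[nm]]
    if (is.null(tp) || is.na(tp)) "float" else tp
  }, "")
  header <- c(
    "ply",
    paste("format",
          if (encoding == "ascii") "ascii" else "binary_little_endian",
          "1.0"),
    "comment produced by berry3d",
    paste("element vertex", n),
    "property float x", "property float y", "property float z",
    "property uchar red", "property uchar green", "property uchar blue",
    if (length(extra_names)) {
      paste("property", extra_types, extra_names)
    },
    "end_header"
  )
  cols <- c(
    list(x = cloud@coords[, 1L], y = cloud@coords[, 2L],
         z = cloud@coords[, 3L],
         red = cloud@rgb[, 1L], green = cloud@rgb[, 2L],
         blue = cloud@rgb[, 3L]),
    as.list(cloud@extra)
  )
  types <- c(rep("float", 3L), rep("uchar", 3L), extra_types)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (encoding == "ascii") {
    fmt <- lapply(seq_along(cols), function(j) {
      if (types[[j]] %in% c("float", "float32", "double", "float64")) {
        sprintf("%.9g", cols[[j]])
      } else {
        sprintf("%d", as.integer(cols[[j]]))
      }
    })
    writeLines(do.call(paste, fmt), con, sep = "\n")
  } else {
    colraw <- lapply(seq_along(cols), function(j) {
      .ply_write_column(cols[[j]], types[[j]])
    })
    sizes <- vapply(colraw, function(r) length(r) %/% n, 1L)
    rowsize <- sum(sizes)
    out <- raw(n * rowsize)
    within <- c(0L, cumsum(sizes))[seq_along(sizes)]
    base <- (seq_len(n) - 1L) * rowsize
    for (j in seq_along(colraw)) {
      idx <- as.vector(outer(seq_len(sizes[j]), base + within[j], `+`))
      out[idx] <- colraw[[j]]
    }
    writeBin(out, con)
  }
  invisible(path)
}

#' Populate the HSV colour channels of a cloud
#'
#' Converts the per-point RGB colours to HSV using the standard hexcone
#' model: hue in degrees in [0, 360), saturation and value in [0, 1].
#' Achromatic points (r = g = b) get hue 0. Note that tools built on
#' OpenCV store hue on a half-degree scale in [0, 180]; all hue thresholds
#' in this package are full degrees.
#'
#' @param cloud a \code{\linkS4class{ColouredPointCloud}}.
#' @return The cloud with its `hsv` slot populated.
#' @examples
#' cl <- newPointCloud(matrix(0, 1, 3), matrix(c(255L, 0L, 0L), 1))
#' hsvColours(rgbToHSV(cl))  # pure red: h = 0, s = 1, v = 1
#' @export
rgbToHSV <- function(cloud) {
  stopifnot(is(cloud, "ColouredPointCloud"))
  m <- grDevices::rgb2hsv(t(cloud@rgb), maxColorValue = 255)
  hsv <- cbind(h = (m[1L, ] * 360) %% 360, s = m[2L, ], v = m[3L, ])
  rownames(hsv) <- NULL
  cloud@hsv <- hsv
  cloud
}

# TRUE where hue (degrees) falls in any interval of `ranges`; an interval
# c(lo, hi) with lo > hi wraps through 0/360. Endpoints inclusive.
.hue_in_ranges <- function(h, ranges) {
  if (is.numeric(ranges)) ranges <- list(ranges)
  hit <- rep(FALSE, length(h))
  for (rg in ranges) {
    lo <- rg[1L] %% 360
    hi <- rg[2L]
    hi <- if (hi == 360) 360 else hi %% 360
    if (lo <= hi) {
      hit <- hit | (h >= lo & h <= hi)
    } else {
      hit <- hit | (h >= lo | h <= hi)
    }
  }
  hit
}
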