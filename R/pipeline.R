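.metric_cols <- c("source_id", "cv_a", "max_min_a", "cv_d", "l_w", "cir",
                  "str", "cv_c", "max_min_c", "body_height_mm",
                  "n_points_body", "flag_degenerate_axis",
                  "flag_missing_max_min_c", "unsmoothed_frac", "error",
                  "config_hash")
.schema_version <- "berry3d-metrics-v1"

#' Compute all eight uniformity metrics from a body cloud
#'
#' Runs the three metric stages on a standardised body: side-view metrics
#' (CV_A, Max_A/Min_A, CV_D) on the equatorial band, slice metrics (L/W,
#' CIR, STR) on the horizontal slice stack, and curvature metrics (CV_C,
#' Max_C/Min_C) on the moving-least-squares-smoothed surface.
#'
#' @param body a \code{\linkS4class{BodyCloud}}.
#' @param cfg a configuration from [berryConfig()].
#' @param quiet suppress stage messages.
#' @return A named list with the eight metrics plus `maxMinMissing` and
#'   `unsmoothedFrac`.
#' @export
computeMetrics <- function(body, cfg = berryConfig(), quiet = TRUE) {
  band <- equatorialBand(body, cfg$bandLowerFrac, cfg$bandUpperFrac)
  views <- projectSideViews(band, cfg$nViews)
  am <- areaMetrics(views)
  cv_d <- orientationCV(views)

  stack <- buildSlices(body, cfg$nSlices, cfg$sliceHalfwidthMm)
  sl <- largestSlice(stack)
  l_w <- bboxAspect(sl)
  cir <- circularity(sl)
  str <- straightness(stack, cfg$strLowerFrac, cfg$strUpperFrac)

  smooth <- mlsSmooth(body, radiusMm = cfg$mlsRadiusMm,
                      radiusFactor = cfg$mlsRadiusFactor, quiet = quiet)
  field <- principalCurvatures(smooth, cfg$kNeighbours)
  sstack <- buildSlices(smooth, cfg$nSlices, cfg$sliceHalfwidthMm)
  patches <- buildPatches(smooth, field, sstack, cfg$nPatches, cfg$patchK)
  cs <- curvatureSummary(patches)

  list(cv_a = am$cv_a, max_min_a = am$max_min_a, cv_d = cv_d,
       l_w = l_w, cir = cir, str = str,
       cv_c = cs$cv_c, max_min_c = cs$max_min_c,
       maxMinMissing = cs$maxMinMissing,
       unsmoothedFrac = attr(smooth, "unsmoothedFrac"))
}

.error_row <- function(source_id, code, hash) {
  row <- as.data.frame(as.list(stats::setNames(rep(NA_real_,
                                                   length(.metric_cols)),
                                               .metric_cols)))
  row$source_id <- source_id
  row$error <- code
  row$config_hash <- hash
  row[.metric_cols]
}

#' Measure one berry point cloud
#'
#' Full single-cloud pipeline: PLY input, pre-processing and all eight
#' uniformity metrics, returned as a one-row data frame matching the
#' batch CSV schema. Hard failures in any stage are caught and reported
#' as an error row (`error` column holds a stage code: `IO_PARSE`,
#' `PREPROCESS` or `METRICS`), so batch runs survive bad
#' reconstructions. The measurement path contains no random number
#' generation: identical input and configuration give identical rows.
#'
#' @param input path to a PLY file, or a
#'   \code{\linkS4class{ColouredPointCloud}}.
#' @param cfg a configuration from [berryConfig()].
#' @param quiet suppress stage messages.
#' @return A one-row data.frame with columns
#'   `source_id, cv_a, max_min_a, cv_d, l_w, cir, str, cv_c, max_min_c,
#'   body_height_mm, n_points_body, flag_degenerate_axis,
#'   flag_missing_max_min_c, unsmoothed_frac, error, config_hash`.
#' @examples
#' gen <- generateBerry(berrySpec(nPoints = 8000, seed = 1))
#' runSingle(gen$cloud, quiet = TRUE)
#' @export
runSingle <- function(input, cfg = berryConfig(), quiet = FALSE) {
  hash <- configHash(cfg)
  id <- if (is.character(input)) basename(input) else sourceId(input)
  cloud <- if (is.character(input)) {
    tryCatch(readPLY(input), error = function(e) {
      if (!quiet) message("read failed for ", input, ": ", conditionMessage(e))
      NULL
    })
  } else {
    input
  }
  if (is.null(cloud)) return(.error_row(id, "IO_PARSE", hash))

  body <- tryCatch(
    withCallingHandlers(
      preprocessCloud(cloud, cfg, quiet = quiet),
      message = function(m) if (quiet) invokeRestart("muffleMessage")),
    error = function(e) {
      if (!quiet) message("preprocess failed for ", id, ": ",
                          conditionMessage(e))
      NULL
    })
  if (is.null(body)) return(.error_row(id, "PREPROCESS", hash))

  if (is.finite(cfg$maxMetricPoints) &&
      nPoints(body) > cfg$maxMetricPoints) {
    keep <- unique(round(seq(1L, nPoints(body),
                             length.out = cfg$maxMetricPoints)))
    body <- .subset_body(body, keep)
  }

  met <- tryCatch(computeMetrics(body, cfg, quiet = quiet),
                  error = function(e) {
                    if (!quiet) message("metrics failed for ", id, ": ",
                                        conditionMessage(e))
                    NULL
                  })
  if (is.null(met)) return(.error_row(id, "METRICS", hash))

  data.frame(source_id = id, cv_a = met$cv_a, max_min_a = met$max_min_a,
             cv_d = met$cv_d, l_w = met$l_w, cir = met$cir, str = met$str,
             cv_c = met$cv_c, max_min_c = met$max_min_c,
             body_height_mm = body@bodyHeightMm,
             n_points_body = nPoints(body),
             flag_degenerate_axis = body@degenerateAxis,
             flag_missing_max_min_c = isTRUE(met$maxMinMissing),
             unsmoothed_frac = met$unsmoothedFrac,
             error = NA_character_, config_hash = hash,
             stringsAsFactors = FALSE)
}

.subset_body <- function(body, idx) {
  body@coords <- body@coords[idx, , drop = FALSE]
  body@rgb <- body@rgb[idx, , drop = FALSE]
  if (nrow(body@hsv) > 0L) body@hsv <- body@hsv[idx, , drop = FALSE]
  if (nrow(body@extra) > 0L) body@extra <- body@extra[idx, , drop = FALSE]
  body
}

#' Measure a directory of berry point clouds
#'
#' Applies [runSingle()] to every `.ply` file in `inputDir` (sorted by
#' name; the result is independent of processing order) and writes one
#' CSV row per file. A schema comment line is written above the header.
#'
#' @param inputDir directory containing `.ply` files.
#' @param cfg a configuration from [berryConfig()].
#' @param outCsv output CSV path, or `NULL` to skip writing.
#' @param quiet suppress per-file messages.
#' @return Invisibly, a list with `table` (the full data.frame),
#'   `processed` and `failed` counts.
#' @export
runBatch <- function(inputDir, cfg = berryConfig(), outCsv = NULL,
                     quiet = FALSE) {
  files <- sort(list.files(inputDir, pattern = "\\.ply$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L) {
    stop("no .ply files found in ", inputDir, call. = FALSE)
  }
  rows <- lapply(files, runSingle, cfg = cfg, quiet = quiet)
  tab <- do.call(rbind, rows)
  failed <- sum(!is.na(tab$error))
  if (!is.null(outCsv)) {
    con <- file(outCsv, "w")
    on.exit(close(con))
    writeLines(paste0("# ", .schema_version), con)
    utils::write.csv(tab, con, row.names = FALSE, na = "")
  }
  if (!quiet) {
    message(sprintf("batch: %d processed, %d failed", nrow(tab) - failed,
                    failed))
  }
  invisible(list(table = tab, processed = nrow(tab) - failed,
                 failed = failed))
}
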