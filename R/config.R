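#' Pipeline run configuration
#'
#' Collects every tunable of the measurement pipeline in one validated
#' list. All hue values are full degrees in [0, 360); an interval whose
#' lower bound exceeds its upper bound wraps through 0 (e.g. `c(330, 30)`
#' is the red band).
#'
#' @param noiseHueKeep list of hue intervals (degrees) to retain during
#'   denoising; everything else is treated as reconstruction noise.
#'   Default: the red berry band `c(330, 30)` plus the blue holder band
#'   `c(200, 260)`.
#' @param holderHueRange hue interval identifying the blue foam holder.
#' @param holderHeightMm physical holder height used for metric scaling;
#'   the reference holder is a 38 x 19 x 19 mm foam block standing on end.
#' @param minSegmentPoints minimum points for a valid berry or holder
#'   segment.
#' @param nViews number of rotational side views (with `nViews` views the
#'   rotation step is `360/nViews` degrees; the default 100 gives 3.6).
#' @param bandLowerFrac,bandUpperFrac height fractions bounding the
#'   equatorial band used for side-view metrics (middle 50% by default).
#' @param nSlices number of evenly spaced horizontal slices.
#' @param sliceHalfwidthMm slab half-thickness per slice; `NA` means
#'   body height / (2 * nSlices), so adjacent slabs tile the height.
#' @param strLowerFrac,strUpperFrac height fractions bounding the
#'   straightness window (middle 80% by default, i.e. 80 of 100 slices).
#' @param mlsRadiusFactor moving-least-squares support radius as a
#'   multiple of the mean nearest-neighbour spacing.
#' @param mlsRadiusMm absolute MLS radius override in mm (`NA` = derive
#'   from `mlsRadiusFactor`).
#' @param kNeighbours neighbourhood size for curvature estimation.
#' @param nPatches number of equatorial curvature patches.
#' @param patchK points per curvature patch (k-nearest to each seed).
#' @param maxMetricPoints cap on the number of body points used for the
#'   metric stages; larger clouds are deterministically thinned. `Inf`
#'   disables the cap.
#' @return A list of class `"BerryConfig"`.
#' @seealso [runSingle()], [configHash()], [dumpConfig()]
#' @export
berryConfig <- function(noiseHueKeep = list(c(330, 30), c(200, 260)),
                        holderHueRange = c(200, 260),
                        holderHeightMm = 38,
                        minSegmentPoints = 500,
                        nViews = 100,
                        bandLowerFrac = 0.25, bandUpperFrac = 0.75,
                        nSlices = 100,
                        sliceHalfwidthMm = NA_real_,
                        strLowerFrac = 0.10, strUpperFrac = 0.90,
                        mlsRadiusFactor = 2.5,
                        mlsRadiusMm = NA_real_,
                        kNeighbours = 30,
                        nPatches = 16,
                        patchK = 200,
                        maxMetricPoints = Inf) {
  if (is.numeric(noiseHueKeep)) noiseHueKeep <- list(noiseHueKeep)
  cfg <- list(
    noiseHueKeep = lapply(noiseHueKeep, as.numeric),
    holderHueRange = as.numeric(holderHueRange),
    holderHeightMm = as.numeric(holderHeightMm),
    minSegmentPoints = as.integer(minSegmentPoints),
    nViews = as.integer(nViews),
    bandLowerFrac = as.numeric(bandLowerFrac),
    bandUpperFrac = as.numeric(bandUpperFrac),
    nSlices = as.integer(nSlices),
    sliceHalfwidthMm = as.numeric(sliceHalfwidthMm),
    strLowerFrac = as.numeric(strLowerFrac),
    strUpperFrac = as.numeric(strUpperFrac),
    mlsRadiusFactor = as.numeric(mlsRadiusFactor),
    mlsRadiusMm = as.numeric(mlsRadiusMm),
    kNeighbours = as.integer(kNeighbours),
    nPatches = as.integer(nPatches),
    patchK = as.integer(patchK),
    maxMetricPoints = as.numeric(maxMetricPoints)
  )
  .validate_config(cfg)
  class(cfg) <- c("BerryConfig", "list")
  cfg
}

.validate_config <- function(cfg) {
  ok_interval <- function(rg) {
    length(rg) == 2L && all(is.finite(rg)) && all(rg >= 0) && all(rg <= 360)
  }
  if (!all(vapply(cfg$noiseHueKeep, ok_interval, TRUE))) {
    stop("noiseHueKeep intervals must lie within [0, 360]", call. = FALSE)
  }
  if (!ok_interval(cfg$holderHueRange)) {
    stop("holderHueRange must lie within [0, 360]", call. = FALSE)
  }
  if (cfg$holderHeightMm <= 0) stop("holderHeightMm must be > 0", call. = FALSE)
  if (cfg$nViews < 3L) stop("nViews must be >= 3", call. = FALSE)
  if (!(cfg$bandLowerFrac >= 0 && cfg$bandUpperFrac <= 1 &&
        cfg$bandLowerFrac < cfg$bandUpperFrac)) {
    stop("band fractions must satisfy 0 <= lower < upper <= 1", call. = FALSE)
  }
  if (!(cfg$strLowerFrac >= 0 && cfg$strUpperFrac <= 1 &&
        cfg$strLowerFrac < cfg$strUpperFrac)) {
    stop("straightness fractions must satisfy 0 <= lower < upper <= 1",
         call. = FALSE)
  }
  if (cfg$nSlices < 2L) stop("nSlices must be >= 2", call. = FALSE)
  if (cfg$kNeighbours < 8L) stop("kNeighbours must be >= 8", call. = FALSE)
  if (cfg$nPatches < 1L) stop("nPatches must be >= 1", call. = FALSE)
  if (cfg$patchK < 2L) stop("patchK must be >= 2", call. = FALSE)
  invisible(TRUE)
}

#' Stable hash of a run configuration
#'
#' MD5 digest of the canonical JSON serialisation of the configuration,
#' recorded in every output row for provenance.
#'
#' @param cfg a configuration from [berryConfig()].
#' @return A 32-character hex string.
#' @export
configHash <- function(cfg) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = FALSE, digits = NA,
                         na = "string")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeChar(as.character(js), tmp, eos = NULL)
  unname(tools::md5sum(tmp))
}

#' Serialise or load a configuration as YAML
#'
#' `dumpConfig` renders the full effective configuration (all defaults
#' merged) as YAML text; `readConfig` loads a YAML file and merges it over
#' the defaults, so partial files are valid.
#'
#' @param cfg a configuration from [berryConfig()].
#' @param path YAML file to read.
#' @return `dumpConfig`: YAML text, invisibly also cat()ed; `readConfig`:
#'   a `"BerryConfig"` list.
#' @export
dumpConfig <- function(cfg = berryConfig()) {
  txt <- yaml::as.yaml(unclass(cfg))
  cat(txt)
  invisible(txt)
}

#' @rdname dumpConfig
#' @export
readConfig <- function(path) {
  user <- yaml::read_yaml(path)
  known <- names(formals(berryConfig))
  unknown <- setdiff(names(user), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(berryConfig, user)
}
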