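## S4 classes for the package: images carry the tone/graylevel normalization
## contract, results of the edge and dynamic-range procedures are structured
## objects with accessors.

#' GrayImage: a bounded-tone raster image
#'
#' Container for raster images under the tone normalization contract
#' \eqn{v = g/D}: integer graylevels \eqn{g \in \{0, \dots, D-1\}} become
#' tones \eqn{v \in [0, 1 - 1/D] \subset [0, 1)}. Normalizing by the number
#' of levels `D` (not `D - 1`) keeps tones strictly below 1, the open upper
#' bound the FLIP isomorphism requires — no epsilon hacks at white. Tones are
#' stored as a matrix (grayscale) or rows x cols x channels array (color).
#'
#' @slot tones numeric matrix or 3-d array with values in \eqn{[0, 1)}.
#' @slot levels number of quantization levels D (256 for 8-bit input).
#' @slot meta character vector of provenance notes.
#' @seealso [GrayImage()], [tones()], [grayLevels()]
#' @export
setClass("GrayImage",
  representation(tones = "array", levels = "numeric", meta = "character"),
  prototype(tones = array(0, c(1L, 1L)), levels = 256, meta = character()))

setValidity("GrayImage", function(object) {
  d <- dim(object@tones)
  if (!(length(d) %in% c(2L, 3L)))
    return("'tones' must be a matrix or a rows x cols x channels array")
  if (length(d) == 3L && !(d[3L] %in% c(1L, 3L)))
    return("color images must have 1 or 3 channels")
  if (anyNA(object@tones)) return("'tones' contains NA")
  if (any(object@tones < 0) || any(object@tones >= 1))
    return("'tones' must lie in [0, 1)")
  if (length(object@levels) != 1L || object@levels < 2)
    return("'levels' must be a single value >= 2")
  TRUE
})

#' Construct a GrayImage
#'
#' @param tones numeric matrix or 3-d array of tones in \eqn{[0, 1)}, or a
#'   matrix of integer graylevels if `fromGraylevels = TRUE`.
#' @param levels number of quantization levels D (default 256).
#' @param meta optional character provenance notes.
#' @param fromGraylevels if `TRUE`, `tones` holds integer graylevels in
#'   \eqn{[0, D-1]} and is divided by `levels`.
#' @return a [GrayImage-class] object.
#' @examples
#' img <- GrayImage(matrix(75, 8, 8), fromGraylevels = TRUE)
#' range(tones(img))  # 75/256
#' @export
GrayImage <- function(tones, levels = 256, meta = character(),
                      fromGraylevels = FALSE) {
  tones <- as.array(tones)
  if (fromGraylevels) {
    if (any(tones < 0) || any(tones > levels - 1))
      stop("graylevels must lie in [0, levels - 1]", call. = FALSE)
    tones <- tones / levels
  }
  methods::new("GrayImage", tones = tones, levels = as.numeric(levels),
               meta = as.character(meta))
}

#' EdgeResult: output of a derivative edge detector
#'
#' @slot signedMap numeric matrix of signed derivative responses in
#'   \eqn{(-1, 1)} (nonnegative for the gradient magnitude).
#' @slot intensityMap `abs(signedMap)`.
#' @slot binaryMap logical matrix, `intensityMap > threshold`.
#' @slot threshold the Otsu threshold applied.
#' @slot detector detector label ("sobel", "laplacian", "linear-laplacian").
#' @slot p model order used (`NA` for the linear detector).
#' @export
setClass("EdgeResult",
  representation(signedMap = "matrix", intensityMap = "matrix",
                 binaryMap = "matrix", threshold = "numeric",
                 detector = "character", p = "numeric"))

setValidity("EdgeResult", function(object) {
  if (!identical(dim(object@signedMap), dim(object@intensityMap)) ||
      !identical(dim(object@signedMap), dim(object@binaryMap)))
    return("map dimensions disagree")
  if (max(abs(object@intensityMap - abs(object@signedMap))) > 1e-12)
    return("intensityMap must equal abs(signedMap)")
  TRUE
})

#' DynamicRangeResult: jointly optimized dynamic range
#'
#' @slot alphaOpt optimal amplification factor.
#' @slot pOpt model order achieving the maximal dynamic range.
#' @slot dr maximal dynamic range over the (alpha, p) search.
#' @slot drClassical maximal dynamic range at p = 1 (classical LIP).
#' @slot query the (vmin, vmax) tone pair optimized for.
#' @export
setClass("DynamicRangeResult",
  representation(alphaOpt = "numeric", pOpt = "numeric", dr = "numeric",
                 drClassical = "numeric", query = "numeric"))

setValidity("DynamicRangeResult", function(object) {
  if (object@dr < object@drClassical - 1e-9)
    return("joint optimum must dominate the p = 1 optimum")
  TRUE
})

#' FlipSweep: dynamic-range sweep over the graylevel plane
#'
#' Result of [drSweep()]: one row per (gmin, gmax) integer pair with the
#' per-pair optimal amplification and model order, plus aggregate statistics.
#' A pair counts as *improved* when the jointly optimal model order exceeds 1
#' and its dynamic range beats the classical (p = 1) optimum by more than the
#' relative tolerance; `fractionBeatClassical` additionally reports the
#' fraction of pairs where any order in the grid (including p < 1) beats
#' p = 1, which is the looser reading of the same question.
#'
#' @slot table data.frame with columns gmin, gmax, pOpt, alphaOpt, dr,
#'   drClassical, ratio.
#' @slot fractionImproved fraction of pairs with pOpt > 1 and ratio > 1 + tol.
#' @slot fractionBeatClassical fraction of pairs with ratio > 1 + tol for any
#'   order in the grid.
#' @slot meanIncreasePct mean of 100 (ratio - 1) over improved pairs.
#' @slot meanIncreaseAllPct mean of 100 (ratio - 1) over all pairs.
#' @slot maxIncreasePct,minIncreasePct extremes over improved pairs.
#' @slot levels,stride sweep geometry.
#' @export
setClass("FlipSweep",
  representation(table = "data.frame", fractionImproved = "numeric",
                 fractionBeatClassical = "numeric",
                 meanIncreasePct = "numeric", meanIncreaseAllPct = "numeric",
                 maxIncreasePct = "numeric", minIncreasePct = "numeric",
                 levels = "numeric", stride = "numeric"))
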