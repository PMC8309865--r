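## Generics and accessor/show methods for the package classes.

#' @describeIn GrayImage-class tone array accessor
#' @param x,object a `GrayImage`.
#' @export
setGeneric("tones", function(x) standardGeneric("tones"))

#' @rdname GrayImage-class
#' @export
setMethod("tones", "GrayImage", function(x) x@tones)

#' @describeIn GrayImage-class number of quantization levels D
#' @export
setGeneric("grayLevels", function(x) standardGeneric("grayLevels"))

#' @rdname GrayImage-class
#' @export
setMethod("grayLevels", "GrayImage", function(x) x@levels)

#' @describeIn GrayImage-class integer graylevels g = floor(v D + 0.5)
#' @export
setGeneric("graylevelMatrix", function(x) standardGeneric("graylevelMatrix"))

#' @rdname GrayImage-class
#' @export
setMethod("graylevelMatrix", "GrayImage", function(x) {
  g <- pmin(pmax(floor(x@tones * x@levels + 0.5), 0), x@levels - 1)
  storage.mode(g) <- "integer"
  g
})

#' @describeIn GrayImage-class TRUE for 3-channel images
#' @export
setGeneric("isColor", function(x) standardGeneric("isColor"))

#' @rdname GrayImage-class
#' @export
setMethod("isColor", "GrayImage", function(x) {
  length(dim(x@tones)) == 3L && dim(x@tones)[3L] == 3L
})

setMethod("show", "GrayImage", function(object) {
  d <- dim(object@tones)
  kind <- if (isColor(object)) "color" else "grayscale"
  cat(sprintf("GrayImage: %d x %d %s, D = %g levels\n", d[1L], d[2L], kind,
              object@levels))
  cat(sprintf("  tone range [%.5f, %.5f]\n", min(object@tones),
              max(object@tones)))
  if (length(object@meta)) cat("  meta:", paste(object@meta, collapse = "; "), "\n")
})

#' @describeIn EdgeResult-class signed derivative map
#' @param x,object an `EdgeResult`.
#' @export
setGeneric("signedMap", function(x) standardGeneric("signedMap"))

#' @rdname EdgeResult-class
#' @export
setMethod("signedMap", "EdgeResult", function(x) x@signedMap)

#' @describeIn EdgeResult-class edge intensity map (absolute response)
#' @export
setGeneric("intensityMap", function(x) standardGeneric("intensityMap"))

#' @rdname EdgeResult-class
#' @export
setMethod("intensityMap", "EdgeResult", function(x) x@intensityMap)

#' @describeIn EdgeResult-class binary edge map after Otsu thresholding
#' @export
setGeneric("binaryMap", function(x) standardGeneric("binaryMap"))

#' @rdname EdgeResult-class
#' @export
setMethod("binaryMap", "EdgeResult", function(x) x@binaryMap)

#' @describeIn EdgeResult-class threshold used for binarization
#' @export
setGeneric("edgeThreshold", function(x) standardGeneric("edgeThreshold"))

#' @rdname EdgeResult-class
#' @export
setMethod("edgeThreshold", "EdgeResult", function(x) x@threshold)

setMethod("show", "EdgeResult", function(object) {
  d <- dim(object@signedMap)
  cat(sprintf("EdgeResult: %s (p = %s), %d x %d\n", object@detector,
              format(object@p), d[1L], d[2L]))
  cat(sprintf("  Otsu threshold %.5f, %d edge pixels\n", object@threshold,
              sum(object@binaryMap)))
})

setMethod("show", "DynamicRangeResult", function(object) {
  cat(sprintf("DynamicRangeResult for tones [%.4f, %.4f]\n",
              object@query[1L], object@query[2L]))
  cat(sprintf("  joint optimum: DR = %.5f at alpha = %.4f, p = %g\n",
              object@dr, object@alphaOpt, object@pOpt))
  cat(sprintf("  classical (p = 1) optimum: DR = %.5f (ratio %.4f)\n",
              object@drClassical, object@dr / object@drClassical))
})

#' @describeIn FlipSweep-class per-pair sweep table
#' @param x,object a `FlipSweep`.
#' @export
setGeneric("sweepTable", function(x) standardGeneric("sweepTable"))

#' @rdname FlipSweep-class
#' @export
setMethod("sweepTable", "FlipSweep", function(x) x@table)

#' @describeIn FlipSweep-class fraction of pairs improved by an order p > 1
#' @export
setGeneric("fractionImproved", function(x) standardGeneric("fractionImproved"))

#' @rdname FlipSweep-class
#' @export
setMethod("fractionImproved", "FlipSweep", function(x) x@fractionImproved)

setMethod("show", "FlipSweep", function(object) {
  cat(sprintf("FlipSweep: D = %g, stride %g, %d (gmin, gmax) pairs\n",
              object@levels, object@stride, nrow(object@table)))
  cat(sprintf("  improved by p > 1: %.1f%% of pairs\n",
              100 * object@fractionImproved))
  cat(sprintf("  beat classical by any order: %.1f%% of pairs\n",
              100 * object@fractionBeatClassical))
  cat(sprintf("  DR increase over improved pairs: mean %.2f%%, min %.2f%%, max %.2f%%\n",
              object@meanIncreasePct, object@minIncreasePct,
              object@maxIncreasePct))
  cat(sprintf("  DR increase over all pairs: mean %.2f%%\n",
              object@meanIncreaseAllPct))
})
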