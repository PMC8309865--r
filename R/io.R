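## Raster I/O under the tone normalization contract v = g/D. PNG and TIFF,
## 8- and 16-bit, grayscale and RGB.

#' Read a raster image as a GrayImage
#'
#' Integer samples g are mapped to tones by v = g/D with D the number of
#' quantization levels (256 for 8-bit, 65536 for 16-bit), so white maps to
#' (D-1)/D, strictly below 1. RGB data are kept channelwise unless
#' `forceGray`, which takes the BT.601 luminance. An alpha channel, if
#' present, is dropped.
#'
#' @param path a PNG or TIFF file.
#' @param forceGray collapse color to luminance.
#' @return a [GrayImage-class].
#' @seealso [writeFlipImage()]
#' @export
readFlipImage <- function(path, forceGray = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    bits <- attr(raw, "info")$bit.depth
    if (is.null(bits)) bits <- 8L
    scale <- 2^bits - 1
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(raw, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
    scale <- 2^bits - 1
  } else {
    stop("unsupported format '", ext, "': expected png, tif or tiff",
         call. = FALSE)
  }
  if (!(bits %in% c(8L, 16L)))
    stop("unsupported bit depth ", bits, ": expected 8 or 16", call. = FALSE)
  D <- 2^bits
  g <- round(raw * scale)            # back to integer samples
  if (length(dim(g)) == 3L && dim(g)[3L] %in% c(2L, 4L))
    g <- g[, , seq_len(dim(g)[3L] - 1L), drop = (dim(g)[3L] == 2L)]
  if (length(dim(g)) == 3L && dim(g)[3L] == 1L) g <- g[, , 1L]
  v <- g / D
  attributes(v) <- list(dim = dim(v))   # drop reader metadata
  if (forceGray && length(dim(v)) == 3L) v <- .luminance601(v)
  GrayImage(as.array(v), levels = D, meta = paste0("read from ", basename(path)))
}

#' Write a GrayImage to PNG or TIFF
#'
#' Tones are quantized back to integers by g = floor(v D + 0.5), clipped to
#' \eqn{[0, D-1]} (clips are counted in a message); the format is chosen by
#' the file extension. Reading a written file recovers the image exactly.
#'
#' @param img a [GrayImage-class].
#' @param path output path ending in .png, .tif or .tiff.
#' @return `path`, invisibly.
#' @export
writeFlipImage <- function(img, path) {
  stopifnot(methods::is(img, "GrayImage"))
  D <- grayLevels(img)
  bits <- round(log2(D))
  if (!(bits %in% c(8L, 16L)) || 2^bits != D)
    stop("only D = 256 or D = 65536 images can be written", call. = FALSE)
  g <- floor(tones(img) * D + 0.5)
  nclip <- sum(g > D - 1 | g < 0)
  if (nclip > 0L) message(nclip, " sample(s) clipped to [0, ", D - 1, "]")
  g <- pmin(pmax(g, 0), D - 1)
  x <- g / (2^bits - 1)              # writers expect [0, 1] over D-1
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bits != 8L)
      stop("16-bit output is only supported for TIFF; use a .tif path",
           call. = FALSE)
    png::writePNG(x, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(x, path, bits.per.sample = bits)
  } else {
    stop("unsupported format '", ext, "': expected png, tif or tiff",
         call. = FALSE)
  }
  invisible(path)
}
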