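## FLIP-arithmetic neighborhood averaging and the uniform-image noise
## reduction experiments.

# reflect-pad a matrix by (rpad, cpad) on each side
.padReflect <- function(m, rpad, cpad) {
  n <- nrow(m); q <- ncol(m)
  ri <- c(rev(seq_len(rpad)), seq_len(n), n + 1L - seq_len(rpad))
  ci <- c(rev(seq_len(cpad)), seq_len(q), q + 1L - seq_len(cpad))
  m[ri, ci, drop = FALSE]
}

.checkKernel <- function(kernel) {
  kernel <- as.matrix(kernel)
  if (any(kernel < 0))
    stop("kernel weights must be nonnegative (FLIP accumulation is defined for nonnegative contributions)",
         call. = FALSE)
  if (nrow(kernel) %% 2L == 0L || ncol(kernel) %% 2L == 0L)
    stop("kernel must have odd dimensions", call. = FALSE)
  kernel
}

#' The 3 x 3 FLIP averaging kernel
#'
#' All weights 1/9 — the window used by the noise-reduction experiments.
#'
#' @return a 3 x 3 numeric matrix.
#' @export
kernelAvg3 <- function() matrix(1 / 9, 3L, 3L)

#' FLIP neighborhood convolution
#'
#' At each pixel, the window contributions \eqn{w_k \otimes_p v_k} are
#' accumulated with the FLIP addition, in row-major left-fold order (the
#' accumulation is associative, so the order only matters at float
#' precision). With [kernelAvg3()] this is exactly the FLIP averaging
#' operation. Borders are handled by reflect padding, which avoids injecting
#' saturating tones at the image edge. Because the weights of an averaging
#' kernel sum to 1, a constant image is a fixed point for every model order
#' (by distributivity, \eqn{(\sum w_k) \otimes_p v = v}).
#'
#' @param img a [GrayImage-class] (grayscale, or color processed per channel).
#' @param kernel matrix of nonnegative weights with odd dimensions.
#' @param p model order.
#' @return the filtered [GrayImage-class].
#' @examples
#' img <- constantImage(100, 16)
#' filtered <- flipConvolve(img, kernelAvg3(), p = 5)
#' all.equal(tones(filtered), tones(img))
#' @export
flipConvolve <- function(img, kernel = kernelAvg3(), p) {
  stopifnot(methods::is(img, "GrayImage"))
  kernel <- .checkKernel(kernel)
  v <- tones(img)
  if (length(dim(v)) == 3L) {
    out <- v
    for (ch in seq_len(dim(v)[3L]))
      out[, , ch] <- .flipConvolve1(v[, , ch], kernel, p)
    return(GrayImage(out, levels = grayLevels(img),
                     meta = c(img@meta, sprintf("FLIP filtered p = %g", p))))
  }
  GrayImage(.flipConvolve1(v, kernel, p), levels = grayLevels(img),
            meta = c(img@meta, sprintf("FLIP filtered p = %g", p)))
}

.flipConvolve1 <- function(v, kernel, p) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  rpad <- (kr - 1L) %/% 2L; cpad <- (kc - 1L) %/% 2L
  padded <- .padReflect(v, rpad, cpad)
  n <- nrow(v); q <- ncol(v)
  acc <- NULL
  for (i in seq_len(kr)) for (j in seq_len(kc)) {   # row-major left fold
    shifted <- padded[(i - 1L) + seq_len(n), (j - 1L) + seq_len(q), drop = FALSE]
    term <- flipMul(kernel[i, j], shifted, p)
    acc <- if (is.null(acc)) term else flipAdd(acc, term, p)
  }
  acc
}

#' Signal-to-noise ratio in decibels
#'
#' \eqn{SNR = 10 \log_{10}\big(\sum (c - \bar c)^2 / \sum (t - c)^2\big)}
#' for a clean reference `clean` and a test image `test`: signal variance
#' over residual power. Returns `Inf` when the images are identical.
#'
#' @param clean,test [GrayImage-class] objects of matching shape.
#' @return SNR in dB (`Inf` for an exact match).
#' @examples
#' tx <- smoothTexture(32, seed = 1)
#' snrDb(tx, addWagn(tx, sigma = 7, seed = 2))
#' @export
snrDb <- function(clean, test) {
  stopifnot(methods::is(clean, "GrayImage"), methods::is(test, "GrayImage"))
  vc <- tones(clean); vt <- tones(test)
  if (!identical(dim(vc), dim(vt))) stop("image shapes differ", call. = FALSE)
  resid <- sum((vt - vc)^2)
  if (resid == 0) return(Inf)
  10 * log10(sum((vc - mean(vc))^2) / resid)
}

#' Uniform-image noise reduction experiment
#'
#' For each (sigma, p): a constant image is degraded by WAGN, filtered with
#' the 3 x 3 FLIP average, and the standard deviation of the residual
#' (filtered minus constant, in graylevel units) is measured, together with
#' its ratio to the classical-LIP (p = 1) residual computed on the *same*
#' noisy image. Deterministic for a fixed seed.
#'
#' @param level graylevel of the uniform image.
#' @param sigmaList WAGN standard deviations in graylevel units.
#' @param pList model orders (1 is added if missing).
#' @param size image side length (default 128).
#' @param seed integer seed.
#' @param levels number of quantization levels D.
#' @return data.frame with columns `level`, `sigma`, `p`, `residualStd`
#'   (graylevel units) and `reductionRatio` (residual std over the p = 1
#'   residual std).
#' @examples
#' noiseReductionExperiment(75, sigmaList = c(5, 15), pList = c(1, 5),
#'                          size = 32, seed = 1)
#' @export
noiseReductionExperiment <- function(level, sigmaList, pList,
                                     size = 128L, seed = 1, levels = 256) {
  if (!any(pList == 1)) pList <- c(1, pList)
  base <- constantImage(level, size, levels = levels)
  rows <- list()
  for (si in seq_along(sigmaList)) {
    sigma <- sigmaList[si]
    noisy <- addWagn(base, sigma, seed = seed + si - 1L)
    stds <- vapply(pList, function(p) {
      filt <- flipConvolve(noisy, kernelAvg3(), p)
      stats::sd(tones(filt) - tones(base)) * levels
    }, numeric(1L))
    ref <- stds[pList == 1][1L]
    rows[[si]] <- data.frame(level = level, sigma = sigma, p = pList,
                             residualStd = stds,
                             reductionRatio = stds / ref)
  }
  do.call(rbind, rows)
}

#' Texture SNR improvement experiment
#'
#' The natural-image analogue of the uniform-image experiment: a smooth
#' random texture is degraded by WAGN and filtered by the FLIP average at
#' several model orders; reported is \eqn{SNR_p - SNR_{p=1}} in dB, so
#' positive values mean the order beats the classical LIP.
#'
#' @param sigma WAGN standard deviation in graylevel units (default 7).
#' @param pList model orders to compare against p = 1.
#' @param size image side length.
#' @param blurSigma texture smoothness (pixels).
#' @param seed integer seed.
#' @param levels number of quantization levels D.
#' @return data.frame with columns `sigma`, `p`, `snrDb`, `snrImprovementDb`.
#' @examples
#' textureSnrExperiment(pList = c(1, 5, 10), size = 32, seed = 1)
#' @export
textureSnrExperiment <- function(sigma = 7, pList = c(1, 2, 5, 10),
                                 size = 128L, blurSigma = 3, seed = 1,
                                 levels = 256) {
  if (!any(pList == 1)) pList <- c(1, pList)
  clean <- smoothTexture(size, blurSigma = blurSigma, seed = seed,
                         levels = levels)
  noisy <- addWagn(clean, sigma, seed = seed + 1L)
  snrs <- vapply(pList, function(p)
    snrDb(clean, flipConvolve(noisy, kernelAvg3(), p)), numeric(1L))
  data.frame(sigma = sigma, p = pList, snrDb = snrs,
             snrImprovementDb = snrs - snrs[pList == 1][1L])
}
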