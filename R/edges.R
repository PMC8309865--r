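## FLIP and linear derivative edge detectors, Otsu binarization and the
## localization / false-positive evaluation harness.

# the 8 shifted copies of a padded image, addressed by row/col offsets
.shift <- function(padded, di, dj, n, q) {
  padded[(1L + di) + seq_len(n), (1L + dj) + seq_len(q), drop = FALSE]
}

.edgeResult <- function(signed, detector, p) {
  intensity <- abs(signed)
  thr <- otsuThreshold(intensity)
  methods::new("EdgeResult", signedMap = signed, intensityMap = intensity,
               binaryMap = intensity > thr, threshold = thr,
               detector = detector, p = as.numeric(p))
}

.imageTones <- function(img, minSide = 3L) {
  stopifnot(methods::is(img, "GrayImage"))
  v <- tones(img)
  if (length(dim(v)) == 3L) v <- .luminance601(v)
  if (nrow(v) < minSide || ncol(v) < minSide)
    stop("image must be at least ", minSide, " x ", minSide, call. = FALSE)
  v
}

#' FLIP Sobel gradient detector
#'
#' The Sobel first-derivative filter written entirely in FLIP arithmetic.
#' Each directional response accumulates the three neighbors of one side
#' with the FLIP addition (the center neighbor entering twice, realizing the
#' Sobel weight 2) and subtracts the opposite side with the signed FLIP
#' subtraction. The two directional magnitudes are combined into one edge
#' intensity by FLIP accumulation, \eqn{|H| \oplus_p |V|} (option
#' `"euclidean"` uses \eqn{\sqrt{H^2 + V^2}} instead). The intensity map is
#' Otsu-thresholded into a binary edge map.
#'
#' @param img a [GrayImage-class], at least 3 x 3 (color: BT.601 luminance).
#' @param p model order.
#' @param combine how to merge the two directional magnitudes.
#' @return an [EdgeResult-class].
#' @examples
#' se <- stepEdgeImage(78, 178, size = 16)
#' flipSobel(se$image, p = 5)
#' @export
flipSobel <- function(img, p, combine = c("flip", "euclidean")) {
  combine <- match.arg(combine)
  v <- .imageTones(img)
  n <- nrow(v); q <- ncol(v)
  padded <- .padReflect(v, 1L, 1L)
  s <- function(di, dj) .shift(padded, di, dj, n, q)
  side <- function(a, b, cc) flipAdd(flipAdd(flipAdd(a, b, p), cc, p), cc, p)
  h <- flipSubSigned(side(s(-1, -1), s(1, -1), s(0, -1)),
                     side(s(-1, 1), s(1, 1), s(0, 1)), p)
  vv <- flipSubSigned(side(s(-1, -1), s(-1, 1), s(-1, 0)),
                      side(s(1, -1), s(1, 1), s(1, 0)), p)
  signed <- if (combine == "flip") flipAdd(abs(h), abs(vv), p)
            else pmin(sqrt(h^2 + vv^2), 1 - .TONE_EPS)
  .edgeResult(signed, "sobel", p)
}

#' Linear N4 Laplacian detector
#'
#' The classical second-derivative operator
#' \eqn{4 f(i,j) - \sum_{N_4} f}, computed as the sum of the four
#' center-minus-neighbor differences in ordinary arithmetic. Response is
#' exactly zero on constant images and on linear ramps (interior).
#'
#' @param img a [GrayImage-class], at least 3 x 3.
#' @return an [EdgeResult-class] (`p` is `NA`).
#' @export
linearLaplacian <- function(img) {
  v <- .imageTones(img)
  n <- nrow(v); q <- ncol(v)
  padded <- .padReflect(v, 1L, 1L)
  s <- function(di, dj) .shift(padded, di, dj, n, q)
  signed <- (v - s(-1, 0)) + (v - s(1, 0)) + (v - s(0, -1)) + (v - s(0, 1))
  .edgeResult(signed, "linear-laplacian", NA_real_)
}

#' FLIP N4 Laplacian detector
#'
#' The four center-minus-neighbor differences are taken with the signed FLIP
#' subtraction and accumulated with the signed FLIP addition (odd extension
#' of the isomorphism), in left-fold order. At p = 2 this coincides with the
#' native homomorphic arithmetic on \eqn{(-1, 1)}.
#'
#' @param img a [GrayImage-class], at least 3 x 3.
#' @param p model order.
#' @return an [EdgeResult-class].
#' @export
flipLaplacian <- function(img, p) {
  v <- .imageTones(img)
  n <- nrow(v); q <- ncol(v)
  padded <- .padReflect(v, 1L, 1L)
  s <- function(di, dj) .shift(padded, di, dj, n, q)
  d <- function(nb) flipSubSigned(v, nb, p)
  signed <- flipAddSigned(
    flipAddSigned(flipAddSigned(d(s(-1, 0)), d(s(1, 0)), p), d(s(0, -1)), p),
    d(s(0, 1)), p)
  .edgeResult(signed, "laplacian", p)
}

# linear Sobel baseline used by the edge experiment
.linearSobel <- function(img) {
  v <- .imageTones(img)
  n <- nrow(v); q <- ncol(v)
  padded <- .padReflect(v, 1L, 1L)
  s <- function(di, dj) .shift(padded, di, dj, n, q)
  h <- (s(-1, -1) + 2 * s(0, -1) + s(1, -1)) -
       (s(-1, 1) + 2 * s(0, 1) + s(1, 1))
  vv <- (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1)) -
        (s(1, -1) + 2 * s(1, 0) + s(1, 1))
  .edgeResult(abs(h) + abs(vv), "linear-sobel", NA_real_)
}

#' Otsu threshold of an intensity map
#'
#' Histogram-based threshold maximizing the between-class variance over a
#' 256-bin histogram of the map values. A constant map returns that constant
#' (so the downstream `>`-binarization is empty).
#'
#' @param x numeric matrix or vector of intensities.
#' @param nbins number of histogram bins (default 256).
#' @return the threshold value (on the scale of `x`).
#' @examples
#' otsuThreshold(c(rep(0.2, 30), rep(0.8, 10)))
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  x <- as.vector(x)
  if (!length(x)) stop("empty intensity map", call. = FALSE)
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(lo)
  breaks <- seq(lo, hi, length.out = nbins + 1L)
  idx <- pmin(pmax(floor((x - lo) / (hi - lo) * nbins) + 1L, 1L), nbins)
  counts <- tabulate(idx, nbins)
  centers <- (breaks[-1L] + breaks[-(nbins + 1L)]) / 2
  w <- cumsum(counts)                     # class-0 mass up to bin k
  m <- cumsum(counts * centers)           # class-0 first moment
  total <- w[nbins]; mTotal <- m[nbins]
  k <- seq_len(nbins - 1L)
  w0 <- w[k]; w1 <- total - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins - 1L)
  bcv[valid] <- (mTotal * w0[valid] / total - m[k][valid])^2 /
    (w0[valid] * w1[valid] / total)
  best <- which.max(bcv)
  breaks[best + 1L]                       # upper edge of the class-0 side
}

# minimal Euclidean distance from each TRUE pixel of `fromMask` to the TRUE
# pixels of `toMask`; Inf when `toMask` is empty
.minDistances <- function(fromMask, toMask) {
  pts <- which(fromMask, arr.ind = TRUE)
  ref <- which(toMask, arr.ind = TRUE)
  if (!nrow(pts)) return(numeric(0L))
  if (!nrow(ref)) return(rep(Inf, nrow(pts)))
  d2 <- outer(pts[, 1L], ref[, 1L], "-")^2 + outer(pts[, 2L], ref[, 2L], "-")^2
  sqrt(apply(d2, 1L, min))
}

#' Pratt figure of merit for edge localization
#'
#' \deqn{FOM = \frac{1}{\max(DE, IE)} \sum_{i=1}^{DE}
#'       \frac{1}{1 + \alpha\, d_i^{\,q}}}
#' where \eqn{DE} and \eqn{IE} count detected and ideal edge pixels and
#' \eqn{d_i} is the Euclidean distance of detected pixel *i* to the nearest
#' ideal pixel. Defaults \eqn{\alpha = 1/9}, \eqn{q = 2} give the canonical
#' Pratt measure; `distanceExponent = 1` selects the plain-distance variant.
#' Equals 1 exactly iff the detection matches the ideal mask. An empty
#' detection returns 0 (with a message).
#'
#' @param detected,ideal logical matrices of the same shape.
#' @param fomAlpha distance scaling constant (default 1/9).
#' @param distanceExponent exponent on \eqn{d_i} (default 2).
#' @return FOM in \eqn{[0, 1]}.
#' @examples
#' m <- matrix(FALSE, 10, 10); m[, 5] <- TRUE
#' shifted <- matrix(FALSE, 10, 10); shifted[, 6] <- TRUE
#' prattFom(shifted, m)  # 0.9
#' @export
prattFom <- function(detected, ideal, fomAlpha = 1 / 9, distanceExponent = 2) {
  if (!identical(dim(detected), dim(ideal)))
    stop("mask shapes differ", call. = FALSE)
  if (fomAlpha <= 0) stop("'fomAlpha' must be positive", call. = FALSE)
  de <- sum(detected); ie <- sum(ideal)
  if (ie == 0) stop("ideal edge mask is empty", call. = FALSE)
  if (de == 0) {
    message("empty detection: FOM = 0 by convention")
    return(0)
  }
  d <- .minDistances(detected, ideal)
  sum(1 / (1 + fomAlpha * d^distanceExponent)) / max(de, ie)
}

#' False-positive edge ratio
#'
#' Fraction of *image* pixels that are detected as edge but lie farther than
#' `matchRadius` from any ideal edge pixel. The denominator is the total
#' pixel count, so the ratio is comparable across detectors with different
#' edge densities.
#'
#' @param detected,ideal logical matrices of the same shape.
#' @param matchRadius matching radius in pixels (default `sqrt(2)`,
#'   8-neighborhood adjacency).
#' @return ratio in \eqn{[0, 1]}.
#' @export
falsePositiveRatio <- function(detected, ideal, matchRadius = sqrt(2)) {
  if (!identical(dim(detected), dim(ideal)))
    stop("mask shapes differ", call. = FALSE)
  if (!sum(detected)) return(0)
  d <- .minDistances(detected, ideal)
  sum(d > matchRadius) / length(detected)
}

#' Step-edge detection experiment
#'
#' For every (sigma, p): a step-edge image with the configured graylevel
#' contrast is degraded by WAGN, run through the chosen FLIP detector and
#' Otsu binarization, and scored by Pratt FOM and false-positive ratio. The
#' linear implementation of the same derivative is scored alongside as a
#' baseline. Deterministic for a fixed seed.
#'
#' @param levelLo,levelHi graylevels across the edge (defaults 78 and 178,
#'   i.e. a contrast of 100 of 256).
#' @param sigmaList WAGN standard deviations in graylevel units.
#' @param pList model orders.
#' @param detector `"sobel"` or `"laplacian"`.
#' @param size image side length (default 64).
#' @param seed integer seed.
#' @param levels number of quantization levels D.
#' @param fomAlpha,distanceExponent,matchRadius evaluation constants, see
#'   [prattFom()] and [falsePositiveRatio()].
#' @return data.frame with columns `sigma`, `p` (`NA` for the linear
#'   baseline), `detector`, `fom`, `fpRatio`.
#' @examples
#' edgeExperiment(sigmaList = c(0, 10), pList = c(1, 10), size = 32, seed = 1)
#' @export
edgeExperiment <- function(levelLo = 78, levelHi = 178, sigmaList,
                           pList, detector = c("sobel", "laplacian"),
                           size = 64L, seed = 1, levels = 256,
                           fomAlpha = 1 / 9, distanceExponent = 2,
                           matchRadius = sqrt(2)) {
  detector <- match.arg(detector)
  se <- stepEdgeImage(levelLo, levelHi, "vertical", size, levels = levels)
  rows <- list()
  for (si in seq_along(sigmaList)) {
    sigma <- sigmaList[si]
    noisy <- addWagn(se$image, sigma, seed = seed + si - 1L)
    score <- function(res, p, label) {
      data.frame(sigma = sigma, p = p, detector = label,
                 fom = prattFom(binaryMap(res), se$mask, fomAlpha,
                                distanceExponent),
                 fpRatio = falsePositiveRatio(binaryMap(res), se$mask,
                                              matchRadius))
    }
    flipRes <- lapply(pList, function(p) {
      res <- if (detector == "sobel") flipSobel(noisy, p)
             else flipLaplacian(noisy, p)
      score(res, p, detector)
    })
    linRes <- if (detector == "sobel") .linearSobel(noisy)
              else linearLaplacian(noisy)
    rows[[si]] <- rbind(do.call(rbind, flipRes),
                        score(linRes, NA_real_, linRes@detector))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Laplacian noise propagation experiment
#'
#' Constant images are degraded by WAGN and run through the linear and FLIP
#' Laplacians; the standard deviation of the signed output map (rescaled to
#' graylevel units) measures how much noise each operator lets through. For
#' the linear stencil the closed form is \eqn{\sigma_{out} = \sigma
#' \sqrt{20}} (variance of \eqn{4c - \sum_{N_4}} on iid noise).
#'
#' @param levelList constant graylevels (defaults 75 and 150).
#' @param sigmaList input WAGN standard deviations, graylevel units.
#' @param pList model orders for the FLIP Laplacian.
#' @param size image side length (default 128).
#' @param seed integer seed.
#' @param levels number of quantization levels D.
#' @return data.frame with columns `level`, `sigma`, `p` (`NA` = linear),
#'   `detector`, `stdOut` (graylevel units).
#' @examples
#' laplacianNoiseExperiment(75, sigmaList = c(5, 10), pList = 5,
#'                          size = 32, seed = 1)
#' @export
laplacianNoiseExperiment <- function(levelList = c(75, 150), sigmaList,
                                     pList, size = 128L, seed = 1,
                                     levels = 256) {
  rows <- list(); k <- 0L
  for (level in levelList) {
    base <- constantImage(level, size, levels = levels)
    for (si in seq_along(sigmaList)) {
      sigma <- sigmaList[si]
      noisy <- addWagn(base, sigma, seed = seed + si - 1L + 1000L * level)
      outStd <- function(res) stats::sd(signedMap(res)) * levels
      k <- k + 1L
      rows[[k]] <- data.frame(level = level, sigma = sigma, p = NA_real_,
                              detector = "linear-laplacian",
                              stdOut = outStd(linearLaplacian(noisy)))
      for (p in pList) {
        k <- k + 1L
        rows[[k]] <- data.frame(level = level, sigma = sigma, p = p,
                                detector = "laplacian",
                                stdOut = outStd(flipLaplacian(noisy, p)))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
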