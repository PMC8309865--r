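## Seeded generators for every synthetic input the experiments use:
## constant images, white additive Gaussian noise, step edges, underexposed
## low-range images and smooth random textures (the natural-image stand-in).

# run `expr` under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Constant (fully uniform) image
#'
#' @param level integer graylevel in \eqn{[0, D-1]}.
#' @param size image size, `c(rows, cols)` or a single side length.
#' @param levels number of quantization levels D (default 256).
#' @return a [GrayImage-class] with all tones equal to `level/levels`.
#' @examples
#' constantImage(75, 32)
#' @export
constantImage <- function(level, size, levels = 256) {
  if (length(size) == 1L) size <- c(size, size)
  if (level < 0 || level > levels - 1)
    stop("'level' must lie in [0, levels - 1]", call. = FALSE)
  GrayImage(matrix(level / levels, size[1L], size[2L]), levels = levels,
            meta = sprintf("constant level %g", level))
}

#' Degrade an image with white additive Gaussian noise (WAGN)
#'
#' Zero-mean Gaussian noise with standard deviation `sigma` *in graylevel
#' units* is added to the graylevel representation, clipped to
#' \eqn{[0, D-1]} and renormalized to tones. Bit-identical output for a
#' fixed seed; the caller's RNG state is left untouched.
#'
#' @param img a [GrayImage-class].
#' @param sigma noise standard deviation in graylevel units.
#' @param seed integer seed (`NULL` to use the current RNG stream).
#' @param clip clip noisy graylevels into \eqn{[0, D-1]} (default `TRUE`).
#' @return a noisy [GrayImage-class]; the number of clipped samples is noted
#'   in `meta` when clipping occurred.
#' @examples
#' noisy <- addWagn(constantImage(128, 64), sigma = 7, seed = 1)
#' @export
addWagn <- function(img, sigma, seed = NULL, clip = TRUE) {
  stopifnot(methods::is(img, "GrayImage"), sigma >= 0)
  if (sigma == 0) return(img)
  D <- grayLevels(img)
  g <- tones(img) * D
  noise <- .withSeed(seed, stats::rnorm(length(g), mean = 0, sd = sigma))
  g <- g + noise
  nclip <- 0L
  if (clip) {
    nclip <- sum(g < 0 | g > D - 1)
    g <- pmin(pmax(g, 0), D - 1)
  }
  meta <- c(img@meta, sprintf("WAGN sigma = %g", sigma),
            if (nclip > 0L) sprintf("%d sample(s) clipped", nclip))
  out <- g / D
  dim(out) <- dim(tones(img))
  GrayImage(out, levels = D, meta = meta)
}

#' Step-edge test image with its ideal edge mask
#'
#' A half-plane image: graylevel `lo` on one side, `hi` on the other, split
#' at the central column (vertical edge) or row (horizontal). The ideal edge
#' mask marks the first line of the brighter half — the convention is
#' immaterial for evaluation as long as detector and mask share it.
#'
#' @param lo,hi graylevels of the two halves, `lo < hi`.
#' @param orientation `"vertical"` (edge along a column) or `"horizontal"`.
#' @param size image size, `c(rows, cols)` or a single side length.
#' @param levels number of quantization levels D.
#' @return list with elements `image` ([GrayImage-class]) and `mask`
#'   (logical matrix, one pixel thick).
#' @examples
#' se <- stepEdgeImage(78, 178, size = 32)
#' sum(se$mask)  # 32
#' @export
stepEdgeImage <- function(lo, hi, orientation = c("vertical", "horizontal"),
                          size = c(64L, 64L), levels = 256) {
  orientation <- match.arg(orientation)
  if (length(size) == 1L) size <- c(size, size)
  if (lo >= hi) stop("'lo' must be smaller than 'hi'", call. = FALSE)
  nr <- size[1L]; nc <- size[2L]
  g <- matrix(lo, nr, nc)
  mask <- matrix(FALSE, nr, nc)
  if (orientation == "vertical") {
    split <- nc %/% 2L
    g[, (split + 1L):nc] <- hi
    mask[, split + 1L] <- TRUE
  } else {
    split <- nr %/% 2L
    g[(split + 1L):nr, ] <- hi
    mask[split + 1L, ] <- TRUE
  }
  list(image = GrayImage(g / levels, levels = levels,
                         meta = sprintf("step edge %g/%g %s", lo, hi, orientation)),
       mask = mask)
}

# separable Gaussian blur with reflect padding (plain linear arithmetic;
# only used to build synthetic textures)
.gaussBlur <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur1 <- function(m) {
    n <- nrow(m)
    idx <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
    padded <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * padded[(i - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(blur1(t(blur1(x))))
}

#' Underexposed low-range test image
#'
#' A smooth random texture squeezed into the dark tone band
#' \eqn{[1/D, } `vmaxTarget`\eqn{]} — the synthetic stand-in for a poorly
#' illuminated photograph used in the enhancement demonstrations.
#'
#' @param vmaxTarget maximal tone of the output (e.g. 0.35).
#' @param size image size, `c(rows, cols)` or a single side length.
#' @param seed integer seed.
#' @param levels number of quantization levels D.
#' @return a [GrayImage-class] with tones in \eqn{[1/D, } `vmaxTarget`\eqn{]}.
#' @examples
#' u <- underexposedImage(0.35, 64, seed = 1)
#' max(tones(u)) <= 0.35
#' @export
underexposedImage <- function(vmaxTarget, size = c(64L, 64L), seed = 1,
                              levels = 256) {
  if (vmaxTarget <= 1 / levels || vmaxTarget >= 1)
    stop("'vmaxTarget' must lie in (1/levels, 1)", call. = FALSE)
  smoothTexture(size = size, blurSigma = 3,
                range = c(1 / levels, vmaxTarget), seed = seed,
                levels = levels)
}

#' Smooth random texture
#'
#' Gaussian-blurred white noise rescaled into a tone range: a seeded,
#' self-contained emulation of the smooth intensity structure of natural
#' images, used wherever the experiments need non-uniform content.
#'
#' @param size image size, `c(rows, cols)` or a single side length.
#' @param blurSigma Gaussian blur standard deviation in pixels (default 3).
#' @param range tone range `c(lo, hi)` of the output (default `c(0.1, 0.9)`).
#' @param seed integer seed.
#' @param levels number of quantization levels D.
#' @return a [GrayImage-class] with tones spanning exactly `range`.
#' @examples
#' tx <- smoothTexture(64, seed = 3)
#' range(tones(tx))
#' @export
smoothTexture <- function(size = c(64L, 64L), blurSigma = 3,
                          range = c(0.1, 0.9), seed = 1, levels = 256) {
  if (length(size) == 1L) size <- c(size, size)
  if (range[1L] < 0 || range[2L] >= 1 || range[1L] >= range[2L])
    stop("'range' must satisfy 0 <= lo < hi < 1", call. = FALSE)
  w <- .withSeed(seed, matrix(stats::rnorm(prod(size)), size[1L], size[2L]))
  s <- .gaussBlur(w, blurSigma)
  s <- (s - min(s)) / (max(s) - min(s))          # [0, 1]
  v <- range[1L] + s * (range[2L] - range[1L])   # spans range exactly
  GrayImage(v, levels = levels,
            meta = sprintf("smooth texture blur %g seed %g", blurSigma, seed))
}
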