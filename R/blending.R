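## Weighted FLIP compositing of two images.

#' Blend two images with FLIP arithmetic
#'
#' Weighted compositing inside the bounded tone range:
#' \eqn{J = (w_1 \otimes_p I_1) \oplus_p (w_2 \otimes_p I_2)}, applied
#' elementwise and, for color images, per channel. The result can never
#' leave \eqn{[0, 1)} — no clipping is required for any weights. With
#' identical inputs and weights summing to 1 the blend is the identity
#' (distributivity).
#'
#' @param i1,i2 [GrayImage-class] objects of matching shape and levels.
#' @param w1,w2 nonnegative weights (default 0.5 each).
#' @param p model order.
#' @return the blended [GrayImage-class].
#' @examples
#' a <- smoothTexture(16, seed = 1)
#' b <- smoothTexture(16, seed = 2)
#' flipBlend(a, b, p = 10)
#' @export
flipBlend <- function(i1, i2, w1 = 0.5, w2 = 0.5, p) {
  stopifnot(methods::is(i1, "GrayImage"), methods::is(i2, "GrayImage"))
  if (!identical(dim(tones(i1)), dim(tones(i2))))
    stop("image shapes differ", call. = FALSE)
  if (w1 < 0 || w2 < 0) stop("weights must be nonnegative", call. = FALSE)
  out <- flipAdd(flipMul(w1, tones(i1), p), flipMul(w2, tones(i2), p), p)
  GrayImage(out, levels = grayLevels(i1),
            meta = sprintf("FLIP blend w1 = %g, w2 = %g, p = %g", w1, w2, p))
}
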