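## Core FLIP algebra: the Hamacher-generated parametric graylevel arithmetic.
## Tones live in [0,1); the model order p >= 0 selects one member of the family.

# tones this close to 1 are clamped before generator evaluation (saturation guard)
.TONE_EPS <- 1e-12

.checkP <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0)
    stop("model order 'p' must be a single nonnegative number", call. = FALSE)
  as.numeric(p)
}

.checkTone <- function(v, name = "v", lower = 0) {
  if (!is.numeric(v)) stop("'", name, "' must be numeric", call. = FALSE)
  if (anyNA(v)) stop("'", name, "' contains NA", call. = FALSE)
  if (any(v < lower) || any(v >= 1))
    stop("'", name, "' must lie in [", lower, ", 1)", call. = FALSE)
  v
}

# clamp tones into [0, 1 - .TONE_EPS]; emits one message per call batch if any
# value was clamped (the saturation guard documented in the vignette)
.clampTone <- function(v, quiet = TRUE) {
  hi <- 1 - .TONE_EPS
  n <- sum(v > hi)
  if (n > 0L) {
    if (!quiet) message(n, " tone(s) clamped to 1 - 1e-12 before generator evaluation")
    v <- pmin(v, hi)
  }
  v
}

# preserve array shape of the dominant operand after arithmetic on vectors
.reshapeLike <- function(res, ...) {
  for (a in list(...)) {
    if (!is.null(dim(a))) { dim(res) <- dim(a); return(res) }
  }
  res
}

#' Hamacher parametric additive generator
#'
#' The decreasing generator \eqn{f_{H,p}} of the Hamacher T-conorm family:
#' \eqn{f_{H,p}(x) = (1-x)/x} for \eqn{p = 0} and
#' \eqn{f_{H,p}(x) = \log((p + (1-p)x)/x)} for \eqn{p > 0}, with
#' \eqn{f_{H,p}(1) = 0}. This generator induces the whole FLIP arithmetic.
#'
#' @param x numeric vector in (0, 1].
#' @param p model order, a single nonnegative number.
#' @param saturate if `TRUE`, `x = 0` returns `Inf` instead of erroring.
#' @return nonnegative numeric vector, same shape as `x`.
#' @seealso [hamacherGeneratorInv()], [flipIso()]
#' @examples
#' hamacherGenerator(0.5, p = 1)  # log(2)
#' @export
hamacherGenerator <- function(x, p, saturate = FALSE) {
  p <- .checkP(p)
  if (!is.numeric(x) || anyNA(x)) stop("'x' must be numeric without NA", call. = FALSE)
  if (any(x > 1) || any(x < 0)) stop("'x' must lie in (0, 1]", call. = FALSE)
  if (any(x == 0) && !saturate)
    stop("'x' = 0 maps to +Inf; call with saturate = TRUE to allow it", call. = FALSE)
  res <- if (p == 0) (1 - x) / x else log((p + (1 - p) * x) / x)
  .reshapeLike(res, x)
}

#' Inverse of the Hamacher generator
#'
#' @param y nonnegative numeric vector.
#' @param p model order, a single nonnegative number.
#' @return numeric vector in (0, 1]; exact round-trip with
#'   [hamacherGenerator()] up to floating-point tolerance.
#' @examples
#' hamacherGeneratorInv(log(2), p = 1)  # 0.5
#' @export
hamacherGeneratorInv <- function(y, p) {
  p <- .checkP(p)
  if (!is.numeric(y) || anyNA(y)) stop("'y' must be numeric without NA", call. = FALSE)
  if (any(y < 0)) stop("'y' must be nonnegative", call. = FALSE)
  res <- if (p == 0) 1 / (y + 1) else {
    # p / (e^y - (1-p)), computed through e^{-y} so large y cannot overflow
    E <- exp(-y)
    p * E / (1 - (1 - p) * E)
  }
  .reshapeLike(res, y)
}

#' Fundamental isomorphism of the FLIP family
#'
#' Maps a tone to the real half-line where FLIP operations become ordinary
#' arithmetic: \eqn{T(v) = f_{H,p}(1-v)}, i.e. \eqn{v/(1-v)} for \eqn{p = 0}
#' and \eqn{\log((1-(1-p)v)/(1-v))} for \eqn{p > 0}. `flipIsoInv()` is its
#' inverse. At p = 0, 1, 2 these are the pseudo-LIP, classical-LIP and
#' homomorphic-LIP isomorphisms respectively.
#'
#' @param v tones in \eqn{[0, 1)}.
#' @param y nonnegative reals.
#' @param p model order.
#' @return `flipIso`: nonnegative reals; `flipIsoInv`: tones in \eqn{[0, 1)}.
#' @examples
#' flipIso(0.5, p = 1)  # log(2)
#' flipIso(0.5, p = 2)  # log(3)
#' @export
flipIso <- function(v, p) {
  p <- .checkP(p)
  v <- .clampTone(.checkTone(v))
  res <- if (p == 0) v / (1 - v) else log((1 - (1 - p) * v) / (1 - v))
  .reshapeLike(res, v)
}

#' @rdname flipIso
#' @export
flipIsoInv <- function(y, p) {
  p <- .checkP(p)
  if (any(y < 0)) stop("'y' must be nonnegative", call. = FALSE)
  res <- if (p == 0) y / (1 + y) else {
    E <- exp(-y)
    (1 - E) / (1 - (1 - p) * E)
  }
  res <- pmin(res, 1 - .TONE_EPS)
  .reshapeLike(res, y)
}

# odd extension of the isomorphism, used for signed tone arithmetic
.isoSigned <- function(v, p) sign(v) * flipIso(abs(v), p)
.isoSignedInv <- function(y, p) sign(y) * flipIsoInv(abs(y), p)

#' FLIP graylevel addition
#'
#' Generalized addition of two fuzzified graylevels: the Hamacher T-conorm of
#' the tones, \eqn{v_1 \oplus_p v_2 = 1 - (1-v_1)(1-v_2)/(1-(1-p)v_1v_2)}.
#' Commutative, associative, has neutral element 0 and never leaves
#' \eqn{[0, 1)}. Operands broadcast by the usual recycling rules; array shape
#' is preserved.
#'
#' @param v1,v2 tones in \eqn{[0, 1)} (scalars or arrays of matching shape).
#' @param p model order (0 = pseudo-LIP, 1 = classical LIP, 2 = homomorphic).
#' @return tones in \eqn{[0, 1)}.
#' @examples
#' flipAdd(0.5, 0.5, p = 1)  # 0.75, the classical-LIP sum
#' flipAdd(0.5, 0.5, p = 0)  # 2/3, the pseudo-LIP sum
#' @export
flipAdd <- function(v1, v2, p) {
  p <- .checkP(p)
  v1 <- .checkTone(v1, "v1"); v2 <- .checkTone(v2, "v2")
  # one closed form covers p = 0 as the continuous limit of the p > 0 branch
  res <- 1 - (1 - v1) * (1 - v2) / (1 - (1 - p) * v1 * v2)
  res <- pmin(pmax(res, 0), 1 - .TONE_EPS)
  .reshapeLike(res, v1, v2)
}

#' FLIP scalar multiplication (amplification)
#'
#' The \eqn{\alpha}-fold FLIP accumulation of a tone with itself, extended to
#' all real \eqn{\alpha \ge 0} through the isomorphism:
#' \eqn{\alpha \otimes_p v = T^{-1}(\alpha\, T(v))}. For integer \eqn{\alpha}
#' it equals repeated [flipAdd()]; \eqn{1 \otimes_p v = v} and
#' \eqn{0 \otimes_p v = 0}.
#'
#' @param alpha nonnegative amplification factor (scalar or array).
#' @param v tones in \eqn{[0, 1)}.
#' @param p model order.
#' @return tones in \eqn{[0, 1)}.
#' @examples
#' flipMul(2, 0.5, p = 1)   # 0.75 = 1 - (1 - 0.5)^2
#' flipMul(3, 0.2, p = 0)   # 3/7
#' @export
flipMul <- function(alpha, v, p) {
  p <- .checkP(p)
  if (any(alpha < 0)) stop("'alpha' must be nonnegative", call. = FALSE)
  v <- .clampTone(.checkTone(v))
  res <- if (p == 0) {
    alpha * v / (1 - v + alpha * v)
  } else {
    # closed form (Q^alpha - 1)/(Q^alpha - (1-p)), Q = (1-(1-p)v)/(1-v),
    # evaluated through E = Q^{-alpha} = exp(-alpha T(v)) for overflow safety
    E <- exp(-alpha * log((1 - (1 - p) * v) / (1 - v)))
    (1 - E) / (1 - (1 - p) * E)
  }
  res <- pmin(pmax(res, 0), 1 - .TONE_EPS)
  .reshapeLike(res, v, alpha)
}

#' FLIP graylevel subtraction
#'
#' The exact inverse of [flipAdd()] under the constraint \eqn{v_1 \ge v_2}:
#' \eqn{v_1 \ominus_p v_2 = (v_1-v_2)/(1+(1-p)v_1v_2+(p-2)v_2)}. Differences
#' of arbitrary sign are handled by [flipSubSigned()].
#'
#' @param v1,v2 tones in \eqn{[0, 1)} with `v1 >= v2` elementwise.
#' @param p model order.
#' @return tones in \eqn{[0, 1)}; `flipSub(flipAdd(a, b, p), b, p)`
#'   recovers `a`.
#' @examples
#' flipSub(0.75, 0.5, p = 1)  # 0.5
#' @export
flipSub <- function(v1, v2, p) {
  p <- .checkP(p)
  v1 <- .checkTone(v1, "v1"); v2 <- .checkTone(v2, "v2")
  if (any(v1 - v2 < -1e-15))
    stop("flipSub requires v1 >= v2 elementwise; use flipSubSigned for signed differences",
         call. = FALSE)
  # denominator grouped as (1 - v2) + (p - 1) v2 (1 - v1): algebraically
  # equal to 1 + (1-p) v1 v2 + (p-2) v2 but free of cancellation near white
  res <- (v1 - v2) / ((1 - v2) + (p - 1) * v2 * (1 - v1))
  res <- pmin(pmax(res, 0), 1 - .TONE_EPS)
  .reshapeLike(res, v1, v2)
}

#' Signed FLIP subtraction
#'
#' Extends [flipSub()] to any operand order:
#' `flipSub(v1, v2, p)` when `v1 >= v2`, otherwise `-flipSub(v2, v1, p)`.
#' Antisymmetric; the natural difference for derivative filters.
#'
#' @inheritParams flipSub
#' @return signed values in \eqn{(-1, 1)}.
#' @examples
#' flipSubSigned(0.5, 0.75, p = 1)  # -0.5
#' @export
flipSubSigned <- function(v1, v2, p) {
  p <- .checkP(p)
  v1 <- .checkTone(v1, "v1"); v2 <- .checkTone(v2, "v2")
  d <- v1 - v2
  lo <- pmin(v1, v2); hi <- pmax(v1, v2)
  mag <- (hi - lo) / ((1 - lo) + (p - 1) * lo * (1 - hi))
  res <- sign(d) * pmin(pmax(mag, 0), 1 - .TONE_EPS)
  .reshapeLike(res, v1, v2)
}

#' Signed FLIP addition
#'
#' Addition on signed tones in \eqn{(-1, 1)} through the odd extension of the
#' fundamental isomorphism, \eqn{\tilde T(-v) = -\tilde T(v)}:
#' \eqn{a \oplus_p b = \tilde T^{-1}(\tilde T(a) + \tilde T(b))}. On
#' nonnegative operands it reduces to [flipAdd()]; at \eqn{p = 2} it is the
#' native homomorphic addition \eqn{(a+b)/(1+ab)} on \eqn{(-1, 1)}. Needed to
#' chain signed differences in the FLIP derivative operators.
#'
#' @param a,b signed tones in \eqn{(-1, 1)}.
#' @param p model order.
#' @return signed tones in \eqn{(-1, 1)}.
#' @examples
#' flipAddSigned(0.5, -0.5, p = 3)  # 0
#' flipAddSigned(0.5, 0.5, p = 2)   # 0.8
#' @export
flipAddSigned <- function(a, b, p) {
  p <- .checkP(p)
  if (any(abs(a) >= 1) || any(abs(b) >= 1))
    stop("signed tones must lie in (-1, 1)", call. = FALSE)
  res <- .isoSignedInv(.isoSigned(a, p) + .isoSigned(b, p), p)
  .reshapeLike(res, a, b)
}
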