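## Independent implementations of the three classical logarithmic models and
## the generic generator-composition construction. These serve as oracles for
## the special-case claims (model order p = 0, 1, 2) and are deliberately
## written from their own native formulas, not through the FLIP code paths.
##
## Operand-order convention (fixed here for all three models): the first
## operand minus the second, requiring first >= second. The original
## homomorphic and pseudo-LIP write-ups label the operands the other way
## around; only the labels differ, the formulas are the same.

.checkD <- function(D) {
  if (!is.numeric(D) || length(D) != 1L || D <= 0)
    stop("'D' must be a single positive number", call. = FALSE)
  D
}

.checkRange <- function(v, D, name = "v") {
  if (any(v < 0) || any(v >= D))
    stop("'", name, "' must lie in [0, ", D, ")", call. = FALSE)
  v
}

#' Classical LIP arithmetic on \[0, D)
#'
#' The classical logarithmic image processing model on gray tones in
#' \eqn{[0, D)}: `lipAdd` is \eqn{v_1 + v_2 - v_1 v_2 / D}, `lipSub` is
#' \eqn{D(v_1 - v_2)/(D - v_2)} (first minus second, first \eqn{\ge} second),
#' `lipMul` is \eqn{D(1 - (1 - v/D)^\lambda)} and `lipIsomorphism` is
#' \eqn{-D \log(1 - v/D)}. With `D = 1` these coincide with the FLIP
#' operations at model order `p = 1`.
#'
#' @param v1,v2,v gray tones in \eqn{[0, D)}.
#' @param lambda nonnegative real scalar multiplier.
#' @param D upper bound of the gray tone range (default 1).
#' @return gray tones in \eqn{[0, D)} (`lipIsomorphism`: nonnegative reals).
#' @examples
#' lipAdd(128, 128, D = 256)  # 192
#' lipMul(2, 0.5)             # 0.75
#' @export
lipAdd <- function(v1, v2, D = 1) {
  D <- .checkD(D); .checkRange(v1, D, "v1"); .checkRange(v2, D, "v2")
  v1 + v2 - v1 * v2 / D
}

#' @rdname lipAdd
#' @export
lipSub <- function(v1, v2, D = 1) {
  D <- .checkD(D); .checkRange(v1, D, "v1"); .checkRange(v2, D, "v2")
  if (any(v1 - v2 < -1e-15 * D)) stop("lipSub requires v1 >= v2", call. = FALSE)
  D * (v1 - v2) / (D - v2)
}

#' @rdname lipAdd
#' @export
lipMul <- function(lambda, v, D = 1) {
  D <- .checkD(D); .checkRange(v, D)
  if (any(lambda < 0)) stop("'lambda' must be nonnegative", call. = FALSE)
  D * (1 - (1 - v / D)^lambda)
}

#' @rdname lipAdd
#' @export
lipIsomorphism <- function(v, D = 1) {
  D <- .checkD(D); .checkRange(v, D)
  -D * log(1 - v / D)
}

#' Pseudo-LIP arithmetic on \[0, 1)
#'
#' The pseudo-logarithmic model, whose isomorphism \eqn{T(v) = v/(1-v)}
#' merely resembles a logarithm: addition \eqn{(v_1+v_2-2v_1v_2)/(1-v_1v_2)},
#' subtraction \eqn{(v_1-v_2)/(1+v_1v_2-2v_2)} (first \eqn{\ge} second),
#' multiplication \eqn{\lambda v/(1+(\lambda-1)v)}. Coincides with FLIP at
#' model order `p = 0`.
#'
#' @param v1,v2,v tones in \eqn{[0, 1)}.
#' @param lambda nonnegative real scalar.
#' @return tones in \eqn{[0, 1)} (`pseudoLipIsomorphism`: nonnegative reals).
#' @examples
#' pseudoLipAdd(0.5, 0.5)  # 2/3
#' pseudoLipMul(3, 0.2)    # 3/7
#' @export
pseudoLipAdd <- function(v1, v2) {
  .checkRange(v1, 1, "v1"); .checkRange(v2, 1, "v2")
  (v1 + v2 - 2 * v1 * v2) / (1 - v1 * v2)
}

#' @rdname pseudoLipAdd
#' @export
pseudoLipSub <- function(v1, v2) {
  .checkRange(v1, 1, "v1"); .checkRange(v2, 1, "v2")
  if (any(v1 - v2 < -1e-15)) stop("pseudoLipSub requires v1 >= v2", call. = FALSE)
  (v1 - v2) / (1 + v1 * v2 - 2 * v2)
}

#' @rdname pseudoLipAdd
#' @export
pseudoLipMul <- function(lambda, v) {
  .checkRange(v, 1)
  if (any(lambda < 0)) stop("'lambda' must be nonnegative", call. = FALSE)
  lambda * v / (1 + (lambda - 1) * v)
}

#' @rdname pseudoLipAdd
#' @export
pseudoLipIsomorphism <- function(v) {
  .checkRange(v, 1)
  v / (1 - v)
}

#' Homomorphic LIP arithmetic on (-1, 1)
#'
#' The symmetric-range logarithmic model on \eqn{(-1, 1)}: addition
#' \eqn{(v_1+v_2)/(1+v_1v_2)}, subtraction \eqn{(v_1-v_2)/(1-v_1v_2)},
#' multiplication \eqn{((1+v)^\lambda-(1-v)^\lambda)/((1+v)^\lambda+(1-v)^\lambda)},
#' isomorphism \eqn{\log((1+v)/(1-v))}. On nonnegative tones it coincides
#' with FLIP at model order `p = 2`; on all of \eqn{(-1, 1)} with the odd
#' signed extension.
#'
#' @param v1,v2,v values in \eqn{(-1, 1)}.
#' @param lambda real scalar.
#' @return values in \eqn{(-1, 1)} (`homomorphicIsomorphism`: reals).
#' @examples
#' homomorphicAdd(0.5, 0.5)  # 0.8
#' homomorphicMul(2, 0.5)    # 0.8
#' @export
homomorphicAdd <- function(v1, v2) {
  .checkSym(v1, "v1"); .checkSym(v2, "v2")
  (v1 + v2) / (1 + v1 * v2)
}

#' @rdname homomorphicAdd
#' @export
homomorphicSub <- function(v1, v2) {
  .checkSym(v1, "v1"); .checkSym(v2, "v2")
  (v1 - v2) / (1 - v1 * v2)
}

#' @rdname homomorphicAdd
#' @export
homomorphicMul <- function(lambda, v) {
  .checkSym(v)
  a <- (1 + v)^lambda; b <- (1 - v)^lambda
  (a - b) / (a + b)
}

#' @rdname homomorphicAdd
#' @export
homomorphicIsomorphism <- function(v) {
  .checkSym(v)
  log((1 + v) / (1 - v))
}

.checkSym <- function(v, name = "v") {
  if (any(abs(v) >= 1)) stop("'", name, "' must lie in (-1, 1)", call. = FALSE)
  v
}

#' T-conorm from an additive generator
#'
#' Generic brute-force construction of a T-conorm from a decreasing additive
#' generator `f` with \eqn{f(1) = 0}:
#' \eqn{S(a, b) = 1 - f^{-1}(f(1-a) + f(1-b))}. Used as the independent
#' oracle for [flipAdd()] (with the Hamacher generator) and for any other
#' generator the caller supplies. The generator is spot-checked for
#' monotonicity on a small sample of points.
#'
#' @param f generator function, decreasing on (0, 1] with `f(1) = 0`.
#' @param fInv its inverse on \eqn{[0, \infty)}.
#' @param a,b fuzzy values in \eqn{[0, 1]}.
#' @return fuzzy values in \eqn{[0, 1]}.
#' @examples
#' f <- function(x) hamacherGenerator(x, p = 1)
#' fi <- function(y) hamacherGeneratorInv(y, p = 1)
#' conormFromGenerator(f, fi, 0.5, 0.5)  # 0.75
#' @export
conormFromGenerator <- function(f, fInv, a, b) {
  if (any(a < 0 | a > 1) || any(b < 0 | b > 1))
    stop("operands must lie in [0, 1]", call. = FALSE)
  probe <- f(c(0.999, 0.5, 0.1, 0.01))
  if (any(diff(probe) <= 0) || abs(f(1)) > 1e-12)
    stop("'f' is not a valid additive generator (must decrease, f(1) = 0)",
         call. = FALSE)
  # clamp the saturating operand away from 1 so f stays finite
  x1 <- pmax(1 - a, .TONE_EPS)
  x2 <- pmax(1 - b, .TONE_EPS)
  res <- 1 - fInv(f(x1) + f(x2))
  .reshapeLike(res, a, b)
}
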