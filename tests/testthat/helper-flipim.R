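# shared fixtures for the suite: operand grids, model-order sets and the
# generator-composition oracles used to cross-check the closed forms

toneGrid <- function(n = 99) seq(0.01, 0.99, length.out = n)

pSet <- c(0, 0.5, 1, 2, 5, 10, 100)

# addition through the raw conorm construction (independent of flipAdd)
oracleAdd <- function(v1, v2, p) {
  conormFromGenerator(function(x) hamacherGenerator(x, p),
                      function(y) hamacherGeneratorInv(y, p), v1, v2)
}

# alpha-fold accumulation through the generator (independent of flipMul)
oracleMul <- function(alpha, v, p) {
  1 - hamacherGeneratorInv(alpha * hamacherGenerator(1 - v, p), p)
}

# subtraction analogue of the conorm construction,
# 1 - f^{-1}(f(1-v1) - f(1-v2)), requiring v1 >= v2 so f's argument stays >= 0
oracleSub <- function(v1, v2, p) {
  1 - hamacherGeneratorInv(hamacherGenerator(1 - v1, p) -
                             hamacherGenerator(1 - v2, p), p)
}

expect_all_close <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}
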