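# core FLIP algebra: generator, isomorphism, the four operations and their
# algebraic structure

test_that("Hamacher generator and inverse match hand values and round-trip", {
  expect_equal(hamacherGenerator(1, p = 0.7), 0)
  expect_equal(hamacherGenerator(0.5, p = 0), 1)
  expect_equal(hamacherGenerator(0.5, p = 1), log(2))
  expect_equal(hamacherGeneratorInv(0, p = 3), 1)
  expect_equal(hamacherGeneratorInv(1, p = 0), 0.5)
  expect_equal(hamacherGeneratorInv(log(2), p = 1), 0.5)
  for (p in pSet) {
    x <- seq(0.01, 1, length.out = 50)
    expect_all_close(hamacherGeneratorInv(hamacherGenerator(x, p), p), x, 1e-10)
    expect_true(all(diff(hamacherGenerator(x, p)) < 0))  # strictly decreasing
  }
  expect_error(hamacherGenerator(0, p = 1), "saturate")
  expect_identical(hamacherGenerator(0, p = 1, saturate = TRUE), Inf)
  expect_error(hamacherGenerator(1.2, p = 1), "0, 1")
  expect_error(hamacherGeneratorInv(-1, p = 1), "nonnegative")
  expect_error(hamacherGenerator(0.5, p = -1), "nonnegative")
})

test_that("fundamental isomorphism matches the three classical special cases", {
  expect_equal(flipIso(0.5, p = 0), 1)
  expect_equal(flipIso(0.5, p = 1), log(2))
  expect_equal(flipIso(0.5, p = 2), log(3))
  v <- toneGrid(40)
  for (p in pSet) {
    expect_all_close(flipIsoInv(flipIso(v, p), p), v, 1e-10)
    expect_true(all(diff(flipIso(v, p)) > 0))
    expect_equal(flipIso(0, p), 0)
  }
  # unbounded as v -> 1
  expect_gt(flipIso(1 - 1e-9, p = 1), 20)
  expect_error(flipIso(1, p = 1), "\\[0, 1\\)")
  expect_error(flipIso(-0.1, p = 1), "\\[0, 1\\)")
})

test_that("operation examples: frozen values for the three special orders", {
  expect_equal(flipAdd(0.3, 0, p = 5), 0.3)          # neutral element
  expect_equal(flipAdd(0.5, 0.5, p = 1), 0.75)
  expect_equal(flipAdd(0.5, 0.5, p = 0), 2 / 3)
  expect_equal(flipAdd(0.5, 0.5, p = 2), 0.8)
  expect_equal(flipMul(1, 0.42, p = 7), 0.42)        # 1 is multiplicative unit
  expect_equal(flipMul(0, 0.42, p = 7), 0)
  expect_equal(flipMul(2, 0.5, p = 1), 0.75)
  expect_equal(flipMul(3, 0.2, p = 0), 3 / 7)
  expect_equal(flipSub(0.4, 0.4, p = 3), 0)
  expect_equal(flipSub(0.75, 0.5, p = 1), 0.5)
  expect_equal(flipSub(0.8, 0.5, p = 2), 0.5)
  expect_equal(flipSubSigned(0.5, 0.75, p = 1), -0.5)
  expect_equal(flipSubSigned(0.75, 0.5, p = 1), 0.5)
  expect_equal(flipSubSigned(0.3, 0.3, p = 9), 0)
  expect_equal(flipAddSigned(0.5, -0.5, p = 4), 0)
  expect_equal(flipAddSigned(0.5, 0.5, p = 2), 0.8, tolerance = 1e-10)
  expect_equal(flipAddSigned(-0.5, -0.5, p = 2), -0.8, tolerance = 1e-10)
})

test_that("domain errors fire for out-of-range operands", {
  expect_error(flipAdd(1, 0.5, p = 1))
  expect_error(flipAdd(0.5, -0.2, p = 1))
  expect_error(flipMul(-1, 0.5, p = 1), "nonnegative")
  expect_error(flipSub(0.4, 0.6, p = 1), "flipSubSigned")
  expect_error(flipAddSigned(1.2, 0, p = 1), "\\(-1, 1\\)")
})

test_that("closed forms agree with the generator-composition oracles", {
  v <- toneGrid(25)
  g <- expand.grid(v1 = v, v2 = v)
  for (p in pSet) {
    expect_all_close(flipAdd(g$v1, g$v2, p), oracleAdd(g$v1, g$v2, p), 1e-10)
    hi <- pmax(g$v1, g$v2); lo <- pmin(g$v1, g$v2)
    expect_all_close(flipSub(hi, lo, p), oracleSub(hi, lo, p), 1e-10)
    for (alpha in c(0.5, 1, 2, 3.7)) {
      expect_all_close(flipMul(alpha, v, p), oracleMul(alpha, v, p), 1e-10)
    }
  }
})

test_that("special orders reduce to the classical models elementwise", {
  v <- toneGrid(30)
  g <- expand.grid(v1 = v, v2 = v)
  hi <- pmax(g$v1, g$v2); lo <- pmin(g$v1, g$v2)
  # p = 0: pseudo-LIP
  expect_all_close(flipAdd(g$v1, g$v2, 0), pseudoLipAdd(g$v1, g$v2), 1e-12)
  expect_all_close(flipSub(hi, lo, 0), pseudoLipSub(hi, lo), 1e-12)
  expect_all_close(flipMul(2.5, v, 0), pseudoLipMul(2.5, v), 1e-12)
  # p = 1: classical LIP with D = 1
  expect_all_close(flipAdd(g$v1, g$v2, 1), lipAdd(g$v1, g$v2, D = 1), 1e-12)
  expect_all_close(flipSub(hi, lo, 1), lipSub(hi, lo, D = 1), 1e-12)
  expect_all_close(flipMul(2.5, v, 1), lipMul(2.5, v, D = 1), 1e-12)
  expect_all_close(flipIso(v, 1), lipIsomorphism(v, D = 1), 1e-12)
  # p = 2: homomorphic model on nonnegative operands
  expect_all_close(flipAdd(g$v1, g$v2, 2), homomorphicAdd(g$v1, g$v2), 1e-12)
  expect_all_close(flipSub(hi, lo, 2), homomorphicSub(hi, lo), 1e-12)
  expect_all_close(flipMul(2.5, v, 2), homomorphicMul(2.5, v), 1e-12)
  expect_all_close(flipIso(v, 2), homomorphicIsomorphism(v), 1e-12)
  expect_all_close(flipIso(v, 0), pseudoLipIsomorphism(v), 1e-12)
})

test_that("algebraic laws hold across random operands and orders", {
  set.seed(42)
  for (rep in 1:60) {
    p <- sample(c(0, runif(1, 0, 3), runif(1, 0, 100)), 1)
    a <- runif(1, 0, 0.98); b <- runif(1, 0, 0.98); cc <- runif(1, 0, 0.98)
    al <- runif(1, 0, 4); be <- runif(1, 0, 4)
    expect_equal(flipAdd(a, b, p), flipAdd(b, a, p), tolerance = 1e-10)
    expect_equal(flipAdd(flipAdd(a, b, p), cc, p),
                 flipAdd(a, flipAdd(b, cc, p), p), tolerance = 1e-9)
    # distributivity of scalar accumulation over FLIP addition
    expect_equal(flipMul(al + be, a, p),
                 flipAdd(flipMul(al, a, p), flipMul(be, a, p), p),
                 tolerance = 1e-9)
    # multiplicative composition
    expect_equal(flipMul(al, flipMul(be, a, p), p), flipMul(al * be, a, p),
                 tolerance = 1e-9)
    # subtraction inverts addition
    expect_equal(flipSub(flipAdd(a, b, p), b, p), a, tolerance = 1e-9)
  }
})

test_that("integer amplification equals repeated FLIP addition", {
  v <- c(0.05, 0.3, 0.7)
  for (p in pSet) {
    expect_all_close(flipMul(2, v, p), flipAdd(v, v, p), 1e-12)
    expect_all_close(flipMul(3, v, p), flipAdd(flipAdd(v, v, p), v, p), 1e-10)
  }
})

test_that("addition is nondecreasing and subtraction nonincreasing in the order", {
  ps <- c(0, 0.25, 0.5, 1, 2, 5, 10, 25, 50, 100)
  for (v1 in c(0.15, 0.5, 0.85)) for (v2 in c(0.1, 0.45, 0.8)) {
    sums <- vapply(ps, function(p) flipAdd(v1, v2, p), numeric(1))
    expect_true(all(diff(sums) >= -1e-12))
    hi <- max(v1, v2); lo <- min(v1, v2)
    difs <- vapply(ps, function(p) flipSub(hi, lo, p), numeric(1))
    expect_true(all(diff(difs) <= 1e-12))
  }
})

test_that("the p > 0 branch is continuous at p -> 0+", {
  v <- toneGrid(30)
  g <- expand.grid(v1 = v, v2 = v)
  expect_all_close(flipAdd(g$v1, g$v2, 1e-8), flipAdd(g$v1, g$v2, 0), 1e-6)
  expect_all_close(flipMul(2.3, v, 1e-8), flipMul(2.3, v, 0), 1e-6)
  expect_all_close(flipSub(pmax(g$v1, g$v2), pmin(g$v1, g$v2), 1e-8),
                   flipSub(pmax(g$v1, g$v2), pmin(g$v1, g$v2), 0), 1e-6)
})

test_that("operations never reach 1 on non-saturating inputs", {
  v <- c(0.2, 0.9, 0.999, 1 - 1e-9)
  g <- expand.grid(v1 = v, v2 = v)
  for (p in pSet) {
    expect_true(all(flipAdd(g$v1, g$v2, p) < 1))
    expect_true(all(flipMul(30, v, p) < 1))
    expect_true(all(flipSub(pmax(g$v1, g$v2), pmin(g$v1, g$v2), p) < 1))
    expect_true(all(abs(flipAddSigned(g$v1, g$v2, p)) < 1))
  }
})

test_that("signed addition is the odd extension and reduces to flipAdd", {
  a <- seq(-0.9, 0.9, by = 0.15); g <- expand.grid(a = a, b = a)
  for (p in c(0, 1, 2, 5)) {
    expect_all_close(flipAddSigned(g$a, g$b, p),
                     -flipAddSigned(-g$a, -g$b, p), 1e-12)
  }
  pos <- expand.grid(a = seq(0.05, 0.9, by = 0.1), b = seq(0.05, 0.9, by = 0.1))
  for (p in pSet)
    expect_all_close(flipAddSigned(pos$a, pos$b, p),
                     flipAdd(pos$a, pos$b, p), 1e-10)
  # p = 2 coincides with native homomorphic addition on all of (-1, 1)
  expect_all_close(flipAddSigned(g$a, g$b, 2), homomorphicAdd(g$a, g$b), 1e-10)
})

test_that("array shapes are preserved and operands broadcast", {
  m <- matrix(seq(0.1, 0.9, length.out = 12), 3, 4)
  expect_identical(dim(flipAdd(m, m, 5)), dim(m))
  expect_identical(dim(flipAdd(m, 0.2, 5)), dim(m))
  expect_identical(dim(flipMul(2, m, 5)), dim(m))
  expect_identical(dim(flipSubSigned(m, 0.5, 5)), dim(m))
  expect_equal(flipAdd(m, 0.2, 5)[2, 3], flipAdd(m[2, 3], 0.2, 5))
})
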