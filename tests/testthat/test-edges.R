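# derivative edge detectors, Otsu binarization and the evaluation measures

test_that("all detectors return exactly zero maps on constant images", {
  img <- constantImage(120, 12)
  for (p in pSet) {
    expect_all_close(signedMap(flipSobel(img, p)), 0, 1e-12)
    expect_all_close(signedMap(flipLaplacian(img, p)), 0, 1e-12)
  }
  expect_all_close(signedMap(linearLaplacian(img)), 0, 1e-12)
  expect_equal(sum(binaryMap(flipSobel(img, 1))), 0)
})

test_that("a vertical step is localized on its two adjacent columns", {
  se <- stepEdgeImage(78, 178, "vertical", size = 20)
  for (p in c(0, 1, 10)) {
    res <- flipSobel(se$image, p)
    m <- intensityMap(res)
    peaks <- unique(which(m == max(m), arr.ind = TRUE)[, 2])
    expect_setequal(peaks, c(10, 11))
    # interior away from the step is flat
    expect_all_close(m[, c(3:8, 13:18)], 0, 1e-12)
  }
})

test_that("FLIP chains at p = 1 equal the classical-LIP operator chains", {
  noisy <- addWagn(smoothTexture(10, seed = 20), 12, seed = 21)
  v <- tones(noisy)
  pad <- rbind(v[1, ], v, v[10, ]); pad <- cbind(pad[, 1], pad, pad[, 10])
  at <- function(di, dj) pad[2:11 + di, 2:11 + dj]
  # Sobel horizontal bracket per side: a (+) b (+) c (+) c in LIP(D = 1)
  side <- function(a, b, cc)
    lipAdd(lipAdd(lipAdd(a, b, D = 1), cc, D = 1), cc, D = 1)
  signedLip <- function(x, y) {
    hi <- pmax(x, y); lo <- pmin(x, y)
    sign(x - y) * lipSub(hi, lo, D = 1)
  }
  hRef <- signedLip(side(at(-1, -1), at(1, -1), at(0, -1)),
                    side(at(-1, 1), at(1, 1), at(0, 1)))
  vRef <- signedLip(side(at(-1, -1), at(-1, 1), at(-1, 0)),
                    side(at(1, -1), at(1, 1), at(1, 0)))
  sobelRef <- lipAdd(abs(hRef), abs(vRef), D = 1)
  expect_all_close(intensityMap(flipSobel(noisy, 1)), sobelRef, 1e-10)
})

test_that("FLIP Laplacian at p = 2 equals native homomorphic arithmetic", {
  noisy <- addWagn(smoothTexture(10, seed = 22), 12, seed = 23)
  v <- tones(noisy)
  pad <- rbind(v[1, ], v, v[10, ]); pad <- cbind(pad[, 1], pad, pad[, 10])
  at <- function(di, dj) pad[2:11 + di, 2:11 + dj]
  d <- function(nb) homomorphicSub(v, nb)
  ref <- homomorphicAdd(homomorphicAdd(homomorphicAdd(
    d(at(-1, 0)), d(at(1, 0))), d(at(0, -1))), d(at(0, 1)))
  expect_all_close(signedMap(flipLaplacian(noisy, 2)), ref, 1e-10)
})

test_that("linear Laplacian: impulse response 4v, zero on ramps", {
  g <- matrix(0, 9, 9); g[5, 5] <- 0.4
  res <- linearLaplacian(GrayImage(g))
  expect_equal(signedMap(res)[5, 5], 1.6)
  ramp <- GrayImage(matrix(rep(seq(0.1, 0.9, length.out = 9), each = 9), 9, 9))
  expect_all_close(signedMap(linearLaplacian(ramp))[2:8, 2:8], 0, 1e-12)
})

test_that("FLIP Laplacian responds wherever the linear one does", {
  noisy <- addWagn(smoothTexture(12, seed = 24), 15, seed = 25)
  lin <- abs(signedMap(linearLaplacian(noisy)))
  for (p in c(0, 1, 5)) {
    fl <- abs(signedMap(flipLaplacian(noisy, p)))
    expect_true(all(fl[lin > 1e-9] > 0))
  }
})

test_that("Otsu threshold separates a two-valued map and matches brute force", {
  x <- c(rep(0.2, 40), rep(0.8, 25))
  thr <- otsuThreshold(x)
  expect_gt(thr, 0.2); expect_lte(thr, 0.8)
  expect_equal(otsuThreshold(rep(0.31, 10)), 0.31)
  # exhaustive 256-candidate search straight from the definition
  bruteOtsu <- function(x, nbins = 256) {
    breaks <- seq(min(x), max(x), length.out = nbins + 1)
    cand <- breaks[2:nbins]
    bcv <- vapply(cand, function(t) {
      lo <- x[x <= t]; hi <- x[x > t]
      if (!length(lo) || !length(hi)) return(-Inf)
      # between-class variance with bin-center means, as in the histogram form
      length(lo) * length(hi) / length(x)^2 * (mean(lo) - mean(hi))^2
    }, numeric(1))
    cand[which.max(bcv)]
  }
  set.seed(77)
  for (i in 1:5) {
    y <- c(rnorm(200, 0.2, 0.03), rnorm(80, 0.7, 0.05))
    y <- pmin(pmax(y, 0), 0.99)
    expect_equal(otsuThreshold(y), bruteOtsu(y), tolerance = 0.05)
  }
})

test_that("Pratt FOM: perfect, shifted and cluttered detections", {
  ideal <- matrix(FALSE, 10, 10); ideal[, 5] <- TRUE
  expect_equal(prattFom(ideal, ideal), 1)
  shifted <- matrix(FALSE, 10, 10); shifted[, 6] <- TRUE
  expect_equal(prattFom(shifted, ideal), 0.9)   # 10 pixels all at distance 1
  # the printed-text variant with q = 1 is selectable
  expect_equal(prattFom(shifted, ideal, fomAlpha = 1 / 9, distanceExponent = 1),
               0.9)
  # an extra isolated false detection lowers the score through max(DE, IE)
  clutter <- ideal; clutter[1, 1] <- TRUE
  expect_lt(prattFom(clutter, ideal), 1)
  expect_message(out <- prattFom(matrix(FALSE, 10, 10), ideal), "empty")
  expect_equal(out, 0)
  expect_error(prattFom(ideal, matrix(FALSE, 10, 10)), "empty")
})

test_that("Pratt FOM agrees with a brute-force nearest-pixel scan", {
  set.seed(55)
  for (i in 1:5) {
    det <- matrix(runif(32 * 32) < 0.1, 32, 32)
    ideal <- matrix(FALSE, 32, 32); ideal[, sample(32, 1)] <- TRUE
    brute <- 0
    pts <- which(det, arr.ind = TRUE)
    ref <- which(ideal, arr.ind = TRUE)
    if (nrow(pts)) {
      for (k in seq_len(nrow(pts))) {
        d2 <- min((pts[k, 1] - ref[, 1])^2 + (pts[k, 2] - ref[, 2])^2)
        brute <- brute + 1 / (1 + d2 / 9)
      }
      brute <- brute / max(nrow(pts), nrow(ref))
      expect_equal(prattFom(det, ideal), brute, tolerance = 1e-12)
    }
  }
})

test_that("false-positive ratio matches an exhaustive distance check", {
  ideal <- matrix(FALSE, 16, 16); ideal[, 8] <- TRUE
  expect_equal(falsePositiveRatio(ideal, ideal), 0)
  expect_equal(falsePositiveRatio(matrix(FALSE, 16, 16), ideal), 0)
  all16 <- matrix(TRUE, 16, 16)
  # pixels farther than sqrt(2) from column 8, counted by hand
  far <- sum(abs(col(all16) - 8) > sqrt(2))
  expect_equal(falsePositiveRatio(all16, ideal), far / 256)
})

test_that("edge experiment: clean steps score near 1, tables are seeded", {
  res <- edgeExperiment(sigmaList = c(0, 15), pList = c(1, 10),
                        detector = "sobel", size = 32, seed = 1)
  expect_identical(res, edgeExperiment(sigmaList = c(0, 15), pList = c(1, 10),
                                       detector = "sobel", size = 32, seed = 1))
  clean <- res[res$sigma == 0, ]
  expect_true(all(clean$fom >= 0.9))
  expect_true(all(res$fpRatio >= 0 & res$fpRatio <= 1))
  expect_true(any(res$detector == "linear-sobel"))
  lap <- edgeExperiment(sigmaList = 0, pList = 1, detector = "laplacian",
                        size = 32, seed = 1)
  expect_true(all(lap$fom >= 0.9))
})

test_that("Laplacian noise propagation: zero in, linear law out", {
  quiet <- laplacianNoiseExperiment(75, sigmaList = 0, pList = c(1, 5),
                                    size = 32, seed = 1)
  expect_true(all(quiet$stdOut == 0))
  res <- laplacianNoiseExperiment(128, sigmaList = c(2, 6, 10, 14), pList = 5,
                                  size = 128, seed = 2)
  lin <- res[res$detector == "linear-laplacian", ]
  slope <- coef(lm(stdOut ~ 0 + sigma, data = lin))[[1]]
  expect_lt(abs(slope - sqrt(20)) / sqrt(20), 0.05)
})
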