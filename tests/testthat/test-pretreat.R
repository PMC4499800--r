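test_that("SNV standardizes each row to mean 0, SD 1 (n-1 denominator)", {
  expect_equal(as.numeric(snv(matrix(1:5, 1))),
               c(-1.2649, -0.6325, 0, 0.6325, 1.2649), tolerance = 1e-4)
  # idempotence on already standardized rows
  z <- snv(matrix(rnorm(30), 3))
  expect_equal(snv(z), z, tolerance = 1e-12)
  expect_error(snv(matrix(2, 1, 3)), "degenerate-spectrum")
  # property: random matrices come out standardized
  set.seed(1)
  X <- matrix(rnorm(200), 10)
  Z <- snv(X)
  expect_equal(rowMeans(Z), rep(0, 10), tolerance = 1e-10)
  expect_equal(apply(Z, 1, sd), rep(1, 10), tolerance = 1e-10)
})

test_that("SNV is invariant to per-row affine transforms (scatter removal)", {
  set.seed(2)
  X <- matrix(rnorm(120, 1, 0.3), 6)
  a <- runif(6, 0.5, 2); b <- rnorm(6)
  expect_equal(snv(X * a + b), snv(X), tolerance = 1e-10)
})

test_that("Savitzky-Golay coefficients match the classic quadratic filter", {
  expect_equal(savgol_coefficients(5, 2, 0, 0),
               c(-3, 12, 17, 12, -3) / 35, tolerance = 1e-10)
})

test_that("SG coefficients agree with a brute-force least-squares oracle", {
  for (w in c(5, 7, 9)) for (po in c(2, 3)) for (d in 0:2) {
    h <- (w - 1) / 2
    for (pos in c(-h, -1, 0, 2)) {
      expect_equal(savgol_coefficients(w, po, d, pos),
                   sg_oracle(w, po, d, pos), tolerance = 1e-10,
                   label = sprintf("w=%d poly=%d deriv=%d pos=%d", w, po, d, pos))
    }
  }
})

test_that("smoothing weights sum to 1 and derivative weights to 0", {
  for (w in c(5, 9)) {
    expect_equal(sum(savgol_coefficients(w, 2, 0, 0)), 1, tolerance = 1e-12)
    expect_equal(sum(savgol_coefficients(w, 2, 1, 0)), 0, tolerance = 1e-12)
    expect_equal(sum(savgol_coefficients(w, 2, 1, -2)), 0, tolerance = 1e-12)
  }
  expect_error(savgol_coefficients(4, 2, 0), "odd")
  expect_error(savgol_coefficients(5, 2, 3), "deriv")
  expect_error(savgol_coefficients(5, 2, 0, position = 5), "position")
})

test_that("SG filtering reproduces polynomials exactly, edges included", {
  ch <- 1:60
  X <- rbind(2 + 0.5 * ch - 0.01 * ch^2, 1 - 0.3 * ch + 0.02 * ch^2)
  out <- apply_savgol(X, window = 9, poly_order = 2, deriv_order = 0)
  expect_equal(out, X, tolerance = 1e-9)
  # first derivative of a linear signal is its slope everywhere
  lin <- rbind(1 + 0.7 * ch, 3 - 0.2 * ch)
  d1 <- apply_savgol(lin, 9, 2, 1, spacing = 1)
  expect_equal(d1, rbind(rep(0.7, 60), rep(-0.2, 60)), tolerance = 1e-9)
  # second derivative of a linear signal is zero; spacing scales results
  d2 <- apply_savgol(lin, 9, 2, 2, spacing = 1)
  expect_equal(max(abs(d2)), 0, tolerance = 1e-9)
  d1s <- apply_savgol(lin, 9, 2, 1, spacing = 2)
  expect_equal(d1s, d1 / 2, tolerance = 1e-12)
  expect_error(apply_savgol(lin[, 1:5, drop = FALSE], 9), "size error")
})

test_that("SG filtering agrees with the signal package on interior channels", {
  skip_if_not_installed("signal")
  set.seed(3)
  x <- cumsum(rnorm(80))
  for (d in 0:2) {
    mine <- apply_savgol(matrix(x, 1), 9, 2, d)[1, ]
    ref <- signal::sgolayfilt(x, p = 2, n = 9, m = d)
    expect_equal(mine[5:76], ref[5:76], tolerance = 1e-9,
                 label = paste("deriv", d))
  }
})

test_that("pretreatment labels parse, canonicalize, and reject bad tokens", {
  expect_identical(pretreatment("raw")$label, "raw")
  expect_length(pretreatment("raw")$steps, 0)
  expect_identical(pretreatment("1D+SG(9)+SNV")$label, "1D+SG(9)+SNV")
  spec <- pretreatment("2D+SG(9)")
  expect_length(spec$steps, 1)           # derivative fused into one SG pass
  expect_equal(spec$steps[[1]]$deriv_order, 2)
  expect_error(pretreatment("3D+SG(4)"), "unknown token|label")
  expect_error(pretreatment("1D"), "followed by its SG window")
  expect_error(pretreatment("SG(4)"), "odd")
})

test_that("pipelines apply left-to-right and preserve shape", {
  set.seed(4)
  X <- matrix(rnorm(2 * 40, 1, 0.2), 2)
  expect_identical(apply_pretreatment(X, "raw"), X)
  # fused derivative label is bit-identical to the single SG pass
  expect_identical(apply_pretreatment(X, "2D+SG(9)", spacing = 2),
                   apply_savgol(X, 9, 2, 2, spacing = 2))
  # order matters on sloped-baseline spectra
  base <- matrix(seq(0, 3, length.out = 40), 2, 40, byrow = TRUE)
  Xb <- X + base
  a <- apply_pretreatment(Xb, "SNV+1D+SG(9)")
  b <- apply_pretreatment(Xb, "1D+SG(9)+SNV")
  expect_gt(max(abs(a - b)), 0)
  for (lab in default_pretreatments())
    expect_identical(dim(apply_pretreatment(X, lab)), dim(X))
})
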