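# Shared small-but-informative dataset for grid runs: two informative
# bands plus pure-noise channels, light noise, fast to search.
traj_fixture <- function(n = 36, seed = 31) {
  spec <- synthetic_spec(constituents = list(
    water = list(bands = list(c(1200, 30, 0.09), c(1320, 25, 0.12)),
                 range = c(9.38, 10.98)),
    matrixc = list(bands = list(c(1250, 60, 0.02)), range = c(55, 60))),
    axis_start = 1100, axis_step = 2, axis_count = 160,
    baseline = c(0.1, 2e-4, 0), scatter_sd = 0.02, offset_sd = 0.05,
    drift_sd = 2e-4, noise_sd = 0.002, seed = seed)
  generate_spectra(spec, n)
}

test_that("grid enumeration is the deterministic Cartesian product", {
  grid <- enumerate_grid(default_pretreatments(), 10, c("full", "VIP"))
  expect_length(grid, 120)
  labs <- vapply(grid, function(g) g$pretreatment$label, character(1))
  expect_identical(labs[1:20], rep("raw", 20))          # pretreatment-major
  expect_identical(vapply(grid[1:4], `[[`, 1L, "n_factors"),
                   c(1L, 1L, 2L, 2L))                   # A ascending
  expect_identical(vapply(grid[1:2], `[[`, "", "varsel"),
                   c("full", "VIP"))
  expect_length(enumerate_grid("raw", 1, "full"), 1)
  expect_identical(grid, enumerate_grid(default_pretreatments(), 10,
                                        c("full", "VIP")))
  expect_error(enumerate_grid(character(0), 5), "parameter error")
})

test_that("a perfect rank-1 model yields near-zero errors on both sets", {
  ds <- rank1_dataset(n = 24, p = 50)
  sp <- split_dataset(ds)
  cal <- plstraj:::subset_samples(ds, sp$calibration_indices)
  val <- plstraj:::subset_samples(ds, sp$validation_indices)
  cfg <- list(pretreatment = pretreatment("raw"), n_factors = 1L,
              varsel = "full")
  rec <- evaluate_path(cfg, cal, val)
  expect_identical(rec$status, "ok")
  expect_lt(rec$metrics$rmsec, 1e-6)
  expect_lt(rec$metrics$rmsep, 1e-6)
  expect_gt(rec$metrics$r2_cal, 0.999999)
  expect_gt(rec$metrics$r2_pre, 0.999999)
  expect_equal(rec$n_selected_variables, 50)
  # identical cal and val sets: RMSEC equals RMSEP exactly
  rec2 <- evaluate_path(cfg, cal, cal)
  expect_equal(rec2$metrics$rmsec, rec2$metrics$rmsep, tolerance = 1e-12)
})

test_that("VIP paths drop pure-noise channels", {
  ds <- rank1_dataset(n = 24, p = 30)
  set.seed(32)
  noise <- matrix(rnorm(24 * 30, 0, 0.01), 24, 30)
  X <- cbind(ds$X, noise)
  ds2 <- spectra_dataset(X, ds$y, seq(1100, by = 2, length.out = 60))
  sp <- split_dataset(ds2)
  cal <- plstraj:::subset_samples(ds2, sp$calibration_indices)
  val <- plstraj:::subset_samples(ds2, sp$validation_indices)
  cfg <- list(pretreatment = pretreatment("raw"), n_factors = 2L,
              varsel = "VIP")
  rec <- evaluate_path(cfg, cal, val)
  expect_identical(rec$status, "ok")
  expect_lt(rec$n_selected_variables, 60)
  # informative channels dominate the selection
  m <- fit_pls(cal$X, cal$y, 2)
  sel <- select_variables(vip_scores(m), 1.0, 2)
  expect_gt(mean(sel <= 30), 0.9)
})

test_that("run_trajectory is complete, best-by-RPD, and record-consistent", {
  ds <- traj_fixture()
  res <- run_trajectory(ds, A_max = 5)
  expect_length(res$records, 6 * 5 * 2)
  expect_identical(nrow(res$table), 60L)
  ok <- res$table$status == "ok"
  expect_true(all(res$table$RPD[ok] <= res$best$metrics$rpd))
  # full-variable records keep every channel
  full_rows <- res$table$varsel == "full" & ok
  expect_true(all(res$table$n_selected[full_rows] == ncol(ds$X)))
  # effective A is recorded, never exceeding the request
  expect_true(all(res$table$A_eff[ok] <= res$table$n_factors[ok]))
})

test_that("infeasible paths are recorded as failed, not fatal", {
  ds <- traj_fixture(n = 8)      # tiny calibration set: large A infeasible CV
  res <- run_trajectory(ds, A_max = 4, cv_folds = 3)
  expect_length(res$records, 48)
  expect_true(res$best$status == "ok")
})

test_that("stepwise choice is a grid member dominated by the trajectory", {
  ds <- traj_fixture()
  sp <- split_dataset(ds)
  cal <- plstraj:::subset_samples(ds, sp$calibration_indices)
  val <- plstraj:::subset_samples(ds, sp$validation_indices)
  res <- run_trajectory(cal = cal, val = val, A_max = 6)
  sw <- stepwise_optimize(cal, val, A_max = 6)
  expect_identical(sw$status, "ok")
  grid <- enumerate_grid(default_pretreatments(), 6, c("full", "VIP"))
  member <- any(vapply(grid, function(g)
    identical(g$pretreatment$label, sw$config$pretreatment$label) &&
      g$n_factors == sw$config$n_factors &&
      identical(g$varsel, sw$config$varsel), logical(1)))
  expect_true(member)
  expect_gte(res$best$metrics$rpd, sw$metrics$rpd)
})

test_that("trajectory reports round-trip and flag failures", {
  ds <- traj_fixture(n = 8)
  res <- run_trajectory(ds, A_max = 4, cv_folds = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(res, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# best:")
  expect_length(lines, 2 + 48)
  tab <- read_report(path)
  ok <- tab$status == "ok"
  expect_equal(tab$RPD[ok], signif(res$table$RPD[ok], 6), tolerance = 1e-5)
  if (any(!ok)) expect_true(all(is.na(tab$RPD[!ok])))
})
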