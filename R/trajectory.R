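#' Enumerate the full processing-trajectory grid
#'
#' Cartesian product of pretreatment chains, latent-factor counts 1..A_max,
#' and variable-selection modes, in deterministic order: pretreatment-major,
#' then factor count ascending, then variable-selection mode in the order
#' given. With the default 6 pretreatments, A_max = 10, and modes
#' full + VIP this is the 120-path grid.
#'
#' @param pretreatments character vector of pretreatment labels, or list of
#'   `pretreatment_spec` objects.
#' @param A_max largest latent-factor count (>= 1).
#' @param varsel_modes subset of `c("full", "VIP")`.
#' @return list of path configurations, each a list with `pretreatment`
#'   (a `pretreatment_spec`), `n_factors`, `varsel`.
#' @export
enumerate_grid <- function(pretreatments = default_pretreatments(),
                           A_max = 10L, varsel_modes = c("full", "VIP")) {
  if (length(pretreatments) == 0 || length(varsel_modes) == 0)
    stop("parameter error: empty pretreatment menu or variable-selection mode list")
  if (A_max < 1) stop("parameter error: A_max must be >= 1")
  if (!all(varsel_modes %in% c("full", "VIP")))
    stop("parameter error: varsel modes must be 'full' or 'VIP'")
  specs <- lapply(pretreatments, function(pt)
    if (inherits(pt, "pretreatment_spec")) pt else pretreatment(pt))
  grid <- list()
  for (pt in specs)
    for (A in seq_len(A_max))
      for (vs in varsel_modes)
        grid[[length(grid) + 1L]] <-
          list(pretreatment = pt, n_factors = as.integer(A), varsel = vs)
  grid
}

# Core path evaluation on already-pretreated matrices. Returns a
# trajectory_record; any error is captured as a failed record so one
# infeasible path never aborts a whole grid.
evaluate_path_mat <- function(config, Xc, yc, Xv, yv,
                              vip_threshold = 1.0, cv_folds = 10L) {
  rec <- list(config = config,
              n_selected_variables = NA_integer_,
              effective_A = NA_integer_,
              rmsecv = NA_real_,
              metrics = NULL,
              status = "ok", message = "")
  class(rec) <- "trajectory_record"
  out <- tryCatch({
    n_cal <- nrow(Xc); p <- ncol(Xc)
    A_req <- config$n_factors
    subset <- seq_len(p)
    if (config$varsel == "VIP") {
      A_fit <- min(A_req, n_cal - 1L, p)
      full <- fit_pls(Xc, yc, A_fit, clip = TRUE)
      vip <- vip_scores(full)
      subset <- select_variables(vip, threshold = vip_threshold, A = A_req)
      Xc <- Xc[, subset, drop = FALSE]
      Xv <- Xv[, subset, drop = FALSE]
    }
    A_eff <- min(A_req, n_cal - 1L, ncol(Xc))
    model <- fit_pls(Xc, yc, A_eff, variable_subset = subset, clip = TRUE)
    A_eff <- model$A                   # clipped further if rank exhausted
    met <- model_metrics(predict(model, Xc), yc, predict(model, Xv), yv)
    k_eff <- min(cv_folds, n_cal)
    A_cv <- min(A_eff, n_cal - ceiling(n_cal / k_eff) - 1L, ncol(Xc))
    rmsecv <- if (A_cv >= 1) cross_validate(Xc, yc, A_cv, k_eff)[A_cv] else NA_real_
    rec$n_selected_variables <- length(subset)
    rec$effective_A <- as.integer(A_eff)
    rec$rmsecv <- rmsecv
    rec$metrics <- met
    rec$model <- model
    rec
  }, error = function(e) {
    rec$status <- "failed"
    rec$message <- conditionMessage(e)
    rec
  })
  out
}

#' Evaluate one processing-trajectory path
#'
#' Pretreats the calibration and validation spectra with the path's chain,
#' optionally performs VIP variable selection (fit at the path's factor
#' count on all channels, score VIP, select with the > threshold rule),
#' refits on the surviving channels at `min(n_factors, feasible)` factors,
#' and computes the full metric panel: RMSEC and R2cal on the calibration
#' set, RMSEP, R2pre, RPD on the validation set, and venetian-blind RMSECV
#' on the calibration set. Infeasible paths return a failed record with a
#' diagnostic instead of raising.
#'
#' @param config one element of [enumerate_grid()]'s output.
#' @param cal,val calibration and validation `spectra_dataset`s sharing an
#'   axis.
#' @param vip_threshold VIP selection cutoff (default 1.0).
#' @param cv_folds folds for RMSECV (default 10).
#' @return a `trajectory_record`.
#' @export
evaluate_path <- function(config, cal, val, vip_threshold = 1.0,
                          cv_folds = 10L) {
  validate_spectra_dataset(cal)
  validate_spectra_dataset(val)
  if (!isTRUE(all.equal(cal$axis, val$axis)))
    stop("parameter error: calibration and validation sets must share the spectral axis")
  sp <- axis_spacing(cal)
  Xc <- apply_pretreatment(cal$X, config$pretreatment, sp)
  Xv <- apply_pretreatment(val$X, config$pretreatment, sp)
  evaluate_path_mat(config, Xc, cal$y, Xv, val$y, vip_threshold, cv_folds)
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat("trajectory_record: ", x$config$pretreatment$label, ", A = ",
      x$config$n_factors, " (effective ", x$effective_A, "), varsel = ",
      x$config$varsel, ", status = ", x$status, "\n", sep = "")
  if (x$status == "ok") print(x$metrics) else cat("  ", x$message, "\n", sep = "")
  invisible(x)
}

# Subset a spectra_dataset by row indices.
subset_samples <- function(ds, idx) {
  spectra_dataset(ds$X[idx, , drop = FALSE], ds$y[idx], ds$axis,
                  sample_ids = ds$sample_ids[idx], axis_unit = ds$axis_unit)
}

# Order of preference among ok records: max RPD, then smaller RMSEP, then
# smaller requested A, then earlier pretreatment in menu order, then full
# before VIP. Returns the index of the best record.
best_record_index <- function(records) {
  ok <- which(vapply(records, function(r) r$status == "ok", logical(1)))
  if (length(ok) == 0) stop("trajectory error: every path failed")
  key <- function(i) {
    r <- records[[i]]
    c(-r$metrics$rpd, r$metrics$rmsep, r$config$n_factors, i)
  }
  # grid order already encodes menu position and full-before-VIP, so the
  # final tie-break is simply the earlier grid index
  keys <- t(vapply(ok, key, numeric(4)))
  ok[do.call(order, as.data.frame(keys))[1]]
}

#' Run the full processing trajectory
#'
#' The core procedure: enumerate every (pretreatment, latent-factor,
#' variable-selection) path over the grid, fit and score each on a fixed
#' calibration/validation split, and select the best path by RPD (ties:
#' smaller RMSEP, then fewer factors, then earlier pretreatment in menu
#' order, then full variables before VIP). Deterministic end to end: the
#' Kennard-Stone split, venetian-blind cross-validation, and the grid order
#' involve no randomness.
#'
#' @param ds a `spectra_dataset` to split internally 2:1 by Kennard-Stone;
#'   or NULL if `cal` and `val` are given.
#' @param cal,val pre-split calibration/validation datasets (used when `ds`
#'   is NULL).
#' @param split an explicit `ks_split` applied to `ds` (overrides
#'   `cal_fraction`).
#' @param pretreatments pretreatment menu (labels or specs); grid order
#'   matters for tie-breaking.
#' @param A_max largest latent-factor count (default 10).
#' @param varsel_modes variable-selection modes (default full and VIP).
#' @param cal_fraction calibration fraction for the internal split.
#' @param vip_threshold VIP cutoff.
#' @param cv_folds folds for RMSECV.
#' @return an object of class `trajectory_result`: `records` (one per grid
#'   point), `table` (data frame of the report columns), `best`,
#'   `best_index`, `criterion`, `split`.
#' @export
run_trajectory <- function(ds = NULL, cal = NULL, val = NULL, split = NULL,
                           pretreatments = default_pretreatments(),
                           A_max = 10L, varsel_modes = c("full", "VIP"),
                           cal_fraction = 2 / 3, vip_threshold = 1.0,
                           cv_folds = 10L) {
  if (!is.null(ds)) {
    if (is.null(split)) split <- split_dataset(ds, cal_fraction)
    cal <- subset_samples(ds, split$calibration_indices)
    val <- subset_samples(ds, split$validation_indices)
  } else if (is.null(cal) || is.null(val)) {
    stop("parameter error: supply either ds or both cal and val")
  }
  grid <- enumerate_grid(pretreatments, A_max, varsel_modes)
  sp <- axis_spacing(cal)

  # pretreat once per distinct chain, not once per path
  labels <- vapply(grid, function(g) g$pretreatment$label, character(1))
  records <- vector("list", length(grid))
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    ptspec <- grid[[idx[1]]]$pretreatment
    Xc <- tryCatch(apply_pretreatment(cal$X, ptspec, sp), error = identity)
    Xv <- tryCatch(apply_pretreatment(val$X, ptspec, sp), error = identity)
    for (i in idx) {
      if (inherits(Xc, "condition") || inherits(Xv, "condition")) {
        bad <- if (inherits(Xc, "condition")) Xc else Xv
        rec <- structure(list(config = grid[[i]],
                              n_selected_variables = NA_integer_,
                              effective_A = NA_integer_, rmsecv = NA_real_,
                              metrics = NULL, status = "failed",
                              message = conditionMessage(bad)),
                         class = "trajectory_record")
        records[[i]] <- rec
      } else {
        records[[i]] <- evaluate_path_mat(grid[[i]], Xc, cal$y, Xv, val$y,
                                          vip_threshold, cv_folds)
      }
    }
  }
  bi <- best_record_index(records)
  structure(list(records = records,
                 table = records_table(records),
                 best = records[[bi]],
                 best_index = bi,
                 criterion = "max RPD; ties: min RMSEP, min n_factors, menu order, full before VIP",
                 split = split,
                 cal = cal, val = val),
            class = "trajectory_result")
}

records_table <- function(records) {
  row <- function(r) {
    m <- r$metrics
    data.frame(pretreatment = r$config$pretreatment$label,
               n_factors = r$config$n_factors,
               A_eff = r$effective_A,
               varsel = r$config$varsel,
               n_selected = r$n_selected_variables,
               RMSEC = if (is.null(m)) NA_real_ else m$rmsec,
               R2cal = if (is.null(m)) NA_real_ else m$r2_cal,
               RMSECV = r$rmsecv,
               RMSEP = if (is.null(m)) NA_real_ else m$rmsep,
               R2pre = if (is.null(m)) NA_real_ else m$r2_pre,
               RPD = if (is.null(m)) NA_real_ else m$rpd,
               category = if (is.null(m)) "" else m$category,
               status = r$status,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(records, row))
}

#' @export
print.trajectory_result <- function(x, ...) {
  ok <- sum(x$table$status == "ok")
  cat("trajectory_result: ", nrow(x$table), " paths (", ok, " ok)\n", sep = "")
  b <- x$best
  cat("best path: ", b$config$pretreatment$label, ", A = ",
      b$config$n_factors, ", varsel = ", b$config$varsel,
      sprintf(", RPD = %.4f (%s), RMSEP = %.4f, R2pre = %.4f\n",
              b$metrics$rpd, b$metrics$category, b$metrics$rmsep,
              b$metrics$r2_pre), sep = "")
  invisible(x)
}

#' Conventional one-parameter-at-a-time optimizer (comparator)
#'
#' The step-by-step routine the trajectory is compared against:
#' (1) pick the pretreatment whose best full-variable RMSECV over
#' A = 1..A_max is smallest; (2) at that pretreatment pick the A minimizing
#' RMSECV; (3) apply VIP selection at that A and keep it only if it improves
#' RMSEP. The result is always a member of the full grid, so the exhaustive
#' trajectory can never do worse by RPD.
#'
#' @inheritParams run_trajectory
#' @return the selected `trajectory_record`.
#' @export
stepwise_optimize <- function(cal, val,
                              pretreatments = default_pretreatments(),
                              A_max = 10L, vip_threshold = 1.0,
                              cv_folds = 10L) {
  validate_spectra_dataset(cal)
  validate_spectra_dataset(val)
  sp <- axis_spacing(cal)
  specs <- lapply(pretreatments, function(pt)
    if (inherits(pt, "pretreatment_spec")) pt else pretreatment(pt))
  n_cal <- nrow(cal$X)
  k_eff <- min(cv_folds, n_cal)

  best_pt <- NULL; best_cv <- Inf; best_A <- NA_integer_
  for (ptspec in specs) {
    Xc <- apply_pretreatment(cal$X, ptspec, sp)
    A_feas <- min(A_max, n_cal - ceiling(n_cal / k_eff) - 1L, ncol(Xc))
    if (A_feas < 1) next
    cv <- cross_validate(Xc, cal$y, A_feas, k_eff)
    if (min(cv) < best_cv) {        # strict: ties keep the earlier menu entry
      best_cv <- min(cv)
      best_pt <- ptspec
      best_A <- which.min(cv)       # ties -> smaller A
    }
  }
  if (is.null(best_pt)) stop("trajectory error: no feasible pretreatment/factor combination")

  cfg_full <- list(pretreatment = best_pt, n_factors = as.integer(best_A),
                   varsel = "full")
  cfg_vip <- list(pretreatment = best_pt, n_factors = as.integer(best_A),
                  varsel = "VIP")
  rec_full <- evaluate_path(cfg_full, cal, val, vip_threshold, cv_folds)
  rec_vip <- evaluate_path(cfg_vip, cal, val, vip_threshold, cv_folds)
  if (rec_vip$status == "ok" &&
      (rec_full$status != "ok" || rec_vip$metrics$rmsep < rec_full$metrics$rmsep))
    rec_vip
  else
    rec_full
}

#' Write a trajectory report
#'
#' A one-line best-path summary (as a `#` comment) followed by a delimited
#' table with one row per path: pretreatment label, requested and effective
#' factor counts, variable-selection mode, number of selected variables,
#' RMSEC, R2cal, RMSECV, RMSEP, R2pre, RPD, category, and status. Metrics
#' are printed to 6 significant digits; failed paths carry empty metric
#' cells and a non-"ok" status. Byte-identical across repeated runs on the
#' same inputs.
#'
#' @param result a `trajectory_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "trajectory_result"))
  tab <- result$table
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.6g", v))
  b <- result$best
  head_line <- sprintf(
    "# best: pretreatment=%s n_factors=%d varsel=%s RPD=%.6g RMSEP=%.6g R2pre=%.6g category=%s",
    b$config$pretreatment$label, b$config$n_factors, b$config$varsel,
    b$metrics$rpd, b$metrics$rmsep, b$metrics$r2_pre, b$metrics$category)
  cols <- c("pretreatment", "n_factors", "A_eff", "varsel", "n_selected",
            "RMSEC", "R2cal", "RMSECV", "RMSEP", "R2pre", "RPD",
            "category", "status")
  lines <- c(head_line, paste(cols, collapse = ","))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    lines <- c(lines, paste(c(
      r$pretreatment, r$n_factors,
      ifelse(is.na(r$A_eff), "", r$A_eff), r$varsel,
      ifelse(is.na(r$n_selected), "", r$n_selected),
      fmt(r$RMSEC), fmt(r$R2cal), fmt(r$RMSECV), fmt(r$RMSEP), fmt(r$R2pre),
      fmt(r$RPD), r$category, r$status), collapse = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a trajectory report written by [write_report()]
#' @param path report file.
#' @return data frame with the report columns.
#' @export
read_report <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
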