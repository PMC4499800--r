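#' Kennard-Stone maximin sample selection
#'
#' Deterministic selection of representative samples: the first two picks are
#' the pair with maximal Euclidean distance; each subsequent pick maximizes
#' the minimum distance to all already-selected samples. Ties are broken by
#' the lowest original index (for the initial pair, the lexicographically
#' smallest index pair, lower index first), so the selection is fully
#' reproducible.
#'
#' Distances are computed on the spectra exactly as given - raw, uncentered -
#' so a single split can serve every pretreatment path of a trajectory.
#'
#' @param X numeric matrix, n x p (n >= 2).
#' @param n_select number of samples to pick, 2 <= n_select <= n.
#' @return integer vector of selected row indices, in selection order.
#' @export
kennard_stone <- function(X, n_select) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("parameter error: need at least 2 samples")
  if (n_select < 2 || n_select > n)
    stop("parameter error: n_select must be in [2, ", n, "] (got ", n_select, ")")
  D <- as.matrix(stats::dist(X))
  # initial pair: maximal distance; ties -> smallest (i, j) lexicographically
  up <- which(upper.tri(D), arr.ind = TRUE)
  dv <- D[up]
  cand <- up[dv == max(dv), , drop = FALSE]
  best <- cand[order(cand[, "row"], cand[, "col"])[1], ]
  sel <- c(best[["row"]], best[["col"]])
  mind <- pmin(D[, sel[1]], D[, sel[2]])  # min distance to selected, per sample
  while (length(sel) < n_select) {
    mind[sel] <- -Inf
    nxt <- which(mind == max(mind))[1]   # which() returns lowest index first
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  as.integer(sel)
}

#' Split a dataset into calibration and validation sets by Kennard-Stone
#'
#' The calibration size is `round(cal_fraction * n)` with half-away-from-zero
#' rounding; calibration samples are picked by [kennard_stone()] on the raw
#' (pretreatment-free) spectra and the remainder becomes the validation set.
#' With the default 2:1 ratio, n = 80 gives 53/27 and n = 72 gives 48/24.
#'
#' @param ds a `spectra_dataset` (n >= 3).
#' @param cal_fraction fraction of samples for calibration (default 2/3).
#' @return an object of class `ks_split` with `calibration_indices`
#'   (selection order), `validation_indices` (original order), and `n_total`.
#' @export
split_dataset <- function(ds, cal_fraction = 2 / 3) {
  validate_spectra_dataset(ds)
  n <- nrow(ds$X)
  if (n < 3) stop("parameter error: need at least 3 samples to split")
  n_cal <- floor(cal_fraction * n + 0.5)  # half away from zero for positive x
  if (n_cal < 2 || n - n_cal < 1)
    stop("parameter error: cal_fraction ", cal_fraction, " leaves n_cal = ",
         n_cal, ", n_val = ", n - n_cal)
  cal <- kennard_stone(ds$X, n_cal)
  structure(list(calibration_indices = cal,
                 validation_indices = setdiff(seq_len(n), cal),
                 n_total = n),
            class = "ks_split")
}

#' @export
print.ks_split <- function(x, ...) {
  cat("ks_split: ", length(x$calibration_indices), " calibration / ",
      length(x$validation_indices), " validation (n = ", x$n_total, ")\n",
      sep = "")
  invisible(x)
}

#' Write a split report to a text file
#'
#' Plain-text key/value lines (`n_total`, `n_cal`, `n_val`) followed by the
#' two index lists, consumable by [read_split()] and the CLI `--split-file`
#' option.
#'
#' @param split a `ks_split`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "ks_split"))
  lines <- c(
    paste("n_total", split$n_total),
    paste("n_cal", length(split$calibration_indices)),
    paste("n_val", length(split$validation_indices)),
    paste(c("calibration", split$calibration_indices), collapse = " "),
    paste(c("validation", split$validation_indices), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a split report written by [write_split()]
#' @param path split file.
#' @return a `ks_split`.
#' @export
read_split <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  grab <- function(key) {
    ln <- grep(paste0("^", key, "\\b"), lines, value = TRUE)
    if (length(ln) != 1) stop("format error: split file needs exactly one '", key, "' line")
    as.integer(strsplit(trimws(ln), "\\s+")[[1]][-1])
  }
  split <- structure(list(calibration_indices = grab("calibration"),
                          validation_indices = grab("validation"),
                          n_total = grab("n_total")[1]),
                     class = "ks_split")
  idx <- sort(c(split$calibration_indices, split$validation_indices))
  if (!identical(idx, seq_len(split$n_total)))
    stop("format error: split indices must partition 1..n_total")
  split
}
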