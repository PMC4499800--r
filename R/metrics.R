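#' Root mean squared error
#'
#' `sqrt(sum((predicted - observed)^2) / n)` - plain n denominator, no
#' degrees-of-freedom correction, the common chemometrics convention for
#' RMSEC, RMSECV, and RMSEP alike. Units follow the reference values (%).
#'
#' @param predicted,observed numeric vectors of equal length >= 1.
#' @return nonnegative scalar.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("shape error: predicted and observed lengths differ")
  if (length(observed) < 1) stop("shape error: need at least one value")
  sqrt(mean((predicted - observed)^2))
}

#' Coefficient of determination
#'
#' `1 - SSres / SStot` with SStot taken about the mean of the evaluated
#' set's own observed values. Can be negative for worse-than-mean
#' predictions; 1 for a perfect fit.
#'
#' @param predicted,observed numeric vectors of equal length >= 2.
#' @return scalar in (-Inf, 1].
#' @export
r_squared <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("shape error: predicted and observed lengths differ")
  if (length(observed) < 2) stop("shape error: need at least two values")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("degenerate error: observed values have zero variance")
  1 - sum((predicted - observed)^2) / sst
}

#' Ratio of performance to deviation (RPD)
#'
#' The standard deviation (n-1 denominator) of the validation set's observed
#' reference values divided by RMSEP. Useful models have RPD well above 1;
#' see [categorize_rpd()] for the quality bands.
#'
#' @param observed_validation reference values of the validation set
#'   (length >= 2, nonzero variance).
#' @param rmsep root mean squared error of prediction (> 0).
#' @return positive scalar.
#' @export
rpd <- function(observed_validation, rmsep) {
  if (length(observed_validation) < 2)
    stop("degenerate error: need at least two validation values")
  s <- stats::sd(observed_validation)
  if (s == 0) stop("degenerate error: validation reference values have zero variance")
  if (rmsep <= 0) stop("undefined-RPD error: RMSEP must be > 0")
  s / rmsep
}

#' Categorize a model by its RPD
#'
#' Bands: inadequate below 2.5; fair on [2.5, 3]; good on (3, 4]; excellent
#' above 4. Monotone non-decreasing in RPD.
#'
#' @param rpd positive scalar.
#' @return one of "inadequate", "fair", "good", "excellent".
#' @export
categorize_rpd <- function(rpd) {
  if (rpd <= 0) stop("parameter error: RPD must be > 0")
  if (rpd < 2.5) "inadequate"
  else if (rpd <= 3) "fair"
  else if (rpd <= 4) "good"
  else "excellent"
}

#' Full evaluation panel for a calibration/validation model pair
#'
#' @param pred_cal,obs_cal predictions and observations on the calibration set.
#' @param pred_val,obs_val predictions and observations on the validation set.
#' @return list of class `model_metrics`: `rmsec`, `r2_cal`, `rmsep`,
#'   `r2_pre`, `rpd`, `category`, `n_cal`, `n_val`.
#' @export
model_metrics <- function(pred_cal, obs_cal, pred_val, obs_val) {
  rmsec <- rmse(pred_cal, obs_cal)
  rmsep <- rmse(pred_val, obs_val)
  # a numerically perfect validation fit is the RPD -> Inf limit, not an error
  rpd_v <- if (rmsep == 0) Inf else rpd(obs_val, rmsep)
  structure(list(rmsec = rmsec,
                 r2_cal = r_squared(pred_cal, obs_cal),
                 rmsep = rmsep,
                 r2_pre = r_squared(pred_val, obs_val),
                 rpd = rpd_v,
                 category = categorize_rpd(rpd_v),
                 n_cal = length(obs_cal),
                 n_val = length(obs_val)),
            class = "model_metrics")
}

#' @export
print.model_metrics <- function(x, ...) {
  cat(sprintf(
    "model_metrics: RMSEC %.6g  R2cal %.6g  RMSEP %.6g  R2pre %.6g  RPD %.6g (%s)\n",
    x$rmsec, x$r2_cal, x$rmsep, x$r2_pre, x$rpd, x$category))
  invisible(x)
}
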