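#' Fit a PLS1 regression model by NIPALS
#'
#' Partial least squares with a single response, mean-centering only (no
#' per-channel variance scaling: absorbance channels share units). Per
#' factor a: the weight vector w_a is proportional to X_a' y_a, normalized
#' to unit norm; scores t_a = X_a w_a; x-loadings p_a = X_a' t_a / (t_a' t_a);
#' y-loading q_a = y_a' t_a / (t_a' t_a); X and y are then deflated. The
#' regression vector b (centered form) is assembled as
#' W (P'W)^-1 q, so predictions are (X - x_mean) b + y_mean.
#'
#' @param X numeric matrix of calibration spectra, n x p.
#' @param y numeric vector of reference values, length n.
#' @param A number of latent factors, 1 <= A <= min(n - 1, p).
#' @param variable_subset optional index vector recording which of the
#'   original channels `X` holds (metadata carried for prediction and
#'   reporting; `X` must already be restricted to these columns).
#' @param clip if TRUE, stop extracting factors once the residual response
#'   is exhausted and return the model with the achieved factor count
#'   instead of raising a rank error (the requested A is still validated
#'   against n and p). Used by path evaluation, where the achievable rank
#'   of a VIP-selected channel subset is not known in advance.
#' @return an object of class `pls_model` with fields `A`, `x_mean`,
#'   `y_mean`, `W`, `P`, `q`, `T`, `b`, `variable_subset`.
#' @export
fit_pls <- function(X, y, A, variable_subset = NULL, clip = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("shape error: length(y) != nrow(X)")
  if (A < 1 || A > min(n - 1, p))
    stop("parameter error: A must be in [1, ", min(n - 1, p), "] (got ", A, ")")
  if (is.null(variable_subset)) variable_subset <- seq_len(p)

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xa <- sweep(X, 2, x_mean)
  ya <- y - y_mean
  W <- P <- matrix(0, p, A)
  q <- numeric(A)
  Tm <- matrix(0, n, A)
  achieved <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xa, ya)                       # p x 1
    wn <- sqrt(sum(w^2))
    degenerate <- wn < 1e-12 * max(1, sqrt(sum(ya^2))) || wn == 0
    if (!degenerate) {
      w <- w / wn
      t <- as.numeric(Xa %*% w)
      degenerate <- sum(t^2) == 0
    }
    if (degenerate) {
      if (clip && achieved >= 1L) break
      stop("rank error: residual response exhausted before factor ", a,
           "; achievable maximum A is ", a - 1)
    }
    tt <- sum(t^2)
    pv <- as.numeric(crossprod(Xa, t)) / tt
    qa <- sum(ya * t) / tt
    Xa <- Xa - tcrossprod(t, pv)
    ya <- ya - qa * t
    W[, a] <- w; P[, a] <- pv; q[a] <- qa; Tm[, a] <- t
    achieved <- a
  }
  W <- W[, seq_len(achieved), drop = FALSE]
  P <- P[, seq_len(achieved), drop = FALSE]
  q <- q[seq_len(achieved)]
  Tm <- Tm[, seq_len(achieved), drop = FALSE]
  b <- as.numeric(W %*% solve(crossprod(P, W), q))
  structure(list(A = achieved, x_mean = x_mean, y_mean = y_mean,
                 W = W, P = P, q = q, T = Tm, b = b,
                 variable_subset = as.integer(variable_subset)),
            class = "pls_model")
}

#' Predict from a fitted PLS model
#'
#' @param object a `pls_model`.
#' @param X matrix of spectra with as many columns as the model's variable
#'   subset (i.e. already restricted to the channels the model was fit on).
#' @param ... unused.
#' @return numeric vector of predictions, one per row of `X`.
#' @export
predict.pls_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$x_mean))
    stop("shape error: ", ncol(X), " channels supplied, model expects ",
         length(object$x_mean))
  as.numeric(sweep(X, 2, object$x_mean) %*% object$b) + object$y_mean
}

#' @export
print.pls_model <- function(x, ...) {
  cat("pls_model: ", x$A, " latent factors, ", length(x$x_mean),
      " variables\n", sep = "")
  invisible(x)
}

# Regression vectors for all factor counts 1..A from one fitted model.
# Column a of the returned p x A matrix is the centered-form b using the
# first a factors. Used by cross-validation to score every A in one pass.
pls_coef_path <- function(model) {
  A <- model$A
  p <- nrow(model$W)
  B <- matrix(0, p, A)
  R <- crossprod(model$P, model$W)   # A x A, upper triangular in exact arithmetic
  for (a in seq_len(A)) {
    B[, a] <- model$W[, 1:a, drop = FALSE] %*%
      solve(R[1:a, 1:a, drop = FALSE], model$q[1:a])
  }
  B
}

#' K-fold cross-validated RMSE over a range of factor counts
#'
#' Venetian-blind (interleaved) fold assignment - sample i goes to fold
#' ((i - 1) mod k) + 1, in calibration row order - so the procedure is fully
#' deterministic. For each factor count A in 1..A_max, RMSECV(A) is the root
#' mean squared error of held-out predictions pooled over all folds.
#'
#' @param X calibration spectra, n x p.
#' @param y reference values, length n.
#' @param A_max largest factor count to score; must satisfy
#'   `A_max <= min(n - ceiling(n / k) - 1, p)`.
#' @param k number of folds (default 10).
#' @return numeric vector of RMSECV values indexed by A = 1..A_max.
#' @export
cross_validate <- function(X, y, A_max, k = 10L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (k < 2 || k > n) stop("parameter error: need n >= k >= 2")
  feas <- min(n - ceiling(n / k) - 1, ncol(X))
  if (A_max < 1 || A_max > feas)
    stop("parameter error: A_max must be in [1, ", feas,
         "] after fold removal (got ", A_max, ")")
  fold <- ((seq_len(n) - 1L) %% k) + 1L
  sse <- numeric(A_max)
  for (f in seq_len(k)) {
    out <- fold == f
    m <- fit_pls(X[!out, , drop = FALSE], y[!out], A_max, clip = TRUE)
    B <- pls_coef_path(m)
    if (m$A < A_max)   # fold rank exhausted: later factors add nothing
      B <- cbind(B, B[, rep(m$A, A_max - m$A), drop = FALSE])
    Xc <- sweep(X[out, , drop = FALSE], 2, m$x_mean)
    pred <- Xc %*% B + m$y_mean                 # n_out x A_max
    sse <- sse + colSums((pred - y[out])^2)
  }
  sqrt(sse / n)
}

#' Variable importance in projection (VIP) scores
#'
#' Standard Wold VIP: with unit-norm weight vectors w_a and the y-variance
#' explained by factor a, SS_a = q_a^2 * (t_a' t_a),
#' \deqn{VIP_j = \sqrt{p \sum_a SS_a w_{aj}^2 / \sum_a SS_a}.}
#' The squared scores average to 1 (sum of VIP_j^2 = p), which is what makes
#' the conventional "greater than one" selection threshold meaningful.
#'
#' @param model a fitted `pls_model`.
#' @return an object of class `vip_result` with `scores` (length p),
#'   `model_factors` (the A used), and slots for the selection produced by
#'   [select_variables()].
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  ss <- model$q^2 * colSums(model$T^2)           # y-variance per factor
  if (sum(ss) == 0)
    stop("degenerate-model error: no factor explains any response variance")
  p <- nrow(model$W)
  scores <- sqrt(p * as.numeric(model$W^2 %*% ss) / sum(ss))
  structure(list(scores = scores, threshold = NA_real_,
                 selected = NULL, model_factors = model$A),
            class = "vip_result")
}

#' Select variables by VIP threshold
#'
#' Returns the indices with VIP above the threshold. If fewer than
#' `max(2, A)` survive, falls back to the `max(2, A)` highest-VIP indices
#' (ties broken toward the lower index), so the downstream refit at A
#' factors stays feasible.
#'
#' @param vip a `vip_result` (or bare numeric score vector).
#' @param threshold selection cutoff (default 1.0, the conventional VIP rule).
#' @param A factor count of the downstream model, used by the fallback.
#' @return integer vector of selected channel indices (ascending).
#' @export
select_variables <- function(vip, threshold = 1.0, A = 1L) {
  scores <- if (inherits(vip, "vip_result")) vip$scores else as.numeric(vip)
  sel <- which(scores > threshold)
  need <- max(2L, as.integer(A))
  if (length(sel) < need) {
    sel <- order(-scores, seq_along(scores))[seq_len(min(need, length(scores)))]
    sel <- sort(sel)
  }
  as.integer(sel)
}

#' Export a fitted model (with its pretreatment) to structured text
#'
#' Writes JSON holding everything needed to re-predict without refitting:
#' factor count, centers, regression vector, variable subset, pretreatment
#' label, and the channel spacing used for derivative scaling.
#'
#' @param model a `pls_model`.
#' @param path output file.
#' @param pretreatment_label canonical label of the pretreatment chain the
#'   model expects its input spectra to receive.
#' @param spacing channel spacing for derivative pretreatments.
#' @return `path`, invisibly.
#' @export
export_model <- function(model, path, pretreatment_label = "raw", spacing = 1) {
  stopifnot(inherits(model, "pls_model"))
  obj <- list(format = "plstraj-model-1",
              A = model$A,
              x_mean = model$x_mean,
              y_mean = model$y_mean,
              b = model$b,
              variable_subset = model$variable_subset,
              pretreatment = pretreatment_label,
              spacing = spacing)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an exported model
#' @param path file written by [export_model()].
#' @return list with fields `A`, `x_mean`, `y_mean`, `b`, `variable_subset`,
#'   `pretreatment`, `spacing`; class `pls_model_export`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "plstraj-model-1")
    stop("format error: not a plstraj model file: ", path)
  obj$variable_subset <- as.integer(obj$variable_subset)
  structure(obj, class = "pls_model_export")
}

#' Predict reference values for a dataset from an exported model
#'
#' Applies the stored pretreatment chain to the full spectra, restricts to
#' the stored variable subset, and evaluates the linear predictor.
#'
#' @param model a `pls_model_export` from [load_model()].
#' @param ds a `spectra_dataset` on the same axis the model was built on.
#' @return numeric vector of predictions.
#' @export
predict_exported <- function(model, ds) {
  stopifnot(inherits(model, "pls_model_export"))
  validate_spectra_dataset(ds)
  Xp <- apply_pretreatment(ds$X, model$pretreatment, model$spacing)
  if (max(model$variable_subset) > ncol(Xp))
    stop("shape error: dataset has ", ncol(Xp),
         " channels, model subset needs up to ", max(model$variable_subset))
  Xs <- Xp[, model$variable_subset, drop = FALSE]
  as.numeric(sweep(Xs, 2, model$x_mean) %*% model$b) + model$y_mean
}
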