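#' Standard normal variate (SNV) transform
#'
#' Standardizes each spectrum (row) to mean 0 and sample standard deviation 1
#' (n-1 denominator), independently of all other rows. SNV removes per-sample
#' multiplicative scatter and additive offset: `snv(a*x + b) == snv(x)` for
#' any a > 0.
#'
#' @param X numeric matrix, n spectra x p channels.
#' @return matrix of the same shape.
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  m <- rowMeans(X)
  s <- sqrt(rowSums((X - m)^2) / (ncol(X) - 1))
  if (any(s == 0)) {
    bad <- which(s == 0)[1]
    stop("degenerate-spectrum error: sample ", bad,
         " is constant (zero variance); SNV undefined")
  }
  (X - m) / s
}

#' Savitzky-Golay convolution coefficients
#'
#' Least-squares polynomial convolution weights: fit a degree-`poly_order`
#' polynomial to the `window` points and evaluate its `deriv_order`-th
#' derivative at offset `position` from the window center (0 = central
#' point; negative toward the left edge). Smoothing weights (deriv 0) sum
#' to 1; derivative weights sum to 0. Weights are in channel-index units;
#' callers divide by spacing^deriv_order for physical-axis derivatives.
#'
#' @param window odd integer >= 3.
#' @param poly_order polynomial degree, < window.
#' @param deriv_order derivative order, <= poly_order.
#' @param position integer offset within the window, in [-h, h] with
#'   h = (window - 1) / 2.
#' @return numeric weight vector of length `window`.
#' @export
savgol_coefficients <- function(window, poly_order = 2L, deriv_order = 0L,
                                position = 0L) {
  check_sg_params(window, poly_order, deriv_order)
  h <- (window - 1L) %/% 2L
  if (abs(position) > h)
    stop("parameter error: position ", position, " outside window half-width ", h)
  z <- -h:h
  V <- outer(z, 0:poly_order, `^`)           # window x (poly_order+1)
  pinv <- solve(crossprod(V), t(V))          # maps values -> poly coefficients
  k <- 0:poly_order
  # d-th derivative of sum a_k t^k at t = position
  ev <- ifelse(k < deriv_order, 0,
               factorial(k) / factorial(pmax(k - deriv_order, 0)) *
                 position^pmax(k - deriv_order, 0))
  ev[k == deriv_order] <- factorial(deriv_order)  # handles position = 0 (0^0)
  as.numeric(ev %*% pinv)
}

check_sg_params <- function(window, poly_order, deriv_order) {
  if (window < 3 || window %% 2 != 1)
    stop("parameter error: SG window must be an odd integer >= 3 (got ", window, ")")
  if (poly_order < 0 || poly_order >= window)
    stop("parameter error: SG polynomial order must satisfy 0 <= poly_order < window")
  if (deriv_order < 0 || deriv_order > poly_order)
    stop("parameter error: SG derivative order must satisfy 0 <= deriv_order <= poly_order")
  invisible(TRUE)
}

#' Apply a Savitzky-Golay filter to spectra
#'
#' Interior channels use the central coefficients; the (window-1)/2 channels
#' at each edge use asymmetric-position coefficients from the nearest full
#' window (fit the first/last window, evaluate at the edge offsets), so the
#' output keeps all p channels and variable indices stay stable. Derivative
#' outputs are divided by spacing^deriv_order.
#'
#' @param X numeric matrix, n x p with p >= window.
#' @param window,poly_order,deriv_order filter parameters (see
#'   [savgol_coefficients()]).
#' @param spacing physical channel spacing (> 0) used to scale derivatives.
#' @return filtered matrix, same shape as `X`.
#' @export
apply_savgol <- function(X, window, poly_order = 2L, deriv_order = 0L,
                         spacing = 1) {
  X <- as.matrix(X)
  p <- ncol(X)
  check_sg_params(window, poly_order, deriv_order)
  if (p < window)
    stop("size error: ", p, " channels < SG window ", window)
  if (spacing <= 0) stop("parameter error: spacing must be > 0")
  h <- (window - 1L) %/% 2L
  # p x p linear operator: banded central part + asymmetric edge rows
  L <- matrix(0, p, p)
  central <- savgol_coefficients(window, poly_order, deriv_order, 0L)
  for (j in seq.int(h + 1L, p - h)) L[j, (j - h):(j + h)] <- central
  for (e in seq_len(h)) {
    L[e, 1:window] <- savgol_coefficients(window, poly_order, deriv_order, e - h - 1L)
    L[p - e + 1L, (p - window + 1L):p] <-
      savgol_coefficients(window, poly_order, deriv_order, h - e + 1L)
  }
  (X %*% t(L)) / spacing^deriv_order
}

# ---- pretreatment chains ---------------------------------------------------

#' Parse a pretreatment label into a pretreatment chain
#'
#' Labels are the canonical configuration vocabulary: `"raw"` (identity),
#' `"SNV"`, `"SG(w)"` (smoothing), `"1D+SG(w)"` / `"2D+SG(w)"` (derivative
#' fused with its SG window into a single filter pass), composed
#' left-to-right with `"+"`, e.g. `"1D+SG(9)+SNV"`. A bare derivative
#' without an SG window is not representable: derivatives are always
#' realized through a Savitzky-Golay filter.
#'
#' @param label pretreatment label string.
#' @param poly_order polynomial degree used by every SG step (default 2, the
#'   conventional chemometrics choice, which admits second derivatives).
#' @return an object of class `pretreatment_spec`: a list of steps plus the
#'   canonical label (a pure function of the steps).
#' @export
pretreatment <- function(label, poly_order = 2L) {
  label0 <- trimws(label)
  if (tolower(label0) %in% c("raw", "")) {
    return(new_pretreatment_spec(list()))
  }
  tokens <- strsplit(label0, "+", fixed = TRUE)[[1]]
  tokens <- trimws(tokens)
  steps <- list()
  i <- 1L
  while (i <= length(tokens)) {
    tok <- tokens[i]
    if (toupper(tok) == "SNV") {
      steps[[length(steps) + 1L]] <- list(kind = "SNV")
      i <- i + 1L
    } else if (grepl("^SG\\(\\d+\\)$", tok, ignore.case = TRUE)) {
      w <- as.integer(sub("^SG\\((\\d+)\\)$", "\\1", tok, ignore.case = TRUE))
      check_sg_params(w, poly_order, 0L)
      steps[[length(steps) + 1L]] <- list(kind = "SG", window = w,
                                          poly_order = as.integer(poly_order),
                                          deriv_order = 0L)
      i <- i + 1L
    } else if (grepl("^[12]D$", tok, ignore.case = TRUE)) {
      d <- as.integer(substr(tok, 1, 1))
      if (i == length(tokens) ||
          !grepl("^SG\\(\\d+\\)$", tokens[i + 1L], ignore.case = TRUE))
        stop("bad pretreatment label '", label,
             "': derivative '", tok, "' must be followed by its SG window, e.g. '",
             tok, "+SG(9)'")
      w <- as.integer(sub("^SG\\((\\d+)\\)$", "\\1", tokens[i + 1L],
                          ignore.case = TRUE))
      check_sg_params(w, poly_order, d)
      steps[[length(steps) + 1L]] <- list(kind = "SG", window = w,
                                          poly_order = as.integer(poly_order),
                                          deriv_order = d)
      i <- i + 2L
    } else {
      stop("bad pretreatment label '", label, "': unknown token '", tok, "'")
    }
  }
  new_pretreatment_spec(steps)
}

new_pretreatment_spec <- function(steps) {
  lab <- if (length(steps) == 0) "raw" else
    paste(vapply(steps, function(s) {
      if (s$kind == "SNV") return("SNV")
      if (s$deriv_order > 0)
        sprintf("%dD+SG(%d)", s$deriv_order, s$window)
      else
        sprintf("SG(%d)", s$window)
    }, character(1)), collapse = "+")
  structure(list(steps = steps, label = lab), class = "pretreatment_spec")
}

#' @export
print.pretreatment_spec <- function(x, ...) {
  cat("pretreatment_spec: ", x$label, " (", length(x$steps), " step",
      if (length(x$steps) != 1) "s", ")\n", sep = "")
  invisible(x)
}

#' Apply a pretreatment chain to spectra
#'
#' Steps are applied left-to-right; the empty chain is the identity. The
#' matrix shape is always preserved. Order matters: SNV before a derivative
#' is not the same transform as a derivative before SNV.
#'
#' @param X numeric matrix, n x p.
#' @param spec a `pretreatment_spec` or a label string accepted by
#'   [pretreatment()].
#' @param spacing physical channel spacing for derivative scaling (the
#'   median absolute axis spacing of the dataset).
#' @return transformed matrix, same shape.
#' @export
apply_pretreatment <- function(X, spec, spacing = 1) {
  if (is.character(spec)) spec <- pretreatment(spec)
  stopifnot(inherits(spec, "pretreatment_spec"))
  X <- as.matrix(X)
  for (s in spec$steps) {
    X <- if (s$kind == "SNV") snv(X)
         else apply_savgol(X, s$window, s$poly_order, s$deriv_order, spacing)
  }
  X
}

#' Default pretreatment menu for trajectory grids
#'
#' The union of methods used across the three NIR applications this package
#' targets: raw spectra, SNV, 9-point Savitzky-Golay smoothing, first and
#' second derivatives fused with SG(9), and the 1D+SG(9)+SNV combination.
#'
#' @return character vector of pretreatment labels.
#' @export
default_pretreatments <- function() {
  c("raw", "SNV", "SG(9)", "1D+SG(9)", "2D+SG(9)", "1D+SG(9)+SNV")
}
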