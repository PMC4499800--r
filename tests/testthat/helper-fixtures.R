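# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code; no binary files ship with the package.

# Small deterministic dataset: linear Beer-Lambert spectra on a uniform axis.
tiny_dataset <- function(n = 6, p = 12, seed = 42) {
  set.seed(seed)
  axis <- seq(1100, by = 2, length.out = p)
  X <- matrix(rnorm(n * p, mean = 1, sd = 0.2), n, p)
  spectra_dataset(X, y = runif(n, 9, 11), axis = axis)
}

# Brute-force Kennard-Stone verifier: checks that `sel` obeys the maximin
# rule (with lowest-index tie-breaks) at every step, recomputing the full
# distance matrix independently of the implementation.
ks_oracle_check <- function(X, sel) {
  D <- as.matrix(dist(X))
  n <- nrow(X)
  # step 1-2: maximal pair, lexicographically smallest, lower index first
  maxd <- max(D)
  pairs <- which(D == maxd & upper.tri(D), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  if (!identical(as.integer(sel[1:2]),
                 as.integer(c(pairs[1, 1], pairs[1, 2])))) return(FALSE)
  if (length(sel) < 3) return(TRUE)
  for (s in 3:length(sel)) {
    chosen <- sel[seq_len(s - 1)]
    remaining <- setdiff(seq_len(n), chosen)
    mind <- vapply(remaining, function(i) min(D[i, chosen]), numeric(1))
    best <- remaining[mind == max(mind)]
    if (sel[s] != min(best)) return(FALSE)
  }
  TRUE
}

# Brute-force Savitzky-Golay weights via lm(): fit the polynomial to each
# unit impulse over the window and differentiate the fitted coefficients.
sg_oracle <- function(window, poly_order, deriv_order, position = 0) {
  h <- (window - 1) / 2
  z <- -h:h
  sapply(seq_len(window), function(j) {
    e <- numeric(window); e[j] <- 1
    fit <- lm(e ~ poly(z, degree = poly_order, raw = TRUE))
    a <- coef(fit)
    a[is.na(a)] <- 0
    k <- 0:poly_order
    dcoef <- ifelse(k >= deriv_order,
                    a * factorial(k) / factorial(pmax(k - deriv_order, 0)),
                    0)
    sum(dcoef[k >= deriv_order] * position^(k[k >= deriv_order] - deriv_order))
  })
}

# Direct-formula VIP oracle from the stored model matrices.
vip_oracle <- function(model) {
  p <- nrow(model$W)
  A <- model$A
  ss <- numeric(A)
  for (a in seq_len(A)) ss[a] <- model$q[a]^2 * sum(model$T[, a]^2)
  out <- numeric(p)
  for (j in seq_len(p)) {
    acc <- 0
    for (a in seq_len(A)) {
      wnorm <- sqrt(sum(model$W[, a]^2))
      acc <- acc + ss[a] * (model$W[j, a] / wnorm)^2
    }
    out[j] <- sqrt(p * acc / sum(ss))
  }
  out
}

# Minimal MAT v5 writer (little-endian, double matrices only), used to
# build fixtures for the reader without shipping binary files.
write_mat5_fixture <- function(path, vars, compress = FALSE) {
  pad8 <- function(r) c(r, rep(as.raw(0), (8 - length(r) %% 8) %% 8))
  int32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                endian = "little")
  element <- function(type, payload) {
    c(int32(type), int32(length(payload)), pad8(payload))
  }
  matrix_element <- function(name, m) {
    m <- as.matrix(m)
    flags <- c(int32(6), int32(0))        # class 6 = mxDOUBLE_CLASS
    dims <- c(int32(nrow(m)), int32(ncol(m)))
    body <- c(element(6, flags),
              element(5, dims),
              element(1, charToRaw(name)),
              element(9, writeBin(as.numeric(m), raw(), size = 8,
                                  endian = "little")))
    el <- c(int32(14), int32(length(body)), body)
    if (compress) {
      z <- memCompress(el, type = "gzip")
      el <- c(int32(15), int32(length(z)), pad8(z))
    }
    el
  }
  txt <- charToRaw("MATLAB 5.0 MAT-file, plstraj test fixture")
  header <- c(txt, rep(as.raw(0x20), 116 - length(txt)),
              rep(as.raw(0), 8),
              as.raw(c(0x00, 0x01)),      # version 0x0100, little-endian
              charToRaw("IM"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  for (nm in names(vars)) writeBin(matrix_element(nm, vars[[nm]]), con)
  invisible(path)
}

# Noise-free rank-1 dataset: y exactly linear in a single spectral
# component, so a 1-factor PLS should interpolate.
rank1_dataset <- function(n = 12, p = 40, seed = 7) {
  set.seed(seed)
  axis <- seq(1100, by = 2, length.out = p)
  eps <- 0.1 * exp(-(axis - median(axis))^2 / (2 * (diff(range(axis)) / 6)^2))
  conc <- runif(n, 9, 11)
  spectra_dataset(conc %o% eps, y = conc, axis = axis)
}
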