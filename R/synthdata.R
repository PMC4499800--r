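#' Specification for a synthetic NIR-like dataset
#'
#' Describes a generative model with known ground truth that reproduces the
#' artifact classes of diffuse-reflectance NIR spectra: overlapping Gaussian
#' absorption bands, Beer-Lambert linear mixing of constituent
#' concentrations, polynomial baseline drift, multiplicative scatter from
#' particle-size variation, per-sample additive offsets, and white noise.
#'
#' Per sample i the spectrum is
#' \deqn{x_i(\lambda) = m_i \sum_k c_{ik}\,\varepsilon_k(\lambda)
#'   + (a + b\lambda + c\lambda^2) + o_i + d_i(\lambda - \bar\lambda)
#'   + e_i(\lambda)}
#' with pure-constituent spectra \eqn{\varepsilon_k} sums of Gaussian bands,
#' concentrations drawn uniformly from each constituent's range,
#' \eqn{m_i \sim N(1, scatter\_sd)}, a per-sample additive drift consisting
#' of an offset \eqn{o_i \sim N(0, offset\_sd)} and a tilt with slope
#' \eqn{d_i \sim N(0, drift\_sd)} about the axis midpoint, and channel noise
#' \eqn{e_i \sim N(0, noise\_sd)}. The fixed polynomial baseline models the
#' instrument's mean background; the per-sample offset and tilt model the
#' drift that changes between measurements. The reference value is the
#' target constituent's concentration (%, w/w).
#'
#' @param axis_start,axis_step,axis_count uniform spectral grid (default:
#'   the 700-channel 1100-2498 nm grid typical of benchtop NIR instruments).
#' @param constituents list of constituents, each
#'   `list(bands = list(c(center, width, amplitude), ...), range = c(lo, hi))`
#'   with concentrations in %, w/w. The default models a moisture-like
#'   minor target (O-H bands near 1190, 1450, 1940 nm; 9.38-10.98%) inside
#'   a matrix of two major constituents with strongly overlapping bands.
#' @param baseline `c(intercept, slope, curvature)` coefficients of a fixed
#'   polynomial baseline in the axis variable.
#' @param scatter_sd SD of the multiplicative scatter factor around 1.
#' @param offset_sd SD of the per-sample additive offset.
#' @param drift_sd SD of the per-sample linear drift slope (absorbance per
#'   axis unit, applied about the axis midpoint).
#' @param noise_sd SD of additive white noise per channel (absorbance units).
#' @param target_constituent index of the constituent reported as y.
#' @param seed integer seed making generation reproducible.
#' @param axis_unit "nm" or "cm-1".
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(axis_start = 1100, axis_step = 2, axis_count = 700L,
                           constituents = default_constituents(),
                           baseline = c(0.30, 4e-4, 0),
                           scatter_sd = 0.15, offset_sd = 0.30,
                           drift_sd = 1.5e-3, noise_sd = 0.001,
                           target_constituent = 1L, seed = 1L,
                           axis_unit = c("nm", "cm-1")) {
  axis_unit <- match.arg(axis_unit)
  spec <- structure(list(axis_start = axis_start, axis_step = axis_step,
                         axis_count = as.integer(axis_count),
                         constituents = constituents, baseline = baseline,
                         scatter_sd = scatter_sd, offset_sd = offset_sd,
                         drift_sd = drift_sd, noise_sd = noise_sd,
                         target_constituent = as.integer(target_constituent),
                         seed = as.integer(seed), axis_unit = axis_unit),
                    class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

#' Default constituent set for synthetic fixtures
#'
#' A moisture-like target (the reference analyte, 9.38-10.98% - the corn
#' water range) with O-H bands near 1190, 1450 and 1940 nm, inside a matrix
#' of two tightly regulated major constituents (closure: a real product's
#' composition sums to ~100%, so the matrix co-varies narrowly) and one
#' wide-swing unmodeled interferent whose broad bands sit directly on the
#' water bands - the severe-overlap regime of complex natural-product
#' matrices, where no analyte channel is free of interference.
#'
#' @return list of constituent descriptions for [synthetic_spec()].
#' @export
default_constituents <- function() {
  list(
    water = list(bands = list(c(1190, 35, 0.030),
                              c(1450, 40, 0.090),
                              c(1940, 45, 0.120)),
                 range = c(9.38, 10.98)),
    starch = list(bands = list(c(1210, 80, 0.004),
                               c(1470, 90, 0.005),
                               c(1580, 70, 0.004),
                               c(1920, 100, 0.006),
                               c(2100, 80, 0.007)),
                  range = c(61.2, 62.6)),
    protein = list(bands = list(c(1510, 60, 0.020),
                                c(1690, 55, 0.016),
                                c(1980, 70, 0.022),
                                c(2180, 50, 0.018)),
                   range = c(9.0, 10.0)),
    interferent = list(bands = list(c(1450, 100, 0.008),
                                    c(1650, 90, 0.006),
                                    c(1940, 110, 0.008)),
                       range = c(5, 50)))
}

validate_synthetic_spec <- function(spec) {
  if (spec$axis_count < 1 || spec$axis_step == 0)
    stop("parameter error: invalid axis grid")
  if (length(spec$constituents) < 1)
    stop("parameter error: need at least one constituent")
  for (k in seq_along(spec$constituents)) {
    con <- spec$constituents[[k]]
    for (bd in con$bands)
      if (length(bd) != 3 || bd[2] < 0 || bd[3] < 0)
        stop("parameter error: each band is c(center, width >= 0, amplitude >= 0)")
    if (length(con$range) != 2 || diff(con$range) <= 0)
      stop("parameter error: constituent ", k, " has a degenerate concentration range")
  }
  if (spec$scatter_sd < 0 || spec$offset_sd < 0 || spec$drift_sd < 0 ||
      spec$noise_sd < 0)
    stop("parameter error: scatter/offset/drift/noise SDs must be >= 0")
  if (spec$target_constituent < 1 ||
      spec$target_constituent > length(spec$constituents))
    stop("parameter error: target_constituent out of range")
  invisible(spec)
}

# Pure-constituent spectra: p x K matrix of epsilon_k(lambda).
pure_spectra <- function(spec) {
  axis <- spec$axis_start + spec$axis_step * (seq_len(spec$axis_count) - 1)
  E <- vapply(spec$constituents, function(con) {
    e <- numeric(length(axis))
    for (bd in con$bands)
      e <- e + bd[3] * exp(-(axis - bd[1])^2 / (2 * bd[2]^2))
    e
  }, numeric(length(axis)))
  list(axis = axis, E = as.matrix(E))
}

#' Generate a synthetic spectral dataset
#'
#' Draws `n` samples from the generative model of a [synthetic_spec()].
#' Fully reproducible: the spec's seed drives all randomness and the global
#' RNG state is restored on exit.
#'
#' @param spec a `synthetic_spec`.
#' @param n number of samples (>= 1).
#' @return a `spectra_dataset` whose `y` is the target constituent's
#'   concentration. The true concentration matrix is attached as attribute
#'   `"concentrations"` (n x K) for ground-truth checks.
#' @export
generate_spectra <- function(spec, n) {
  validate_synthetic_spec(spec)
  if (n < 1) stop("parameter error: n must be >= 1")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  ps <- pure_spectra(spec)
  K <- ncol(ps$E); p <- length(ps$axis)
  C <- vapply(spec$constituents, function(con)
    stats::runif(n, con$range[1], con$range[2]), numeric(n))
  C <- matrix(C, nrow = n)
  m <- stats::rnorm(n, 1, spec$scatter_sd)
  o <- stats::rnorm(n, 0, spec$offset_sd)
  d <- stats::rnorm(n, 0, spec$drift_sd)
  bl <- spec$baseline[1] + spec$baseline[2] * ps$axis +
    spec$baseline[3] * ps$axis^2
  X <- (C %*% t(ps$E)) * m                       # Beer-Lambert mix, scattered
  X <- X + matrix(bl, n, p, byrow = TRUE) + o +
    d %o% (ps$axis - mean(ps$axis))              # per-sample drift: offset + tilt
  if (spec$noise_sd > 0)
    X <- X + matrix(stats::rnorm(n * p, 0, spec$noise_sd), n, p)
  ds <- spectra_dataset(X, C[, spec$target_constituent], ps$axis,
                        axis_unit = spec$axis_unit)
  attr(ds, "concentrations") <- C
  ds
}
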