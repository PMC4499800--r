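---
title: "Processing-trajectory optimization of NIR calibration models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing-trajectory optimization of NIR calibration models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plstraj)
```

## The problem

A quantitative NIR calibration predicts an analyte's content (%, w/w) from
an absorbance spectrum via partial least squares (PLS). Three modeling
choices dominate the quality of such a model: the spectral pretreatment,
the number of latent factors A, and whether (and how) uninformative
wavelength channels are discarded. These choices interact — the best factor
count under one pretreatment is rarely the best under another, and variable
selection changes both — yet they are conventionally optimized one at a
time. `plstraj` instead evaluates the complete grid of
(pretreatment, A, variable-selection) combinations, records the full metric
panel for every path, and picks the best path by RPD. The conventional
sequential optimizer is retained as a comparator; since its result is by
construction one of the grid's paths, the exhaustive search can never do
worse.

## The model and its assumptions

PLS1 is fit by NIPALS on mean-centered data, without per-channel variance
scaling — absorbance channels share units, and autoscaling would inflate
noise channels. Per factor $a$, with $X_a$, $y_a$ the deflated data:

$$ w_a \propto X_a^\top y_a,\quad \|w_a\| = 1,\quad t_a = X_a w_a,\quad
   p_a = \frac{X_a^\top t_a}{t_a^\top t_a},\quad
   q_a = \frac{y_a^\top t_a}{t_a^\top t_a}, $$

followed by deflation $X_{a+1} = X_a - t_a p_a^\top$,
$y_{a+1} = y_a - q_a t_a$. The regression vector in centered form is
$b = W (P^\top W)^{-1} q$. For a single response the weight vector is
available in closed form, so no inner iteration is needed. Scores are
mutually orthogonal by construction; the tests verify this to 1e-8
relative, and verify that at full rank the PLS predictions coincide with
the pseudoinverse least-squares solution (1e-6 relative over 20 random
instances).

Variable importance in projection uses the standard formulation

$$ \mathrm{VIP}_j = \sqrt{ p \, \frac{\sum_a SS_a \, w_{aj}^2}{\sum_a SS_a} },
   \qquad SS_a = q_a^2 \, t_a^\top t_a, $$

whose squared scores average to one, making the conventional
"keep channels with VIP > 1" rule scale-free. Each VIP path fits a
full-channel model at the path's A, scores VIP at that same A, selects,
and refits on the surviving channels. Selection is single-pass; iterating
select–refit–reselect is a known variant but is not what a "VIP with
different latent factors" grid calls for, and it would multiply the grid
cost without changing the search structure.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| pretreatment menu | raw, SNV, SG(9), 1D+SG(9), 2D+SG(9), 1D+SG(9)+SNV | canonical labels |
| A (latent factors) | 1..10 | grid upper bound avoids overfitting |
| variable selection | full, VIP | VIP threshold 1.0 |
| SG polynomial order | 2 | quadratic; admits second derivatives |
| calibration fraction | 2/3 | 2:1 Kennard–Stone split |
| CV folds | 10 | venetian blind (deterministic) |

The SG polynomial order is fixed at 2 because it is the conventional
chemometrics default for 9-point windows; orders above 3 with small
windows reproduce noise. Derivative labels ("1D", "2D") are always fused
with their SG window into a single least-squares derivative filter —
a bare finite-difference derivative without smoothing is deliberately not
representable, since it is never advisable on real spectra.

## Numerical choices

- **SG edge handling.** The (window−1)/2 channels at each end are filtered
  with asymmetric-position coefficients from the nearest full window (fit
  the first/last window's polynomial, evaluate its derivative at the edge
  offsets). This keeps all p channels, so channel indices remain stable
  for VIP bookkeeping across pretreatments. Polynomials up to the filter
  order are reproduced exactly at every channel, edges included (verified
  to 1e-9).
- **Derivative spacing.** Derivatives are divided by spacing^order using
  the median absolute axis spacing; axes non-uniform beyond 1% relative
  are rejected at load, because polynomial convolution filters assume a
  uniform grid.
- **Kennard–Stone ties.** Equal distances are resolved toward the lowest
  original index (and the lexicographically smallest pair for the seed
  pair), making the split a pure function of the data. The split runs on
  raw, uncentered spectra: one split serves every pretreatment path, so
  the path comparison is not confounded by path-dependent sample sets.
- **Cross-validation folds.** Venetian-blind assignment (sample i to fold
  i mod k in calibration order) rather than random folds; RMSECV is then
  deterministic, and two runs of the same configuration produce
  byte-identical reports.
- **RMSE denominators.** Plain n for RMSEC, RMSECV, and RMSEP alike; no
  degrees-of-freedom correction, the dominant chemometrics convention.
- **RPD orientation.** RPD = SD(validation reference values)/RMSEP with the
  n−1 SD. Although "ratio of SEP to SD" phrasing circulates, useful models
  must have RPD > 1, which fixes the orientation; SEP is identified with
  RMSEP (no bias correction). Bands: < 2.5 inadequate, [2.5, 3] fair,
  (3, 4] good, > 4 excellent.
- **Degenerate inputs.** Constant spectra are rejected by SNV with the
  offending sample named; a residual response exhausted before the
  requested factor count raises a rank error naming the achievable
  maximum, except inside path evaluation and CV folds, where the factor
  count is clipped to the achievable rank and the effective A is recorded
  — a grid must tolerate infeasible corners without dying. A numerically
  perfect validation fit (RMSEP = 0) is reported as the RPD → Inf limit.
- **Best-path ties.** Max RPD, then smaller RMSEP, then fewer factors,
  then earlier pretreatment in menu order, then full variables before
  VIP. Every run of the same inputs selects the same path.

## What the synthetic generator emulates

`synthetic_spec()` draws Beer–Lambert mixtures: per sample,
$x(\lambda) = m \sum_k c_k \varepsilon_k(\lambda) + \mathrm{baseline}
(\lambda) + o + d(\lambda - \bar\lambda) + e(\lambda)$, with Gaussian-band
pure spectra, uniform concentrations, multiplicative scatter
$m \sim N(1, 0.15)$, a per-sample additive drift made of an offset
$o \sim N(0, 0.3)$ and a tilt of slope $d \sim N(0, 1.5\times10^{-3})$
absorbance per nm, and white channel noise of SD 0.001 (0.1% of the ~1 AU
peak absorbance). The per-sample tilt is part of the drift model by
design: a fixed baseline polynomial disappears under mean-centering and a
constant offset is a rank-1 nuisance that costs one latent factor, so
only drift that varies in shape between samples actually exercises
derivative pretreatment.

The default constituent set mirrors a moisture calibration in a
grain-like matrix: the target spans 9.38–10.98% with O–H bands near 1190,
1450 and 1940 nm on a 700-channel 1100–2498 nm axis; two major matrix
constituents are tightly constrained (closure — a real product's
composition sums to about 100%); and one broad-band interferent with a
wide concentration swing (5–50) sits directly on both main water bands,
emulating the severe spectral overlap of complex natural-product
matrices. These conditions were chosen once, from the mechanism of each
pretreatment, and make the grid search genuinely discriminating:

- the per-sample drift corrupts SNV's normalization scale at first order,
  so SNV-only paths degrade;
- the product of scatter with the wide-swing interferent is a bilinear
  artifact that no additive linear model can absorb, so paths without SNV
  degrade;
- the broad overlap denies raw-spectrum VIP any interference-free analyte
  channel;
- the 1D+SG(9)+SNV chain removes offset and tilt exactly (derivative),
  then scatter exactly (normalization of a purely multiplicative row),
  which is why a derivative-containing path is the mechanistically
  correct winner.

What the generator does **not** emulate: wavelength-dependent scatter
(the MSC regime), instrument line-shape convolution, detector
nonlinearity, wavelength misregistration between instruments, and
reference-assay error in y. Passing the end-to-end recovery test
therefore demonstrates that the search machinery ranks pretreatments
according to the artifacts present — not that any particular pretreatment
is best for a given real instrument.

## Problem sizes

The study dataset is 60 samples × 700 channels, split 40/20 by
Kennard–Stone, searched over the default 120-path grid with 10-fold
cross-validation per path — small enough to run in seconds, large enough
that calibration and validation statistics are meaningfully different.
Unit fixtures are smaller (tens of samples, tens of channels) and built
in code by the test helpers.

## Known limitations

- Exhaustive search scales as the product of the grids; with the default
  menu this is 120 fits plus 1200 cross-validation fits, which is cheap,
  but user-supplied menus multiply quickly.
- RPD on a 20-sample validation set has substantial sampling noise; paths
  within a few percent of each other are statistically interchangeable,
  and the tie chain (not the science) decides among them.
- The stepwise comparator implements one specific sequential protocol
  (pretreatment by min-over-A RMSECV, then A by RMSECV, then VIP kept if
  RMSEP improves). Other sequential protocols exist; all are members of
  the same grid and therefore also dominated by the exhaustive search.
- The MAT v5 reader covers plain (optionally zlib-compressed) numeric
  arrays — sufficient for the public benchmark containers, nothing more.
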