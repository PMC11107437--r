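---
title: "Methods: correlating per-cell RNAscope signal with Fura-2 calcium responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlating per-cell RNAscope signal with Fura-2 calcium responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

Whether an mRNA signal predicts a functional ion channel is an empirical
question, and for TRPA1 — a chemosensory cation channel of nociceptive
sensory neurons for which no well-validated antibody exists — it has to be
answered cell by cell. The design this package supports couples two
measurements made on the *same* cultured DRG neurons:

1. **Functional response.** Fura-2 ratiometric calcium imaging during
   sequential agonist applications (AITC 100 µM / 60 s for TRPA1,
   capsaicin 1 µM / 30 s for TRPV1, and a KCl 60 mM / 15 s depolarization
   at the end as a viability control). The response metric is the
   baseline-corrected area under the F340/F385 ratio curve (AUC) over the
   60 s following each application start.
2. **Transcript signal.** RNAscope single-molecule in situ hybridization
   performed immediately after imaging, quantified per cell from confocal
   Z-stacks as the background-subtracted mean of the average-intensity
   projection over the cell's ROI.

The two imaging rounds live in different coordinate frames; a similarity
transform (rotation, translation, isotropic scale) estimated from the
transmitted-light images aligns them, and the functional ROIs are
propagated into the confocal frame. Each modality gets a *mean + 2 SD*
positivity threshold; cells above threshold on *either* modality form the
union set, on which the Pearson product-moment correlation between mRNA
signal and AUC is computed.

## Functional quantification

The per-pixel ratio is `(F340 − bg340) / (F385 − bg385)`, with the
background subtracted before forming the ratio; pixels whose
background-subtracted denominator is non-positive are invalid and excluded
from ROI means. The background estimator is the mode of the off-ROI
pixels (configurable override), which is robust against the minority of
bright cell-free debris pixels.

Baseline is the mean over 5 s ending 3 s before the application, taken as
the half-open interval `[start − 8 s, start − 3 s)`, which holds exactly
five samples on the 1 Hz grid. The AUC is the trapezoidal integral of
`ratio − baseline` over `[start, start + 60 s]`. Trapezoid on the native
grid was chosen because nothing finer is observed; at 1 Hz it is
essentially indistinguishable from the rectangle rule, and the same rule
is used in the amplitude calibration of the synthetic generator, so
generator and analysis agree by construction. Negative AUCs are retained:
clipping would bias the Gaussian non-responder fit below.

The AUC window stays 60 s for every agonist, including the 30 s capsaicin
application — the window is anchored to the application start, not its
end. The KCl gate passes a cell when the peak baseline-corrected ratio in
the application window (extended by 10 s, since depolarization peaks can
trail the application) reaches `min_delta`, default 0.1 ratio units. The
gate cut-off is not dictated by the analysis design; 0.1 is roughly five
times the default trace noise and well below the typical depolarization
response, and it is exposed as a parameter.

## The response thresholds

**RNAscope.** The threshold is `mean + 2 SD` of the per-cell intensities
measured with the intra-day negative-control probe (bacterial DapB), with
the sample SD (n − 1 denominator; control sets are small). It follows
that about 2.3% of truly negative cells will exceed the threshold — that
is the price of a 2 SD rule and is visible in the package's own
false-positive tests.

**Functional.** A Gaussian is fitted to the AUCs of cells without a
response and `mean + 2 SD` is the response threshold. This definition is
circular — non-responders are defined by the threshold being fitted — and
the package resolves it with an iterative trimmed fit: fit, exclude
values above `mean + 2 SD`, refit, repeat until the excluded set is
stable (or 50 iterations, reported as non-convergence with the final
state). One subtlety matters: naively recomputing the sample mean and SD
of the kept values converges to a *biased* fixed point near
`mu + 1.72 sigma` even on purely Gaussian input, because the kept sample
is upper-truncated. Each refit therefore inverts the truncated-normal
moment equations at the known cut (a maximum-likelihood-consistent
correction), which makes the estimator consistent for `mu + 2 sigma`: on
pure `N(mu, sigma^2)` samples of 10,000 cells the threshold lands within
`±0.1 sigma` of `mu + 2 sigma` and the induced false-positive rate is the
one-sided 2 SD tail (~2.3%). The fit is deterministic and binning-free
(no histogram).

Positivity is strict (`> threshold`): a value exactly at threshold is
negative, following the "above-threshold" wording of the rule.

## Registration

The transform class is a similarity (rotation + translation + isotropic
scale): that is exactly the parameter set recorded and propagated between
channels, even where the alignment is loosely called "rigid". Two
estimators are provided:

* **Landmark mode** — the computational analog of manual alignment: an
  operator marks paired cells in both transmission images and the
  transform is the closed-form least-squares similarity fit (complex
  regression, the 2-D Procrustes solution without reflection). Exact
  landmark pairs are recovered to machine precision; the synthetic
  generator emits landmark pairs with 0.3 px "click" jitter.
* **Intensity mode** — a coarse grid over rotation (±15°, 3° steps) and
  scale (0.9–1.1, 0.05 steps), recovering the translation for each
  candidate by FFT cross-correlation, followed by Nelder-Mead refinement
  of all four parameters on the normalized cross-correlation. A final NCC
  below a configurable floor flags the result as low-confidence. On
  textured cell fields at SNR 5 the estimator recovers transforms in the
  search range within 0.2°, 0.5 px and 0.005 scale.

Coordinates are 0-based with pixel centers at integer positions, origin
top-left, x rightward, y downward. Images are resampled by inverse
mapping with bilinear interpolation; out-of-frame pixels are marked
invalid (`NA`) and excluded from ROI statistics rather than filled. ROI
labels are propagated by nearest-neighbor lookup under the forward
transform; ROIs with no pixel inside the confocal field are dropped and
reported.

## Correlation scale

`run_correlation()` computes the Pearson correlation between RNAscope
intensity and AUC over the union set. By default the intensity enters
through an `asinh` transform: per-cell mRNA abundance is approximately
lognormal over the expressing population, so a correlation on the raw
intensity scale is systematically attenuated relative to the
log-abundance correlation (by `sigma / sqrt(exp(sigma^2) − 1)` for
lognormal spread `sigma`); `asinh` behaves like `log` for clearly
positive signal but stays defined at and below zero, so union sets
containing functional-only cells (no mRNA signal, background-subtracted
intensities near or below zero) are handled without dropping cells. The
raw scale (`"identity"`) and a pure `log` are exposed as options. The
p-value uses the exact t-transform with n − 2 degrees of freedom; a
seeded permutation p-value is available as a robustness check.

## The synthetic generator

The generator exists so the full pipeline — pixels to Pearson R — can be
verified without any external dataset. It emulates:

* a field of cells on a jittered grid, a configurable fraction of which
  are KCl-responsive neurons (default 0.85); non-neuronal cells never
  respond to KCl and are excluded by the gate;
* Fura-2 ratio traces at 1 Hz: per-cell baseline `N(0.8, 0.05)`, response
  kernels with exponential rise (tau 3 s), plateau during the
  application, and exponential decay (tau 20 s) — the exact shape is
  immaterial because the AUC is the analysis currency, so each kernel's
  amplitude is calibrated so that its trapezoidal AUC on the acquisition
  grid equals the cell's true AUC exactly;
* a two-channel 16-bit movie: per-cell F385 levels around 2500 counts,
  backgrounds of 150/300 counts, Poisson photon noise on cell pixels and
  Gaussian read noise everywhere, integer counts so TIFF round-trips are
  lossless;
* confocal Z-stacks (21 planes) in a frame displaced by a configurable
  similarity transform (default 2°, (6, −4) px, scale 1.02 about the
  image center): per-cell RNAscope signal rendered as diffuse intensity
  proportional to expression — at 10x the dense perikaryal signal is
  unresolved, which is also why the per-cell statistic is an intensity,
  not a puncta count — plus per-cell autofluorescence `N(5, 1.5)` in
  every channel, a DAPI channel, and transmission images used for
  registration;
* intra-day negative-control intensities drawn from the same
  autofluorescence distribution, emulating control cells carrying no
  specific probe signal;
* separately, a sparse "neurite" spot-field renderer with known
  ground-truth positions for validating the Laplacian-of-Gaussian puncta
  detector.

**The correlation parameter.** Among expressing responders, per-cell
log-expression (lognormal, `meanlog = log 40`, `sdlog = 0.8`) and true
AUC (`N(25, 10)` ratio·s) are coupled through a Gaussian copula whose
latent pair is rotated to the *exact sample* correlation
`true_correlation` (an empirical-copula rotation). Enforcing the realized
rather than the population correlation is deliberate: recovery error in a
pipeline run then measures the measurement chain (photon noise, ROI
averaging, registration, thresholding), not the sampling noise of the
generator, which is what an end-to-end verification should isolate. At
`true_correlation = 1` with zero noise the generated log-expression and
AUC are exactly collinear.

**Default population structure.** By default `fraction_expressing = 1`
and the discordance rates are zero: every gated neuron belongs to the one
continuous co-expression population, and the union set coincides with the
population on which the correlation is defined. This is the reference
condition for correlation-recovery benchmarking; a hard zero-expression
point mass would make the ~2.3% of threshold-crossing false positives
high-leverage outliers in the union-set Pearson, and the correlation
parameter would no longer mean what it claims. The bimodal structure of
real sensory-neuron data is emulated explicitly instead:
`fraction_expressing < 1` adds a zero-expression population, and
`rate_rnascope_only` / `rate_functional_only` add discordant cells
(mRNA without function and function without mRNA). With discordance
configured, `true_correlation` applies to the doubly-positive population
— for functional-only cells log-expression does not exist, so a
union-wide definition would be ill-posed — and the union-set correlation
becomes an emergent quantity, as it is in real data.

**What the generator does not emulate.** No optics or PSF model, no
motion or bleaching, no bursty transcription, no spatial expression
gradients, no day-to-day batch structure. Passing the recovery tests
therefore shows the pipeline is faithful to its own model of the data; it
does not certify performance on real recordings with those artifacts.

## Problem sizes and numerical choices

The package's own verification runs use fields of 500 cells (about 345 ×
330 px at 14 px cell spacing) with the full 510 s schedule for
end-to-end correlation recovery (20 seeds), 144 × 144 px textured fields
for the 50-transform registration benchmark, lightweight (table-level)
datasets for the 150-replicate correlation-coverage sweep, and 10,000
samples for threshold calibration. These sizes were chosen so the whole
suite exercises every code path at meaningful statistical resolution
while staying convenient to run routinely.

Other numerical conventions: ties at the positivity threshold are
negative (strict inequality); ROI means ignore invalid pixels and error
only when a whole ROI is invalid; the trimmed threshold fit stops on a
stable kept set, returns `sd = 0` for all-identical input, and reports
non-convergence rather than failing; Fisher-z intervals use
`SE = 1/sqrt(n − 3)`; all seeds are explicit and every generator output
is bit-reproducible under its config.

## Known limitations

* The intensity-mode registration assumes the fields overlap
  substantially and share texture; it is not a mosaicking tool and will
  report low confidence on featureless fields.
* The per-cell RNAscope statistic is a mean intensity; integrated
  (area-weighted) signal is exposed as an option but the two are not
  interchangeable when ROI areas vary strongly.
* The trimmed Gaussian threshold assumes the non-responder AUC
  distribution is approximately Gaussian; on strongly skewed null
  distributions the threshold is still deterministic but no longer a
  2.3%-tail rule.
* Puncta counting is provided for neurite-level analysis only and is not
  used in the headline correlation.
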