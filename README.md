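# furascope

Per-cell correlation of RNAscope in situ hybridization signal with
Fura-2 calcium-imaging responses.

## The problem

Antibody-based detection of some ion channels — TRPA1 in nociceptive
sensory neurons being the canonical case — is unreliable, so transcript
detection by RNAscope is an attractive surrogate. But mRNA is itself only
a surrogate for a functional channel. The decisive experiment measures
both on the *same* cells: image cytosolic calcium responses to a
selective agonist (AITC for TRPA1, capsaicin for TRPV1) with the
ratiometric dye Fura-2, fix the culture immediately, perform RNAscope,
align the confocal images back onto the functional field of view, and ask
how well the per-cell mRNA signal and the per-cell functional response
correlate.

`furascope` implements that analysis end to end, for experimenters running
this kind of joint functional/transcript protocol and for methodologists
who want a fully synthetic, ground-truthed testbed for it:

* **Functional scoring** — background-subtracted F340/F385 ratio traces
  per ROI; baseline = mean over the 5 s ending 3 s before each
  application; response = trapezoidal AUC of `ratio − baseline` over the
  60 s after application start; KCl 60 mM depolarization at the end of
  the protocol gates viable neurons.
* **RNAscope scoring** — average-intensity projection of the confocal
  Z-stack, background-subtracted ROI mean per cell; optional
  Laplacian-of-Gaussian puncta detection for single molecules in
  neurites.
* **Registration** — similarity transform (rotation, translation,
  isotropic scale) from confocal to wide-field coordinates, by landmark
  least squares or automated intensity matching, propagated to all
  channels and to the ROIs.
* **Thresholds and classification** — RNAscope positivity at
  `mean + 2·SD` of intra-day negative controls; functional positivity at
  `mean + 2·SD` of a Gaussian fitted to non-responders by an iterative,
  truncation-corrected trimmed fit; every gated cell lands in one of four
  categories (both / RNAscope-only / functional-only / neither).
* **Statistics** — Pearson product-moment correlation R with t-based
  p-value on the union set (cells positive on *either* modality),
  `R` being computed per probe/agonist pairing.
* **Synthetic data** — a seeded generator that renders the whole
  experiment (16-bit movie pairs, confocal stacks, misaligned frames,
  negative controls, ground truth) with a configurable true correlation,
  so the pipeline is verifiable from pixels to R without any external
  dataset.

The statistic at the core is the union-set Pearson correlation

    R = cov(S, A) / (sd(S) · sd(A)),   over {cells: S > t_S or A > t_A}

with S the per-cell RNAscope signal, A the baseline-corrected AUC, and
`t_S`, `t_A` the two `mean + 2·SD` thresholds.

## Worked example

Generate a synthetic experiment with a true latent correlation of 0.43
between log mRNA expression and AUC, render the images, and run the full
analysis:

```r
library(furascope)

cfg    <- synth_config(n_cells = 300, true_correlation = 0.43, seed = 7)
ds     <- generate_dataset(cfg)
report <- analyze_dataset(ds)
```

which prints, via the snippets below:

```r
cc <- report$channels$TRPA1
sprintf("gated neurons: %d of %d cells", cc$counts$total, report$n_cells)
#> gated neurons: 255 of 300 cells
sprintf("RNAscope threshold: %.2f a.u.; functional threshold: %.2f ratio*s",
        report$rnascope_threshold, cc$functional_threshold)
#> RNAscope threshold: 8.12 a.u.; functional threshold: 43.91 ratio*s
sprintf("TRPA1 x AITC union n = %d: R = %.3f (p = %.2g)",
        cc$union_n, cc$correlation$r, cc$correlation$p_value)
#> TRPA1 x AITC union n = 255: R = 0.420 (p = 2.5e-12)
sprintf("estimated transform: %.2f deg, (%.2f, %.2f) px, scale %.4f",
        report$transform$rotation_deg, report$transform$dx_px,
        report$transform$dy_px, report$transform$scale)
#> estimated transform: 2.00 deg, (7.82, -11.66) px, scale 1.0213
```

Reading the output: 255 of 300 cells passed the KCl viability gate (the
generator plants 15% non-neuronal cells, which never depolarize). The
RNAscope threshold (8.12) is `mean + 2·SD` of the 30 intra-day negative
controls. The registration recovered the planted misalignment (2°,
scale 1.02) from eight landmark pairs with sub-pixel translation error.
The recovered union-set correlation, 0.420 on 255 cells, sits inside the
Fisher-z 95% interval of the generating value 0.43 at that n
(`fisher_ci(0.43, 255)` → [0.324, 0.525]). Because every gated neuron is
drawn from one continuous co-expression population under the default
configuration, the union is the whole gated population and the
functional threshold — fitted to what is in truth an all-responder AUC
distribution — is high and classifies most cells as RNAscope-only; set
`fraction_expressing < 1` and the discordance rates to emulate bimodal
populations.

A command-line front end wrapping the same functions lives at
`inst/cli/furascope.R` (`simulate`, `analyze`, `report` subcommands).

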