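---
title: "Models and methods behind svcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind svcycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(svcycle)
```

This vignette is the package's own account of its science: the forward
model the simulator implements, the analysis pipeline and its tunable
parameters, the statistical model, the numerical choices, and — most
importantly — what a green test does and does not establish.

## 1. The vesicle-cycle forward model

The simulator tracks reporter mass in four pools, as fractions of the total
reporter in a bouton:

* `R` — releasable vesicles (quenched),
* `s` — reporter on the surface (fluorescent),
* `i` — internalized, not yet re-acidified (fluorescent),
* `P` — re-acidified recycled vesicles awaiting re-pooling (quenched),

plus a fixed non-releasable reserve `1 - releasable_fraction` (quenched).
During an AP train, exocytosis drains the releasable pool at first order
(`dR/dt = -k_exo R`); endocytosis retrieves surface reporter at first order
at all times (`k_endo s`); internalized reporter re-acidifies with time
constant `tau_reacid` and matures back into the releasable pool with time
constant `tau_repool`.  Bafilomycin sets `tau_reacid` to infinity from its
addition time.  Fluorescence is

    f(t) = s + i + quench_ratio * (R + P + reserve),

jumping to 1 after NH4Cl.  Mass is conserved exactly (tested at 1e-9), and
first-order pool drain reproduces the two behaviors the analysis relies on:
a near-linear early rise (rate fits) and a plateau at the releasable
fraction under a depleting stimulus, identical across kinetic variants.

Why `tau_repool`: if re-acidified vesicles rejoined the releasable pool
instantly, recycled reporter would be re-released *within* a train, making
the first-train exocytosis exceed the Baf-train exocytosis and corrupting
the subtraction that defines the endocytosis trace.  Newly retrieved
vesicles are not release-competent for tens of seconds, so maturation is
slow relative to a 30 s train and fast relative to the ~5 min inter-train
recovery (default 60 s).  A corollary worth knowing: with `k_endo = 0` a
mass-conserving two-train world cannot refill its pool between trains, so
the "no endocytosis implies a null difference trace" check is run on two
fresh-pool single-train simulations instead.

### Default constants and why

| parameter | default | rationale |
|---|---|---|
| `k_exo` | 0.025 /s | a 30 s train releases ~53% of the pool (no visible plateau in a 300 AP train) while 1200 APs release ~95% (the depleting stimulus genuinely depletes); with `k_endo` below, measured exocytic rates are ~3x endocytic rates, the reported regime |
| `k_endo` | 0.028 /s | see above; acts on the (smaller) surface pool |
| `tau_reacid` | 4 s | canonical pHluorin re-acidification time constant |
| `tau_repool` | 60 s | slow vs train, fast vs inter-train interval |
| `releasable_fraction` | 0.3 | typical recycling-pool fraction |
| `quench_ratio` | 1/20 | the ~20-fold unquenching of pHluorin |

The absolute rate constants are simulator constructs: the source literature
reports normalized slopes, not rate constants, and states only the ~3x
exo/endo ratio and the depletion behavior; the defaults are calibrated once
to land in that regime and are not fitted to any dataset.

The Ca²⁺ branch is deliberately minimal: free concentration integrates a
constant influx during stimulation and clears exponentially; the sensor
reads it through a Hill function (default coefficient 2) and saturates
under ionomycin, which provides the normalization maximum.  It reproduces
saturation *qualitatively* (long trains approach the ionomycin ceiling;
20 AP responses stay in the near-linear regime); it does not model
facilitation, buffering, or the partial decay during sustained stimulation
seen in real boutons.

### Rendering and noise

Boutons are Gaussian spots (σ = 1.5 px, integrated intensity normalized to
1) with lognormal per-bouton amplitudes (median 10⁴ counts, log-SD 0.4) on
a flat background (50 counts), with Poisson shot noise and Gaussian read
noise (SD 3) — the standard CCD model.  Stage drift is whole-frame
integer-pixel translation, matching a re-alignment stage that does no
sub-pixel interpolation.  Not emulated: photobleaching (flag reserved),
focus drift, non-uniform illumination, overlapping neurites, or
auto-fluorescent debris.  A green segmentation test therefore establishes
correctness of the algorithm under the stated noise model, not robustness
to every real-world artifact.

## 2. The analysis pipeline

**Re-alignment.**  Per-frame integer shift vs the first pre-stimulation
frame, estimated by mean-subtracted FFT cross-correlation; shifts beyond
`max_shift` (default 5 px) are flagged and left unapplied; vacated pixels
take the frame median.  Tests check the estimator against an exhaustive
shift search.

**Response map.**  `F_baseline` is the per-pixel mean over pre-stimulation
frames; `F_peak` the per-pixel maximum of a 3-frame moving average over the
first-train window (the smoothing suppresses single-frame shot-noise
spikes); `dF = F_peak - F_baseline`.

**Segmentation.**  Binarize `dF >= threshold * max(F_baseline, floor)`,
4-connected components, drop components whose mean `dF / baseline` is below
`min_rel_df` (default 0.05 — the "responses below 5%" exclusion), dilate
each survivor by a 1 px disk with contested pixels going to the nearest
original component (ties to the lower label), then size-gate (default
4–150 px).  Both cuts are relative, so segmentation is invariant to a
global intensity scale (tested).  The `floor` (default: the image-median
baseline) is a robustness refinement: without it, shot-noise dips in dark
background pixels lower the local threshold bar and produce spurious
single-pixel components; the median floor scales with the image, preserving
scale invariance.  The same bouton map is used for both trains by
construction.  Defaults for the unquantified choices (connectivity,
dilation radius, gate bounds, smoothing window) are exposed in the config
and logged with every run; the pixel threshold is shared across conditions
within an experiment and its cross-experiment spread is validated to stay
within 10%.

**Traces and QC.**  Per-label trace = mean (not sum) over label pixels —
robust to the dilation-radius choice, and the NH4Cl normalization cancels
the difference either way.  Normalization divides by the mean of the last
5 post-NH4Cl frames.  Exclusions: `nh4cl_invalid` when the post-NH4Cl
level does not exceed baseline; `baseline_drift` when the pre-train-2
median baseline moves more than `drift_tol` (default 0.10 normalized
units — the source never quantifies "significant drift", so this is a
config default, not a literature value) from the pre-train-1 baseline, or
when the post-Baf segment's fitted drift accumulates more than `drift_tol`
over the segment.

**Rates.**  Six-point OLS slopes.  The exocytic fit starts at the first
frame at-or-after the train-2 onset.  The endocytic fit starts 9 frames
(18 s) after onset — "when endocytosis kicks in" is unquantified in the
source, so the offset is a config parameter reported with every run.  Two
known, quantified biases are worth stating plainly: pool depletion
compresses slopes (≈ e^(-k·t̄) over the window, so a planted 40% rate
knockdown reads out as ≈ 37% at the default constants), and the
re-acidification lag delays the endocytosis trace by ≈ `tau_reacid`,
biasing the endocytic slope ≈ 11–13% low against the instantaneous truth.
The acceptance tolerances (10% exo in its linear regime, 15% endo) cover
these; a green rate test certifies recovery *within those bands*, not
unbiasedness.  The no-Baf mode (first-train slope, used for acute-toxin
comparisons) additionally underestimates the true exocytic rate by the
concurrent endocytosis; the flag exists, and users should compare only
like with like.

## 3. Clustered statistics

The bouton is not an independent observation: boutons share fields (and
preparations), and planted field heterogeneity of realistic size makes a
pooled t-test reject a true null far above its nominal level (demonstrated
at >15% rejection for ICC 0.3 in the acceptance suite).  The model is

y = μ_group + π_prep + u_field + ε, with u_field ~ N(0, σ_f²) and
ε ~ N(0, σ²); preparations are sum-to-zero fixed effects, so group
coefficients are means at the average preparation.  Estimation is REML with
the variance ratio θ = σ_f²/σ² profiled: for fixed θ the covariance is
block-diagonal with per-field inverse `I - θ/(1 + n_f θ) J`, so the
criterion is computed from per-field sufficient statistics in O(n) and
minimized over log θ by golden-section search (tolerance 1e-10), with the
θ = 0 boundary always evaluated (negative variance truncates to zero and
sets a flag).  Fixed effects and their covariance are the GLS solution at
the optimum.  Against the general-purpose reference implementation (lme4)
on small instances, fixed effects and both variance components agree to
1e-6.

Inference: two groups — Wald z on the group-mean difference with its GLS
standard error, normal reference by default (the source software's exact
degrees-of-freedom convention is unknowable from the text; a
between-within t option is exposed behind `df_method` and logged); three
groups — joint chi-square Wald against the control, df = G − 1.  No
multiplicity correction by default, matching the stated 5% testing level.
When a group is perfectly confounded with a preparation the prep term is
dropped with a warning rather than silently absorbed.  In balanced designs
the LMM two-group statistic equals the field-means t statistic exactly (a
classical identity, tested to 1e-8 at interior variance optima); the
calibration suite verifies 3–7% empirical size at ICC 0, 0.2 and 0.5 for
both the LMM and the field-averaging comparator, and that LMM power
dominates field averaging across an effect grid.

## 4. Boltzmann fits

Both printed models are fit by `nls(algorithm = "port")` — a bounded
trust-region least-squares solver — with data-driven initialization (Erev
from the linear zero-crossing beyond the peak; V½ at half-maximal current;
k = 5 mV; Gmax from the peak) and three seeded jittered restarts on
failure.  k is bounded to (0.1, 30) mV.  Ingest enforces the
positive-density convention (predominantly negative curves are flipped
with a message).  The tail-protocol parameters are printed in the source
with "inactivation" symbols although the protocol measures activation; the
fit object exposes neutral `v_half`/`k` plus the printed-symbol aliases in
`$aliases`.  Zero-noise round trips recover parameters to 1e-6 over seeded
random parameter grids; with 2% multiplicative noise the median V½ error
stays under 1 mV.  The "27% vs 38%" ambiguity in percent-change
conventions (per-cell change vs ratio of group means) cannot be resolved
from printed information; `compare_groups` reports the ratio-of-means
convention and the summary-statistics Welch path is provided for printed
mean ± SEM inputs, with neither asserted against published values.

## 5. Reproducibility plumbing

Every stochastic stage consumes an explicit seed; identical config implies
byte-identical TIFF/CSV outputs (tested).  Each run writes its effective
config next to the outputs and a manifest with package version, seed,
timestamp, QC counts (segmented = kept + excluded, reconciled) and the MD5
of the effective config.  Movies are uncompressed 16-bit multi-page TIFFs
written and read by a minimal built-in codec (no TIFF package is assumed);
tables are CSV; summaries JSON.

## 6. Design decisions that were genuinely open

* **Trace-level vs movie-level validation scale.**  Statistical acceptance
  properties (calibration, power, effect recovery) are measured on
  trace-level simulations — the same kinetic model with the noise level a
  rendered bouton shows after normalization (~0.01 normalized units per
  frame) — because rendering hundreds of 256×256 movies per replicate
  buys no additional coverage of the statistics while costing orders of
  magnitude more time.  The imaging stages are validated separately on
  rendered movies (segmentation recall/false positives, drift recovery,
  extraction exactness, end-to-end CLI reconciliation).
* **"ΔF below 5%" as a relative cut** (`dF / F_baseline < 0.05`), since an
  absolute-counts cut would not transfer across expression levels.
* **Depletion-plateau check at fast kinetics** (k_exo 0.06 vs 0.04): the
  plateau-equality claim holds when the stimulus genuinely depletes both
  groups; at the default constants a 40%-slower group releases only ~84%
  of its pool in 120 s, which would test depletion *failure*, not plateau
  equality.
* **Quenched reporter contributes 1/20 brightness, not zero**, matching
  the stated unquench factor; plateau and extraction tests are
  quench-adjusted accordingly.

## 7. Known limitations

Trace extraction has no local-background subtraction by default (the
normalization is ratio-based); an annulus mode exists behind a flag but is
not the tested default.  The endocytic-rate estimator inherits the
re-acidification lag bias described above.  The aligner is integer-pixel
only.  The simulator's Ca²⁺ branch is a caricature sufficient for testing
normalization and ordering properties, not a biophysical model.  No
watershed splitting of touching boutons; heavily overlapping boutons
segment as one.  Crossed random effects, random slopes and Bayesian
estimation are out of scope.
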