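---
title: "Replicate denoising of SHAPE reactivity profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate denoising of SHAPE reactivity profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapekf)
```

## The measurement model

A SHAPE experiment yields one reactivity per nucleotide; repeating it yields
replicates that disagree. Two empirical features of such data argue against
the usual additive-Gaussian treatment: the distribution of normalized
reactivities is strongly right-skewed but near-Gaussian after a log
transform, and the between-replicate SD grows nearly proportionally with the
mean. `shapekf` therefore models the noise as additive Gaussian in the *log*
domain: with $l_m = \log s_m$ the true log reactivity of nucleotide $m$,

$$ l_{mi} = l_m + w_{mi}, \qquad w_{mi} \sim N(0, \sigma_{wm}) \ \text{i.i.d.}, $$

equivalently multiplicative log-normal noise $r_{mi} = e^{w_{mi}} s_m$ in the
data domain. Nucleotides are treated as independent, and the true reactivity
is assumed constant across replicates.

Consequences that drive the package design:

* Data-domain averaging is biased: $E[r_{mi}] = s_m e^{\sigma_{wm}^2/2}$.
* The maximum-likelihood combiner without a prior is the mean of the log
  measurements, i.e. the geometric mean (`log_average_profile()`).
* Because log reactivities across RNAs are themselves near-Gaussian, a
  Gaussian prior $N(\mu_0, \sigma_0)$ is available as an auxiliary
  information source, which the Kalman filter exploits.

## The per-nucleotide Kalman filter

`kalman_filter_nucleotide()` runs a one-dimensional filter on the log
measurements of one nucleotide. The state is constant, so the predict step
is the identity and each iteration is a single update with gain
$K_i = \sigma^2_{i-1} / (\sigma^2_{i-1} + \hat\sigma_w^2)$:

$$ \hat l_i = \hat l_{i-1} + K_i (l_i - \hat l_{i-1}), \qquad
   \sigma^2_i = (1 - K_i)\,\sigma^2_{i-1}, $$

initialized at the prior ($\hat l_0 = \mu_0$, $\sigma^2_0 = \sigma_0^2$).
The measurement variance $\hat\sigma_w^2$ is the unbiased sample variance of
the nucleotide's log measurements, which is why nucleotides with fewer than
two positive measurements are excluded by default (`meas_sd` supplies an
external SD to filter them anyway). The final estimate equals the
conjugate-normal posterior mean

$$ \hat l_N \;=\; \frac{\mu_0/\sigma_0^2 + N \bar l/\hat\sigma_w^2}
                       {1/\sigma_0^2 + N/\hat\sigma_w^2}, $$

a convex combination of prior mean and log-average; the test suite asserts
this equivalence to $10^{-9}$ on randomized instances, which also fixes the
reading of the variance recursion (it is the posterior-variance update; an
SD-scale reading would not reproduce the closed form). The filter is
invariant to measurement order and its posterior variance strictly decreases
while $\hat\sigma_w^2 > 0$.

### Numerical choices

* The variance update is computed as
  $\sigma^2 \hat\sigma_w^2 / (\sigma^2 + \hat\sigma_w^2)$ rather than
  $(1-K)\sigma^2$: for near-flat priors ($\sigma_0 \sim 10^6$) the gain is
  within machine epsilon of 1 and the subtraction would lose all precision.
* Degenerate cases: $\sigma_0 = 0$ pins the output at $\mu_0$ with zero
  posterior variance (every gain is 0); identical measurements
  ($\hat\sigma_w^2 = 0$) return the common value with zero variance, the
  $\hat\sigma_w^2 \to 0$ limit of the posterior and the resolution of the
  otherwise undefined gain at the second iteration. When both hold, the
  prior wins.
* Estimates are produced in the log domain and exponentiated once at the
  end (`fitted()`/`kalman_profile()`), so no intermediate exp/log
  round-trips accumulate error.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| prior $\mu_0, \sigma_0$ | $-1.74, 1.52$ | Gaussian fit to a reference database of 10690 processed log reactivities (log units); override with `fit_prior()` on your own data |
| background cutoff | $-0.25$ | truncation of the empirical negative-reactivity distribution used to replace non-positive values (reactivity units) |
| `top_fraction` | 0.10 | fraction of (non-outlier) values averaged into the normalization factor; the field uses 8–10% |
| outlier cap | 5% (< 100 nt), 10% (≥ 100 nt) | maximum fraction of values flagged by the box-plot rule |
| noise regimes | low (0, 0.5), medium (0.5, 1), high (1, 1.5) | uniform ranges for the per-nucleotide log-domain noise SD, calibrated on replicated SHAPE experiments |

Quartiles in `detect_outliers()` use linear interpolation between order
statistics (R's default type 7); the convention is configurable via
`quantile_type` since published pipelines rarely state theirs. When the
outlier cap binds, the largest values are retained, ties broken toward the
lower position. Negative values take part in quartile computation but can
never be flagged (the rule is upper-tail) nor contribute to the factor.

Preprocessing replaces each reactivity $\le 0$ by the absolute value of a
uniform draw from the truncated background distribution — the minimal
assumption given only "sampling from the truncated distribution"; zeros are
replacement targets, never background samples, and the background pools
negatives only. Missing values (−999 on disk) propagate untouched through
every transform and are dropped per nucleotide when combining.

## What the synthetic generator does and does not emulate

`generate_ground_truth()` draws $l_m \sim N(-1.74, 1.52)$ i.i.d. and
exponentiates — matching the marginal log-normal reactivity distribution of
curated SHAPE databases. `simulate_replicates()` draws one $\sigma_{wm}$ per
nucleotide, uniform over the regime, shared by all $N$ replicates of that
nucleotide (the noise level is a property of the nucleotide, not of the
replicate), then adds independent Gaussian log noise. Draws are consumed in
position order, so a length-$M$ prefix of a longer profile receives the same
values under the same seed. Simulated replicates are **not** re-normalized:
the noise model describes post-normalization variation (the two re-normalization
variants of `normalize_profile()` exist for studying exactly that choice).

The generator does *not* emulate: correlation between neighbouring
nucleotides (real adduct formation and reverse-transcription readout are
locally correlated), position-dependent coverage and the resulting
count-level (Poisson/binomial) noise, primer-proximal missing stretches, or
any dependence of $\sigma_{wm}$ on $s_m$. Passing tests on synthetic data
therefore certify the estimator under the stated model, not the full
behaviour of wet-lab profiles.

## Evaluation statistics

* `rms_error()` computes $\sqrt{\tfrac1{M'}\sum (\hat l_m - l_m)^2}$ over
  positions present in both profiles, in the log domain by default (where
  the noise model is additive); a data-domain option exists.
* `confusion_counts()`/`mcc()` compare base-pair sets over the universe of
  all $M(M-1)/2$ unordered position pairs. The universe is deliberately
  unrestricted (no loop-length or base-identity filter): TN dominates any
  restriction, so the MCC is insensitive to it at typical lengths. A zero
  denominator returns MCC 0, the standard convention.
* `mean_sd_fit()` regresses log(SD) on log(mean) across nucleotides
  (ordinary least squares, $\ge 2$ strictly positive measurements, zero-SD
  nucleotides excluded). Under the multiplicative model the slope is near 1;
  under additive data-domain noise it is near 0 — a quick diagnostic of
  which regime a data set is in.

## Study design choices

The simulation studies shipped in `run_experiment_grid()` and exercised by
the test suite use a $10^4$-nucleotide synthetic profile for the
replicate-count sweep (N = 2…10, per regime) and heat maps, 3000 nucleotides
for the prior accuracy/precision grid, and 2216 nucleotides with 5
replicates and $\sigma \in (0, 1.5)$ for the heteroskedasticity diagnostic —
sizes at which the Monte-Carlo error of an RMS (relative SE
$\approx 1/\sqrt{2M}$) is well below the effects being measured, while a
full grid runs in seconds. The prior-sensitivity study runs at the medium
noise regime, the representative middle of the three. Monotonicity checks on
RMS-versus-N allow a 3-SE multiplicative slack for simulation jitter, since
each N is a fresh simulation.

```{r example}
truth <- generate_ground_truth(2000, seed = 7)
reps  <- simulate_replicates(truth, N = 3, regime = "high", seed = 8)
lt    <- to_log_domain(truth)
c(logavg = rms_error(to_log_domain(log_average_profile(reps)), lt),
  kalman = rms_error(to_log_domain(kalman_profile(reps)), lt))
```

## Known limitations

* The filter's optimality is conditional on the log-normal model and on
  $\hat\sigma_w^2$ being a good variance estimate; at $N = 2$ or 3 the
  sample variance is itself very noisy, which is precisely when the prior
  matters most.
* A database-wide prior shrinks every nucleotide toward the same mean;
  highly reactive nucleotides are pulled down most. Per-nucleotide priors
  (`ideal_prior()`) quantify how much a better-specified prior would help,
  but constructing one for real data is out of scope.
* Dot-bracket parsing is restricted to nested structures; pseudoknots must
  arrive as CT files.
* No count-level simulation or folding engine is included; MCC evaluation
  compares two given structures.
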