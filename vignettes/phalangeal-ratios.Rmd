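---
title: "Phalangeal length ratios: normative ranges, TS screening, and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phalangeal length ratios: normative ranges, TS screening, and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phalanx)
```

## The problem

On a pediatric left-hand bone-age radiograph, absolute bone lengths are not
comparable across images because magnification varies; length *ratios* of
bones on the same film are. Three ratios carry diagnostic information about
skeletal dysplasias and in particular Turner syndrome (TS):

* **4:3 MC** — 4th to 3rd metacarpal length,
* **5:3 MC** — 5th to 3rd metacarpal length,
* **5:3 MP** — 5th to 3rd middle phalanx length.

The package builds age-stratified normative reference ranges for these
ratios from a large female reference cohort, screens subjects against them
(metacarpal sign: age-matched z-score below −2; brachydactyly type A3:
5:3 MP ratio below 0.5), and evaluates threshold classification with
ROC/Youden analysis. A calibrated synthetic-cohort generator stands in for
the radiograph collections, so the entire pipeline is testable end to end
without any image data.

## The bone-length model

Each subject's bone length (in pixels, bone $b$, age group $g$) is
multiplicative log-normal:

$$L_b = M \cdot H \cdot p_{g,b} \cdot e^{\varepsilon_b},
\qquad \varepsilon_b \sim N(0, sd_b^2),$$

with $M$ a per-image uniform magnification, $H$ a shared log-normal hand
scale, $p_{g,b}$ the expected proportion of bone $b$ at group $g$, and
independent per-bone noise. Ratios cancel $M$ and $H$ exactly — the model's
central property, mirroring why ratios rather than absolute lengths are
analysed in practice — so ratio moments depend only on proportions and the
per-bone noise SDs. The ratio mean is
$(p_{num}/p_{den}) e^{(sd_{num}^2 + sd_{den}^2)/2}$; the proportion defaults
absorb the exponential correction so the group ratio means hit their targets
exactly.

### Noise calibration

Because the 4:3 MC and 5:3 MC ratios share the MC3 denominator, denominator
noise induces a positive correlation between them. In the small-noise regime:

$$cv_{43}^2 = sd_3^2 + sd_4^2,\qquad cv_{53}^2 = sd_3^2 + sd_5^2,\qquad
\rho \, cv_{43} cv_{53} = sd_3^2.$$

`calibrate_reference_noise()` solves this closed form; the defaults use the
pooled reference targets ($cv_{43} = 0.019/0.889$, $cv_{53} = 0.022/0.822$,
$\rho = 0.49$), giving $sd_3 \approx 0.0167$, $sd_4 \approx 0.0133$,
$sd_5 \approx 0.0209$. A correlation larger than the shared-variance bound
makes a solved variance non-positive and raises an explicit infeasibility
error. MC and MP ratios share no bone, so their correlation vanishes by
construction, matching the observed near-zero cross-family association.

### Default study conditions

* Reference cohort n = 4438, TS cohort n = 81; TS bone ages uniform on
  3.0–17.9 y (only the range is reported for that cohort); reference
  age-group occupancy uniform over the six groups (the source collection's
  composition is not reported).
* Group ratio means: 4:3 MC 0.8903 (groups 1–5) dipping to 0.8823 in group
  6; 5:3 MC 0.8235 dipping to 0.8145; chosen so pooled means are exactly
  0.889 / 0.822 under uniform occupancy while the group-6 dip is many times
  the between-group standard error (early growth-plate closure of the 4th
  and 5th metacarpals in late puberty).
* 5:3 MP group means 0.605 (groups 1–4) stepping to 0.635 (groups 5–6), a
  within-group SD near 0.055. The 5:3 MP reference marginal is not reported;
  these derived defaults put the pre-trim pooled fraction below 0.5 at about
  2.1%, the reported reference BDA3 prevalence. After trimming, the left
  tail is partly removed, so the post-trim fraction is necessarily lower;
  the package treats 2.1% as a calibration anchor, not a reproducible
  output.
* Magnification uniform on 0.8–1.25, hand-scale log-SD 0.12, median MC3
  scale 55 px — plausible radiogrammetry scales; none of them influence any
  ratio.
* TS metadata: 45,X karyotype probability 33/81, GH treatment 0.82,
  SHOX-sign prevalences 0.333 / 0.235 / 0.136, consumed only as boolean
  annotations (the signs are image-reading judgments outside this package's
  inputs).

The generator's calibration targets the printed pooled moments applied
*pre-trim*. Trimming a normal sample at 2.25 SDS shrinks its SD by the
truncated-normal factor ≈ 0.924, so the post-trim pooled SD is ≈ 0.0176
rather than 0.019. The pooled mean is unaffected (symmetric trimming), which
is what the pipeline-level mean check relies on.

## The TS 4:3 MC mixture

A single normal with the TS pooled moments (0.860 ± 0.050) would put about
43% of subjects below the age-matched −2 SD threshold, incompatible with
the observed 27.2% flag prevalence. `fit_ts_mixture()` therefore fits a
two-component normal mixture — an unaffected component centred at the
reference mean and an affected component shifted down by $\delta$, common
SD — matching three targets with closed-form implied quantities: cohort
mean $c - \pi\delta$, cohort SD $\sqrt{\sigma^2 + \pi(1-\pi)\delta^2}$, and
the threshold tail probability averaged over the TS age-group occupancy.
Against the default reference table the fit converges to
$\pi \approx 0.26$, $\delta \approx 0.108$, $\sigma \approx 0.016$ with all
three targets reproduced to well under 1%. The mixture is one admissible
mechanism reconciling the published summaries, not a claim about the true
TS distribution; the affected fraction is close to, but conceptually
distinct from, the flag prevalence.

## The two TS backends

**ratio_level** draws the three ratios from a Gaussian copula: normal
margins for 5:3 MC and 5:3 MP with the TS pooled moments, the mixture for
4:3 MC via its quantile transform. A monotone non-linear transform
attenuates Pearson correlation, so the latent correlations are
pre-compensated by the attenuation factor
$a = \mathrm{corr}(Q_{mix}(\Phi(Z)), Z)$, computed by quadrature at
generation time ($a \approx 0.89$ for the fitted mixture). Sample
correlations then land on the configured targets (0.478 with 5:3 MC, 0.26
with 5:3 MP; the unreported third pair defaults to 0.2). An implied latent
matrix that is not positive definite raises an error naming the matrix.

**length_level** reuses the reference length model on the TS age range and
adds a shared half-normal severity latent that multiplicatively shortens
MC4, MC5 and MP5. It supports the full landmark round trip (lengths →
landmark annotations → measured lengths → ratios, exact to 1e-9) and
collapses exactly to the reference model at zero loading, but it is not
calibrated to the printed TS moments — no single simple model satisfies
both requirements, which is why both backends exist.

Note one consequence of the mixture marginal: the *empirical* AUC of the
4:3 MC ratio under this generator is the mixture-vs-normal concordance
(≈ 0.63), not the binormal value (≈ 0.71) computed from the pooled moments.
The package reports both routes and never substitutes one for the other.

## Trimming and reference-table semantics

* Trimming is **single pass**: pooled (all-age) mean/SD per ratio are
  computed once on the input; a subject is excluded when $|z| > 2.25$ on
  *any* ratio (union rule, subject-level exclusion). The union reading is
  supported by the reported retained fraction (92.0%) sitting close to the
  independent-union expectation (92.85%). Trimming is deliberately not
  idempotent — re-trimming a trimmed sample excludes more — so the builder
  never iterates.
* The boundary is strict: $|z|$ exactly at the limit is retained.
* A ratio with zero SD contributes no exclusions (degenerate guard, with a
  warning).
* Group and pooled SDs use the $n-1$ denominator, standard for reference
  ranges. A group with $n < 2$ keeps its row with an unavailable SD;
  screening against it refuses explicitly rather than falling back to
  pooled values.
* Skewness and kurtosis diagnostics use the bias-adjusted (type 2)
  conventions with *excess* kurtosis (normal → 0), the convention under
  which near-normal data can print small negative kurtosis.

## Screening and statistics conventions

* Flags use strict inequalities: metacarpal sign at $z < -2$ (exactly −2 is
  not flagged), BDA3 at ratio $< 0.5$. "Age-matched" means the subject's
  bone-age group row; the groups are discrete, so no interpolation.
* ROC orientation is fixed globally — a lower ratio indicates TS — so all
  AUCs are above 0.5 in the expected direction. The empirical AUC is the
  Mann–Whitney concordance with ties counted 1/2; its CI is DeLong's. The
  Youden scan uses midpoints between adjacent distinct pooled values, with
  sens $= P(\mathrm{ts} < c)$, spec $= P(\mathrm{ref} \ge c)$ (the cutoff
  value itself counts as negative) and the smallest maximizing cutoff as
  the deterministic tie-break.
* The fixed operating cutoff defaults to 0.876. The published account is
  ambiguous between 0.88 ("Youden index = 0.88", which cannot be the J
  value since sens + spec − 1 ≈ 0.37 there) and 0.876; the package uses
  0.876 wherever a fixed cutoff is required and treats neither as a
  reproducible optimum.
* Proportions are compared by Pearson chi-square (no continuity
  correction) when all expected counts are ≥ 5, otherwise Fisher's exact
  test; degenerate 2×2 tables (a zero margin) return p = 1. Partial
  correlation is the correlation of residuals from simple regressions on
  the covariate, with a t reference on $n-3$ df. An optional log-transform
  preprocessing flag is deliberately *not* applied by default: ratio
  skewness is near zero and the necessity criterion is unstated.

## Reproducibility and numerics

All generator randomness flows from one integer seed with fixed substream
offsets (magnification and landmark placement draw from their own
substreams, so changing the magnification range or landmark seed leaves
every ratio unchanged). Identical config + seed give byte-identical
artifact files; no artifact embeds a timestamp. Mixture quantiles use
monotone interpolation of the CDF on an 8192-point grid (error far below
Monte-Carlo noise); the copula attenuation uses a 16384-point Gauss
quadrature on ±8 SD. The mixture fit runs Nelder-Mead from three starts on
(logit π, log δ, log σ) and errors — carrying its best parameters and
residuals — if any target misses by more than 2% relative.

## Problem sizes

The test suite and the acceptance script run the generator at the study's
cohort sizes (4438 reference, 81 TS) and use 10⁴–10⁵ subjects where a
sample statistic is checked against a calibration target, sizes at which
Monte-Carlo error is comfortably inside each check's tolerance.

## What passing tests do and do not show

The generator reproduces the *reported statistical structure* of the two
cohorts: pooled moments, inter-ratio correlations, age-group trends, flag
prevalences, and the measurement convention's invariances. It does not
emulate real radiographic features — epiphyseal morphology, angulated
bones, manual measurement error correlated across bones, non-normal tails
from undiagnosed pathology — so passing tests validate the pipeline's
statistical machinery, not the clinical performance of the thresholds on
real images. The package deliberately stops short of combining flags into
a diagnostic score: the distributional overlap between cohorts limits
individual-level diagnostic utility.

## A minimal run

```{r example, eval = FALSE}
cfg <- generator_config(seed = 7)
cohort <- simulate_reference_cohort(cfg)
ratios <- compute_ratios(cohort$lengths)
trimmed <- trim_outliers(ratios)
reference <- build_reference(trimmed$retained, cohort$subjects)

cfg$ts_mixture <- fit_ts_mixture(reference, 0.860, 0.050, 0.272)
ts <- simulate_ts_cohort(cfg)
screened <- screen_cohort(ts$ratios, ts$subjects, reference)
cohort_prevalence(screened)

roc_analysis(trimmed$retained$r43mc, ts$ratios$r43mc, cutoff = 0.876)
autoplot(reference)
```

Or as one orchestrated, fully reproducible run writing every artifact
(cohort CSVs, reference JSON, trim report, screening CSV, prevalence and
ROC JSON, markdown report):

```{r pipeline, eval = FALSE}
run_pipeline("artifacts/", config = generator_config(seed = 7))
```
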