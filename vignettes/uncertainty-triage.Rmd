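---
title: "Entropy-based uncertainty triage: models, choices, and limits"
author: "uqtriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based uncertainty triage: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uqtriage)
```

## The problem and the score

An ensemble classifier for pulmonary nodule malignancy risk emits, per nodule,
N member probabilities (N = 20 in the deployment this package targets). The
pooled risk — the unweighted mean of the members — drives the diagnosis; the
package quantifies *confidence* in that diagnosis through the mean binary
entropy, in bits:

$$\bar H = \frac{1}{N}\sum_{i=1}^{N} -\left[p_i \log_2 p_i +
  (1-p_i)\log_2(1-p_i)\right].$$

Two properties matter for interpretation. First, $\bar H$ is an average of
per-member entropies, so it captures how *committed* each member is, not how
much members *disagree*: an ensemble whose members alternate between 0 and 1
scores exactly 0. That behaviour is intrinsic to the score and is preserved
here (tested, not "fixed"); users wanting a disagreement-sensitive score need
a different statistic (mutual information, variance), which is out of scope.
Second, $\bar H$ lives on an absolute scale: 0 iff every member is 0 or 1, and
1 iff every member is 0.5, so cut-offs are portable across cohorts of the same
ensemble.

`binaryEntropy()` implements the $0\log_2 0 = 0$ convention with an exact
branch rather than clamping, so the limits `binaryEntropy(0) == 0` and
`binaryEntropy(0.5) == 1` hold exactly, not to within an epsilon.

## Triage: calibration and transfer

`calibrateThresholds()` places cut-offs at percentiles of the development
cohort's $\bar H$ distribution, by default the 90th and 95th: referral rates
of 10% and 5% keep the workload argument for automation intact while leaving
enough uncertain cases to measure performance on. The optimal referral rate is
a healthcare-setting decision and deliberately not optimized here.

Two numerical conventions are fixed and tested:

* **Quantile definition.** The cutoff at percentile $q$ is the inverse-ECDF
  quantile (R's `type = 1`): the $\lceil nq/100\rceil$-th order statistic.
  Together with the tie rule below it guarantees, for *every* $n$, that
  re-classifying the calibration scores retains at least $q\%$ as certain
  (at $n = 883$, $q = 90$: exactly 795 nodules, 90.03%). Interpolating
  definitions (such as the common `type = 7`) can retain slightly *fewer*
  than $q\%$ — at $n = 883$ they retain 794/883 = 89.92% — which would break
  the retention contract. Descriptive median/IQR values in the subgroup table
  use the standard `type = 7` convention, since no retention guarantee is
  attached to them.
* **Tie rule.** A score exactly equal to the cutoff is *certain*
  (uncertain iff $\bar H >$ cutoff). Because the cutoff is an order statistic
  of the calibration scores, serialized thresholds are written with 17
  significant digits so the rule survives a JSON round trip.

Thresholds carry provenance (source cohort, $n$); applying them to an external
cohort (`assignGroups()`) may flag any fraction as uncertain — a larger
fraction than nominal is itself a finding about distribution shift.

## Performance evaluation

All discrimination statistics are authored in the package and tested against
brute-force oracles and against `pROC` as an independent reference:

* `rocAuc()` is the Mann–Whitney statistic via midranks
  ($P(s^+ > s^-) + \tfrac12 P(\text{tie})$); it errors on single-class groups
  rather than returning NaN.
* `delongVariance()` uses the structural components
  $\mathrm{var}(V_{10})/m + \mathrm{var}(V_{01})/n$; `compareAuc()` forms the
  unpaired $z = (\hat A_1 - \hat A_2)/\sqrt{V_1 + V_2}$ with a two-sided
  normal p-value. For the *full vs certain* comparison the groups share
  nodules and the covariance term is not estimable from group-level inputs;
  the result is still reported (it is the comparison practitioners ask for)
  but carries `overlapping = TRUE`. Ignoring a positive covariance makes the
  test conservative, which is the safe direction for a "removal did not hurt"
  claim. Certain-vs-uncertain comparisons are disjoint and exact in the
  DeLong sense.
* `bootstrapAucCI()` resamples nodules with replacement (1000 replicates by
  default, the standard choice at these cohort sizes), redraws resamples that
  lose a class, and reports the 2.5–97.5 percentile interval. The same
  resampling stream yields the CI for sensitivity at fixed specificity.
* `sensitivityAtSpecificity()` sweeps thresholds over the distinct observed
  scores with the convention *positive iff score > t* and returns the maximum
  sensitivity with specificity at or above the target (0.95 by default, the
  false-positive-averse operating point).

Two-sided tests at $\alpha = 0.05$ throughout; no multiplicity correction is
applied across subgroup tests, matching common practice for descriptive
subgroup tables.

## Subgroup characterization

`sizeClass()` implements the Lung-RADS 2022 boundaries — small $< 6$ mm,
medium $\ge 6$ and $< 8$ mm, large $\ge 8$ mm, closed lower bounds — and
`buildSubgroupTable()` reports, per label × certainty group, counts and
percentages by type and size class plus diameter summaries, with an
independent-samples t-test on diameters and chi-square tests on composition.
Part-solid and non-solid nodules are pooled as *subsolid* for testing because
their separate counts are small in realistic cohorts.

Defaults where the field's conventions genuinely vary:

* The t-test defaults to the pooled-variance Student form (the classical
  "independent samples t-test"); Welch is available via `variant = "welch"`.
* 2×2 chi-square tests default to the Yates continuity correction. On the
  published benign solid/subsolid counts for a screening vs a clinical cohort
  (695/123 vs 136/31) the corrected test gives $p = 0.3047$, matching the
  printed $p = 0.305$, while the uncorrected Pearson test gives 0.253 — the
  correction choice is identifiable from the printed value, and the package
  default reproduces it. `yates = FALSE` selects the uncorrected test.

## The synthetic cohort generator

Real screening/clinical CT cohorts are not redistributable, so testability
rests on `generateCohort()`. The generator's defaults *are* the study
conditions, chosen once from the published cohort descriptions and then left
alone:

* **Composition.** The `"screening"` preset draws 883 nodules with expected
  65 malignant; benign type mix 85/3.3/11.7% (solid/part-solid/non-solid),
  malignant 69/18.5/12.3%; sizes truncated log-normal (≥ 2 mm) with benign
  median 5 mm (sdlog 0.415) and malignant median 11 mm (sdlog 0.559), the
  sdlog values back-solved from published IQRs. The `"clinical"` preset:
  374 nodules, 207 expected malignant, benign median 6.8 mm, malignant
  22.4 mm, more solid malignancies, and a +0.5 shift of the baseline
  difficulty reflecting heterogeneous acquisition protocols.
* **Difficulty.** Each nodule gets a latent difficulty
  $d = \mathrm{logit}^{-1}(z)$ with
  $z = -2.7 + 2.1\,[\text{malignant}] + 1.9\,[\text{subsolid}] +
  2.8\,[\text{benign}]\min(\max(\log_2(\mathrm{diam}/6), 0), 2) +
  \varepsilon$, $\varepsilon \sim N(0, 0.8^2)$. The coefficients encode the
  structural findings the analysis is designed to detect: uncertainty
  concentrates in subsolid nodules, large benign nodules, and malignant
  nodules generally.
* **Members.** Given $d$, the ensemble's central tendency on the logit scale
  is $e \sim N\!\big((2L-1)\cdot 5 (1-d)^3,\ (2.2 \cdot 4d(1-d))^2\big)$ and
  members are conditionally i.i.d.
  $\mathrm{Beta}(\mu\kappa, (1-\mu)\kappa)$ with
  $\mu = \mathrm{logit}^{-1}(e)$ and $\kappa = 500^{1-d}40^{d}$. The cubic
  collapse of the evidence mean and the bell-shaped noise are what make
  intermediate-difficulty cases land confidently on the wrong side — the
  mechanism by which the uncertain group's AUC degrades toward chance — while
  keeping the limits exact: at $d = 0$ every nodule scores
  $\bar H < 0.1$ bits, at $d = 1$ members cluster at 0.5 and
  $\bar H > 0.9$ bits.
* **Calibration.** With these defaults the full screening-like cohort attains
  AUC ≈ 0.93, the uncertain decile ≈ 0.55–0.65, and the clinical-like cohort
  ≈ 0.85–0.88 with ≈ 20–30% flagged uncertain under transferred thresholds —
  the regime the analysis assumes. `calibrateDifficulty()` additionally
  retargets the intercept to any full-cohort AUC by bisection (within ±0.03
  at $n = 2000$, a tested property).

What the generator does **not** emulate: patient-level clustering (multiple
nodules per participant are treated as independent), 2-D vs 3-D member
structure (members are exchangeable), scanner/protocol covariates, reader
variability in diameters and types, and any particular marginal *shape* of the
real entropy distribution. Passing tests therefore demonstrate that the
*pipeline* is correct and that the *statistical machinery* behaves as claimed
under a realistic regime — not that any particular clinical AUC would be
reproduced on real data.

## Reproducibility and problem sizes

`runPipeline()` fans one master seed out into independent sub-seeds per stage
(development generation, external generation, per-cohort bootstraps), so
changing `bootstrap_reps` does not perturb the cohorts; identical config and
seed yield a byte-identical report bundle. The test suite exercises the
statistics at the sizes the analysis is designed for — cohorts of 883/374,
bootstrap and null-calibration studies of 1000–2000 replicates, 200-replicate
power checks of the certain-vs-uncertain comparison — and the complete suite
runs in well under a minute on one CPU.

## Known limitations

* The full-vs-certain DeLong comparison ignores the (positive) covariance of
  the two AUC estimates, as discussed above; it is flagged, conservative, and
  should not be read as an exact test.
* Mean entropy is blind to inter-member disagreement by construction.
* The bootstrap CI is the simple percentile interval; no BCa or studentized
  refinement is offered.
* Sensitivity-at-specificity is an empirical operating point; with few
  positives its bootstrap CI is wide and its point estimate can be 0 in small
  uncertain groups.
* The generator's difficulty model is a modeling choice: the distribution of
  real member-level predictions is not publicly characterized, and any
  bounded two-parameter family with location/spread control could be
  substituted.
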