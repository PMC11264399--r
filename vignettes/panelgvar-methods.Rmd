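---
title: "Panel GVAR symptom networks: model, estimation, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Panel GVAR symptom networks: model, estimation, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`panelgvar` estimates symptom networks from short ordinal questionnaire
panels — the canonical use case being the ten-item Edinburgh Postnatal
Depression Scale (EPDS, items scored 0–3) measured at three postpartum
waves in community samples of new mothers and fathers. This vignette is the
package's own account of the model it fits, the choices made where the
methodology is genuinely open, and what the synthetic validation suite does
and does not demonstrate.

## The model

For person $i$ at wave $t$ the $p$-vector of (preprocessed, continuous)
item scores is decomposed as

$$ y_{it} = \nu_t + b_i + e_{it}, $$

with $b_i \sim N(0, \Sigma_B)$ a person-level random intercept vector
(stable, trait-like differences) and $e_{it}$ a within-person deviation
following a stationary lag-1 vector autoregression

$$ e_{it} = B\, e_{i,t-1} + \zeta_{it}, \qquad
   \zeta_{it} \sim N(0, \Sigma_\zeta), \qquad
   e_{i1} \sim N(0, \Sigma^*), $$

where $\Sigma^*$ solves the discrete Lyapunov equation
$\Sigma^* = B \Sigma^* B^\top + \Sigma_\zeta$. The three reported networks
are:

* **temporal** — the entries of $B$ (we store $B$ receiver-row /
  predictor-column and export the transpose so that edge $[i,j]$ reads
  "item $i$ predicts item $j$ at the next wave");
* **contemporaneous** — the partial correlations
  $\omega_{ij} = -\kappa_{ij}/\sqrt{\kappa_{ii}\kappa_{jj}}$ of the
  innovation precision $K_\zeta = \Sigma_\zeta^{-1}$;
* **between-person** — the same transform of $K_B = \Sigma_B^{-1}$.

The implied covariance of the stacked observation vector has blocks
$\mathrm{Cov}(y_t, y_s) = B^{t-s}\Sigma^* + \Sigma_B$ for $t \ge s$. The
model is parameterized directly in the free elements of $B$, $K_\zeta$,
$K_B$ and the wave means $\nu_t$, so that zero-constraints from pruning are
expressible exactly.

Wave means are estimated freely even after detrending (when they are close
to zero); this keeps the fit correct when users skip detrending. Equal wave
spacing is assumed: one $B$ governs both 6-month transitions.

## Preprocessing

Ordinal item scores are deliberately treated as continuous — the standard
practice for this model class, and the regime the validation suite
stresses. The pipeline applies, in order:

1. **Variance screening.** An item whose modal category exceeds 95% of
   pooled responses (configurable `max_modal_share`) is removed. On data
   calibrated to published community EPDS tables this excludes exactly the
   suicidal-ideation item (≈98.7% zeros) while keeping the other heavily
   skewed items. The criterion is a share threshold because no exact rule
   is standard; the default reproduces the conventional exclusion. Note
   that on data calibrated to published fathers' tables the ninth item
   (crying, ≈96% zeros there) also crosses the default threshold — a
   stricter threshold (e.g. 0.97) retains it if the nine-item set must be
   preserved.
2. **Detrending.** A pooled (not per-person) OLS line of score on wave
   index is removed per item: with only three waves a per-person line would
   absorb nearly all within-person variance.
3. **Standardization.** Each item is z-scored with its pooled mean/SD
   across all waves jointly (denominator $n-1$), so wave differences remain
   interpretable on one scale. Order is detrend → standardize;
   both steps and the order are configurable, and a complete-case filter is
   available for sensitivity reanalysis.

## Estimation

Missing data are handled by full-information maximum likelihood: each
person contributes the multivariate-normal log-density of their observed
cells only, with persons grouped by missingness pattern (the grouping is an
implementation detail; the likelihood is invariant to it). This is unbiased
under missing-at-random dropout, which the attrition generator reproduces
by construction.

The optimizer is BFGS on the per-person mean negative log-likelihood with
central-difference gradients (step $10^{-6}$), followed when needed by a
floored-eigenvalue damped-Newton polish that finishes convergence in the
flat, ill-conditioned valleys that arise when the between covariance
estimate approaches singularity. Stationarity
($\rho(B) < 1$) and positive-definiteness of both precisions are enforced
by rejecting invalid proposals during line search rather than by
reparameterization — precision entries remain the free parameters, so
pruned zeros are exact. Convergence requires a gradient max-norm below
$10^{-5}$ (mean scale) and a relative objective change below $10^{-9}$;
non-convergence is reported as a flag, never an exception, because the
stability protocol codes non-converged replicates as all-absent.

Standard errors come from the numerically differentiated observed
information. When the between-person covariance estimate drifts toward
singularity (a boundary phenomenon analogous to Heywood cases, common in
three-wave random-intercept models at moderate $n$), the information
acquires near-flat directions; we invert it spectrally with an eigenvalue
floor ($10^{-8}$ of the largest eigenvalue) so affected parameters receive
very large standard errors and are pruned, instead of the fit failing. The
`se_regularized` flag records when this happened.

**Pruning** fixes to zero, simultaneously, every edge parameter whose
two-sided Wald $p$ exceeds `alpha`, refits, and by default repeats the
test on the refitted model until the pattern stabilizes. The recursion is
not cosmetic: a saturated fit whose between covariance sits near the
singularity boundary carries inflated precision entries with spuriously
large $z$; the first refit moves off the boundary and the re-test removes
them, keeping the pruning false-discovery rate near its nominal level. The
default
`alpha = 0.01` follows the upstream convention in network psychometrics;
0.05 is the documented alternative. Autoregressive self-loops are prunable
like any temporal edge (they appear and disappear in published pruned
networks, so they must be testable); a flag exempts them. Means and
precision diagonals are never pruned.

**Model search** greedily re-introduces the single zero edge whose release
most lowers BIC, re-prunes, and stops when BIC no longer improves, with a
deterministic (matrix, column, row) tie-break. BIC uses $N$ = persons;
RMSEA uses $N-1$; both conventions are configurable because the literature
is not unanimous.

**Fit indices** compare the structured model to an FIML-saturated model
(unrestricted stacked mean and covariance, fitted by EM — closed-form in
one step for complete data) and an independence baseline (free means and
variances, zero covariances, closed-form observed-data MLE):
$\chi^2 = 2(\ell_{sat} - \ell_M)$, $df$ = parameter-count difference, and
the standard CFI/TLI/RMSEA formulas with TLI truncated at 1. The usual
cut-offs (CFI > 0.90, TLI > 0.90, RMSEA < 0.05) are reported guidance, not
enforced.

## Case-drop stability

`casedrop_stability()` draws person subsamples *without replacement*
(matching the "75% extracted" protocol; this is a subsample, not a
bootstrap), re-runs the entire configured pipeline — including
re-estimating standardization statistics on each subsample, the
conservative choice — and codes each edge present (1) if free and non-zero
in the final pattern, else 0. A non-converged replicate scores 0
everywhere. One random substream is derived per replicate index from the
master seed, so results are independent of execution order and bit-exactly
reproducible.

## The synthetic generator

Because raw clinical panel data of this kind are typically restricted, the
generator is first-class, tested code that reproduces the statistical
regime the method faces:

* **Ground truth** (`make_truth()`): sparse $B$ rescaled to an exact target
  spectral radius; sparse symmetric precisions made positive-definite by
  diagonal dominance.
* **Calibrated preset** (`simulate_lin_like()`): 9 interconnected items
  plus a near-constant tenth (to exercise screening), 3 waves,
  $n = 869$ mothers / $579$ fathers. The deterministic preset truth makes
  sadness and anxiety the temporal hubs — the qualitative pattern reported
  for postnatal samples. Latent Gaussian scores are discretized with
  thresholds solved numerically so the categorical mean and SD of every
  item match the published wave-1 item moments shipped in
  `inst/extdata/epds_item_moments.csv` (within 0.01; a mean-only fallback
  covers unattainable SDs). Attrition base rates (mothers 6.5%/2.2%,
  fathers 3.0%/3.6% per transition, log-odds slope 0.2 per unit of
  previous-wave total) were chosen once so that marginal dropout lands in
  the published 5–15% band and dropouts score higher at baseline —
  matching the published negative completers-minus-dropouts $t$ — and are
  not revisited.
* **What it does not emulate:** real EPDS data have item-level (not only
  wave-level) missingness, potential non-linear trends, measurement
  non-invariance between groups, and genuinely non-Gaussian latent
  structure. Passing tests therefore demonstrate estimator correctness and
  robustness to coarse ordinal measurement plus MAR attrition — not that
  any particular published network is recovered (those estimates are
  data-dependent and the data are restricted).

Parameter-recovery tests use the continuous complete-data mode to isolate
estimator correctness; regime tests use the ordinal+attrition mode to show
that coarse measurement attenuates but does not invert strong temporal
effects (sign preservation of $|w| \ge 0.3$ edges across seeds).

## Problem sizes and numerical choices

The shipped validation suite uses sizes chosen to make Monte-Carlo noise
small relative to the tolerances while staying pleasant to run end-to-end:
20 replicate datasets at $n = 1000$, $p = 6$ for recovery/coverage/pruning
calibration; 20 seeds of the full calibrated preset at $n = 869$, $p = 10$
for the regime checks; 50 replicates at 75% for the stability protocol;
oracle equivalences (Lyapunov series, dense likelihood,
regression-residual partials, brute-force centrality) at machine-precision
tolerances. The Lyapunov equation is solved by a squaring/doubling
iteration (quadratically convergent for $\rho(B) < 1$); positive
definiteness is checked by Cholesky success, tolerance-free.

## Known limitations

* No polychoric/threshold likelihood: items are continuous by design here.
* No multi-group simultaneous estimation or between-group edge tests.
* No unequal wave spacing or continuous-time extension.
* The BIC search explores single-edge additions greedily; it is
  deterministic but not guaranteed to find the global BIC optimum.
* Figures are out of scope: networks export as edge lists/JSON for
  external layout tools.
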