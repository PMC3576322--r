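---
title: "Mixed treatment comparisons of anti-TNF agents on continuous and binary outcomes"
author: "ramtc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed treatment comparisons of anti-TNF agents on continuous and binary outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Five anti-TNF agents are licensed in Europe for rheumatoid arthritis in
patients with an inadequate response to methotrexate (MTX): adalimumab (Ada),
infliximab (Inf), etanercept (Eta), golimumab (Gol) and certolizumab (Cert).
Essentially all randomized evidence compares one agent with placebo, so the
evidence network is a *star*: any estimate of one agent against another must
be an indirect comparison through the common placebo anchor.  A Bayesian
mixed treatment comparison (MTC, also called network meta-analysis) pools the
whole network and yields every pairwise contrast as a difference of
*basic parameters* (effects versus placebo).

Indirect comparisons are noisy, which makes the choice of efficacy measure
consequential.  This package fits the same network on a continuous measure
(the improvement in the Health Assessment Questionnaire disability score,
HAQ, 0--3) and on binary responder measures (ACR 20/50/70, and dichotomized
HAQ 20/50), so the information lost by dichotomization can be quantified as
lost power to detect differences between agents.

## Data and preprocessing

The bundled dataset (`anti_tnf_trials()`) holds one row per trial arm of the
sixteen placebo-controlled trials: arm size, MTX indicator, mean and SD of
HAQ improvement, nested ACR 20/50/70 responder counts, and baseline HAQ.
Missing summaries are `-` in the file and `NA` internally -- never zero.

Missing-summary rules, applied in this order by the upstream extractors and
by this package:

* a reported median stands in for a missing mean (already applied in the
  bundled table; the package takes those cells at face value);
* a reported IQR is converted by the normal approximation
  `sd = IQR / (2 * qnorm(0.75))` (`sd_from_iqr()`);
* remaining missing SDs receive the maximum SD observed anywhere in the
  dataset (`impute_missing_sd()`; 0.7 HAQ units here) -- deliberately
  conservative, since it inflates rather than shrinks sampling variance.

Thirteen trials report HAQ completely and enter the HAQ-family analyses; all
sixteen report ACR and enter the ACR-family analyses (`filter_trials()`).

For the continuous models each treatment arm is reduced to a contrast
against its own placebo arm (`build_contrasts()`): the observed difference
in mean improvement, with standard error
`sqrt(sd_t^2/n_t + sd_c^2/n_c)`.  The SE construction is this package's
choice -- the source tables report only per-arm summaries, and the Welch-type
two-sample SE is the only construction available from them.  Contrasts that
share a control arm are treated as independent in the likelihood, matching
the independent-contrast formulation of the multi-arm model; the ignored
positive correlation makes the analysis slightly conservative for
between-drug comparisons.  Dose arms of the same drug stay separate arms
sharing one study-level effect (dose is deliberately not modelled).

## Constructed outcome measures

**Dichotomized HAQ.**  A patient is a HAQ 20 (HAQ 50) responder if their
HAQ score improved by at least 20% (50%) of baseline, so the threshold on
the improvement scale is `cutoff * baseline`, with the arm-level baseline.
Responder counts are generated from the arm's normal improvement
distribution: either by simulating 1000 patients and scaling the responder
proportion to the arm size (`mode = "montecarlo"`, the procedure behind the
bundled derived table) or analytically as
`n * (1 - pnorm((threshold - mean)/sd))` (`mode = "analytic"`, the
infinite-draw limit and the default for testing, since it is deterministic).
Thresholds are inclusive ("at least"), scaled counts are rounded half away
from zero, and `sd = 0` is a point mass.  The 1000-draw procedure has
binomial noise with SD about `0.0158 * n` at a 50% response rate -- about 3
patients for a 200-patient arm -- which is exactly the disagreement observed
between the analytic limit and the bundled Monte-Carlo table, and the
tolerance the tests use.

**Continuous ACR.**  The nested ACR counts partition each arm into four
response groups (non-responder; 20-not-50; 50-not-70; 70).  Given a mean
fractional improvement `m_i` per group, the arm mean and SD of the
continuous ACR response are the weighted mean `sum(N_i m_i) / N` and the
population-form SD `sqrt(sum(N_i (m_i - mean)^2) / N)` (divisor `N`,
as defined -- not `N - 1`).  Treatment arms use group means estimated from
patient-level registry data of biologic-treated patients (`"meanACR"` by
default, `"ACRhybrid"` as a sensitivity variant); no such data exist for
control arms, so control arms use conservative interval midpoints
(0.00, 0.35, 0.60, 0.85 -- with 0 rather than a midpoint for the wide
non-responder interval).  Both choices are exposed; reusing treatment means
for controls is the documented sensitivity alternative, not the default.

## The models

All variants share the hierarchical core.  Writing `s(j)` for the study of
treatment arm `j`, `k` for its drug, and `I.t`, `I.c` for the MTX indicators:

**Continuous** (HAQ, and reconstructed continuous ACR):

    Delta_j ~ N(alpha_{s(j),k} * lambda_j + b (I.t_j - I.c_{s(j)}), se_j^2)
    alpha_{s,k} ~ N(a_k, sigma^2)

The baseline multiplier `lambda_j` (arm baseline HAQ) makes `a_k` a
*fractional* improvement of baseline disability; it is used for HAQ, where
effect size scales with baseline severity.  For the continuous ACR response
the multiplier is dropped (the measure is already relative to baseline), so
`a_k` is a difference in fractional response.  The reported contrast between
two active drugs is `IC_{k,l} = a_k - a_l`.

**Binomial** (ACR 20/50/70, HAQ 20/50):

    r.c_s ~ Bin(n.c_s, p.c_s),  logit(p.c_s) = mu_s + b I.c_s
    r.t_j ~ Bin(n.t_j, p.t_j),  logit(p.t_j) = mu_{s(j)} + b I.t_j + alpha_{s(j),k}
    alpha_{s,k} ~ N(a_k, sigma^2)

so `a_k` is a log odds ratio versus placebo.  Each control arm enters the
likelihood once per study.  An optional meta-regression term
`gamma * lambda_s` on the treatment-arm logit is available
(`covariate_gamma = TRUE`) but off by default: binary responder measures are
already defined relative to baseline, and the regression adds nothing on
these data.

Model assumptions worth stating plainly: effects are fixed within a study
(all arms of the same study and drug share one `alpha_{s,k}`), random
between studies with a single heterogeneity SD `sigma` for all comparisons;
the MTX effect `b` is additive and fixed-effect (the data contain too few
MTX-discordant arms to inform a random `b`); and exchangeability across
trials is assumed but untestable here, because a star network has no closed
loops to check consistency on.

**Priors.**  All location parameters (`a_k`, `b`, `mu_s`, `gamma`) get
normal(0, 10000) priors -- read as *variance* 10000, i.e. SD 100, vague on
both the improvement-difference and log-odds scales; the prior variance is
configurable, which also covers the sensitivity range for the prior
precision.  The heterogeneity SD gets a uniform(0, 2) prior; reruns with
upper bounds 5 and 7 leave the estimates unchanged (the posterior
concentrates far below 2 on these data).

## Computation

`build_mtc_model()` produces both an R evaluator of the joint log density
(tested against an independently coded term-by-term oracle at 1e-10) and the
matching JAGS model code; `run_mcmc()` samples it with JAGS, the same Gibbs
sampling family used for the original analyses.  Defaults follow the
published run lengths -- 2 chains, 50,000 burn-in iterations, 100,000 kept
per chain -- which take a few seconds (continuous) to about twenty seconds
(binomial) per fit here.  A `"fast"` profile (4 chains, 2,500 kept each) is
provided for simulation studies; its adequacy is judged by effective sample
size and split-chain Rhat, which `run_mcmc()` computes and attaches to every
fit, not by fidelity to run length.  The test suite uses intermediate
lengths (2 chains, 12,500 kept for binomial fits, 6,000 for continuous
ones), again checked by diagnostics.

Initial values are deterministic functions of the seed: effects jittered
around zero, `sigma` around mid-support, control logits at their empirical
values; an initialization point with non-finite joint density is redrawn.
The same seed and configuration reproduce every draw bit for bit.  No
thinning is applied by default.  No continuity corrections are applied to
binomial cells -- zero counts are handled by the likelihood itself.

**Reporting.**  `summarize_comparisons()` returns each agent versus placebo,
all active-versus-active pairs, and the heterogeneity SD, with posterior
means and equal-tailed 80% credible intervals; a comparison is "significant"
when its interval excludes the null (0 for differences, 1 for odds ratios).
The 80% level is the reporting convention of the underlying analysis and is
configurable.  Odds ratios are summarized by exponentiating the log-OR draws
draw-wise and then taking means and quantiles, so the reported mean is the
posterior mean of the OR -- a determinate convention worth documenting
because `mean(exp(x)) > exp(mean(x))`; at these posterior spreads the
difference is a few percent, well inside the Monte-Carlo and specification
tolerances used in the tests.  Tables print at two decimals.

## Synthetic networks and what they do (and do not) show

`simulate_network()` generates star networks from the generative form of the
model itself, with known parameters, so every pipeline stage is testable
without external data and interval calibration can be measured
(`recovery_experiment()`).  The `"joint"` family draws patient-level
fractional improvements, then derives *both* the continuous summaries and
the nested responder counts from the same latent patients -- mirroring how
the continuous-versus-binary power comparison is constructed, and
guaranteeing nested counts by construction.  The `"binomial"` family draws
counts directly from the logistic model for log-OR-scale recovery.

Defaults are chosen once to echo the regime of the real data: effects
0.10--0.31 on the fraction-of-baseline scale, heterogeneity SD 0.03, three
trials per drug, 200 patients per arm, baseline HAQ uniform on 1.2--1.9
(the bundled range), control response rate 0.25 (a typical placebo
responder rate in these trials), per-patient SD 0.25 on the fraction scale
(0.4--0.5 HAQ units, as printed), and a 20% chance that a treatment arm
lacks MTX so the additive MTX effect stays estimable.

The generator emulates the model, not the world: normal patient
improvements with a common per-patient SD, exact arm-level exchangeability,
no dose structure, no reporting selection, no missingness mechanism, and
responder measures derived from one latent trait.  Passing recovery tests
therefore demonstrates the estimator's internal correctness and calibration
under its own assumptions -- not robustness to the ways real trial data
violate them.

## Numerical and reproducibility notes

* Rounding of constructed responder counts and displayed tables is half away
  from zero, with a 1e-9 guard where exact decimal halves (e.g. 0.055) hit
  binary floating point.
* The published derived-outcome table bundled for comparison has two
  printed-table quirks, preserved verbatim and handled at the comparison
  layer: the two adalimumab arms of one trial have their N labels swapped
  relative to their outcomes, and two trials print same-drug rows in
  scrambled order, so comparisons match arms within trial and drug.  One
  printed continuous-ACR cell (the Schiff placebo arm, printed 0.22) is
  inconsistent with its own inputs, which give 25.15/110 = 0.2286 -> 0.23;
  the package reports the recomputed value.
* The between-trial SD prior support excludes 0; a degenerate
  no-heterogeneity fit is approximated by the posterior piling near 0, not
  by a point mass.

## Limitations

Doses are not modelled; arms of the same drug at different doses share one
study-level effect.  Only randomized placebo-controlled evidence enters.
The star topology precludes consistency checks of the exchangeability
assumption.  The continuous ACR response is a reconstruction from four
group means estimated on treated patients elsewhere -- it carries the
uncertainty of those means without propagating it.  And the independence
approximation for contrasts sharing a control arm slightly overstates the
information in multi-arm trials' between-drug comparisons.

## A complete run

```{r}
library(ramtc)
arms <- anti_tnf_trials()

fit <- mtc_fit(arms, "haq", mcmc = mtc_mcmc(seed = 1))
summary(fit)              # 15 pairwise rows + heterogeneity SD
plot(fit)                 # forest plot, significant contrasts in red

fit_acr <- mtc_fit(arms, "acr20", mcmc = mtc_mcmc(seed = 1))
forest_export(summary(fit_acr), "acr20_forest.pdf", format = "plot")

# calibration of the machinery on synthetic networks
rec <- recovery_experiment(sim_config(), n_rep = 20,
                           mcmc = mtc_mcmc(profile = "fast"), seed = 7)
mean(rec$covered[grepl("^a_", rec$parameter)])   # ~0.80
```
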