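---
title: "Latent-class choice models with utility- and regret-based segments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-class choice models with utility- and regret-based segments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcchoice)
```

## The model

`lcchoice` estimates finite-mixture multinomial logit models for repeated
(panel) choice data in which each latent segment may follow its own decision
rule. Let $c = 1,\dots,C$ index respondents, $k = 1,\dots,K$ their choice
occasions, $i = 1,\dots,I$ the alternatives, and $m$ the attributes
$x_{cikm}$. A respondent belongs to segment $s$ with logit probability

$$P_{cs} = \frac{\exp(\gamma_s' z_c)}{\sum_{s'} \exp(\gamma_{s'}' z_c)},$$

where $z_c$ are respondent covariates and the base segment's $\gamma$ is
fixed at zero for identification. Conditional on the segment, choices follow
either

* **random utility maximization (RUM)**: $U_{cik} = \alpha_s' x_{cik}$ and
  $P_c(i)\mid s = \exp(U_{cik}) / \sum_r \exp(U_{crk})$; or
* **random regret minimization (RRM)**:
  $R_{cik} = \sum_{j \ne i} \sum_m \ln\!\big[1 + \exp\{\delta_m (x_{cjmk} -
  x_{cimk})\}\big]$ and $P_c(i)\mid s = \exp(-R_{cik}) / \sum_r \exp(-R_{crk})$.

The sample log-likelihood is
$LL = \sum_c \log \sum_s P_{cs} \prod_k P_c(i_{ck})\mid s$: the product over
a respondent's occasions sits *inside* the segment sum, which is what makes
the segments latent classes rather than per-observation mixtures.

Within a segment, any subset of coefficients may be random,
$\beta_m = \mu_m + \sigma_m \xi$ with $\xi \sim N(0,1)$. We parameterize the
random coefficient as a mean plus a normal deviation (rather than a strictly
mean-zero coefficient) because an estimated location is needed for any
attribute that also enters the deterministic part; the mixing integral is
approximated by averaging the panel product over respondent-level draws, so
the draw is shared across a respondent's $K$ occasions (panel mixing). With
observation-level draws the simulated likelihood would target a different —
and for panel data wrong — estimand.

## Estimation and numerical choices

`lc_choice()` maximizes the (simulated) log-likelihood directly with BFGS
over the flattened parameter vector. We chose direct maximization over EM
because the M-step has no closed form once mixing or regret kernels are
involved, and quasi-Newton iterations with an analytic score are fast at
this scale. Specific choices:

* **Score.** For models without random coefficients the gradient is
  analytic (posterior-weighted logit scores for RUM, posterior-weighted
  regret-derivative scores for RRM); a property test checks it against
  central finite differences at random points. Mixed models fall back to
  `optim`'s finite-difference gradient.
* **Stability.** All softmaxes subtract the row maximum; the regret softplus
  is evaluated as $\max(u,0) + \log(1+e^{-|u|})$; the segment sum in the
  log-likelihood uses log-sum-exp. Unavailable (not-shown) attributes
  contribute exactly zero to both utility and regret — in particular a
  masked attribute does *not* contribute the $\ln 2$ a naive
  $\text{softplus}(0)$ would add.
* **Positivity.** Mixing spreads enter as $\log \sigma$, so they are
  positive by construction and the optimization is unconstrained.
* **Draws.** Randomized Halton sequences (consecutive prime bases, first 50
  points dropped, independent uniform shift modulo one per dimension, then
  the normal quantile), 200 draws per respondent by default. Each
  respondent receives a *contiguous block* of the sequence: leapfrogging a
  Halton sequence by a stride that shares factors with the base destroys
  its equidistribution, which we observed directly as a biased simulated
  likelihood before switching to block allocation. Plain pseudo-random
  draws are available for comparison.
* **Starts.** Multi-segment fits warm-start each segment at its own
  single-segment estimate, then perturb additional starts by
  $N(0, 0.25|\theta| + 0.1)$; 5 starts by default. Two-rule mixtures have a
  characteristic local optimum in which the behavioral classes swap across
  rule slots — visibly inferior in likelihood but reachable from symmetric
  starts, which is why the default is several perturbed starts rather than
  one.
* **Convergence.** Relative log-likelihood tolerance $10^{-8}$ (tightenable;
  the conditional-logit cross-check against `glm()` uses $10^{-13}$ to reach
  $10^{-6}$ agreement in the coefficients).
* **Inference.** Standard errors come from the inverse numerical Hessian at
  the optimum (computed after canonicalization, so membership coefficients
  are differentiated in the reported base). If the Hessian is not positive
  definite the fit is returned with inference flagged unavailable rather
  than with fabricated errors. A robust sandwich estimator is not
  implemented; the reported t-statistics are conventional Hessian-based
  ones.
* **Label switching.** The likelihood is invariant to permuting same-rule
  segments. Reported results are canonicalized — RRM segments before RUM,
  descending population share within rule — and membership coefficients are
  re-expressed against the new base segment (subtracting the new base's
  $\gamma$ leaves all $P_{cs}$ unchanged).

## Model selection

`AIC = 2k - 2\ln L` and `BIC = -2\ln L + K\ln Q$ with $Q$ the number of
choice observations. `search_compositions()` implements the sequential
strategy: estimate both single-rule models, then repeatedly add one RUM or
one RRM segment to the incumbent and keep the addition only if the
criterion improves. The stopping criterion is BIC by default — the
criterion most commonly recommended for selecting the number of latent
classes, and the more conservative of the two here since $\ln Q > 2$ for
any $Q \ge 8$. "No further improvement" is deliberately interpreted as *in
BIC* (not AIC or raw likelihood); AIC is always reported alongside.
Compositions whose smallest population share falls below `min_share`
(default 0.05) are recorded but inadmissible as incumbents: a segment
holding under 5% of the population is rarely interpretable, and a concrete
floor makes the share screen executable. The greedy search never removes a
segment; an exhaustive enumeration up to `max_segments` is available behind
a flag.

## Trade-offs

For a RUM segment, minutes of travel time a respondent will trade for one
unit of an attribute is the coefficient ratio $\beta_t/\beta_r$ (reported
as positive minutes; the raw signed ratio is available). The *Value of
Clean Ride* is this ratio for the mean- and maximum-exposure coefficients,
in min/ppb. For an RRM segment the trade-off is choice-set dependent:

$$\frac{\sum_{j \ne i} -\beta_t \,/\, (1 + 1/\exp[\beta_t(t_j - t_i)])}
       {\sum_{j \ne i} -\beta_r \,/\, (1 + 1/\exp[\beta_r(r_j - r_i)])},$$

each term being $-\beta$ times the logistic of $\beta \Delta$. At zero
differences every logistic is $1/2$ and the expression collapses to
$\beta_t/\beta_r$ — an exact identity we test to $10^{-12}$. Because the
evaluation points $(t_j - t_i, r_j - r_i)$ behind any published RRM
trade-off table cannot be inferred from coefficients alone,
`tradeoff_table()` takes the difference configuration explicitly and echoes
it in the CSV header; the default (a single competitor holding the
attribute advantage and the travel-time advantage of the fastest grid
option) produces columns that decrease in travel time, the qualitative
pattern such tables show, but is *our* convention, not a reconstruction.

## The synthetic stated-preference generator

`generate_design()` emulates a partitioned route-choice experiment: three
generic route alternatives, five scenarios per respondent, and exactly five
attributes shown per scenario — mean NO2 exposure (5/10/15 ppb), maximum
exposure (20/40/60 ppb) and travel time (20–40 min in steps of 5) always,
plus one roadway attribute (grade, traffic volume or roadway type; three
levels each) and one cycling-infrastructure attribute (continuity or
segregation; two levels each) assigned per respondent round-robin. Levels
are drawn uniformly and independently per alternative; categorical
attributes are dummy-coded against their base levels (flat, light,
residential, discontinuous, shared). Two simplifications relative to a
fielded survey: real designs use orthogonal or D-efficient level
allocation, not uniform draws (externally constructed designs can be read
in through the CSV interface), and the rotating-block schedule is a simple
round-robin rather than an optimized overlap. Respondent covariates default
to a commuter-cyclist-like mix (42% female, 40% aged 35+, 58% car-owning
households, 35% daily riders, commute split 45/35/20) and are configurable.

`simulate_choices()` inverts the model: draw each respondent's segment from
the membership logit, draw respondent-level coefficients if the segment is
mixed, then draw each scenario's choice from the segment's RUM or RRM
probabilities. True segment labels ride along as an attribute for
diagnostics but are never visible to estimation.

Passing parameter recovery on these panels shows the estimator is correct
*under its own assumptions* — logit kernels, normal mixing, independent
uniform attribute levels, no scale heterogeneity, no attribute
non-attendance. It does not certify behavior on real survey data, where
attribute correlation, lexicographic responders and design artifacts all
exist.

## Problem sizes used in validation

The acceptance checks run at the scales a desk validation supports:
parameter recovery uses 2,000 respondents (10,000 choice observations) from
a well-separated one-RUM-plus-one-RRM truth with five optimizer starts;
composition search uses 800 respondents for the one-class check and 1,200
for the two-class check with three starts each. Closed-form checks (fit
statistics, trade-off ratios, kernel oracles) are instantaneous. Published
coefficient tables are reproduced only where they are closed-form functions
of printed inputs; re-estimating a survey's coefficient tables requires the
survey's raw responses, which are not redistributable here.

## Known limitations

* No correlated (full-covariance) random coefficients, no lognormal or
  triangular mixing, no scale-heterogeneity (G-MNL) variants, no nested
  logit, and no hybrid RRM generalizations (muRRM, P-RRM).
* Membership covariates enter linearly in the logit; no covariate selection
  is automated.
* The greedy composition search can in principle stop at a local BIC
  optimum; the exhaustive flag trades time for certainty.
* Standard errors assume a correctly specified likelihood (no sandwich
  correction), and simulated-likelihood noise at small draw counts biases
  spreads toward zero — use more draws when mixing matters.
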