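---
title: "Methods: choice-experiment design and analysis for ICU admission preferences"
author: "icudce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: choice-experiment design and analysis for ICU admission preferences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icudce)
```

## The problem

When a ward patient deteriorates, an ICU consultant must decide whether to
admit them to intensive care. These decisions are made under time pressure
with limited prognostic support, and they vary between clinicians. A
discrete choice experiment (DCE) makes the implicit weighting of patient
factors measurable: consultants are shown pairs of hypothetical patient
profiles built from eight attributes (age; type and severity of the main
comorbidity; the family's view on admission; functional status; acute
severity as a NEWS band; the registrar's subjective report; ward nursing
capacity) and answer three questions per pair — admit A? admit B? who gets
priority? The answers identify, up to scale, a linear utility index
$V(x) = \sum_k \beta_{k,\ell(x_k)}$ over dummy-coded attribute levels, with
one reference level per attribute fixed at $\beta = 0$.

`icudce` implements the full pipeline: efficient design of the choice
tasks, simulation of a synthetic respondent population, response-quality
screening, pooled logit estimation with cluster-robust inference,
range-based relative importance (RI), latent-class preference segmentation,
and the comorbidity type-by-severity interaction analysis.

## Choice-task design

Tasks are paired profiles. For the paired conditional logit the information
contributed by a task with profiles $a, b$ at coefficients $\beta$ is
$p(1-p)\,dd^\top$ with $d = x_a - x_b$ and $p = \operatorname{logit}^{-1}(d^\top\beta)$.
The design criterion is the **D-error** $\det(M)^{-1/K}$ of the summed
information $M$; lower is better. `generate_design()` minimizes it by
coordinate exchange: starting from a random valid design, each sweep visits
every (task, alternative, attribute) cell in seed-randomized order and
accepts the first strictly improving level swap. The acceptance rule makes
the search monotone, so the result never has a higher D-error than its
start. The prior is $\beta = 0$ (utility-neutral) by default; the original
study cites "experimental design methods" without naming a criterion, so
the choice of D-error minimization under a zero prior is this package's own
reconstruction of standard practice — both the criterion's prior and the
number of sweeps are arguments.

Constraints maintained throughout the search: the two profiles of a task
differ; no task is a dominance pair (one profile at least as desirable on
every *ordinal* attribute and strictly better on one); no two tasks repeat
the same unordered pair. Ordinal flags mark attributes with a defensible
desirability ordering — younger age, milder comorbidity, better functional
status, a more supportive family. Acute severity, the registrar's report,
ward capacity and comorbidity type are deliberately non-ordinal: whether a
sicker patient is a "better" admission candidate is exactly the judgement
the experiment measures, so those attributes never enter dominance logic.

The study configuration is 24 tasks in 2 blocks of 12 (each respondent sees
one block). `inject_quality_tasks()` adds three non-estimation tasks per
block: a warm-up (random valid pair), a dominance pair (ordinal attributes
set to best versus worst, non-ordinal attributes held equal), and an exact
repeat of one randomly chosen standard task in the block.

## Estimation

The spec of the original analysis leaves open how the three answers per
task enter the likelihood. The package's default treats the two binary
admit answers as the estimation target, pooled across alternatives:

$$\Pr(\text{admit} \mid x) = \operatorname{logit}^{-1}(\alpha + V(x)),$$

maximized by Newton-Raphson with step-halving (gradient max-norm tolerance
$10^{-8}$, at most 100 iterations). This matches the reported quantity —
odds ratios for *admission*. The priority answers are fitted separately as
a paired conditional logit (`model = "priority"`, difference coding, no
intercept), which recovers the same preference vector up to choice-scale
and serves as a cross-check. Standard errors are cluster-robust sandwich
estimates by respondent with a $G/(G-1)$ correction, since each respondent
contributes 24 correlated answers. Warm-up tasks are always excluded;
repeat and dominance tasks are excluded by default so quality checks do not
double-count information.

Numerical guards: rank-deficient design matrices are rejected with the
collinear columns named; a fitted coefficient exceeding 15 in absolute
value (odds ratio above three million) is reported as perfect separation
rather than returned.

## Relative importance

An attribute's range is the spread of its level coefficients with the
reference counted at zero, $r_k = \max(0, \beta_{k\cdot}) - \min(0,
\beta_{k\cdot})$, and its relative importance is $RI_k = 100\, r_k /
\sum_j r_j$, so the scores add to 100%. With eight attributes, equal
weighting puts every attribute at 12.5% (100/8) — the benchmark drawn in
the package's outputs. RI is computed from the admit-model coefficients and
never includes the intercept. Uncertainty is propagated by the parametric
bootstrap (Krinsky-Robb): draws from $N(\hat\beta, \hat V)$, RI recomputed
per draw, percentile 95% intervals.

## Latent classes

Preference heterogeneity is modelled as a finite mixture: respondent $n$
belongs to class $c$ with probability $\pi_c(z_n; \theta)$ — a multinomial
logit on respondent covariates (age band, years in ICU, ICU size, hospital
type, gender), reference class fixed at zero — and answers with
class-specific $\beta_c$. Estimation is EM (E-step: posterior
responsibilities; M-step: weighted logits for each $\beta_c$ and a weighted
multinomial logit for $\theta$) from random Dirichlet initializations,
followed by a BFGS polish of the observed-data likelihood with analytic
gradients. The observed-data log-likelihood is asserted to be
non-decreasing at every EM iteration; a decrease is a hard error, not a
warning. Starts in which a class's posterior mass falls below 1% of
respondents, or in which a weighted logit separates, are discarded as
degenerate. Labels are switched deterministically to descending share
order (ties by the first coefficient), so a fit is reproducible from its
seed. Membership standard errors come from the numerically differentiated
Hessian of the polished likelihood; when that Hessian is singular (for
example, constant covariates) they are reported as `NA`, never fabricated.

The number of classes is a model-selection question, not an input rule:
`select_classes()` scans a range of $C$ and flags the BIC minimizer, with
$n$ = number of respondents (the independent sampling units) in the BIC
penalty. The study's four-pattern solution is mirrored by `C = 4`.

## Type-by-severity interaction

`fit_interaction_model()` replaces the two comorbidity main-effect blocks
with one dummy per type-severity cell (12 cells minus the severe
prostate-cancer reference = 11 dummies), all other attributes unchanged.
Saturated cell coding is a reparameterization of main effects plus
products with identical fit; it is used because the quantity of interest is
each cell's odds ratio against the single reference cell.
`interaction_or_grid()` emits the 4 x 3 grid with a flag for intervals
crossing the null OR = 1.

## The synthetic world

No raw survey data are deposited, so every downstream stage is exercised on
simulated respondents. The generator's defaults are the study's stated
world:

* four preference classes — "age-oriented", "age-dominant", "holistic",
  "family-dominant" — with shares 0.310, 0.332, 0.174, 0.184;
* pooled odds-ratio anchors: age 39 vs 89 OR 12, 66 vs 89 OR 5, mild vs
  severe comorbidity OR 6.4, family against admission OR 1/6, and
  COPD/heart failure/dementia vs prostate cancer OR 1/1.04, 1/1.34,
  1/1.48;
* coefficients not pinned by a printed OR (moderate severity, family
  insists, functional status, NEWS bands, registrar report, ward capacity)
  are generator defaults chosen once so the pooled RI profile is ordered as
  reported (age 23.9% > family 19.9% > severity 17.9% > functional status >
  registrar report > NEWS 7.5% > type 3.8% > ward 2.5%); they are
  documented as defaults, not study facts;
* covariate marginals from the sample description (79.5% male, 21.1% under
  40, 28.1% over 50, 76.9% more than 10 years in ICU, 33.6% university
  hospital; the unreported ICU-size split is set to 30/40/30);
* membership coefficients emulating the reported significant effects
  (consultants over 40, and especially over 50, lean toward patterns 1 and
  3 rather than 4; medium-ICU consultants away from pattern 1;
  university-hospital consultants away from pattern 3), with intercepts
  calibrated so the population-average shares equal the printed shares;
* a `careless_rate` fraction of respondents (default 0.1) who answer
  uniformly at random with log-normal response times one fifth of the
  careful median — purely a fixture for the quality module.

**Calibration choice.** The printed pooled odds ratios are the output of a
pooled MNL fitted to a *heterogeneous* population. A mixture of logits is
not a logit; fitting one logit to mixture data recovers an attenuated
projection of the mean coefficient vector, and the attenuation depends on
the design's profile distribution. The generator therefore calibrates the
class coefficients (by an additive fixed point on a shared base vector,
class-specific attribute emphasis held fixed) so that the *pooled-logit
projection over the canonical study design* equals the printed
coefficients. Consequences worth knowing: the share-weighted mean of the
class betas is slightly larger in magnitude than the printed contrasts, and
the class intercepts are set so each class's mean admit probability over
the design is 0.5 (the intercept is not identified by any printed
quantity). A related caveat: the *raw marginal* odds ratio of admission by
age — ignoring the other seven attributes — is far smaller than 12 in this
world (odds ratios are not collapsible); only the adjusted, model-based OR
reproduces the printed values, which is also the only quantity the study
itself reports.

**What a green test does not establish.** The simulator draws independent
answers from exact logit probabilities with discrete, well-separated
classes. Real respondents exhibit scale heterogeneity, learning and fatigue
over the task sequence, attribute non-attendance, and continuous preference
variation; none of that is emulated, so passing recovery tests demonstrate
correctness of the estimators under the assumed model, not robustness to
model violation. Non-patient factors (bed availability, time of day) are
out of scope, as they were excluded from the original experiment.

## Quality screening

The four criteria are reconstructions (the defining supplement is not
available): desirability = prioritized the dominant profile in the
dominance task; stability = same priority answer on the repeat task as on
its original; logical consistency = when exactly one profile is admitted,
priority must name it, with at most `max_inconsistencies = 1` violation
tolerated; response time = median per-task time at least
`min_median_ms = 2000`. Both thresholds are arguments. Following the
original analysis, quality is reported but respondents are *not* dropped by
default (`drop_failures` exists for sensitivity analyses). Note that
probabilistic respondents legitimately fail stability sometimes — a repeat
task is re-answered, not copied — so even a fully careful simulated cohort
does not pass at 100%; deterministic fixtures are used where exact pass
behaviour is asserted.

## Numerical and testing choices

* All randomness flows through explicit integer seeds; seeded functions
  restore the caller's RNG state. Identical configuration and seed give
  byte-identical artifacts.
* Calibration fixed points (population projection, membership intercepts)
  iterate to residuals below 1e-8 / 1e-12 and are deterministic.
* The acceptance-criteria suite runs the latent-class recovery with 4 EM
  starts (package default 20) and the RI coverage check at 8 replicates of
  n = 800 (rather than 20 of n = 2000) to stay inside a CI time budget;
  the monotonicity assertion still runs on every EM iteration of every
  start.
* The interaction likelihood-ratio calibration uses 200 replicates of
  n = 60 respondents under an additive single-class generator, comparing
  the rejection rate at the 0.05 level against three Monte-Carlo standard
  errors.

## Known limitations

* The D-error search is a local first-improvement exchange; it is seeded
  and restartable but not guaranteed globally optimal (the random-search
  comparison test bounds how bad it can be).
* The latent-class likelihood is multimodal; the default of 20 random
  starts is a pragmatic, not exhaustive, defence.
* Sample-size planning, Bayesian-prior efficient designs, partial
  profiles, mixed logit, and survey delivery are out of scope.
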