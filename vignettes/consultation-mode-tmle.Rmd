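---
title: "Targeted learning of consultation-mode effects on antibiotic prescribing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted learning of consultation-mode effects on antibiotic prescribing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the estimands

Remote (telephone, video, SMS, online) GP consultations became routine in
English primary care after 2020, and there is concern that clinicians who
cannot examine a patient prescribe antibiotics more readily. The package
estimates the causal effect of consultation mode on antibiotic prescribing
for acute respiratory infection (ARI) episodes, comparing pure-remote
episodes (exposure $A=1$) against face-to-face or mixed episodes ($A=0$).

With $Y$ the binary any-antibiotic outcome and $W$ the episode covariates,
the targets are the average treatment effect and the marginal odds ratio

$$\psi = \psi_1 - \psi_0, \qquad
\mathrm{OR} = \frac{\psi_1/(1-\psi_1)}{\psi_0/(1-\psi_0)},
\qquad \psi_a = E\big[E[Y \mid A=a, W]\big].$$

Identification needs no unmeasured confounding given $W$, positivity
(every covariate stratum can plausibly receive either mode — diagnosed
here through propensity-score extremes), and no interference between
episodes.

## Targeted maximum likelihood estimation

`tmle_fit()` implements the standard one-dimensional fluctuation for a
binary outcome:

1. Initial estimates: a propensity model $g(W) = P(A=1\mid W)$ and an
   outcome model $Q_0(A, W) = E[Y \mid A, W]$, both fitted by the
   cross-validated superlearner below.
2. The clever covariate $H(A, W) = A/g(W) - (1-A)/(1-g(W))$.
3. The fluctuation $\operatorname{logit} Q^*(A,W) =
   \operatorname{logit} Q_0(A,W) + \varepsilon H(A,W)$, with
   $\varepsilon$ the maximum-likelihood solution of a one-parameter
   logistic model with offset. `fluctuate()` solves it by Newton-Raphson
   with the analytic gradient and step-halving, to a mean-score tolerance
   of $10^{-10}$; at the solution the efficient-score equation
   $\tfrac1n\sum_i H_i (Y_i - Q^*_i) = 0$ holds, which is what gives the
   estimator its double robustness.
4. Plug-in: $\hat\psi_a = \tfrac1n\sum_i Q^*(a, W_i)$, with the ATE and
   marginal OR formed from $\hat\psi_1, \hat\psi_0$.
5. Inference from the efficient influence curve
   $D_a = \tfrac{\mathbb 1\{A=a\}}{P(A=a\mid W)}(Y - Q^*) + Q^*(a,W) - \psi_a$:
   $\mathrm{SE} = \mathrm{sd}(D)/\sqrt n$, OR inference on the log scale by
   the delta method, and intervals using the 1.96 normal quantile.

Design choices where the procedure was genuinely open:

* **Fluctuation form.** The signed single-$\varepsilon$ submodel is the
  default; the weighted two-parameter variant (one intercept per arm,
  weights $1/P(A=a\mid W)$) is a recognised alternative but is not needed
  for the desk-scale designs here, so only the standard form is shipped.
* **Propensity clipping.** Bounds default to $[0.005, 0.995]$ —
  deliberately loose, because propensity extremes in the 0.04–0.96
  range are expected in this setting and should be surfaced by the
  positivity diagnostics rather than truncated away. Both bounds are
  configurable (`g_bounds`).
* **Variance.** The default is the individual-level empirical
  influence-curve SE. Because episodes cluster in practices, a
  cluster-robust option (`variance = "cluster"`, practice-summed
  influence curves with an $m/(m-1)$ correction) is provided; the package
  leaves the choice to the analyst because the intra-practice correlation
  the generator induces is largely absorbed by the practice-level
  covariates (prior-year prescribing and consultation rates).
* **Degenerate inputs.** Probabilities are clipped to $[10^{-6},
  1-10^{-6}]$ before any logit; a targeted mean pinned at a clipping
  bound aborts rather than returning a vacuous interval; a single-arm
  stratum is an error, not a warning.

## The superlearner

Both nuisance models are stacked ensembles over a pluggable learner
library behind one `fit`/`predict`-probability interface
(`learner_library()`):

| profile | learners |
|---|---|
| `default` | logistic; GAM (smooth terms, `mgcv`); random forest (`ranger`); gradient boosting (`xgboost`); natural-cubic-spline logistic; L1-penalised logistic (`glmnet`) |
| `fast` | logistic; L1 logistic; shallow boosting (depth 2, 30 rounds) |
| `glm` | logistic only |

The six `default` families span the model classes commonly combined in
applied targeted-learning analyses (a plain parametric model, an
additive model, two tree ensembles, a spline family, a sparse
penalised model). The adaptive-spline slot is filled by a natural-cubic-spline
logistic learner built on `splines::ns` (df 4 per continuous covariate).
The `fast` profile exists because the simulation studies below need
hundreds of refits; its hyperparameters (30 boosting rounds at depth 2,
BIC-selected lasso path) were fixed when the profile was defined.
Hyperparameters are all exposed in the learner constructors rather than
hard-coded, since reasonable defaults — not tuned values — are all that
desk-scale data support. The L1 learner selects its penalty by training
BIC along the `glmnet` path instead of nested cross-validation, keeping
the whole stack at one level of cross-validation.

**Folds.** `make_folds()` assigns whole practices to K = 10 folds
(every episode of a practice shares a fold, which also nests the
patient level, because a patient belongs to one practice). Outcome
stratification under clustering is done by sorting practices by outcome
prevalence, dealing them to folds serpentine-style, then rebalancing
fold sizes with pairwise swaps that never worsen the spread of
fold-level prevalence. This is one reasonable algorithm for a
constraint (cluster-respecting, outcome-stratified) that has no single
standard implementation; it is deterministic given a seed and is
validated in the tests against random cluster assignment.

**Metalearner.** Non-negative least squares (Lawson–Hanson, via
`pracma::lsqnonneg`) on the out-of-fold prediction matrix, weights then
normalised to the simplex. The normalisation can move the training-
criterion optimum by $O((1-\sum\alpha)^2)$, which is negligible for
probability columns but is why the optimality test carries a small
slack. A discrete metalearner (all weight on the best single learner)
is available for testing even though it is not the default. A learner
that fails on any fold is dropped entirely with a warning — never
silently replaced by zeros.

## The synthetic EHR generator

No public data carries the structure this analysis needs (patients in
practices, repeated ARI consultations, mode markers, linkable
prescriptions), so `generate_study()` produces it synthetically with a
known causal truth:

* **Covariate law.** ~30% of patients are children (under 16); child
  ages are drawn skewed-young (median ≈ 4y) and adult ages with median
  ≈ 49y; sex, IMD quintile, ethnicity (with an explicit missing
  category), and comorbidity flags are Bernoulli/categorical with
  prevalences chosen to resemble a primary-care ARI cohort. These
  prevalences are free parameters of the generator, not calibrated
  quantities.
* **Structural models.** Consultation mode and prescribing follow
  logistic models in a fixed set of named terms (age, child, sex, IMD,
  infection subtype with URTI as reference, urban practice, GP-registrar
  role) plus practice random intercepts. Subtype mixes differ for adults
  and children (URTI dominant in both; LRTI mostly adult, otitis media
  mostly paediatric), which together with the subtype coefficients is
  the main engine of confounding: prescribing-heavy subtypes are also
  mode-predictive.
* **Ground truth.** `true_marginal_effects()` integrates the outcome
  model over the covariate law by Monte Carlo, setting $A$ to 1 and 0,
  and reports the marginal ATE and OR with a Monte-Carlo SE. The default
  treatment coefficient (0.27) was calibrated once with
  `calibrate_treatment_coef()` so the implied true marginal OR is 1.25,
  the design point of the recovery simulations.
* **Record-level noise.** Repeat consultation records within the 7-day
  episode window (rate 0.45 per index consultation, mostly same-day,
  so raw records outnumber episodes by roughly 1.46 — typical of
  repeat-contact behaviour in primary-care event data); 10% of
  face-to-face records carry an `unknown` mode marker; 5%
  of episodes mix both modes; 2.5% of consultations carry a second
  subtype code.
* **Determinism.** A single root seed feeds named per-stage streams
  (practices, patients, episodes, consultations, prescriptions,
  prevalence), so identical configurations are byte-identical and
  extending one stage never perturbs another.

Three generator choices keep the ground truth exactly the estimand the
analysis targets, and are deliberate simplifications:

* The practice random effects of the mode and outcome models are drawn
  **independently**. A shared effect would be unmeasured practice-level
  confounding, invalidating the oracle; independence preserves
  intra-practice correlation (the reason for clustered CV) without it.
* `unknown` markers only mask **face-to-face** records, so the
  assume-face-to-face classification rule is correct by construction.
* A mixed episode's outcome is generated under exposure 0, matching the
  analysis rule that mixed episodes are analysed in the face-to-face
  arm.

The generator makes no attempt at clinical-code realism (subtype labels
stand in for codelists), free text, differential coding quality by mode,
or realistic within-practice patient flows. Passing tests therefore show
that the estimator works when its structural assumptions hold and the
covariate set is sufficient — not that any real-data estimate is
unbiased.

## Cohort and covariate rules

* **Episodes.** GP-only ARI consultations are grouped per patient with an
  anchored 7-day window: a record joins an episode iff its date is
  strictly within 7 days of the episode's first date (days 0–6), so an
  episode spans at most 7 calendar days and keeps the first date. A
  rolling (chained) variant is available (`grouping = "rolling"`)
  because the published description does not pin the boundary; anchored
  is the default as it is the reading most consistent with "retaining
  the date of first consultation". Day-6 plus day-12 records therefore
  form two episodes under the default.
* **Arms.** All-remote episodes are arm 1; face-to-face and mixed are
  arm 0; `drop_mixed = TRUE` reruns without mixed episodes.
* **Outcome linkage.** An antibiotic prescription links by explicit
  consultation ID (any date) or by sharing a date with any grouped
  consultation.
* **Eligibility.** Recorded male/female sex, recorded IMD, index date in
  the analysis window. Children are `age at index < 16` completed years
  (the boundary the text fixes, where the table's "(0–16)"/"(16+)"
  labels are ambiguous); age enters the covariate set fractionally.
* **Lookbacks** are half-open $[t-w, t)$ for $w \in \{7, 30, 365\}$
  days: events "before the consultation" exclude the index day itself.
  The full grid (consultations, ARI consultations and antibiotics, by
  mode, plus recorded-COVID flags) is emitted for all three windows.
* **Practice rates** are events per 10,000 registered patient-days over
  the 365 days before index, with patient-days accumulated from exact
  registration spans.
* **Prevalence** joins last-observation-carried-forward from the weekly
  regional series.
* **Encoding** is one-hot with explicit, schema-recorded reference
  levels; missingness is a category (ethnicity), never imputed; the
  child stratum drops adult-only comorbidity columns.

## Balance and positivity diagnostics

`balance_report()` computes standardized mean differences with the
unweighted two-group pooled SD (the standard Austin form), flags
SMD > 0.10, reports
multi-level categoricals both per level and as the per-level maximum,
and marks comparisons suppressed when either arm holds fewer than 10
episodes. Suppression in `summary_table()` is presentational only:
unsuppressed cells are identical with and without it.
`positivity_report()` returns propensity extremes and the share outside
configurable bounds, warning — never erroring — on breaches.

## Simulation designs and problem sizes

The package validates itself at three scales, chosen so the full suite
runs comfortably on a single CPU:

* **CI calibration:** 200 generate–analyse replicates of ~2,000 episodes
  (42 practices × 60 patients) under the OR-1.25 design, fast learner
  profile, K = 10. Nominal 95% intervals must cover the truth within the
  99% binomial band for 200 draws, [90.8%, 98.0%].
* **Recovery:** one ~20,000-episode study (250 practices × 92 patients);
  the ATE must land within 3 SEs of the Monte-Carlo truth.
* **Double robustness:** 50,000-episode draws from the structural law
  under a deliberately one-directional confounding design (mode and
  outcome coefficients aligned in sign, no random effects, no mixed
  episodes, so parametric working models in the structural terms are
  exactly correct). TMLE with an intercept-only outcome model but
  correct propensity, and vice versa, must be nearly unbiased
  (|bias| < 0.01); with both intercept-only it collapses to the crude
  contrast and stays heavily biased (> 0.02).

## Limitations

* The generator's covariate law is stylised; lookback counts and
  prevalence are noise covariates rather than structural confounders, so
  the simulations do not probe time-varying confounding.
* No CV-TMLE: nuisance models are refit on the full data for prediction,
  as in the standard single-cross-validation stack.
* No missing-outcome machinery and no continuous or time-varying
  exposures.
* The interface is the R functions themselves (`run_all()`,
  `simulate_calibration()` and the module functions); there is no shell
  CLI.
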