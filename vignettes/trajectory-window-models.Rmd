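---
title: "Trajectory groups and sliding-window marginal structural models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory groups and sliding-window marginal structural models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrmsm)
```

## The problem

Longitudinal treatment data — a binary treatment indicator recorded month
after month, together with time-varying covariates and an absorbing
time-to-event outcome — raise two entangled difficulties. First, the number
of distinct treatment trajectories grows as $2^K$ with follow-up length
$K$, so trajectory-specific effects are not estimable without some
summary. Second, time-varying covariates can be *both* confounders of later
treatment and consequences of earlier treatment (treatment–confounder
feedback), which makes naive regression adjustment invalid.

`hrmsm` addresses both at once:

1. **Sliding windows.** Follow-up is cut into overlapping windows of $s$
   consecutive treatment times; window $d$ covers times $d, \dots, d+s-1$
   and reads the outcome at $d+s$. Only individuals still event-free at the
   window start ($Y_d = 0$) are at risk in window $d$, and an event during
   a window's exposure times is recoded as censoring within that window
   (its outcome still propagates). This yields the *history-restricted*
   marginal structural model (HRMSM): the causal contrast at any outcome
   time is indexed by the *recent* treatment history only, which avoids the
   interpretational problems of hazard ratios and of survival curves built
   from window-specific fits.

2. **Trajectory groups.** The $2^s$ within-window treatment sequences are
   summarised by a latent class growth analysis (LCGA): a finite mixture of
   logistic trajectory curves fit to all windows pooled. Each observed
   window sequence and each deterministic regime is assigned to its modal
   group.

3. **A log-linear working model.** The causal estimand is the projection of
   the window- and regime-specific counterfactual risks
   $\mu_d(\bar a_d) = E[Y_{d+s}^{\bar a_d} \mid Y_d = 0]$, defined under
   the regime *and* the no-censoring intervention. Because events during a
   window's exposure times are coded as censoring, that intervention also
   prevents events strictly inside the window: $\mu_d$ is the risk of a
   first event at the window-end time among individuals event-free through
   the exposure times — a discrete-time hazard indexed by the recent
   treatment history, not a cumulative risk. (The ground-truth simulator
   suppresses interior-window events accordingly, so the Monte-Carlo truth
   and all three estimators target the same quantity.) These risks are
   projected onto
   $\log m(\bar a_d \mid \beta) = \beta_{0,d} + \beta_1 z_1(\bar a_d) +
   \dots + \beta_{J-1} z_{J-1}(\bar a_d)$,
   with projection weights $\lambda_d(\bar a_d)$ and either the
   log-binomial or the Poisson negative log-likelihood as loss.
   $\exp(\beta_k)$ is the relative risk of trajectory group $k$ versus the
   reference (lowest-adherence) group.

Three estimators of $\beta$ are provided: inverse probability of treatment
and censoring weighting (IPTW), iterated-conditional-expectation (ICE)
g-computation with block-bootstrap inference, and a pooled longitudinal
targeted maximum likelihood estimator (LTMLE) whose influence-curve
variance corrects for the correlation induced by individuals contributing
several overlapping windows.

## Data model and conventions

A panel is long-format: one row per individual and time with columns `id,
t, A, C, Y, L*, V*`. Time is 1-based and consecutive; $Y_1 = 0$ for
everyone; $Y$ and $C$ are absorbing; after censoring all later values are
missing. Within a time point the order is outcome, treatment, covariate:
the treatment model at time $t$ conditions on covariates through $t-1$,
while the iterated outcome regressions condition on covariates through the
current time.

`build_augmented()` stacks the windows: each at-risk `(id, d)` pair
becomes one row holding the within-window treatments `a1..as`, censoring
flags, the window-end outcome, and a completeness indicator. Events during
the exposure follow-up are coded as censoring from the event time on, with
the reason kept for diagnostics; estimators treat loss to follow-up and
event-censoring identically.

## The trajectory model, and a warning about short windows

The LCGA likelihood for a window row with observed entries
$a_j$ is $\sum_k \pi_k \prod_j p_{kj}^{a_j}(1-p_{kj})^{1-a_j}$ with
$p_{kj} = \operatorname{expit}(\theta_k^\top b(j))$ over within-window
time $j = 1..s$; censored entries simply drop out of the product (missing
at random). The EM collapses rows to unique observed patterns, so its cost
does not grow with $n$.

Short windows deserve a warning that standard LCGA software will not give
you. A length-3 binary sequence has $2^3 = 8$ cells, i.e. 7 degrees of
freedom, while a 3-class mixture with class-specific intercepts *and*
slopes has 8 free parameters. The likelihood is then a ridge: runs from
different starts reach solutions with indistinguishable likelihood but
*completely different* group partitions (often two near-duplicate classes,
or a class that is never any pattern's modal class). Three defaults in
`fit_lcga()` address this, and each can be switched off:

* `share_slope = TRUE`: the time-basis coefficients are common to all
  classes and only the adherence levels (intercepts) differ, removing the
  excess parameter. Class-specific slopes remain available for longer
  windows.
* Starts are explored in a fixed seeded order, and the first solution in
  which **every group is the modal class of at least one observed
  pattern** is retained. A group that wins no pattern leaves the
  downstream working model unidentified (its dummy column is empty), so
  such solutions are only kept as a last resort; and because likelihood
  differences along the ridge are far below sampling noise, discriminating
  by likelihood would let the retained partition flip haphazardly between
  datasets.
* The deterministic first start places flat trajectories at $J$ adherence
  levels equally spaced over the observed range of sequence means, with
  equal priors.

Groups are relabelled after fitting: the lowest-adherence class is the
reference (group $J$), and the remaining classes are numbered by
*increasing* adherence, so group $J-1$ is the highest-adherence group.
Posterior assignment (class prior times likelihood) is used both for
observed rows and for deterministic regimes, with ties broken toward the
lower label.

Model selection is deliberately out of scope: $J$ and the basis are user
inputs, and the fitted object reports log-likelihood and class structure
as diagnostics. Groups are best read as points of support for the
projection, not as a claim about the true data-generating mixture.

## Nuisance models

* **Treatment and censoring.** One logistic model per window and
  within-window time, fit on the window's at-risk set among rows still
  uncensored; the default history is every earlier treatment and
  time-varying covariate plus the baseline covariates. Windows without
  censoring give degenerate censoring models contributing a factor of one.
  Separated or rank-deficient fits fall back to a lightly ridge-penalised
  logistic (penalty $10^{-6}$) and are flagged.
* **Projection weights** $\lambda_d$: either 1 for every regime
  (unstabilized) or the empirical regime frequency among complete at-risk
  rows (stabilized — the saturated estimate of the marginal within-window
  treatment law). The two modes target *different* projections whenever
  risks vary within a group, so the same mode should be used for an
  estimator and for any ground truth it is compared against.
* **Q models.** The iterated outcome regressions default to the
  within-window treatment and covariate history plus baseline covariates,
  on the logit link with quasi-binomial fitting (iterated outcomes are
  fractional after the first step).

## Estimators

**IPTW** weights each complete at-risk row by
$\lambda_d(\bar a_{\mathrm{obs}}) / \prod_{j} g_{d,j}$, the denominator
being the cumulative probability of the observed treatments times the
probability of remaining uncensored, and fits the weighted log-link
working model with a cluster-robust (by individual) sandwich variance that
treats the weights as known — conservative by construction. Estimated
cumulative probabilities below $10^{-12}$ abort with a positivity
diagnostic rather than producing silent extreme weights.

**ICE g-computation** runs a backward recursion per window and regime:
starting from the window-end outcome, regress the current iterated outcome
on the observed history among rows still uncensored at the relevant time,
predict with the within-window treatments set to the regime, and average
the final predictions over the window's at-risk set. The $2^s \times D$
grid of counterfactual means is projected onto the groups with weights
$\lambda$. Standard errors come from a block bootstrap that resamples
individuals with all their windows and re-runs nuisance fits and the
estimator — but never the LCGA, whose data-driven estimation is ancillary
to $\beta$. Default 50 replications for simulation work, 100 recommended
for applications.

**Pooled LTMLE** starts from the ICE estimates and, at every backward
step, fluctuates them by a pooled intercept-free logistic regression
across all $2^s$ regimes on the clever covariates
$H_{d,j} = \mathbf{1}(\bar A_{d,j} = \bar a_{d,j},\ \text{uncensored})
\big/ \prod_{t\le j} g_{d,t} \times \lambda(\bar a_d) \times
\partial_\beta m \cdot \mathrm{Var}^{-1}m$,
with the logit of the current predictions as offset. The
$\partial_\beta m \cdot \mathrm{Var}^{-1} m$ factor is the regime's design
row $(1, z_1, \dots, z_{J-1})$ for the Poisson loss, scaled by
$1/(1-m)$ for the log-binomial loss, evaluated at coefficients anchored at
the g-computation projection (no outer loop). Updates of the
regime-specific predictions use the clever covariate at the intervened
exposure (indicator replaced by one, cumulative probability evaluated at
the regime). Cumulative probabilities are bounded below at 0.01 before
inversion — the conventional bound in longitudinal targeted estimation;
without it the fluctuation is erratic for rarely observed regimes.

The LTMLE variance maps per-individual influence pieces — the
inverse-probability-weighted fluctuation residuals summed over backward
steps plus the exactly-centred projection residual — through the inverse
bread of the projection regression, scales window $d$'s contributions by
$n/n_d$, and sums within individuals across windows before taking the
empirical second moment. Because risk sets are nested, this is
algebraically identical to the decomposition
$(1/n^2)\left[\sum_d n_d \sigma_d^2 +
2 \sum_{d<d'} n_{d'} \rho_{d,d'}\right]$,
and both forms are computed and cross-checked. With a single window it
reduces to $\sigma_1^2/n$. Note what this variance conditions on: the
trajectory model. Variability from refitting the LCGA on new data is
invisible to it, which is the main source of the mild under-coverage seen
in the replication study below.

## Working-model numerics

The log-link fits are solved by iteratively reweighted least squares with
a convergence certificate: the weighted score at the solution
(`score_residual()`) must vanish. For the log-binomial loss, step-halving
(up to 20 halvings) keeps every fitted mean strictly below one; a fit
stopping at the iteration cap is returned with `converged = FALSE` rather
than discarded — boundary log-binomial problems are a known feature of
log-link risk regression, and discarding them would bias summaries.
Multiplying all weights by a constant provably leaves the solution
unchanged, and saturated designs give identical coefficients under both
losses (group means are then free parameters).

## The simulator and what the replication study shows

`generate_observed()` draws cohorts from a structural model with a scalar
baseline covariate $V = N(0,1)/4 + 1$, a binary time-varying covariate
with treatment–confounder feedback, strong treatment persistence, and an
absorbing outcome that can first occur at time 4; scenarios truncate
follow-up to give 1, 2 or 3 windows of length 3. All conditional
probabilities are strictly interior, so positivity holds by construction.
In this mechanism sustained treatment *raises* the window-end risk, both
directly and through the covariate; the simulator exposes a null-effect
variant (`a_effect = 0`) and a no-confounding variant for diagnostics.

Ground truth is computed by t-specific counterfactual simulation: within
the window treatments are fixed to a regime, before the window they follow
the observed law, and the risk among window-start survivors is averaged
over Monte-Carlo replicates (`true_counterfactual_means()`); an exact
enumeration over the discrete covariate paths and a dense $V$ grid serves
as an independent oracle in the tests. The true coefficients are the
projection of these means using the regime-to-group map and weights from
one large simulated cohort.

`run_study()` replicates the full pipeline and reports bias, the
empirical standard deviation of the estimates (SEE, the headline
dispersion; the mean estimated SE is reported alongside), and 95% Wald
coverage using each estimator's own variance. Replicate seeds derive
deterministically from the master seed; hard estimator failures are
recorded and excluded with a count, while non-converged log-binomial fits
with finite estimates are *included* (their convergence flag is tallied).
Problem sizes used by the packaged replication (200 replicates of
$n = 5000$, Monte-Carlo truth from $20 \times 25{,}000$ draws per regime
and window) were chosen so the Monte-Carlo error of a bias cell is a few
thousandths — small against the effects of interest.

What passing the replication does and does not show: the simulator has no
loss to follow-up (event-recoding still exercises the censoring
machinery), one binary covariate, and strong treatment persistence, so the
study probes confounding control and window pooling, not missing-data
robustness or high-dimensional adjustment. And because the short-window
LCGA is only set-identified (see above), operating characteristics of the
*crude* comparator in particular depend on which partition convention is
used; with this package's convention the crude high-adherence contrast is
biased by about $-0.10$ to $-0.13$ while its standard error remains near
$0.09$ (the low-adherence reference holds only a few hundred individuals),
so its nominal 95% coverage erodes to roughly 75% rather than collapsing
outright. The doubly robust estimators are unbiased under the same
convention, which is the substantive point.

## Known limitations

* Hard (modal) classification; classification-uncertainty propagation is
  not implemented.
* Covariate-independent class membership; no growth-mixture random
  effects; no not-missing-at-random extensions.
* Binary treatments only, fixed window length, single absorbing event (no
  recurrent events).
* The influence-curve variance conditions on the fitted trajectory model;
  when the mixture is weakly identified its coverage is anti-conservative.
  The block bootstrap (which also holds the LCGA fixed, by design) shares
  this property.
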