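#' Simulated longitudinal cohort with treatment-confounder feedback
#'
#' [generate_observed()] draws a seeded cohort from a structural model with a
#' continuous baseline covariate `V`, a binary time-varying covariate `L`
#' that both confounds and is affected by treatment, a binary treatment `A`,
#' and an absorbing binary outcome `Y` that can first occur at time 4. The
#' three scenarios truncate follow-up so that 1, 2 or 3 sliding windows of
#' length `s = 3` are available (outcome times 4, 5, 6). Treatment *raises*
#' the event risk in this mechanism (the `-0.5 A` term sits inside the
#' complemented expit of the event probability), both directly and through
#' the covariate; the structural equations keep all conditional
#' probabilities strictly inside (0, 1), so positivity holds by
#' construction. There is no loss to
#' follow-up in the simulated observed data; the censoring machinery is
#' still exercised because events occurring during the exposure follow-up of
#' later windows are recoded as censoring when the augmented dataset is
#' built.
#'
#' Structural equations (time order `Y_t`, `L_t`, `A_t` within a time):
#' \deqn{V = N(0,1)/4 + 1}
#' \deqn{A_1 ~ Bern(expit(-0.5 + 2.5 V)),\quad L_1 ~ Bern(expit(1 + V + 0.5 A_1))}
#' \deqn{A_t ~ Bern(expit(-0.5 + V + 1.2 L_{t-1})),\quad t \ge 2}
#' \deqn{L_t ~ Bern(expit(1 + L_{t-1} + 0.5 A_t)),\ t = 2..4;\quad
#'       L_5 ~ Bern(expit(1 + L_4 + 0.5 A_4))}
#' \deqn{Y_4|Y_3=0 ~ Bern(1 - expit(1 + V - 0.7 L_3 - 0.5 A_3))}
#' \deqn{Y_5|Y_4=0 ~ Bern(1 - expit(0.8 V - 0.7 L_4 - 0.5 A_4))}
#' \deqn{Y_6|Y_5=0 ~ Bern(1 - expit(0.5 V - 0.7 L_5 - 0.5 A_5))}
#' `Y_1 = Y_2 = Y_3 = 0` structurally and `Y` is absorbing.
#'
#' @param n number of individuals.
#' @param scenario number of length-3 windows: 1 (times 1..4), 2 (times
#'   1..5) or 3 (times 1..6).
#' @param seed integer seed; identical seeds give identical panels.
#' @param a_effect treatment coefficient in the outcome equations (default
#'   -0.5 on the "no event" linear predictor; set to 0 for a null-effect
#'   variant).
#' @param confounded if `FALSE`, treatment is drawn Bernoulli(0.5)
#'   independently of `V` and `L` (a no-confounding variant used for
#'   diagnostics).
#' @return an [as_longitudinal_panel()] object in long format with columns
#'   `id, t, A, C, Y, L, V` (`A`, `L` are `NA` at the final outcome-only
#'   time; `C` is 0 throughout).
#' @export
generate_observed <- function(n, scenario = 1, seed = 1, a_effect = -0.5,
                              confounded = TRUE) {
  scenario <- match.arg(as.character(scenario), c("1", "2", "3"))
  Tmax <- c("1" = 4L, "2" = 5L, "3" = 6L)[[scenario]]
  set.seed(seed)
  sim <- simulate_paths(n, Tmax, regime = NULL, window_start = NA,
                        a_effect = a_effect, confounded = confounded)
  paths_to_panel(sim, Tmax)
}

# core structural-equation engine. If `regime` is a 0/1 vector of length s,
# treatments at times window_start .. window_start+s-1 are set to it; earlier
# treatments follow the observed law. `suppress_y` lists times at which the
# event draw is forced to zero (the no-censoring intervention of a window
# prevents events strictly inside its exposure period).
simulate_paths <- function(n, Tmax, regime = NULL, window_start = NA,
                           a_effect = -0.5, confounded = TRUE,
                           suppress_y = integer(0)) {
  rbern <- function(p) as.numeric(stats::runif(n) < p)
  V <- stats::rnorm(n) / 4 + 1
  A <- matrix(NA_real_, n, Tmax); L <- matrix(NA_real_, n, Tmax)
  Y <- matrix(0, n, Tmax)
  fixed_at <- function(t) {
    !is.null(regime) && t >= window_start && t <= window_start + length(regime) - 1L
  }
  draw_A <- function(t, lp) {
    if (fixed_at(t)) rep(regime[t - window_start + 1L], n)
    else if (confounded) rbern(expit(lp)) else rbern(rep(0.5, n))
  }
  n_treat <- min(Tmax, 5L)   # treatments/covariates exist through time 5
  for (t in seq_len(n_treat)) {
    if (t == 1L) {
      A[, 1] <- draw_A(1L, -0.5 + 2.5 * V)
      L[, 1] <- rbern(expit(1 + V + 0.5 * A[, 1]))
    } else {
      A[, t] <- draw_A(t, -0.5 + V + 1.2 * L[, t - 1])
      # L5 depends on A4 in this mechanism; L2..L4 on the concurrent A
      a_for_L <- if (t == 5L) A[, 4] else A[, t]
      L[, t] <- rbern(expit(1 + L[, t - 1] + 0.5 * a_for_L))
    }
  }
  # outcomes: Y_t realised at the START of time t (before L_t, A_t). Because
  # the hazards only depend on variables up to t-1, drawing them after the
  # loop is distributionally identical; absorption is applied in order.
  if (Tmax >= 4L) {
    h4 <- 1 - expit(1 + V - 0.7 * L[, 3] + a_effect * A[, 3])
    Y[, 4] <- if (4L %in% suppress_y) 0 else rbern(h4)
  }
  if (Tmax >= 5L) {
    h5 <- 1 - expit(0.8 * V - 0.7 * L[, 4] + a_effect * A[, 4])
    Y[, 5] <- if (5L %in% suppress_y) Y[, 4] else pmax(Y[, 4], rbern(h5))
  }
  if (Tmax >= 6L) {
    h6 <- 1 - expit(0.5 * V - 0.7 * L[, 5] + a_effect * A[, 5])
    Y[, 6] <- if (6L %in% suppress_y) Y[, 5] else pmax(Y[, 5], rbern(h6))
  }
  list(V = V, A = A, L = L, Y = Y, n = n, Tmax = Tmax)
}

paths_to_panel <- function(sim, Tmax) {
  n <- sim$n
  n_treat <- min(Tmax - 1L, 5L)
  long <- do.call(rbind, lapply(seq_len(Tmax), function(t) {
    data.frame(id = seq_len(n), t = t,
               A = if (t <= n_treat) sim$A[, t] else NA_real_,
               C = 0,
               Y = sim$Y[, t],
               L = if (t <= n_treat) sim$L[, t] else NA_real_,
               V = sim$V)
  }))
  long <- long[order(long$id, long$t), ]
  rownames(long) <- NULL
  as_longitudinal_panel(long, tv_covariates = "L", baseline = "V")
}

#' Draw a t-specific counterfactual cohort
#'
#' Same structural equations as [generate_observed()], except that the
#' treatments inside window `d` (times `d .. d+s-1`) are fixed to `regime`
#' while treatments before the window are left random under the observed
#' law. Used to compute ground-truth window-specific counterfactual risks.
#'
#' Because events occurring during a window's exposure follow-up are coded
#' as censoring, the no-censoring intervention of window `d` also prevents
#' events strictly inside the window: the event draws at times
#' `d+1 .. d+s-1` are suppressed, and the window-end outcome is the first
#' event at `d+s` among individuals event-free through the exposure times.
#' The window-specific counterfactual risk is therefore a discrete-time
#' hazard at the window end, not a cumulative risk over the window.
#'
#' @inheritParams generate_observed
#' @param regime 0/1 vector of length `s`.
#' @param d window index (window start time).
#' @param s window length.
#' @return a longitudinal panel; summaries should restrict to individuals
#'   with `Y_d = 0` (at risk at the window start).
#' @export
generate_counterfactual <- function(n, scenario, regime, d, s = 3, seed = 1,
                                    a_effect = -0.5) {
  scenario <- match.arg(as.character(scenario), c("1", "2", "3"))
  Tmax <- c("1" = 4L, "2" = 5L, "3" = 6L)[[scenario]]
  if (length(regime) != s) stop("regime length (", length(regime),
                                ") must equal the window length s (", s, ")")
  if (d < 1 || d + s > Tmax) stop("window index d = ", d, " is not valid for this scenario")
  set.seed(seed)
  sim <- simulate_paths(n, Tmax, regime = regime, window_start = d,
                        a_effect = a_effect,
                        suppress_y = seq_len(s - 1L) + d)
  paths_to_panel(sim, Tmax)
}

#' Monte-Carlo truth for window-specific counterfactual risks
#'
#' For every window `d` and every deterministic regime of length `s`,
#' estimates `E[Y_{d+s} | Y_d = 0]` under that regime (with events during
#' the exposure times prevented by the no-censoring intervention, see
#' [generate_counterfactual()]) by repeated counterfactual simulation,
#' together with its Monte-Carlo standard error.
#'
#' @inheritParams generate_observed
#' @param s window length.
#' @param mc_reps number of Monte-Carlo replicate datasets per regime.
#' @param mc_n individuals per replicate dataset.
#' @return a data frame with one row per `(d, regime)`: columns `d`,
#'   `regime` (string), `mean`, `mc_se`, `n_at_risk`.
#' @export
true_counterfactual_means <- function(scenario, s = 3, mc_reps = 100,
                                      mc_n = 10000, seed = 1, a_effect = -0.5) {
  scenario <- match.arg(as.character(scenario), c("1", "2", "3"))
  Tmax <- c("1" = 4L, "2" = 5L, "3" = 6L)[[scenario]]
  D <- Tmax - s
  regimes <- enumerate_regimes(s)
  out <- list()
  for (d in seq_len(D)) {
    for (r in seq_len(nrow(regimes))) {
      regime <- regimes[r, ]
      sums <- 0; nn <- 0
      per_rep <- numeric(mc_reps)
      for (b in seq_len(mc_reps)) {
        set.seed(derive_seed(seed, (d * 1000L + r) * 10000L + b))
        sim <- simulate_paths(mc_n, Tmax, regime = regime, window_start = d,
                              a_effect = a_effect,
                              suppress_y = seq_len(s - 1L) + d)
        at_risk <- if (d == 1L) rep(TRUE, mc_n) else sim$Y[, d] == 0
        y <- sim$Y[at_risk, d + s]
        per_rep[b] <- mean(y)
        sums <- sums + sum(y); nn <- nn + length(y)
      }
      out[[length(out) + 1L]] <- data.frame(
        d = d, regime = rownames(regimes)[r],
        mean = sums / nn,
        mc_se = stats::sd(per_rep) / sqrt(mc_reps),
        n_at_risk = nn)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("hrmsm_truth", "data.frame")
  res
}
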