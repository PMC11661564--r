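#' Inverse-probability-weighted estimator of trajectory-group effects
#'
#' Weighted pooled log-link regression of the window-end outcome on the
#' trajectory groups assigned to the observed window sequences. Each
#' complete at-risk row of window `d` receives weight
#' `lambda_d(observed regime) / prod g` where the denominator is the
#' cumulative probability of the observed treatments times the probability
#' of remaining uncensored over the window ([g_product()]). Unstabilized
#' weights use `lambda = 1`; stabilized weights use the empirical marginal
#' regime law ([fit_lambda()]). Individuals contribute one row per window,
#' so inference uses a cluster-robust sandwich variance by individual,
#' treating the weights as known (conservative).
#'
#' @param aug an augmented dataset.
#' @param assignments [assign_groups()] result for the same rows.
#' @param propensities a [fit_propensities()] object.
#' @param lambda a [fit_lambda()] object (its mode selects stabilized or
#'   unstabilized weighting).
#' @param family working-model loss (`"poisson"` or `"logbin"`).
#' @param J number of trajectory groups.
#' @return an `msm_fit` with provenance `"iptw"`; the row weights are
#'   attached as attribute `"weights"`.
#' @export
estimate_iptw <- function(aug, assignments, propensities, lambda,
                          family = c("poisson", "logbin"), J = NULL) {
  family <- match.arg(family)
  grp <- assignments$group
  J <- J %||% max(grp, na.rm = TRUE)
  dat <- aug$data
  obs <- observed_regime(aug)
  w <- rep(NA_real_, nrow(dat))
  for (d in seq_len(aug$D)) {
    rows <- which(dat$d == d)
    g <- g_product(propensities, aug, d)
    lam_d <- lambda$by_window[[d]]
    num <- ifelse(is.na(obs[rows]), NA_real_, lam_d[obs[rows]])
    w[rows] <- num / g
  }
  sel <- dat$complete & !is.na(grp) & !is.na(w)
  if (!any(sel)) stop("no complete at-risk rows with group assignments")
  for (d in seq_len(aug$D)) {
    if (!any(sel & dat$d == d))
      warning("window ", d, " has no complete rows and is dropped")
  }
  X <- msm_design(dat$d[sel], grp[sel], aug$D, J)
  fit <- fit_weighted_glm(dat$y_end[sel], X, weights = w[sel], family = family,
                          cluster = dat$id[sel], provenance = "iptw")
  attr(fit, "weights") <- w[sel]
  fit
}
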