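#' Pooled longitudinal targeted maximum likelihood estimation
#'
#' Doubly robust estimator of the trajectory-group effects: the iterated
#' conditional expectation (g-computation) estimates of the window- and
#' regime-specific counterfactual risks are fluctuated, at every backward
#' step, by a pooled logistic regression across all regimes on "clever
#' covariates" built from the inverse cumulative treatment/censoring
#' probabilities and the working-model gradient, so that the efficient
#' influence curve equation is solved. Standard errors come from the
#' empirical influence curve with a correction for the correlation induced
#' by individuals contributing several overlapping windows.
#'
#' @name pooled_ltmle
NULL

# working-model gradient vector of a regime: (1, z_1, ..., z_{J-1}) scaled by
# the family's inverse-variance factor at the anchoring coefficient value
regime_gradient <- function(group, J, family, m) {
  u <- c(1, as.numeric(seq_len(J - 1L) == group))
  if (J == 1L) u <- 1
  famfac <- switch(family, poisson = 1, logbin = 1 / pmax(1 - m, 1e-8))
  u * famfac
}

#' Clever covariates for one window and regime
#'
#' Returns, for every at-risk row and within-window time, the clever
#' covariate in its observed-data version (regime-follower indicator over
#' the cumulative probability of the observed treatments and of remaining
#' uncensored) and its intervened version (indicator replaced by one, the
#' cumulative probability evaluated at the regime), both scaled by the
#' projection weight of the regime and by the working-model gradient.
#'
#' @param aug augmented dataset.
#' @param d window index.
#' @param regime 0/1 vector of length `s`.
#' @param propensities [fit_propensities()] fit.
#' @param lambda [fit_lambda()] weights.
#' @param group trajectory group of the regime (from [map_regimes()]).
#' @param J number of groups.
#' @param family working-model loss.
#' @param m working-model mean for this `(d, regime)` at the anchoring
#'   coefficients (used by the log-binomial variance factor; ignored for
#'   Poisson).
#' @param g_bound lower bound applied to the cumulative treatment/censoring
#'   probability products before inversion (default 0.01, the conventional
#'   bound for longitudinal targeted estimation).
#' @return list with `H_obs` and `H_int` (`n_d x s x J` arrays; the inverse
#'   probability factor times `lambda` times each gradient component),
#'   `follow` (`n_d x s` logical), `grad` (length-J gradient).
#' @export
clever_covariates <- function(aug, d, regime, propensities, lambda, group,
                              J, family = c("poisson", "logbin"), m = 0.5,
                              g_bound = 0.01) {
  family <- match.arg(family)
  s <- aug$s
  ctx <- window_context(aug, d)
  amat <- as.matrix(aug$data[ctx$rows, paste0("a", seq_len(s)), drop = FALSE])
  # cumulative treatment/censoring probabilities, bounded below: unbounded
  # inverse weights for rarely observed regimes make the fluctuation step
  # erratic under near-positivity violations
  cg_obs <- pmax(g_cumulative(propensities, aug, d), g_bound)
  cg_int <- pmax(g_cumulative(propensities, aug, d, regime = regime), g_bound)
  eqs <- sweep(amat, 2, regime, function(a, r) !is.na(a) & a == r)
  follow <- t(apply(eqs, 1, cumprod)) == 1
  if (s == 1L) follow <- matrix(eqs, ncol = 1)
  lam <- lambda$by_window[[d]][[paste(regime, collapse = "")]]
  grad <- regime_gradient(group, J, family, m)
  base_obs <- ifelse(follow & !is.na(cg_obs), lam / cg_obs, 0)
  base_int <- lam / cg_int
  H_obs <- outer(base_obs, grad)
  H_int <- outer(base_int, grad)
  list(H_obs = H_obs, H_int = H_int, follow = follow, grad = grad,
       cg_obs = cg_obs, cg_int = cg_int, lambda = lam)
}

#' Fluctuation step: offset logistic regression on clever covariates
#'
#' Fits the fluctuation parameter vector by a pooled intercept-free
#' logistic regression of the current iterated outcomes on the clever
#' covariates, with the logit of the initial predictions as offset. Rows
#' with an all-zero clever covariate contribute nothing; if no informative
#' row exists the fluctuation is zero.
#'
#' @param H matrix of clever-covariate columns (one per coefficient
#'   component).
#' @param offset vector `logit(Qhat)` (already bounded).
#' @param outcome current iterated outcomes in `[0, 1]`.
#' @return the fluctuation vector `epsilon` (zeros when not estimable).
#' @export
fluctuate <- function(H, offset, outcome) {
  H <- as.matrix(H)
  info <- rowSums(abs(H)) > 0 & !is.na(outcome)
  eps <- rep(0, ncol(H))
  if (!any(info)) return(eps)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(H[info, , drop = FALSE], outcome[info],
                                    offset = offset[info],
                                    family = stats::quasibinomial(),
                                    control = stats::glm.control(maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients) || !all(is.finite(fit$coefficients))) {
    warning("fluctuation regression failed; epsilon set to 0")
    return(eps)
  }
  fit$coefficients
}

#' LTMLE recursion for one window
#'
#' Backward over within-window times: initial ICE fit and regime
#' predictions, clever covariates, pooled fluctuation over all regimes,
#' update. Returns the updated counterfactual means and the per-individual
#' influence-curve pieces of the window.
#'
#' @param aug augmented dataset.
#' @param d window index.
#' @param regimes regime matrix.
#' @param propensities,lambda nuisance fits.
#' @param q_terms Q-model design function (or `NULL` for the default).
#' @param family working-model loss.
#' @param regime_groups named group map from [map_regimes()].
#' @param J number of groups.
#' @param m_init named vector of working-model means per regime at the
#'   anchoring coefficients (names = regime strings).
#' @param force_epsilon optional fixed value for every fluctuation (e.g. 0
#'   to reproduce plain g-computation).
#' @return list with `means` (per regime), `eic` (n_d x J matrix of
#'   pre-bread influence contributions), `ctx`, `epsilons`.
#' @export
ltmle_window <- function(aug, d, regimes, propensities, lambda, q_terms = NULL,
                         family = c("poisson", "logbin"), regime_groups, J,
                         m_init, force_epsilon = NULL) {
  family <- match.arg(family)
  q_terms <- q_terms %||% default_q_terms
  s <- aug$s
  ctx <- window_context(aug, d)
  R <- nrow(regimes)
  cc <- lapply(seq_len(R), function(r) {
    key <- rownames(regimes)[r]
    clever_covariates(aug, d, regimes[r, ], propensities, lambda,
                      group = regime_groups[[key]], J = J, family = family,
                      m = m_init[[key]])
  })
  p_eps <- length(cc[[1]]$grad)
  Qnext <- matrix(NA_real_, ctx$n, R)
  Qnext[ctx$complete, ] <- ctx$y_end[ctx$complete]
  eic <- matrix(0, ctx$n, p_eps)
  epsilons <- matrix(NA_real_, s, p_eps)
  for (k in seq(s, 1L)) {
    j <- d + k - 1L
    avail <- ctx$cmat[, k] == 0L
    terms <- q_terms(d, j, aug)
    Qhat <- matrix(NA_real_, ctx$n, R)
    shared_fit <- NULL
    for (r in seq_len(R)) {
      fitmask <- !is.na(Qnext[, r])
      if (k == s) {
        if (is.null(shared_fit))
          shared_fit <- fit_q(ctx$frame[fitmask, , drop = FALSE],
                              Qnext[fitmask, r], terms)
        fit <- shared_fit
      } else {
        fit <- fit_q(ctx$frame[fitmask, , drop = FALSE], Qnext[fitmask, r], terms)
      }
      fr <- regime_frame(ctx$frame[avail, , drop = FALSE], d, regimes[r, ], k)
      Qhat[avail, r] <- predict_q(fit, fr)
    }
    # pooled fluctuation across regimes
    Hrows <- list(); offs <- list(); outs <- list(); idx <- list()
    for (r in seq_len(R)) {
      use <- cc[[r]]$follow[, k] & !is.na(Qnext[, r]) & avail
      if (!any(use)) next
      Hrows[[length(Hrows) + 1L]] <- matrix(cc[[r]]$H_obs[use, k, ], ncol = p_eps)
      offs[[length(offs) + 1L]] <- logit_bounded(Qhat[use, r])
      outs[[length(outs) + 1L]] <- Qnext[use, r]
      idx[[length(idx) + 1L]] <- data.frame(i = which(use), r = r)
    }
    if (length(Hrows)) {
      Hs <- do.call(rbind, Hrows)
      eps <- if (is.null(force_epsilon)) {
        fluctuate(Hs, unlist(offs), unlist(outs))
      } else rep(force_epsilon, p_eps)
    } else eps <- rep(0, p_eps)
    epsilons[k, ] <- eps
    # update every regime's prediction with the intervened clever covariate
    Qstar <- Qhat
    for (r in seq_len(R)) {
      shift <- drop(matrix(cc[[r]]$H_int[, k, ], ncol = p_eps) %*% eps)
      Qstar[avail, r] <- expit(logit_bounded(Qhat[avail, r]) + shift[avail])
    }
    # influence-curve pieces: fluctuation residuals at the observed data
    for (r in seq_len(R)) {
      use <- cc[[r]]$follow[, k] & !is.na(Qnext[, r]) & avail
      if (!any(use)) next
      Hk <- matrix(cc[[r]]$H_obs[use, k, ], ncol = p_eps)
      eic[use, ] <- eic[use, ] + Hk * (Qnext[use, r] - Qstar[use, r])
    }
    Qnext <- Qstar
  }
  keep <- ctx$cmat[, 1L] == 0L
  means <- colMeans(Qnext[keep, , drop = FALSE])
  names(means) <- rownames(regimes)
  # projection residual piece (exactly mean-zero over the at-risk set)
  for (r in seq_len(R)) {
    grad <- cc[[r]]$grad
    lam <- cc[[r]]$lambda
    resid <- (Qnext[keep, r] - means[r])
    eic[keep, ] <- eic[keep, ] + outer(lam * resid, grad)
  }
  list(means = means, eic = eic, ctx = ctx, epsilons = epsilons,
       Q_first = Qnext)
}

#' Influence-curve variance with cross-window correlation
#'
#' Maps per-window influence pieces through the inverse bread of the
#' projection regression and combines them into the variance of the
#' coefficient vector, using the empirical second moment of each
#' individual's summed influence function. The equivalent decomposition
#' into per-window variances and cross-window covariances (individuals
#' appear in every window they are at risk in) is returned alongside and is
#' algebraically identical.
#'
#' @param window_pieces list over windows: each with `eic` (n_d x J matrix)
#'   and `ids` (individual identifiers of the window rows).
#' @param fit the projection `msm_fit` (supplies the bread).
#' @param n number of individuals in the study.
#' @param D number of windows.
#' @return list with `vcov`, `sigma2` (per-window second-moment matrices of
#'   the mapped influence functions), `rho` (cross-window matrices),
#'   `vcov_decomposed` (rebuilt from sigma/rho; equals `vcov`).
#' @export
eic_variance <- function(window_pieces, fit, n, D) {
  Xn <- colnames(fit$X)
  p <- length(Xn)
  cfam <- switch(fit$family, poisson = fit$fitted,
                 logbin = fit$fitted / pmax(1 - fit$fitted, 1e-8))
  bread <- crossprod(fit$X, fit$X * (fit$w * cfam))
  Cinv <- solve(bread)
  # per window: map the J-vector pieces (win-intercept, group dummies) into
  # the full coefficient space and scale by n / n_d
  mapped <- vector("list", D)
  all_ids <- unique(unlist(lapply(window_pieces, function(w) w$ids)))
  U <- matrix(0, length(all_ids), p, dimnames = list(all_ids, Xn))
  for (d in seq_len(D)) {
    wp <- window_pieces[[d]]
    n_d <- nrow(wp$eic)
    full <- matrix(0, n_d, p)
    colnames(full) <- Xn
    win_col <- paste0("win", d)
    if (win_col %in% Xn) full[, win_col] <- wp$eic[, 1]
    gcols <- grep("^group", Xn, value = TRUE)
    for (gc in gcols) {
      k <- as.integer(sub("group", "", gc))
      if (1 + k <= ncol(wp$eic)) full[, gc] <- wp$eic[, 1 + k]
    }
    full <- full %*% t(Cinv) * (n / n_d)
    mapped[[d]] <- list(m = full, ids = wp$ids)
    U[as.character(wp$ids), ] <- U[as.character(wp$ids), , drop = FALSE] + full
  }
  vcov <- crossprod(U) / n^2
  sigma2 <- lapply(seq_len(D), function(d) {
    crossprod(mapped[[d]]$m) / nrow(mapped[[d]]$m)
  })
  rho <- list()
  total <- matrix(0, p, p)
  for (d in seq_len(D)) total <- total + nrow(mapped[[d]]$m) * sigma2[[d]]
  if (D > 1) {
    for (d in seq_len(D - 1)) for (d2 in (d + 1):D) {
      common <- intersect(mapped[[d]]$ids, mapped[[d2]]$ids)
      i1 <- match(common, mapped[[d]]$ids)
      i2 <- match(common, mapped[[d2]]$ids)
      cr <- crossprod(mapped[[d]]$m[i1, , drop = FALSE],
                      mapped[[d2]]$m[i2, , drop = FALSE]) / length(common)
      rho[[paste(d, d2, sep = ",")]] <- cr
      total <- total + length(common) * (cr + t(cr))
    }
  }
  dimnames(vcov) <- list(Xn, Xn)
  list(vcov = vcov, sigma2 = sigma2, rho = rho,
       vcov_decomposed = total / n^2)
}

#' Pooled LTMLE estimator of trajectory-group effects
#'
#' Runs the full pipeline: g-computation projection to anchor the
#' working-model coefficients, LTMLE recursion in every window, projection
#' of the updated counterfactual means onto trajectory groups, and the
#' influence-curve variance with cross-window correction.
#'
#' @param aug augmented dataset.
#' @param lcga fitted trajectory model.
#' @param propensities,lambda nuisance fits (`lambda` is used both to
#'   weight the projection and inside the clever covariates).
#' @param family working-model loss.
#' @param q_terms Q-model design function or `NULL`.
#' @param variance `"eic"` or `"none"` (bootstrap can be applied externally
#'   with [block_bootstrap()]).
#' @param force_epsilon optional fixed fluctuation (0 reproduces plain
#'   g-computation exactly).
#' @return an `msm_fit` with provenance `"ltmle"`; the updated means grid is
#'   attached as attribute `"means"`, the EIC decomposition as `"eic"`.
#' @export
estimate_ltmle <- function(aug, lcga, propensities, lambda,
                           family = c("poisson", "logbin"), q_terms = NULL,
                           variance = c("eic", "none"), force_epsilon = NULL) {
  family <- match.arg(family)
  variance <- match.arg(variance)
  regimes <- enumerate_regimes(aug$s)
  map <- map_regimes(lcga, regimes)
  J <- lcga$J
  init_means <- gcomp_all(aug, regimes, q_terms)
  init_fit <- project_gcomp(init_means, map, lambda, family, J = J)
  m_init_grid <- exp(pmin(drop(msm_design(init_means$d, map[init_means$regime],
                                          aug$D, J) %*%
                                 align_beta(init_fit$beta, aug$D, J)), log(1 - 1e-8)))
  pieces <- vector("list", aug$D)
  rows_means <- list()
  for (d in seq_len(aug$D)) {
    m_init <- stats::setNames(m_init_grid[init_means$d == d],
                              init_means$regime[init_means$d == d])
    res <- ltmle_window(aug, d, regimes, propensities, lambda, q_terms,
                        family, regime_groups = map, J = J, m_init = m_init,
                        force_epsilon = force_epsilon)
    pieces[[d]] <- list(eic = res$eic, ids = res$ctx$id)
    rows_means[[d]] <- data.frame(d = d, regime = names(res$means),
                                  mean = unname(res$means), n_d = aug$n_d[d])
  }
  means <- do.call(rbind, rows_means)
  class(means) <- c("cf_means", "data.frame")
  fit <- project_gcomp(means, map, lambda, family, J = J, provenance = "ltmle")
  if (variance == "eic") {
    v <- eic_variance(pieces, fit, n = aug$n, D = aug$D)
    keep <- intersect(names(fit$beta), colnames(v$vcov))
    fit$vcov <- v$vcov[keep, keep, drop = FALSE]
    attr(fit, "eic") <- v
  }
  attr(fit, "means") <- means
  fit
}

# expand a possibly column-dropped beta back to the full (D + J - 1) layout
align_beta <- function(beta, D, J) {
  full <- stats::setNames(rep(0, D + J - 1L),
                          c(paste0("win", seq_len(D)), paste0("group", seq_len(J - 1L))))
  full[names(beta)] <- beta
  full
}
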