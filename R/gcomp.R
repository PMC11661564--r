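#' Iterated-conditional-expectation g-computation
#'
#' Estimates the counterfactual window-end risk under every deterministic
#' within-window treatment regime by backward iterated conditional
#' expectations: starting from the window-end outcome, a logistic regression
#' of the current iterated outcome on the observed treatment and covariate
#' history is fit among at-risk rows still uncensored at the relevant time,
#' and predictions are taken with the within-window treatments set to the
#' regime. The final predictions are averaged over the window's at-risk set.
#' The counterfactual means are then projected onto trajectory groups via a
#' weighted log-link working model, and standard errors come from a block
#' bootstrap that resamples individuals with all their windows (the LCGA is
#' never refit inside the bootstrap).
#'
#' @name gcomp
NULL

# default Q-model history: within-window treatments/covariates up to absolute
# time j, plus baseline covariates
default_q_terms <- function(d, j, aug) {
  tv <- aug$tv_covariates
  c(paste0("A.", d:j),
    unlist(lapply(tv, function(v) paste0(v, ".", d:j))),
    aug$baseline)
}

fit_q <- function(frame, y, terms) {
  if (max(y, na.rm = TRUE) - min(y, na.rm = TRUE) < 1e-12) {
    return(list(degenerate = TRUE, p = mean(y, na.rm = TRUE)))
  }
  X <- build_design(frame, terms)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::quasibinomial()))
  if (anyNA(fit$coefficients)) {
    beta <- ridge_logit(X[stats::complete.cases(X), , drop = FALSE],
                        y[stats::complete.cases(X)], 1e-6)
    return(list(coef = beta, terms = terms, degenerate = FALSE))
  }
  list(coef = fit$coefficients, terms = terms, degenerate = FALSE)
}

predict_q <- function(fit, frame) {
  if (isTRUE(fit$degenerate)) return(rep(fit$p, nrow(frame)))
  expit(drop(build_design(frame, fit$terms) %*% fit$coef))
}

# window context used by the ICE and LTMLE recursions
window_context <- function(aug, d) {
  rows <- which(aug$data$d == d)
  wd <- aug$wide[aug$data$wrow[rows], , drop = FALSE]
  cmat <- as.matrix(aug$data[rows, paste0("c", seq_len(aug$s)), drop = FALSE])
  list(rows = rows, frame = wd, cmat = cmat,
       y_end = aug$data$y_end[rows],
       complete = aug$data$complete[rows],
       id = aug$data$id[rows], n = length(rows))
}

#' Counterfactual risk for one window and one regime (ICE recursion)
#'
#' @param aug an augmented dataset.
#' @param d window index.
#' @param regime 0/1 vector of length `s`.
#' @param q_terms optional `function(d, j, aug)` giving the Q-model design
#'   columns (or a one-sided formula for saturated designs); `NULL` uses the
#'   within-window default history.
#' @return the estimated counterfactual risk (scalar in `[0, 1]`).
#' @export
ice_window <- function(aug, d, regime, q_terms = NULL) {
  res <- gcomp_window(aug, d, matrix(regime, 1), q_terms)
  unname(res$means[1])
}

# joint backward recursion over all regimes of one window; the innermost fit
# is shared (the initial outcome does not depend on the regime)
gcomp_window <- function(aug, d, regimes, q_terms = NULL) {
  q_terms <- q_terms %||% default_q_terms
  s <- aug$s
  ctx <- window_context(aug, d)
  R <- nrow(regimes)
  Qnext <- matrix(NA_real_, ctx$n, R)
  Qnext[ctx$complete, ] <- ctx$y_end[ctx$complete]
  for (k in seq(s, 1L)) {
    j <- d + k - 1L
    avail <- ctx$cmat[, k] == 0L
    terms <- q_terms(d, j, aug)
    Qhat <- matrix(NA_real_, ctx$n, R)
    shared_fit <- NULL
    for (r in seq_len(R)) {
      fitmask <- !is.na(Qnext[, r])
      if (k == s) {
        # the initial outcome is regime-free: one shared innermost fit
        if (is.null(shared_fit))
          shared_fit <- fit_q(ctx$frame[fitmask, , drop = FALSE], Qnext[fitmask, r], terms)
        fit <- shared_fit
      } else {
        fit <- fit_q(ctx$frame[fitmask, , drop = FALSE], Qnext[fitmask, r], terms)
      }
      fr <- regime_frame(ctx$frame[avail, , drop = FALSE], d, regimes[r, ], k)
      Qhat[avail, r] <- predict_q(fit, fr)
    }
    Qnext <- Qhat
  }
  keep <- ctx$cmat[, 1L] == 0L
  list(means = colMeans(Qnext[keep, , drop = FALSE]),
       Q_first = Qnext, ctx = ctx)
}

#' Full grid of counterfactual risks over windows and regimes
#'
#' @inheritParams ice_window
#' @param regimes regime matrix (default [enumerate_regimes()]).
#' @return data frame of class `"cf_means"`: `d`, `regime`, `mean`, `n_d`.
#' @export
gcomp_all <- function(aug, regimes = NULL, q_terms = NULL) {
  regimes <- regimes %||% enumerate_regimes(aug$s)
  out <- lapply(seq_len(aug$D), function(d) {
    res <- gcomp_window(aug, d, regimes, q_terms)
    data.frame(d = d, regime = rownames(regimes), mean = unname(res$means),
               n_d = aug$n_d[d])
  })
  res <- do.call(rbind, out)
  class(res) <- c("cf_means", "data.frame")
  res
}

#' Project counterfactual means onto trajectory groups
#'
#' Weighted log-link regression of the regime-specific counterfactual means
#' on the trajectory group of each regime (plus window intercepts), with the
#' projection weights `lambda`.
#'
#' @param means a [gcomp_all()] (or LTMLE) counterfactual-means grid.
#' @param regime_groups named integer vector from [map_regimes()].
#' @param lambda a [fit_lambda()] object.
#' @param family working-model loss.
#' @param J number of groups.
#' @param provenance provenance label for the fit.
#' @return an `msm_fit`.
#' @export
project_gcomp <- function(means, regime_groups, lambda, family = c("poisson", "logbin"),
                          J = NULL, provenance = "gcomp") {
  family <- match.arg(family)
  J <- J %||% max(regime_groups)
  D <- max(means$d)
  grp <- regime_groups[means$regime]
  lam <- vapply(seq_len(nrow(means)),
                function(i) lambda$by_window[[means$d[i]]][[means$regime[i]]],
                numeric(1))
  for (d in seq_len(D)) {
    gl <- unique(grp[means$d == d & lam > 0])
    if (length(gl) < 2L)
      warning("window ", d, ": all positively weighted regimes map to one group; ",
              "it contributes no group contrast")
  }
  X <- msm_design(means$d, grp, D, J)
  fit_weighted_glm(means$mean, X, weights = lam, family = family,
                   provenance = provenance)
}

#' G-computation estimator with block-bootstrap inference
#'
#' Runs [gcomp_all()], maps regimes to groups with the supplied LCGA fit,
#' projects with stabilized weights, and (optionally) bootstrap-resamples
#' individuals with all their repeated windows to estimate standard errors;
#' the trajectory model is held fixed across bootstrap replicates.
#'
#' @param panel the longitudinal panel (needed for resampling; may be `NULL`
#'   when `B = 0`).
#' @param aug the augmented dataset built from `panel`.
#' @param lcga a fitted [fit_lcga()] model.
#' @param family working-model loss.
#' @param q_terms optional Q-model design function.
#' @param B number of bootstrap replications (0 = point estimates only).
#' @param seed bootstrap seed.
#' @param lambda_mode projection-weight mode.
#' @return an `msm_fit` with provenance `"gcomp"`; when `B > 0`, `vcov` is
#'   the bootstrap covariance and the replicate draws are attached as
#'   attribute `"boot"`.
#' @export
estimate_gcomp <- function(panel, aug, lcga, family = c("poisson", "logbin"),
                           q_terms = NULL, B = 0, seed = 1,
                           lambda_mode = "stabilized") {
  family <- match.arg(family)
  regimes <- enumerate_regimes(aug$s)
  map <- map_regimes(lcga, regimes)
  lam <- fit_lambda(aug, lambda_mode)
  means <- gcomp_all(aug, regimes, q_terms)
  fit <- project_gcomp(means, map, lam, family, J = lcga$J)
  fit$provenance <- "gcomp"
  # inference for g-computation comes from the bootstrap; the model-based
  # curvature of the projection regression is not a sampling variance
  fit$vcov[] <- NA_real_
  if (B > 0) {
    stat <- function(panel_b) {
      aug_b <- build_augmented(panel_b, aug$s)
      lam_b <- fit_lambda(aug_b, lambda_mode)
      means_b <- gcomp_all(aug_b, regimes, q_terms)
      project_gcomp(means_b, map, lam_b, family, J = lcga$J)$beta
    }
    boot <- block_bootstrap(panel, stat, B = B, seed = seed,
                            template = fit$beta)
    keep <- intersect(names(fit$beta), colnames(boot$draws))
    V <- stats::cov(boot$draws[, keep, drop = FALSE])
    fit$vcov <- V
    attr(fit, "boot") <- boot
  }
  fit
}

#' Block bootstrap over individuals
#'
#' Resamples `n` individuals with replacement, carrying each individual's
#' entire longitudinal record (all windows) into the replicate, and
#' re-evaluates a statistic on each resampled panel. Replicates that fail
#' are dropped and counted; more than 10% failures triggers a warning.
#'
#' @param panel a longitudinal panel.
#' @param statistic `function(panel) -> named numeric vector`.
#' @param B number of replications.
#' @param seed seed; replicate seeds are derived deterministically.
#' @param template optional named template vector used to align replicate
#'   results with possibly missing names.
#' @return list with `draws` (B_ok x p matrix), `se` (columnwise SD),
#'   `ci_percentile`, `n_failed`.
#' @export
block_bootstrap <- function(panel, statistic, B = 50, seed = 1, template = NULL) {
  ids <- unique(panel$id)
  n <- length(ids)
  by_id <- split(seq_len(nrow(panel)), panel$id)
  draws <- list(); n_failed <- 0
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, b))
    pick <- sample(ids, n, replace = TRUE)
    idx <- unlist(by_id[as.character(pick)], use.names = FALSE)
    pb <- as.data.frame(panel)[idx, , drop = FALSE]
    reps <- vapply(by_id[as.character(pick)], length, integer(1))
    pb$id <- rep(seq_len(n), times = reps)
    pb <- as_longitudinal_panel(pb, tv_covariates = attr(panel, "tv_covariates"),
                                baseline = attr(panel, "baseline"))
    est <- tryCatch(statistic(pb), error = function(e) NULL)
    if (is.null(est)) { n_failed <- n_failed + 1; next }
    if (!is.null(template)) {
      full <- stats::setNames(rep(NA_real_, length(template)), names(template))
      full[names(est)] <- est
      est <- full
    }
    draws[[length(draws) + 1L]] <- est
  }
  if (n_failed > 0.1 * B)
    warning("block bootstrap: ", n_failed, " of ", B, " replications failed")
  if (!length(draws)) stop("all bootstrap replications failed")
  M <- do.call(rbind, draws)
  list(draws = M, se = apply(M, 2, stats::sd, na.rm = TRUE),
       ci_percentile = t(apply(M, 2, stats::quantile,
                               probs = c(0.025, 0.975), na.rm = TRUE)),
       n_failed = n_failed)
}
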