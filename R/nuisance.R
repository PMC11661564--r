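#' Treatment and censoring models for each window and time
#'
#' Fits, for every window `d` and within-window time `k` (absolute time
#' `j = d + k - 1`), a logistic model for the treatment given the observed
#' history, and a logistic model for remaining uncensored given the same
#' history, both restricted to the window's at-risk set (event-free at the
#' window start) and to rows still uncensored at the relevant time. The
#' default history is the full observed past: all treatments and
#' time-varying covariates up to time `j - 1` plus the baseline covariates
#' (the time-varying covariate measured concurrently with the treatment is
#' not conditioned on, matching the within-time ordering outcome, covariate,
#' treatment). Windows with no censoring give degenerate censoring models
#' that contribute a factor of one.
#'
#' @param aug an [build_augmented()] object.
#' @param g_terms optional `function(d, j, aug)` returning the character
#'   vector of design columns (names of wide-format columns, e.g. `"A.2"`,
#'   `"L.1"`, `"V"`) for the treatment model at absolute time `j` of window
#'   `d`; `NULL` uses the full-history default.
#' @param cens_terms same for the censoring model (default: same history as
#'   the treatment model).
#' @param ridge ridge penalty used as a fallback when a logistic fit
#'   separates or is rank deficient; fallbacks are flagged in the result.
#' @return an object of class `"propensity_set"`: nested list
#'   `fits[[d]][[k]]` with elements `treat` and `cens`, each holding
#'   coefficients, the term set and a `degenerate`/`penalized` flag.
#' @export
fit_propensities <- function(aug, g_terms = NULL, cens_terms = NULL,
                             ridge = 1e-6) {
  s <- aug$s
  g_terms <- g_terms %||% default_g_terms
  cens_terms <- cens_terms %||% g_terms
  fits <- vector("list", aug$D)
  for (d in seq_len(aug$D)) {
    rows <- aug$data$d == d
    wd <- aug$wide[aug$data$wrow[rows], , drop = FALSE]
    cmat <- as.matrix(aug$data[rows, paste0("c", seq_len(s)), drop = FALSE])
    fits[[d]] <- vector("list", s)
    for (k in seq_len(s)) {
      j <- d + k - 1L
      unc_prev <- if (k == 1L) rep(TRUE, nrow(wd)) else cmat[, k - 1L] == 0L
      unc_now <- cmat[, k] == 0L
      a_obs <- wd[[paste0("A.", j)]]
      tfit <- fit_logistic_terms(wd[unc_now, , drop = FALSE], a_obs[unc_now],
                                 g_terms(d, j, aug), ridge)
      c_out <- as.numeric(cmat[, k] == 1L)
      if (sum(c_out[unc_prev]) == 0) {
        cfit <- list(degenerate = TRUE, p = 0)
      } else {
        cfit <- fit_logistic_terms(wd[unc_prev, , drop = FALSE], c_out[unc_prev],
                                   cens_terms(d, j, aug), ridge)
      }
      fits[[d]][[k]] <- list(treat = tfit, cens = cfit)
    }
  }
  structure(list(fits = fits, s = s, D = aug$D), class = "propensity_set")
}

# default history: A.1..A.{j-1}, <cov>.1..<cov>.{j-1}, baseline
default_g_terms <- function(d, j, aug) {
  tv <- aug$tv_covariates
  terms <- character(0)
  if (j > 1) {
    terms <- c(paste0("A.", seq_len(j - 1)),
               unlist(lapply(tv, function(v) paste0(v, ".", seq_len(j - 1)))))
  }
  c(terms, aug$baseline)
}

fit_logistic_terms <- function(frame, y, terms, ridge = 1e-6) {
  X <- build_design(frame, terms)
  ok <- stats::complete.cases(X) & !is.na(y)
  Xo <- X[ok, , drop = FALSE]; yo <- y[ok]
  if (length(unique(yo)) < 2L) {
    return(list(degenerate = TRUE, p = mean(yo), terms = terms))
  }
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(Xo, yo, family = stats::binomial())),
    error = function(e) NULL)
  bad <- is.null(fit) || !fit$converged || anyNA(fit$coefficients) ||
    any(abs(fit$coefficients) > 20)
  if (bad) {
    beta <- ridge_logit(Xo, yo, ridge)
    return(list(coef = beta, terms = terms, degenerate = FALSE, penalized = TRUE))
  }
  list(coef = fit$coefficients, terms = terms, degenerate = FALSE, penalized = FALSE)
}

# small ridge-penalized logistic IRLS fallback
ridge_logit <- function(X, y, lambda = 1e-6, max_iter = 100) {
  p <- ncol(X)
  beta <- rep(0, p)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- expit(eta)
    W <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(X, y - mu) - lambda * beta
    H <- crossprod(X, X * W) + diag(lambda, p)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  drop(beta)
}

predict_logistic <- function(fit, frame) {
  if (isTRUE(fit$degenerate)) return(rep(fit$p, nrow(frame)))
  X <- build_design(frame, fit$terms)
  expit(drop(X %*% fit$coef))
}

# set within-window treatment columns of a wide frame to regime values up to
# within-window time k (absolute times d .. d+k-1)
regime_frame <- function(frame, d, regime, k) {
  for (t in seq_len(k)) frame[[paste0("A.", d + t - 1L)]] <- regime[t]
  frame
}

#' Cumulative treatment x censoring probability products for one window
#'
#' For every at-risk row of window `d` returns the `n_d x s` matrix of
#' cumulative products over within-window times of (probability of the
#' treatment value) x (probability of remaining uncensored). With
#' `regime = NULL` the probability of the *observed* treatment value is
#' used (entries are `NA` once a row is censored); with a regime, the
#' probability that treatment *equals the regime value* is evaluated with
#' the within-window treatment history set to the regime and the observed
#' covariate history (entries are `NA` once covariates are unobserved).
#'
#' @param prop a [fit_propensities()] object.
#' @param aug the augmented dataset.
#' @param d window index.
#' @param regime optional 0/1 vector of length `s`.
#' @return matrix of cumulative products.
#' @export
g_cumulative <- function(prop, aug, d, regime = NULL) {
  s <- aug$s
  rows <- aug$data$d == d
  wd <- aug$wide[aug$data$wrow[rows], , drop = FALSE]
  cmat <- as.matrix(aug$data[rows, paste0("c", seq_len(s)), drop = FALSE])
  n <- nrow(wd)
  out <- matrix(NA_real_, n, s)
  cum <- rep(1, n)
  for (k in seq_len(s)) {
    j <- d + k - 1L
    frame <- if (is.null(regime)) wd else regime_frame(wd, d, regime, k - 1L)
    fitk <- prop$fits[[d]][[k]]
    pA <- predict_logistic(fitk$treat, frame)
    a_val <- if (is.null(regime)) wd[[paste0("A.", j)]] else rep(regime[k], n)
    dens <- ifelse(a_val == 1, pA, 1 - pA)
    p_unc <- 1 - predict_logistic(fitk$cens, frame)
    cum <- cum * dens * p_unc
    alive <- if (is.null(regime)) cmat[, k] == 0L
             else (if (k == 1L) rep(TRUE, n) else cmat[, k - 1L] == 0L)
    out[alive, k] <- cum[alive]
    cum[!alive] <- NA_real_
  }
  out
}

#' Inverse-probability denominator for complete rows of a window
#'
#' The product over the window of the probability of the observed treatment
#' value times the probability of remaining uncensored; defined for
#' complete (fully uncensored) at-risk rows, `NA` otherwise.
#'
#' @inheritParams g_cumulative
#' @param floor products below this value trigger a positivity error.
#' @return numeric vector aligned with the window's at-risk rows.
#' @export
g_product <- function(prop, aug, d, floor = 1e-12) {
  g <- g_cumulative(prop, aug, d)[, aug$s]
  if (any(!is.na(g) & g < floor))
    stop("positivity diagnostic: estimated cumulative treatment/censoring ",
         "probability below ", floor, " in window ", d)
  g
}

#' Projection weights over regimes (the marginal treatment-process law)
#'
#' In stabilized mode, the weight of each regime in each window is its
#' empirical frequency among complete at-risk rows (the saturated estimate
#' of the marginal within-window treatment process); weights sum to one per
#' window and regimes never observed in a window get weight zero (flagged).
#' In unstabilized mode all weights are one.
#'
#' @param aug an augmented dataset.
#' @param mode `"stabilized"` or `"unstabilized"`.
#' @return a list with one named numeric vector per window (names are
#'   regime strings), plus the mode.
#' @export
fit_lambda <- function(aug, mode = c("stabilized", "unstabilized")) {
  mode <- match.arg(mode)
  regimes <- enumerate_regimes(aug$s)
  keys <- rownames(regimes)
  obs <- observed_regime(aug)
  lam <- lapply(seq_len(aug$D), function(d) {
    if (mode == "unstabilized") {
      stats::setNames(rep(1, length(keys)), keys)
    } else {
      sel <- aug$data$d == d & aug$data$complete
      tab <- table(factor(obs[sel], levels = keys))
      stats::setNames(as.numeric(tab) / sum(tab), keys)
    }
  })
  structure(list(by_window = lam, mode = mode), class = "lambda_weights")
}
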