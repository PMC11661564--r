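#' Log-linear working models on trajectory groups
#'
#' The causal parameter of the package is defined by projecting window- and
#' regime-specific counterfactual risks onto a log-linear working model
#' `log m = X beta` whose design holds one intercept per window plus dummy
#' variables for all trajectory groups except the reference (the
#' lowest-adherence group), so that `exp(beta_k)` is the relative risk of
#' group `k` versus the reference. Two loss functions share this mean model:
#' the log-binomial negative log-likelihood (variance function `m(1-m)`) and
#' the Poisson negative log-likelihood (variance function `m`).
#'
#' [fit_weighted_glm()] solves the weighted score equation by iteratively
#' reweighted least squares with step-halving that keeps log-binomial fitted
#' means below one; convergence is certified by the weighted score at the
#' solution ([score_residual()]). A cluster-robust sandwich variance over a
#' supplied clustering (individuals contributing multiple windows) is
#' available; it treats the weights as known, which is conservative.
#'
#' @name msm_projection
NULL

#' Design matrix of window intercepts and trajectory-group dummies
#'
#' @param d integer vector of window indices per observation.
#' @param group integer vector of group labels (1..J; group `J`, the lowest
#'   adherence, is the reference).
#' @param D number of windows.
#' @param J number of groups.
#' @return numeric matrix with columns `win1..winD`, `group1..group{J-1}`.
#' @export
msm_design <- function(d, group, D, J) {
  n <- length(d)
  X <- matrix(0, n, D + J - 1L)
  colnames(X) <- c(paste0("win", seq_len(D)), paste0("group", seq_len(J - 1L)))
  X[cbind(seq_len(n), d)] <- 1
  for (k in seq_len(J - 1L)) X[group == k, D + k] <- 1
  X
}

#' Fit a weighted log-link working model (log-binomial or Poisson loss)
#'
#' @param y outcomes: individual 0/1 outcomes or risk estimates in `[0, 1]`.
#' @param X design matrix (see [msm_design()]).
#' @param weights non-negative observation weights.
#' @param family `"poisson"` or `"logbin"` loss.
#' @param cluster optional cluster identifiers for a robust sandwich
#'   variance (e.g. individual ids when individuals contribute several
#'   windows); `NULL` gives the model-based (inverse expected information)
#'   variance.
#' @param max_iter,tol IRLS control: stop when the maximum absolute
#'   component of the weighted score falls below `tol * scale`, where
#'   `scale` is the magnitude of the score's leading term.
#' @param provenance label stored on the fit (`"crude"`, `"iptw"`,
#'   `"gcomp"`, `"ltmle"`, ...).
#' @return an object of class `"msm_fit"`: `beta`, `vcov`, `family`,
#'   `fitted`, `converged`, `score`, `n`, `provenance`.
#' @export
fit_weighted_glm <- function(y, X, weights = NULL, family = c("poisson", "logbin"),
                             cluster = NULL, max_iter = 100, tol = 1e-10,
                             provenance = "custom") {
  family <- match.arg(family)
  X <- as.matrix(X)
  weights <- weights %||% rep(1, length(y))
  keep <- weights > 0 & !is.na(y)
  y <- y[keep]; Xk <- X[keep, , drop = FALSE]; w <- weights[keep]
  if (!is.null(cluster)) cluster <- cluster[keep]
  empty <- colSums(abs(Xk)) == 0
  if (any(empty)) {
    warning("dropping empty design columns: ",
            paste(colnames(Xk)[empty], collapse = ", "))
    Xk <- Xk[, !empty, drop = FALSE]
  }
  p <- ncol(Xk)
  qrX <- qr(Xk)
  if (qrX$rank < p)
    stop("working-model design is rank deficient (a group or window has no data)")

  # initial value: intercepts at log of weighted mean, effects at 0
  mu0 <- max(min(sum(w * y) / sum(w), 0.99), 1e-4)
  beta <- qr.coef(qrX, rep(log(mu0), length(y)))
  eta_cap <- log(1 - 1e-8)

  score_fun <- function(beta) {
    eta <- drop(Xk %*% beta)
    mu <- exp(pmin(eta, eta_cap))
    res <- switch(family, poisson = (y - mu), logbin = (y - mu) / (1 - mu))
    drop(crossprod(Xk, w * res))
  }
  scale <- max(1, sum(abs(w * y)))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xk %*% beta)
    if (family == "logbin") eta <- pmin(eta, eta_cap)
    mu <- exp(eta)
    # IRLS weights for log link: w * mu^2 / Var(mu)
    w_irls <- switch(family,
                     poisson = w * mu,
                     logbin = w * mu / pmax(1 - mu, 1e-8))
    z <- eta + (y - mu) / mu
    fitls <- stats::lm.wfit(Xk, z, w_irls)
    beta_new <- fitls$coefficients
    if (anyNA(beta_new)) break
    if (family == "logbin") {
      # step-halving keeps fitted means strictly below one
      half <- 0
      while (half < 20 && max(drop(Xk %*% beta_new)) >= 0) {
        beta_new <- (beta + beta_new) / 2
        half <- half + 1
      }
      if (max(drop(Xk %*% beta_new)) >= 0)
        beta_new <- beta + (beta_new - beta) * 1e-3
    }
    moved <- max(abs(beta_new - beta))
    beta <- beta_new
    sc <- score_fun(beta)
    if (max(abs(sc)) < tol * scale && moved < 1e-8) { converged <- TRUE; break }
  }
  sc <- score_fun(beta)
  converged <- converged || max(abs(sc)) < 1e-6 * scale

  eta <- drop(Xk %*% beta)
  if (family == "logbin") eta <- pmin(eta, eta_cap)
  mu <- exp(eta)
  if (family == "poisson" && any(mu > 1))
    warning("Poisson working model produced fitted risks above 1")
  cfam <- switch(family, poisson = mu, logbin = mu / pmax(1 - mu, 1e-8))
  bread <- crossprod(Xk, Xk * (w * cfam))
  bread_inv <- solve(bread)
  if (is.null(cluster)) {
    vcov <- bread_inv
  } else {
    sres <- switch(family, poisson = (y - mu), logbin = (y - mu) / pmax(1 - mu, 1e-8))
    S <- Xk * (w * sres)
    Ssum <- rowsum(S, cluster)
    meat <- crossprod(Ssum)
    vcov <- bread_inv %*% meat %*% bread_inv
  }
  dimnames(vcov) <- list(colnames(Xk), colnames(Xk))
  structure(list(beta = stats::setNames(beta, colnames(Xk)), vcov = vcov,
                 family = family, fitted = mu, y = y, X = Xk, w = w,
                 cluster = cluster, converged = converged, score = sc,
                 n = length(y), provenance = provenance),
            class = "msm_fit")
}

#' Weighted score of a working model at (or near) its solution
#'
#' Evaluates the estimating function `sum w * x * fam(y - m)` at a given
#' coefficient vector; at the IRLS solution it is numerically zero, which
#' serves as a convergence certificate.
#'
#' @param fit an [fit_weighted_glm()] object.
#' @param beta coefficients (default: the fitted ones).
#' @return numeric score vector.
#' @export
score_residual <- function(fit, beta = fit$beta) {
  eta <- drop(fit$X %*% beta)
  mu <- exp(pmin(eta, log(1 - 1e-8)))
  res <- switch(fit$family, poisson = (fit$y - mu),
                logbin = (fit$y - mu) / (1 - mu))
  drop(crossprod(fit$X, fit$w * res))
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("Working-model fit (", x$family, " loss, provenance: ", x$provenance,
      ")\n", sep = "")
  se <- sqrt(diag(x$vcov))
  tab <- cbind(estimate = x$beta, RR = exp(x$beta), SE = se,
               lower95 = exp(x$beta - 1.96 * se),
               upper95 = exp(x$beta + 1.96 * se))
  print(round(tab, 4))
  if (!x$converged) cat("NOTE: IRLS did not meet the score tolerance\n")
  invisible(x)
}

#' Tidy coefficient summary of a working-model fit
#'
#' @param fit an `msm_fit`.
#' @return data frame with term, estimate, RR, SE and Wald 95% CI bounds.
#' @export
summary_msm <- function(fit) {
  se <- sqrt(diag(fit$vcov))
  data.frame(term = names(fit$beta), estimate = unname(fit$beta),
             RR = exp(unname(fit$beta)), SE = se,
             lower95 = exp(unname(fit$beta) - 1.96 * se),
             upper95 = exp(unname(fit$beta) + 1.96 * se),
             row.names = NULL)
}

#' Crude (unadjusted) trajectory-group model
#'
#' Unweighted log-link regression of the window-end outcome on trajectory
#' groups and window intercepts over complete at-risk rows, with a
#' cluster-robust variance by individual. Serves as the no-adjustment
#' comparator: with treatment-confounder feedback it is biased for the
#' causal group effects.
#'
#' @param aug an augmented dataset.
#' @param assignments result of [assign_groups()] on the same rows.
#' @param family working-model loss.
#' @param J number of groups (default: max label in the assignment).
#' @return an `msm_fit` with provenance `"crude"`.
#' @export
crude_fit <- function(aug, assignments, family = c("poisson", "logbin"), J = NULL) {
  family <- match.arg(family)
  grp <- assignments$group
  J <- J %||% max(grp, na.rm = TRUE)
  sel <- aug$data$complete & !is.na(grp)
  present <- sort(unique(grp[sel]))
  if (length(setdiff(seq_len(J), present)))
    warning("groups absent from the complete data: ",
            paste(setdiff(seq_len(J), present), collapse = ", "))
  X <- msm_design(aug$data$d[sel], grp[sel], aug$D, J)
  fit_weighted_glm(aug$data$y_end[sel], X, family = family,
                   cluster = aug$data$id[sel], provenance = "crude")
}
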