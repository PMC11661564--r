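setup_pipeline <- function(n = 1500, scenario = 1, seed = 30) {
  panel <- generate_observed(n, scenario, seed = seed)
  aug <- build_augmented(panel, 3)
  lcga <- fit_lcga(aug, 3, seed = 777)
  list(panel = panel, aug = aug, lcga = lcga,
       prop = fit_propensities(aug),
       lam = fit_lambda(aug, "stabilized"))
}

test_that("clever covariates vanish off-regime and scale as inverse weights", {
  pp <- setup_pipeline(600)
  regimes <- enumerate_regimes(3)
  map <- map_regimes(pp$lcga, regimes)
  cc <- clever_covariates(pp$aug, 1, c(1, 1, 1), pp$prop, pp$lam,
                          group = map[["111"]], J = 3, family = "poisson")
  amat <- as.matrix(pp$aug$data[paste0("a", 1:3)])
  deviator <- which(amat[, 1] == 0)[1]
  expect_true(all(cc$H_obs[deviator, , ] == 0))
  follower <- which(amat[, 1] == 1 & amat[, 2] == 1 & amat[, 3] == 1)[1]
  # the gradient components are (1, z1, z2) for the regime's group, so the
  # follower's covariate is positive exactly in the intercept component and
  # the regime's own group component
  z <- as.numeric(1:2 == map[["111"]])
  expect_equal(cc$grad, c(1, z))
  expect_gt(cc$H_obs[follower, 3, 1], 0)
  expect_gt(cc$H_obs[follower, 3, 1 + map[["111"]]], 0)
})

test_that("a single-period half-probability follower gets factor two", {
  # hand-built setting: s = 1, g = 0.5, lambda = 1
  p <- data.frame(id = rep(1:4, each = 2), t = rep(1:2, 4),
                  A = c(1, NA, 0, NA, 1, NA, 0, NA), C = 0,
                  Y = c(0, 1, 0, 0, 0, 1, 0, 0),
                  L = c(1, NA, 0, NA, 0, NA, 1, NA), V = 1)
  aug <- build_augmented(as_longitudinal_panel(p), 1)
  prop <- structure(list(fits = list(list(list(
    treat = list(degenerate = TRUE, p = 0.5),
    cens = list(degenerate = TRUE, p = 0)))), s = 1L, D = 1L),
    class = "propensity_set")
  lam <- structure(list(by_window = list(c("0" = 1, "1" = 1)),
                        mode = "unstabilized"), class = "lambda_weights")
  cc <- clever_covariates(aug, 1, 1L, prop, lam, group = 1, J = 2,
                          family = "poisson")
  followers <- aug$data$a1 == 1
  expect_equal(unname(cc$H_obs[followers, 1, 1]), rep(2, sum(followers)))
  expect_true(all(cc$H_obs[!followers, 1, 1] == 0))
})

test_that("a zero fluctuation leaves the initial estimates untouched", {
  pp <- setup_pipeline(1000)
  g0 <- estimate_gcomp(pp$panel, pp$aug, pp$lcga, "poisson", B = 0)
  l0 <- estimate_ltmle(pp$aug, pp$lcga, pp$prop, pp$lam, "poisson",
                       force_epsilon = 0)
  expect_equal(l0$beta, g0$beta, tolerance = 1e-10)
  means_l <- attr(l0, "means")
  means_g <- gcomp_all(pp$aug)
  expect_equal(means_l$mean, means_g$mean, tolerance = 1e-10)
  # with no informative rows the fluctuation returns exactly zero
  expect_equal(fluctuate(matrix(0, 5, 2), rep(0, 5), runif(5)), c(0, 0))
})

test_that("targeting with saturated nuisances reproduces the g-formula", {
  panel <- discrete_panel()
  aug <- build_augmented(panel, 2)
  g_sat <- function(d, j, aug) {
    past <- c(if (j > 1) paste0("A.", seq_len(j - 1)),
              if (j > 1) paste0("L.", seq_len(j - 1)), "V")
    stats::as.formula(paste("~", paste(past, collapse = "*")))
  }
  prop <- fit_propensities(aug, g_terms = g_sat)
  lam <- fit_lambda(aug, "stabilized")
  regimes <- enumerate_regimes(2)
  map <- stats::setNames(c(2L, 1L, 1L, 2L), rownames(regimes))
  m_init <- stats::setNames(rep(0.3, 4), rownames(regimes))
  res <- ltmle_window(aug, 1, regimes, prop, lam, q_terms = saturated_q_terms,
                      family = "poisson", regime_groups = map, J = 2,
                      m_init = m_init)
  for (key in rownames(regimes)) {
    reg <- regimes[key, ]
    expect_equal(unname(res$means[key]),
                 gformula_oracle(panel, reg[1], reg[2]), tolerance = 1e-6)
  }
  # the fluctuations themselves are numerically nil in the saturated case
  expect_lt(max(abs(res$epsilons)), 1e-6)
})

test_that("the fluctuation solves the clever-covariate score", {
  pp <- setup_pipeline(1500)
  regimes <- enumerate_regimes(3)
  map <- map_regimes(pp$lcga, regimes)
  m_init <- stats::setNames(rep(0.3, 8), rownames(regimes))
  res <- ltmle_window(pp$aug, 1, regimes, pp$prop, pp$lam, NULL, "poisson",
                      regime_groups = map, J = 3, m_init = m_init)
  # empirical mean of the influence pieces is numerically zero: the
  # fluctuation score vanishes at the estimate and the projection residual
  # is centred exactly
  expect_lt(max(abs(colMeans(res$eic))), 1e-5)

  fit <- estimate_ltmle(pp$aug, pp$lcga, pp$prop, pp$lam, "poisson")
  v <- attr(fit, "eic")
  expect_identical(fit$provenance, "ltmle")
  expect_equal(unname(v$vcov), unname(v$vcov_decomposed), tolerance = 1e-12)
  expect_true(all(diag(v$vcov) > 0))
})

test_that("influence-curve variance obeys the window decompositions", {
  # synthetic influence pieces with known moments
  set.seed(40)
  n <- 500
  fitX <- matrix(1, 4, 1, dimnames = list(NULL, "win1"))
  fake_fit <- list(X = fitX, w = rep(1, 4), fitted = rep(0.5, 4),
                   family = "poisson")
  # D = 1: variance reduces to sigma^2 / n
  if1 <- matrix(rnorm(n), n, 1)
  v1 <- eic_variance(list(list(eic = if1, ids = 1:n)), fake_fit, n = n, D = 1)
  C <- sum(rep(1, 4) * 0.5)  # bread of the intercept-only projection
  mapped <- if1 / C
  expect_equal(v1$vcov[1, 1], sum(mapped^2) / n^2, tolerance = 1e-12)
  expect_equal(v1$vcov, v1$vcov_decomposed, tolerance = 1e-14)

  # two windows with nested risk sets: matches the sigma/rho combination
  n2 <- 300
  if2 <- matrix(rnorm(n2), n2, 1)
  fake_fit2 <- list(X = rbind(cbind(win1 = 1, win2 = 0), cbind(win1 = 0, win2 = 1)),
                    w = rep(1, 2), fitted = rep(0.5, 2), family = "poisson")
  pieces <- list(list(eic = if1, ids = 1:n),
                 list(eic = if2, ids = 1:n2))
  v2 <- eic_variance(pieces, fake_fit2, n = n, D = 2)
  expect_equal(v2$vcov, v2$vcov_decomposed, tolerance = 1e-12)
  r12 <- v2$rho[["1,2"]]
  # cross-window block carries exactly n_2 * rho_{1,2} / n^2
  expect_equal(v2$vcov[1, 2], n2 * r12[1, 2] / n^2, tolerance = 1e-12)
  # diagonal blocks carry n_d * sigma_d^2 / n^2
  expect_equal(v2$vcov[1, 1], n * v2$sigma2[[1]][1, 1] / n^2, tolerance = 1e-12)
  expect_equal(v2$vcov[2, 2], n2 * v2$sigma2[[2]][2, 2] / n^2, tolerance = 1e-12)

  # independent windows: vanishing cross-covariance
  if3 <- matrix(rnorm(n), n, 1)
  pieces3 <- list(list(eic = if1, ids = 1:n), list(eic = if3, ids = 1:n))
  v3 <- eic_variance(pieces3, fake_fit2, n = n, D = 2)
  expect_lt(abs(v3$rho[["1,2"]][1, 2]),
            3 / sqrt(n) * sqrt(v3$sigma2[[1]][1, 1] * v3$sigma2[[2]][2, 2]))
})

test_that("targeting with correct treatment models repairs a broken Q model", {
  # intercept-only iterated regressions are badly misspecified; the update
  # step uses the (correct) treatment models to remove the bias
  set.seed(41)
  panel <- generate_observed(8000, scenario = 1, seed = 42)
  aug <- build_augmented(panel, 3)
  lcga <- fit_lcga(aug, 3, seed = 777)
  prop <- fit_propensities(aug)
  lam <- fit_lambda(aug, "stabilized")
  q_null <- function(d, j, aug) character(0)
  g0 <- estimate_gcomp(panel, aug, lcga, "poisson", q_terms = q_null, B = 0)
  l0 <- estimate_ltmle(aug, lcga, prop, lam, "poisson", q_terms = q_null)
  means_g <- gcomp_all(aug, q_terms = q_null)
  means_l <- attr(l0, "means")
  truth <- true_counterfactual_means(1, s = 3, mc_reps = 4, mc_n = 25000, seed = 2)
  # compare per-regime means for the two dominant regimes
  for (key in c("111", "110")) {
    err_g <- abs(means_g$mean[means_g$regime == key] -
                   truth$mean[truth$regime == key])
    err_l <- abs(means_l$mean[means_l$regime == key] -
                   truth$mean[truth$regime == key])
    expect_lt(err_l, err_g)
    expect_lt(err_l, 0.08)
  }
})
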