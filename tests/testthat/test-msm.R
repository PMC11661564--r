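test_that("an intercept-only fit returns the log of the weighted mean", {
  y <- rep(0.3, 20)
  X <- matrix(1, 20, 1, dimnames = list(NULL, "win1"))
  for (fam in c("poisson", "logbin")) {
    fit <- fit_weighted_glm(y, X, family = fam)
    expect_equal(unname(fit$beta), log(0.3), tolerance = 1e-10)
  }
  # non-uniform weights
  w <- runif(20, 0.5, 2)
  y2 <- runif(20, 0.1, 0.5)
  fit2 <- fit_weighted_glm(y2, X, weights = w, family = "poisson")
  expect_equal(unname(fit2$beta), log(weighted.mean(y2, w)), tolerance = 1e-8)
})

test_that("saturated designs give identical fits for both loss functions", {
  set.seed(10)
  grp <- rep(1:3, each = 4)
  y <- runif(12, 0.05, 0.6)
  w <- runif(12, 0.2, 3)
  X <- msm_design(rep(1, 12), grp, D = 1, J = 3)
  fp <- fit_weighted_glm(y, X, w, "poisson")
  fl <- fit_weighted_glm(y, X, w, "logbin")
  expect_equal(fp$beta, fl$beta, tolerance = 1e-7)
  # saturated oracle: coefficients are log weighted group means
  X1 <- msm_design(rep(1, 12), grp[1:12], D = 1, J = 3)
  f1 <- fit_weighted_glm(y[1:12], X1, w[1:12], "poisson")
  gm <- vapply(1:3, function(k) weighted.mean(y[1:12][grp[1:12] == k],
                                              w[1:12][grp[1:12] == k]), 0)
  expect_equal(unname(f1$beta["win1"]), log(gm[3]), tolerance = 1e-8)
  expect_equal(unname(f1$beta["group1"]), log(gm[1] / gm[3]), tolerance = 1e-8)
  expect_equal(unname(f1$beta["group2"]), log(gm[2] / gm[3]), tolerance = 1e-8)
})

test_that("rescaling the weights leaves the coefficients unchanged", {
  set.seed(11)
  grp <- rep(1:2, each = 10)
  y <- rbinom(20, 1, 0.3)
  w <- runif(20, 0.5, 2)
  X <- msm_design(rep(1, 20), grp, 1, 2)
  f1 <- fit_weighted_glm(y, X, w, "poisson")
  f2 <- fit_weighted_glm(y, X, w * 7.3, "poisson")
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)
})

test_that("the weighted score certifies the solution", {
  set.seed(12)
  grp <- sample(1:3, 200, replace = TRUE)
  d <- sample(1:2, 200, replace = TRUE)
  y <- rbinom(200, 1, 0.25)
  X <- msm_design(d, grp, 2, 3)
  for (fam in c("poisson", "logbin")) {
    fit <- fit_weighted_glm(y, X, family = fam)
    expect_lt(max(abs(score_residual(fit))), 1e-8)
    expect_gt(max(abs(score_residual(fit, fit$beta + 0.05))), 1e-3)
  }
  # Poisson score equals the finite-difference gradient of the Poisson loss
  fit <- fit_weighted_glm(y, X, family = "poisson")
  beta <- fit$beta + c(0.1, -0.05, 0.02, 0.03)
  loss <- function(b) {
    mu <- exp(drop(X %*% b))
    -sum(y * log(mu) - mu)
  }
  num_grad <- vapply(seq_along(beta), function(j) {
    h <- 1e-6; bp <- beta; bm <- beta
    bp[j] <- bp[j] + h; bm[j] <- bm[j] - h
    (loss(bp) - loss(bm)) / (2 * h)
  }, numeric(1))
  expect_equal(unname(score_residual(fit, beta)), unname(-num_grad),
               tolerance = 1e-4)
})

test_that("cluster sandwich matches its algebraic definition", {
  set.seed(13)
  n <- 60
  cl <- rep(1:20, each = 3)
  grp <- sample(1:2, n, replace = TRUE)
  y <- rbinom(n, 1, 0.3)
  X <- msm_design(rep(1, n), grp, 1, 2)
  fit <- fit_weighted_glm(y, X, family = "poisson", cluster = cl)
  mu <- fit$fitted
  B <- crossprod(fit$X, fit$X * mu)
  S <- rowsum(fit$X * (y - mu), cl)
  V <- solve(B) %*% crossprod(S) %*% solve(B)
  expect_equal(unname(fit$vcov), unname(V), tolerance = 1e-10)
  # with singleton clusters and a correctly specified Poisson-variance
  # outcome the sandwich approaches the model-based variance
  set.seed(14)
  n2 <- 20000
  grp2 <- sample(1:2, n2, replace = TRUE)
  y2 <- rbinom(n2, 1, ifelse(grp2 == 1, 0.25, 0.35))
  X2 <- msm_design(rep(1, n2), grp2, 1, 2)
  fs <- fit_weighted_glm(y2, X2, family = "poisson", cluster = seq_len(n2))
  fm <- fit_weighted_glm(y2, X2, family = "poisson")
  ratio <- diag(fs$vcov) / diag(fm$vcov)
  # binary outcomes have variance mu(1-mu) < mu, so the sandwich shrinks the
  # model-based Poisson variance by roughly 1 - mu
  expect_true(all(ratio > 0.5 & ratio < 0.9))
})

test_that("a boundary log-binomial problem is flagged, not silently wrong", {
  y <- rep(1, 15)
  X <- matrix(1, 15, 1, dimnames = list(NULL, "win1"))
  fit <- suppressWarnings(fit_weighted_glm(y, X, family = "logbin"))
  expect_false(fit$converged)
  expect_true(all(fit$fitted < 1))
})

test_that("the crude comparator fits group contrasts with robust variance", {
  panel <- generate_observed(2500, scenario = 2, seed = 16)
  aug <- build_augmented(panel, 3)
  lcga <- fit_lcga(aug, 3, seed = 777)
  asg <- assign_groups(lcga, aug)
  fit <- crude_fit(aug, asg, "poisson")
  expect_identical(fit$provenance, "crude")
  expect_true(all(c("win1", "win2") %in% names(fit$beta)))
  # saturated check in window 1: fitted group risks equal raw group means
  sel <- aug$data$d == 1 & aug$data$complete
  m1 <- tapply(aug$data$y_end[sel], asg$group[sel], mean)
  co <- hrmsm:::align_beta(fit$beta, aug$D, 3)
  # group effects are shared across windows, so only compare when D = 1
  aug1 <- build_augmented(generate_observed(2500, 1, seed = 16), 3)
  asg1 <- assign_groups(fit_lcga(aug1, 3, seed = 777), aug1)
  f1 <- crude_fit(aug1, asg1, "poisson")
  sel1 <- aug1$data$complete & !is.na(asg1$group)
  m <- tapply(aug1$data$y_end[sel1], asg1$group[sel1], mean)
  b <- hrmsm:::align_beta(f1$beta, 1, 3)
  expect_equal(unname(exp(b["win1"])), unname(m["3"]), tolerance = 1e-7)
  expect_equal(unname(exp(b["win1"] + b["group1"])), unname(m["1"]), tolerance = 1e-7)
})
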