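# hand-built propensity sets with known constant probabilities let the
# weight arithmetic be checked exactly
constant_propensities <- function(p_treat, p_cens, D, s) {
  fits <- lapply(seq_len(D), function(d) {
    lapply(seq_len(s), function(k) {
      list(treat = list(degenerate = TRUE, p = p_treat[k]),
           cens = list(degenerate = TRUE, p = p_cens))
    })
  })
  structure(list(fits = fits, s = s, D = D), class = "propensity_set")
}

test_that("inverse-probability products follow the weight arithmetic", {
  panel <- toy_panel()
  aug <- build_augmented(panel, 3)
  # all probabilities one half, no censoring: product 1/8, weight 8
  prop <- constant_propensities(rep(0.5, 3), 0, aug$D, 3)
  g <- g_product(prop, aug, 1)
  expect_equal(unname(g), rep(0.125, 4))
  expect_equal(unname(1 / g), rep(8, 4))
  # probabilities (0.8, 0.5, 0.25) of the observed values give weight 10
  prop2 <- constant_propensities(c(0.8, 0.5, 0.25), 0, aug$D, 3)
  g2 <- g_cumulative(prop2, aug, 1)
  # id 1 follows (1,1,1): density of observed values = .8 * .5 * .25
  expect_equal(g2[1, 3], 0.1)
  expect_equal(1 / g2[1, 3], 10)
  # id 2 follows (0,0,0): density = .2 * .5 * .75
  expect_equal(g2[2, 3], 0.075)
})

test_that("event-censored rows have missing products from the event on", {
  aug <- build_augmented(toy_panel(), 3)
  prop <- constant_propensities(rep(0.5, 3), 0, aug$D, 3)
  g <- g_cumulative(prop, aug, 2)  # id 4 censored at within-window time 3
  i4 <- which(aug$data$id[aug$data$d == 2] == 4)
  expect_false(is.na(g[i4, 2]))
  expect_true(is.na(g[i4, 3]))
  expect_true(is.na(g_product(prop, aug, 2)[i4]))
})

test_that("degenerate censoring models contribute a factor of one", {
  panel <- generate_observed(500, scenario = 1, seed = 3)
  aug <- build_augmented(panel, 3)
  prop <- fit_propensities(aug)
  for (k in 1:3) {
    cf <- prop$fits[[1]][[k]]$cens
    expect_true(isTRUE(cf$degenerate))
    expect_equal(cf$p, 0)
  }
})

test_that("fitted treatment models recover the generating coefficients", {
  panel <- generate_observed(20000, scenario = 1, seed = 14)
  aug <- build_augmented(panel, 3)
  prop <- fit_propensities(aug)
  # window 1, time 1: A1 ~ V (matching the mechanism A1 ~ expit(-0.5+2.5V))
  f11 <- prop$fits[[1]][[1]]$treat
  expect_identical(f11$terms, "V")
  # independent oracle: stats::glm on the same data supplies the SE scale
  w <- hrmsm:::panel_wide(panel)
  or <- stats::glm(A.1 ~ V, family = stats::binomial(), data = w)
  expect_equal(unname(f11$coef), unname(stats::coef(or)), tolerance = 1e-6)
  se <- summary(or)$coefficients[, 2]
  expect_lt(abs(f11$coef[1] - (-0.5)), 3 * se[1])
  expect_lt(abs(f11$coef[2] - 2.5), 3 * se[2])
  # time 2 conditions on the observed past
  expect_identical(prop$fits[[1]][[2]]$treat$terms, c("A.1", "L.1", "V"))
})

test_that("propensity predictions are invariant to row order", {
  panel <- generate_observed(400, scenario = 1, seed = 6)
  aug <- build_augmented(panel, 3)
  prop <- fit_propensities(aug)
  g1 <- g_product(prop, aug, 1)
  perm <- sample(nrow(as.data.frame(panel)))
  panel2 <- as_longitudinal_panel(as.data.frame(panel)[perm, ])
  aug2 <- build_augmented(panel2, 3)
  prop2 <- fit_propensities(aug2)
  g2 <- g_product(prop2, aug2, 1)
  ord <- match(aug$data$id[aug$data$d == 1], aug2$data$id[aug2$data$d == 1])
  expect_equal(unname(g1), unname(g2[ord]), tolerance = 1e-8)
})

test_that("projection weights form the empirical regime law", {
  panel <- generate_observed(2000, scenario = 2, seed = 9)
  aug <- build_augmented(panel, 3)
  lam <- fit_lambda(aug, "stabilized")
  for (d in 1:2) {
    expect_equal(sum(lam$by_window[[d]]), 1, tolerance = 1e-12)
    expect_true(all(lam$by_window[[d]] >= 0))
  }
  lam1 <- fit_lambda(aug, "unstabilized")
  expect_true(all(unlist(lam1$by_window) == 1))
  # degenerate case: a single observed regime takes all the mass
  p <- toy_panel()
  p$A[p$id %in% 1:4 & p$t <= 5] <- 1
  p <- as_longitudinal_panel(as.data.frame(p))
  lam2 <- fit_lambda(build_augmented(p, 3), "stabilized")
  expect_equal(unname(lam2$by_window[[1]]["111"]), 1)
})

test_that("stabilized inverse-probability weights average to about one", {
  panel <- generate_observed(5000, scenario = 1, seed = 17)
  aug <- build_augmented(panel, 3)
  prop <- fit_propensities(aug)
  lam <- fit_lambda(aug, "stabilized")
  g <- g_product(prop, aug, 1)
  obs <- hrmsm:::observed_regime(aug)
  wgt <- lam$by_window[[1]][obs] / g
  expect_lt(abs(mean(wgt) - 1), 0.05)
})

test_that("positivity failures abort with a diagnostic", {
  aug <- build_augmented(toy_panel(), 3)
  prop <- constant_propensities(c(1e-6, 1e-6, 1e-5), 0, aug$D, 3)
  expect_error(g_product(prop, aug, 1), "positivity")
})
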