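# Deterministic toy panels used across the suite.

# small hand-written panel: 4 individuals, treatments at t = 1..5,
# outcomes through t = 6; one event at t = 4, one loss to follow-up
toy_panel <- function() {
  grid <- expand.grid(t = 1:6, id = 1:4)[, c("id", "t")]
  p <- grid[order(grid$id, grid$t), ]
  p$A <- c(1, 1, 1, 1, 1, NA,   # id 1: always treated
           0, 0, 0, 0, 0, NA,   # id 2: never treated
           1, 0, 1, 0, 1, NA,   # id 3: alternating
           1, 1, 0, NA, NA, NA) # id 4: event at t = 4
  p$C <- 0
  p$Y <- c(0, 0, 0, 0, 0, 0,
           0, 0, 0, 0, 0, 1,
           0, 0, 0, 0, 0, 0,
           0, 0, 0, 1, 1, 1)
  p$L <- c(1, 1, 0, 1, 1, NA,
           0, 0, 0, 0, 1, NA,
           1, 0, 1, 1, 0, NA,
           0, 1, 1, NA, NA, NA)
  p$V <- rep(c(0.5, 1.2, 0.9, 1.5), each = 6)
  as_longitudinal_panel(p)
}

# fully discrete toy cohort (binary V), deterministic multiplicities over
# every configuration, s = 2: used for exact g-formula oracle checks
discrete_panel <- function(reps = 2) {
  cfg <- expand.grid(V = 0:1, L1 = 0:1, A1 = 0:1, L2 = 0:1, A2 = 0:1, Y3 = 0:1)
  # non-uniform integer multiplicities so conditional means are non-trivial
  w <- 1 + cfg$V + 2 * cfg$A1 * cfg$L1 + cfg$Y3 * (1 + cfg$A2) + 2 * cfg$L2
  cfg <- cfg[rep(seq_len(nrow(cfg)), w * reps), ]
  n <- nrow(cfg)
  long <- data.frame(
    id = rep(seq_len(n), each = 3),
    t = rep(1:3, n),
    A = as.numeric(t(cbind(cfg$A1, cfg$A2, NA))),
    C = 0,
    Y = as.numeric(t(cbind(0, 0, cfg$Y3))),
    L = as.numeric(t(cbind(cfg$L1, cfg$L2, NA))),
    V = rep(cfg$V, each = 3))
  as_longitudinal_panel(long)
}

# exhaustive nonparametric g-formula for the discrete s = 2 cohort:
# E[Y3 | do(A1 = a1, A2 = a2)] by summing empirical conditionals over the
# discrete covariate histories
gformula_oracle <- function(panel, a1, a2) {
  w <- hrmsm:::panel_wide(panel)
  num <- 0
  for (v in 0:1) {
    pv <- mean(w$V == v)
    if (pv == 0) next
    inner <- 0
    for (l1 in 0:1) {
      sel1 <- w$V == v & w$A.1 == a1
      pl1 <- mean(w$L.1[w$V == v] == l1)  # L1 precedes A1? ordering: Y,L,A
      sel_l1 <- w$V == v & w$L.1 == l1
      for (l2 in 0:1) {
        sel_l2 <- sel_l1 & w$A.1 == a1
        pl2 <- mean(w$L.2[sel_l2] == l2)
        sely <- sel_l2 & w$L.2 == l2 & w$A.2 == a2
        ey <- mean(w$Y.3[sely])
        inner <- inner + pl1 * pl2 * ey
      }
    }
    num <- num + pv * inner
  }
  num
}

# saturated Q-model formulas over the discrete covariates for s = 2 windows
saturated_q_terms <- function(d, j, aug) {
  vars <- c(paste0("A.", d:j), paste0("L.", d:j), "V")
  stats::as.formula(paste("~", paste(vars, collapse = "*")))
}
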