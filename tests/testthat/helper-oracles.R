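# Shared test helpers: independent oracles and compact simulators.

# Dense grid-search oracle for the MAP of the bivariate model: coarse pass
# over [-lim, lim]^2, then a fine pass at `fine` resolution around the coarse
# optimum. Fully independent of the package's optimizer (direct evaluation of
# the log-posterior over the grid).
grid_fit_biv <- function(sc, prior_sd = 5, lim = 10, coarse = 0.02, fine = 0.01) {
  logpost <- function(a_vec, b) {
    ll <- 0
    for (i in seq_along(sc$x)) {
      eta <- b * (a_vec + sc$x[i])
      lp <- ifelse(eta > 0, -log1p(exp(-eta)), eta - log1p(exp(eta)))
      lm <- ifelse(-eta > 0, -log1p(exp(eta)), -eta - log1p(exp(-eta)))
      ll <- ll + sc$k_x[i] * lp + (sc$n_x[i] - sc$k_x[i]) * lm
    }
    ll + dnorm(a_vec, 0, prior_sd, log = TRUE) + dnorm(b, 0, prior_sd, log = TRUE)
  }
  scan <- function(as, bs) {
    best <- c(NA, NA); bestv <- -Inf
    for (b in bs) {
      v <- logpost(as, b)
      i <- which.max(v)
      if (v[i] > bestv) { bestv <- v[i]; best <- c(as[i], b) }
    }
    best
  }
  g1 <- scan(seq(-lim, lim, by = coarse), seq(-lim, lim, by = coarse))
  scan(seq(g1[1] - 2 * coarse, g1[1] + 2 * coarse, by = fine),
       seq(g1[2] - 2 * coarse, g1[2] + 2 * coarse, by = fine))
}

# 1-D grid oracle for the univariate model.
grid_fit_uni <- function(sc, prior_sd = 5, lim = 15, step = 0.001) {
  cc <- seq(-lim, lim, by = step)
  k <- sum(sc$k_x); n <- sc$n
  lp <- ifelse(cc > 0, -log1p(exp(-cc)), cc - log1p(exp(cc)))
  lm <- ifelse(-cc > 0, -log1p(exp(cc)), -cc - log1p(exp(-cc)))
  v <- k * lp + (n - k) * lm + dnorm(cc, 0, prior_sd, log = TRUE)
  cc[which.max(v)]
}

# Compact choice simulator for fitting tests: n trials with dEV sampled
# uniformly from the permitted set and reveals drawn from the given model.
sim_choices <- function(n, a = NULL, b = NULL, c = NULL, seed = 1) {
  set.seed(seed)
  dev <- sample(delta_ev_set(), n, replace = TRUE)
  p <- if (!is.null(c)) rep(sigmoid(c), n) else sigmoid(b * (a + dev / 110))
  standardize_choices(runif(n) < p, dev)
}

# Cohort with well-separated strategy classes for recovery tests: |b| >= 3
# for EV-sensitive, c = 0 exactly for Random, c >= 2.5 for Uncertainty-only.
separated_config <- function(n) {
  cohort_config(n_participants = n,
                random_c_mean = 0, random_c_sd = 0,
                unc_c_mean = 3, unc_c_sd = 0.4, unc_c_min = 2.5,
                ev_b_mean = 5, ev_b_sd = 1.5, ev_b_range = c(3, 9))
}
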