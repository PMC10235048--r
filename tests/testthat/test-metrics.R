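test_that("efficiency summaries and the decomposition identity are exact", {
  rec <- data.frame(reveal = c(rep("hiVar", 100), rep("loVar", 26)),
                    delta_ev = rep(delta_ev_set(), 6))
  s <- efficiency_summary(rec)
  expect_equal(s$pct_reveal_hivar, 100 * 100 / 126)
  expect_equal(s$uncertainty_shortfall + s$ev_cost, 100 - s$pct_reveal_hivar)
  # optimal agent: 100% with a (0, 0) decomposition
  opt <- data.frame(reveal = rep("hiVar", 126), delta_ev = rep(delta_ev_set(), 6))
  so <- efficiency_summary(opt)
  expect_equal(so$pct_reveal_hivar, 100)
  expect_equal(so$uncertainty_shortfall, 0)
  expect_equal(so$ev_cost, 0)
  # no dEV = 0 trials: the dEV-0 measures are flagged as undefined
  s2 <- efficiency_summary(data.frame(reveal = "hiVar", delta_ev = 10))
  expect_true(s2$deltaev0_missing)
  expect_true(is.na(s2$pct_at_deltaev0))
  # identity holds across a heterogeneous simulated cohort
  co <- simulate_cohort(cohort_config(n_participants = 8), seed = 3)
  eff <- efficiency_table(co$trials)
  expect_equal(eff$uncertainty_shortfall + eff$ev_cost,
               100 - eff$pct_reveal_hivar)
})

test_that("EV-sensitive agents pay a positive EV cost in expectation", {
  signs <- vapply(1:100, function(s) {
    sc <- build_schedule("p", seed = s, trials_per_block = 126)
    ag <- agent_spec("p", "EV_sensitive", a = with_seed(s, rnorm(1, 0.2, 0.3)),
                     b = 5)
    rec <- simulate_choices(ag, sc, seed = 1000 + s)
    efficiency_summary(rec[rec$block == "Observe1", ])$ev_cost > 0
  }, logical(1))
  expect_lt(binom.test(sum(signs), 100, 0.5, alternative = "greater")$p.value,
            0.01)
})

test_that("psychometric curve bins aggregate exactly and follow the model", {
  ag <- agent_spec("p", "EV_sensitive", a = 0.5, b = 5)
  rec <- simulate_choices(ag, build_schedule("p", seed = 4, trials_per_block = 2100),
                          seed = 5)
  obs <- rec[rec$block == "Observe1", ]
  cb <- psychometric_curve(obs)
  # cohort %reveal equals the trial-weighted mean of the bins
  expect_equal(sum(cb$fraction * cb$n) / sum(cb$n),
               mean(obs$reveal[obs$valid] == "hiVar"))
  # monotone increasing for b > 0
  expect_gt(cor(cb$delta_ev, cb$fraction, method = "spearman"), 0)
  # fitted overlay at dEV = 0 equals sigmoid(a * b)
  f <- fit_strategy(reveal ~ delta_ev, data = obs)
  cb2 <- psychometric_curve(obs, fit = f)
  expect_equal(cb2$fitted[cb2$delta_ev == 0],
               sigmoid(f$bivariate$a * f$bivariate$b))
  # an optimal agent's curve is flat at 1
  optrec <- simulate_choices(agent_spec("q", "Uncertainty_only", c = 30),
                             build_schedule("q", seed = 6), seed = 7)
  expect_true(all(psychometric_curve(optrec)$fraction == 1))
})

test_that("task comparisons recover a planted instrumentality effect", {
  cfg <- cohort_config(n_participants = 265,
                       mixture = c(EV_sensitive = 1, Random = 0,
                                   Uncertainty_only = 0),
                       shift_estimate = 0.4, shift_intervene = 0.4)
  co <- simulate_cohort(cfg, seed = 8)
  fits <- fit_cohort(co$trials)
  eff <- efficiency_table(co$trials)
  tc <- task_comparisons(fits, efficiency = eff, agents = co$agents)
  expect_gt(tc$a_estimate_vs_observe$mean, 0.2)
  expect_lt(tc$a_estimate_vs_observe$mean, 0.6)
  expect_lt(tc$a_estimate_vs_observe$p, 0.001)
  expect_gt(tc$a_intervene_vs_observe$mean, 0.2)
  expect_lt(tc$a_intervene_vs_observe$p, 0.001)
  # no order effect was planted: the order ANOVA stays quiet
  expect_gt(tc$order_anova$p_order, 0.01)
  # %reveal improves alongside a
  expect_gt(tc$pct_estimate_vs_observe$median, 0)
  expect_lt(tc$pct_estimate_vs_observe$p, 0.001)
})

test_that("identical fits across blocks give exactly zero differences", {
  one <- data.frame(participant_id = sprintf("p%02d", 1:12),
                    a = rnorm(12), b = rnorm(12, 4), c = rnorm(12),
                    label = "EV_sensitive", stringsAsFactors = FALSE)
  fits <- do.call(rbind, lapply(c("Observe1", "Estimate", "Intervene", "Observe2"),
                                function(blk) cbind(one, block = blk)))
  tc <- task_comparisons(fits)
  expect_equal(tc$a_estimate_vs_observe$mean, 0)
  expect_equal(tc$a_estimate_vs_observe$p, 1)
  expect_equal(tc$b_intervene_vs_estimate$mean, 0)
})

test_that("paired Wilcoxon p-values are uniform when no effect is planted", {
  p <- vapply(1:100, function(s) {
    cfg <- cohort_config(n_participants = 24,
                         mixture = c(EV_sensitive = 1, Random = 0,
                                     Uncertainty_only = 0),
                         shift_estimate = 0, shift_intervene = 0)
    co <- simulate_cohort(cfg, seed = 3000 + s)
    keep <- co$trials$block %in% c("Observe1", "Estimate")
    fits <- fit_cohort(co$trials[keep, ])
    w <- merge(fits[fits$block == "Observe1", c("participant_id", "a")],
               fits[fits$block == "Estimate", c("participant_id", "a")],
               by = "participant_id")
    stats::wilcox.test(w$a.x - w$a.y, exact = FALSE)$p.value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("strategy consistency counts repetitions conditional on the first strategy", {
  mk_fits <- function(labels) {
    do.call(rbind, lapply(names(labels), function(b) {
      data.frame(participant_id = sprintf("p%03d", seq_along(labels[[b]])),
                 block = b, label = labels[[b]], stringsAsFactors = FALSE)
    }))
  }
  agents <- data.frame(participant_id = sprintf("p%03d", 1:40),
                       instrumental_order = rep(c("EstimateFirst", "InterveneFirst"), 20),
                       stringsAsFactors = FALSE)
  # perfectly consistent cohort: repetition probabilities are 1
  lab <- rep(c("Uncertainty_only", "EV_sensitive"), each = 20)
  fits <- mk_fits(list(Observe1 = lab, Estimate = lab, Intervene = lab,
                       Observe2 = lab))
  sc <- strategy_consistency(fits, agents)
  expect_equal(sc$p_repeat_uncertainty, 1)
  expect_equal(sc$p_repeat_ev, 1)
  expect_equal(sum(sc$groups), 40)
  expect_equal(unname(sc$groups["8"]), 20L)  # uncertainty-only everywhere
  expect_equal(unname(sc$groups["1"]), 20L)
  # label-shuffled cohorts: the chi-square p-value is null-calibrated
  p <- vapply(1:300, function(s) {
    set.seed(s)
    l1 <- sample(c("Uncertainty_only", "EV_sensitive"), 200, TRUE)
    l2 <- sample(c("Uncertainty_only", "EV_sensitive"), 200, TRUE)
    ag <- data.frame(participant_id = sprintf("p%03d", 1:200),
                     instrumental_order = rep("EstimateFirst", 200))
    f <- mk_fits(list(Observe1 = l1, Estimate = l1, Intervene = l2,
                      Observe2 = l1))
    strategy_consistency(f, ag)$repetition_test$p
  }, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 2 * sqrt(0.05 * 0.95 / 300) + 0.01)
  # planted switching asymmetry (Cramer's V ~ 0.2) is detected with power
  power <- mean(vapply(1:100, function(s) {
    set.seed(10000 + s)
    n <- 450
    first <- sample(c("Uncertainty_only", "EV_sensitive"), n, TRUE)
    repeat_prob <- ifelse(first == "Uncertainty_only", 0.55, 0.75)
    second <- ifelse(runif(n) < repeat_prob, first,
                     ifelse(first == "Uncertainty_only", "EV_sensitive",
                            "Uncertainty_only"))
    ag <- data.frame(participant_id = sprintf("p%03d", 1:n),
                     instrumental_order = rep("EstimateFirst", n))
    f <- mk_fits(list(Observe1 = first, Estimate = first, Intervene = second,
                      Observe2 = first))
    strategy_consistency(f, ag)$repetition_test$p < 0.05
  }, logical(1)))
  expect_gte(power, 0.8)
})

test_that("sequential effects are null for memoryless agents and detect a win-stay bolt-on", {
  # memoryless cohort
  co <- simulate_cohort(cohort_config(n_participants = 30), seed = 9)
  se <- sequential_effect(co$trials)
  ok <- !is.na(se$per_participant$effect)
  sem <- sd(se$per_participant$effect[ok]) / sqrt(sum(ok))
  expect_lt(abs(se$mean_effect), 3 * sem)
  # planted win-stay carry-over of +0.15
  cfgw <- cohort_config(n_participants = 100, win_stay = 0.15)
  cow <- simulate_cohort(cfgw, seed = 10)
  sew <- sequential_effect(cow$trials)
  expect_gt(sew$mean_effect, 0.1)
  expect_lt(sew$p, 0.01)
  # under the null the effect is uncorrelated with EV sensitivity
  fits <- fit_cohort(co$trials[co$trials$block == "Observe1", ])
  se2 <- sequential_effect(co$trials, fits = fits)
  expect_lt(abs(se2$correlation_with_b$r), 3 / sqrt(30) + 0.2)
})

test_that("within-block learning trends are null for stationary agents and track drift", {
  co <- simulate_cohort(cohort_config(n_participants = 25), seed = 11)
  wl <- within_block_learning(co$trials)
  for (b in names(wl$group_tests)) {
    gt <- wl$group_tests[[b]]
    sem <- sd(wl$per_block$half_diff[wl$per_block$block == b]) / sqrt(gt$n)
    expect_lt(abs(gt$mean_half_diff), 3 * sem)
  }
  # drift on a/c within instrumental blocks only
  cfgd <- cohort_config(n_participants = 40, drift_instrumental = 0.01)
  cod <- simulate_cohort(cfgd, seed = 12)
  wld <- within_block_learning(cod$trials)
  expect_gt(wld$group_tests$Estimate$mean_half_diff, 0)
  expect_lt(wld$group_tests$Estimate$p, 0.01)
  expect_gt(wld$group_tests$Intervene$mean_half_diff, 0)
  # non-instrumental blocks stay flat
  sem_o <- sd(wld$per_block$half_diff[wld$per_block$block == "Observe1"]) /
    sqrt(wld$group_tests$Observe1$n)
  expect_lt(abs(wld$group_tests$Observe1$mean_half_diff), 3 * sem_o)
})

test_that("obey rates follow the generative policy and recover planted coupling", {
  # obey_prob = 1 agents obey always
  ag <- agent_spec("p", "Random", c = 0, obey_prob = 1)
  rec <- simulate_choices(ag, build_schedule("p", "EstimateFirst", seed = 13),
                          seed = 14)
  oa <- obey_analysis(rec)
  expect_equal(oa$per_participant$obey_rate, 1)
  # planted negative coupling between loVar sampling and obeying
  cfg <- cohort_config(n_participants = 80, obey_coupling = 0.3)
  co <- simulate_cohort(cfg, seed = 15)
  oc <- obey_analysis(co$trials)
  expect_lt(oc$correlation$r, 0)
  expect_lt(oc$correlation$p, 0.01)
  # uncoupled cohort: correlation near zero
  co0 <- simulate_cohort(cohort_config(n_participants = 80,
                                       mixture = c(EV_sensitive = 1, Random = 0,
                                                   Uncertainty_only = 0),
                                       obey_coupling = 0), seed = 16)
  oc0 <- obey_analysis(co0$trials)
  expect_lt(abs(oc0$correlation$r), 0.3)
})
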