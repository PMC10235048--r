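# Shared cohorts for the decoding tests (simulated once per run).
planted_cohort <- local({
  co <- NULL
  function() {
    if (is.null(co)) {
      cfg <- cohort_config(n_participants = 500,
                           loadings = c(big5_extraversion = -0.5,
                                        need_for_cognition = 0.4,
                                        c5d_thrill_seeking = -0.3,
                                        c5d_stress_tolerance = 0.3))
      co <<- simulate_cohort(cfg, seed = 42)
      co$eff <<- efficiency_table(co$trials)
    }
    co
  }
})

test_that("planted personality loadings are decodable with the right signs", {
  co <- planted_cohort()
  obs1 <- co$eff[co$eff$block == "Observe1", ]
  target <- stats::setNames(obs1$pct_reveal_hivar, obs1$participant_id)
  d <- decode(co$personality, target, n_boot = 100, seed = 7)
  expect_gt(d$excess_accuracy$mean, 5)
  expect_gt(d$excess_accuracy$ci[1], 0)
  cf <- d$coefficients
  ext <- cf[cf$predictor == "big5_extraversion", ]
  expect_lt(ext$mean, 0)
  expect_true(ext$significant)
  expect_gt(cf$mean[cf$predictor == "need_for_cognition"], 0)
  expect_true(cf$significant[cf$predictor == "need_for_cognition"])
})

test_that("linear SVM and logistic decoding agree on significant coefficient signs", {
  co <- planted_cohort()
  obs1 <- co$eff[co$eff$block == "Observe1", ]
  target <- stats::setNames(obs1$pct_reveal_hivar, obs1$participant_id)
  ds <- decode(co$personality, target, method = "svm_linear", n_boot = 60, seed = 8)
  dl <- decode(co$personality, target, method = "logistic", n_boot = 60, seed = 8)
  both <- merge(ds$coefficients, dl$coefficients, by = "predictor")
  sig <- both[both$significant.x & both$significant.y, ]
  expect_gt(nrow(sig), 0)
  expect_true(all(sign(sig$mean.x) == sign(sig$mean.y)))
  expect_gt(dl$excess_accuracy$mean, 5)
})

test_that("unplanted targets decode at chance", {
  co <- planted_cohort()
  # EV sensitivity, pooled across classes (b-hat, 0 for EV-insensitive),
  # carries no planted signal
  fits <- fit_cohort(co$trials[co$trials$block == "Observe1", ])
  pp <- pooled_parameters(fits)
  target <- stats::setNames(pp$ev, pp$participant_id)
  d <- decode(co$personality, target, n_boot = 100, seed = 9)
  expect_lt(d$excess_accuracy$ci[1], 0)
  expect_gt(d$excess_accuracy$ci[2], 0)
})

test_that("a zero-loadings cohort shows no decodable signal", {
  cfg0 <- cohort_config(n_participants = 200, loadings = c(big5_extraversion = 0))
  co0 <- simulate_cohort(cfg0, seed = 11)
  eff0 <- efficiency_table(co0$trials)
  obs1 <- eff0[eff0$block == "Observe1", ]
  d0 <- decode(co0$personality, stats::setNames(obs1$pct_reveal_hivar,
                                                obs1$participant_id),
               n_boot = 100, seed = 12)
  expect_lt(d0$excess_accuracy$ci[1], 0)
  expect_gt(d0$excess_accuracy$ci[2], 0)
})

test_that("decode rejects degenerate inputs", {
  co <- planted_cohort()
  target <- stats::setNames(rep(1, nrow(co$personality)),
                            co$personality$participant_id)
  expect_error(decode(co$personality, target), "constant")
  expect_error(decode(co$personality[1:30, ],
                      target[1:30]), "at least 50")
})

test_that("leave-one-out variance attribution is calibrated and localizes signal", {
  # pure-noise scores explain almost nothing
  n <- 500
  ok <- vapply(1:100, function(s) {
    set.seed(s)
    X <- matrix(rnorm(n * 18), n, 18,
                dimnames = list(NULL, c(infodemand:::.SCORE_NAMES,
                                        "age_band", "sex", "education")))
    prof <- data.frame(participant_id = seq_len(n), X)
    y <- stats::setNames(rnorm(n), seq_len(n))
    all(variance_explained(prof, y)$per_score$delta_r2 < 0.02)
  }, logical(1))
  expect_gte(sum(ok), 95)
  # a single planted score has the largest delta R2
  set.seed(5)
  X <- matrix(rnorm(n * 18), n, 18,
              dimnames = list(NULL, c(infodemand:::.SCORE_NAMES,
                                      "age_band", "sex", "education")))
  y <- stats::setNames(0.6 * X[, "need_for_cognition"] + rnorm(n, 0, 0.8),
                       seq_len(n))
  ve <- variance_explained(data.frame(participant_id = seq_len(n), X), y)
  expect_equal(ve$per_score$predictor[which.max(ve$per_score$delta_r2)],
               "need_for_cognition")
  # duplicated predictors share their variance: each duplicate's delta R2 ~ 0
  Xd <- cbind(X, need_copy = X[, "need_for_cognition"] + rnorm(n, 0, 1e-6))
  ved <- suppressWarnings(
    variance_explained(data.frame(participant_id = seq_len(n), Xd), y))
  d2 <- ved$per_score
  expect_lt(d2$delta_r2[d2$predictor == "need_for_cognition"], 0.01)
  expect_lt(d2$delta_r2[d2$predictor == "need_copy"], 0.01)
})

test_that("the extraversion-quartile table concentrates uncertainty-only sampling", {
  co <- planted_cohort()
  fits <- fit_cohort(co$trials[co$trials$block %in% c("Estimate", "Intervene"), ])
  qt <- quartile_strategy_table(co$personality, fits)
  pu <- qt$counts[, "uncertainty_only_both"]
  # planted negative extraversion loading: uncertainty-only samplers sit in
  # the low quartiles, with a significant decreasing trend
  expect_gt(sum(pu[1:2]), sum(pu[3:4]))
  tot <- rowSums(qt$counts)
  tr <- stats::prop.trend.test(pu, tot)
  expect_lt(tr$p.value, 0.05)
  expect_error(quartile_strategy_table(co$personality[1:5, ], fits), "at least 8")
})
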