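## Model-free behavioural metrics and cohort-level analyses: sampling
## efficiency and its decomposition, psychometric curve bins, task
## comparisons, strategy consistency across blocks, sequential and
## within-block learning effects, and the obey-rate analysis.

#' Sampling-efficiency summary for one participant-block
#'
#' Computes %reveal hiVar (the model-free efficiency measure; optimal =
#' 100%), %reveal hiEV (the fraction of trials on which the revealed lottery
#' had the higher EV; trials with dEV = 0 are excluded since no higher-EV
#' lottery exists), %reveal hiVar restricted to dEV = 0 trials, and the
#' efficiency decomposition: `uncertainty_shortfall = 100 - pct_at_deltaev0`
#' (loss due to imperfect uncertainty sensitivity) and `ev_cost =
#' pct_at_deltaev0 - pct_reveal_hivar` (additional loss due to EV
#' sensitivity). The two terms sum to `100 - pct_reveal_hivar` exactly.
#'
#' @param records trial records of one participant-block with `reveal`,
#'   `delta_ev` and optionally `valid` columns.
#' @return a list with `pct_reveal_hivar`, `pct_reveal_hiev`,
#'   `pct_at_deltaev0` (NA with a flag if no dEV = 0 trials),
#'   `uncertainty_shortfall`, `ev_cost` and `n_valid`.
#' @export
efficiency_summary <- function(records) {
  keep <- if ("valid" %in% names(records)) records$valid else rep(TRUE, nrow(records))
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no valid trials", call. = FALSE)
  hi <- rec$reveal == "hiVar"
  pct_hivar <- 100 * mean(hi)
  nz <- rec$delta_ev != 0
  pct_hiev <- if (any(nz)) {
    hi_ev_revealed <- ifelse(rec$delta_ev[nz] > 0, hi[nz], !hi[nz])
    100 * mean(hi_ev_revealed)
  } else NA_real_
  z <- rec$delta_ev == 0
  pct0 <- if (any(z)) 100 * mean(hi[z]) else NA_real_
  list(pct_reveal_hivar = pct_hivar,
       pct_reveal_hiev = pct_hiev,
       pct_at_deltaev0 = pct0,
       uncertainty_shortfall = if (is.na(pct0)) NA_real_ else 100 - pct0,
       ev_cost = if (is.na(pct0)) NA_real_ else pct0 - pct_hivar,
       n_valid = nrow(rec),
       deltaev0_missing = !any(z))
}

#' Efficiency summaries for every participant-block
#'
#' @param trials trial records for a cohort.
#' @return data frame with one row per participant-block.
#' @export
efficiency_table <- function(trials) {
  parts <- split(seq_len(nrow(trials)),
                 list(trials$participant_id, trials$block), drop = TRUE)
  rows <- lapply(parts, function(idx) {
    sub <- trials[idx, ]
    s <- efficiency_summary(sub)
    data.frame(participant_id = sub$participant_id[1], block = sub$block[1],
               pct_reveal_hivar = s$pct_reveal_hivar,
               pct_reveal_hiev = s$pct_reveal_hiev,
               pct_at_deltaev0 = s$pct_at_deltaev0,
               uncertainty_shortfall = s$uncertainty_shortfall,
               ev_cost = s$ev_cost, n_valid = s$n_valid,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant_id, out$block), ]
}

#' Psychometric curve bins
#'
#' Empirical fraction of hiVar reveals per dEV level with binomial standard
#' errors, optionally with the fitted curve of a [fit_strategy()] object
#' evaluated at the bin centres.
#'
#' @param records trial records (one participant-block).
#' @param fit optional `strategy_fit` overlay.
#' @return data frame with `delta_ev`, `n`, `fraction`, `se` and (with a
#'   fit) `fitted`.
#' @export
psychometric_curve <- function(records, fit = NULL) {
  keep <- if ("valid" %in% names(records)) records$valid else rep(TRUE, nrow(records))
  rec <- records[keep, , drop = FALSE]
  lv <- sort(unique(rec$delta_ev))
  n <- vapply(lv, function(d) sum(rec$delta_ev == d), numeric(1))
  k <- vapply(lv, function(d) sum(rec$delta_ev == d & rec$reveal == "hiVar"), numeric(1))
  frac <- k / n
  out <- data.frame(delta_ev = lv, n = n, fraction = frac,
                    se = sqrt(frac * (1 - frac) / n))
  if (!is.null(fit)) out$fitted <- predict(fit, newdata = lv)
  out
}

#' Paired task comparisons of fitted parameters
#'
#' For participants with the reference label (default EV-sensitive) in all
#' compared blocks: paired differences of a, b and %reveal hiVar between
#' each instrumental block and the first Observe block (two-tailed Wilcoxon
#' signed-rank tests), the Estimate-vs-Intervene contrast on b, a two-way
#' ANOVA of a on block order x instrumentality, and the Spearman correlation
#' between the task effects on a and on b.
#'
#' @param fits cohort fit table from [fit_cohort()].
#' @param efficiency optional efficiency table from [efficiency_table()] for
#'   the %reveal comparisons.
#' @param agents optional agent table providing `instrumental_order` (for
#'   the order ANOVA); defaults to counterbalancing inferred from nothing
#'   and skips the ANOVA when absent.
#' @param labels_required label a participant must hold in all compared
#'   blocks (default `"EV_sensitive"`).
#' @return a list of per-contrast results.
#' @export
task_comparisons <- function(fits, efficiency = NULL, agents = NULL,
                             labels_required = "EV_sensitive") {
  blocks <- c("Observe1", "Estimate", "Intervene")
  wide <- function(col) {
    out <- lapply(blocks, function(b) {
      sub <- fits[fits$block == b, c("participant_id", col)]
      names(sub)[2] <- b
      sub
    })
    Reduce(function(x, y) merge(x, y, by = "participant_id"), out)
  }
  lab <- wide("label")
  keep_ids <- lab$participant_id[rowSums(lab[blocks] == labels_required) == 3L]
  if (length(keep_ids) < 2L) stop("fewer than 2 participants hold the required label in all blocks",
                                  call. = FALSE)
  pair <- function(col, b1, b2) {
    w <- wide(col)
    w <- w[w$participant_id %in% keep_ids, ]
    d <- w[[b1]] - w[[b2]]
    list(n = length(d), mean = mean(d), sem = stats::sd(d) / sqrt(length(d)),
         median = stats::median(d),
         p = if (all(d == 0)) 1 else stats::wilcox.test(d, exact = FALSE)$p.value)
  }
  out <- list(
    n = length(keep_ids),
    a_estimate_vs_observe = pair("a", "Estimate", "Observe1"),
    a_intervene_vs_observe = pair("a", "Intervene", "Observe1"),
    b_intervene_vs_estimate = pair("b", "Intervene", "Estimate"))
  if (!is.null(efficiency)) {
    eff_fits <- merge(efficiency, fits[c("participant_id", "block")],
                      by = c("participant_id", "block"))
    ew <- function(b) {
      s <- efficiency[efficiency$block == b &
                        efficiency$participant_id %in% keep_ids, ]
      s[order(s$participant_id), "pct_reveal_hivar"]
    }
    d_est <- ew("Estimate") - ew("Observe1")
    d_int <- ew("Intervene") - ew("Observe1")
    out$pct_estimate_vs_observe <- list(median = stats::median(d_est),
                                        p = stats::wilcox.test(d_est, exact = FALSE)$p.value)
    out$pct_intervene_vs_observe <- list(median = stats::median(d_int),
                                         p = stats::wilcox.test(d_int, exact = FALSE)$p.value)
  }
  ## correlation between task effects on a and on b (Intervene - Estimate)
  aw <- wide("a"); bw <- wide("b")
  aw <- aw[aw$participant_id %in% keep_ids, ]; bw <- bw[bw$participant_id %in% keep_ids, ]
  da <- aw$Intervene - aw$Estimate
  db <- bw$Intervene - bw$Estimate
  out$effect_correlation <- if (stats::sd(da) == 0 || stats::sd(db) == 0) {
    list(r = NA_real_, p = NA_real_)  # degenerate: no variation to correlate
  } else {
    ct <- stats::cor.test(da, db, method = "spearman", exact = FALSE)
    list(r = unname(ct$estimate), p = ct$p.value)
  }
  if (!is.null(agents) && "instrumental_order" %in% names(agents)) {
    long <- fits[fits$block %in% c("Estimate", "Intervene") &
                   fits$participant_id %in% keep_ids, ]
    long <- merge(long, agents[c("participant_id", "instrumental_order")],
                  by = "participant_id")
    long$task <- factor(long$block)
    long$order <- factor(long$instrumental_order)
    an <- stats::anova(stats::aov(a ~ order * task, data = long))
    out$order_anova <- list(
      p_order = an["order", "Pr(>F)"],
      p_interaction = an["order:task", "Pr(>F)"],
      F_order = an["order", "F value"],
      F_interaction = an["order:task", "F value"])
  }
  out
}

#' Strategy consistency across blocks
#'
#' Groups participants by the combination of blocks (first Observe, first
#' instrumental, second instrumental) in which they used an Uncertainty-only
#' strategy (2^3 = 8 groups; the second Observe block is reported
#' separately), and tests whether starting the first instrumental block with
#' an Uncertainty-only strategy predicts repeating it in the second,
#' conditional on the starting strategy (one-way chi-square on the
#' repetition counts, df = 1, with Cramer's V).
#'
#' @param fits cohort fit table from [fit_cohort()].
#' @param agents agent table with `instrumental_order`.
#' @return a list with the 8-group table, repetition probabilities, the
#'   chi-square test and the count repeating Uncertainty-only in Observe2.
#' @export
strategy_consistency <- function(fits, agents) {
  wide <- stats::reshape(fits[c("participant_id", "block", "label")],
                         idvar = "participant_id", timevar = "block",
                         direction = "wide")
  names(wide) <- sub("^label\\.", "", names(wide))
  wide <- merge(wide, agents[c("participant_id", "instrumental_order")],
                by = "participant_id")
  ## participants with a withheld (unconverged) label in any grouping block
  ## cannot be placed in the 2^3 grouping and are dropped
  wide <- wide[!is.na(wide$Observe1) & !is.na(wide$Estimate) &
                 !is.na(wide$Intervene), ]
  first <- ifelse(wide$instrumental_order == "EstimateFirst",
                  wide$Estimate, wide$Intervene)
  second <- ifelse(wide$instrumental_order == "EstimateFirst",
                   wide$Intervene, wide$Estimate)
  u <- function(x) x == "Uncertainty_only"
  grp <- 1L + 4L * u(wide$Observe1) + 2L * u(first) + 1L * u(second)
  groups <- table(factor(grp, levels = 1:8))
  ## conditional repetition: started X in first instrumental block, kept X?
  started_u <- u(first); started_e <- first == "EV_sensitive"
  rep_u <- sum(started_u & u(second)); n_u <- sum(started_u)
  rep_e <- sum(started_e & second == "EV_sensitive"); n_e <- sum(started_e)
  test <- if (n_u == 0L || n_e == 0L) NULL else {
    m <- matrix(c(rep_u, n_u - rep_u, rep_e, n_e - rep_e), 2, byrow = TRUE)
    ch <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    list(chisq = unname(ch$statistic), df = 1, p = ch$p.value,
         cramers_v = sqrt(unname(ch$statistic) / sum(m)))
  }
  list(groups = groups,
       p_repeat_uncertainty = if (n_u > 0) rep_u / n_u else NA_real_,
       p_repeat_ev = if (n_e > 0) rep_e / n_e else NA_real_,
       n_started_uncertainty = n_u, n_started_ev = n_e,
       repetition_test = test,
       observe2_uncertainty_only = sum(u(wide$Observe2), na.rm = TRUE))
}

#' Sequential (prior-outcome) effect on sampling
#'
#' For each participant: the difference in the probability of revealing the
#' same lottery as on the previous trial, after observing that lottery's
#' high versus low prize. Memoryless agents have effect 0; a win-stay
#' carry-over makes it positive.
#'
#' @param trials cohort trial records.
#' @param fits optional fit table; when given, the Spearman correlation of
#'   the effect with the fitted slope b across participants is added.
#' @param min_transitions minimum valid transitions per participant.
#' @return a list with the per-participant effects data frame (`effect` is
#'   NA when below `min_transitions`, flagged), a group-level Wilcoxon test
#'   and optionally the correlation with b.
#' @export
sequential_effect <- function(trials, fits = NULL, min_transitions = 20L) {
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(id) {
    sub <- trials[trials$participant_id == id, ]
    sub <- sub[order(sub$block_position, sub$trial_index), ]
    prev_same_block <- c(FALSE, sub$block[-1] == sub$block[-nrow(sub)])
    keep <- if ("valid" %in% names(sub)) sub$valid & c(FALSE, sub$valid[-nrow(sub)]) else rep(TRUE, nrow(sub))
    use <- prev_same_block & keep
    prev_reveal <- c(NA, sub$reveal[-nrow(sub)])
    prev_high <- c(NA, ifelse(sub$reveal == "hiVar",
                              sub$draw_hivar == sub$hi_prize_high,
                              sub$draw_lovar == sub$lo_prize_high)[-nrow(sub)])
    same <- sub$reveal == prev_reveal
    hi_tr <- use & prev_high
    lo_tr <- use & !prev_high
    n_tr <- sum(use)
    eff <- if (n_tr < min_transitions || !any(hi_tr) || !any(lo_tr)) NA_real_
    else mean(same[hi_tr]) - mean(same[lo_tr])
    data.frame(participant_id = id, effect = eff, n_transitions = n_tr,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  ok <- !is.na(per$effect)
  out <- list(per_participant = per,
              mean_effect = mean(per$effect[ok]),
              p = if (sum(ok) >= 2) stats::wilcox.test(per$effect[ok], exact = FALSE)$p.value else NA_real_)
  if (!is.null(fits)) {
    b1 <- fits[fits$block == "Observe1", c("participant_id", "b")]
    m <- merge(per[ok, ], b1, by = "participant_id")
    if (nrow(m) >= 3) {
      ct <- stats::cor.test(m$effect, m$b, method = "spearman", exact = FALSE)
      out$correlation_with_b <- list(r = unname(ct$estimate), p = ct$p.value)
    }
  }
  out
}

#' Within-block learning of sampling efficiency
#'
#' Per participant-block: the logistic trend of revealing hiVar on trial
#' index and the first-half vs second-half difference in %reveal hiVar (the
#' primary statistic), with a group-level Wilcoxon test per block type.
#'
#' @param trials cohort trial records.
#' @return a list with the per-participant-block data frame and group tests
#'   by block.
#' @export
within_block_learning <- function(trials) {
  parts <- split(seq_len(nrow(trials)),
                 list(trials$participant_id, trials$block), drop = TRUE)
  rows <- lapply(parts, function(idx) {
    sub <- trials[idx, ]
    if ("valid" %in% names(sub)) sub <- sub[sub$valid, ]
    y <- as.integer(sub$reveal == "hiVar")
    half <- sub$trial_index > stats::median(sub$trial_index)
    slope <- tryCatch(
      unname(stats::coef(suppressWarnings(
        stats::glm(y ~ sub$trial_index, family = stats::binomial())))[2]),
      error = function(e) NA_real_)
    data.frame(participant_id = sub$participant_id[1], block = sub$block[1],
               logistic_slope = slope,
               half_diff = 100 * (mean(y[half]) - mean(y[!half])),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  tests <- lapply(split(per, per$block), function(s) {
    d <- s$half_diff[is.finite(s$half_diff)]
    list(n = length(d), mean_half_diff = mean(d),
         p = if (length(d) >= 2 && any(d != 0)) stats::wilcox.test(d, exact = FALSE)$p.value else NA_real_)
  })
  list(per_block = per, group_tests = tests)
}

#' Obey-rate analysis of Estimate guesses after loVar reveals
#'
#' The obey rate is the probability that a participant's Estimate guess
#' follows the valence of the observed prize (high prize -> guess above)
#' after revealing the loVar lottery. Reports per-participant obey rates and
#' the Spearman correlation between %inspect loVar and the obey rate.
#'
#' @param trials cohort trial records (Estimate block used).
#' @return a list with the per-participant data frame (participants with no
#'   loVar reveals are excluded) and the correlation test.
#' @export
obey_analysis <- function(trials) {
  est <- trials[block_type(trials$block) == "Estimate", ]
  if ("valid" %in% names(est)) est <- est[est$valid, ]
  ids <- unique(est$participant_id)
  rows <- lapply(ids, function(id) {
    sub <- est[est$participant_id == id, ]
    lov <- sub$reveal == "loVar"
    if (!any(lov)) return(NULL)
    obs_high <- sub$draw_lovar[lov] == sub$lo_prize_high[lov]
    obeyed <- ifelse(obs_high, sub$post_action[lov] == "guess_above",
                     sub$post_action[lov] == "guess_below")
    data.frame(participant_id = id,
               pct_inspect_lovar = 100 * mean(lov),
               obey_rate = mean(obeyed),
               n_lovar = sum(lov), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  ct <- if (!is.null(per) && nrow(per) >= 3)
    stats::cor.test(per$pct_inspect_lovar, per$obey_rate,
                    method = "spearman", exact = FALSE) else NULL
  list(per_participant = per,
       correlation = if (is.null(ct)) NULL else list(r = unname(ct$estimate),
                                                     p = ct$p.value))
}
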