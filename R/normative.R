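## Normative observer: exhaustive enumeration of post-reveal outcomes,
## expected guess accuracy, Intervene recuperation and expected earnings per
## sampling policy. Everything here is exact arithmetic over the four
## equiprobable draw combinations of a trial; no simulation is involved.

#' Possible sums after revealing one lottery
#'
#' Given a revealed prize, enumerates the possible total draws: the observed
#' prize plus each prize of the unrevealed lottery. The residual uncertainty
#' (range of the possible sums) always equals the unrevealed lottery's range.
#'
#' @param pair a lottery pair from [make_lottery_pair()].
#' @param reveal `"hiVar"` or `"loVar"`.
#' @param observed_prize the prize observed from the revealed lottery; must be
#'   one of that lottery's two prizes.
#' @return a list with `possible_sums` (sorted increasing), `sum_range`,
#'   `optimal_guess` (`"above"`, `"below"`, or `"indifferent"` when the two
#'   sums straddle 500) and `guess_accuracy` (probability the optimal guess is
#'   correct: 1 unless indifferent, then 0.5).
#' @export
possible_sums <- function(pair, reveal = c("hiVar", "loVar"), observed_prize) {
  reveal <- match.arg(reveal)
  revealed <- if (reveal == "hiVar") pair$hivar else pair$lovar
  other <- if (reveal == "hiVar") pair$lovar else pair$hivar
  if (!observed_prize %in% c(revealed$prize_high, revealed$prize_low)) {
    stop("observed_prize ", observed_prize, " is not a prize of the revealed (",
         reveal, ") lottery", call. = FALSE)
  }
  sums <- sort(observed_prize + c(other$prize_low, other$prize_high))
  above <- sums > .TOTAL_EV
  guess <- if (all(above)) "above" else if (all(!above)) "below" else "indifferent"
  list(
    possible_sums = sums,
    sum_range = diff(sums),
    optimal_guess = guess,
    guess_accuracy = if (guess == "indifferent") 0.5 else 1
  )
}

#' Expected accuracy of the optimal Estimate guess
#'
#' Probability that the optimal above/below-500 guess is correct after
#' revealing the given lottery, averaged over the four equiprobable draw
#' combinations. Because the total EV is constant at 500 and the loVar range
#' (30) is smaller than the hiVar range (120), a hiVar reveal pins the sum to
#' one side of 500 (accuracy 1) while a loVar reveal leaves one possible sum
#' on each side (accuracy 0.5), for every permitted dEV.
#'
#' @inheritParams possible_sums
#' @return probability in \{0.5, 1\}.
#' @export
expected_estimate_accuracy <- function(pair, reveal = c("hiVar", "loVar")) {
  reveal <- match.arg(reveal)
  revealed <- if (reveal == "hiVar") pair$hivar else pair$lovar
  mean(vapply(c(revealed$prize_low, revealed$prize_high), function(p) {
    possible_sums(pair, reveal, p)$guess_accuracy
  }, numeric(1)))
}

#' Intervene recuperation after revealing one lottery
#'
#' Points recoverable in the Intervene task by exchanging a revealed low draw
#' for the lottery's mean: 60 for the hiVar lottery, 15 for the loVar lottery
#' (a 4x ratio). Under the optimal "switch iff the draw is below the EV"
#' rule, a low draw occurs with probability 1/2, so the per-trial expected
#' gain is half the low-draw gain.
#'
#' @inheritParams possible_sums
#' @return a list with `low_draw_gain` and `per_trial_expected_gain` (points).
#' @export
expected_intervene_recuperation <- function(pair, reveal = c("hiVar", "loVar")) {
  reveal <- match.arg(reveal)
  revealed <- if (reveal == "hiVar") pair$hivar else pair$lovar
  gain <- revealed$ev - revealed$prize_low
  list(low_draw_gain = gain, per_trial_expected_gain = gain / 2)
}

## Enumerate the four equiprobable draw combinations of a pair.
enumerate_draws <- function(pair) {
  expand.grid(draw_hivar = c(pair$hivar$prize_low, pair$hivar$prize_high),
              draw_lovar = c(pair$lovar$prize_low, pair$lovar$prize_high))
}

#' Expected earnings per trial under a sampling policy
#'
#' Exact expected payoff per trial for a deterministic reveal policy combined
#' with the optimal post-sampling rule, averaged over the permitted dEV set
#' and the four equiprobable draw combinations of each pair. The optimal
#' post-rule is: Observe, none; Estimate, guess the side of 500 favoured by
#' the possible sums (ties scored at 0.5 accuracy); Intervene, switch iff the
#' observed draw is below the revealed lottery's EV.
#'
#' @param reveal_policy `"hiVar"`, `"loVar"`, or a function
#'   `function(delta_ev)` returning `"hiVar"`/`"loVar"` per trial type.
#' @param block `"Observe"`, `"Estimate"` or `"Intervene"`.
#' @param delta_evs dEV values to average over (default the permitted set).
#' @return expected points per trial.
#' @export
expected_earnings <- function(reveal_policy, block = c("Observe", "Estimate", "Intervene"),
                              delta_evs = delta_ev_set()) {
  block <- match.arg(block)
  pick <- if (is.function(reveal_policy)) reveal_policy else function(dev) reveal_policy
  per_dev <- vapply(delta_evs, function(dev) {
    pair <- make_lottery_pair(dev, permissive = TRUE)
    reveal <- match.arg(pick(dev), c("hiVar", "loVar"))
    revealed <- if (reveal == "hiVar") pair$hivar else pair$lovar
    draws <- enumerate_draws(pair)
    observed <- if (reveal == "hiVar") draws$draw_hivar else draws$draw_lovar
    payoff <- switch(block,
      Observe = draws$draw_hivar + draws$draw_lovar,
      Estimate = {
        acc <- vapply(observed, function(p) {
          ps <- possible_sums(pair, reveal, p)
          ps$guess_accuracy
        }, numeric(1))
        ## expected payoff of the optimal guess: accuracy times the realized
        ## sum (for the indifferent case, each sum is obtained w.p. 1/2 when
        ## guessed correctly, which averages to 0.5 * sum over draws)
        acc * (draws$draw_hivar + draws$draw_lovar)
      },
      Intervene = {
        unrevealed <- if (reveal == "hiVar") draws$draw_lovar else draws$draw_hivar
        kept <- pmax(observed, revealed$ev)  # switch iff draw < EV
        unrevealed + kept
      })
    mean(payoff)
  }, numeric(1))
  mean(per_dev)
}

#' Missed earnings of a policy relative to the optimal policy
#'
#' @inheritParams expected_earnings
#' @return expected points per trial lost relative to always revealing the
#'   hiVar lottery with the optimal post-rule.
#' @export
missed_earnings <- function(reveal_policy, block, delta_evs = delta_ev_set()) {
  expected_earnings("hiVar", block, delta_evs) -
    expected_earnings(reveal_policy, block, delta_evs)
}

#' Normative report
#'
#' Task-level normative constants and expected earnings per block and policy,
#' suitable for JSON serialization.
#'
#' @param trials_per_block block length used to scale per-block earnings.
#' @return a nested list.
#' @export
normative_report <- function(trials_per_block = 126L) {
  blocks <- c("Observe", "Estimate", "Intervene")
  earn <- lapply(blocks, function(b) {
    per_trial <- c(reveal_hivar = expected_earnings("hiVar", b),
                   reveal_lovar = expected_earnings("loVar", b))
    list(per_trial = as.list(per_trial),
         per_block = as.list(per_trial * trials_per_block))
  })
  names(earn) <- blocks
  pair0 <- make_lottery_pair(0)
  list(
    total_ev = .TOTAL_EV,
    estimate_accuracy = list(hiVar = expected_estimate_accuracy(pair0, "hiVar"),
                             loVar = expected_estimate_accuracy(pair0, "loVar")),
    intervene_recuperation = list(
      hiVar = expected_intervene_recuperation(pair0, "hiVar")$low_draw_gain,
      loVar = expected_intervene_recuperation(pair0, "loVar")$low_draw_gain),
    expected_earnings = earn
  )
}
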