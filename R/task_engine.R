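## Task engine: construction of lottery pairs, trial schedules, draws, payoff
## resolution and bonus selection for the two-lottery sampling task.
##
## Design constants. Each trial shows two two-prize lotteries whose expected
## values sum to 500 points. The high-variance (hiVar) lottery has a 120-point
## spread between its prizes, the low-variance (loVar) lottery a 30-point
## spread. The relative expected value dEV = EV(hiVar) - EV(loVar) is drawn
## uniformly from a fixed 21-element set.

.TOTAL_EV <- 500
.HI_RANGE <- 120
.LO_RANGE <- 30
.TRIALS_PER_BLOCK <- 126L
.RT_WINDOW <- c(0.5, 10)
.POINTS_PER_DOLLAR <- 2000

#' Permitted relative expected values
#'
#' The 21 values of dEV (expected value of the high-variance lottery minus
#' that of the low-variance lottery) used by the task. Note the set is not
#' symmetric in its extremes: it contains -110 and 110 but skips -100 and 100.
#'
#' @return integer vector of length 21.
#' @export
delta_ev_set <- function() {
  c(-110, -90, -80, -70, -60, -50, -40, -30, -20, -10,
    0, 10, 20, 30, 40, 50, 60, 70, 80, 90, 110)
}

#' Construct a hiVar/loVar lottery pair
#'
#' Builds the pair of two-prize lotteries with total expected value 500 and
#' relative expected value `delta_ev`. The hiVar lottery has prizes at its EV
#' +/- 60 (range 120); the loVar lottery at its EV +/- 15 (range 30).
#'
#' @param delta_ev relative expected value in points. Must belong to
#'   [delta_ev_set()] unless `permissive = TRUE` (useful for worked examples
#'   outside the task's design, e.g. dEV = -100).
#' @param permissive allow arbitrary `delta_ev` values.
#' @return a list with components `hivar` and `lovar`, each a list with
#'   `prize_high`, `prize_low`, `ev` and `range`. Prizes are stored as
#'   numbers; no integrality is imposed.
#' @examples
#' make_lottery_pair(0)
#' make_lottery_pair(-100, permissive = TRUE)  # hiVar {260,140}, loVar {315,285}
#' @export
make_lottery_pair <- function(delta_ev, permissive = FALSE) {
  stopifnot(length(delta_ev) == 1L, is.numeric(delta_ev))
  if (!permissive && !delta_ev %in% delta_ev_set()) {
    stop("delta_ev = ", delta_ev, " is not in the permitted set [",
         paste(delta_ev_set(), collapse = ", "),
         "]; use permissive = TRUE to allow arbitrary values.", call. = FALSE)
  }
  hi_ev <- (.TOTAL_EV + delta_ev) / 2
  lo_ev <- (.TOTAL_EV - delta_ev) / 2
  list(
    hivar = list(prize_high = hi_ev + .HI_RANGE / 2,
                 prize_low  = hi_ev - .HI_RANGE / 2,
                 ev = hi_ev, range = .HI_RANGE),
    lovar = list(prize_high = lo_ev + .LO_RANGE / 2,
                 prize_low  = lo_ev - .LO_RANGE / 2,
                 ev = lo_ev, range = .LO_RANGE)
  )
}

#' Block labels and types
#'
#' Sessions consist of four blocks: a first Observe block, the Estimate and
#' Intervene blocks in counterbalanced order, and a final Observe block.
#' `block_type()` strips the Observe repetition index, giving the task type
#' used by payoff rules.
#'
#' @param block character vector of block labels
#'   ("Observe1", "Estimate", "Intervene", "Observe2").
#' @return character vector of types ("Observe", "Estimate", "Intervene").
#' @export
block_type <- function(block) {
  out <- ifelse(block %in% c("Observe1", "Observe2"), "Observe", block)
  bad <- !out %in% c("Observe", "Estimate", "Intervene")
  if (any(bad)) stop("unknown block label(s): ",
                     paste(unique(block[bad]), collapse = ", "), call. = FALSE)
  out
}

#' Build a session schedule of trials
#'
#' Generates the four-block trial schedule for one participant: 126 trials per
#' block, dEV drawn uniformly from [delta_ev_set()], prizes constructed by
#' [make_lottery_pair()], and one prize drawn from each lottery independently
#' with probability 1/2.
#'
#' @param participant_id identifier stored with each trial.
#' @param instrumental_order `"EstimateFirst"` or `"InterveneFirst"`.
#' @param seed integer seed for the trial-level randomness.
#' @param trials_per_block number of trials per block (default 126).
#' @return a data frame with one row per trial and columns
#'   `participant_id`, `block`, `block_position`, `trial_index`,
#'   `hi_prize_high`, `hi_prize_low`, `lo_prize_high`, `lo_prize_low`,
#'   `delta_ev`, `draw_hivar`, `draw_lovar`.
#' @export
build_schedule <- function(participant_id, instrumental_order = c("EstimateFirst", "InterveneFirst"),
                           seed = 1L, trials_per_block = .TRIALS_PER_BLOCK) {
  instrumental_order <- match.arg(instrumental_order)
  middle <- if (instrumental_order == "EstimateFirst") c("Estimate", "Intervene")
            else c("Intervene", "Estimate")
  blocks <- c("Observe1", middle, "Observe2")
  n_per <- as.integer(trials_per_block)
  n_tot <- 4L * n_per
  with_seed(seed, {
    dev <- sample(delta_ev_set(), n_tot, replace = TRUE)
    hi_ev <- (.TOTAL_EV + dev) / 2
    lo_ev <- (.TOTAL_EV - dev) / 2
    hi_high <- stats::runif(n_tot) < 0.5
    lo_high <- stats::runif(n_tot) < 0.5
    data.frame(
      participant_id = participant_id,
      block = rep(blocks, each = n_per),
      block_position = rep(1:4, each = n_per),
      trial_index = rep(seq_len(n_per), times = 4L),
      hi_prize_high = hi_ev + .HI_RANGE / 2,
      hi_prize_low  = hi_ev - .HI_RANGE / 2,
      lo_prize_high = lo_ev + .LO_RANGE / 2,
      lo_prize_low  = lo_ev - .LO_RANGE / 2,
      delta_ev = dev,
      draw_hivar = ifelse(hi_high, hi_ev + .HI_RANGE / 2, hi_ev - .HI_RANGE / 2),
      draw_lovar = ifelse(lo_high, lo_ev + .LO_RANGE / 2, lo_ev - .LO_RANGE / 2),
      stringsAsFactors = FALSE
    )
  })
}

#' Draw prizes for one trial
#'
#' Draws one prize from each lottery of a trial, independently and with
#' probability 1/2 for the high prize.
#'
#' @param trial a one-row data frame (or list) with the prize columns produced
#'   by [build_schedule()].
#' @return the trial with `draw_hivar` and `draw_lovar` set.
#' @export
draw_outcomes <- function(trial) {
  trial$draw_hivar <- if (stats::runif(1) < 0.5) trial$hi_prize_high else trial$hi_prize_low
  trial$draw_lovar <- if (stats::runif(1) < 0.5) trial$lo_prize_high else trial$lo_prize_low
  trial
}

## Vectorized payoff resolution used by both the single-trial interface and
## the cohort simulator. All arguments are parallel vectors.
payoff_points <- function(type, draw_hivar, draw_lovar, hi_ev, lo_ev,
                          reveal, post_action) {
  total <- draw_hivar + draw_lovar
  observed <- ifelse(reveal == "hiVar", draw_hivar, draw_lovar)
  unrevealed <- ifelse(reveal == "hiVar", draw_lovar, draw_hivar)
  revealed_ev <- ifelse(reveal == "hiVar", hi_ev, lo_ev)

  ok_obs <- type == "Observe" & post_action == "none"
  ok_est <- type == "Estimate" & post_action %in% c("guess_above", "guess_below")
  ok_int <- type == "Intervene" & post_action %in% c("keep", "switch")
  if (!all(ok_obs | ok_est | ok_int)) {
    bad <- which(!(ok_obs | ok_est | ok_int))[1L]
    stop(sprintf("post_action '%s' is not valid in a %s block",
                 post_action[bad], type[bad]), call. = FALSE)
  }

  correct <- (post_action == "guess_above" & total > .TOTAL_EV) |
             (post_action == "guess_below" & total < .TOTAL_EV)
  ifelse(type == "Observe", total,
  ifelse(type == "Estimate", ifelse(correct, total, 0),
         unrevealed + ifelse(post_action == "keep", observed, revealed_ev)))
}

#' Resolve the payoff of a trial
#'
#' Applies the block's payoff rule. Observe: the sum of the two draws.
#' Estimate: the sum if the above/below-500 guess matches the true sum, else
#' 0 (the sum can never equal 500: realized sums are 500 +/- 45 or
#' 500 +/- 75). Intervene: the unrevealed draw plus either the observed draw
#' (keep) or the revealed lottery's expected value (switch).
#'
#' @param trial a one-row data frame (or list) with prize and draw columns and
#'   a `block` column.
#' @param reveal `"hiVar"` or `"loVar"`.
#' @param post_action `"none"` (Observe), `"guess_above"`/`"guess_below"`
#'   (Estimate), or `"keep"`/`"switch"` (Intervene).
#' @return payoff in points.
#' @export
resolve_payoff <- function(trial, reveal, post_action) {
  stopifnot(reveal %in% c("hiVar", "loVar"))
  hi_ev <- (trial$hi_prize_high + trial$hi_prize_low) / 2
  lo_ev <- (trial$lo_prize_high + trial$lo_prize_low) / 2
  payoff_points(block_type(trial$block), trial$draw_hivar, trial$draw_lovar,
                hi_ev, lo_ev, reveal, post_action)
}

#' Select the bonus for a block
#'
#' One trial is chosen uniformly at random from those played in the block and
#' its payoff converted to dollars at 2000 points per dollar.
#'
#' @param payoffs numeric vector of the block's trial payoffs (points).
#' @return bonus in dollars.
#' @export
select_bonus <- function(payoffs) {
  if (length(payoffs) == 0L) stop("cannot select a bonus from an empty block", call. = FALSE)
  payoffs[sample.int(length(payoffs), 1L)] / .POINTS_PER_DOLLAR
}

#' Session bonus
#'
#' Sums the four block bonuses and the show-up fee.
#'
#' @param trials trial records for one participant with `block` and `payoff`
#'   columns.
#' @param show_up_fee dollars added to the summed block bonuses (default 1).
#' @return total payment in dollars.
#' @export
session_bonus <- function(trials, show_up_fee = 1) {
  per_block <- vapply(split(trials$payoff, trials$block), select_bonus, numeric(1))
  show_up_fee + sum(per_block)
}
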