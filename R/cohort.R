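## Synthetic cohort: labelled generative agents for the two-lottery task,
## their simulated choices, and personality profiles with planted
## associations to uncertainty sensitivity. The generator gives every
## downstream stage (fitting, classification, metrics, decoding) ground
## truth to recover.

.SCORE_NAMES <- c(
  "bis", "bas_drive", "bas_fun_seeking", "bas_reward",
  "big5_extraversion", "big5_agreeableness", "big5_conscientiousness",
  "big5_neuroticism", "big5_openness",
  "need_for_cognition",
  "c5d_joyous_exploration", "c5d_deprivation_sensitivity",
  "c5d_stress_tolerance", "c5d_social_curiosity", "c5d_thrill_seeking")

#' Cohort configuration
#'
#' Parameters of the synthetic cohort: the strategy-class mixture, per-class
#' parameter distributions, per-class post-sampling reliability, the
#' instrumental shift in uncertainty sensitivity, optional trial-by-trial
#' mechanisms (win-stay bolt-on, within-block drift), reaction-time
#' generation, and the personality loadings (planted on the standardized
#' long-run probability of revealing the hiVar lottery, never on EV
#' sensitivity).
#'
#' @param n_participants cohort size.
#' @param mixture named class proportions (must sum to 1).
#' @param ev_a_mean,ev_a_sd Normal distribution of the uncertainty
#'   sensitivity a of EV-sensitive agents (logit units inside the slope).
#' @param ev_b_mean,ev_b_sd,ev_b_range Normal distribution of the EV slope b,
#'   truncated to `ev_b_range`.
#' @param random_c_mean,random_c_sd constant-rate logit of Random agents.
#' @param unc_c_mean,unc_c_sd,unc_c_min constant-rate logit of
#'   Uncertainty-only agents, truncated below at `unc_c_min`.
#' @param obey_prob named per-class probability that an Estimate guess after
#'   a loVar reveal follows the observed prize's valence.
#' @param obey_coupling additive coupling of an agent's obey probability to
#'   its standardized hiVar-sampling tendency (0 = none).
#' @param intervene_lapse named per-class probability of deviating from the
#'   switch-iff-below-EV rule.
#' @param shift_estimate,shift_intervene additive shifts on a (and c) in the
#'   Estimate and Intervene blocks, emulating the instrumentality effect.
#' @param drift_instrumental per-trial additive drift on a (and c) within
#'   instrumental blocks (0 = stationary agents).
#' @param win_stay prior-outcome carry-over: after observing the revealed
#'   lottery's high prize the probability of revealing the same lottery on
#'   the next trial is shifted by `+win_stay`, and by `-win_stay` after its
#'   low prize (0 = memoryless agents).
#' @param loadings named loadings of planted personality scores on the
#'   standardized long-run %reveal hiVar; scores keep unit variance
#'   (`score = loading * z + sqrt(1 - loading^2) * noise`). Names must be
#'   among the 15 questionnaire score names.
#' @param rt_meanlog,rt_sdlog log-normal reaction-time generator (a
#'   placeholder that feeds the 0.5-10 s validity filter; no reaction-time
#'   model is claimed).
#' @param trials_per_block trials per block (default 126).
#' @return a list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_participants = 60L,
                          mixture = c(EV_sensitive = 0.70, Random = 0.10,
                                      Uncertainty_only = 0.20),
                          ev_a_mean = 0.2, ev_a_sd = 0.4,
                          ev_b_mean = 5, ev_b_sd = 1.5, ev_b_range = c(3, 9),
                          random_c_mean = 0, random_c_sd = 0.2,
                          unc_c_mean = 3, unc_c_sd = 0.4, unc_c_min = 2.5,
                          obey_prob = c(EV_sensitive = 0.90, Random = 0.60,
                                        Uncertainty_only = 0.95),
                          obey_coupling = 0,
                          intervene_lapse = c(EV_sensitive = 0.05, Random = 0.40,
                                              Uncertainty_only = 0.03),
                          shift_estimate = 0.4, shift_intervene = 0.4,
                          drift_instrumental = 0,
                          win_stay = 0,
                          loadings = c(big5_extraversion = -0.5,
                                       need_for_cognition = 0.4,
                                       c5d_thrill_seeking = -0.3,
                                       c5d_stress_tolerance = 0.3),
                          rt_meanlog = log(1.5), rt_sdlog = 0.4,
                          trials_per_block = 126L) {
  stopifnot(abs(sum(mixture) - 1) < 1e-8, all(mixture >= 0))
  if (!all(names(loadings) %in% .SCORE_NAMES)) {
    stop("unknown loading name(s): ",
         paste(setdiff(names(loadings), .SCORE_NAMES), collapse = ", "),
         call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Construct an agent specification
#'
#' @param participant_id identifier.
#' @param strategy_class `"EV_sensitive"`, `"Random"` or `"Uncertainty_only"`.
#' @param a,b bivariate parameters (EV-sensitive agents).
#' @param c constant-rate logit (Random / Uncertainty-only agents).
#' @param obey_prob,intervene_lapse post-sampling reliability parameters.
#' @param shift_estimate,shift_intervene,drift_instrumental,win_stay
#'   block modifiers, see [cohort_config()].
#' @return a list of class `"agent_spec"`.
#' @export
agent_spec <- function(participant_id, strategy_class, a = NULL, b = NULL, c = NULL,
                       obey_prob = 0.9, intervene_lapse = 0.05,
                       shift_estimate = 0, shift_intervene = 0,
                       drift_instrumental = 0, win_stay = 0) {
  strategy_class <- match.arg(strategy_class,
                              c("EV_sensitive", "Random", "Uncertainty_only"))
  if (strategy_class == "EV_sensitive") {
    stopifnot(!is.null(a), !is.null(b))
  } else {
    stopifnot(!is.null(c))
  }
  stopifnot(obey_prob >= 0, obey_prob <= 1,
            intervene_lapse >= 0, intervene_lapse <= 1)
  structure(list(participant_id = participant_id,
                 strategy_class = strategy_class,
                 a = a, b = b, c = c,
                 obey_prob = obey_prob, intervene_lapse = intervene_lapse,
                 shift_estimate = shift_estimate,
                 shift_intervene = shift_intervene,
                 drift_instrumental = drift_instrumental,
                 win_stay = win_stay),
            class = "agent_spec")
}

#' Sample an agent from a cohort configuration
#'
#' @param cfg a [cohort_config()].
#' @param class strategy class to draw parameters for.
#' @param participant_id identifier.
#' @return an [agent_spec()].
#' @export
sample_agent <- function(cfg, class, participant_id = "agent") {
  rtrunc <- function(mean, sd, lower = -Inf, upper = Inf) {
    if (sd == 0) return(mean)
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v >= lower && v <= upper) return(v)
    }
  }
  args <- switch(class,
    EV_sensitive = list(a = stats::rnorm(1, cfg$ev_a_mean, cfg$ev_a_sd),
                        b = rtrunc(cfg$ev_b_mean, cfg$ev_b_sd,
                                   cfg$ev_b_range[1], cfg$ev_b_range[2])),
    Random = list(c = stats::rnorm(1, cfg$random_c_mean, cfg$random_c_sd)),
    Uncertainty_only = list(c = rtrunc(cfg$unc_c_mean, cfg$unc_c_sd,
                                       lower = cfg$unc_c_min)),
    stop("unknown strategy class: ", class, call. = FALSE))
  ## disengaged Random agents sample at chance in every block: the
  ## instrumentality shift applies only to classes with real uncertainty
  ## sensitivity
  shifted <- class != "Random"
  do.call(agent_spec, c(list(participant_id = participant_id,
                             strategy_class = class),
                        args,
                        list(obey_prob = unname(cfg$obey_prob[class]),
                             intervene_lapse = unname(cfg$intervene_lapse[class]),
                             shift_estimate = if (shifted) cfg$shift_estimate else 0,
                             shift_intervene = if (shifted) cfg$shift_intervene else 0,
                             drift_instrumental = cfg$drift_instrumental,
                             win_stay = cfg$win_stay)))
}

## Probability of revealing the hiVar lottery for an agent on given trials.
## `shift` is the block modifier on a (or c); `drift` a per-trial increment.
reveal_prob <- function(agent, delta_ev, shift = 0, drift_steps = 0) {
  x <- delta_ev / .DEV_SCALE
  if (agent$strategy_class == "EV_sensitive") {
    sigmoid(agent$b * (agent$a + shift + drift_steps + x))
  } else {
    sigmoid(agent$c + shift + drift_steps + 0 * x)
  }
}

#' Long-run probability of revealing the hiVar lottery
#'
#' The agent's expected reveal rate averaged over the permitted dEV set in a
#' non-instrumental (Observe) block; the generative summary on which planted
#' personality scores load.
#'
#' @param agent an [agent_spec()].
#' @return probability.
#' @export
long_run_reveal <- function(agent) {
  mean(reveal_prob(agent, delta_ev_set()))
}

#' Simulate an agent's choices over a session schedule
#'
#' Reveal choices are Bernoulli draws from the agent's psychometric model
#' with the block modifier applied in instrumental blocks (and optional
#' within-block drift and win-stay carry-over). Estimate guesses use the
#' optimal side-of-500 guess after hiVar reveals and follow the observed
#' prize's valence with probability `obey_prob` after loVar reveals.
#' Intervene actions follow switch-iff-below-EV, flipped with probability
#' `intervene_lapse`. Reaction times are log-normal placeholders; trials with
#' any reaction time outside 0.5-10 s are marked invalid.
#'
#' @param agent an [agent_spec()].
#' @param schedule a trial schedule from [build_schedule()].
#' @param seed integer seed.
#' @param rt_meanlog,rt_sdlog reaction-time generator parameters.
#' @return the schedule with `reveal`, `observed_prize`, `post_action`,
#'   `payoff`, `rt_reveal`, `rt_post` and `valid` columns appended.
#' @export
simulate_choices <- function(agent, schedule, seed = 1L,
                             rt_meanlog = log(1.5), rt_sdlog = 0.4) {
  n <- nrow(schedule)
  type <- block_type(schedule$block)
  shift <- ifelse(type == "Estimate", agent$shift_estimate,
           ifelse(type == "Intervene", agent$shift_intervene, 0))
  drift <- ifelse(type %in% c("Estimate", "Intervene"),
                  agent$drift_instrumental * (schedule$trial_index - 1), 0)
  with_seed(seed, {
    p_hi <- reveal_prob(agent, schedule$delta_ev, shift, drift)
    if (agent$win_stay == 0) {
      reveal_hi <- stats::runif(n) < p_hi
    } else {
      ## prior-outcome carry-over: p(repeat the previous reveal) is shifted
      ## by +win_stay after a high observed prize and -win_stay after a low
      ## one (win-stay / lose-shift)
      reveal_hi <- logical(n)
      u <- stats::runif(n)
      prev_hi <- NA
      prev_won <- FALSE
      prev_block <- ""
      for (i in seq_len(n)) {
        p <- p_hi[i]
        if (identical(schedule$block[i], prev_block) && !is.na(prev_hi)) {
          p_same <- if (prev_hi) p else 1 - p
          shift <- if (isTRUE(prev_won)) agent$win_stay else -agent$win_stay
          p_same <- min(1, max(0, p_same + shift))
          p <- if (prev_hi) p_same else 1 - p_same
        }
        reveal_hi[i] <- u[i] < p
        prev_won <- if (reveal_hi[i]) {
          schedule$draw_hivar[i] == schedule$hi_prize_high[i]
        } else {
          schedule$draw_lovar[i] == schedule$lo_prize_high[i]
        }
        prev_hi <- reveal_hi[i]
        prev_block <- schedule$block[i]
      }
    }
    reveal <- ifelse(reveal_hi, "hiVar", "loVar")
    observed <- ifelse(reveal_hi, schedule$draw_hivar, schedule$draw_lovar)
    observed_is_high <- ifelse(reveal_hi,
                               schedule$draw_hivar == schedule$hi_prize_high,
                               schedule$draw_lovar == schedule$lo_prize_high)
    hi_ev <- (schedule$hi_prize_high + schedule$hi_prize_low) / 2
    lo_ev <- (schedule$lo_prize_high + schedule$lo_prize_low) / 2
    revealed_ev <- ifelse(reveal_hi, hi_ev, lo_ev)

    post <- rep("none", n)
    est <- type == "Estimate"
    if (any(est)) {
      ## after a hiVar reveal the optimal guess coincides with the observed
      ## prize's valence; after a loVar reveal the valence is followed with
      ## probability obey_prob
      follow <- ifelse(reveal_hi[est], TRUE,
                       stats::runif(sum(est)) < agent$obey_prob)
      guess_above <- ifelse(follow, observed_is_high[est], !observed_is_high[est])
      post[est] <- ifelse(guess_above, "guess_above", "guess_below")
    }
    int <- type == "Intervene"
    if (any(int)) {
      optimal_switch <- observed[int] < revealed_ev[int]
      lapse <- stats::runif(sum(int)) < agent$intervene_lapse
      sw <- xor(optimal_switch, lapse)
      post[int] <- ifelse(sw, "switch", "keep")
    }

    payoff <- payoff_points(type, schedule$draw_hivar, schedule$draw_lovar,
                            hi_ev, lo_ev, reveal, post)
    rt_reveal <- stats::rlnorm(n, rt_meanlog, rt_sdlog)
    rt_post <- ifelse(type == "Observe", NA_real_,
                      stats::rlnorm(n, rt_meanlog, rt_sdlog))
    valid <- rt_reveal >= .RT_WINDOW[1] & rt_reveal <= .RT_WINDOW[2] &
      (is.na(rt_post) | (rt_post >= .RT_WINDOW[1] & rt_post <= .RT_WINDOW[2]))

    out <- schedule
    out$reveal <- reveal
    out$observed_prize <- observed
    out$post_action <- post
    out$payoff <- payoff
    out$rt_reveal <- rt_reveal
    out$rt_post <- rt_post
    out$valid <- valid
    out
  })
}

#' Sample personality profiles for a cohort of agents
#'
#' Planted scores load on the standardized long-run %reveal hiVar of the
#' cohort (`score = loading * z + sqrt(1 - loading^2) * noise`, unit
#' variance); all other scores are independent standard normal noise.
#' Demographic indicators (age band, sex, education) are categorical codes
#' independent of behaviour. EV sensitivity never enters any score.
#'
#' @param agents agent table from [simulate_cohort()] (needs an `efficiency`
#'   column with the long-run reveal probability).
#' @param cfg a [cohort_config()].
#' @param seed integer seed.
#' @return a data frame with `participant_id`, the 15 standardized scores and
#'   3 demographic codes (18 predictors).
#' @export
sample_personality <- function(agents, cfg, seed = 1L) {
  n <- nrow(agents)
  z <- as.vector(scale(agents$efficiency))
  if (any(!is.finite(z))) z <- rep(0, n)  # degenerate cohort: no variance
  with_seed(seed, {
    scores <- sapply(.SCORE_NAMES, function(nm) {
      lam <- if (nm %in% names(cfg$loadings)) cfg$loadings[[nm]] else 0
      lam * z + sqrt(1 - lam^2) * stats::rnorm(n)
    })
    out <- data.frame(participant_id = agents$participant_id,
                      scores, stringsAsFactors = FALSE)
    out$age_band <- sample(1:12, n, replace = TRUE)
    out$sex <- stats::rbinom(n, 1, 0.5)
    out$education <- sample(1:4, n, replace = TRUE)
    out
  })
}

#' Simulate a full labelled cohort
#'
#' Draws strategy classes from the mixture, samples agent parameters, builds
#' counterbalanced session schedules, simulates choices and generates
#' personality profiles. Child seeds are derived deterministically from
#' `seed` per participant and stage, so cohorts are bit-reproducible.
#'
#' @param cfg a [cohort_config()].
#' @param seed master seed.
#' @return a list with `trials` (all choice records), `agents` (ground-truth
#'   labels and parameters, with `efficiency` = long-run reveal probability
#'   and `instrumental_order`), and `personality`.
#' @export
simulate_cohort <- function(cfg = cohort_config(), seed = 1L) {
  n <- cfg$n_participants
  ids <- sprintf("p%03d", seq_len(n))
  classes <- with_seed(child_seed(seed, "classes"), {
    sample(names(cfg$mixture), n, replace = TRUE, prob = cfg$mixture)
  })
  order <- rep(c("EstimateFirst", "InterveneFirst"), length.out = n)
  agents_list <- lapply(seq_len(n), function(i) {
    with_seed(child_seed(seed, "agent", i), sample_agent(cfg, classes[i], ids[i]))
  })
  if (cfg$obey_coupling != 0) {
    eff <- vapply(agents_list, long_run_reveal, numeric(1))
    zz <- as.vector(scale(eff)); zz[!is.finite(zz)] <- 0
    for (i in seq_len(n)) {
      agents_list[[i]]$obey_prob <-
        min(1, max(0, agents_list[[i]]$obey_prob + cfg$obey_coupling * zz[i]))
    }
  }
  trials <- do.call(rbind, lapply(seq_len(n), function(i) {
    sch <- build_schedule(ids[i], order[i], seed = child_seed(seed, "schedule", i),
                          trials_per_block = cfg$trials_per_block)
    simulate_choices(agents_list[[i]], sch, seed = child_seed(seed, "choices", i),
                     rt_meanlog = cfg$rt_meanlog, rt_sdlog = cfg$rt_sdlog)
  }))
  agents <- data.frame(
    participant_id = ids,
    strategy_class = classes,
    a = vapply(agents_list, function(a) a$a %||% NA_real_, numeric(1)),
    b = vapply(agents_list, function(a) a$b %||% NA_real_, numeric(1)),
    c = vapply(agents_list, function(a) a$c %||% NA_real_, numeric(1)),
    obey_prob = vapply(agents_list, function(a) a$obey_prob, numeric(1)),
    intervene_lapse = vapply(agents_list, function(a) a$intervene_lapse, numeric(1)),
    efficiency = vapply(agents_list, long_run_reveal, numeric(1)),
    instrumental_order = order,
    stringsAsFactors = FALSE)
  personality <- sample_personality(agents, cfg, seed = child_seed(seed, "personality"))
  list(trials = trials, agents = agents, personality = personality)
}
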