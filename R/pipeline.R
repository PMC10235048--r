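## Pipeline orchestration: configuration, one-call reproducible runs
## (simulate -> fit -> classify -> metrics -> decode -> report), trial-table
## validation, and CSV/JSON input-output.

#' Run configuration
#'
#' @param seed master seed; every stage derives its own child seed from it.
#' @param cohort a [cohort_config()].
#' @param prior_sd,criterion fitting configuration (see [fit_strategy()]).
#' @param decode_targets behavioural targets to decode
#'   (subset of `c("pct_reveal_hivar", "pct_reveal_hiev")`).
#' @param n_boot bootstrap iterations for decoding.
#' @return a list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, cohort = cohort_config(),
                       prior_sd = 5, criterion = 4.6,
                       decode_targets = c("pct_reveal_hivar", "pct_reveal_hiev"),
                       n_boot = 100) {
  stopifnot(inherits(cohort, "cohort_config"),
            all(decode_targets %in% c("pct_reveal_hivar", "pct_reveal_hiev")))
  structure(list(seed = as.integer(seed), cohort = cohort,
                 prior_sd = prior_sd, criterion = criterion,
                 decode_targets = decode_targets, n_boot = n_boot),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates a labelled cohort, fits and classifies every participant-block,
#' computes efficiency metrics and cohort analyses, decodes the requested
#' behavioural targets from personality, and (optionally) writes all
#' artifacts to a directory: `trials.csv`, `agents.json`,
#' `personality.csv`, `fits.csv`, `metrics.csv`, `comparisons.json`,
#' `decoding.json` and `config.json` (the configuration is embedded
#' verbatim for provenance). Runs with the same configuration and seed
#' produce identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing.
#' @return a list with `trials`, `agents`, `personality`, `fits`,
#'   `efficiency`, `comparisons`, `consistency`, `dip`, `decoding` and
#'   `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cohort <- stage("simulate", simulate_cohort(config$cohort, seed = config$seed))
  fits <- stage("fit", fit_cohort(cohort$trials, prior_sd = config$prior_sd,
                                  criterion = config$criterion))
  eff <- stage("metrics", efficiency_table(cohort$trials))
  comparisons <- tryCatch(
    task_comparisons(fits, efficiency = eff, agents = cohort$agents),
    error = function(e) NULL)
  consistency <- stage("consistency", strategy_consistency(fits, cohort$agents))
  dip <- stage("dip", {
    lapply(split(eff, block_type(eff$block)), function(s) {
      if (nrow(s) >= 10)
        dip_test(s$pct_reveal_hivar,
                 seed = child_seed(config$seed, "dip"))[c("dip", "p_value")]
      else NULL
    })
  })
  decoding <- stage("decode", {
    out <- list()
    for (tg in config$decode_targets) {
      obs1 <- eff[eff$block == "Observe1", ]
      target <- stats::setNames(obs1[[tg]], obs1$participant_id)
      out[[tg]] <- tryCatch(
        decode(cohort$personality, target, n_boot = config$n_boot,
               seed = child_seed(config$seed, "decode")),
        error = function(e) list(error = conditionMessage(e)))
    }
    out
  })
  result <- list(trials = cohort$trials, agents = cohort$agents,
                 personality = cohort$personality, fits = fits,
                 efficiency = eff, comparisons = comparisons,
                 consistency = consistency, dip = dip,
                 decoding = decoding, config = config)
  if (!is.null(out_dir)) write_run(result, out_dir)
  invisible(result)
}

write_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) utils::write.csv(df, file.path(out_dir, name),
                                              row.names = FALSE)
  wjson <- function(x, name) jsonlite::write_json(
    x, file.path(out_dir, name), auto_unbox = TRUE, digits = NA,
    force = TRUE, pretty = TRUE, null = "null")
  wcsv(result$trials, "trials.csv")
  wcsv(result$personality, "personality.csv")
  wcsv(result$fits, "fits.csv")
  wcsv(result$efficiency, "metrics.csv")
  wjson(result$agents, "agents.json")
  wjson(list(comparisons = result$comparisons,
             consistency = list(
               groups = as.list(stats::setNames(as.integer(result$consistency$groups),
                                                names(result$consistency$groups))),
               p_repeat_uncertainty = result$consistency$p_repeat_uncertainty,
               p_repeat_ev = result$consistency$p_repeat_ev,
               repetition_test = result$consistency$repetition_test),
             dip = result$dip), "comparisons.json")
  wjson(lapply(result$decoding, function(d) {
    if (!is.null(d$error)) return(d)
    list(method = d$method, n = d$n, n_boot = d$n_boot,
         excess_accuracy = list(mean = d$excess_accuracy$mean,
                                ci = d$excess_accuracy$ci),
         coefficients = d$coefficients)
  }), "decoding.json")
  wjson(unclass_config(result$config), "config.json")
  invisible(out_dir)
}

unclass_config <- function(cfg) {
  out <- unclass(cfg)
  out$cohort <- unclass(out$cohort)
  out
}

#' Read a trial-record CSV
#'
#' @param path CSV file (UTF-8, header row, dot decimal) with the trial
#'   schema written by [run_pipeline()]/[write_trials()].
#' @return data frame of trial records.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a trial-record CSV
#'
#' @param trials trial records.
#' @param path output path.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
}

.TRIAL_COLUMNS <- c("participant_id", "block", "block_position", "trial_index",
                    "hi_prize_high", "hi_prize_low", "lo_prize_high",
                    "lo_prize_low", "delta_ev", "draw_hivar", "draw_lovar",
                    "reveal", "observed_prize", "post_action", "payoff",
                    "rt_reveal", "rt_post", "valid")

#' Validate a trial table against the task's invariants
#'
#' Schema check plus row-level invariants: lottery EVs sum to 500 with
#' ranges 120/30, dEV in the permitted set and consistent with the prizes,
#' draws belong to their lotteries, the realized sum never equals 500,
#' reveal/observed-prize consistency, post-action/block consistency, and
#' the reaction-time validity flag.
#'
#' @param trials a data frame of trial records or a CSV path.
#' @return a list with `ok`, `n_rows`, a data frame of `violations`
#'   (row, rule) and `extra_columns`; unknown extra columns are accepted
#'   with a warning.
#' @export
validate_trials <- function(trials) {
  if (is.character(trials)) trials <- read_trials(trials)
  missing_cols <- setdiff(.TRIAL_COLUMNS, names(trials))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(trials), .TRIAL_COLUMNS)
  if (length(extra)) warning("extra column(s) accepted: ",
                             paste(extra, collapse = ", "))
  v <- list()
  flag <- function(rule, bad) {
    if (any(bad)) v[[length(v) + 1L]] <<- data.frame(row = which(bad), rule = rule)
  }
  hi_ev <- (trials$hi_prize_high + trials$hi_prize_low) / 2
  lo_ev <- (trials$lo_prize_high + trials$lo_prize_low) / 2
  flag("total_ev_500", abs(hi_ev + lo_ev - 500) > 1e-8)
  flag("hi_range_120", abs(trials$hi_prize_high - trials$hi_prize_low - 120) > 1e-8)
  flag("lo_range_30", abs(trials$lo_prize_high - trials$lo_prize_low - 30) > 1e-8)
  flag("delta_ev_consistent", abs(trials$delta_ev - (hi_ev - lo_ev)) > 1e-8)
  flag("delta_ev_in_set", !trials$delta_ev %in% delta_ev_set())
  flag("draw_hivar_member", !(trials$draw_hivar == trials$hi_prize_high |
                                trials$draw_hivar == trials$hi_prize_low))
  flag("draw_lovar_member", !(trials$draw_lovar == trials$lo_prize_high |
                                trials$draw_lovar == trials$lo_prize_low))
  flag("sum_never_500", trials$draw_hivar + trials$draw_lovar == 500)
  flag("reveal_valid", !trials$reveal %in% c("hiVar", "loVar"))
  obs <- ifelse(trials$reveal == "hiVar", trials$draw_hivar, trials$draw_lovar)
  flag("observed_prize_consistent", abs(trials$observed_prize - obs) > 1e-8)
  type <- block_type(trials$block)
  flag("post_action_matches_block", !(
    (type == "Observe" & trials$post_action == "none") |
      (type == "Estimate" & trials$post_action %in% c("guess_above", "guess_below")) |
      (type == "Intervene" & trials$post_action %in% c("keep", "switch"))))
  rt_ok <- trials$rt_reveal >= 0.5 & trials$rt_reveal <= 10 &
    (is.na(trials$rt_post) | (trials$rt_post >= 0.5 & trials$rt_post <= 10))
  flag("valid_flag_consistent", trials$valid != rt_ok)
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(row = integer(0), rule = character(0))
  list(ok = nrow(violations) == 0L, n_rows = nrow(trials),
       violations = violations, extra_columns = extra)
}
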