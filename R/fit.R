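## Strategy fitting: maximum a posteriori estimation of two psychometric
## models of the reveal choice, BIC-based model comparison, and three-way
## strategy classification.
##
## Bivariate model:  p(reveal hiVar) = 1 / (1 + exp(-b * (a + dEV)))
## with dEV standardized to [-1, 1] (division by 110, the set maximum);
## a is the sensitivity to uncertainty, b the sensitivity to EV.
## Univariate model: p(reveal hiVar) = 1 / (1 + exp(-c)), a constant rate.
## Independent Normal(0, sd = 5) priors are placed on a, b and c; fitting
## maximizes the Bernoulli log-likelihood plus log prior density.

.DEV_SCALE <- 110

#' Standardize reveal choices for fitting
#'
#' Collapses trial records to the sufficient statistics of the psychometric
#' models: per standardized-dEV level, the number of trials and the number of
#' hiVar reveals. Only trials with `valid = TRUE` (reaction times inside the
#' 0.5-10 s window) are included when a `valid` column is present.
#'
#' @param revealed_hivar logical vector (or a data frame of trial records with
#'   `reveal`, `delta_ev` and optionally `valid` columns).
#' @param delta_ev dEV in points (ignored when a data frame is given).
#' @return a list with `x` (unique standardized dEV levels), `n_x` (trials per
#'   level), `k_x` (hiVar reveals per level) and `n` (total valid trials).
#' @export
standardize_choices <- function(revealed_hivar, delta_ev = NULL) {
  if (is.data.frame(revealed_hivar)) {
    df <- revealed_hivar
    keep <- if ("valid" %in% names(df)) df$valid else rep(TRUE, nrow(df))
    y <- (df$reveal == "hiVar")[keep]
    dev <- df$delta_ev[keep]
  } else {
    y <- as.logical(revealed_hivar)
    dev <- delta_ev
  }
  stopifnot(length(y) == length(dev))
  x <- dev / .DEV_SCALE
  lv <- sort(unique(x))
  idx <- match(x, lv)
  list(x = lv,
       n_x = as.vector(tabulate(idx, length(lv))),
       k_x = as.vector(vapply(seq_along(lv), function(i) sum(y[idx == i]), numeric(1))),
       n = length(y))
}

## log(sigmoid(eta)) and log(1 - sigmoid(eta)) computed stably.
log_sigmoid <- function(eta) ifelse(eta > 0, -log1p(exp(-eta)), eta - log1p(exp(eta)))

## Negative log-posterior of the bivariate model at (a, b). The full Normal
## log density (constant included) is used so that the value at the MAP is
## the log "a posteriori likelihood" entering the BIC.
neg_log_post_biv <- function(par, sc, prior_sd) {
  eta <- par[2] * (par[1] + sc$x)
  ll <- sum(sc$k_x * log_sigmoid(eta) + (sc$n_x - sc$k_x) * log_sigmoid(-eta))
  -(ll + sum(stats::dnorm(par, 0, prior_sd, log = TRUE)))
}

grad_neg_log_post_biv <- function(par, sc, prior_sd) {
  a <- par[1]; b <- par[2]
  p <- sigmoid(b * (a + sc$x))
  r <- sc$k_x - sc$n_x * p
  c(-b * sum(r) + a / prior_sd^2,
    -sum(r * (a + sc$x)) + b / prior_sd^2)
}

neg_log_post_uni <- function(cc, sc, prior_sd) {
  k <- sum(sc$k_x); n <- sc$n
  -(k * log_sigmoid(cc) + (n - k) * log_sigmoid(-cc) +
      stats::dnorm(cc, 0, prior_sd, log = TRUE))
}

## Wald 95% CIs from the numerically differentiated Hessian of the negative
## log-posterior at the MAP.
wald_ci <- function(par, hess) {
  cov <- tryCatch(solve(hess), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(cov)) || any(diag(cov) <= 0)) {
    return(list(se = rep(NA_real_, length(par)),
                lower = rep(NA_real_, length(par)),
                upper = rep(NA_real_, length(par)), ok = FALSE))
  }
  se <- sqrt(diag(cov))
  z <- stats::qnorm(0.975)
  list(se = se, lower = par - z * se, upper = par + z * se, ok = TRUE)
}

#' Fit the bivariate psychometric model
#'
#' MAP estimation of (a, b) in `p(reveal) = sigmoid(b * (a + dEV_std))` under
#' independent Normal(0, `prior_sd`) priors, by multi-start quasi-Newton
#' optimization (starts at the prior mode and +/-2 on each axis, to avoid the
#' flat ridge at b ~ 0 where the likelihood carries no information about a).
#'
#' @param choices output of [standardize_choices()].
#' @param prior_sd standard deviation of the Normal priors (default 5).
#' @return a list with MAP estimates `a`, `b`, their Wald 95% intervals
#'   `ci_a`, `ci_b`, `log_posterior` at the MAP, `bic`, `k = 2`, `n`, and a
#'   `converged` flag (gradient norm below 1e-6 and a positive-definite
#'   observed information).
#' @export
fit_bivariate <- function(choices, prior_sd = 5) {
  sc <- choices
  starts <- list(c(0, 0), c(2, 0), c(-2, 0), c(0, 2), c(0, -2))
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      stats::nlminb(s, neg_log_post_biv, gradient = grad_neg_log_post_biv,
                    sc = sc, prior_sd = prior_sd,
                    control = list(rel.tol = 1e-14, x.tol = 1.5e-10, iter.max = 500)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$objective < best$objective)) best <- res
  }
  par <- best$par
  ## damped Newton polish down to gradient norm 1e-8
  obj <- neg_log_post_biv(par, sc, prior_sd)
  for (it in 1:50) {
    g <- grad_neg_log_post_biv(par, sc, prior_sd)
    if (sqrt(sum(g^2)) < 1e-8) break
    H <- stats::optimHess(par, neg_log_post_biv, sc = sc, prior_sd = prior_sd)
    step <- tryCatch(solve(H, g), error = function(e) g)
    lambda <- 1
    repeat {
      cand <- par - lambda * step
      ocand <- neg_log_post_biv(cand, sc, prior_sd)
      if (ocand <= obj + 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (ocand > obj + 1e-12) break
    par <- cand; obj <- ocand
  }
  gnorm <- sqrt(sum(grad_neg_log_post_biv(par, sc, prior_sd)^2))
  hess <- stats::optimHess(par, neg_log_post_biv, sc = sc, prior_sd = prior_sd)
  ci <- wald_ci(par, hess)
  lp <- -obj
  list(a = par[1], b = par[2],
       se_a = ci$se[1], se_b = ci$se[2],
       ci_a = c(ci$lower[1], ci$upper[1]), ci_b = c(ci$lower[2], ci$upper[2]),
       log_posterior = lp, k = 2L, n = sc$n,
       bic = compute_bic(lp, 2L, sc$n),
       converged = gnorm < 1e-6 && ci$ok)
}

#' Fit the univariate (constant-rate) psychometric model
#'
#' MAP estimation of c in `p(reveal hiVar) = sigmoid(c)` under a Normal(0,
#' `prior_sd`) prior. The prior keeps the MAP finite even for 0/126 or
#' 126/126 reveal counts.
#'
#' @inheritParams fit_bivariate
#' @return a list with `c`, `ci_c`, the transformed reveal rate `p_reveal =
#'   sigmoid(c)` with its transformed interval `ci_p`, `log_posterior`,
#'   `bic`, `k = 1`, `n` and `converged`.
#' @export
fit_univariate <- function(choices, prior_sd = 5) {
  sc <- choices
  res <- stats::optimize(neg_log_post_uni, c(-30, 30), sc = sc, prior_sd = prior_sd,
                         tol = 1e-12)
  cc <- res$minimum
  hess <- stats::optimHess(cc, neg_log_post_uni, sc = sc, prior_sd = prior_sd)
  ci <- wald_ci(cc, hess)
  lp <- -res$objective
  list(c = cc, se_c = ci$se[1], ci_c = c(ci$lower[1], ci$upper[1]),
       p_reveal = sigmoid(cc), ci_p = sigmoid(c(ci$lower[1], ci$upper[1])),
       log_posterior = lp, k = 1L, n = sc$n,
       bic = compute_bic(lp, 1L, sc$n),
       converged = ci$ok)
}

#' Bayesian Information Criterion from a log a posteriori likelihood
#'
#' `BIC = -2 log(L) + k log(n)` where, following the fitting convention of
#' this package, `log(L)` is the log-posterior density (likelihood times
#' prior) at the MAP. Set `variant = "likelihood"` for the conventional
#' pure-likelihood BIC.
#'
#' @param log_l log a posteriori likelihood at the MAP (or log-likelihood for
#'   `variant = "likelihood"`; then pass that value).
#' @param k number of free parameters.
#' @param n number of data points.
#' @return the BIC value.
#' @export
compute_bic <- function(log_l, k, n) {
  -2 * log_l + k * log(n)
}

#' Classify a participant's sampling strategy
#'
#' Participants are EV-sensitive by default; only if the BIC difference
#' `bic_bivariate - bic_univariate` exceeds `criterion` (default 4.6,
#' corresponding to a Bayes factor of 10) is the univariate model accepted
#' and the participant called EV-insensitive. EV-insensitive participants are
#' `Random` when the transformed interval of c covers the 0.5 chance rate,
#' `Uncertainty_only` when it lies entirely above 0.5, and `LoVar_preferring`
#' when it lies entirely below (a case on which the classification scheme is
#' otherwise silent; it is counted separately, never merged into Random).
#' `robust` records whether the EV-sensitivity verdict agrees with the one
#' obtained under the mirrored criterion (univariate by default, bivariate
#' only when `delta_bic < -criterion`, Bayes factor 0.1).
#'
#' @param biv,uni fits from [fit_bivariate()] and [fit_univariate()].
#' @param criterion BIC difference required to accept the univariate model.
#' @return a list with `label`, `delta_bic`, `criterion_used` and `robust`.
#' @export
classify_strategy <- function(biv, uni, criterion = 4.6) {
  if (!isTRUE(biv$converged) || !isTRUE(uni$converged)) {
    return(list(label = NA_character_, delta_bic = biv$bic - uni$bic,
                criterion_used = criterion, robust = NA))
  }
  delta <- biv$bic - uni$bic
  insens_default_sens <- delta > criterion     # EV-sensitive unless strong evidence
  insens_default_insens <- !(delta < -criterion) # EV-insensitive unless strong evidence
  label <- if (!insens_default_sens) "EV_sensitive" else {
    if (uni$ci_p[1] > 0.5) "Uncertainty_only"
    else if (uni$ci_p[2] < 0.5) "LoVar_preferring"
    else "Random"
  }
  list(label = label, delta_bic = delta, criterion_used = criterion,
       robust = insens_default_sens == insens_default_insens)
}

#' Fit sampling-strategy models to one participant-block
#'
#' The central model fit: estimates the bivariate (uncertainty + EV
#' sensitivity) and univariate (constant-rate) psychometric models of the
#' reveal choice by MAP, compares them by BIC, and assigns a strategy label.
#'
#' @param formula either a formula `reveal ~ delta_ev` evaluated in `data`
#'   (where `reveal` is logical or the strings "hiVar"/"loVar" and `delta_ev`
#'   is in points), or a logical vector of hiVar reveals.
#' @param data a data frame of trial records when `formula` is a formula;
#'   rows with `valid = FALSE` are dropped if a `valid` column exists.
#' @param delta_ev dEV in points when `formula` is a vector.
#' @param prior_sd standard deviation of the Normal priors (default 5).
#' @param criterion BIC criterion for accepting the univariate model
#'   (default 4.6).
#' @return an object of class `"strategy_fit"` with components `bivariate`,
#'   `univariate`, `label`, `delta_bic`, `robust`, `choices` (sufficient
#'   statistics), `prior_sd` and `criterion`. Methods: `print`, `summary`,
#'   `coef`, `predict`, `plot`, `simulate`, `logLik`.
#' @examples
#' sch <- build_schedule("p1", seed = 1)
#' ag <- agent_spec("p1", "EV_sensitive", a = 1, b = 5)
#' rec <- simulate_choices(ag, sch, seed = 2)
#' fit_strategy(reveal ~ delta_ev, data = rec)
#' @export
fit_strategy <- function(formula, data = NULL, delta_ev = NULL,
                         prior_sd = 5, criterion = 4.6) {
  if (inherits(formula, "formula")) {
    stopifnot(!is.null(data))
    mf <- stats::model.frame(formula, data = data)
    y <- mf[[1L]]
    if (!is.logical(y)) y <- y == "hiVar"
    dev <- mf[[2L]]
    if ("valid" %in% names(data)) {
      keep <- data$valid[match(rownames(mf), rownames(data))]
      keep[is.na(keep)] <- TRUE
      y <- y[keep]; dev <- dev[keep]
    }
    sc <- standardize_choices(y, dev)
  } else {
    sc <- standardize_choices(formula, delta_ev)
  }
  if (sc$n < 1L) stop("no valid trials to fit", call. = FALSE)
  biv <- fit_bivariate(sc, prior_sd)
  uni <- fit_univariate(sc, prior_sd)
  cls <- classify_strategy(biv, uni, criterion)
  structure(list(bivariate = biv, univariate = uni,
                 label = cls$label, delta_bic = cls$delta_bic,
                 robust = cls$robust, choices = sc,
                 prior_sd = prior_sd, criterion = criterion,
                 call = match.call()),
            class = "strategy_fit")
}

#' @export
print.strategy_fit <- function(x, ...) {
  cat("Sampling-strategy fit (", x$choices$n, " trials)\n", sep = "")
  cat(sprintf("  bivariate : a = %.3f [%.3f, %.3f], b = %.3f [%.3f, %.3f], BIC = %.2f\n",
              x$bivariate$a, x$bivariate$ci_a[1], x$bivariate$ci_a[2],
              x$bivariate$b, x$bivariate$ci_b[1], x$bivariate$ci_b[2],
              x$bivariate$bic))
  cat(sprintf("  univariate: c = %.3f, p(reveal hiVar) = %.3f [%.3f, %.3f], BIC = %.2f\n",
              x$univariate$c, x$univariate$p_reveal,
              x$univariate$ci_p[1], x$univariate$ci_p[2], x$univariate$bic))
  cat(sprintf("  delta BIC (biv - uni) = %.2f; strategy: %s%s\n",
              x$delta_bic, x$label,
              if (isTRUE(x$robust)) " (robust to criterion sign)" else ""))
  invisible(x)
}

#' @export
summary.strategy_fit <- function(object, ...) {
  est <- rbind(
    a = c(object$bivariate$a, object$bivariate$se_a, object$bivariate$ci_a),
    b = c(object$bivariate$b, object$bivariate$se_b, object$bivariate$ci_b),
    c = c(object$univariate$c, object$univariate$se_c, object$univariate$ci_c))
  colnames(est) <- c("estimate", "se", "ci_lower", "ci_upper")
  structure(list(estimates = est, label = object$label,
                 delta_bic = object$delta_bic, robust = object$robust,
                 n = object$choices$n), class = "summary.strategy_fit")
}

#' @export
print.summary.strategy_fit <- function(x, ...) {
  cat("n =", x$n, "valid trials\n")
  print(round(x$estimates, 4))
  cat(sprintf("delta BIC = %.2f -> %s\n", x$delta_bic, x$label))
  invisible(x)
}

#' @export
coef.strategy_fit <- function(object, ...) {
  c(a = object$bivariate$a, b = object$bivariate$b, c = object$univariate$c)
}

#' Predicted reveal probability
#'
#' @param object a `strategy_fit`.
#' @param newdata numeric vector of dEV values in points (defaults to the
#'   fitted levels).
#' @param model `"selected"` (the model chosen by the BIC comparison),
#'   `"bivariate"` or `"univariate"`.
#' @param ... unused.
#' @return vector of probabilities of revealing the hiVar lottery.
#' @export
predict.strategy_fit <- function(object, newdata = NULL,
                                 model = c("selected", "bivariate", "univariate"), ...) {
  model <- match.arg(model)
  dev <- newdata %||% (object$choices$x * .DEV_SCALE)
  use_biv <- switch(model, selected = identical(object$label, "EV_sensitive"),
                    bivariate = TRUE, univariate = FALSE)
  if (use_biv) {
    sigmoid(object$bivariate$b * (object$bivariate$a + dev / .DEV_SCALE))
  } else {
    rep(sigmoid(object$univariate$c), length(dev))
  }
}

#' @export
logLik.strategy_fit <- function(object, ...) {
  sc <- object$choices
  b <- object$bivariate
  eta <- b$b * (b$a + sc$x)
  ll <- sum(sc$k_x * log_sigmoid(eta) + (sc$n_x - sc$k_x) * log_sigmoid(-eta))
  structure(ll, df = 2L, nobs = sc$n, class = "logLik")
}

#' Simulate reveal choices from a fitted strategy model
#'
#' @param object a `strategy_fit`.
#' @param nsim number of replicate datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of logical vectors of hiVar reveals, one per replicate,
#'   over the fitted design (each level repeated its observed number of
#'   times).
#' @export
simulate.strategy_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sc <- object$choices
  p <- rep(predict(object), sc$n_x)
  gen <- function() stats::runif(length(p)) < p
  if (is.null(seed)) replicate(nsim, gen(), simplify = FALSE)
  else with_seed(seed, replicate(nsim, gen(), simplify = FALSE))
}

#' Plot a fitted psychometric curve
#'
#' Empirical fraction of hiVar reveals per dEV level with +/-1 binomial SE,
#' overlaid with the fitted curve of the selected model.
#'
#' @param x a `strategy_fit`.
#' @param ... passed to `plot()`.
#' @export
plot.strategy_fit <- function(x, ...) {
  sc <- x$choices
  dev <- sc$x * .DEV_SCALE
  frac <- sc$k_x / sc$n_x
  se <- sqrt(pmax(frac * (1 - frac), 1e-9) / sc$n_x)
  grid <- seq(min(dev), max(dev), length.out = 101)
  plot(dev, frac, ylim = c(0, 1), xlab = expression(Delta * "EV (points)"),
       ylab = "fraction revealed hiVar", pch = 16, ...)
  graphics::arrows(dev, frac - se, dev, frac + se, angle = 90, code = 3,
                   length = 0.02, col = "grey50")
  graphics::lines(grid, predict(x, newdata = grid), col = "firebrick", lwd = 2)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Fit strategy models to every participant-block of a trial table
#'
#' @param trials trial records with `participant_id`, `block`, `reveal`,
#'   `delta_ev` and optionally `valid` columns.
#' @param prior_sd,criterion passed to [fit_strategy()].
#' @return a data frame with one row per participant-block: parameter
#'   estimates with 95% intervals, log-posteriors, BICs, `delta_bic`,
#'   `label` and `robust`.
#' @export
fit_cohort <- function(trials, prior_sd = 5, criterion = 4.6) {
  parts <- split(seq_len(nrow(trials)),
                 list(trials$participant_id, trials$block), drop = TRUE)
  rows <- lapply(parts, function(idx) {
    sub <- trials[idx, ]
    f <- fit_strategy(reveal ~ delta_ev, data = sub,
                      prior_sd = prior_sd, criterion = criterion)
    data.frame(participant_id = sub$participant_id[1], block = sub$block[1],
               n_valid = f$choices$n,
               a = f$bivariate$a, a_lo = f$bivariate$ci_a[1], a_hi = f$bivariate$ci_a[2],
               b = f$bivariate$b, b_lo = f$bivariate$ci_b[1], b_hi = f$bivariate$ci_b[2],
               c = f$univariate$c, c_lo = f$univariate$ci_c[1], c_hi = f$univariate$ci_c[2],
               p_reveal = f$univariate$p_reveal,
               p_lo = f$univariate$ci_p[1], p_hi = f$univariate$ci_p[2],
               log_post_biv = f$bivariate$log_posterior,
               log_post_uni = f$univariate$log_posterior,
               bic_biv = f$bivariate$bic, bic_uni = f$univariate$bic,
               delta_bic = f$delta_bic, label = f$label, robust = f$robust,
               converged = f$bivariate$converged && f$univariate$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant_id, out$block), ]
}

#' Diagnose the sign-flip indeterminacy of the bivariate model
#'
#' When the slope b is close to zero the bivariate likelihood is nearly flat
#' in a (at b = 0 it is exactly flat: p = 0.5 regardless of a), so residual
#' noise in b dictates the sign of a and strongly uncertainty-sensitive
#' participants can be fit with large negative intercepts. This diagnostic
#' flags such fits and verifies that the univariate model comparison
#' reassigns them with a positive constant rate.
#'
#' @param fits a cohort fit table from [fit_cohort()].
#' @param b_threshold |b| below which the slope counts as near zero.
#' @param a_threshold |a| above which the intercept counts as large.
#' @return a list with the flagged subset (`flagged`), the fraction flagged,
#'   and among flagged fits the fraction reassigned to an EV-insensitive
#'   label with a reveal rate above chance (`reassigned_insensitive`).
#' @export
diagnose_sign_flip <- function(fits, b_threshold = 0.5, a_threshold = 1.5) {
  flag <- abs(fits$b) < b_threshold & abs(fits$a) > a_threshold
  flagged <- fits[flag, , drop = FALSE]
  reassigned <- if (nrow(flagged) == 0L) NA_real_ else {
    mean(flagged$label %in% c("Uncertainty_only") & flagged$p_reveal > 0.5)
  }
  list(flagged = flagged, fraction_flagged = mean(flag),
       reassigned_insensitive = reassigned)
}

#' Pool fitted parameters across strategy classes
#'
#' Combines EV-sensitive and EV-insensitive participants on common scales:
#' the uncertainty sensitivity is a for EV-sensitive fits and c otherwise,
#' and the EV sensitivity is b for EV-sensitive fits and 0 otherwise.
#'
#' @param fits cohort fit table from [fit_cohort()].
#' @return data frame with `participant_id`, `block`, `uncertainty`, `ev`
#'   and `label`.
#' @export
pooled_parameters <- function(fits) {
  ev_sens <- fits$label == "EV_sensitive"
  data.frame(participant_id = fits$participant_id, block = fits$block,
             uncertainty = ifelse(ev_sens, fits$a, fits$c),
             ev = ifelse(ev_sens, fits$b, 0),
             label = fits$label, stringsAsFactors = FALSE)
}
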