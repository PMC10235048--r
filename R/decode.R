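## Personality decoding: bootstrap classification of sampling efficiency
## from the 18 personality/demographic predictors, leave-one-score-out
## variance attribution, and the extraversion-quartile strategy table.

predictor_columns <- function(profiles) {
  setdiff(names(profiles), "participant_id")
}

#' Decode a behavioural target from personality profiles
#'
#' Median-splits the target into high/low classes and, over `n_boot`
#' bootstrap iterations, draws a random 50:50 train/test split, standardizes
#' the predictors on the training half only, fits a linear-boundary
#' classifier (linear-kernel SVM or logistic regression), and scores test
#' accuracy. Excess accuracy is the paired difference between the true-label
#' accuracy and that of a second classifier trained on label-shuffled data
#' with the same split. Coefficients are stored per iteration; a predictor
#' is significant when the 95% interval of its coefficients excludes 0.
#'
#' @param profiles personality table from [sample_personality()] (column
#'   `participant_id` plus 18 predictors).
#' @param target named numeric vector (names = participant ids) or a data
#'   frame with `participant_id` and a `value` column: the behavioural
#'   quantity to decode (e.g. %reveal hiVar).
#' @param method `"svm_linear"` (default) or `"logistic"`.
#' @param n_boot bootstrap iterations (default 100).
#' @param seed integer seed.
#' @return a list of class `"decoding_result"`: `excess_accuracy` (mean, 95%
#'   CI, per-iteration values), `accuracy`, `coefficients` (per-predictor
#'   mean, CI, significance), `method`, `n`, `class_balance`.
#' @export
decode <- function(profiles, target, method = c("svm_linear", "logistic"),
                   n_boot = 100, seed = 1L) {
  method <- match.arg(method)
  if (is.data.frame(target)) {
    tv <- target$value
    names(tv) <- target$participant_id
    target <- tv
  }
  complete <- stats::complete.cases(profiles)
  dropped <- sum(!complete)
  profiles <- profiles[complete, , drop = FALSE]
  ids <- intersect(profiles$participant_id, names(target))
  if (length(ids) < 50L) stop("need at least 50 participants with complete profiles",
                              call. = FALSE)
  X <- as.matrix(profiles[match(ids, profiles$participant_id),
                          predictor_columns(profiles)])
  y <- target[ids]
  if (length(unique(y)) == 1L) stop("constant decoding target", call. = FALSE)
  ## median split: strictly above the median is "high"
  lab <- factor(ifelse(y > stats::median(y), "high", "low"), levels = c("low", "high"))
  n <- length(lab)
  fit_one <- function(Xtr, ytr, Xte) {
    if (method == "svm_linear") {
      m <- e1071::svm(Xtr, ytr, kernel = "linear", scale = FALSE)
      w <- drop(crossprod(m$coefs, m$SV))
      ## canonicalize the boundary's orientation: positive decision value
      ## must mean "high" regardless of training-row order
      dv <- drop(Xtr %*% w) - m$rho
      if (mean(dv[ytr == "high"]) < mean(dv[ytr == "low"])) w <- -w
      pred <- stats::predict(m, Xte)
      list(pred = pred, coefs = w)
    } else {
      df <- data.frame(y = ytr, Xtr)
      m <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
      pr <- stats::predict(m, newdata = data.frame(Xte), type = "response")
      list(pred = factor(ifelse(pr > 0.5, "high", "low"), levels = levels(ytr)),
           coefs = stats::coef(m)[-1])
    }
  }
  res <- with_seed(seed, {
    acc <- acc_sh <- numeric(n_boot)
    coefs <- matrix(NA_real_, n_boot, ncol(X), dimnames = list(NULL, colnames(X)))
    for (it in seq_len(n_boot)) {
      repeat {
        tr <- sample.int(n, floor(n / 2))
        if (length(unique(lab[tr])) == 2L && length(unique(lab[-tr])) == 2L) break
      }
      mu <- colMeans(X[tr, , drop = FALSE])
      sg <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sg[sg == 0] <- 1
      Xtr <- scale(X[tr, , drop = FALSE], mu, sg)
      Xte <- scale(X[-tr, , drop = FALSE], mu, sg)
      f <- fit_one(Xtr, lab[tr], Xte)
      acc[it] <- mean(f$pred == lab[-tr])
      coefs[it, ] <- f$coefs
      f2 <- fit_one(Xtr, sample(lab[tr]), Xte)
      acc_sh[it] <- mean(f2$pred == lab[-tr])
    }
    list(acc = acc, acc_sh = acc_sh, coefs = coefs)
  })
  excess <- 100 * (res$acc - res$acc_sh)
  qs <- stats::quantile(excess, c(0.025, 0.975), names = FALSE)
  co <- apply(res$coefs, 2, function(v) {
    q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    c(mean = mean(v), lower = q[1], upper = q[2])
  })
  coef_df <- data.frame(predictor = colnames(X), mean = co["mean", ],
                        lower = co[2, ], upper = co[3, ],
                        significant = co[2, ] > 0 | co[3, ] < 0,
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    excess_accuracy = list(mean = mean(excess), ci = qs, values = excess),
    accuracy = list(mean = 100 * mean(res$acc), values = 100 * res$acc),
    coefficients = coef_df,
    method = method, n = n, n_boot = n_boot,
    class_balance = as.vector(table(lab)) / n,
    dropped_incomplete = dropped), class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("Decoding (%s, n = %d, %d bootstrap iterations)\n",
              x$method, x$n, x$n_boot))
  cat(sprintf("  excess accuracy: %.1f%% [%.1f%%, %.1f%%]\n",
              x$excess_accuracy$mean, x$excess_accuracy$ci[1],
              x$excess_accuracy$ci[2]))
  sig <- x$coefficients[x$coefficients$significant, ]
  if (nrow(sig)) {
    cat("  significant coefficients:\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("    %-28s %+.3f [%+.3f, %+.3f]\n", sig$predictor[i],
                  sig$mean[i], sig$lower[i], sig$upper[i]))
  } else cat("  no significant coefficients\n")
  invisible(x)
}

#' Variance in a behavioural measure explained by each score
#'
#' Multiple linear regression of the target on all 18 predictors; each
#' predictor's contribution is the drop in R-squared when it is removed
#' (`delta_r2 = R2(full) - R2(without score)`).
#'
#' @param profiles personality table.
#' @param target named numeric vector or data frame as in [decode()].
#' @return a list with `full_r2` and a data frame of per-predictor
#'   `delta_r2`.
#' @export
variance_explained <- function(profiles, target) {
  if (is.data.frame(target)) {
    tv <- target$value; names(tv) <- target$participant_id; target <- tv
  }
  profiles <- profiles[stats::complete.cases(profiles), , drop = FALSE]
  ids <- intersect(profiles$participant_id, names(target))
  X <- as.data.frame(profiles[match(ids, profiles$participant_id),
                              predictor_columns(profiles)])
  y <- unname(target[ids])
  r2 <- function(cols) {
    fit <- stats::lm(y ~ ., data = X[, cols, drop = FALSE])
    if (any(is.na(stats::coef(fit))))
      warning("rank-deficient design; aliased coefficients dropped")
    summary(fit)$r.squared
  }
  full <- r2(names(X))
  dr2 <- vapply(names(X), function(p) full - r2(setdiff(names(X), p)), numeric(1))
  list(full_r2 = full,
       per_score = data.frame(predictor = names(X), delta_r2 = unname(dr2),
                              stringsAsFactors = FALSE))
}

#' Extraversion quartiles versus instrumental sampling strategy
#'
#' Splits participants into extraversion quartiles and cross-tabulates them
#' against two strategy groups: Uncertainty-only in both instrumental blocks
#' versus EV-sensitive-or-Random in both.
#'
#' @param profiles personality table (needs `big5_extraversion`).
#' @param fits cohort fit table from [fit_cohort()].
#' @return a list with the percentage of each quartile in each group and the
#'   underlying counts; quartiles with no participants are flagged.
#' @export
quartile_strategy_table <- function(profiles, fits) {
  if (nrow(profiles) < 8L) stop("need at least 8 participants for quartiles",
                                call. = FALSE)
  inst <- fits[fits$block %in% c("Estimate", "Intervene"), ]
  wide <- stats::reshape(inst[c("participant_id", "block", "label")],
                         idvar = "participant_id", timevar = "block",
                         direction = "wide")
  names(wide) <- sub("^label\\.", "", names(wide))
  u_both <- wide$Estimate == "Uncertainty_only" & wide$Intervene == "Uncertainty_only"
  ev_both <- wide$Estimate %in% c("EV_sensitive", "Random") &
    wide$Intervene %in% c("EV_sensitive", "Random")
  grp <- ifelse(u_both, "uncertainty_only_both",
                ifelse(ev_both, "ev_or_random_both", NA))
  m <- merge(wide[c("participant_id")], profiles[c("participant_id", "big5_extraversion")],
             by = "participant_id")
  m$group <- grp[match(m$participant_id, wide$participant_id)]
  m <- m[!is.na(m$group), ]
  qs <- stats::quantile(m$big5_extraversion, c(0.25, 0.5, 0.75))
  m$quartile <- cut(m$big5_extraversion,
                    breaks = c(-Inf, qs, Inf), labels = paste0("Q", 1:4))
  counts <- table(m$quartile, m$group)
  pct <- 100 * prop.table(counts, margin = 2)
  list(counts = counts, pct_of_group = pct,
       empty_quartiles = rownames(counts)[rowSums(counts) == 0])
}

#' Forest plot of decoding coefficients
#'
#' Bootstrap means and 95% intervals of the classifier coefficients, ordered
#' by absolute mean; significant predictors are filled.
#'
#' @param x a `decoding_result`.
#' @param ... passed to `plot()`.
#' @export
plot.decoding_result <- function(x, ...) {
  cf <- x$coefficients[order(abs(x$coefficients$mean)), ]
  n <- nrow(cf)
  old <- graphics::par(mar = c(4, 11, 2, 1)); on.exit(graphics::par(old))
  plot(cf$mean, seq_len(n), xlim = range(c(cf$lower, cf$upper, 0)),
       yaxt = "n", ylab = "", xlab = "coefficient (bootstrap mean, 95% CI)",
       pch = ifelse(cf$significant, 16, 1), ...)
  graphics::axis(2, at = seq_len(n), labels = cf$predictor, las = 1,
                 cex.axis = 0.7)
  graphics::segments(cf$lower, seq_len(n), cf$upper, seq_len(n))
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
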