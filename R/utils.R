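#' @keywords internal
#' @useDynLib infodemand, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

#' Logistic function
#'
#' @param x numeric vector of logits.
#' @return `1 / (1 + exp(-x))`.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Inverse logistic function
#'
#' @param p probabilities in (0, 1).
#' @return logits.
#' @export
logit <- function(p) log(p / (1 - p))

## Deterministic child seeds: one master seed per run, per-stream children so
## that stages (cohort generation, bootstraps, decoding) can be re-run
## independently without perturbing each other. Kept strictly below 2^31.
child_seed <- function(master, stream, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- (as.double(master) %% 2147483647) + 1
  for (ch in utf8ToInt(as.character(stream))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((h * 131071 + as.double(index) * 2654435761) %% 2147483647)
}

## Run `expr` under a local RNG state seeded with `seed`; restores the caller's
## RNG state afterwards so library code never disturbs user-level randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
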