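## Hartigan's dip test of unimodality. The statistic is the smallest
## sup-norm distance between the empirical CDF and any unimodal CDF; the
## test compares it against dips of uniform null samples of the same size
## (the uniform being the least favourable unimodal null).

#' Hartigan's dip statistic
#'
#' Minimal sup-norm distance between the empirical CDF of `x` and the class
#' of unimodal CDFs (convex below the mode, concave above, an atom allowed
#' at the mode). The dip of any sample lies in `[1/(2n), 0.25]`; perfectly
#' unimodal configurations attain the lower bound and the equal two-point
#' mass the upper.
#'
#' @param x numeric sample (ties allowed).
#' @param tol bisection tolerance on the statistic (default 1e-9).
#' @return the dip statistic.
#' @export
dip_stat <- function(x, tol = 1e-9) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("empty sample", call. = FALSE)
  tab <- table(x)
  dip_stat_cpp(as.numeric(names(tab)), as.numeric(tab), tol)
}

#' Bootstrap dip test of unimodality
#'
#' Computes the dip of `x` and a bootstrap p-value: the fraction of
#' uniform(0,1) null samples of the same size whose dip is at least the
#' observed one.
#'
#' @param x numeric sample, `n >= 10`.
#' @param n_boot number of null samples (default 1000).
#' @param seed integer seed for the null draws.
#' @param null_dips optional pre-computed vector of null dips for samples of
#'   the same size (overrides `n_boot`/`seed`); useful when testing many
#'   samples of identical size.
#' @return a list with `dip`, `p_value`, `n` and `n_boot`.
#' @export
dip_test <- function(x, n_boot = 1000, seed = 1L, null_dips = NULL) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 10L) stop("dip test requires at least 10 observations", call. = FALSE)
  if (length(unique(x)) == 1L) {
    warning("constant input: the dip test is degenerate, p = 1")
    return(list(dip = dip_stat(x), p_value = 1, n = n,
                n_boot = length(null_dips) %||% n_boot))
  }
  d <- dip_stat(x)
  if (is.null(null_dips)) {
    null_dips <- with_seed(seed, replicate(n_boot, dip_stat(stats::runif(n))))
  }
  list(dip = d, p_value = mean(null_dips >= d), n = n, n_boot = length(null_dips))
}

#' Null dips for samples of a given size
#'
#' Dips of `n_boot` uniform(0,1) samples of size `n`, for reuse across many
#' tests of equally sized samples.
#'
#' @param n sample size.
#' @param n_boot number of null samples.
#' @param seed integer seed.
#' @return numeric vector of null dip statistics.
#' @export
dip_null_distribution <- function(n, n_boot = 1000, seed = 1L) {
  with_seed(seed, replicate(n_boot, dip_stat(stats::runif(n))))
}
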