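#' Hartigan's dip statistic
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical distribution function and any unimodal distribution function
#' (convex then concave, possibly with an atom at the mode). It is computed
#' exactly, by bisection over the feasibility of fitting a unimodal CDF
#' within a band of half-width `d` around the ECDF (see the package
#' vignette for the characterisation).
#'
#' The dip of any sample of size n lies in `[1/(2n), 1/4]`; a sample with
#' fewer than two distinct values has dip 0 by convention.
#'
#' @param x numeric sample.
#' @return the dip statistic (a single number).
#' @export
dip_statistic <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(0)
  .dip_stat_cpp(as.numeric(x))
}

#' Dip test of unimodality for a latency sample
#'
#' Tests the bimodality of a distribution of evoked-spike latencies using
#' Hartigan's dip statistic. The p-value is obtained by parametric bootstrap
#' against the uniform null: `n_boot` uniform samples of the same size are
#' drawn, their dips computed, and `p = (1 + #{dip_boot >= dip_obs}) /
#' (n_boot + 1)`. The uniform is the least-favourable unimodal null, so the
#' test is conservative for peaked unimodal alternatives.
#'
#' A precomputed vector of null dips (for the same sample size) can be
#' supplied to amortise the bootstrap across many tests.
#'
#' @param latencies numeric sample (>= 4 values required).
#' @param n_boot number of bootstrap samples.
#' @param seed integer seed for the bootstrap.
#' @param null_dips optional precomputed null dips (see [dip_null()]).
#' @return list with `statistic` (the dip), `p_value`, `n`, `n_boot`.
#' @export
dip_bimodality <- function(latencies, n_boot = 500, seed = 1,
                           null_dips = NULL) {
  x <- latencies[!is.na(latencies)]
  if (length(x) < 4) stop("dip_bimodality requires at least 4 latency values")
  if (length(unique(x)) < 2)
    return(list(statistic = 0, p_value = 1, n = length(x), n_boot = 0L))
  d <- dip_statistic(x)
  if (is.null(null_dips)) null_dips <- dip_null(length(x), n_boot, seed)
  p <- (1 + sum(null_dips >= d)) / (length(null_dips) + 1)
  list(statistic = d, p_value = p, n = length(x), n_boot = length(null_dips))
}

#' Null distribution of the dip under the uniform
#'
#' @param n sample size.
#' @param n_boot number of bootstrap samples.
#' @param seed integer seed.
#' @return numeric vector of `n_boot` dip statistics of uniform samples.
#' @export
dip_null <- function(n, n_boot = 500, seed = 1) {
  stopifnot(n >= 2, n_boot >= 1)
  set.seed(seed)
  vapply(seq_len(n_boot), function(i) .dip_stat_cpp(runif(n)), numeric(1))
}
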