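# Slow, independent R implementation of the dip statistic used as an oracle
# for the compiled version: explicit triple-loop feasibility test and
# bisection, with no shared code.

dip_slow <- function(x) {
  x <- sort(x)
  v <- unique(x)
  m <- length(v)
  if (m < 2) return(0)
  n <- length(x)
  cc <- c(0, cumsum(tabulate(match(x, v), m)) / n)

  feasible <- function(d) {
    lo <- pmax(0, cc[-1] - d)
    hi <- pmin(1, cc[-(m + 1)] + d)
    if (any(lo > hi)) return(FALSE)
    ext_up <- function(i, j, l)  # chord through (v_i, hi_i), (v_j, lo_j) at v_l
      lo[j] + (lo[j] - hi[i]) / (v[j] - v[i]) * (v[l] - v[j])
    ext_dn <- function(j, i, l)  # chord through (v_i, lo_i), (v_j, hi_j) at v_l
      hi[j] + (hi[j] - lo[i]) / (v[i] - v[j]) * (v[j] - v[l])
    alpha <- lo
    for (l in 2:m)
      for (j in 2:l - 1)
        for (i in seq_len(j - 1))
          alpha[l] <- max(alpha[l], ext_up(i, j, l))
    beta <- hi
    for (l in 1:(m - 1))
      for (j in (l + 1):m)
        if (j < m)
          for (i in (j + 1):m)
            beta[l] <- min(beta[l], ext_dn(j, i, l))
    pref_ok <- cumprod(alpha <= hi + 1e-15) > 0
    suff_ok <- rev(cumprod(rev(beta >= lo - 1e-15)) > 0)
    for (k in 1:m) {
      pre <- if (k == 1) TRUE else pref_ok[k - 1]
      suf <- if (k == m) TRUE else suff_ok[k + 1]
      if (pre && suf && alpha[k] <= beta[k] + 1e-15) return(TRUE)
    }
    FALSE
  }

  d_lo <- 0; d_hi <- 0.3
  for (it in 1:50) {
    mid <- (d_lo + d_hi) / 2
    if (feasible(mid)) d_hi <- mid else d_lo <- mid
  }
  (d_lo + d_hi) / 2
}
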