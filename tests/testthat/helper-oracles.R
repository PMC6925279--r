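# independent oracles, kept deliberately naive

# closed-form Pearson chi-square for a 2x2 table
chi2_closed_form <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# two-sample KS statistic by sort-merge over the pooled values
ks_stat_oracle <- function(x, y) {
  pooled <- sort(unique(c(x, y)))
  fx <- vapply(pooled, function(v) mean(x <= v), numeric(1))
  fy <- vapply(pooled, function(v) mean(y <= v), numeric(1))
  max(abs(fx - fy))
}

# hypergeometric upper tail by exhaustive enumeration of target draws
hyper_oracle <- function(universe, members, n_target, k_obs) {
  combos <- utils::combn(length(universe), n_target)
  is_member <- universe %in% members
  hits <- apply(combos, 2, function(ix) sum(is_member[ix]))
  mean(hits >= k_obs)
}
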