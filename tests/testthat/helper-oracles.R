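# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the code paths they check.

# BH step-up by direct definition: q_i = min over j with p_j >= p_i of
# m * p_j / rank_j, capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- m * ranked[i:m] / (i:m)
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# Log-rank chi-square from the textbook O/E/V sum over distinct event days
# (no censoring in the fixtures that use this).
logrank_brute <- function(days_a, days_b) {
  days <- sort(unique(c(days_a, days_b)))
  nA <- length(days_a); nB <- length(days_b)
  O <- E <- V <- 0
  for (d in days) {
    dA <- sum(days_a == d); dB <- sum(days_b == d)
    dT <- dA + dB; nT <- nA + nB
    E <- E + dT * nA / nT
    if (nT > 1) {
      V <- V + dT * (nA / nT) * (nB / nT) * (nT - dT) / (nT - 1)
    }
    O <- O + dA
    nA <- nA - dA; nB <- nB - dB
  }
  (O - E)^2 / V
}

# Upper-tail hypergeometric by exhaustive enumeration over overlap counts.
hyper_brute <- function(k, set_size, query_size, universe_size) {
  ks <- k:min(set_size, query_size)
  sum(choose(set_size, ks) * choose(universe_size - set_size, query_size - ks)) /
    choose(universe_size, query_size)
}

# Comparison table for constructed significance patterns: one row per gene
# per comparison with q set below/above the threshold.
pattern_comparisons <- function(patterns, fdr = 0.05,
                                diff_rf_cf = 1, diff_sf_cf = 1) {
  # patterns: data.frame gene_id, d, s2, s3 (logical)
  rows <- list()
  for (i in seq_len(nrow(patterns))) {
    g <- patterns$gene_id[i]
    qs <- ifelse(c(patterns$d[i], patterns$s2[i], patterns$s3[i]),
                 fdr / 10, 0.5)
    rows[[i]] <- data.frame(
      gene_id = g,
      comparison = c("RF_vs_CF", "SF_vs_CF", "SF_vs_RF"),
      mean_diff_log2 = c(diff_rf_cf, diff_sf_cf, 0),
      fold_change = 2^c(diff_rf_cf, diff_sf_cf, 0),
      t = 1, p = qs, q = qs, zero_variance = FALSE,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_table", "data.frame")
  out
}

# Tiny event-record builder.
make_events <- function(death_days = integer(0), censor_days = integer(0),
                        cohort = "CF") {
  data.frame(
    fly_id = sprintf("%s_%03d", cohort,
                     seq_len(length(death_days) + length(censor_days))),
    cohort = cohort,
    day = c(death_days, censor_days),
    status = c(rep("death", length(death_days)),
               rep("censored", length(censor_days))),
    stringsAsFactors = FALSE)
}

# Constant-hazard series over a day range.
make_hazard <- function(days, hazard) {
  out <- data.frame(day = days, hazard = hazard)
  class(out) <- c("hazard_series", "data.frame")
  out
}
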