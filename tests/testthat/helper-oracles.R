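# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Benjamini-Hochberg step-up, written from the definition: sort ascending,
# q_i = p_(i) * m / i, enforce monotonicity from the largest rank down.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Exhaustive one-sample bootstrap p value at tiny n: every one of the n^n
# equally likely resamples, smaller strict tail of the resample means.
enumerate_one_sample_p <- function(values) {
  n <- length(values)
  idx <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  means <- rowMeans(matrix(values[idx], nrow = nrow(idx)))
  min(mean(means > 0), mean(means < 0))
}

# Exhaustive two-sample bootstrap: all joint resamples of both groups,
# smaller strict tail of the difference of resample means.
enumerate_two_sample_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  ia <- as.matrix(expand.grid(rep(list(seq_len(na)), na)))
  ib <- as.matrix(expand.grid(rep(list(seq_len(nb)), nb)))
  ma <- rowMeans(matrix(a[ia], nrow = nrow(ia)))
  mb <- rowMeans(matrix(b[ib], nrow = nrow(ib)))
  d <- as.vector(outer(ma, mb, "-"))
  min(mean(d > 0), mean(d < 0))
}

# Mann-Whitney AUC: P(score_pos > score_neg) + 0.5 P(tie).
mann_whitney_auc <- function(scores, is_pos) {
  sp <- scores[is_pos]; sn <- scores[!is_pos]
  cmp <- outer(sp, sn, function(x, y) (x > y) + 0.5 * (x == y))
  mean(cmp)
}

# Raw periodogram power at one frequency (Hz) of a single series.
periodogram_power <- function(x, freq, fs) {
  n <- length(x)
  k <- round(freq * n / fs) + 1
  Mod(stats::fft(x)[k])^2 / n
}

rms <- function(x) sqrt(mean(x^2))

# Laterality of one band x region cell of a long power table, computed by a
# plain split-by-subject loop (no package reshaping involved).
cell_li_oracle <- function(cohort, band, region, group) {
  sub <- cohort[cohort$band == band & cohort$region == region &
                  cohort$group == group, ]
  sapply(split(sub, sub$subject_id, drop = TRUE), function(d) {
    (d$power[d$hemisphere == "L"] - d$power[d$hemisphere == "R"]) /
      (d$power[d$hemisphere == "L"] + d$power[d$hemisphere == "R"])
  })
}

# Small cohort used by several files.
small_cohort <- function(seed = 11, ...) {
  simulate_power_cohort(synth_config(n_ctr = 12, n_lt = 6, n_rt = 6,
                                     seed = seed, ...))
}
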