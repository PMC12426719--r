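# Shared fixtures: random probability vectors and tiny hand-built cohorts.

# Uniform draw from the K-simplex (exponential spacings).
rand_simplex <- function(k = 4L) {
  g <- stats::rexp(k)
  g / sum(g)
}

rand_prob_matrix <- function(n, k = 4L) {
  g <- matrix(stats::rexp(n * k), nrow = n)
  g / rowSums(g)
}

# Brute-force two-sided Mann-Whitney p-value by enumerating every
# assignment of the pooled sample to the two groups.
permutation_u_pvalue <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  rk <- rank(pooled)
  u_of <- function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_of)
  min(1, 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs)))
}

# One-hot hypnodensity matching a hypnogram.
onehot_hd <- function(h) {
  k <- nlevels(h$stages)
  p <- diag(k)[as.integer(h$stages), , drop = FALSE]
  hypnodensity(p, h$stage_set, h$epoch_duration)
}

# Minimal two-group cohort built entirely by hand (no simulator), with a
# manual staging plus one automated method carrying a hypnodensity.
tiny_cohort <- function(perfect = FALSE) {
  ss <- stage_set("aasm4")
  mk <- function(id, group, labels, flip_at = integer()) {
    manual <- hypnogram(labels, ss)
    test_lab <- labels
    if (!perfect && length(flip_at)) {
      test_lab[flip_at] <- ifelse(test_lab[flip_at] == "W", "N1+N2", "W")
    }
    test <- hypnogram(test_lab, ss)
    hd <- onehot_hd(test)
    subject_record(id, group,
                   list(manual = list(hypnogram = manual),
                        auto = list(hypnogram = test, hypnodensity = hd)))
  }
  base <- c("W", "W", "N1+N2", "N1+N2", "N3", "N3", "N1+N2", "R", "R", "W")
  cohort(list(
    mk("a1", "g1", base, flip_at = 2L),
    mk("a2", "g1", rev(base), flip_at = 5L),
    mk("b1", "g2", base, flip_at = c(1L, 6L)),
    mk("b2", "g2", rev(base), flip_at = c(3L, 9L))
  ), name = "tiny")
}
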