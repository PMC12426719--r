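test_that("ambiguity matches its boundary and closed-form values", {
  expect_identical(ambiguity(c(1, 0, 0, 0)), 0)
  expect_equal(ambiguity(rep(0.25, 4)), 1, tolerance = 1e-15)
  expect_equal(ambiguity(c(0.5, 0.5, 0, 0)), 0.5, tolerance = 1e-15)
  expect_equal(ambiguity(c(1, 1, 1, 0) / 3), log(3) / log(4), tolerance = 1e-15)
  # any K >= 2, normalised by log K
  expect_equal(ambiguity(c(0.5, 0.5)), 1, tolerance = 1e-15)
  expect_error(ambiguity(c(0.5, 0.4)), "sums to")
  expect_error(ambiguity(c(1.2, -0.2, 0, 0)), "\\[0, 1\\]")
})

test_that("ambiguity equals direct entropy, permutation- and base-invariant", {
  set.seed(11)
  for (i in 1:200) {
    p <- rand_simplex(4L)
    direct <- -sum(ifelse(p > 0, p * log(p), 0)) / log(4)
    expect_equal(ambiguity(p), direct, tolerance = 1e-12)
    expect_equal(ambiguity(sample(p)), ambiguity(p), tolerance = 1e-12)
    base2 <- -sum(ifelse(p > 0, p * log2(p), 0)) / log2(4)
    expect_equal(ambiguity(p), base2, tolerance = 1e-12)
  }
})

test_that("restricted-support suprema match the printed thresholds", {
  # 2-support: grid over one free coordinate at step 0.01
  a <- seq(0, 1, by = 0.01)
  two <- vapply(a, function(x) ambiguity(c(x, 1 - x, 0, 0)), numeric(1))
  expect_equal(max(two), 0.5, tolerance = 1e-15)
  # 3-support: grid at step 0.005; supremum log 3 / log 4 = 0.79 to 2 dp
  best <- 0
  for (i in 0:200) for (j in 0:(200 - i)) {
    best <- max(best, ambiguity(c(i, j, 200 - i - j, 0) / 200))
  }
  expect_lte(best, log(3) / log(4))
  expect_equal(round(best, 2), 0.79)
  expect_equal(round(log(3) / log(4), 2), 0.79)
})

test_that("ambiguity_series tags epochs with the classifier's own staging", {
  h <- hypnogram(c("W", "N3", "R"))
  hd <- onehot_hd(h)
  as_ <- ambiguity_series(hd, h)
  expect_equal(as_$values, c(0, 0, 0))
  expect_equal(as.character(as_$stage), c("W", "N3", "R"))

  set.seed(3)
  p <- rand_prob_matrix(30, 4L)
  hd <- hypnodensity(p)
  as_ <- ambiguity_series(hd)  # defaults to the argmax staging
  expect_equal(as_$values, apply(p, 1, ambiguity), tolerance = 1e-12)
  expect_equal(as.character(as_$stage),
               as.character(hypnogram_from_hypnodensity(hd)$stages))
  # grouping by stage then pooling reproduces the full multiset
  pooled <- sort(unlist(split(as_$values, as_$stage)))
  expect_equal(pooled, sort(as_$values), ignore_attr = TRUE)

  expect_error(ambiguity_series(hd, hypnogram(rep("W", 5))), "mismatch")
})

test_that("transition detection and bout extraction partition the record", {
  h <- hypnogram(c("W", "W", "N1+N2", "N1+N2", "R"))
  tr <- detect_transitions(h)
  expect_equal(tr$boundary_index, c(1L, 3L))
  expect_equal(as.character(tr$from_stage), c("W", "N1+N2"))
  expect_equal(as.character(tr$to_stage), c("N1+N2", "R"))

  expect_equal(nrow(detect_transitions(hypnogram(rep("W", 3)))), 0L)
  expect_error(detect_transitions(hypnogram("W")), "at least 2")

  b <- extract_bouts(hypnogram(c("W", "W", "N1+N2", "N1+N2", "N1+N2", "W")))
  expect_equal(as.character(b$stage), c("W", "N1+N2", "W"))
  expect_equal(b$duration, c(1.0, 1.5, 0.5))
  expect_equal(b$start_epoch, c(0L, 2L, 5L))

  expect_equal(nrow(extract_bouts(hypnogram(rep("R", 4)))), 1L)

  set.seed(21)
  for (i in 1:20) {
    lab <- sample(c("W", "N1+N2", "N3", "R"), 50, replace = TRUE)
    h <- hypnogram(lab)
    b <- extract_bouts(h)
    tr <- detect_transitions(h)
    expect_equal(nrow(tr), nrow(b) - 1L)                   # partition identity
    expect_equal(sum(b$duration), 50 * 30 / 60)            # time conserved
    expect_true(all(b$length_epochs >= 1L))
    expect_true(all(as.character(b$stage)[-1] !=
                    as.character(b$stage)[-nrow(b)]))      # adjacent differ
  }

  # edge bouts dropped on request
  b2 <- extract_bouts(hypnogram(c("W", "N3", "N3", "R")), drop_edges = TRUE)
  expect_equal(as.character(b2$stage), "N3")
})

test_that("continuity equals 1 - total variation and is symmetric", {
  expect_equal(transition_continuity(c(0.4, 0.3, 0.2, 0.1),
                                     c(0.4, 0.3, 0.2, 0.1)), 1)
  expect_equal(transition_continuity(c(1, 0, 0, 0), c(0, 1, 0, 0)), 0)
  expect_equal(transition_continuity(c(0.5, 0.5, 0, 0), c(0, 0.5, 0.5, 0)), 0.5)
  expect_error(transition_continuity(c(0.5, 0.5), c(0.5, 0.25, 0.25)),
               "different lengths")
  set.seed(13)
  for (i in 1:200) {
    p <- rand_simplex(4L); q <- rand_simplex(4L)
    tv <- 0.5 * sum(abs(p - q))
    expect_equal(transition_continuity(p, q), 1 - tv, tolerance = 1e-12)
    expect_equal(transition_continuity(p, q), transition_continuity(q, p),
                 tolerance = 1e-15)
  }
})

test_that("annotated continuity uses the rows flanking each boundary", {
  h <- hypnogram(c("W", "W", "N3", "R", "R"))
  tr <- annotate_transition_continuity(onehot_hd(h), h)
  expect_equal(tr$continuity, c(0, 0))   # disjoint one-hots

  expect_equal(nrow(annotate_transition_continuity(
    hypnodensity(matrix(0.25, 3, 4)), hypnogram(rep("W", 3)))), 0L)

  # continuity reads exactly rows t and t+1 around the boundary
  p <- rbind(c(0.6, 0.3, 0.05, 0.05),
             c(0.2, 0.6, 0.1, 0.1),
             c(0.1, 0.2, 0.6, 0.1))
  hd <- hypnodensity(p)
  tr <- annotate_transition_continuity(hd)
  expect_equal(tr$continuity,
               c(transition_continuity(p[1, ], p[2, ]),
                 transition_continuity(p[2, ], p[3, ])), tolerance = 1e-12)
  # stages whose probabilities do not change across the boundary do not
  # contribute: continuity reduces to the involved coordinates only
  set.seed(31)
  for (i in 1:50) {
    cd <- rand_simplex(4L)[1:2] / 2          # shared, unchanged N3/R mass
    rest <- 1 - sum(cd)
    ab <- stats::runif(1) * rest; ab2 <- stats::runif(1) * rest
    p_before <- c(ab, rest - ab, cd)
    p_after <- c(ab2, rest - ab2, cd)
    expect_equal(transition_continuity(p_before, p_after),
                 1 - 0.5 * (abs(ab - ab2) + abs((rest - ab) - (rest - ab2))),
                 tolerance = 1e-12)
  }
})

test_that("continuity tail fractions count strict exceedances", {
  tr <- data.frame(continuity = c(0.01, 0.5, 0.99))
  expect_equal(continuity_tail_fractions(tr, 0.05, 0.95),
               c(below = 1 / 3, above = 1 / 3))
  expect_equal(continuity_tail_fractions(rep(0.5, 10)),
               c(below = 0, above = 0))
  tf <- continuity_tail_fractions(runif(50))
  expect_lte(sum(tf), 1)
  expect_error(continuity_tail_fractions(numeric()), "undefined")
  expect_error(continuity_tail_fractions(c(0.2, NA)), "missing")
})
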