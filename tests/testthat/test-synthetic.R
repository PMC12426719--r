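test_that("profiles validate their parameters", {
  tm <- diag(4)
  expect_s3_class(group_profile("p", tm, 5), "group_profile")
  bad <- tm; bad[1, 1] <- 0.5
  expect_error(group_profile("p", bad, 5), "sum to 1")
  expect_error(group_profile("p", tm, -1), "concentration")
  expect_error(group_profile("p", tm, 5, rem_leak = 1), "rem_leak")
})

test_that("hypnogram simulation is a deterministic Markov chain", {
  prof <- rbd_like_profile()
  h1 <- simulate_hypnogram(prof, 300, seed = 7)
  h2 <- simulate_hypnogram(prof, 300, seed = 7)
  expect_identical(as.character(h1$stages), as.character(h2$stages))
  expect_false(identical(as.character(h1$stages),
                         as.character(simulate_hypnogram(prof, 300, 8)$stages)))

  # absorbing states: identity matrix keeps the chain in W
  frozen <- group_profile("frozen", diag(4), 5)
  expect_equal(unique(as.character(simulate_hypnogram(frozen, 50, 1)$stages)),
               "W")

  # diagonal 0.95 gives geometric bouts with mean about 1/(1-0.95) = 20
  tm <- matrix(0.05 / 3, 4, 4); diag(tm) <- 0.95
  prof95 <- group_profile("d95", tm, 5)
  b <- extract_bouts(simulate_hypnogram(prof95, 100000, seed = 3))
  expect_equal(mean(b$length_epochs), 20, tolerance = 0.05)

  # simulators leave the caller's RNG stream untouched
  set.seed(99); before <- .Random.seed
  invisible(simulate_hypnogram(prof, 50, 1))
  expect_identical(.Random.seed, before)
})

test_that("hypnodensity rows are valid, sharp at high concentration", {
  prof <- osa_like_profile()
  truth <- simulate_hypnogram(prof, 400, seed = 2)
  hd <- simulate_hypnodensity(truth, prof, seed = 3)
  expect_equal(rowSums(hd$probs), rep(1, 400), tolerance = 1e-12)
  expect_true(all(hd$probs >= 0))
  expect_identical(hd$probs,
                   simulate_hypnodensity(truth, prof, seed = 3)$probs)

  sharp <- prof; sharp$concentration <- 1e6
  sharp$rem_leak <- 0; sharp$crossfade_epochs <- 0L
  hds <- simulate_hypnodensity(truth, sharp, seed = 4)
  expect_lt(mean(ambiguity_series(hds)$values), 0.01)
  # and its argmax recovers the truth exactly
  expect_identical(as.character(hypnogram_from_hypnodensity(hds)$stages),
                   as.character(truth$stages))
})

test_that("rem_leak halves REM probability and feeds N1+N2 over W", {
  prof <- osa_like_profile()
  prof$crossfade_epochs <- 0L
  truth <- hypnogram(rep("R", 10000))  # pure REM record, no boundaries
  base <- prof; base$rem_leak <- 0
  half <- prof; half$rem_leak <- 0.5
  p0 <- simulate_hypnodensity(truth, base, seed = 6)$probs
  p5 <- simulate_hypnodensity(truth, half, seed = 6)$probs
  expect_equal(mean(p5[, "R"]), 0.5 * mean(p0[, "R"]), tolerance = 0.01)
  moved_n12 <- mean(p5[, "N1+N2"] - p0[, "N1+N2"])
  moved_w <- mean(p5[, "W"] - p0[, "W"])
  expect_equal(moved_n12 / moved_w, 2, tolerance = 0.05)
})

test_that("mean ambiguity falls with concentration, continuity rises with crossfade", {
  prof <- osa_like_profile()
  prof$rem_leak <- 0
  truth <- simulate_hypnogram(prof, 5000, seed = 12)
  means <- vapply(c(1, 3, 10, 30, 100), function(cc) {
    p <- prof; p$concentration <- cc; p$crossfade_epochs <- 0L
    mean(ambiguity_series(simulate_hypnodensity(truth, p, seed = 13))$values)
  }, numeric(1))
  expect_true(all(diff(means) < 0))

  cont <- vapply(0:3, function(w) {
    p <- prof; p$crossfade_epochs <- as.integer(w)
    hd <- simulate_hypnodensity(truth, p, seed = 14)
    mean(annotate_transition_continuity(hd, truth)$continuity)
  }, numeric(1))
  expect_true(all(diff(cont) > 0))
})

test_that("manual scorer noise degrades agreement monotonically", {
  prof <- rbd_like_profile()
  truth <- simulate_hypnogram(prof, 2000, seed = 20)
  clean <- prof; clean$manual_noise <- 0
  expect_identical(as.character(simulate_manual(truth, clean, 1)$stages),
                   as.character(truth$stages))

  all_wrong <- prof; all_wrong$manual_noise <- 1
  m1 <- simulate_manual(truth, all_wrong, seed = 21)
  expect_equal(mean(as.character(m1$stages) == as.character(truth$stages)), 0)

  kappas <- vapply(c(0.02, 0.1, 0.3, 0.6), function(nz) {
    p <- prof; p$manual_noise <- nz
    mean(vapply(1:10, function(s) {
      cohens_kappa(confusion(truth, simulate_manual(truth, p, seed = 100 + s)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(kappas) < 0))
})

test_that("argmax agreement with truth falls as concentration falls", {
  prof <- osa_like_profile(); prof$rem_leak <- 0
  truth <- simulate_hypnogram(prof, 3000, seed = 30)
  kap <- vapply(c(1, 2, 4, 8), function(cc) {  # below the saturation plateau
    p <- prof; p$concentration <- cc
    hd <- simulate_hypnodensity(truth, p, seed = 31)
    cohens_kappa(confusion(truth, hypnogram_from_hypnodensity(hd)))
  }, numeric(1))
  expect_true(all(diff(kap) > 0))
})

test_that("REM leakage sends REM epochs predominantly to N1+N2", {
  prof <- osa_like_profile()
  truth <- simulate_hypnogram(prof, 4000, seed = 40)
  sens <- c(); to_n12 <- c(); to_w <- c()
  for (leak in c(0, 0.3, 0.6)) {
    p <- prof; p$rem_leak <- leak
    hd <- simulate_hypnodensity(truth, p, seed = 41)
    pred <- hypnogram_from_hypnodensity(hd)
    cm <- confusion(truth, pred)
    sens <- c(sens, cm["R", "R"] / sum(cm["R", ]))
    to_n12 <- c(to_n12, cm["R", "N1+N2"])
    to_w <- c(to_w, cm["R", "W"])
  }
  expect_true(all(diff(sens) < 0))
  expect_gt(to_n12[3], to_w[3])  # dominant confusion direction
})

test_that("cohorts honour sizes, invariants and reproducibility", {
  co <- simulate_cohort(n_subjects = 3L, n_epochs = 120L, seed = 77L)
  expect_equal(length(co$records), 6L)
  groups <- vapply(co$records, `[[`, character(1), "group")
  expect_equal(unname(table(groups)[c("rbd_like", "osa_like")]),
               c(3L, 3L), ignore_attr = TRUE)
  for (rec in co$records) {
    expect_setequal(names(rec$stagings), c("manual", "exg", "hrvm"))
    expect_null(rec$stagings$manual$hypnodensity)
    for (m in c("exg", "hrvm")) {
      st <- rec$stagings[[m]]
      expect_equal(n_epochs(st$hypnogram), 120L)
      expect_equal(rowSums(st$hypnodensity$probs), rep(1, 120L),
                   tolerance = 1e-12)
      expect_identical(
        as.character(st$hypnogram$stages),
        as.character(hypnogram_from_hypnodensity(st$hypnodensity)$stages))
    }
  }
  co2 <- simulate_cohort(n_subjects = 3L, n_epochs = 120L, seed = 77L)
  expect_equal(co$records[[4]]$stagings$exg$hypnodensity$probs,
               co2$records[[4]]$stagings$exg$hypnodensity$probs)
})
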