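#' Define a synthetic group profile
#'
#' Bundles the parameters of the cohort generator for one clinical
#' group. Stage dynamics follow a first-order Markov chain over the
#' 4-stage alphabet, so bout lengths are geometric with mean
#' `1/(1 - diagonal)` epochs — enough control for bout-duration analyses
#' without claiming physiological realism. Hypnodensity rows are
#' Dirichlet draws with parameters `concentration * onehot + 1`, so the
#' rows concentrate on the true stage as `concentration` grows (higher
#' concentration, sharper rows, lower ambiguity). `rem_leak` re-assigns a fraction of the REM probability
#' mass to N1+N2 and W (2:1), emulating the REM-to-light-sleep confusion
#' that loss of REM atonia induces in automated scorers.
#' `crossfade_epochs` blends the stage target distributions linearly
#' across each stage boundary, so longer crossfades yield higher
#' transition continuity. `manual_noise` is the per-epoch probability
#' that a simulated human scorer deviates from the true stage.
#'
#' @param name Profile name.
#' @param transition_matrix 4x4 row-stochastic matrix over
#'   (W, N1+N2, N3, R); rows must sum to 1.
#' @param concentration Positive Dirichlet scale.
#' @param crossfade_epochs Non-negative integer blending half-window.
#' @param rem_leak REM probability fraction re-assigned, in \[0, 1).
#' @param manual_noise Scorer deviation probability, in \[0, 1\].
#' @param confusion_kernel Optional 4x4 matrix; row s gives the scorer's
#'   stage distribution when it deviates from true stage s (diagonal 0,
#'   rows sum to 1). Default: uniform over the other three stages.
#' @return An object of class `group_profile`.
#' @export
group_profile <- function(name, transition_matrix, concentration,
                          crossfade_epochs = 0L, rem_leak = 0,
                          manual_noise = 0, confusion_kernel = NULL) {
  tm <- as.matrix(transition_matrix)
  if (!all(dim(tm) == c(4L, 4L))) stop("transition_matrix must be 4 x 4")
  if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-8)) {
    stop("transition_matrix rows must be non-negative and sum to 1")
  }
  stopifnot(concentration > 0, crossfade_epochs >= 0,
            rem_leak >= 0, rem_leak < 1,
            manual_noise >= 0, manual_noise <= 1)
  ss <- stage_set("aasm4")
  dimnames(tm) <- list(unclass(ss), unclass(ss))
  if (is.null(confusion_kernel)) {
    confusion_kernel <- matrix(1 / 3, 4L, 4L, dimnames = dimnames(tm))
    diag(confusion_kernel) <- 0
  } else {
    confusion_kernel <- as.matrix(confusion_kernel)
    if (!all(dim(confusion_kernel) == c(4L, 4L)) ||
        any(diag(confusion_kernel) != 0) ||
        any(abs(rowSums(confusion_kernel) - 1) > 1e-8)) {
      stop("confusion_kernel must be 4 x 4 with zero diagonal and unit row sums")
    }
  }
  structure(list(name = name, transition_matrix = tm,
                 concentration = concentration,
                 crossfade_epochs = as.integer(crossfade_epochs),
                 rem_leak = rem_leak, manual_noise = manual_noise,
                 confusion_kernel = confusion_kernel,
                 stage_set = ss),
            class = "group_profile")
}

#' Built-in group presets
#'
#' `rbd_like_profile()` emulates the staging phenotype of REM sleep
#' behaviour disorder as seen by automated classifiers: substantial REM
#' probability leakage towards N1+N2 and W (RSWA-driven confusion),
#' broader probability distributions, and gradual cross-transition
#' probability drift (higher continuity). `osa_like_profile()` emulates
#' a fragmented-sleep comparison group: more frequent brief awakenings
#' (arousals), sharper probability distributions, abrupt transitions,
#' and minimal REM leakage. Both use the same simulated-scorer noise so
#' agreement contrasts are driven by the hypnodensity structure.
#'
#' @return A [group_profile()].
#' @export
rbd_like_profile <- function() {
  tm <- rbind(
    W       = c(0.920, 0.072, 0.000, 0.008),
    `N1+N2` = c(0.035, 0.915, 0.030, 0.020),
    N3      = c(0.020, 0.045, 0.935, 0.000),
    R       = c(0.020, 0.030, 0.000, 0.950)
  )
  group_profile("rbd_like", tm, concentration = 8,
                crossfade_epochs = 2L, rem_leak = 0.35,
                manual_noise = 0.08)
}

#' @rdname rbd_like_profile
#' @export
osa_like_profile <- function() {
  tm <- rbind(
    W       = c(0.900, 0.092, 0.000, 0.008),
    `N1+N2` = c(0.060, 0.890, 0.030, 0.020),
    N3      = c(0.035, 0.050, 0.915, 0.000),
    R       = c(0.045, 0.030, 0.000, 0.925)
  )
  group_profile("osa_like", tm, concentration = 8,
                crossfade_epochs = 1L, rem_leak = 0.05,
                manual_noise = 0.08)
}

# Deterministic substream scheme: every random component of a cohort
# gets its own 32-bit seed derived from (global seed, subject counter,
# component code). Component codes: 1 truth chain, 2 manual scorer,
# 3 metadata, 10 + j hypnodensity of method j.
substream_seed <- function(seed, subject = 0L, component = 0L) {
  as.integer((as.numeric(seed) %% 65011
              + subject * 104729
              + component * 7919) %% 2147483629 + 1)
}

#' Simulate a hypnogram from a group profile
#'
#' First-order Markov chain over the 4-stage alphabet, started in W
#' (lights-off wake), one step per 30-s epoch.
#'
#' @param profile A [group_profile()].
#' @param n_epochs Number of epochs (>= 2).
#' @param seed Integer seed; the same seed reproduces the same record.
#' @return A [hypnogram()].
#' @export
simulate_hypnogram <- function(profile, n_epochs, seed) {
  stopifnot(inherits(profile, "group_profile"), n_epochs >= 2L)
  tm <- profile$transition_matrix
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  s <- integer(n_epochs)
  s[1L] <- 1L  # W
  u <- stats::runif(n_epochs - 1L)
  cum <- t(apply(tm, 1L, cumsum))
  for (t in 2:n_epochs) {
    s[t] <- 1L + sum(u[t - 1L] > cum[s[t - 1L], ])
  }
  hypnogram(rownames(tm)[s], profile$stage_set)
}

# Save/restore the RNG state so simulators are pure functions of their
# seed argument and never disturb the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Dirichlet target mean for each true stage under alpha = c*onehot + 1:
# row s is (c*e_s + 1)/(c + 4), REM row adjusted for probability leakage.
stage_target_means <- function(profile) {
  k <- 4L
  cc <- profile$concentration
  m <- (diag(k) * cc + 1) / (cc + k)
  dimnames(m) <- dimnames(profile$transition_matrix)
  if (profile$rem_leak > 0) {
    leak <- profile$rem_leak * m["R", "R"]
    m["R", "R"] <- m["R", "R"] - leak
    m["R", "N1+N2"] <- m["R", "N1+N2"] + 2 / 3 * leak
    m["R", "W"] <- m["R", "W"] + 1 / 3 * leak
  }
  m
}

#' Simulate a hypnodensity for a true hypnogram
#'
#' Per epoch, a Dirichlet draw with parameters
#' `concentration * onehot(true stage) + 1`: the unit pseudo-count floor
#' keeps every stage's expected probability non-zero, lets genuinely
#' ambiguous epochs occur at low concentration, and makes the mean
#' ambiguity strictly decreasing in the concentration (the draw
#' converges to the one-hot vector as concentration grows).
#' For true-REM epochs a fraction `rem_leak` of the drawn REM
#' probability is then moved to N1+N2 and W (split 2:1). Finally, within
#' `crossfade_epochs` of each stage boundary the row is replaced by the
#' linear blend of the leak-adjusted target distributions of the two
#' flanking stages, so the probability mass drifts smoothly across the
#' transition; each epoch is claimed by its nearest boundary.
#'
#' @param truth A 4-stage [hypnogram()] (the true stage sequence).
#' @param profile A [group_profile()].
#' @param seed Integer seed.
#' @return A [hypnodensity()] paired with `truth`.
#' @export
simulate_hypnodensity <- function(truth, profile, seed) {
  stopifnot(inherits(truth, "hypnogram"), inherits(profile, "group_profile"))
  n <- n_epochs(truth)
  k <- 4L
  s <- as.integer(truth$stages)
  alpha <- diag(k)[s, , drop = FALSE] * profile$concentration + 1
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  g <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n)
  p <- g / rowSums(g)
  # REM leakage on the drawn rows
  if (profile$rem_leak > 0) {
    rem <- s == 4L
    if (any(rem)) {
      leak <- profile$rem_leak * p[rem, 4L]
      p[rem, 4L] <- p[rem, 4L] - leak
      p[rem, 2L] <- p[rem, 2L] + 2 / 3 * leak
      p[rem, 1L] <- p[rem, 1L] + 1 / 3 * leak
    }
  }
  # cross-fade around boundaries
  w <- profile$crossfade_epochs
  if (w > 0L) {
    bounds <- which(s[-1L] != s[-n])  # 1-based epoch before each change
    if (length(bounds)) {
      targets <- stage_target_means(profile)[, , drop = FALSE]
      owner <- integer(n)
      dist <- rep(Inf, n)
      for (j in seq_along(bounds)) {
        b <- bounds[j]
        idx <- max(1L, b - w + 1L):min(n, b + w)
        d <- abs(idx - (b + 0.5))
        claim <- d < dist[idx]
        owner[idx[claim]] <- j
        dist[idx[claim]] <- d[claim]
      }
      for (j in seq_along(bounds)) {
        b <- bounds[j]
        idx <- which(owner == j)
        if (!length(idx)) next
        u <- (idx - (b - w)) / (2 * w + 1)
        m_from <- targets[s[b], ]
        m_to <- targets[s[b + 1L], ]
        p[idx, ] <- outer(1 - u, m_from) + outer(u, m_to)
      }
    }
  }
  p <- p / rowSums(p)
  colnames(p) <- rownames(profile$transition_matrix)
  hypnodensity(p, truth$stage_set, truth$epoch_duration)
}

#' Simulate a manual scorer
#'
#' Each epoch is reported correctly with probability
#' `1 - manual_noise`; otherwise the reported stage is drawn from the
#' profile's confusion kernel (default uniform over the other three
#' stages). Emulates single-human-scorer disagreement with the true
#' stage sequence.
#'
#' @inheritParams simulate_hypnodensity
#' @return A [hypnogram()].
#' @export
simulate_manual <- function(truth, profile, seed) {
  stopifnot(inherits(truth, "hypnogram"), inherits(profile, "group_profile"))
  n <- n_epochs(truth)
  s <- as.integer(truth$stages)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  flip <- stats::runif(n) < profile$manual_noise
  if (any(flip)) {
    ck <- profile$confusion_kernel
    cum <- t(apply(ck, 1L, cumsum))
    u <- stats::runif(sum(flip))
    s[flip] <- 1L + rowSums(u > cum[s[flip], , drop = FALSE])
  }
  hypnogram(levels(truth$stages)[s], truth$stage_set, truth$epoch_duration)
}

#' Simulate a full cohort
#'
#' For every subject: a true stage chain, a simulated manual hypnogram,
#' and one staging per automated method — a hypnodensity simulated with
#' method-specific modifiers plus its argmax hypnogram. The default
#' methods emulate an electrophysiology-based classifier (`exg`: full
#' concentration, full crossfade) and a cardiorespiratory one (`hrvm`:
#' 40% of the concentration, one epoch less crossfade), reflecting that
#' surrogate signals carry less stage information. Every random
#' component draws from its own substream derived from `seed` and a
#' subject counter, so cohorts are reproducible record by record.
#'
#' @param profiles Named list of [group_profile()]s, one per group.
#'   Default: `rbd_like` and `osa_like` presets.
#' @param n_subjects Subjects per group.
#' @param n_epochs Epochs per subject (default 960, i.e. 8 h of 30-s
#'   epochs).
#' @param seed Integer seed for the whole cohort.
#' @param methods Named list of method modifiers, each with elements
#'   `concentration_mult` and `crossfade_delta`.
#' @param name Cohort name.
#' @return A [cohort()].
#' @export
simulate_cohort <- function(profiles = list(rbd_like = rbd_like_profile(),
                                            osa_like = osa_like_profile()),
                            n_subjects = 20L, n_epochs = 960L, seed = 1L,
                            methods = list(
                              exg = list(concentration_mult = 1,
                                         crossfade_delta = 0L),
                              hrvm = list(concentration_mult = 0.4,
                                          crossfade_delta = -1L)),
                            name = "synthetic") {
  stopifnot(length(profiles) >= 1L, !is.null(names(profiles)),
            n_subjects >= 1L, n_epochs >= 2L)
  records <- list()
  counter <- 0L
  for (g in names(profiles)) {
    prof <- profiles[[g]]
    for (i in seq_len(n_subjects)) {
      counter <- counter + 1L
      truth <- simulate_hypnogram(prof, n_epochs,
                                  substream_seed(seed, counter, 1L))
      manual <- simulate_manual(truth, prof,
                                substream_seed(seed, counter, 2L))
      stagings <- list(manual = list(hypnogram = manual))
      for (j in seq_along(methods)) {
        mod <- methods[[j]]
        mprof <- prof
        mprof$concentration <- prof$concentration *
          (mod$concentration_mult %||% 1)
        mprof$crossfade_epochs <- max(0L, prof$crossfade_epochs +
                                        as.integer(mod$crossfade_delta %||% 0L))
        hd <- simulate_hypnodensity(truth, mprof,
                                    substream_seed(seed, counter, 10L + j))
        stagings[[names(methods)[j]]] <-
          list(hypnogram = hypnogram_from_hypnodensity(hd),
               hypnodensity = hd)
      }
      records[[counter]] <- subject_record(
        sprintf("%s_%02d", g, i), g, stagings,
        metadata = synth_metadata(g, substream_seed(seed, counter, 3L)))
    }
  }
  cohort(records, name = name)
}

# Plausible covariates for the manifest: age (years), AHI (events/h),
# RAI (REM atonia index; reduced in the RBD-like group).
synth_metadata <- function(group, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (grepl("rbd", group, ignore.case = TRUE)) {
    list(age = round(stats::rnorm(1, 66, 6.5), 1),
         ahi = round(stats::rlnorm(1, log(9.7), 0.6), 1),
         rai = round(stats::runif(1, 0.55, 0.85), 3))
  } else {
    list(age = round(stats::rnorm(1, 64, 6.8), 1),
         ahi = round(stats::rlnorm(1, log(19.2), 0.5), 1),
         rai = round(stats::runif(1, 0.9, 0.99), 3))
  }
}
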