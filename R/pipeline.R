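#' Analysis configuration
#'
#' Collects the knobs of the end-to-end analysis. By default every
#' staging method other than the reference is analysed, p-values from
#' all stages are adjusted as one Benjamini-Hochberg family at a 10%
#' false discovery rate, and continuity tail fractions are evaluated at
#' 0.05 and 0.95.
#'
#' @param reference_method Name of the reference staging (default
#'   `"manual"`); must be present in every record.
#' @param methods Character vector of automated methods to analyse;
#'   `NULL` = every non-reference method found in the cohort.
#' @param fdr False discovery rate for the joint adjustment, in (0, 1).
#' @param pooling Unit of analysis for the bout, ambiguity and
#'   continuity group tests: `"per_subject"` (default) first reduces
#'   each subject to a median, so the rank tests compare independent
#'   units and stay calibrated under the null; `"pooled_epochs"` feeds
#'   every epoch/bout/transition into the tests, reproducing the pooled
#'   design used in published hypnodensity analyses at the cost of
#'   treating autocorrelated epochs as independent. Summary tables
#'   (medians, IQRs, tail fractions) always pool, as published tables
#'   do.
#' @param continuity_tails Numeric `c(low, high)` thresholds.
#' @param groups Optional explicit group ordering (first group is the
#'   left side of every two-group comparison); default: sorted unique.
#' @param output_dir If non-`NULL`, [run_all()] writes its CSV tables
#'   and run log there.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(reference_method = "manual", methods = NULL,
                            fdr = 0.10,
                            pooling = c("per_subject", "pooled_epochs"),
                            continuity_tails = c(0.05, 0.95),
                            groups = NULL, output_dir = NULL) {
  stopifnot(fdr > 0, fdr < 1, length(continuity_tails) == 2L,
            continuity_tails[1L] < continuity_tails[2L])
  pooling <- match.arg(pooling)
  structure(list(reference_method = reference_method, methods = methods,
                 fdr = fdr, pooling = pooling,
                 continuity_tails = continuity_tails,
                 groups = groups, output_dir = output_dir),
            class = "analysis_config")
}

# Reduce a value vector to the test sample the config asks for: the raw
# pooled values, or one median per subject.
test_sample <- function(values, subject_id, config) {
  if (config$pooling == "per_subject") {
    as.numeric(tapply(values, subject_id, stats::median))
  } else {
    values
  }
}

cohort_methods <- function(x, config) {
  found <- unique(unlist(lapply(x$records, function(r) names(r$stagings))))
  methods <- config$methods %||% setdiff(found, config$reference_method)
  if (!length(methods)) stop("no automated methods to analyse")
  methods
}

cohort_groups <- function(x, config) {
  g <- vapply(x$records, `[[`, character(1), "group")
  config$groups %||% sort(unique(g))
}

median_iqr <- function(x) {
  c(median = stats::median(x), iqr = unname(stats::IQR(x)), n = length(x))
}

#' Agreement stage: kappa and per-class F1 versus the reference
#'
#' Computes per-subject Cohen's kappa and per-class scores for every
#' automated method against the reference staging, then queues the group
#' comparisons: Welch t-tests on kappa (per method and between methods)
#' and Mann-Whitney U tests on per-class F1 between groups. Subjects
#' missing a method are skipped with a log entry.
#'
#' @param x A [cohort()].
#' @param config An [analysis_config()].
#' @return List with `table` (one row per subject and method), `tests`
#'   (list of `test_result`) and `log` (character).
#' @export
run_agreement_stage <- function(x, config = analysis_config()) {
  stopifnot(inherits(x, "cohort"))
  methods <- cohort_methods(x, config)
  log <- character()
  rows <- list()
  for (rec in x$records) {
    ref <- rec$stagings[[config$reference_method]]
    if (is.null(ref)) {
      stop(sprintf("subject %s lacks reference method '%s'",
                   rec$subject_id, config$reference_method))
    }
    for (m in methods) {
      st <- rec$stagings[[m]]
      if (is.null(st)) {
        log <- c(log, sprintf("agreement: subject %s has no method '%s'; skipped",
                              rec$subject_id, m))
        next
      }
      ag <- agreement(ref$hypnogram, st$hypnogram)
      pc <- ag$per_class
      row <- data.frame(subject_id = rec$subject_id, group = rec$group,
                        method = m, kappa = ag$kappa,
                        n_epochs = ag$n_epochs)
      for (i in seq_len(nrow(pc))) {
        row[[paste0("f1_", pc$stage[i])]] <- pc$f1[i]
        row[[paste0("sens_", pc$stage[i])]] <- pc$sensitivity[i]
        row[[paste0("ppv_", pc$stage[i])]] <- pc$ppv[i]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tests <- list()
  groups <- cohort_groups(x, config)
  stages <- unclass(x$records[[1L]]$stagings[[1L]]$hypnogram$stage_set)
  if (length(groups) == 2L) {
    g1 <- groups[1L]; g2 <- groups[2L]
    for (m in methods) {
      sub <- tab[tab$method == m, ]
      k1 <- sub$kappa[sub$group == g1]; k2 <- sub$kappa[sub$group == g2]
      if (length(k1) >= 2L && length(k2) >= 2L) {
        res <- tryCatch(welch_t(k1, k2, sprintf("kappa [%s]: %s vs %s",
                                                m, g1, g2)),
                        error = function(e) conditionMessage(e))
        if (inherits(res, "test_result")) {
          tests[[length(tests) + 1L]] <- res
        } else {
          log <- c(log, sprintf("agreement: kappa [%s] group test skipped (%s)",
                                m, res))
        }
      }
      for (st in stages) {
        f <- sub[[paste0("f1_", st)]]
        f1 <- f[sub$group == g1]; f2 <- f[sub$group == g2]
        f1 <- f1[!is.na(f1)]; f2 <- f2[!is.na(f2)]
        if (length(f1) >= 2L && length(f2) >= 2L) {
          tests[[length(tests) + 1L]] <-
            mann_whitney(f1, f2, sprintf("f1 %s [%s]: %s vs %s", st, m, g1, g2))
        } else {
          log <- c(log, sprintf("agreement: f1 %s [%s] group test skipped (too few defined values)",
                                st, m))
        }
      }
    }
  }
  if (length(methods) >= 2L) {
    pairs <- utils::combn(methods, 2L, simplify = FALSE)
    for (pr in pairs) {
      k1 <- tab$kappa[tab$method == pr[1L]]
      k2 <- tab$kappa[tab$method == pr[2L]]
      if (length(k1) >= 2L && length(k2) >= 2L) {
        res <- tryCatch(welch_t(k1, k2, sprintf("kappa: %s vs %s",
                                                pr[1L], pr[2L])),
                        error = function(e) conditionMessage(e))
        if (inherits(res, "test_result")) {
          tests[[length(tests) + 1L]] <- res
        } else {
          log <- c(log, sprintf("agreement: kappa %s vs %s test skipped (%s)",
                                pr[1L], pr[2L], res))
        }
      }
    }
  }
  list(table = tab, tests = tests, log = log)
}

#' Bout stage: sleep-stability comparisons on bout durations
#'
#' Extracts bouts from every staging (reference included), compares
#' pooled bout durations between groups within each method and stage
#' (Mann-Whitney U), and compares the scoring methods with a Friedman
#' test on per-subject median bout durations followed by post-hoc U
#' tests on the pooled, stage-aggregated durations of each method pair.
#'
#' @inheritParams run_agreement_stage
#' @return List with `bouts` (one row per bout), `summary` (median/IQR
#'   per method, group and stage), `tests`, `log`.
#' @export
run_bout_stage <- function(x, config = analysis_config()) {
  stopifnot(inherits(x, "cohort"))
  methods <- c(config$reference_method, cohort_methods(x, config))
  log <- character()
  rows <- list()
  for (rec in x$records) {
    for (m in methods) {
      st <- rec$stagings[[m]]
      if (is.null(st)) next
      b <- extract_bouts(st$hypnogram)
      if (!nrow(b)) next
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = rec$subject_id, group = rec$group,
                   method = m, b)
    }
  }
  bouts <- do.call(rbind, rows)
  rownames(bouts) <- NULL
  agg <- stats::aggregate(duration ~ method + group + stage, data = bouts,
                          FUN = median_iqr)
  summary <- data.frame(agg[, c("method", "group", "stage")],
                        as.data.frame(agg$duration))
  summary <- summary[order(summary$method, summary$group, summary$stage), ]
  rownames(summary) <- NULL
  tests <- list()
  groups <- cohort_groups(x, config)
  stages <- levels(bouts$stage)
  if (length(groups) == 2L) {
    g1 <- groups[1L]; g2 <- groups[2L]
    for (m in methods) {
      for (st in stages) {
        s1 <- bouts$method == m & bouts$group == g1 & bouts$stage == st
        s2 <- bouts$method == m & bouts$group == g2 & bouts$stage == st
        d1 <- test_sample(bouts$duration[s1], bouts$subject_id[s1], config)
        d2 <- test_sample(bouts$duration[s2], bouts$subject_id[s2], config)
        if (length(d1) >= 2L && length(d2) >= 2L) {
          tests[[length(tests) + 1L]] <-
            mann_whitney(d1, d2, sprintf("bout %s [%s]: %s vs %s",
                                         st, m, g1, g2))
        } else {
          log <- c(log, sprintf("bouts: %s [%s] group test skipped (too few bouts)",
                                st, m))
        }
      }
    }
  }
  if (length(methods) >= 3L) {
    # blocks = subjects with all methods; value = median bout duration
    med <- stats::aggregate(duration ~ subject_id + method, data = bouts,
                            FUN = stats::median)
    wide <- stats::reshape(med, idvar = "subject_id", timevar = "method",
                           direction = "wide")
    mat <- as.matrix(wide[, paste0("duration.", methods), drop = FALSE])
    keep <- stats::complete.cases(mat)
    if (sum(keep) >= 2L) {
      tests[[length(tests) + 1L]] <-
        friedman(mat[keep, , drop = FALSE],
                 sprintf("bout durations across methods (%s)",
                         paste(methods, collapse = ", ")))
    }
  }
  if (length(methods) >= 2L) {
    pairs <- utils::combn(methods, 2L, simplify = FALSE)
    for (pr in pairs) {
      s1 <- bouts$method == pr[1L]
      s2 <- bouts$method == pr[2L]
      d1 <- test_sample(bouts$duration[s1], bouts$subject_id[s1], config)
      d2 <- test_sample(bouts$duration[s2], bouts$subject_id[s2], config)
      tests[[length(tests) + 1L]] <-
        mann_whitney(d1, d2, sprintf("bouts aggregated: %s vs %s",
                                     pr[1L], pr[2L]))
    }
  }
  list(bouts = bouts, summary = summary, tests = tests, log = log)
}

#' Hypnodensity stage: ambiguity and transition continuity
#'
#' Pools per-epoch ambiguity across subjects within each group and
#' method — overall and split by the stage the method itself classified
#' — and transition continuity at the method's own transitions. Queues
#' pooled-epoch U tests between groups within each method and between
#' methods within each group, and evaluates the continuity tail
#' fractions at the configured thresholds. Epochs are treated as
#' independent in the pooled tests (a known simplification: they are
#' autocorrelated within a subject).
#'
#' @inheritParams run_agreement_stage
#' @return List with `ambiguity` and `continuity` (epoch/transition
#'   level), `ambiguity_summary`, `continuity_summary`, `tails`,
#'   `tests`, `log`.
#' @export
run_hypnodensity_stage <- function(x, config = analysis_config()) {
  stopifnot(inherits(x, "cohort"))
  methods <- cohort_methods(x, config)
  log <- character()
  amb_rows <- list(); con_rows <- list()
  for (rec in x$records) {
    for (m in methods) {
      st <- rec$stagings[[m]]
      if (is.null(st) || is.null(st$hypnodensity)) {
        log <- c(log, sprintf("hypnodensity: subject %s method '%s' skipped (no hypnodensity)",
                              rec$subject_id, m))
        next
      }
      as_ <- ambiguity_series(st$hypnodensity, st$hypnogram)
      amb_rows[[length(amb_rows) + 1L]] <-
        data.frame(subject_id = rec$subject_id, group = rec$group,
                   method = m, stage = as_$stage, values = as_$values)
      tr <- annotate_transition_continuity(st$hypnodensity, st$hypnogram)
      if (nrow(tr)) {
        con_rows[[length(con_rows) + 1L]] <-
          data.frame(subject_id = rec$subject_id, group = rec$group,
                     method = m, tr)
      }
    }
  }
  if (!length(amb_rows)) stop("no hypnodensities found in cohort")
  amb <- do.call(rbind, amb_rows); rownames(amb) <- NULL
  if (length(con_rows)) {
    con <- do.call(rbind, con_rows); rownames(con) <- NULL
  } else {
    log <- c(log, "hypnodensity: no stage transitions in any record")
    con <- data.frame(subject_id = character(), group = character(),
                      method = character(), boundary_index = integer(),
                      from_stage = character(), to_stage = character(),
                      continuity = numeric())
  }

  summarise_amb <- function(df) {
    overall <- stats::aggregate(values ~ method + group, data = df,
                                FUN = median_iqr)
    overall <- data.frame(overall[, c("method", "group")], stage = "overall",
                          as.data.frame(overall$values))
    by_stage <- stats::aggregate(values ~ method + group + stage, data = df,
                                 FUN = median_iqr)
    by_stage <- data.frame(by_stage[, c("method", "group", "stage")],
                           as.data.frame(by_stage$values))
    out <- rbind(overall, by_stage)
    out <- out[order(out$method, out$group,
                     match(out$stage, c("overall", levels(df$stage)))), ]
    rownames(out) <- NULL
    out
  }
  amb_summary <- summarise_amb(amb)
  if (nrow(con)) {
    con_agg <- stats::aggregate(continuity ~ method + group, data = con,
                                FUN = median_iqr)
    con_summary <- data.frame(con_agg[, c("method", "group")],
                              as.data.frame(con_agg$continuity))
  } else {
    con_summary <- data.frame(method = character(), group = character(),
                              median = numeric(), iqr = numeric(),
                              n = numeric())
  }
  rownames(con_summary) <- NULL

  lo <- config$continuity_tails[1L]; hi <- config$continuity_tails[2L]
  tails <- do.call(rbind, lapply(methods, function(m) {
    v <- con$continuity[con$method == m]
    if (!length(v)) return(NULL)
    tf <- continuity_tail_fractions(v, lo, hi)
    per_group <- do.call(rbind, lapply(cohort_groups(x, config), function(g) {
      vg <- con$continuity[con$method == m & con$group == g]
      if (!length(vg)) return(NULL)
      tg <- continuity_tail_fractions(vg, lo, hi)
      data.frame(method = m, group = g, below = tg[["below"]],
                 above = tg[["above"]], n = length(vg))
    }))
    rbind(data.frame(method = m, group = "all", below = tf[["below"]],
                     above = tf[["above"]], n = length(v)), per_group)
  }))
  if (is.null(tails)) {
    tails <- data.frame(method = character(), group = character(),
                        below = numeric(), above = numeric(), n = numeric())
  }
  rownames(tails) <- NULL

  tests <- list()
  groups <- cohort_groups(x, config)
  stages <- levels(amb$stage)
  if (length(groups) == 2L) {
    g1 <- groups[1L]; g2 <- groups[2L]
    for (m in methods) {
      s1 <- amb$method == m & amb$group == g1
      s2 <- amb$method == m & amb$group == g2
      a1 <- test_sample(amb$values[s1], amb$subject_id[s1], config)
      a2 <- test_sample(amb$values[s2], amb$subject_id[s2], config)
      if (length(a1) >= 2L && length(a2) >= 2L) {
        tests[[length(tests) + 1L]] <-
          mann_whitney(a1, a2, sprintf("ambiguity overall [%s]: %s vs %s",
                                       m, g1, g2))
      }
      for (st in stages) {
        t1 <- s1 & amb$stage == st
        t2 <- s2 & amb$stage == st
        v1 <- test_sample(amb$values[t1], amb$subject_id[t1], config)
        v2 <- test_sample(amb$values[t2], amb$subject_id[t2], config)
        if (length(v1) >= 2L && length(v2) >= 2L) {
          tests[[length(tests) + 1L]] <-
            mann_whitney(v1, v2, sprintf("ambiguity %s [%s]: %s vs %s",
                                         st, m, g1, g2))
        } else {
          log <- c(log, sprintf("ambiguity: %s [%s] group test skipped (too few epochs)",
                                st, m))
        }
      }
      k1 <- con$method == m & con$group == g1
      k2 <- con$method == m & con$group == g2
      c1 <- test_sample(con$continuity[k1], con$subject_id[k1], config)
      c2 <- test_sample(con$continuity[k2], con$subject_id[k2], config)
      if (length(c1) >= 2L && length(c2) >= 2L) {
        tests[[length(tests) + 1L]] <-
          mann_whitney(c1, c2, sprintf("continuity [%s]: %s vs %s", m, g1, g2))
      }
    }
  }
  if (length(methods) >= 2L) {
    pairs <- utils::combn(methods, 2L, simplify = FALSE)
    for (pr in pairs) {
      for (g in groups) {
        s1 <- amb$method == pr[1L] & amb$group == g
        s2 <- amb$method == pr[2L] & amb$group == g
        a1 <- test_sample(amb$values[s1], amb$subject_id[s1], config)
        a2 <- test_sample(amb$values[s2], amb$subject_id[s2], config)
        if (length(a1) >= 2L && length(a2) >= 2L) {
          tests[[length(tests) + 1L]] <-
            mann_whitney(a1, a2, sprintf("ambiguity overall [%s]: %s vs %s",
                                         g, pr[1L], pr[2L]))
        }
        k1 <- con$method == pr[1L] & con$group == g
        k2 <- con$method == pr[2L] & con$group == g
        c1 <- test_sample(con$continuity[k1], con$subject_id[k1], config)
        c2 <- test_sample(con$continuity[k2], con$subject_id[k2], config)
        if (length(c1) >= 2L && length(c2) >= 2L) {
          tests[[length(tests) + 1L]] <-
            mann_whitney(c1, c2, sprintf("continuity [%s]: %s vs %s",
                                         g, pr[1L], pr[2L]))
        }
      }
    }
  }
  list(ambiguity = amb, continuity = con,
       ambiguity_summary = amb_summary, continuity_summary = con_summary,
       tails = tails, tests = tests, log = log)
}

#' Run the full analysis
#'
#' Executes the agreement, bout and hypnodensity stages, pools every
#' queued p-value into one Benjamini-Hochberg family at `config$fdr`,
#' and (when `config$output_dir` is set) writes `agreement.csv`,
#' `bouts.csv`, `ambiguity.csv`, `continuity.csv`, `tails.csv`,
#' `tests.csv` and `run.log`. Deterministic: the same cohort and config
#' yield byte-identical tables.
#'
#' @inheritParams run_agreement_stage
#' @return A list of class `analysis_result` with the stage outputs, the
#'   joint `report` ([comparison_report()]) and `counts` (epochs, bouts
#'   and transitions analysed).
#' @export
run_all <- function(x, config = analysis_config()) {
  stopifnot(inherits(x, "cohort"))
  if (!length(x$records)) stop("empty cohort")
  ag <- run_agreement_stage(x, config)
  bo <- run_bout_stage(x, config)
  hy <- run_hypnodensity_stage(x, config)
  tests <- c(ag$tests, bo$tests, hy$tests)
  if (!length(tests)) stop("no tests were queued; cohort too small?")
  report <- comparison_report(tests, fdr = config$fdr)
  counts <- c(epochs = nrow(hy$ambiguity), bouts = nrow(bo$bouts),
              transitions = nrow(hy$continuity))
  run_log <- c(ag$log, bo$log, hy$log,
               sprintf("analysed %d epochs, %d bouts, %d transitions; %d tests in one BH family (FDR %.2f)",
                       counts[["epochs"]], counts[["bouts"]],
                       counts[["transitions"]], nrow(report), config$fdr))
  res <- structure(list(agreement = ag$table, bouts = bo$summary,
                        bouts_raw = bo$bouts,
                        ambiguity = hy$ambiguity_summary,
                        continuity = hy$continuity_summary,
                        tails = hy$tails,
                        ambiguity_raw = hy$ambiguity,
                        continuity_raw = hy$continuity,
                        report = report, counts = counts, log = run_log),
                   class = "analysis_result")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$output_dir, f)
    write_report_table(res$agreement, out("agreement.csv"))
    write_report_table(res$bouts, out("bouts.csv"))
    write_report_table(res$ambiguity, out("ambiguity.csv"))
    write_report_table(res$continuity, out("continuity.csv"))
    write_report_table(res$tails, out("tails.csv"))
    write_report_table(as.data.frame(res$report), out("tests.csv"))
    writeLines(run_log, out("run.log"))
  }
  res
}

#' @export
print.analysis_result <- function(x, ...) {
  cat(sprintf("<analysis_result> %d epochs, %d bouts, %d transitions; %d tests, %d BH-significant\n",
              x$counts[["epochs"]], x$counts[["bouts"]],
              x$counts[["transitions"]], nrow(x$report),
              sum(x$report$significant)))
  invisible(x)
}
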