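#' Read a hypnogram from disk
#'
#' Accepts either plain text (one stage label per line) or a two-column
#' CSV `epoch,stage` with a header and 1-based contiguous epoch indices.
#' Common aliases (Wake, REM, N12, ...) are resolved through a built-in
#' map which can be extended per call.
#'
#' @param path File path.
#' @param stage_set Target [stage_set()], default 4-stage.
#' @param epoch_duration Epoch length in seconds, default 30.
#' @param aliases Optional named character vector of extra label aliases,
#'   e.g. `c("SLEEP-REM" = "R")`.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, stage_set = hypnodense::stage_set("aasm4"),
                           epoch_duration = 30, aliases = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("empty hypnogram file: %s", path))
  if (grepl(",", lines[1L], fixed = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("CSV hypnogram needs columns epoch,stage")
    epoch <- as.integer(df[[1L]])
    if (any(epoch != seq_along(epoch))) {
      stop("non-contiguous epoch indices in hypnogram CSV (expected 1..T)")
    }
    raw <- as.character(df[[2L]])
    offset <- 1L  # header line
  } else {
    raw <- trimws(lines)
    offset <- 0L
  }
  lab <- resolve_stage_labels(raw, stage_set, aliases)
  bad <- which(!lab %in% stage_set)
  if (length(bad)) {
    stop(sprintf("unknown stage label '%s' at line %d of %s",
                 raw[bad[1L]], bad[1L] + offset, path))
  }
  hypnogram(lab, stage_set, epoch_duration)
}

#' Read a hypnodensity from CSV
#'
#' Expects a header `epoch,<stage columns>` where the stage columns are a
#' permutation-free match of the stage set (aliases allowed). Row sums
#' are validated as in [hypnodensity()].
#'
#' @inheritParams read_hypnogram
#' @return A [hypnodensity()].
#' @export
read_hypnodensity <- function(path, stage_set = hypnodense::stage_set("aasm4"),
                              epoch_duration = 30, aliases = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df)) stop(sprintf("empty hypnodensity file: %s", path))
  cols <- resolve_stage_labels(names(df), stage_set, aliases)
  names(df) <- cols
  missing <- setdiff(unclass(stage_set), cols)
  if (length(missing)) {
    stop(sprintf("missing stage column(s) in %s: %s", path,
                 paste(missing, collapse = ", ")))
  }
  if ("epoch" %in% cols) {
    epoch <- as.integer(df[["epoch"]])
    if (any(epoch != seq_along(epoch))) {
      stop("non-contiguous epoch indices in hypnodensity CSV")
    }
  }
  probs <- as.matrix(df[, unclass(stage_set), drop = FALSE])
  hypnodensity(probs, stage_set, epoch_duration)
}

#' Write a hypnogram or hypnodensity to CSV
#'
#' `write_hypnogram()` writes `epoch,stage`; `write_hypnodensity()`
#' writes `epoch,<stage columns>` with full precision. Both round-trip
#' through the matching readers.
#'
#' @param x The object to write.
#' @param path Destination file path.
#' @return Invisibly, `path`.
#' @export
write_hypnogram <- function(x, path) {
  stopifnot(inherits(x, "hypnogram"))
  df <- data.frame(epoch = seq_len(n_epochs(x)),
                   stage = as.character(x$stages))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
write_hypnodensity <- function(x, path) {
  stopifnot(inherits(x, "hypnodensity"))
  df <- data.frame(epoch = seq_len(n_epochs(x)), x$probs,
                   check.names = FALSE)
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a result table as CSV or JSON
#'
#' Generic emitter for pipeline outputs. Column order is preserved as
#' given (deterministic); list-columns are not supported. Format is
#' inferred from the file extension (`.csv` or `.json`).
#'
#' @param rows A data frame.
#' @param path Destination path ending in `.csv` or `.json`.
#' @return Invisibly, `path`.
#' @export
write_report_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(rows, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(rows, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE, pretty = TRUE)
  } else {
    stop(sprintf("unsupported report extension '.%s' (use .csv or .json)", ext))
  }
  invisible(path)
}

#' Assemble a subject record
#'
#' Bundles one subject's stagings by scoring method. The reference
#' ("manual") method carries only a hypnogram — a single human scorer
#' produces no probability distribution — while automated methods carry
#' a hypnogram and usually a hypnodensity. Stagings of unequal length
#' are truncated to the common minimum with a message, since concurrent
#' recordings may differ by trailing epochs.
#'
#' @param subject_id Unique subject identifier.
#' @param group Group label, e.g. `"rbd_like"` / `"osa_like"`.
#' @param stagings Named list; each element is a list with `$hypnogram`
#'   (required) and optional `$hypnodensity`.
#' @param metadata Optional named list of numeric covariates
#'   (age in years, ahi in events/hour, rai in \[0, 1\]).
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, group, stagings, metadata = list()) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            is.list(stagings), length(stagings) >= 1L,
            !is.null(names(stagings)))
  durs <- vapply(stagings, function(s) s$hypnogram$epoch_duration, numeric(1))
  if (length(unique(durs)) != 1L) {
    stop(sprintf("subject %s: stagings disagree on epoch_duration", subject_id))
  }
  lens <- vapply(stagings, function(s) {
    n <- n_epochs(s$hypnogram)
    if (!is.null(s$hypnodensity)) {
      if (n_epochs(s$hypnodensity) != n) {
        stop(sprintf("subject %s: hypnogram/hypnodensity length mismatch",
                     subject_id))
      }
    }
    n
  }, integer(1))
  tmin <- min(lens)
  if (any(lens > tmin)) {
    message(sprintf("subject %s: truncating %d staging(s) to %d epochs",
                    subject_id, sum(lens > tmin), tmin))
    stagings <- lapply(stagings, function(s) {
      s$hypnogram <- hypnogram(as.character(s$hypnogram$stages)[seq_len(tmin)],
                               s$hypnogram$stage_set,
                               s$hypnogram$epoch_duration)
      if (!is.null(s$hypnodensity)) {
        s$hypnodensity <- hypnodensity(
          s$hypnodensity$probs[seq_len(tmin), , drop = FALSE],
          s$hypnodensity$stage_set, s$hypnodensity$epoch_duration)
      }
      s
    })
  }
  structure(list(subject_id = subject_id, group = as.character(group),
                 stagings = stagings, metadata = metadata),
            class = "subject_record")
}

#' Assemble a cohort
#'
#' @param records List of [subject_record()] objects with unique ids.
#' @param name Cohort name.
#' @return An object of class `cohort`.
#' @export
cohort <- function(records, name = "cohort") {
  ids <- vapply(records, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate subject_id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  structure(list(records = records, name = name), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  groups <- vapply(x$records, `[[`, character(1), "group")
  cat(sprintf("<cohort '%s'> %d subjects\n", x$name, length(x$records)))
  print(table(groups))
  invisible(x)
}

#' Write a cohort to a directory
#'
#' Emits one CSV per staging plus a JSON manifest listing subject ids,
#' groups, per-method file paths and metadata. The layout round-trips
#' through [read_cohort()].
#'
#' @param x A `cohort`.
#' @param dir Destination directory (created if absent).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- lapply(x$records, function(rec) {
    methods <- lapply(names(rec$stagings), function(m) {
      s <- rec$stagings[[m]]
      hg <- file.path(dir, sprintf("%s_%s_hypnogram.csv", rec$subject_id, m))
      write_hypnogram(s$hypnogram, hg)
      entry <- list(hypnogram = basename(hg))
      if (!is.null(s$hypnodensity)) {
        hd <- file.path(dir, sprintf("%s_%s_hypnodensity.csv",
                                     rec$subject_id, m))
        write_hypnodensity(s$hypnodensity, hd)
        entry$hypnodensity <- basename(hd)
      }
      entry
    })
    names(methods) <- names(rec$stagings)
    list(subject_id = rec$subject_id, group = rec$group,
         stagings = methods, metadata = rec$metadata)
  })
  ed <- x$records[[1L]]$stagings[[1L]]$hypnogram$epoch_duration
  ss <- stage_set_name(x$records[[1L]]$stagings[[1L]]$hypnogram$stage_set)
  manifest <- list(name = x$name, stage_set = ss, epoch_duration = ed,
                   subjects = subjects)
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mf)
}

#' Read a cohort from a manifest
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [write_cohort()] (paths are resolved relative to the manifest).
#' @return A [cohort()].
#' @export
read_cohort <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  ss <- stage_set(m$stage_set)
  ed <- as.numeric(m$epoch_duration)
  records <- lapply(m$subjects, function(sub) {
    stagings <- lapply(sub$stagings, function(entry) {
      s <- list(hypnogram = read_hypnogram(file.path(dir, entry$hypnogram),
                                           ss, ed))
      if (!is.null(entry$hypnodensity)) {
        s$hypnodensity <- read_hypnodensity(
          file.path(dir, entry$hypnodensity), ss, ed)
      }
      s
    })
    names(stagings) <- names(sub$stagings)
    subject_record(sub$subject_id, sub$group, stagings,
                   metadata = lapply(sub$metadata, as.numeric))
  })
  cohort(records, name = m$name %||% "cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
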