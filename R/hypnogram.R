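#' Construct a hypnogram
#'
#' A hypnogram is the conventional discrete representation of sleep
#' macrostructure: one stage label per scoring epoch (30 s by AASM
#' convention). Stages are stored as a factor whose levels are exactly
#' the declared stage set, so containers with different alphabets can
#' never be silently combined.
#'
#' @param stages Character vector (or factor) of stage labels, length
#'   `T >= 1`. Every element must belong to `stage_set`.
#' @param stage_set A [stage_set()]; defaults to the 4-stage alphabet.
#' @param epoch_duration Epoch length in seconds (> 0), default 30.
#' @return An object of class `hypnogram`.
#' @examples
#' h <- hypnogram(c("W", "W", "N1+N2", "R"))
#' n_epochs(h)
#' @export
hypnogram <- function(stages, stage_set = hypnodense::stage_set("aasm4"),
                      epoch_duration = 30) {
  stopifnot(is_stage_set(stage_set))
  if (length(stages) < 1L) stop("hypnogram must contain at least one epoch")
  if (!is.numeric(epoch_duration) || length(epoch_duration) != 1L ||
      epoch_duration <= 0) {
    stop("epoch_duration must be a single positive number of seconds")
  }
  stages <- as.character(stages)
  bad <- which(!stages %in% stage_set)
  if (length(bad)) {
    stop(sprintf("unknown stage label(s) %s at epoch(s) %s (stage set: %s)",
                 paste(unique(stages[bad]), collapse = ", "),
                 paste(utils::head(bad, 5L), collapse = ", "),
                 paste(stage_set, collapse = " ")))
  }
  structure(
    list(stages = factor(stages, levels = unclass(stage_set)),
         stage_set = stage_set,
         epoch_duration = as.numeric(epoch_duration)),
    class = "hypnogram"
  )
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs x %gs, stage set '%s'\n",
              n_epochs(x), x$epoch_duration, stage_set_name(x$stage_set)))
  tab <- table(x$stages)
  cat(paste(sprintf("%s:%d", names(tab), tab), collapse = "  "), "\n")
  invisible(x)
}

#' Number of scoring epochs in a container
#'
#' @param x A `hypnogram` or `hypnodensity`.
#' @return Integer epoch count.
#' @export
n_epochs <- function(x) UseMethod("n_epochs")

#' @export
n_epochs.hypnogram <- function(x) length(x$stages)

#' @export
n_epochs.hypnodensity <- function(x) nrow(x$probs)

#' Construct a hypnodensity
#'
#' A hypnodensity is the epoch-by-epoch probability distribution over
#' sleep stages produced by an automated classifier; the usual hypnogram
#' is its per-epoch argmax trace. Rows must be valid probability
#' vectors: entries in \[0, 1\] and row sums of 1. Row sums within
#' `renorm_tol` of 1 are renormalised (CSV rounding); deviations beyond
#' `reject_tol` are an error (corrupt input). Deviations between the two
#' tolerances are renormalised with a warning.
#'
#' @param probs Numeric `T x K` matrix, `K = length(stage_set)`.
#' @param stage_set A [stage_set()], default 4-stage.
#' @param epoch_duration Epoch length in seconds, default 30.
#' @param renorm_tol Silent renormalisation band (default `1e-6`).
#' @param reject_tol Rejection threshold on `|rowsum - 1|` (default `1e-3`).
#' @return An object of class `hypnodensity`.
#' @examples
#' hd <- hypnodensity(rbind(c(1, 0, 0, 0), rep(0.25, 4)))
#' ambiguity_series(hd)$values
#' @export
hypnodensity <- function(probs, stage_set = hypnodense::stage_set("aasm4"),
                         epoch_duration = 30,
                         renorm_tol = 1e-6, reject_tol = 1e-3) {
  stopifnot(is_stage_set(stage_set))
  probs <- as.matrix(probs)
  storage.mode(probs) <- "double"
  if (nrow(probs) < 1L) stop("hypnodensity must contain at least one epoch")
  if (ncol(probs) != length(stage_set)) {
    stop(sprintf("expected %d stage columns, got %d",
                 length(stage_set), ncol(probs)))
  }
  if (anyNA(probs)) stop("hypnodensity contains missing probabilities")
  if (any(probs < 0)) {
    stop(sprintf("negative probability at epoch %d",
                 which(apply(probs < 0, 1L, any))[1L]))
  }
  if (any(probs > 1 + reject_tol)) stop("probability greater than 1")
  rs <- rowSums(probs)
  dev <- abs(rs - 1)
  if (any(dev > reject_tol)) {
    i <- which(dev > reject_tol)[1L]
    stop(sprintf("row %d sums to %.6f (deviation %.2g exceeds %.0e)",
                 i, rs[i], dev[i], reject_tol))
  }
  if (any(dev > renorm_tol)) {
    warning(sprintf("%d row sum(s) deviated from 1 by more than %.0e; renormalised",
                    sum(dev > renorm_tol), renorm_tol))
  }
  off <- dev > 0
  if (any(off)) probs[off, ] <- probs[off, , drop = FALSE] / rs[off]
  colnames(probs) <- unclass(stage_set)
  structure(
    list(probs = probs, stage_set = stage_set,
         epoch_duration = as.numeric(epoch_duration)),
    class = "hypnodensity"
  )
}

#' @export
print.hypnodensity <- function(x, ...) {
  cat(sprintf("<hypnodensity> %d epochs x %d stages (%s), %gs epochs\n",
              n_epochs(x), ncol(x$probs),
              paste(colnames(x$probs), collapse = " "), x$epoch_duration))
  invisible(x)
}

check_paired <- function(hd, staging) {
  stopifnot(inherits(hd, "hypnodensity"), inherits(staging, "hypnogram"))
  if (!same_stage_set(hd$stage_set, staging$stage_set)) {
    stop("hypnodensity and hypnogram use different stage sets")
  }
  if (n_epochs(hd) != n_epochs(staging)) {
    stop(sprintf("length mismatch: hypnodensity has %d epochs, hypnogram %d",
                 n_epochs(hd), n_epochs(staging)))
  }
  invisible(TRUE)
}

#' Collapse a 5-stage container to the 4-stage alphabet
#'
#' Merges N1 and N2 into a single N1+N2 class. For hypnograms both
#' labels map to N1+N2; for hypnodensities the N1+N2 column is the
#' elementwise sum of the N1 and N2 columns, so row sums are preserved
#' exactly.
#'
#' @param x A 5-stage `hypnogram` or `hypnodensity`.
#' @return The same kind of object on the 4-stage set.
#' @export
collapse_to_4stage <- function(x) UseMethod("collapse_to_4stage")

#' @export
collapse_to_4stage.hypnogram <- function(x) {
  if (stage_set_name(x$stage_set) != "aasm5") {
    stop("input is already on the 4-stage set")
  }
  lab <- as.character(x$stages)
  lab[lab %in% c("N1", "N2")] <- "N1+N2"
  hypnogram(lab, stage_set("aasm4"), x$epoch_duration)
}

#' @export
collapse_to_4stage.hypnodensity <- function(x) {
  if (stage_set_name(x$stage_set) != "aasm5") {
    stop("input is already on the 4-stage set")
  }
  p <- x$probs
  collapsed <- cbind(W = p[, "W"],
                     `N1+N2` = p[, "N1"] + p[, "N2"],
                     N3 = p[, "N3"],
                     R = p[, "R"])
  hypnodensity(collapsed, stage_set("aasm4"), x$epoch_duration)
}

#' Derive the argmax hypnogram from a hypnodensity
#'
#' Assigns to each epoch the stage with the highest probability. Exact
#' ties are broken by stage-set order (earlier stage wins: W over N1+N2
#' over N3 over R on the 4-stage set). Classifiers that resolve epochs
#' through an undisclosed internal hierarchy rather than the argmax can
#' instead supply their own hypnogram alongside the hypnodensity; all
#' analysis functions accept an explicit staging.
#'
#' @param hd A `hypnodensity`.
#' @return A `hypnogram` on the same stage set and epoch duration.
#' @export
hypnogram_from_hypnodensity <- function(hd) {
  stopifnot(inherits(hd, "hypnodensity"))
  idx <- max.col(hd$probs, ties.method = "first")
  hypnogram(colnames(hd$probs)[idx], hd$stage_set, hd$epoch_duration)
}
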