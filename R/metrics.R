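#' Per-epoch ambiguity: normalised Shannon entropy
#'
#' Quantifies the spread of one epoch's stage probability distribution:
#' \deqn{A(p) = -\frac{1}{\log K} \sum_i p_i \log p_i}
#' with the convention \eqn{0 \log 0 = 0}. The normaliser \eqn{\log K}
#' (K = 4 for 4-stage scoring) maps the entropy to \[0, 1\]: a one-hot
#' vector (the classifier is certain) scores 0 and the uniform vector
#' scores 1. With K = 4 a value above 0.5 requires non-zero probability
#' on at least three stages, and above log 3 / log 4 (about 0.79) on all
#' four; these support thresholds make the score directly interpretable.
#' Natural logarithms are used in both the sum and the normaliser; the
#' result is base-invariant as long as the two match.
#'
#' @param p Numeric probability vector, length K >= 2, entries >= 0,
#'   summing to 1 within `tol`.
#' @param tol Validation tolerance on `sum(p) - 1` (default `1e-6`).
#' @return A value in \[0, 1\].
#' @examples
#' ambiguity(c(1, 0, 0, 0))       # 0
#' ambiguity(rep(0.25, 4))        # 1
#' ambiguity(c(0.5, 0.5, 0, 0))   # 0.5
#' @export
ambiguity <- function(p, tol = 1e-6) {
  check_prob_vector(p, tol)
  k <- length(p)
  nz <- p[p > 0]
  ent <- -sum(nz * log(nz))
  val <- ent / log(k) + 0  # + 0 normalises IEEE negative zero
  min(max(val, 0), 1)
}

check_prob_vector <- function(p, tol = 1e-6) {
  if (!is.numeric(p) || length(p) < 2L) {
    stop("probability vector must be numeric with at least 2 entries")
  }
  if (anyNA(p) || any(p < 0) || any(p > 1 + tol)) {
    stop("probability vector entries must lie in [0, 1]")
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("probability vector sums to %.8f, not 1", sum(p)))
  }
  invisible(TRUE)
}

#' Ambiguity of every epoch in a hypnodensity
#'
#' Computes the normalised-entropy ambiguity per epoch and tags each
#' value with the stage that the *same* classifier assigned to that
#' epoch, so stage-specific summaries group epochs by the model's own
#' classification, not by a reference scorer. When no staging is given
#' the argmax hypnogram of `hd` is used.
#'
#' @param hd A [hypnodensity()].
#' @param staging Optional [hypnogram()] giving the classified stage per
#'   epoch (same length and stage set); defaults to
#'   [hypnogram_from_hypnodensity()].
#' @return A data frame with columns `epoch` (1-based), `stage`
#'   (factor on the stage set) and `values` in \[0, 1\], of class
#'   `ambiguity_series`.
#' @export
ambiguity_series <- function(hd, staging = NULL) {
  stopifnot(inherits(hd, "hypnodensity"))
  if (is.null(staging)) staging <- hypnogram_from_hypnodensity(hd)
  check_paired(hd, staging)
  p <- hd$probs
  pl <- p * log(p)
  pl[p == 0] <- 0
  vals <- pmin(pmax(-rowSums(pl) / log(ncol(p)) + 0, 0), 1)
  out <- data.frame(epoch = seq_len(nrow(p)),
                    stage = staging$stages,
                    values = vals)
  class(out) <- c("ambiguity_series", "data.frame")
  out
}

#' Detect stage transitions in a hypnogram
#'
#' A transition is an adjacent pair of epochs with different stages. The
#' boundary index is 0-based and names the epoch *before* the change:
#' boundary `t` lies between epochs `t` and `t + 1`.
#'
#' @param h A [hypnogram()] with at least 2 epochs.
#' @return A data frame with columns `boundary_index`, `from_stage`,
#'   `to_stage` and `continuity` (`NA` until annotated), one row per
#'   transition in temporal order; zero rows for a constant hypnogram.
#' @export
detect_transitions <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  if (n_epochs(h) < 2L) stop("need at least 2 epochs to detect transitions")
  s <- as.integer(h$stages)
  idx <- which(s[-1L] != s[-length(s)])  # 1-based epoch before the change
  lev <- levels(h$stages)
  data.frame(
    boundary_index = idx - 1L,
    from_stage = factor(lev[s[idx]], levels = lev),
    to_stage = factor(lev[s[idx + 1L]], levels = lev),
    continuity = rep(NA_real_, length(idx))
  )
}

#' Transition continuity between two adjacent probability vectors
#'
#' One minus the total-variation distance between the stage probability
#' vectors flanking a stage transition:
#' \deqn{C = 1 - \tfrac{1}{2} \sum_i |p_i^{t} - p_i^{t+1}|}
#' The two epochs are the ones immediately before and after the boundary
#' (superscripts t and t + 1). Continuity is 1 when the distribution
#' does not change across the transition and 0 at maximal change
#' (disjoint supports, e.g. two different one-hot vectors).
#'
#' @param p_before,p_after Probability vectors of equal length K.
#' @param tol Validation tolerance, as in [ambiguity()].
#' @return A value in \[0, 1\].
#' @examples
#' transition_continuity(c(1, 0, 0, 0), c(0, 1, 0, 0))  # 0
#' transition_continuity(rep(0.25, 4), rep(0.25, 4))    # 1
#' @export
transition_continuity <- function(p_before, p_after, tol = 1e-6) {
  check_prob_vector(p_before, tol)
  check_prob_vector(p_after, tol)
  if (length(p_before) != length(p_after)) {
    stop("probability vectors have different lengths")
  }
  val <- 1 - 0.5 * sum(abs(p_before - p_after))
  min(max(val, 0), 1)
}

#' Annotate a staging's transitions with hypnodensity continuity
#'
#' Detects the transitions of `staging` (normally the same classifier's
#' hypnogram) and fills each with the continuity computed from the
#' hypnodensity rows flanking the boundary.
#'
#' @param hd A [hypnodensity()].
#' @param staging Optional paired [hypnogram()]; defaults to the argmax
#'   hypnogram of `hd`.
#' @return The data frame of [detect_transitions()] with `continuity`
#'   filled in.
#' @export
annotate_transition_continuity <- function(hd, staging = NULL) {
  stopifnot(inherits(hd, "hypnodensity"))
  if (is.null(staging)) staging <- hypnogram_from_hypnodensity(hd)
  check_paired(hd, staging)
  tr <- detect_transitions(staging)
  if (nrow(tr)) {
    t0 <- tr$boundary_index + 1L  # 1-based row of the epoch before
    d <- abs(hd$probs[t0, , drop = FALSE] - hd$probs[t0 + 1L, , drop = FALSE])
    tr$continuity <- pmin(pmax(1 - 0.5 * rowSums(d), 0), 1)
  }
  tr
}

#' Extract bouts (stage runs) from a hypnogram
#'
#' A bout is a maximal run of consecutive epochs in the same stage; its
#' duration is the standard sleep-stability measure. This is the
#' run-length encoding of the hypnogram: bouts partition the record, so
#' total bout time equals recording time. The (possibly censored) runs
#' at the start and end of the recording are kept by default.
#'
#' @param h A [hypnogram()].
#' @param drop_edges If `TRUE`, drop the first and last run (they are
#'   censored: the recording window clips them). Default `FALSE`.
#' @return A data frame with columns `stage`, `start_epoch` (0-based),
#'   `length_epochs` and `duration` (minutes).
#' @export
extract_bouts <- function(h, drop_edges = FALSE) {
  stopifnot(inherits(h, "hypnogram"))
  r <- rle(as.integer(h$stages))
  lev <- levels(h$stages)
  out <- data.frame(
    stage = factor(lev[r$values], levels = lev),
    start_epoch = cumsum(c(0L, r$lengths[-length(r$lengths)])),
    length_epochs = r$lengths,
    duration = r$lengths * h$epoch_duration / 60
  )
  if (drop_edges && nrow(out) > 0L) {
    keep <- setdiff(seq_len(nrow(out)), c(1L, nrow(out)))
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Tail fractions of transition continuity
#'
#' Fractions of transitions with continuity below `low` and above
#' `high`. The low tail marks abrupt distribution shifts (clear,
#' unambiguous stage changes); the high tail marks transitions where the
#' distribution barely moved (the argmax flipped on a small change).
#'
#' @param transitions Data frame from [annotate_transition_continuity()]
#'   (or any data frame with a complete `continuity` column), or a bare
#'   numeric vector of continuity values.
#' @param low,high Thresholds in \[0, 1\] with `low < high`; defaults
#'   0.05 and 0.95.
#' @return Named numeric vector `c(below = ..., above = ...)`.
#' @export
continuity_tail_fractions <- function(transitions, low = 0.05, high = 0.95) {
  stopifnot(low >= 0, high <= 1, low < high)
  vals <- if (is.data.frame(transitions)) transitions$continuity else transitions
  if (is.null(vals) || !length(vals)) {
    stop("no transitions: tail fractions are undefined")
  }
  if (anyNA(vals)) stop("transitions carry missing continuity values")
  c(below = mean(vals < low), above = mean(vals > high))
}
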