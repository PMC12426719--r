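#' Confusion matrix between two stagings
#'
#' Epoch-by-epoch cross-tabulation of a reference staging (rows,
#' normally the manual scorer) against a test staging (columns, normally
#' an automated classifier). Both hypnograms must share length and stage
#' set; all stages of the set appear in the margins even when absent.
#'
#' @param ref,test Paired [hypnogram()]s.
#' @return A `K x K` integer matrix of class `confusion_matrix` with the
#'   stage set attached as attribute `stage_set`.
#' @export
confusion <- function(ref, test) {
  stopifnot(inherits(ref, "hypnogram"), inherits(test, "hypnogram"))
  if (!same_stage_set(ref$stage_set, test$stage_set)) {
    stop("reference and test hypnograms use different stage sets")
  }
  if (n_epochs(ref) != n_epochs(test)) {
    stop(sprintf("length mismatch: reference %d epochs, test %d",
                 n_epochs(ref), n_epochs(test)))
  }
  cm <- table(ref = ref$stages, test = test$stages)
  cm <- matrix(as.integer(cm), nrow = nrow(cm),
               dimnames = list(ref = rownames(cm), test = colnames(cm)))
  structure(cm, stage_set = ref$stage_set, class = c("confusion_matrix", "matrix"))
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected multi-class agreement:
#' \deqn{\kappa = (p_o - p_e) / (1 - p_e)}
#' where \eqn{p_o} is observed agreement (the diagonal fraction) and
#' \eqn{p_e = \sum_k r_k c_k / T^2} the agreement expected from the row
#' and column margins alone. When the margins force agreement
#' (\eqn{p_e = 1}, e.g. both scorers constant on one stage) kappa is
#' undefined and `NA` is returned.
#'
#' @param cm A [confusion()] matrix (any non-negative square count
#'   matrix works).
#' @return Kappa in \[-1, 1\], or `NA` when undefined.
#' @export
cohens_kappa <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (1 - pe < .Machine$double.eps^0.5) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Per-class sensitivity, PPV and F1
#'
#' For each stage k: sensitivity (recall) = TP / (TP + FN) over the
#' reference rows, positive predictive value (precision) = TP / (TP +
#' FP) over the test columns, and F1 their harmonic mean. A stage absent
#' from both scorers has all three undefined (`NA`) rather than 0, so
#' short records do not fabricate performance for stages they never
#' contain. A stage present in the reference but never predicted gets
#' sensitivity 0, undefined PPV, and F1 = 0.
#'
#' @param cm A [confusion()] matrix.
#' @return Data frame with columns `stage`, `sensitivity`, `ppv`, `f1`.
#' @export
per_class_scores <- function(cm) {
  m <- unclass(cm)
  if (sum(m) <= 0) stop("empty confusion matrix")
  tp <- diag(m)
  ref_n <- rowSums(m)
  pred_n <- colSums(m)
  sens <- ifelse(ref_n > 0, tp / ref_n, NA_real_)
  ppv <- ifelse(pred_n > 0, tp / pred_n, NA_real_)
  f1 <- mapply(function(s, p) {
    if (is.na(s) && is.na(p)) return(NA_real_)   # stage absent everywhere
    if (!is.na(s) && s == 0) return(0)            # present but never recovered
    if (is.na(s) || is.na(p)) return(NA_real_)
    if (s + p == 0) return(0)
    2 * s * p / (s + p)
  }, sens, ppv)
  data.frame(stage = rownames(m), sensitivity = unname(sens),
             ppv = unname(ppv), f1 = unname(f1))
}

#' Agreement summary between a reference and a test staging
#'
#' Convenience wrapper returning kappa, per-class scores and the epoch
#' count in one object.
#'
#' @inheritParams confusion
#' @return A list of class `agreement_result` with elements `kappa`,
#'   `per_class`, `n_epochs` and `confusion`.
#' @export
agreement <- function(ref, test) {
  cm <- confusion(ref, test)
  structure(list(kappa = cohens_kappa(cm),
                 per_class = per_class_scores(cm),
                 n_epochs = sum(cm),
                 confusion = cm),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement> kappa = %.3f over %d epochs\n", x$kappa, x$n_epochs))
  print(x$per_class, digits = 3)
  invisible(x)
}
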