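#' Per-subtype concordance of two labellings
#'
#' Evaluates a test labelling against a reference labelling one subtype at
#' a time, one-vs-rest: a sample is positive for a subtype iff it carries
#' that label, and negative otherwise — including when it is UNCLASSIFIED.
#' Sensitivity is TP / (TP + FN) and specificity TN / (TN + FP); a
#' zero denominator yields `NA` (undefined), never 0. Unclassified
#' reference samples are kept as negatives by default, so a test call on a
#' reference-unclassified sample costs specificity; set
#' `exclude_unclassified_reference = TRUE` to drop them from all
#' denominators instead.
#'
#' @param test,reference Labellings over the same samples: named character
#'   vectors (names = sample IDs), data.frames with `sample`/`label`
#'   columns, or `"subtype_calls"` objects. When the sample sets differ,
#'   the intersection is used with a warning; an empty intersection is an
#'   error.
#' @param subtypes Subtypes to evaluate; defaults to the five genetic
#'   subtypes.
#' @param exclude_unclassified_reference Drop reference-UNCLASSIFIED
#'   samples before counting.
#' @return A list of class `"concordance_result"` with elements `counts`
#'   (data.frame: subtype, TP, FP, TN, FN, sensitivity, specificity as
#'   fractions), `crosstab` (test x reference contingency table) and
#'   `n` (number of evaluable samples).
#' @export
#' @examples
#' ref <- c(S1 = "MCD", S2 = "MCD", S3 = "EZB")
#' tst <- c(S1 = "MCD", S2 = "UNCLASSIFIED", S3 = "EZB")
#' concordance(tst, ref)
concordance <- function(test, reference, subtypes = .SUBTYPES,
                        exclude_unclassified_reference = FALSE) {
  test <- .as_labels(test)
  reference <- .as_labels(reference)
  common <- intersect(names(test), names(reference))
  if (length(common) == 0L) {
    stop("test and reference labellings share no samples", call. = FALSE)
  }
  if (length(common) < length(test) || length(common) < length(reference)) {
    warning("labellings cover different samples; using the ",
            length(common), "-sample intersection", call. = FALSE)
  }
  test <- test[common]
  reference <- reference[common]
  if (exclude_unclassified_reference) {
    keep <- reference != "UNCLASSIFIED"
    test <- test[keep]
    reference <- reference[keep]
    if (length(test) == 0L) {
      stop("no evaluable samples after excluding unclassified reference",
           call. = FALSE)
    }
  }
  n <- length(test)
  counts <- do.call(rbind, lapply(subtypes, function(st) {
    tp <- sum(test == st & reference == st)
    fp <- sum(test == st & reference != st)
    fn <- sum(test != st & reference == st)
    tn <- sum(test != st & reference != st)
    data.frame(subtype = st, TP = tp, FP = fp, TN = tn, FN = fn,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  lev <- unique(c(.LABELS, test, reference))
  structure(list(counts = counts,
                 crosstab = table(test = factor(test, levels = lev),
                                  reference = factor(reference, levels = lev)),
                 n = n),
            class = "concordance_result")
}

## Round half away from zero, as in the reported percentage tables
## (base round() rounds half to even).
.round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a concordance result as a percentage grid
#'
#' @param x A `"concordance_result"`.
#' @return A data.frame with sensitivity/specificity as percentages
#'   rounded (half up) to one decimal; `NA` where undefined.
#' @export
concordance_table <- function(x) {
  stopifnot(inherits(x, "concordance_result"))
  data.frame(subtype = x$counts$subtype,
             sensitivity_pct = .round_half_up(100 * x$counts$sensitivity),
             specificity_pct = .round_half_up(100 * x$counts$specificity),
             stringsAsFactors = FALSE)
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("Concordance over", x$n, "samples (one-vs-rest)\n")
  tab <- concordance_table(x)
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-4s sensitivity %6s  specificity %6s\n",
                tab$subtype[i],
                ifelse(is.na(tab$sensitivity_pct[i]), "--",
                       sprintf("%.1f%%", tab$sensitivity_pct[i])),
                ifelse(is.na(tab$specificity_pct[i]), "--",
                       sprintf("%.1f%%", tab$specificity_pct[i]))))
  }
  invisible(x)
}
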