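#' Per-sample feature set for classification
#'
#' Bundles everything the two-step rule inspects for one sample: the set
#' of genes carrying at least one retained somatic mutation plus the BCL2
#' and BCL6 break-apart FISH statuses.
#'
#' @param sample_id Sample identifier.
#' @param mutated_genes Character vector of mutated gene symbols
#'   (uppercased internally).
#' @param bcl2,bcl6 Translocation status: `"present"`, `"absent"` or
#'   `"unknown"`.
#' @return A list of class `"sample_features"`.
#' @export
sample_features <- function(sample_id, mutated_genes = character(),
                            bcl2 = "unknown", bcl6 = "unknown") {
  stopifnot(bcl2 %in% .TRANSLOC_STATUS, bcl6 %in% .TRANSLOC_STATUS)
  structure(list(sample_id = as.character(sample_id),
                 mutated_genes = unique(.normalize_gene(mutated_genes)),
                 bcl2 = bcl2, bcl6 = bcl6),
            class = "sample_features")
}

#' Evaluate one panel feature on one sample
#'
#' A plain gene symbol scores 1 iff the gene is in the sample's mutated
#' set. `BCL6_TRANSLOC` (resp. `BCL2_TRANSLOC`) scores 1 iff the
#' corresponding FISH status is `"present"`; `"unknown"` scores 0. The
#' `BCL2` feature is special: it scores 1 if the gene is mutated *or* the
#' BCL2 translocation is present — one feature, contributing at most 1 —
#' reflecting the tight coupling of BCL2 mutation and translocation in
#' germinal-center lymphomas. A panel wanting translocation-free BCL2
#' scoring can use a custom symbol plus `BCL2_TRANSLOC` instead.
#'
#' @param feature Feature token: a gene symbol, `"BCL2_TRANSLOC"` or
#'   `"BCL6_TRANSLOC"`.
#' @param sample A [sample_features()] object.
#' @return `0L` or `1L`.
#' @export
feature_hit <- function(feature, sample) {
  .feature_hit(feature, sample)$hit
}

## Internal scorer that also reports whether an unknown FISH status was
## consulted (drives the FISH_UNKNOWN audit flag).
.feature_hit <- function(feature, sample) {
  stopifnot(inherits(sample, "sample_features"))
  if (length(feature) != 1L || is.na(feature) || !nzchar(feature)) {
    stop("invalid feature token", call. = FALSE)
  }
  feature <- .normalize_gene(feature)
  if (feature == "BCL6_TRANSLOC") {
    return(list(hit = as.integer(sample$bcl6 == "present"),
                fish_unknown = sample$bcl6 == "unknown"))
  }
  if (feature == "BCL2_TRANSLOC") {
    return(list(hit = as.integer(sample$bcl2 == "present"),
                fish_unknown = sample$bcl2 == "unknown"))
  }
  if (grepl("_TRANSLOC$", feature)) {
    stop("unknown translocation feature '", feature, "'", call. = FALSE)
  }
  if (feature == "BCL2") {
    mut <- "BCL2" %in% sample$mutated_genes
    return(list(hit = as.integer(mut || sample$bcl2 == "present"),
                fish_unknown = !mut && sample$bcl2 == "unknown"))
  }
  list(hit = as.integer(feature %in% sample$mutated_genes),
       fish_unknown = FALSE)
}

.score_features <- function(features, sample) {
  hits <- lapply(features, .feature_hit, sample = sample)
  list(score = sum(vapply(hits, `[[`, integer(1L), "hit")),
       fish_unknown = any(vapply(hits, `[[`, logical(1L), "fish_unknown")))
}

#' Classify one sample with the two-step rule
#'
#' Step 0 (precedence): a sample hitting any N1 step-1 marker — NOTCH1 in
#' the default panel — is called N1 regardless of every other alteration.
#' Step 1: the step-1 marker hits are counted for MCD, BN2, EZB and ST2;
#' a unique maximum of at least 1 assigns that subtype. Step 2 (reached on
#' a step-1 tie or when no step-1 marker is hit): hits are counted over
#' the union of each subtype's step-1 and step-2 lists, all four non-N1
#' subtypes competing; a unique maximum of at least 2 assigns that
#' subtype. Anything else is UNCLASSIFIED. An unknown FISH status counts
#' as no translocation and raises the `FISH_UNKNOWN` flag on the call.
#'
#' @param sample A [sample_features()] object.
#' @param panel A `"marker_panel"`; defaults to [default_panel()].
#' @return A list of class `"subtype_call"` with elements `sample_id`,
#'   `label`, `decided_at` (`"step1"`, `"step2"` or `"none"`),
#'   `step1_scores` (named integer vector over all five subtypes),
#'   `step2_scores` (over the four non-N1 subtypes, scored on the
#'   combined lists) and `flags`.
#' @export
#' @examples
#' classify_sample(sample_features("S1", c("MYD88", "CD79B")))
classify_sample <- function(sample, panel = default_panel()) {
  stopifnot(inherits(sample, "sample_features"),
            inherits(panel, "marker_panel"))
  flags <- character()
  competing <- setdiff(.SUBTYPES, "N1")

  s1 <- lapply(panel, function(e) .score_features(e$step1, sample))
  step1_scores <- vapply(s1, `[[`, numeric(1L), "score")
  step1_scores <- stats::setNames(as.integer(step1_scores), names(s1))
  if (any(vapply(s1, `[[`, logical(1L), "fish_unknown"))) {
    flags <- "FISH_UNKNOWN"
  }

  make_call <- function(label, decided_at, step2_scores = NULL, flags2 = flags) {
    structure(list(sample_id = sample$sample_id, label = label,
                   decided_at = decided_at, step1_scores = step1_scores,
                   step2_scores = step2_scores, flags = flags2),
              class = "subtype_call")
  }

  # hard N1 precedence, independent of all scores
  if (step1_scores[["N1"]] >= 1L) {
    return(make_call("N1", "step1"))
  }

  sc1 <- step1_scores[competing]
  top1 <- max(sc1)
  if (top1 >= 1L && sum(sc1 == top1) == 1L) {
    return(make_call(competing[which.max(sc1)], "step1"))
  }

  # step 2: combined step1+step2 lists, all four subtypes compete
  s2 <- lapply(panel[competing], function(e) {
    .score_features(c(e$step1, e$step2), sample)
  })
  step2_scores <- vapply(s2, `[[`, numeric(1L), "score")
  step2_scores <- stats::setNames(as.integer(step2_scores), competing)
  if (any(vapply(s2, `[[`, logical(1L), "fish_unknown")) &&
      length(flags) == 0L) {
    flags <- "FISH_UNKNOWN"
  }
  top2 <- max(step2_scores)
  if (top2 >= 2L && sum(step2_scores == top2) == 1L) {
    return(make_call(competing[which.max(step2_scores)], "step2",
                     step2_scores, flags))
  }
  make_call("UNCLASSIFIED", "none", step2_scores, flags)
}

#' Classify a cohort from a mutation matrix and FISH table
#'
#' Applies [classify_sample()] to every row of the matrix, in row order.
#' Panel genes missing from the matrix are treated as wild-type for all
#' samples (with one warning listing them). Samples absent from the FISH
#' table — or the entire table, when `fish = NULL` — get unknown
#' translocation status, flagged `FISH_UNKNOWN` on the call; FISH entries
#' for samples not in the matrix are ignored with a warning, the matrix
#' defining the cohort.
#'
#' @param matrix Binary mutation matrix (samples x genes), e.g. from
#'   [binarize()] or [read_matrix()].
#' @param fish Optional `"fish_table"`.
#' @param panel A `"marker_panel"`.
#' @return A `data.frame` of class `"subtype_calls"`, one row per sample
#'   in matrix order, with columns `sample`, `label`, `decided_at`,
#'   step-1 scores `score_N1` ... `score_ST2`, step-2 scores
#'   `score2_MCD` ... `score2_ST2` (NA when step 2 was not reached) and
#'   `flags` (comma-separated). The per-label summary is available via
#'   [subtype_counts()].
#' @export
classify_cohort <- function(matrix, fish = NULL, panel = default_panel()) {
  .validate_matrix(matrix)
  stopifnot(inherits(panel, "marker_panel"))
  samples <- rownames(matrix) %||% character()

  missing_genes <- setdiff(panel_genes(panel), colnames(matrix))
  if (length(missing_genes) > 0L) {
    warning("panel gene(s) absent from matrix, treated as wild-type: ",
            paste(missing_genes, collapse = ", "), call. = FALSE)
  }

  if (is.null(fish)) {
    fish <- fish_table(character())
  }
  stopifnot(inherits(fish, "fish_table"))
  extra <- setdiff(fish$sample, samples)
  if (length(extra) > 0L) {
    warning("FISH entry(ies) for sample(s) not in matrix, ignored: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  fish_idx <- match(samples, fish$sample)

  calls <- lapply(seq_along(samples), function(i) {
    j <- fish_idx[i]
    feats <- sample_features(
      samples[i],
      colnames(matrix)[matrix[i, ] == 1L],
      bcl2 = if (is.na(j)) "unknown" else fish$bcl2[j],
      bcl6 = if (is.na(j)) "unknown" else fish$bcl6[j]
    )
    classify_sample(feats, panel)
  })

  competing <- setdiff(.SUBTYPES, "N1")
  out <- data.frame(
    sample = samples,
    label = vapply(calls, `[[`, character(1L), "label"),
    decided_at = vapply(calls, `[[`, character(1L), "decided_at"),
    stringsAsFactors = FALSE
  )
  for (st in .SUBTYPES) {
    out[[paste0("score_", st)]] <-
      vapply(calls, function(cl) cl$step1_scores[[st]], integer(1L))
  }
  for (st in competing) {
    out[[paste0("score2_", st)]] <- vapply(calls, function(cl) {
      if (is.null(cl$step2_scores)) NA_integer_ else cl$step2_scores[[st]]
    }, integer(1L))
  }
  out$flags <- vapply(calls, function(cl) paste(cl$flags, collapse = ","),
                      character(1L))
  class(out) <- c("subtype_calls", "data.frame")
  out
}

#' Summarize subtype calls
#'
#' @param calls A `"subtype_calls"` data.frame, or anything coercible by
#'   the same label rules as [concordance()].
#' @return Named integer vector of label counts over
#'   N1, MCD, BN2, EZB, ST2, UNCLASSIFIED; sums to the cohort size.
#' @export
#' @examples
#' m <- matrix(0L, 1, 1, dimnames = list("S1", "NOTCH1"))
#' m[1, 1] <- 1L
#' subtype_counts(classify_cohort(m))
subtype_counts <- function(calls) {
  labels <- if (inherits(calls, "subtype_calls")) calls$label
            else unname(.as_labels(calls))
  counts <- table(factor(labels, levels = .LABELS))
  stats::setNames(as.integer(counts), .LABELS)
}

#' @export
print.subtype_calls <- function(x, ...) {
  counts <- subtype_counts(x)
  n <- nrow(x)
  cat("Two-step subtype calls for", n, "samples\n")
  for (lb in names(counts)) {
    cat(sprintf("  %-12s %3d (%.1f%%)\n", lb, counts[[lb]],
                if (n > 0) 100 * counts[[lb]] / n else 0))
  }
  invisible(x)
}

#' Write or read subtype calls as TSV
#'
#' @param calls A `"subtype_calls"` data.frame.
#' @param path Output path.
#' @return `path` (write) or a `"subtype_calls"` data.frame (read).
#' @export
write_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  out <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample", "label") %in% names(out))) {
    stop("calls table must have columns 'sample' and 'label'", call. = FALSE)
  }
  class(out) <- c("subtype_calls", "data.frame")
  out
}
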