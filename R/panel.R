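.TRANSLOC_FEATURES <- c("BCL2_TRANSLOC", "BCL6_TRANSLOC")

#' Marker panel for the two-step classifier
#'
#' A marker panel holds, for each of the five genetic subtypes, an ordered
#' step-1 list (the "top" markers, at least one of which must be hit for a
#' step-1 assignment) and a step-2 list of additional markers (step 2
#' scores the union of both lists and requires at least two hits). A
#' feature is an uppercase gene symbol or one of the translocation markers
#' `BCL2_TRANSLOC` / `BCL6_TRANSLOC`; see [feature_hit()] for how each is
#' evaluated, including the combined mutation-or-translocation semantics
#' of the `BCL2` feature.
#'
#' @param subtypes Named list, one entry per subtype in
#'   `c("N1", "MCD", "BN2", "EZB", "ST2")`, each a list with character
#'   vectors `step1` and `step2`.
#' @return An object of class `"marker_panel"`.
#' @export
marker_panel <- function(subtypes) {
  if (is.null(names(subtypes)) || any(names(subtypes) == "")) {
    stop("panel subtypes must be named", call. = FALSE)
  }
  unknown <- setdiff(names(subtypes), .SUBTYPES)
  if (length(unknown) > 0L) {
    stop("unknown subtype key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(.SUBTYPES, names(subtypes))
  if (length(missing) > 0L) {
    stop("panel is missing subtype(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  panel <- lapply(subtypes[.SUBTYPES], function(entry) {
    step1 <- .normalize_gene(entry$step1 %||% character())
    step2 <- .normalize_gene(entry$step2 %||% character())
    list(step1 = step1, step2 = step2)
  })
  for (st in .SUBTYPES) {
    feats <- c(panel[[st]]$step1, panel[[st]]$step2)
    if (length(panel[[st]]$step1) == 0L) {
      stop("subtype ", st, " has an empty step-1 marker list", call. = FALSE)
    }
    if (anyDuplicated(feats)) {
      stop("duplicate feature(s) within subtype ", st, ": ",
           paste(unique(feats[duplicated(feats)]), collapse = ", "),
           call. = FALSE)
    }
  }
  structure(panel, class = "marker_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The default 26-gene + translocation marker panel
#'
#' The panel shipped with the package: step-1 markers
#' N1 = NOTCH1; MCD = MYD88, CD79B, PIM1; BN2 = BCL6 translocation,
#' NOTCH2, BCL10, TNFAIP3; EZB = BCL2, EZH2, CREBBP; ST2 = SGK1, TET2,
#' SOCS1; step-2 additions MCD = PRDM1, BTG1, PIM2, CD58; BN2 = UBE2A,
#' CD70, CCND3, DTX1; EZB = TNFRSF14, KMT2D, IRF8, EP300; ST2 = STAT3.
#' In total 26 distinct gene symbols plus the BCL6 translocation marker
#' (the BCL2 translocation enters through the combined `BCL2` feature).
#'
#' @return A `"marker_panel"`.
#' @export
#' @examples
#' p <- default_panel()
#' p$N1$step1
#' length(panel_genes(p))
default_panel <- function() {
  marker_panel(list(
    N1 = list(step1 = "NOTCH1", step2 = character()),
    MCD = list(step1 = c("MYD88", "CD79B", "PIM1"),
               step2 = c("PRDM1", "BTG1", "PIM2", "CD58")),
    BN2 = list(step1 = c("BCL6_TRANSLOC", "NOTCH2", "BCL10", "TNFAIP3"),
               step2 = c("UBE2A", "CD70", "CCND3", "DTX1")),
    EZB = list(step1 = c("BCL2", "EZH2", "CREBBP"),
               step2 = c("TNFRSF14", "KMT2D", "IRF8", "EP300")),
    ST2 = list(step1 = c("SGK1", "TET2", "SOCS1"),
               step2 = "STAT3")
  ))
}

#' Distinct gene symbols used by a panel
#'
#' @param panel A `"marker_panel"`.
#' @return Character vector of distinct gene symbols (translocation
#'   markers excluded), in order of first appearance.
#' @export
panel_genes <- function(panel) {
  stopifnot(inherits(panel, "marker_panel"))
  feats <- unlist(lapply(panel, function(e) c(e$step1, e$step2)),
                  use.names = FALSE)
  unique(feats[!feats %in% .TRANSLOC_FEATURES])
}

#' Load or save a marker panel as JSON
#'
#' The JSON schema is an object keyed by subtype, each value an object
#' with `step1` and `step2` string arrays, e.g.
#' `{"MCD": {"step1": ["MYD88", ...], "step2": [...]}, ...}`. All panel
#' invariants (known subtype keys, non-empty step-1 lists, no duplicated
#' feature within a subtype) are enforced on load.
#'
#' @param path Path to a JSON file.
#' @return For `load_panel`, a `"marker_panel"`; for `save_panel`, `path`
#'   invisibly.
#' @export
load_panel <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- lapply(raw, function(entry) {
    list(step1 = as.character(entry$step1 %||% character()),
         step2 = as.character(entry$step2 %||% character()))
  })
  marker_panel(raw)
}

#' @rdname load_panel
#' @param panel A `"marker_panel"`.
#' @export
save_panel <- function(panel, path) {
  stopifnot(inherits(panel, "marker_panel"))
  jsonlite::write_json(unclass(panel), path, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Two-step marker panel (", length(panel_genes(x)),
      " genes + translocations)\n", sep = "")
  for (st in names(x)) {
    cat(sprintf("  %-4s step1: %s\n", st,
                paste(x[[st]]$step1, collapse = ", ")))
    if (length(x[[st]]$step2) > 0L) {
      cat(sprintf("       step2: %s\n", paste(x[[st]]$step2, collapse = ", ")))
    }
  }
  invisible(x)
}

#' Rank genes by subtype discrimination with Fisher's exact test
#'
#' Panel-curation utility: for each gene in the matrix, builds the 2x2
#' contingency table of mutation status (mutated / wild-type) against
#' subtype membership (in-subtype / not) over a labelled cohort, and
#' computes the two-sided Fisher exact p-value (the usual convention:
#' total probability of all tables at the observed margins with point
#' probability at most that of the observed table). The shipped
#' [default_panel()] is fixed; this ranking supports curating alternative
#' panels, not re-deriving the default.
#'
#' @param matrix Binary mutation matrix (samples x genes).
#' @param labels Sample-to-subtype mapping: either a named character
#'   vector (names = samples) or a data.frame with columns `sample` and
#'   `label`.
#' @param subtype Subtype defining the positive class; must occur in
#'   `labels`.
#' @return A `data.frame` sorted by ascending p-value (ties broken by
#'   gene symbol) with columns `gene`, `a` (mutated, in-subtype), `b`
#'   (mutated, out), `c` (wild-type, in), `d` (wild-type, out),
#'   `odds_ratio` (`(a*d)/(b*c)`, with `Inf`/`0` on single zero cells and
#'   1 for the degenerate 0/0 case), `p_value`, and `zero_cell`.
#' @export
rank_genes <- function(matrix, labels, subtype) {
  .validate_matrix(matrix)
  labels <- .as_labels(labels)
  absent <- setdiff(names(labels), rownames(matrix))
  if (length(absent) > 0L) {
    stop("labelled sample(s) absent from matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (!subtype %in% labels) {
    stop("subtype '", subtype, "' does not occur in the labels",
         call. = FALSE)
  }
  m <- matrix[names(labels), , drop = FALSE]
  in_sub <- labels == subtype
  res <- lapply(colnames(m), function(g) {
    mut <- m[, g] == 1L
    a <- sum(mut & in_sub)
    b <- sum(mut & !in_sub)
    cc <- sum(!mut & in_sub)
    d <- sum(!mut & !in_sub)
    ad <- a * d
    bc <- b * cc
    if (ad == 0 && bc == 0) {
      or <- 1
      zero <- TRUE
    } else if (bc == 0) {
      or <- Inf
      zero <- TRUE
    } else if (ad == 0) {
      or <- 0
      zero <- TRUE
    } else {
      or <- ad / bc
      zero <- FALSE
    }
    p <- stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2L,
                                   byrow = TRUE))$p.value
    data.frame(gene = g, a = a, b = b, c = cc, d = d, odds_ratio = or,
               p_value = p, zero_cell = zero, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p_value, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Coerce a labelling (named vector or sample/label data.frame) to a
## named character vector.
.as_labels <- function(labels) {
  if (is.data.frame(labels)) {
    cols <- tolower(names(labels))
    si <- match("sample", cols)
    li <- match("label", cols)
    if (is.na(si) || is.na(li)) {
      stop("label data.frame must have columns 'sample' and 'label'",
           call. = FALSE)
    }
    labels <- stats::setNames(as.character(labels[[li]]),
                              as.character(labels[[si]]))
  }
  if (is.factor(labels)) labels <- stats::setNames(as.character(labels),
                                                   names(labels))
  if (is.null(names(labels))) {
    stop("labels must be named by sample identifier", call. = FALSE)
  }
  if (anyDuplicated(names(labels))) {
    stop("duplicate sample identifier(s) in labels", call. = FALSE)
  }
  labels
}
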