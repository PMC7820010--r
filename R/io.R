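## Controlled vocabularies shared across the package.
.SUBTYPES <- c("N1", "MCD", "BN2", "EZB", "ST2")
.LABELS <- c(.SUBTYPES, "UNCLASSIFIED")
.EFFECTS <- c("nonsynonymous_SNV", "stopgain", "stoploss", "splicing",
              "frameshift_indel", "nonframeshift_indel", "synonymous_SNV",
              "other")
.NONSYNONYMOUS_EFFECTS <- setdiff(.EFFECTS, c("synonymous_SNV", "other"))
.LOCALIZATIONS <- c("exonic", "UTR5", "UTR3", "splice_site", "intronic",
                    "intergenic", "other")
.TRANSLOC_STATUS <- c("present", "absent", "unknown")

## Token normalization maps. Keys are lowercased input tokens; both
## ANNOVAR-style and MAF Variant_Classification vocabularies are accepted.
.EFFECT_MAP <- c(
  nonsynonymous_snv = "nonsynonymous_SNV",
  missense_mutation = "nonsynonymous_SNV",
  missense = "nonsynonymous_SNV",
  stopgain = "stopgain",
  nonsense_mutation = "stopgain",
  stoploss = "stoploss",
  nonstop_mutation = "stoploss",
  splicing = "splicing",
  splice_site = "splicing",
  frameshift_indel = "frameshift_indel",
  frameshift_insertion = "frameshift_indel",
  frameshift_deletion = "frameshift_indel",
  frame_shift_ins = "frameshift_indel",
  frame_shift_del = "frameshift_indel",
  nonframeshift_indel = "nonframeshift_indel",
  nonframeshift_insertion = "nonframeshift_indel",
  nonframeshift_deletion = "nonframeshift_indel",
  in_frame_ins = "nonframeshift_indel",
  in_frame_del = "nonframeshift_indel",
  synonymous_snv = "synonymous_SNV",
  silent = "synonymous_SNV"
)

.LOCALIZATION_MAP <- c(
  exonic = "exonic",
  utr5 = "UTR5", `5'utr` = "UTR5", `5utr` = "UTR5", `5'flank` = "UTR5",
  utr3 = "UTR3", `3'utr` = "UTR3", `3utr` = "UTR3",
  splicing = "splice_site", splice_site = "splice_site",
  intronic = "intronic", intron = "intronic",
  intergenic = "intergenic"
)

#' Default column mapping for MAF-like variant tables
#'
#' Maps the canonical field names used by [read_variant_table()] to the
#' column names found in the input file. The defaults follow the Mutation
#' Annotation Format (MAF) conventions for the mandatory fields; optional
#' fields default to their canonical names.
#'
#' @return Named character vector: canonical field -> input column name.
#' @export
#' @examples
#' default_dialect()
default_dialect <- function() {
  c(sample = "Tumor_Sample_Barcode",
    gene = "Hugo_Symbol",
    effect = "Variant_Classification",
    localization = "localization",
    total_depth = "t_depth",
    alt_depth = "t_alt_count",
    vaf = "vaf",
    pop_af = "pop_af",
    is_known_snp = "is_known_snp")
}

## Resolve one canonical field to an input column, falling back to the
## canonical name itself when the dialect name is absent from the header.
.resolve_column <- function(field, dialect, header) {
  cand <- unique(c(unname(dialect[field]), field))
  cand <- cand[!is.na(cand)]
  hit <- cand[cand %in% header]
  if (length(hit) == 0L) NA_character_ else hit[[1L]]
}

.normalize_gene <- function(x) toupper(trimws(as.character(x)))

.normalize_token <- function(x, map, default = "other") {
  key <- tolower(trimws(as.character(x)))
  out <- unname(map[key])
  out[is.na(out)] <- default
  out
}

#' Read an annotated somatic variant table
#'
#' Parses a MAF-like TSV/CSV of annotated somatic variant calls into the
#' canonical variant table used by [filter_variants()]. Gene symbols are
#' uppercased and whitespace-stripped; variant effect and localization
#' tokens are normalized from either ANNOVAR- or MAF-style vocabularies.
#'
#' Mandatory input columns (after applying `dialect`): sample, gene,
#' effect, and either both read-depth columns or a VAF column. When the
#' VAF column is absent it is computed as `alt_depth / total_depth`.
#' A missing localization column defaults every record to `"exonic"`;
#' a missing `is_known_snp` column is derived as `!is.na(pop_af)` (a
#' variant with a population allele frequency annotation is treated as a
#' database-listed SNP).
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Named character vector mapping canonical field names to
#'   file column names; see [default_dialect()].
#' @param sep Field separator; `"\t"` by default, use `","` for CSV.
#' @return A `data.frame` of class `"variant_table"` with columns
#'   `sample`, `gene`, `effect`, `localization`, `total_depth`,
#'   `alt_depth`, `vaf`, `pop_af`, `is_known_snp`.
#' @export
read_variant_table <- function(path, dialect = default_dialect(), sep = "\t") {
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", "", "."))
  header <- names(raw)
  dialect <- c(dialect, default_dialect()[setdiff(names(default_dialect()),
                                                  names(dialect))])

  cols <- vapply(c("sample", "gene", "effect", "localization", "total_depth",
                   "alt_depth", "vaf", "pop_af", "is_known_snp"),
                 .resolve_column, character(1L),
                 dialect = dialect, header = header)

  for (field in c("sample", "gene", "effect")) {
    if (is.na(cols[[field]])) {
      stop("variant table is missing a mandatory column for '", field,
           "' (looked for '", dialect[[field]], "')", call. = FALSE)
    }
  }
  has_depths <- !is.na(cols[["total_depth"]]) && !is.na(cols[["alt_depth"]])
  if (!has_depths && is.na(cols[["vaf"]])) {
    stop("variant table must provide read depth columns ('",
         dialect[["total_depth"]], "', '", dialect[["alt_depth"]],
         "') or a VAF column ('", dialect[["vaf"]], "')", call. = FALSE)
  }

  n <- nrow(raw)
  out <- data.frame(
    sample = trimws(as.character(raw[[cols[["sample"]]]])),
    gene = .normalize_gene(raw[[cols[["gene"]]]]),
    effect = .normalize_token(raw[[cols[["effect"]]]], .EFFECT_MAP),
    localization = if (is.na(cols[["localization"]])) {
      rep("exonic", n)
    } else {
      .normalize_token(raw[[cols[["localization"]]]], .LOCALIZATION_MAP)
    },
    total_depth = if (has_depths) {
      as.integer(raw[[cols[["total_depth"]]]])
    } else rep(NA_integer_, n),
    alt_depth = if (has_depths) {
      as.integer(raw[[cols[["alt_depth"]]]])
    } else rep(NA_integer_, n),
    vaf = if (!is.na(cols[["vaf"]])) {
      as.numeric(raw[[cols[["vaf"]]]])
    } else rep(NA_real_, n),
    pop_af = if (!is.na(cols[["pop_af"]])) {
      as.numeric(raw[[cols[["pop_af"]]]])
    } else rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  if (is.na(cols[["is_known_snp"]])) {
    out$is_known_snp <- !is.na(out$pop_af)
  } else {
    tok <- tolower(trimws(as.character(raw[[cols[["is_known_snp"]]]])))
    out$is_known_snp <- tok %in% c("true", "t", "yes", "1")
  }
  missing_vaf <- is.na(out$vaf)
  out$vaf[missing_vaf] <- out$alt_depth[missing_vaf] /
    out$total_depth[missing_vaf]

  .validate_variant_table(out)
  class(out) <- c("variant_table", "data.frame")
  out
}

## Invariant checks; reports offending 1-based data-row numbers.
.validate_variant_table <- function(x) {
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0L) {
      stop("invalid variant record(s) at row ",
           paste(utils::head(rows, 5L), collapse = ", "),
           if (length(rows) > 5L) " ..." else "", ": ", what, call. = FALSE)
    }
  }
  bad(is.na(x$gene) | x$gene == "", "empty gene symbol")
  bad(is.na(x$sample) | x$sample == "", "empty sample identifier")
  bad(!is.na(x$total_depth) & x$total_depth < 0L, "negative total depth")
  bad(!is.na(x$alt_depth) & x$alt_depth < 0L, "negative variant-supporting depth")
  bad(!is.na(x$alt_depth) & !is.na(x$total_depth) &
        x$alt_depth > x$total_depth,
      "variant-supporting depth exceeds total depth")
  bad(is.na(x$vaf), "VAF missing and not computable from depths")
  bad(x$vaf < 0 | x$vaf > 1, "VAF outside [0, 1]")
  bad(!is.na(x$pop_af) & (x$pop_af < 0 | x$pop_af > 1),
      "population allele frequency outside [0, 1]")
  invisible(x)
}

#' Read or write a binary gene-by-sample mutation matrix
#'
#' The on-disk format is a TSV whose first column (`sample`) holds sample
#' identifiers and whose remaining columns are uppercase gene symbols, with
#' every cell 0 or 1 (1 = at least one retained somatic mutation in that
#' gene for that sample). `read_matrix(write_matrix(m, f))` returns a
#' matrix identical to `m`.
#'
#' @param path Path to the TSV file.
#' @return For `read_matrix`, an integer matrix with samples in rows and
#'   genes in columns. For `write_matrix`, `path`, invisibly.
#' @export
read_matrix <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(raw) < 1L) stop("empty mutation matrix file", call. = FALSE)
  samples <- trimws(as.character(raw[[1L]]))
  genes <- .normalize_gene(names(raw)[-1L])
  if (anyDuplicated(samples)) {
    stop("duplicate sample identifier(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene column(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  values <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(values) <- "integer"
  dimnames(values) <- list(samples, genes)
  bad <- which(is.na(values) | !(values %in% c(0L, 1L)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-binary cell at sample '", samples[bad[1L, 1L]], "', gene '",
         genes[bad[1L, 2L]], "'", call. = FALSE)
  }
  values
}

#' @rdname read_matrix
#' @param matrix Integer matrix as returned by [binarize()] or
#'   [read_matrix()].
#' @export
write_matrix <- function(matrix, path) {
  .validate_matrix(matrix)
  df <- data.frame(sample = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.validate_matrix <- function(m) {
  if (!is.matrix(m) || (nrow(m) > 0L && is.null(rownames(m))) ||
      (ncol(m) > 0L && is.null(colnames(m)))) {
    stop("mutation matrix must be a matrix with sample rownames and gene colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate sample identifier(s) in mutation matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate gene column(s) in mutation matrix", call. = FALSE)
  }
  if (any(is.na(m)) || !all(m %in% c(0L, 1L))) {
    stop("mutation matrix cells must all be 0 or 1", call. = FALSE)
  }
  invisible(m)
}

#' Read a BCL2/BCL6 translocation (FISH) table
#'
#' Parses a TSV with columns `sample`, `BCL2`, `BCL6` holding break-apart
#' FISH results as case-insensitive `yes` / `no` / `NA` tokens. `NA` (or an
#' empty cell) becomes `"unknown"`; any other token is rejected.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of class `"fish_table"` with columns `sample`,
#'   `bcl2`, `bcl6`; statuses are `"present"`, `"absent"` or `"unknown"`.
#' @export
read_fish_table <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  header <- tolower(names(raw))
  need <- c("sample", "bcl2", "bcl6")
  if (!all(need %in% header)) {
    stop("FISH table must have columns sample, BCL2, BCL6; missing: ",
         paste(setdiff(need, header), collapse = ", "), call. = FALSE)
  }
  names(raw) <- header
  parse_status <- function(x, col) {
    tok <- tolower(trimws(x))
    tok[is.na(tok) | tok == "" | tok == "na"] <- "unknown"
    tok[tok == "yes"] <- "present"
    tok[tok == "no"] <- "absent"
    bad <- which(!tok %in% .TRANSLOC_STATUS)
    if (length(bad) > 0L) {
      stop("invalid ", col, " token '", x[bad[1L]], "' at row ", bad[1L],
           " (expected yes/no/NA)", call. = FALSE)
    }
    tok
  }
  out <- data.frame(
    sample = trimws(raw$sample),
    bcl2 = parse_status(raw$bcl2, "BCL2"),
    bcl6 = parse_status(raw$bcl6, "BCL6"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$sample)) {
    stop("duplicate sample identifier(s) in FISH table: ",
         paste(unique(out$sample[duplicated(out$sample)]), collapse = ", "),
         call. = FALSE)
  }
  class(out) <- c("fish_table", "data.frame")
  out
}

#' Construct a translocation table in code
#'
#' @param sample Character vector of sample identifiers (unique).
#' @param bcl2,bcl6 Status vectors, each `"present"`, `"absent"` or
#'   `"unknown"`; recycled if length 1.
#' @return A `data.frame` of class `"fish_table"`.
#' @export
fish_table <- function(sample, bcl2 = "unknown", bcl6 = "unknown") {
  out <- data.frame(sample = as.character(sample),
                    bcl2 = rep_len(bcl2, length(sample)),
                    bcl6 = rep_len(bcl6, length(sample)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample)) {
    stop("duplicate sample identifier(s) in FISH table", call. = FALSE)
  }
  stopifnot(all(out$bcl2 %in% .TRANSLOC_STATUS),
            all(out$bcl6 %in% .TRANSLOC_STATUS))
  class(out) <- c("fish_table", "data.frame")
  out
}
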