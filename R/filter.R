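#' Variant filter configuration
#'
#' Thresholds for the post-annotation quality and relevance filter applied
#' to targeted-panel somatic calls before binarization. The defaults are
#' the published criteria: total read depth at least 50, at least 5
#' variant-supporting reads, variant allele frequency at least 5%, variant
#' located in exonic/UTR/splice-site regions, a non-synonymous effect, and
#' either absent from population SNP databases or listed with a population
#' minor allele frequency below 0.01% (fraction 1e-4).
#'
#' @param min_total_depth Minimum quality read depth (inclusive).
#' @param min_alt_depth Minimum depth of variant-supporting bases
#'   (inclusive).
#' @param min_vaf Minimum variant allele frequency, fraction (inclusive).
#' @param max_pop_af Population allele frequency ceiling for
#'   database-listed SNPs (exclusive); `0.0001` encodes "MAF < 0.01%".
#' @param allowed_localizations Localization classes retained.
#' @param allowed_effects Variant effect classes retained; the default is
#'   every non-synonymous class, including in-frame indels.
#' @return A list of class `"filter_config"`.
#' @export
#' @examples
#' cfg <- filter_config()
#' cfg$min_total_depth
filter_config <- function(min_total_depth = 50L,
                          min_alt_depth = 5L,
                          min_vaf = 0.05,
                          max_pop_af = 1e-4,
                          allowed_localizations = c("exonic", "UTR5", "UTR3",
                                                    "splice_site"),
                          allowed_effects = .NONSYNONYMOUS_EFFECTS) {
  cfg <- list(min_total_depth = as.integer(min_total_depth),
              min_alt_depth = as.integer(min_alt_depth),
              min_vaf = as.numeric(min_vaf),
              max_pop_af = as.numeric(max_pop_af),
              allowed_localizations = as.character(allowed_localizations),
              allowed_effects = as.character(allowed_effects))
  if (cfg$min_total_depth < 0L || cfg$min_alt_depth < 0L ||
      cfg$min_vaf < 0 || cfg$max_pop_af < 0) {
    stop("filter thresholds must be non-negative", call. = FALSE)
  }
  if (cfg$min_vaf >= 1) stop("min_vaf must be < 1", call. = FALSE)
  class(cfg) <- "filter_config"
  cfg
}

#' Filter annotated somatic variants
#'
#' Retains a variant record iff all of the following hold:
#' total depth >= `min_total_depth`, variant-supporting depth >=
#' `min_alt_depth`, localization in `allowed_localizations`, effect in
#' `allowed_effects`, VAF >= `min_vaf`, and the variant is either not a
#' database-listed SNP or is listed with population allele frequency
#' strictly below `max_pop_af`. Quality comparisons are inclusive and the
#' population-frequency comparison strict, matching the published wording.
#' Retention is decided per record; input order is preserved. A record
#' lacking a population allele frequency and not flagged as a known SNP
#' passes the SNP criterion (it is listed in no database). Records without
#' depth columns (VAF-only input) pass the depth criteria vacuously.
#'
#' @param records A `variant_table` from [read_variant_table()].
#' @param cfg A [filter_config()].
#' @return The retained subset of `records`, same class and column order.
#' @export
filter_variants <- function(records, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (nrow(records) == 0L) return(records)
  depth_ok <- (is.na(records$total_depth) |
                 records$total_depth >= cfg$min_total_depth) &
              (is.na(records$alt_depth) |
                 records$alt_depth >= cfg$min_alt_depth)
  snp_ok <- !records$is_known_snp |
    (!is.na(records$pop_af) & records$pop_af < cfg$max_pop_af)
  keep <- depth_ok &
    records$localization %in% cfg$allowed_localizations &
    records$effect %in% cfg$allowed_effects &
    records$vaf >= cfg$min_vaf &
    snp_ok
  records[keep, , drop = FALSE]
}

#' Binarize filtered variants into a mutation matrix
#'
#' Collapses retained variant records to gene-level presence/absence: cell
#' (sample, gene) is 1 iff at least one record remains for that pair.
#' Duplicate records and record order do not affect the result. Samples
#' listed in `samples` but carrying no retained record appear as all-zero
#' rows, so a fully wild-type sample is still part of the cohort.
#'
#' @param records A (typically filtered) `variant_table`.
#' @param samples Optional character vector fixing the row set and order;
#'   defaults to the samples observed in `records`, in order of first
#'   appearance.
#' @param genes Optional character vector fixing the column set and order
#'   (e.g. the panel genes); defaults to observed genes, sorted.
#' @return Integer matrix, samples in rows, genes in columns, cells 0/1.
#' @export
#' @examples
#' v <- data.frame(sample = c("S1", "S1", "S2"),
#'                 gene = c("MYD88", "MYD88", "EZH2"))
#' binarize(v)
binarize <- function(records, samples = NULL, genes = NULL) {
  obs_samples <- unique(records$sample)
  obs_genes <- sort(unique(records$gene))
  if (is.null(samples)) samples <- obs_samples
  samples <- as.character(samples)
  if (anyDuplicated(samples)) {
    stop("duplicate sample identifier(s) in explicit sample list",
         call. = FALSE)
  }
  dropped <- setdiff(obs_samples, samples)
  if (length(dropped) > 0L) {
    warning("dropping record(s) for sample(s) outside the declared cohort: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (is.null(genes)) genes <- obs_genes
  genes <- .normalize_gene(genes)
  if (anyDuplicated(genes)) {
    stop("duplicate gene(s) in explicit gene list", call. = FALSE)
  }
  m <- matrix(0L, nrow = length(samples), ncol = length(genes),
              dimnames = list(samples, genes))
  keep <- records$sample %in% samples & records$gene %in% genes
  if (any(keep)) {
    m[cbind(records$sample[keep], records$gene[keep])] <- 1L
  }
  m
}
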