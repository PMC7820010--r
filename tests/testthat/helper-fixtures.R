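# Shared fixtures built in code.

# One canonical variant record that passes every default filter; override
# fields to probe individual criteria.
variant_record <- function(sample = "S1", gene = "MYD88",
                           effect = "nonsynonymous_SNV",
                           localization = "exonic",
                           total_depth = 100L, alt_depth = 20L,
                           vaf = 0.2, pop_af = NA_real_,
                           is_known_snp = FALSE) {
  data.frame(sample = sample, gene = gene, effect = effect,
             localization = localization, total_depth = total_depth,
             alt_depth = alt_depth, vaf = vaf, pop_af = pop_af,
             is_known_snp = is_known_snp, stringsAsFactors = FALSE)
}

variant_tbl <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("variant_table", "data.frame")
  out
}

# Random variant table for property tests.
random_variants <- function(n, seed) {
  set.seed(seed)
  tbl <- do.call(rbind, lapply(seq_len(n), function(i) {
    td <- sample(0:200, 1L)
    ad <- sample(0:td, 1L)
    variant_record(
      sample = sprintf("S%d", sample(1:8, 1L)),
      gene = sample(c("MYD88", "EZH2", "PIM1", "TP53", "KMT2D"), 1L),
      effect = sample(dlbcl2s:::.EFFECTS, 1L),
      localization = sample(dlbcl2s:::.LOCALIZATIONS, 1L),
      total_depth = td, alt_depth = ad,
      vaf = if (td > 0) ad / td else 0,
      pop_af = if (runif(1) < 0.5) NA_real_ else runif(1, 0, 0.01),
      is_known_snp = runif(1) < 0.5
    )
  }))
  class(tbl) <- c("variant_table", "data.frame")
  tbl
}

# Independent two-sided Fisher exact p via explicit hypergeometric
# enumeration with choose(); the two-sided mass uses the standard
# "point probability <= observed (with relative fuzz)" convention.
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  N <- m + n2
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    choose(m, x) * choose(n2, k - x) / choose(N, k)
  }, numeric(1L))
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Wrap a single 2x2 table as a one-gene labelled cohort so rank_genes can
# be asked for its p-value: a = mutated & in-subtype, etc.
rank_genes_p <- function(a, b, c, d) {
  n <- a + b + c + d
  samples <- sprintf("S%03d", seq_len(n))
  mut <- c(rep(1L, a), rep(1L, b), rep(0L, c), rep(0L, d))
  lab <- c(rep("MCD", a), rep("EZB", b), rep("MCD", c), rep("EZB", d))
  m <- matrix(mut, ncol = 1L, dimnames = list(samples, "G1"))
  rank_genes(m, stats::setNames(lab, samples), "MCD")$p_value[1L]
}

# Random mutated-gene sets over the default panel vocabulary.
random_feature_sample <- function(id, seed_genes, p = 0.25) {
  genes <- seed_genes[runif(length(seed_genes)) < p]
  sample_features(id, genes,
                  bcl2 = sample(c("present", "absent", "unknown"), 1L),
                  bcl6 = sample(c("present", "absent", "unknown"), 1L))
}
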