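test_that("each published filter criterion is enforced at its boundary", {
  cfg <- filter_config()
  keep1 <- function(rec) nrow(filter_variants(rec, cfg)) == 1L

  # all boundaries inclusive on the quality side
  expect_true(keep1(variant_tbl(variant_record(
    total_depth = 50L, alt_depth = 5L, vaf = 0.05, effect = "stopgain"))))
  expect_false(keep1(variant_tbl(variant_record(total_depth = 49L))))
  expect_false(keep1(variant_tbl(variant_record(alt_depth = 4L))))
  expect_false(keep1(variant_tbl(variant_record(vaf = 0.049))))
  # relevance criteria
  expect_false(keep1(variant_tbl(variant_record(effect = "synonymous_SNV"))))
  expect_false(keep1(variant_tbl(variant_record(localization = "intronic"))))
  expect_true(keep1(variant_tbl(variant_record(localization = "UTR3"))))
  expect_true(keep1(variant_tbl(variant_record(
    effect = "nonframeshift_indel"))))
  # population-SNP criterion: strict < 0.01% for database-listed variants
  expect_true(keep1(variant_tbl(variant_record(
    is_known_snp = TRUE, pop_af = 5e-5))))
  expect_false(keep1(variant_tbl(variant_record(
    is_known_snp = TRUE, pop_af = 2e-4))))
  expect_false(keep1(variant_tbl(variant_record(
    is_known_snp = TRUE, pop_af = 1e-4))))
  # absent from every database: passes regardless of pop_af being missing
  expect_true(keep1(variant_tbl(variant_record(
    is_known_snp = FALSE, pop_af = NA_real_))))
})

test_that("filtering is monotone in the thresholds and idempotent", {
  recs <- random_variants(200L, seed = 11)
  base <- filter_config()
  kept <- filter_variants(recs, base)
  expect_identical(filter_variants(kept, base), kept)

  set.seed(12)
  for (i in 1:40) {
    tighter <- filter_config(
      min_total_depth = base$min_total_depth + sample(0:50, 1L),
      min_alt_depth = base$min_alt_depth + sample(0:10, 1L),
      min_vaf = min(0.99, base$min_vaf + runif(1, 0, 0.3)),
      max_pop_af = base$max_pop_af * runif(1, 0, 1),
      allowed_localizations = sample(base$allowed_localizations,
                                     sample(seq_along(base$allowed_localizations), 1L)),
      allowed_effects = sample(base$allowed_effects,
                               sample(seq_along(base$allowed_effects), 1L))
    )
    kept_tight <- filter_variants(recs, tighter)
    # tightening any threshold never recovers a removed record
    expect_true(all(rownames(kept_tight) %in% rownames(kept)))
    expect_identical(filter_variants(kept_tight, tighter), kept_tight)
  }
})

test_that("binarization is idempotent over duplicates and order-invariant", {
  recs <- variant_tbl(
    variant_record(sample = "S1", gene = "MYD88"),
    variant_record(sample = "S1", gene = "MYD88", vaf = 0.4),
    variant_record(sample = "S2", gene = "EZH2")
  )
  m <- binarize(recs)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(sum(m), 2L)
  expect_equal(m["S1", "MYD88"], 1L)
  expect_equal(m["S2", "EZH2"], 1L)

  # record order does not matter
  shuffled <- recs[c(3L, 1L, 2L), ]
  m2 <- binarize(shuffled, samples = rownames(m), genes = colnames(m))
  expect_identical(m2, m)

  # explicitly declared samples with no retained records become zero rows
  empty <- recs[0L, ]
  m3 <- binarize(empty, samples = c("A", "B", "C"), genes = "MYD88")
  expect_equal(dim(m3), c(3L, 1L))
  expect_true(all(m3 == 0L))
})
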