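test_that("the two-step rule reproduces its defining cases", {
  lbl <- function(genes, bcl2 = "absent", bcl6 = "absent") {
    cl <- classify_sample(sample_features("S", genes, bcl2, bcl6))
    c(cl$label, cl$decided_at)
  }
  # NOTCH1 precedence regardless of other alterations
  expect_equal(lbl(c("NOTCH1", "MYD88", "CD79B")), c("N1", "step1"))
  # unique step-1 maximum
  expect_equal(lbl(c("MYD88", "CD79B")), c("MCD", "step1"))
  # step-1 tie resolved at step 2 over the combined lists:
  # MCD counts MYD88 + PRDM1 = 2, BN2 only NOTCH2 = 1
  expect_equal(lbl(c("MYD88", "NOTCH2", "PRDM1")), c("MCD", "step2"))
  # step-1 tie, both step-2 scores below 2
  expect_equal(lbl(c("MYD88", "NOTCH2")), c("UNCLASSIFIED", "none"))
  # no alterations at all
  expect_equal(lbl(character()), c("UNCLASSIFIED", "none"))
  # zero step-1 hits but two step-2 markers of one subtype
  expect_equal(lbl(c("PRDM1", "BTG1")), c("MCD", "step2"))
  # BCL6 translocation is a BN2 step-1 feature
  expect_equal(lbl(character(), bcl6 = "present"), c("BN2", "step1"))

  cl <- classify_sample(sample_features("S", c("MYD88", "NOTCH2", "PRDM1")))
  expect_equal(cl$step1_scores[["MCD"]], 1L)
  expect_equal(cl$step1_scores[["BN2"]], 1L)
  expect_equal(cl$step2_scores[["MCD"]], 2L)
  expect_equal(cl$step2_scores[["BN2"]], 1L)
})

test_that("BCL2 scores as mutation or translocation, once", {
  s_transloc <- sample_features("S", character(), bcl2 = "present")
  expect_equal(feature_hit("BCL2", s_transloc), 1L)
  s_both <- sample_features("S", "BCL2", bcl2 = "present")
  expect_equal(feature_hit("BCL2", s_both), 1L)
  s_neither <- sample_features("S", character(), bcl2 = "absent")
  expect_equal(feature_hit("BCL2", s_neither), 0L)
  expect_equal(feature_hit("BCL2_TRANSLOC", s_transloc), 1L)
  expect_equal(feature_hit("BCL6_TRANSLOC",
                           sample_features("S", character(), bcl6 = "present")),
               1L)
  expect_equal(feature_hit("PIM1", sample_features("S", character())), 0L)
  expect_error(feature_hit("MYC_TRANSLOC", s_neither), "unknown")
  # translocation alone plus EZH2 gives EZB two step-1 hits
  cl <- classify_sample(sample_features("S", "EZH2", bcl2 = "present"))
  expect_equal(cl$label, "EZB")
  expect_equal(cl$step1_scores[["EZB"]], 2L)
})

test_that("unknown FISH status scores zero and is flagged", {
  cl <- classify_sample(sample_features("S", c("MYD88", "CD79B"),
                                        bcl2 = "unknown", bcl6 = "unknown"))
  expect_equal(cl$label, "MCD")
  expect_true("FISH_UNKNOWN" %in% cl$flags)
  cl2 <- classify_sample(sample_features("S", c("MYD88", "CD79B"),
                                         bcl2 = "absent", bcl6 = "absent"))
  expect_false("FISH_UNKNOWN" %in% cl2$flags)
})

test_that("NOTCH1 precedence and score bookkeeping hold over random feature sets", {
  genes <- c(panel_genes(default_panel()), "TP53", "CARD11")
  set.seed(99)
  n1_seen <- FALSE
  for (i in 1:600) {
    s <- random_feature_sample(sprintf("R%d", i), genes)
    cl <- classify_sample(s)
    # totality: exactly one label from the closed vocabulary
    expect_true(cl$label %in% c("N1", "MCD", "BN2", "EZB", "ST2",
                                "UNCLASSIFIED"))
    if ("NOTCH1" %in% s$mutated_genes) {
      n1_seen <- TRUE
      expect_equal(cl$label, "N1")
      expect_equal(cl$decided_at, "step1")
    }
    if (cl$decided_at == "step1" && cl$label != "N1") {
      sc <- cl$step1_scores[c("MCD", "BN2", "EZB", "ST2")]
      expect_gte(sc[[cl$label]], 1L)
      expect_equal(sum(sc == max(sc)), 1L)
      expect_equal(names(which.max(sc)), cl$label)
    }
    if (cl$decided_at == "step2") {
      sc <- cl$step2_scores
      expect_gte(sc[[cl$label]], 2L)
      expect_equal(sum(sc == max(sc)), 1L)
    }
    if (cl$label == "UNCLASSIFIED") expect_equal(cl$decided_at, "none")
    # monotone trigger: adding one more step-1 marker of the winning
    # subtype keeps the step-1 call (NOTCH1 aside)
    if (cl$decided_at == "step1" && cl$label != "N1") {
      extra <- setdiff(setdiff(default_panel()[[cl$label]]$step1,
                               "BCL6_TRANSLOC"),
                       s$mutated_genes)
      if (length(extra) > 0L) {
        s2 <- sample_features(s$sample_id, c(s$mutated_genes, extra[1L]),
                              s$bcl2, s$bcl6)
        expect_equal(classify_sample(s2)$label, cl$label)
      }
    }
  }
  expect_true(n1_seen)
})

test_that("cohort classification is order-invariant and audits its inputs", {
  co <- simulate_cohort(simulation_config(seed = 21))
  calls <- classify_cohort(co$matrix, co$fish)
  expect_equal(calls$sample, rownames(co$matrix))
  expect_equal(sum(subtype_counts(calls)), nrow(co$matrix))

  perm <- sample(nrow(co$matrix))
  calls_perm <- classify_cohort(co$matrix[perm, ], co$fish)
  reord <- calls_perm[match(calls$sample, calls_perm$sample), ]
  rownames(reord) <- NULL
  expect_equal(reord, calls)

  # duplicated sample identifiers are rejected
  dup <- co$matrix[c(1L, 1L), ]
  expect_error(classify_cohort(dup, co$fish), "duplicate")

  # panel genes absent from the matrix are wild-type, with one warning
  slim <- co$matrix[, setdiff(colnames(co$matrix), "STAT3")]
  expect_warning(classify_cohort(slim, co$fish), "STAT3")

  # FISH rows for unknown samples are ignored with a warning
  fish_extra <- fish_table(c(co$fish$sample, "GHOST"),
                           bcl2 = c(co$fish$bcl2, "present"),
                           bcl6 = c(co$fish$bcl6, "present"))
  expect_warning(classify_cohort(co$matrix, fish_extra), "GHOST")
})

test_that("subtype calls round-trip through TSV", {
  co <- simulate_cohort(simulation_config(seed = 4))
  calls <- classify_cohort(co$matrix, co$fish)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_calls(calls, p)
  back <- read_calls(p)
  expect_equal(back$sample, calls$sample)
  expect_equal(back$label, calls$label)
  expect_equal(back$decided_at, calls$decided_at)
})
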