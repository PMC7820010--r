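test_that("a fixed seed reproduces the cohort bit-identically", {
  cfg <- simulation_config(seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  # a different seed changes the draw
  c2 <- simulate_cohort(simulation_config(seed = 124))
  expect_false(identical(a$matrix, c2$matrix))
  # the caller's RNG stream is left untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_cohort(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("degenerate probabilities produce the exact marker profiles", {
  cfg <- simulation_config(n_per_subtype = c(MCD = 3),
                           marker_penetrance = 1, step2_penetrance = 0,
                           background_rate = 0, fish_missing_rate = 0,
                           seed = 1)
  co <- simulate_cohort(cfg)
  for (i in 1:3) {
    mutated <- colnames(co$matrix)[co$matrix[i, ] == 1L]
    expect_setequal(mutated, c("MYD88", "CD79B", "PIM1"))
  }
  calls <- classify_cohort(co$matrix, co$fish)
  expect_true(all(calls$label == "MCD"))
  expect_true(all(calls$decided_at == "step1"))
})

test_that("noise-free cohorts are recovered exactly; silent cohorts are not", {
  cfg <- simulation_config(
    n_per_subtype = c(N1 = 6, MCD = 6, BN2 = 6, EZB = 6, ST2 = 6, NONE = 6),
    marker_penetrance = 1, background_rate = 0, fish_missing_rate = 0,
    seed = 8)
  co <- simulate_cohort(cfg)
  calls <- classify_cohort(co$matrix, co$fish)
  rec <- recovery_report(co, calls)
  expect_true(all(rec$counts$sensitivity == 1))
  truth <- co$truth
  expect_true(all(calls$label[truth != "NONE"] == truth[truth != "NONE"]))

  mute <- simulation_config(n_per_subtype = c(MCD = 5, EZB = 5),
                            marker_penetrance = 0, step2_penetrance = 0,
                            background_rate = 0, fish_missing_rate = 0,
                            seed = 9)
  co0 <- simulate_cohort(mute)
  calls0 <- classify_cohort(co0$matrix, co0$fish)
  expect_true(all(calls0$label == "UNCLASSIFIED"))
  rec0 <- recovery_report(co0, calls0)
  expect_true(all(rec0$counts$sensitivity[rec0$counts$subtype %in%
                                            c("MCD", "EZB")] == 0))
})

test_that("marginal marker frequencies converge to their penetrance", {
  cfg <- simulation_config(n_per_subtype = c(MCD = 2000), seed = 31)
  co <- simulate_cohort(cfg)
  n <- nrow(co$matrix)
  tol1 <- 3 * sqrt(0.8 * 0.2 / n)
  for (g in c("MYD88", "CD79B", "PIM1")) {
    expect_lt(abs(mean(co$matrix[, g]) - cfg$marker_penetrance), tol1)
  }
  tol2 <- 3 * sqrt(0.4 * 0.6 / n)
  expect_lt(abs(mean(co$matrix[, "PRDM1"]) - cfg$step2_penetrance), tol2)
  tolb <- 3 * sqrt(0.02 * 0.98 / n)
  expect_lt(abs(mean(co$matrix[, "EZH2"]) - cfg$background_rate), tolb)
  # FISH missingness rate
  tolf <- 3 * sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(co$fish$bcl2 == "unknown") - cfg$fish_missing_rate),
            tolf)
})

test_that("simulated cohorts serialize to the package's TSV formats", {
  co <- simulate_cohort(simulation_config(seed = 2))
  prefix <- file.path(withr::local_tempdir(), "cohort_")
  paths <- write_cohort(co, prefix)
  expect_identical(read_matrix(paths[1L]), co$matrix)
  fish <- read_fish_table(paths[2L])
  expect_equal(fish$bcl2, co$fish$bcl2)
  expect_equal(fish$bcl6, co$fish$bcl6)
  truth <- utils::read.delim(paths[3L], stringsAsFactors = FALSE)
  expect_equal(stats::setNames(truth$label, truth$sample), co$truth)
})
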