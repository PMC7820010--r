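#' Synthetic-cohort simulation settings
#'
#' Configures a cohort of samples each drawn from one latent genetic
#' subtype (or from a subtype-free background class, `"NONE"`). A sample's
#' own-subtype step-1 features are altered independently with probability
#' `marker_penetrance`, its own step-2 features with `step2_penetrance`,
#' and every other panel feature with `background_rate`; translocation
#' features are emitted into the FISH table, where each sample's FISH
#' status is additionally masked to unknown with probability
#' `fish_missing_rate` (FISH is run on a tissue block that is simply
#' unavailable for some archival samples, so both probes go missing
#' together). The default cohort composition mirrors a published
#' 84-sample diagnostic series: 5 N1, 14 MCD, 18 BN2, 25 EZB, 10 ST2 and
#' 12 background samples.
#'
#' @param n_per_subtype Named integer vector; names from
#'   `c("N1", "MCD", "BN2", "EZB", "ST2", "NONE")`.
#' @param marker_penetrance Probability an own-subtype step-1 feature is
#'   altered (default 0.8).
#' @param step2_penetrance Probability an own-subtype step-2 feature is
#'   altered (default 0.4).
#' @param background_rate Probability any off-subtype feature is altered
#'   (default 0.02).
#' @param fish_missing_rate Probability a sample's FISH status is unknown
#'   (default 0.3).
#' @param seed Integer seed; a fixed seed yields a bit-identical cohort.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_per_subtype = c(N1 = 5, MCD = 14, BN2 = 18,
                                                EZB = 25, ST2 = 10,
                                                NONE = 12),
                              marker_penetrance = 0.8,
                              step2_penetrance = 0.4,
                              background_rate = 0.02,
                              fish_missing_rate = 0.3,
                              seed = 1L) {
  classes <- c(.SUBTYPES, "NONE")
  if (is.null(names(n_per_subtype)) ||
      !all(names(n_per_subtype) %in% classes)) {
    stop("n_per_subtype must be named with subtypes from ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  if (any(n_per_subtype < 0)) stop("cohort sizes must be >= 0", call. = FALSE)
  probs <- c(marker_penetrance, step2_penetrance, background_rate,
             fish_missing_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all rates must be probabilities in [0, 1]", call. = FALSE)
  }
  structure(list(n_per_subtype = n_per_subtype,
                 marker_penetrance = marker_penetrance,
                 step2_penetrance = step2_penetrance,
                 background_rate = background_rate,
                 fish_missing_rate = fish_missing_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

## Run fn under a seeded RNG without disturbing the caller's RNG state.
.with_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Simulate a cohort with known latent subtypes
#'
#' Draws a mutation matrix, FISH table and truth labelling under
#' independent-Bernoulli mutation profiles (see [simulation_config()]).
#' Samples are ordered in subtype blocks following the order of
#' `cfg$n_per_subtype` and named `"<subtype>_<index>"`. The BCL6
#' translocation is an own-subtype step-1 feature of BN2 samples; the
#' BCL2 translocation arises only at the background rate, EZB samples
#' carrying the BCL2 signal as gene mutations. Feature independence is a
#' deliberate simplification: real cohorts show co-mutation structure the
#' rule logic never inspects.
#'
#' @param cfg A [simulation_config()].
#' @param panel The `"marker_panel"` defining the feature space.
#' @return A list of class `"synthetic_cohort"` with elements `matrix`
#'   (binary samples x genes), `fish` (a `"fish_table"`) and `truth`
#'   (named character vector, `"NONE"` for background samples).
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_config(seed = 7))
#' subtype_counts(classify_cohort(cohort$matrix, cohort$fish))
simulate_cohort <- function(cfg = simulation_config(),
                            panel = default_panel()) {
  stopifnot(inherits(cfg, "simulation_config"),
            inherits(panel, "marker_panel"))
  genes <- panel_genes(panel)
  classes <- names(cfg$n_per_subtype)

  own_features <- function(st, step) {
    if (st == "NONE") character() else panel[[st]][[step]]
  }

  .with_seed(cfg$seed, function() {
    rows <- list()
    fish_rows <- list()
    truth <- character()
    for (st in classes) {
      n <- cfg$n_per_subtype[[st]]
      if (n == 0) next
      own1 <- own_features(st, "step1")
      own2 <- own_features(st, "step2")
      for (i in seq_len(n)) {
        id <- sprintf("%s_%03d", st, i)
        p_gene <- ifelse(genes %in% own1, cfg$marker_penetrance,
                         ifelse(genes %in% own2, cfg$step2_penetrance,
                                cfg$background_rate))
        muts <- stats::rbinom(length(genes), 1L, p_gene)
        p_bcl6 <- if ("BCL6_TRANSLOC" %in% own1) cfg$marker_penetrance
                  else if ("BCL6_TRANSLOC" %in% own2) cfg$step2_penetrance
                  else cfg$background_rate
        bcl6 <- stats::rbinom(1L, 1L, p_bcl6) == 1L
        bcl2 <- stats::rbinom(1L, 1L, cfg$background_rate) == 1L
        missing_fish <- stats::runif(1L) < cfg$fish_missing_rate
        rows[[id]] <- muts
        fish_rows[[id]] <- if (missing_fish) c("unknown", "unknown") else
          c(ifelse(bcl2, "present", "absent"),
            ifelse(bcl6, "present", "absent"))
        truth[[id]] <- st
      }
    }
    samples <- names(rows)
    m <- matrix(0L, nrow = length(samples), ncol = length(genes),
                dimnames = list(samples, genes))
    for (id in samples) m[id, ] <- as.integer(rows[[id]])
    fish <- fish_table(samples,
                       bcl2 = vapply(fish_rows, `[`, character(1L), 1L),
                       bcl6 = vapply(fish_rows, `[`, character(1L), 2L))
    structure(list(matrix = m, fish = fish, truth = truth),
              class = "synthetic_cohort")
  })
}

#' Recovery of simulated truth by the classifier
#'
#' Convenience wrapper: concordance of a set of subtype calls against the
#' cohort's latent truth, background (`"NONE"`) samples counting as
#' UNCLASSIFIED in the reference.
#'
#' @param cohort A `"synthetic_cohort"`.
#' @param calls `"subtype_calls"` computed on `cohort$matrix` /
#'   `cohort$fish`.
#' @param ... Passed to [concordance()].
#' @return A `"concordance_result"`; per-subtype sensitivity is the
#'   classifier's recall of the latent subtype.
#' @export
recovery_report <- function(cohort, calls, ...) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  truth <- cohort$truth
  truth[truth == "NONE"] <- "UNCLASSIFIED"
  concordance(calls, truth, ...)
}

#' Write a synthetic cohort to TSV files
#'
#' @param cohort A `"synthetic_cohort"`.
#' @param prefix Output path prefix; writes `<prefix>matrix.tsv`,
#'   `<prefix>fish.tsv` and `<prefix>truth.tsv`.
#' @return The three paths, invisibly.
#' @export
write_cohort <- function(cohort, prefix) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  paths <- paste0(prefix, c("matrix.tsv", "fish.tsv", "truth.tsv"))
  write_matrix(cohort$matrix, paths[1L])
  fish_out <- data.frame(
    sample = cohort$fish$sample,
    BCL2 = c(present = "yes", absent = "no",
             unknown = "NA")[cohort$fish$bcl2],
    BCL6 = c(present = "yes", absent = "no",
             unknown = "NA")[cohort$fish$bcl6],
    stringsAsFactors = FALSE
  )
  utils::write.table(fish_out, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(cohort$truth), label = unname(cohort$truth),
               stringsAsFactors = FALSE),
    paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
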