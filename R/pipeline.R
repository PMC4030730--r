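#' Compositional differential abundance between two conditions
#'
#' The full pipeline: drop all-zero features, draw Monte Carlo instances of
#' per-sample proportions from the Dirichlet posterior (counts + 1/2 prior),
#' clr-transform every instance, test every feature between conditions in
#' every instance (Welch's t and/or Wilcoxon rank-sum), BH-correct within
#' each instance, and report expected p / expected BH values alongside median
#' clr abundances, between/within difference medians and the effect size.
#'
#' @param counts a [count_table] (or matrix coercible to one).
#' @param conditions a [condition_design], or a named character vector of
#'   labels.
#' @param n_instances Monte Carlo instances (default 128; 16 is usually
#'   enough for large tables).
#' @param prior Dirichlet prior added to every count (default 0.5).
#' @param seed master integer seed.
#' @param tests `"both"` (default), `"welch"` or `"wilcoxon"`.
#' @param expected `"mean"` (default) or `"median"` summary across instances.
#' @return data frame of class `clrdmc_results`, one row per retained
#'   feature: `feature_id`, `rab_all`, `rab_condA`, `rab_condB`, `diff_btw`
#'   (B minus A, log2), `diff_win`, `effect`, and per requested test
#'   `we_ep`/`we_eBH` and/or `wi_ep`/`wi_eBH`.  Attributes record the
#'   conditions, instance count, prior, seed, and removed features.
#' @examples
#' sim <- generate_selex(synthetic_spec(50, 4, 5000, 0.1, 4, seed = 7))
#' res <- diff_abundance(sim$counts, sim$conditions, n_instances = 16, seed = 7)
#' head(res[order(res$we_eBH), ])
#' @export
diff_abundance <- function(counts, conditions, n_instances = 128L,
                           prior = 0.5, seed = 1L,
                           tests = c("both", "welch", "wilcoxon"),
                           expected = c("mean", "median")) {
  tests <- match.arg(tests)
  expected <- match.arg(expected)
  if (!is_count_table(counts)) counts <- count_table(counts)
  if (!inherits(conditions, "condition_design"))
    conditions <- condition_design(conditions, sample_ids = colnames(counts))
  else if (!setequal(names(conditions), colnames(counts)))
    stop("conditions do not cover the count table's samples")
  test_set <- if (tests == "both") c("welch", "wilcoxon") else tests

  filtered <- filter_features(counts)
  ens <- build_ensemble(filtered, n_instances = n_instances, prior = prior,
                        seed = seed)
  stats <- instance_tests(ens, conditions, tests = test_set)
  est <- expected_statistics(stats, method = expected)
  ab <- abundance_medians(ens, conditions)
  eff <- effect_size(difference_distributions(ens, conditions, seed = seed))

  out <- merge(merge(ab, eff, by = "feature_id", sort = FALSE),
               est, by = "feature_id", sort = FALSE)
  out <- out[match(rownames(filtered), out$feature_id), ]
  rownames(out) <- NULL
  structure(out,
            conditions = attr(conditions, "conditions"),
            n_instances = as.integer(n_instances),
            prior = prior,
            seed = as.integer(seed),
            removed_features = attr(filtered, "removed_features"),
            class = c("clrdmc_results", "data.frame"))
}
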