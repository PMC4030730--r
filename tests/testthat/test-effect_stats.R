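# minimal hand-built ensemble: clr values set directly, no randomness
fixed_ensemble <- function(clr_by_sample, n_instances = 1) {
  nf <- nrow(clr_by_sample)
  ns <- ncol(clr_by_sample)
  cl <- array(rep(clr_by_sample, n_instances), dim = c(nf, ns, n_instances),
              dimnames = list(rownames(clr_by_sample),
                              colnames(clr_by_sample), NULL))
  structure(list(clr = cl, proportions = NULL,
                 feature_ids = rownames(clr_by_sample),
                 sample_ids = colnames(clr_by_sample),
                 n_instances = as.integer(n_instances),
                 prior = 0.5, seed = 1L),
            class = "clr_ensemble")
}

test_that("abundance_medians computes direct medians, per condition and overall", {
  m <- rbind(f1 = c(1, 1, 3, 5, 5, 7), f2 = rep(2.5, 6))
  colnames(m) <- paste0("s", 1:6)
  ens <- fixed_ensemble(m)
  ab <- abundance_medians(ens, six_sample_design())
  expect_equal(ab$rab_condA, c(1, 2.5))
  expect_equal(ab$rab_condB, c(5, 2.5))
  expect_equal(ab$rab_all, c(4, 2.5))   # median of {1,1,3,5,5,7}
  # invariant under sample reordering
  perm <- c(2, 4, 6, 1, 3, 5)  # starts with an A sample: level order kept
  ens_p <- fixed_ensemble(m[, perm])
  des_p <- condition_design(stats::setNames(
    rep(c("A", "B"), each = 3)[perm], colnames(m)[perm]))
  ab_p <- abundance_medians(ens_p, des_p)
  expect_equal(ab_p$rab_all, ab$rab_all)
  expect_equal(ab_p$rab_condA, ab$rab_condA)
})

test_that("pure shift fixtures concentrate the between-difference at the shift", {
  # condition B = condition A + 2 for f1; identical within-group values
  m <- rbind(f1 = c(1, 1, 1, 3, 3, 3), f2 = c(-1, -1, -1, -1, -1, -1))
  colnames(m) <- paste0("s", 1:6)
  dists <- difference_distributions(fixed_ensemble(m, 8), six_sample_design(),
                                    seed = 4)
  expect_true(all(dists$btw[1, ] == 2))
  expect_true(all(dists$btw[2, ] == 0))
  expect_true(all(dists$win == 0))
  eff <- effect_size(dists)
  expect_equal(eff$diff_btw, c(2, 0))
  expect_equal(eff$diff_win, c(1e-3, 1e-3))  # floored dispersion
  expect_equal(eff$effect[2], 0)             # degenerate no-variation: 0
})

test_that("effect_size summarises constant distributions exactly", {
  dists <- list(btw = matrix(4, 1, 10), win = matrix(2, 1, 10),
                feature_ids = "f1")
  eff <- effect_size(dists)
  expect_equal(eff$diff_btw, 4)
  expect_equal(eff$diff_win, 2)
  expect_equal(eff$effect, 2)
  # symmetric between draws give effect near 0
  set.seed(6)
  dists2 <- list(btw = matrix(c(-1, 1, -2, 2, -3, 3, 0, 0), 1),
                 win = matrix(1, 1, 8), feature_ids = "f1")
  expect_equal(effect_size(dists2)$effect, 0)
})

test_that("a constructed 6.2-log2 shift is recovered by diff_btw", {
  # counts built from proportions whose clr differs by exactly 6.2 log2
  # units for the shifted feature; small within noise
  set.seed(61)
  nf <- 100
  base <- rep(1, nf); base[1] <- 2^(-3)
  shifted <- base; shifted[1] <- base[1] * 2^6.2
  mk <- function(p, n, prefix) {
    counts <- vapply(seq_len(n), function(i)
      rmultinom(1, 3e5, p / sum(p))[, 1], numeric(nf))
    colnames(counts) <- paste0(prefix, seq_len(n))
    counts
  }
  m <- cbind(mk(base, 4, "a"), mk(shifted, 4, "b"))
  rownames(m) <- sprintf("f%03d", 1:nf)
  des <- condition_design(stats::setNames(rep(c("A", "B"), each = 4),
                                          colnames(m)))
  res <- suppressMessages(
    diff_abundance(count_table(m), des, n_instances = 64, seed = 61))
  # clr shift of f1 = 6.2 minus the geometric-mean shift 6.2/nf
  target <- 6.2 * (1 - 1 / nf)
  expect_lt(abs(res$diff_btw[1] - target), 0.2)
  expect_gt(res$effect[1], 2)
})

test_that("null data give between-differences centred at zero", {
  sim <- generate_null(synthetic_spec(150, 5, 2e4, seed = 71))
  res <- suppressMessages(
    diff_abundance(sim$counts, sim$conditions, n_instances = 32, seed = 71,
                   tests = "welch"))
  expect_lt(abs(median(res$diff_btw)), 0.2)
  expect_lt(abs(median(res$effect)), 0.2)
})

test_that("effect is antisymmetric under label swap and scale invariant", {
  sim <- generate_selex(synthetic_spec(80, 5, 2e4, 0.1, 5, seed = 81))
  res <- suppressMessages(
    diff_abundance(sim$counts, sim$conditions, n_instances = 64, seed = 81,
                   tests = "welch"))
  # swap the roles of the groups: the first-seen condition defines "A", so
  # present the labels with a B sample first
  labs <- stats::setNames(as.character(sim$conditions), names(sim$conditions))
  res_f <- suppressMessages(
    diff_abundance(sim$counts, condition_design(labs[c(6:10, 1:5)]),
                   n_instances = 64, seed = 81, tests = "welch"))
  # antisymmetry holds in distribution; compare medians within MC tolerance
  expect_gt(cor(res_f$diff_btw, -res$diff_btw), 0.99)
  expect_lt(median(abs(res_f$diff_btw + res$diff_btw)), 0.2)
  expect_gt(cor(res_f$effect, -res$effect), 0.95)
  expect_lt(abs(median(res_f$effect + res$effect)), 0.15)

  # per-sample count scaling leaves the analysis invariant (clr inherits it);
  # deeper samples only tighten their Dirichlet posteriors slightly
  scaled <- unclass(sim$counts)
  scaled[, 1] <- scaled[, 1] * 10
  scaled[, 8] <- scaled[, 8] * 7
  res_s <- suppressMessages(
    diff_abundance(count_table(scaled), sim$conditions, n_instances = 64,
                   seed = 81, tests = "welch"))
  expect_gt(cor(res_s$effect, res$effect), 0.98)
  expect_gt(cor(res_s$diff_btw, res$diff_btw), 0.98)
})

test_that("the printed selex variants behave as the analysis reports", {
  fix <- embedded_variant_table()
  res <- suppressMessages(
    diff_abundance(fix$counts, fix$conditions, n_instances = 64, seed = 42))
  kdie <- res[res$feature_id == fix$kdie, ]
  segd <- res[res$feature_id == fix$segd, ]
  # inactive variant tracks the geometric mean: no relative change
  expect_gt(kdie$we_eBH, 0.2)
  expect_lt(abs(kdie$effect), 0.5)
  # weakly functional variant is relatively enriched
  expect_gt(segd$diff_btw, 2)
  expect_gt(segd$effect, 1)
})

test_that("group sizes below 2 are rejected for within-condition dispersion", {
  m <- rbind(f1 = 1:6); colnames(m) <- paste0("s", 1:6)
  ens <- fixed_ensemble(m)
  bad <- structure(factor(c("A", "B", "B", "B", "B", "B")),
                   names = paste0("s", 1:6), conditions = c("A", "B"),
                   class = c("condition_design", "factor"))
  expect_error(difference_distributions(ens, bad, seed = 1), "at least 2")
})
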