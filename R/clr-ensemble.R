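#' Remove features with zero counts in every sample
#'
#' Features never observed in any sample carry no information and cannot be
#' differentially abundant; they are dropped before the Dirichlet model sees
#' the table.  Features with zeros in only some samples are retained — those
#' zeros are handled by the Bayesian prior, not by filtering.
#'
#' @param table a [count_table].
#' @return the [count_table] restricted to features with at least one positive
#'   count, original order preserved.  The removed feature ids are reported
#'   via `message()` and attached as attribute `removed_features`.
#' @export
filter_features <- function(table) {
  stopifnot(is_count_table(table))
  keep <- rowSums(table) > 0
  if (!any(keep))
    stop("all features have zero counts in every sample; nothing to analyse")
  removed <- rownames(table)[!keep]
  if (length(removed) > 0L)
    message(length(removed), " all-zero feature(s) removed: ",
            paste(utils::head(removed, 10L), collapse = ", "),
            if (length(removed) > 10L) ", ..." else "")
  out <- table[keep, , drop = FALSE]
  attr(out, "removed_features") <- removed
  out
}

# Deterministic substream seed derived from (master seed, stream tag, index).
# Keeps every derived seed in [1, 2^31 - 2] and makes per-sample draws
# invariant to processing order.
substream_seed <- function(seed, tag, index = 0L) {
  m <- 2147483647  # 2^31 - 1, prime
  s <- (as.numeric(seed) %% m)
  s <- (s * 48271 + as.numeric(tag) * 16807 + as.numeric(index) * 69621 + 1) %% m
  as.integer(s)
}

# run fn() under a private RNG stream without disturbing the caller's state
with_substream <- function(seed, tag, index, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(substream_seed(seed, tag, index))
  fn()
}

#' Monte Carlo draws of per-sample proportions from the Dirichlet posterior
#'
#' For each sample \eqn{j} with counts \eqn{n_{1,j}, \dots, n_{D,j}}, draws
#' `n_instances` proportion vectors from
#' \eqn{\mathrm{Dir}(n_{1,j} + prior, \dots, n_{D,j} + prior)}.  With the
#' default uniform prior of 1/2, each instance is a read-proportion vector
#' consistent with re-sequencing the same library at the observed depth;
#' zero-count features always receive strictly positive proportions.
#'
#' @param table a filtered [count_table].
#' @param n_instances number of Monte Carlo instances (>= 1; 128 by default
#'   in the pipeline).
#' @param prior positive scalar added to every count (default 0.5).
#' @param seed master integer seed; per-sample substreams are derived from it
#'   so results do not depend on sample processing order.
#' @return numeric array `[feature, sample, instance]` of proportions; every
#'   slice `[, j, k]` is strictly positive and sums to 1.
#' @export
sample_dirichlet_instances <- function(table, n_instances, prior = 0.5,
                                       seed = 1L) {
  stopifnot(is_count_table(table))
  if (!is.numeric(n_instances) || n_instances < 1 ||
      n_instances != round(n_instances))
    stop("n_instances must be a positive integer")
  if (!is.numeric(prior) || length(prior) != 1L || prior <= 0)
    stop("prior must be a single positive number")
  d <- nrow(table)
  p <- array(NA_real_,
             dim = c(d, ncol(table), n_instances),
             dimnames = list(rownames(table), colnames(table), NULL))
  counts <- unclass(table)
  for (j in seq_len(ncol(table))) {
    alpha <- counts[, j] + prior
    g <- with_substream(seed, tag = 1L, index = j, function()
      matrix(stats::rgamma(d * n_instances, shape = alpha), nrow = d))
    p[, j, ] <- sweep(g, 2L, colSums(g), "/")
  }
  p
}

#' Centered log-ratio transform (base 2)
#'
#' `clr(x)[i] = log2(x[i]) - mean(log2(x))`: each part relative to the
#' geometric mean of all parts, in log2 units so that differences between
#' elements are fold changes.  Scale invariant — closure to proportions is a
#' no-op — and sub-compositionally coherent in differences: `clr(x)[i] -
#' clr(x)[j]` does not change when other elements are deleted.
#'
#' @param x strictly positive numeric vector (or a matrix, transformed
#'   column-wise).
#' @return vector (or matrix) of base-2 log-ratios summing to 0 per
#'   composition.
#' @examples
#' round(clr_transform(c(10, 35, 50, 500)), 2)  # -2.44 -0.64 -0.12  3.20
#' @export
clr_transform <- function(x) {
  if (!is.numeric(x) || any(x <= 0) || anyNA(x))
    stop("clr requires strictly positive values")
  lx <- log2(x)
  if (is.matrix(x)) sweep(lx, 2L, colMeans(lx), "-")
  else lx - mean(lx)
}

#' Build the clr-transformed Monte Carlo ensemble
#'
#' Composes [sample_dirichlet_instances()] and [clr_transform()]: every
#' Dirichlet instance of every sample is clr-transformed, giving for each
#' feature a distribution of relative-abundance values that reflects the
#' count-based precision of its estimate (narrow for well-covered features,
#' wide for low-count ones).
#'
#' @inheritParams sample_dirichlet_instances
#' @param keep_proportions retain the raw proportion draws alongside the clr
#'   values (doubles memory; off by default).
#' @return an object of class `clr_ensemble`: list with `clr` (array
#'   `[feature, sample, instance]`, base-2 log-ratio units), `feature_ids`,
#'   `sample_ids`, `n_instances`, `prior`, `seed`, and optionally
#'   `proportions`.
#' @export
build_ensemble <- function(table, n_instances = 128L, prior = 0.5, seed = 1L,
                           keep_proportions = FALSE) {
  p <- sample_dirichlet_instances(table, n_instances, prior, seed)
  cl <- log2(p)
  # center each (sample, instance) composition over features
  cl <- sweep(cl, c(2L, 3L), colMeans(cl, dims = 1L), "-")
  structure(list(clr = cl,
                 proportions = if (keep_proportions) p else NULL,
                 feature_ids = rownames(table),
                 sample_ids = colnames(table),
                 n_instances = as.integer(n_instances),
                 prior = prior,
                 seed = as.integer(seed)),
            class = "clr_ensemble")
}

#' @export
print.clr_ensemble <- function(x, ...) {
  cat(sprintf("clr_ensemble: %d features x %d samples x %d instances (prior %g)\n",
              length(x$feature_ids), length(x$sample_ids), x$n_instances,
              x$prior))
  invisible(x)
}
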