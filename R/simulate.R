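#' Parameters of a simulated two-condition sequencing experiment
#'
#' Defines a stated world with known truth: a baseline composition drawn
#' log-normal (heavy right tail, many low-count features — the abundance
#' structure typical of OTU tables and variant libraries), multinomial
#' sampling of reads per sample at an expected depth with +/-10% uniform
#' jitter to emulate unequal sequencing effort.
#'
#' @param n_features number of features.
#' @param n_per_group samples per condition (>= 3).
#' @param depth expected reads per sample.
#' @param enriched_fraction fraction of features truly changed (in \[0, 1)).
#' @param log2_fold_change log2 fold change applied to changed features.
#' @param sdlog standard deviation of the log-normal baseline abundances
#'   (natural-log scale; default 2 gives several orders of magnitude of
#'   abundance spread).
#' @param dispersion between-replicate composition noise: each sample's
#'   expected proportions are the condition's composition perturbed
#'   feature-wise by log-normal noise with this standard deviation in log2
#'   units, then re-closed.  Default 0.5 log2, the spread visible between
#'   replicate libraries in real selective-growth count data; 0 gives pure
#'   multinomial resampling.
#' @param seed integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_features = 1000L, n_per_group = 7L, depth = 1e5,
                           enriched_fraction = 0, log2_fold_change = 0,
                           sdlog = 2, dispersion = 0.5, seed = 1L) {
  if (n_features < 1L || n_per_group < 3L || depth < 1)
    stop("invalid spec: need n_features >= 1, n_per_group >= 3, depth >= 1")
  if (enriched_fraction < 0 || enriched_fraction >= 1)
    stop("enriched_fraction must lie in [0, 1)")
  if (log2_fold_change != 0 && enriched_fraction * n_features < 1)
    stop("a non-zero fold change needs at least one enriched feature")
  if (depth < n_features)
    warning("expected depth below the number of features; ",
            "most features will be unobserved zeros")
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(list(n_features = as.integer(n_features),
                 n_per_group = as.integer(n_per_group),
                 depth = depth,
                 enriched_fraction = enriched_fraction,
                 log2_fold_change = log2_fold_change,
                 sdlog = sdlog,
                 dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# per-sample draws for one group: replicate-level log-normal composition
# noise around the condition's composition, then multinomial sampling at a
# jittered depth
sim_group <- function(props, n, depth, dispersion, prefix, seed, tag) {
  d <- length(props)
  counts <- with_substream(seed, tag = tag, index = 0L, function() {
    depths <- round(depth * stats::runif(n, 0.9, 1.1))
    vapply(seq_len(n), function(s) {
      pj <- props * 2^stats::rnorm(d, 0, dispersion)
      stats::rmultinom(1L, depths[s], pj / sum(pj))[, 1L]
    }, numeric(d))
  })
  colnames(counts) <- paste0(prefix, seq_len(n))
  counts
}

sim_table <- function(spec, props_a, props_b, truth) {
  ca <- sim_group(props_a, spec$n_per_group, spec$depth, spec$dispersion,
                  "A", spec$seed, 10L)
  cb <- sim_group(props_b, spec$n_per_group, spec$depth, spec$dispersion,
                  "B", spec$seed, 11L)
  counts <- cbind(ca, cb)
  rownames(counts) <- sprintf("F%04d", seq_len(spec$n_features))
  design <- condition_design(stats::setNames(
    rep(c("A", "B"), each = spec$n_per_group), colnames(counts)))
  list(counts = count_table(counts),
       conditions = design,
       truth = data.frame(feature_id = rownames(counts),
                          truth = truth,
                          stringsAsFactors = FALSE))
}

baseline_props <- function(spec) {
  with_substream(spec$seed, tag = 12L, index = 0L, function() {
    w <- stats::rlnorm(spec$n_features, meanlog = 0, sdlog = spec$sdlog)
    w / sum(w)
  })
}

#' Simulate a null experiment (no differential features)
#'
#' Every sample in both conditions is a multinomial draw from the same
#' baseline composition; truth labels are all `"null"`.
#'
#' @param spec a [synthetic_spec].
#' @return list: `counts` ([count_table]), `conditions`
#'   ([condition_design]), `truth` (data frame feature_id, truth).
#' @export
generate_null <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- baseline_props(spec)
  sim_table(spec, p, p, rep("null", spec$n_features))
}

#' Simulate a selective-growth (selex-like) experiment
#'
#' Condition A (unselected) samples the baseline; in condition B (selected) a
#' chosen minority of features has its proportions multiplied by
#' `2^log2_fold_change` and the composition re-closed to 1.  No feature is
#' made absolutely less abundant — exactly the structure of a bacteriostatic
#' selection, where inactive variants keep their input relative abundance and
#' active variants grow.  Truth labels mark the enriched set.
#'
#' @inheritParams generate_null
#' @return as [generate_null()]; truth is `"enriched"` or `"null"`.
#' @export
generate_selex <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$log2_fold_change != 0 && spec$enriched_fraction <= 0)
    stop("generate_selex needs enriched_fraction > 0")
  p <- baseline_props(spec)
  n_enr <- round(spec$enriched_fraction * spec$n_features)
  enr <- with_substream(spec$seed, tag = 13L, index = 0L, function()
    sort(sample.int(spec$n_features, n_enr)))
  pb <- p
  pb[enr] <- pb[enr] * 2^spec$log2_fold_change
  pb <- pb / sum(pb)
  truth <- rep("null", spec$n_features)
  truth[enr] <- "enriched"
  sim_table(spec, p, pb, truth)
}

#' Simulate a symmetric two-group shift experiment (RNA-seq-like)
#'
#' Half of the differential features go up in condition B and half down, by
#' the spec's fold change, then the composition is re-closed.
#'
#' @inheritParams generate_null
#' @return as [generate_null()]; truth is `"up"`, `"down"` or `"null"`.
#' @export
generate_shift <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- baseline_props(spec)
  n_diff <- round(spec$enriched_fraction * spec$n_features)
  idx <- with_substream(spec$seed, tag = 14L, index = 0L, function()
    sample.int(spec$n_features, n_diff))
  up <- idx[seq_len(ceiling(n_diff / 2))]
  down <- setdiff(idx, up)
  pb <- p
  pb[up] <- pb[up] * 2^spec$log2_fold_change
  pb[down] <- pb[down] / 2^spec$log2_fold_change
  pb <- pb / sum(pb)
  truth <- rep("null", spec$n_features)
  truth[up] <- "up"
  truth[down] <- "down"
  sim_table(spec, p, pb, truth)
}
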