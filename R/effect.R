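#' Median clr abundances, overall and per condition
#'
#' The median clr value of a feature over all (sample, instance) pairs is its
#' relative abundance in log2 units: 0 means "at the geometric mean of the
#' sample", negative means rarer than the mean.
#'
#' @param ensemble a `clr_ensemble`.
#' @param design a [condition_design].
#' @return data frame with `feature_id`, `rab_all`, `rab_condA`, `rab_condB`
#'   (log2 units; A is the design's first condition).
#' @export
abundance_medians <- function(ensemble, design) {
  stopifnot(inherits(ensemble, "clr_ensemble"))
  design <- design[match(ensemble$sample_ids, names(design))]
  lev <- attr(design, "conditions") %||% levels(design)
  ia <- which(design == lev[1L]); ib <- which(design == lev[2L])
  cl <- ensemble$clr
  med_over <- function(cols) {
    m <- cl[, cols, , drop = FALSE]
    dim(m) <- c(dim(cl)[1L], length(cols) * dim(cl)[3L])
    apply(m, 1L, stats::median)
  }
  data.frame(feature_id = ensemble$feature_ids,
             rab_all = med_over(seq_along(ensemble$sample_ids)),
             rab_condA = med_over(ia),
             rab_condB = med_over(ib),
             stringsAsFactors = FALSE)
}

#' Monte Carlo distributions of between- and within-condition differences
#'
#' For each Monte Carlo instance, random sample pairs give draws from the
#' between-condition difference distribution (clr of a random B sample minus
#' clr of a random A sample, per feature) and from the within-condition
#' dispersion distribution (per draw, the larger of the two conditions'
#' absolute differences between two distinct random samples of that
#' condition).  The number of draws per instance is the larger group size.
#'
#' @param ensemble a `clr_ensemble`.
#' @param design a [condition_design]; both groups need >= 2 samples so a
#'   within-condition pair exists.
#' @param seed integer seed for the pairing randomness (independent of the
#'   Dirichlet stream).
#' @return list with matrices `btw` and `win`, both
#'   `[feature, draw * instance]`; `win` entries are >= 0.
#' @export
difference_distributions <- function(ensemble, design, seed = 1L) {
  stopifnot(inherits(ensemble, "clr_ensemble"))
  design <- design[match(ensemble$sample_ids, names(design))]
  lev <- attr(design, "conditions") %||% levels(design)
  ia <- which(design == lev[1L]); ib <- which(design == lev[2L])
  if (length(ia) < 2L || length(ib) < 2L)
    stop("within-condition dispersion needs at least 2 samples per condition")
  nf <- dim(ensemble$clr)[1L]
  nk <- ensemble$n_instances
  nd <- max(length(ia), length(ib))
  btw <- matrix(NA_real_, nf, nd * nk)
  win <- matrix(NA_real_, nf, nd * nk)
  pair_distinct <- function(idx, nd) {
    # nd (first, second) pairs of distinct members of idx
    first <- idx[sample.int(length(idx), nd, replace = TRUE)]
    offset <- sample.int(length(idx) - 1L, nd, replace = TRUE)
    second <- idx[(match(first, idx) + offset - 1L) %% length(idx) + 1L]
    cbind(first, second)
  }
  for (k in seq_len(nk)) {
    draws <- with_substream(seed, tag = 2L, index = k, function() {
      list(a = ia[sample.int(length(ia), nd, replace = TRUE)],
           b = ib[sample.int(length(ib), nd, replace = TRUE)],
           pa = pair_distinct(ia, nd),
           pb = pair_distinct(ib, nd))
    })
    cl <- ensemble$clr[, , k]
    if (nf == 1L) cl <- matrix(cl, nrow = 1L)
    cols <- (k - 1L) * nd + seq_len(nd)
    btw[, cols] <- cl[, draws$b, drop = FALSE] - cl[, draws$a, drop = FALSE]
    wa <- abs(cl[, draws$pa[, 1L], drop = FALSE] -
              cl[, draws$pa[, 2L], drop = FALSE])
    wb <- abs(cl[, draws$pb[, 1L], drop = FALSE] -
              cl[, draws$pb[, 2L], drop = FALSE])
    win[, cols] <- pmax(wa, wb)
  }
  list(btw = btw, win = win, feature_ids = ensemble$feature_ids)
}

#' Median differences and effect size
#'
#' Summarises the Monte Carlo difference distributions per feature:
#' `diff_btw` is the median between-condition difference (log2 fold change,
#' reported as B minus A), `diff_win` the median within-condition dispersion
#' (floored at `win_floor` so it remains a usable denominator), and `effect`
#' the median over draws of the ratio of each between-draw to its paired
#' within-draw — a unitless standardised effect.  A feature whose relative
#' abundance does not change has draws symmetric about zero and effect near
#' zero regardless of how its raw counts moved.
#'
#' @param dists output of [difference_distributions()].
#' @param win_floor positive floor applied to within-dispersion draws before
#'   division (default 1e-3 log2 units) to avoid blow-ups on degenerate
#'   no-variation fixtures.
#' @return data frame with `feature_id`, `diff_btw`, `diff_win`, `effect`.
#' @export
effect_size <- function(dists, win_floor = 1e-3) {
  stopifnot(is.matrix(dists$btw), is.matrix(dists$win),
            all(dim(dists$btw) == dim(dists$win)))
  med <- function(m) apply(m, 1L, stats::median)
  data.frame(feature_id = dists$feature_ids,
             diff_btw = med(dists$btw),
             diff_win = pmax(med(dists$win), win_floor),
             effect = med(dists$btw / pmax(dists$win, win_floor)),
             stringsAsFactors = FALSE)
}
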