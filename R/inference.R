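#' Welch's unequal-variance t-test p-value
#'
#' Two-sided p-value for a difference in means without assuming equal
#' variances, using the Welch-Satterthwaite degrees of freedom.  Degenerate
#' inputs are resolved without NaNs: when both groups have zero variance the
#' p-value is 1 for equal means (no evidence against the null) and the
#' smallest representable positive double for unequal means.
#'
#' @param a,b numeric vectors, each of length >= 3 (the pipeline's minimum
#'   group size).
#' @return two-sided p-value in \[0, 1\].
#' @export
welch_t_p <- function(a, b) {
  if (length(a) < 3L || length(b) < 3L)
    stop("Welch's t requires at least 3 observations per group")
  drop(welch_rows(matrix(a, nrow = 1L), matrix(b, nrow = 1L)))
}

# row-wise Welch p over matrices [feature x samples-in-group]
welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  tt <- (ma - mb) / sqrt(se2)
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  # both variances zero: se2 == 0, t and df are NaN
  degen <- se2 == 0
  if (any(degen))
    p[degen] <- ifelse(ma[degen] == mb[degen], 1, .Machine$double.xmin)
  p
}

#' Wilcoxon rank-sum (Mann-Whitney) p-value
#'
#' Two-sided p-value for a location difference.  The exact null distribution
#' of the rank-sum statistic is used when the total sample size is at most 20
#' and there are no ties; otherwise a normal approximation with tie
#' correction and continuity correction.  Two-sided p is twice the smaller
#' tail, capped at 1 (the null distribution is symmetric, so this equals the
#' both-tails enumeration).
#'
#' @inheritParams welch_t_p
#' @return two-sided p-value in \[0, 1\].
#' @export
wilcoxon_p <- function(a, b) {
  if (length(a) < 3L || length(b) < 3L)
    stop("rank-sum test requires at least 3 observations per group")
  drop(wilcoxon_rows(matrix(a, nrow = 1L), matrix(b, nrow = 1L)))
}

# row-wise Wilcoxon p over matrices [feature x samples-in-group]
wilcoxon_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  n <- na + nb
  x <- cbind(a, b)
  rk <- t(apply(x, 1L, rank))
  if (nrow(x) == 1L) rk <- matrix(rk, nrow = 1L)  # apply drops dims
  w <- rowSums(rk[, seq_len(na), drop = FALSE]) - na * (na + 1) / 2
  ties <- apply(x, 1L, anyDuplicated) > 0L
  p <- numeric(nrow(x))
  exact <- !ties & n <= 20L
  if (any(exact)) {
    we <- w[exact]
    lower <- stats::pwilcox(we, na, nb)
    upper <- stats::pwilcox(we - 1, na, nb, lower.tail = FALSE)
    p[exact] <- pmin(2 * pmin(lower, upper), 1)
  }
  if (any(!exact)) {
    idx <- which(!exact)
    mu <- na * nb / 2
    sig <- vapply(idx, function(i) {
      tie_tab <- table(rk[i, ])
      tiesum <- sum(tie_tab^3 - tie_tab)
      sqrt(na * nb / 12 * ((n + 1) - tiesum / (n * (n - 1))))
    }, numeric(1L))
    z <- w[idx] - mu
    z <- (z - sign(z) * 0.5) / sig   # continuity correction toward the mean
    pv <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    pv[sig == 0] <- 1                 # all values tied: no evidence
    p[idx] <- pmin(pv, 1)
  }
  p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR adjustment: with p-values sorted ascending,
#' `adjusted_(r) = min_{s >= r} p_(s) * m / s`, capped at 1, returned in the
#' original order.  Adjusted values are never smaller than the raw p-values.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of BH-adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(cummin(p[o] * (m / seq.int(m, 1L))), 1)
  # the step-up value is analytically >= p; clamp away 1-ulp rounding dips
  adj <- pmax(adj, p[o])
  adj[order(o)]
}

#' Per-instance tests across the Monte Carlo ensemble
#'
#' For every Monte Carlo instance, compares each feature's clr values between
#' the two conditions with Welch's t-test and/or the Wilcoxon rank-sum test,
#' then BH-corrects each instance's p-value vector across features.  The
#' correction is applied within each instance and only then summarised across
#' instances — never BH-after-averaging.
#'
#' @param ensemble a `clr_ensemble` from [build_ensemble()].
#' @param design a [condition_design] covering the ensemble's samples.
#' @param tests which tests to run: `"welch"`, `"wilcoxon"`, or both.
#' @return object of class `instance_statistics`: list of matrices
#'   `[feature, instance]` named `welch_p`, `welch_bh`, `wilcoxon_p`,
#'   `wilcoxon_bh` (only the requested tests are present).
#' @export
instance_tests <- function(ensemble, design,
                           tests = c("welch", "wilcoxon")) {
  tests <- match.arg(tests, several.ok = TRUE)
  stopifnot(inherits(ensemble, "clr_ensemble"))
  design <- design[match(ensemble$sample_ids, names(design))]
  if (anyNA(design)) stop("design does not cover all ensemble samples")
  lev <- attr(design, "conditions") %||% levels(design)
  ia <- which(design == lev[1L]); ib <- which(design == lev[2L])
  nf <- length(ensemble$feature_ids)
  nk <- ensemble$n_instances
  out <- list()
  tmpl <- matrix(NA_real_, nf, nk, dimnames = list(ensemble$feature_ids, NULL))
  for (t in tests) {
    out[[paste0(t, "_p")]] <- tmpl
    out[[paste0(t, "_bh")]] <- tmpl
  }
  for (k in seq_len(nk)) {
    a <- ensemble$clr[, ia, k, drop = FALSE]; dim(a) <- c(nf, length(ia))
    b <- ensemble$clr[, ib, k, drop = FALSE]; dim(b) <- c(nf, length(ib))
    if ("welch" %in% tests) {
      p <- welch_rows(a, b)
      out$welch_p[, k] <- p
      out$welch_bh[, k] <- bh_adjust(p)
    }
    if ("wilcoxon" %in% tests) {
      p <- wilcoxon_rows(a, b)
      out$wilcoxon_p[, k] <- p
      out$wilcoxon_bh[, k] <- bh_adjust(p)
    }
  }
  structure(out, class = "instance_statistics",
            feature_ids = ensemble$feature_ids)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Expected test statistics across Monte Carlo instances
#'
#' Summarises per-instance p-values and BH values as their expected value
#' across instances: the arithmetic mean by default (the literal expectation
#' estimator), with the median available as an option.  Because averaging is
#' linear, the expected BH value remains >= the expected p-value per feature.
#'
#' @param stats an `instance_statistics` object from [instance_tests()].
#' @param method `"mean"` (default) or `"median"`.
#' @return data frame with `feature_id` and, per test present, `we_ep` /
#'   `we_eBH` (Welch) and `wi_ep` / `wi_eBH` (Wilcoxon).
#' @export
expected_statistics <- function(stats, method = c("mean", "median")) {
  method <- match.arg(method)
  stopifnot(inherits(stats, "instance_statistics"))
  agg <- function(m) {
    if (method == "mean") rowMeans(m) else apply(m, 1L, stats::median)
  }
  out <- data.frame(feature_id = attr(stats, "feature_ids"),
                    stringsAsFactors = FALSE)
  if (!is.null(stats$welch_p)) {
    out$we_ep <- agg(stats$welch_p)
    out$we_eBH <- agg(stats$welch_bh)
  }
  if (!is.null(stats$wilcoxon_p)) {
    out$wi_ep <- agg(stats$wilcoxon_p)
    out$wi_eBH <- agg(stats$wilcoxon_bh)
  }
  out
}
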