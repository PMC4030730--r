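#' Plot style: significance thresholds and colors
#'
#' @param p_cut expected p-value threshold (default 0.05).
#' @param fdr_cut expected BH threshold (default 0.05).
#' @param test which test's expected statistics drive the coloring; Welch by
#'   default (its power degrades less at small sample sizes).
#' @return a `plot_style` list with thresholds, test choice and the color
#'   map: BH-significant red, p-only cyan, rare non-significant black,
#'   abundant non-significant gray.
#' @export
plot_style <- function(p_cut = 0.05, fdr_cut = 0.05,
                       test = c("welch", "wilcoxon")) {
  if (!(p_cut > 0 && p_cut <= 1) || !(fdr_cut > 0 && fdr_cut <= 1))
    stop("thresholds must lie in (0, 1]")
  structure(list(p_cut = p_cut, fdr_cut = fdr_cut, test = match.arg(test),
                 colors = c(significant_fdr = "red",
                            significant_p_only = "cyan",
                            rare_nonsig = "black",
                            abundant_nonsig = "gray")),
            class = "plot_style")
}

#' Classify features for plotting
#'
#' Pure function of the expected statistics and median abundance.  Precedence:
#' expected BH below `fdr_cut` is `significant_fdr`; otherwise expected p
#' below `p_cut` is `significant_p_only` (significance outranks rarity);
#' otherwise features whose median clr is below the geometric mean
#' (`rab_all < 0`) are `rare_nonsig`; the rest `abundant_nonsig`.
#'
#' @param ep,eBH,rab_all numeric vectors (expected p, expected BH, median clr).
#' @param style a [plot_style].
#' @return character vector of class labels; every feature gets exactly one.
#' @export
classify_features <- function(ep, eBH, rab_all, style = plot_style()) {
  stopifnot(length(ep) == length(eBH), length(ep) == length(rab_all))
  ifelse(eBH < style$fdr_cut, "significant_fdr",
    ifelse(ep < style$p_cut, "significant_p_only",
      ifelse(rab_all < 0, "rare_nonsig", "abundant_nonsig")))
}

pick_stats <- function(results, style) {
  if (style$test == "welch") {
    if (is.null(results$we_ep)) stop("results lack Welch statistics")
    list(ep = results$we_ep, eBH = results$we_eBH)
  } else {
    if (is.null(results$wi_ep)) stop("results lack Wilcoxon statistics")
    list(ep = results$wi_ep, eBH = results$wi_eBH)
  }
}

open_device <- function(path, width = 7, height = 7) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 150),
         svg = grDevices::svg(path, width = width, height = height),
         pdf = grDevices::pdf(path, width = width, height = height),
         stop("unsupported plot format '", ext, "' (use png, svg or pdf)"))
}

scatter_classed <- function(x, y, class, style, xlab, ylab, main,
                            identity_lines = FALSE) {
  plot(x, y, type = "n", xlab = xlab, ylab = ylab, main = main)
  if (identity_lines) {
    graphics::abline(a = 0, b = 1, lty = 2, col = "darkgray")
    graphics::abline(a = 0, b = -1, lty = 2, col = "darkgray")
  }
  ord <- c("abundant_nonsig", "rare_nonsig", "significant_p_only",
           "significant_fdr")  # draw significant points on top
  for (cl in ord) {
    sel <- class == cl
    if (any(sel))
      graphics::points(x[sel], y[sel], pch = 19, cex = 0.4,
                       col = style$colors[[cl]])
  }
}

#' MW plot: between- vs within-condition difference
#'
#' Each feature is placed at (median within-condition dispersion, median
#' between-condition difference); the dashed lines `y = +/-x` mark equal
#' variation within and between conditions — reliable calls lie outside
#' them.  Colors follow [classify_features()].
#'
#' @param results result data frame from [diff_abundance()].
#' @param style a [plot_style].
#' @param path output image path (`.png`, `.svg` or `.pdf`).
#' @return invisibly, the class label vector used.
#' @export
mw_plot <- function(results, style = plot_style(), path) {
  if (NROW(results) == 0L) stop("empty result table")
  st <- pick_stats(results, style)
  cls <- classify_features(st$ep, st$eBH, results$rab_all, style)
  open_device(path)
  on.exit(grDevices::dev.off())
  scatter_classed(results$diff_win, results$diff_btw, cls, style,
                  xlab = "median within-condition difference (log2)",
                  ylab = "median between-condition difference (log2)",
                  main = "MW plot", identity_lines = TRUE)
  invisible(cls)
}

#' MA plot: between-condition difference vs median relative abundance
#'
#' Bland-Altman style view: each feature at (median clr over all samples,
#' median between-condition difference), colored as in [mw_plot()].
#'
#' @inheritParams mw_plot
#' @return invisibly, the class label vector used.
#' @export
ma_plot <- function(results, style = plot_style(), path) {
  if (NROW(results) == 0L) stop("empty result table")
  st <- pick_stats(results, style)
  cls <- classify_features(st$ep, st$eBH, results$rab_all, style)
  open_device(path)
  on.exit(grDevices::dev.off())
  scatter_classed(results$rab_all, results$diff_btw, cls, style,
                  xlab = "median clr abundance (log2)",
                  ylab = "median between-condition difference (log2)",
                  main = "MA plot")
  invisible(cls)
}
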