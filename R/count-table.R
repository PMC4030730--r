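#' Construct a validated count table
#'
#' A count table is a feature-by-sample matrix of non-negative integer read
#' counts with unique feature (row) and sample (column) identifiers.  The
#' per-sample totals \eqn{N_j = \sum_i n_{i,j}} are carried as an attribute;
#' they reflect sequencing effort, not biology, and the downstream analysis is
#' invariant to them.
#'
#' @param counts numeric matrix of non-negative integers, features as rows,
#'   samples as columns; must carry unique rownames and colnames.
#' @return an object of class `count_table`: the integer matrix with a
#'   `sample_totals` attribute (named per-sample column sums).
#' @examples
#' m <- matrix(c(10, 35, 50, 500), ncol = 1,
#'             dimnames = list(paste0("f", 1:4), "s1"))
#' tab <- count_table(m)
#' sample_totals(tab)  # 595
#' @export
count_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop("count table has no ", if (nrow(counts) == 0L) "features" else "samples")
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing cells")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-integer or negative count at feature '%s', sample '%s'",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]))
  storage.mode(counts) <- "double"   # doubles hold counts > .Machine$integer.max
  structure(counts,
            sample_totals = colSums(counts),
            class = c("count_table", "matrix", "array"))
}

#' @rdname count_table
#' @param x a `count_table`.
#' @export
sample_totals <- function(x) attr(x, "sample_totals")

#' @rdname count_table
#' @export
is_count_table <- function(x) inherits(x, "count_table")

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d features x %d samples; depth %s-%s reads\n",
              nrow(x), ncol(x),
              format(min(sample_totals(x))), format(max(sample_totals(x)))))
  invisible(x)
}

# subsetting keeps the class and recomputes totals when the result is a matrix
#' @export
`[.count_table` <- function(x, ..., drop = FALSE) {
  m <- unclass(x)
  attr(m, "sample_totals") <- NULL
  out <- m[..., drop = drop]
  if (is.matrix(out) && !is.null(rownames(out)) && !is.null(colnames(out)))
    count_table(out)
  else out
}

#' Construct a two-condition design
#'
#' Maps each sample identifier to one of exactly two condition labels.  At
#' least three samples per condition are required: with fewer, the
#' within-condition variance of the per-instance tests is not estimable in any
#' useful way.
#'
#' @param labels named character vector (or factor): names are sample ids,
#'   values are condition labels.
#' @param sample_ids optional character vector; when given, every id must be
#'   labelled and the design is reordered to match.
#' @return object of class `condition_design`: a 2-level factor named by
#'   sample, with attributes `conditions` (level names, first-seen order) and
#'   `group_sizes`.
#' @export
condition_design <- function(labels, sample_ids = NULL) {
  if (is.null(names(labels)) || anyNA(names(labels)) || any(names(labels) == ""))
    stop("condition labels must be named by sample identifier")
  labs <- as.character(labels)
  if (anyNA(labs) || any(labs == ""))
    stop("missing condition label")
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing) > 0L)
      stop("samples without a condition label: ", paste(missing, collapse = ", "))
    labs <- labs[match(sample_ids, names(labels))]
    names(labs) <- sample_ids
  } else {
    names(labs) <- names(labels)
  }
  lev <- unique(labs)  # first-seen order: first sample's condition is "A"
  if (length(lev) != 2L)
    stop("design must have exactly two conditions, got ", length(lev), ": ",
         paste(lev, collapse = ", "))
  sizes <- table(factor(labs, levels = lev))
  if (any(sizes < 3L))
    stop("each condition needs at least 3 samples; got ",
         paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "))
  structure(factor(labs, levels = lev),
            names = names(labs),
            conditions = lev,
            group_sizes = as.integer(sizes),
            class = c("condition_design", "factor"))
}

#' @export
print.condition_design <- function(x, ...) {
  lev <- attr(x, "conditions")
  gs <- attr(x, "group_sizes")
  cat(sprintf("condition_design: %s (n=%d) vs %s (n=%d)\n",
              lev[1L], gs[1L], lev[2L], gs[2L]))
  invisible(x)
}

#' Read a feature-by-sample count table from delimited text
#'
#' Expects features as rows (identifiers in the first column), samples as
#' columns (identifiers in the header row), cells as non-negative integers.
#' Missing cells are errors, not zeros: silent imputation would hide upstream
#' corruption.
#'
#' @param path path to the file.
#' @param sep field delimiter; tab by default, `","` for CSV.
#' @return a [count_table].
#' @export
read_counts <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("count table '", path, "' has a header but no rows")
  if (ncol(df) < 2L) stop("count table '", path, "' has no sample columns")
  ids <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  mat <- matrix(NA_real_, nrow = nrow(body), ncol = ncol(body),
                dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0L)
      stop(sprintf(
        "cell is not a non-negative integer at feature '%s', sample '%s': '%s'",
        ids[bad[1L]], colnames(body)[j], body[[j]][bad[1L]]))
    mat[, j] <- v
  }
  count_table(mat)
}

#' Read a sample-to-condition mapping
#'
#' Accepts either a two-column delimited file (sample_id, condition; no
#' header required — a header line is detected when its second field is not a
#' condition shared with later lines) or an inline named vector.
#'
#' @param path path to a two-column file, or `NULL` when `labels` is given.
#' @param labels optional named character vector used instead of a file.
#' @param table optional [count_table]; when given, sample coverage and order
#'   are validated against it.
#' @param sep field delimiter for file input.
#' @return a [condition_design].
#' @export
read_conditions <- function(path = NULL, labels = NULL, table = NULL,
                            sep = "\t") {
  if (is.null(labels)) {
    if (is.null(path)) stop("either 'path' or 'labels' must be given")
    df <- utils::read.table(path, header = FALSE, sep = sep,
                            colClasses = "character", comment.char = "",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("condition file needs two columns: sample, condition")
    # tolerate a header line
    if (!is.null(table) && !(df[1L, 1L] %in% colnames(table)))
      df <- df[-1L, , drop = FALSE]
    labels <- stats::setNames(df[[2L]], df[[1L]])
  }
  condition_design(labels,
                   sample_ids = if (is.null(table)) NULL else colnames(table))
}

#' Write the per-feature result table
#'
#' Tab-separated, one row per retained feature, eleven columns:
#' `feature_id`, `rab_all`, `rab_condA`, `rab_condB`, `diff_btw`, `diff_win`,
#' `effect`, `we_ep`, `we_eBH`, `wi_ep`, `wi_eBH`.  `diff_btw` is reported as
#' condition B minus condition A, where "A" is the condition of the first
#' sample in input order.  Numeric values keep at least 6 significant digits.
#'
#' @param results a result data frame as produced by [diff_abundance()].
#' @param path output path.
#' @param sep field delimiter.
#' @return invisibly, `path`.
#' @export
write_results <- function(results, path, sep = "\t") {
  cols <- c("feature_id", "rab_all", "rab_condA", "rab_condB",
            "diff_btw", "diff_win", "effect",
            "we_ep", "we_eBH", "wi_ep", "wi_eBH")
  missing <- setdiff(cols, names(results))
  if (length(missing) > 0L)
    stop("result table is missing columns: ", paste(missing, collapse = ", "))
  out <- results[, cols]
  for (nm in cols[-1L])
    out[[nm]] <- formatC(out[[nm]], digits = 8, format = "g")
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Write a count table as delimited text
#'
#' Inverse of [read_counts()]; `read_counts(write_counts(tab, p))` reproduces
#' the table exactly.
#'
#' @inheritParams write_results
#' @param table a [count_table].
#' @export
write_counts <- function(table, path, sep = "\t") {
  df <- data.frame(feature_id = rownames(table),
                   as.data.frame(unclass(table), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
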