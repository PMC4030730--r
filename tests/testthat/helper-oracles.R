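# Independent oracles, kept deliberately naive and separate from the
# package's vectorised implementations.

# Two-sided rank-sum p by full enumeration of all C(m+n, m) rank
# assignments: probability of a rank-sum at least as far from its null mean
# as the observed one.  Valid for tie-free data.
enumerate_wilcoxon_p <- function(a, b) {
  m <- length(a); n <- length(b)
  rk <- rank(c(a, b))
  obs <- sum(rk[seq_len(m)])
  center <- m * (m + n + 1) / 2
  sets <- utils::combn(m + n, m)
  sums <- colSums(matrix(seq_len(m + n)[sets], nrow = m))
  mean(abs(sums - center) >= abs(obs - center) - 1e-9)
}

# Literal transcription of the BH step-up definition:
# adjusted_(r) = min_{s >= r} p_(s) * m / s, capped at 1.
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- vapply(seq_len(m), function(r)
    min(1, min(p[o][r:m] * m / (r:m))), numeric(1))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# small count table used across files
worked_example_table <- function() {
  count_table(matrix(c(10, 35, 50, 500), ncol = 1,
                     dimnames = list(paste0("f", 1:4), "s1")))
}

make_table <- function(counts_list) {
  m <- do.call(rbind, counts_list)
  rownames(m) <- names(counts_list)
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  count_table(m)
}

six_sample_design <- function(ids = paste0("s", 1:6)) {
  condition_design(stats::setNames(rep(c("A", "B"), each = 3), ids))
}

# selex-like library with the two variants whose counts the source data
# prints: a non-functional variant that tracks the geometric mean in both
# conditions, and a weakly functional one that is relatively enriched.
# Most features drop ~100x in the selected condition because a few strongly
# enriched variants take over the library.
embedded_variant_table <- function(seed = 42L) {
  set.seed(seed)
  nf <- 400L
  base <- rlnorm(nf, 0, 1)
  base <- base / sum(base)
  sel <- base
  strong <- 1:8                      # strongly-enriched variants take ~99%
  sel[strong] <- sel[strong] * 4000
  sel <- sel / sum(sel)
  depth <- 5e4
  draw <- function(p) {
    pj <- p * 2^rnorm(nf, 0, 0.5)
    rmultinom(1, round(depth * runif(1, 0.9, 1.1)), pj / sum(pj))[, 1]
  }
  counts <- cbind(vapply(1:7, function(i) draw(base), numeric(nf)),
                  vapply(1:7, function(i) draw(sel), numeric(nf)))
  rownames(counts) <- sprintf("v%03d", seq_len(nf))
  colnames(counts) <- c(paste0("NS", 1:7), paste0("S", 1:7))
  # printed replicate counts of the two illustrative variants
  counts["v100", ] <- c(149, 89, 165, 68, 135, 128, 199,   # K:D:I:E (inactive)
                        0, 0, 1, 0, 1, 0, 0)
  counts["v200", ] <- c(755, 554, 669, 797, 862, 650, 2170, # S:E:G:D (active)
                        4710, 995, 906, 1716, 784, 804, 641)
  list(counts = count_table(counts),
       conditions = condition_design(
         stats::setNames(rep(c("NS", "S"), each = 7), colnames(counts))),
       kdie = "v100", segd = "v200")
}
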