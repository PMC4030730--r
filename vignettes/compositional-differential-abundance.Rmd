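---
title: "Compositional differential abundance with Dirichlet Monte Carlo and the clr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional differential abundance with Dirichlet Monte Carlo and the clr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clrdmc)
```

## The model and its assumptions

A sequencing experiment delivers a feature-by-sample table of read counts
$n_{i,j}$ with per-sample totals $N_j = \sum_i n_{i,j}$.  The totals are an
instrument artifact, so the table is treated as a set of per-sample
*compositions*: only the proportions $p_{i,j}$ carry information, and any
analysis must be invariant to per-sample rescaling.

Two sources of variation are modelled separately:

1. **Technical (sampling) variation.** Conditional on the library, the read
   counts of one sample are multinomial; the conjugate posterior over the
   underlying proportions is Dirichlet.  We draw $K$ Monte Carlo instances
   per sample from $\mathrm{Dir}(n_{1,j}+\tfrac12,\dots,n_{D,j}+\tfrac12)$.
   The uniform $\tfrac12$ prior (Jeffreys for the multinomial) gives
   strictly positive proportions to zero-count features while adding as
   little information as possible.  Posterior spread is wide exactly where
   the data are weak — low counts, shallow samples — and that width is
   propagated through every downstream statistic instead of being discarded
   by a single point normalisation.
2. **Between-replicate (biological) variation.** Handled
   non-parametrically: the per-instance tests compare actual replicates, so
   no negative-binomial or other mean–variance model is assumed.

Each instance is centered log-ratio transformed in base 2,
$c_{i,j} = \log_2 p_{i,j} - \operatorname{mean}_i \log_2 p_{i,j}$, placing
every feature relative to its sample's geometric mean.  The clr is scale
invariant, and *differences between two features* are invariant to deleting
any other features (sub-compositional coherence of differences) — the
property that makes conclusions robust to rRNA removal, abundance filtering
and similar common manipulations.  The geometric mean is taken over **all**
retained features of the sample; features zero in every sample are removed
first (they cannot be differential and only dilute the mean).

Within each instance, every feature is tested between the two conditions
with Welch's $t$ (no equal-variance assumption) and the Wilcoxon rank-sum
test (no normality assumption — the clr does not guarantee normality), and
each instance's p-value vector is Benjamini–Hochberg corrected across
features.  The reported `we_ep`/`wi_ep` and `we_eBH`/`wi_eBH` are the
means of these per-instance values across the $K$ instances.

**Order of operations.** BH is applied *within* each instance and the
corrected values are then averaged — never BH applied to averaged
p-values.  The per-instance correction operates on an exchangeable set of
p-values from one coherent realisation of the data; averaging afterwards is
what damps features whose significance depends on lucky realisations.
Because averaging is linear and BH is pointwise $\ge$ the raw p-value, the
expected BH value stays $\ge$ the expected p-value.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_instances` | 128 | draws | enough to stabilise central tendencies (means/medians); tail quantiles are never reported. 16 suffices for large tables — the acceptance-style convergence check shows low-abundance false positives already gone at 16. |
| `prior` | 0.5 | pseudocounts | Jeffreys-style uninformative prior; exposed for sensitivity analysis only. |
| `seed` | — | integer | master seed; per-sample substreams are derived from (seed, sample index), so results do not depend on sample processing order. |
| `tests` | both | — | Welch is the recommended default for small $n$ (see below); both are reported. |
| `expected` | mean | — | the literal expectation estimator; median available as a robustness check. |
| `win_floor` | 1e-3 | log2 | floor on the within-condition dispersion before it is used as a denominator; only binds on degenerate no-variation fixtures. |

A structural note on the test choice: at 3+3 replicates the most extreme
tie-free rank assignment has exact two-sided Wilcoxon $p = 2/20 = 0.1$, so
no Wilcoxon BH value can ever reach 0.05 at three replicates, while Welch's
$t$ retains power.  This is an analytic fact about the rank-sum null, not a
property of any dataset.

## Effect size and the difference distributions

Per instance, the between-condition difference distribution is sampled by
pairing a random sample of condition B with a random sample of condition A
(per feature, `nd = max(group sizes)` draws per instance); the
within-condition dispersion draw is the **larger** of the two conditions'
absolute differences between two distinct random samples of that
condition.  Then

* `diff_btw` = median of the between draws (log2 fold change, B − A),
* `diff_win` = median of the within draws (floored at `win_floor`),
* `effect` = median over draws of (between draw / paired within draw).

Using the per-draw maximum of the two groups' dispersions (rather than the
maximum of per-group medians) was a genuinely open choice; we follow the
per-draw form because it is the quantity the MW plot's x-axis ("maximum
within-condition variation") visualises draw-wise, and it is the more
conservative denominator.  An `|effect|` of 1 means the between-condition
difference is comparable to the within-condition spread; calls worth
following up typically have `|effect|` well above 1.

The result table reports *median* clr abundances (`rab_*`).  Summaries of
this pipeline's outputs elsewhere sometimes describe the abundance column
as an average; we expose medians throughout for consistency with the
median-based difference summaries and note the discrepancy here.

## The synthetic worlds

The generator exists so that every pipeline stage is testable against known
truth without external data.

* **Baseline composition**: log-normal ($\mathrm{sdlog} = 2$), giving the
  several-orders-of-magnitude abundance spread and the heavy low-count tail
  real OTU tables and variant libraries show.
* **Replicate noise** (`dispersion`, default 0.5 log2): each sample's
  expected proportions are the condition composition perturbed feature-wise
  by log-normal noise, then re-closed.  The value is read off real
  selective-growth replicate counts (seven unselected replicates of a
  typical inactive variant span 68–199 reads, ≈0.5 log2 sd — about 4× the
  multinomial floor).  Pure multinomial resampling (`dispersion = 0`) is an
  unrealistically quiet world: replicates become so tight that the small
  geometric-mean shift induced by closure (enriching 69/1600 features by
  6 log2 moves every other feature's clr by −0.26) is declared significant
  for abundant features, which no real replicated experiment supports.
* **Depth**: expected reads per sample with ±10% uniform jitter (unequal
  sequencing effort); counts are multinomial given the per-sample
  composition.
* **Selex world**: condition B multiplies a chosen minority of features by
  $2^{\mathrm{lfc}}$ and re-closes — no feature becomes absolutely less
  abundant, as in a bacteriostatic selection.  **Shift world**: half the
  differential features up, half down (RNA-seq-like).  **Null world**: both
  conditions share one composition.

What the generator does **not** emulate: PCR and GC bias, chimeras,
OTU-clustering artifacts, sample outliers, batch effects, and
feature–feature interactions beyond closure.  A green test on synthetic
data therefore establishes that the *statistical machinery* behaves as
designed under the stated world — it does not certify performance on any
particular real dataset.

## Numerical choices

* **Zero-variance groups** (Welch): equal means give $p = 1$ (no evidence);
  unequal means with zero variance give the smallest positive double rather
  than NaN.  Never reachable from Dirichlet instances; matters for direct
  API use.
* **Wilcoxon**: exact rank-sum null for total $n \le 20$ without ties;
  otherwise normal approximation with tie correction and continuity
  correction.  Two-sided p doubles the smaller tail (equal, for the
  symmetric null, to summing both tails) and is capped at 1.
* **BH**: step-up via cumulative minima; the adjusted value is clamped at
  the raw p-value to guard against a one-ulp rounding dip of $(p\,m)/m$
  below $p$.
* **clr domain**: non-positive inputs are errors, never silently nudged —
  zeros must be handled by the prior upstream.
* **RNG**: all randomness (Dirichlet draws, effect-size pairing,
  simulation) flows from deterministic substreams of one master seed, and
  the caller's `.Random.seed` is restored afterwards.
* **Sign conventions**: the condition of the first sample in input order is
  "A" and `diff_btw` is B − A; plot classification gives significance
  precedence over the rarity (black) coloring when both apply.

## Known limitations

* Exactly two conditions, unpaired, ≥3 replicates each; no multi-group or
  longitudinal designs.
* The clr is the only transform offered (no isometric or additive
  log-ratio); its denominator is the all-feature geometric mean, so a
  condition that changes a *large fraction* of features shifts the
  reference and redistributes apparent change onto unchanged features —
  interpretation is always relative to the geometric mean.
* Expected BH values are means of per-instance BH values, not a BH
  adjustment of expected p-values; the two disagree slightly and the former
  is the deliberate, reported quantity.
* Memory is $O(\text{features} \times \text{samples} \times K)$ doubles for
  the ensemble; very large tables should drop to $K = 16$.
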