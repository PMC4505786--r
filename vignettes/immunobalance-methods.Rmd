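---
title: "Methods: moderated paired differential expression and regulator-balance scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: moderated paired differential expression and regulator-balance scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunobalance)
```

`immunobalance` compares the balance of negative (immunosuppressive) versus
positive (inflammatory) immune-regulator transcripts between a transient
delayed-type hypersensitivity (DTH) skin reaction — elicited by the hapten
diphencyprone (DPCP) and biopsied at its day-3 peak against paired
placebo-treated skin — and chronic psoriasis lesions contrasted with
non-lesional skin. This vignette documents the statistical model, the
tunable parameters, the synthetic-data generator used for validation, and
the design decisions taken where the problem was genuinely open.

## The paired model and its moderated test

Each subject contributes a placebo and a treated biopsy at each sampling
day, so the natural mixed model for a probe's log2 intensity has fixed
treatment and day effects and a subject random intercept. On a *balanced,
complete* paired design the generalized-least-squares estimate of the
treatment effect under that model is identical to the mean of the
per-subject (treated − placebo) differences, so `paired_effects()` computes
exactly that reduction: per probe $g$, differences $d_{g1},\dots,d_{gn}$,
effect $\hat\beta_g = \bar d_g$, residual variance $s_g^2$ (the sample
variance of the differences) on $d_g = n-1$ degrees of freedom. This avoids
an iterative REML solver without approximating anything on the design the
package targets; subjects missing either arm are dropped (with a warning)
rather than recovered by REML, which is the one place the reduction is
conservative. A cross-day contrast can be formed by differencing per-day
paired differences.

With 11 subjects, per-probe variance estimates are noisy, so the test is
*moderated*: variances are assumed exchangeable, drawn from a scaled
inverse chi-square prior with $d_0$ degrees of freedom and scale $s_0^2$.
The posterior variance

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}$$

replaces $s_g^2$, and $t_g = \hat\beta_g / \sqrt{\tilde s_g^2 / n}$ follows
a Student distribution on $d_0 + d_g$ df under the null. Hyperparameters
are estimated by moments matching on the log scale: writing
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$, the spread of $e_g$ in
excess of the sampling contribution $\psi'(d_g/2)$ equals $\psi'(d_0/2)$,
solved by Newton inversion of the trigamma function (tolerance $10^{-10}$,
at most 75 iterations); $s_0^2$ then comes from the mean of $e_g$. If the
observed spread does not exceed the sampling contribution there is no
finite solution: $d_0 = \infty$ is used (complete shrinkage, normal
reference), with $s_0^2$ the plain mean of the variances — in that regime
all probes share one variance and the mean is its moment estimate. The
override `d0 = 0` disables shrinkage and reproduces the classical paired
t-test exactly, which the test suite verifies to 12 digits. Probes with
zero moderated variance are flagged: $t=\pm\infty$ is reported as $p=0$
(or $p=1$ when the effect is also zero). Raw p-values are adjusted by the
Benjamini–Hochberg step-up procedure (via `stats::p.adjust`, verified
against a brute-force implementation of the step-up definition).

Fold changes are reported linear and positive: $\mathrm{FCH} = 2^{\hat\beta}$,
so 0.3 means roughly 3.3-fold *down*.

## Filtering and batch adjustment

`filter_low()` keeps probes exceeding `expr_floor` (default 4.0 log2
units, the bottom of the usual array intensity range) in at least
`min_fraction` (default 0.25) of samples and whose variance exceeds
`var_floor` (default 0.01). The source analysis states such a filter
without thresholds; these defaults are explicit, exposed arguments, and no
attempt was made to reverse-engineer the originals.

`adjust_batch()` removes hybridization-date batch effects with the
parametric empirical-Bayes location/scale model: probe-wise
standardization regressing out protected covariates (treatment, day),
per-(batch, probe) location $\gamma$ and scale $\delta^2$ estimates, a
normal prior on locations and inverse-gamma on scales with hyperparameters
by method of moments, iterative shrinkage (relative tolerance $10^{-6}$,
cap 200 iterations), then back-transformation. Batch scale estimates use
$1/n_b$ (maximum-likelihood) denominators, which makes an input of two
exactly duplicated batches a numerical no-op; when scale estimates are
essentially constant across probes the moment prior degenerates and
complete shrinkage is applied directly. A single batch bypasses adjustment;
a batch with one sample is an error (its scale is not estimable). One
property worth stating honestly: *no* empirical-Bayes location/scale
adjustment is exactly idempotent, because a second pass re-estimates and
re-shrinks the chi-square sampling noise of the scale estimates; measured
on simulated data the second-pass footprint is below 1% of the first-pass
adjustment, which is what the test suite asserts.

## Regulator gene lists

The positive-regulator list is constructed from an ontology and annotation
file: all genes annotated (non-`NOT`) under the closure of `GO:0002684`
("positive regulation of immune system process"), minus all genes under
the closure of `GO:0002683` ("negative regulation of immune system
process"). Closures follow `is_a` and `part_of` edges only — following
`regulates` edges would let the two families engulf each other. The
subtraction is symbol-level, the output is asserted disjoint from the
negative family on every run, and the result depends on the GO release and
annotation file supplied, which the package deliberately does not pin.

The negative-regulator list ships curated: the unique symbols of the
packaged differential table plus the qPCR/immunohistology panel members
not in it (LAG3, PDCD1, IDO1, IL10), under official symbols. Users can
substitute their own lists via `read_gene_list()`.

## Transcriptomes, enrichment and the balance score

A *transcriptome* here is the set of probes or genes passing
`fdr < fdr_max` and a directional fold-change threshold. The defaults
`fch_min = 2`, `fdr_max = 0.05`, up-regulated only, reproduce the packaged
table's two headline counts (7 psoriasis genes, 52 DPCP day-3 probes)
exactly; the table's two down-regulated probes (VTCN1, GEM at FCH 0.3) are
excluded by the direction default, and `direction` is an argument. Both
counting levels are first-class because the source counts mix them (the
"7" is gene-level, the "52" probe-level at identical thresholds); every
report labels the level. Gene-level collapse takes the *representative
probe* with maximal $|\log_2 \mathrm{FCH}|$, ties broken lexicographically
by probe id — CTLA4's five probes collapse to the 21.6-fold one, matching
how genes are conventionally quoted.

Enrichment of a list in a transcriptome fills the 2×2 table over a stated
gene universe (by default all symbols on the filtered table — the only
universe two contrasts share), reports the sample odds ratio with a
Haldane–Anscombe +0.5 correction when any cell is zero (flagged), a Woolf
normal-theory 95% CI on the log scale, and the exact conditional two-sided
p (`stats::fisher.test`, verified against exhaustive hypergeometric
enumeration on small universes).

The balance score summarizes a contrast by the mean $\log_2$ fold change
over each list's genes and their ratio (negative / positive). The
averaging scope is genuinely ambiguous in the source ("all genes in the
given gene set" versus only transcriptome members), so both are
implemented behind `scope = "list"` (default) and `"transcriptome"`; the
ratio is flagged undefined when the positive-list mean is within $10^{-8}$
of zero. Sampling days are treated as independent contrasts (day 120
labelled "late"); whether they entered one joint model originally is not
recoverable from the source.

## The synthetic-data generator

`simulate_expression()` generates
$y_{gi} = \mu_g + u_{s(i)} + b_{k(i),g} + x_i \beta_{g,\mathrm{day}} + \varepsilon_{gi}$:
baseline $\mu_g \sim U[4, 12]$ log2 units (spanning the array range, so
the low-expression filter is exercised), subject intercepts
$u_s \sim N(0, 1^2)$, per-(batch, probe) shifts
$b \sim N(0, 0.5^2)$ with subjects assigned whole to batches (balanced
across treatment), residual variances
$\sigma_g^2 \sim s_0^2 d_0/\chi^2_{d_0}$ with defaults $d_0 = 4$,
$s_0^2 = 0.05$ — a realistic microarray variance hierarchy and exactly the
family under which moderation is calibrated. Defaults: 11 subjects, days
{3, 14, 120}, 3 batches, one placebo/treated pair per subject and day.
Effect sets ("negative", "positive", background) are assigned at gene
level, some genes carry two probes (exercising collapse), and the two
built-in effect profiles encode the study's qualitative signatures: the
DTH-like profile induces the negative set strongly at day 3 with decay
(3, 2, 1 log2 units over days), the chronic-lesion-like profile induces
the positive set (2 log2 units, flat) over a weak negative signal (0.5).
`simulate_qpcr()` mirrors the two-group qPCR layout with the true
difference encoded in ΔCt and noise in the target Ct, so `noise_sd = 0`
gives the closed-form $2^{\Delta}$ ratio exactly.

What the generator does *not* emulate: probe-level cross-hybridization,
intensity-dependent variance trends, correlated probes within a gene,
unbalanced or missing pairs, and batch effects confounded with treatment.
Passing recovery tests therefore validates the pipeline's statistics under
its own assumptions, not its robustness to violations of them on real
arrays.

## Problem sizes and numerical conventions

The test suite runs with 200–5,000 probes per simulated dataset, 20,000
draws for hyperparameter recovery, 100 replicates for the DTH-vs-chronic
ordering property and 1,000 for qPCR calibration — sizes chosen so the
full suite completes in well under a minute while keeping Monte-Carlo
standard errors far below the asserted tolerances. All tabular IO is
UTF-8, tab-separated, `.`-decimal; printed `0.0E+00` FDR values are kept
as exact zeros and compared with `<` semantics against thresholds; gene
symbols are upper-cased at every boundary and are the join key across
tables. Every simulation takes an explicit integer seed and records it in
its output.

## Known limitations

* The curated negative-regulator table covers the published portion of the
  original list only; the full lists live in an unavailable supplement, so
  ontology-derived lists depend on the user's GO/GAF files.
* The paired reduction requires each analysed subject to have both arms at
  the contrasted day; it does not borrow strength across incomplete pairs.
* Odds-ratio CIs are Woolf (normal-theory) intervals; for very sparse 2×2
  tables the exact p and the corrected OR are the quantities to trust.
* The qPCR comparison assumes a common amplification efficiency of 2 and a
  single housekeeping reference; multi-reference normalization and
  standard-curve efficiency correction are out of scope.
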