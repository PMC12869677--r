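---
title: "Methods: overlap-aware consensus GWAS estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: overlap-aware consensus GWAS estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bottomline)
```

## The problem and the model

A trait with several published GWAS has several published association
estimates per variant. Combining them naively by fixed-effects
inverse-variance weighting (IVW) assumes the studies are independent; in
practice large biobanks and consortium cohorts recur across publications,
so the studies' estimation errors are positively correlated and the naive
combined standard error is too small. Under the standard approximation for
shared samples, two studies of sizes $n_1, n_2$ sharing $n_o$ participants
have null association z-statistics correlated by

$$ r = \frac{n_o}{\sqrt{n_1 n_2}}. $$

`bottomline` treats this correlation matrix $R$ as estimable from the data
and plugs it into the generalized IVW solution: with per-study weights
$w_i = 1/se_i^2$ and $\Sigma_{ij} = R_{ij}\, se_i\, se_j$,

$$ \hat\beta = \frac{\sum_i w_i b_i}{\sum_i w_i}, \qquad
   \mathrm{var}(\hat\beta) = \frac{w^\top \Sigma\, w}{(\sum_i w_i)^2}, \qquad
   N_\mathrm{eff} = \frac{(\sum_i n_i)^2}{s^\top R\, s},\; s_i = \sqrt{n_i}. $$

The estimator keeps the naive point estimate (weights are unchanged) and
inflates its variance; at $R = I$ it is exactly textbook IVW, and for a
study duplicated with $r = 1$ it returns the original estimate — no
spurious information gain. The assumptions are those of any fixed-effects
synthesis: one shared true effect per variant across studies of the same
trait and ancestry, well-calibrated per-study standard errors, and effect
sizes on a common scale (the package exposes per-study scaling as explicit
user configuration rather than inferring it, since no principled automatic
procedure exists given only summary statistics).

## Estimating the overlap matrix

For each study pair, $\hat r$ is computed from the variants shared by the
pair that look null in both — $|z| < 1.96$ on each side. Two details
matter:

* **Truncation de-biasing.** Conditioning a bivariate normal on the box
  $|z_1| < c,\ |z_2| < c$ attenuates its correlation substantially (a true
  0.5 yields a sample correlation near 0.41 at $c = 1.96$). The raw sample
  correlation is therefore mapped back through the inverse of
  $\rho \mapsto \mathrm{corr}(z_1, z_2 \mid \text{box})$, computed by
  two-dimensional Gauss–Legendre quadrature and inverted by monotone
  interpolation. The estimator is unbiased across $r \in [0,1]$ at the
  null-variant counts used here (recovery within $\pm 0.05$ at $10^4$
  shared null variants); `debias = FALSE` gives the raw estimate.
* **Constraints.** Negative estimates are clipped to zero — overlap can
  only positively correlate two studies of one trait. Pairs with fewer
  than `min_null` shared null variants are set to $r = 0$ with a warning
  rather than estimated noisily. The assembled matrix is projected to the
  nearest positive semi-definite correlation matrix by clipping negative
  eigenvalues and re-normalizing the diagonal to one, so every per-variant
  submatrix yields a valid variance.

The estimator assumes most variants are null; dense polygenicity inflates
$\hat r$ slightly because true effects correlate across studies too. The
$|z| < 1.96$ screen removes the strong signals that dominate that bias.

## Signal enumeration

Association signals are enumerated by greedy LD clumping with deliberately
conservative parameters: lead threshold `p1 = 5e-8` (genome-wide
significance), member threshold `p2 = 5e-6`, `r2 = 0.01`, and a `kb = 5000`
setting read as a ±2.5 Mb window around the lead. The low `r²` threshold
merges aggressively, which under-counts signals but makes cross-approach
signal comparisons robust to LD leakage. Members require `p < p2`
(established clumping semantics); leads require `p < p1`. When a dataset
yields no genome-wide-significant leads, `p1` is relaxed in 10-fold steps
until at least `min_clumps` (default 50) clumps exist, but never beyond
`p2`; the value used is reported. Ties in p are broken by
(chrom, pos, ref, alt), making the output deterministic. Significant
variants absent from the LD panel (typically rare) become single-variant
clumps when they fall outside every clump span; inside a span they are
attached to the covering clump (nearest lead when spans overlap), with the
lead reassigned if the newcomer is more significant, preserving lead
dominance. Clumps from different sources (approaches or ancestries) merge
into one signal whenever they share a variant — connected components of
the variant co-membership graph; singleton appending runs per ancestry
before the cross-ancestry merge.

## The bottom-line procedure

Per trait and ancestry, variants are partitioned at MAF 5% (boundary on
the rare side). Common variants present in ≥ 2 studies get the
overlap-corrected meta-analysis; common variants in one study pass through
unchanged; rare variants take their record verbatim from the largest
dataset containing them — rare-variant estimates are fragile and the
"largest study wins" rule avoids combining heterogeneous low-frequency
calls. Records lacking an allele frequency cannot be MAF-classified and
are routed down the same conservative largest-dataset path, with a count
in the QC report. A variant classified common in one dataset and rare in
another resolves to the largest dataset's record; "largest" means the
largest declared total sample size among datasets containing the variant
(dataset-level, matching how curators describe studies), not per-variant n.
Across ancestries the per-ancestry bottom lines are combined by identity-R
fixed effects (ancestry panels are assumed sample-disjoint), and each
variant is arbitrated against any published trans-ancestry study by
per-variant sample size — the meta-analysis effective N against the
published study's per-variant N — keeping whichever is larger. With no
single-ancestry data at all, the published trans-ancestry statistics are
returned verbatim.

## Validation machinery

The leave-one-out analysis removes the largest study of a trait-ancestry
pair, enumerates its signals as the gold standard (adaptive clumping), and
scores each consensus approach run on the remaining studies (≥ 2 required,
so ≥ 3 overall). A candidate signal replicates if its variant set
intersects any gold signal's variant set — the same conservative
same-signal rule used everywhere in the package. Inside validation the
approaches are clumped at fixed `p1 = 5e-8` without adaptive relaxation:
relaxing the threshold per approach would change what counts as a false
positive across approaches. The analysis is restricted to common variants,
where all approaches are defined. A breakdown of replication by lead
significance bins is available for studying borderline signals.

## What the simulator emulates — and what it does not

`simulate_studies()` draws per-study z-statistics jointly normal with mean
$\sqrt{n_i}\,\lambda_v$, unit variance, cross-study correlation
$n_o/\sqrt{n_i n_j}$, and within-block cross-variant correlation $\rho$
(the study and LD correlations factorize as a Kronecker product per
block). Effect sizes are $\beta = z \cdot se$ with $se = 1/\sqrt{n}$ —
standardized genotypes, so allele frequency does not enter the power
calculation; frequencies are generated only to exercise MAF partitioning.
LD blocks are compound-symmetric with zero correlation across blocks, and
panel r² is exactly $\rho^2$ within blocks. Optional study-private
"artifact" variants receive an additive z-shift in one study only,
emulating study-specific technical signals.

This emulates the features the method's claims depend on — overlap-induced
covariance, block LD, sparse causal effects, sample sizes spanning orders
of magnitude — and omits much of what real summary statistics contain:
realistic LD decay and panel mismatch, frequency-dependent power and
population stratification, binary-trait liability scaling, heterogeneous
per-variant sample sizes within a study, and effect-size heterogeneity
across studies. Passing tests therefore demonstrate correctness of the
algorithms under the stated generative law, not robustness to every
pathology of real data.

The test and acceptance corpora use $10^4$–$2\times10^4$ variants for
calibration and recovery checks, and ten corpora of 12,000 variants × 5
studies for the approach-ordering comparison — sizes at which the
Monte-Carlo error of each checked quantity is several times smaller than
the margin being asserted. For the ordering comparison specifically, the
corpus sits in a near-complete-overlap regime (95% of the smaller study
shared per pair): uncorrected-meta inflation is a per-variant effect, and
at desk-scale variant counts milder overlap produces too few false
positives to separate the approaches; near-complete overlap is also
realistic for repeated analyses of the same biobank. The two smallest
studies carry two artifact variants each, giving the "any GWAS" approach
its documented false-positive source.

## Numerical choices

* P-values are carried as $\log_{10} p$ throughout; combined p-values come
  from the normal log-survival function, stable to $\log_{10} p \approx
  -5000$. Input p of exactly 0 is remapped to the smallest positive double
  and flagged. On disk, the p column is reconstructed from `log10p` in
  scientific notation, so values far below double underflow survive
  round-trips.
* A singular per-variant covariance (possible after aggressive clipping)
  falls back to the identity model for that variant, with a warning.
* Duplicate variant records within one study keep the smallest p.
  Strand-ambiguous (A/T, C/G) variants are harmonized by allele identity
  only; an option drops them. Records whose alleles match the panel in
  neither orientation are dropped and counted.
* The permutation p-value uses the plus-one estimator
  $(1 + \#\{S_b \ge S_\mathrm{obs}\})/(1 + B)$, bounded away from zero and
  super-uniform under the null.
* The enrichment walk is the unweighted running-sum statistic
  ($+1/|\mathrm{ref}|$ at hits, $-1/(N-|\mathrm{ref}|)$ otherwise, score =
  max positive deviation, floored at 0). A significance-weighted variant
  of the walk was considered and rejected: the score feeds a permutation
  test whose null permutes set identity, not significance, and the
  unweighted form keeps the null exchangeable.

## Limitations

The overlap correction inflates standard errors globally, which biases
downstream variance-component estimates (e.g. heritability) downward —
users comparing such estimates across sources should use the
through-origin bias regression provided here to quantify the shift. The
correction assumes a single correlation per study pair; variant-specific
overlap (e.g. partially shared genotyping arrays) is not modeled. The
sample-size-weighted meta-analysis scheme is not implemented — the
effect-size (IVW) scheme is used for both the corrected and uncorrected
paths. Random-effects trans-ancestry modeling, conditional analysis, and
heritability estimation itself are out of scope; only their outputs are
compared by the concordance tools.
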