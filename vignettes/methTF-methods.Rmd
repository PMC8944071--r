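---
title: "Predicting TF drivers of aberrant DNA methylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting TF drivers of aberrant DNA methylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methTF)
```

# The problem

Cancer genomes lose DNA methylation at distal regulatory regions and
gain it at CpG-rich promoters. One mechanism that can produce focal
hypo-methylation is the binding of a transcription factor (TF): an
occupied site is protected from maintenance methylation, so an
up-regulated TF leaves a footprint of hypo-methylated regions
enriched for its motif. Conversely, loss of a TF lets its sites drift
towards methylation. methTF implements a pipeline that works backwards
from this logic: it calls signed differentially methylated regions
(DMRs) between cancer and healthy cohorts from methylation-array beta
values, asks which TF motifs are over-represented in those regions
relative to carefully matched background regions, and keeps the TFs
whose expression change matches the direction of the methylation
change.

Every stage is exercisable without external data through the
synthetic-data module, which generates genomes, probe manifests, beta
matrices with planted DMRs, embedded motif instances, expression
fold-changes and accessibility peaks with known ground truth.

# Sample quality control

Cohorts are first cleaned with `sampleQC()`: PCA (SVD on the
column-centered matrix of the 5000 most variable probes; probes are
not scaled because beta values share the [0,1] scale), retention of
every component whose variance is at least 10% of the first
component's, then quadratic discriminant analysis on the retained
scores with priors equal to class frequencies. Samples whose
maximum-posterior class differs from their label are discarded. The
QDA is fit once on all samples; no refit loop is performed after the
discard, and the probe variance ranking is computed in a single pass.
Class covariances receive a ridge of `1e-6 * mean(diag(cov))`, which
matters when the number of retained components approaches the
per-class sample count.

# DMR calling

Per-CpG statistics come from limma's moderated t (empirical-Bayes
shrinkage of per-probe variances), computed on beta values directly —
an M-value transform is available (`useM = TRUE`) but off by default,
matching the convention of testing the normalized methylation
fraction. Group means, their difference (delta = cancer − healthy),
two-sided p-values and BH q-values are attached per CpG, and CpGs in
exons are excluded.

The region statistic is a Gaussian-kernel smooth of the *signed* t:

$$S_i = \frac{\sum_j w_{ij} t_j}{\sum_j w_{ij}}, \qquad
  w_{ij} = e^{-(x_i-x_j)^2 / 2\sigma^2},\ |x_i-x_j| \le \lambda$$

with $\lambda = 1000$ bp and $\sigma = \lambda/C$, $C = 2$. Because
the per-CpG t statistics are approximately standard normal and
independent under the null, $\mathrm{Var}(S_i) = \sum_j w_{ij}^2 /
(\sum_j w_{ij})^2$, giving a z-score and a two-sided normal p-value
per CpG. Smoothing the signed statistic (rather than a squared
statistic with a chi-square reference) makes the caller sensitive to
the direction of change, so hypo- and hyper-methylated CpGs cannot
reinforce each other into one region. $C$ is the main reconstruction
choice: only $\lambda$ is fixed by convention, and $C = 2$ (a 500 bp
kernel sd truncated at 1 kb) is exposed in the configuration.

Significant CpGs (smoothed p < 0.001 **and** per-CpG BH q < 0.05 —
both gates are applied and both are configurable, since their
interaction is a genuinely open choice) are grouped into candidate
regions wherever consecutive significant CpGs are at most $\lambda$
apart. Within a candidate, maximal runs of at least 2 consecutive
CpGs with the same delta sign become directional regions, whose end
is extended by 2 bp to cover the final CpG dinucleotide. Reporting
filters then require: length ≥ 200 bp, |mean delta| ≥ 0.20 (region
mean, not per-CpG: boundary ties are implemented as ≥ 0.20 and the
start rule as strict > 0.50 / < 0.50), healthy-cohort mean above 50%
for hypo regions and below 50% for hyper regions, and finally the
accessibility rule: hypo DMRs must overlap at least one cancer ATAC
peak (TF binding needs open chromatin), hyper DMRs must overlap none.

# Genomic-context classification

Each DMR is classified on three independent axes by `annotateDMRs()`:

* **CpG composition** — G+C content $x$ against the observed/expected
  CpG ratio $y = N_{CpG} L / (N_C N_G)$ (the Gardiner-Garden form;
  the ratio's exact formula is a reconstruction choice), split by the
  boundary line $y = -1.4(x - 0.38) + 0.51$: above is CpG-rich, below
  CpG-poor. A point exactly on the line is classed poor; this and the
  proximity tie below each affect well under 0.1% of simulated
  regions.
* **TSS proximity** — gap distance from the region interval to the
  nearest TSS, proximal iff ≤ 2000 bp (tie at exactly 2000 bp →
  proximal); no TSS on the chromosome gives distal with infinite
  distance.
* **Context** — the region midpoint decides promoter (within 2 kb of
  a TSS), else intron (inside a gene body), else intergenic. The
  midpoint rule and the promoter > intron > intergenic precedence are
  reconstructions; only the three category names are fixed.

# Motif enrichment

Motif summaries follow the information-content formulas
$local.IC_j = 2 + \sum_i f_{ij}\log_2 f_{ij}$ (with $0\log 0 = 0$),
$IC = \sum_j local.IC_j$, $GC.freq_j = f_{Gj}+f_{Cj}$, and mean GC =
the IC-weighted mean of $GC.freq_j$, classed rich above 0.75 and poor
below 0.25.

`scanHits()` scores both strands with the log-odds of the frequency
matrix against an iid background. Zero frequencies are replaced by a
pseudofrequency of 0.01 (columns renormalised) for scanning only; IC
uses the raw frequencies. Scores are discretised at 1/1000 bit and
the exact null score distribution is obtained by convolving the
per-column distributions, so every offset receives an exact position
p-value; a hit is an offset with p ≤ 2^−IC. This threshold
self-calibrates stringency to motif specificity and makes the
expected chance-hit rate per offset approximately 2^−IC. Position
p-values (not sequence-level E-values) are used, consistent with
counting per-region occurrences. The background defaults to the
pooled composition of the scanned sequence set (uniform by flag).

Control regions are rejection-sampled per DMR (`nPerDmr = 10` by
default; the multiplicity is unspecified by convention and exposed):
identical length, same CpG class, proximity class and context,
exactly the same number of manifest probes, fully mappable
(non-repeat), not on chromosome Y, and non-overlapping with any DMR
or other control. When the sampling cap is reached, the probe-count
match relaxes to ±1 (logged); a DMR with no control even then is
excluded with a warning.

Enrichment counts regions containing ≥ 1 occurrence. A pseudocount
of 1 is added to **all four** counts (the alternative — numerators
only — is available by flag, as is excluding the pseudocount from the
test), the fold is the percent of DMRs with the motif over the
percent of controls, and significance is the one-sided upper-tail
hypergeometric p on the pseudocounted urn; contrasting hypo- against
hyper-methylated DMRs uses a two-sided p (2 × min of the tails,
capped at 1) to catch depletion. Motifs are flagged enriched at
p < 0.001; no multiple-testing correction is applied across motifs by
design.

Motif clustering is a deliberately simple stand-in for alignment
tools: pairwise similarity is the best mean column-wise Pearson
correlation over ungapped offsets with ≥ 4 overlapping columns
(including the reverse complement), clustered by average linkage on
1 − similarity and cut at 0.05. Cluster counts are not expected to
match those of dedicated motif-alignment software.

# TF-expression integration

Expression arrives as FPKM. Group means are arithmetic;
`differentialExpression()` reports
`log2FC = log2((mean_cancer + 0.5) / (mean_healthy + 0.5))` with a
Welch t on `log2(FPKM + 1)` and BH correction. A count-based
negative-binomial model is intentionally not used: this pipeline
consumes FPKM-level tables, not read counts, and the selection gate
(below) only uses the sign of the mean difference.

`selectCandidateTFs()` emits a (TF, motif) pair when the motif is
enriched (p < 0.001) and the TF's mean FPKM difference has the
matching sign: positive for hypo-DMR enrichments (an up-regulated TF
protecting its sites), negative for hyper-DMR enrichments (a lost TF
whose sites gain methylation). Expression p and q are reported but
not thresholded — no expression significance cutoff enters the
selection. `panCancerSummary()` picks one motif per TF across runs by
the largest sum of −log10 p (interpreting "best p-value summed"
multiplicatively; ranking by the single best p is available with
`method = "min"`), ties broken by motif id.

# Validation statistics

For binding-site validation the package provides:
`windowMeanMethylation()` (200 bp windows around peak summits, CpGs
with ≥ 5 reads, windows with ≥ 2 eligible CpGs in every condition,
unweighted mean of per-CpG fractions);
`amplificationPeakFilter()` (keep peaks whose input read density is
below the peak set's Q3 — linear-interpolation quantile — or that are
≥ 10-fold enriched over input); `filterWgbsDmrs()` (the array gates
applied to externally called bisulfite DMRs);
`overlapFoldEnrichment()` (fraction-of-regions-with-overlap ratio
with the same pseudocounted hypergeometric urn as the motif test —
the fold definition is a documented reconstruction, counting regions
rather than peaks); and `shuffleOverlapEnrichment()` (each region
relocated uniformly within the shuffle space of its own chromosome,
preserving length but not inter-region spacing; empirical
p = (1 + #{null ≥ observed}) / (1 + n)).

# The synthetic benchmark

`simulateStudy()` fans one global seed out to per-generator child
seeds (`childSeed(seed, k)`, counters 1–7), so adding a generator
does not perturb the others. The defaults define the package's
benchmark conditions: 8 autosomes of 2 Mb at GC 0.5 plus a chrY
(with a 5% repeat mask, so the mappability and chromosome-Y exclusion
rules are exercisable), 80 genes, 40,000 probes at CpG dinucleotides
with 30% promoter bias, 120 hypo + 80 hyper planted regions with a
methylation change of 0.3 spanning ≥ 3 probes, 20 + 20 samples, Beta
precision φ = 30. These sizes keep a full pipeline run around half a
minute while leaving hundreds of regions for the enrichment
statistics; the tests state the sizes they use.

Design choices worth knowing:

* **Beta noise.** Beta values are drawn from Beta(μφ, (1−μ)φ) — the
  bounded-support analogue of array betas. No published noise model
  exists for normalized array betas, so this is a modeling
  substitute; background probes use a bimodal baseline (40% lowly,
  60% highly methylated) mimicking real array marginals. At φ = 30
  and 20 vs 20 samples the per-CpG moderated p-values are uniform
  under the null (pooled KS across 20 runs in the tests).
* **Planted regions are coherent CpG neighbourhoods.** Consecutive
  member probes are at most 900 bp apart (inside the 1 kb smoothing
  window) and the probe span clears 260 bp; regions avoid exons and
  chrY and sit ≥ 2 kb apart so neighbouring regions are not merged
  by the caller. Hypo regions take healthy means in (0.65, 0.85),
  hyper in (0.15, 0.35), satisfying the start-methylation gates by
  construction.
* **Motif embedding writes the consensus** (highest-frequency base
  per column) rather than a sampled instance: the consensus is the
  maximum-score word, whose exact p-value never exceeds 2^−IC, so an
  embedded instance is guaranteed to be a scan hit and enrichment
  tests are deterministic in expectation. Embedding sites avoid
  manifest probe CpGs so the methylation signal is untouched.
* **Random motif libraries** sharpen Dirichlet columns to ICs of
  roughly 10–14 bits at width 8, the range typical of curated TF
  motif collections — informative enough that chance presence does
  not saturate 300–2000 bp regions.
* **Accessibility fixtures** cover every hypo truth region with a
  peak and no hyper region, so the ATAC filter is loss-free on truth;
  bisulfite fixtures draw coverage Poisson(10) and methylated counts
  binomially at the truth methylation level.

What passing the synthetic benchmark does **not** show: the generator
has iid genome composition (no repeat families or CpG islands with
realistic structure), no batch effects, no cell-type heterogeneity,
no copy-number structure, and probe-level noise that is independent
across probes. Results on real arrays depend on all of these; the
benchmark demonstrates correctness of the statistical machinery, not
biological recall rates.

A note on one property of the benchmark: the reporting filter
|mean delta| ≥ 0.20 censors a region whose true effect is exactly
0.20 with probability ≈ 1/2 regardless of sample size (the estimate
is unbiased and symmetric around the gate), so recovery after
reporting filters is not monotone in n at that boundary. The
monotonicity test therefore measures detection recall (filters
disabled); recovery at the benchmark's delta = 0.3 is unaffected.

# Numerical choices and degenerate inputs

* Score discretisation for exact scan p-values: 1/1000 bit,
  configurable.
* A probe with identical values in both groups has delta = 0, t = 0,
  p = 1 (with moderation; the unmoderated t is 0/0 there).
* An isolated CpG (no neighbour within λ) is its own kernel:
  smoothed z equals its t.
* Empty inputs propagate as empty results (no DMRs, empty candidate
  lists, empty peak sets: all hypo rejected, all hyper kept).
* `quantile(type = 7)` (linear interpolation) defines Q3 in the peak
  amplification filter.
* Hierarchical-cluster ids are renumbered in motif order so output
  is deterministic.
* All external interval files are 0-based half-open (BED
  convention); internal `GRanges` are 1-based closed, and the IO
  helpers convert.

# Known limitations

* The smoothing variance assumes independent per-CpG statistics;
  correlated probes (e.g. within 50 bp) make the normal p-values
  slightly anti-conservative. The per-CpG FDR gate limits the
  practical impact.
* Control matching is rejection sampling; extremely atypical DMRs
  (very long, very probe-dense) may exhaust the candidate cap and be
  excluded from enrichment (always logged).
* The Welch-on-log2 expression test is a substitute for count-based
  models and is only used for reporting; selection uses the sign of
  the mean difference.
* Motif clustering is similarity-based and ungapped; it is not a
  replacement for alignment-based motif comparison tools.
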