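# methTF

Predicting transcription factors (TFs) that drive aberrant DNA
methylation in cancer.

TF binding protects regulatory DNA from maintenance methylation, so a
TF that is up-regulated in a tumour leaves focal *hypo*-methylated
regions enriched for its binding motif, while a TF that is lost lets
its sites gain methylation. methTF turns this logic into a tested
pipeline for probe-level methylation arrays:

1. **Sample QC** (`sampleQC`) — PCA on the 5000 most variable probes,
   retention of components with ≥ 10% of the first component's
   variance, quadratic discriminant analysis, and discard of
   misclassified samples.
2. **DMR calling** (`callDMRs`) — limma moderated t per CpG, exon
   exclusion, Gaussian-kernel smoothing of the *signed* t
   (λ = 1000 bp, σ = λ/2) with normal p-values
   (z_i = Σ w_ij t_j / Σ w_ij, scaled by √(Σ w_ij² / (Σ w_ij)²)),
   grouping of significant CpGs (smoothed p < 0.001, per-CpG BH
   q < 0.05), direction-consistent runs of ≥ 2 CpGs, then the
   reporting filters: ≥ 200 bp, |mean Δβ| ≥ 0.20, healthy mean > 50%
   (hypo) / < 50% (hyper), and the chromatin-accessibility rule
   (hypo DMRs must overlap an ATAC peak, hyper DMRs must not).
3. **Genomic-context classification** (`annotateDMRs`) — CpG-poor vs
   CpG-rich by the boundary line y = −1.4(x − 0.38) + 0.51 in the
   (G+C content, observed/expected CpG) plane; proximal vs distal at
   2 kb from the nearest TSS; promoter/intron/intergenic by region
   midpoint.
4. **Motif enrichment** (`motifEnrichment`) — per-motif information
   content IC = Σ_j (2 + Σ_i f_ij log2 f_ij), exact-p-value motif
   scanning at threshold 2^−IC, matched control regions (same length,
   CpG class, proximity, context and probe count; mappable, non-chrY),
   and a one-sided hypergeometric test with a pseudocount of 1 on all
   counts (two-sided when contrasting hypo vs hyper DMRs).
5. **TF integration** (`selectCandidateTFs`, `panCancerSummary`) —
   emit TFs whose motif is enriched (p < 0.001) *and* whose mean FPKM
   difference matches the methylation direction; summarise across
   cancer types by the best −log10 p sum.
6. **Validation statistics** (`overlapFoldEnrichment`,
   `shuffleOverlapEnrichment`, `windowMeanMethylation`,
   `amplificationPeakFilter`, `filterWgbsDmrs`) — the overlap and
   window statistics used to check TF–methylation relationships
   against binding peaks and per-CpG bisulfite calls.

A first-class synthetic-data module (`simulateStudy` and the
`generate*`/`simulate*` functions) produces genomes, probe manifests,
beta matrices with planted DMRs, embedded motif consensus instances,
expression fold-changes and accessibility peaks with known ground
truth, so the whole pipeline is benchmarkable offline.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "methTF",
                               load_package = "installed")'
```

## Worked example

Simulate a small study with 25 planted DMRs, embed a 10-bp motif
consensus in 80% of the hypo regions, and recover both:

```r
library(methTF)

set.seed(1)
f <- matrix(0.03, 4, 10)
f[cbind(sample(1:4, 10, TRUE), 1:10)] <- 0.91
planted <- Motif("planted", f, tf = "TF_planted")
lib <- c(list(planted), randomMotifSet(9, seed = 3))

study <- simulateStudy(seed = 42, nChrom = 2, chromLength = 5e5,
                       nGenes = 20, nProbes = 4000,
                       nHypo = 15, nHyper = 10,
                       embedMotifs = list(planted), embedRate = 0.8)

dmrs <- callDMRs(study$beta, exons = study$annotation$exons,
                 atacPeaks = study$fixtures$atacPeaks)
unlist(scoreRecovery(dmrs, study$truth))
#>    recall precision   nCalled    nTruth
#>         1         1        25        25

hypo <- dmrs[dmrs$direction == "hypo"]
names(hypo) <- paste0("dmr", seq_along(hypo))
hypo <- annotateDMRs(hypo, study$genome, study$annotation)
ctrl <- generateMatchedControls(hypo, study$genome, study$manifest,
                                study$annotation, nPerDmr = 5, seed = 1)
enr <- motifEnrichment(lib, hypo, ctrl, study$genome)
head(enr[, c("motif", "n_dmr_with", "n_ctrl_with", "fold", "p",
             "enriched")], 3)
#>    motif n_dmr_with n_ctrl_with      fold            p enriched
#>  planted          9           4 10.406250 8.332924e-06     TRUE
#>   motif5          5          10  2.312500 9.216833e-02    FALSE
#>   motif8          9          26  1.600962 9.982195e-02    FALSE
```

All 25 planted regions are recovered with no false positives, and the
embedded motif is the only one enriched over the matched controls
(fold 10.4, hypergeometric p = 8.3 × 10⁻⁶; the pseudocount of 1 is
included in the printed counts). At the package's full benchmark
scale (200 planted DMRs, 16 Mb genome, 40k probes, a 20-motif
library, a planted +2 log2FC for the embedded motif's TF and a −2
decoy) the planted motif ranks first at p ≈ 3 × 10⁻¹² and the planted
TF is the sole predicted hypo-driver.

## Documentation

The methods vignette (`vignettes/methTF-methods.Rmd`) describes the
models, the tunable parameters and their defaults, what the
synthetic generator does and does not emulate, the numerical choices,
and known limitations.
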