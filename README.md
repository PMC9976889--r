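# h33dyn

Downstream analysis of inducible histone-H3.3 incorporation time courses
(Time-Seq) with matched RNA-seq, for chromatin biologists studying how the
oncohistone-type substitutions H3.3K27M and H3.3K27L change where and how
fast H3.3 is deposited — and what that does to gene expression during stem
cell differentiation.

The experimental design the package serves: mouse ESC lines carrying a
Dox-inducible tagged H3.3 (wild type, K27M, or K27L, plus a PRC2-inhibitor
control), profiled by ChIP-seq of the tag at 4, 8, 24 and 72 h after
induction, in undifferentiated (ESC) and retinoic-acid-differentiated (RA)
states, with RNA-seq alongside.

## What it computes

* **Binned coverage tracks** — bedGraph coverage is binned at 200 bp
  (fractional-overlap weighting) and RPM-normalized,
  `v'_b = 10^6 · v_b / Σ_included v`, with chromosome 8 excluded from the
  denominator (and from all gene-level analyses) because of a suspected
  duplication in the study system.
* **Anchor-centred profiles** — strand-oriented anchors × offsets matrices
  around TSSs or enhancers (±10 kb), metagene curves (mean ± 2·SE), and
  score-sorted heatmap ordering. H3.3 shows its characteristic double peak
  flanking the TSS.
* **Gene window score** — the per-gene binding statistic: mean bin signal
  over the TSS-flanking windows −1.2 kb…−200 b and +400 b…+1.2 kb (nine
  200 bp bins), strand-oriented.
* **Comparative statistics** — average-rank Spearman ρ (exact permutation p
  below n = 10), Student t / Mann–Whitney U group tests (U when group sizes
  differ; exact enumeration for small samples), Fisher-z comparison of
  correlations, hypergeometric over-representation with BH correction, and
  a two-sided Fisher exact test by point-probability summation.
* **Expression pipeline** — TPM (`10^6·(c_g/l_g)/Σ(c/l)`), max-expression
  transcript-variant collapse, fold-change/BH DE classification
  (padj < 0.05 and FC < 0.5 or > 2), gene groups by between-line fold
  change, and **state-retention correlations**: Spearman ρ between ESC and
  RA expression of one line — elevated ρ in a mutant is the signature of
  retained stem-state expression.
* **Dynamics** — binding-target stability across timepoints, and the
  early-binding → late-expression contingency procedure: among genes with
  high (top-quartile) tag binding at 8 h, the fraction highly expressed at
  72 h, compared between lines by Fisher's exact test.
* **CyTOF normalization** — arcsinh(x/5), per-marker standardization, and
  per-cell subtraction of the mean standardized core-histone level from
  each epigenetic marker.
* **A synthetic-experiment generator** — genomes, expression programs and
  ChIP tracks with the qualitative structure above (double TSS peak with
  amplitude ∝ expression percentile, mutant incorporation boost β ramping
  in with Dox kinetics, ESC-program retention r after differentiation,
  early-binding → late-expression coupling δ), fully deterministic in one
  seed, emitting plain bedGraph/BED/TSV bundles that round-trip through the
  package's own readers.

## Worked example

```r
library(h33dyn)
cfg <- simulationConfig(seed = 42, timepoints = c(8, 72))
genome <- makeGenome(cfg)
sim <- simulateExpression(cfg, genome)
expr <- tpmNormalize(sim$counts, geneLengths(genome$genes))   # chr8 excluded

tracks <- lapply(c(WT = "WT", K27M = "K27M"), function(ln)
  rpmNormalize(binCoverage(
    simulateChip(cfg, genome, sim$truth, ln, timepoint = 72), genome$layout)))

prof <- metageneProfile(anchorMatrix(tracks$WT, tssAnchors(genome$genes)))
head(prof[prof$offset >= -600 & prof$offset < 0, ], 3)
#>    offset     mean      se2
#> 48   -600 63.79428 7.584745
#> 49   -400 63.54027 7.588132
#> 50   -200 45.67176 4.344819

scores <- lapply(tracks, geneWindowScore, genes = genome$genes)
for (ln in names(scores)) {
  r <- bindingExpressionCorrelation(
    scores[[ln]], expr,
    sampleSelect(expr, line = ln, state = "ESC", timepoint = 72))
  cat(sprintf("%-5s binding-expression Spearman rho = %.3f (n = %d)\n",
              ln, r$rho, r$n))
}
#> WT    binding-expression Spearman rho = 0.560 (n = 255)
#> K27M  binding-expression Spearman rho = 0.710 (n = 255)

for (ln in names(scores))
  cat(sprintf("%-5s ESC-RA retention rho = %.3f\n", ln,
              stateRetentionCorrelation(expr, ln)$rho))
#> WT    ESC-RA retention rho = -0.111
#> K27M  ESC-RA retention rho = 0.603
```

The metagene rows show the upstream arm of the double peak (the −400 bp
component spans the −600/−400 offset bins; `se2` is twice the standard
error across the 255 non-chr8 genes). The correlations recover the two
injected mutant effects: binding tracks expression more tightly in K27M
(ρ 0.71 vs 0.56), and after RA differentiation the K27M transcriptome stays
correlated with the undifferentiated state (ρ 0.60) while WT reorganizes.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

generates a complete synthetic bundle under the given seed, re-runs the
entire pipeline on it from the files on disk (binning, normalization,
profiles, window scores, stability, binding–expression and retention
correlations, and the contingency procedure), prints a short summary, and
writes the JSON report to `--out`.

## Vignette

`vignettes/h33-incorporation-dynamics.Rmd` documents the model, every
tunable parameter of the synthetic generator with its rationale, the
coordinate and tie-breaking conventions, and known limitations — including
a candid analysis of which simulated effects are and are not detectable at
desk scale.
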