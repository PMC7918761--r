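# met1C

Methionine-cycle kinetics and RRBS differential methylation for early
embryos.

## The problem

One-carbon (1C) metabolism supplies the methyl groups for DNA methylation
through the methionine cycle: methionine → SAM (by MAT isoforms), SAM → SAH
(transmethylation, including DNA methyltransferases), SAH → homocysteine
(AHCY), and homocysteine either remethylated to methionine — by
folate/B12-dependent methionine synthase (MTR) or by betaine-dependent BHMT
— or removed by transsulfuration (CBS). Ovarian follicular and embryonic
cells of cattle (and several other species) lack BHMT, unlike liver. That
raises two linked questions this package addresses quantitatively:

1. **Kinetics.** Does losing the BHMT remethylation route make SAM-mediated
   transmethylation more volatile when methionine supply fluctuates — as it
   does between culture media, or with maternal diet?
2. **Methylome.** When bovine embryos are produced in vitro at 10 vs 50 µM
   added methionine, which CpGs, genes and pathways change methylation in
   the inner-cell mass (ICM) and trophectoderm (TE), and are imprinted
   genes affected?

`met1C` implements a deterministic ODE model of the methionine cycle
(enzyme knockouts, steady states, periodic forcing, volatility metrics) and
the full count-level RRBS workflow (bismark coverage import, coverage and
variant filtering, λ spike-in conversion QC, per-CpG chi-squared testing
with Benjamini–Hochberg correction, >20-point effect filtering,
promoter/exon/intron and CpG-island/shore annotation, ≥5-DMCs-in-1-kb gene
clustering, hypergeometric gene-set enrichment, and per-gene REML mixed
models with a random CpG intercept). A seeded synthetic-data generator
reproduces the 12-library design (3 replicates × {ICM, TE} × {10, 50} µM)
with complete ground truth, so every stage is validated end to end. See the
methods vignette (`vignettes/methionine-methylome.Rmd`) for the model, the
rate laws, and all design choices.

## The statistics in brief

* Per-CpG test: binomial deviance (likelihood-ratio) chi-squared on pooled
  group counts, 1 df — equal to the classical 2×2 G-test; BH q-values over
  all tested sites; DMC = q ≤ 0.05, |Δ| > 20 percentage points, in gene
  body or promoter.
* Clustering: gene qualifies iff sorted DMC positions satisfy
  p[i+4] − p[i] ≤ 1000 for some i.
* Enrichment: P(X ≥ k) under Hypergeometric(N, K, n) per GMT term, BH
  across terms, universe = genes with ≥1 tested CpG in gene/promoter.
* Imprinted genes: `prop ~ replicate + methionine × lineage + (1 | CpG)`,
  REML, Wald z-tests, OLS fallback on singular fits.
* Volatility: relative amplitude (max − min)/mean of the transmethylation
  flux over 3 forcing periods after discarding 5 transient periods.

## Worked example

Kinetics — what removing BHMT does:

```r
library(met1C)
hep <- enzymeProfile("hepatic")          # MATI/MATIII/BHMT present
steadyState(hep, 100)                    # constant 100 uM/h methionine input
#>   met   sam   sah   hcy
#> 41.35 42.63  1.65 17.10                # uM

ko <- knockoutExperiment(hep, "BHMT", sinusoidInput(100, 0.3, 2))
ko$baseline$volatility$relAmplitude      #> 0.0634
ko$knockout$volatility$relAmplitude      #> 0.123
ko$knockout$mtrFraction                  #> 1
```

With a ±30% sinusoidal methionine supply (period 2 h), the relative
amplitude of the SAM-dependent transmethylation flux roughly doubles
(0.063 → 0.123) when BHMT is removed, and homocysteine remethylation
becomes 100% MTR-dependent — the kinetic basis for expecting BHMT-less
cell types to be epigenetically sensitive to methionine supply.

RRBS — end-to-end on a synthetic dataset with known truth:

```r
d <- rrbsDesign(seed = 1)                # 12 samples, 6000 CpGs, truth known
s <- runPipeline(d, "run1")
s$contrasts$ICM_10v50
#> tested 6104 CpGs; 183 DMCs: 39 gain (21.3%), 144 loss (78.7%);
#> 20 genes; sensitivity 0.91, empirical FDR 0.005
s$enrichment$ICM
#> 10 qualifying cluster genes, 10/10 designed recovered;
#> 'affected_set' FDR 2.7e-05 (top term)
```

The numbers mean: of ~6100 testable CpGs, 183 pass q ≤ 0.05 with a >20
point difference inside genes/promoters, predominantly hypomethylated at
the lower methionine concentration (as designed, 80% of planted effects
are losses); 91% of planted differential CpGs that survive coverage
filtering are recovered at 0.5% false discovery; all ten genes planted with
clustered DMCs qualify under the ≥5-in-1-kb rule, and the planted gene set
is the top enrichment hit. Per-contrast outputs (`dmc_*.tsv`,
`clusters_*.tsv`, `enrichment_*.tsv`, `imprint_report.tsv`) and a JSON run
summary are written to the run directory.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/met1c.R simulate --profile follicular --amplitude 0.3 --out traj.tsv
Rscript inst/scripts/met1c.R run --seed 1 --out run1/
```

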