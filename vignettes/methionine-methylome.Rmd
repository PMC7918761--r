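---
title: "Methionine-cycle kinetics and RRBS differential methylation: methods"
author: "met1C authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methionine-cycle kinetics and RRBS differential methylation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(met1C)
```

# Scope

`met1C` couples two analyses of one-carbon (1C) metabolism in early embryos.
First, a deterministic kinetic model of the methionine cycle asks what the
absence of betaine–homocysteine methyltransferase (BHMT) — the situation in
ovarian follicular and embryonic cells of cattle and several other species —
does to the stability of SAM-mediated transmethylation when methionine
supply fluctuates. Second, an RRBS (reduced-representation bisulfite
sequencing) workflow carries per-CpG methylated/unmethylated read counts
from bismark-style coverage files through differential-methylation calling,
genomic annotation, DMC clustering, gene-set enrichment and imprinted-gene
mixed models. A seeded synthetic-data generator emulates the 12-library
design (3 replicates × {ICM, TE} × {10, 50} µM added methionine) with known
ground truth, so every downstream stage can be validated end to end.

# The kinetic model

## States, fluxes and stoichiometry

Four metabolites are dynamic state variables (µM): methionine (Met), SAM,
SAH and homocysteine (Hcy). Nine reactions connect them:

* Met → SAM: the three methionine adenosyltransferase isoforms. MATI and
  MATII follow Michaelis–Menten kinetics with SAM product inhibition,
  `vmax·Met/(Km+Met)·Ki/(Ki+SAM)`; MATII has a much lower Km for methionine
  (4 µM vs 41 µM). MATIII is activated cooperatively by SAM,
  `vmax·Met/(Km+Met)·(1 + α·SAM²/(Ka²+SAM²))`.
* SAM → SAH: GNMT, a Hill (n = 2) function of SAM inhibited by SAH, and a
  generic SAM-dependent transmethylation flux (labelled DNMT),
  `vmax·SAM/(Km+SAM)·Ki/(Ki+SAH)`. The DNMT flux is the model's readout for
  "SAM-mediated transmethylation".
* SAH ⇌ Hcy: AHCY as reversible mass action, `αf·SAH − αr·Hcy·Ado`, with the
  adenosine pool held fixed.
* Hcy removal: remethylation by MTR (saturable in Hcy and in the fixed
  5-methyltetrahydrofolate pool) and BHMT (saturable in Hcy and the fixed
  betaine pool), and transsulfuration by CBS, activated by (SAM+SAH)².

These regulatory motifs — SAM inhibition of MATI, SAM activation of MATIII,
SAH inhibition of methyltransferases, (SAM+SAH) activation of CBS — are the
canonical ones in liver-based models of this pathway. The derivative system
is

```
dMet/dt = V_in(t) + V_MTR + V_BHMT − V_MATI − V_MATII − V_MATIII
dSAM/dt = V_MATI + V_MATII + V_MATIII − V_GNMT − V_DNMT
dSAH/dt = V_GNMT + V_DNMT − V_AHCY
dHcy/dt = V_AHCY − V_MTR − V_BHMT − V_CBS
```

so the 1C backbone enters only through the methionine input and leaves only
through transsulfuration: summing the four equations gives
`d(total)/dt = V_in − V_CBS`, an identity the tests verify numerically
along trajectories.

## Parameters and presets

The default parameter table (units µM and h) is a package default chosen so
that the hepatic preset settles, under a 100 µM/h methionine input, at
Met ≈ 41, SAM ≈ 43, SAH ≈ 1.7 and Hcy ≈ 17 µM — the right orders of
magnitude for mammalian cells — with BHMT carrying roughly 70% of
homocysteine remethylation. The values are not fitted to any published
measurement, and reproducing any specific published steady state is a
non-goal; the claim the model is used for is qualitative and robust across
this parameter neighbourhood. Two presets differ only in enzyme presence:
`"hepatic"` (MATI, MATIII, BHMT present) and `"follicular"` (MATII only,
BHMT absent), mirroring the expression patterns of liver versus ovarian
somatic/embryonic cells. `present = FALSE` forces a flux to zero
identically and is bit-for-bit equivalent to `vmax = 0`.

Folate (5-mTHF), betaine and adenosine are fixed pools, not states: the
question under study concerns methionine-cycle dynamics under substrate or
cofactor provision, and all three pools are exposed as perturbable inputs
(`pools =` argument) rather than modelled dynamically.

## Numerics

Integration uses `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`
(stiff-capable; AHCY makes the SAH equation fast). Steady states are found
by Newton-type root finding (`pracma::fsolve`, polished by a damped Newton
pass on the numerical Jacobian) seeded from a 2000 h integration, and are
accepted only if the residual max-norm is below 1e-10 µM/h — otherwise the
call fails loudly rather than returning the best iterate. The independent
cross-check, enforced in the test suite, is agreement between the long-time
integrator limit and the root-finder solution to better than 1e-6 µM per
metabolite.

## The volatility experiment

`transmethylationVolatility()` starts the system at its constant-input
steady state, forces the methionine input sinusoidally
(`baseline·(1 + a·sin(2πt/T))`), discards 5 forcing periods as transient,
and summarises the DNMT flux over the following 3 periods as a relative
amplitude, `(max − min)/mean`, sampled at 200 points per period. Those
window choices are fixed so that volatility numbers are reproducible; by 5
periods the periodic orbit is reached to well within the reporting
precision.

The model's core reproducible result: with the default table, removing BHMT
roughly doubles the relative amplitude of transmethylation for forcing
amplitudes between 0.1 and 0.5 (e.g. 0.063 → 0.123 at amplitude 0.3,
period 2 h). The mechanism is that BHMT is an extra, nearly
amplitude-insensitive methionine source (its substrate pool is fixed and
its Hcy dependence is saturable), so removing it makes total methionine
supply — and hence SAM and the transmethylation flux — track input
fluctuations more closely, while remethylation becomes entirely dependent
on MTR (`knockoutExperiment()` reports the MTR fraction of remethylation,
which is 1 after BHMT knockout). The package asserts the strict ordering,
not its magnitude, which is parameter-dependent.

# The RRBS workflow

## Data model and import

Counts live in a `MethylCountExperiment`, a `RangedSummarizedExperiment`
with assays `M` (methylated reads) and `Cov` (coverage) over width-1 CpG
ranges, and design factors `replicate`, `lineage`, `methionine` in
`colData`. Import (`readBismarkCoverage()`) takes bismark `.cov` files
(1-based, start = end, percent, count-methylated, count-unmethylated),
takes the union of sites across samples, reports malformed lines by number
and treats mixed chromosome-naming styles ("chr1" vs "1") as a hard error.
Strands are taken as given; no destranding or CpG-pair merging is applied.

Filtering (`uniteAndFilter()`) retains sites covered ≥ `mincov` (default 5)
in *every* sample of the contrast and drops sites at known variant
positions (BED/positions/GRanges), so that apparent methylation differences
cannot reflect underlying sequence polymorphism. Read-level filters
(mapping quality, mate-overlap de-duplication) act upstream of count files
and are out of scope here by construction; counts are taken as final.

Conversion QC (`conversionQC()`) estimates per-sample bisulfite conversion
from an unmethylated spike-in contig as unconverted/total reads; samples
below 98% are flagged, never silently dropped, and a missing spike-in gives
"not assessable" rather than a pass.

## The per-CpG test

`testDMC()` fits, per CpG, a binomial model of methylated/coverage on group
membership and reports the 1-df likelihood-ratio (deviance) chi-squared
p-value. With group as the only covariate the fitted proportions are the
group-pooled proportions, so the statistic is exactly the classical G-test
on the pooled 2×2 table (a Pearson-chi-squared mode is available). Group
means are pooled percentages, the reported difference is group A minus
group B in percentage points, and q-values are Benjamini–Hochberg across
all tested sites. The test suite pins the statistic to an independent
closed-form 2×2 oracle (< 1e-10) and to `glm()` deviance tests per site on
replicate fixtures, and checks the rejection decision against Fisher's
exact test.

DMCs are then filtered (`filterDMC()`): q ≤ 0.05, absolute difference
strictly greater than 20 percentage points, and located in a gene body or
promoter (intergenic records removed). The q threshold is a parameter, as
different upstream tools default differently. Direction summaries
(`summarizeDirection()`) report gain/loss counts with percentages to one
decimal, the format used in per-contrast summary tables.

## Annotation

`buildFeatureIndex()` reads gene/mRNA/exon models from GFF3 and CpG islands
from BED (half-open BED coordinates converted to 1-based at import).
Promoters are TSS ± 1 kb (strand-aware), introns are transcript spans minus
exons, and shores are symmetric 2 kb flanks on each side of an island,
clipped against islands and chromosome bounds so that the island and shore
classes are disjoint. Promoter and shore widths follow common annotation
defaults and are configurable; they are reported with the index. Each site
gets exactly one label per axis: promoter > exon > intron > intergenic on
the gene axis (nearest TSS breaks ties between transcripts, then transcript
id for determinism) and island > shore > open sea on the CpG axis. A
brute-force per-position oracle in the test suite checks both axes,
including every interval boundary ± 1 bp.

## DMC clustering and enrichment

A gene qualifies for enrichment when ≥ 5 of its DMCs fall within a sliding
1 kb window; with sorted DMC positions *p*, that is `p[i+4] − p[i] ≤ 1000`
for some *i* (span inclusive, windows anchored on DMC positions — the
window slides over DMCs, not over all CpGs, which is the literal reading of
the selection rule). The reported best window is the densest stretch,
leftmost on ties, and the decision is checked against exhaustive window
enumeration on random fixtures.

Enrichment is a hypergeometric over-representation test per GMT term with
BH correction. The universe defaults to genes with at least one *tested*
CpG in gene body or promoter, not the whole genome: RRBS covers a biased
CpG-dense subset, and a genome-wide universe would overstate significance.
A flag allows overriding the universe. `rankPathways()` reports significant
terms ordered by the number of genes of interest they contain (ties by
FDR), reflecting a reporting style that favours well-populated terms over
narrow ones.

## Imprinted-gene mixed models

For a panel of imprinted genes, per-sample per-CpG methylation proportions
are modelled per gene as `prop ~ replicate + methionine * lineage`, with a
random intercept per CpG, fitted by REML (`lme4::lmer`). The response is
the raw proportion — no transform is applied by default, matching the
original analysis description; an arcsine-square-root option exists behind
a flag. Fixed effects are reported with Wald z-tests; reference levels are
50 µM and TE, so the interaction coefficient is the additional 10 µM effect
in the ICM. A singular fit (zero CpG variance) falls back to ordinary least
squares with an explicit flag — in that degenerate limit the fixed effects
equal the OLS estimates, which the tests assert. Panel reports flag
lineage, methionine and interaction terms at p < 0.001, a deliberately
conservative reporting threshold, together with the four model-based cell
means (replicate-averaged predictions) for heat-map display. Per-sample
per-CpG proportions (not per-CpG averages) are the modelling unit, keeping
replicate as a meaningful fixed effect.

# The synthetic-data generator

`rrbsDesign()`/`generateRRBS()` write a complete dataset with ground truth:
a two-chromosome 1 Mb-per-chromosome genome with 60 non-overlapping gene
models (2–5 exons; ~20% of genes get a second transcript), CpG islands over
alternating promoters, 6000 CpG sites (≈10% placed in promoters, 55% in
gene bodies, the rest intergenic), and a 200-site unmethylated spike-in
contig.

Counts are drawn as negative binomial coverage (mean 30, size 8, truncated
at ≥ 1) and beta-binomial methylated reads with replicate-level
overdispersion ρ = 0.01 around the group-truth proportion. Baseline
methylation is bimodal (modes 0.1 and 0.9 with weights 0.4/0.6 and a small
site-level jitter), the standard shape of CpG methylation landscapes. The
methionine effect (default 30 percentage points, both lineages) is placed
in 20 affected genes × 10 CpGs; affected sites start at the baseline modes,
loss genes at the high mode and gain genes (20% of affected genes, echoing
the ~80/20 loss/gain asymmetry of such contrasts) at the low mode. Ten of
the affected genes carry their shifted CpGs within an 800 bp stretch
(guaranteeing the ≥5-in-1-kb rule); the rest are dispersed with > 250 bp
gaps so that no five fall within 1 kb. A disjoint set of 150 in-gene CpGs
carries an ICM-vs-TE effect at both concentrations, so all four contrasts
of the 2×2 design have signal. Fifty unaffected CpG sites are marked as
known variants and must be masked. The gene-set GMT contains `affected_set`
(all affected genes) plus random control sets. Everything is deterministic
given the design seed, with integer counts in files, so outputs are
byte-identical across runs.

What the generator does *not* emulate: read-level artefacts (alignment,
mapping quality, mate overlap), MspI fragment structure and the coverage
correlations it induces along fragments, non-CpG methylation, chromosome-
scale methylation domains, and any correlation between neighbouring CpGs
beyond gene-level placement. Passing the recovery suites therefore shows
the count-level statistics behave as designed, not that upstream processing
of real libraries is validated.

# Recovery behaviour and calibration

Two calibration facts shape the validation suites:

* **Null calibration.** The deviance test assumes binomial sampling. On
  pure-binomial null fixtures (ρ = 0) its type-I error at nominal 0.05 sits
  within [0.03, 0.07], and the mixed-model interaction Wald test sits
  within [0.02, 0.09] on balanced null simulations. With replicate
  overdispersion ρ = 0.01 at coverage ~30 the pooled test is mildly
  anti-conservative (variance inflation ≈ 1.3), which is why null
  calibration fixtures are generated with ρ = 0 while realistic fixtures
  keep ρ = 0.01. This anti-conservatism is a known property of pooled
  chi-squared methylation tests and is the reason the >20-point effect
  filter matters in practice: it removes essentially all overdispersion-
  driven false positives (empirical FDR ≈ 0.02 after filtering, versus
  ≈ 0.19 for the q-filter alone on the default fixture).

* **Sensitivity sits at the design boundary.** Under the default
  conditions (Δ = 30 points, coverage mean 30, n = 3/group, ρ = 0.01,
  q ≤ 0.05, strict >20-point filter), the observed between-group difference
  at a true site is unbiased with an SD of ≈ 7 points, so ≈ 7–8% of true
  sites fall below the strict filter or the BH cutoff by sampling noise
  alone. Measured over 30 generation seeds, mean sensitivity is 0.904
  among truth sites that survive coverage filtering (98–99% of them) and
  0.900 against all designed sites. Recovery metrics in `runPipeline()`
  therefore report sensitivity among tested truth sites together with the
  tested fraction, and the validation suites average over several
  generation seeds; single unlucky seeds can still land marginally below
  0.90. Gene-level recovery is much stronger: designed cluster genes
  essentially always qualify (10 shifted CpGs in 800 bp, of which ≈ 9 are
  detected), and the planted `affected_set` attains the smallest
  enrichment FDR.

# Problem sizes

The shipped suites run at desk scale: 6000-site default fixtures (1500 for
module tests), five generation seeds for recovery, 2000-site null fixtures,
50-seed mixed-model recovery and 500-run null-size simulations, and
kinetic-model simulations of a few thousand hours at rtol 1e-8. These sizes
give Monte-Carlo error comfortably inside the asserted bands while keeping
the full suite in the low minutes on one core.

# Known limitations

* The kinetic model is constitutive: it does not model transcriptional
  adaptation (e.g. MAT2A up-regulation under methionine restriction), so it
  speaks to short-horizon dynamics, not chronic adjustment.
* The volatility ordering is asserted qualitatively; its magnitude depends
  on the parameter table, which is not fitted to data.
* The per-CpG test pools replicates and inherits the anti-conservatism
  described above under replicate overdispersion; a beta-binomial or
  dispersion-shrinkage test is an explicit non-goal here.
* Published genome-wide counts from the real libraries (e.g. total DMCs per
  contrast) depend on the real data and unstated threshold choices and are
  not reproducible from synthetic fixtures; the arithmetic of the published
  direction percentages, the qualitative model prediction, and the
  statistical behaviour of every stage are what this package reproduces.
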