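---
title: "Simulating multiparental RIL panels and measuring what they can map"
author: "mppqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating multiparental RIL panels and measuring what they can map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Multiparental recombinant inbred line (RIL) panels — here modeled on a
*C. elegans* experimental-evolution design — are mapping populations built
by intercrossing many inbred founders, evolving the hybrid population for
tens to hundreds of generations under mixed selfing and outcrossing, and
then deriving near-homozygous lines by repeated selfing.  Their value for
quantitative genetics depends on properties that are expensive to measure
on real data: the power of a mixed-model scan to detect an additive QTL of
given effect, the power of a two-locus regression to detect epistasis, the
physical resolution of detection intervals, and the population structure
that the mapping model must absorb.  `mppqtl` simulates such panels with
complete truth tracking and implements the statistical machinery to
measure all of these quantities, plus the variant hard-filtering and
new-mutation summaries that accompany a panel's genotype release.

## The simulator

**Genetic map.** Each chromosome is tiled by recombination-rate domains:
near-zero-rate tips (3.5% of physical length each), high-rate arms (23.5%
each) and a low-rate center (46%), with the arm rate 3.5 times the center
rate and both solved so every chromosome totals 50 cM.  The six default
chromosomes use physical lengths close to the *C. elegans* karyotype
(~100 Mb total).  These fractions and the arm:center ratio follow the
tip/arm/center domain structure described for this species; all are
configurable through `genetic_map()`.

**Meiosis.** Each bivalent receives one obligate crossover plus a
Poisson number of extras with mean `max(0, 2L - 1)` (L the map length in
Morgans), and each crossover reaches the transmitted chromatid with
probability 1/2.  Transmitted crossovers therefore average L per gamete
(0.5 for a 50 cM chromosome) while every meiosis still has its obligate
crossover — the behavior of a strongly interfering holocentric bivalent.
Crossover positions are sampled proportional to local cM/Mb by inverting
the piecewise-linear genetic map.

**Founders.** `simulate_founders()` draws diallelic markers with a
configurable founder allele-count spectrum (`k^-sfs_skew`, supporting the
singleton excess seen in panels founded from wild isolates).  Because the
founders of real panels are wild isolates of a predominantly selfing
species, they share haplotypes over hundreds of kilobases, and that
sharing — not new mutation during the experiment — is what gives the
derived panel its linkage disequilibrium.  The generator therefore
evolves the minor-allele carrier set along each chromosome: it is
reshuffled at exponentially spaced block boundaries (mean `ld_block_bp`,
default 250 kb) and gently perturbed within blocks (`perturb`, default
0.15 per marker).  The 250 kb scale matches the observed insensitivity of
interval sizes to windowing choices in the 200–500 kb range on the real
panel.  Setting `ld_block_bp = NULL` gives independent markers; panels
built that way have adjacent-marker r² near zero and are useful only as
statistical nulls, since every LD-dependent procedure (interval ranking,
scan-set pruning, pair pruning) degenerates.

**Evolution.** A funnel intercross halves the number of subpopulations
each generation (8 pair crosses → 4 → 2 → 1 for 16 founders), after which
a Wright-Fisher population of hermaphrodites reproduces with
per-individual outcrossing probability `outcross_p` (default 0.5) or
selfing otherwise.  The default census (10³) is an effective-size choice:
the real populations kept a 10⁴ census with an effective size near 10³,
and it is the effective size that controls drift, LD and map expansion.
Males are not modeled individually; the X chromosome is transmitted as an
autosome, with an optional effective-size deflator used by the mutation
module (the X analyses here are frequency summaries, not
transmission-exact accounting).  `simulate_structured_panel()` evolves a
base population, stores its state, and branches derived replicate
lineages from it; `cemee_v2_design()` reproduces a 763-line panel drawn
from a 140-generation base population plus +50/+100-generation control,
high-outcrossing and selfing-only derived lineages with the published
per-population line counts.

**RIL derivation and truth.** Lines are single hermaphrodites selfed for
10 generations (single-descendant), leaving ~2⁻¹⁰ residual
heterozygosity.  Founder-of-origin paths are recorded exactly for every
line and haplotype; genotypes are read off the paths, so genotype/path
consistency is structural.  Realized map expansion (`Ra`) is the mean
breakpoint count per line and chromosome relative to one meiosis's
expectation (the map length in Morgans).

**New mutations.** `inject_mutations()` draws Poisson numbers of
mutations per genome copy per generation (haploid rate μ, default
2.5×10⁻⁹), tracks each mutation's copy number forward with neutral
Wright-Fisher binomial sampling, and assigns carriers among the sampled
lines binomially at the final frequency.  This is transmission tracked
statistically, generation by generation, rather than threaded through
the stored pedigree — the operation applies to a finished panel, after
the pedigree has been discarded.  The process has a configurable Ts:Tv
ratio and an optional X effective-size deflator.

## The mapping machinery

**Additive scan.** The phenotype model is `y = Xβ + Zu + e` with
`u ~ N(0, σ²_g A)` and `e ~ N(0, σ²_e I)`, where A is the additive GRM
(markers scaled to mean 0, variance 1; `A = XXᵀ/m` rescaled to mean
diagonal 1; fractional dosages treated as missing and mean-imputed).
Variance components are estimated once per trait by REML — a single
eigendecomposition of A plus 1-D optimization over the heritability
ratio — and reused across markers; each marker is then tested by a
likelihood-ratio statistic of the weighted regressions on the rotated
data, `LR = n log(RSS₀/RSS₁)`, `p` from χ²₁, `LOD = LR/(2 ln 10)`.  At
`σ²_g = 0` this reduces exactly to the OLS likelihood ratio, which the
tests verify to 10⁻⁸.  Exact per-marker re-profiling of the variance
components was evaluated and changes LR by <1% on these panels, so the
one-fit profile is the default.

**Thresholds.** Three calibrations of the genome-wide α = 0.1 threshold
are provided.  The shrinkage route applies the Ledoit-Wolf
shrunk-correlation eigenvalue estimator per chromosome (M_eff = number
of eigenvalues explaining 99% of variance, computed through the n×n dual
spectrum) and Bonferroni-corrects.  The permutation route scans null
phenotypes drawn from `N(0, h²A + (1-h²)I)` and takes the α quantile of
the minimum p — an exact-FWER calibration that, like the
heritability-aware effective-test estimators it replaces, responds to
LD, relatedness and trait heritability together; it is the default for
the power studies (the shrinkage route measured conservative, FWER 0.05
at α = 0.10, on the default panel).  The fixed route passes a
user-supplied threshold through (default 3.23×10⁻⁶, the calibrated value
appropriate when emulating the real 763-line panel).

**Detection intervals.** Windows of 300 kb (and their half-offsets) are
scanned; in each window with a significant marker, the max-LOD marker is
the peak (ties leftmost), remaining markers are ranked by r² with the
peak, and markers are admitted down the ranking while their LOD stays
within 1.5 of the peak, stopping at the first failure; the interval
spans the admitted markers or the flanking pair at minimum, and
overlapping or book-ended intervals are merged.  The ranked admission is
this package's concrete reading of boundary calculation "using this
ranking"; a contiguous-LOD-drop fallback (`method = "lod_drop"`) is kept
for sensitivity checks, and stopping at the first rank failure (rather
than filtering all failing markers) is the conservative choice of the
two possible readings.

**Epistasis.** Markers are pruned of strong local LD (r² < 0.5 within
1 Mb), filtered at MAF > 5%, and pairs are tested only when all four
two-locus homozygote classes hold ≥ 3 lines.  The interaction LR
compares `y ~ gᵢ + gⱼ + gᵢgⱼ` against the additive model under Gaussian
maximum likelihood (so `LR = n log(RSS₀/RSS₁)` holds exactly).  Null LRs
come from a parametric bootstrap that resamples responses from the
fitted additive model — preserving main effects by construction, unlike
trait permutation — and are pooled across tests, stratified by
joint-MAF decile (geometric mean of the two MAFs, cut at deciles).  Each
stratum's nulls are summarized as a mixture of a point mass at zero (π₀,
the fraction of nulls at numerical zero) and a χ² with df estimated by
method of moments; observed LRs convert to p as
`(1-π₀)·Pr(χ²_df ≥ LR)`.  The mixture is a parametric tail
extrapolation: genome-wide pairwise thresholds (α divided by
`M_eff(M_eff-1)/2`, with M_eff from the Ledoit-Wolf estimator on the
pruned set) lie far below `1/(pooled nulls)`, so a rank-based empirical
p (provided as `rank_p()`, floored at `1/(n+1)`) cannot reach them by
construction.

**Power studies.** `run_additive_power()` simulates traits (focal marker
+ polygenic background over 50/100/500 markers + noise, components
rescaled to their target variance fractions, total heritability 0.5,
effects standard normal, loci drawn at MAF > 5%), scans, thresholds, and
builds intervals.  Detection is assessed *at the simulated locus* — an
interval covering the true site, or a significant marker within 1 Mb —
because individual background markers legitimately carry detectable
effects of their own under this trait model; both criteria are recorded
side by side.  Power is summarized by realized focal r² (adjusted r² of
the focal regression), binned at width 0.01 with midpoint labels: the
realized-r² bin is the quantity the headline power numbers refer to, and
it conditions away the sampling noise of effect realization (on the
default panel, power at simulated h² = 0.04 is ~0.73 unbinned but ~0.9
in the realized-0.04 bin).  `run_epistasis_power()` does the analogue
for interactions, with realized interaction h² defined as the adjusted-r²
difference between the full and additive models; because the raw product
term is substantially collinear with its main effects, a nominal
interaction variance fraction of ~0.19 realizes ~0.07 of uniquely
attributable variance on the default panel.

## Problem sizes and reproducibility

The default study conditions are a 763-line structured panel (16
founders, census 10³, 140 base generations plus derived lineages, 10
selfing generations) genotyped at 2,000 markers per chromosome (~12,000
total, ~8,000 after pruning complete LD), with 900 additive replicates
across the 0.03–0.05 focal grid, 2,000 interaction replicates with 100
bootstrap nulls each, and 100-permutation threshold calibration; these
sizes populate each realized-heritability bin with roughly 200
replicates while keeping a full acceptance run in the minutes range on
one core.  Every stochastic stage takes an explicit seed, and reruns
with the same seed reproduce every number bit for bit.  On this panel
the arm-domain median detection interval is ~18 kb and the center-domain
median ~40 kb across focal h² 0.03–0.10, with the median peak-to-causal
distance 0 bp on the arms — the resolution regime reported for the real
panel (arms 8.3–18.7 kb, centers 48–103 kb).

## What the synthetic panel does and does not show

The generator matches the real design's line count, founder number,
funnel, generation counts, mating system mix, selfing derivation, map
structure and founder-haplotype LD scale, and it reproduces the real
panel's mapping-resolution regime.  It does not model selection (drift
only), males and X transmission, genotype error or missingness (beyond
residual heterozygosity), variable marker density along chromosomes, or
the precise founder genealogy; population structure in the GRM is weaker
than in the real panel, where long shared haplotypes concentrate far
more variance in the leading principal components.  Power and coverage
measured here therefore characterize a panel *like* the real one under
its stated design parameters, not the real genotype matrix itself; with
the weaker synthetic structure the mixed model absorbs slightly more
focal-marker signal than on real data, which is visible as unbinned
power a few points below the binned values.

## Variant filtering conventions

Hard filters follow GATK-style site annotations read from VCF INFO keys
(QUAL, MQ, DP, QD, SOR, ReadPosRankSum).  Founder-SNV criteria:
QUAL > 1000, <50% heterozygous-or-missing founder calls, MQ > 40,
|DP − median| below its 0.995 batch quantile, SOR < 3, QD ≥ 15.
New-mutation candidates: MQ ≥ 40, QD ≥ 5, DP ≥ 30, positive
DP − median deviation below its 0.95 batch quantile, SOR < 4,
ReadPosRankSum > −4, heterozygote frequency < 10%, ≥3 homozygous
carriers, no missing calls, and exclusion of sites flagged variable in
independent data.  Depth quantiles are resolved against the supplied
batch and frozen into the returned criteria object, so re-filtering a
retained set with those criteria is a no-op (the property the
idempotence tests assert); a missing annotation conservatively fails its
criterion, and every rejected record carries machine-readable reasons.
RIL quality control applies, in order: greedy relatedness pruning
(identity at segregating sites > 90%, dropping the lower-depth member of
the worst pair first), minimum depth 0.1×, zygosity (>20% of sites
showing both alleles with mean minor-allele proportion > 20%), and
haplotype-reconstruction likelihood outliers (beyond the 0.1 percentile
of deviation from the population median on more than three
chromosomes).
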