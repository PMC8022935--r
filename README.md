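# mppqtl

Simulation and QTL mapping power analysis for multiparental recombinant
inbred line (RIL) panels.

## What this is for

Multiparental RIL panels — modeled here on a *C. elegans*
experimental-evolution design in which 16 wild founders are combined
through a funnel intercross, evolved for 140+ generations under mixed
selfing and outcrossing at effective size ~10³, and sampled into
near-homozygous lines by 10 generations of selfing — are workhorses for
mapping quantitative trait loci (QTL).  Their usefulness is governed by
quantities that must be measured by simulation: detection power,
mapping resolution, false-positive control, and the population
structure the mapping model has to absorb.

`mppqtl` provides:

* a forward-in-time recombination simulator with domain-structured
  crossover rates (low-recombining chromosome centers, high-recombining
  arms), founder haplotype-sharing blocks, branching experimental
  lineages, and exact truth tracking of founder-of-origin paths;
* de novo mutation injection under neutral Wright-Fisher drift with a
  configurable Ts:Tv process and X-chromosome effective-size deflation;
* the single-marker linear mixed-model scan
  `y = Xβ + Zu + e`, `u ~ N(0, σ²_g A)`, `e ~ N(0, σ²_e I)`,
  with REML variance components via one eigendecomposition of the
  genomic relatedness matrix `A = XXᵀ/m` (markers standardized, mean
  diagonal scaled to 1), per-marker likelihood-ratio tests, and
  genome-wide thresholds by Ledoit-Wolf shrinkage M_eff, permutation,
  or a fixed value;
* QTL detection intervals by the 1.5-LOD drop with LD-ranked admission
  in 300-kb half-offset windows, merged by union;
* two-locus epistasis tests — LR of `y ~ gᵢ + gⱼ + gᵢgⱼ` against the
  additive model, parametric-bootstrap null LRs that preserve main
  effects, χ² mixture conversion to empirical p stratified by joint-MAF
  decile, and the pairwise Bonferroni threshold
  `α / (M_eff(M_eff−1)/2)`;
* population-structure summaries (GRM, PCA, Hudson's F_ST as a ratio of
  averages, founder-haplotype entropy, pairwise identity);
* GATK-style variant hard filters for founder SNVs and new-mutation
  candidates, RIL quality control, and new-mutation statistics (Ts/Tv,
  Gini inhomogeneity, X-depletion Fisher test, mutation fate classes,
  expected mutation counts).

## Worked example

```r
library(mppqtl)

map <- default_genetic_map()                      # 6 chromosomes, 50 cM each
founders <- simulate_founders(map, m_markers = 500, seed = 1)
cfg <- evolution_config(census = 500, generations = 60, outcross_p = 0.5,
                        n_lines = 200, selfing_gens = 10, seed = 2)
panel <- simulate_panel(founders, map, cfg)
panel
#> <panel_realization> 200 lines x 3000 markers (60 evolution + 10 selfing
#> generations; 0 injected mutations)

round(estimate_map_expansion(panel), 1)
#>    I   II  III   IV    V    X
#> 40.5 39.1 41.1 39.9 42.2 40.9
```

Map expansion (`Ra`) is the realized breakpoint count relative to a
single meiosis: after 60 generations of mixed selfing/outcrossing plus
derivation, each chromosome carries ~40 times the recombination of one
meiosis.  Now simulate a
trait in which one marker explains 8% of the variance on a polygenic
background, scan it, and define detection intervals:

```r
engine <- scan_engine(panel$genotypes)
trait <- simulate_trait(panel, h2_focal = 0.08, background = 100,
                        h2_total = 0.5, seed = 3)
scan <- scan_additive(trait$y, engine)
cal <- calibrate_threshold(panel$genotypes, method = "shrinkage",
                           chrom = panel$markers$chrom)
iv <- define_intervals(scan, panel$genotypes, panel$markers, cal)
iv[, c("chrom", "start", "end", "peak_pos", "peak_lod")]
#>   chrom    start      end peak_pos peak_lod
#> 1    II 13427028 13537964 13462644 3.755373
panel$markers$pos[trait$focal]
#> [1] 13462644
```

The single significant interval sits on chromosome II and its peak
marker is exactly the simulated causal marker (13,462,644 bp), with the
interval spanning the markers within 1.5 LOD of the peak.  Power studies
wrap this loop: `run_additive_power()` and `run_epistasis_power()`
return per-replicate records, power with binomial standard errors by
realized-heritability bin, and interval-resolution summaries by
recombination-rate domain.

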