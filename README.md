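# chronopop

Temporal population genomics from serially collected specimens.

Natural-history collections let us genotype the *same* populations at
several points in time — formalin-fixed liver from mid-century vouchers,
frozen blood from later decades, fresh tissue from today — and ask whether
diversity rose or fell, whether the change is demographic or selective,
and whether archival-DNA artifacts could explain it instead. `chronopop`
implements that analysis chain for multilocus biallelic SNP panels:

* **Filter chain** — indel-proximity pruning, QUAL ≥ 30, biallelic SNPs,
  genotype masking by depth (DP ≥ 5) and heterozygote allele balance
  (0.25 < AB < 0.75), then MAC ≥ 3, MAF > 0.015 and ≥ 50% presence
  computed after masking; one-random-SNP-per-locus thinning;
  coding/non-coding partitioning against a BED map; depth downsampling;
  missingness accounting.
* **Diversity statistics**, written from first principles and
  oracle-tested: per-site nucleotide diversity
  π = n/(n−1)·2p(1−p), observed/expected heterozygosity, private
  alleles, and windowed Watterson's θ_W = S/(a₁L) and Tajima's
  D = (π_tot − S/a₁)/√(e₁S + e₂S(S−1)) in 150-bp windows.
* **Temporal inference** — permutation subsampling from 3 up to all
  available samples (20 replicates per size), neutrality (|D̄| > 1.5) and
  variability (CV > 1.0) rules, one-way ANOVA with Tukey HSD across time
  periods, regressions on sampling design covariates, and a trend
  classifier mapping the joint direction of π, θ_W and D to
  expansion / contraction / stable / mixed.
* **Selection scan** — per-site Weir–Cockerham Fst (θ̂ = a/(a+b+c)), a
  neutral baseline from non-coding SNPs, outlier flags above
  mean + 2 SD, allele-frequency trajectories through time, and
  per-species polymorphism/allele-sharing summaries.
* **Synthetic data** — a forward Wright–Fisher simulator (neutral-SFS
  initialisation, piecewise-constant N, mutational influx) plus an
  archival-artifact layer (tissue-specific coverage, missingness, allelic
  dropout, C→T/G→A miscalls) that emits VCF + BED + metadata, so the whole
  pipeline runs and is tested with no external data.

The central container is `GenotypeMatrix`, a `SummarizedExperiment`
subclass (assays `gt`, `dp`, `adRef`, `adAlt`; site table in `rowData`,
sample metadata in `colData`).

## Worked example

```r
library(chronopop)

# simulate a 20-fold bottleneck sampled at three time periods,
# overlay archival artifacts, and emit standard files
sc  <- scenarioPreset("bottleneck", seed = 42)
tr  <- simulateTemporalPopulation(sc)
gm  <- applyArchivalArtifacts(tr, artifactModel())
emitDataset(gm, "demo")          # demo.vcf, demo.bed, demo_meta.tsv

# read back, filter, and summarise diversity per time period
gm2 <- readGenotypeVcf("demo.vcf")
flt <- applySiteFilters(gm, filterConfig(minMac = 0, maxMafExcluded = 0))
periodDiversity(flt$matrix, totalSites = nrow(gm))
#>   time_period         pi n_variant_sites      theta_w  tajimas_d n_windows
#> 1          T1 0.04379068             956 0.0032908595 0.08921707       688
#> 2          T2 0.02613705             956 0.0014763595 0.63546016       374
#> 3          T3 0.01535411             956 0.0008429557 0.57999808       240

recoverScenario("bottleneck", seed = 42)$call$classification
#> [1] "contraction"
```

Diversity halves and Tajima's D rises from ~0 to ~0.6 across the three
periods — rare alleles were culled by the crash and drift eroded
heterozygosity — so the trend classifier calls a contraction. (Numbers
above are from the run shown; your exact values depend only on the seed.)

The full pipeline (six dataset tags: {all reads, downsampled} ×
{all sites, coding, non-coding}, permutation ANOVA, trend call, Fst-outlier
scan, manifest) is one call:

```r
res <- runPipeline(scenarioPreset("bottleneck", seed = 42), seed = 42,
                   outDir = "results_demo")
res$manifest$trend
```

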