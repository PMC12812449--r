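---
title: "Temporal population genomics from archival specimens: models and methods"
author: "chronopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal population genomics from archival specimens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronopop)
```

## The problem

Natural-history collections hold series of specimens from the same
populations across decades. Genotyping them — formalin-fixed liver from the
1960s–70s, frozen blood from the 1980s–90s, fresh tissue from the 2010s —
turns a museum drawer into a time series of allele frequencies, from which
one can ask whether a population expanded, stayed stable, or contracted, and
whether particular loci (immune genes, say) changed faster than the neutral
background. The difficulty is that archival DNA carries artifacts that mimic
biology: allelic dropout deflates heterozygosity (the documented
"homozygous bias" of degraded tissue), deamination-type miscalls (C→T, G→A)
masquerade as rare variants, and coverage differs systematically by tissue
preparation, so missingness is confounded with time period.

`chronopop` implements the full analysis chain for such data — a VCF-level
filter chain, from-scratch diversity statistics, a permutation framework
over uneven sample sizes, demographic trend classification, and an
Fst-outlier scan — together with a forward simulator whose artifact layer
emulates exactly those failure modes, so every stage can be validated
against known truth without any external data.

## The forward model

`simulateTemporalPopulation()` runs a forward Wright–Fisher simulation of
biallelic sites across independent loci under a piecewise-constant diploid
size $N(t)$:

* Each tracked site is initialised as segregating with probability
  `propSegregating`; segregating sites draw a derived count
  $i \in \{1, \dots, 2N-1\}$ from the neutral site-frequency spectrum,
  $\Pr(i) \propto 1/i$.
* Each generation, the derived frequency is resampled binomially with the
  current $2N$ chromosomes.
* Monomorphic sites (including sites that fixed or were lost) gain a new
  derived allele with probability $2N\mu$ per generation, entering at
  frequency $1/2N$. Mutational influx is part of the forward model because
  the expansion signature — rising $S$ and $\pi$ with falling Tajima's $D$
  — is driven by new rare variants entering a grown population; pure drift
  on standing variation cannot produce it.
* At each labelled sampling epoch, diploid genotypes are drawn binomially
  from the current frequency (Hardy–Weinberg).

Sites within a locus are independent (free recombination). This is noted
rather than fixed: the one-SNP-per-locus thinning operation makes the
downstream single-SNP statistics insensitive to within-locus linkage, and
none of the window statistics compare sites across loci.

A master seed spawns named substreams (site layout, initialisation, each
generation, each sampling epoch, the artifact layer), so identical seeds
replay byte-identically and partial re-runs are reproducible.

### Scenario presets

The three presets in `scenarioPreset()` are deliberately *toy*
demographies: effective sizes of tens to thousands, a per-site mutation
rate of $10^{-6}$–$6\times10^{-5}$, and epochs at generations 5/40/70.
Real vertebrate parameters ($N_e \sim 10^3$–$10^5$,
$\mu \approx 6\times10^{-9}$, three sampling points ~25 generations apart)
produce drift and mutation signals far too small to measure at a few
thousand sites; the presets scale $N$ down and $\mu$ up so the *relative*
magnitudes (a 20-fold crash, a 20-fold expansion) yield measurable
signatures at desk scale. These sizes were fixed once, from the expected
heterozygosity-decay and mutational-influx rates, before any acceptance
checks were run:

* **stable** — $N = 4000$ throughout, no mutational influx; over 65
  generations heterozygosity decays by $<1\%$, below the trend
  classifier's flatness tolerance.
* **expansion** — $N: 30 \to 600$ at generation 10, $\mu = 6\times10^{-5}$,
  5% of sites initially segregating: the small, low-diversity founder
  population grows and mutational influx adds rare variants, so $\pi$ and
  $\theta_W$ rise while $D$ falls.
* **bottleneck** — $N: 600 \to 30$ at generation 10, $\mu = 10^{-6}$, 30%
  of sites segregating: the crash culls rare alleles
  (an allele at frequency $p$ survives with probability
  $1-(1-p)^{2N_{new}}$) and drift erodes heterozygosity by
  $\approx 1 - (1-\tfrac{1}{60})^{60} \approx 63\%$ by the last epoch, so
  $\pi$ and $\theta_W$ fall while $D$ rises.

The per-epoch sample size defaults to 16 diploids, a generous but
realistic museum-series size.

## The artifact layer

`applyArchivalArtifacts()` converts true genotypes into observed VCF
records. Per genotype, in order:

1. **Depth** is drawn from a tissue-specific normal (historic liver
   19.2×, SD 16.7; frozen blood 37.7×, SD 25.8; modern liver 54.0×,
   SD 33.6 — each time period gets one preparation type, oldest first);
   draws below 1 become missing genotypes.
2. **Missingness**: genotypes are additionally uncalled outright with
   `missingRate` (default 0.15, chosen so that overall missingness lands
   near the ~16% typical of filtered museum SNP matrices).
3. **Allelic dropout**: a true heterozygote is observed as a homozygote
   for one of its alleles, chosen uniformly, with `dropoutRate` (default
   0.05). Dropout deflates observed heterozygosity but leaves expected
   allele frequencies unbiased, which is why $\pi$ is relatively robust
   to it while $H_{obs}$ is not.
4. **Damage miscalls**: at sites whose REF/ALT pair is C/T (or G/A), each
   C (or G) allele copy flips with rate 0.008 (or 0.006).
5. **AD fields** are a binomial split of depth by observed genotype —
   with one deliberate exception. A heterozygote *created* by a damage
   flip is, physically, a genotype whose minor allele is supported only
   by damaged reads; its allele-depth fraction is therefore drawn at the
   per-read miscall rate rather than at 0.5. This matters: it is exactly
   what allows the allele-balance filter (AB strictly inside
   (0.25, 0.75)) to remove damage-induced false heterozygotes, as it does
   in real pipelines. Had damage errors been given balanced AD, no filter
   in the chain could distinguish them from real variants, and after a
   population crash the (constant-rate) damage noise would dominate the
   shrinking true frequency spectrum, inverting the Tajima's-$D$
   signature of the bottleneck.

What the artifact layer does **not** emulate: read-level errors and their
correlation structure (the model starts at the genotype), reference bias,
index hopping, contamination, and batch effects in capture efficiency.
Passing the recovery tests therefore shows the *statistical* chain is
sound under the modelled error processes, not that any real dataset is
free of the unmodelled ones.

## The filter chain

`applySiteFilters()` applies, in a fixed order: indel-proximity pruning
(SNPs within 3 bp of an indel, and indel clusters with gaps ≤ 5 bp),
site QUAL ≥ 30, biallelic SNPs only, genotype-level masking (DP < 5, or a
heterozygote with allele balance outside the open interval (0.25, 0.75)),
then site-level filters computed *after* masking: minor allele count ≥ 3,
minor allele frequency > 0.015, and ≥ 50% of individuals called. The
order matters only at the genotype/site boundary: site-level frequencies
must be computed from the masked matrix for internal consistency, and
applying the chain twice equals applying it once. Both the MAC and MAF
thresholds are enforced even though they overlap — at small sample sizes
they are not redundant (MAC 2 of 100 chromosomes fails MAC ≥ 3 but passes
MAF > 0.015). Missing QUAL fails the QUAL filter; absent DP or AD fields
turn the corresponding mask into a logged no-op rather than an error.

Boundary conventions are deliberately explicit: QUAL ≥ 30 and DP ≥ 5 pass;
allele balance passes only strictly inside the interval; capture-target
length/GC bounds (200–400 bp, 30–70% GC) are inclusive; BED intervals are
0-based half-open while VCF POS is 1-based, so a site at POS $p$ is coding
iff $p-1$ lies inside a coding interval.

For trend classification the pipeline uses a quality-only variant of the
chain (masking and presence, but no MAC/MAF threshold): the study-scale
minor-allele filters are calibrated for hundreds of chromosomes, and at
the demonstration scale of ~32 chromosomes per epoch they would censor the
rare tail of the frequency spectrum that carries the $S$ and $D$ signals.

## Statistics

All estimators are written from first principles and cross-checked in the
test suite against independent oracles (exhaustive pair enumeration for
$\pi$, an allele-indicator ANOVA-table implementation for Fst, hand sums
of squares for the ANOVA):

* per-site $\pi = \frac{n}{n-1} 2p(1-p)$, the mean pairwise difference
  among called chromosomes; SNP-matrix $\pi$ averages over variant sites,
  per-bp $\pi$ divides by a supplied total length instead.
* $H_{obs}$, $H_{exp}$, private alleles (alleles seen in exactly one
  population).
* Watterson's $\theta_W = S / (a_1 L)$ and Tajima's
  $D = (\pi_{tot} - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$ with the standard
  constants, in 150-bp windows tiling each locus (step = size, final
  partial window used at its true length). Within a window the called
  chromosome count varies by site under missingness; the window uses the
  rounded mean, and $D$ is undefined for $S = 0$ or fewer than 4
  chromosomes.
* Weir–Cockerham Fst from the a/b/c variance components, per site, with
  both the ratio-of-averages and the mean of per-site ratios retained;
  the per-site mean is the default for baseline/outlier work because
  outliers are judged site by site against the baseline's mean and SD.
  Half-calls contribute one chromosome to allele counts but are excluded
  from the diploid-only Fst components.

The optional conversion $N_e = \theta_W / 4\mu$ (e.g. with the fish mean
rate $5.97\times10^{-9}$ when no taxon-specific rate exists) is an
interpretation aid only; no package computation depends on $\mu$.

## Temporal inference

`permuteSubsample()` draws, for every subsample size from 3 up to the
population's full size, 20 subsamples without replacement and recomputes
the statistic, summarising each size by median, mean, SD and CV. Two
decision rules operate on these summaries: a population departs from
neutrality when $|\bar D| > 1.5$ (strict), and $\theta_W$ is flagged as
significantly variable when CV > 1.0. One-way ANOVA with Tukey HSD
compares the replicate values across time periods within a species × site
stratum; the inputs are permutation replicates, so the test inherits the
pseudo-replication of the resampling design — this is reproduced
knowingly, not corrected, and no cross-stratum correction is applied.
OLS regressions of median $\pi$ on sample size, years sampled, or
sampling timespan quantify design artifacts.

`classifyTrend()` reduces each population's trajectory to the direction
of change (first vs last time point) of $\pi$, $\theta_W$ and $D$:
rising $\pi$ and $\theta_W$ with falling $D$ is called expansion; falling
$\pi$ with rising $D$ is contraction; all flat is stable; anything else
is mixed. "Flat" is $|\Delta| \le 2\%$ of the earlier value for $\pi$ and
$\theta_W$, and an absolute $|\Delta D| \le 0.1$ for $D$ — a relative
tolerance is meaningless for a statistic centred on zero.

## Selection scan

`neutralBaseline()` summarises per-site Weir–Cockerham Fst over
non-coding sites (mean and sample SD — the n−1 form, an explicit choice);
fewer than 30 informative sites attaches a low-power warning, fewer than
2 is an error. `fstOutliers()` flags candidate sites strictly above
mean + 2 SD and reports the candidate-set mean and its percent elevation
over the baseline. Under a normal null this flags ~2.3% of sites — the
calibration the test suite checks. `polymorphismSummary()` pools each
species across time points and localities and reports total/polymorphic/
fixed SNP counts (percent polymorphic rounded to one decimal), per-locus
polymorphic counts, percent heterozygosity over polymorphic sites, and
allele sharing (unique and missing alleles relative to the all-species
union). "Fixed" means monomorphic within the pooled species; "percent
heterozygosity" is the mean per-site heterozygote fraction over the
species' polymorphic sites × 100 (one of several possible definitions —
documented because no canonical one exists). Large temporal frequency
shifts are reported descriptively against a configurable cutoff
(default |Δf| > 0.25), labelled a reconstruction.

## Numerical and degenerate-input choices

* Genotype codes carry half-calls (one called allele) distinctly from
  missingness; half-calls contribute one chromosome to allele counts.
* An empty matrix after filtering is a valid result with a balanced
  report, not an error; an all-missing population yields NaN with a
  warning.
* ANOVA with zero within-group variance and unequal means reports
  p ≈ 0 flagged as degenerate; identical groups report F = 0, p = 1.
* CV is NaN when the replicate mean is zero; at the full sample size the
  permutation distribution is a point mass and SD = CV = 0 exactly.
* Thinning ties are broken by the seeded uniform draw; all seeds are
  kept below $2^{31}$.

## Problem sizes

The test suite and the reproduction script run at deliberately small
scale, chosen so the whole suite completes on one CPU in minutes: neutral
calibration uses 500 single-window loci at $N = 1000$; scenario recovery
uses 25 seeds per scenario at 300 loci × 20 sites with 16 samples per
epoch; the Fst-outlier null uses $10^4$ sites. The estimators themselves
are vectorised and handle study-scale matrices (tens of thousands of
sites, hundreds of samples) without modification.

## Known limitations

* The simulator has no linkage, no selection, and genotype-level (not
  read-level) errors; it validates the statistical chain, not upstream
  bioinformatics.
* Trend classification from three time points is a coarse rule table;
  with weak signals it returns "mixed" rather than guessing.
* The permutation ANOVA's pseudo-replication deflates p-values; treat
  those p-values comparatively, not literally.
* The Fst baseline assumes non-coding sites are neutral; linked selection
  in flanking sequence would inflate the baseline and hide true outliers.
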