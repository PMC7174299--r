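---
title: "Detecting within-generation polygenic selection from pooled sequencing"
author: "polyshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting within-generation polygenic selection from pooled sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyshift)
```

## The scientific problem

When a genetically mixed population is exposed to a novel environment,
directional selection is expected to shift allele frequencies at the many
loci underlying local adaptation. Over a single generation those shifts are
individually tiny — far below what a naive genome-wide before/after
comparison can resolve — but they may be detectable as a *collective*
signal across loci that were predicted to be under selection *a priori*.

`polyshift` implements this a-priori-prediction strategy for a
release–recapture design with pooled whole-genome sequencing, as used in
lake–stream stickleback ecotype pairs:

1. **Scan.** Two natural populations adapted to contrasting habitats
   ("lake" and "stream") are pool-sequenced at high depth. Per-SNP
   differentiation is quantified by the absolute allele frequency
   difference, $\mathrm{AFD} = |p_\text{lake} - p_\text{stream}|$, a
   bounded $[0,1]$ measure that is directly comparable across SNPs.
   Exceptionally differentiated regions are candidate targets of divergent
   selection.
2. **Experiment.** A laboratory F2 hybrid cross of the two ecotypes is
   released into one habitat; survivors are recaptured a year later. A
   reference sample frozen at release time provides the pre-selection
   allele frequencies.
3. **Test.** At one representative "target" SNP per candidate region, the
   frequency shift of the *stream allele* (the allele more common in the
   natural stream population) from the reference to the pooled survivors is
   computed. If survival was selective in the stream direction, shifts
   should be collectively positive — assessed by an exact binomial sign
   test and by comparison with a resampling null built from neutral SNPs.
4. **Interpretation.** Individual-based forward simulations translate the
   observed shift magnitude into plausible per-locus selection
   coefficients under two multilocus fitness models.

## The scan: SNP calling, thresholds, regions

Per-site nucleotide counts (one row per genomic position, four read counts)
are the raw observable of pool-seq. SNP calling retains sites that are
well-measured and informative:

* read depth within **100–360×** in *each* natural pool (excludes poorly
  sequenced and repetitive regions),
* effectively biallelic: the two top-ranked nucleotides across the summed
  counts of both pools must carry **≥ 99%** of reads (the tolerance absorbs
  sequencing error; a count tie between the second- and third-ranked
  nucleotide makes the allele pair ambiguous and drops the site),
* minor allele frequency **≥ 0.25** over the summed counts of both pools
  (low-MAF SNPs cannot show high differentiation and only dilute the scan).

Frequencies are always renormalised over the two retained alleles.
Missing sites (no coverage in one pool) are treated as unsequenced, never
as frequency zero.

High-differentiation SNPs are those at or above the top **0.1 percentile**
of the AFD distribution, computed **per chromosome** with a nearest-rank
(type 1) quantile — parameter-free and exactly reproducible. Chromosome-
specific thresholds absorb differences in baseline differentiation driven
by chromosome-scale variation in crossover rate; a genome-wide threshold
mode is available as a configuration flag. High SNPs within **50 kb** of a
neighbour are chained into one candidate region (single linkage, so a run
of SNPs each within 50 kb joins even if the region ends are farther apart —
the natural reading of pairwise proximity on sorted positions).

One target SNP represents each region: the member with maximal AFD that
also has **≥ 70×** depth and **MAF ≥ 0.25** in the reference sample and is
sequenced (≥ 1 read) in **≥ 35 of the 37** survivors. Ties at maximal AFD
go to the smallest position for determinism. Regions with no passing
member stay untagged; that is expected, not an error.

## The shift test

Survivor counts are summed across individuals into a single pool —
deliberately avoiding diploid genotype calling at ~3× per-fish depth. Each
target's shift is

$$\Delta = f_\text{survivors}(\text{stream allele}) -
  f_\text{reference}(\text{stream allele}).$$

**Sign test.** With $k$ positive shifts among $n$ nonzero shifts, the
two-tailed probability is $\min(1,\, 2\Pr[X \ge \max(k, n-k)])$ for
$X \sim \mathrm{Bin}(n, 1/2)$ — twice the smaller tail, capped at one,
which for the symmetric null equals the exact two-sided test. Zero shifts
carry no direction and are excluded from $n$.

**Resampling null.** The observed median (and mean) shift is compared with
the same statistics computed over 9999 resampled sets of "neutral" SNPs.
Panel SNPs must satisfy exactly the filters applied to the targets (70×
depth in reference and survivor pool, ≥ 35 survivors covered) plus:

* AFD within **0–0.1** in the natural comparison (SNPs assumed little
  affected by divergent selection), and
* reference MAF **≥ 0.35**. This matters: the magnitude of measurable
  differentiation is contingent on MAF, and the targets are by
  construction high-MAF SNPs. The stringent MAF filter matches the panel's
  MAF spectrum to the targets' so that a shift difference cannot be a
  diversity artifact.

Each resampled set contains as many SNPs as there are targets, drawn
without replacement within a set and with pairwise physical spacing
> 50 kb (mirroring the independence of the target regions); the same SNP
may recur across iterations. The spacing is enforced by rejection: a random
permutation of the panel is walked, SNPs violating spacing against already
accepted ones are skipped, and an exhausted permutation restarts the
iteration (with a restart cap guarding against infeasible panels). The
empirical two-tailed probability is the fraction of iterations whose
|statistic| reaches the observed |statistic| — `count/iterations` by
default, with a plus-one–corrected variant available by flag for users who
prefer a strictly positive estimate.

Six published robustness variants are bundled: the low-AFD panel at
reference MAF 0.25 / 0.35 / 0.40, a fully independent mid-AFD panel
(0.1–0.17, markers within 25% of the genome-wide median differentiation),
and unrestricted-AFD panels at MAF 0.25 / 0.35.

Note one deliberate distinction: the *median of per-SNP shifts* is not the
difference of median frequencies. The two statistics are computed
independently and a regression test keeps them that way.

## Simulators

### Single generation

A population of $N = 1000$ diploids (the release cohort minus presumed
early emigration) carries $L = 100$ unlinked biallelic codominant loci.
Initial favorable-allele frequencies are drawn with replacement from an
empirical spectrum (below) and genotypes follow Hardy–Weinberg. With $n$
the number of unfavored alleles in an individual:

* **multiplicative** fitness $w = (1-s)^n$ — background-independent,
  positive for $s < 1$;
* **additive** fitness $w = \max(0,\, 1 - s\,n)$ — allelic effects
  interact through the truncation at zero; when many individuals hit the
  floor, selection becomes truncational.

Viability selection draws **40 survivors** without replacement with
probability proportional to fitness — implemented via exponential races
(`rexp(n)/w`, keep the smallest keys), which is distributionally identical
to successive fitness-proportional draws but $O(n\log n)$. If fewer than
40 individuals have positive fitness the replicate is recorded as extinct.
The replicate statistic is the median over loci of (survivor frequency −
*realized* pre-selection frequency); using the realized rather than the
drawn frequency removes initialisation noise, mirroring the empirical
reference-vs-survivor design. Grids over $s$ summarise replicate medians
by their grand median and 2.5/97.5 percentiles, plus truncation and
extinction fractions. Robustness modes: $N = 3000$, $L = 200$, and
per-locus coefficients drawn from an exponential distribution with rate
$1/s$ (multiplicative draws ≥ 1 are redrawn).

### Multiple generations

A constant population of $K = 5000$ hermaphrodites evolves for 500
generations under fertility selection: each generation has $K/2$ matings;
both parents of a mating are drawn independently with probability
proportional to fitness (individuals may mate repeatedly; selfing is
possible but negligible at this $K$, and excluding it is not implied by
the mating model), each mating leaves two offspring, and transmission is
Mendelian and unlinked. Twenty neutral loci initialised uniformly on
$[0.2, 0.8]$ ride along as a drift control. Fitness is recomputed every
generation with constant $s$ (a stated model assumption), additive
negatives are clamped to zero before parent sampling, and offspring per
mating is configurable (higher counts change nothing qualitatively).

The analytic oracle
$p' = p / \left(p + (1-p)(1-s)\right)$
— the one-generation update of the favorable-allele frequency under
multiplicative selection in an infinite HWE population — validates both
simulators: the single-generation survivor frequency at $L = 1$ matches
it within Monte-Carlo error, and the multi-generation selected-loci median
tracks its iterate inside the replicate envelope for the first dozens of
generations.

### The default frequency spectrum

The empirical stream-allele frequencies of the targets in the reference
sample are not shipped with the package, so simulations default to a
deterministic stand-in: the 126 quantiles of a Beta(2.2, 1.9) rescaled to
$[0.25, 0.75]$ — the support implied by the MAF ≥ 0.25 ascertainment —
with median 0.522 and mean 0.518, anchored on the published median
reference frequency of 0.523. Two non-obvious consequences of this choice
were checked analytically before simulating: the mean unfavored-allele
count $2L(1-\bar p) \approx 96.5$ places the additive truncation onset
(first zero-fitness individuals in a cohort of 1000) between $s = 0.008$
and $s = 0.009$, and a minority (~30%) of generation-0 individuals starts
with negative pre-clamp fitness at additive $s = 0.01$ — both are
spectrum-sensitive quantities, which is why the package's checks treat
them as brackets rather than point targets.

## The synthetic-data generator

The generator produces complete study bundles — genome map, lake/stream/
reference count tables, 37 per-survivor count tables, and a truth
manifest — so the scan, the shift test, and calibration studies run
without any external data. It emulates:

* SNP density of one per 440 bp (homogeneous point process);
* pool depths of 210× (natural pools) and 127× (reference), Poisson per
  site, with a 0.1% per-read error redistributed uniformly over the other
  three nucleotides;
* per-survivor mean depths uniform on 2.6–4.4× (published mean 3.1×), so
  zero-coverage sites arise naturally and exercise the 35-of-37 filter;
  pooled survivor depth lands near the published ~115–130×;
* an F2 reference whose true frequency is the lake/stream midpoint plus
  binomial noise from 510 diploid founders;
* 126 planted divergent loci, pairwise > 50 kb apart, with true AFD drawn
  uniformly from 0.477–0.934 and lake/stream frequencies placed
  symmetrically about 0.5 (an offset option reproduces the slight
  asymmetry of the published medians 0.219/0.816);
* a released cohort of 3000 fish from which 37 survivors are drawn either
  uniformly (null bundles) or by fitness acting on the planted loci
  (selection bundles). Because loci are unlinked and fitness ignores
  background loci, survivor genotypes at background loci are drawn
  directly at Hardy–Weinberg — the exact distribution of the 37-fish
  bottleneck — without materialising all 3000 genomes.

**Background differentiation.** Only the median (0.139) and mean (0.165)
of the genome-wide AFD distribution are anchored by the study; its shape
is not published. The generator uses true background AFD
$= d \cdot \mathrm{Beta}(1.2, 1.5)$ with $d$ tuned by bisection so the
median is 0.139 ($d \approx 0.324$). This shape was chosen for two
properties the measured data demonstrably had: about 35–40% of SNPs fall
below AFD 0.1 (the published neutral-panel share is 38%), and the
*measured* background 0.1-percentile — after 210× binomial sampling noise
— stays below 0.477, the least differentiated real target SNP. A
fatter-tailed shape could also match the published mean of 0.165, but
would push measured background beyond the weakest targets, contradicting
the fact that the real thresholds separated them; the generator accepts a
realized mean near 0.148 instead. Ancestral frequencies are uniform on
[0.15, 0.85] and are redrawn if a divergence draw would cross a frequency
boundary, so the drawn AFD magnitude is preserved exactly.

**Selection strength in bundles.** With 126 planted loci at reference
frequency ~0.5, an additive per-locus coefficient as small as 0.01 already
gives a mean load of $0.01 \times 126 \approx 1.26$: nearly the whole
released cohort truncates to zero fitness and no 37-survivor draw exists.
Selection bundles therefore default to multiplicative $s = 0.1$, which is
always feasible and — by the oracle above — produces an expected per-locus
shift of $\approx 0.026$ at $p = 0.5$, the same order as the empirically
observed median shift of 2.5%.

## Calibration and what passing means

The package's own validation (see `tests/testthat/`) includes a
calibration study: 200 reduced null bundles (five 2.5-Mb chromosomes at
one SNP per 2.5 kb ≈ 5000 SNPs, neutral survivors, 999 resampling
iterations each) in which the planted positions act as unselected target
stand-ins. The nominal-0.05 rejection rate of the resampling test must
fall inside the 99% binomial band around 0.05; across development runs it
sits near 0.05–0.07. The residual excess is a known small-genome artifact:
the eligible panel of a 12.5-Mb genome holds only a few hundred SNPs, so
drawing ~110 of them without replacement under the 50-kb spacing rule
narrows the null slightly relative to the independent targets
(finite-population correction). At the real study's scale (hundreds of
thousands of panel SNPs across 447 Mb) the effect is negligible.

Problem sizes used by the packaged checks were chosen to keep the full
suite in the tens of minutes on a single core: the calibration study as
above; planted-locus recovery on a 5 × 20 Mb genome at full SNP density
(so that 126 planted loci stay below the 0.1% tail and the threshold is
set by the background, as in the real data); selection grids at 1000
replicates per point; the multi-generation run at $K = 1000$, 10
replicates, 100 generations. The full published operating points
($10^4$ replicates, $K = 5000$, 500 generations) are the function
defaults.

What passing does **not** show: the generator draws unlinked SNPs, so
linkage disequilibrium between nearby background SNPs, haplotype structure
in candidate regions, reference-genome mapping bias, and unequal
individual representation within pools are all outside what these tests
exercise. Conclusions about the real data's robustness to those features
must come from the published robustness checks, not from this package's
synthetic calibration.

## Numerical and design choices

* Nearest-rank quantiles, inclusive thresholds (`afd >= cutoff`,
  `depth >= 70`), and smallest-position tie-breaks make every filter
  decision deterministic.
* "Sequenced in a survivor" means ≥ 1 read at the site; the survivor
  analysis is count-based throughout, so no genotype-quality notion is
  needed.
* A SNP with exactly equal lake and stream frequencies cannot be
  polarized; such SNPs are flagged and excluded (they cannot be targets,
  whose AFD exceeds a positive threshold).
* Coordinates are 1-based inclusive; all distances in bp; chromosomes are
  treated as autosomes (exclusion lists are a configuration concern).
* All randomness flows from one master seed through a documented
  Park–Miller derivation (`derive_seed(master, stage, index)`), so any
  stage or replicate can be reproduced in isolation; rerunning a pipeline
  with the same inputs, config, and seed is bit-identical.
* The empirical probability's default `count/iterations` form is the one
  consistent with published arithmetic at 9999 iterations; the plus-one
  correction is provided but off by default.

## A worked example

```{r example, eval = FALSE}
library(polyshift)

cfg <- study_config(
  n_chrom = 5, chrom_length = 8e6, mean_spacing = 800,
  scheme = fitness_scheme("multiplicative", 0.3)
)
bundle <- generate_study_bundle(cfg, seed = 42)

report <- run_full_analysis(
  bundle,
  config = list(iterations = 999, run_robustness = FALSE),
  seed = 2
)
report
glance(report)
autoplot(report$null)
```

## Known limitations

* The AFD scan assumes the pool accurately represents population allele
  frequencies; unequal individual contributions to a pool bias frequencies
  in ways the generator does not model.
* Per-SNP inference is out of scope by design: the method detects a global
  signal, and nothing in the package should be read as a significance call
  on an individual locus.
* The simulators are free of linkage, dominance (beyond codominance),
  mutation, and migration; they bracket plausibility of selection
  strength, they do not estimate $s$.
* At reduced genome sizes the resampling null is mildly anticonservative
  (finite panel; see Calibration), which is why calibration is assessed
  against a binomial band rather than a point value.
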