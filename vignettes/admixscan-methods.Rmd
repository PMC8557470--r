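---
title: "Methods: scanning admixed genomes for introgression, sweeps and balancing selection"
author: "admixscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning admixed genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Post-glacial recolonisation leaves many outcrossing species — forest
trees are the canonical case — structured as mosaics of divergent
ancestral gene pools that met again on secondary contact.  In such a
cohort three selective signals coexist and must be told apart:
**adaptive introgression** (a donor haplotype entering a hybrid
population and rising to fixation), **selective sweeps** (loss of
haplotype diversity around a favoured allele), and **balancing
selection** (clusters of intermediate-frequency variants maintained
across all populations).  admixscan implements the full scan stack for
this setting, together with a synthetic-cohort generator so that every
stage can be validated against known truth.

Coordinates follow two conventions, stated at every boundary: site
positions are 1-based (VCF); windows, bins and tract coordinates are
0-based half-open (BED).

# Site-level filters

Sites are dropped when missing in more than 30% of samples, when the
pooled minor-allele frequency is below 0.05, or when a one-sided exact
test of heterozygote excess (the conditional Hardy–Weinberg exact test,
summing the probability of at least the observed heterozygote count
given the allele counts) is significant at a Benjamini–Hochberg FDR of
0.01.  The excess-heterozygosity FDR is computed genome-wide, not per
chromosome: the test statistic's null distribution does not depend on
chromosome, and pooling maximises the stability of the BH threshold.
Filtering is idempotent — BH on the surviving subset can only become
more conservative, which the suite asserts.  LD pruning is the greedy
sliding-window procedure (window 100 SNPs, step 10, r² > 0.2 drops the
later site) with r² computed on genotype dosages over pairwise-complete
observations.

# Windowed diversity and divergence

Within non-overlapping windows (default 10 kb, the last window
truncated at the chromosome end so the partition tiles exactly):

* π per population: per-site unbiased heterozygosity
  2c(n−c)/(n(n−1)) summed and divided by the window length in bp —
  monomorphic positions are treated as invariant, so the denominator is
  physical length;
* D~XY~ per population pair: p₁(1−p₂) + p₂(1−p₁) summed per bp.  The
  package's site-level helper excludes self-pairs, so D~XY~ of a
  population against itself reduces exactly to its π (an identity the
  tests check);
* Hudson's F~ST~ as a ratio of sums — numerator
  (p₁−p₂)² − p₁(1−p₁)/(n₁−1) − p₂(1−p₂)/(n₂−1), denominator
  p₁(1−p₂)+p₂(1−p₁) — which is the standard stable choice for windowed
  scans at modest SNP counts.  F~ST~ is not clamped: it is ≤ 1 by
  construction and may be slightly negative near panmixia.

The folded SFS is the minor-allele-count histogram over the
population's segregating sites, dropping sites with missing genotypes
(the count is reported); Σξ equals the segregating-site count by
construction.

# Four-taxon introgression scan

Derived-allele frequencies are obtained by outgroup polarization: the
ancestral allele is the outgroup majority allele; sites where the
outgroup minor frequency exceeds 0.1, or where it is entirely missing,
are flagged unpolarized and excluded from derived-allele statistics
(they remain available to folded statistics).  Per site,
ABBA = (1−p₁)p₂p₃(1−p~O~) and BABA = p₁(1−p₂)p₃(1−p~O~).  Per window:

* D = Σ(ABBA−BABA)/Σ(ABBA+BABA);
* f~dM~ uses the same numerator with the dynamic-donor denominator:
  when p₂ ≥ p₁ the denominator site pattern substitutes
  p~D~ = max(p₂,p₃) into both the P2 and P3 slots; when p₁ > p₂,
  symmetrically with a sign flip.  This makes the windowed statistic
  exactly antisymmetric under P1↔P2 and bounded in [−1, 1];
* the distance fraction is implemented as
  d~f~ = (D~XY~(P1,P3) − D~XY~(P2,P3)) / (D~XY~(P1,P3) + D~XY~(P2,P3)).
  The defining properties — a purely distance-based estimator on the
  −1…1 scale, positive for P3→P2 gene flow, antisymmetric in P1↔P2,
  and insensitive to gene-flow timing because per-site distances do not
  decay with time since admixture the way f-type numerators do — pin
  this form; the property suite (range, sign, antisymmetry, tract
  recovery) holds for it exactly.

Windows with fewer than 100 usable (polarized, biallelic) SNPs are
masked.  Outlier calling follows the genome-wide-Z description: all
unmasked windows are pooled across chromosomes, each receives
Z = (x−mean)/SD, a one-sided normal p toward the configured direction
(positive = P3→P2), and BH q-values; windows with q < FDR (default
0.05; 0.01 is the stricter published alternative, exposed in config)
are flagged.  At least 30 unmasked windows are required — with fewer
there is no usable genome-wide null and the scan refuses to call
outliers.  A block-jackknife alternative was considered and rejected as
the default because the genome-wide-Z formulation is what the windowed
scan literature this package follows actually uses.

# Local ancestry and the allele dosage difference

Local ancestry uses a deliberately transparent single-layer HMM over
two donor panels — a documented surrogate for two-layer
haplotype-cluster models, not a reimplementation of them.  Hidden state
= donor ancestry per haplotype; emission of a derived/alternate allele
under donor k is ε + f~k~(1−2ε) with f~k~ the panel frequency and
ε = 0.02 an error floor absorbing genotyping error and panel sampling
noise; transitions between adjacent sites at distance d bp switch with
probability 1 − exp(−g·r·d) toward the stationary prior (g = 100
admixture generations; r = 3 × 10⁻⁷ per bp so that g·r matches ancestry
segments of a few tens of kb, the scale of the reference simulations).
Phased input decodes each haplotype with a 2-state forward–backward
pass; unphased input uses the 4-state ordered haplotype-pair chain with
diploid emissions.  Sites where a panel frequency is unavailable get
uninformative emissions (likelihood 1), so their posterior is smoothly
interpolated through the transition model.  The model is small enough
to be validated against exhaustive path enumeration, which the suite
does to 10⁻⁹.

Dosages are reported per haplotype and averaged over the two
haplotypes, so per-sample donor dosages lie in [0, 1] and sum to one
over donors; ADD = |mean dosage~A~ − mean dosage~B~| over the hybrid
population is then also in [0, 1], consistent with published ADD
summaries being below 1 (tools that emit 0–2 diploid dosages put ADD on
a doubled scale).  High-ADD sites are those at or above the genome-wide
0.75 quantile (type-7 linear interpolation, ties kept by ≥).

Supervised global admixture proportions minimise ‖g/2 − Fq‖ over the
probability simplex (g the sample's dosages, F the donor-panel
frequencies), solved exactly by active-set enumeration since the number
of donors is small.

# HAF, SAFE and the iSAFE-style aggregation

HAF(h) is the sum over derived alleles carried by haplotype h of each
allele's derived count in the sample; carriers of a sweeping haplotype
accumulate high HAF.  For variant m in a window, φ(m) is the carriers'
share of total HAF mass, κ(m) the fraction of *distinct* window
haplotypes among carriers, and SAFE(m) = (φ−κ)/√(κ(1−κ)), defined as 0
at κ ∈ {0,1}.  SAFE windows hold 300 variants and overlap by 50%; the
published description of the window unit (bp) conflicts with the cited
method's unit (variants), so the unit is configurable and defaults to
variants, with a bp mode that converts at the region's SNP density.

The aggregation of window SAFE scores into a per-variant iSAFE-style
score is under-specified in the sources this package follows, so it is
pinned and documented here: within each window every variant
contributes its positive SAFE numerator max(φ−κ, 0) — a [0, 1]
quantity that orders variants like SAFE within a frequency class — and
contributions are averaged over the windows containing the variant,
weighted by each window's total positive SAFE mass (its sweep
evidence).  The resulting score is bounded in [0, 1], small (≪ 0.1)
under neutrality, and large for variants whose carriers hold most of
the HAF mass while collapsing to few distinct haplotypes.  Validation
is by simulation recovery and null calibration, not bit-compatibility
with any external implementation.  Significance is strict: score > 0.1.

Case/control mode pools case and control haplotypes for the SAFE
computation (a completed sweep is monomorphic within the case
population alone) and damps each variant by
max(0, f~case~ − f~control~)/f~case~, down-weighting shared,
non-sweep variation — a frequency-based surrogate for random-outgroup
machinery.  One identifiability limit is inherent: hitchhikers fixed on
the swept core share the focal variant's exact carrier set, so the
focal variant is expected among the top-ranked scores, not uniquely
first.

# Folded-β balancing-selection scan

For each core SNP with folded frequency ≥ 0.1 (the `-fold -m 0.1`
semantics), flanking SNPs within 1 kb are weighted by a triangular
similarity kernel w = max(0, 1 − |f~i~ − f~core~|/maxDiff) on folded
frequencies, and β is the weighted flank count minus its neutral
expectation — the local SNP density times 2×halfwidth times the mean
kernel weight under the Watterson-shaped neutral folded SFS
(ψ~k~ ∝ 1/k + 1/(n−k)).  Clusters of SNPs at matching intermediate
frequency therefore score high, and an isolated core scores negative.
The kernel width (maxDiff = 0.1) and halfwidth (1,000 bp) are exposed
in config; the sources pin only the folded mode and the 0.1 core
minimum.

P-values: a literal rank-based empirical p is exactly uniform by
construction, which makes BH degenerate (no rejections at any FDR
below 1).  β p-values therefore come from a robust normal
approximation — median/MAD Z-scores of the genome-wide β distribution,
upper tail — followed by BH per population.  This keeps the
genome-wide-null spirit of an empirical calibration while giving BH a
workable tail; the neutral-simulation calibration in the acceptance
suite bounds the realised false-positive rate.

Shared balancing-selection sites are the intersection of the
per-population q < 0.01 sets over the common core-site universe (the
intersection of the tables' positions — pinned over per-population
universes so that "shared by all populations" is evaluated on sites
every population could have called).  The genome is tiled in 10-kb
bins; bins with ≥ 15 shared sites qualify, and their mean π is
contrasted with the genome-wide bin mean.

β×ADD classification of significant sites: ADD ≥ 0.5 → donor-derived,
signed by the larger mean donor dosage; ADD below the genome-wide 0.75
quantile → shared-standing; between the two cutoffs → intermediate
(significant, but with no confident ancestry attribution);
missing ADD → unscored.  A quantile threshold necessarily leaves ~25%
of ancestry-balanced loci above it, so the discriminating boundary for
donor attribution is the absolute ADD ≥ 0.5 rule; the
intermediate class absorbs the quantile tail rather than forcing it
into either end.

# The synthetic-cohort generator

The generator is a mosaic-frequency model, not a coalescent: fast,
analytically transparent, and sufficient for every downstream
statistic, at the price of realism it does not claim (below).

Reference conditions (the defaults, chosen once):

* one chromosome of 1 Mb carrying 20,000 SNPs (20 SNPs/kb — about
   40% of the SNP density of a deep resequencing study, and enough that
 10-kb windows comfortably exceed the 100-SNP threshold);
* ancestral alternate frequency p ~ U(0.05, 0.95) per site, the
  reference allele ancestral; per-population frequencies from the
  Balding–Nichols Beta(p(1−F)/F, (1−p)(1−F)/F);
* two donor panels, F = 0.1, n = 15 each.  The donors stand in for
  moderately diverged glacial-refugium gene pools; desk-scale ancestry
  inference needs more per-site frequency divergence than deeply
  sampled real panels, which compensate with 100× more sites;
* an outgroup (F = 0.9, n = 10) with 5% of sites fixed for the allele
  opposite the common ingroup allele, so outgroup polarization is
  informative and its failure mode (mispolarized sites) is present;
* two hybrid populations of 10: `hybridN` with donor-B admixture 0.5
  and `hybridS` with 0.1, mirroring a northern/southern contrast in
  which only the north carries a strong eastern-donor component;
  hybrid haplotypes are Markov ancestry mosaics with switch rate
  20/chromosome (expected segment ≈ 50 kb) after 100 admixture
  generations;
* one introgressed-and-swept 60-kb tract (240–300 kb) fixed in
  `hybridN` (carrier frequency 1.0).  Carrier haplotypes copy a shared
  core haplotype exactly between recombination breakpoints drawn
  exponentially (scale 150 kb) on either side of the focal site and are
  fresh donor-B draws beyond them; every carrier derives the focal
  allele.  The donor panel itself carries the swept core at frequency
  0.9 — an adaptively introgressed allele is also at high frequency in
  its donor pool, and without this donor-side sharing f~dM~ and d~f~
  cannot approach the near-1 values the scan is designed to detect;
* three balancing-selection clusters of 24 SNPs in 1 kb at folded
  frequency ≈ 0.5 (jitter SD 0.01, alleles assigned by exact counts so
  the realised folded frequency is pinned), two species-wide and one
  inside the tract; each is centred within a single 10-kb bin, since a
  boundary-straddling cluster can never produce a qualifying bin;
* mutation rate 2.5 × 10⁻⁹ per bp per generation and a 15-year
  generation time carried as annotation for time conversions; no
  missingness by default; a single seed drives all randomness and a
  fixed seed yields byte-identical VCF output.

What the generator does *not* emulate: coalescent genealogies and
linkage disequilibrium beyond the ancestry-mosaic scale, recombination
maps, selection dynamics (the sweep is a haplotype-homogenisation
pattern, not a trajectory), gene conversion, sequencing depth and
genotyping error models.  Passing tests therefore demonstrate that the
statistics recover the *patterns* they are defined to detect, under an
idealised but structurally faithful null — not that any particular
real data set will show them.

The truth record keeps per-sample generative donor dosages, the tract,
the focal site, the balancing-selection loci and per-population
generative frequencies; `validateSim()` checks dosage bounds, folded-SFS
conservation, and frequency recovery (correlation > 0.95 for
populations with ≥ 20 samples, where sampling noise permits a sharp
check).

# Numerical choices and degenerate inputs

BH is `p.adjust(method = "BH")` everywhere.  Zero denominators (empty
windows, zero SAFE evidence, zero genome-wide SD) yield NA/no-outlier
results with a warning, never NaN propagation.  The quantile rule is
type-7 with ≥ at the threshold.  The HMM forward–backward is scaled
per site; posteriors are validated to 10⁻⁹ against enumeration.  The
simplex least squares enumerates active sets, so it is exact and
deterministic.  Multi-allelic and indel VCF records are dropped (with a
count), never split.  All scans are deterministic for fixed input; the
pipeline writes a checksum MANIFEST and two runs with the same seed
produce identical manifests.

# Problem sizes

The test suite validates oracle equivalence on toy instances (≤ 50
sites, ≤ 8 haplotypes, exact to 10⁻⁹) and runs the stochastic
calibration and recovery checks on 20 seeds of the reference conditions
(20,000 sites, 60 samples) and 20 neutral seeds (5,000 sites, 300 kb,
60 samples) — sizes at which every distributional property the scans
rely on is already expressed.  `scripts/acceptance.R` re-measures the
same quantities on 10 fresh seeds per condition.

# Known limitations

* The d~f~ form is pinned from its defining properties (distance-based,
  bounded, antisymmetric), not transcribed from an external reference;
  numerical parity with other implementations is not claimed.
* The iSAFE aggregation and the case/control damping are documented
  surrogates validated by recovery, not re-implementations.
* β's Watterson-scaled expectation assumes a neutral-shaped background
  SFS; the robust-Z p-values absorb moderate deviations, but heavily
  non-equilibrium backgrounds shift the β null, which is why the
  per-population empirical calibration matters.
* The ancestry HMM is single-layer: it does not model haplotype
  structure within panels and will lose precision when donor panels are
  very closely related or very small.
* Window-level FDR uses normal-theory p-values from genome-wide Z; with
  strong genome-wide autocorrelation of the statistic a block jackknife
  would be more conservative.
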