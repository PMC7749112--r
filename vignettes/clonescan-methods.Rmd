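---
title: "Detecting recombination and genetic exchange in clonal diploids: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recombination and genetic exchange in clonal diploids: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Putatively ancient asexuals — bdelloid rotifers being the canonical case —
are expected to carry characteristic genomic signatures: a large excess of
heterozygotes at individual loci (inbreeding coefficient F_IS approaching
-1 as the two alleles of each locus diverge independently, the Meselson
effect), strong linkage disequilibrium (LD) at all distances, congruent
haplotype phylogenies across the genome, and a deficit of triallelic sites
carrying all three heterozygous genotypes. A small population sample of
diploid genomes is enough to test all of these. `clonescan` implements the
full battery: per-site F_IS with a simulation-calibrated clonality test, LD
decay from phased and unphased data, per-segment recombination tests, a
modified four-gamete test that within-locus gene conversion cannot fool,
quality control for read-based phasing, and haplotype-incongruence
detection. A forward simulator of facultatively clonal diploids generates
the calibration and test data.

## The forward simulator

`run_simulation()` evolves a Wright-Fisher population of `Ne` diploids.
Each offspring is, independently, **clonal** with probability
`cloning_rate` — a mitotic copy of one fitness-weighted parent — or
**sexual**: two fitness-weighted parents each transmit one gamete with
crossovers arising as a Poisson process at `crossover_rate` per bp. Parents
are drawn with replacement proportional to fitness; selfing is allowed
(nothing in the model forbids it, and at the sample sizes used it is a
1/Ne effect). Mutations arise at `mutation_rate` per bp per genome copy per
generation; a fraction 0.4/1.4 of them (neutral:deleterious = 1:0.4) draw a
selection coefficient from a negative gamma distribution with mean -0.01
and shape 0.1. Fitness is multiplicative across sites with additive
within-locus dominance (heterozygote effect s/2). Within-locus gene
conversion is applied per segregating site per individual per generation at
rate `conversion_rate` (alpha): a heterozygous site becomes homozygous, the
donor haplotype chosen with probability 1/2, so the expected population
allele frequency is unchanged. Conversion tracts have length one site;
tract-length models are out of scope.

Two sites models are available. Under `"infinite"` sites every mutation
creates a new biallelic site. Under `"finite4"` each position carries one
of four nucleotide states with equal exchange rates (Jukes-Cantor-like), so
recurrent mutation can produce triallelic and quadallelic sites — required
for the triallelic-site analyses.

Coordinates are striped over `n_contigs` equal-length contigs. Contigs
represent independent scaffolds: in meiosis they assort freely (a boundary
crossover with probability 1/2), while within a contig crossovers follow
the per-bp rate. Distances are only defined within a contig. Free
assortment matters for calibration work: the mean F_IS of a replicate is an
average over contig genealogies, and with a single linked genome its
replicate-to-replicate spread would be several times larger than the effect
sizes being resolved.

The full-scale default (`sim_config()`) is Ne = 2500, mu = 1e-6, crossover
1e-6 per bp per sexual generation, L = 1e6 bp, 200000 generations — a
population-scaled mutation rate 4\*Ne\*mu = 0.01, matching the diversity of
the natural population that motivates the package.

### Desk-scale rescaling

`scaled_config(scale = k)` applies standard population-genetic rescaling:
`Ne/k` individuals, per-generation rates multiplied by `k`. This preserves
4\*Ne\*mu, 4\*Ne\*r **and** — less commonly appreciated — the
population-scaled sexual rate Ne\*(1 - cloning_rate), by mapping the
nominal cloning rate c to an effective per-generation value
1 - min(1, k\*(1 - c)). The deviation of F_IS from 0 under partial
clonality is governed by roughly -1/(2\*Ne\*s + 4\*Ne\*mu) with s the
sexual fraction, so without the sexual-rate mapping a rescaled sweep would
place the sexuality detection threshold an order of magnitude too high.

Two quantities are deliberately **not** rescaled:

* **Selection coefficients.** Multiplying s by k = 25-50 produces
  coefficients of order 0.25-1, outside the diffusion-equivalence regime.
  Empirically this induces associative overdominance around selected sites
  and biases the F_IS of fully sexual populations to about -0.15, an
  artifact the full-scale model does not show. The DFE therefore keeps its
  per-generation values; at desk scale selection is correspondingly weaker
  (2\*Ne\*s of order 1), which is immaterial for the neutral-site
  statistics this package targets.
* **The conversion rate.** The clonal-HWE equilibrium alpha = 1/(2\*Ne) is
  a statement about the simulated population itself, so alpha is given in
  simulation units.

### Problem sizes used by the tests and the acceptance script

The cloning-rate sweep runs `sweep_config()`: scale 25 (Ne = 100,
mu = 2.5e-5), 40 contigs of 1 kb (L = 4e4), 2000 generations (20 Ne, ample
for mutation-drift equilibrium at the 2\*Ne coalescent timescale), 20
replicates per cloning rate. Each replicate yields one mean F_IS over 8
randomly drawn individuals, sites with minor allele count (MAC) >= 4 within
that subsample, and 200 randomly drawn SNPs — the same reduction applied to
observed data, so simulated and observed set means are directly comparable.
Per-segment test calibration uses independent single-contig populations
(Ne = 80, 2.5 kb, 1600 generations), one segment per replicate, because
segments cut from one clonal population share a single genealogy and are
not independent draws. Other checks use similarly sized configurations;
each is stated in the test that runs it.

## F_IS and the clonality test

For a biallelic site with genotype counts (n_AA, n_AB, n_BB) and n
individuals, `site_fis()` computes p = (2 n_AA + n_AB)/(2n), the expected
heterozygote count He = 2p(1-p)n **rounded to the nearest integer**, and
F_IS = 1 - Ho/He. The integer rounding of He is part of the convention this
package reproduces; the tie rule is round-half-to-even by default
(`rounding = "up"` selects half-up — ties never occur at n = 8, where
2p(1-p)n has denominator 16). F_IS is 0 at Hardy-Weinberg proportions, -1
when every individual is heterozygous (which forces p = 1/2), and +1 when
no individual is.

Two small-sample properties matter when reading mean F_IS values. He is
computed from the sample allele frequency without the 2n/(2n-1) correction,
which biases F_IS down by about 1/(2n-1); and conditioning on MAC >= 4
together with the rounding pushes the *per-site mean* further down, to
about -0.05 to -0.1 at n = 8 even for perfectly panmictic data. Both
conventions follow the original analysis, and the clonality test is immune
to them because observed and simulated set means carry identical biases.
The conversion-equilibrium check (below) instead uses the unfiltered
per-site mean (MAC >= 1), where the conditioning bias is small.

`subsample_mean_fis()` implements the reduction described above;
`clonality_pvalue()` is the one-sided p-value: the fraction of simulated
set means at or above the *minimum* observed set mean, with no
multiple-comparison correction. `sexual_rate_threshold()` summarises a
sweep: a cloning rate is indistinguishable from full sexuality when at
least half of its replicate means lie inside the central 95% interval of
the cloning-rate-0 means, and it falls below when the mean of its means is
under that interval. The threshold rule (half the replicates in-band) is a
design choice: demanding *all* means in-band would be noise-dominated at 20
replicates, and the 50% mark separates distributions shifted by more than
about one interquartile range.

## The clonal-HWE conversion equilibrium

In a strictly clonal population, within-individual allele divergence is
eroded by conversion (rate alpha) and replenished by mutation (rate 2u per
site pair), giving within-individual identity x = alpha/(alpha + 2u);
between-individual identity is set by drift. Equating the two shows the
population sits at Hardy-Weinberg proportions when alpha = 1/(2 Ne), with
heterozygote excess below and homozygote excess above. The package verifies
the equilibrium point and both directions by simulation in neutral runs.
Neutrality matters here: with deleterious mutations, background selection
in a fully clonal population (where the whole genome is one linkage block)
roughly halves the effective population size and shifts the equilibrium
toward alpha = 1/Ne of the census size.

## LD statistics

`pair_r2_table()` computes r2 = D^2 / (pA qA pB qB) between biallelic sites
across phased haplotypes (equivalently, the squared Pearson correlation of
allele indicators); `genotype_pair_table()` computes the squared Pearson
correlation between genotype dosages, which needs no phasing; and
`homozygote_haplotypes()` builds one unambiguous pseudo-haplotype per
individual from sites homozygous in everyone, a second phasing-free route.
Sites are filtered to MAC >= 4 by default. Within-contig pairs up to 4 kb
form the decay records; pairs on different contigs, where distance is
undefined, are sampled as the unlinked baseline. `bin_and_bootstrap()` bins
by distance (fixed 200-bp widths or equal-count bins) with 1000-replicate
percentile bootstrap CIs, and `decay_curve()` fits a second-degree LOESS
(span 0.4) and reports the smallest distance at which the curve enters the
baseline mean +/- 1 SE band.

## Per-segment recombination tests

Three tests run on a phased segment's haplotype matrix, each with a
permutation null that shuffles SNP positions while holding the haplotype
columns fixed (the observed genotype configuration is exchangeable over
positions exactly when position carries no information, i.e. no
recombination):

* `segment_r2_distance_test()`: Pearson correlation of pairwise r2 with
  distance; one-sided toward negative correlations.
* `sum_of_distances_test()`: D4, the summed distance over pairs displaying
  all four gametes; one-sided toward large D4 (recombination concentrates
  four-gamete pairs at long range). No four-gamete pair gives D4 = 0 and
  p = 1.
* `phi_test()`: the pairwise homoplasy index — mean incompatibility over
  informative-site pairs within a window (100 units; base pairs when
  positions are supplied, which matches running the original tool on full
  sequences where non-SNP columns are monomorphic). Without recombination,
  homoplasy is independent of position, so nearby pairs score like random
  ones; recombination makes nearby sites *more* compatible, and the test
  rejects when the observed PHI is low. The default p-value is by
  permutation; a moment-matched normal approximation is available as
  `method = "normal"` for compatibility with the convention of assessing
  PHI against a normal null, but the permutation mode is more robust for
  segments with few informative sites.

All permutation p-values use the add-one convention (b + 1)/(m + 1), so
they are bounded below by 1/(m + 1) and never exactly zero. Segments with
fewer than 4 SNPs (or fewer than 2 informative sites for PHI) are skipped
with a flag. Bonferroni correction across segments is left to the caller.

## The modified four-gamete test

The classical four-gamete test reads the presence of all four two-locus
gametes in a population as evidence of recombination, but a mutation
followed by within-locus gene conversion can also produce all four
haplotypes. Conversion, however, can only turn a heterozygous genotype
homozygous — never the reverse — so it cannot produce **two individuals,
each heterozygous at both loci, jointly displaying all four gametes**.
`scan_recombinant_pairs()` enumerates, per phased segment and per unordered
individual pair, the SNP pairs heterozygous in both individuals and
classifies each by the size of its gamete set; size 4 is a "recombinant"
pair. Recurrent mutation (finite-sites) can also create recombinant pairs,
but their frequency carries no distance trend, whereas crossovers make the
recombinant fraction grow with distance: `recombinant_fraction_by_bin()`
splits the records into equal-count distance bins (boundary ties to the
lower bin) with bootstrap CIs and all-pairs permutation comparisons, and
`distance_shift_test()` compares mean distances of recombinant and
non-recombinant pairs by label permutation. Records are pooled over
individual pairs by default; `dedupe = TRUE` keeps each site pair once.

## Phasing quality control

Read-based phasers emit per-individual blocks of jointly phased
heterozygous SNPs. `conflicting_evidence_filter()` drops blocks where read
fragments support more than two two-site allele combinations in one
individual (template switching / paralogy; the support threshold defaults
to 1 read and is exposed). `quality_split()` drops blocks with more than
one SNP of switch or mismatch quality < 100 and splits blocks with exactly
one at that SNP, excluding it from both halves (its phase is exactly what
is in doubt). `complement_homozygous()` adds homozygous SNPs lying strictly
inside a block's span to both haplotypes; it runs after the filters.
`common_phased_segments()` intersects blocks across individuals into
maximal co-phased intervals and keeps those with at least 15 non-singleton
SNPs — a non-singleton SNP being one whose minor allele occurs in at least
two of the phased haplotypes (the term is used in the field without a
formal definition; this is the natural reading). `switch_inconsistency()`
compares two independent phasings of the same individual by the relative
phase orientation of consecutive shared het SNPs; it is invariant to global
haplotype flips, so only genuine switch points count.

## Haplotype incongruence and trees

Within a phased segment, `hap_distance_matrix()` counts SNP differences
between all 2n haplotypes (non-SNP positions are treated as monomorphic;
decisions use counts, not proportions, so segment length does not enter).
`closest_counterpart()` finds each haplotype's nearest haplotype in *other*
individuals and calls the match unambiguous when the runner-up is at least
3 SNPs farther. `classify_grouping()` then requires, for a focal
individual, (1) unambiguous counterparts for both haplotypes, (2) both
counterpart distances strictly smaller than the within-individual distance
— groupings that gene conversion could generate fail here — and (3)
reciprocal best matches. The grouping is congruent when both counterparts
sit in one individual and incongruent otherwise; the incongruence pattern
is the unordered pair of partner individuals, and a segment can contribute
one pattern per focal individual. `paralog_screen()` removes segments whose
haplotypes hit more than 10 contigs or have more than 2 high-identity
(>= 90%) hits in a reference assembly, so diverged repeats are not mistaken
for alleles.

Trees are neighbor-joining (`nj_tree()`, via ape) with supports from
resampling SNP columns (`bootstrap_support()`, 1000 replicates by default)
and midpoint rooting (`midpoint_root()`, via phangorn). NJ is deliberately
a baseline engine — the package's contribution is the scanning logic, and
externally inferred maximum-likelihood trees can be imported as newick
(`read_newick()`) and scanned identically. `monophyly_scan()` enumerates
maximal clades composed exclusively of a target haplotype set with
bootstrap support >= 70%, reporting clade sizes, whether a clade holds
exactly one haplotype per target individual, and whether the root
bipartition separates it from everything else — the hybrid-origin
signature: each F1 carries one haplotype from an unsampled source
population, and those haplotypes, one per hybrid, form a well-supported
clade of their own while the full set of hybrid haplotypes never does.

## What the generator does and does not emulate

The synthetic data reproduce the population-genetic structure of the study
system: diploid genotypes and truth haplotypes for ~8-11 individuals,
tunable cloning rate, gene conversion, gamma-distributed deleterious
effects, 4\*Ne\*mu near 0.01, multi-contig coordinates, finite-site
mutation for triallelic sites, and a two-population F1 scenario. They do
**not** emulate sequencing artifacts: read mapping and variant-calling
error, falsely homozygous calls (the corresponding read-evidence filter is
exercised with constructed fragment tables), index hopping, contamination,
or real phasing error (truth haplotypes are perfectly phased; the phasing
QC filters are tested on constructed blocks). Passing tests therefore
demonstrate the statistical machinery and its calibration on clean data,
not robustness to upstream bioinformatic noise.

## Numerical choices and degenerate inputs

* He = 0 after rounding is flagged undefined and excluded from means; for
  biallelic sites with both alleles present He_raw >= 0.75, so this cannot
  occur — the flag guards programmatic edge cases only.
* Monomorphic sites are rejected by `site_fis()` and LD statistics with
  explicit errors; monomorphic samples export as valid VCFs with zero
  records.
* Equal-count bin edges are distance quantiles; ties go to the lower bin.
* Empty bins yield n = 0 rows without CIs; single-record bins collapse the
  CI onto the value.
* Cross-contig baselines subsample at most 20000 pairs (the full set is
  quadratic and its mean stabilises long before that).
* All simulator randomness flows from R's RNG: `set.seed()` makes any run,
  including the compiled core, reproducible.

## Known limitations

* The simulator's conversion acts per site (tract length 1); conversion
  tracts spanning several SNPs would produce correlated conversions the
  four-gamete logic still tolerates (it is conversion-proof regardless) but
  the alpha calibration would change.
* Desk-scale runs leave selection effectively weak (unscaled DFE, see
  above); analyses of linked selection are out of scope.
* The incongruence margin (3 SNPs) is the original convention; segments
  with very low diversity rarely clear it, so "undetermined" dominates when
  within-population diversity is small relative to the margin.
* `sexual_rate_threshold()` resolves only the rates present in the sweep
  grid; the 1% readout is grid-limited, not a continuous estimate.
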