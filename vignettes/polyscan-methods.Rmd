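---
title: "Methods: ploidy-aware divergence scans, LD-based phasing and topology weighting"
author: "polyscan developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ploidy-aware divergence scans, LD-based phasing and topology weighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Two outcrossing sister species each contain diploid and autotetraploid
populations. The tetraploids arose by whole-genome duplication (WGD) at
different times, inherit tetrasomically (all four homologs pair), and --
although the species are deeply diverged -- exchange alleles with each other
specifically at the tetraploid level, because shared ploidy removes the
triploid-block barrier. Two questions drive the analysis:

1. Which loci show exceptional differentiation between diploids and
   tetraploids of the same species (candidate adaptations to the WGD
   state)?
2. Are those loci the product of localized interspecific introgression
   between the tetraploids, rather than de novo change?

`polyscan` implements the full desk-scale pipeline: mixed-ploidy VCF
ingestion, windowed divergence scans with outlier-overlap permutation
tests, heuristic phasing of diploid and tetraploid genotypes, per-window
BIONJ genealogies, and exact or Monte-Carlo topology weighting over the
fifteen rooted five-taxon topologies, plus a coalescent generator that
produces data with known truth for every stage.

# Data model

Genotypes are stored as ALT-allele dosages: a diploid `0/1` is dosage 1 of
ploidy 2, a tetraploid `0/1/1/1` is dosage 3 of ploidy 4. Ploidy is
inferred per sample from the arity of its GT field and must be constant.
Missing calls stay missing (`NA`); no downstream statistic imputes them --
every denominator counts called alleles only. Default site filters (at
most 10% missing alleles per site, minimum genotype depth 5) follow the
hard-filter conventions of structure-type analyses of these data and can
be overridden per stage.

# Divergence statistics

For populations $A, B$ and window $W$ with per-site ALT frequencies
$p_{A,s}, p_{B,s}$ over called alleles ($n_{A,s}, n_{B,s}$ of them):

* **AFD** $= \mathrm{mean}_s |p_{A,s} - p_{B,s}|$ (absolute difference;
  the sign convention is a package choice, the source does not state one).
* **dXY** $= \mathrm{mean}_s [p_{A,s}(1-p_{B,s}) + p_{B,s}(1-p_{A,s})]$.
  Averaged per SNP, not per bp: values are comparable between windows of
  this pipeline but not to per-bp dXY from other tools.
* **Fst**: Hudson-type ratio of sums $1 - \sum_s \bar H_{w,s} / \sum_s
  H_{b,s}$ with unbiased within-population expected heterozygosity
  $2p(1-p)\,n/(n-1)$ and $H_b$ as in dXY. Ratio-of-sums is used for
  small-window stability; SNPs with fewer than 2 called alleles in either
  population are excluded from the Fst sums only.
* **Rho**: the intraclass correlation of *individual allele frequencies*
  $x_{i} = \text{dosage}_i/\text{ploidy}_i$, accumulated as a ratio of
  sums of one-way ANOVA components across SNPs:
  $\rho_W = \sum_s (MS_{B,s} - MS_{W,s}) / \sum_s (MS_{B,s} + (n_0 - 1)
  MS_{W,s})$ with the standard unequal-$n$ coefficient $n_0$. Because $x$
  is ploidy-free, Rho is invariant when a diploid population is re-encoded
  as tetraploid with doubled dosage (tested to 1e-9), and is unaffected by
  double reduction -- the reason this statistic is used for
  diploid-tetraploid contrasts at all.
* **Fixed differences**: count of SNPs with $p_A, p_B$ fixed for opposite
  alleles.

Group-level metrics are unweighted means over all between-group population
pairs. Negative Fst/Rho values are reported as computed; nothing is
clipped in tables.

# Outliers and overlap

Sweep candidates are windows at or above the empirical 99th percentile per
metric (ties included; quantile type 7). Metrics combine by union by
default -- extreme in any metric -- with intersection available; the
source does not print its rule, so the choice is exposed. Overlap between
two independent scans is assessed against a label-permutation null: two
uniform random subsets of the observed sizes are drawn from the common
universe (windows with finite metrics in both scans), and
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_{\text{perm}} + 1)$. The
null is exactly hypergeometric, which the tests exploit as an independent
closed-form oracle; the permutation implementation is kept so the check
stays two-route.

# Phasing by LD maximisation

Within a window, sites are processed in decreasing order of heterozygote
count (ties by position). The first site takes the canonical configuration
(ALT alleles in the lowest slots); each later site takes the configuration
maximising the mean $r^2$ against all previously phased polymorphic sites,
where $r^2$ is the squared Pearson correlation of 0/1 indicators across
haplotype slots ($r^2$ rather than $r$ or $D'$ because it is sign-free
under allele relabelling; the source does not name its LD statistic). The
per-site search over samples is exhaustive when the joint configuration
space is small (the work bound scales inversely with the number of
reference columns) and coordinate ascent in fixed sample order otherwise;
after the sequential pass, up to two polish rounds re-select each site
against all other sites. All tie-breaks are deterministic (canonical
configuration order), so phasing has no hidden randomness. An exhaustive
optimiser over the whole window (feasible only for tiny instances, after
pinning one site to remove the per-sample slot-relabelling symmetry) is
retained as the testing oracle; on 100 random instances of up to 4 samples
x 4 sites the heuristic attains the optimum in all of them.

Phase validation mirrors the source's design: randomise the true phase
(dosages preserved), re-infer it, and compare topology weightings under
perfect, randomised, and inferred phase. One subtlety matters: on fully
taxon-sorted windows, topology weighting is *insensitive* to within-taxon
phase errors (the method's own robustness property), so all three
conditions coincide and nothing can be measured. The validation therefore
uses windows with a partial introgression pulse (probability 0.6), where
genealogical mixture makes phase informative; there, inferred-phase
weightings are an order of magnitude closer (L1) to perfect-phase
weightings than randomised-phase ones.

# Window genealogies and topology weighting

Per 50-SNP window, haplotype p-distances (mismatch fraction over co-called
sites; no multiple-hit correction -- distances are small at this scale,
and a Jukes-Cantor switch would be a one-line change) feed BIONJ (via
`ape`); negative branch estimates are clamped to zero, which cannot affect
topology-based weighting.

The five taxa (diploid and tetraploid populations of both species, plus an
outgroup) admit fifteen rooted topologies, enumerated with stable ids by
canonical newick key. Structural classes: the single **species** topology
(conspecifics sister), three **introgression** topologies (tetraploids of
the two species form a clade), five **ILS** topologies (a diploid of one
species with the tetraploid of the other), six **other**.

Weighting a window tree: same-taxon monophyletic clades are collapsed to
multiplicity-carrying tips (weighting-invariant; verified against
exhaustive enumeration on uncollapsed trees). If the number of remaining
distinct combinations (product over taxa of remaining tip counts) is at
most 2000, every combination of one tip per taxon is evaluated exactly --
the induced rooted topology is resolved by integer four-point tests on
edge-count distances -- and weights are multiplicity mass over the total,
summing to 1 exactly. Otherwise combinations are sampled
(multiplicity-weighted) in batches of 100 until the 95% Wilson interval
half-width of all fifteen weightings is below 0.05. A note on the
threshold's unit: the collapsed tree's *sum* of multiplicities per taxon
always equals the original tip count, so the 2000-combination rule is
meaningful only on distinct remaining combinations; that reading is used
here.

Introgression peaks are contiguous runs of windows whose
introgression-class weight exceeds a threshold (defaults 0.5 and 0.7),
reported with the maximum-weight window as summit.

# The synthetic world

`demography_scenario()` encodes the reference history: species split at
931k generations, WGDs at 81k (lyrata, with a founder bottleneck) and 226k
(arenosa, none) generations, tetraploid-tetraploid gene flow of 0.1
alleles/generation in each direction while both tetraploid demes exist,
mutation rate 3.7e-8 per bp per generation. Those values are the
published point estimates for this system. The remaining knobs are package
choices, made once:

* **Ne = 50,000** per deme. Large enough that species clades are
  monophyletic in essentially every window (the splits are then 9+
  coalescent units deep) while diploid-tetraploid divergence within a
  species stays shallow; small enough that pulse-introgressed lineages
  coalesce into the donor cluster before the WGD merger.
* **Founder bottleneck** Ne/4 for the 5k generations after the lyrata WGD
  -- a strong but not degenerate founder event.
* **Sampling** of 8/6/4/6 individuals per ingroup taxon plus 2 outgroup
  individuals, split into two populations per ingroup taxon (panmictic
  within taxon; the population split exercises group averaging and gives
  two quasi-independent tetraploid contrasts).
* **500 bp windows in 4 recombination segments.** Windows are laid out as
  disjoint "genes"; each aggregates four independently simulated
  genealogies (free recombination between segments, none within). With
  literally one genealogy per scan window, any fully lineage-sorted
  background window drives Rho -- a variance ratio, blind to divergence
  magnitude -- to ~1, and the 1% outlier tail becomes a dense continuum
  that no sweep can clear; multi-genealogy windows restore the regime the
  statistic assumes in real data. The per-window *tree* model downstream
  still sees few-genealogy 50-SNP windows.
* **Truth layout**: five introgression tracts (pulse at 5k generations,
  probability 0.95 per lineage), three with the lyrata tetraploids as
  recipients; those three are additionally swept to fixation (f = 1.0) of
  an introgressed haplotype -- the coupled introgression-then-selection
  signal the scan/weighting overlap is designed to detect. The sweeping
  haplotype is chosen as the candidate (target- or donor-group true
  haplotype) closest to the donor consensus, i.e. a genuine donor-lineage
  haplotype.

The end-to-end recovery test runs this world with the continuous migration
rate set to zero, which is the configuration the recovery claims are
stated for: designated tracts and sweeps against an otherwise clean
background. With the continuous 0.1 alleles/generation flow switched on,
sporadic *real* introgression windows appear genome-wide -- as they do in
the real data -- and "designated windows are the only peaks" is no longer
a fair assertion.

What a green end-to-end test establishes: the three swept windows are
inside the top-1% outlier sets for AFD and Rho in both tetraploid
contrasts, appear in the between-scan overlap with a permutation p below
0.01, every introgression-class peak at threshold 0.5 is a designated
tract, and the three arenosa-to-lyrata tracts are themselves peaks. What
it does not establish: recovery of the reverse-direction
(lyrata-to-arenosa) tracts at the 0.5 threshold. In this demography the
donor deme for that direction (tetraploid lyrata) exists for only 81k
generations ~ 0.8 coalescent units, so migrant lineages frequently fail to
coalesce into the donor cluster before the WGD merger and those windows
plateau near weight 0.3-0.5. That asymmetry is a property of the stated
history, not of the detector.

# Numerical and degenerate-input conventions

* Quantile thresholds use R's default type-7 empirical quantile; threshold
  ties are all included.
* Permutation p-values carry the +1 correction and can never be 0.
* r-squared LD is defined 0 for monomorphic columns and for pairs with
  fewer than 2 shared called slots (with a warning).
* Haplotype pairs sharing zero called sites get p-distance 1 (warning).
* BIONJ: NaN distances are an error; negative branch lengths are clamped
  to 0; equal-distance matrices resolve by the library's deterministic
  tie rule, and identical input always yields identical newick.
* Exact weights are integer-mass ratios and sum to 1 exactly; sampled
  weights are frequencies and sum to 1 by construction.
* The simulator draws all randomness from the session RNG stream seeded
  once per dataset, so outputs are byte-for-byte reproducible from the
  seed.

# Known limitations

* No within-segment recombination and no selection dynamics: sweeps are
  imposed on genotypes, not simulated forward.
* Windowed dXY is per-SNP, not per-bp.
* The simulator's Ne and sampling depths are desk-scale; absolute
  divergence magnitudes (e.g. genome-wide Fst between ploidies) are
  compressed relative to the published tables and are not comparison
  targets.
* Gene windows from GFF3 resolve overlapping gene models by midpoint
  truncation and drop fully nested models -- a package choice where the
  source is silent.
* Phasing quality is assessed within windows only; no cross-window
  statistical phasing is attempted.
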