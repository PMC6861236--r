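# polyscan

Ploidy-aware population-genomic scans for species pairs with coexisting
diploid and autotetraploid populations.

Whole-genome duplication (WGD) is an abrupt, genome-wide mutation:
autotetraploids must re-stabilise meiosis with four pairing homologs, and
because tetraploids of related species can hybridise across a barrier
their diploids cannot cross, adaptive alleles may move between species
specifically at the tetraploid level. `polyscan` implements the analysis
pipeline for detecting both signals in mixed-ploidy resequencing data:

* **Ingestion** of mixed-ploidy VCFs (`0/1` next to `0/1/1/1`) into an
  ALT-dosage matrix, with per-site missing-allele and depth filters;
  population maps over five taxon groups (diploid/tetraploid of each
  species + outgroup); gene-sized, fixed-SNP-count and BED windows.
* **Windowed divergence scans**: AFD, per-SNP dXY, Hudson-type Fst, the
  ploidy- and double-reduction-independent intraclass correlation **Rho**
  on individual allele frequencies (dosage/ploidy), and fixed differences
  — per population pair and averaged over between-group pairs.
* **Outlier analysis**: empirical 1% outliers per metric, set algebra
  across metrics, overlap of independent scans, and a label-permutation
  test for overlap significance (null = hypergeometric).
* **Phasing** of diploids and tetraploids simultaneously by the iterative
  heuristic that maximises mean pairwise r² LD within a window, with an
  exhaustive optimiser as testing oracle, phase randomisation and
  slot-permutation-aware concordance for validation.
* **Window genealogies** from haplotype p-distances via BIONJ.
* **Topology weighting** over the fifteen rooted five-taxon topologies:
  exact enumeration for trees that simplify to ≤ 2000 haplotype
  combinations, Monte-Carlo sampling with a Wilson-interval (95%, < 0.05
  half-width) stopping rule otherwise; topologies classified as species /
  introgression (tetraploids of both species together) / ILS / other,
  with introgression peak calling.
* **Synthetic data**: a structured-coalescent generator with a deep
  species split (931k generations), two WGDs (81k with founder
  bottleneck, 226k without), tetraploid-tetraploid gene flow, localized
  introgression pulses and imposed selective sweeps — emitting VCF,
  popmap, BED and full truth (including true phase) for every stage.

See `vignettes/polyscan-methods.Rmd` for the statistical details, default
parameters and the design rationale of the synthetic world.

## Worked example

Simulate a 120-gene genome with three introgression-plus-sweep windows
(`w018`, `w042`, `w066`, lyrata tetraploids sweeping an introgressed
arenosa haplotype) and two reverse-direction tracts, then scan diploid
vs. tetraploid lyrata:

```r
library(polyscan)

sc    <- demography_scenario(migration_rate = 0)   # recovery world
truth <- default_truth_spec(n_windows = 120)
ds    <- generate_dataset(sc, n_windows = 120,
                          sweep_spec = truth$sweep_spec,
                          introgression_spec = truth$introgression_spec,
                          seed = 42)
ds$gm
#> genotype_matrix: 19212 biallelic SNPs x 26 samples (14 diploid, 12 tetraploid)
#>   chromosomes: chr1
#>   missing genotypes: 0.00%

scan <- scan_windows(ds$gm, ds$popmap, ds$windows, "lyrata2x", "lyrata4x")
head(scan[order(-scan$rho),
          c("label", "n_snps", "afd", "dxy", "fst", "rho", "fixed_diff")], 5)
#>     label n_snps    afd    dxy   fst   rho fixed_diff
#> 18   w018    145 0.2065 0.2065 0.954 0.970       28.0
#> 8    w008    121 0.0670 0.0670 0.865 0.969        4.5
#> 42   w042    160 0.2355 0.2355 0.934 0.961       34.0
#> 66   w066    164 0.1905 0.1905 0.938 0.941       27.0
#> 118  w118    150 0.0776 0.0782 0.780 0.906        5.5
```

The three swept windows carry both the highest absolute divergence (AFD
0.19–0.24 against a genome-wide background of ~0.04) and dozens of fixed
differences; `w008` shows that a high *Rho* alone (lineage sorting) does
not come with elevated AFD or fixed differences. Fractional counts are
means over the 2 × 2 between-group population pairs. Outlier calling at
the default 1% keeps the top two of 120 windows per metric:

```r
call_outliers(scan, "rho")
#> outlier_set [rho/rho]: 2 of 120 windows at quantile 0.99 (threshold 0.9673)
```

(The full-scale recovery test uses 500 windows, so the three sweeps fit
inside the 1% tail of both AFD and Rho; see `test-acceptance.R`.)

Topology weighting localises the introgression. Phasing, tree building
and weighting for a swept window and a background window:

```r
hms   <- phase_windows(ds$gm, windows = ds$windows[c(18, 60), ])
trees <- trees_for_windows(hms, pm_taxon_of_sample(ds$popmap))
prof  <- weighting_profile(trees, seed = 1)
prof$table[, c("window", "mode", "species", "introgression", "ils")]
#>   window  mode species introgression ils
#> 1   w018 exact       0             1   0
#> 2   w060 exact       1             0   0
```

The swept window puts its entire weight on introgression-class topologies
(tetraploids of the two species form a clade); the background window is
fully concordant with the species tree.

## Command line

```sh
exec/polyscan simulate --n-windows 120 --seed 42 --out simdir
exec/polyscan scan --vcf simdir/sim.vcf --popmap simdir/popmap.tsv \
    --windows simdir/genes.bed --contrast lyrata2x:lyrata4x --out scan.tsv
exec/polyscan outliers --scan scan.tsv --metrics afd,rho --out outliers.txt
exec/polyscan twisst --vcf simdir/sim.vcf --popmap simdir/popmap.tsv \
    --window-snps 50 --ci 0.05 --seed 1 --out weightings.tsv
```

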