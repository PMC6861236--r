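# shared fixtures, all built in code

write_toy_vcf <- function(path, lines) {
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=chr1,length=100000>",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">")
  writeLines(c(header, lines), path)
  path
}

# genotype matrix with two diploid populations, random dosages
random_gm <- function(n_site = 20, n_dip = 4, n_tet = 0, seed = 1,
                      miss_frac = 0) {
  set.seed(seed)
  samples <- c(paste0("d", seq_len(n_dip)),
               if (n_tet) paste0("t", seq_len(n_tet)))
  ploidy <- setNames(c(rep(2L, n_dip), rep(4L, n_tet)), samples)
  d <- vapply(ploidy, function(p)
    sample(0:p, n_site, replace = TRUE), integer(n_site))
  if (n_site == 1) d <- matrix(d, 1L, dimnames = list(NULL, samples))
  if (miss_frac > 0) d[runif(length(d)) < miss_frac] <- NA_integer_
  genotype_matrix(data.frame(chrom = "chr1", pos = seq_len(n_site) * 10L,
                             ref = "A", alt = "T"),
                  d, ploidy)
}

# a perfectly taxon-sorted genealogy: cherries of conspecifics
taxon_sorted_tree <- function(n_per = c(lyrata2x = 4, lyrata4x = 8,
                                        arenosa2x = 4, arenosa4x = 8,
                                        outgroup = 2)) {
  clade <- function(tips) paste0("(",
    paste(paste0(tips, ":1"), collapse = ","), ")")
  tips <- lapply(names(n_per), function(tx)
    paste0(substr(tx, 1, 2), which(names(n_per) == tx), "_",
           seq_len(n_per[[tx]])))
  names(tips) <- names(n_per)
  nwk <- sprintf("(((%s:1,%s:1):1,(%s:1,%s:1):1):1,%s:1);",
                 clade(tips$lyrata2x), clade(tips$lyrata4x),
                 clade(tips$arenosa2x), clade(tips$arenosa4x),
                 clade(tips$outgroup))
  tr <- ape::read.tree(text = nwk)
  taxa <- setNames(rep(names(n_per), lengths(tips)), unlist(tips))
  attr(tr, "taxa") <- taxa[tr$tip.label]
  tr
}

# random binary tree with given tips per taxon
random_taxon_tree <- function(n_per, seed) {
  set.seed(seed)
  n <- sum(n_per)
  tr <- ape::rtree(n)
  taxa <- setNames(sample(rep(names(n_per), n_per)), tr$tip.label)
  attr(tr, "taxa") <- taxa
  tr
}

# small simulation scenario used by several suites
small_scenario <- function(...) {
  demography_scenario(migration_rate = 0, n_segments = 1, seq_len = 250,
                      samples = c(lyrata2x = 3, lyrata4x = 3, arenosa2x = 3,
                                  arenosa4x = 3, outgroup = 1), ...)
}

scenario_ploidy <- function(sc) {
  ss <- scenario_samples(sc)
  setNames(ss$ploidy, ss$sample)
}

scenario_popmap <- function(sc) {
  ss <- scenario_samples(sc)
  population_map(ss$sample, ss$population, ss$taxon)
}

# weighting of a haplotype matrix (used by phasing-validation tests)
weights_of_hm <- function(hm, taxon_of_sample, seed = 5) {
  tr <- bionj_tree(hamming_pdist(hm))
  taxa <- setNames(taxon_of_sample[attr(hm, "sample")], rownames(hm))
  attr(tr, "taxa") <- taxa[tr$tip.label]
  topology_weighting(tr, seed = seed)$weights
}
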