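test_that("scenario construction validates its invariants", {
  expect_error(demography_scenario(split_gen = 50000), "wgd_lyrata_gen")
  expect_error(demography_scenario(migration_rate = -1), "migration_rate")
  sc <- small_scenario()
  expect_s3_class(sc, "demography_scenario")
  expect_error(simulate_genealogy(sc, introgression = list(
    recipient = "lyrata4x", donor = "arenosa4x", time = 90000, prob = 1)),
    "no longer exists")
})

test_that("pairwise coalescence time in one deme is about 2Ne", {
  sc <- demography_scenario(Ne = 5000, migration_rate = 0, bottleneck = NULL,
                            samples = c(lyrata2x = 2, lyrata4x = 0,
                                        arenosa2x = 0, arenosa4x = 0,
                                        outgroup = 0))
  set.seed(21)
  mean_t <- mean(replicate(600, {
    tr <- simulate_genealogy(sc)
    mean(cophenetic(tr)) / 2 * (16 / 12)   # over the 12 off-diagonal pairs
  }))
  # E[pairwise T] = 2Ne = 10000; MC tolerance ~ 4 SE
  expect_lt(abs(mean_t - 10000) / 10000, 0.12)
})

test_that("deep splits make species clades monophyletic in most windows", {
  sc <- small_scenario()
  tm <- pm_taxon_of_sample(scenario_popmap(sc))
  set.seed(4)
  mono <- replicate(30, {
    tr <- simulate_genealogy(sc)
    taxa <- attr(tr, "taxa")
    lyr <- names(taxa)[taxa %in% c("lyrata2x", "lyrata4x")]
    are <- names(taxa)[taxa %in% c("arenosa2x", "arenosa4x")]
    ape::is.monophyletic(tr, lyr) && ape::is.monophyletic(tr, are)
  })
  expect_gt(mean(mono), 0.9)
})

test_that("an introgression pulse nests recipients inside the donor clade", {
  sc <- small_scenario()
  set.seed(9)
  ok <- replicate(15, {
    tr <- simulate_genealogy(sc, introgression = list(
      recipient = "lyrata4x", donor = "arenosa4x", time = 5000, prob = 1))
    taxa <- attr(tr, "taxa")
    arena <- names(taxa)[taxa %in% c("arenosa2x", "arenosa4x", "lyrata4x")]
    ape::is.monophyletic(tr, arena)
  })
  expect_gt(mean(ok), 0.8)
})

test_that("drop_mutations obeys the infinite-sites expectations", {
  sc <- small_scenario()
  set.seed(2)
  tr <- simulate_genealogy(sc)
  expect_equal(ncol(drop_mutations(tr, 0, 100)$haps), 0L)
  # E[S | tree] = mu * L * total length (Watterson-style, conditioned)
  set.seed(3)
  S <- exp_S <- numeric(120)
  for (i in 1:120) {
    tr <- simulate_genealogy(sc)
    exp_S[i] <- sc$mu * sc$seq_len * sum(tr$edge.length)
    S[i] <- length(drop_mutations(tr, sc$mu, sc$seq_len)$pos)
  }
  expect_lt(abs(mean(S) - mean(exp_S)) / mean(exp_S), 0.05)
  # determinism under a fixed stream
  set.seed(7); a <- drop_mutations(tr, sc$mu, sc$seq_len)
  set.seed(7); b <- drop_mutations(tr, sc$mu, sc$seq_len)
  expect_identical(a, b)
  # positions are distinct, sorted, within range
  expect_false(any(duplicated(a$pos)))
  expect_true(all(diff(a$pos) > 0))
  expect_true(all(a$pos >= 1 & a$pos <= sc$seq_len))
})

test_that("collapse_to_genotypes sums slots and keeps phase truth", {
  haps <- rbind("x.1" = c(1L, 0L), "x.2" = c(0L, 0L),
                "t.1" = c(1L, 1L), "t.2" = c(1L, 0L),
                "t.3" = c(1L, 0L), "t.4" = c(0L, 0L))
  pl <- c(x = 2L, t = 4L)
  set.seed(1)
  cg <- collapse_to_genotypes(haps, c(5L, 9L), "chr1", pl)
  expect_equal(unname(cg$gm$dosage[, "x"]), c(1L, 0L))
  expect_equal(unname(cg$gm$dosage[, "t"]), c(3L, 1L))
  set.seed(1)
  cg_r <- collapse_to_genotypes(haps, c(5L, 9L), "chr1", pl,
                                randomise_phase = TRUE, seed = 4)
  expect_identical(cg_r$gm$dosage, cg$gm$dosage)   # dosage invariant
  expect_identical(attr(cg_r$truth_hm, "provenance"), "randomised")
})

test_that("spike_sweep raises AFD at the spiked windows in expectation", {
  ts <- list(windows = c(2L, 5L), target_group = "lyrata4x",
             target_freq = 1.0, background_group = "arenosa4x")
  # paired design: same genomes with and without the spike
  d_spiked <- d_plain <- numeric(0)
  for (seed in 31:32) {
    # per-population allele counts must be large enough that sampling noise
    # in p-hat does not drown the interspecific background signal
    sc <- demography_scenario(migration_rate = 0)
    ds0 <- generate_dataset(sc, n_windows = 8, seed = seed)
    ds <- generate_dataset(sc, n_windows = 8, sweep_spec = ts, seed = seed)
    if (seed == 31) {
      expect_equal(ds$truth$sweeps$label, c("w002", "w005"))
      expect_true(all(ds$truth$sweeps$shift > 0))
      # dosage bounds still hold (validated by the constructor on re-ingest)
      expect_s3_class(genotype_matrix(ds$gm$sites, ds$gm$dosage,
                                      ds$gm$ploidy), "genotype_matrix")
      # only sweep-window genotypes changed
      sw_idx <- unlist(lapply(ts$windows, function(i)
        window_sites(ds$gm, ds$windows[i, , drop = FALSE])))
      expect_identical(ds$gm$dosage[-sw_idx, ], ds0$gm$dosage[-sw_idx, ])
      expect_false(identical(ds$gm$dosage[sw_idx, ],
                             ds0$gm$dosage[sw_idx, ]))
    }
    tab <- scan_windows(ds$gm, ds$popmap, ds$windows, "lyrata2x", "lyrata4x")
    tab0 <- scan_windows(ds0$gm, ds0$popmap, ds0$windows, "lyrata2x",
                         "lyrata4x")
    sp <- tab$label %in% ds$truth$sweeps$label
    d_spiked <- c(d_spiked, tab$afd[sp])
    d_plain <- c(d_plain, tab0$afd[sp])
  }
  # spiking raises window AFD in expectation over replicates
  expect_gt(mean(d_spiked), mean(d_plain))
  expect_gt(mean(d_spiked > d_plain), 0.5)
})

test_that("generate_dataset is reproducible byte-for-byte and re-readable", {
  sc <- small_scenario()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  ds1 <- generate_dataset(sc, n_windows = 5, out_dir = d1, seed = 77)
  ds2 <- generate_dataset(sc, n_windows = 5, out_dir = d2, seed = 77)
  for (f in c("sim.vcf", "popmap.tsv", "genes.bed"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  gm <- read_vcf(file.path(d1, "sim.vcf"), max_missing_frac = 1, min_dp = 0)
  expect_identical(gm$dosage, ds1$gm$dosage[, gm$samples])
  expect_identical(gm$ploidy, ds1$gm$ploidy[gm$samples])
  pm <- read_popmap(file.path(d1, "popmap.tsv"))
  expect_s3_class(pm_validate(pm, gm), "population_map")
  # truth phase matches the emitted genotypes window by window
  w1 <- ds1$truth$phase_by_window[["w001"]]
  idx <- window_sites(ds1$gm, ds1$windows[1, , drop = FALSE])
  expect_identical(hm_dosage(w1), ds1$gm$dosage[idx, , drop = FALSE])
})

test_that("the default truth layout designates tracts and nested sweeps", {
  ts <- default_truth_spec(500)
  expect_equal(nrow(ts$introgression_spec), 5L)
  expect_true(all(ts$sweep_spec$windows %in% ts$introgression_spec$window))
  expect_setequal(unique(ts$introgression_spec$recipient),
                  c("lyrata4x", "arenosa4x"))
})
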