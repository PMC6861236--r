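#' Demographic scenario for the mixed-ploidy simulator
#'
#' Encodes the reference history the pipeline is validated against: a deep
#' species split, two whole-genome duplications of different ages (each
#' modelled demographically as the founding of a daughter deme; the lyrata
#' WGD with a founder bottleneck, the arenosa one without), continuous
#' low-level bidirectional gene flow between the coexisting tetraploid
#' demes, and an outgroup splitting before everything else. All times are
#' in generations; `Ne` is the diploid-equivalent deme size (expected
#' pairwise within-deme coalescence time 2*Ne generations); the migration
#' rate is in alleles per generation (backward per-lineage rate
#' `migration_rate / (2 Ne)` while both tetraploid demes exist).
#'
#' @param split_gen species split time (default 931000 generations).
#' @param wgd_lyrata_gen,wgd_arenosa_gen WGD (deme founding) times
#'   (defaults 81000 and 226000).
#' @param outgroup_split_gen outgroup divergence (default 2.5e6).
#' @param Ne scalar or per-deme named vector (default 50000).
#' @param bottleneck NULL or list(deme, start, end, Ne): reduced size on the
#'   backward time interval \[start, end). Default: a founder bottleneck in
#'   lyrata4x just after its WGD.
#' @param migration_rate tetraploid-tetraploid gene flow, each direction
#'   (default 0.1 alleles/generation).
#' @param mu per-bp per-generation mutation rate (default 3.7e-8).
#' @param seq_len simulated bp per window (default 500).
#' @param n_segments independently simulated genealogy segments per window
#'   (default 4): free recombination between segments, none within, so a
#'   gene-sized window aggregates several genealogies while the 50-SNP
#'   tree windows remain dominated by few genealogies.
#' @param samples individuals per taxon (named; outgroup is diploid).
#' @param pops_per_taxon populations each ingroup taxon is split into for
#'   the popmap (panmictic within taxon; default 2).
#' @return A `demography_scenario` list.
#' @export
demography_scenario <- function(split_gen = 931000,
                                wgd_lyrata_gen = 81000,
                                wgd_arenosa_gen = 226000,
                                outgroup_split_gen = 2.5e6,
                                Ne = 50000,
                                bottleneck = list(deme = "lyrata4x",
                                                  start = 76000,
                                                  end = 81000,
                                                  Ne = 12500),
                                migration_rate = 0.1,
                                mu = 3.7e-8,
                                seq_len = 500,
                                n_segments = 4,
                                samples = c(lyrata2x = 8, lyrata4x = 6,
                                            arenosa2x = 4, arenosa4x = 6,
                                            outgroup = 2),
                                pops_per_taxon = 2) {
  stopifnot(wgd_lyrata_gen < split_gen, wgd_arenosa_gen < split_gen,
            split_gen < outgroup_split_gen,
            migration_rate >= 0, mu >= 0, seq_len >= 1,
            n_segments >= 1, seq_len %% n_segments == 0)
  ne <- if (length(Ne) == 1L) setNames(rep(Ne, 5), TAXA) else Ne[TAXA]
  stopifnot(all(ne > 0), !anyNA(ne))
  structure(list(split_gen = split_gen, wgd_lyrata_gen = wgd_lyrata_gen,
                 wgd_arenosa_gen = wgd_arenosa_gen,
                 outgroup_split_gen = outgroup_split_gen, Ne = ne,
                 bottleneck = bottleneck, migration_rate = migration_rate,
                 mu = mu, seq_len = seq_len, n_segments = n_segments,
                 samples = samples, pops_per_taxon = pops_per_taxon),
            class = "demography_scenario")
}

#' Sample sheet implied by a scenario
#' @param scenario a [demography_scenario()].
#' @return data.frame: sample, population, taxon, ploidy.
#' @export
scenario_samples <- function(scenario) {
  pop_code <- c(lyrata2x = "LD", lyrata4x = "LT", arenosa2x = "AD",
                arenosa4x = "AT", outgroup = "OU")
  rows <- lapply(TAXA, function(tx) {
    n <- scenario$samples[[tx]]
    if (is.null(n) || n == 0) return(NULL)
    k <- if (tx == "outgroup") 1L else scenario$pops_per_taxon
    pops <- paste0(pop_code[[tx]], LETTERS[seq_len(k)])
    pop_of <- rep_len(pops, n)
    data.frame(sample = paste0(pop_of, ave(seq_len(n), pop_of,
                                           FUN = seq_along)),
               population = pop_of, taxon = tx,
               ploidy = if (tx %in% c("lyrata4x", "arenosa4x")) 4L else 2L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate one window genealogy under the structured coalescent
#'
#' Backward-in-time simulation with per-deme piecewise-constant sizes,
#' deme mergers at the WGD and split times, continuous tetraploid-tetraploid
#' migration while both tetraploid demes exist, and an optional single-window
#' introgression pulse: at `time`, each lineage of the recipient taxon moves
#' into the donor deme with probability `prob` (forward in time this is a
#' localized transfer of donor haplotypes into the recipient). Tetraploids
#' contribute four exchangeable lineages per individual (tetrasomic
#' inheritance). Uses the session RNG stream; seed externally.
#'
#' @param scenario a [demography_scenario()].
#' @param introgression NULL or list(recipient, donor, time, prob).
#' @return An ultrametric `phylo` (branch lengths in generations) with tip
#'   labels `sample.slot` and a `taxa` attribute.
#' @export
simulate_genealogy <- function(scenario, introgression = NULL) {
  ss <- scenario_samples(scenario)
  tips <- unlist(lapply(seq_len(nrow(ss)), function(i)
    paste(ss$sample[i], seq_len(ss$ploidy[i]), sep = ".")))
  tip_taxon <- rep(ss$taxon, ss$ploidy)
  n <- length(tips)

  if (!is.null(introgression)) {
    stopifnot(all(c("recipient", "donor", "time", "prob") %in%
                  names(introgression)))
    alive_until <- c(lyrata2x = Inf, arenosa2x = scenario$split_gen,
                     lyrata4x = scenario$wgd_lyrata_gen,
                     arenosa4x = scenario$wgd_arenosa_gen, outgroup =
                       scenario$outgroup_split_gen)
    for (d in c(introgression$recipient, introgression$donor))
      if (introgression$time >= alive_until[[d]])
        stop("introgression pulse at ", introgression$time,
             " into a deme that no longer exists: ", d)
  }

  ne_of <- function(deme, t) {
    b <- scenario$bottleneck
    if (!is.null(b) && deme == b$deme && t >= b$start && t < b$end)
      return(b$Ne)
    scenario$Ne[[deme]]
  }

  boundaries <- sort(unique(c(
    if (!is.null(introgression)) introgression$time,
    if (!is.null(scenario$bottleneck))
      c(scenario$bottleneck$start, scenario$bottleneck$end),
    scenario$wgd_lyrata_gen, scenario$wgd_arenosa_gen,
    scenario$split_gen, scenario$outgroup_split_gen)))

  deme <- tip_taxon
  node <- as.list(seq_len(n))         # newick fragments under construction
  height <- rep(0, n)                 # time of each lineage's head node
  frag <- as.list(tips)
  t <- 0
  mig_on <- function(t) scenario$migration_rate > 0 &&
    t < scenario$wgd_lyrata_gen && t < scenario$wgd_arenosa_gen

  apply_boundary <- function(tb) {
    if (!is.null(introgression) && tb == introgression$time) {
      rec <- which(deme == introgression$recipient)
      mv <- rec[runif(length(rec)) < introgression$prob]
      deme[mv] <<- introgression$donor
    }
    if (tb == scenario$wgd_lyrata_gen)
      deme[deme == "lyrata4x"] <<- "lyrata2x"
    if (tb == scenario$wgd_arenosa_gen)
      deme[deme == "arenosa4x"] <<- "arenosa2x"
    if (tb == scenario$split_gen)
      deme[deme == "arenosa2x"] <<- "lyrata2x"
    if (tb == scenario$outgroup_split_gen)
      deme[deme == "outgroup"] <<- "lyrata2x"
  }

  while (length(frag) > 1) {
    demes_now <- unique(deme)
    k <- table(factor(deme, levels = demes_now))
    coal_rate <- vapply(demes_now, function(d)
      k[[d]] * (k[[d]] - 1) / 2 / (2 * ne_of(d, t)), numeric(1))
    mig_rate <- if (mig_on(t)) {
      vapply(demes_now, function(d)
        if (d %in% c("lyrata4x", "arenosa4x"))
          k[[d]] * scenario$migration_rate / (2 * ne_of(d, t)) else 0,
        numeric(1))
    } else rep(0, length(demes_now))
    R <- sum(coal_rate) + sum(mig_rate)
    tb <- boundaries[boundaries > t][1]
    if (is.na(tb)) tb <- Inf
    dt <- if (R > 0) rexp(1, R) else Inf
    if (t + dt >= tb) {
      t <- tb
      apply_boundary(tb)
      next
    }
    t <- t + dt
    ev <- sample(length(demes_now) * 2, 1,
                 prob = c(coal_rate, mig_rate))
    if (ev <= length(demes_now)) {
      d <- demes_now[ev]
      in_d <- which(deme == d)
      pair <- if (length(in_d) == 2) in_d else sample(in_d, 2)
      i <- pair[1]; j <- pair[2]
      bl_i <- t - height[i]; bl_j <- t - height[j]
      frag[[i]] <- sprintf("(%s:%.8g,%s:%.8g)", frag[[i]], bl_i,
                           frag[[j]], bl_j)
      height[i] <- t
      frag <- frag[-j]; height <- height[-j]; deme <- deme[-j]
    } else {
      d <- demes_now[ev - length(demes_now)]
      in_d <- which(deme == d)
      mvr <- if (length(in_d) == 1) in_d else sample(in_d, 1)
      deme[mvr] <- if (d == "lyrata4x") "arenosa4x" else "lyrata4x"
    }
  }
  tr <- ape::read.tree(text = paste0(frag[[1]], ";"))
  attr(tr, "taxa") <- setNames(tip_taxon, tips)[tr$tip.label]
  tr
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Poisson(`mu * branch length`) mutations per branch per bp; each mutation
#' creates one new biallelic site (no back-mutation) whose derived allele is
#' carried by all tips below the branch. Site positions are distinct
#' integers in `1..seq_len`; if more mutations arise than positions exist,
#' the excess is dropped with a warning. Uses the session RNG stream.
#'
#' @param genealogy `phylo` with branch lengths in generations.
#' @param mu per-bp per-generation mutation rate.
#' @param seq_len window length in bp.
#' @return List: `haps` (0/1 matrix, tips x sites, sorted by position),
#'   `pos` (integer positions).
#' @export
drop_mutations <- function(genealogy, mu, seq_len) {
  tr <- genealogy
  n <- length(tr$tip.label)
  n_mut <- rpois(nrow(tr$edge), mu * seq_len * tr$edge.length)
  S <- sum(n_mut)
  if (S == 0L)
    return(list(haps = matrix(0L, n, 0, dimnames = list(tr$tip.label, NULL)),
                pos = integer(0)))
  if (S > seq_len) {
    warning("more mutations (", S, ") than positions (", seq_len,
            "); excess dropped")
    keep <- sort(sample.int(S, seq_len))
  } else keep <- seq_len(S)
  edge_of_mut <- rep(seq_len(nrow(tr$edge)), n_mut)[keep]
  S <- length(edge_of_mut)
  po <- ape::reorder.phylo(tr, "postorder")
  below <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) below[[i]] <- i
  for (e in seq_len(nrow(po$edge)))
    below[[po$edge[e, 1]]] <- c(below[[po$edge[e, 1]]],
                                below[[po$edge[e, 2]]])
  haps <- matrix(0L, n, S, dimnames = list(tr$tip.label, NULL))
  for (s in seq_len(S)) {
    child <- tr$edge[edge_of_mut[s], 2]
    haps[below[[child]], s] <- 1L
  }
  pos <- sort(sample.int(seq_len, S))
  ord <- sample.int(S)                 # mutations assigned to positions
  haps <- haps[, ord, drop = FALSE]
  list(haps = haps, pos = pos)
}

#' Collapse haplotypes to unphased genotypes, keeping phase truth
#'
#' @param haps 0/1 matrix, rows labelled `sample.slot`.
#' @param pos integer site positions.
#' @param chrom chromosome name for the site table.
#' @param ploidy_map named ploidy vector per sample.
#' @param randomise_phase if TRUE, slot order is shuffled per sample and
#'   site before recording the "true" haplotypes (dosages unchanged).
#' @param seed seed used only when `randomise_phase` is TRUE.
#' @return List: `gm` (a [genotype_matrix()] with random REF/ALT alleles),
#'   `truth_hm` (a [haplotype_matrix()], provenance `"true"`).
#' @export
collapse_to_genotypes <- function(haps, pos, chrom = "chr1", ploidy_map,
                                  randomise_phase = FALSE, seed = 1) {
  samp <- sub("\\.[0-9]+$", "", rownames(haps))
  samples <- unique(samp)
  ord <- order(match(samp, samples),
               as.integer(sub("^.*\\.", "", rownames(haps))))
  haps <- haps[ord, , drop = FALSE]
  samp <- samp[ord]
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, length(pos), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
  hm <- haplotype_matrix(haps, samp, ploidy_map[samples],
                         sites = data.frame(chrom = chrom, pos = pos,
                                            ref = ref, alt = alt,
                                            stringsAsFactors = FALSE),
                         provenance = "true")
  if (randomise_phase) hm <- phase_randomise(hm, seed)$hm
  gm <- genotype_matrix(attr(hm, "sites"), hm_dosage(hm),
                        attr(hm, "ploidy"))
  list(gm = gm, truth_hm = hm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Impose a selective-sweep signal on designated windows
#'
#' Within each sweep window, the dosages of the target group are resampled
#' towards a designated background haplotype: per site, the background
#' allele is drawn as a random gamete of one randomly chosen carrier
#' individual from `background_group` (allele probability dosage/ploidy),
#' and each target individual's new dosage is
#' Binomial(ploidy, f*b + (1-f)*p) where `f = target_freq`, `b` the
#' background allele and `p` the target group's original frequency. Other
#' groups are untouched; missing genotypes stay missing. Emulates the tight
#' single-locus peaks of differentiation that sweeps leave in a scan; with
#' `background_group` set to the sister species' tetraploid, it emulates a
#' sweep on an introgressed haplotype.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap a [population_map()].
#' @param windows window data.frame rows designating the sweep windows.
#' @param target_group taxon or population codes whose genotypes are swept.
#' @param target_freq sweep frequency f in (0, 1\].
#' @param background_group source of the background haplotype (default the
#'   target group itself: a sweep on standing variation).
#' @param background_haplotypes optional named list (window label -> 0/1
#'   vector over the window's sites) giving the exact sweeping haplotype,
#'   e.g. a true simulated haplotype; overrides the gamete draw.
#' @param seed integer seed.
#' @return List: `gm` (modified), `truth` (data.frame: label, target,
#'   achieved mean absolute frequency shift).
#' @export
spike_sweep <- function(gm, popmap, windows, target_group,
                        target_freq = 0.95, background_group = target_group,
                        background_haplotypes = NULL, seed = 1) {
  stopifnot(target_freq > 0, target_freq <= 1)
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(seed)
  tgt <- intersect(gm$samples, pm_samples(popmap, target_group))
  bgs <- intersect(gm$samples, pm_samples(popmap, background_group))
  stopifnot(length(tgt) >= 1, length(bgs) >= 1)
  truth <- NULL
  for (i in seq_len(nrow(windows))) {
    idx <- window_sites(gm, windows[i, , drop = FALSE])
    if (!length(idx)) {
      message("sweep window ", windows$label[i], " has no SNPs; skipped")
      next
    }
    b <- background_haplotypes[[windows$label[i]]]
    if (is.null(b)) {
      # background = one random gamete of a random carrier: per site, draw
      # the allele from the carrier's dosage (linkage within the carrier is
      # not representable from dosages alone)
      bg_sample <- sample(bgs, 1)
      bd <- gm$dosage[idx, bg_sample]
      pb <- ifelse(is.na(bd), 0, bd / gm$ploidy[[bg_sample]])
      b <- rbinom(length(idx), 1L, pb)
    }
    stopifnot(length(b) == length(idx))
    tgt_d <- gm$dosage[idx, tgt, drop = FALSE]
    called_al <- (!is.na(tgt_d)) %*% gm$ploidy[tgt]
    p_old <- ifelse(called_al > 0,
                    rowSums(tgt_d, na.rm = TRUE) / called_al, 0)
    p_eff <- target_freq * b + (1 - target_freq) * p_old
    for (s in tgt) {
      keep_na <- is.na(gm$dosage[idx, s])
      newd <- rbinom(length(idx), gm$ploidy[[s]], p_eff)
      newd[keep_na] <- NA_integer_
      gm$dosage[idx, s] <- newd
    }
    tgt_d2 <- gm$dosage[idx, tgt, drop = FALSE]
    called2 <- (!is.na(tgt_d2)) %*% gm$ploidy[tgt]
    p_new <- ifelse(called2 > 0, rowSums(tgt_d2, na.rm = TRUE) / called2, 0)
    truth <- rbind(truth, data.frame(
      label = windows$label[i],
      target = paste(target_group, collapse = "+"),
      shift = mean(abs(p_new - p_old)), stringsAsFactors = FALSE))
  }
  list(gm = gm, truth = truth)
}

#' Generate a full synthetic mixed-ploidy dataset with ground truth
#'
#' Simulates `n_windows` independent window genealogies under `scenario`
#' (no recombination within a window), applies introgression pulses and
#' sweep spikes at the designated windows, and assembles a genome-like
#' dataset: genotype matrix, popmap, gene windows (one per simulated
#' window), true phase, and truth tables. Optionally writes VCF, popmap
#' TSV and BED files. Fully reproducible from `seed`.
#'
#' @param scenario a [demography_scenario()].
#' @param n_windows number of windows (default 500).
#' @param sweep_spec NULL or list(windows = indices, target_group,
#'   target_freq, background_group).
#' @param introgression_spec NULL or data.frame(window, recipient, donor,
#'   time, prob).
#' @param out_dir NULL or output directory (created if needed).
#' @param seed integer seed driving every random choice.
#' @param randomise_phase passed to [collapse_to_genotypes()].
#' @return List: `gm`, `popmap`, `windows` (gene-window table), `truth`
#'   (list: `phase_by_window` of true [haplotype_matrix()]s, `sweeps`,
#'   `introgression`), `scenario`, `seed`, and file `paths` when written.
#' @export
generate_dataset <- function(scenario = demography_scenario(),
                             n_windows = 500,
                             sweep_spec = NULL, introgression_spec = NULL,
                             out_dir = NULL, seed = 1,
                             randomise_phase = FALSE) {
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(seed)
  ss <- scenario_samples(scenario)
  ploidy_map <- setNames(ss$ploidy, ss$sample)
  pm <- population_map(ss$sample, ss$population, ss$taxon)
  L <- scenario$seq_len
  starts <- (seq_len(n_windows) - 1L) * (2L * L) + 1L
  labels <- sprintf("w%03d", seq_len(n_windows))
  intro_of <- if (!is.null(introgression_spec))
    split(introgression_spec, introgression_spec$window) else list()

  nseg <- scenario$n_segments %||% 1L
  seg_len <- L %/% nseg
  ss0 <- scenario_samples(scenario)
  tip_order <- unlist(lapply(seq_len(nrow(ss0)), function(i)
    paste(ss0$sample[i], seq_len(ss0$ploidy[i]), sep = ".")))
  hap_list <- vector("list", n_windows)
  pos_list <- vector("list", n_windows)
  for (i in seq_len(n_windows)) {
    spec <- intro_of[[as.character(i)]]
    intro <- if (!is.null(spec))
      list(recipient = spec$recipient[1], donor = spec$donor[1],
           time = spec$time[1], prob = spec$prob[1]) else NULL
    segs <- lapply(seq_len(nseg), function(j) {
      tr <- simulate_genealogy(scenario, introgression = intro)
      mt <- drop_mutations(tr, scenario$mu, seg_len)
      list(h = mt$haps[tip_order, , drop = FALSE],
           p = mt$pos + (j - 1L) * seg_len)
    })
    hap_list[[i]] <- do.call(cbind, lapply(segs, `[[`, "h"))
    pos_list[[i]] <- unlist(lapply(segs, `[[`, "p")) + starts[i] - 1L
  }
  haps <- do.call(cbind, hap_list)
  pos <- unlist(pos_list)
  cg <- collapse_to_genotypes(haps, pos, "chr1", ploidy_map,
                              randomise_phase = randomise_phase,
                              seed = seed)
  gm <- cg$gm
  windows <- window_frame("chr1", starts, starts + L - 1L, "gene", labels)

  phase_by_window <- setNames(lapply(seq_len(n_windows), function(i) {
    idx <- which(cg$gm$sites$pos >= windows$start[i] &
                 cg$gm$sites$pos <= windows$end[i])
    hm_window(cg$truth_hm, idx)
  }), labels)

  truth_sweeps <- NULL
  if (!is.null(sweep_spec)) {
    # the sweeping background is a true haplotype of a random target-group
    # slot (for pulsed windows, an actually introgressed haplotype)
    tgt_rows <- which(attr(cg$truth_hm, "sample") %in%
                      pm_samples(pm, sweep_spec$target_group))
    bg_rows <- which(attr(cg$truth_hm, "sample") %in%
                     pm_samples(pm, sweep_spec$background_group %||%
                                sweep_spec$target_group))
    # candidate sweeping haplotypes: target-group slots (introgressed copies
    # in pulsed windows) and background-group slots; take the one closest to
    # the background consensus, i.e. a genuine donor-lineage haplotype
    cand_rows <- union(tgt_rows, bg_rows)
    bh <- setNames(lapply(sweep_spec$windows, function(i) {
      hw <- unclass(phase_by_window[[labels[i]]])
      cons <- colMeans(hw[bg_rows, , drop = FALSE]) > 0.5
      score <- rowMeans(hw[cand_rows, , drop = FALSE] == rep(cons,
                        each = length(cand_rows)))
      hw[cand_rows[which.max(score)], ]
    }), labels[sweep_spec$windows])
    sw <- spike_sweep(gm, pm, windows[sweep_spec$windows, , drop = FALSE],
                      target_group = sweep_spec$target_group,
                      target_freq = sweep_spec$target_freq %||% 0.95,
                      background_group = sweep_spec$background_group %||%
                        sweep_spec$target_group,
                      background_haplotypes = bh,
                      seed = seed + 1L)
    gm <- sw$gm
    truth_sweeps <- sw$truth
  }
  truth_intro <- if (!is.null(introgression_spec))
    data.frame(label = labels[introgression_spec$window],
               introgression_spec, stringsAsFactors = FALSE) else NULL

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(vcf = file.path(out_dir, "sim.vcf"),
                  popmap = file.path(out_dir, "popmap.tsv"),
                  genes = file.path(out_dir, "genes.bed"),
                  sweeps = file.path(out_dir, "truth_sweeps.bed"),
                  introgression = file.path(out_dir,
                                            "truth_introgression.bed"))
    write_vcf(gm, paths$vcf)
    write_popmap(pm, paths$popmap)
    write_bed(windows, paths$genes)
    if (!is.null(truth_sweeps))
      write_bed(windows[windows$label %in% truth_sweeps$label, ],
                paths$sweeps)
    if (!is.null(truth_intro))
      write_bed(windows[windows$label %in% truth_intro$label, ],
                paths$introgression)
  }
  list(gm = gm, popmap = pm, windows = windows,
       truth = list(phase_by_window = phase_by_window,
                    sweeps = truth_sweeps, introgression = truth_intro),
       scenario = scenario, seed = seed, paths = paths)
}

# window slice of a haplotype matrix by site indices
hm_window <- function(hm, idx) {
  haplotype_matrix(unclass(hm)[, idx, drop = FALSE], attr(hm, "sample"),
                   attr(hm, "ploidy"),
                   sites = attr(hm, "sites")[idx, , drop = FALSE],
                   provenance = attr(hm, "provenance"))
}

#' Default sweep and introgression designations for a scenario
#'
#' Places five introgression windows evenly along the genome (three with
#' the lyrata tetraploids as recipients of arenosa tetraploid haplotypes,
#' two in the opposite direction) and sweeps the three lyrata-recipient
#' windows towards an arenosa background haplotype -- the coupled
#' introgression-then-selection signal the scan/weighting overlap is meant
#' to detect.
#'
#' @param n_windows total window count.
#' @param pulse_time,pulse_prob pulse parameters (defaults 5000 gen, 0.95).
#' @param target_freq sweep frequency (default 0.95).
#' @return List with `sweep_spec` and `introgression_spec` ready for
#'   [generate_dataset()].
#' @export
default_truth_spec <- function(n_windows = 500, pulse_time = 5000,
                               pulse_prob = 0.95, target_freq = 1.0) {
  at <- unique(pmax(1L, round(n_windows * c(0.15, 0.35, 0.55, 0.75, 0.9))))
  stopifnot(length(at) == 5)
  introgression_spec <- data.frame(
    window = at,
    recipient = c("lyrata4x", "lyrata4x", "lyrata4x",
                  "arenosa4x", "arenosa4x"),
    donor = c("arenosa4x", "arenosa4x", "arenosa4x",
              "lyrata4x", "lyrata4x"),
    time = pulse_time, prob = pulse_prob, stringsAsFactors = FALSE)
  list(sweep_spec = list(windows = at[1:3], target_group = "lyrata4x",
                         target_freq = target_freq,
                         background_group = "arenosa4x"),
       introgression_spec = introgression_spec)
}
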