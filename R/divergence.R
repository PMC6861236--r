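#' Per-site allele frequencies by population
#'
#' Computes, for each requested population, the ALT allele frequency over
#' called alleles (a tetraploid `0/1/1/1` contributes 3 ALT of 4 alleles)
#' together with the called allele count, and per-individual allele
#' frequencies `x = dosage / ploidy`, the ploidy-independent unit on which
#' the Rho statistic operates.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap a [population_map()] covering all samples of `gm`.
#' @param populations population codes to tabulate (default: all).
#' @return A `site_freq_table`: list with matrices `p` and `n_alleles`
#'   (sites x populations), `n_ind` (called individuals), the individual
#'   frequency matrix `x`, and bookkeeping fields.
#' @export
site_freqs <- function(gm, popmap, populations = NULL) {
  popmap <- pm_validate(popmap, gm)
  if (is.null(populations)) populations <- unique(popmap$population)
  pop_of <- setNames(popmap$population, popmap$sample)[gm$samples]
  x <- sweep(gm$dosage, 2, gm$ploidy, "/")
  p <- n_al <- n_ind <- matrix(NA_real_, nrow(gm$sites), length(populations),
                               dimnames = list(NULL, populations))
  for (pop in populations) {
    j <- which(pop_of == pop)
    if (!length(j)) stop("population has no samples: ", pop)
    d <- gm$dosage[, j, drop = FALSE]
    called <- !is.na(d)
    al <- called %*% gm$ploidy[j]
    n_al[, pop] <- al
    n_ind[, pop] <- rowSums(called)
    alt <- rowSums(d, na.rm = TRUE)
    p[, pop] <- ifelse(al > 0, alt / al, NA_real_)
  }
  structure(list(p = p, n_alleles = n_al, n_ind = n_ind, x = x,
                 pop_of = pop_of, ploidy = gm$ploidy, sites = gm$sites),
            class = "site_freq_table")
}

#' Pairwise window divergence metrics
#'
#' For one window and one pair of populations computes: AFD (mean absolute
#' allele frequency difference), dXY (mean of `pA(1-pB) + pB(1-pA)` over
#' SNPs -- note per-SNP, not per-bp), Hudson-type ratio-of-sums Fst
#' (`1 - sum(Hw)/sum(Hb)` with unbiased within-population expected
#' heterozygosity `2p(1-p) n/(n-1)`), the Rho intraclass correlation on
#' individual allele frequencies (one-way ANOVA ratio of sums across SNPs,
#' ploidy-independent by construction) and the number of fixed differences.
#'
#' SNPs where either population has fewer than 2 called alleles are excluded
#' from the Fst sums, and SNPs without at least one called individual in each
#' population plus one spare degree of freedom are excluded from the Rho
#' sums; AFD, dXY and fixed differences use every SNP at which both
#' populations have at least one called allele.
#'
#' @param freqs a `site_freq_table` from [site_freqs()].
#' @param window one-row window data.frame (or NULL for all sites).
#' @param popA,popB population codes present in `freqs`.
#' @return One-row data.frame: popA, popB, n_snps, afd, dxy, fst, rho,
#'   fixed_diff. All metric fields are NaN when the window has no
#'   informative SNP. Negative Fst/Rho are reported as computed.
#' @export
pair_metrics <- function(freqs, window = NULL, popA, popB) {
  idx <- if (is.null(window)) seq_len(nrow(freqs$sites)) else {
    gm_like <- list(sites = freqs$sites)
    window_sites(gm_like, window)
  }
  pA <- freqs$p[idx, popA]; pB <- freqs$p[idx, popB]
  nA <- freqs$n_alleles[idx, popA]; nB <- freqs$n_alleles[idx, popB]
  inf <- !is.na(pA) & !is.na(pB)
  n_snps <- sum(inf)
  if (n_snps == 0L)
    return(data.frame(popA = popA, popB = popB, n_snps = 0L, afd = NaN,
                      dxy = NaN, fst = NaN, rho = NaN, fixed_diff = NaN))
  afd <- mean(abs(pA[inf] - pB[inf]))
  hb <- pA * (1 - pB) + pB * (1 - pA)
  dxy <- mean(hb[inf])
  fixed <- sum((pA[inf] == 1 & pB[inf] == 0) | (pA[inf] == 0 & pB[inf] == 1))

  ok_fst <- inf & nA >= 2 & nB >= 2
  if (any(ok_fst)) {
    hw <- (2 * pA * (1 - pA) * nA / (nA - 1) +
           2 * pB * (1 - pB) * nB / (nB - 1)) / 2
    denom <- sum(hb[ok_fst])
    fst <- if (denom > 0) 1 - sum(hw[ok_fst]) / denom else NaN
  } else fst <- NaN

  rho <- rho_ratio_of_sums(freqs, idx, popA, popB)

  data.frame(popA = popA, popB = popB, n_snps = n_snps, afd = afd, dxy = dxy,
             fst = fst, rho = rho, fixed_diff = fixed)
}

# One-way ANOVA intraclass correlation on x = dosage/ploidy, accumulated as
# a ratio of sums over the window's SNPs (n0 is the standard unequal-n
# coefficient). Vectorised over sites.
rho_ratio_of_sums <- function(freqs, idx, popA, popB) {
  jA <- which(freqs$pop_of == popA)
  jB <- which(freqs$pop_of == popB)
  xA <- freqs$x[idx, jA, drop = FALSE]
  xB <- freqs$x[idx, jB, drop = FALSE]
  nA <- rowSums(!is.na(xA)); nB <- rowSums(!is.na(xB))
  N <- nA + nB
  ok <- nA >= 1 & nB >= 1 & (N - 2) >= 1
  if (!any(ok)) return(NaN)
  mA <- rowSums(xA, na.rm = TRUE) / nA
  mB <- rowSums(xB, na.rm = TRUE) / nB
  gm_mean <- (nA * mA + nB * mB) / N
  ssb <- nA * (mA - gm_mean)^2 + nB * (mB - gm_mean)^2
  ssw <- rowSums((xA - mA)^2, na.rm = TRUE) + rowSums((xB - mB)^2, na.rm = TRUE)
  msb <- ssb / (2 - 1)
  msw <- ssw / (N - 2)
  n0 <- (N - (nA^2 + nB^2) / N) / (2 - 1)
  num <- msb - msw
  den <- msb + (n0 - 1) * msw
  s_den <- sum(den[ok])
  if (s_den <= 0) NaN else sum(num[ok]) / s_den
}

#' Group-averaged window divergence metrics
#'
#' The unweighted mean of [pair_metrics()] over all between-group population
#' pairs; pairs with zero informative SNPs in the window are excluded from
#' the mean. Reduces to [pair_metrics()] when each group holds one
#' population.
#'
#' @param freqs a `site_freq_table`.
#' @param window one-row window data.frame or NULL.
#' @param groupA_pops,groupB_pops character vectors of population codes.
#' @return One-row data.frame with the same metric fields; `n_snps` is the
#'   mean informative SNP count over contributing pairs.
#' @export
group_metrics <- function(freqs, window = NULL, groupA_pops, groupB_pops) {
  stopifnot(length(groupA_pops) >= 1, length(groupB_pops) >= 1)
  pairs <- expand.grid(a = groupA_pops, b = groupB_pops,
                       stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    pair_metrics(freqs, window, pairs$a[i], pairs$b[i])))
  use <- rows$n_snps > 0
  if (!any(use)) {
    message("window with zero informative SNPs in every population pair")
    return(data.frame(n_snps = 0, afd = NaN, dxy = NaN, fst = NaN,
                      rho = NaN, fixed_diff = NaN))
  }
  rows <- rows[use, , drop = FALSE]
  data.frame(n_snps = mean(rows$n_snps),
             afd = mean(rows$afd), dxy = mean(rows$dxy),
             fst = mean(rows$fst), rho = mean(rows$rho),
             fixed_diff = mean(rows$fixed_diff))
}

#' Windowed divergence scan between two population groups
#'
#' @param gm a [genotype_matrix()].
#' @param popmap a [population_map()].
#' @param windows window data.frame (from [gene_windows()], [snp_windows()]
#'   or [read_bed()]).
#' @param groupA,groupB taxon labels or character vectors of population
#'   codes; taxon labels expand via the popmap.
#' @return Scan table: one row per window (chrom, start, end, label,
#'   n_snps, afd, dxy, fst, rho, fixed_diff), in window order.
#' @export
scan_windows <- function(gm, popmap, windows, groupA, groupB) {
  popsA <- pm_populations(popmap, groupA)
  popsB <- pm_populations(popmap, groupB)
  freqs <- site_freqs(gm, popmap, unique(c(popsA, popsB)))
  if (nrow(windows) == 0L) {
    warning("empty window set; empty scan table")
    return(cbind(windows[, c("chrom", "start", "end", "label")],
                 n_snps = numeric(0), afd = numeric(0), dxy = numeric(0),
                 fst = numeric(0), rho = numeric(0), fixed_diff = numeric(0)))
  }
  rows <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i)
    group_metrics(freqs, windows[i, , drop = FALSE], popsA, popsB)))
  out <- cbind(windows[, c("chrom", "start", "end", "label")], rows)
  rownames(out) <- NULL
  out
}

#' Write a scan table as TSV
#' @param scan_table output of [scan_windows()].
#' @param path output path.
#' @export
write_scan <- function(scan_table, path) {
  write.table(scan_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
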