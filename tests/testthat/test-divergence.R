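# straightforward per-formula oracle, written independently of the package
# implementation: explicit loops, no ratio-of-sums shortcuts shared
oracle_metrics <- function(gm, samplesA, samplesB) {
  nS <- nrow(gm$sites)
  afd <- dxy <- hw_sum <- hb_sum <- num_sum <- den_sum <- 0
  n_afd <- fixed <- 0
  for (s in seq_len(nS)) {
    freq <- function(ss) {
      d <- gm$dosage[s, ss]; pl <- gm$ploidy[ss]
      ok <- !is.na(d)
      if (!any(ok)) return(c(NA, 0))
      c(sum(d[ok]) / sum(pl[ok]), sum(pl[ok]))
    }
    fa <- freq(samplesA); fb <- freq(samplesB)
    pA <- fa[1]; nA <- fa[2]; pB <- fb[1]; nB <- fb[2]
    if (is.na(pA) || is.na(pB)) next
    n_afd <- n_afd + 1
    afd <- afd + abs(pA - pB)
    dxy <- dxy + pA * (1 - pB) + pB * (1 - pA)
    if ((pA == 1 && pB == 0) || (pA == 0 && pB == 1)) fixed <- fixed + 1
    if (nA >= 2 && nB >= 2) {
      hw_sum <- hw_sum + (2 * pA * (1 - pA) * nA / (nA - 1) +
                          2 * pB * (1 - pB) * nB / (nB - 1)) / 2
      hb_sum <- hb_sum + pA * (1 - pB) + pB * (1 - pA)
    }
    # one-way ANOVA on individual frequencies
    xa <- gm$dosage[s, samplesA] / gm$ploidy[samplesA]
    xb <- gm$dosage[s, samplesB] / gm$ploidy[samplesB]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    na <- length(xa); nb <- length(xb); N <- na + nb
    if (na >= 1 && nb >= 1 && N - 2 >= 1) {
      gmn <- mean(c(xa, xb))
      msb <- (na * (mean(xa) - gmn)^2 + nb * (mean(xb) - gmn)^2) / 1
      msw <- (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) / (N - 2)
      n0 <- (N - (na^2 + nb^2) / N) / 1
      num_sum <- num_sum + (msb - msw)
      den_sum <- den_sum + (msb + (n0 - 1) * msw)
    }
  }
  list(afd = afd / n_afd, dxy = dxy / n_afd, fst = 1 - hw_sum / hb_sum,
       rho = num_sum / den_sum, fixed = fixed, n = n_afd)
}

two_pop_map <- function(gm, nA) {
  population_map(gm$samples,
                 rep(c("PA", "PB"), c(nA, length(gm$samples) - nA)),
                 rep("lyrata2x", length(gm$samples)))
}

test_that("site_freqs respects per-sample ploidy", {
  pl <- c(a = 2L, b = 2L, t = 4L, u = 4L)
  d <- rbind(c(1L, 1L, 3L, 1L),
             c(2L, NA, 1L, 0L))
  gm <- genotype_matrix(data.frame(chrom = "c", pos = c(1L, 2L), ref = "A",
                                   alt = "T"), d, pl)
  pm <- population_map(names(pl), c("P1", "P1", "P2", "P3"),
                       c("lyrata2x", "lyrata2x", "lyrata4x", "lyrata4x"))
  fr <- site_freqs(gm, pm)
  expect_equal(unname(fr$p[1, "P1"]), 0.5)  # two diploids 0/1
  expect_equal(unname(fr$p[1, "P2"]), 0.75) # tetraploid 0/1/1/1
  # diploid 1/1 + tetraploid 0/0/0/1 pooled: 3 ALT of 6 alleles
  pm2 <- population_map(names(pl), c("M", "X", "M", "X2"),
                        c("lyrata4x", "lyrata2x", "lyrata4x", "lyrata4x"))
  fr2 <- site_freqs(gm, pm2)
  expect_equal(unname(fr2$p[2, "M"]), 0.5)
  expect_equal(unname(fr2$n_alleles[2, "M"]), 6)
})

test_that("fixed-difference and no-differentiation limits hold", {
  pl <- setNames(rep(2L, 6), paste0("s", 1:6))
  dA <- matrix(2L, 10, 3); dB <- matrix(0L, 10, 3)
  gm <- genotype_matrix(data.frame(chrom = "c", pos = 1:10, ref = "A",
                                   alt = "T"), cbind(dA, dB), pl)
  fr <- site_freqs(gm, two_pop_map(gm, 3))
  m <- pair_metrics(fr, NULL, "PA", "PB")
  expect_equal(m$afd, 1); expect_equal(m$dxy, 1)
  expect_equal(m$fst, 1); expect_equal(m$fixed_diff, 10L)
  expect_equal(m$n_snps, 10L)

  gm2 <- random_gm(n_site = 25, n_dip = 8, seed = 5)
  fr2 <- site_freqs(gm2, two_pop_map(gm2, 4))
  # same samples in both "populations" is impossible; instead scan a
  # population against a copy of itself by construction
  pl2 <- setNames(rep(2L, 8), paste0("s", 1:8))
  d <- gm2$dosage[, c(1:4, 1:4)]
  colnames(d) <- names(pl2)
  gm3 <- genotype_matrix(gm2$sites, d, pl2)
  m3 <- pair_metrics(site_freqs(gm3, two_pop_map(gm3, 4)), NULL, "PA", "PB")
  expect_equal(m3$afd, 0)
  expect_equal(m3$fixed_diff, 0L)
  expect_lt(abs(m3$fst), 0.2)   # unbiased estimator fluctuates around 0
  expect_lt(m3$rho, 0.05)
})

test_that("pair metrics equal brute-force recomputation on random data", {
  for (seed in 1:5) {
    gm <- random_gm(n_site = 20, n_dip = 4, n_tet = 4, seed = seed,
                    miss_frac = if (seed > 3) 0.1 else 0)
    pm <- two_pop_map(gm, 4)
    fr <- site_freqs(gm, pm)
    m <- pair_metrics(fr, NULL, "PA", "PB")
    o <- oracle_metrics(gm, gm$samples[1:4], gm$samples[5:8])
    expect_equal(m$afd, o$afd, tolerance = 1e-12)
    expect_equal(m$dxy, o$dxy, tolerance = 1e-12)
    expect_equal(m$fst, o$fst, tolerance = 1e-12)
    expect_equal(m$rho, o$rho, tolerance = 1e-12)
    expect_equal(m$fixed_diff, o$fixed)
    expect_equal(m$n_snps, o$n)
    # symmetry
    m2 <- pair_metrics(fr, NULL, "PB", "PA")
    expect_equal(m2[, 3:8], m[, 3:8], ignore_attr = TRUE)
  }
})

test_that("Rho is invariant under diploid-to-tetraploid dosage doubling", {
  gm <- random_gm(n_site = 30, n_dip = 8, seed = 11)
  pm <- two_pop_map(gm, 4)
  rho2 <- pair_metrics(site_freqs(gm, pm), NULL, "PA", "PB")$rho
  pl4 <- setNames(rep(4L, 8), gm$samples)
  gm4 <- genotype_matrix(gm$sites, gm$dosage * 2L, pl4)
  rho4 <- pair_metrics(site_freqs(gm4, pm), NULL, "PA", "PB")$rho
  expect_equal(rho2, rho4, tolerance = 1e-9)
})

test_that("metric bounds hold on random instances", {
  for (seed in 6:10) {
    gm <- random_gm(n_site = 15, n_dip = 6, seed = seed)
    m <- pair_metrics(site_freqs(gm, two_pop_map(gm, 3)), NULL, "PA", "PB")
    expect_gte(m$afd, 0); expect_lte(m$afd, 1)
    expect_gte(m$dxy, 0); expect_lte(m$dxy, 1)
    expect_lte(m$fst, 1)
    expect_lte(m$fixed_diff, m$n_snps)
    if (m$fixed_diff == m$n_snps) expect_equal(m$afd, 1)
  }
})

test_that("group metrics average between-group pairs", {
  gm <- random_gm(n_site = 20, n_dip = 6, seed = 3)
  pm <- population_map(gm$samples, rep(c("A1", "B1", "B2"), each = 2),
                       rep(c("lyrata2x", "lyrata4x", "lyrata4x"), each = 2))
  fr <- site_freqs(gm, pm)
  g <- group_metrics(fr, NULL, "A1", c("B1", "B2"))
  p1 <- pair_metrics(fr, NULL, "A1", "B1")
  p2 <- pair_metrics(fr, NULL, "A1", "B2")
  expect_equal(g$afd, mean(c(p1$afd, p2$afd)))
  expect_equal(g$rho, mean(c(p1$rho, p2$rho)))
  # single population per group degenerates to pair_metrics
  g1 <- group_metrics(fr, NULL, "A1", "B1")
  expect_equal(g1$afd, p1$afd)
  expect_equal(g1$fst, p1$fst)
})

test_that("scan_windows emits one deterministic row per window", {
  gm <- random_gm(n_site = 60, n_dip = 6, seed = 8)
  pm <- population_map(gm$samples, rep(c("PA", "PB"), each = 6 / 2),
                       rep(c("lyrata2x", "lyrata4x"), each = 3))
  w <- window_frame(rep("chr1", 3), c(1L, 201L, 401L), c(200L, 400L, 700L),
                    "gene", paste0("g", 1:3))
  tab <- scan_windows(gm, pm, w, "lyrata2x", "lyrata4x")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$label, paste0("g", 1:3))
  expect_identical(tab, scan_windows(gm, pm, w, "lyrata2x", "lyrata4x"))
  expect_warning(empty <- scan_windows(gm, pm, w[0, ], "lyrata2x",
                                       "lyrata4x"), "empty")
  expect_equal(nrow(empty), 0L)
})
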