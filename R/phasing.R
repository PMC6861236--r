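#' Construct a haplotype matrix
#'
#' Rows are haplotype slots (`ploidy[sample]` rows per sample, stable
#' `sample.slot` ids), columns are window SNPs, entries 0/1 or `NA`.
#'
#' @param mat 0/1 integer matrix, total ploidy x n sites.
#' @param sample character vector assigning each row to a sample.
#' @param ploidy named ploidy vector of the samples.
#' @param sites optional site metadata data.frame carried along.
#' @param provenance `"inferred"`, `"true"` or `"randomised"`.
#' @return An integer matrix of class `haplotype_matrix` with attributes
#'   `sample`, `ploidy`, `sites`, `provenance`.
#' @export
haplotype_matrix <- function(mat, sample, ploidy, sites = NULL,
                             provenance = "inferred") {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  stopifnot(nrow(mat) == length(sample),
            nrow(mat) == sum(ploidy[unique(sample)]))
  slot <- unlist(lapply(unique(sample), function(s) seq_len(ploidy[s])))
  rownames(mat) <- paste(sample, slot, sep = ".")
  structure(mat, sample = sample, ploidy = ploidy, sites = sites,
            provenance = provenance, class = c("haplotype_matrix", "matrix"))
}

#' Dosage matrix implied by a haplotype matrix
#' @param hm a [haplotype_matrix()].
#' @return Integer matrix, sites x samples (per-sample column sums of slots).
#' @export
hm_dosage <- function(hm) {
  samp <- attr(hm, "sample")
  us <- unique(samp)
  out <- vapply(us, function(s)
    colSums(hm[samp == s, , drop = FALSE]), numeric(ncol(hm)))
  if (ncol(hm) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, us))
  storage.mode(out) <- "integer"
  out
}

#' All phase configurations for one genotype
#'
#' Every way of placing `dosage` ALT alleles into `ploidy` haplotype slots:
#' `choose(ploidy, dosage)` 0/1 vectors in deterministic (combinadic) order;
#' the first is the canonical configuration (ALT in the lowest slots).
#'
#' @param dosage ALT dosage, 0..ploidy.
#' @param ploidy 2 or 4.
#' @return Matrix with `ploidy` rows, one column per configuration.
#' @export
enumerate_configurations <- function(dosage, ploidy) {
  stopifnot(dosage >= 0, dosage <= ploidy)
  if (dosage == 0L) return(matrix(0L, ploidy, 1L))
  sel <- combn(ploidy, dosage)
  out <- matrix(0L, ploidy, ncol(sel))
  out[cbind(as.vector(sel), rep(seq_len(ncol(sel)), each = dosage))] <- 1L
  out
}

#' Squared-correlation LD between two haplotype columns
#'
#' Squared Pearson correlation of the 0/1 indicators across haplotype
#' slots, with missing slots excluded pairwise. Defined as 0 when either
#' column is monomorphic over the shared called slots; sign-free under
#' allele relabelling.
#'
#' @param hapcol_a,hapcol_b 0/1 vectors over the same slots.
#' @return r-squared in \[0, 1\].
#' @export
pairwise_ld <- function(hapcol_a, hapcol_b) {
  ok <- !is.na(hapcol_a) & !is.na(hapcol_b)
  if (sum(ok) < 2L) {
    warning("fewer than 2 shared called slots; LD set to 0")
    return(0)
  }
  a <- hapcol_a[ok]; b <- hapcol_b[ok]
  va <- var(a); vb <- var(b)
  if (va == 0 || vb == 0) return(0)
  cor(a, b)^2
}

# vectorised r^2 of candidate column v against previously phased columns P
# (slots x m). Complete-data fast path; pairwise-complete fallback.
r2_vs_columns <- function(v, P, Psum = NULL, Pden = NULL, n = NULL) {
  if (!anyNA(v) && !is.null(Psum)) {
    sv <- sum(v)
    dv <- n * sv - sv * sv
    if (dv == 0) return(numeric(ncol(P)))
    cr <- as.numeric(crossprod(P, v))
    num <- (n * cr - sv * Psum)^2
    den <- dv * Pden
    out <- ifelse(den > 0, num / den, 0)
    return(out)
  }
  vapply(seq_len(ncol(P)), function(j) {
    ok <- !is.na(v) & !is.na(P[, j])
    if (sum(ok) < 2L) return(0)
    a <- v[ok]; b <- P[ok, j]
    if (var(a) == 0 || var(b) == 0) return(0)
    cor(a, b)^2
  }, numeric(1))
}

#' Phase one window by iterative LD maximisation
#'
#' Re-implements the heuristic that separates diploid and tetraploid
#' haplotypes simultaneously: sites are processed in decreasing order of
#' heterozygous-genotype count (ties by ascending position); the first site
#' receives the canonical configuration, and each subsequent site the
#' configuration maximising the mean r-squared LD against all previously
#' phased polymorphic sites. The per-site search over samples is coordinate
#' ascent in fixed sample order, iterated to a fixed point (at most
#' `max_iter` sweeps); objective ties are broken by canonical configuration
#' order, so the result is deterministic.
#'
#' After the sequential pass, `polish` rounds revisit every site in the
#' same order and re-select its configuration against *all* other phased
#' polymorphic sites, which repairs early commitments made with little
#' context.
#'
#' @param gm_window a [genotype_matrix()] restricted to one window.
#' @param max_iter maximum coordinate-ascent sweeps per site (default 20).
#' @param polish maximum polish rounds over the whole window (default 2).
#' @return A [haplotype_matrix()] with provenance `"inferred"`. Missing
#'   genotypes give all-`NA` slots at that site.
#' @export
phase_window <- function(gm_window, max_iter = 20, polish = 2) {
  gm <- gm_window
  n_site <- nrow(gm$sites)
  stopifnot(n_site >= 1)
  ploidy <- gm$ploidy
  samp_rows <- rep(gm$samples, ploidy)
  n_slot <- length(samp_rows)
  row_of <- split(seq_len(n_slot), factor(samp_rows, levels = gm$samples))

  het <- vapply(seq_len(n_site), function(i) {
    d <- gm$dosage[i, ]
    sum(!is.na(d) & d > 0L & d < ploidy)
  }, numeric(1))
  ord <- order(-het, gm$sites$pos)

  H <- matrix(NA_integer_, n_slot, n_site)
  any_missing <- anyNA(gm$dosage)
  cfgs_of <- lapply(seq_len(n_site), function(i) {
    d <- gm$dosage[i, ]
    lapply(seq_along(gm$samples), function(j) {
      if (is.na(d[j])) matrix(NA_integer_, ploidy[j], 1L)
      else enumerate_configurations(d[j], ploidy[j])
    })
  })

  # optimal configuration for site i against reference columns P, starting
  # from v: joint enumeration over samples when the per-site space is small,
  # coordinate ascent in fixed sample order otherwise
  ascend <- function(i, P, v) {
    cfgs <- cfgs_of[[i]]
    free <- which(vapply(cfgs, ncol, integer(1)) > 1L)
    if (!length(free) || !ncol(P)) return(v)
    if (!any_missing && !anyNA(P)) {
      Psum <- colSums(P)
      Pden <- n_slot * Psum - Psum^2
    } else Psum <- Pden <- NULL
    space <- prod(vapply(cfgs[free], ncol, integer(1)))
    # joint enumeration whenever its work stays bounded (space scaled by
    # the number of reference columns); large sites use coordinate ascent
    joint_limit <- max(256, 4096 %/% max(1L, ncol(P)))
    if (space <= joint_limit) {
      grid <- as.matrix(do.call(expand.grid,
                                lapply(cfgs[free], function(m)
                                  seq_len(ncol(m)))))
      vals <- vapply(seq_len(nrow(grid)), function(g) {
        v2 <- v
        for (jj in seq_along(free))
          v2[row_of[[free[jj]]]] <- cfgs[[free[jj]]][, grid[g, jj]]
        mean(r2_vs_columns(v2, P, Psum, Pden, n_slot))
      }, numeric(1))
      best <- which.max(vals)   # first maximum = canonical-order tie-break
      for (jj in seq_along(free))
        v[row_of[[free[jj]]]] <- cfgs[[free[jj]]][, grid[best, jj]]
      return(v)
    }
    for (it in seq_len(max_iter)) {
      changed <- FALSE
      for (j in free) {
        cj <- cfgs[[j]]
        vals <- vapply(seq_len(ncol(cj)), function(k) {
          v2 <- v
          v2[row_of[[j]]] <- cj[, k]
          mean(r2_vs_columns(v2, P, Psum, Pden, n_slot))
        }, numeric(1))
        cur <- match_cfg(cj, v[row_of[[j]]])
        best <- which.max(vals)   # first maximum = canonical-order tie-break
        if (best != cur && (vals[best] > vals[cur] + 1e-12 || best < cur)) {
          v[row_of[[j]]] <- cj[, best]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    v
  }

  canonical_v <- function(i) {
    v <- integer(n_slot)
    for (j in seq_along(cfgs_of[[i]])) v[row_of[[j]]] <- cfgs_of[[i]][[j]][, 1L]
    v
  }
  is_poly <- function(v) {
    cc <- v[!is.na(v)]
    length(cc) >= 2L && var(cc) > 0
  }

  phased_poly <- integer(0)        # previously phased, non-constant columns
  for (i in ord) {
    v <- ascend(i, H[, phased_poly, drop = FALSE], canonical_v(i))
    H[, i] <- v
    if (is_poly(v)) phased_poly <- c(phased_poly, i)
  }
  # polish: re-select each site's configuration against all other sites
  poly_all <- which(apply(H, 2, is_poly))
  for (round in seq_len(polish)) {
    changed_any <- FALSE
    for (i in ord) {
      others <- setdiff(poly_all, i)
      if (!length(others)) next
      v <- ascend(i, H[, others, drop = FALSE], H[, i])
      if (!identical(v, H[, i])) {
        H[, i] <- v
        changed_any <- TRUE
        if (is_poly(v) && !(i %in% poly_all)) poly_all <- sort(c(poly_all, i))
      }
    }
    if (!changed_any) break
  }
  haplotype_matrix(H, samp_rows, ploidy, sites = gm$sites,
                   provenance = "inferred")
}

# index of configuration matching slot vector x among columns of cj
match_cfg <- function(cj, x) {
  if (anyNA(x)) return(1L)
  which(colSums(cj == x) == nrow(cj))[1]
}

#' Mean pairwise LD objective of a phased window
#'
#' The quantity the phasing heuristic targets: mean r-squared over all
#' unordered pairs of polymorphic sites (columns non-constant over called
#' slots). `NaN` when fewer than two polymorphic sites exist.
#'
#' @param hm a [haplotype_matrix()].
#' @return Mean pairwise r-squared.
#' @export
ld_objective <- function(hm) {
  poly <- which(apply(hm, 2, function(col) {
    c0 <- col[!is.na(col)]
    length(c0) >= 2L && var(c0) > 0
  }))
  if (length(poly) < 2L) return(NaN)
  prs <- combn(poly, 2L)
  mean(vapply(seq_len(ncol(prs)), function(k)
    suppressWarnings(pairwise_ld(hm[, prs[1, k]], hm[, prs[2, k]])),
    numeric(1)))
}

#' Exhaustive-search phasing oracle (tiny windows only)
#'
#' Maximises [ld_objective()] by enumerating all phase configurations,
#' after pinning the first het-carrying site to its canonical configuration
#' (per-sample slot relabelling is a symmetry of the objective). Intended
#' as the independent optimum against which the heuristic is tested.
#'
#' @param gm_window a [genotype_matrix()]; the configuration space after
#'   symmetry reduction must not exceed `max_combos`.
#' @param max_combos guard on the enumeration size (default 2e5).
#' @return List: `objective` (the optimum), `hm` (an argmax
#'   [haplotype_matrix()]).
#' @export
phase_window_exhaustive <- function(gm_window, max_combos = 2e5) {
  gm <- gm_window
  n_site <- nrow(gm$sites)
  ploidy <- gm$ploidy
  samp_rows <- rep(gm$samples, ploidy)
  n_slot <- length(samp_rows)
  row_of <- split(seq_len(n_slot), factor(samp_rows, levels = gm$samples))

  site_cols <- vector("list", n_site)   # candidate columns per site
  for (i in seq_len(n_site)) {
    d <- gm$dosage[i, ]
    per <- lapply(seq_along(gm$samples), function(j) {
      if (is.na(d[j])) matrix(NA_integer_, ploidy[j], 1L)
      else enumerate_configurations(d[j], ploidy[j])
    })
    ks <- vapply(per, ncol, integer(1))
    grid <- do.call(expand.grid, lapply(ks, seq_len))
    cols <- matrix(NA_integer_, n_slot, nrow(grid))
    for (g in seq_len(nrow(grid)))
      for (j in seq_along(per))
        cols[row_of[[j]], g] <- per[[j]][, grid[g, j]]
    site_cols[[i]] <- cols
  }
  # pin the first site with >1 configuration to canonical (symmetry)
  k <- vapply(site_cols, ncol, integer(1))
  pin <- which(k > 1L)[1]
  if (!is.na(pin)) {
    site_cols[[pin]] <- site_cols[[pin]][, 1L, drop = FALSE]
    k[pin] <- 1L
  }
  if (prod(k) > max_combos)
    stop("exhaustive search space too large: ", prod(k))

  poly <- which(vapply(seq_len(n_site), function(i) {
    any(apply(site_cols[[i]], 2, function(col) {
      c0 <- col[!is.na(col)]
      length(c0) >= 2L && var(c0) > 0
    }))
  }, logical(1)))
  if (length(poly) < 2L) {
    H <- vapply(site_cols, function(m) m[, 1L], integer(n_slot))
    return(list(objective = NaN,
                hm = haplotype_matrix(H, samp_rows, ploidy, gm$sites)))
  }
  prs <- combn(poly, 2L)
  n_pair <- ncol(prs)
  free <- which(k > 1L)
  grid <- if (length(free))
    as.matrix(do.call(expand.grid, setNames(lapply(k[free], seq_len),
                                            paste0("s", free))))
  else matrix(1L, 1L, 0L)
  total <- numeric(nrow(grid))
  choice_of <- function(i, g) if (i %in% free) g[, match(i, free)] else
    rep(1L, nrow(g))
  for (q in seq_len(n_pair)) {
    i <- prs[1, q]; j <- prs[2, q]
    A <- site_cols[[i]]; B <- site_cols[[j]]
    tab <- matrix(0, ncol(A), ncol(B))
    for (a in seq_len(ncol(A)))
      for (b in seq_len(ncol(B)))
        tab[a, b] <- suppressWarnings(pairwise_ld(A[, a], B[, b]))
    total <- total + tab[cbind(choice_of(i, grid), choice_of(j, grid))]
  }
  best <- which.max(total)
  H <- matrix(NA_integer_, n_slot, n_site)
  for (i in seq_len(n_site))
    H[, i] <- site_cols[[i]][, if (i %in% free) grid[best, match(i, free)] else 1L]
  list(objective = total[best] / n_pair,
       hm = haplotype_matrix(H, samp_rows, ploidy, gm$sites))
}

#' Randomise the phase of a haplotype matrix
#'
#' Per sample and per site, reassigns the ALT alleles to a uniformly random
#' slot subset; dosages are preserved exactly. This is the degraded-input
#' condition used to validate phase inference.
#'
#' @param hm a [haplotype_matrix()] (typically true simulated phase).
#' @param seed integer seed.
#' @return List: `hm` (provenance `"randomised"`), `dosage` (unchanged
#'   sites x samples dosage matrix).
#' @export
phase_randomise <- function(hm, seed = 1) {
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(seed)
  samp <- attr(hm, "sample")
  ploidy <- attr(hm, "ploidy")
  out <- unclass(hm)
  for (s in unique(samp)) {
    rows <- which(samp == s)
    p <- length(rows)
    for (i in seq_len(ncol(hm))) {
      col <- hm[rows, i]
      if (anyNA(col)) next
      d <- sum(col)
      new <- integer(p)
      if (d > 0L) new[sample.int(p, d)] <- 1L
      out[rows, i] <- new
    }
  }
  hm2 <- haplotype_matrix(out, samp, ploidy, attr(hm, "sites"),
                          provenance = "randomised")
  list(hm = hm2, dosage = hm_dosage(hm2))
}

perms_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Phase concordance between an estimated and a true haplotype matrix
#'
#' Haplotype slots within a sample are exchangeable, so per sample the
#' concordance is maximised over slot permutations of the estimate before
#' averaging the per-entry agreement across samples.
#'
#' @param estimated,truth [haplotype_matrix()] objects over the same
#'   samples and sites.
#' @return Fraction in \[0, 1\].
#' @export
phase_concordance <- function(estimated, truth) {
  if (!all(dim(estimated) == dim(truth)))
    stop("haplotype matrix dimension mismatch")
  samp <- attr(estimated, "sample")
  if (!identical(samp, attr(truth, "sample")))
    stop("sample layout mismatch")
  per_sample <- vapply(unique(samp), function(s) {
    rows <- which(samp == s)
    E <- estimated[rows, , drop = FALSE]
    Tm <- truth[rows, , drop = FALSE]
    pp <- perms_of(length(rows))
    best <- 0
    for (r in seq_len(nrow(pp))) {
      ok <- !is.na(E[pp[r, ], ]) & !is.na(Tm)
      if (!any(ok)) next
      best <- max(best, sum(E[pp[r, ], ][ok] == Tm[ok]) / sum(ok))
    }
    best
  }, numeric(1))
  mean(per_sample)
}
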