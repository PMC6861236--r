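#' Read a mixed-ploidy VCF into a genotype matrix
#'
#' Retains biallelic SNPs only. Ploidy is inferred per sample from the
#' number of alleles in its GT field (`0/1` diploid, `0/1/1/1` tetraploid)
#' and must be constant across sites. Genotypes with depth below `min_dp`
#' are set missing, and sites whose fraction of missing *alleles* (ploidy-
#' weighted) exceeds `max_missing_frac` are dropped. The defaults mirror the
#' usual hard filter for structure-type analyses: at most 10% missing
#' alleles per site at a 5x minimum genotype depth.
#'
#' @param path path to a VCF 4.x file (plain or bgzipped).
#' @param max_missing_frac maximum tolerated fraction of missing alleles per
#'   site (default 0.10).
#' @param min_dp minimum per-genotype depth; genotypes below it are set
#'   missing (default 5). Ignored when the VCF has no DP FORMAT field.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, max_missing_frac = 0.10, min_dp = 5) {
  v <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(v)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt <- rep(NA_character_, length(ref))
  alt[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  keep <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt) & nchar(alt) == 1L &
    alt %in% c("A", "C", "G", "T") & ref %in% c("A", "C", "G", "T")
  if (!any(keep)) stop("no biallelic SNPs in ", path)
  gt <- VariantAnnotation::geno(v)$GT[keep, , drop = FALSE]
  dp <- if ("DP" %in% names(VariantAnnotation::geno(v)))
    VariantAnnotation::geno(v)$DP[keep, , drop = FALSE] else NULL
  chrom <- as.character(GenomicRanges::seqnames(rr))[keep]
  pos <- GenomicRanges::start(rr)[keep]
  ref <- ref[keep]; alt <- alt[keep]
  samples <- colnames(gt)

  parsed <- parse_gt_matrix(gt)
  dosage <- parsed$dosage
  arity <- parsed$arity

  # reject sites containing a malformed GT arity (not 2 or 4)
  bad_arity <- arity != 0L & !(arity %in% c(2L, 4L))
  bad_site <- rowSums(bad_arity) > 0L
  if (any(bad_site)) {
    warning(sum(bad_site), " site(s) rejected with malformed GT arity")
    dosage <- dosage[!bad_site, , drop = FALSE]
    arity <- arity[!bad_site, , drop = FALSE]
    dp <- if (!is.null(dp)) dp[!bad_site, , drop = FALSE]
    chrom <- chrom[!bad_site]; pos <- pos[!bad_site]
    ref <- ref[!bad_site]; alt <- alt[!bad_site]
  }

  # per-sample ploidy must be constant across called sites
  ploidy <- vapply(seq_along(samples), function(j) {
    a <- unique(arity[, j]); a <- a[a != 0L]
    if (length(a) > 1L)
      stop("inconsistent ploidy for sample ", samples[j], ": GT arities ",
           paste(sort(a), collapse = ","))
    if (length(a) == 0L) 2L else a
  }, integer(1))
  names(ploidy) <- samples

  if (!is.null(dp)) {
    low <- !is.na(dp) & dp < min_dp
    dosage[low] <- NA_integer_
  }

  miss_alleles <- (is.na(dosage)) %*% ploidy
  frac <- as.numeric(miss_alleles) / sum(ploidy)
  keep_site <- frac <= max_missing_frac
  if (!any(keep_site)) stop("all sites exceed max_missing_frac")
  gm_sites <- data.frame(chrom = chrom[keep_site], pos = pos[keep_site],
                         ref = ref[keep_site], alt = alt[keep_site],
                         stringsAsFactors = FALSE)
  dup <- unlist(tapply(seq_len(nrow(gm_sites)), gm_sites$chrom,
                       function(i) i[duplicated(gm_sites$pos[i])]))
  if (length(dup)) {
    warning(length(dup), " duplicate-position site(s) dropped")
    gm_sites <- gm_sites[-dup, , drop = FALSE]
    dosage <- dosage[keep_site, , drop = FALSE][-dup, , drop = FALSE]
  } else {
    dosage <- dosage[keep_site, , drop = FALSE]
  }
  genotype_matrix(gm_sites, dosage, ploidy)
}

# GT string matrix -> list(dosage, arity); "." alleles make the call missing
parse_gt_matrix <- function(gt) {
  u <- unique(as.vector(gt))
  toks <- strsplit(u, "[/|]")
  ar <- vapply(toks, length, integer(1))
  dos <- vapply(toks, function(t) {
    if (any(t == ".")) NA_integer_
    else {
      z <- suppressWarnings(as.integer(t))
      if (anyNA(z) || any(z > 1L | z < 0L)) NA_integer_ else sum(z)
    }
  }, integer(1))
  # fully uncalled entries ("." or ".|.") keep arity 0 so ploidy inference
  # skips them; partially called entries keep their arity
  ar[vapply(toks, function(t) all(t == "."), logical(1)) & ar <= 2L] <- 0L
  idx <- match(as.vector(gt), u)
  list(dosage = matrix(dos[idx], nrow(gt), ncol(gt)),
       arity = matrix(ar[idx], nrow(gt), ncol(gt)))
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits unphased GT fields whose arity encodes each sample's ploidy, so
#' that `read_vcf(write_vcf(gm))` round-trips dosages and ploidies exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param phased optional haplotype matrix; when supplied, GT fields are
#'   written phased (`0|1|1|0`) in slot order.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, phased = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", unique(gm$sites$chrom)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples), collapse = "\t")), con)
  n <- nrow(gm$sites)
  gt_cols <- vapply(seq_along(gm$samples), function(j) {
    p <- gm$ploidy[j]
    if (is.null(phased)) {
      d <- gm$dosage[, j]
      sep <- "/"
      alleles <- vapply(d, function(di) {
        if (is.na(di)) paste(rep(".", p), collapse = sep)
        else paste(c(rep("0", p - di), rep("1", di)), collapse = sep)
      }, character(1))
    } else {
      rows <- which(attr(phased, "sample") == gm$samples[j])
      alleles <- apply(phased[rows, , drop = FALSE], 2, function(col) {
        if (anyNA(col)) paste(rep(".", p), collapse = "|")
        else paste(col, collapse = "|")
      })
    }
    alleles
  }, character(n))
  if (n == 1L) gt_cols <- matrix(gt_cols, nrow = 1L)
  body <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref,
                gm$sites$alt, ".", "PASS", ".", "GT",
                apply(gt_cols, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a tab-separated population map
#'
#' Expects three columns: sample, population, taxon (one of [TAXA]).
#' @param path path to the TSV (a header line is detected and skipped).
#' @return A [population_map()].
#' @export
read_popmap <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#")
  if (ncol(d) < 3) stop("popmap must have sample, population, taxon columns")
  if (identical(tolower(d[1, 1]), "sample")) d <- d[-1, , drop = FALSE]
  population_map(d[[1]], d[[2]], d[[3]])
}

#' Write a population map TSV
#' @param pm a [population_map()].
#' @param path output path.
#' @export
write_popmap <- function(pm, path) {
  write.table(pm, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Gene-sized windows from a GFF3 annotation
#'
#' One window per `gene` feature (span plus `flank_bp` on each side).
#' Overlapping windows are truncated at the midpoint of their overlap so
#' that the windows of a scan remain non-overlapping; a window nested
#' entirely inside another after truncation is dropped with a warning.
#'
#' @param gff_path path to a GFF3 file containing gene features.
#' @param flank_bp flank added to each side of the gene span (default 0).
#' @param known_chroms optional chromosome whitelist; genes on other
#'   chromosomes are skipped with a warning.
#' @return Window data.frame (chrom, start, end, kind, label).
#' @export
gene_windows <- function(gff_path, flank_bp = 0, known_chroms = NULL) {
  g <- rtracklayer::import(gff_path)
  g <- g[tolower(as.character(g$type)) == "gene"]
  if (!length(g)) return(window_frame(character(0), integer(0), integer(0),
                                      "gene", character(0)))
  chrom <- as.character(GenomicRanges::seqnames(g))
  if (!is.null(known_chroms)) {
    bad <- !chrom %in% known_chroms
    if (any(bad)) {
      warning(sum(bad), " gene(s) on unknown chromosome(s) skipped")
      g <- g[!bad]; chrom <- chrom[!bad]
    }
  }
  id <- if (!is.null(g$ID)) as.character(g$ID) else
    if (!is.null(g$Name)) as.character(g$Name) else
      paste0("gene", seq_along(g))
  w <- window_frame(chrom, pmax(1L, GenomicRanges::start(g) - flank_bp),
                    GenomicRanges::end(g) + flank_bp, "gene", id)
  w <- w[order(w$chrom, w$start, w$end), , drop = FALSE]
  drop <- logical(nrow(w))
  for (i in seq_len(nrow(w))[-1]) {
    j <- i - 1L
    while (j >= 1L && drop[j]) j <- j - 1L
    if (j < 1L || w$chrom[i] != w$chrom[j]) next
    if (w$start[i] <= w$end[j]) {
      if (w$end[i] <= w$end[j]) { # nested
        drop[i] <- TRUE
        next
      }
      mid <- (w$start[i] + w$end[j]) %/% 2L
      w$end[j] <- mid
      w$start[i] <- mid + 1L
    }
  }
  if (any(drop)) warning(sum(drop), " nested gene window(s) dropped")
  w <- w[!drop, , drop = FALSE]
  rownames(w) <- NULL
  w
}

#' Consecutive fixed-SNP-count windows
#'
#' Partitions each chromosome's SNPs into consecutive non-overlapping blocks
#' of exactly `n_snps` sites (default 50, the usual window size for
#' genealogy inference); a trailing block with fewer SNPs is discarded.
#'
#' @param gm a [genotype_matrix()].
#' @param n_snps SNPs per window (>= 2).
#' @return Window data.frame with extra columns `snp_from`, `snp_to` giving
#'   global site-index ranges into `gm$sites`.
#' @export
snp_windows <- function(gm, n_snps = 50) {
  stopifnot(n_snps >= 2)
  out <- lapply(unique(gm$sites$chrom), function(ch) {
    idx <- which(gm$sites$chrom == ch)
    k <- length(idx) %/% n_snps
    if (k == 0L) {
      message("chromosome ", ch, " has fewer than ", n_snps,
              " SNPs; no windows")
      return(NULL)
    }
    from <- idx[seq(1L, by = n_snps, length.out = k)]
    to <- from + n_snps - 1L
    w <- window_frame(ch, gm$sites$pos[from], gm$sites$pos[to], "snp-count",
                      sprintf("%s:%d-%d", ch, gm$sites$pos[from],
                              gm$sites$pos[to]))
    w$snp_from <- from
    w$snp_to <- to
    w
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- cbind(window_frame(character(0), integer(0), integer(0),
                              "snp-count", character(0)),
                 snp_from = integer(0), snp_to = integer(0))
  rownames(out) <- NULL
  out
}

#' Site indices of a window
#' @param gm a [genotype_matrix()].
#' @param window one-row window data.frame.
#' @return Integer vector of indices into `gm$sites`.
#' @export
window_sites <- function(gm, window) {
  if (!is.null(window$snp_from) && !is.na(window$snp_from))
    return(seq(window$snp_from, window$snp_to))
  which(gm$sites$chrom == window$chrom & gm$sites$pos >= window$start &
        gm$sites$pos <= window$end)
}

#' Write windows as BED (0-based half-open)
#' @param windows window data.frame.
#' @param path output path.
#' @export
write_bed <- function(windows, path) {
  write.table(data.frame(windows$chrom, windows$start - 1L, windows$end,
                         windows$label),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read BED windows (0-based half-open on disk, 1-based inclusive in memory)
#' @param path BED path (3 or more columns; 4th used as label).
#' @param kind window kind label.
#' @return Window data.frame.
#' @export
read_bed <- function(path, kind = "fixed-bp") {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  lab <- if (ncol(d) >= 4) d[[4]] else paste0(d[[1]], ":", d[[2]] + 1L, "-", d[[3]])
  window_frame(d[[1]], d[[2]] + 1L, d[[3]], kind, lab)
}
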