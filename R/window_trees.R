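#' Pairwise p-distances between haplotypes
#'
#' Mismatch fraction over sites called in both haplotypes (no multiple-hit
#' correction: window distances are small at 50 SNPs). Pairs sharing zero
#' called sites get distance 1 with a warning.
#'
#' @param hm a [haplotype_matrix()] with at least 3 haplotypes and 1 SNP.
#' @return Symmetric distance matrix with zero diagonal, entries in
#'   \[0, 1\], labelled by haplotype slot ids.
#' @export
hamming_pdist <- function(hm) {
  if (nrow(hm) < 3L) stop("need at least 3 haplotypes")
  if (ncol(hm) < 1L) stop("need at least 1 SNP")
  M <- unclass(hm)
  if (!anyNA(M)) {
    Md <- M * 1.0
    g <- tcrossprod(Md)                      # shared 1s
    ones <- rowSums(Md)
    L <- ncol(M)
    mism <- outer(ones, ones, "+") - 2 * g   # hamming distance
    D <- mism / L
  } else {
    ok <- !is.na(M)
    M0 <- M; M0[!ok] <- 0L
    M0 <- M0 * 1.0
    okd <- ok * 1.0
    shared <- tcrossprod(okd)
    g11 <- tcrossprod(M0)
    r1 <- M0 %*% t(okd)                      # i's 1s at shared sites
    mism <- r1 + t(r1) - 2 * g11
    D <- ifelse(shared > 0, mism / shared, 1)
    if (any(shared[upper.tri(shared)] == 0))
      warning("haplotype pair(s) share zero called sites; distance set to 1")
  }
  diag(D) <- 0
  dimnames(D) <- list(rownames(hm), rownames(hm))
  D
}

#' BIONJ genealogy from a distance matrix
#'
#' Neighbor joining with variance-weighted branch-length updates, the
#' agglomeration used for window genealogies. Deterministic for a given
#' matrix; negative branch-length estimates are clamped to zero (topology
#' is unaffected).
#'
#' @param dist symmetric distance matrix (n >= 3), no NaN entries.
#' @return An unrooted `phylo` tree.
#' @export
bionj_tree <- function(dist) {
  D <- as.matrix(dist)
  if (any(!is.finite(D))) stop("non-finite distances")
  if (nrow(D) < 3L) stop("need at least 3 tips")
  tr <- ape::bionj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Genealogies for a list of phased windows
#'
#' @param hm_by_window list of [haplotype_matrix()] objects, one per
#'   window (names used as window ids).
#' @param taxon_map named character vector sample -> taxon; expanded to
#'   haplotype tips internally.
#' @return List of `phylo` trees with a `taxa` attribute (named character
#'   vector tip -> taxon). Windows whose distances are undefined (fewer
#'   than 3 haplotypes or no called SNP) are skipped with a message.
#' @export
trees_for_windows <- function(hm_by_window, taxon_map) {
  out <- list()
  for (wid in seq_along(hm_by_window)) {
    hm <- hm_by_window[[wid]]
    name <- names(hm_by_window)[wid]
    if (is.null(name) || !nzchar(name)) name <- as.character(wid)
    tr <- tryCatch({
      D <- suppressWarnings(hamming_pdist(hm))
      bionj_tree(D)
    }, error = function(e) {
      message("window ", name, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(tr)) next
    taxa <- taxon_map[attr(hm, "sample")]
    names(taxa) <- rownames(hm)
    attr(tr, "taxa") <- taxa[tr$tip.label]
    out[[name]] <- tr
  }
  out
}

#' Write window trees as newick, one per line, with a taxon-map sidecar
#' @param trees output of [trees_for_windows()].
#' @param path newick output path; the sidecar TSV is `path`.taxa.tsv.
#' @export
write_trees <- function(trees, path) {
  txt <- vapply(trees, ape::write.tree, character(1))
  writeLines(paste0(txt, " # ", names(trees)), path)
  taxa <- attr(trees[[1]], "taxa")
  write.table(data.frame(tip = names(taxa), taxon = unname(taxa)),
              paste0(path, ".taxa.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
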