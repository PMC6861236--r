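#' Construct a mixed-ploidy genotype matrix
#'
#' The central unphased container of the package: one row of site metadata
#' per biallelic SNP and an integer ALT-dosage matrix with one column per
#' sample. A diploid sample takes dosages in 0..2, a tetraploid in 0..4;
#' `NA` marks a missing call and is never coerced to dosage 0 -- every
#' downstream denominator counts called alleles only.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; positions must be strictly increasing within each chromosome.
#' @param dosage integer matrix, `nrow(sites)` x `length(ploidy)`, entries in
#'   `0..ploidy[sample]` or `NA`.
#' @param ploidy named integer vector (values 2 or 4), one entry per sample;
#'   names are the sample ids and must match `colnames(dosage)` if set.
#' @return An object of class `genotype_matrix` with fields `sites`,
#'   `samples`, `ploidy`, `dosage`.
#' @export
genotype_matrix <- function(sites, dosage, ploidy) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  ploidy <- setNames(as.integer(round(ploidy)), names(ploidy))
  samples <- names(ploidy)
  if (is.null(samples)) stop("ploidy must be a named vector of samples")
  if (!all(ploidy %in% c(2L, 4L)))
    stop("ploidy values must be 2 or 4")
  if (nrow(dosage) != nrow(sites) || ncol(dosage) != length(ploidy))
    stop("dosage must be sites x samples")
  if (!is.null(colnames(dosage)) && !identical(colnames(dosage), samples))
    stop("dosage column names disagree with ploidy names")
  colnames(dosage) <- samples
  bad <- sweep(dosage, 2, ploidy, ">") | dosage < 0L
  if (any(bad, na.rm = TRUE))
    stop("dosage outside 0..ploidy for ",
         sum(bad, na.rm = TRUE), " entries")
  ord <- order(sites$chrom, sites$pos)
  if (is.unsorted(ord)) {
    sites <- sites[ord, , drop = FALSE]
    dosage <- dosage[ord, , drop = FALSE]
  }
  if (any(unlist(tapply(sites$pos, sites$chrom, function(p) duplicated(p)))))
    stop("duplicate positions within a chromosome")
  rownames(sites) <- NULL
  structure(list(sites = sites, samples = samples,
                 ploidy = setNames(ploidy, samples), dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d biallelic SNPs x %d samples (%d diploid, %d tetraploid)\n",
              nrow(x$sites), length(x$samples),
              sum(x$ploidy == 2L), sum(x$ploidy == 4L)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$sites$chrom), collapse = ", ")))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix to a site index range or window
#'
#' @param gm a [genotype_matrix()].
#' @param sites integer vector of site indices, or a one-row window
#'   data.frame with `chrom`, `start`, `end` (1-based inclusive).
#' @return A `genotype_matrix` restricted to the selected sites.
#' @export
gm_subset <- function(gm, sites) {
  if (is.data.frame(sites)) {
    stopifnot(nrow(sites) == 1L)
    sites <- which(gm$sites$chrom == sites$chrom &
                   gm$sites$pos >= sites$start &
                   gm$sites$pos <= sites$end)
  }
  genotype_matrix(gm$sites[sites, , drop = FALSE],
                  gm$dosage[sites, , drop = FALSE], gm$ploidy)
}

#' The five taxon groups recognised by the pipeline
#'
#' Diploid and autotetraploid populations of each of two sister species,
#' plus an outgroup used to root topology weighting.
#' @export
TAXA <- c("lyrata2x", "lyrata4x", "arenosa2x", "arenosa4x", "outgroup")

#' Construct a population map
#'
#' Maps each sample to a population code and each population to one of the
#' five taxon groups in [TAXA].
#'
#' @param sample character vector of sample ids (no duplicates).
#' @param population character vector of population codes, parallel to
#'   `sample`.
#' @param taxon character vector of taxon labels, parallel to `sample`; each
#'   must be one of [TAXA] and constant within a population.
#' @return A data.frame of class `population_map`.
#' @export
population_map <- function(sample, population, taxon) {
  if (anyDuplicated(sample))
    stop("duplicate sample in population map: ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "))
  bad <- setdiff(unique(taxon), TAXA)
  if (length(bad))
    stop("unknown taxon label(s): ", paste(bad, collapse = ", "))
  tab <- unique(data.frame(population = population, taxon = taxon))
  if (anyDuplicated(tab$population))
    stop("population assigned to more than one taxon")
  pm <- data.frame(sample = as.character(sample),
                   population = as.character(population),
                   taxon = as.character(taxon),
                   stringsAsFactors = FALSE)
  class(pm) <- c("population_map", "data.frame")
  pm
}

#' Samples belonging to a population or taxon group
#'
#' @param pm a [population_map()].
#' @param populations character vector of population codes and/or taxon
#'   labels; taxon labels expand to all their populations.
#' @return Character vector of sample ids.
#' @export
pm_samples <- function(pm, populations) {
  keep <- pm$population %in% populations | pm$taxon %in% populations
  pm$sample[keep]
}

#' Populations belonging to a taxon group (or identity on population codes)
#' @param pm a [population_map()].
#' @param group a taxon label or vector of population codes.
#' @return Character vector of population codes.
#' @export
pm_populations <- function(pm, group) {
  out <- unique(c(pm$population[pm$taxon %in% group],
                  intersect(group, pm$population)))
  if (!length(out)) stop("no populations match group: ",
                         paste(group, collapse = ", "))
  out
}

#' Check a population map against a genotype matrix
#'
#' Samples in the map but absent from the genotype matrix are dropped with a
#' warning; genotype samples missing from the map raise an error.
#' @param pm a [population_map()].
#' @param gm a [genotype_matrix()].
#' @return The (possibly reduced) population map.
#' @export
pm_validate <- function(pm, gm) {
  extra <- setdiff(pm$sample, gm$samples)
  if (length(extra)) {
    warning("dropping popmap samples absent from genotypes: ",
            paste(extra, collapse = ", "))
    pm <- pm[!pm$sample %in% extra, , drop = FALSE]
  }
  missing <- setdiff(gm$samples, pm$sample)
  if (length(missing))
    stop("genotype samples missing from population map: ",
         paste(missing, collapse = ", "))
  pm
}

#' Taxon of each sample
#' @param pm a [population_map()].
#' @return Named character vector sample -> taxon.
#' @export
pm_taxon_of_sample <- function(pm) setNames(pm$taxon, pm$sample)

window_frame <- function(chrom, start, end, kind, label) {
  stopifnot(all(start <= end))
  data.frame(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), kind = rep_len(kind, length(chrom)),
             label = as.character(label), stringsAsFactors = FALSE)
}
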