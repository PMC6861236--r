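#' Call empirical outlier windows for one metric
#'
#' Selective-sweep candidates are the windows at or above the empirical
#' `quantile` (default the 99th percentile, i.e. 1% outliers) of a metric's
#' distribution over windows with a finite value; ties at the threshold are
#' all included.
#'
#' @param scan_table a scan table from [scan_windows()] (or any data.frame
#'   with a `label` column and the metric column).
#' @param metric column name: one of `afd`, `dxy`, `fst`, `rho`,
#'   `fixed_diff`.
#' @param quantile empirical quantile defining outliers (default 0.99).
#' @param scan_id identifier stored with the set.
#' @return An `outlier_set`: list with `scan_id`, `metric`, `quantile`,
#'   `threshold`, `windows` (labels at/above threshold) and `universe`
#'   (labels with a finite metric).
#' @export
call_outliers <- function(scan_table, metric, quantile = 0.99,
                          scan_id = metric) {
  x <- scan_table[[metric]]
  if (is.null(x)) stop("no such metric column: ", metric)
  fin <- is.finite(x)
  if (!any(fin)) stop("metric ", metric, " has no finite values")
  if (sum(fin) < 100 && quantile >= 0.99)
    warning("fewer than 100 finite windows; the ", quantile,
            " quantile is poorly resolved")
  xs <- x[fin]
  if (max(xs) == min(xs))
    warning("constant metric: every window ties at the threshold")
  thr <- stats::quantile(xs, quantile, names = FALSE, type = 7)
  structure(list(scan_id = scan_id, metric = metric, quantile = quantile,
                 threshold = thr,
                 windows = scan_table$label[fin][xs >= thr],
                 universe = scan_table$label[fin]),
            class = "outlier_set")
}

#' @export
print.outlier_set <- function(x, ...) {
  cat(sprintf("outlier_set [%s/%s]: %d of %d windows at quantile %.3g (threshold %.4g)\n",
              x$scan_id, x$metric, length(x$windows), length(x$universe),
              x$quantile, x$threshold))
  invisible(x)
}

#' Combine outlier sets across metrics of one scan
#'
#' Default mode `union`: a window is an outlier if extreme in any metric.
#'
#' @param outlier_sets list of `outlier_set`s over the same window universe.
#' @param mode `"union"` or `"intersection"`.
#' @return An `outlier_set` with metric `"combined"`.
#' @export
combine_metrics <- function(outlier_sets, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  stopifnot(length(outlier_sets) >= 1)
  uni <- outlier_sets[[1]]$universe
  for (s in outlier_sets)
    if (!setequal(s$universe, uni))
      stop("outlier sets have mismatched window universes")
  w <- outlier_sets[[1]]$windows
  for (s in outlier_sets[-1])
    w <- if (mode == "union") union(w, s$windows) else intersect(w, s$windows)
  structure(list(scan_id = outlier_sets[[1]]$scan_id, metric = "combined",
                 quantile = outlier_sets[[1]]$quantile, threshold = NA_real_,
                 windows = sort(w), universe = uni),
            class = "outlier_set")
}

#' Overlap of outlier sets from two independent scans
#'
#' Restricted to the common universe (windows with a finite metric in both
#' scans), so that the permutation null has a common support.
#'
#' @param outA,outB `outlier_set`s.
#' @return List: `windows` (sorted overlap labels), `universe`, and the
#'   restricted set sizes `sizeA`, `sizeB`.
#' @export
scan_overlap <- function(outA, outB) {
  uni <- intersect(outA$universe, outB$universe)
  if (!length(uni)) stop("empty common window universe")
  a <- intersect(outA$windows, uni)
  b <- intersect(outB$windows, uni)
  list(windows = sort(intersect(a, b)), universe = sort(uni),
       sizeA = length(a), sizeB = length(b))
}

#' Permutation test for outlier-set overlap
#'
#' Draws two uniform random label subsets of the observed sizes from the
#' common universe and counts how often their overlap reaches the observed
#' one; `p = (1 + #{perm >= obs}) / (n_perm + 1)` (never exactly zero).
#' Matches the hypergeometric tail in distribution; kept as an explicit
#' permutation so the hypergeometric closed form stays available as an
#' independent oracle.
#'
#' @param universe_size number of windows in the common universe.
#' @param sizeA,sizeB outlier-set sizes (each <= `universe_size`).
#' @param observed observed overlap count (<= `min(sizeA, sizeB)`).
#' @param n_perm number of permutations (>= 999).
#' @param seed integer seed for reproducibility.
#' @return An `overlap_result` list: sizes, universe, observed, `p_value`,
#'   `n_perm`, `seed`, and the vector of permuted overlap counts.
#' @export
overlap_permutation_test <- function(universe_size, sizeA, sizeB, observed,
                                     n_perm = 9999, seed = 1) {
  stopifnot(sizeA <= universe_size, sizeB <= universe_size, n_perm >= 999)
  if (observed > min(sizeA, sizeB))
    stop("observed overlap exceeds the smaller set size")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    a <- sample.int(universe_size, sizeA)
    b <- sample.int(universe_size, sizeB)
    sum(match(a, b, nomatch = 0L) > 0L)
  }, integer(1))
  p <- (1 + sum(perm >= observed)) / (n_perm + 1)
  structure(list(universe_size = universe_size, sizeA = sizeA, sizeB = sizeB,
                 observed = observed, p_value = p, n_perm = n_perm,
                 seed = seed, perm_overlaps = perm),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap_result: %d observed (sets %d & %d of %d); p = %.4g (%d permutations, seed %d)\n",
    x$observed, x$sizeA, x$sizeB, x$universe_size, x$p_value, x$n_perm,
    x$seed))
  invisible(x)
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream
.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
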