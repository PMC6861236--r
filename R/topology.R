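#' Enumerate all rooted taxon topologies
#'
#' All distinct rooted binary topologies of the ingroup taxa, with the
#' outgroup attached at the root; four ingroup taxa give the fifteen
#' possible rooted taxon topologies ((2n-3)!! in general). Topology ids are
#' assigned by sorting a canonical newick-style key, so they are stable and
#' independent of enumeration order.
#'
#' @param ingroup_taxa character vector of ingroup taxon names (>= 2,
#'   distinct).
#' @param outgroup outgroup taxon name.
#' @return data.frame of class `taxon_topologies`: `id`, `key` (canonical
#'   ingroup key), `newick` (rooted, including outgroup), plus the taxa as
#'   attributes.
#' @export
enumerate_topologies <- function(ingroup_taxa = TAXA[1:4],
                                 outgroup = "outgroup") {
  taxa <- c(ingroup_taxa, outgroup)
  if (anyDuplicated(taxa)) stop("duplicate taxon names")
  stopifnot(length(ingroup_taxa) >= 2)
  trees <- list(ingroup_taxa[1])
  for (lf in ingroup_taxa[-1])
    trees <- unlist(lapply(trees, attach_on_every_edge, lf = lf),
                    recursive = FALSE)
  keys <- vapply(trees, topo_key, character(1))
  stopifnot(!anyDuplicated(keys))
  ord <- order(keys)
  out <- data.frame(id = seq_along(keys), key = keys[ord],
                    newick = paste0("(", keys[ord], ",", outgroup, ");"),
                    stringsAsFactors = FALSE)
  attr(out, "ingroup") <- ingroup_taxa
  attr(out, "outgroup") <- outgroup
  attr(out, "trees") <- trees[ord]
  class(out) <- c("taxon_topologies", "data.frame")
  out
}

# attach leaf lf on every edge of nested-list tree tr (including above the
# root); enumerates all rooted binary shapes
attach_on_every_edge <- function(tr, lf) {
  res <- list(list(tr, lf))
  if (is.list(tr)) {
    for (i in 1:2) {
      for (sub in attach_on_every_edge(tr[[i]], lf)) {
        nt <- tr
        nt[[i]] <- sub
        res <- c(res, list(nt))
      }
    }
  }
  res
}

topo_key <- function(tr) {
  if (!is.list(tr)) return(tr)
  ks <- sort(c(topo_key(tr[[1]]), topo_key(tr[[2]])))
  paste0("(", ks[1], ",", ks[2], ")")
}

topo_clades <- function(tr) {
  if (!is.list(tr)) return(list(tr))
  l <- topo_clades(tr[[1]]); r <- topo_clades(tr[[2]])
  c(l, r, list(sort(c(l[[length(l)]], r[[length(r)]]))))
}

#' Classify the fifteen topologies into interpretation classes
#'
#' With ingroup taxa (lyrata2x, lyrata4x, arenosa2x, arenosa4x): the single
#' species topology groups conspecifics as sisters; introgression-class
#' topologies contain the clade grouping the tetraploids of the two species;
#' ILS-class topologies pair a diploid of one species with the tetraploid of
#' the other (and are not introgression-classified); the remainder are
#' `other`. Cardinalities are 1 + 3 + 5 + 6 = 15.
#'
#' @param topologies a `taxon_topologies` table over the default taxa (or a
#'   compatible renaming given via the arguments).
#' @param lyr2,lyr4,are2,are4 taxon names playing the diploid/tetraploid
#'   roles of the two species.
#' @return Factor of classes, one per topology id, levels
#'   `species`, `introgression`, `ILS`, `other`.
#' @export
classify_topologies <- function(topologies, lyr2 = "lyrata2x",
                                lyr4 = "lyrata4x", are2 = "arenosa2x",
                                are4 = "arenosa4x") {
  trees <- attr(topologies, "trees")
  pk <- sort(c(key_of_pair(lyr2, lyr4), key_of_pair(are2, are4)))
  species_key <- paste0("(", pk[1], ",", pk[2], ")")
  has_clade <- function(tr, set) {
    any(vapply(topo_clades(tr), function(cl) identical(cl, sort(set)),
               logical(1)))
  }
  cls <- vapply(seq_len(nrow(topologies)), function(i) {
    tr <- trees[[i]]
    if (identical(topologies$key[i], species_key)) return("species")
    if (has_clade(tr, c(lyr4, are4))) return("introgression")
    if (has_clade(tr, c(are2, lyr4)) || has_clade(tr, c(lyr2, are4)))
      return("ILS")
    "other"
  }, character(1))
  factor(cls, levels = c("species", "introgression", "ILS", "other"))
}

key_of_pair <- function(a, b) {
  s <- sort(c(a, b))
  paste0("(", s[1], ",", s[2], ")")
}

#' Collapse same-taxon clades of a window genealogy
#'
#' Iteratively collapses every maximal clade whose tips all belong to one
#' taxon into a single tip carrying the clade's tip count as a
#' multiplicity. Topology weighting is invariant under this simplification
#' (any tip of a monotaxon clade induces the same pruned topology), while
#' the number of distinct haplotype combinations to evaluate drops to the
#' product over taxa of the remaining tip counts.
#'
#' @param genealogy a `phylo` tree (tips = haplotypes).
#' @param taxon_map named character vector tip label -> taxon (or NULL to
#'   use the tree's `taxa` attribute).
#' @return A `simplified_tree`: list with `tree` (collapsed `phylo`),
#'   `taxa` (tip -> taxon), `mult` (tip -> multiplicity), `n_comb`
#'   (distinct combinations) and `n_total` (multiplicity-weighted
#'   combinations).
#' @export
simplify_tree <- function(genealogy, taxon_map = NULL) {
  if (is.null(taxon_map)) taxon_map <- attr(genealogy, "taxa")
  tr <- genealogy
  taxa <- taxon_map[tr$tip.label]
  if (anyNA(taxa)) stop("unmapped tip(s): ",
                        paste(tr$tip.label[is.na(taxa)], collapse = ", "))
  n <- length(tr$tip.label)
  m <- tr$Nnode
  po <- ape::reorder.phylo(tr, "postorder")
  sets <- vector("list", n + m)
  for (i in seq_len(n)) sets[[i]] <- taxa[i]
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sets[[par]] <- unique(c(sets[[par]], sets[[ch]]))
  }
  pure <- vapply(sets, function(s) length(s) == 1L, logical(1))
  parent <- rep(NA_integer_, n + m)
  parent[po$edge[, 2]] <- po$edge[, 1]
  # maximal pure internal nodes: pure, parent impure (or absent)
  maximal <- which(pure & (is.na(parent) | !pure[parent]))
  drop <- character(0)
  mult <- setNames(rep(1L, n), tr$tip.label)
  for (nd in maximal) {
    if (nd <= n) next                      # single tip, nothing to collapse
    below <- tips_below(po, nd, n)
    keep1 <- tr$tip.label[below[1]]
    mult[keep1] <- length(below)
    drop <- c(drop, tr$tip.label[below[-1]])
  }
  tr2 <- if (length(drop)) ape::drop.tip(tr, drop) else tr
  mult <- mult[tr2$tip.label]
  taxa2 <- taxa[tr2$tip.label]
  per_taxon <- split(seq_along(taxa2), taxa2)
  structure(list(tree = tr2, taxa = taxa2, mult = mult,
                 n_comb = prod(vapply(per_taxon, length, numeric(1))),
                 n_total = prod(vapply(per_taxon, function(i)
                   sum(mult[i]), numeric(1)))),
            class = "simplified_tree")
}

tips_below <- function(po, node, n_tip) {
  res <- integer(0)
  stack <- node
  edge <- po$edge
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (nd <= n_tip) res <- c(res, nd) else
      stack <- c(stack, edge[edge[, 1] == nd, 2])
  }
  sort(res)
}

#' @export
print.simplified_tree <- function(x, ...) {
  cat(sprintf("simplified_tree: %d tips over %d taxa; %g distinct combinations (%g weighted)\n",
              length(x$taxa), length(unique(x$taxa)), x$n_comb, x$n_total))
  invisible(x)
}

# --- combo -> topology machinery -------------------------------------------
# Induced rooted 4-taxon topology of a chosen (a, b, c, d, o) tip combo,
# decided from integer edge-count distances on the (binary) tree via the
# four-point condition: (x,y) is a rooted cherry iff the quartets {x,y,z,o}
# and {x,y,w,o} both resolve as xy | .o. Two cherries = balanced topology,
# one cherry = caterpillar.

topo_setup <- function(st, ingroup, outgroup) {
  taxa <- st$taxa
  need <- c(ingroup, outgroup)
  miss <- setdiff(need, unique(taxa))
  if (length(miss)) stop("taxa absent from tree: ",
                         paste(miss, collapse = ", "))
  tr <- st$tree
  tr$edge.length <- rep(1, nrow(tr$edge))
  n <- length(tr$tip.label)
  D <- ape::dist.nodes(tr)[seq_len(n), seq_len(n)]
  storage.mode(D) <- "integer"
  tips_by <- lapply(need, function(tx) which(taxa == tx))
  names(tips_by) <- need
  list(D = D, tips_by = tips_by, mult = st$mult)
}

# id lookup tables from structural patterns to topology ids, on taxon ROLE
# positions 1..4 (the order of `ingroup`)
topo_id_tables <- function(topologies, ingroup) {
  key_bal <- function(x, y) {
    rest <- setdiff(1:4, c(x, y))
    k <- sort(c(key_of_pair(ingroup[x], ingroup[y]),
                key_of_pair(ingroup[rest[1]], ingroup[rest[2]])))
    paste0("(", k[1], ",", k[2], ")")
  }
  key_cat <- function(x, y, z, w) {
    k1 <- key_of_pair(ingroup[x], ingroup[y])
    k2 <- sort(c(k1, ingroup[z]))
    k2 <- paste0("(", k2[1], ",", k2[2], ")")
    k3 <- sort(c(k2, ingroup[w]))
    paste0("(", k3[1], ",", k3[2], ")")
  }
  prs <- combn(4, 2)
  bal <- integer(ncol(prs))
  cat_z1 <- cat_z2 <- integer(ncol(prs))
  for (p in seq_len(ncol(prs))) {
    x <- prs[1, p]; y <- prs[2, p]
    rest <- setdiff(1:4, c(x, y))
    bal[p] <- match(key_bal(x, y), topologies$key)
    cat_z1[p] <- match(key_cat(x, y, rest[1], rest[2]), topologies$key)
    cat_z2[p] <- match(key_cat(x, y, rest[2], rest[1]), topologies$key)
  }
  list(pairs = prs, bal = bal, cat_z1 = cat_z1, cat_z2 = cat_z2)
}

# vectorised over combos: tip index vectors a,b,c,d (role order) and o
combo_topology_ids <- function(D, a, b, c_, d, o, tables) {
  roles <- cbind(a, b, c_, d)
  pairing1 <- function(i, j, k, l) {
    s1 <- D[cbind(i, j)] + D[cbind(k, l)]
    s2 <- D[cbind(i, k)] + D[cbind(j, l)]
    s3 <- D[cbind(i, l)] + D[cbind(j, k)]
    s1 < s2 & s1 < s3
  }
  prs <- tables$pairs
  nc <- length(a)
  cherry <- matrix(FALSE, nc, ncol(prs))
  zfirst <- matrix(FALSE, nc, ncol(prs))
  for (p in seq_len(ncol(prs))) {
    x <- roles[, prs[1, p]]; y <- roles[, prs[2, p]]
    rest <- setdiff(1:4, prs[, p])
    z <- roles[, rest[1]]; w <- roles[, rest[2]]
    cherry[, p] <- pairing1(x, y, z, o) & pairing1(x, y, w, o)
    zfirst[, p] <- pairing1(x, z, w, o)
  }
  nch <- rowSums(cherry)
  ids <- integer(nc)
  balr <- which(nch == 2L)
  if (length(balr)) {
    p_first <- max.col(cherry[balr, , drop = FALSE], ties.method = "first")
    ids[balr] <- tables$bal[p_first]
  }
  catr <- which(nch == 1L)
  if (length(catr)) {
    p <- max.col(cherry[catr, , drop = FALSE], ties.method = "first")
    zf <- zfirst[cbind(catr, p)]
    ids[catr] <- ifelse(zf, tables$cat_z1[p], tables$cat_z2[p])
  }
  if (any(nch != 1L & nch != 2L))
    stop("unresolved combo topology (non-binary tree?)")
  ids
}

#' Exact topology weighting of a simplified window genealogy
#'
#' Iterates over every distinct combination of one haplotype tip per taxon
#' (weighted by the collapsed multiplicities), prunes the genealogy to the
#' five chosen tips, roots it at the outgroup tip and matches the induced
#' rooted ingroup topology. Weights are matched multiplicity mass over the
#' total and sum to 1 exactly.
#'
#' @param simplified a [simplify_tree()] result (or a `phylo`, which is
#'   simplified first).
#' @param topologies a [enumerate_topologies()] table (default the standard
#'   five-taxon set).
#' @param exact_threshold refuse (deferring to [sampled_weighting()]) when
#'   the number of distinct combinations exceeds this (default 2000).
#' @return A `weighting_result`: list with `weights` (named vector over
#'   topology ids), `mode = "exact"`, `n_comb`, `n_total`.
#' @export
exact_weighting <- function(simplified, topologies = NULL,
                            exact_threshold = 2000) {
  if (inherits(simplified, "phylo"))
    simplified <- simplify_tree(simplified)
  if (is.null(topologies)) topologies <- enumerate_topologies()
  ingroup <- attr(topologies, "ingroup")
  outgroup <- attr(topologies, "outgroup")
  if (simplified$n_comb > exact_threshold)
    stop("combination count ", simplified$n_comb, " exceeds exact threshold ",
         exact_threshold, "; use sampled_weighting")
  su <- topo_setup(simplified, ingroup, outgroup)
  tables <- topo_id_tables(topologies, ingroup)
  grid <- as.matrix(expand.grid(c(lapply(ingroup, function(tx)
    su$tips_by[[tx]]), list(su$tips_by[[outgroup]]))))
  ids <- combo_topology_ids(su$D, grid[, 1], grid[, 2], grid[, 3],
                            grid[, 4], grid[, 5], tables)
  w <- su$mult[grid[, 1]] * su$mult[grid[, 2]] * su$mult[grid[, 3]] *
    su$mult[grid[, 4]] * su$mult[grid[, 5]]
  counts <- vapply(seq_len(nrow(topologies)), function(t)
    sum(w[ids == t]), numeric(1))
  weights <- counts / sum(counts)
  names(weights) <- topologies$id
  structure(list(weights = weights, mode = "exact",
                 n_comb = simplified$n_comb, n_total = sum(w),
                 n_samples = NA_integer_, ci_halfwidth = NA_real_,
                 seed = NA_integer_),
            class = "weighting_result")
}

#' Monte-Carlo topology weighting with a Wilson-interval stopping rule
#'
#' Samples haplotype combinations uniformly (multiplicity-weighted, with
#' replacement) in batches, and stops once the 95% Wilson confidence
#' interval half-width of every topology weighting falls below `ci_target`
#' (the sampling rule used when a window tree cannot be simplified to a
#' tractable number of combinations).
#'
#' @param simplified a [simplify_tree()] result (or a `phylo`).
#' @param topologies a [enumerate_topologies()] table.
#' @param ci_target stopping bound on all CI half-widths (default 0.05).
#' @param conf confidence level (default 0.95).
#' @param batch combinations sampled between interval checks (default 100).
#' @param seed integer seed (reproducible estimates).
#' @param max_samples hard cap on draws.
#' @return A `weighting_result` with `mode = "sampled"`, `n_samples` and
#'   per-topology `ci_halfwidth`.
#' @export
sampled_weighting <- function(simplified, topologies = NULL,
                              ci_target = 0.05, conf = 0.95, batch = 100,
                              seed = 1, max_samples = 1e6) {
  if (inherits(simplified, "phylo"))
    simplified <- simplify_tree(simplified)
  if (is.null(topologies)) topologies <- enumerate_topologies()
  ingroup <- attr(topologies, "ingroup")
  outgroup <- attr(topologies, "outgroup")
  su <- topo_setup(simplified, ingroup, outgroup)
  tables <- topo_id_tables(topologies, ingroup)
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(seed)
  k <- numeric(nrow(topologies))
  n <- 0L
  draw_tip <- function(tx, m) {
    tips <- su$tips_by[[tx]]
    if (length(tips) == 1L) rep(tips, m) else
      sample(tips, m, replace = TRUE, prob = su$mult[tips])
  }
  repeat {
    a <- draw_tip(ingroup[1], batch); b <- draw_tip(ingroup[2], batch)
    c_ <- draw_tip(ingroup[3], batch); d <- draw_tip(ingroup[4], batch)
    o <- draw_tip(outgroup, batch)
    ids <- combo_topology_ids(su$D, a, b, c_, d, o, tables)
    k <- k + tabulate(ids, nbins = nrow(topologies))
    n <- n + batch
    hw <- vapply(k, function(ki) {
      ci <- wilson_interval(ki, n, conf)
      (ci[2] - ci[1]) / 2
    }, numeric(1))
    if (all(hw < ci_target) || n >= max_samples) break
  }
  weights <- k / n
  names(weights) <- topologies$id
  structure(list(weights = weights, mode = "sampled",
                 n_comb = simplified$n_comb, n_total = simplified$n_total,
                 n_samples = n, ci_halfwidth = hw, seed = seed),
            class = "weighting_result")
}

#' @export
print.weighting_result <- function(x, ...) {
  cat(sprintf("weighting_result (%s): %g combinations%s\n", x$mode,
              x$n_comb,
              if (x$mode == "sampled")
                sprintf(", %d samples (max CI half-width %.3f)",
                        x$n_samples, max(x$ci_halfwidth)) else ""))
  top <- sort(x$weights, decreasing = TRUE)
  top <- top[top > 0]
  cat("  top weights:",
      paste(sprintf("T%s=%.3f", names(head(top, 4)), head(top, 4)),
            collapse = " "), "\n")
  invisible(x)
}

#' Topology weighting of one window tree (exact or sampled)
#'
#' Simplifies the genealogy, then computes weightings exactly when at most
#' `exact_threshold` distinct haplotype combinations remain and by
#' Monte-Carlo sampling otherwise.
#'
#' @inheritParams exact_weighting
#' @inheritParams sampled_weighting
#' @param genealogy a `phylo` with a `taxa` attribute, or pass `taxon_map`.
#' @param taxon_map named tip -> taxon vector.
#' @return A `weighting_result`.
#' @export
topology_weighting <- function(genealogy, taxon_map = NULL,
                               topologies = NULL, exact_threshold = 2000,
                               ci_target = 0.05, conf = 0.95, seed = 1) {
  st <- simplify_tree(genealogy, taxon_map)
  if (st$n_comb <= exact_threshold)
    exact_weighting(st, topologies, exact_threshold)
  else
    sampled_weighting(st, topologies, ci_target = ci_target, conf = conf,
                      seed = seed)
}

#' Wilson score interval for a binomial proportion
#'
#' @param k successes (0..n).
#' @param n trials (>= 1).
#' @param conf confidence level (default 0.95).
#' @return `c(lo, hi)`.
#' @export
wilson_interval <- function(k, n, conf = 0.95) {
  if (n < 1) stop("n must be >= 1")
  stopifnot(k >= 0, k <= n)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  centre <- (k + z^2 / 2) / (n + z^2)
  half <- z / (n + z^2) * sqrt(k * (n - k) / n + z^2 / 4)
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}

#' Independent brute-force topology weighting (testing oracle)
#'
#' Enumerates every combination of one original tip per taxon and, for each,
#' prunes the tree with `ape::keep.tip`, roots it on the chosen outgroup tip
#' and reads the induced topology by recursive canonical labelling --
#' machinery entirely disjoint from [exact_weighting()]'s distance-based
#' matching, so the two can check each other.
#'
#' @param genealogy a binary `phylo`.
#' @param taxon_map named tip -> taxon vector (or `taxa` attribute).
#' @param topologies a [enumerate_topologies()] table.
#' @return Named weight vector over topology ids (sums to 1).
#' @export
weighting_bruteforce <- function(genealogy, taxon_map = NULL,
                                 topologies = NULL) {
  if (is.null(taxon_map)) taxon_map <- attr(genealogy, "taxa")
  if (is.null(topologies)) topologies <- enumerate_topologies()
  ingroup <- attr(topologies, "ingroup")
  outgroup <- attr(topologies, "outgroup")
  taxa <- taxon_map[genealogy$tip.label]
  tips_by <- lapply(c(ingroup, outgroup), function(tx)
    genealogy$tip.label[which(taxa == tx)])
  grid <- expand.grid(tips_by, stringsAsFactors = FALSE)
  counts <- numeric(nrow(topologies))
  for (i in seq_len(nrow(grid))) {
    tips <- as.character(unlist(grid[i, ]))
    sub <- ape::keep.tip(genealogy, tips)
    key <- rooted_ingroup_key(sub, taxon_map, tips[5])
    id <- match(key, topologies$key)
    if (is.na(id)) stop("pruned topology did not match: ", key)
    counts[id] <- counts[id] + 1
  }
  w <- counts / sum(counts)
  names(w) <- topologies$id
  w
}

rooted_ingroup_key <- function(phy, taxon_map, outgroup_tip) {
  r <- ape::root(phy, outgroup = outgroup_tip, resolve.root = TRUE)
  n <- length(r$tip.label)
  children <- split(r$edge[, 2], r$edge[, 1])
  key_of_node <- function(nd) {
    if (nd <= n) return(unname(taxon_map[r$tip.label[nd]]))
    ks <- sort(vapply(children[[as.character(nd)]], key_of_node,
                      character(1)))
    paste0("(", paste(ks, collapse = ","), ")")
  }
  root_nd <- setdiff(r$edge[, 1], r$edge[, 2])[1]
  kids <- children[[as.character(root_nd)]]
  og <- match(outgroup_tip, r$tip.label)
  in_kid <- kids[kids != og]
  if (length(in_kid) != 1L) stop("outgroup rooting failed")
  key_of_node(in_kid)
}

#' Per-window weighting table with class sums and peak calls
#'
#' Runs [topology_weighting()] over a list of window trees, sums weights by
#' interpretation class, and calls introgression peaks: contiguous runs of
#' windows whose introgression-class weight exceeds a threshold, merged into
#' one peak reported with its maximum-weight window as summit.
#'
#' @param trees list of window trees from [trees_for_windows()].
#' @param taxon_map optional named tip -> taxon vector applying to all
#'   windows (defaults to each tree's `taxa` attribute).
#' @param thresholds peak thresholds on the introgression-class weight
#'   (default `c(0.5, 0.7)`).
#' @param topologies,exact_threshold,ci_target passed through.
#' @param seed base seed; window `i` uses `seed + i` for sampled windows.
#' @return List: `table` (one row per window: mode, n_samples, weights
#'   `w<id>`, class sums), `peaks` (threshold, from, to, summit, summit
#'   weight), `classes` (topology class factor).
#' @export
weighting_profile <- function(trees, taxon_map = NULL,
                              thresholds = c(0.5, 0.7), topologies = NULL,
                              exact_threshold = 2000, ci_target = 0.05,
                              seed = 1) {
  if (is.null(topologies)) topologies <- enumerate_topologies()
  cls <- classify_topologies(topologies)
  rows <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    wr <- topology_weighting(trees[[i]], taxon_map, topologies,
                             exact_threshold, ci_target, seed = seed + i)
    csum <- tapply(wr$weights, cls, sum)
    rows[[i]] <- data.frame(window = names(trees)[i], mode = wr$mode,
                            n_samples = ifelse(is.na(wr$n_samples), 0L,
                                               wr$n_samples),
                            t(wr$weights),
                            species = csum[["species"]],
                            introgression = csum[["introgression"]],
                            ils = csum[["ILS"]], other = csum[["other"]],
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  names(tab)[4:(3 + nrow(topologies))] <- paste0("w", topologies$id)
  peaks <- do.call(rbind, lapply(thresholds, function(th) {
    above <- tab$introgression > th
    if (!any(above)) return(NULL)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    do.call(rbind, lapply(runs, function(ri) {
      i0 <- starts[ri]; i1 <- ends[ri]
      summit <- (i0:i1)[which.max(tab$introgression[i0:i1])]
      data.frame(threshold = th, from = tab$window[i0], to = tab$window[i1],
                 summit = tab$window[summit],
                 weight = tab$introgression[summit],
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(peaks))
    peaks <- data.frame(threshold = numeric(0), from = character(0),
                        to = character(0), summit = character(0),
                        weight = numeric(0))
  list(table = tab, peaks = peaks, classes = cls)
}
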