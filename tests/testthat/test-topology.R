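tt <- enumerate_topologies()
cls <- classify_topologies(tt)

test_that("topology enumeration counts follow (2n-3)!!", {
  expect_equal(nrow(tt), 15L)
  expect_false(anyDuplicated(tt$key) > 0)
  expect_equal(nrow(enumerate_topologies(c("a", "b", "c"), "o")), 3L)
  expect_equal(nrow(enumerate_topologies(c("a", "b"), "o")), 1L)
  expect_error(enumerate_topologies(c("a", "a", "b", "c"), "o"), "duplicate")
  # ids are stable under enumeration-order perturbation of the taxa
  tt2 <- enumerate_topologies(rev(TAXA[1:4]), "outgroup")
  expect_identical(tt2$key, tt$key)
})

test_that("interpretation classes partition 15 as 1 + 3 + 5 + 6", {
  expect_equal(as.vector(table(cls)), c(1L, 3L, 5L, 6L))
  sp <- tt$key[cls == "species"]
  expect_match(sp, "arenosa2x,arenosa4x")
  expect_match(sp, "lyrata2x,lyrata4x")
  # every introgression topology contains the tetraploid-tetraploid clade
  for (k in tt$key[cls == "introgression"])
    expect_true(grepl("arenosa4x,lyrata4x", k, fixed = TRUE))
})

test_that("taxon-sorted trees simplify to 5 tips and weight 1", {
  tr <- taxon_sorted_tree()
  st <- simplify_tree(tr)
  expect_equal(length(st$taxa), 5L)
  expect_equal(st$n_comb, 1)
  expect_equal(st$n_total, 4 * 8 * 4 * 8 * 2)
  w <- exact_weighting(st, tt)
  expect_equal(sum(w$weights), 1)
  expect_equal(max(w$weights), 1)
  expect_equal(as.character(cls[which.max(w$weights)]), "species")
  # one discordant haplotype prevents full collapse of its taxon
  tr2 <- tr
  sw <- c(which(attr(tr, "taxa")[tr$tip.label] == "lyrata4x")[1],
          which(attr(tr, "taxa")[tr$tip.label] == "arenosa4x")[1])
  taxa2 <- attr(tr, "taxa")
  taxa2[tr$tip.label[sw]] <- taxa2[tr$tip.label[rev(sw)]]
  st2 <- simplify_tree(tr2, taxa2)
  expect_gte(sum(st2$taxa == "lyrata4x"), 2L)
  expect_lt(exact_weighting(st2, tt)$weights[which.max(w$weights)], 1)
})

test_that("simplification leaves the weighting invariant (oracle check)", {
  for (seed in 1:8) {
    tr <- random_taxon_tree(c(lyrata2x = 4, lyrata4x = 4, arenosa2x = 4,
                              arenosa4x = 4, outgroup = 4), seed)
    w_exact <- exact_weighting(simplify_tree(tr), tt)$weights
    w_brute <- weighting_bruteforce(tr, topologies = tt)
    expect_equal(w_exact, w_brute, tolerance = 1e-12)
    expect_equal(sum(w_exact), 1)
  }
})

test_that("a migrant haplotype splits the weighting as hand-enumerated", {
  # taxa A..D two tips each; b1 is a cherry-mate of the A tips, b2 sits
  # inside the D cherry: 16 ingroup combinations, half see (A,B),(C,D),
  # half see (((B,D),C),A)
  nwk <- paste0("((((a1:1,b1:1):1,a2:2):2,((c1:1,c2:1):2,",
                "((d1:1,d2:1):1,b2:2):1):1):1,o:8);")
  tr <- ape::read.tree(text = nwk)
  taxa <- c(a1 = "lyrata2x", a2 = "lyrata2x", b1 = "lyrata4x",
            b2 = "lyrata4x", c1 = "arenosa2x", c2 = "arenosa2x",
            d1 = "arenosa4x", d2 = "arenosa4x", o = "outgroup")
  w <- exact_weighting(simplify_tree(tr, taxa), tt)$weights
  k_bal <- paste0("((arenosa2x,arenosa4x),(lyrata2x,lyrata4x))")
  k_cat <- "(((arenosa4x,lyrata4x),arenosa2x),lyrata2x)"
  expect_equal(unname(w[tt$id[tt$key == k_bal]]), 0.5)
  expect_equal(unname(w[tt$id[tt$key == k_cat]]), 0.5)
  expect_equal(sum(w), 1)
  expect_equal(w, weighting_bruteforce(tr, taxa, tt), tolerance = 1e-12)
})

test_that("exact mode defers to sampling above the combination threshold", {
  tr <- random_taxon_tree(c(lyrata2x = 7, lyrata4x = 7, arenosa2x = 7,
                            arenosa4x = 3, outgroup = 2), 5)
  st <- simplify_tree(tr)
  expect_gt(st$n_comb, 2000)
  expect_error(exact_weighting(st, tt), "exceeds")
  w <- topology_weighting(tr, topologies = tt, seed = 2)
  expect_equal(w$mode, "sampled")
  expect_true(all(w$ci_halfwidth < 0.05))
  expect_equal(sum(w$weights), 1)
})

test_that("sampled weighting is reproducible and CI-consistent with exact", {
  tr <- random_taxon_tree(c(lyrata2x = 7, lyrata4x = 7, arenosa2x = 7,
                            arenosa4x = 3, outgroup = 2), 11)
  st <- simplify_tree(tr)
  we <- exact_weighting(st, tt, exact_threshold = 1e6)$weights
  hits <- 0; total <- 0
  for (seed in 1:10) {
    ws <- sampled_weighting(st, tt, seed = seed)
    total <- total + length(we)
    hits <- hits + sum(abs(ws$weights - we) <= ws$ci_halfwidth + 1e-12)
  }
  expect_gte(hits / total, 0.95)
  w1 <- sampled_weighting(st, tt, seed = 3)
  w2 <- sampled_weighting(st, tt, seed = 3)
  expect_identical(w1$weights, w2$weights)
  expect_identical(w1$n_samples, w2$n_samples)
  # tighter target converges closer on average
  err1 <- mean(abs(sampled_weighting(st, tt, seed = 4)$weights - we))
  err2 <- mean(abs(sampled_weighting(st, tt, ci_target = 0.01,
                                     seed = 4)$weights - we))
  expect_lt(err2, err1 + 1e-9)
  # concordant trees stop at the first batch
  wc <- sampled_weighting(simplify_tree(taxon_sorted_tree()), tt, seed = 1)
  expect_equal(unname(max(wc$weights)), 1)
})

test_that("wilson_interval matches the closed form and its boundaries", {
  ref <- function(k, n, conf) {       # independent direct evaluation
    z <- qnorm(1 - (1 - conf) / 2)
    p <- k / n
    c((p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
        (1 + z^2 / n),
      (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
        (1 + z^2 / n))
  }
  for (case in list(c(5, 10), c(0, 7), c(7, 7), c(193, 1000))) {
    got <- wilson_interval(case[1], case[2], 0.95)
    expect_equal(unname(got), ref(case[1], case[2], 0.95), tolerance = 1e-9)
  }
  expect_equal(wilson_interval(8, 8)[["hi"]], 1)
  expect_equal(wilson_interval(0, 8)[["lo"]], 0)
  expect_error(wilson_interval(1, 0), ">= 1")
})

test_that("weightings are robust to within-sample slot permutation", {
  # permuting slot assignments within samples relabels tips inside
  # monotaxon clades: weight changes stay below the sampling CI target
  tr <- taxon_sorted_tree(c(lyrata2x = 4, lyrata4x = 8, arenosa2x = 4,
                            arenosa4x = 8, outgroup = 2))
  w0 <- exact_weighting(simplify_tree(tr), tt)$weights
  set.seed(3)
  taxa <- attr(tr, "taxa")
  for (r in 1:3) {
    tr2 <- tr
    for (tx in TAXA) {                 # shuffle tip labels within taxon
      tips <- which(taxa[tr$tip.label] == tx)
      tr2$tip.label[tips] <- sample(tr$tip.label[tips])
    }
    attr(tr2, "taxa") <- taxa[tr2$tip.label]
    w1 <- exact_weighting(simplify_tree(tr2), tt)$weights
    expect_lt(max(abs(w1 - w0)), 0.05)
  }
})

test_that("weighting_profile sums classes and calls nested peaks", {
  trees <- list()
  sorted <- taxon_sorted_tree()
  for (i in 1:6) trees[[sprintf("w%02d", i)]] <- sorted
  # make windows 3-4 introgressed: tetraploids of both species together
  mixed <- taxon_sorted_tree()
  taxa <- attr(mixed, "taxa")
  l4 <- names(taxa)[taxa == "lyrata4x"]
  a4 <- names(taxa)[taxa == "arenosa4x"]
  # relabel so the lyrata4x tips sit in the arenosa half of the tree:
  # ((lyrata2x, arenosa2x), (lyrata4x, arenosa4x)) -> introgression clade
  taxa2 <- taxa
  taxa2[names(taxa)[taxa == "arenosa2x"]] <- "lyrata4x"
  taxa2[l4] <- "arenosa2x"
  attr(mixed, "taxa") <- taxa2
  trees[["w03"]] <- mixed
  trees[["w04"]] <- mixed
  prof <- weighting_profile(trees, thresholds = c(0.5, 0.7), topologies = tt,
                            seed = 1)
  expect_equal(nrow(prof$table), 6L)
  expect_equal(prof$table$species[1], 1)
  expect_true(all(abs(rowSums(prof$table[, paste0("w", tt$id)]) - 1) < 1e-9))
  pk5 <- prof$peaks[prof$peaks$threshold == 0.5, ]
  pk7 <- prof$peaks[prof$peaks$threshold == 0.7, ]
  expect_equal(pk5$from, "w03"); expect_equal(pk5$to, "w04")
  # nested: every 0.7 peak window is inside a 0.5 peak
  expect_true(nrow(pk7) <= nrow(pk5))
})
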