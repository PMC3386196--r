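# NJ tree building, bootstrap support, and intraspecific lineage detection.

test_that("three-taxon NJ solves the branch-length equations exactly", {
  d <- matrix(c(0, 0.2, 0.3,
                0.2, 0, 0.4,
                0.3, 0.4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- nj_tree(d)
  tip_len <- setNames(tree$edge.length[tree$edge[, 2] <= 3],
                      tree$tip.label[tree$edge[tree$edge[, 2] <= 3, 2]])
  expect_equal(tip_len[c("a", "b", "c")], c(a = 0.05, b = 0.15, c = 0.25),
               tolerance = 1e-12)
})

test_that("NJ recovers an additive four-taxon tree and rejects NA entries", {
  gen <- ape::read.tree(text = "((a:0.10,b:0.20):0.05,(c:0.15,d:0.10):0.07);")
  d <- ape::cophenetic.phylo(gen)
  tree <- nj_tree(d)
  expect_equal(max(abs(ape::cophenetic.phylo(tree)[rownames(d), colnames(d)] -
                         d)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen), tree)), 0)

  d_na <- d
  d_na["a", "c"] <- d_na["c", "a"] <- NA
  expect_error(nj_tree(d_na), "undefined")
})

test_that("NJ on random additive matrices recovers topology and branch lengths", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(5:8, 1)
    gen <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.5))
    d <- ape::cophenetic.phylo(gen)
    tree <- nj_tree(d)
    expect_lt(max(abs(ape::cophenetic.phylo(tree)[rownames(d), colnames(d)] -
                        d)), 1e-9)
  }
})

test_that("degenerate all-equal distances still give a deterministic tree", {
  ids <- letters[1:4]
  d <- matrix(0.2, 4, 4, dimnames = list(ids, ids))
  diag(d) <- 0
  t1 <- nj_tree(d)
  t2 <- nj_tree(d)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length >= 0))
})

test_that("bootstrap support is high for a clean split and reproducible by seed", {
  set.seed(99)
  root <- random_acgt(600)
  anc_a <- evolve_sequence(root, 0.1)
  anc_b <- evolve_sequence(root, 0.1)
  rec <- make_records(
    c(vapply(1:3, function(i) evolve_sequence(anc_a, 0.0025), character(1)),
      vapply(1:3, function(i) evolve_sequence(anc_b, 0.0025), character(1))),
    species = rep(c("A", "B"), each = 3),
    ids = c("a1", "a2", "a3", "b1", "b2", "b3"))
  tree <- bootstrap_support(rec, replicates = 200, seed = 7)
  support <- as.numeric(tree$node.label)
  pp <- ape::prop.part(tree)
  target <- sort(c("b1", "b2", "b3"))
  split_idx <- which(vapply(pp, function(cl) {
    tips <- sort(tree$tip.label[cl])
    identical(tips, target) || identical(tips, sort(setdiff(tree$tip.label,
                                                            target)))
  }, logical(1)))
  expect_true(length(split_idx) >= 1)
  expect_true(any(support[split_idx] >= 95))

  tree2 <- bootstrap_support(rec, replicates = 200, seed = 7)
  expect_identical(tree$node.label, tree2$node.label)

  one <- bootstrap_support(rec, replicates = 1, seed = 3)
  expect_true(all(as.numeric(one$node.label) %in% c(0, 100)))
})

test_that("bootstrap supports are invariant to leaf order given the seed", {
  set.seed(123)
  root <- random_acgt(300)
  rec <- make_records(
    vapply(1:6, function(i) evolve_sequence(root, 0.08), character(1)),
    species = rep(c("A", "B"), each = 3))
  t1 <- bootstrap_support(rec, replicates = 50, seed = 11)
  s1 <- setNames(attr(t1, "support_pct"),
                 vapply(ape::prop.part(t1), function(cl)
                   paste(sort(t1$tip.label[cl]), collapse = ","), character(1)))
  perm <- c(4, 2, 6, 1, 3, 5)
  t2 <- bootstrap_support(rec[perm, ], replicates = 50, seed = 11)
  s2 <- setNames(attr(t2, "support_pct"),
                 vapply(ape::prop.part(t2), function(cl)
                   paste(sort(t2$tip.label[cl]), collapse = ","), character(1)))
  shared <- intersect(names(s1), names(s2))
  expect_true(length(shared) >= 3)
  expect_equal(s1[shared], s2[shared])
})

test_that("lineage detection flags deep within-species splits", {
  # one species at mutual 0.3%: a single lineage, not flagged
  ids <- sprintf("x%d", 1:4)
  d <- matrix(0.3, 4, 4, dimnames = list(ids, ids)); diag(d) <- 0
  ls1 <- detect_lineages(pairs_from_matrix(d, rep("A", 4)))
  expect_equal(ls1$species$n_lineages, 1)
  expect_false(ls1$species$flagged)

  # two groups: within 0.4%, between 9.4%, segregated localities
  ids <- sprintf("m%d", 1:6)
  d <- matrix(9.4, 6, 6, dimnames = list(ids, ids))
  d[1:3, 1:3] <- 0.4; d[4:6, 4:6] <- 0.4; diag(d) <- 0
  loc <- c("NIT", "NIT", "NIT", "CIT", "SIT", "CIT")
  ls2 <- detect_lineages(pairs_from_matrix(d, rep("M_nattereri", 6), loc))
  expect_equal(ls2$species$n_lineages, 2)
  expect_true(ls2$species$flagged)
  expect_equal(ls2$between$mean_pct, 9.4)
  expect_equal(ls2$lineages$localities,
               list("NIT", c("CIT", "SIT")))
  expect_true(all(ls2$between$mean_pct >= ls2$lineages$mean_within_pct))
})

test_that("lineage partition matches the brute-force graph oracle", {
  for (seed in 1:10) {
    inst <- random_distance_instance(10, 2, seed = 400 + seed)
    cutoff <- runif(1, 0.5, 8)
    pr <- pairs_from_matrix(inst$d, inst$species)
    ls <- detect_lineages(pr, min_divergence_pct = cutoff)
    for (sp in unique(inst$species)) {
      sel <- inst$species == sp
      oracle <- brute_components(inst$d[sel, sel, drop = FALSE], cutoff)
      got <- ls$samples$lineage[match(rownames(inst$d)[sel],
                                      ls$samples$sample_id)]
      expect_equal(length(unique(got)), length(unique(oracle)))
      # same partition: equal label co-membership
      expect_equal(outer(got, got, "=="), outer(oracle, oracle, "=="),
                   ignore_attr = TRUE)
    }
  }
})

test_that("the lineage criterion bounds collapse and shatter the partition", {
  inst <- random_distance_instance(8, 1, seed = 77)
  pr <- pairs_from_matrix(inst$d, inst$species)
  off <- inst$d[upper.tri(inst$d)]
  above <- detect_lineages(pr, min_divergence_pct = max(off) + 0.1)
  expect_equal(above$species$n_lineages, 1)
  below <- detect_lineages(pr, min_divergence_pct = min(off) / 2)
  expect_equal(below$species$n_lineages, 8)

  expect_error(detect_lineages(pr, species = "not_there"), "absent")
})
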