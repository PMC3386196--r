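# Entity partitioning, rank assignment and query identification.

three_species_matrix <- function() {
  ids <- c("a1", "a2", "b1", "b2", "c1", "c2")
  d <- matrix(20, 6, 6, dimnames = list(ids, ids))
  d[1:2, 1:2] <- 0.5; d[3:4, 3:4] <- 0.5; d[5:6, 5:6] <- 0.5
  diag(d) <- 0
  list(d = d, species = rep(c("A", "B", "C"), each = 2))
}

test_that("well-separated species partition into one entity each", {
  inst <- three_species_matrix()
  pr <- pairs_from_matrix(inst$d, inst$species)
  ent <- partition_entities(pr, 4.4)
  expect_equal(length(unique(ent$entity_id)), 3)
  expect_equal(unname(table(ent$entity_id)), rep(2L, 3), ignore_attr = TRUE)
})

test_that("species below the OT merge into a single entity", {
  ids <- c("es1", "es2", "en1", "en2")
  d <- matrix(0.9, 4, 4, dimnames = list(ids, ids))
  d[1:2, 1:2] <- 0.3; d[3:4, 3:4] <- 0.3; diag(d) <- 0
  pr <- pairs_from_matrix(d, c("E_serotinus", "E_serotinus",
                               "E_nilsonii", "E_nilsonii"))
  ent <- partition_entities(pr, 4.4)
  expect_equal(length(unique(ent$entity_id)), 1)
  ranks <- assign_ranks(ent, pr, 4.4)
  expect_equal(ranks$rank, "MT_MOTU")
  expect_equal(ranks$species_set[[1]], c("E_nilsonii", "E_serotinus"))
})

test_that("entity partition matches the brute-force component oracle and is monotone in the cutoff", {
  for (seed in 1:10) {
    inst <- random_distance_instance(sample(6:20, 1), 4, seed = 900 + seed)
    pr <- pairs_from_matrix(inst$d, inst$species)
    cutoff <- runif(1, 0.5, 12)
    ent <- partition_entities(pr, cutoff)
    oracle <- brute_components(inst$d, cutoff)
    got <- as.integer(factor(ent$entity_id[match(rownames(inst$d),
                                                 ent$sample_id)]))
    expect_equal(outer(got, got, "=="), outer(oracle, oracle, "=="),
                 ignore_attr = TRUE)

    n_at <- vapply(c(1, 2, 5, 10, 20), function(t)
      length(unique(partition_entities(pr, t)$entity_id)), numeric(1))
    expect_true(all(diff(n_at) <= 0))
  }
})

test_that("a geographically segregated deep split yields IOTUs, overlap yields UCS", {
  ids <- c(sprintf("n%d", 1:3), sprintf("s%d", 1:3), "o1", "o2")
  d <- matrix(20, 8, 8, dimnames = list(ids, ids))
  d[1:3, 1:3] <- 0.4          # northern lineage
  d[4:6, 4:6] <- 0.4          # central/southern lineage
  d[1:3, 4:6] <- d[4:6, 1:3] <- 9.4
  d[7:8, 7:8] <- 0.5          # outgroup species, cohesive
  diag(d) <- 0
  species <- c(rep("M_nattereri", 6), "M_myotis", "M_myotis")

  # disjoint localities: both split entities become IOTUs
  loc <- c("NIT", "NIT", "NIT", "CIT", "SIT", "CIT", "NIT", "NIT")
  pr <- pairs_from_matrix(d, species, loc)
  ent <- partition_entities(pr, 4.4)
  expect_equal(length(unique(ent$entity_id)), 3)
  ranks <- assign_ranks(ent, pr, 4.4)
  nat <- ranks[vapply(ranks$species_set, identical, logical(1),
                      "M_nattereri"), ]
  expect_equal(nrow(nat), 2)
  expect_true(all(nat$rank == "IOTU"))
  expect_true(all(grepl("GEOGRAPHY_CONGRUENT", nat$evidence)))
  expect_true(all(grepl("DIVERGENCE_GT_OT", nat$evidence)))
  other <- ranks[vapply(ranks$species_set, identical, logical(1),
                        "M_myotis"), ]
  expect_equal(other$rank, "SPECIES_MATCH")

  # overlapping localities: the same split is only a UCS
  loc2 <- c("NIT", "CIT", "NIT", "CIT", "SIT", "CIT", "NIT", "NIT")
  pr2 <- pairs_from_matrix(d, species, loc2)
  ranks2 <- assign_ranks(partition_entities(pr2, 4.4), pr2, 4.4)
  nat2 <- ranks2[vapply(ranks2$species_set, identical, logical(1),
                        "M_nattereri"), ]
  expect_true(all(nat2$rank == "UCS"))
})

test_that("sub-threshold lineage structure inside a cohesive entity is a UCS", {
  # P. auritus pattern: three shallow lineages at ~2.5-2.6%, below the OT
  ids <- sprintf("p%d", 1:6)
  d <- matrix(2.55, 6, 6, dimnames = list(ids, ids))
  d[1:2, 1:2] <- 0.3; d[3:4, 3:4] <- 0.3; d[5:6, 5:6] <- 0.3
  diag(d) <- 0
  pr <- pairs_from_matrix(d, rep("P_auritus", 6),
                          c("NIT", "CIT", "NIT", "SIT", "CIT", "SIT"))
  ent <- partition_entities(pr, 4.4)
  expect_equal(length(unique(ent$entity_id)), 1)
  ranks <- assign_ranks(ent, pr, 4.4)
  expect_equal(ranks$rank, "UCS")
  expect_equal(ranks$evidence, "DIVERGENCE_2_TO_5")

  # a plain cohesive species stays a species match
  inst <- three_species_matrix()
  pr3 <- pairs_from_matrix(inst$d, inst$species)
  ranks3 <- assign_ranks(partition_entities(pr3, 4.4), pr3, 4.4)
  expect_true(all(ranks3$rank == "SPECIES_MATCH"))
  expect_equal(sort(unique(ranks3$rank %in% c(
    "SPECIES_MATCH", "MT_MOTU", "UCS", "IOTU", "MOTU_UNLABELLED"))), TRUE)
})

test_that("unknown-labelled samples are rejected unless routed to MOTU_UNLABELLED", {
  ids <- c("u1", "u2", "a1", "a2")
  d <- matrix(20, 4, 4, dimnames = list(ids, ids))
  d[1:2, 1:2] <- 0.5; d[3:4, 3:4] <- 0.5; diag(d) <- 0
  pr <- pairs_from_matrix(d, c("UNKNOWN", "UNKNOWN", "A", "A"))
  ent <- partition_entities(pr, 4.4)
  expect_error(assign_ranks(ent, pr, 4.4), "identify_queries")
  ranks <- assign_ranks(ent, pr, 4.4, unknown = "motu")
  expect_setequal(ranks$rank, c("MOTU_UNLABELLED", "SPECIES_MATCH"))
})

test_that("every entity receives exactly one rank", {
  for (seed in 1:5) {
    inst <- random_distance_instance(12, 3, seed = 700 + seed)
    pr <- pairs_from_matrix(inst$d, inst$species)
    ent <- partition_entities(pr, 5)
    ranks <- assign_ranks(ent, pr, 5)
    expect_equal(sort(ranks$entity_id), sort(unique(ent$entity_id)))
    expect_true(all(ranks$rank %in% c("SPECIES_MATCH", "MT_MOTU", "UCS",
                                      "IOTU", "MOTU_UNLABELLED")))
    expect_equal(sum(ranks$n_samples), nrow(ent))
  }
})

test_that("query identification assigns, abstains and flags ties correctly", {
  set.seed(55)
  root <- random_acgt(300)
  anc_a <- evolve_sequence(root, 0.1)
  anc_b <- evolve_sequence(root, 0.1)
  reference <- make_records(
    c(vapply(1:3, function(i) evolve_sequence(anc_a, 0.005), character(1)),
      vapply(1:3, function(i) evolve_sequence(anc_b, 0.005), character(1))),
    species = rep(c("A", "B"), each = 3),
    ids = sprintf("r%d", 1:6))

  # identical to a reference: assigned at distance zero
  q1 <- make_records(reference$sequence[1], species = "UNKNOWN", ids = "q1")
  out1 <- identify_queries(q1, reference, ot_pct = 4.4)
  expect_equal(out1$status, "ASSIGNED")
  expect_equal(out1$assigned_species, "A")
  expect_equal(out1$best_min_pct, 0)

  # far from everything: unassigned
  q2 <- make_records(random_acgt(300), species = "UNKNOWN", ids = "q2")
  out2 <- identify_queries(q2, reference, ot_pct = 4.4)
  expect_equal(out2$status, "UNASSIGNED")
  expect_true(is.na(out2$assigned_species))

  # two species both below OT within the tie margin: ambiguous
  twin_ref <- make_records(c(anc_a, anc_a), species = c("A", "B"),
                           ids = c("t1", "t2"))
  q3 <- make_records(evolve_sequence(anc_a, 0.01), species = "UNKNOWN",
                     ids = "q3")
  out3 <- identify_queries(q3, twin_ref, ot_pct = 4.4)
  expect_equal(out3$status, "AMBIGUOUS")

  expect_error(identify_queries(
    make_records("ACGT", ids = "q"), reference, 4.4), "alignment length")
})

test_that("identification never assigns a species at or above the OT", {
  set.seed(66)
  root <- random_acgt(200)
  for (rep in 1:5) {
    reference <- make_records(
      vapply(1:6, function(i) evolve_sequence(root, runif(1, 0, 0.3)),
             character(1)),
      species = rep(c("A", "B", "C"), each = 2))
    queries <- make_records(
      vapply(1:4, function(i) evolve_sequence(root, runif(1, 0, 0.3)),
             character(1)),
      species = "UNKNOWN", ids = sprintf("q%d", 1:4))
    ot <- runif(1, 0.5, 8)
    out <- identify_queries(queries, reference, ot)
    assigned <- out[out$status == "ASSIGNED", ]
    if (nrow(assigned) > 0) expect_true(all(assigned$best_min_pct < ot))
  }
})

test_that("the entity report round-trips ids and ranks through TSV", {
  inst <- three_species_matrix()
  pr <- pairs_from_matrix(inst$d, inst$species)
  ranks <- assign_ranks(partition_entities(pr, 4.4), pr, 4.4)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  entity_report(ranks, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$entity_id, ranks$entity_id)
  expect_equal(back$rank, ranks$rank)
  expect_equal(nrow(back), 3)
  expect_equal(sum(table(back$rank)), nrow(ranks))
})
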