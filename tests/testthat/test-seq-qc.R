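# Sequence I/O, metadata merging, trimming and the NUMT screen.

test_that("FASTA round-trip preserves records, headers parse field-wise", {
  rec <- make_records(c("ACGTACGT", "ACGTACGA", "ACGTACGC"),
                      species = c("Myotis_myotis", "UNKNOWN", "Myotis_blythii"),
                      locality = c("NIT", NA, "CIT"),
                      ids = c("a", "b", "c"))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_barcode_fasta(rec, fa)
  back <- read_barcode_fasta(fa)
  expect_equal(as.data.frame(back), as.data.frame(rec))

  # bare header: species defaults to UNKNOWN, locality missing
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT"), fa2)
  solo <- read_barcode_fasta(fa2)
  expect_equal(solo$species_label, "UNKNOWN")
  expect_true(is.na(solo$locality_group))
})

test_that("FASTA reader rejects duplicates and malformed input, warns on empty", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a|x|NIT", "ACGT", ">a|y|CIT", "ACGA"), fa)
  expect_error(read_barcode_fasta(fa), "Duplicate sample id")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACGT", ">a", "ACGT"), bad)
  expect_error(read_barcode_fasta(bad), "line 1")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), empty)
  expect_warning(out <- read_barcode_fasta(empty), "Empty")
  expect_equal(nrow(out), 0)
})

test_that("metadata merging overrides header values and validates its input", {
  rec <- make_records(c("ACGT", "ACGA"), species = c("UNKNOWN", "sp_b"),
                      ids = c("a", "b"))
  meta <- tibble::tibble(sample_id = "a", species_label = "Myotis_nattereri",
                         locality_group = "CIT")
  merged <- merge_metadata(rec, meta)
  expect_equal(merged$species_label, c("Myotis_nattereri", "sp_b"))
  expect_equal(merged$locality_group, c("CIT", NA))

  # empty table leaves records unchanged
  expect_equal(merge_metadata(rec, meta[0, ]), rec)

  # unseen id: warning, no record added
  expect_warning(out <- merge_metadata(rec, tibble::tibble(
    sample_id = "z", species_label = "x", locality_group = "NIT")),
    "unknown sample id")
  expect_equal(nrow(out), 2)

  # conflicting duplicates are an error
  expect_error(merge_metadata(rec, tibble::tibble(
    sample_id = c("a", "a"), species_label = c("x", "y"),
    locality_group = c("NIT", "CIT"))), "duplicate")
})

test_that("trimming yields the common window (658 -> 556 bp) and checks bounds", {
  set.seed(1)
  rec <- make_records(c(random_acgt(658), random_acgt(658)))
  trimmed <- trim_alignment(rec, 52, 607)
  expect_true(all(nchar(trimmed$sequence) == 556))
  expect_equal(trimmed$sequence[1], substr(rec$sequence[1], 52, 607))

  # full-length window is the identity
  expect_equal(trim_alignment(rec, 1, 658), rec)

  # window past the end names the offending record
  short <- make_records(c(random_acgt(658), random_acgt(100)),
                        ids = c("long", "short"))
  expect_error(trim_alignment(short, 52, 607), "short")
  expect_error(trim_alignment(rec, 10, 5), "start")
})

test_that("NUMT screen finds gaps and in-frame stops in the best frame", {
  set.seed(7)
  clean <- vapply(1:4, function(i) iotu:::random_coding_sequence(60),
                  character(1))
  rec <- make_records(clean)
  rep0 <- numt_screen(rec)
  expect_true(all(rep0$passed))
  expect_equal(attr(rep0, "frame_used"), 0L)

  # substitute codon 5 of record 2 with TAA; oracle = codon-table lookup
  seqs <- clean
  substr(seqs[2], 13, 15) <- "TAA"
  rec2 <- make_records(seqs)
  rep2 <- numt_screen(rec2)
  code <- Biostrings::getGeneticCode("2")
  oracle_stops <- function(s) {
    codons <- substring(s, seq(1, 58, by = 3), seq(3, 60, by = 3))
    sum(code[codons] == "*")
  }
  expect_equal(rep2$stop_codon_count, vapply(seqs, oracle_stops, numeric(1),
                                             USE.NAMES = FALSE))
  expect_false(rep2$passed[2])
  expect_true(all(rep2$passed[-2]))

  # gap characters fail the screen regardless of translation
  gappy <- clean
  substr(gappy[3], 30, 30) <- "-"
  rep3 <- numt_screen(make_records(gappy))
  expect_true(rep3$has_internal_gap[3])
  expect_false(rep3$passed[3])

  # frame choice minimises total stops; ties resolved to the lowest frame
  expect_equal(unname(which.min(attr(rep2, "stops_by_frame"))) - 1L,
               attr(rep2, "frame_used"))
  shifted <- make_records(paste0("C", substr(clean, 1, 59)))
  rep_s <- numt_screen(shifted)
  totals <- attr(rep_s, "stops_by_frame")
  expect_equal(unname(totals[rep_s$frame_used[1] + 1L]), min(totals))
})

test_that("base composition counts unambiguous bases only and is order-invariant", {
  expect_equal(
    base_composition(make_records("AAAA"))[, 1:4],
    tibble::tibble(pi_A = 1, pi_C = 0, pi_G = 0, pi_T = 0))
  bc <- base_composition(make_records("ACGT"))
  expect_equal(unlist(bc[, 1:4], use.names = FALSE), rep(0.25, 4))

  set.seed(3)
  rec <- make_records(replicate(5, random_acgt(90)))
  a <- base_composition(rec)
  b <- base_composition(rec[sample(5), ])
  expect_equal(a, b)
  expect_equal(a$pi_A + a$pi_C + a$pi_G + a$pi_T, 1, tolerance = 1e-12)

  # ambiguity codes are excluded; an all-ambiguous alignment is an error
  with_n <- make_records(c("ACGTNN", "ACGT--"))
  expect_equal(base_composition(with_n)$n_sites, 8)
  expect_error(base_composition(make_records("NNNN")), "unambiguous")
})
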