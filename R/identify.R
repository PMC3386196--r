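#' Identify unknown queries against a reference dataset
#'
#' For each query sequence, computes the minimum K2P distance to every
#' reference species. The query is assigned to the species with the
#' smallest minimum when that distance is below the OT and no second
#' species lies both below the OT and within `tie_margin` of the best;
#' with two or more species below the OT inside the tie margin the result
#' is `AMBIGUOUS`, and with no species below the OT it is `UNASSIGNED`.
#'
#' @param queries A barcode record tibble of query samples (labels are
#'   ignored).
#' @param reference A labelled barcode record tibble; `"UNKNOWN"` records
#'   are dropped.
#' @param ot_pct Identification threshold in percent (the OT calibrated on
#'   the reference dataset).
#' @param tie_margin Absolute margin in percent below which two candidate
#'   species are considered tied (default 0.3).
#' @return A tibble with one row per query: `sample_id`, `status`
#'   (`ASSIGNED` / `AMBIGUOUS` / `UNASSIGNED`), `assigned_species`,
#'   `best_species`, `best_min_pct`, `second_species`, `second_min_pct`,
#'   `ot_pct`, and `species_min_pct` (list column of named per-species
#'   minima).
#' @export
identify_queries <- function(queries, reference, ot_pct, tie_margin = 0.3) {
  queries <- validate_records(queries, arg = "queries")
  reference <- validate_records(reference, arg = "reference")
  reference <- filter(reference, .data$species_label != UNKNOWN_LABEL)
  if (nrow(reference) == 0) abort("Reference dataset has no labelled records.")
  if (nrow(queries) == 0) {
    return(tibble(sample_id = character(), status = character(),
                  assigned_species = character(), best_species = character(),
                  best_min_pct = numeric(), second_species = character(),
                  second_min_pct = numeric(), ot_pct = numeric(),
                  species_min_pct = list()))
  }
  if (length(unique(nchar(c(queries$sequence, reference$sequence)))) != 1) {
    abort("Queries and references must share the alignment length.")
  }
  combined <- bind_rows(queries[, c("sample_id", "sequence")],
                        reference[, c("sample_id", "sequence")])
  combined$sample_id <- make.unique(combined$sample_id)
  idx <- seq_index_matrix(combined)
  d <- k2p_matrix_from_counts(k2p_count_matrices(idx))
  nq <- nrow(queries)
  cross_pct <- 100 * d[seq_len(nq), nq + seq_len(nrow(reference)),
                       drop = FALSE]
  species <- sort(unique(reference$species_label))

  purrr::map_dfr(seq_len(nq), function(qi) {
    row <- cross_pct[qi, ]
    mins <- vapply(species, function(sp) {
      v <- row[reference$species_label == sp]
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else min(v)
    }, numeric(1))
    ord <- order(mins, species, na.last = TRUE)
    best_sp <- species[ord[1]]
    best <- unname(mins[ord[1]])
    second_sp <- if (length(ord) > 1) species[ord[2]] else NA_character_
    second <- if (length(ord) > 1) unname(mins[ord[2]]) else NA_real_
    below <- !is.na(mins) & mins < ot_pct
    tied_below <- !is.na(mins) & mins < ot_pct &
      (mins - best) < tie_margin
    if (is.na(best) || !below[ord[1]]) {
      status <- "UNASSIGNED"; assigned <- NA_character_
    } else if (sum(tied_below) >= 2) {
      status <- "AMBIGUOUS"; assigned <- NA_character_
    } else {
      status <- "ASSIGNED"; assigned <- best_sp
    }
    tibble(sample_id = queries$sample_id[qi], status = status,
           assigned_species = assigned, best_species = best_sp,
           best_min_pct = best, second_species = second_sp,
           second_min_pct = second, ot_pct = ot_pct,
           species_min_pct = list(mins))
  })
}

#' Write an assignment report to TSV
#'
#' @param assignments A tibble from [identify_queries()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  out <- select(assignments, -"species_min_pct")
  readr::write_tsv(out, path)
  invisible(path)
}
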