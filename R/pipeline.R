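# Full-analysis orchestration: QC -> distances -> OT calibration ->
# query identification -> entity partition -> lineage detection -> rank
# assignment -> report bundle.

#' Run the integrated barcoding pipeline
#'
#' Stage order mirrors the standard integrated-taxonomy workflow: (1) NUMT
#' screen and base composition; (2) build the reference dataset (labelled
#' records minus `exclusions`) and calibrate the OT on it; (3) identify
#' `"UNKNOWN"`-labelled records against the reference; (4) rebuild the
#' comprehensive dataset (all labelled records, plus — in two-pass mode —
#' the identified unknowns under their assigned labels); (5) partition it
#' into molecular entities at the OT; (6) detect divergent intraspecific
#' lineages; (7) assign taxonomic ranks; (8) optionally build a bootstrap
#' NJ tree; (9) write the report bundle.
#'
#' @param records A barcode record tibble (aligned; see
#'   [read_barcode_fasta()], [merge_metadata()], [trim_alignment()]).
#' @param exclusions Species labels excluded from the OT reference (still
#'   present in the comprehensive dataset), e.g. taxa with known deep
#'   intraspecific structure.
#' @param step OT grid step in percent.
#' @param tie_rule Tie rule for [optimum_threshold()].
#' @param ucs_low_pct,cryptic_pct Lineage criteria in percent (defaults 2
#'   and 5).
#' @param min_support Bootstrap support criterion for lineage flags.
#' @param bootstrap_replicates Bootstrap replicates for the NJ tree; 0
#'   skips tree building.
#' @param seed Seed for stochastic stages (bootstrap).
#' @param two_pass If `TRUE` (default), identified unknowns re-enter the
#'   comprehensive dataset under their assigned species labels;
#'   unassigned/ambiguous queries are always left out of the partition.
#' @param tie_margin Tie margin for [identify_queries()], percent.
#' @param genetic_code Genetic code id for the NUMT screen.
#' @param drop_failed_qc Drop records failing the NUMT screen with a
#'   warning (default) instead of aborting.
#' @param out_dir Optional directory for the report bundle
#'   (distance matrix, threshold curve, Newick tree, entity and
#'   assignment reports, QC report, run log).
#' @return An object of class `barcode_pipeline`: list with `qc`,
#'   `composition`, `ot_scan`, `ot`, `assignments`, `entities`, `ranks`,
#'   `lineages`, `tree`, `pairs`, `params`.
#' @export
run_pipeline <- function(records, exclusions = character(), step = 0.1,
                         tie_rule = c("lowest", "midpoint"),
                         ucs_low_pct = 2, cryptic_pct = 5,
                         min_support = 95, bootstrap_replicates = 0,
                         seed = 1, two_pass = TRUE, tie_margin = 0.3,
                         genetic_code = "2", drop_failed_qc = TRUE,
                         out_dir = NULL) {
  tie_rule <- match.arg(tie_rule)
  records <- validate_records(records, require_aligned = TRUE)
  params <- list(exclusions = exclusions, step = step, tie_rule = tie_rule,
                 ucs_low_pct = ucs_low_pct, cryptic_pct = cryptic_pct,
                 min_support = min_support,
                 bootstrap_replicates = bootstrap_replicates, seed = seed,
                 two_pass = two_pass, tie_margin = tie_margin,
                 genetic_code = genetic_code)

  # 1. QC
  qc <- tryCatch(numt_screen(records, genetic_code),
                 error = function(e) stage_abort("qc", e))
  if (any(!qc$passed)) {
    bad <- qc$sample_id[!qc$passed]
    if (!drop_failed_qc) {
      stage_abort("qc", simpleError(sprintf(
        "Records failing the NUMT screen: %s", paste(bad, collapse = ", "))))
    }
    warn(sprintf("Dropping %d record(s) failing the NUMT screen: %s",
                 length(bad), paste(bad, collapse = ", ")))
    records <- filter(records, !.data$sample_id %in% bad)
  }
  composition <- base_composition(records)

  labelled <- filter(records, .data$species_label != UNKNOWN_LABEL)
  unknowns <- filter(records, .data$species_label == UNKNOWN_LABEL)

  # 2. reference dataset and OT
  reference <- filter(labelled, !.data$species_label %in% exclusions)
  ref_pairs <- tryCatch(pairwise_k2p(reference),
                        error = function(e) stage_abort("distances", e))
  scan <- tryCatch(threshold_scan(ref_pairs, step = step),
                   error = function(e) stage_abort("threshold", e))
  ot <- optimum_threshold(scan, tie_rule = tie_rule)

  # 3. identify unknowns against the reference
  assignments <- if (nrow(unknowns) > 0) {
    tryCatch(identify_queries(unknowns, reference, ot$ot_pct, tie_margin),
             error = function(e) stage_abort("identification", e))
  } else {
    identify_queries(unknowns[0, ], reference, ot$ot_pct, tie_margin)
  }

  # 4. comprehensive dataset
  comprehensive <- labelled
  if (two_pass && nrow(assignments) > 0) {
    assigned <- filter(assignments, .data$status == "ASSIGNED")
    if (nrow(assigned) > 0) {
      relabelled <- unknowns |>
        filter(.data$sample_id %in% assigned$sample_id) |>
        mutate(species_label = assigned$assigned_species[
          match(.data$sample_id, assigned$sample_id)])
      comprehensive <- bind_rows(comprehensive, relabelled)
    }
  }

  # 5-7. partition, lineages, ranks
  comp_pairs <- tryCatch(pairwise_k2p(comprehensive),
                         error = function(e) stage_abort("distances", e))
  entities <- partition_entities(comp_pairs, ot$ot_pct)
  lineages <- detect_lineages(comp_pairs,
                              min_divergence_pct = ucs_low_pct,
                              min_support = min_support)
  ranks <- assign_ranks(entities, comp_pairs, ot$ot_pct,
                        ucs_low_pct = ucs_low_pct,
                        cryptic_pct = cryptic_pct)

  # 8. tree
  tree <- NULL
  if (bootstrap_replicates > 0) {
    tree <- tryCatch(
      bootstrap_support(comprehensive, bootstrap_replicates, seed = seed),
      error = function(e) stage_abort("tree", e))
    lineages <- detect_lineages(comp_pairs,
                                min_divergence_pct = ucs_low_pct,
                                tree = tree, min_support = min_support)
  }

  result <- structure(list(
    qc = qc, composition = composition, ot_scan = scan, ot = ot,
    assignments = assignments, entities = entities, ranks = ranks,
    lineages = lineages, tree = tree, pairs = comp_pairs,
    divergence = divergence_summary(comp_pairs),
    params = params,
    n_samples = nrow(records), n_reference = nrow(reference),
    n_unknowns = nrow(unknowns)
  ), class = "barcode_pipeline")

  if (!is.null(out_dir)) write_pipeline_bundle(result, comprehensive, out_dir)
  result
}

stage_abort <- function(stage, e) {
  abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                conditionMessage(e)))
}

write_pipeline_bundle <- function(result, comprehensive, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- k2p_matrix(comprehensive)
  dm <- as.data.frame(round(d, 6))
  dm <- cbind(sample_id = rownames(d), dm)
  readr::write_tsv(as_tibble(dm), file.path(out_dir, "distance_matrix.tsv"))
  write_error_curve(result$ot_scan, file.path(out_dir, "threshold_scan.tsv"))
  entity_report(result$ranks, file.path(out_dir, "entities.tsv"))
  write_qc_report(result$qc, file.path(out_dir, "qc_report.tsv"))
  if (nrow(result$assignments) > 0) {
    write_assignments(result$assignments,
                      file.path(out_dir, "assignments.tsv"))
  }
  if (!is.null(result$tree)) {
    ape::write.tree(result$tree, file.path(out_dir, "tree.nwk"))
  }
  p <- result$params
  log_lines <- c(
    sprintf("iotu version: %s",
            as.character(utils::packageVersion("iotu"))),
    sprintf("R version: %s", R.version.string),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("n_samples: %d", result$n_samples),
    sprintf("n_reference: %d", result$n_reference),
    sprintf("n_unknowns: %d", result$n_unknowns),
    sprintf("exclusions: %s",
            paste(p$exclusions, collapse = ",") %|empty|% "(none)"),
    sprintf("grid step (pct): %g", p$step),
    sprintf("tie rule: %s", p$tie_rule),
    sprintf("ucs_low_pct: %g", p$ucs_low_pct),
    sprintf("cryptic_pct: %g", p$cryptic_pct),
    sprintf("min_support: %g", p$min_support),
    sprintf("bootstrap replicates: %d", p$bootstrap_replicates),
    sprintf("seed: %d", p$seed),
    sprintf("two_pass: %s", p$two_pass),
    sprintf("tie_margin (pct): %g", p$tie_margin),
    sprintf("genetic code: %s", p$genetic_code),
    sprintf("OT (pct): %g", result$ot$ot_pct),
    sprintf("MCE (pct): %g", result$ot$mce_pct)
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

`%|empty|%` <- function(x, y) if (length(x) == 0 || !nzchar(x)) y else x

#' @export
print.barcode_pipeline <- function(x, ...) {
  cat("Integrated barcoding pipeline\n")
  cat(sprintf("  %d samples (%d reference, %d unknown queries)\n",
              x$n_samples, x$n_reference, x$n_unknowns))
  cat(sprintf("  OT = %.2f%%, MCE = %.3f%%\n", x$ot$ot_pct, x$ot$mce_pct))
  counts <- table(x$ranks$rank)
  cat(sprintf("  %d molecular entities: %s\n", nrow(x$ranks),
              paste(sprintf("%s=%d", names(counts), counts),
                    collapse = ", ")))
  if (nrow(x$assignments) > 0) {
    cat(sprintf("  queries: %d assigned, %d ambiguous, %d unassigned\n",
                sum(x$assignments$status == "ASSIGNED"),
                sum(x$assignments$status == "AMBIGUOUS"),
                sum(x$assignments$status == "UNASSIGNED")))
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `barcode_pipeline` object.
#' @param ... Unused.
#' @method glance barcode_pipeline
#' @export
glance.barcode_pipeline <- function(x, ...) {
  tibble(
    n_samples = x$n_samples, n_reference = x$n_reference,
    n_unknowns = x$n_unknowns,
    ot_pct = x$ot$ot_pct, mce_pct = x$ot$mce_pct,
    n_entities = nrow(x$ranks),
    n_species_match = sum(x$ranks$rank == "SPECIES_MATCH"),
    n_mt_motu = sum(x$ranks$rank == "MT_MOTU"),
    n_iotu = sum(x$ranks$rank == "IOTU"),
    n_ucs = sum(x$ranks$rank == "UCS"),
    n_assigned = sum(x$assignments$status == "ASSIGNED")
  )
}

#' Divergence histogram (barcode-gap plot)
#'
#' Overlaid histograms of intraspecific and interspecific pairwise K2P
#' divergence, optionally with the OT marked.
#'
#' @param pairs A pair table from [pairwise_k2p()].
#' @param ot Optional `ot_result`.
#' @param binwidth Histogram bin width in percent.
#' @return A ggplot object.
#' @export
plot_divergence <- function(pairs, ot = NULL, binwidth = 0.5) {
  dat <- filter(pairs, !is.na(.data$intraspecific),
                !is.na(.data$distance_pct)) |>
    mutate(comparison = ifelse(.data$intraspecific, "intraspecific",
                               "interspecific"))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$distance_pct,
                                         fill = .data$comparison)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6) +
    ggplot2::labs(x = "K2P distance (%)", y = "Pairs", fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(ot)) {
    p <- p + ggplot2::geom_vline(xintercept = ot$ot_pct,
                                 linetype = "dashed")
  }
  p
}
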