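# Divergent intraspecific lineage detection: within each nominal species,
# lineages are the single-linkage connected components obtained by joining
# samples whose K2P divergence falls below the criterion (default 2%). A
# species is flagged when it splits into >= 2 lineages and every
# between-lineage mean divergence exceeds the criterion.

#' Detect divergent intraspecific lineages
#'
#' @param pairs A pair table from [pairwise_k2p()].
#' @param min_divergence_pct Lineage criterion in percent (default 2):
#'   samples closer than this are linked into the same lineage.
#' @param tree Optional support tree from [bootstrap_support()]; each
#'   lineage is annotated with the support of its smallest containing
#'   clade.
#' @param min_support Bootstrap support (%) a lineage clade must reach for
#'   the `meets_support` flag (default 95). Lineages are reported at any
#'   support; the flag records whether the criterion is met.
#' @param species Optional subset of species to examine (default: all
#'   labelled species in `pairs`). Asking for a species absent from the
#'   pair table is an error.
#' @return An object of class `lineage_set`: list of tibbles
#'   `samples` (sample_id, species_label, locality_group, lineage),
#'   `lineages` (per lineage: size, mean internal divergence, locality
#'   profile, clade support), `between` (per within-species lineage pair:
#'   mean divergence, `meets_support`), and `species` (per species:
#'   `n_lineages`, `flagged`).
#' @export
detect_lineages <- function(pairs, min_divergence_pct = 2, tree = NULL,
                            min_support = 95, species = NULL) {
  if (min_divergence_pct <= 0) abort("`min_divergence_pct` must be > 0.")
  info <- pair_sample_info(pairs) |>
    filter(.data$species_label != UNKNOWN_LABEL)
  all_species <- sort(unique(info$species_label))
  if (is.null(species)) {
    species <- all_species
  } else {
    absent <- setdiff(species, all_species)
    if (length(absent) > 0) {
      abort(sprintf("Species absent from the pair table: %s.",
                    paste(absent, collapse = ", ")))
    }
  }

  samples_out <- list()
  lineage_out <- list()
  between_out <- list()
  species_out <- list()
  for (sp in species) {
    ids <- info$sample_id[info$species_label == sp]
    sp_pairs <- filter(pairs, .data$species_1 == sp, .data$species_2 == sp)
    edges <- filter(sp_pairs, !is.na(.data$distance_pct),
                    .data$distance_pct < min_divergence_pct)
    comp <- single_linkage_components(ids, edges[c("sample_1", "sample_2")])
    lineage_id <- sprintf("%s/L%d", sp, comp)
    loc <- info$locality_group[match(ids, info$sample_id)]
    samples_out[[sp]] <- tibble(sample_id = ids, species_label = sp,
                                locality_group = loc,
                                lineage = lineage_id)
    n_lin <- length(unique(comp))
    lin_tbl <- tibble(
      species_label = sp,
      lineage = sort(unique(lineage_id)),
    )
    lin_tbl <- lin_tbl |>
      mutate(
        members = purrr::map(.data$lineage, ~ids[lineage_id == .x]),
        n_samples = purrr::map_int(.data$members, length),
        mean_within_pct = purrr::map_dbl(.data$members, function(mem) {
          w <- filter(sp_pairs, .data$sample_1 %in% mem,
                      .data$sample_2 %in% mem, !is.na(.data$distance_pct))
          if (nrow(w) == 0) NA_real_ else mean(w$distance_pct)
        }),
        localities = purrr::map(.data$members, function(mem) {
          sort(unique(stats::na.omit(loc[match(mem, ids)])))
        }),
        support = purrr::map_dbl(.data$members, ~clade_support(tree, .x))
      )
    lineage_out[[sp]] <- lin_tbl

    lins <- lin_tbl$lineage
    if (n_lin >= 2) {
      combs <- utils::combn(lins, 2)
      bt <- purrr::map_dfr(seq_len(ncol(combs)), function(k) {
        a <- combs[1, k]; b <- combs[2, k]
        mem_a <- lin_tbl$members[[match(a, lins)]]
        mem_b <- lin_tbl$members[[match(b, lins)]]
        cross <- filter(sp_pairs,
                        (.data$sample_1 %in% mem_a & .data$sample_2 %in% mem_b) |
                          (.data$sample_1 %in% mem_b & .data$sample_2 %in% mem_a),
                        !is.na(.data$distance_pct))
        sup <- suppressWarnings(min(lin_tbl$support[match(c(a, b), lins)],
                                    na.rm = TRUE))
        if (!is.finite(sup)) sup <- NA_real_
        tibble(species_label = sp, lineage_a = a, lineage_b = b,
               mean_pct = if (nrow(cross)) mean(cross$distance_pct)
                          else NA_real_,
               min_support = sup,
               meets_support = !is.na(sup) & sup >= min_support)
      })
      between_out[[sp]] <- bt
      flagged <- all(bt$mean_pct > min_divergence_pct, na.rm = FALSE)
      flagged <- isTRUE(flagged)
    } else {
      flagged <- FALSE
    }
    species_out[[sp]] <- tibble(species_label = sp, n_lineages = n_lin,
                                flagged = flagged)
  }
  structure(list(
    samples = bind_rows(samples_out),
    lineages = bind_rows(lineage_out),
    between = if (length(between_out)) bind_rows(between_out) else
      tibble(species_label = character(), lineage_a = character(),
             lineage_b = character(), mean_pct = numeric(),
             min_support = numeric(), meets_support = logical()),
    species = bind_rows(species_out),
    min_divergence_pct = min_divergence_pct,
    min_support = min_support
  ), class = "lineage_set")
}

#' @export
print.lineage_set <- function(x, ...) {
  flagged <- x$species$species_label[x$species$flagged]
  cat(sprintf(
    "Lineage detection at %.1f%% K2P: %d species, %d flagged with divergent lineages\n",
    x$min_divergence_pct, nrow(x$species), length(flagged)))
  if (length(flagged) > 0) {
    cat("  flagged:", paste(flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname detect_lineages
#' @param x A `lineage_set`.
#' @param ... Unused.
#' @method tidy lineage_set
#' @export
tidy.lineage_set <- function(x, ...) x$samples

#' @rdname detect_lineages
#' @method glance lineage_set
#' @export
glance.lineage_set <- function(x, ...) {
  tibble(n_species = nrow(x$species),
         n_flagged = sum(x$species$flagged),
         min_divergence_pct = x$min_divergence_pct)
}
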