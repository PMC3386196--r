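# Molecular entity partitioning and taxonomic rank assignment.
#
# Entities are single-linkage connected components at the optimum
# threshold. Each entity is then ranked: a multi-species entity is an
# MT-MOTU (the marker fails to separate the nominal taxa); a species split
# across entities yields IOTUs when the sibling entities are geographically
# segregated (molecular + one more congruent character) and UCS otherwise;
# a cohesive single-species entity hiding sub-lineages above the lineage
# criterion but below the OT is a UCS; everything else is a species match.

#' Partition samples into molecular entities at a threshold
#'
#' Entities are the connected components of the graph joining samples whose
#' pairwise divergence is strictly below `ot_pct` (single linkage).
#' Undefined distances contribute no edge.
#'
#' @param pairs A pair table from [pairwise_k2p()].
#' @param ot_pct Threshold in percent (> 0), typically the OT from
#'   [optimum_threshold()].
#' @return A tibble with columns `sample_id`, `species_label`,
#'   `locality_group`, `entity_id` (entities numbered `E01`, `E02`, ... by
#'   first appearance); attribute `ot_pct`.
#' @export
partition_entities <- function(pairs, ot_pct) {
  if (!is.numeric(ot_pct) || ot_pct <= 0) abort("`ot_pct` must be > 0.")
  info <- pair_sample_info(pairs)
  edges <- filter(pairs, !is.na(.data$distance_pct),
                  .data$distance_pct < ot_pct)
  comp <- single_linkage_components(info$sample_id,
                                    edges[c("sample_1", "sample_2")])
  out <- info
  out$entity_id <- sprintf("E%02d", comp)
  attr(out, "ot_pct") <- ot_pct
  out
}

#' Assign taxonomic ranks to molecular entities
#'
#' Applies the rank rules in order: (1) an entity containing >= 2 nominal
#' species is an `MT_MOTU`; (2) when a nominal species is split across
#' >= 2 entities, each of its entities is an `IOTU` if its locality-group
#' set is disjoint from every sibling entity's set (geographic congruence)
#' and a `UCS` otherwise; (3) a single-species entity containing
#' sub-lineages whose between-lineage mean divergence lies above
#' `ucs_low_pct` (but which did not split at the OT) is a `UCS`, with
#' evidence `DIVERGENCE_2_TO_5` when all between-lineage means are at most
#' `cryptic_pct`; (4) otherwise the entity is a `SPECIES_MATCH`.
#'
#' `DCL` and `CCS` ranks require extra-molecular evidence (morphology,
#' formal description) outside this data model; they exist as valid values
#' of the `rank` column for manual override but are never auto-assigned.
#'
#' @param entities An entity partition from [partition_entities()].
#' @param pairs The pair table the partition was computed from.
#' @param ot_pct The threshold used for the partition (percent).
#' @param ucs_low_pct Lower lineage criterion in percent (default 2).
#' @param cryptic_pct Indicative cryptic-species cutoff in percent
#'   (default 5); must exceed `ucs_low_pct`.
#' @param unknown How to treat `"UNKNOWN"`-labelled samples: `"error"`
#'   (default; route them through [identify_queries()] first) or `"motu"`
#'   (entities consisting entirely of unknowns become `MOTU_UNLABELLED`).
#' @return A tibble with one row per entity: `entity_id`, `rank`,
#'   `n_samples`, `n_species`, `species` (collapsed label), `members`,
#'   `species_set`, `localities` (list columns), `evidence`
#'   (`;`-collapsed codes), `mean_internal_pct`, `max_internal_pct`.
#' @export
assign_ranks <- function(entities, pairs, ot_pct, ucs_low_pct = 2,
                         cryptic_pct = 5, unknown = c("error", "motu")) {
  unknown <- match.arg(unknown)
  if (!(ucs_low_pct < cryptic_pct)) {
    abort("`ucs_low_pct` must be smaller than `cryptic_pct`.")
  }
  has_unknown <- entities$species_label == UNKNOWN_LABEL
  if (any(has_unknown) && unknown == "error") {
    abort(paste("Unknown-labelled samples present; identify them with",
                "identify_queries() (or use unknown = \"motu\")."))
  }
  ids <- unique(entities$entity_id)

  # species -> set of entities it occurs in (rule 2 needs siblings)
  sp_entities <- entities |>
    filter(.data$species_label != UNKNOWN_LABEL) |>
    distinct(.data$species_label, .data$entity_id)

  entity_row <- function(eid) {
    mem <- entities[entities$entity_id == eid, ]
    species_set <- sort(unique(
      mem$species_label[mem$species_label != UNKNOWN_LABEL]))
    localities <- sort(unique(stats::na.omit(mem$locality_group)))
    internal <- filter(pairs, .data$sample_1 %in% mem$sample_id,
                       .data$sample_2 %in% mem$sample_id,
                       !is.na(.data$distance_pct))
    evidence <- character()
    if (length(species_set) == 0) {
      rank <- "MOTU_UNLABELLED"
    } else if (length(species_set) >= 2) {
      rank <- "MT_MOTU"
      evidence <- "MULTIPLE_NOMINAL_SPECIES"
    } else {
      sp <- species_set
      siblings <- setdiff(
        sp_entities$entity_id[sp_entities$species_label == sp], eid)
      if (length(siblings) > 0) {
        # the species is split across entities at the OT
        evidence <- "DIVERGENCE_GT_OT"
        sib_loc <- lapply(siblings, function(s) {
          m <- entities[entities$entity_id == s, ]
          unique(stats::na.omit(m$locality_group))
        })
        congruent <- length(localities) > 0 &&
          all(vapply(sib_loc,
                     function(l) length(intersect(l, localities)) == 0,
                     logical(1)))
        if (congruent) {
          rank <- "IOTU"
          evidence <- c(evidence, "GEOGRAPHY_CONGRUENT")
        } else {
          rank <- "UCS"
        }
      } else if (nrow(internal) == 0) {
        # a singleton (or pair-less) entity cannot hide sub-lineages
        rank <- "SPECIES_MATCH"
      } else {
        # cohesive entity: look for internal sub-lineages above ucs_low_pct
        sub <- detect_lineages(internal, min_divergence_pct = ucs_low_pct,
                               species = sp)
        sp_row <- sub$species[sub$species$species_label == sp, ]
        if (nrow(mem) >= 2 && sp_row$flagged) {
          rank <- "UCS"
          means <- sub$between$mean_pct
          evidence <- if (all(means <= cryptic_pct, na.rm = TRUE)) {
            "DIVERGENCE_2_TO_5"
          } else {
            "DIVERGENCE_GT_5"
          }
        } else {
          rank <- "SPECIES_MATCH"
        }
      }
    }
    tibble(
      entity_id = eid,
      rank = rank,
      n_samples = nrow(mem),
      n_species = length(species_set),
      species = if (length(species_set)) paste(species_set, collapse = ",")
                else UNKNOWN_LABEL,
      members = list(mem$sample_id),
      species_set = list(species_set),
      localities = list(localities),
      evidence = paste(evidence, collapse = ";"),
      mean_internal_pct = if (nrow(internal)) mean(internal$distance_pct)
                          else NA_real_,
      max_internal_pct = if (nrow(internal)) max(internal$distance_pct)
                         else NA_real_
    )
  }
  out <- purrr::map_dfr(ids, entity_row)
  attr(out, "ot_pct") <- ot_pct
  attr(out, "ucs_low_pct") <- ucs_low_pct
  attr(out, "cryptic_pct") <- cryptic_pct
  class(out) <- c("entity_ranks", class(out))
  out
}

#' Write an entity report to TSV
#'
#' One row per entity: id, rank, sample count, species set, evidence,
#' mean internal divergence, locality groups, member sample ids.
#'
#' @param ranked An entity table from [assign_ranks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
entity_report <- function(ranked, path) {
  if (nrow(ranked) == 0) abort("No entities to report.")
  out <- tibble(
    entity_id = ranked$entity_id,
    rank = ranked$rank,
    n_samples = ranked$n_samples,
    species = ranked$species,
    evidence = ranked$evidence,
    mean_internal_pct = round(ranked$mean_internal_pct, 4),
    localities = vapply(ranked$localities, paste, character(1),
                        collapse = ","),
    members = vapply(ranked$members, paste, character(1), collapse = ",")
  )
  readr::write_tsv(out, path)
  invisible(path)
}
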