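# Kimura 2-parameter distances under pairwise deletion.
#
# The engine encodes each sequence as four 0/1 indicator matrices (one per
# base); transition, transversion and comparable-site counts for every pair
# then fall out of a handful of n x n cross-products, which keeps a
# ~200-sequence matrix (and its bootstrap replicates) fast in plain R.

#' Kimura 2-parameter distance from transition/transversion proportions
#'
#' Evaluates `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` where `P` and `Q`
#' are the proportions of sites showing a transition and a transversion
#' difference. Returns `NA` where the logs are undefined (saturation:
#' `1 - 2P - Q <= 0` or `1 - 2Q <= 0`).
#'
#' @param P,Q Numeric vectors of transition and transversion proportions.
#' @return Numeric vector of distances in substitutions/site (`NA` where
#'   undefined).
#' @examples
#' k2p_from_proportions(0.1, 0)  # -0.5 * log(0.8)
#' @export
k2p_from_proportions <- function(P, Q) {
  n <- max(length(P), length(Q))
  P <- rep_len(P, n)
  Q <- rep_len(Q, n)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  ok <- !is.na(w1) & !is.na(w2) & w1 > 0 & w2 > 0
  d <- rep(NA_real_, length(ok))
  d[ok] <- -0.5 * log(w1[ok]) - 0.25 * log(w2[ok])
  d
}

# Transition / transversion / comparable-site count matrices for all pairs.
# `idx` is an integer-coded sequence matrix (see seq_index_matrix); `cols`
# optionally resamples alignment columns (bootstrap).
k2p_count_matrices <- function(idx, cols = NULL) {
  if (!is.null(cols)) idx <- idx[, cols, drop = FALSE]
  B <- base_indicators(idx)
  M <- B[[1]] + B[[2]] + B[[3]] + B[[4]]
  comparable <- tcrossprod(M)
  matches <- tcrossprod(B[[1]]) + tcrossprod(B[[2]]) +
    tcrossprod(B[[3]]) + tcrossprod(B[[4]])
  # transitions: A<->G, C<->T
  ts <- tcrossprod(B[[1]], B[[3]]) + tcrossprod(B[[3]], B[[1]]) +
    tcrossprod(B[[2]], B[[4]]) + tcrossprod(B[[4]], B[[2]])
  tv <- comparable - matches - ts
  list(ts = ts, tv = tv, comparable = comparable)
}

k2p_matrix_from_counts <- function(cnt) {
  P <- ifelse(cnt$comparable > 0, cnt$ts / cnt$comparable, NA_real_)
  Q <- ifelse(cnt$comparable > 0, cnt$tv / cnt$comparable, NA_real_)
  d <- k2p_from_proportions(P, Q)
  dim(d) <- dim(cnt$comparable)
  diag(d) <- 0
  d
}

#' K2P distance between two sequences
#'
#' Columns where either sequence carries a gap or ambiguity code are
#' excluded for that pair (pairwise deletion); `P` and `Q` are computed over
#' the remaining comparable sites.
#'
#' @param seq_a,seq_b Nucleotide strings of equal length.
#' @return A one-row tibble with `n_sites` (comparable sites),
#'   `transitions`, `transversions`, `P`, `Q`, `distance`
#'   (substitutions/site, `NA` when undefined) and `distance_pct`.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    abort("Sequences must have equal length.")
  }
  rec <- tibble(sample_id = c("a", "b"), sequence = c(seq_a, seq_b))
  rec <- validate_records(rec)
  idx <- seq_index_matrix(rec)
  cnt <- k2p_count_matrices(idx)
  ns <- cnt$comparable[1, 2]
  P <- if (ns > 0) cnt$ts[1, 2] / ns else NA_real_
  Q <- if (ns > 0) cnt$tv[1, 2] / ns else NA_real_
  d <- k2p_from_proportions(P, Q)
  tibble(n_sites = ns, transitions = cnt$ts[1, 2],
         transversions = cnt$tv[1, 2], P = P, Q = Q,
         distance = d, distance_pct = 100 * d)
}

#' Full pairwise K2P distance matrix
#'
#' @param records An aligned barcode record tibble (>= 2 records).
#' @return A symmetric numeric matrix (substitutions/site) with zero
#'   diagonal and sample ids as dimnames; undefined (saturated or
#'   zero-overlap) entries are `NA`.
#' @export
k2p_matrix <- function(records) {
  records <- validate_records(records, require_aligned = TRUE)
  if (nrow(records) < 2) abort("Need at least 2 records.")
  idx <- seq_index_matrix(records)
  d <- k2p_matrix_from_counts(k2p_count_matrices(idx))
  dimnames(d) <- list(records$sample_id, records$sample_id)
  d
}

#' Long table of pairwise K2P distances
#'
#' The tidy currency of the pipeline: one row per unordered sample pair,
#' annotated with each sample's nominal species and locality group so that
#' downstream stages (threshold scan, entity partition, lineage detection)
#' can work directly on it.
#'
#' @param records An aligned barcode record tibble (>= 2 records).
#' @return A tibble with columns `sample_1`, `sample_2`, `species_1`,
#'   `species_2`, `locality_1`, `locality_2`, `n_sites`, `P`, `Q`,
#'   `distance` (substitutions/site), `distance_pct`, and `intraspecific`
#'   (`NA` when either species is `"UNKNOWN"`).
#' @export
pairwise_k2p <- function(records) {
  records <- validate_records(records, require_aligned = TRUE)
  if (nrow(records) < 2) abort("Need at least 2 records.")
  idx <- seq_index_matrix(records)
  cnt <- k2p_count_matrices(idx)
  n <- nrow(records)
  ut <- upper.tri(cnt$comparable)
  i <- row(cnt$comparable)[ut]
  j <- col(cnt$comparable)[ut]
  ns <- cnt$comparable[ut]
  P <- ifelse(ns > 0, cnt$ts[ut] / ns, NA_real_)
  Q <- ifelse(ns > 0, cnt$tv[ut] / ns, NA_real_)
  d <- k2p_from_proportions(P, Q)
  sp <- records$species_label
  pairs <- tibble(
    sample_1 = records$sample_id[i],
    sample_2 = records$sample_id[j],
    species_1 = sp[i],
    species_2 = sp[j],
    locality_1 = records$locality_group[i],
    locality_2 = records$locality_group[j],
    n_sites = ns, P = P, Q = Q,
    distance = d, distance_pct = 100 * d
  )
  pairs$intraspecific <- ifelse(
    pairs$species_1 == UNKNOWN_LABEL | pairs$species_2 == UNKNOWN_LABEL,
    NA, pairs$species_1 == pairs$species_2)
  pairs
}

# Per-sample metadata recovered from a pair table (every sample appears in
# at least one pair when n >= 2).
pair_sample_info <- function(pairs) {
  bind_rows(
    tibble(sample_id = pairs$sample_1, species_label = pairs$species_1,
           locality_group = pairs$locality_1),
    tibble(sample_id = pairs$sample_2, species_label = pairs$species_2,
           locality_group = pairs$locality_2)
  ) |> distinct(.data$sample_id, .keep_all = TRUE)
}

#' Intra/interspecific divergence summary
#'
#' Summarises pairwise K2P divergence within and between nominal species.
#' Pairs involving `"UNKNOWN"` or excluded species, and pairs with
#' undefined distances, are omitted. The dispersion statistic reported
#' alongside each mean is the standard deviation of the pairwise values.
#'
#' @param pairs A pair table from [pairwise_k2p()].
#' @param exclusions Character vector of species labels to omit entirely
#'   (e.g. taxa with unresolved taxonomy).
#' @return An object of class `divergence_summary`: a list with tibbles
#'   `intraspecific` (per species; `NA` mean for species with < 2 samples),
#'   `interspecific` (per species pair) and `overall` (one row: pooled
#'   intraspecific, interspecific and all-pair means, percent scale).
#' @export
divergence_summary <- function(pairs, exclusions = character()) {
  drop <- c(UNKNOWN_LABEL, exclusions)
  usable <- filter(pairs,
                   !.data$species_1 %in% drop, !.data$species_2 %in% drop,
                   !is.na(.data$distance))
  n_undefined <- sum(!pairs$species_1 %in% drop &
                       !pairs$species_2 %in% drop & is.na(pairs$distance))
  info <- pair_sample_info(pairs) |> filter(!.data$species_label %in% drop)
  species <- sort(unique(info$species_label))
  n_samples <- vapply(species, function(s) sum(info$species_label == s),
                      integer(1))

  intra_pairs <- filter(usable, .data$species_1 == .data$species_2)
  intra <- tibble(species_label = species, n_samples = n_samples) |>
    left_join(
      intra_pairs |>
        group_by(species_label = .data$species_1) |>
        summarise(n_pairs = n(),
                  mean_pct = mean(.data$distance_pct),
                  sd_pct = stats::sd(.data$distance_pct),
                  min_pct = min(.data$distance_pct),
                  max_pct = max(.data$distance_pct), .groups = "drop"),
      by = "species_label") |>
    mutate(n_pairs = ifelse(is.na(.data$n_pairs), 0L, .data$n_pairs))

  inter_pairs <- filter(usable, .data$species_1 != .data$species_2) |>
    mutate(sp_a = pmin(.data$species_1, .data$species_2),
           sp_b = pmax(.data$species_1, .data$species_2))
  inter <- inter_pairs |>
    group_by(species_a = .data$sp_a, species_b = .data$sp_b) |>
    summarise(n_pairs = n(),
              mean_pct = mean(.data$distance_pct),
              sd_pct = stats::sd(.data$distance_pct),
              min_pct = min(.data$distance_pct),
              max_pct = max(.data$distance_pct), .groups = "drop")

  overall <- tibble(
    intra_mean_pct = if (nrow(intra_pairs)) mean(intra_pairs$distance_pct)
                     else NA_real_,
    intra_sd_pct = if (nrow(intra_pairs) > 1)
      stats::sd(intra_pairs$distance_pct) else NA_real_,
    intra_min_pct = if (nrow(intra_pairs)) min(intra_pairs$distance_pct)
                    else NA_real_,
    intra_max_pct = if (nrow(intra_pairs)) max(intra_pairs$distance_pct)
                    else NA_real_,
    inter_mean_pct = if (nrow(inter_pairs)) mean(inter_pairs$distance_pct)
                     else NA_real_,
    inter_sd_pct = if (nrow(inter_pairs) > 1)
      stats::sd(inter_pairs$distance_pct) else NA_real_,
    inter_min_pct = if (nrow(inter_pairs)) min(inter_pairs$distance_pct)
                    else NA_real_,
    inter_max_pct = if (nrow(inter_pairs)) max(inter_pairs$distance_pct)
                    else NA_real_,
    overall_mean_pct = if (nrow(usable)) mean(usable$distance_pct)
                       else NA_real_,
    n_intra_pairs = nrow(intra_pairs),
    n_inter_pairs = nrow(inter_pairs),
    n_undefined = n_undefined
  )
  structure(list(intraspecific = intra, interspecific = inter,
                 overall = overall,
                 dispersion = "standard deviation of pairwise values"),
            class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  o <- x$overall
  cat("Divergence summary (K2P, % scale; dispersion = SD of pairwise values)\n")
  cat(sprintf("  intraspecific: mean %.2f +/- %.2f (range %.2f-%.2f), %d pairs\n",
              o$intra_mean_pct, o$intra_sd_pct, o$intra_min_pct,
              o$intra_max_pct, o$n_intra_pairs))
  cat(sprintf("  interspecific: mean %.2f +/- %.2f (range %.2f-%.2f), %d pairs\n",
              o$inter_mean_pct, o$inter_sd_pct, o$inter_min_pct,
              o$inter_max_pct, o$n_inter_pairs))
  cat(sprintf("  overall mean diversity: %.2f%%\n", o$overall_mean_pct))
  if (o$n_undefined > 0) {
    cat(sprintf("  (%d undefined pairwise distances excluded)\n",
                o$n_undefined))
  }
  invisible(x)
}

#' @rdname divergence_summary
#' @param x A `divergence_summary` object.
#' @param ... Unused.
#' @method tidy divergence_summary
#' @export
tidy.divergence_summary <- function(x, ...) {
  bind_rows(
    x$intraspecific |>
      mutate(comparison = "intraspecific") |>
      rename(species_a = "species_label") |>
      mutate(species_b = .data$species_a),
    x$interspecific |> mutate(comparison = "interspecific")
  ) |>
    select("comparison", "species_a", "species_b", dplyr::everything())
}

#' @rdname divergence_summary
#' @method glance divergence_summary
#' @export
glance.divergence_summary <- function(x, ...) x$overall
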