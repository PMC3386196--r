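# Fixture builders and independent oracles shared across the suite.

make_records <- function(sequences, species = "sp", locality = NA_character_,
                         ids = sprintf("s%02d", seq_along(sequences))) {
  tibble::tibble(sample_id = ids,
                 species_label = rep_len(species, length(sequences)),
                 locality_group = rep_len(locality, length(sequences)),
                 sequence = sequences)
}

# Pair table built directly from a symmetric percent-scale distance matrix
# plus per-sample metadata; lets threshold/partition/rank tests inject
# exact divergence structure without crafting sequences.
pairs_from_matrix <- function(d_pct, species, locality = NULL) {
  ids <- rownames(d_pct)
  stopifnot(!is.null(ids), length(species) == nrow(d_pct))
  if (is.null(locality)) locality <- rep(NA_character_, length(ids))
  ut <- which(upper.tri(d_pct), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  tibble::tibble(
    sample_1 = ids[i], sample_2 = ids[j],
    species_1 = species[i], species_2 = species[j],
    locality_1 = locality[i], locality_2 = locality[j],
    n_sites = 500, P = NA_real_, Q = NA_real_,
    distance = d_pct[ut] / 100, distance_pct = d_pct[ut],
    intraspecific = species[i] == species[j]
  )
}

# Pair table with prescribed intra/inter distance multisets (one species
# pair, arbitrary sample ids); enough for threshold-scan arithmetic.
pairs_from_distances <- function(intra_pct, inter_pct) {
  n1 <- length(intra_pct)
  n2 <- length(inter_pct)
  d <- c(intra_pct, inter_pct)
  tibble::new_tibble(list(
    sample_1 = c(sprintf("a%d", seq_len(n1)), sprintf("c%d", seq_len(n2))),
    sample_2 = c(sprintf("b%d", seq_len(n1)), sprintf("d%d", seq_len(n2))),
    species_1 = rep("X", n1 + n2),
    species_2 = rep(c("X", "Y"), c(n1, n2)),
    locality_1 = rep(NA_character_, n1 + n2),
    locality_2 = rep(NA_character_, n1 + n2),
    n_sites = rep(500, n1 + n2),
    P = rep(NA_real_, n1 + n2), Q = rep(NA_real_, n1 + n2),
    distance = d / 100, distance_pct = d,
    intraspecific = rep(c(TRUE, FALSE), c(n1, n2))
  ), nrow = n1 + n2)
}

# Independent error counting for a candidate threshold: matrix comparison
# rather than the package's per-candidate tallies.
brute_error_counts <- function(d_intra, d_inter, thresholds) {
  type_I <- colSums(outer(d_intra, thresholds, ">"))
  type_II <- colSums(outer(d_inter, thresholds, "<"))
  cbind(type_I = type_I, type_II = type_II)
}

# Exhaustive graph components by breadth-first search over an adjacency
# matrix (edges where distance < cutoff), independent of the union-find.
brute_components <- function(d_pct, cutoff) {
  n <- nrow(d_pct)
  adj <- !is.na(d_pct) & d_pct < cutoff
  diag(adj) <- TRUE
  comp <- rep(NA_integer_, n)
  label <- 0L
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    label <- label + 1L
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- label
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

random_acgt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random symmetric percent-scale distance matrix with labelled samples.
random_distance_instance <- function(n_samples, n_species, seed) {
  set.seed(seed)
  species <- sort(sample(sprintf("sp%02d", seq_len(n_species)), n_samples,
                         replace = TRUE))
  d <- matrix(0, n_samples, n_samples)
  for (i in seq_len(n_samples - 1)) {
    for (j in (i + 1):n_samples) {
      d[i, j] <- d[j, i] <- if (species[i] == species[j]) {
        runif(1, 0, 6)
      } else {
        runif(1, 0.5, 30)
      }
    }
  }
  rownames(d) <- colnames(d) <- sprintf("s%03d", seq_len(n_samples))
  list(d = d, species = species)
}
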