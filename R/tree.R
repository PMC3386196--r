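# Neighbour-joining trees with bootstrap support. Tree construction is
# delegated to ape::nj; bootstrap replication resamples alignment columns,
# recomputes the K2P matrix with the indicator-matrix engine and maps
# bipartition frequencies onto the full-data tree.

#' Neighbour-joining tree from a K2P distance matrix
#'
#' Wraps [ape::nj()] and post-processes negative branch lengths: a negative
#' edge is clamped to zero and its deficit moved to the sibling edge, which
#' preserves the path length between the taxa it separates.
#'
#' @param dist A symmetric distance matrix with sample ids as dimnames
#'   (e.g. from [k2p_matrix()]), or a `dist` object.
#' @return An unrooted `phylo` tree with branch lengths in
#'   substitutions/site.
#' @export
nj_tree <- function(dist) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  if (any(is.na(dist[upper.tri(dist)]))) {
    bad <- which(is.na(dist) & upper.tri(dist), arr.ind = TRUE)
    ids <- unique(c(rownames(dist)[bad[, 1]], colnames(dist)[bad[, 2]]))
    abort(sprintf(
      "Distance matrix has undefined entries (involving: %s); exclude these samples before tree building.",
      paste(head(ids, 5), collapse = ", ")))
  }
  if (nrow(dist) < 3) abort("Need >= 3 samples for a tree.")
  tree <- ape::nj(stats::as.dist(dist))
  clamp_negative_edges(tree)
}

# Move negative branch lengths onto the sibling edge (zeroing them), so
# tip-to-tip path lengths through the parent are preserved.
clamp_negative_edges <- function(tree) {
  for (pass in 1:5) {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0) break
    for (e in neg) {
      parent <- tree$edge[e, 1]
      sibs <- setdiff(which(tree$edge[, 1] == parent), e)
      deficit <- tree$edge.length[e]
      tree$edge.length[e] <- 0
      if (length(sibs) > 0) {
        tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + deficit
      }
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbour-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, recomputes the K2P
#' distance matrix and NJ tree for each replicate, and maps the frequency
#' of each full-tree bipartition across replicates onto the internal nodes
#' (as percentages in `node.label`). Replicates whose resampled matrix
#' contains undefined distances are skipped and counted; a warning is
#' raised when more than 10% are skipped.
#'
#' @param records An aligned barcode record tibble.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the resampling stream (required: bootstrap
#'   runs must be reproducible and logged).
#' @return A `phylo` tree with `node.label` giving support percentages and
#'   attributes `n_replicates_used`, `n_replicates_skipped`, `seed`.
#' @export
bootstrap_support <- function(records, replicates = 1000, seed) {
  if (missing(seed)) abort("`seed` is required for bootstrap runs.")
  if (replicates < 1) abort("`replicates` must be >= 1.")
  records <- validate_records(records, require_aligned = TRUE)
  idx <- seq_index_matrix(records)
  full_d <- k2p_matrix_from_counts(k2p_count_matrices(idx))
  dimnames(full_d) <- list(records$sample_id, records$sample_id)
  full <- nj_tree(full_d)
  L <- ncol(idx)

  trees <- vector("list", replicates)
  used <- 0L
  skipped <- 0L
  withr_seed <- get_rng_state()
  on.exit(restore_rng_state(withr_seed), add = TRUE)
  set.seed(seed)
  for (r in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    d <- k2p_matrix_from_counts(k2p_count_matrices(idx, cols))
    if (any(is.na(d[upper.tri(d)]))) {
      skipped <- skipped + 1L
      next
    }
    dimnames(d) <- list(records$sample_id, records$sample_id)
    used <- used + 1L
    trees[[used]] <- ape::nj(stats::as.dist(d))
  }
  if (used == 0) abort("All bootstrap replicates had undefined distances.")
  if (skipped > 0.1 * replicates) {
    warn(sprintf("%d of %d bootstrap replicates skipped (undefined distances).",
                 skipped, replicates))
  }
  trees <- trees[seq_len(used)]
  counts <- ape::prop.clades(full, trees, rooted = FALSE)
  support <- 100 * counts / used
  support[is.na(support)] <- 0
  support <- pmin(pmax(support, 0), 100)
  full$node.label <- formatC(support, format = "f", digits = 1)
  attr(full, "support_pct") <- support
  attr(full, "n_replicates_used") <- used
  attr(full, "n_replicates_skipped") <- skipped
  attr(full, "seed") <- seed
  full
}

# Save/restore the global RNG state so that seeded operations do not
# perturb the caller's stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Support (%) of the smallest clade of `tree` containing all of `samples`,
# read from node labels. NA for fewer than 2 samples or when the tree
# carries no labels.
clade_support <- function(tree, samples) {
  if (is.null(tree) || is.null(tree$node.label) || length(samples) < 2) {
    return(NA_real_)
  }
  samples <- intersect(samples, tree$tip.label)
  if (length(samples) < 2) return(NA_real_)
  node <- ape::getMRCA(tree, samples)
  if (is.null(node)) return(NA_real_)
  lab <- tree$node.label[node - ape::Ntip(tree)]
  suppressWarnings(as.numeric(lab))
}
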