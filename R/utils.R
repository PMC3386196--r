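# Internal helpers shared across modules: record validation, sequence
# encoding, and the single-linkage union-find used by entity partitioning
# and lineage detection.

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

# Validate a barcode record tibble: unique sample ids, IUPAC alphabet.
# Returns the tibble (sequences uppercased) invisibly for chaining.
validate_records <- function(records, require_aligned = FALSE,
                             arg = "records") {
  if (!is.data.frame(records)) {
    abort(sprintf("`%s` must be a data frame of barcode records.", arg))
  }
  needed <- c("sample_id", "sequence")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s.", arg,
                  paste(missing_cols, collapse = ", ")))
  }
  records <- as_tibble(records)
  if (!"species_label" %in% names(records)) {
    records$species_label <- UNKNOWN_LABEL
  }
  if (!"locality_group" %in% names(records)) {
    records$locality_group <- NA_character_
  }
  dup <- records$sample_id[duplicated(records$sample_id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate sample id(s): %s.",
                  paste(unique(dup), collapse = ", ")))
  }
  records$sequence <- toupper(records$sequence)
  bad <- vapply(records$sequence, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    any(!chars %in% IUPAC_CHARS)
  }, logical(1))
  if (any(bad)) {
    abort(sprintf(
      "Non-IUPAC characters in sequence(s): %s.",
      paste(records$sample_id[bad], collapse = ", ")))
  }
  if (require_aligned && nrow(records) > 0) {
    lens <- nchar(records$sequence)
    if (length(unique(lens)) != 1) {
      abort(sprintf(
        "Sequences must be aligned to equal length (found lengths %s).",
        paste(sort(unique(lens)), collapse = ", ")))
    }
  }
  records
}

# Character matrix (n x L) of the sequences.
seq_char_matrix <- function(records) {
  n <- nrow(records)
  L <- nchar(records$sequence[1])
  m <- matrix(unlist(strsplit(records$sequence, "", fixed = TRUE),
                     use.names = FALSE),
              nrow = n, ncol = L, byrow = TRUE)
  rownames(m) <- records$sample_id
  m
}

# Integer encoding A=1 C=2 G=3 T=4, anything else (gap/ambiguity) NA.
# Pairwise deletion works on the NA pattern.
seq_index_matrix <- function(records) {
  m <- seq_char_matrix(records)
  idx <- match(m, c("A", "C", "G", "T"))
  dim(idx) <- dim(m)
  rownames(idx) <- rownames(m)
  idx
}

# 0/1 indicator matrices per base, used by the vectorised K2P engine.
base_indicators <- function(idx) {
  lapply(1:4, function(b) {
    z <- idx == b
    z[is.na(z)] <- FALSE
    storage.mode(z) <- "double"
    z
  })
}

# Single-linkage connected components. `ids` is the universe; `edges` a
# two-column matrix/data frame of id pairs. Returns an integer component
# label per id, numbered by first appearance in `ids`.
single_linkage_components <- function(ids, edges) {
  parent <- seq_along(ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges) > 0 && nrow(edges) > 0) {
    a <- match(edges[[1]], ids)
    b <- match(edges[[2]], ids)
    for (k in seq_along(a)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  match(roots, unique(roots))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
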