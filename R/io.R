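#' Read barcode sequences from a FASTA file
#'
#' Headers are parsed as `sample_id|species_label|locality_group`; the second
#' and third fields are optional. A missing species becomes `"UNKNOWN"`, a
#' missing locality becomes `NA`. Sequences are uppercased and checked
#' against the IUPAC nucleotide alphabet (plus `-`).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `sample_id`, `species_label`,
#'   `locality_group`, `sequence` (one row per FASTA entry).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1|Myotis_myotis|NIT", "ACGTACGT", ">s2", "ACGTACGA"), fa)
#' read_barcode_fasta(fa)
#' @export
read_barcode_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    warn(sprintf("Empty FASTA file: %s", path))
    return(tibble(sample_id = character(), species_label = character(),
                  locality_group = character(), sequence = character()))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    abort(sprintf("Malformed FASTA: line %d of %s does not start with '>'.",
                  nonblank[1], path))
  }
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  fields <- strsplit(headers, "|", fixed = TRUE)
  records <- tibble(
    sample_id = vapply(fields, function(f) trimws(f[1]), character(1)),
    species_label = vapply(fields, function(f) {
      v <- if (length(f) >= 2) trimws(f[2]) else ""
      if (nzchar(v)) v else UNKNOWN_LABEL
    }, character(1)),
    locality_group = vapply(fields, function(f) {
      v <- if (length(f) >= 3) trimws(f[3]) else ""
      if (nzchar(v)) v else NA_character_
    }, character(1)),
    sequence = toupper(as.character(seqs))
  )
  validate_records(records)
}

#' Write barcode records to a FASTA file
#'
#' The header encodes `sample_id|species_label|locality_group`; the locality
#' field is omitted when `NA`, so `read_barcode_fasta()` round-trips records
#' exactly.
#'
#' @param records A barcode record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_barcode_fasta <- function(records, path) {
  records <- validate_records(records)
  header <- ifelse(
    is.na(records$locality_group),
    paste(records$sample_id, records$species_label, sep = "|"),
    paste(records$sample_id, records$species_label, records$locality_group,
          sep = "|"))
  out <- character(2L * nrow(records))
  out[c(TRUE, FALSE)] <- paste0(">", header)
  out[c(FALSE, TRUE)] <- records$sequence
  writeLines(out, path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects a tab-separated file with header columns `sample_id`,
#' `species_label`, `locality_group`.
#'
#' @param path Path to a TSV file.
#' @return A tibble with the three metadata columns.
#' @export
read_barcode_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  needed <- c("sample_id", "species_label", "locality_group")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols) > 0) {
    abort(sprintf("Metadata is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  meta[needed]
}

#' Merge a metadata table into barcode records
#'
#' Metadata values override header-derived values; records without a
#' metadata row are kept unchanged. Metadata rows whose `sample_id` does not
#' occur among the records trigger a warning and are ignored. Duplicate
#' conflicting metadata rows are an error.
#'
#' @param records A barcode record tibble.
#' @param metadata A tibble with columns `sample_id`, `species_label`,
#'   `locality_group` (e.g. from [read_barcode_metadata()]).
#' @return The updated record tibble.
#' @export
merge_metadata <- function(records, metadata) {
  records <- validate_records(records)
  metadata <- as_tibble(metadata)
  needed <- c("sample_id", "species_label", "locality_group")
  missing_cols <- setdiff(needed, names(metadata))
  if (length(missing_cols) > 0) {
    abort(sprintf("Metadata is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(metadata) == 0) return(records)
  metadata <- distinct(metadata[needed])
  dup <- metadata$sample_id[duplicated(metadata$sample_id)]
  if (length(dup) > 0) {
    abort(sprintf("Conflicting duplicate metadata rows for: %s.",
                  paste(unique(dup), collapse = ", ")))
  }
  unseen <- setdiff(metadata$sample_id, records$sample_id)
  if (length(unseen) > 0) {
    warn(sprintf("Metadata rows for unknown sample id(s) ignored: %s.",
                 paste(unseen, collapse = ", ")))
    metadata <- filter(metadata, .data$sample_id %in% records$sample_id)
  }
  i <- match(records$sample_id, metadata$sample_id)
  hit <- !is.na(i)
  new_species <- metadata$species_label[i[hit]]
  new_loc <- metadata$locality_group[i[hit]]
  records$species_label[hit] <- ifelse(
    is.na(new_species) | !nzchar(new_species),
    records$species_label[hit], new_species)
  records$locality_group[hit] <- ifelse(
    is.na(new_loc) | !nzchar(new_loc),
    records$locality_group[hit], new_loc)
  records
}

#' Trim aligned records to a common window
#'
#' Extracts the columns `start..end` (1-based, inclusive) from every
#' sequence, producing an alignment of equal-length sequences. Inputs are
#' assumed pre-aligned; no alignment is performed.
#'
#' @param records A barcode record tibble.
#' @param start,end 1-based inclusive window bounds. `end = NULL` trims to
#'   the shortest sequence (`start..min(length)`).
#' @return The trimmed record tibble; every sequence has length
#'   `end - start + 1`.
#' @examples
#' rec <- tibble::tibble(sample_id = "a", species_label = "sp",
#'                       locality_group = NA, sequence = strrep("ACGT", 20))
#' nchar(trim_alignment(rec, 5, 24)$sequence)  # 20
#' @export
trim_alignment <- function(records, start = 1L, end = NULL) {
  records <- validate_records(records)
  if (nrow(records) == 0) abort("No records to trim.")
  lens <- nchar(records$sequence)
  if (is.null(end)) end <- min(lens)
  if (!(start >= 1 && start <= end)) {
    abort("Require 1 <= start <= end.")
  }
  short <- records$sample_id[lens < end]
  if (length(short) > 0) {
    abort(sprintf("Window [%d, %d] exceeds sequence length for: %s.",
                  start, end, paste(short, collapse = ", ")))
  }
  records$sequence <- substr(records$sequence, start, end)
  records
}
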