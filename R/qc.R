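#' Screen a coding alignment for NUMT/pseudogene artefacts
#'
#' Nuclear pseudogenes of mitochondrial origin (NUMTs) typically betray
#' themselves through internal indels and in-frame stop codons. The screen
#' reports, per record, whether the sequence contains gap characters and how
#' many stop codons it carries when translated in the reading frame that
#' minimises the total stop count over the whole alignment (ties broken by
#' the lowest frame offset). A record passes when it has no gaps and no
#' stops.
#'
#' Codons containing gaps or ambiguity codes are not translated and never
#' counted as stops; the trailing partial codon is ignored.
#'
#' @param records An aligned barcode record tibble.
#' @param genetic_code A genetic code id accepted by
#'   [Biostrings::getGeneticCode()] (default `"2"`, vertebrate
#'   mitochondrial) or a named codon-to-amino-acid vector with `"*"` for
#'   stops.
#' @return A tibble (one row per record) with columns `sample_id`,
#'   `has_internal_gap`, `stop_codon_count`, `frame_used`, `passed`;
#'   attributes `frame_used` (0, 1 or 2) and `stops_by_frame`.
#' @export
numt_screen <- function(records, genetic_code = "2") {
  records <- validate_records(records, require_aligned = TRUE)
  if (nrow(records) == 0) abort("Alignment is empty.")
  code <- if (is.character(genetic_code) && length(genetic_code) == 1 &&
              is.null(names(genetic_code))) {
    Biostrings::getGeneticCode(genetic_code)
  } else {
    genetic_code
  }
  stops <- names(code)[code == "*"]
  m <- seq_char_matrix(records)
  L <- ncol(m)

  count_stops <- function(frame) {
    # frame = offset in {0,1,2}; complete codons only
    n_codon <- (L - frame) %/% 3
    if (n_codon == 0) return(rep(0L, nrow(m)))
    sub <- m[, frame + seq_len(3L * n_codon), drop = FALSE]
    apply(sub, 1, function(ch) {
      codons <- paste0(ch[c(TRUE, FALSE, FALSE)],
                       ch[c(FALSE, TRUE, FALSE)],
                       ch[c(FALSE, FALSE, TRUE)])
      sum(codons %in% stops)
    })
  }
  per_frame <- lapply(0:2, count_stops)
  totals <- vapply(per_frame, sum, numeric(1))
  frame_used <- which.min(totals) - 1L  # which.min takes the first minimum
  stop_counts <- as.integer(per_frame[[frame_used + 1L]])

  has_gap <- apply(m, 1, function(ch) any(ch == "-"))
  report <- tibble(
    sample_id = records$sample_id,
    has_internal_gap = unname(has_gap),
    stop_codon_count = stop_counts,
    frame_used = frame_used,
    passed = !has_gap & stop_counts == 0L
  )
  attr(report, "frame_used") <- frame_used
  attr(report, "stops_by_frame") <- setNames(totals, paste0("frame_", 0:2))
  class(report) <- c("qc_report", class(report))
  report
}

#' Average base composition of an alignment
#'
#' Frequencies are computed over unambiguous A/C/G/T characters only; gaps
#' and ambiguity codes are excluded.
#'
#' @param records An aligned barcode record tibble.
#' @return A one-row tibble with columns `pi_A`, `pi_C`, `pi_G`, `pi_T`
#'   (summing to 1) and `n_sites` (number of unambiguous characters
#'   counted).
#' @export
base_composition <- function(records) {
  records <- validate_records(records)
  if (nrow(records) == 0) abort("Alignment is empty.")
  chars <- unlist(strsplit(records$sequence, "", fixed = TRUE),
                  use.names = FALSE)
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(chars == b),
                   numeric(1))
  total <- sum(counts)
  if (total == 0) {
    abort("No unambiguous A/C/G/T characters in the alignment.")
  }
  freqs <- counts / total
  tibble(pi_A = freqs[["A"]], pi_C = freqs[["C"]],
         pi_G = freqs[["G"]], pi_T = freqs[["T"]],
         n_sites = total)
}

#' Write a QC report to TSV
#'
#' @param report A tibble from [numt_screen()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  readr::write_tsv(as_tibble(report), path)
  invisible(path)
}
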