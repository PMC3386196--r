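# Optimum-threshold calibration: scan candidate divergence cutoffs, count
# Type I (conspecific pair above the cutoff) and Type II (heterospecific
# pair below it) identification errors, and locate the minimum cumulative
# error (MCE).

#' Scan candidate identification thresholds
#'
#' For every candidate threshold `t` (percent scale) counts Type I errors
#' (intraspecific pairs with divergence strictly above `t`) and Type II
#' errors (interspecific pairs strictly below `t`); pairs exactly at `t`
#' count as neither. Percentages are relative to the total number of
#' compared pairs (intraspecific + interspecific pooled) by default, or to
#' the respective class sizes with `denominator = "per_class"`. Pairs with
#' an `"UNKNOWN"` species or an undefined distance are excluded.
#'
#' @param pairs A pair table from [pairwise_k2p()] (needs `species_1`,
#'   `species_2`, `distance_pct`).
#' @param step Grid step in percent (default 0.1). The default grid runs
#'   from 0 to `ceiling(max(distance_pct))`.
#' @param grid Optional explicit vector of candidate thresholds (percent,
#'   ascending); overrides `step`.
#' @param denominator `"pooled"` (default) or `"per_class"`.
#' @return A `threshold_scan` tibble with columns `threshold_pct`,
#'   `type_I_pct`, `type_II_pct`, `cumulative_error_pct`, and attributes
#'   `n_intra`, `n_inter`, `n_pairs`, `denominator`, `distances_pct`.
#' @export
threshold_scan <- function(pairs, step = 0.1, grid = NULL,
                           denominator = c("pooled", "per_class")) {
  denominator <- match.arg(denominator)
  d <- pairs$distance_pct
  keep <- pairs$species_1 != UNKNOWN_LABEL &
    pairs$species_2 != UNKNOWN_LABEL & !is.na(d)
  intra <- pairs$species_1 == pairs$species_2
  d_intra <- d[keep & intra]
  d_inter <- d[keep & !intra]
  if (length(d_intra) == 0) {
    abort("Reference dataset needs >= 2 conspecific samples (no intraspecific pairs).")
  }
  if (length(d_inter) == 0) {
    abort("Reference dataset has no interspecific pairs.")
  }
  if (is.null(grid)) {
    grid <- seq(0, ceiling(max(c(d_intra, d_inter))), by = step)
  }
  grid <- sort(unique(round(grid, 9)))
  n_intra <- length(d_intra)
  n_inter <- length(d_inter)
  n_total <- n_intra + n_inter
  # strict inequalities: pairs exactly at a candidate count as neither
  type_I_n <- n_intra - findInterval(grid, sort(d_intra))
  type_II_n <- findInterval(grid, sort(d_inter), left.open = TRUE)
  den_I <- if (denominator == "pooled") n_total else n_intra
  den_II <- if (denominator == "pooled") n_total else n_inter
  scan <- tibble(
    threshold_pct = grid,
    type_I_pct = 100 * type_I_n / den_I,
    type_II_pct = 100 * type_II_n / den_II
  )
  scan$cumulative_error_pct <- scan$type_I_pct + scan$type_II_pct
  attr(scan, "n_intra") <- n_intra
  attr(scan, "n_inter") <- n_inter
  attr(scan, "n_pairs") <- n_total
  attr(scan, "denominator") <- denominator
  attr(scan, "distances_pct") <- sort(unique(c(d_intra, d_inter)))
  class(scan) <- c("threshold_scan", class(scan))
  scan
}

#' Optimum threshold at the minimum cumulative error
#'
#' Finds the minimum cumulative error (MCE) over the scan and the first
#' contiguous run of grid candidates achieving it. The reported optimal
#' interval stretches from the largest observed pairwise distance strictly
#' below the first optimal candidate (the point where the error function
#' actually changes) to the last optimal candidate. The OT itself is, by
#' default, the lowest optimal candidate (`tie_rule = "lowest"`; this is
#' also what minimum-cumulative-error barcode calibrations conventionally
#' report); `tie_rule = "midpoint"` returns the midpoint of the optimal
#' interval, maximising the margin on both sides.
#'
#' @param scan A `threshold_scan` tibble.
#' @param tie_rule `"lowest"` (default) or `"midpoint"`.
#' @return An object of class `ot_result`: list with `ot_pct`, `mce_pct`,
#'   `interval` (`c(low, high)`, percent), `tie_rule`, `n_pairs`.
#' @export
optimum_threshold <- function(scan, tie_rule = c("lowest", "midpoint")) {
  tie_rule <- match.arg(tie_rule)
  if (!inherits(scan, "threshold_scan") || nrow(scan) == 0) {
    abort("`scan` must be a nonempty threshold_scan.")
  }
  ce <- scan$cumulative_error_pct
  mce <- min(ce)
  optimal <- which(abs(ce - mce) < 1e-9)
  # first contiguous run of optimal candidates
  run_end <- if (length(optimal) > 1) {
    brk <- which(diff(optimal) > 1)
    if (length(brk) > 0) optimal[brk[1]] else optimal[length(optimal)]
  } else {
    optimal[1]
  }
  first <- optimal[1]
  t_first <- scan$threshold_pct[first]
  t_last <- scan$threshold_pct[run_end]
  dists <- attr(scan, "distances_pct") %||% numeric()
  # The error function changes only at observed distances; the continuous
  # optimal region therefore starts at the first optimal candidate itself
  # when it coincides with a distance, and otherwise at the largest
  # distance below it.
  low <- if (any(abs(dists - t_first) < 1e-9)) {
    t_first
  } else {
    below <- dists[dists < t_first]
    if (length(below) > 0) max(below) else 0
  }
  interval <- c(low = low, high = t_last)
  ot <- switch(tie_rule,
               lowest = t_first,
               midpoint = (low + t_last) / 2)
  structure(list(ot_pct = ot, mce_pct = mce, interval = interval,
                 tie_rule = tie_rule,
                 n_pairs = attr(scan, "n_pairs"),
                 n_intra = attr(scan, "n_intra"),
                 n_inter = attr(scan, "n_inter"),
                 denominator = attr(scan, "denominator")),
            class = "ot_result")
}

#' @export
print.ot_result <- function(x, ...) {
  cat(sprintf("Optimum threshold: OT = %.2f%%, MCE = %.3f%%\n",
              x$ot_pct, x$mce_pct))
  cat(sprintf("  optimal interval: (%.2f, %.2f]%%; tie rule: %s\n",
              x$interval[["low"]], x$interval[["high"]], x$tie_rule))
  cat(sprintf("  %d pairs (%d intra, %d inter); error denominator: %s\n",
              x$n_pairs, x$n_intra, x$n_inter, x$denominator))
  invisible(x)
}

#' @rdname optimum_threshold
#' @param x An `ot_result`.
#' @param ... Unused.
#' @method tidy ot_result
#' @export
tidy.ot_result <- function(x, ...) {
  tibble(ot_pct = x$ot_pct, mce_pct = x$mce_pct,
         interval_low_pct = x$interval[["low"]],
         interval_high_pct = x$interval[["high"]],
         tie_rule = x$tie_rule, n_pairs = x$n_pairs,
         n_intra = x$n_intra, n_inter = x$n_inter)
}

#' @rdname optimum_threshold
#' @method glance ot_result
#' @export
glance.ot_result <- function(x, ...) tidy(x)

#' Write the threshold error curve to TSV
#'
#' Columns `threshold`, `typeI`, `typeII`, `CE` (all percent scale).
#'
#' @param scan A `threshold_scan` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_error_curve <- function(scan, path) {
  out <- tibble(threshold = scan$threshold_pct,
                typeI = scan$type_I_pct,
                typeII = scan$type_II_pct,
                CE = scan$cumulative_error_pct)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Plot a threshold scan
#'
#' Type I, Type II and cumulative error against the candidate threshold;
#' optionally marks an OT.
#'
#' @param object A `threshold_scan` tibble.
#' @param ot Optional `ot_result` whose OT is drawn as a vertical line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot threshold_scan
#' @export
autoplot.threshold_scan <- function(object, ot = NULL, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("threshold_pct", "type_I_pct", "type_II_pct",
                        "cumulative_error_pct")],
    cols = -"threshold_pct", names_to = "component", values_to = "error_pct")
  long$component <- factor(long$component,
                           levels = c("type_I_pct", "type_II_pct",
                                      "cumulative_error_pct"),
                           labels = c("Type I", "Type II", "Cumulative"))
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$threshold_pct, y = .data$error_pct,
    colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Threshold (K2P %)", y = "Error (% of pairs)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(ot)) {
    p <- p + ggplot2::geom_vline(xintercept = ot$ot_pct, linetype = "dashed")
  }
  p
}
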