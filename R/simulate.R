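# Synthetic barcode data with controlled divergence structure and known
# ground truth. Species are arranged on a star: each species ancestor
# evolves from a common root by half the configured interspecific
# divergence, and each sample from its (sub-)ancestor by half the
# intraspecific divergence, so configured divergences are exact in
# expectation. Scenario injections (MT-MOTU pair, IOTU split, UCS split)
# override the structure of designated species; their ancestor splits are
# rejection-controlled so the realised divergence matches the nominal
# value.

MITO_STOPS <- c("TAA", "TAG", "AGA", "AGG")

#' Evolve a sequence under the K2P substitution process
#'
#' Per-site continuous-time Kimura two-parameter process with uniform
#' stationary base frequencies: transitions occur at `kappa` times the
#' rate of each transversion type, and `branch_length` is the expected
#' number of substitutions per site.
#'
#' @param sequence An A/C/G/T string (no gaps or ambiguities).
#' @param branch_length Expected substitutions/site (>= 0).
#' @param kappa Transition/transversion rate ratio (> 0; default 4,
#'   typical for mammalian mtDNA).
#' @param seed Optional integer seed; when supplied the caller's RNG state
#'   is left untouched.
#' @return The descendant sequence (same length).
#' @export
evolve_sequence <- function(sequence, branch_length, kappa = 4, seed = NULL) {
  if (branch_length < 0) abort("`branch_length` must be >= 0.")
  if (kappa <= 0) abort("`kappa` must be > 0.")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))
  if (anyNA(idx)) abort("Ancestor sequence must contain only A/C/G/T.")
  if (!is.null(seed)) {
    state <- get_rng_state()
    on.exit(restore_rng_state(state), add = TRUE)
    set.seed(seed)
  }
  paste(evolve_idx(idx, branch_length, kappa), collapse = "")
}

# Core site-wise sampler on integer-coded sequences (1=A 2=C 3=G 4=T).
# Closed-form K80 transition probabilities: with beta*t = d/(kappa+2),
# alpha*t = kappa*beta*t,
#   p(transition)      = 1/4 + 1/4 e1 - 1/2 e2
#   p(each transversion) = 1/4 - 1/4 e1
# where e1 = exp(-4 beta t), e2 = exp(-2 (alpha+beta) t).
evolve_idx <- function(idx, branch_length, kappa) {
  L <- length(idx)
  bt <- branch_length / (kappa + 2)
  at <- kappa * bt
  e1 <- exp(-4 * bt)
  e2 <- exp(-2 * (at + bt))
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1     # each of two transversion targets
  u <- runif(L)
  ts_partner <- c(3L, 4L, 1L, 2L)       # A<->G, C<->T
  tv1 <- c(2L, 1L, 2L, 1L)              # A->C, C->A, G->C, T->A
  tv2 <- c(4L, 3L, 4L, 3L)              # A->T, C->G, G->T, T->G
  out <- idx
  sel_ts <- u < p_ts
  sel_tv1 <- !sel_ts & u < p_ts + p_tv
  sel_tv2 <- !sel_ts & !sel_tv1 & u < p_ts + 2 * p_tv
  out[sel_ts] <- ts_partner[idx[sel_ts]]
  out[sel_tv1] <- tv1[idx[sel_tv1]]
  out[sel_tv2] <- tv2[idx[sel_tv2]]
  c("A", "C", "G", "T")[out]
}

# Evolve a coding sequence and re-evolve any codon that lands on an
# in-frame stop (rejection resampling; frame 1). The ancestor is assumed
# stop-free, so falling back to the ancestral codon always terminates.
evolve_coding <- function(sequence, branch_length, kappa) {
  anc <- strsplit(sequence, "", fixed = TRUE)[[1]]
  child <- evolve_idx(match(anc, c("A", "C", "G", "T")), branch_length, kappa)
  n_codon <- length(child) %/% 3
  for (try in 1:50) {
    codons <- paste0(child[c(TRUE, FALSE, FALSE)][seq_len(n_codon)],
                     child[c(FALSE, TRUE, FALSE)][seq_len(n_codon)],
                     child[c(FALSE, FALSE, TRUE)][seq_len(n_codon)])
    bad <- which(codons %in% MITO_STOPS)
    if (length(bad) == 0) break
    for (b in bad) {
      pos <- (b - 1) * 3 + 1:3
      child[pos] <- if (try < 50) {
        evolve_idx(match(anc[pos], c("A", "C", "G", "T")),
                   branch_length, kappa)
      } else {
        anc[pos]
      }
    }
  }
  paste(child, collapse = "")
}

# Random stop-free coding sequence (uniform over non-stop codons).
random_coding_sequence <- function(length) {
  stopifnot(length %% 3 == 0)
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  ok <- setdiff(all_codons, MITO_STOPS)
  paste(sample(ok, length %/% 3, replace = TRUE), collapse = "")
}

# Realised K2P % between two sequences (internal convenience).
realised_k2p <- function(a, b) {
  k2p_distance(a, b)$distance
}

# Evolve `n` descendants from `ancestor` such that every pairwise realised
# K2P distance is within `rel_tol` of `target` (each descendant sits at
# target/2 from the ancestor). Gives scenario injections the divergence
# they claim, rather than a draw centred on it.
evolve_controlled_split <- function(ancestor, n, target, kappa,
                                    rel_tol = 0.05, max_tries = 200) {
  best <- NULL
  best_err <- Inf
  for (try in seq_len(max_tries)) {
    subs <- replicate(n, evolve_coding(ancestor, target / 2, kappa))
    dd <- utils::combn(n, 2)
    realised <- vapply(seq_len(ncol(dd)), function(k) {
      realised_k2p(subs[dd[1, k]], subs[dd[2, k]])
    }, numeric(1))
    err <- max(abs(realised - target) / target)
    if (is.na(err)) next
    if (err < best_err) {
      best <- subs
      best_err <- err
    }
    if (best_err <= rel_tol) break
  }
  best
}

#' Scenario injections for the simulator
#'
#' Constructors for the structures [simulate_barcodes()] can inject:
#' * `scenario_mt_motu()` — two nominal species sharing nearly identical
#'   barcodes (ancestors separated by `divergence`), the marker-failure
#'   case; expected rank `MT_MOTU`.
#' * `scenario_iotu_split()` — one species split into `n_lineages` deep
#'   lineages (`lineage_divergence` apart) with disjoint locality groups;
#'   expected rank `IOTU` for each lineage. The species is recorded as an
#'   OT-reference exclusion in the ground truth, since its deep
#'   intraspecific divergence would otherwise contaminate the reference
#'   Type-I tail (the same reason deeply structured taxa are excluded from
#'   threshold calibration in practice).
#' * `scenario_ucs_split()` — a shallower split (`divergence`) with
#'   overlapping locality groups; expected rank `UCS`.
#'
#' @param divergence,lineage_divergence Expected K2P divergence
#'   (substitutions/site) between the injected ancestors.
#' @param n_lineages Number of lineages for an IOTU split.
#' @param localities List of locality-group character vectors, one per
#'   lineage (recycled for `scenario_mt_motu`, which takes a single pool).
#' @param n_samples Samples for the scenario species (per species for
#'   `scenario_mt_motu`); overrides the dataset-level draw so splits are
#'   always populated.
#' @return A scenario specification list.
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_mt_motu <- function(divergence = 0.005, n_samples = 6,
                             localities = c("NIT", "CIT", "SIT")) {
  list(type = "MT_MOTU_PAIR", divergence = divergence,
       n_samples = n_samples, localities = localities)
}

#' @rdname scenarios
#' @export
scenario_iotu_split <- function(n_lineages = 2, lineage_divergence = 0.09,
                                localities = list("NIT", c("CIT", "SIT")),
                                n_samples = 8) {
  if (length(localities) != n_lineages) {
    abort("`localities` must have one entry per lineage.")
  }
  list(type = "IOTU_SPLIT", n_lineages = n_lineages,
       lineage_divergence = lineage_divergence,
       localities = localities, n_samples = n_samples)
}

#' @rdname scenarios
#' @export
scenario_ucs_split <- function(divergence = 0.025,
                               localities = list(c("NIT", "CIT"),
                                                 c("CIT", "SIT")),
                               n_samples = 6) {
  list(type = "UCS_SPLIT", n_lineages = 2, lineage_divergence = divergence,
       localities = localities, n_samples = n_samples)
}

#' Simulation configuration
#'
#' Defaults emulate a coxI barcode survey of a regional bat fauna: ~30
#' species, 556-bp coding alignment, per-species sample counts drawn from
#' a negative binomial with mean ~5.8 (clamped to 1-22), low intraspecific
#' divergence (1%), high interspecific divergence (20%), kappa = 4.
#'
#' @param n_species Number of nominal species.
#' @param samples_per_species `NULL` (negative-binomial draw), a single
#'   count applied to all species, or a length-`n_species` vector.
#' @param sequence_length Alignment length in bp; must be divisible by 3
#'   so the coding frame (and the NUMT screen) stays clean.
#' @param kappa Transition/transversion rate ratio.
#' @param intra_divergence Expected within-species K2P distance
#'   (substitutions/site).
#' @param inter_divergence Expected between-species K2P distance; must
#'   exceed `intra_divergence`.
#' @param scenarios List of scenario injections (see [scenarios]); each
#'   consumes one species slot (two for `scenario_mt_motu`).
#' @param n_unknown Number of unlabelled query samples to generate (drawn
#'   from randomly chosen clean species).
#' @param seed Integer seed (required; logged with the output).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 30, samples_per_species = NULL,
                       sequence_length = 555, kappa = 4,
                       intra_divergence = 0.01, inter_divergence = 0.20,
                       scenarios = list(), n_unknown = 0, seed) {
  if (missing(seed)) abort("`seed` is required.")
  if (sequence_length %% 3 != 0) {
    abort("`sequence_length` must be divisible by 3.")
  }
  if (!(intra_divergence >= 0 && intra_divergence < inter_divergence)) {
    abort("Require 0 <= intra_divergence < inter_divergence.")
  }
  if (kappa <= 0) abort("`kappa` must be > 0.")
  slots_needed <- sum(vapply(scenarios, function(s) {
    if (s$type == "MT_MOTU_PAIR") 2L else 1L
  }, integer(1)))
  if (slots_needed > n_species) {
    abort("More scenario species than `n_species`.")
  }
  structure(list(n_species = n_species,
                 samples_per_species = samples_per_species,
                 sequence_length = sequence_length, kappa = kappa,
                 intra_divergence = intra_divergence,
                 inter_divergence = inter_divergence,
                 scenarios = scenarios, n_unknown = n_unknown,
                 seed = seed),
            class = "sim_config")
}

LOCALITY_POOL <- c("NIT", "CIT", "SIT", "SAR")

#' Simulate a barcode dataset with known ground truth
#'
#' @param config A [sim_config()].
#' @return An object of class `barcode_sim`: list with `records` (a
#'   barcode record tibble, unknowns labelled `"UNKNOWN"`), `truth`
#'   (per-sample true species, lineage, locality and expected rank) and
#'   `config`. The ground truth carries an `ot_exclusions` attribute
#'   naming species to exclude from OT calibration (IOTU-split species).
#' @examples
#' sim <- simulate_barcodes(sim_config(n_species = 4,
#'                                     samples_per_species = 3, seed = 1))
#' sim$records
#' @export
simulate_barcodes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  state <- get_rng_state()
  on.exit(restore_rng_state(state), add = TRUE)
  set.seed(config$seed)

  n_sp <- config$n_species
  counts <- config$samples_per_species
  if (is.null(counts)) {
    counts <- pmin(1L + stats::rnbinom(n_sp, mu = 4.84, size = 2.5), 22L)
  } else if (length(counts) == 1) {
    counts <- rep(as.integer(counts), n_sp)
  } else if (length(counts) != n_sp) {
    abort("`samples_per_species` must have length 1 or n_species.")
  }
  species_names <- sprintf("Species_%02d", seq_len(n_sp))

  # assign scenario species to the first slots
  scenario_of <- vector("list", n_sp)
  slot <- 1L
  for (sc in config$scenarios) {
    if (sc$type == "MT_MOTU_PAIR") {
      scenario_of[[slot]] <- c(sc, role = "mt_a", partner = slot + 1L)
      scenario_of[[slot + 1L]] <- c(sc, role = "mt_b", partner = slot)
      counts[slot] <- counts[slot + 1L] <- sc$n_samples
      slot <- slot + 2L
    } else {
      if (sc$n_samples < 2 * sc$n_lineages) {
        abort("Scenario needs at least 2 samples per lineage.")
      }
      scenario_of[[slot]] <- sc
      counts[slot] <- sc$n_samples
      slot <- slot + 1L
    }
  }

  root <- random_coding_sequence(config$sequence_length)
  half_inter <- config$inter_divergence / 2
  half_intra <- config$intra_divergence / 2
  kappa <- config$kappa

  ancestors <- character(n_sp)
  for (i in seq_len(n_sp)) {
    sc <- scenario_of[[i]]
    if (!is.null(sc) && identical(sc$role, "mt_b")) {
      # second member of an MT-MOTU pair: bud off the partner's ancestor
      ancestors[i] <- evolve_coding(ancestors[sc$partner], sc$divergence,
                                    kappa)
    } else {
      ancestors[i] <- evolve_coding(root, half_inter, kappa)
    }
  }

  records <- list()
  truth <- list()
  sample_no <- 0L
  for (i in seq_len(n_sp)) {
    sc <- scenario_of[[i]]
    n_i <- counts[i]
    sp <- species_names[i]
    if (!is.null(sc) && sc$type %in% c("IOTU_SPLIT", "UCS_SPLIT")) {
      n_lin <- sc$n_lineages
      subs <- evolve_controlled_split(ancestors[i], n_lin,
                                      sc$lineage_divergence, kappa)
      lin_sizes <- diff(round(seq(0, n_i, length.out = n_lin + 1)))
      expected <- if (sc$type == "IOTU_SPLIT") "IOTU" else "UCS"
      for (l in seq_len(n_lin)) {
        for (s in seq_len(lin_sizes[l])) {
          sample_no <- sample_no + 1L
          loc <- sample(sc$localities[[l]], 1)
          records[[sample_no]] <- tibble(
            sample_id = sprintf("S%03d", sample_no), species_label = sp,
            locality_group = loc,
            sequence = evolve_coding(subs[l], half_intra, kappa))
          truth[[sample_no]] <- tibble(
            sample_id = sprintf("S%03d", sample_no), true_species = sp,
            true_lineage = sprintf("%s/L%d", sp, l), locality_group = loc,
            expected_rank = expected, is_unknown = FALSE)
        }
      }
    } else {
      expected <- if (!is.null(sc) && sc$type == "MT_MOTU_PAIR") "MT_MOTU"
                  else "SPECIES_MATCH"
      loc_pool <- if (!is.null(sc)) sc$localities else LOCALITY_POOL
      for (s in seq_len(n_i)) {
        sample_no <- sample_no + 1L
        loc <- sample(loc_pool, 1)
        records[[sample_no]] <- tibble(
          sample_id = sprintf("S%03d", sample_no), species_label = sp,
          locality_group = loc,
          sequence = evolve_coding(ancestors[i], half_intra, kappa))
        truth[[sample_no]] <- tibble(
          sample_id = sprintf("S%03d", sample_no), true_species = sp,
          true_lineage = sprintf("%s/L1", sp), locality_group = loc,
          expected_rank = expected, is_unknown = FALSE)
      }
    }
  }

  # unknown queries drawn from clean species
  clean <- which(vapply(scenario_of, is.null, logical(1)))
  if (config$n_unknown > 0 && length(clean) == 0) {
    abort("Unknown queries require at least one clean species.")
  }
  for (u in seq_len(config$n_unknown)) {
    i <- sample(clean, 1)
    sample_no <- sample_no + 1L
    loc <- sample(LOCALITY_POOL, 1)
    records[[sample_no]] <- tibble(
      sample_id = sprintf("S%03d", sample_no),
      species_label = UNKNOWN_LABEL, locality_group = loc,
      sequence = evolve_coding(ancestors[i], half_intra, kappa))
    truth[[sample_no]] <- tibble(
      sample_id = sprintf("S%03d", sample_no),
      true_species = species_names[i],
      true_lineage = sprintf("%s/L1", species_names[i]),
      locality_group = loc, expected_rank = "SPECIES_MATCH",
      is_unknown = TRUE)
  }

  records <- bind_rows(records)
  truth <- bind_rows(truth)
  exclusions <- species_names[vapply(scenario_of, function(s) {
    !is.null(s) && s$type == "IOTU_SPLIT"
  }, logical(1))]
  attr(truth, "ot_exclusions") <- exclusions
  structure(list(records = records, truth = truth, config = config),
            class = "barcode_sim")
}

#' @export
print.barcode_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated barcode dataset: %d samples, %d species, %d bp (seed %d)\n",
    nrow(x$records), x$config$n_species, x$config$sequence_length,
    x$config$seed))
  if (length(x$config$scenarios) > 0) {
    cat("  scenarios:",
        paste(vapply(x$config$scenarios, `[[`, character(1), "type"),
              collapse = ", "), "\n")
  }
  invisible(x)
}
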