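# Synthetic substrate phage display: library generation, cleavage-driven
# biopanning simulation, clone sampling and kinetic time series. Provides
# ground-truth-labelled inputs for every downstream stage of the pipeline.

#' Phage display context
#'
#' The constant sequence context in which the randomized insert is displayed
#' on the phage capsid protein: `upstream_arm` + insert + `downstream_arm`.
#' The default emulates a T7 display library where nonamers are presented as
#' PGG(X)9HHHHHH, the C-terminal His6 tag immobilizing phages on Ni-NTA beads
#' so that only cleavage within the insert releases them.
#'
#' @param upstream_arm Residues N-terminal of the insert (default `"PGG"`).
#' @param downstream_arm Residues C-terminal of the insert (default
#'   `"HHHHHH"`).
#' @param insert_length Length of the randomized insert (default 9).
#' @return An object of class `display_context`.
#' @export
#' @examples
#' display_context()
display_context <- function(upstream_arm = "PGG", downstream_arm = "HHHHHH",
                            insert_length = 9L) {
  split_residues(upstream_arm, "upstream_arm")
  split_residues(downstream_arm, "downstream_arm")
  insert_length <- as.integer(insert_length)
  stopifnot(insert_length >= 1L)
  structure(list(upstream_arm = toupper(upstream_arm),
                 downstream_arm = toupper(downstream_arm),
                 insert_length = insert_length),
            class = "display_context")
}

#' @export
print.display_context <- function(x, ...) {
  cat(sprintf("Display context: %s(X)%d%s\n",
              x$upstream_arm, x$insert_length, x$downstream_arm))
  invisible(x)
}

#' Peptide set constructor
#'
#' Peptides are represented throughout the package as a data frame with
#' columns `sequence` (insert residues) and `count` (multiplicity: the number
#' of times an identical sequence was observed among sequenced clones).
#'
#' @param sequence Character vector of residue strings.
#' @param count Integer multiplicities (recycled; default 1).
#' @return A `data.frame` with columns `sequence`, `count`.
#' @export
#' @examples
#' peptide_set(c("AAAFAAAAA", "GWGDESAAA"), count = c(3, 1))
peptide_set <- function(sequence, count = 1L) {
  if (length(sequence) == 0) stop("empty peptide set", call. = FALSE)
  for (s in sequence) split_residues(s, "sequence")
  count <- as.integer(rep_len(count, length(sequence)))
  if (any(count < 1L)) stop("multiplicity must be >= 1", call. = FALSE)
  data.frame(sequence = toupper(sequence), count = count,
             stringsAsFactors = FALSE)
}

#' Ground-truth specificity model for the biopanning simulator
#'
#' An independent-subsite (product of positional weights) model of extended
#' cleavage specificity. Each subsite of the frame carries a probability
#' vector over the 20 residues; a candidate cleavage site (a P1 residue in
#' the insert belonging to `admissible_p1`) is cleaved in one selection round
#' with probability `site_efficiency_scale` times the product of subsite
#' weights read off the displayed sequence at that alignment. Phages are also
#' released nonspecifically at rate `background_release` (the analogue of a
#' protease-free PBS control).
#'
#' @param subsite_weights Named list (or matrix with subsite rownames) mapping
#'   each frame subsite label to a 20-residue probability vector (named by
#'   residue or in [aa_alphabet()] order, summing to 1). Subsites omitted from
#'   the list default to the uniform vector.
#' @param admissible_p1 Character vector of residues that can occupy P1.
#' @param site_efficiency_scale Positive scale mapping the weight product to a
#'   per-round cleavage probability (capped at 1).
#' @param background_release Nonspecific per-round release probability in
#'   [0, 1).
#' @param frame A [subsite_frame()]; default P5-P4'.
#' @return An object of class `specificity_model` with a `weights` matrix
#'   (subsites x 20 residues).
#' @export
#' @examples
#' m <- specificity_model(
#'   subsite_weights = list(P1 = residue_weights(c(F = 1/3, Y = 1/3, W = 1/3))),
#'   admissible_p1 = c("F", "Y", "W"))
specificity_model <- function(subsite_weights = list(),
                              admissible_p1,
                              site_efficiency_scale = 1,
                              background_release = 1e-3,
                              frame = subsite_frame()) {
  aa <- aa_alphabet()
  stopifnot(is.numeric(site_efficiency_scale), site_efficiency_scale > 0,
            background_release >= 0, background_release < 1)
  admissible_p1 <- toupper(admissible_p1)
  if (!all(admissible_p1 %in% aa)) {
    stop("admissible_p1 contains non-standard residues", call. = FALSE)
  }
  w <- matrix(1 / 20, nrow = length(frame$labels), ncol = 20,
              dimnames = list(frame$labels, aa))
  if (is.matrix(subsite_weights)) {
    subsite_weights <- setNames(
      lapply(seq_len(nrow(subsite_weights)), function(i) subsite_weights[i, ]),
      rownames(subsite_weights))
  }
  for (lab in names(subsite_weights)) {
    if (!lab %in% frame$labels) {
      stop("unknown subsite label in subsite_weights: ", lab, call. = FALSE)
    }
    v <- subsite_weights[[lab]]
    if (!is.null(names(v))) {
      full <- setNames(numeric(20), aa)
      full[toupper(names(v))] <- v
      v <- full
    }
    if (length(v) != 20 || abs(sum(v) - 1) > 1e-9 || any(v < 0)) {
      stop(sprintf(
        "subsite %s weights must be a 20-residue probability vector (sum is %.6g)",
        lab, sum(v)), call. = FALSE)
    }
    w[lab, ] <- v
  }
  structure(list(weights = w, admissible_p1 = admissible_p1,
                 site_efficiency_scale = site_efficiency_scale,
                 background_release = background_release,
                 frame = frame),
            class = "specificity_model")
}

#' Build a 20-residue probability vector from named masses
#'
#' Helper for specifying subsite weights: named residue masses are placed on
#' the 20-residue alphabet and any remaining probability mass is spread
#' uniformly over the unnamed residues.
#'
#' @param masses Named numeric vector, e.g. `c(D = 0.25, E = 0.25)`; sum must
#'   not exceed 1.
#' @return Named numeric vector over [aa_alphabet()], summing to 1.
#' @export
#' @examples
#' residue_weights(c(D = 0.25, E = 0.25))["G"]  # (1 - 0.5) / 18
residue_weights <- function(masses) {
  aa <- aa_alphabet()
  stopifnot(!is.null(names(masses)), all(toupper(names(masses)) %in% aa),
            all(masses >= 0), sum(masses) <= 1 + 1e-12)
  v <- setNames(numeric(20), aa)
  v[toupper(names(masses))] <- masses
  rest <- setdiff(aa, toupper(names(masses)))
  if (length(rest) > 0) v[rest] <- (1 - sum(masses)) / length(rest)
  v / sum(v)
}

#' Generate a random peptide library
#'
#' Draws insert sequences i.i.d. per position from a residue composition,
#' emulating a randomized display library (e.g. 5e7 unique nonamer clones; at
#' simulation scale the library is smaller and identical draws are merged).
#'
#' @param n_clones Number of clones to draw (>= 1).
#' @param context A [display_context()].
#' @param composition Either `"uniform"` or a 20-vector of per-position
#'   residue probabilities (named by residue or in [aa_alphabet()] order).
#' @param seed Integer seed; generation is reproducible for a fixed seed.
#' @return A peptide data frame (`sequence`, `count`) of unique sequences
#'   whose counts sum to `n_clones`.
#' @export
#' @examples
#' lib <- generate_library(100, seed = 1)
#' sum(lib$count)
generate_library <- function(n_clones, context = display_context(),
                             composition = "uniform", seed) {
  n_clones <- as.integer(n_clones)
  if (is.na(n_clones) || n_clones < 1L) {
    stop("n_clones must be >= 1", call. = FALSE)
  }
  aa <- aa_alphabet()
  if (identical(composition, "uniform")) {
    comp <- rep(1 / 20, 20)
  } else {
    comp <- composition
    if (!is.null(names(comp))) comp <- comp[aa]
    if (length(comp) != 20 || any(is.na(comp)) || any(comp < 0) ||
        abs(sum(comp) - 1) > 1e-9) {
      stop(sprintf("composition is not a probability vector (sum is %.6g)",
                   sum(comp, na.rm = TRUE)), call. = FALSE)
    }
  }
  L <- context$insert_length
  seqs <- withr::with_seed(seed, {
    draws <- matrix(sample(aa, n_clones * L, replace = TRUE, prob = comp),
                    nrow = n_clones, ncol = L)
    do.call(paste0, as.data.frame(draws, stringsAsFactors = FALSE))
  })
  tab <- table(seqs)
  data.frame(sequence = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Residues of the displayed sequence covered by the frame when P1 sits at
# 1-based insert offset `offset`. Positions beyond the displayed sequence are
# NA. Returns a character vector named by subsite label, with an
# "arm_derived" logical attribute.
frame_residues_at <- function(sequence, offset, context, frame) {
  disp <- paste0(context$upstream_arm, sequence, context$downstream_arm)
  disp_chars <- strsplit(disp, "", fixed = TRUE)[[1]]
  n_up <- nchar(context$upstream_arm)
  p1_pos <- n_up + offset
  pos <- p1_pos + frame_offsets(frame)
  in_range <- pos >= 1 & pos <= length(disp_chars)
  res <- disp_chars[ifelse(in_range, pos, NA)]  # NA index keeps the slot
  arm <- !is.na(res) & (pos <= n_up | pos > n_up + nchar(sequence))
  names(res) <- frame$labels
  attr(res, "arm_derived") <- setNames(arm, frame$labels)
  res
}

# Per-site cleavage probabilities for one insert sequence: one value per
# admissible P1 offset. Subsites outside the displayed sequence contribute a
# uniform 1/20 factor (an unobserved random residue).
site_probabilities <- function(sequence, context, model) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  offsets <- which(chars %in% model$admissible_p1)
  if (length(offsets) == 0) return(numeric(0))
  vapply(offsets, function(o) {
    res <- frame_residues_at(sequence, o, context, model$frame)
    wts <- ifelse(is.na(res), 1 / 20,
                  model$weights[cbind(model$frame$labels, res)])
    min(1, model$site_efficiency_scale * prod(wts))
  }, numeric(1))
}

#' Per-round cleavage probability of a displayed peptide
#'
#' Probability that at least one admissible site within the insert is cleaved
#' in one selection round: `1 - prod(1 - p_site)` over candidate sites, where
#' each `p_site` is the scaled product of the model's subsite weights read off
#' the displayed sequence at that alignment. Sites whose P1 lies in the arms
#' are never cleavable (only insert cleavage releases the phage from the
#' beads), but primed-side subsites may read into the downstream His-tag arm.
#' Nonspecific background release is not included; see
#' [simulate_biopanning()].
#'
#' @param sequence Insert residue string (a single peptide sequence).
#' @param context A [display_context()].
#' @param model A [specificity_model()].
#' @return Probability in [0, 1].
#' @export
#' @examples
#' m <- specificity_model(admissible_p1 = "F", site_efficiency_scale = 20^9)
#' cleavage_probability("AAAAAAAAA", model = m)  # no candidate site -> 0
cleavage_probability <- function(sequence, context = display_context(),
                                 model) {
  p <- site_probabilities(sequence, context, model)
  if (length(p) == 0) return(0)
  1 - prod(1 - p)
}

# Release weights (cleavage + background, capped at 1) for a library of
# sequences. The workhorse of simulate_biopanning.
release_probabilities <- function(sequences, context, model) {
  p_cleave <- cleavage_probability_batch(sequences, context, model)
  pmin(1, p_cleave + model$background_release)
}

#' Simulate cleavage-driven biopanning selection
#'
#' Iterative selection of phage clones: in each round every displayed peptide
#' is released with probability `cleavage_probability + background_release`
#' (capped at 1), and the next round's sub-library is formed by resampling a
#' fixed number of phages (`carryover`) with multinomial weights proportional
#' to abundance times release probability. Enrichment per round is recorded as
#' the abundance-weighted mean release probability divided by
#' `background_release` — the simulated analogue of released phage counts
#' relative to a protease-free control.
#'
#' With `mode = "infinite"` the multinomial sampling is replaced by the exact
#' frequency-propagation recursion `f' = f * w / sum(f * w)` on the unique
#' sequences, providing a deterministic analytic reference for the finite
#' simulation.
#'
#' @param library Peptide data frame (`sequence`, `count`), e.g. from
#'   [generate_library()].
#' @param model A [specificity_model()].
#' @param rounds Number of selection rounds (>= 1; selections of this kind
#'   typically use 5-8).
#' @param carryover Number of phages resampled into each round
#'   (finite mode only; >= 1).
#' @param seed Integer seed (finite mode only).
#' @param context A [display_context()].
#' @param mode `"finite"` (multinomial resampling) or `"infinite"`
#'   (deterministic recursion on frequencies).
#' @return An object of class `biopanning_result`: list with
#'   `per_round_libraries` (peptide data frames; frequencies in a `freq`
#'   column in infinite mode), `per_round_enrichment`, `mode`, and the inputs.
#' @export
#' @examples
#' lib <- generate_library(500, seed = 1)
#' m <- specificity_model(admissible_p1 = "F", site_efficiency_scale = 20^8,
#'                        background_release = 0.01)
#' res <- simulate_biopanning(lib, m, rounds = 3, carryover = 500, seed = 2)
#' res$per_round_enrichment
simulate_biopanning <- function(library, model, rounds, carryover = NULL,
                                seed = NULL, context = display_context(),
                                mode = c("finite", "infinite")) {
  mode <- match.arg(mode)
  rounds <- as.integer(rounds)
  stopifnot(rounds >= 1L)
  if (mode == "finite") {
    stopifnot(!is.null(carryover), carryover >= 1L, !is.null(seed))
  }
  w_release <- release_probabilities(library$sequence, context, model)
  bg <- model$background_release
  per_round <- vector("list", rounds)
  enrich <- numeric(rounds)

  if (mode == "infinite") {
    freq <- library$count / sum(library$count)
    for (r in seq_len(rounds)) {
      mean_release <- sum(freq * w_release)
      enrich[r] <- if (bg > 0) mean_release / bg else NA_real_
      tot <- sum(freq * w_release)
      if (tot <= 0) {
        stop(sprintf("all-zero release weights in round %d", r), call. = FALSE)
      }
      freq <- freq * w_release / tot
      per_round[[r]] <- data.frame(sequence = library$sequence, freq = freq,
                                   stringsAsFactors = FALSE)
    }
    final <- per_round[[rounds]]
  } else {
    counts <- library$count
    round_seeds <- withr::with_seed(seed,
      sample.int(.Machine$integer.max, rounds))
    for (r in seq_len(rounds)) {
      wt <- counts * w_release
      mean_release <- sum(wt) / sum(counts)
      enrich[r] <- if (bg > 0) mean_release / bg else NA_real_
      if (sum(wt) <= 0) {
        stop(sprintf("all-zero release weights in round %d", r), call. = FALSE)
      }
      counts <- withr::with_seed(round_seeds[r], {
        as.integer(stats::rmultinom(1, size = carryover, prob = wt))
      })
      keep <- counts > 0
      per_round[[r]] <- data.frame(sequence = library$sequence[keep],
                                   count = counts[keep],
                                   stringsAsFactors = FALSE)
      # subsequent rounds operate on the full index to keep weights aligned
    }
    final <- per_round[[rounds]]
  }

  structure(list(per_round_libraries = per_round,
                 per_round_enrichment = enrich,
                 final_library = final, mode = mode,
                 model = model, context = context),
            class = "biopanning_result")
}

#' @export
print.biopanning_result <- function(x, ...) {
  cat(sprintf("Biopanning result (%s mode): %d round(s)\n",
              x$mode, length(x$per_round_libraries)))
  cat("Per-round enrichment vs background:",
      paste(signif(x$per_round_enrichment, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Sample sequenced clones from a selected library
#'
#' Draws `n` clones with replacement from the final library (abundance- or
#' frequency-weighted), merging identical sequences with summed multiplicity —
#' the simulated analogue of isolating plaques after the last biopanning and
#' sequencing ~96 clean PCR products, where recurrent sequences are reported
#' with their observed count.
#'
#' @param final_library Peptide data frame with `count` (finite mode) or
#'   `freq` (infinite mode) column, or a `biopanning_result`.
#' @param n Number of clones to sample (>= 1; default 96).
#' @param seed Integer seed.
#' @return Peptide data frame (`sequence`, `count`) with `sum(count) == n`.
#' @export
#' @examples
#' lib <- generate_library(1000, seed = 1)
#' clones <- sample_clones(lib, n = 96, seed = 2)
#' sum(clones$count)
sample_clones <- function(final_library, n = 96L, seed) {
  if (inherits(final_library, "biopanning_result")) {
    final_library <- final_library$final_library
  }
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (nrow(final_library) == 0) stop("empty library", call. = FALSE)
  wt <- if ("count" %in% names(final_library)) final_library$count
        else final_library$freq
  idx <- withr::with_seed(seed, {
    sample.int(nrow(final_library), n, replace = TRUE, prob = wt)
  })
  tab <- table(final_library$sequence[idx])
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a first-order cleavage time course
#'
#' Fraction cleaved follows `f(t) = 1 - exp(-k t)`; observations add
#' truncated Gaussian noise and are clipped to [0, 1]. With
#' `value_kind = "absorbance"` the returned signal is
#' `baseline + amplitude * f(t)` (noise added on the fraction scale before
#' scaling), emulating chromogenic substrate hydrolysis monitored at 405 nm.
#'
#' @param k First-order rate constant per minute (>= 0).
#' @param times Sampling times in minutes (non-negative).
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   fraction scale (>= 0).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @param value_kind `"fraction"` or `"absorbance"`.
#' @param baseline,amplitude Absorbance transform parameters.
#' @param substrate_id Identifier carried into the result.
#' @return A [time_course()] object.
#' @export
#' @examples
#' simulate_timecourse(0.02, c(0, 15, 45, 150), noise_sd = 0)$values
simulate_timecourse <- function(k, times, noise_sd = 0, seed = NULL,
                                value_kind = c("fraction", "absorbance"),
                                baseline = 0.05, amplitude = 1,
                                substrate_id = "substrate") {
  value_kind <- match.arg(value_kind)
  stopifnot(k >= 0, all(times >= 0))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  f <- 1 - exp(-k * times)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed is required when noise_sd > 0", call. = FALSE)
    f <- withr::with_seed(seed, f + stats::rnorm(length(times), 0, noise_sd))
    f <- pmin(1, pmax(0, f))
  }
  values <- if (value_kind == "fraction") f else baseline + amplitude * f
  time_course(substrate_id, times, values, value_kind = value_kind)
}
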