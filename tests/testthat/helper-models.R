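# Shared fixtures: small ground-truth models, instance generators and
# independent oracles used across test files.

# A model whose only non-uniform subsites are P1 (aromatic) and P2' (acidic
# mass 0.5); the default scale puts background-typical sites at partial
# per-round survival while acidic-P2' sites saturate, the regime in which
# sampled clones reflect the planted subsite weights.
chymase_model <- function(scale = 6e10, background = 1e-3) {
  specificity_model(
    subsite_weights = list(
      "P1" = residue_weights(c(F = 1 / 3, Y = 1 / 3, W = 1 / 3)),
      "P2'" = residue_weights(c(D = 0.25, E = 0.25))),
    admissible_p1 = c("F", "Y", "W"),
    site_efficiency_scale = scale,
    background_release = background)
}

# A model with exactly one cleavable site of known probability: P1 = F with
# weight 1, all other subsites uniform. scale chosen so p_site = p for a
# peptide with one F.
single_site_model <- function(p, background = 0) {
  specificity_model(
    subsite_weights = list("P1" = residue_weights(c(F = 1))),
    admissible_p1 = "F",
    site_efficiency_scale = p * 20^8,
    background_release = background)
}

# Independent oracle for cleavage_probability: enumerate all per-site
# Bernoulli outcome combinations and sum the probability of "at least one
# site cleaved".
brute_force_cleavage <- function(sequence, context, model) {
  p <- cleavemap:::site_probabilities(sequence, context, model)
  if (length(p) == 0) return(0)
  stopifnot(length(p) <= 6)
  outcomes <- expand.grid(rep(list(c(0, 1)), length(p)))
  total <- 0
  for (i in seq_len(nrow(outcomes))) {
    o <- as.numeric(outcomes[i, ])
    if (sum(o) == 0) next
    total <- total + prod(ifelse(o == 1, p, 1 - p))
  }
  total
}

# Random small alignment instances with >= 1 unambiguous peptide, <= 3
# candidate sites per peptide and a bounded number of ambiguous peptides, so
# joint assignments can be enumerated exhaustively.
random_alignment_instance <- function(seed, p1_set = c("F", "Y"),
                                      n_range = 8:12, max_ambiguous = 5) {
  pool <- c("A", "G", "D", "E", "S", "L", "V", "F", "Y")
  prob <- c(.2, .14, .1, .1, .12, .12, .1, .07, .05)
  withr::with_seed(seed, {
    repeat {
      n <- sample(n_range, 1)
      seqs <- replicate(n, paste(sample(pool, 9, TRUE, prob), collapse = ""))
      ns <- vapply(seqs, function(s) {
        sum(strsplit(s, "")[[1]] %in% p1_set)
      }, numeric(1))
      if (all(ns >= 1) && all(ns <= 3) && sum(ns == 1) >= 1 &&
          sum(ns >= 2) >= 1 && sum(ns >= 2) <= max_ambiguous) {
        return(peptide_set(unique(seqs)))
      }
    }
  })
}

# Exhaustive joint-assignment oracle: the maximal total profile
# log-likelihood over every combination of candidate offsets for the
# ambiguous peptides.
exhaustive_best_ll <- function(peptides, p1_set, pseudocount = 0.5) {
  parts <- align_unambiguous(peptides, p1_set)
  bg <- cleavemap:::empirical_background(peptides)
  amb <- parts$ambiguous
  combos <- expand.grid(lapply(amb, `[[`, "sites"))
  if (nrow(combos) == 0) combos <- data.frame(row.names = 1)
  best <- -Inf
  for (i in seq_len(nrow(combos))) {
    al <- c(parts$aligned, lapply(seq_along(amb), function(j) {
      cleavemap:::new_aligned_peptide(amb[[j]]$sequence, amb[[j]]$count,
                                      combos[i, j], display_context(),
                                      subsite_frame())
    }))
    ll <- cleavemap:::assignment_log_likelihood(al, pseudocount, bg, "mask",
                                                subsite_frame())
    if (ll > best) best <- ll
  }
  best
}

# One biopanning + alignment recovery replicate under a planted model.
recovery_replicate <- function(model, p1_set, seed, n_clones = 1e5,
                               rounds = 5, n_sampled = 96) {
  seeds <- withr::with_seed(seed, sample.int(2^31 - 1, 3))
  lib <- generate_library(n_clones, seed = seeds[1])
  res <- simulate_biopanning(lib, model, rounds = rounds,
                             carryover = n_clones, seed = seeds[2])
  clones <- sample_clones(res, n = n_sampled, seed = seeds[3])
  resolve_and_iterate(clones, p1_set)
}
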