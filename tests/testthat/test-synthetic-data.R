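# Library generation, cleavage model, biopanning selection, clone sampling
# and kinetic time-course simulation.

test_that("generate_library draws per-position from the composition", {
  # degenerate composition puts every residue at A
  comp <- residue_weights(c(A = 1))
  lib <- generate_library(1, composition = comp, seed = 1)
  expect_equal(lib$sequence, "AAAAAAAAA")
  expect_equal(lib$count, 1L)

  # uniform composition: per-position frequencies near 1/20
  lib <- generate_library(1e4, seed = 1)
  chars <- do.call(rbind, strsplit(rep(lib$sequence, lib$count), ""))
  for (pos in c(1, 5, 9)) {
    freq <- table(factor(chars[, pos], levels = aa_alphabet())) / nrow(chars)
    expect_true(all(abs(freq - 0.05) < 0.01))
  }
  expect_equal(sum(lib$count), 1e4)
})

test_that("generate_library rejects bad inputs and is seed-reproducible", {
  expect_error(generate_library(0, seed = 1), "n_clones")
  bad <- rep(0.1, 20)  # sums to 2
  expect_error(generate_library(10, composition = bad, seed = 1), "2")
  expect_identical(generate_library(500, seed = 7),
                   generate_library(500, seed = 7))
  expect_false(identical(generate_library(500, seed = 7),
                         generate_library(500, seed = 8)))
})

test_that("cleavage_probability handles zero-, one- and two-site peptides", {
  m <- single_site_model(0.5)
  expect_equal(cleavage_probability("AAAAAAAAA", model = m), 0)
  expect_equal(cleavage_probability("AAAFAAAAA", model = m), 0.5,
               tolerance = 1e-12)
  # two independent sites at p = 0.5 each: 1 - 0.25
  expect_equal(cleavage_probability("AFAAAFAAA", model = m), 0.75,
               tolerance = 1e-12)
})

test_that("cleavage_probability equals brute-force outcome enumeration", {
  ctx <- display_context()
  models <- list(single_site_model(0.3), chymase_model(scale = 3e10))
  seqs <- withr::with_seed(11, replicate(25, paste(
    sample(c("A", "G", "F", "Y", "W", "D", "E", "S"), 9, TRUE,
           prob = c(.25, .15, .12, .1, .08, .1, .1, .1)), collapse = "")))
  for (m in models) {
    for (s in seqs) {
      n_sites <- length(cleavemap:::site_probabilities(s, ctx, m))
      if (n_sites > 4) next
      expect_equal(cleavage_probability(s, ctx, m),
                   brute_force_cleavage(s, ctx, m), tolerance = 1e-12)
    }
  }
})

test_that("batch cleavage probabilities agree with the per-peptide path", {
  ctx <- display_context()
  m <- chymase_model()
  seqs <- generate_library(300, seed = 3)$sequence
  batch <- cleavemap:::cleavage_probability_batch(seqs, ctx, m)
  single <- vapply(seqs, cleavage_probability, numeric(1),
                   context = ctx, model = m, USE.NAMES = FALSE)
  expect_equal(batch, single, tolerance = 1e-12)
})

test_that("null-model biopanning shows no enrichment", {
  null_model <- specificity_model(admissible_p1 = character(0),
                                  background_release = 0.01)
  lib <- generate_library(2000, seed = 21)
  res <- simulate_biopanning(lib, null_model, rounds = 4, carryover = 2000,
                             seed = 22)
  # release weight is exactly the background for every clone
  expect_equal(res$per_round_enrichment, rep(1, 4), tolerance = 1e-12)
  inf <- simulate_biopanning(lib, null_model, rounds = 4, mode = "infinite")
  expect_equal(inf$per_round_enrichment, rep(1, 4), tolerance = 1e-12)
})

test_that("infinite-population mode reproduces the analytic recursion", {
  # two-type library: 1% motif with known p_site, 99% inert background
  m <- single_site_model(0.4, background = 0.01)
  lib <- data.frame(sequence = c("AAAFAAAAA", "AAAAAAAAA"),
                    count = c(10L, 990L), stringsAsFactors = FALSE)
  res <- simulate_biopanning(lib, m, rounds = 3, mode = "infinite")
  # independent closed-form recursion on the motif frequency
  f <- 0.01
  w <- c(min(1, 0.4 + 0.01), 0.01)
  expected <- numeric(3)
  for (r in 1:3) {
    f <- f * w[1] / (f * w[1] + (1 - f) * w[2])
    expected[r] <- f
  }
  got <- vapply(res$per_round_libraries, function(d) d$freq[1], numeric(1))
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("finite-population prevalence matches the recursion within 3 SE", {
  m <- single_site_model(0.4, background = 0.01)
  lib <- data.frame(sequence = c("AAAFAAAAA", "AAAAAAAAA"),
                    count = c(50L, 4950L), stringsAsFactors = FALSE)
  inf <- simulate_biopanning(lib, m, rounds = 3, mode = "infinite")
  target <- inf$per_round_libraries[[3]]$freq[1]
  n_rep <- 12
  prev <- vapply(seq_len(n_rep), function(r) {
    res <- simulate_biopanning(lib, m, rounds = 3, carryover = 5000,
                               seed = 500 + r)
    fin <- res$final_library
    i <- match("AAAFAAAAA", fin$sequence)
    if (is.na(i)) 0 else fin$count[i] / sum(fin$count)
  }, numeric(1))
  se <- stats::sd(prev) / sqrt(n_rep)
  expect_lt(abs(mean(prev) - target), 3 * se + 1e-12)
})

test_that("biopanning is seed-reproducible and reports all-zero weights", {
  m <- chymase_model()
  lib <- generate_library(1000, seed = 31)
  r1 <- simulate_biopanning(lib, m, rounds = 2, carryover = 1000, seed = 32)
  r2 <- simulate_biopanning(lib, m, rounds = 2, carryover = 1000, seed = 32)
  expect_identical(r1$final_library, r2$final_library)
  dead <- specificity_model(admissible_p1 = character(0),
                            background_release = 0)
  expect_error(simulate_biopanning(lib, dead, rounds = 2, carryover = 10,
                                   seed = 1), "round 1")
})

test_that("sample_clones merges duplicates and keeps the requested size", {
  lib <- data.frame(sequence = "AAAFAAAAA", count = 5L,
                    stringsAsFactors = FALSE)
  cl <- sample_clones(lib, n = 96, seed = 41)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$count, 96L)

  # draws from a large uniform library are essentially duplicate-free
  big <- generate_library(5e4, seed = 42)
  cl <- sample_clones(big, n = 96, seed = 43)
  expect_gte(nrow(cl), 95)
  expect_equal(sum(cl$count), 96L)
  expect_identical(cl, sample_clones(big, n = 96, seed = 43))
  expect_error(sample_clones(big[0, ], n = 10, seed = 1), "empty")
})

test_that("simulate_timecourse follows the first-order closed form", {
  tc <- simulate_timecourse(0, c(0, 10, 20), noise_sd = 0)
  expect_equal(tc$values, c(0, 0, 0))
  tc <- simulate_timecourse(0.01, c(0, 150), noise_sd = 0)
  expect_equal(tc$values[2], 1 - exp(-1.5), tolerance = 1e-10)
  tc <- simulate_timecourse(0.02, c(0, 15, 45, 150), noise_sd = 0)
  expect_equal(tc$values, c(0, 0.2592, 0.5934, 0.9502), tolerance = 1e-4)
  expect_error(simulate_timecourse(0.01, c(0, 10), noise_sd = -1), "noise_sd")
  # noisy values stay in [0, 1] and are seed-reproducible
  tc1 <- simulate_timecourse(0.02, 0:50, noise_sd = 0.1, seed = 5)
  tc2 <- simulate_timecourse(0.02, 0:50, noise_sd = 0.1, seed = 5)
  expect_identical(tc1$values, tc2$values)
  expect_true(all(tc1$values >= 0 & tc1$values <= 1))
})

test_that("absorbance time courses apply baseline and amplitude", {
  tc <- simulate_timecourse(0.02, c(0, 15), noise_sd = 0,
                            value_kind = "absorbance",
                            baseline = 0.1, amplitude = 2)
  expect_equal(tc$values, 0.1 + 2 * (1 - exp(-0.02 * c(0, 15))),
               tolerance = 1e-12)
})

test_that("motif prevalence is non-decreasing across rounds in expectation", {
  m <- single_site_model(0.4, background = 0.01)
  lib <- data.frame(sequence = c("AAAFAAAAA", "AAAAAAAAA"),
                    count = c(100L, 9900L), stringsAsFactors = FALSE)
  inf <- simulate_biopanning(lib, m, rounds = 5, mode = "infinite")
  freqs <- vapply(inf$per_round_libraries, function(d) d$freq[1], numeric(1))
  expect_true(all(diff(c(0.01, freqs)) > 0))
})
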