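# Site enumeration, unambiguous anchoring, profile construction, offset
# scoring and the iterative profile/placement loop.

test_that("enumerate_sites scans the insert for candidate P1 residues", {
  expect_equal(enumerate_sites("AAAFAAAAA", "F"), 4L)
  expect_equal(enumerate_sites("AFAAYAAAW", c("F", "Y", "W")), c(2L, 5L, 9L))
  expect_equal(enumerate_sites("AAAAAAAAA", c("F", "Y", "W")), integer(0))
  # arm residues are never candidate sites even when in the P1 set
  expect_equal(enumerate_sites("AAAAAAAAA", c("P", "G", "H")), integer(0))
  expect_error(enumerate_sites("AAAFAAAAA", character(0)), "empty")
})

test_that("align_unambiguous partitions peptides disjointly", {
  peps <- peptide_set(c("AAAFAAAAA",   # one site -> aligned
                        "AFAAAFAAA",   # two sites -> ambiguous
                        "AAAAAAAAA"))  # no site -> unalignable
  parts <- align_unambiguous(peps, "F")
  expect_length(parts$aligned, 1)
  expect_length(parts$ambiguous, 1)
  expect_length(parts$unalignable, 1)
  ap <- parts$aligned[[1]]
  expect_equal(ap$p1_offset, 4L)
  expect_equal(unname(ap$frame_residues[c("P1", "P1'", "P2'")]),
               c("F", "A", "A"))
  # frame positions outside the insert read from the arms and are flagged
  ap_edge <- align_unambiguous(peptide_set("FAAAAAAAA"), "F")$aligned[[1]]
  expect_equal(unname(ap_edge$frame_residues[c("P2", "P3", "P4")]),
               c("G", "G", "P"))
  expect_true(all(ap_edge$arm_derived[c("P2", "P3", "P4")]))
  expect_true(is.na(ap_edge$frame_residues[["P5"]]))
})

test_that("build_profile weights, masks and normalizes correctly", {
  aligned <- align_unambiguous(peptide_set("DAGFAEAAA"), "F")$aligned
  prof <- build_profile(aligned, pseudocount = 0, arm_policy = "include")
  # indicator distributions at observed residues
  expect_equal(unname(prof$probs["P1", "F"]), 1)
  expect_equal(unname(prof$probs["P2'", "E"]), 1)
  expect_equal(unname(rowSums(prof$probs)), rep(1, 9))

  # two identical peptides == one peptide with multiplicity 2
  two <- align_unambiguous(peptide_set(c("DAGFAEAAA", "DAGFAEAAA")),
                           "F")$aligned
  one_x2 <- align_unambiguous(peptide_set("DAGFAEAAA", count = 2),
                              "F")$aligned
  p_two <- build_profile(two, pseudocount = 0.5)
  p_one <- build_profile(one_x2, pseudocount = 0.5)
  expect_equal(p_two$probs, p_one$probs)
  expect_equal(p_two$effective_n, p_one$effective_n)

  # unique weighting ignores multiplicity
  p_uniq <- build_profile(one_x2, pseudocount = 0.5, weighting = "unique")
  expect_equal(unname(p_uniq$effective_n["P1"]), 1)

  # pseudocount lower bound on every probability
  aligned_many <- align_unambiguous(
    peptide_set(c("DAGFAEAAA", "GGAFDESTA", "AAWFAEGGA")), "F")$aligned
  pc <- 0.5
  prof <- build_profile(aligned_many, pseudocount = pc)
  n_eff <- prof$effective_n
  for (s in rownames(prof$probs)) {
    expect_true(all(prof$probs[s, ] >= pc / (n_eff[[s]] + 20 * pc) - 1e-12))
  }
  expect_error(build_profile(list()), "zero")
})

test_that("arm masking removes arm-derived counts from the profile", {
  # P1 at offset 1: P2-P4 read GGP from the upstream arm
  aligned <- align_unambiguous(peptide_set("FAAAAAAAA"), "F")$aligned
  masked <- build_profile(aligned, pseudocount = 0, arm_policy = "mask")
  included <- build_profile(aligned, pseudocount = 0, arm_policy = "include")
  expect_equal(unname(masked$effective_n[c("P2", "P3", "P4")]), c(0, 0, 0))
  expect_equal(unname(included$probs["P2", "G"]), 1)
  # masking never increases the upstream Gly frequency
  expect_lte(masked$probs["P2", "G"], included$probs["P2", "G"])
  expect_lte(masked$probs["P3", "G"], included$probs["P3", "G"])
})

test_that("score_offset matches its closed forms", {
  aa <- aa_alphabet()
  uniform_bg <- setNames(rep(1 / 20, 20), aa)
  # profile equal to background scores zero at every offset
  flat <- build_profile(
    align_unambiguous(peptide_set("AAAFAAAAA"), "F")$aligned)
  flat$probs[] <- 1 / 20
  for (o in enumerate_sites("AFAYAFAYA", c("F", "Y"))) {
    expect_equal(score_offset("AFAYAFAYA", o, flat, uniform_bg), 0)
  }

  # indicator profile, matching peptide, all frame positions inside the
  # insert: 8 scored subsites, each log(20)
  pep <- "DAGWFEASA"   # P1 = F at offset 5; P5..P4' covers offsets 1..9
  prof <- build_profile(align_unambiguous(peptide_set(pep), "F")$aligned,
                        pseudocount = 0, arm_policy = "include")
  expect_equal(score_offset(pep, 5, prof, uniform_bg), 8 * log(20),
               tolerance = 1e-12)

  # chosen offset equals the exhaustive argmax
  prof2 <- build_profile(align_unambiguous(
    peptide_set(c("DAGWFEASA", "AAGWFEAGA")), "F")$aligned)
  two_site <- "AAFWFEAGA"
  sites <- enumerate_sites(two_site, "F")
  scores <- vapply(sites, function(o) {
    score_offset(two_site, o, prof2, uniform_bg)
  }, numeric(1))
  expect_equal(sites[which.max(scores)], 5L)
  expect_error(score_offset(pep, 5, prof, rep(0, 20)), "background")
})

test_that("resolve_and_iterate is a fixed point on unambiguous input", {
  peps <- peptide_set(c("AAAFAAAAA", "DAGFAEAAA"))
  aln <- resolve_and_iterate(peps, "F")
  expect_equal(aln$n_iterations, 1L)
  expect_true(aln$converged)
  expect_equal(vapply(aln$aligned, `[[`, integer(1), "p1_offset"),
               c(4L, 4L))
  parts <- align_unambiguous(peps, "F")
  expect_setequal(vapply(aln$aligned, `[[`, character(1), "sequence"),
                  vapply(parts$aligned, `[[`, character(1), "sequence"))
})

test_that("every aligned P1 residue belongs to the candidate set", {
  for (s in 1:5) {
    peps <- random_alignment_instance(s)
    aln <- resolve_and_iterate(peps, c("F", "Y"))
    p1s <- vapply(aln$aligned, function(ap) {
      ap$frame_residues[["P1"]]
    }, character(1))
    expect_true(all(p1s %in% c("F", "Y")))
  }
})

test_that("the objective trace is non-decreasing and reaches the optimum", {
  for (s in 1:10) {
    peps <- random_alignment_instance(s)
    aln <- resolve_and_iterate(peps, c("F", "Y"))
    expect_true(all(diff(aln$ll_trace) > -1e-9))
    expect_equal(aln$log_likelihood, exhaustive_best_ll(peps, c("F", "Y")),
                 tolerance = 1e-9)
  }
})

test_that("alignment is invariant to input peptide order", {
  peps <- random_alignment_instance(99)
  aln1 <- resolve_and_iterate(peps, c("F", "Y"))
  perm <- withr::with_seed(7, peps[sample.int(nrow(peps)), , drop = FALSE])
  aln2 <- resolve_and_iterate(perm, c("F", "Y"))
  expect_identical(alignment_table(aln1), alignment_table(aln2))
  expect_equal(aln1$profile$probs, aln2$profile$probs)
})

test_that("alignment errors without anchors and accepts a P1 set object", {
  amb_only <- peptide_set("AFAFAAAAA")  # two sites, nothing unambiguous
  expect_error(resolve_and_iterate(amb_only, "F"), "unambiguous")
  p1 <- structure(list(residues = "F", threshold_used = 0.2,
                       provenance = "test"), class = "p1_candidate_set")
  aln <- resolve_and_iterate(peptide_set(c("AAAFAAAAA", "AFAFAAAAA")), p1)
  expect_length(aln$aligned, 2)
})

test_that("alignment_table mirrors the subsite layout", {
  aln <- resolve_and_iterate(peptide_set("DAGFAEAAA", count = 3), "F")
  tab <- alignment_table(aln)
  expect_equal(tab$P1, "F")
  expect_equal(tab$"P2'", "E")
  expect_equal(tab$count, 3L)
  # arm-derived positions are lower-cased
  tab_edge <- alignment_table(resolve_and_iterate(
    peptide_set(c("FAAAAAAAA", "AAAFAAAAA")), "F"))
  expect_equal(tab_edge$P2[tab_edge$sequence == "FAAAAAAAA"], "g")
})
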