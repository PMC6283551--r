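---
title: "Profiling extended protease cleavage specificity from substrate phage display"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling extended protease cleavage specificity from substrate phage display}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Serine proteases such as the mast-cell chymases recognise their substrates
through a set of subsites flanking the scissile bond. In Schechter–Berger
nomenclature the substrate residues are counted outward from the cleaved
bond: P1 immediately N-terminal of the cut, P1' immediately C-terminal, so
that cleavage occurs between P1 and P1'. The *primary* specificity — which
residues are tolerated at P1 — is classically read off a panel of
chromogenic para-nitroanilide (pNA) substrates: hydrolysis releases the
chromophore and the initial rise in A405 measures activity against each P1
variant. The *extended* specificity — preferences at P5 through P4' — can be
determined by substrate phage display: a library of phages displaying random
nonamer peptides between a constant arm (ending in PGG) and a C-terminal
His6 tag is immobilised on Ni-NTA beads; only phages whose displayed insert
is cleaved are released, and iterating this selection over several
biopanning rounds enriches cleavable sequences. Sequencing ~96 clones after
the last round, anchoring each nonamer at its cleavage position, and
tabulating residue frequencies per subsite gives a positional profile that
can be rendered as a probability-unit sequence logo.

`cleavemap` implements this analysis chain end to end — P1 calling from
panel kinetics, anchored alignment, positional profiling and logos, and
substrate efficiency ranking from cleavage time courses — together with a
seeded biopanning simulator, so that every stage can be validated against a
known ground truth without any experimental input.

## The simulator

### Model

The ground truth is an independent-subsite model (`specificity_model()`):
each subsite of the P5–P4' frame carries a probability vector over the 20
residues, and a candidate site (an insert residue from the admissible P1 set)
is cleaved in one round with probability

$$p_{\text{site}} = \min\!\left(1,\; c \prod_{s \in \text{frame}} w_s(x_s)\right),$$

where $c$ is `site_efficiency_scale` and $x_s$ the residue the frame reads
at subsite $s$ of that alignment. A peptide with several candidate sites is
released if at least one site is cleaved,
$p = 1 - \prod_i (1 - p_{\text{site},i})$. Sites whose P1 would fall in the
constant arms are never cleavable (only insert cleavage releases the phage),
but primed subsites of an insert site may read into the His-tag arm. Frame
positions that fall outside the displayed sequence altogether (P5 for a site
at the first insert position) contribute a neutral uniform factor of 1/20.
There are no pairwise couplings between subsites — deliberately, since the
positional-frequency representation the pipeline reports is itself
independent per subsite.

### Selection

`simulate_biopanning()` resamples a fixed number of phages each round with
multinomial weights proportional to abundance times the release probability
$\min(1, p + b)$, where $b$ (`background_release`) is the nonspecific
release rate — the analogue of the protease-free PBS control. Enrichment per
round is reported as the abundance-weighted mean release probability divided
by $b$. A deterministic infinite-population mode propagates frequencies by
the exact recursion $f' \propto f \cdot w$ and serves as the analytic
reference for the finite simulation in the tests.

### Default conditions

The defaults emulate the selection experiment the pipeline is designed to
analyse: nonamers in the context PGG(X)9HHHHHH, five biopanning rounds
(round counts are a config parameter; such selections typically run five to
eight rounds), 96 sequenced clones with duplicates merged by multiplicity,
and library sizes of 2×10^4 (demo) to 10^5 (validation runs) — scaled-down
stand-ins for the experimental 5×10^7 diversity that keep simulations fast
while leaving the per-clone selection dynamics unchanged.

`site_efficiency_scale` deserves comment. Iterated selection compounds
per-round survival ratios geometrically, so the residue distribution among
surviving clones generally does *not* equal the model's subsite weights: too
weak a selection leaves the library unselected, too discriminating a
selection drives the best extended sequences to fixation. The simulator's
default scale (6×10^10 for the bundled models) is calibrated once so that
favoured sites saturate ($p_{\text{site}} = 1$) while background-typical
sites retain a partial per-round survival — the regime in which the
sampled-clone subsite distribution reproduces the planted weights at face
value (a planted P2' acidic mass of 0.5 is recovered as ≈0.5 from 96 clones
after five rounds). This mirrors the operating point of the real assay,
where favoured substrates are cleaved to completion within a round while
mediocre ones are only partially released.

What the simulator does **not** model: phage amplification bias and burst
size, Ni-NTA binding chemistry, PCR and sequencing errors, and any coupling
between subsites. Passing recovery tests therefore shows that the analysis
chain is correct and well-calibrated for selection-driven data of this
structure — not that real libraries are free of these additional effects.

## Panel kinetics and P1 calling

`estimate_initial_rate()` fits the least-squares slope over the initial
near-linear window of the A405 trace: the earliest points whose rise stays
within 20% (`window_fraction`) of the total signal rise, minimum three
points. The estimate is invariant to baseline shifts and linear in signal
amplitude; negative slopes are clipped to zero. Relative activities are
expressed against the panel maximum, and `call_p1_candidates()` admits every
residue whose best substrate reaches at least 20% of that maximum. No
universal cut-off exists for such panels; 0.2 cleanly separates the
"cleaved efficiently" from the "not cleaved" pattern that P1 panels of
chymases and elastases show in practice, and it is exposed in the
configuration. The call is monotone: raising the threshold never adds
residues.

`classify_primary_specificity()` maps the called set onto the conventional
labels — chymotryptic (⊆ {F, Y, W} with Leu tolerated), elastolytic
(⊆ {A, V, I} with Leu tolerated), tryptic ({K, R}), asp-ase ({D, E}),
`mixed` otherwise, `undetermined` when empty. Leu alone is ambiguous between
the two aliphatic-tolerant classes and is reported as `mixed`. Note the
asymmetry the pipeline deliberately preserves: chromogenic Leu substrates
are often not cleaved by chymases whose recombinant Leu-P1 substrates are
cleaved efficiently (a roughly 3-fold drop against the best aromatic
substrates is typical). Leu is therefore *not* part of the default
anchoring P1 set for a chymotryptic enzyme, but both readouts — the panel
call and the recombinant-substrate ranking — are reported side by side and
never merged.

For recombinant (two-thioredoxin type) substrate time courses,
`fit_rate_constant()` fits the single-exponential
$f(t) = 1 - e^{-kt}$ by least squares. Because the problem has one
parameter, the fit uses a log-spaced grid bracket followed by
golden-section refinement and a short Gauss–Newton polish; it cannot fail to
converge, recovers $k$ to at least four significant digits on noiseless data
for $k\,t_{\max} \in [0.1, 5]$, and returns $k = 0$ for flat traces.
`rank_efficiencies()` sorts substrates by $k$ and reports
`fold_vs_best` $= k_{\text{best}}/k$, flagging uncleaved substrates rather
than dividing by zero.

## Anchored alignment

The alignment procedure formalises the manual consensus construction used
with phage-display cleavage data: every selected nonamer must be placed so
that a P1-candidate residue sits at the cleavage position of the fixed
frame.

1. **Anchors.** Peptides with exactly one candidate residue are aligned at
   it (`align_unambiguous()`); they are the evidence that does not depend on
   any modelling choice. Peptides with no candidate are set aside as
   unalignable and excluded from the profile (one cleavage site per peptide,
   matching how such alignments are reported).
2. **Profile.** `build_profile()` tabulates per-subsite residue counts,
   weighted by clone multiplicity by default (`weighting = "unique"` is
   available; published figures report duplicate counts, and weighting by
   them is the natural reading, but whether published percentage tables do
   so is generally unstated — hence both modes). A Dirichlet pseudocount of
   0.5 per residue per subsite regularises the profile and keeps every
   placement scoreable.
3. **Ambiguous placement.** Candidate offsets are scored by
   `score_offset()`: the sum over non-P1 frame subsites of
   $\log(p_s(x_s)/q(x_s))$ against a background $q$, by default the
   empirical residue composition of the input peptides (the library
   composition as observed, which absorbs library bias). P1 is excluded so
   that the choice among candidate sites is driven by the extended
   positions. The total objective of an assignment is this score summed
   over all aligned peptides plus the pseudocount penalty, evaluated under
   the profile refit from that same assignment. `resolve_and_iterate()`
   maximises it by coordinate ascent — each ambiguous peptide in turn is
   re-placed at the offset that maximises the total objective, profile
   refit included — iterating sweeps to a fixed point. Each move is exactly
   monotone, and the per-sweep objective trace is exposed as `ll_trace`.
   Because single-move ascent can stall on joint moves, the ascent is run
   from a small set of deterministic initialisations (the score-based
   placement plus cyclic candidate-site placements) and the best converged
   solution is kept; on exhaustive-enumeration probes (≤ 12 peptides, ≤ 3
   sites each) this attains the global joint optimum.
4. **Determinism.** Ties are broken by the smallest (most N-terminal)
   offset; ambiguous peptides are processed in canonical sequence order, so
   the result is invariant to input order. Offsets are 1-based, the R
   convention, and appear in reports only through Schechter–Berger labels.
   `max_iter` defaults to 50; non-convergence (never observed in testing)
   warns and returns the last state.

### Arm policy

Frame positions can extend past the randomized insert into the constant
arms. Because the upstream arm ends in PGG, counting arm residues inflates
Gly at P2–P4 for sites near the insert start — an artefact of the vector,
not of selection. The default (`arm_policy = "mask"`) therefore counts only
insert-derived residues; `"include"` is available for faithful
reproduction of alignment-table figures that display the arm residues.
Masked subsites simply contribute fewer observations (`effective_n` is
reported per subsite). Positions outside the displayed sequence entirely
are never counted under either policy.

The alignment frame is P5–P4' (the widest window the nonamer context
supports); reported profiles default to the P4–P4' window in which such
results are conventionally displayed. Both are `subsite_frame()` options.

## Reporting layer

`group_percentages()` collapses residue percentages into side-chain
classes: aromatic (F, Y, W), small aliphatic (G, A), large aliphatic
(V, L, I, P), hydrophilic (S, T, H, N, Q, C, M), basic (K, R), acidic
(D, E). `logo_matrix()` passes probabilities through unchanged (probability
units, not information content) and attaches the conventional logo colour
classes — K, R, H yellow; D, E red; F, Y, W green; S, T, C, M, N, Q white;
G, A, V, L, I, P blue. The two schemes intentionally disagree on His
(hydrophilic in the grouping, coloured with the basic residues in logos);
both usages are established, so both are provided as distinct named
schemes rather than silently reconciled. `consensus_string()` summarises a
profile with one symbol per subsite (residue if its probability exceeds the
threshold, lowercase class initial if a class dominates, else `x`);
`p2prime_acidity()` reports the D+E mass at P2', the standard summary for
comparing chymases' acidic P2' preference; and `profile_divergence()`
computes per-subsite base-2 Jensen–Shannon divergence (symmetric, in
[0, 1]) for cross-enzyme comparison.

## Numerical choices, degenerate inputs, limitations

* Subsite probability vectors must sum to 1 within 1e-9; profile columns
  are renormalized on TSV round trips to absorb print rounding.
* A profile built from zero observations at a subsite (fully masked) falls
  back to the uniform distribution.
* All-zero panels yield an empty P1 set with a warning, and an
  `undetermined` classification; all-zero time-course sets refuse to rank.
* Seeds are explicit function arguments everywhere; nothing reads or writes
  global RNG state (`withr::with_seed` scopes every draw), so identical
  config + seed reproduce byte-identical artifacts.
* Problem sizes in the bundled validation runs — 10^5-clone libraries, five
  rounds, 96 clones, 20 replicates — were chosen as the smallest sizes at
  which recovery statistics are stable; the simulator itself handles larger
  libraries linearly in clone count.
* The aligner models exactly one cleavage site per peptide; peptides whose
  true susceptibility involves several sites are represented by their
  best-scoring site only.
* Gapped alignment, automatic P1-set discovery from the peptides
  themselves, Michaelis–Menten parameterisation (panel assays run at a
  single substrate concentration) and gel densitometry are out of scope.

## A worked run

```{r, eval = FALSE}
library(cleavemap)

cfg <- demo_config("chymase", seed = 1)
report <- run_pipeline(cfg)

report$classification   # "chymotryptic"
report$p1_candidates    # "F" "W" "Y"
report$p2prime_acidity  # ~0.5: the planted acidic-P2' preference, recovered
report$consensus        # e.g. "xxxxFxdxx"-style summary

aln_tab <- read.delim(file.path(cfg$out_dir, "aligned_peptides.tsv"),
                      check.names = FALSE)
head(aln_tab)           # the P5...P4' table with clone counts

lm <- read_profile_tsv(file.path(cfg$out_dir, "profile_probs.tsv"))
plot_logo(logo_matrix(lm))  # probability-unit logo (requires ggplot2)
```

The same configuration with `demo_config("elastase", ...)` plants a
V/I/A-specific model and classifies as `elastolytic` end to end.
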