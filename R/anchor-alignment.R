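# P1-anchored alignment of selected peptides into a fixed subsite frame:
# unambiguous peptides (exactly one candidate P1) anchor the positional
# profile; ambiguous peptides are placed at their best-scoring offset and the
# profile/placement loop is iterated to a fixed point.

#' Enumerate candidate cleavage sites in a peptide
#'
#' All 1-based insert offsets whose residue belongs to the P1 candidate set,
#' ascending. Only insert residues are candidates: cleavage within the
#' display arms does not release the phage and is never aligned.
#'
#' @param sequence Insert residue string.
#' @param p1_set A `p1_candidate_set` or character vector of residues.
#' @param context A [display_context()] (present for interface symmetry; the
#'   arms contribute no candidate sites).
#' @return Integer vector of offsets (possibly empty).
#' @export
#' @examples
#' enumerate_sites("AAAFAAAAA", c("F"))        # 4
#' enumerate_sites("AFAAYAAAW", c("F", "Y", "W"))  # 2 5 9
enumerate_sites <- function(sequence, p1_set, context = display_context()) {
  residues <- p1_residues(p1_set)
  if (length(residues) == 0) stop("empty P1 candidate set", call. = FALSE)
  chars <- split_residues(sequence)
  which(chars %in% residues)
}

p1_residues <- function(p1_set) {
  if (inherits(p1_set, "p1_candidate_set")) p1_set$residues
  else toupper(p1_set)
}

new_aligned_peptide <- function(sequence, count, p1_offset, context, frame) {
  res <- frame_residues_at(sequence, p1_offset, context, frame)
  list(sequence = sequence, count = count, p1_offset = p1_offset,
       frame_residues = res,
       arm_derived = attr(res, "arm_derived"))
}

#' Partition peptides by alignment ambiguity and align the unambiguous ones
#'
#' Peptides with exactly one candidate P1 site are aligned at it; peptides
#' with several candidate sites are routed to the `ambiguous` partition for
#' profile-guided placement; peptides with none are `unalignable`. The three
#' partitions are disjoint and exhaustive.
#'
#' @param peptides Peptide data frame (`sequence`, `count`).
#' @param p1_set P1 candidate residues.
#' @param context A [display_context()].
#' @param frame A [subsite_frame()]; default P5-P4'.
#' @return List with `aligned` (list of aligned peptides), `ambiguous`
#'   (peptide rows + their candidate offsets), `unalignable` (peptide rows).
#' @export
align_unambiguous <- function(peptides, p1_set, context = display_context(),
                              frame = subsite_frame()) {
  aligned <- list(); ambiguous <- list(); unalignable <- list()
  for (i in seq_len(nrow(peptides))) {
    seq_i <- peptides$sequence[i]; cnt_i <- peptides$count[i]
    sites <- enumerate_sites(seq_i, p1_set, context)
    if (length(sites) == 1) {
      aligned[[length(aligned) + 1]] <-
        new_aligned_peptide(seq_i, cnt_i, sites, context, frame)
    } else if (length(sites) > 1) {
      ambiguous[[length(ambiguous) + 1]] <-
        list(sequence = seq_i, count = cnt_i, sites = sites)
    } else {
      unalignable[[length(unalignable) + 1]] <-
        list(sequence = seq_i, count = cnt_i)
    }
  }
  list(aligned = aligned, ambiguous = ambiguous, unalignable = unalignable)
}

#' Build a positional residue profile from aligned peptides
#'
#' Per-subsite residue counts, weighted by clone multiplicity
#' (`weighting = "by_multiplicity"`) or counting each unique sequence once
#' (`"unique"`). Arm-derived frame positions (residues read from the constant
#' display arms rather than the randomized insert) are skipped under
#' `arm_policy = "mask"` — the default, because arm residues reflect vector
#' sequence, not selection — and counted under `"include"`. Frame positions
#' outside the displayed sequence are never counted. A pseudocount is added
#' to every cell before per-subsite normalization.
#'
#' @param aligned List of aligned peptides (from [align_unambiguous()] or
#'   [resolve_and_iterate()]).
#' @param pseudocount Added to each residue count per subsite; default 0.5.
#' @param weighting `"by_multiplicity"` or `"unique"`.
#' @param arm_policy `"mask"` or `"include"`.
#' @param frame A [subsite_frame()].
#' @return An object of class `positional_profile`: list with `counts` and
#'   `probs` matrices (subsites x 20 residues), `effective_n` per subsite,
#'   and the settings used.
#' @export
build_profile <- function(aligned, pseudocount = 0.5,
                          weighting = c("by_multiplicity", "unique"),
                          arm_policy = c("mask", "include"),
                          frame = subsite_frame()) {
  weighting <- match.arg(weighting)
  arm_policy <- match.arg(arm_policy)
  if (length(aligned) == 0) {
    stop("cannot build a profile from zero aligned peptides", call. = FALSE)
  }
  stopifnot(pseudocount >= 0)
  aa <- aa_alphabet()
  counts <- matrix(0, nrow = length(frame$labels), ncol = 20,
                   dimnames = list(frame$labels, aa))
  for (ap in aligned) {
    w <- if (weighting == "by_multiplicity") ap$count else 1
    for (s in frame$labels) {
      res <- ap$frame_residues[[s]]
      if (is.na(res)) next
      if (arm_policy == "mask" && ap$arm_derived[[s]]) next
      counts[s, res] <- counts[s, res] + w
    }
  }
  eff_n <- rowSums(counts)
  probs <- counts + pseudocount
  denom <- rowSums(probs)
  zero_rows <- denom == 0
  probs[!zero_rows, ] <- probs[!zero_rows, , drop = FALSE] / denom[!zero_rows]
  probs[zero_rows, ] <- 1 / 20   # no observations, no pseudocount: uniform
  structure(list(counts = counts, probs = probs, effective_n = eff_n,
                 pseudocount = pseudocount, weighting = weighting,
                 arm_policy = arm_policy, frame = frame),
            class = "positional_profile")
}

#' @export
print.positional_profile <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Positional profile: %s, weighting=%s, arm_policy=%s, pseudocount=%g\n",
    paste(range(x$frame$labels[c(1, length(x$frame$labels))]), collapse = "-"),
    x$weighting, x$arm_policy, x$pseudocount))
  cat("Effective n per subsite:",
      paste(x$effective_n, collapse = " "), "\n")
  top <- apply(x$probs, 1, function(p) {
    i <- which.max(p)
    sprintf("%s (%.*f)", colnames(x$probs)[i], digits, p[i])
  })
  print(data.frame(subsite = x$frame$labels, top_residue = top,
                   row.names = NULL))
  invisible(x)
}

#' Score a candidate P1 offset against a profile
#'
#' Background-relative log-likelihood of placing the peptide with P1 at
#' `offset`: the sum over non-P1 frame subsites of
#' `log(p_subsite(residue) / background(residue))`. Subsites outside the
#' displayed sequence are skipped, as are arm-derived subsites when the
#' profile was built with `arm_policy = "mask"`. P1 itself is excluded so
#' the choice among candidate sites is driven by the extended (non-anchor)
#' positions. Higher is better.
#'
#' @param sequence Insert residue string.
#' @param offset 1-based insert offset of the candidate P1.
#' @param profile A `positional_profile`.
#' @param background 20-vector of background residue probabilities (named or
#'   in [aa_alphabet()] order).
#' @param context A [display_context()].
#' @return Scalar score.
#' @export
score_offset <- function(sequence, offset, profile, background,
                         context = display_context()) {
  aa <- aa_alphabet()
  if (!is.null(names(background))) background <- background[aa]
  stopifnot(length(background) == 20, all(background > 0))
  frame <- profile$frame
  res <- frame_residues_at(sequence, offset, context, frame)
  arm <- attr(res, "arm_derived")
  score <- 0
  for (j in seq_along(frame$labels)) {
    if (j == frame$p1_index) next
    r <- res[[j]]
    if (is.na(r)) next
    if (profile$arm_policy == "mask" && arm[[j]]) next
    p <- profile$probs[frame$labels[j], r]
    if (p <= 0) {
      stop("zero profile probability encountered; rebuild the profile with pseudocount > 0",
           call. = FALSE)
    }
    score <- score + log(p / background[[r]])
  }
  unname(score)
}

# Empirical residue composition of a peptide set (multiplicity-weighted),
# the default scoring background.
empirical_background <- function(peptides) {
  aa <- aa_alphabet()
  counts <- setNames(numeric(20), aa)
  for (i in seq_len(nrow(peptides))) {
    chars <- strsplit(peptides$sequence[i], "", fixed = TRUE)[[1]]
    tab <- table(chars)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab) * peptides$count[i]
  }
  (counts + 0.5) / sum(counts + 0.5)   # small regularizer: no zero background
}

# Total background-relative profile log-likelihood of a full assignment:
# multiplicity-weighted sum of score_offset over all aligned peptides under
# the profile refit (with its Dirichlet pseudocount) from that same
# assignment, plus the pseudocount penalty term. With this penalty the
# profile refit and the per-peptide re-placement of resolve_and_iterate are
# the two blocks of a coordinate ascent on one objective, so the trace is
# non-decreasing and the converged value is comparable with exhaustive
# enumeration over joint assignments.
assignment_log_likelihood <- function(aligned, pseudocount, background,
                                      arm_policy, frame,
                                      context = display_context(),
                                      weighting = "by_multiplicity") {
  profile <- build_profile(aligned, pseudocount = pseudocount,
                           weighting = weighting, arm_policy = arm_policy,
                           frame = frame)
  ll <- pseudocount * sum(log(profile$probs))
  for (ap in aligned) {
    w <- if (weighting == "by_multiplicity") ap$count else 1
    ll <- ll + w * score_offset(ap$sequence, ap$p1_offset, profile,
                                background, context)
  }
  ll
}

#' Align all peptides by iterative profile refinement
#'
#' Implements the anchored consensus-alignment procedure: peptides with a
#' single candidate P1 site are aligned first and define the initial
#' positional profile; every ambiguous peptide is then placed at its
#' best-scoring candidate offset, the profile is rebuilt from all aligned
#' peptides, and placement is repeated until no placement changes (or
#' `max_iter` is reached, in which case the last state is returned with a
#' warning). Ties are broken deterministically: highest score, then the
#' smallest (most N-terminal) offset. The result is invariant to the input
#' order of the peptides.
#'
#' @param peptides Peptide data frame (`sequence`, `count`).
#' @param p1_set P1 candidate residues (a `p1_candidate_set` or character
#'   vector).
#' @param pseudocount Profile pseudocount; default 0.5 (must be > 0 so every
#'   offset is scoreable).
#' @param background Scoring background; default `"empirical"` (residue
#'   composition of the input peptides). May be a 20-vector.
#' @param max_iter Maximum profile/placement iterations; default 50.
#' @param weighting,arm_policy,frame Passed to [build_profile()].
#' @param context A [display_context()].
#' @return An object of class `anchored_alignment`: list with `aligned`
#'   (all placed peptides, canonical order), `unalignable`, `profile`,
#'   `n_iterations`, `converged`, `log_likelihood` (the converged penalized
#'   background-relative objective), `ll_trace` (objective after each
#'   placement pass; non-decreasing), `background`.
#' @export
#' @examples
#' peps <- peptide_set(c("AAAFAAAAA", "AFAAAAFAA", "DAGFAEAAA"))
#' aln <- resolve_and_iterate(peps, c("F"))
#' vapply(aln$aligned, `[[`, integer(1), "p1_offset")
resolve_and_iterate <- function(peptides, p1_set, pseudocount = 0.5,
                                background = "empirical", max_iter = 50L,
                                weighting = c("by_multiplicity", "unique"),
                                arm_policy = c("mask", "include"),
                                frame = subsite_frame(),
                                context = display_context()) {
  weighting <- match.arg(weighting)
  arm_policy <- match.arg(arm_policy)
  stopifnot(pseudocount > 0, max_iter >= 1)
  parts <- align_unambiguous(peptides, p1_set, context, frame)
  if (length(parts$aligned) == 0 && length(parts$ambiguous) > 0) {
    stop("no unambiguously alignable peptides to seed the profile; supply a narrower P1 set or seed profile",
         call. = FALSE)
  }
  if (identical(background, "empirical")) {
    background <- empirical_background(peptides)
  } else {
    aa <- aa_alphabet()
    if (!is.null(names(background))) background <- background[aa]
    stopifnot(length(background) == 20, all(background > 0))
  }

  # canonical processing order: by sequence then count, so results do not
  # depend on input order
  amb <- parts$ambiguous
  if (length(amb) > 0) {
    ord <- order(vapply(amb, `[[`, character(1), "sequence"),
                 vapply(amb, `[[`, integer(1), "count"))
    amb <- amb[ord]
  }

  placements <- rep(NA_integer_, length(amb))
  n_iter <- 0L
  converged <- TRUE
  ll_trace <- numeric(0)
  if (length(amb) > 0) {
    converged <- FALSE
    # The objective is a function of the subsite x residue counts matrix
    # alone: sum over non-P1 cells of count * log(prob/background) plus the
    # pseudocount penalty, with prob the per-subsite normalized counts.
    # Placement moves are evaluated by O(frame) incremental count updates;
    # agreement with assignment_log_likelihood is property-tested.
    n_sub <- length(frame$labels)
    not_p1 <- rep(seq_len(n_sub) != frame$p1_index, times = 20)
    log_bg_cell <- rep(log(background), each = n_sub)
    obj_from_counts <- function(counts) {
      pr <- counts + pseudocount
      pr <- pr / rowSums(pr)
      lp <- log(pr)
      sum(counts[not_p1] * (lp[not_p1] - log_bg_cell[not_p1])) +
        pseudocount * sum(lp)
    }
    # per-peptide, per-site count increments (cell indices + weight)
    cell_incs <- lapply(amb, function(a) {
      w <- if (weighting == "by_multiplicity") a$count else 1
      lapply(a$sites, function(o) {
        res <- frame_residues_at(a$sequence, o, context, frame)
        arm <- attr(res, "arm_derived")
        keep <- !is.na(res) & !(arm_policy == "mask" & arm)
        j <- which(keep)
        list(cells = cbind(j, match(res[j], aa_alphabet())), w = w)
      })
    })
    base_counts <- build_profile(parts$aligned, pseudocount, weighting,
                                 arm_policy, frame)$counts
    counts_for <- function(pl) {
      counts <- base_counts
      for (i in seq_along(pl)) {
        inc <- cell_incs[[i]][[match(pl[i], amb[[i]]$sites)]]
        counts[inc$cells] <- counts[inc$cells] + inc$w
      }
      counts
    }
    obj <- function(pl) obj_from_counts(counts_for(pl))
    ascent <- function(placements) {
      # sweeps of exact coordinate ascent: each ambiguous peptide in turn is
      # re-placed at the offset maximizing the total objective (profile
      # refit from all aligned peptides included); monotone by construction
      trace <- obj(placements)
      conv <- FALSE
      iters <- 0L
      counts <- counts_for(placements)
      for (iter in seq_len(max_iter)) {
        iters <- iter
        changed <- FALSE
        for (i in seq_along(amb)) {
          sites <- amb[[i]]$sites
          inc_old <- cell_incs[[i]][[match(placements[i], sites)]]
          counts[inc_old$cells] <- counts[inc_old$cells] - inc_old$w
          lls <- vapply(seq_along(sites), function(si) {
            inc <- cell_incs[[i]][[si]]
            counts[inc$cells] <- counts[inc$cells] + inc$w
            obj_from_counts(counts)
          }, numeric(1))
          best_si <- which(lls >= max(lls) - 1e-9)[1]  # tie: smallest offset
          inc_new <- cell_incs[[i]][[best_si]]
          counts[inc_new$cells] <- counts[inc_new$cells] + inc_new$w
          if (sites[best_si] != placements[i]) {
            placements[i] <- sites[best_si]
            changed <- TRUE
          }
        }
        trace <- c(trace, obj_from_counts(counts))
        if (!changed) { conv <- TRUE; break }
      }
      list(placements = placements, trace = trace, converged = conv,
           iters = iters)
    }
    # initial placement: best-scoring offset under the profile of the
    # unambiguous anchors
    profile0 <- build_profile(parts$aligned, pseudocount, weighting,
                              arm_policy, frame)
    init_score <- vapply(seq_along(amb), function(i) {
      sites <- amb[[i]]$sites
      scores <- vapply(sites, function(o) {
        score_offset(amb[[i]]$sequence, o, profile0, background, context)
      }, numeric(1))
      sites[which(scores >= max(scores) - 1e-12)][1]
    }, integer(1))
    # deterministic multi-start: the score-based initialization plus cyclic
    # candidate-site initializations, to escape local fixed points of the
    # single-sweep ascent
    inits <- c(list(init_score), lapply(1:3, function(r) {
      vapply(amb, function(a) {
        a$sites[1L + (r - 1L) %% length(a$sites)]
      }, integer(1))
    }))
    runs <- lapply(unique(inits), ascent)
    best_run <- runs[[which.max(vapply(runs, function(r) {
      r$trace[length(r$trace)]
    }, numeric(1)))]]
    placements <- best_run$placements
    ll_trace <- best_run$trace
    converged <- best_run$converged
    n_iter <- best_run$iters
    if (!converged) {
      warning(sprintf(
        "alignment did not converge within %d iterations; returning last state",
        max_iter), call. = FALSE)
    }
  }

  all_aligned <- c(parts$aligned,
                   aligned_from_placements(amb, placements, context, frame))
  profile <- build_profile(all_aligned, pseudocount, weighting, arm_policy,
                           frame)
  ll <- assignment_log_likelihood(all_aligned, pseudocount, background,
                                  arm_policy, frame, context, weighting)
  # report in canonical (sequence) order
  ord <- order(vapply(all_aligned, `[[`, character(1), "sequence"))
  structure(list(aligned = all_aligned[ord],
                 unalignable = parts$unalignable,
                 profile = profile,
                 n_iterations = max(1L, n_iter),
                 converged = converged,
                 log_likelihood = ll,
                 ll_trace = ll_trace,
                 background = background),
            class = "anchored_alignment")
}

aligned_from_placements <- function(amb, placements, context, frame) {
  keep <- which(!is.na(placements))
  lapply(keep, function(i) {
    new_aligned_peptide(amb[[i]]$sequence, amb[[i]]$count, placements[i],
                        context, frame)
  })
}

#' @export
print.anchored_alignment <- function(x, ...) {
  cat(sprintf(
    "Anchored alignment: %d aligned peptide(s) (%d clones), %d unalignable, %d iteration(s)%s\n",
    length(x$aligned),
    sum(vapply(x$aligned, `[[`, integer(1), "count")),
    length(x$unalignable), x$n_iterations,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Tabulate an anchored alignment as a subsite table
#'
#' One row per aligned peptide with the residue occupying each frame subsite
#' (arm-derived residues lower-cased, out-of-range positions "-") and the
#' clone count — the layout of published phage-display alignment figures.
#'
#' @param alignment An `anchored_alignment`.
#' @return Data frame with one column per subsite plus `sequence`, `count`.
#' @export
alignment_table <- function(alignment) {
  frame <- alignment$profile$frame
  rows <- lapply(alignment$aligned, function(ap) {
    res <- ap$frame_residues
    shown <- ifelse(is.na(res), "-",
                    ifelse(ap$arm_derived, tolower(res), res))
    c(setNames(as.list(shown), frame$labels),
      list(sequence = ap$sequence, count = ap$count))
  })
  do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)
  }))
}
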