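# Reporting layer: class-grouped positional percentages, probability-unit
# logo matrices with side-chain colour classes, consensus strings, and
# cross-enzyme comparison metrics (P2' acidity, per-subsite divergence).

# Restrict a profile to a narrower frame (e.g. report P4-P4' from a P5-P4'
# alignment frame).
restrict_profile <- function(profile, frame) {
  keep <- frame$labels
  missing <- setdiff(keep, profile$frame$labels)
  if (length(missing) > 0) {
    stop("profile lacks subsite(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- profile
  out$counts <- profile$counts[keep, , drop = FALSE]
  out$probs <- profile$probs[keep, , drop = FALSE]
  out$effective_n <- profile$effective_n[keep]
  out$frame <- frame
  out
}

#' Class-grouped positional percentages
#'
#' Collapses a positional profile's per-residue percentages into side-chain
#' class percentages per subsite (class percentage = sum of member-residue
#' percentages; classes sum to 100% per subsite under any covering scheme).
#'
#' @param profile A `positional_profile`.
#' @param scheme A [class_scheme()]; default `"grouping"`.
#' @return Data frame: `subsite` plus one percentage column per class.
#' @export
#' @examples
#' peps <- peptide_set(c("AAAFDEAAA", "GGWFDESTA"))
#' aln <- resolve_and_iterate(peps, "F")
#' group_percentages(aln$profile)
group_percentages <- function(profile, scheme = class_scheme("grouping")) {
  stopifnot(inherits(profile, "positional_profile"),
            inherits(scheme, "class_scheme"))
  validate_class_scheme(scheme$classes)
  pct <- vapply(scheme$classes, function(members) {
    rowSums(profile$probs[, members, drop = FALSE]) * 100
  }, numeric(nrow(profile$probs)))
  out <- data.frame(subsite = profile$frame$labels, pct,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Probability-unit sequence logo matrix
#'
#' Passes the profile's per-subsite residue probabilities through unchanged
#' (probability units on the y axis, not information content) and attaches
#' the conventional side-chain colour classes: K,R,H yellow; D,E red; F,Y,W
#' green; S,T,C,M,N,Q white; G,A,V,L,I,P blue. The matrix serializes to a
#' subsite x residue table consumable by standard logo renderers.
#'
#' @param profile A `positional_profile`.
#' @return An object of class `logo_matrix`: list with `probs` (subsites x
#'   20), `y_axis = "probability"`, `color_map` (residue -> colour name).
#' @export
#' @examples
#' peps <- peptide_set(c("AAAFDEAAA", "GGWFDESTA"))
#' lm <- logo_matrix(resolve_and_iterate(peps, "F")$profile)
#' lm$color_map[["H"]]  # "yellow"
logo_matrix <- function(profile) {
  stopifnot(inherits(profile, "positional_profile"))
  scheme <- class_scheme("logo_colors")
  color_map <- setNames(rep(NA_character_, 20), aa_alphabet())
  for (col in names(scheme$classes)) {
    color_map[scheme$classes[[col]]] <- col
  }
  structure(list(probs = profile$probs, y_axis = "probability",
                 color_map = as.list(color_map), frame = profile$frame),
            class = "logo_matrix")
}

#' Consensus string from a positional profile
#'
#' One symbol per subsite: the top residue (upper case) if its probability
#' reaches `major_threshold`; otherwise the initial of the top residue class
#' in lower case if that class dominates; otherwise `"x"`.
#'
#' @param profile A `positional_profile`.
#' @param major_threshold Probability required to report a single residue,
#'   in (0, 1]; default 0.5. The same threshold is applied to the class mass
#'   for the lowercase class symbol.
#' @param scheme A [class_scheme()] for the class fallback.
#' @return Character scalar with one symbol per subsite.
#' @export
consensus_string <- function(profile, major_threshold = 0.5,
                             scheme = class_scheme("grouping")) {
  stopifnot(major_threshold > 0, major_threshold <= 1)
  class_pct <- group_percentages(profile, scheme)
  symbols <- vapply(seq_len(nrow(profile$probs)), function(i) {
    p <- profile$probs[i, ]
    top <- which.max(p)
    if (p[top] >= major_threshold) return(names(p)[top])
    cls <- unlist(class_pct[i, -1])
    top_cls <- which.max(cls)
    if (cls[top_cls] >= major_threshold * 100) {
      return(tolower(substr(names(cls)[top_cls], 1, 1)))
    }
    "x"
  }, character(1))
  paste(symbols, collapse = "")
}

#' Acidic preference at P2'
#'
#' Probability mass of the negatively charged residues (Asp + Glu) at the
#' P2' subsite — the summary used to compare chymases' preference for acidic
#' residues two positions downstream of the cleavage site.
#'
#' @param profile A `positional_profile` whose frame includes P2'.
#' @return Value in [0, 1].
#' @export
p2prime_acidity <- function(profile) {
  if (!"P2'" %in% profile$frame$labels) {
    stop("profile frame does not include P2'", call. = FALSE)
  }
  unname(sum(profile$probs["P2'", c("D", "E")]))
}

#' Per-subsite Jensen-Shannon divergence between two profiles
#'
#' Base-2 Jensen-Shannon divergence between the residue distributions of two
#' profiles at each shared subsite: symmetric, bounded in [0, 1], zero iff
#' the distributions are equal. Used for cross-enzyme specificity
#' comparisons.
#'
#' @param a,b `positional_profile` objects over the same frame.
#' @return Named numeric vector, one value per subsite.
#' @export
profile_divergence <- function(a, b) {
  if (!identical(a$frame$labels, b$frame$labels)) {
    stop("profiles are over different frames: ",
         paste(a$frame$labels, collapse = ","), " vs ",
         paste(b$frame$labels, collapse = ","), call. = FALSE)
  }
  vapply(seq_along(a$frame$labels), function(i) {
    jsd_base2(a$probs[i, ], b$probs[i, ])
  }, numeric(1)) -> d
  setNames(d, a$frame$labels)
}

jsd_base2 <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(x, y) {
    i <- x > 0
    sum(x[i] * log2(x[i] / y[i]))
  }
  max(0, min(1, (kl(p, m) + kl(q, m)) / 2))
}

#' Render a probability sequence logo
#'
#' Simple ggplot2 rendering of a [logo_matrix()]: stacked residue letters per
#' subsite, letter height proportional to probability, coloured by the
#' conventional side-chain classes. Requires ggplot2 (Suggests).
#'
#' @param lm A `logo_matrix`.
#' @param min_prob Residues below this probability are omitted from the
#'   stack; default 0.02.
#' @return A ggplot object.
#' @export
plot_logo <- function(lm, min_prob = 0.02) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_logo requires the ggplot2 package", call. = FALSE)
  }
  stopifnot(inherits(lm, "logo_matrix"))
  labs <- lm$frame$labels
  rows <- list()
  for (i in seq_along(labs)) {
    p <- sort(lm$probs[i, lm$probs[i, ] >= min_prob], decreasing = FALSE)
    if (length(p) == 0) next
    tops <- cumsum(p)
    rows[[i]] <- data.frame(
      subsite = factor(labs[i], levels = labs),
      residue = names(p), prob = as.numeric(p),
      y = tops - p / 2,
      color = vapply(names(p), function(r) lm$color_map[[r]], character(1)),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  fill_vals <- c(yellow = "#E6C200", red = "#CC3333", green = "#2E8B57",
                 white = "grey35", blue = "#3366CC")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subsite, y = .data$y)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$residue,
                                    size = .data$prob,
                                    colour = .data$color),
                       fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = fill_vals) +
    ggplot2::scale_size_continuous(range = c(2, 12), limits = c(0, 1)) +
    ggplot2::scale_y_continuous(limits = c(0, 1), name = "probability") +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal()
}
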