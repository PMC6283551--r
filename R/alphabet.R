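# Shared constants: the 20-residue alphabet, subsite frames, class schemes.

#' The 20 standard amino acid one-letter codes
#'
#' Alphabetical order; all residue-indexed vectors and matrices in the
#' package use this ordering.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Split a residue string into a character vector, validating the alphabet.
# `what` names the offending record in error messages.
split_residues <- function(x, what = "sequence") {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), aa_alphabet())
  if (length(bad) > 0) {
    stop(sprintf("%s '%s' contains non-standard residue(s): %s",
                 what, x, paste(bad, collapse = ", ")), call. = FALSE)
  }
  chars
}

is_valid_residues <- function(x) {
  all(strsplit(toupper(x), "", fixed = TRUE)[[1]] %in% aa_alphabet())
}

#' Subsite frame in Schechter-Berger nomenclature
#'
#' A fixed ordered window of subsites around the scissile bond. The
#' nomenclature counts substrate residues outward from the cleaved bond:
#' P-side subsites (P5...P1) are N-terminal, primed subsites (P1'...P4')
#' C-terminal; cleavage occurs between P1 and P1'.
#'
#' @param n_upstream Number of P-side subsites (default 5, giving P5...P1).
#' @param n_downstream Number of primed subsites (default 4, P1'...P4').
#' @return An object of class `subsite_frame`: list with `labels` (ordered
#'   subsite labels) and `p1_index` (position of P1 within `labels`).
#' @export
#' @examples
#' subsite_frame()          # P5-P4', the alignment frame
#' subsite_frame(4, 4)      # P4-P4', the default reporting frame
subsite_frame <- function(n_upstream = 5, n_downstream = 4) {
  stopifnot(n_upstream >= 1, n_downstream >= 1)
  labels <- c(paste0("P", n_upstream:1),
              paste0("P", seq_len(n_downstream), "'"))
  structure(list(labels = labels, p1_index = n_upstream),
            class = "subsite_frame")
}

#' @export
print.subsite_frame <- function(x, ...) {
  cat("Subsite frame:", paste(x$labels, collapse = " "),
      "(cleavage between P1 and P1')\n")
  invisible(x)
}

# Relative offsets of each subsite from P1 (P1 = 0, P2 = -1, P1' = +1, ...).
frame_offsets <- function(frame) {
  seq_along(frame$labels) - frame$p1_index
}

#' Named residue class schemes
#'
#' Two schemes are used in specificity reporting and both are provided as
#' distinct named schemes because they group His differently:
#' * `"grouping"` — the side-chain property grouping used for class-grouped
#'   positional percentages: aromatic (F,Y,W), acidic (D,E), basic (K,R),
#'   small aliphatic (G,A), large aliphatic (V,L,I,P), hydrophilic
#'   (S,T,H,N,Q,C,M).
#' * `"logo_colors"` — the colour classes used in probability-unit sequence
#'   logos: K,R,H yellow; D,E red; F,Y,W green; S,T,C,M,N,Q white;
#'   G,A,V,L,I,P blue. Note His is coloured with the basic residues here
#'   although the grouping scheme counts it as hydrophilic.
#'
#' @param name One of `"grouping"`, `"logo_colors"`.
#' @return An object of class `class_scheme`: list with `name` and `classes`
#'   (named list of residue character vectors; disjoint, covering all 20).
#' @export
#' @examples
#' class_scheme("grouping")$classes$aromatic
class_scheme <- function(name = c("grouping", "logo_colors")) {
  name <- match.arg(name)
  classes <- switch(name,
    grouping = list(
      aromatic        = c("F", "Y", "W"),
      aliphatic_small = c("G", "A"),
      aliphatic_large = c("V", "L", "I", "P"),
      hydrophilic     = c("S", "T", "H", "N", "Q", "C", "M"),
      basic           = c("K", "R"),
      acidic          = c("D", "E")
    ),
    logo_colors = list(
      yellow = c("K", "R", "H"),
      red    = c("D", "E"),
      green  = c("F", "Y", "W"),
      white  = c("S", "T", "C", "M", "N", "Q"),
      blue   = c("G", "A", "V", "L", "I", "P")
    )
  )
  validate_class_scheme(classes)
  structure(list(name = name, classes = classes), class = "class_scheme")
}

validate_class_scheme <- function(classes) {
  all_res <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(all_res)) {
    stop("class scheme groups are not disjoint: ",
         paste(unique(all_res[duplicated(all_res)]), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(aa_alphabet(), all_res)
  if (length(missing) > 0) {
    stop("class scheme does not cover all 20 residues; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
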