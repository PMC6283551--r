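# Readers and writers for the pipeline's plain-text formats: peptide lists
# (FASTA with "count=N" headers, or CSV), kinetic time-course CSV, and TSV
# tables for profiles, alignments and rankings.

#' Read a peptide list
#'
#' FASTA records carry multiplicity as `count=N` in the header (default 1
#' when absent); CSV files have columns `sequence,count` (header optional
#' when two unnamed columns are supplied). Sequences are validated against
#' the 20-residue alphabet; offending records are named in the error.
#'
#' @param path File path.
#' @param format `"fasta"` or `"csv"`; guessed from the extension when
#'   missing.
#' @return Peptide data frame (`sequence`, `count`).
#' @export
read_peptides <- function(path, format = c("auto", "fasta", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE))
      "fasta" else "csv"
  }
  if (format == "fasta") {
    set <- Biostrings::readAAStringSet(path)
    if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
    seqs <- as.character(set)
    counts <- vapply(names(set), function(h) {
      m <- regmatches(h, regexpr("count=([0-9]+)", h))
      if (length(m) == 1) as.integer(sub("count=", "", m)) else 1L
    }, integer(1))
    for (i in seq_along(seqs)) {
      if (!is_valid_residues(seqs[i])) {
        stop(sprintf("record '%s' contains non-standard residues: %s",
                     names(set)[i], seqs[i]), call. = FALSE)
      }
    }
    out <- data.frame(sequence = toupper(unname(seqs)),
                      count = unname(counts), stringsAsFactors = FALSE)
  } else {
    first <- readLines(path, n = 1)
    has_header <- grepl("sequence", first, ignore.case = TRUE)
    df <- utils::read.csv(path, header = has_header,
                          stringsAsFactors = FALSE)
    if (!has_header) {
      names(df)[1] <- "sequence"
      if (ncol(df) >= 2) names(df)[2] <- "count"
    }
    if (!"count" %in% names(df)) df$count <- 1L
    if (nrow(df) == 0) stop("empty peptide CSV: ", path, call. = FALSE)
    for (i in seq_len(nrow(df))) {
      if (!is_valid_residues(df$sequence[i])) {
        stop(sprintf("row %d ('%s') contains non-standard residues",
                     i, df$sequence[i]), call. = FALSE)
      }
    }
    out <- data.frame(sequence = toupper(df$sequence),
                      count = as.integer(df$count), stringsAsFactors = FALSE)
  }
  if (any(out$count < 1)) stop("multiplicity must be >= 1", call. = FALSE)
  out
}

#' Write a peptide list
#'
#' @param peptides Peptide data frame (`sequence`, `count`).
#' @param path Output path.
#' @param format `"fasta"` (headers `>pN count=M`) or `"csv"`
#'   (`sequence,count`).
#' @return `path`, invisibly.
#' @export
write_peptides <- function(peptides, path, format = c("fasta", "csv")) {
  format <- match.arg(format)
  if (format == "fasta") {
    set <- Biostrings::AAStringSet(peptides$sequence)
    names(set) <- sprintf("p%d count=%d", seq_len(nrow(peptides)),
                          peptides$count)
    Biostrings::writeXStringSet(set, path)
  } else {
    utils::write.csv(peptides[, c("sequence", "count")], path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read kinetic time courses from CSV
#'
#' Expected columns: `substrate_id`, `time_min`, `value`, and optionally
#' `p1_residue` and `value_kind` (constant per substrate). One
#' [time_course()] is built per substrate.
#'
#' @param path CSV path.
#' @param value_kind Default value kind when the file has no `value_kind`
#'   column.
#' @return Named list of `time_course` objects.
#' @export
read_timecourses <- function(path, value_kind = "absorbance") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("substrate_id", "time_min", "value")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("time-course CSV lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(df, df$substrate_id), function(d) {
    d <- d[order(d$time_min), , drop = FALSE]
    time_course(
      substrate_id = d$substrate_id[1],
      times = d$time_min, values = d$value,
      value_kind = if ("value_kind" %in% names(d)) d$value_kind[1]
                   else value_kind,
      p1_residue = if ("p1_residue" %in% names(d)) d$p1_residue[1]
                   else NA_character_)
  })
  out[unique(df$substrate_id)]
}

#' Write time courses to CSV
#'
#' @param courses List of [time_course()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(courses, path) {
  rows <- do.call(rbind, lapply(courses, function(tc) {
    data.frame(substrate_id = tc$substrate_id, time_min = tc$times,
               value = tc$values, value_kind = tc$value_kind,
               p1_residue = tc$p1_residue, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a positional profile (or logo matrix) as TSV
#'
#' Subsite rows, residue columns; prime subsites use an ASCII apostrophe
#' ("P2'") in the first column.
#'
#' @param x A `positional_profile` or `logo_matrix`.
#' @param path Output path.
#' @param what `"probs"` or `"counts"` (profiles only).
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(x, path, what = c("probs", "counts")) {
  what <- match.arg(what)
  m <- if (inherits(x, "logo_matrix")) x$probs else x[[what]]
  df <- data.frame(subsite = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a positional profile written by [write_profile_tsv()]
#'
#' Probabilities are renormalized per subsite to absorb round-trip rounding.
#'
#' @param path TSV path.
#' @param arm_policy,weighting,pseudocount Metadata restored onto the object
#'   (not stored in the TSV).
#' @return A `positional_profile` (counts unavailable; set to the probs).
#' @export
read_profile_tsv <- function(path, arm_policy = "mask",
                             weighting = "by_multiplicity",
                             pseudocount = 0) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, aa_alphabet()])
  rownames(m) <- df$subsite
  m <- m / rowSums(m)
  n_up <- sum(!grepl("'", df$subsite))
  frame <- subsite_frame(n_up, nrow(df) - n_up)
  structure(list(counts = m, probs = m,
                 effective_n = setNames(rep(NA_real_, nrow(m)), rownames(m)),
                 pseudocount = pseudocount, weighting = weighting,
                 arm_policy = arm_policy, frame = frame),
            class = "positional_profile")
}

#' Write a generic data frame as TSV
#'
#' Used for panel results, alignment tables, class percentages, rankings.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
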