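#' Validate and canonicalize a peptide sequence
#'
#' Strips whitespace, folds to uppercase, and enforces the natural-residue
#' contract: only the 20 canonical amino acids are accepted and the chain
#' must be at least 3 residues long (the shortest length for which every
#' descriptor block, including tripeptide composition, has at least one
#' window). Ambiguity and non-canonical codes (B, J, O, U, X, Z, ...) are
#' hard errors, not silently dropped.
#'
#' @param raw Character scalar, the raw sequence (case-insensitive, may
#'   contain whitespace/newlines from FASTA wrapping).
#' @return The canonical uppercase sequence.
#' @examples
#' validate_sequence("gigklfk")
#' @export
validate_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    cpp_stop("`raw` must be a single character string", "noncanonical")
  }
  seq <- toupper(gsub("[[:space:]]", "", raw))
  if (!nzchar(seq)) {
    cpp_stop("sequence is empty after whitespace stripping", "too_short")
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad)) {
    cpp_stop(
      sprintf("non-canonical residue(s) %s at position(s) %s",
              paste(sQuote(chars[bad]), collapse = ", "),
              paste(bad, collapse = ", ")),
      "noncanonical", positions = bad, residues = chars[bad]
    )
  }
  if (nchar(seq) < 3L) {
    cpp_stop(sprintf("sequence %s has length %d; minimum is 3",
                     sQuote(seq), nchar(seq)), "too_short")
  }
  seq
}

#' Construct a labeled peptide dataset
#'
#' The dataset is an ordinary data frame with columns `id`, `sequence` and
#' (optionally) `label`, carrying class `cpp_dataset`. All sequences are
#' validated; ids must be unique; labels, when present, must be 0/1 and
#' complete.
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Character vector of peptide sequences.
#' @param label Optional integer/numeric vector of 0/1 labels
#'   (1 = CPP / high efficiency).
#' @return A `cpp_dataset` data frame.
#' @export
cpp_dataset <- function(id, sequence, label = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    cpp_stop(sprintf("duplicate peptide id(s): %s",
                     paste(unique(id[duplicated(id)]), collapse = ", ")),
             "duplicate_id")
  }
  if (length(sequence) != length(id)) {
    cpp_stop("`id` and `sequence` lengths differ", "length_mismatch")
  }
  sequence <- vapply(sequence, validate_sequence, character(1L),
                     USE.NAMES = FALSE)
  out <- data.frame(id = id, sequence = sequence, stringsAsFactors = FALSE)
  if (!is.null(label)) {
    if (length(label) != length(id) || anyNA(label)) {
      cpp_stop("labels must be complete when provided", "missing_label")
    }
    label <- as.integer(label)
    if (!all(label %in% c(0L, 1L))) {
      cpp_stop("labels must be binary 0/1", "missing_label")
    }
    out$label <- label
  }
  class(out) <- c("cpp_dataset", "data.frame")
  out
}

#' @export
print.cpp_dataset <- function(x, ...) {
  cat(sprintf("<cpp_dataset> %d peptide(s)", nrow(x)))
  if (!is.null(x$label)) {
    cat(sprintf(", labels: %d positive / %d negative",
                sum(x$label == 1L), sum(x$label == 0L)))
  }
  cat("\n")
  NextMethod()
  invisible(x)
}

#' Class counts of a labeled dataset
#'
#' @param ds A `cpp_dataset`.
#' @return Named integer vector `c(negative=, positive=)`.
#' @export
class_counts <- function(ds) {
  if (is.null(ds$label)) {
    cpp_stop("dataset has no labels", "missing_label")
  }
  c(negative = sum(ds$label == 0L), positive = sum(ds$label == 1L))
}

#' Read peptides from FASTA, optionally joining labels from a sidecar TSV
#'
#' The first whitespace-delimited token of each FASTA header is the peptide
#' id. The label sidecar is a two-column TSV (`id`, `label` in 0/1) with a
#' header row; every FASTA record must be labeled when a sidecar is given.
#'
#' @param path Path to a FASTA file.
#' @param labels Optional path to the label TSV.
#' @return A [cpp_dataset()].
#' @export
read_fasta <- function(path, labels = NULL) {
  if (!file.exists(path)) {
    cpp_stop(sprintf("FASTA file not found: %s", path), "io")
  }
  seqs <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(seqs), "[[:space:]]+"), `[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    cpp_stop(sprintf("duplicate FASTA id(s): %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "duplicate_id")
  }
  raw <- as.character(seqs)
  lab <- NULL
  if (!is.null(labels)) {
    tab <- utils::read.delim(labels, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) {
      cpp_stop("label sidecar must have at least 2 columns (id, label)",
               "unknown_header")
    }
    names(tab)[1:2] <- c("id", "label")
    missing <- setdiff(ids, tab$id)
    if (length(missing)) {
      cpp_stop(sprintf("no label for id(s): %s",
                       paste(missing, collapse = ", ")), "missing_label")
    }
    lab <- tab$label[match(ids, tab$id)]
  }
  tryCatch(
    cpp_dataset(ids, raw, label = lab),
    cpptools_error = function(e) {
      # re-raise with record context so the offending FASTA entry is named
      bad <- which(vapply(raw, function(s) {
        inherits(tryCatch(validate_sequence(s), error = identity), "error")
      }, logical(1L)))
      if (length(bad)) {
        cpp_stop(sprintf("record %s: %s", ids[bad[1L]], conditionMessage(e)),
                 sub("^cpptools_error_", "", class(e)[1L]))
      }
      stop(e)
    }
  )
}

#' Write a peptide dataset to FASTA (and optionally its labels to TSV)
#'
#' @param ds A `cpp_dataset`.
#' @param path Output FASTA path.
#' @param labels Optional output path for the label sidecar TSV.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ds, path, labels = NULL) {
  x <- Biostrings::AAStringSet(ds$sequence)
  names(x) <- ds$id
  Biostrings::writeXStringSet(x, path)
  if (!is.null(labels)) {
    if (is.null(ds$label)) cpp_stop("dataset has no labels", "missing_label")
    utils::write.table(data.frame(id = ds$id, label = ds$label),
                       labels, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
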