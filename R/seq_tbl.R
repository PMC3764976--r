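#' Build a sequence table
#'
#' The universal currency of the toolkit: a tibble with one row per sequence
#' record and columns `id` (character, unique, non-empty), `desc` (character,
#' the remainder of the header), `seq` (character, uppercased) and `qual`
#' (list-column of integer Phred vectors, or `NULL` entries when no qualities
#' are available).  All pipeline stages take such a tibble first and return a
#' new one; records are never mutated in place.
#'
#' @param id Character vector of record identifiers.
#' @param seq Character vector of sequences (nucleotide over A/C/G/T/N or
#'   amino acid); lowercase letters are uppercased.
#' @param desc Optional character vector of descriptions (defaults to `""`).
#' @param qual Optional list of integer Phred quality vectors, one per
#'   record, each the same length as its sequence.
#' @return A tibble of class `hx_seq_tbl` with columns `id`, `desc`, `seq`,
#'   `qual`.
#' @examples
#' seq_tbl(c("a", "b"), c("acgt", "GGGT"))
#' @export
seq_tbl <- function(id, seq, desc = NULL, qual = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) {
    rlang::abort("`id` and `seq` must have the same length")
  }
  if (any(!nzchar(id))) {
    rlang::abort("record ids must be non-empty")
  }
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicate record id(s): ", paste(dup, collapse = ", ")))
  }
  if (is.null(desc)) desc <- rep("", length(id))
  if (is.null(qual)) {
    qual <- rep(list(NULL), length(id))
  } else {
    if (length(qual) != length(id)) {
      rlang::abort("`qual` must have one entry per record")
    }
    bad <- which(!vapply(seq_along(qual), function(i) {
      is.null(qual[[i]]) || length(qual[[i]]) == nchar(seq[[i]])
    }, logical(1)))
    if (length(bad) > 0) {
      rlang::abort(paste0(
        "quality length differs from sequence length for record(s): ",
        paste(id[bad], collapse = ", ")
      ))
    }
    qual <- lapply(qual, function(q) if (is.null(q)) NULL else as.integer(q))
  }
  out <- tibble::tibble(id = id, desc = desc, seq = seq, qual = qual)
  class(out) <- c("hx_seq_tbl", class(out))
  out
}

has_qual <- function(records) {
  !vapply(records$qual, is.null, logical(1))
}

#' Reverse-complement sequences
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Character vector of reverse complements (N maps to N).
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

seq_lengths <- function(records) nchar(records$seq)
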