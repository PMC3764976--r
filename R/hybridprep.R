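#' Contig chopping parameters
#'
#' Constants of the Illumina-priority co-assembly trick: contigs longer
#' than `max_len` (1999 nt, the input size limit of 454-era assemblers)
#' are chopped into `max_len`-nt segments overlapping by `overlap`
#' (1899 nt, i.e. a 100-nt step), and an artificial quality file assigns
#' Phred `internal_qual` (40) to internal bases and `edge_qual` (10) to
#' `edge_len` (25 bp) edges, as edges are more error-prone.
#'
#' @param max_len Maximum emitted segment length.
#' @param overlap Overlap between consecutive segments.
#' @param edge_qual,internal_qual,edge_len Artificial quality scheme.
#' @return A list of class `hx_chop_params`.
#' @export
chop_params <- function(max_len = 1999, overlap = 1899,
                        edge_qual = 10, internal_qual = 40, edge_len = 25) {
  stopifnot(overlap > 0, overlap < max_len)
  structure(list(
    max_len = as.integer(max_len), overlap = as.integer(overlap),
    step = as.integer(max_len - overlap),
    edge_qual = as.integer(edge_qual),
    internal_qual = as.integer(internal_qual),
    edge_len = as.integer(edge_len)
  ), class = "hx_chop_params")
}

#' Duplicate contigs with a one-base 5' offset
#'
#' Each contig is emitted twice: the original, then a duplicate missing its
#' first base (so the two are not exact duplicates) with `"_dup"` appended
#' to the id.  Originals precede the duplicates of the same contig.
#'
#' @param contigs A [seq_tbl()].
#' @return A [seq_tbl()] with `2 * nrow(contigs)` records.
#' @export
duplicate_contigs <- function(contigs) {
  if (nrow(contigs) == 0) {
    return(contigs)
  }
  idx <- rep(seq_len(nrow(contigs)), each = 2)
  dup <- rep(c(FALSE, TRUE), nrow(contigs))
  seq_tbl(
    ifelse(dup, paste0(contigs$id[idx], "_dup"), contigs$id[idx]),
    ifelse(dup, substr(contigs$seq[idx], 2L, nchar(contigs$seq[idx])),
           contigs$seq[idx]),
    desc = contigs$desc[idx]
  )
}

chop_starts <- function(len, params) {
  if (len <= params$max_len) {
    return(0L)
  }
  regular <- seq.int(0L, len - params$max_len, by = params$step)
  last_end <- regular[length(regular)] + params$max_len
  if (last_end < len) regular <- c(regular, len - params$max_len)
  regular
}

#' Chop one contig into overlapping segments
#'
#' Contigs of length <= `max_len` pass through unchanged.  Longer contigs
#' are cut into segments of exactly `max_len` starting at 0, step,
#' 2*step, ...; when the regular tiling leaves a tail uncovered, a final
#' clamped segment starting at `len - max_len` is appended, so every base
#' is covered and all segments have equal length (the final pair may
#' overlap by more than `overlap`).  Segment ids are `<id>_part<k>`.
#'
#' @param rec A single-row [seq_tbl()].
#' @param params A [chop_params()].
#' @return A [seq_tbl()] of segments.
#' @export
chop_contig <- function(rec, params = chop_params()) {
  len <- nchar(rec$seq[[1]])
  starts <- chop_starts(len, params)
  if (length(starts) == 1 && len <= params$max_len) {
    return(rec[1, , drop = FALSE])
  }
  seq_tbl(
    paste0(rec$id[[1]], "_part", seq_along(starts)),
    substring(rec$seq[[1]], starts + 1L, starts + params$max_len),
    desc = rep(rec$desc[[1]], length(starts))
  )
}

#' Synthesize an artificial quality vector
#'
#' The first and last `edge_len` positions get `edge_qual`, the remainder
#' `internal_qual`; for short sequences the edges meet and every base gets
#' `edge_qual`.
#'
#' @param length Sequence length (>= 1).
#' @param params A [chop_params()].
#' @return An integer vector of Phred scores.
#' @examples
#' table(synthesize_quality(100))
#' @export
synthesize_quality <- function(length, params = chop_params()) {
  if (length < 1) rlang::abort("length must be >= 1")
  q <- rep(params$internal_qual, length)
  e <- min(params$edge_len, length)
  q[seq_len(e)] <- params$edge_qual
  q[seq.int(length - e + 1L, length)] <- params$edge_qual
  q
}

#' Prepare cleaned short-read contigs for hybrid co-assembly
#'
#' The full Illumina-priority preparation: duplicate (one-base 5' offset),
#' chop into overlapping `max_len`-nt segments, then attach artificial
#' qualities.  A manifest maps each emitted segment back to its source
#' contig.
#'
#' @param contigs A cleaned [seq_tbl()].
#' @param params A [chop_params()].
#' @return A list with `records` (segments with qualities, ready for
#'   [write_fasta_qual()]) and `manifest` (tibble: `segment_id`,
#'   `source_id`, `is_duplicate`, `start`, `length`).
#' @export
prepare_hybrid_input <- function(contigs, params = chop_params()) {
  dups <- duplicate_contigs(contigs)
  if (nrow(dups) == 0) {
    return(list(records = dups,
                manifest = tibble::tibble(segment_id = character(),
                                          source_id = character(),
                                          is_duplicate = logical(),
                                          start = integer(),
                                          length = integer())))
  }
  pieces <- lapply(seq_len(nrow(dups)), function(i) {
    rec <- dups[i, , drop = FALSE]
    segs <- chop_contig(rec, params)
    starts <- chop_starts(nchar(rec$seq[[1]]), params)
    is_dup <- endsWith(rec$id[[1]], "_dup")
    src <- if (is_dup) sub("_dup$", "", rec$id[[1]]) else rec$id[[1]]
    tibble::tibble(
      segment_id = segs$id, seq = segs$seq, desc = segs$desc,
      source_id = src, is_duplicate = is_dup, start = as.integer(starts),
      length = nchar(segs$seq)
    )
  })
  flat <- dplyr::bind_rows(pieces)
  records <- seq_tbl(flat$segment_id, flat$seq, desc = flat$desc,
                     qual = lapply(nchar(flat$seq), synthesize_quality,
                                   params = params))
  manifest <- flat |>
    dplyr::select("segment_id", "source_id", "is_duplicate", "start",
                  "length")
  list(records = records, manifest = manifest)
}

#' Reconstruct a contig from its chopped segments
#'
#' Collapses the overlaps of consecutive segments; the inverse of
#' [chop_contig()], used to verify coverage.
#'
#' @param segments A [seq_tbl()] of segments of one contig, in emission
#'   order.
#' @param starts Integer vector of segment start offsets (0-based).
#' @return The reconstructed sequence string.
#' @export
reconstruct_contig <- function(segments, starts) {
  len <- max(starts + nchar(segments$seq))
  out <- character(len)
  for (i in seq_len(nrow(segments))) {
    chars <- strsplit(segments$seq[[i]], "")[[1]]
    out[seq_along(chars) + starts[[i]]] <- chars
  }
  paste(out, collapse = "")
}
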