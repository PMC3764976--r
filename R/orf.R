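#' Six-frame translation
#'
#' Standard genetic code (table 1); stops appear as `*`, codons containing
#' N translate to `X`, and trailing partial codons are dropped.
#'
#' @param rec A single-row [seq_tbl()] with a nucleotide sequence of length
#'   >= 3.
#' @return A named character vector of 6 peptides, frames `+0, +1, +2`
#'   (forward) and `-0, -1, -2` (reverse complement).
#' @examples
#' six_frame_translate(seq_tbl("t", "ATGAAATAG"))[["+0"]]
#' @export
six_frame_translate <- function(rec) {
  seq <- rec$seq[[1]]
  if (nchar(seq) < 3) rlang::abort("sequence shorter than one codon")
  fwd <- translate_frames(seq)
  rev <- translate_frames(revcomp(seq))
  stats::setNames(c(fwd, rev), c("+0", "+1", "+2", "-0", "-1", "-2"))
}

# codon table from the standard genetic code; unknown codons (N, ...) -> X
codon_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- Biostrings::GENETIC_CODE
    cache
  }
})

translate_one <- function(seq, offset) {
  n <- nchar(seq)
  w <- ((n - offset) %/% 3) * 3
  if (w < 3) {
    return("")
  }
  starts <- seq.int(offset + 1L, offset + w, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- codon_table()[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

translate_frames <- function(seq) {
  vapply(0:2, function(f) translate_one(seq, f), character(1))
}

# longest stop-free codon stretch over all six frames of one sequence
longest_orf_one <- function(seq) {
  n <- nchar(seq)
  if (n < 3) rlang::abort("sequence shorter than one codon")
  frames <- list(fwd = translate_frames(seq),
                 rev = translate_frames(revcomp(seq)))
  best <- NULL
  for (strand_i in 1:2) {
    strand <- c("+", "-")[strand_i]
    peps <- frames[[strand_i]]
    for (f in 0:2) {
      pep <- peps[[f + 1]]
      if (!nzchar(pep)) next
      m <- gregexpr("[^*]+", pep)[[1]]
      if (m[1] == -1) next
      lens <- attr(m, "match.length")
      for (k in seq_along(m)) {
        a <- m[[k]] - 1L            # 0-based aa offset within the frame
        L <- lens[[k]]
        stop_after <- (a + L) < nchar(pep) # next codon is a stop
        s_local <- f + 3L * a
        e_local <- s_local + 3L * L + (if (stop_after) 3L else 0L)
        if (strand == "+") {
          nt_start <- s_local
          nt_end <- e_local
        } else {
          nt_start <- n - e_local
          nt_end <- n - s_local
        }
        cand <- list(
          strand = strand, frame = f,
          nt_start = nt_start, nt_end = nt_end,
          span = e_local - s_local,
          peptide = substr(pep, a + 1L, a + L),
          aa_len = L,
          has_start = substr(pep, a + 1L, a + 1L) == "M",
          has_stop = stop_after
        )
        if (orf_better(cand, best)) best <- cand
      }
    }
  }
  if (is.null(best)) rlang::abort("no codon in any frame")
  best
}

# ORFs compare by nucleotide span (terminating stop included), so a
# stop-bounded ORF is not penalized against an end-bounded one; ties break
# towards the + strand, then the lower frame, then the lower forward start.
orf_better <- function(cand, best) {
  if (is.null(best)) {
    return(TRUE)
  }
  if (cand$span != best$span) {
    return(cand$span > best$span)
  }
  if (cand$strand != best$strand) {
    return(cand$strand == "+")
  }
  if (cand$frame != best$frame) {
    return(cand$frame < best$frame)
  }
  cand$nt_start < best$nt_start
}

#' Longest open reading frame per transcript
#'
#' Over all six frames, the longest stop-free stretch of codons
#' (stop-to-stop or end-bounded) is selected; a leading ATG is not
#' required.  Stretches compare by nucleotide span with the terminating
#' stop codon included, so a stop-bounded ORF is not penalized against an
#' end-bounded one; ties break towards the + strand, then the lower
#' frame, then the lower start coordinate.  The stop codon is excluded
#' from the peptide but included in the nucleotide span.
#'
#' @param records A [seq_tbl()] of transcripts (all of length >= 3).
#' @return A tibble with one row per transcript: `transcript_id`, `strand`,
#'   `frame`, `nt_start`, `nt_end` (0-based half-open, forward strand),
#'   `aa_len`, `peptide`, `has_start` (leading ATG), `has_stop`,
#'   `transcript_len`, and `coverage_fraction` = (nt_end - nt_start) /
#'   transcript_len.
#' @export
longest_orfs <- function(records) {
  res <- lapply(records$seq, longest_orf_one)
  tibble::tibble(
    transcript_id = records$id,
    strand = vapply(res, `[[`, character(1), "strand"),
    frame = vapply(res, `[[`, integer(1), "frame"),
    nt_start = vapply(res, `[[`, integer(1), "nt_start"),
    nt_end = vapply(res, `[[`, integer(1), "nt_end"),
    aa_len = vapply(res, `[[`, integer(1), "aa_len"),
    peptide = vapply(res, `[[`, character(1), "peptide"),
    has_start = vapply(res, `[[`, logical(1), "has_start"),
    has_stop = vapply(res, `[[`, logical(1), "has_stop"),
    transcript_len = nchar(records$seq),
    coverage_fraction = (vapply(res, `[[`, integer(1), "nt_end") -
                           vapply(res, `[[`, integer(1), "nt_start")) /
      nchar(records$seq)
  )
}

#' Peptides of the longest ORFs as a protein sequence table
#'
#' @param orfs A tibble from [longest_orfs()].
#' @return A [seq_tbl()] of peptides; `desc` records the source transcript.
#' @export
orf_peptides <- function(orfs) {
  seq_tbl(orfs$transcript_id, orfs$peptide,
          desc = paste0("orf:", orfs$strand, orfs$frame, ":",
                        orfs$nt_start, "-", orfs$nt_end))
}

#' Keep full-length ORFs longer than a cutoff
#'
#' Full-length means bounded by a start codon (leading ATG) and a stop
#' codon; the length filter is strict (`aa_len > min_aa`).
#'
#' @param orfs A tibble from [longest_orfs()].
#' @param min_aa Strict lower bound on peptide length (default 100).
#' @return The qualifying subset of `orfs`.
#' @export
full_length_filter <- function(orfs, min_aa = 100) {
  dplyr::filter(orfs, .data$has_start, .data$has_stop,
                .data$aa_len > min_aa)
}

#' ORF coverage profile
#'
#' Histogram of the proportion of each transcript covered by its longest
#' ORF, plus the count of transcripts whose ORF spans at least `threshold`
#' of their length.
#'
#' @param orfs A tibble from [longest_orfs()].
#' @param bins Number of equal-width bins over (0, 1].
#' @param threshold Span threshold (default 0.95).
#' @return An `hx_orf_profile`: list with `histogram` (tibble: `bin_low`,
#'   `bin_high`, `count`), `n_spanning`, `threshold`, `n_total`.
#' @export
coverage_profile <- function(orfs, bins = 20, threshold = 0.95) {
  breaks <- seq(0, 1, length.out = bins + 1)
  idx <- pmin(pmax(ceiling(orfs$coverage_fraction * bins), 1L), bins)
  counts <- tabulate(idx, nbins = bins)
  structure(list(
    histogram = tibble::tibble(
      bin_low = breaks[-(bins + 1)], bin_high = breaks[-1], count = counts
    ),
    n_spanning = sum(orfs$coverage_fraction >= threshold),
    threshold = threshold,
    n_total = nrow(orfs)
  ), class = "hx_orf_profile")
}

#' Long transcripts that encode only short ORFs
#'
#' The pseudogene-suspect profile: transcripts of at least `min_nt`
#' nucleotides whose longest ORF is shorter than `max_aa` residues.
#'
#' @param orfs A tibble from [longest_orfs()].
#' @param min_nt Minimum transcript length (inclusive).
#' @param max_aa Strict upper bound on ORF length.
#' @return The qualifying subset of `orfs`.
#' @export
long_transcript_short_orf <- function(orfs, min_nt = 1000, max_aa = 100) {
  dplyr::filter(orfs, .data$transcript_len >= min_nt, .data$aa_len < max_aa)
}

#' Write an ORF table as TSV
#'
#' @param orfs A tibble from [longest_orfs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orf_tsv <- function(orfs, path) {
  utils::write.table(
    orfs[, c("transcript_id", "strand", "frame", "nt_start", "nt_end",
             "aa_len", "has_start", "has_stop", "coverage_fraction")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
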