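NT_ALPHABET <- "ACGT"
AA_ALPHABET <- "ARNDCQEGHILKMFPSTWYVBZX"

#' Alignment search parameters
#'
#' Scoring and filtering knobs for the internal seed-and-extend local
#' aligner.  Defaults follow megablast-like conventions for nucleotides
#' (match +1, mismatch -2, gap open 5, gap extend 2, word size 11) and
#' BLOSUM62 with gap open 11 / extend 1 and 4-mer seeding for proteins.
#' A gap of length L costs `gap_open + L * gap_extend`.
#'
#' E-values use the Karlin-Altschul form `E = K * m * n * exp(-lambda * S)`
#' with fixed, documented constants per scoring scheme (nucleotide:
#' lambda 1.28, K 0.46; protein: lambda 0.267, K 0.041).  They gate hits;
#' no attempt is made at exact parameter estimation.
#'
#' @param type `"nt"` or `"protein"`.
#' @param word_size Seed word length (>= 4); defaults 11 (nt) / 4 (protein).
#' @param min_identity_pct Minimum percent identity for a reported hit
#'   (identity is computed over all alignment columns, gap columns counting
#'   as non-matches).
#' @param max_evalue Maximum E-value for a reported hit.
#' @param max_hits_per_query Hit-list cap per query (default 250, the
#'   classic BLAST default that also caps the redundancy index).
#' @param soft_mask Mask low-complexity stretches during seeding while still
#'   scoring them during extension.
#' @param match,mismatch Nucleotide match/mismatch scores.
#' @param gap_open,gap_extend Positive gap penalties.
#' @param band_pad Extra diagonals allowed on each side of a seed cluster
#'   during banded extension.
#' @param max_diag_gap Seeds whose diagonals differ by more than this found
#'   separate clusters.
#' @param mask_window,mask_threshold Low-complexity window length and
#'   Shannon-entropy threshold (bits) for [low_complexity_mask()].
#' @param min_raw_score Minimum raw alignment score to report.
#' @param min_ungapped_score Seed clusters of fewer than three words must
#'   reach this score under ungapped X-drop extension before banded DP is
#'   attempted (a BLAST-style two-stage trigger that discards spurious
#'   single-word seeds cheaply); 0 disables the pretest.
#' @param lambda,karlin_k Karlin-Altschul constants; defaults depend on
#'   `type`.
#' @return A list of class `hx_search_params`.
#' @export
search_params <- function(type = c("nt", "protein"),
                          word_size = NULL,
                          min_identity_pct = 0,
                          max_evalue = 10,
                          max_hits_per_query = 250,
                          soft_mask = FALSE,
                          match = 1, mismatch = -2,
                          gap_open = NULL, gap_extend = NULL,
                          band_pad = 32, max_diag_gap = 16,
                          mask_window = 12, mask_threshold = 1.5,
                          min_raw_score = 0,
                          min_ungapped_score = NULL,
                          lambda = NULL, karlin_k = NULL) {
  type <- match.arg(type)
  if (is.null(word_size)) word_size <- if (type == "nt") 11L else 4L
  if (word_size < 4) rlang::abort("word_size must be >= 4")
  if (max_hits_per_query < 1) rlang::abort("max_hits_per_query must be >= 1")
  if (is.null(gap_open)) gap_open <- if (type == "nt") 5L else 11L
  if (is.null(gap_extend)) gap_extend <- if (type == "nt") 2L else 1L
  if (is.null(min_ungapped_score)) {
    min_ungapped_score <- if (type == "nt") 18L else 22L
  }
  if (is.null(lambda)) lambda <- if (type == "nt") 1.28 else 0.267
  if (is.null(karlin_k)) karlin_k <- if (type == "nt") 0.46 else 0.041
  structure(list(
    type = type, word_size = as.integer(word_size),
    min_identity_pct = min_identity_pct, max_evalue = max_evalue,
    max_hits_per_query = as.integer(max_hits_per_query),
    soft_mask = isTRUE(soft_mask),
    match = as.integer(match), mismatch = as.integer(mismatch),
    gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
    band_pad = as.integer(band_pad), max_diag_gap = as.integer(max_diag_gap),
    mask_window = as.integer(mask_window), mask_threshold = mask_threshold,
    min_raw_score = as.integer(min_raw_score),
    min_ungapped_score = as.integer(min_ungapped_score),
    lambda = lambda, karlin_k = karlin_k
  ), class = "hx_search_params")
}

# substitution matrix over alphabet codes + one trailing "unknown" class
# (N and any other out-of-alphabet letter); unknown mismatches everything,
# including itself.
build_submat <- function(params) {
  if (params$type == "nt") {
    k <- nchar(NT_ALPHABET) + 1L
    m <- matrix(params$mismatch, k, k)
    diag(m) <- params$match
    m[k, k] <- params$mismatch
    storage.mode(m) <- "integer"
    return(m)
  }
  b62 <- get_blosum62()
  letters_aa <- strsplit(AA_ALPHABET, "")[[1]]
  k <- length(letters_aa) + 1L
  m <- matrix(-4L, k, k)
  m[seq_along(letters_aa), seq_along(letters_aa)] <-
    b62[letters_aa, letters_aa]
  storage.mode(m) <- "integer"
  m
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

aln_alphabet <- function(params) {
  if (params$type == "nt") NT_ALPHABET else AA_ALPHABET
}

#' Locate low-complexity intervals
#'
#' A position is masked when it is covered by any window of `window`
#' residues whose Shannon entropy of composition falls below `threshold`
#' bits (a dust-like heuristic).  Soft masking excludes such positions from
#' alignment seeding only; banded extension still scores them.
#'
#' @param seq A single sequence string.
#' @param window Window length (default 12).
#' @param threshold Entropy threshold in bits (default 1.5).
#' @param type `"nt"` or `"protein"`.
#' @return A tibble of masked intervals with 1-based inclusive `start`,
#'   `end` columns.
#' @examples
#' low_complexity_mask(strrep("A", 60))
#' @export
low_complexity_mask <- function(seq, window = 12, threshold = 1.5,
                                type = c("nt", "protein")) {
  type <- match.arg(type)
  alpha <- if (type == "nt") NT_ALPHABET else AA_ALPHABET
  m <- cpp_entropy_mask(toupper(seq), alpha, as.integer(window), threshold)
  mask_to_intervals(m)
}

mask_to_intervals <- function(mask) {
  if (!any(mask)) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}

mask_fraction <- function(seq, params) {
  m <- cpp_entropy_mask(toupper(seq), aln_alphabet(params),
                        params$mask_window, params$mask_threshold)
  if (length(m) == 0) 0 else mean(m)
}

compute_masks <- function(seqs, params) {
  if (!params$soft_mask) {
    return(rep(list(NULL), length(seqs)))
  }
  lapply(seqs, function(s) {
    cpp_entropy_mask(s, aln_alphabet(params), params$mask_window,
                     params$mask_threshold)
  })
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)`: strictly decreasing in the score and
#' linear in both the query length `m` and the database length `n`.
#'
#' @param score Raw alignment score(s) (> 0).
#' @param query_len,db_len Query and database lengths in residues.
#' @param params A [search_params()] carrying `lambda` and `karlin_k`.
#' @return Numeric E-value(s).
#' @examples
#' p <- search_params("nt")
#' align_evalue(60, 100, 1e6, p)
#' @export
align_evalue <- function(score, query_len, db_len, params = search_params()) {
  if (any(query_len <= 0) || any(db_len <= 0)) {
    rlang::abort("query_len and db_len must be positive")
  }
  if (any(score <= 0)) rlang::abort("score must be positive")
  params$karlin_k * query_len * db_len * exp(-params$lambda * score)
}

# shared engine behind local_align() and seq_search()
run_search <- function(queries, subjects, params, db_len = NULL) {
  stopifnot(is.data.frame(queries), is.data.frame(subjects))
  if (nrow(queries) == 0 || nrow(subjects) == 0) {
    return(empty_hits())
  }
  qseq <- toupper(queries$seq)
  sseq <- toupper(subjects$seq)
  if (any(!nzchar(qseq))) rlang::abort("empty query sequence")
  submat <- build_submat(params)
  alpha <- aln_alphabet(params)
  n_seed <- if (params$type == "nt") 4L else 20L
  smask <- compute_masks(sseq, params)
  qmask <- compute_masks(qseq, params)
  if (is.null(db_len)) db_len <- sum(nchar(sseq))

  collect <- function(qs, qm, strand) {
    df <- cpp_search(qs, sseq, alpha, n_seed, submat,
                     params$gap_open, params$gap_extend,
                     params$word_size, params$band_pad, params$max_diag_gap,
                     max(1L, params$min_raw_score), qm, smask, 100000L,
                     params$min_ungapped_score)
    df <- tibble::as_tibble(df)
    df$strand <- strand
    df
  }
  hits <- collect(qseq, qmask, "+")
  if (params$type == "nt") {
    rc <- revcomp(qseq)
    rcmask <- lapply(qmask, function(m) if (is.null(m)) NULL else rev(m))
    hits_m <- collect(rc, rcmask, "-")
    if (nrow(hits_m) > 0) {
      qlen <- nchar(qseq)[hits_m$query]
      qs_fwd <- qlen - hits_m$q_end
      hits_m$q_end <- qlen - hits_m$q_start
      hits_m$q_start <- qs_fwd
    }
    hits <- dplyr::bind_rows(hits, hits_m)
  }
  if (nrow(hits) == 0) {
    return(empty_hits())
  }
  hits |>
    dplyr::mutate(
      query_id = queries$id[.data$query],
      subject_id = subjects$id[.data$subject],
      identity_pct = 100 * .data$matches / .data$aln_len,
      evalue = align_evalue(.data$score, nchar(qseq)[.data$query], db_len,
                            params)
    ) |>
    dplyr::filter(
      .data$identity_pct >= params$min_identity_pct,
      .data$evalue <= params$max_evalue
    ) |>
    dplyr::distinct(.data$query_id, .data$subject_id, .data$strand,
                    .data$q_start, .data$q_end, .data$s_start, .data$s_end,
                    .keep_all = TRUE) |>
    dplyr::select("query_id", "subject_id", "strand", "q_start", "q_end",
                  "s_start", "s_end", "aln_len", "matches", "gaps",
                  "identity_pct", "score", "evalue")
}

empty_hits <- function() {
  tibble::tibble(
    query_id = character(), subject_id = character(), strand = character(),
    q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(),
    aln_len = integer(), matches = integer(), gaps = integer(),
    identity_pct = numeric(), score = integer(), evalue = numeric()
  )
}

#' Local alignment of one query against one subject
#'
#' Seed-and-extend with banded affine-gap dynamic programming: shared words
#' seed diagonal clusters, each cluster is extended independently, and every
#' resulting local alignment is reported.  Both strands are searched for
#' nucleotides.  Coordinates are 0-based half-open on the forward sequences;
#' identity is computed over all alignment columns (a gap column is a
#' non-match).
#'
#' @param query,subject Single-row [seq_tbl()]s (or data frames with `id`
#'   and `seq`).
#' @param params A [search_params()].
#' @return A tibble of alignment hits (possibly empty), sorted by
#'   descending score.
#' @export
local_align <- function(query, subject, params = search_params()) {
  run_search(query[1, , drop = FALSE], subject[1, , drop = FALSE], params,
             db_len = nchar(subject$seq[[1]])) |>
    dplyr::arrange(dplyr::desc(.data$score))
}

#' Search queries against a sequence database
#'
#' For every query, the best hit per subject is retained, hits are filtered
#' by `min_identity_pct` and `max_evalue`, sorted by descending score then
#' ascending subject id, and truncated to `max_hits_per_query`.
#'
#' @param queries,subjects [seq_tbl()]s (id + seq).
#' @param params A [search_params()].
#' @return A tibble of alignment hits.
#' @export
seq_search <- function(queries, subjects, params = search_params()) {
  hits <- run_search(queries, subjects, params)
  if (nrow(hits) == 0) {
    return(hits)
  }
  hits |>
    dplyr::group_by(.data$query_id, .data$subject_id) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(
      match(.data$query_id, queries$id),
      dplyr::desc(.data$score), .data$subject_id
    ) |>
    dplyr::group_by(.data$query_id) |>
    dplyr::slice_head(n = params$max_hits_per_query) |>
    dplyr::ungroup()
}

#' Write hits as a BLAST outfmt-6-like TSV
#'
#' Columns: qid, sid, pident, length, mismatch, gapcols, qstart, qend,
#' sstart, send, evalue, bitscore.  Coordinates are 1-based inclusive in the
#' TSV (internal coordinates are 0-based half-open); minus-strand hits have
#' sstart > send, BLAST style.
#'
#' @param hits A hit tibble from [seq_search()] or [local_align()].
#' @param path Output path.
#' @param params The [search_params()] used (for bit-score constants).
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path, params = search_params()) {
  minus <- hits$strand == "-"
  sstart <- ifelse(minus, hits$s_end, hits$s_start + 1L)
  send <- ifelse(minus, hits$s_start + 1L, hits$s_end)
  out <- data.frame(
    qid = hits$query_id, sid = hits$subject_id,
    pident = sprintf("%.2f", hits$identity_pct),
    length = hits$aln_len,
    mismatch = hits$aln_len - hits$matches - hits$gaps,
    gapcols = hits$gaps,
    qstart = hits$q_start + 1L, qend = hits$q_end,
    sstart = sstart, send = send,
    evalue = format(hits$evalue, digits = 3),
    bitscore = sprintf("%.1f", (params$lambda * hits$score -
                                  log(params$karlin_k)) / log(2))
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
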