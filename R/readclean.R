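#' Read-cleaning parameters
#'
#' Constants of the Illumina / 454 / contig cleaning heuristics: a 5-bp
#' barcode at the read start, exact matching of the first 12 bp of the 3'
#' adapters, removal of 3'-terminal homopolymer runs longer than 5 nt,
#' discarding reads with more than 90% of bases at Phred <= 5, a 30-bp
#' minimum length, and trans-spliced-leader hallmark motifs (TAAG within
#' the first 15 bp of a contig, its reverse complement CTTA within the
#' last 15 bp).
#'
#' @param barcode_len Bases stripped from the 5' end of each Illumina read.
#' @param adapter_seqs Character vector of 3' adapter sequences.
#' @param adapter_prefix_len Length of the adapter prefix matched exactly.
#' @param homopolymer_max Longest 3' homopolymer run retained.
#' @param lowq_phred,lowq_frac Quality filter: discard when more than
#'   `lowq_frac` of bases have Phred <= `lowq_phred`.
#' @param min_len Minimum surviving read length.
#' @param edge_window Edge window (bp) for leader-motif and 454
#'   adapter/leader anchoring.
#' @param leader_motif,leader_motif_rc Trans-spliced leader hallmark motif
#'   and its reverse complement.
#' @return A list of class `hx_clean_params`.
#' @export
clean_params <- function(barcode_len = 5,
                         adapter_seqs = character(),
                         adapter_prefix_len = 12,
                         homopolymer_max = 5,
                         lowq_phred = 5,
                         lowq_frac = 0.90,
                         min_len = 30,
                         edge_window = 15,
                         leader_motif = "TAAG",
                         leader_motif_rc = "CTTA") {
  stopifnot(barcode_len >= 0, adapter_prefix_len > 0, homopolymer_max > 0,
            min_len > 0, edge_window > 0, lowq_frac > 0, lowq_frac <= 1)
  structure(list(
    barcode_len = as.integer(barcode_len),
    adapter_seqs = toupper(adapter_seqs),
    adapter_prefix_len = as.integer(adapter_prefix_len),
    homopolymer_max = as.integer(homopolymer_max),
    lowq_phred = as.integer(lowq_phred),
    lowq_frac = lowq_frac,
    min_len = as.integer(min_len),
    edge_window = as.integer(edge_window),
    leader_motif = toupper(leader_motif),
    leader_motif_rc = toupper(leader_motif_rc)
  ), class = "hx_clean_params")
}

# single-read Illumina pipeline; returns list(seq, qual, filter) where
# filter is NA when the read survives
clean_illumina_one <- function(seq, qual, params) {
  n <- nchar(seq)
  # (1) barcode
  if (n <= params$barcode_len) {
    return(list(seq = "", qual = integer(), filter = "min_len"))
  }
  seq <- substr(seq, params$barcode_len + 1L, n)
  qual <- qual[(params$barcode_len + 1L):n]
  # (2) exact adapter-prefix match anywhere: truncate at match start
  for (ad in params$adapter_seqs) {
    pre <- substr(ad, 1L, params$adapter_prefix_len)
    pos <- regexpr(pre, seq, fixed = TRUE)
    if (pos > 0) {
      seq <- substr(seq, 1L, pos - 1L)
      qual <- qual[seq_len(pos - 1L)]
    }
  }
  # (3) inexact 3'-anchored adapter overlap (>= 8 nt, <= 1 mismatch)
  for (ad in params$adapter_seqs) {
    k <- adapter_overlap(seq, ad, min_overlap = 8L, max_mismatch = 1L)
    if (k > 0) {
      keep <- nchar(seq) - k
      seq <- substr(seq, 1L, keep)
      qual <- qual[seq_len(keep)]
    }
  }
  # (4) 3'-terminal homopolymer run longer than homopolymer_max: remove run
  run <- terminal_homopolymer_run(seq)
  if (run > params$homopolymer_max) {
    keep <- nchar(seq) - run
    seq <- substr(seq, 1L, keep)
    qual <- qual[seq_len(keep)]
  }
  # (5) low-quality fraction
  if (length(qual) > 0 &&
      mean(qual <= params$lowq_phred) > params$lowq_frac) {
    return(list(seq = seq, qual = qual, filter = "low_quality"))
  }
  # (6) minimum length
  if (nchar(seq) < params$min_len) {
    return(list(seq = seq, qual = qual, filter = "min_len"))
  }
  list(seq = seq, qual = qual, filter = NA_character_)
}

# longest 3'-anchored overlap (>= min_overlap) between the read suffix and
# the adapter prefix with <= max_mismatch mismatches; returns overlap length
adapter_overlap <- function(seq, adapter, min_overlap = 8L, max_mismatch = 1L) {
  n <- nchar(seq)
  maxk <- min(n, nchar(adapter))
  if (maxk < min_overlap) {
    return(0L)
  }
  sv <- strsplit(seq, "")[[1]]
  av <- strsplit(adapter, "")[[1]]
  for (k in seq(maxk, min_overlap)) {
    mm <- sum(sv[(n - k + 1L):n] != av[1:k])
    if (mm <= max_mismatch) {
      return(k)
    }
  }
  0L
}

terminal_homopolymer_run <- function(seq) {
  n <- nchar(seq)
  if (n == 0) {
    return(0L)
  }
  m <- regexpr("(A+|C+|G+|T+|N+)$", seq)
  attr(m, "match.length")
}

#' Clean one set of Illumina reads
#'
#' Per-read pipeline, in fixed order: (1) strip the 5' barcode; (2) truncate
#' at any exact match of an adapter's first `adapter_prefix_len` bases;
#' (3) trim inexact 3'-anchored adapter overlaps (>= 8 nt, at most one
#' mismatch); (4) remove 3'-terminal homopolymer runs longer than
#' `homopolymer_max` (the whole run); (5) discard reads with more than
#' `lowq_frac` of bases at Phred <= `lowq_phred`; (6) discard reads shorter
#' than `min_len`.  Homopolymer trimming deliberately runs after adapter
#' removal (adapter removal can expose a terminal homopolymer), and the
#' quality fraction is judged on the final retained bases.
#'
#' @param records A [seq_tbl()] whose records all carry qualities.
#' @param params A [clean_params()].
#' @return A list with `reads` (the surviving, trimmed [seq_tbl()]) and
#'   `report` (an `hx_clean_report`, see [clean_report()]).
#' @export
clean_illumina_reads <- function(records, params = clean_params()) {
  if (any(!has_qual(records))) {
    rlang::abort("all Illumina reads must carry qualities")
  }
  res <- purrr::map2(records$seq, records$qual, clean_illumina_one,
                     params = params)
  finalize_clean(records, res, "illumina")
}

#' Clean contig edges of trans-spliced leader hallmarks
#'
#' If the leader motif (TAAG) occurs entirely within the first
#' `edge_window` bp, the prefix through the end of the last such occurrence
#' is removed; symmetrically, if its reverse complement (CTTA) occurs
#' entirely within the last `edge_window` bp, the suffix from the first
#' such occurrence is removed.  Applied once, 5' end then 3' end.
#'
#' @param records A [seq_tbl()] of contigs.
#' @param params A [clean_params()].
#' @return A new [seq_tbl()] with trimmed sequences (qualities, if present,
#'   are trimmed alongside).
#' @export
clean_contig_edges <- function(records, params = clean_params()) {
  out <- records
  for (i in seq_len(nrow(out))) {
    seq <- out$seq[[i]]
    qual <- out$qual[[i]]
    n <- nchar(seq)
    w <- params$edge_window
    motif <- params$leader_motif
    ml <- nchar(motif)
    # 5': last occurrence fully inside the first w bases
    starts <- gregexpr(motif, substr(seq, 1L, min(w, n)), fixed = TRUE)[[1]]
    starts <- starts[starts > 0 & starts + ml - 1L <= w]
    if (length(starts) > 0) {
      cut <- max(starts) + ml - 1L
      seq <- substr(seq, cut + 1L, n)
      if (!is.null(qual)) qual <- qual[-seq_len(cut)]
      n <- nchar(seq)
    }
    # 3': first occurrence fully inside the last w bases
    motif_rc <- params$leader_motif_rc
    mrl <- nchar(motif_rc)
    if (n >= mrl) {
      tail_start <- max(1L, n - w + 1L)
      tail_seq <- substr(seq, tail_start, n)
      pos <- regexpr(motif_rc, tail_seq, fixed = TRUE)
      if (pos > 0) {
        cut_from <- tail_start + pos - 1L
        seq <- substr(seq, 1L, cut_from - 1L)
        if (!is.null(qual)) qual <- qual[seq_len(cut_from - 1L)]
      }
    }
    out$seq[[i]] <- seq
    out$qual[i] <- list(qual)
  }
  out
}

#' Clean one set of 454-style reads
#'
#' Exact adapter/leader occurrences anchored within `edge_window` bp of
#' either read end are trimmed together with the intervening edge; the
#' minimum-length filter is then applied.  Internal occurrences are left
#' alone.
#'
#' @param records A [seq_tbl()] of 454 reads.
#' @param adapters,leaders Character vectors of adapter and trans-spliced
#'   leader sequences (matched exactly).
#' @param params A [clean_params()].
#' @return A list with `reads` and `report`, as for
#'   [clean_illumina_reads()].
#' @export
clean_454_reads <- function(records, adapters = character(),
                            leaders = character(),
                            params = clean_params()) {
  motifs <- toupper(c(adapters, leaders))
  res <- purrr::map2(records$seq, records$qual, function(seq, qual) {
    for (mo in motifs) {
      n <- nchar(seq)
      if (n == 0) break
      pos <- gregexpr(mo, seq, fixed = TRUE)[[1]]
      pos <- pos[pos > 0]
      if (length(pos) == 0) next
      ml <- nchar(mo)
      w <- params$edge_window
      # anchored near the 5' end: trim through the match end
      p5 <- pos[pos <= w]
      if (length(p5) > 0) {
        cut <- max(p5) + ml - 1L
        seq <- substr(seq, cut + 1L, n)
        if (!is.null(qual)) qual <- qual[-seq_len(cut)]
        n <- nchar(seq)
        pos <- pos - cut
        pos <- pos[pos > 0]
      }
      # anchored near the 3' end: trim from the match start
      p3 <- pos[pos + ml - 1L >= n - w + 1L & pos + ml - 1L <= n]
      if (length(p3) > 0) {
        cut_from <- min(p3)
        seq <- substr(seq, 1L, cut_from - 1L)
        if (!is.null(qual)) qual <- qual[seq_len(cut_from - 1L)]
      }
    }
    filt <- if (nchar(seq) < params$min_len) "min_len" else NA_character_
    list(seq = seq, qual = qual, filter = filt)
  })
  finalize_clean(records, res, "454")
}

finalize_clean <- function(records, res, kind) {
  filters <- vapply(res, function(x) x$filter, character(1))
  keep <- is.na(filters)
  trimmed <- vapply(seq_along(res), function(i) {
    nchar(res[[i]]$seq) != nchar(records$seq[[i]])
  }, logical(1))
  reads <- seq_tbl(
    records$id[keep],
    vapply(res[keep], function(x) x$seq, character(1)),
    desc = records$desc[keep],
    qual = lapply(res[keep], function(x) x$qual)
  )
  report <- clean_report(
    n_input = nrow(records), n_output = sum(keep),
    removed = table(factor(filters[!keep])),
    n_trimmed = sum(trimmed & keep),
    kind = kind
  )
  list(reads = reads, report = report)
}

#' Build a cleaning report
#'
#' @param n_input,n_output Read counts before and after cleaning.
#' @param removed Named counts of discarded reads per filter.
#' @param n_trimmed Number of surviving reads that were trimmed.
#' @param kind Which cleaner produced the report.
#' @return An `hx_clean_report`: a one-row tibble with the counts and the
#'   integer `retention_pct` = round(100 * n_output / n_input).
#' @export
clean_report <- function(n_input, n_output, removed = NULL, n_trimmed = NA,
                         kind = "reads") {
  stopifnot(n_output <= n_input)
  out <- tibble::tibble(
    kind = kind,
    n_input = as.double(n_input),
    n_output = as.double(n_output),
    n_removed = as.double(n_input - n_output),
    n_trimmed = as.double(n_trimmed),
    retention_pct = retention_pct(n_input, n_output)
  )
  attr(out, "removed_by_filter") <-
    if (is.null(removed)) integer() else c(removed)
  class(out) <- c("hx_clean_report", class(out))
  out
}

#' Retention percentage
#'
#' The report-only arithmetic mode of the cleaning stage: the percentage of
#' reads surviving, rounded to an integer (e.g. 64,433,175 raw and
#' 53,599,364 kept reads give 83).
#'
#' @param n_input,n_output Raw and kept read counts.
#' @return Integer percentage.
#' @examples
#' retention_pct(64433175, 53599364)
#' @export
retention_pct <- function(n_input, n_output) {
  if (n_input <= 0) rlang::abort("n_input must be positive")
  as.integer(round(100 * n_output / n_input))
}

#' Clean a whole dataset
#'
#' Applies the per-read cleaner appropriate for `type` and reports
#' retention.
#'
#' @param records A [seq_tbl()].
#' @param type `"illumina"`, `"454"`, or `"contig"`.
#' @param params A [clean_params()].
#' @param adapters,leaders Motifs for the 454 cleaner.
#' @return A list with `reads` and `report` (for contigs the report counts
#'   trimmed edges; contigs are never discarded).
#' @export
clean_dataset <- function(records, type = c("illumina", "454", "contig"),
                          params = clean_params(),
                          adapters = character(), leaders = character()) {
  type <- match.arg(type)
  switch(type,
    illumina = clean_illumina_reads(records, params),
    `454` = clean_454_reads(records, adapters, leaders, params),
    contig = {
      out <- clean_contig_edges(records, params)
      report <- clean_report(
        n_input = nrow(records), n_output = nrow(out),
        n_trimmed = sum(nchar(out$seq) != nchar(records$seq)),
        kind = "contig"
      )
      list(reads = out, report = report)
    }
  )
}
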