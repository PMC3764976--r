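#' Redundancy-removal parameters
#'
#' Constants of the protein-level redundancy removal: ORFs shorter than
#' `min_aa` (50) are dropped, `cterm_trim` (25) C-terminal residues are
#' trimmed before clustering (the nonsense polypeptide translated after a
#' frameshift averages ~15 residues, so trimming suppresses that noise),
#' greedy clustering uses a global identity threshold of
#' `cluster_identity` (95%) with a linear gap penalty of `gap_penalty`
#' (20) per gap column, and the six-criterion discard filter uses
#' `min_aln_aa` (25), `min_block_identity` (95%), `min_match_span` (95%)
#' and `max_unmatched_aa` (100).
#'
#' @param min_aa Minimum ORF length considered.
#' @param cterm_trim C-terminal residues trimmed during clustering and
#'   filtering only; final outputs are untruncated.
#' @param cluster_identity Global-identity threshold for clustering (0-1).
#' @param gap_penalty Linear per-gap-column penalty of the global aligner.
#' @param min_aln_aa Criterion i: alignments shorter than this are ignored.
#' @param min_block_identity Criterion iii threshold (0-1, strict).
#' @param min_match_span Criterion v: alignment must span at least this
#'   fraction of the match.
#' @param max_unmatched_aa Criterion vi: maximum match residues outside
#'   the alignment.
#' @return A list of class `hx_dedup_params`.
#' @export
dedup_params <- function(min_aa = 50, cterm_trim = 25,
                         cluster_identity = 0.95, gap_penalty = 20,
                         min_aln_aa = 25, min_block_identity = 0.95,
                         min_match_span = 0.95, max_unmatched_aa = 100) {
  stopifnot(min_aa > 0, cterm_trim >= 0,
            cluster_identity > 0, cluster_identity <= 1,
            min_block_identity > 0, min_block_identity <= 1,
            min_match_span > 0, min_match_span <= 1)
  structure(list(
    min_aa = as.integer(min_aa), cterm_trim = as.integer(cterm_trim),
    cluster_identity = cluster_identity, gap_penalty = as.integer(gap_penalty),
    min_aln_aa = as.integer(min_aln_aa),
    min_block_identity = min_block_identity,
    min_match_span = min_match_span,
    max_unmatched_aa = as.integer(max_unmatched_aa)
  ), class = "hx_dedup_params")
}

#' Global alignment identity between two proteins
#'
#' End-to-end (Needleman-Wunsch-style) alignment maximizing
#' `matches - gap_penalty * gap_columns`; identity is matches over all
#' alignment columns.
#'
#' @param p1,p2 Protein sequence strings.
#' @param gap_penalty Linear per-gap-column penalty (default 20).
#' @return Percent identity in `[0, 100]`.
#' @examples
#' global_identity("MKLV", "MKLV")
#' @export
global_identity <- function(p1, p2, gap_penalty = 20) {
  if (!nzchar(p1) || !nzchar(p2)) rlang::abort("empty protein sequence")
  cpp_global_identity(toupper(p1), toupper(p2), AA_ALPHABET,
                      as.integer(gap_penalty))$identity_pct
}

#' Greedy centroid clustering of proteins
#'
#' Sequences are processed in decreasing length; each joins the first
#' (earliest-founded) centroid whose global identity reaches
#' `cluster_identity`, otherwise it founds a new cluster.  The
#' representative of a cluster is its centroid, i.e. its longest member.
#'
#' @param proteins A [seq_tbl()] of (already length-filtered, C-trimmed)
#'   proteins.
#' @param params A [dedup_params()].
#' @return A tibble: `id`, `cluster`, `is_representative`, in input order.
#' @export
cluster_proteins <- function(proteins, params = dedup_params()) {
  n <- nrow(proteins)
  ord <- order(-nchar(proteins$seq))
  cluster <- integer(n)
  centroid_idx <- integer(0)
  thr <- 100 * params$cluster_identity
  for (i in ord) {
    si <- proteins$seq[[i]]
    li <- nchar(si)
    assigned <- 0L
    for (k in seq_along(centroid_idx)) {
      sc <- proteins$seq[[centroid_idx[[k]]]]
      lc <- nchar(sc)
      # identity can never reach thr when lengths are too dissimilar
      if (100 * min(li, lc) / max(li, lc) < thr) next
      if (global_identity(si, sc, params$gap_penalty) >= thr) {
        assigned <- k
        break
      }
    }
    if (assigned == 0L) {
      centroid_idx <- c(centroid_idx, i)
      assigned <- length(centroid_idx)
    }
    cluster[[i]] <- assigned
  }
  tibble::tibble(
    id = proteins$id,
    cluster = cluster,
    is_representative = seq_len(n) %in% centroid_idx
  )
}

#' Six-criterion redundancy discard filter
#'
#' Cluster representatives are searched all-vs-all at the protein level
#' (no low-complexity masking).  For an ordered (query, match) pair, the
#' match is discarded if and only if all of: (i) the best alignment block
#' is at least `min_aln_aa` residues and the pair is not a self match;
#' (ii) the query is strictly longer than the match; (iii) the block
#' identity exceeds `min_block_identity`; (iv) the alignment has no gap
#' columns (so splice variants are retained); (v) the alignment spans at
#' least `min_match_span` of the match; and (vi) at most
#' `max_unmatched_aa` match residues lie outside the alignment.
#'
#' @param representatives A [seq_tbl()] of representative proteins.
#' @param params A [dedup_params()].
#' @param search A [search_params()] for the all-vs-all protein search.
#' @return A list with `kept` (the surviving [seq_tbl()]) and `decisions`
#'   (one row per aligned ordered pair: `query_id`, `match_id`, criterion
#'   outcome in `failed_criterion`, and the match's `kept` flag).
#' @export
redundancy_filter <- function(representatives, params = dedup_params(),
                              search = search_params("protein")) {
  search$soft_mask <- FALSE
  search$min_identity_pct <- 0
  hits <- seq_search(representatives, representatives, search)
  lens <- stats::setNames(nchar(representatives$seq), representatives$id)
  if (nrow(hits) == 0) {
    return(list(kept = representatives,
                decisions = tibble::tibble(query_id = character(),
                                           match_id = character(),
                                           failed_criterion = character(),
                                           kept = logical())))
  }
  decisions <- hits |>
    dplyr::mutate(
      match_len = lens[.data$subject_id],
      query_len = lens[.data$query_id],
      span = .data$s_end - .data$s_start,
      failed_criterion = dplyr::case_when(
        query_id == subject_id ~ "self",
        aln_len < params$min_aln_aa ~ "aln_too_short",
        query_len <= match_len ~ "query_not_bigger",
        identity_pct <= 100 * params$min_block_identity ~ "identity_low",
        gaps > 0 ~ "has_gaps",
        span < params$min_match_span * match_len ~ "span_low",
        match_len - span > params$max_unmatched_aa ~ "unmatched_high",
        TRUE ~ "discarded"
      )
    ) |>
    dplyr::transmute(
      query_id = .data$query_id, match_id = .data$subject_id,
      failed_criterion = .data$failed_criterion
    )
  discarded <- unique(decisions$match_id[decisions$failed_criterion ==
                                           "discarded"])
  decisions$kept <- !(decisions$match_id %in% discarded)
  list(
    kept = representatives[!(representatives$id %in% discarded), ],
    decisions = decisions
  )
}

#' Remove redundancy from a transcript dataset
#'
#' The full procedure: extract the longest ORF of each transcript, drop
#' ORFs shorter than `min_aa`, trim `cterm_trim` C-terminal residues,
#' cluster globally, keep cluster representatives, apply the
#' six-criterion discard filter, and finally restore the untruncated
#' transcripts (and peptides) of the survivors.
#'
#' @param transcripts A [seq_tbl()] of nucleotide transcripts.
#' @param params A [dedup_params()].
#' @param search A [search_params()] for the protein search stage.
#' @return An `hx_dedup` list: `kept` (untruncated surviving transcripts),
#'   `peptides` (their untruncated ORF peptides), `report` (one row per
#'   removed transcript with `reason` and, where applicable, the id that
#'   displaced it), `decisions` (the filter's pair decisions), `clusters`
#'   (the clustering table).
#' @export
deduplicate <- function(transcripts, params = dedup_params(),
                        search = search_params("protein")) {
  orfs <- longest_orfs(transcripts)
  report <- list()

  short <- orfs$aa_len < params$min_aa
  if (any(short)) {
    report$min_aa <- tibble::tibble(
      id = orfs$transcript_id[short], reason = "min_aa",
      displaced_by = NA_character_
    )
  }
  orfs_kept <- orfs[!short, , drop = FALSE]
  if (nrow(orfs_kept) == 0) {
    return(structure(list(
      kept = transcripts[0, ], peptides = seq_tbl(character(), character()),
      report = dplyr::bind_rows(report),
      decisions = NULL, clusters = NULL
    ), class = "hx_dedup"))
  }

  trimmed <- substr(orfs_kept$peptide, 1L,
                    pmax(1L, orfs_kept$aa_len - params$cterm_trim))
  prot <- seq_tbl(orfs_kept$transcript_id, trimmed)

  clusters <- cluster_proteins(prot, params)
  reps <- clusters$is_representative
  if (any(!reps)) {
    rep_of <- clusters$id[clusters$is_representative]
    names(rep_of) <- as.character(clusters$cluster[clusters$is_representative])
    report$cluster <- tibble::tibble(
      id = clusters$id[!reps], reason = "cluster_member",
      displaced_by = unname(rep_of[as.character(clusters$cluster[!reps])])
    )
  }

  filt <- redundancy_filter(prot[reps, , drop = FALSE], params, search)
  discarded_ids <- setdiff(prot$id[reps], filt$kept$id)
  if (length(discarded_ids) > 0) {
    by_q <- filt$decisions |>
      dplyr::filter(.data$failed_criterion == "discarded") |>
      dplyr::distinct(.data$match_id, .keep_all = TRUE)
    report$filter <- tibble::tibble(
      id = discarded_ids, reason = "redundant",
      displaced_by = by_q$query_id[match(discarded_ids, by_q$match_id)]
    )
  }

  kept_ids <- filt$kept$id
  kept_orfs <- orfs_kept[orfs_kept$transcript_id %in% kept_ids, , drop = FALSE]
  structure(list(
    kept = transcripts[transcripts$id %in% kept_ids, , drop = FALSE],
    peptides = orf_peptides(kept_orfs),
    report = dplyr::bind_rows(report),
    decisions = filt$decisions,
    clusters = clusters
  ), class = "hx_dedup")
}
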