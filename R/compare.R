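best_identity_by_query <- function(hits) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(query_id = character(),
                          best_identity_pct = numeric()))
  }
  hits |>
    dplyr::group_by(.data$query_id) |>
    dplyr::summarise(best_identity_pct = max(.data$identity_pct),
                     .groups = "drop")
}

#' Find the "only" set of one dataset versus another
#'
#' A query belongs to the only-set when its best nucleotide hit in the
#' subject dataset falls below the identity threshold (or no hit exists at
#' all).  Low-complexity masking is disabled, matching how unpredicted /
#' predicted-only sequences are counted; run the symmetric direction
#' separately for the other only-set.
#'
#' @param queries,subjects [seq_tbl()]s.
#' @param identity_threshold Percent identity (default 95); the only-set
#'   is `best identity < threshold`.
#' @param max_evalue E-value gate of the underlying search.
#' @return A tibble: `query_id`, `status` (`"shared"` / `"only"`),
#'   `best_identity_pct` (NA when no hit).
#' @export
find_only_set <- function(queries, subjects, identity_threshold = 95,
                          max_evalue = 1e-10) {
  sp <- search_params("nt", min_identity_pct = 0, max_evalue = max_evalue,
                      soft_mask = FALSE)
  hits <- seq_search(queries, subjects, sp)
  tibble::tibble(query_id = queries$id) |>
    dplyr::left_join(best_identity_by_query(hits), by = "query_id") |>
    dplyr::mutate(status = dplyr::if_else(
      !is.na(.data$best_identity_pct) &
        .data$best_identity_pct >= identity_threshold,
      "shared", "only"
    )) |>
    dplyr::select("query_id", "status", "best_identity_pct")
}

#' Annotate an only-set with expression evidence
#'
#' Each only-sequence is tagged with every evidence dataset (ESTs, other
#' transcriptomes, ...) containing a hit at the same identity threshold;
#' sequences with an empty tag set are `novel`.
#'
#' @param only_set Output of [find_only_set()] (rows with
#'   `status == "only"` are annotated; others pass through untagged).
#' @param queries The [seq_tbl()] the only-set was computed from.
#' @param evidence_datasets Named list of [seq_tbl()]s.
#' @param identity_threshold Percent identity (default 95).
#' @return The only-set tibble with list-column `evidence_tags` and
#'   logical `novel`.
#' @export
evidence_annotate <- function(only_set, queries, evidence_datasets,
                              identity_threshold = 95) {
  only_ids <- only_set$query_id[only_set$status == "only"]
  qsub <- queries[queries$id %in% only_ids, , drop = FALSE]
  tag_sets <- stats::setNames(
    rep(list(character()), length(only_ids)), only_ids
  )
  for (nm in names(evidence_datasets)) {
    res <- find_only_set(qsub, evidence_datasets[[nm]],
                         identity_threshold = identity_threshold)
    found <- res$query_id[res$status == "shared"]
    for (id in found) tag_sets[[id]] <- c(tag_sets[[id]], nm)
  }
  only_set |>
    dplyr::mutate(
      evidence_tags = unname(tag_sets[.data$query_id]),
      evidence_tags = lapply(.data$evidence_tags,
                             function(x) if (is.null(x)) character() else x),
      novel = .data$status == "only" & lengths(.data$evidence_tags) == 0
    )
}

#' Sequential contaminant screen
#'
#' Queries are tested against an ordered list of contaminant databases;
#' each query is assigned to the first database in which it hits and is
#' not realigned to later ones, so the assignment is a partition.  When
#' `low_complexity_first` is set, queries whose low-complexity mask covers
#' at least `mask_coverage` of their length are labelled
#' `"low_complexity"` before any database is consulted.  Unassigned
#' queries are `"clean"`.
#'
#' @param queries A [seq_tbl()].
#' @param contaminant_dbs Ordered named list of [seq_tbl()]s.
#' @param low_complexity_first Check the mask before the databases.
#' @param mask_coverage Masked-fraction threshold (default 0.8).
#' @param min_identity_pct,max_evalue Hit thresholds per database.
#' @return A tibble: `query_id`, `label` (database name,
#'   `"low_complexity"`, or `"clean"`).
#' @export
contaminant_screen <- function(queries, contaminant_dbs,
                               low_complexity_first = TRUE,
                               mask_coverage = 0.8,
                               min_identity_pct = 90, max_evalue = 1e-10) {
  label <- stats::setNames(rep(NA_character_, nrow(queries)), queries$id)
  remaining <- queries
  if (low_complexity_first && nrow(remaining) > 0) {
    sp <- search_params("nt")
    frac <- vapply(remaining$seq, mask_fraction, numeric(1), sp)
    lowc <- frac >= mask_coverage
    label[remaining$id[lowc]] <- "low_complexity"
    remaining <- remaining[!lowc, , drop = FALSE]
  }
  for (nm in names(contaminant_dbs)) {
    if (nrow(remaining) == 0) break
    sp <- search_params("nt", min_identity_pct = min_identity_pct,
                        max_evalue = max_evalue, soft_mask = FALSE)
    hits <- seq_search(remaining, contaminant_dbs[[nm]], sp)
    found <- unique(hits$query_id)
    label[found] <- nm
    remaining <- remaining[!(remaining$id %in% found), , drop = FALSE]
  }
  label[is.na(label)] <- "clean"
  tibble::tibble(query_id = queries$id, label = unname(label[queries$id]))
}

#' Genomic support of transcripts
#'
#' A transcript is supported when its best genomic hit exceeds
#' `min_identity_pct` identity.
#'
#' @param transcripts A [seq_tbl()].
#' @param genome A [seq_tbl()] of genomic contigs.
#' @param min_identity_pct Strict identity threshold (default 75).
#' @return A tibble: `transcript_id`, `supported`, `best_identity_pct`
#'   (NA when no alignment).
#' @export
genome_support <- function(transcripts, genome, min_identity_pct = 75) {
  sp <- search_params("nt", min_identity_pct = 0, max_evalue = 1e-6,
                      soft_mask = FALSE)
  hits <- seq_search(transcripts, genome, sp)
  tibble::tibble(transcript_id = transcripts$id) |>
    dplyr::left_join(best_identity_by_query(hits),
                     by = c(transcript_id = "query_id")) |>
    dplyr::mutate(supported = !is.na(.data$best_identity_pct) &
                    .data$best_identity_pct > min_identity_pct)
}

#' Classify pseudogene candidates
#'
#' The operational screen for processed/degenerate gene copies: a
#' transcript is a candidate if and only if its longest ORF is shorter
#' than `max_orf_aa` residues, the ORF does not span `orf_span_threshold`
#' of the transcript, the transcript aligns to the genome perfectly (a
#' single gap-free 100%-identity alignment covering its whole length —
#' spliced pseudogenes therefore escape, which keeps the screen
#' deliberately stringent), and its best identity to any genome-predicted
#' transcript is below `predicted_identity_pct`.
#'
#' @param transcripts A [seq_tbl()] of candidate transcripts.
#' @param orfs Their [longest_orfs()] table.
#' @param genome A [seq_tbl()] of genomic contigs.
#' @param predicted_set A [seq_tbl()] of genome-predicted transcripts.
#' @param max_orf_aa Strict ORF-length bound (default 100).
#' @param orf_span_threshold Spanning-ORF coverage bound (default 0.95).
#' @param predicted_identity_pct Identity bound versus predicted
#'   transcripts (default 95, strict).
#' @return A tibble: `transcript_id`, `orf_aa_len`, `orf_spans_full`,
#'   `genome_perfect`, `max_identity_to_predicted_pct`,
#'   `is_pseudogene_candidate`.
#' @export
pseudogene_classify <- function(transcripts, orfs, genome, predicted_set,
                                max_orf_aa = 100,
                                orf_span_threshold = 0.95,
                                predicted_identity_pct = 95) {
  info <- orfs[match(transcripts$id, orfs$transcript_id), , drop = FALSE]
  out <- tibble::tibble(
    transcript_id = transcripts$id,
    orf_aa_len = info$aa_len,
    orf_spans_full = info$coverage_fraction >= orf_span_threshold
  )
  # cheap ORF criteria first; only survivors are aligned
  cand <- !is.na(out$orf_aa_len) & out$orf_aa_len < max_orf_aa &
    !out$orf_spans_full
  sub <- transcripts[cand, , drop = FALSE]

  perfect <- rep(FALSE, nrow(transcripts))
  if (nrow(sub) > 0) {
    sp <- search_params("nt", min_identity_pct = 0, max_evalue = 1e-6,
                        soft_mask = FALSE)
    ghits <- run_search(sub, genome, sp)
    if (nrow(ghits) > 0) {
      qlen <- stats::setNames(nchar(sub$seq), sub$id)
      pg <- ghits |>
        dplyr::filter(
          .data$gaps == 0,
          .data$matches == .data$aln_len,
          (.data$q_end - .data$q_start) == qlen[.data$query_id]
        )
      perfect[match(unique(pg$query_id), transcripts$id)] <- TRUE
    }
  }
  out$genome_perfect <- perfect

  max_ident <- rep(NA_real_, nrow(transcripts))
  sub2 <- transcripts[cand & perfect, , drop = FALSE]
  if (nrow(sub2) > 0 && nrow(predicted_set) > 0) {
    sp <- search_params("nt", min_identity_pct = 0, max_evalue = 1e-6,
                        soft_mask = FALSE)
    phits <- seq_search(sub2, predicted_set, sp)
    if (nrow(phits) > 0) {
      bp <- best_identity_by_query(phits)
      max_ident[match(bp$query_id, transcripts$id)] <- bp$best_identity_pct
    }
  }
  out$max_identity_to_predicted_pct <- max_ident
  out$is_pseudogene_candidate <-
    !is.na(out$orf_aa_len) & out$orf_aa_len < max_orf_aa &
    !out$orf_spans_full & out$genome_perfect &
    (is.na(out$max_identity_to_predicted_pct) |
       out$max_identity_to_predicted_pct < predicted_identity_pct)
  out
}
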