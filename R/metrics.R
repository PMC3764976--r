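#' Redundancy-index search parameters
#'
#' The within-dataset search behind the redundancy index: only matches
#' with more than `min_identity_pct` (98) percent identity and an E-value
#' at most `max_evalue` (1e-30) count, at most `max_hits` (250) alignments
#' are retained per query, and low-complexity stretches are soft-masked
#' (excluded from seeding, still scored during extension — without soft
#' masking too many hits would fall below the identity gate through masked
#' stretches counted as mismatches).
#'
#' @param min_identity_pct Strict identity gate (percent).
#' @param max_evalue E-value gate.
#' @param max_hits Hit-list cap per query.
#' @param soft_mask_search Soft-mask the search phase.
#' @return A list of class `hx_ri_params`.
#' @export
ri_params <- function(min_identity_pct = 98, max_evalue = 1e-30,
                      max_hits = 250, soft_mask_search = TRUE) {
  structure(list(
    min_identity_pct = min_identity_pct, max_evalue = max_evalue,
    max_hits = as.integer(max_hits),
    soft_mask_search = isTRUE(soft_mask_search)
  ), class = "hx_ri_params")
}

#' Redundancy index of a coding-sequence dataset
#'
#' All-vs-all nucleotide search of the dataset against itself; the RI is
#' the arithmetic mean over queries of the number of retained hits.  Self
#' hits count, so a dataset of mutually unrelated sequences has RI = 1 and
#' the gene-number estimator n / RI returns n for it.  Coding sequences,
#' not full-length transcripts, should be supplied: UTRs, vector
#' contaminants and trans-spliced leaders otherwise bias the hit counts.
#'
#' @param coding_seqs A [seq_tbl()] of coding (ORF) nucleotide sequences.
#' @param params An [ri_params()].
#' @return An `hx_ri` list: `ri` (the index), `n` (dataset size), and
#'   `per_query` (tibble of hit counts per query).
#' @export
redundancy_index <- function(coding_seqs, params = ri_params()) {
  if (nrow(coding_seqs) == 0) rlang::abort("empty dataset")
  sp <- search_params(
    "nt",
    min_identity_pct = params$min_identity_pct,
    max_evalue = params$max_evalue,
    max_hits_per_query = params$max_hits,
    soft_mask = params$soft_mask_search
  )
  hits <- seq_search(coding_seqs, coding_seqs, sp) |>
    dplyr::filter(.data$identity_pct > params$min_identity_pct)
  counts <- tibble::tibble(query_id = coding_seqs$id) |>
    dplyr::left_join(dplyr::count(hits, .data$query_id), by = "query_id") |>
    dplyr::mutate(n_hits = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::select("query_id", "n_hits")
  structure(list(
    ri = mean(counts$n_hits),
    n = nrow(coding_seqs),
    per_query = counts
  ), class = "hx_ri")
}

#' @export
print.hx_ri <- function(x, ...) {
  cat(sprintf("Redundancy index: %.2f over %d sequences (gene estimate %.0f)\n",
              x$ri, x$n, gene_number_estimate(x$n, x$ri)))
  invisible(x)
}

#' Estimate the gene number from dataset size and redundancy
#'
#' Each sequence matches `ri` closely related sequences of its own dataset
#' on average (itself included), so the distinct-gene count is estimated
#' as `n_sequences / ri`.
#'
#' @param n_sequences Number of sequences in the dataset (>= 1).
#' @param ri Redundancy index (>= 1).
#' @return The estimate `n_sequences / ri` (unrounded).
#' @examples
#' gene_number_estimate(48909, 2.0)
#' @export
gene_number_estimate <- function(n_sequences, ri) {
  if (any(n_sequences < 1)) rlang::abort("n_sequences must be >= 1")
  if (any(ri < 1)) rlang::abort("ri must be >= 1 (self hits count)")
  n_sequences / ri
}

#' Compare coding lengths against a reference transcriptome
#'
#' For each reference coding sequence, the best-scoring gap-free
#' ("uninterrupted") hit in the test set longer than `min_aln_nt` with at
#' least `min_identity_pct` identity is taken; the hit sequence's length
#' relative to the reference classifies it into `>=100%`, `75-99%` or
#' `<75%`.  References with no qualifying hit are `unmatched`.
#'
#' @param reference_cds,test_cds [seq_tbl()]s of coding sequences.
#' @param min_aln_nt Strict lower bound on alignment length (default 100).
#' @param min_identity_pct Identity threshold (default 95, inclusive).
#' @return An `hx_length_compare` list: `per_reference` (tibble:
#'   `reference_id`, `hit_id`, `length_ratio_pct`, `class`) and
#'   `matched_pct`.
#' @export
coding_length_compare <- function(reference_cds, test_cds,
                                  min_aln_nt = 100, min_identity_pct = 95) {
  sp <- search_params("nt", min_identity_pct = min_identity_pct,
                      max_evalue = 1e-10, soft_mask = FALSE)
  hits <- seq_search(reference_cds, test_cds, sp) |>
    dplyr::filter(.data$gaps == 0, .data$aln_len > min_aln_nt) |>
    dplyr::group_by(.data$query_id) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  test_len <- stats::setNames(nchar(test_cds$seq), test_cds$id)
  ref_len <- stats::setNames(nchar(reference_cds$seq), reference_cds$id)
  per_ref <- tibble::tibble(reference_id = reference_cds$id) |>
    dplyr::left_join(
      dplyr::select(hits, reference_id = "query_id", hit_id = "subject_id"),
      by = "reference_id"
    ) |>
    dplyr::mutate(
      length_ratio_pct = 100 * test_len[.data$hit_id] /
        ref_len[.data$reference_id],
      class = dplyr::case_when(
        is.na(.data$hit_id) ~ "unmatched",
        length_ratio_pct >= 100 ~ ">=100%",
        length_ratio_pct >= 75 ~ "75-99%",
        TRUE ~ "<75%"
      )
    )
  structure(list(
    per_reference = per_ref,
    matched_pct = 100 * mean(per_ref$class != "unmatched")
  ), class = "hx_length_compare")
}

#' Read-sampling saturation analysis
#'
#' Reads are mapped once to the reference (best hit wins; a read maps when
#' it aligns at >= `map_identity_pct` identity over at least
#' `map_coverage` of its length).  A single seeded permutation is then
#' prefix-sliced at each fraction (nested sampling without replacement, so
#' the curves are monotone by construction) and the number of reference
#' sequences reaching each hit threshold is counted.
#'
#' @param reads A [seq_tbl()] of reads.
#' @param reference A [seq_tbl()] of reference transcripts.
#' @param fractions Increasing fractions in (0, 1].
#' @param hit_thresholds Integer thresholds (default `c(1, 100)`).
#' @param seed Integer seed for the permutation.
#' @param map_identity_pct,map_coverage Near-exact mapping mode thresholds.
#' @return An `hx_saturation` tibble: one row per fraction with `fraction`,
#'   `n_reads`, and a `refs_ge<k>` column per threshold.
#' @export
saturation_curve <- function(reads, reference, fractions = c(
                               0.01, 0.05, 0.1, 0.2, 0.5, 1
                             ),
                             hit_thresholds = c(1, 100), seed = 1,
                             map_identity_pct = 95, map_coverage = 0.9) {
  if (any(fractions > 1) || any(fractions <= 0)) {
    rlang::abort("fractions must lie in (0, 1]")
  }
  fractions <- sort(fractions)
  sp <- search_params("nt", min_identity_pct = map_identity_pct,
                      max_evalue = 1e-6, soft_mask = FALSE)
  hits <- seq_search(reads, reference, sp) |>
    dplyr::mutate(qcov = (.data$q_end - .data$q_start) /
                    nchar(reads$seq)[match(.data$query_id, reads$id)]) |>
    dplyr::filter(.data$qcov >= map_coverage) |>
    dplyr::group_by(.data$query_id) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  mapped_ref <- stats::setNames(hits$subject_id, hits$query_id)

  n <- nrow(reads)
  perm <- with_seed_local(seed, sample.int(n))
  rows <- lapply(fractions, function(f) {
    take <- round(f * n)
    ids <- reads$id[perm[seq_len(take)]]
    refs <- mapped_ref[ids]
    refs <- refs[!is.na(refs)]
    counts <- table(refs)
    row <- tibble::tibble(fraction = f, n_reads = take)
    for (thr in hit_thresholds) {
      row[[paste0("refs_ge", thr)]] <- sum(counts >= thr)
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hx_saturation", class(out))
  attr(out, "n_reference") <- nrow(reference)
  out
}

# run code under a seed without disturbing the caller's RNG state
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Analytic occupancy expectation for uniform coverage
#'
#' Under uniform random assignment of `n_reads` reads to `n_refs`
#' references, the expected number of references receiving at least one
#' read is `R (1 - (1 - 1/R)^n)`; the variance follows the classical
#' occupancy formula.
#'
#' @param n_refs Number of references.
#' @param n_reads Number of reads drawn.
#' @return A list with `mean` and `sd`.
#' @export
occupancy_expectation <- function(n_refs, n_reads) {
  R <- n_refs
  q1 <- (1 - 1 / R)^n_reads
  q2 <- (1 - 2 / R)^n_reads
  mean_occ <- R * (1 - q1)
  var_empty <- R * q1 + R * (R - 1) * q2 - R^2 * q1^2
  list(mean = mean_occ, sd = sqrt(max(0, var_empty)))
}
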