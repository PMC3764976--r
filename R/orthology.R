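#' Reciprocal-best-hit ortholog detection
#'
#' Protein search of proteome A against proteome B and vice versa under an
#' E-value gate (default 1e-8) with soft masking.  A pair (a, b) is
#' emitted when b is a's unique best-scoring hit in B and a is b's unique
#' best-scoring hit in A.  A tied best score means the query has no
#' unique best and forms no pair (a conservative convention); each id
#' appears in at most one pair.
#'
#' @param proteome_a,proteome_b [seq_tbl()]s of proteins.
#' @param max_evalue E-value threshold (default 1e-8).
#' @param soft_mask Soft-mask the search phase (default TRUE).
#' @return A tibble: `id_a`, `id_b`, `score_ab`, `score_ba`, `evalue_ab`,
#'   `evalue_ba`.
#' @export
rbh <- function(proteome_a, proteome_b, max_evalue = 1e-8,
                soft_mask = TRUE) {
  if (nrow(proteome_a) == 0 || nrow(proteome_b) == 0) {
    return(empty_rbh())
  }
  sp <- search_params("protein", max_evalue = max_evalue,
                      soft_mask = soft_mask)
  ab <- unique_best(seq_search(proteome_a, proteome_b, sp))
  ba <- unique_best(seq_search(proteome_b, proteome_a, sp))
  if (nrow(ab) == 0 || nrow(ba) == 0) {
    return(empty_rbh())
  }
  ab |>
    dplyr::inner_join(ba, by = c(query_id = "subject_id",
                                 subject_id = "query_id"),
                      suffix = c("_ab", "_ba")) |>
    dplyr::transmute(
      id_a = .data$query_id, id_b = .data$subject_id,
      score_ab = .data$score_ab, score_ba = .data$score_ba,
      evalue_ab = .data$evalue_ab, evalue_ba = .data$evalue_ba
    )
}

empty_rbh <- function() {
  tibble::tibble(id_a = character(), id_b = character(),
                 score_ab = numeric(), score_ba = numeric(),
                 evalue_ab = numeric(), evalue_ba = numeric())
}

# best-scoring hit per query, dropped when the best score is tied
unique_best <- function(hits) {
  if (nrow(hits) == 0) {
    return(hits)
  }
  hits |>
    dplyr::group_by(.data$query_id) |>
    dplyr::filter(.data$score == max(.data$score)) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup() |>
    dplyr::select("query_id", "subject_id", "score", "evalue")
}

#' Restrict RBH pairs to a sequence subset
#'
#' RBH pairs are computed on whole proteomes first, then filtered; this
#' keeps the reciprocal-best property intact while reporting, say, the
#' pairs whose A-side sequence belongs to an only-set.
#'
#' @param pairs Output of [rbh()].
#' @param id_subset Character vector of A-side ids to keep.
#' @return The filtered pair tibble.
#' @export
rbh_subset <- function(pairs, id_subset) {
  dplyr::filter(pairs, .data$id_a %in% id_subset)
}
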