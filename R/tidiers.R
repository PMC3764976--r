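#' Tidy a redundancy-index result
#'
#' @param x An `hx_ri` from [redundancy_index()].
#' @param ... Unused.
#' @return Per-query hit counts as a tibble.
#' @export
tidy.hx_ri <- function(x, ...) x$per_query

#' @rdname tidy.hx_ri
#' @return For `glance()`: a one-row tibble with `ri`, `n_sequences` and
#'   the implied `gene_estimate`.
#' @export
glance.hx_ri <- function(x, ...) {
  tibble::tibble(ri = x$ri, n_sequences = x$n,
                 gene_estimate = gene_number_estimate(x$n, x$ri))
}

#' Tidy a cleaning report
#'
#' @param x An `hx_clean_report`.
#' @param ... Unused.
#' @return Per-filter removal counts as a tibble.
#' @export
tidy.hx_clean_report <- function(x, ...) {
  removed <- attr(x, "removed_by_filter")
  tibble::tibble(filter = names(removed),
                 n_removed = as.integer(removed))
}

#' @rdname tidy.hx_clean_report
#' @return For `glance()`: the one-row summary (counts and
#'   `retention_pct`).
#' @export
glance.hx_clean_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Tidy a redundancy-removal result
#'
#' @param x An `hx_dedup` from [deduplicate()].
#' @param ... Unused.
#' @return The removal report: one row per removed transcript with its
#'   reason.
#' @export
tidy.hx_dedup <- function(x, ...) x$report

#' @rdname tidy.hx_dedup
#' @return For `glance()`: a one-row tibble of input/kept/removed counts.
#' @export
glance.hx_dedup <- function(x, ...) {
  tibble::tibble(
    n_kept = nrow(x$kept),
    n_removed = nrow(x$report),
    n_clusters = if (is.null(x$clusters)) NA_integer_ else
      length(unique(x$clusters$cluster))
  )
}

#' Tidy a coding-length comparison
#'
#' @param x An `hx_length_compare` from [coding_length_compare()].
#' @param ... Unused.
#' @return The per-reference classification tibble.
#' @export
tidy.hx_length_compare <- function(x, ...) x$per_reference

#' @rdname tidy.hx_length_compare
#' @return For `glance()`: `matched_pct` plus per-class counts.
#' @export
glance.hx_length_compare <- function(x, ...) {
  counts <- table(x$per_reference$class)
  out <- tibble::tibble(matched_pct = x$matched_pct)
  for (nm in names(counts)) out[[paste0("n_", nm)]] <- as.integer(counts[[nm]])
  out
}

#' Tidy an ORF coverage profile
#'
#' @param x An `hx_orf_profile` from [coverage_profile()].
#' @param ... Unused.
#' @return The histogram tibble.
#' @export
tidy.hx_orf_profile <- function(x, ...) x$histogram

#' @rdname tidy.hx_orf_profile
#' @return For `glance()`: totals and the spanning-ORF count.
#' @export
glance.hx_orf_profile <- function(x, ...) {
  tibble::tibble(n_total = x$n_total, n_spanning = x$n_spanning,
                 threshold = x$threshold,
                 spanning_pct = 100 * x$n_spanning / max(1, x$n_total))
}
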