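#' Read a FASTA file into a sequence table
#'
#' Records keep file order; multi-line sequences are joined and lowercase is
#' uppercased.  The record id is the first whitespace-delimited token of the
#' header, the rest becomes `desc`.
#'
#' @param path Path to a FASTA file.
#' @return A [seq_tbl()] with empty `qual` entries.
#' @export
read_fasta <- function(path) {
  check_fasta_syntax(path)
  x <- Biostrings::readBStringSet(path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_tbl(ids, as.character(x), desc = descs)
}

# Light pre-parse so format errors can name the offending line.
check_fasta_syntax <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    rlang::abort(paste0("FASTA format error in ", path, ": file is empty"))
  }
  if (!startsWith(lines[[1]], ">")) {
    rlang::abort(paste0(
      "FASTA format error in ", path, " at line 1: expected a '>' header"
    ))
  }
  hdr <- which(startsWith(lines, ">"))
  empty_hdr <- hdr[!nzchar(sub("^>\\s*", "", lines[hdr]))]
  if (length(empty_hdr) > 0) {
    rlang::abort(paste0(
      "FASTA format error in ", path, " at line ", empty_hdr[[1]],
      ": header has no identifier"
    ))
  }
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    rlang::abort(paste0(
      "duplicate record id(s) in ", path, ": ", paste(dup, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Read a 4-line FASTQ file into a sequence table
#'
#' @param path Path to a FASTQ file.
#' @param offset Phred encoding offset; 33 (default, Sanger/modern Illumina)
#'   or 64 (early Genome Analyzer dialect).
#' @return A [seq_tbl()] with decoded integer qualities.
#' @export
read_fastq <- function(path, offset = 33) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  check_fastq_syntax(path)
  parsed <- tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(x = x,
         seqs = as.character(x),
         quals = as.character(S4Vectors::mcols(x)$qualities))
  }, error = function(e) {
    rlang::abort(paste0("FASTQ format error in ", path, ": ",
                        conditionMessage(e)))
  })
  x <- parsed$x
  quals <- parsed$quals
  seqs <- parsed$seqs
  if (any(nchar(quals) != nchar(seqs))) {
    bad <- which(nchar(quals) != nchar(seqs))[[1]]
    rlang::abort(paste0(
      "FASTQ format error in ", path, ": sequence and quality lengths differ ",
      "for record ", names(x)[[bad]]
    ))
  }
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  qual <- lapply(quals, function(q) utf8ToInt(q) - as.integer(offset))
  seq_tbl(ids, seqs, desc = descs, qual = qual)
}

# 4-line-record sanity check so truncation is reported cleanly
check_fastq_syntax <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4 != 0) {
    rlang::abort(paste0(
      "FASTQ format error in ", path, ": truncated record (",
      length(lines), " lines is not a multiple of 4)"
    ))
  }
  first <- lines[seq(1, length(lines), by = 4)]
  if (!all(startsWith(first, "@"))) {
    bad <- which(!startsWith(first, "@"))[[1]]
    rlang::abort(paste0(
      "FASTQ format error in ", path, " at line ", (bad - 1) * 4 + 1,
      ": expected an '@' header"
    ))
  }
  seqs <- lines[seq(2, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  if (any(nchar(seqs) != nchar(quals))) {
    bad <- which(nchar(seqs) != nchar(quals))[[1]]
    rlang::abort(paste0(
      "FASTQ format error in ", path, ": sequence and quality lengths ",
      "differ in record ", bad
    ))
  }
  invisible(TRUE)
}

#' Read a 454-style QUAL file
#'
#' FASTA-like headers followed by whitespace-separated integer Phred scores.
#'
#' @param path Path to a QUAL file.
#' @return A named list of integer vectors keyed by record id.
#' @export
read_qual <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) == 0) {
    rlang::abort(paste0("QUAL format error in ", path, ": no '>' header found"))
  }
  ends <- c(hdr[-1] - 1L, length(lines))
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  vals <- lapply(seq_along(hdr), function(i) {
    body <- lines[seq.int(hdr[[i]] + 1L, length.out = max(0L, ends[[i]] - hdr[[i]]))]
    as.integer(strsplit(paste(body, collapse = " "), "\\s+")[[1]] |>
      (\(x) x[nzchar(x)])())
  })
  stats::setNames(vals, ids)
}

#' Write a sequence table to FASTA
#'
#' @param records A [seq_tbl()].
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  x <- Biostrings::BStringSet(records$seq)
  names(x) <- ifelse(nzchar(records$desc),
                     paste(records$id, records$desc),
                     records$id)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Write paired FASTA and QUAL files
#'
#' The 454-era representation of reads-with-qualities: a FASTA file plus a
#' parallel file of whitespace-separated integer Phred scores with identical
#' headers and record order.  Round-trips through [read_fasta()] +
#' [read_qual()].
#'
#' @param records A [seq_tbl()]; every record must carry qualities.
#' @param fasta_path,qual_path Output paths.
#' @return A list with elements `fasta` and `qual`, invisibly.
#' @export
write_fasta_qual <- function(records, fasta_path, qual_path) {
  missing_q <- !has_qual(records)
  if (any(missing_q)) {
    rlang::abort(paste0(
      "records without qualities cannot be written to FASTA+QUAL: ",
      paste(records$id[missing_q], collapse = ", ")
    ))
  }
  write_fasta(records, fasta_path)
  con <- file(qual_path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$desc[[i]])) {
      paste(records$id[[i]], records$desc[[i]])
    } else {
      records$id[[i]]
    }
    writeLines(paste0(">", hdr), con)
    writeLines(paste(records$qual[[i]], collapse = " "), con)
  }
  invisible(list(fasta = fasta_path, qual = qual_path))
}

#' Read paired FASTA and QUAL files
#'
#' @param fasta_path,qual_path Input paths.
#' @return A [seq_tbl()] with qualities attached by record id.
#' @export
read_fasta_qual <- function(fasta_path, qual_path) {
  records <- read_fasta(fasta_path)
  quals <- read_qual(qual_path)
  missing <- setdiff(records$id, names(quals))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "records missing from QUAL file: ", paste(missing, collapse = ", ")
    ))
  }
  records$qual <- unname(quals[records$id])
  bad <- which(lengths(records$qual) != nchar(records$seq))
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "quality length differs from sequence length for record(s): ",
      paste(records$id[bad], collapse = ", ")
    ))
  }
  records
}

#' Write a sequence table to FASTQ (Phred+33 by default)
#'
#' @param records A [seq_tbl()]; every record must carry qualities.
#' @param path Output path.
#' @param offset Phred encoding offset (33 or 64).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path, offset = 33) {
  missing_q <- !has_qual(records)
  if (any(missing_q)) {
    rlang::abort(paste0(
      "records without qualities cannot be written to FASTQ: ",
      paste(records$id[missing_q], collapse = ", ")
    ))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(c(
      paste0("@", records$id[[i]]),
      records$seq[[i]],
      "+",
      intToUtf8(records$qual[[i]] + as.integer(offset))
    ), con)
  }
  invisible(path)
}
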