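# shared fixture builders; everything is generated in code under fixed seeds

BASES4 <- c("A", "C", "G", "T")
AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

rand_dna_str <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES4, n, replace = TRUE, prob = p), collapse = "")
}

rand_prot_str <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# substitutions only
mutate_dna <- function(seq, n_sub) {
  v <- strsplit(seq, "")[[1]]
  pos <- sample(length(v), n_sub)
  for (p in pos) v[[p]] <- sample(setdiff(BASES4, v[[p]]), 1)
  paste(v, collapse = "")
}

mutate_prot <- function(seq, rate) {
  v <- strsplit(seq, "")[[1]]
  k <- round(rate * length(v))
  pos <- sample(length(v), k)
  v[pos] <- sample(AA20, k, replace = TRUE)
  paste(v, collapse = "")
}

# substitutions + small indels
mutate_dna_indel <- function(seq, sub_rate, n_indel) {
  v <- strsplit(seq, "")[[1]]
  k <- stats::rbinom(1, length(v), sub_rate)
  pos <- sample(length(v), k)
  for (p in pos) v[[p]] <- sample(setdiff(BASES4, v[[p]]), 1)
  for (z in seq_len(n_indel)) {
    at <- sample(length(v) - 2, 1)
    if (stats::runif(1) < 0.5) {
      v <- append(v, sample(BASES4, 1), after = at)
    } else {
      v <- v[-at]
    }
  }
  paste(v, collapse = "")
}

# Biostrings Smith-Waterman oracle with the package's nucleotide scoring
sw_oracle_nt <- function(a, b, gap_open = 5, gap_ext = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_ext
  )
  list(score = Biostrings::score(pa),
       identity = Biostrings::pid(pa, type = "PID1"))
}

# Biostrings protein local-alignment score oracle (BLOSUM62, 11/1)
sw_oracle_prot_score <- function(a, b) {
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1
  ))
}

# a transcript with a clean single ORF: utr5 + ATG..stop + utr3.  The 5'
# UTR is frame-aligned and ends in an in-frame stop, so the longest
# stop-free stretch begins exactly at the ATG (has_start is then TRUE).
make_transcript <- function(n_codons, utr5 = 30, utr3 = 40, gc = 0.5) {
  sense <- setdiff(apply(expand.grid(BASES4, BASES4, BASES4), 1,
                         paste, collapse = ""),
                   c("TAA", "TAG", "TGA"))
  cds <- paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                             collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1))
  u5 <- if (utr5 >= 3) {
    paste0(rand_dna_str(3 * (utr5 %/% 3) - 3, gc), "TAA")
  } else {
    ""
  }
  paste0(u5, cds, rand_dna_str(utr3, gc))
}
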