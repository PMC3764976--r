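test_that("six-frame translation follows the standard code", {
  peps <- six_frame_translate(seq_tbl("t", "ATGAAATAG"))
  expect_equal(peps[["+0"]], "MK*")
  # N-containing codons become X; trailing partial codons are dropped
  expect_equal(six_frame_translate(seq_tbl("t", "ATGNAAC"))[["+0"]], "MX")
  expect_error(six_frame_translate(seq_tbl("t", "AT")), "codon")
})

test_that("reverse-strand frames equal forward translation of the revcomp", {
  set.seed(501)
  for (rep in 1:6) {
    s <- rand_dna_str(sample(30:120, 1))
    peps <- six_frame_translate(seq_tbl("t", s))
    rc <- six_frame_translate(seq_tbl("t", revcomp(s)))
    expect_equal(unname(peps[c("-0", "-1", "-2")]),
                 unname(rc[c("+0", "+1", "+2")]))
  }
})

test_that("longest ORF selection handles bounds, strands and ties", {
  o <- longest_orfs(seq_tbl("t", "ATGAAATAG"))
  expect_equal(o$peptide, "MK")
  expect_true(o$has_start)
  expect_true(o$has_stop)
  expect_equal(o$aa_len, 2L)
  expect_equal(o$strand, "+")

  # ORF without a leading ATG is still returned (exhaustive scan oracle)
  set.seed(502)
  for (rep in 1:10) {
    s <- rand_dna_str(sample(60:200, 1))
    o <- longest_orfs(seq_tbl("t", s))
    # oracle: longest stop-free codon span over explicit frame scan
    best_span <- 0
    for (str in c("+", "-")) {
      sq <- if (str == "+") s else revcomp(s)
      for (f in 0:2) {
        pep <- hydratx:::translate_one(sq, f)
        if (!nzchar(pep)) next
        m <- gregexpr("[^*]+", pep)[[1]]
        if (m[1] == -1) next
        lens <- attr(m, "match.length")
        for (k in seq_along(m)) {
          span <- 3 * lens[[k]] +
            (if (m[[k]] - 1 + lens[[k]] < nchar(pep)) 3 else 0)
          best_span <- max(best_span, span)
        }
      }
    }
    expect_equal(o$nt_end - o$nt_start, best_span)
  }

  # equal spans on both strands resolve to the + strand
  s <- "ATGAAATAG"
  expect_equal(longest_orfs(seq_tbl("t", s))$strand, "+")
})

test_that("longest ORF is invariant under reverse complementation", {
  set.seed(503)
  for (rep in 1:8) {
    s <- rand_dna_str(sample(90:300, 1))
    a <- longest_orfs(seq_tbl("t", s))
    b <- longest_orfs(seq_tbl("t", revcomp(s)))
    expect_equal(a$aa_len, b$aa_len)
    expect_equal(a$nt_end - a$nt_start, b$nt_end - b$nt_start)
    expect_true(a$aa_len * 3 <= nchar(s))
    expect_equal(a$coverage_fraction, (a$nt_end - a$nt_start) / nchar(s))
  }
})

test_that("full-length filtering requires start, stop and strict length", {
  orfs <- tibble::tibble(
    transcript_id = c("a", "b", "c", "d"),
    aa_len = c(100L, 150L, 150L, 101L),
    has_start = c(TRUE, FALSE, TRUE, TRUE),
    has_stop = c(TRUE, TRUE, FALSE, TRUE)
  )
  kept <- full_length_filter(orfs)
  expect_equal(kept$transcript_id, "d")   # 100 aa is excluded ("longer than")

  # constructed set: exactly the qualifying ORFs come back
  set.seed(504)
  seqs <- c(
    vapply(1:7, function(i) make_transcript(150), ""),   # full length, >100 aa
    vapply(1:6, function(i) make_transcript(60), ""),    # too short
    vapply(1:7, function(i) substr(make_transcript(150), 40, 400), "")
  )
  orfs2 <- longest_orfs(seq_tbl(sprintf("t%02d", 1:20), seqs))
  expect_equal(nrow(full_length_filter(orfs2)), 7)
})

test_that("coverage profile tallies ORF spans", {
  set.seed(505)
  full <- make_transcript(60, utr5 = 0, utr3 = 0)
  o1 <- longest_orfs(seq_tbl("t", full))
  expect_equal(o1$coverage_fraction, 1.0)

  seqs <- vapply(1:15, function(i) make_transcript(sample(40:200, 1)), "")
  orfs <- longest_orfs(seq_tbl(sprintf("t%02d", 1:15), seqs))
  prof <- coverage_profile(orfs, bins = 10, threshold = 0.95)
  expect_equal(sum(prof$histogram$count), 15)
  expect_equal(prof$n_spanning, sum(orfs$coverage_fraction >= 0.95))
  expect_equal(glance(prof)$n_total, 15)
})

test_that("long transcripts with short ORFs are selected on both bounds", {
  orfs <- tibble::tibble(
    transcript_id = c("a", "b", "c"),
    transcript_len = c(1000L, 999L, 1500L),
    aa_len = c(99L, 50L, 100L)
  )
  out <- long_transcript_short_orf(orfs)
  expect_equal(out$transcript_id, "a") # 1000 nt / 99 aa kept; 999 nt excluded
})
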