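test_that("a sequence aligns to itself full length at identity 100", {
  set.seed(101)
  a <- rand_dna_str(150)
  h <- local_align(seq_tbl("q", a), seq_tbl("s", a))
  expect_equal(nrow(h), 1)
  expect_equal(h$identity_pct, 100)
  expect_equal(h$gaps, 0L)
  expect_equal(h$aln_len, 150L)
  expect_equal(h$strand, "+")
})

test_that("two substitutions in 100 nt give the oracle's 98% top hit", {
  set.seed(102)
  a <- rand_dna_str(100)
  b <- mutate_dna(a, 2)
  h <- local_align(seq_tbl("q", a), seq_tbl("s", b))
  o <- sw_oracle_nt(a, b)
  expect_equal(h$score[[1]], o$score)
  expect_equal(h$identity_pct[[1]], 98)
})

test_that("sequences sharing no seed word yield no hit (oracle confirms)", {
  set.seed(103)
  repeat {
    a <- rand_dna_str(100)
    b <- rand_dna_str(100)
    kmers <- function(s) {
      substring(s, 1:(nchar(s) - 10), 11:nchar(s))
    }
    if (length(intersect(kmers(a), kmers(b))) == 0 &&
        length(intersect(kmers(a), kmers(revcomp(b)))) == 0) {
      break
    }
  }
  h <- local_align(seq_tbl("q", a), seq_tbl("s", b))
  expect_equal(nrow(h), 0)
})

test_that("search returns the database's query first and respects the hit cap", {
  set.seed(104)
  a <- rand_dna_str(120)
  db <- seq_tbl(sprintf("c%03d", 1:300), rep(a, 300))
  hits <- seq_search(seq_tbl("q", a), db, search_params("nt"))
  expect_equal(nrow(hits), 250)
  expect_true(all(hits$identity_pct == 100))
  # sorted by descending score then ascending subject id
  expect_equal(hits$subject_id, sort(hits$subject_id))
})

test_that("search equals the all-pairs Smith-Waterman oracle on a mixed database", {
  set.seed(105)
  base <- rand_dna_str(160)
  db_seqs <- c(
    vapply(1:6, function(i) mutate_dna(base, sample(0:12, 1)), ""),
    vapply(1:6, function(i) rand_dna_str(sample(80:200, 1)), "")
  )
  db <- seq_tbl(sprintf("d%02d", seq_along(db_seqs)), db_seqs)
  q <- seq_tbl("q", base)
  hits <- seq_search(q, db, search_params("nt", max_evalue = 1e-10))
  oracle <- vapply(db_seqs, function(s) sw_oracle_nt(base, s)$score, 0)
  for (i in seq_len(nrow(hits))) {
    j <- match(hits$subject_id[[i]], db$id)
    expect_equal(hits$score[[i]], oracle[[j]])
  }
  # every oracle score passing the same E-value gate is found
  ev <- align_evalue(pmax(oracle, 1), 160, sum(nchar(db_seqs)),
                     search_params("nt"))
  expect_setequal(hits$subject_id, db$id[oracle > 0 & ev <= 1e-10])
})

test_that("best-hit score is symmetric and reverse-complement consistent", {
  set.seed(106)
  for (rep in 1:8) {
    a <- rand_dna_str(sample(80:150, 1))
    b <- mutate_dna_indel(a, stats::runif(1, 0, 0.06), sample(0:1, 1))
    hab <- local_align(seq_tbl("a", a), seq_tbl("b", b))
    hba <- local_align(seq_tbl("b", b), seq_tbl("a", a))
    expect_equal(hab$score[[1]], hba$score[[1]])
    hrc <- local_align(seq_tbl("a", a), seq_tbl("b", revcomp(b)))
    expect_equal(hrc$score[[1]], hab$score[[1]])
    expect_equal(hrc$strand[[1]], "-")
  }
})

test_that("E-values follow the Karlin-Altschul closed form", {
  p <- search_params("nt")
  # linear in db length
  expect_equal(align_evalue(50, 100, 2e6, p),
               2 * align_evalue(50, 100, 1e6, p))
  # strictly decreasing in score
  expect_lt(align_evalue(60, 100, 1e6, p), align_evalue(50, 100, 1e6, p))
  # direct evaluation with the documented nucleotide constants
  expect_equal(align_evalue(60, 100, 1e6, p),
               0.46 * 100 * 1e6 * exp(-1.28 * 60))
  expect_error(align_evalue(60, 0, 1e6, p), "positive")
  expect_error(align_evalue(-3, 100, 1e6, p), "positive")
})

test_that("low-complexity masking hides seeds but not scoring", {
  # whole poly-A masked
  m <- low_complexity_mask(strrep("A", 60))
  expect_equal(as.integer(m$start), 1L)
  expect_equal(as.integer(m$end), 60L)
  # random uniform sequence unmasked
  set.seed(907)
  expect_equal(nrow(low_complexity_mask(rand_dna_str(60))), 0)
  # dinucleotide repeat masked
  expect_gt(nrow(low_complexity_mask(strrep("AT", 20))), 0)

  # a poly-A region is not seeded, but extension still scores across it
  set.seed(108)
  flank1 <- rand_dna_str(60)
  flank2 <- rand_dna_str(60)
  sq <- paste0(flank1, strrep("A", 40), flank2)
  p_masked <- search_params("nt", soft_mask = TRUE)
  h <- local_align(seq_tbl("q", sq), seq_tbl("s", sq), p_masked)
  expect_equal(h$aln_len[[1]], nchar(sq))   # scored across the masked run
  expect_equal(h$identity_pct[[1]], 100)
  # pure poly-A query finds no seeds at all under soft masking
  h2 <- local_align(seq_tbl("q", strrep("A", 60)),
                    seq_tbl("s", strrep("A", 60)), p_masked)
  expect_equal(nrow(h2), 0)
})

test_that("top-hit score matches full Smith-Waterman on random mutated pairs", {
  set.seed(109)
  for (rep in 1:40) {
    a <- rand_dna_str(sample(60:200, 1))
    b <- mutate_dna_indel(a, stats::runif(1, 0, 0.08), sample(0:2, 1))
    h <- local_align(seq_tbl("q", a), seq_tbl("s", b))
    o <- sw_oracle_nt(a, b)
    expect_equal(h$score[[1]], o$score)
    expect_lt(abs(h$identity_pct[[1]] - o$identity), 2)
  }
})

test_that("hit TSV uses 1-based inclusive coordinates", {
  set.seed(110)
  a <- rand_dna_str(90)
  h <- local_align(seq_tbl("q", a), seq_tbl("s", a))
  fp <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(h, fp)
  row <- strsplit(readLines(fp), "\t")[[1]]
  expect_equal(as.integer(row[[7]]), 1L)
  expect_equal(as.integer(row[[8]]), 90L)
})
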