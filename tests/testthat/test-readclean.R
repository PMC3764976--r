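ADAPTER <- "AGATCGGAAGAGCGGTTCAGCAGGAATGCCGAG"

good_read <- function(seq) {
  seq_tbl("r", seq, qual = list(rep(38L, nchar(seq))))
}

test_that("a clean 76-nt read loses exactly its 5-bp barcode", {
  set.seed(201)
  r <- good_read(rand_dna_str(76))
  out <- clean_illumina_reads(r)
  expect_equal(nrow(out$reads), 1)
  expect_equal(nchar(out$reads$seq), 71L)
  expect_equal(out$reads$seq[[1]], substr(r$seq[[1]], 6, 76))
})

test_that("exact adapter-prefix matches truncate the read at the match", {
  set.seed(202)
  insert <- rand_dna_str(40)
  seq <- paste0(rand_dna_str(5), insert, substr(ADAPTER, 1, 12),
                rand_dna_str(19))
  r <- good_read(seq)
  out <- clean_illumina_reads(r, clean_params(adapter_seqs = ADAPTER))
  expect_equal(out$reads$seq[[1]], insert)
})

test_that("inexact 3'-anchored adapter overlaps are trimmed", {
  set.seed(203)
  insert <- rand_dna_str(55)
  tail10 <- substr(ADAPTER, 1, 10)
  substr(tail10, 4, 4) <- if (substr(tail10, 4, 4) == "A") "C" else "A"
  r <- good_read(paste0(rand_dna_str(5), insert, tail10))
  out <- clean_illumina_reads(r, clean_params(adapter_seqs = ADAPTER))
  expect_equal(out$reads$seq[[1]], insert)
})

test_that("3' homopolymers longer than five are removed whole; five stays", {
  set.seed(204)
  stem <- paste0(rand_dna_str(5), rand_dna_str(50, gc = 1)) # GC stem, no A run
  r7 <- good_read(paste0(stem, strrep("A", 7)))
  out7 <- clean_illumina_reads(r7)
  expect_equal(nchar(out7$reads$seq), 50L)
  r5 <- good_read(paste0(stem, strrep("A", 5)))
  out5 <- clean_illumina_reads(r5)
  expect_equal(nchar(out5$reads$seq), 55L)
})

test_that("reads dominated by low-quality bases are discarded", {
  set.seed(205)
  # after the 5-bp barcode, 28 of 30 bases (93% > 90%) sit at Phred <= 5
  qual <- c(rep(38L, 5), rep(2L, 28), rep(38L, 2))
  r <- seq_tbl("r", paste(rep(c("A", "C", "G", "T"), length.out = 35),
                          collapse = ""), qual = list(qual))
  out <- clean_illumina_reads(r)
  expect_equal(nrow(out$reads), 0)
  expect_equal(tidy(out$report)$filter, "low_quality")
})

test_that("reads ending below 30 nt are discarded", {
  set.seed(206)
  r <- good_read(rand_dna_str(34, gc = 1))  # 29 nt after barcode
  out <- clean_illumina_reads(r)
  expect_equal(nrow(out$reads), 0)
  expect_equal(glance(out$report)$retention_pct, 0L)
})

test_that("homopolymer trimming runs after adapter removal", {
  set.seed(207)
  # adapter removal exposes a terminal A-run that must then be trimmed
  insert <- paste0(rand_dna_str(40, gc = 1), strrep("A", 8))
  seq <- paste0(rand_dna_str(5), insert, substr(ADAPTER, 1, 12))
  out <- clean_illumina_reads(good_read(seq),
                              clean_params(adapter_seqs = ADAPTER))
  expect_equal(nchar(out$reads$seq), 40L)
})

test_that("cleaning is idempotent and never leaves an adapter or short read", {
  set.seed(208)
  params <- clean_params(adapter_seqs = ADAPTER, barcode_len = 5)
  reads <- seq_tbl(
    sprintf("r%02d", 1:40),
    vapply(1:40, function(i) {
      body <- rand_dna_str(71)
      if (i %% 4 == 0) body <- paste0(substr(body, 1, 40), ADAPTER)
      paste0(rand_dna_str(5), substr(body, 1, 71))
    }, ""),
    qual = lapply(1:40, function(i) rep(38L, 76))
  )
  first <- clean_illumina_reads(reads, params)
  expect_true(all(nchar(first$reads$seq) >= params$min_len))
  expect_false(any(grepl(ADAPTER, first$reads$seq, fixed = TRUE)))
  again <- clean_illumina_reads(first$reads,
                                clean_params(adapter_seqs = ADAPTER,
                                             barcode_len = 0))
  expect_equal(again$reads$seq, first$reads$seq)
})

test_that("contig edges lose trans-spliced leader hallmarks", {
  set.seed(209)
  body <- rand_dna_str(60, gc = 1)
  # TAAG at offset 3 (0-based): prefix of 7 removed
  c1 <- seq_tbl("c1", paste0("ACG", "TAAG", body))
  out1 <- clean_contig_edges(c1)
  expect_equal(out1$seq[[1]], body)
  # CTTA inside the last 15 bp: suffix removed from its first base
  c2 <- seq_tbl("c2", paste0(body, "GGG", "CTTA", "AC"))
  out2 <- clean_contig_edges(c2)
  expect_equal(out2$seq[[1]], paste0(body, "GGG"))
  # neither motif near an edge: unchanged
  c3 <- seq_tbl("c3", body)
  expect_equal(clean_contig_edges(c3)$seq, c3$seq)
  # multiple TAAG in the first window: trim through the last one
  c4 <- seq_tbl("c4", paste0("TAAGC", "TAAG", body))
  expect_equal(clean_contig_edges(c4)$seq[[1]], body)
})

test_that("454 cleaning trims edge-anchored motifs only", {
  set.seed(210)
  leader <- "GGCCTTAAGG"
  body <- rand_dna_str(120, gc = 1)
  r1 <- seq_tbl("a", paste0(leader, body))
  out1 <- clean_454_reads(r1, leaders = leader)
  expect_equal(out1$reads$seq[[1]], body)
  # internal occurrence (offset 30) is untouched
  r2 <- seq_tbl("b", paste0(substr(body, 1, 30), leader,
                            substr(body, 31, 120)))
  out2 <- clean_454_reads(r2, leaders = leader)
  expect_equal(nchar(out2$reads$seq), 130L)
  # shrinking below the minimum length discards
  r3 <- seq_tbl("c", paste0(leader, rand_dna_str(20, gc = 1)))
  out3 <- clean_454_reads(r3, leaders = leader)
  expect_equal(nrow(out3$reads), 0)
})

test_that("retention percentage reproduces constructed and printed counts", {
  set.seed(211)
  # constructed: exactly 17 of 100 reads violate a filter
  seqs <- c(
    vapply(1:83, function(i) paste0(rand_dna_str(5), rand_dna_str(71)), ""),
    vapply(1:17, function(i) rand_dna_str(20), "")   # too short
  )
  reads <- seq_tbl(sprintf("r%03d", 1:100), seqs,
                   qual = lapply(nchar(seqs), function(k) rep(38L, k)))
  out <- clean_illumina_reads(reads)
  expect_equal(glance(out$report)$retention_pct, 83L)
  # report-only arithmetic on the published scale
  expect_equal(retention_pct(64433175, 53599364), 83L)
})
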