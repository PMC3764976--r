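test_that("the generator is fully deterministic under its seed", {
  cfg <- sim_config(seed = 1001, n_genes = 20, pseudogene_rate = 0.1,
                    contaminant_counts = c(artemia = 3),
                    illumina = list(n_reads = 60),
                    fourfivefour = list(n_reads = 20))
  w1 <- sim_transcriptome(cfg)
  w2 <- sim_transcriptome(cfg)
  expect_identical(w1, w2)
  r1 <- sim_reads(w1$transcripts, cfg)
  r2 <- sim_reads(w2$transcripts, cfg)
  expect_identical(r1, r2)
  # read-model parameters do not perturb the genome (independent streams)
  cfg2 <- sim_config(seed = 1001, n_genes = 20, pseudogene_rate = 0.1,
                     contaminant_counts = c(artemia = 3),
                     illumina = list(n_reads = 999),
                     fourfivefour = list(n_reads = 20))
  expect_identical(sim_transcriptome(cfg2)$genome, w1$genome)
})

test_that("truth rows exist for every emitted sequence and honour the rates", {
  cfg <- sim_config(seed = 1002, n_genes = 30, pseudogene_rate = 0,
                    contaminant_counts = c())
  w <- sim_transcriptome(cfg)
  expect_setequal(w$truth$id, w$transcripts$id)
  expect_false(any(w$truth$is_pseudogene))
  # rnaseq-only genes are absent from the predicted set and vice versa
  rnaseq_only <- w$truth$id[!is.na(w$truth$status) &
                              w$truth$status == "rnaseq_only"]
  expect_false(any(rnaseq_only %in% w$predicted$id))
  pred_only <- w$genes$id[w$genes$status == "predicted_only"]
  expect_true(all(pred_only %in% w$predicted$id))
  expect_false(any(pred_only %in% w$transcripts$id))
})

test_that("realized genome GC tracks the configured low-GC target", {
  cfg <- sim_config(seed = 1003, n_genes = 60)
  w <- sim_transcriptome(cfg)
  bases <- strsplit(paste(w$genome$seq, collapse = ""), "")[[1]]
  gc <- mean(bases %in% c("G", "C"))
  expect_gt(length(bases), 2e5)
  expect_lt(abs(gc - 0.30), 0.01)
})

test_that("error-free reads are exact substrings after barcode/leader removal", {
  cfg <- sim_config(seed = 1004, n_genes = 15,
                    illumina = list(n_reads = 40, substitution_rate = 0,
                                    adapter_readthrough_rate = 0),
                    fourfivefour = list(n_reads = 20,
                                        homopolymer_indel_rate = 0,
                                        leader_rate = 1))
  w <- sim_transcriptome(cfg)
  rd <- sim_reads(w$transcripts, cfg)
  tx <- stats::setNames(w$transcripts$seq, w$transcripts$id)
  il_truth <- rd$truth[rd$truth$platform == "illumina", ]
  for (i in seq_len(nrow(rd$illumina))) {
    insert <- substr(rd$illumina$seq[[i]], 6, 76)
    expect_true(grepl(insert, tx[[il_truth$origin[[i]]]], fixed = TRUE))
  }
  leader <- cfg$fourfivefour$leader_seq
  ff_truth <- rd$truth[rd$truth$platform == "454", ]
  for (i in seq_len(nrow(rd$fourfivefour))) {
    r <- rd$fourfivefour$seq[[i]]
    expect_true(startsWith(r, leader))
    body <- substr(r, nchar(leader) + 1, nchar(r))
    expect_true(grepl(body, tx[[ff_truth$origin[[i]]]], fixed = TRUE))
  }
})

test_that("substitution counts follow the configured binomial rate", {
  cfg <- sim_config(seed = 1005, n_genes = 15,
                    illumina = list(n_reads = 1500,
                                    substitution_rate = 0.01,
                                    adapter_readthrough_rate = 0))
  w <- sim_transcriptome(cfg)
  rd <- sim_reads(w$transcripts, cfg)
  il <- rd$truth[rd$truth$platform == "illumina", ]
  n_bases <- 1500 * 76
  expected <- n_bases * 0.01
  sdev <- sqrt(n_bases * 0.01 * 0.99)
  expect_lt(abs(sum(il$n_subs) - expected), 3 * sdev)
})

test_that("every induced 454 indel lies inside a homopolymer run of >= 3", {
  cfg <- sim_config(seed = 1006, n_genes = 15,
                    fourfivefour = list(n_reads = 200,
                                        homopolymer_indel_rate = 0.3))
  w <- sim_transcriptome(cfg)
  rd <- sim_reads(w$transcripts, cfg)
  expect_gt(nrow(rd$indel_log), 0)
  expect_true(all(rd$indel_log$run_len >= 3))
})

test_that("redundancy expansion respects factor and the identity floor", {
  set.seed(1007)
  tx <- seq_tbl(sprintf("t%02d", 1:10),
                vapply(rep(400, 10), rand_dna_str, ""))
  ex1 <- expand_redundancy(tx, 1, seed = 5)
  expect_identical(ex1$expanded$seq, tx$seq)
  ex3 <- expand_redundancy(tx, 3, seed = 5)
  expect_equal(nrow(ex3$expanded), 30)
  # pairwise identity of copies of a gene stays at or above the floor
  for (g in tx$id) {
    copies <- ex3$expanded$seq[ex3$truth$origin == g]
    for (i in 1:2) {
      for (j in (i + 1):3) {
        same <- mapply(identical, strsplit(copies[[i]], "")[[1]],
                       strsplit(copies[[j]], "")[[1]])
        expect_gte(mean(same), 0.98)
      }
    }
  }
  ri <- redundancy_index(ex3$expanded)
  expect_equal(ri$ri, 3, tolerance = 0.05 / 3)
})
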