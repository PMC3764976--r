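test_that("only-set detection separates shared from private sequences", {
  set.seed(801)
  shared <- vapply(rep(500, 8), rand_dna_str, "")
  private_q <- vapply(rep(500, 3), rand_dna_str, "")
  private_s <- vapply(rep(500, 4), rand_dna_str, "")
  queries <- seq_tbl(c(sprintf("sh%d", 1:8), sprintf("pq%d", 1:3)),
                     c(shared, private_q))
  subjects <- seq_tbl(c(sprintf("sh%d", 1:8), sprintf("ps%d", 1:4)),
                      c(shared, private_s))
  os <- find_only_set(queries, subjects)
  expect_equal(sort(os$query_id[os$status == "only"]), sprintf("pq%d", 1:3))
  os_rev <- find_only_set(subjects, queries)
  expect_equal(sort(os_rev$query_id[os_rev$status == "only"]),
               sprintf("ps%d", 1:4))
  # 90%-identical counterpart is still "only" under the 95% threshold
  q90 <- mutate_dna(shared[[1]], 50)
  os90 <- find_only_set(seq_tbl("q90", q90), subjects)
  expect_equal(os90$status, "only")
  expect_lt(os90$best_identity_pct, 95)
  # a dataset against itself has no only-sequences
  os_self <- find_only_set(queries, queries)
  expect_true(all(os_self$status == "shared"))
})

test_that("evidence annotation tags only-sequences per dataset", {
  set.seed(802)
  only_seqs <- vapply(rep(400, 30), rand_dna_str, "")
  queries <- seq_tbl(sprintf("o%02d", 1:30), only_seqs)
  subjects <- seq_tbl("z", rand_dna_str(400))
  os <- find_only_set(queries, subjects)
  # 10 sequences seeded into evidence set A, 5 of them also into B
  evidence <- list(
    A = seq_tbl(sprintf("a%02d", 1:10), only_seqs[1:10]),
    B = seq_tbl(sprintf("b%02d", 1:5), only_seqs[6:10])
  )
  ann <- evidence_annotate(os, queries, evidence)
  tags <- ann$evidence_tags
  expect_equal(sum(vapply(tags, function(x) "A" %in% x, TRUE)), 10)
  expect_equal(sum(vapply(tags, function(x) all(c("A", "B") %in% x), TRUE)), 5)
  expect_equal(sum(ann$novel), 20)
})

test_that("contaminant screening assigns each query once, in database order", {
  set.seed(803)
  db1_seq <- rand_dna_str(600)
  db2_seq <- rand_dna_str(600)
  dbs <- list(db1 = seq_tbl("d1", db1_seq), db2 = seq_tbl("d2", db2_seq))
  queries <- seq_tbl(
    c("in_both", "in_db2", "lowc", "clean"),
    c(db1_seq, db2_seq, strrep("AT", 150), rand_dna_str(500))
  )
  # a query matching both databases is assigned to the first only
  dbs_both <- list(db1 = seq_tbl("d1", db1_seq),
                   db2 = seq_tbl("d2", paste0(db1_seq, db2_seq)))
  res <- contaminant_screen(queries, dbs_both)
  lab <- stats::setNames(res$label, res$query_id)
  expect_equal(unname(lab["in_both"]), "db1")
  expect_equal(unname(lab["in_db2"]), "db2")
  expect_equal(unname(lab["lowc"]), "low_complexity")
  expect_equal(unname(lab["clean"]), "clean")
  # the assignment is a partition
  expect_equal(nrow(res), nrow(queries))
  expect_false(any(is.na(res$label)))
})

test_that("spiked contaminants of three kinds are recovered with their labels", {
  cfg <- sim_config(seed = 81, n_genes = 30, pseudogene_rate = 0,
                    splice_variant_rate = 0,
                    contaminant_counts = c(artemia = 8, curvibacter = 6,
                                           low_complexity = 5))
  world <- sim_transcriptome(cfg)
  res <- contaminant_screen(world$transcripts, world$contaminant_dbs)
  truth <- world$truth[match(res$query_id, world$truth$id), ]
  expected <- ifelse(is.na(truth$contaminant), "clean", truth$contaminant)
  expect_equal(res$label, expected)
})

test_that("genome support thresholds at 75% identity", {
  set.seed(804)
  genome <- seq_tbl("chr", rand_dna_str(20000))
  excised <- substr(genome$seq[[1]], 5001, 5800)
  mutated <- mutate_dna(excised, 240)      # 70% identity to the source
  absent <- rand_dna_str(800)
  gs <- genome_support(seq_tbl(c("ex", "mut", "ab"),
                               c(excised, mutated, absent)), genome)
  expect_equal(gs$supported, c(TRUE, FALSE, FALSE))
  expect_equal(gs$best_identity_pct[[1]], 100)
  expect_true(is.na(gs$best_identity_pct[[3]]) ||
                gs$best_identity_pct[[3]] < 75)
})

test_that("pseudogene classification enforces all four criteria", {
  cfg <- sim_config(seed = 82, n_genes = 40, pseudogene_rate = 0.5,
                    splice_variant_rate = 0, contaminant_counts = c())
  world <- sim_transcriptome(cfg)
  orfs <- longest_orfs(world$transcripts)
  calls <- pseudogene_classify(world$transcripts, orfs, world$genome,
                               world$predicted)
  truth <- world$truth[match(calls$transcript_id, world$truth$id), ]
  tp <- sum(calls$is_pseudogene_candidate & truth$is_pseudogene)
  fp <- sum(calls$is_pseudogene_candidate & !truth$is_pseudogene)
  fn <- sum(!calls$is_pseudogene_candidate & truth$is_pseudogene)
  expect_gte(tp / (tp + fp), 0.9)
  expect_gte(tp / (tp + fn), 0.9)
  # unit rules: a long ORF or high predicted-identity excludes a transcript
  long_orf <- calls[calls$orf_aa_len >= 100, ]
  expect_false(any(long_orf$is_pseudogene_candidate))
  near_predicted <- calls[!is.na(calls$max_identity_to_predicted_pct) &
                            calls$max_identity_to_predicted_pct >= 95, ]
  expect_false(any(near_predicted$is_pseudogene_candidate))
})
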