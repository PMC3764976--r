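test_that("global identity matches a Needleman-Wunsch oracle", {
  expect_equal(global_identity("MKLVAGH", "MKLVAGH"), 100)
  set.seed(601)
  p1 <- rand_prot_str(100)
  v <- strsplit(p1, "")[[1]]
  pos <- sample(100, 4)
  for (p in pos) v[[p]] <- sample(setdiff(AA20, v[[p]]), 1)
  p2 <- paste(v, collapse = "")
  expect_equal(global_identity(p1, p2), 96)
  # unrelated proteins score far below the clustering threshold
  expect_lt(global_identity(rand_prot_str(120), rand_prot_str(120)), 50)
  expect_error(global_identity("", "MK"), "empty")
})

test_that("greedy clustering groups near-identical proteins under the centroid", {
  set.seed(602)
  a <- rand_prot_str(120)
  prots <- seq_tbl(c("a1", "a2", "a3", "u"),
                   c(a, a, a, rand_prot_str(110)))
  cl <- cluster_proteins(prots)
  expect_equal(length(unique(cl$cluster)), 2)
  # a truncated fragment at 100% local identity is globally dissimilar:
  # it founds its own cluster (criteria i-vi catch it later)
  frag <- substr(a, 1, 80)
  cl2 <- cluster_proteins(seq_tbl(c("full", "frag"), c(a, frag)))
  expect_equal(length(unique(cl2$cluster)), 2)
  expect_true(all(cl2$is_representative))
})

test_that("clustering of well-separated clusters is order-independent", {
  set.seed(603)
  centers <- vapply(1:5, function(i) rand_prot_str(sample(90:150, 1)), "")
  seqs <- unlist(lapply(centers, function(ce) {
    c(ce, vapply(1:2, function(k) mutate_prot(ce, 0.02), ""))
  }))
  ids <- sprintf("p%02d", seq_along(seqs))
  prots <- seq_tbl(ids, seqs)
  cl <- cluster_proteins(prots)
  perm <- sample(nrow(prots))
  cl_shuf <- cluster_proteins(prots[perm, ])
  # same partition under relabelling
  part <- function(cl) {
    unname(split(cl$id, cl$cluster)) |>
      lapply(sort) |>
      (\(x) x[order(vapply(x, `[[`, "", 1))])()
  }
  expect_equal(part(cl), part(cl_shuf))
})

test_that("the six discard criteria behave as specified on unit fixtures", {
  set.seed(604)
  big <- rand_prot_str(200)
  sub <- substr(big, 26, 175)                    # 150-aa exact substring
  r <- redundancy_filter(seq_tbl(c("big", "sub"), c(big, sub)))
  expect_equal(r$kept$id, "big")
  dec <- r$decisions[r$decisions$query_id == "big" &
                       r$decisions$match_id == "sub", ]
  expect_equal(dec$failed_criterion, "discarded")

  # criterion i: alignments under 25 aa are ignored, both kept
  set.seed(605)
  core <- rand_prot_str(24)
  p1 <- paste0(rand_prot_str(60), core)
  p2 <- paste0(core, rand_prot_str(40))
  r2 <- redundancy_filter(seq_tbl(c("p1", "p2"), c(p1, p2)))
  expect_setequal(r2$kept$id, c("p1", "p2"))

  # criterion iv: a gap column in the best alignment keeps both (splice
  # variants survive); the skip is small so block identity stays above 95%
  set.seed(606)
  full <- rand_prot_str(200)
  skipped <- paste0(substr(full, 1, 90), substr(full, 95, 200)) # 4-aa skip
  r3 <- redundancy_filter(seq_tbl(c("full", "var"), c(full, skipped)))
  expect_setequal(r3$kept$id, c("full", "var"))
  dec3 <- r3$decisions[r3$decisions$query_id == "full" &
                         r3$decisions$match_id == "var", ]
  expect_equal(dec3$failed_criterion, "has_gaps")

  # criterion v: alignment spanning less than 95% of the match keeps it
  set.seed(607)
  shared <- rand_prot_str(280)
  query <- paste0(shared, rand_prot_str(40))
  match_seq <- paste0(shared, rand_prot_str(20))    # span 280/300 = 93.3%
  r4 <- redundancy_filter(seq_tbl(c("q", "m"), c(query, match_seq)))
  expect_setequal(r4$kept$id, c("q", "m"))
  dec4 <- r4$decisions[r4$decisions$query_id == "q" &
                         r4$decisions$match_id == "m", ]
  expect_true(dec4$failed_criterion %in% c("span_low", "unmatched_high"))

  # criterion vi: more than 100 unmatched match residues keep it even when
  # the alignment spans 95% of the match (possible only above 2000 aa)
  set.seed(608)
  shared6 <- rand_prot_str(2045)
  # tails that can never extend the alignment (every W-G column scores < 0)
  q6 <- paste0(shared6, strrep("W", 300))
  m6 <- paste0(shared6, strrep("G", 105))     # span 2045/2150 = 95.1%
  r6 <- redundancy_filter(seq_tbl(c("q", "m"), c(q6, m6)))
  expect_true("m" %in% r6$kept$id)
  dec6 <- r6$decisions[r6$decisions$query_id == "q" &
                         r6$decisions$match_id == "m", ]
  expect_equal(dec6$failed_criterion, "unmatched_high")

  # criterion ii: equal lengths keep both
  set.seed(609)
  twin <- rand_prot_str(150)
  r5 <- redundancy_filter(seq_tbl(c("t1", "t2"), c(twin, twin)))
  expect_setequal(r5$kept$id, c("t1", "t2"))
})

test_that("deduplication keeps the longest uncorrupted variant per gene", {
  set.seed(610)
  cfg <- sim_config(seed = 71, n_genes = 12,
                    paralog_family_sizes = c(`1` = 1),
                    cds_codons_range = c(150, 400),
                    pseudogene_rate = 0, splice_variant_rate = 0,
                    frac_unpredicted = 0, frac_predicted_only = 0)
  world <- sim_transcriptome(cfg)
  cv <- sim_corrupt_variants(world$transcripts, seed = 72)
  dd <- deduplicate(cv$corrupted)
  kept_truth <- cv$truth[match(dd$kept$id, cv$truth$id), ]
  expect_equal(nrow(dd$kept), 12)
  expect_true(all(kept_truth$variant == "full"))
  # every removal is reported with a reason
  expect_setequal(c(dd$kept$id, tidy(dd)$id), cv$corrupted$id)
})

test_that("deduplication is idempotent and drops sub-50-aa ORFs with a reason", {
  set.seed(611)
  uniq <- seq_tbl(sprintf("u%02d", 1:6),
                  vapply(1:6, function(i) make_transcript(sample(120:250, 1)),
                         ""))
  once <- deduplicate(uniq)
  expect_equal(sort(once$kept$id), sort(uniq$id))
  twice <- deduplicate(once$kept)
  expect_equal(sort(twice$kept$id), sort(once$kept$id))

  # a sub-50-aa ORF in every frame by construction
  short_tx <- paste0("ATG", strrep("TTA", 47), "TAA")
  dd <- deduplicate(dplyr::bind_rows(uniq, seq_tbl("short49", short_tx)))
  expect_false("short49" %in% dd$kept$id)
  expect_equal(tidy(dd)$reason[tidy(dd)$id == "short49"], "min_aa")
})
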