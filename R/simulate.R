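#' Simulation configuration
#'
#' Parameters of the seeded ground-truth generator.  Defaults are sized
#' for desk scale (200 genes, a ~1-Mb genome, 50k Illumina reads, 5k
#' 454-style reads) and emulate the hallmarks of a low-GC invertebrate
#' RNAseq project: paralog families, in-frame splice variants,
#' pseudogenized gene copies embedded verbatim in the genome, 76-nt
#' barcoded Illumina reads with substitution errors and 3' adapter
#' read-through, 454-style reads with homopolymer indels and trans-spliced
#' leaders, and contaminant sequences.
#'
#' @param seed Integer seed; together with the per-artifact stream offsets
#'   it fully determines every output.
#' @param n_genes Total number of genes (families partition them).
#' @param paralog_family_sizes Named numeric vector of family-size
#'   probabilities (names are sizes).
#' @param paralog_divergence Fraction of codons resampled in a paralog.
#' @param splice_variant_rate Fraction of genes that also emit an in-frame
#'   exon-skipped variant.
#' @param redundancy_factor Copies per transcript for
#'   [expand_redundancy()] when driven from the config.
#' @param gc_content Genome GC fraction (default 0.30, a Hydra-like low
#'   GC).
#' @param pseudogene_rate Pseudogenized copies per gene (expected).
#' @param stop_inductions_per_pseudogene Internal stops placed in each
#'   pseudogene's reading frame (more are added if any frame still holds a
#'   long ORF).
#' @param pseudogene_divergence Substitution rate applied to a pseudogene
#'   before stop induction (keeps it clearly below the predicted-identity
#'   gate).
#' @param contaminant_counts Named integer vector, e.g.
#'   `c(artemia = 20, curvibacter = 10, low_complexity = 15)`.
#' @param frac_unpredicted Fraction of genes withheld from the predicted
#'   set (RNAseq-only truth).
#' @param frac_predicted_only Fraction of genes withheld from the RNAseq
#'   transcript set (predicted-only truth).
#' @param cds_codons_range,utr5_range,utr3_range Length ranges of gene
#'   parts (codons / nt).
#' @param introns_range,intron_len_range Intron count and length ranges
#'   (GT...AG ends).
#' @param genes_per_contig,intergenic_range Genomic layout.
#' @param illumina,fourfivefour Read-model parameter lists; see Details.
#' @details The Illumina model is
#'   `list(read_len, barcode_len, substitution_rate, adapter_seq,
#'   adapter_readthrough_rate, n_reads)`; the 454 model is
#'   `list(mean_len, sd_len, homopolymer_indel_rate, leader_seq,
#'   leader_rate, n_reads)` (the leader ends in the TAAG hallmark).
#' @return A list of class `hx_sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 200,
                       paralog_family_sizes = c(`1` = 0.8, `2` = 0.15,
                                                `3` = 0.05),
                       paralog_divergence = 0.12,
                       splice_variant_rate = 0.10,
                       redundancy_factor = 1,
                       gc_content = 0.30,
                       pseudogene_rate = 0.05,
                       stop_inductions_per_pseudogene = 3,
                       pseudogene_divergence = 0.08,
                       contaminant_counts = c(),
                       frac_unpredicted = 0.10,
                       frac_predicted_only = 0.10,
                       cds_codons_range = c(112, 500),
                       utr5_range = c(20, 100),
                       utr3_range = c(50, 200),
                       introns_range = c(0, 5),
                       intron_len_range = c(60, 500),
                       genes_per_contig = 20,
                       intergenic_range = c(1000, 3000),
                       illumina = list(),
                       fourfivefour = list()) {
  il <- utils::modifyList(list(
    read_len = 76L, barcode_len = 5L, substitution_rate = 0.005,
    adapter_seq = "AGATCGGAAGAGCGGTTCAGCAGGAATGCCGAG",
    adapter_readthrough_rate = 0.05, n_reads = 50000L
  ), illumina)
  fff <- utils::modifyList(list(
    mean_len = 295, sd_len = 75, homopolymer_indel_rate = 0.15,
    leader_seq = "ACTCACTATTTGCCTAAG", leader_rate = 0.3, n_reads = 5000L
  ), fourfivefour)
  rates <- c(splice_variant_rate, gc_content, pseudogene_rate,
             pseudogene_divergence, frac_unpredicted, frac_predicted_only,
             il$substitution_rate, il$adapter_readthrough_rate,
             fff$homopolymer_indel_rate, fff$leader_rate)
  if (any(rates < 0 | rates > 1)) rlang::abort("rates must lie in [0, 1]")
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    paralog_family_sizes = paralog_family_sizes,
    paralog_divergence = paralog_divergence,
    splice_variant_rate = splice_variant_rate,
    redundancy_factor = as.integer(redundancy_factor),
    gc_content = gc_content,
    pseudogene_rate = pseudogene_rate,
    stop_inductions_per_pseudogene = as.integer(stop_inductions_per_pseudogene),
    pseudogene_divergence = pseudogene_divergence,
    contaminant_counts = contaminant_counts,
    frac_unpredicted = frac_unpredicted,
    frac_predicted_only = frac_predicted_only,
    cds_codons_range = cds_codons_range,
    utr5_range = utr5_range, utr3_range = utr3_range,
    introns_range = introns_range, intron_len_range = intron_len_range,
    genes_per_contig = as.integer(genes_per_contig),
    intergenic_range = intergenic_range,
    illumina = il, fourfivefour = fff
  ), class = "hx_sim_config")
}

# independent RNG streams per artifact
stream_seed <- function(config, offset) {
  as.integer((config$seed %% 20000000L) * 97L + offset)
}

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, gc) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

sense_codons <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      all <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
      cache <<- setdiff(all, c("TAA", "TAG", "TGA"))
    }
    cache
  }
})

codon_weights <- function(gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  cods <- sense_codons()
  w <- vapply(strsplit(cods, ""), function(b) prod(p[b]), numeric(1))
  w / sum(w)
}

make_cds <- function(n_codons, gc) {
  cods <- sample(sense_codons(), n_codons - 2L, replace = TRUE,
                 prob = codon_weights(gc))
  paste0("ATG", paste(cods, collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

substitute_bases <- function(seq, n_sub) {
  if (n_sub <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), min(n_sub, length(chars)))
  for (p in pos) {
    chars[[p]] <- sample(setdiff(BASES, chars[[p]]), 1)
  }
  paste(chars, collapse = "")
}

# resample a fraction of internal codons; never introduces a stop
diverge_cds <- function(cds, rate, gc) {
  n_cod <- nchar(cds) %/% 3
  internal <- 2:(n_cod - 1)
  k <- round(rate * length(internal))
  if (k == 0) return(cds)
  pick <- sample(internal, k)
  chars <- strsplit(cds, "")[[1]]
  for (ci in pick) {
    new <- sample(sense_codons(), 1, prob = codon_weights(gc))
    chars[(3 * (ci - 1) + 1):(3 * ci)] <- strsplit(new, "")[[1]]
  }
  paste(chars, collapse = "")
}

insert_introns <- function(seq, config) {
  n_int <- sample(config$introns_range[1]:config$introns_range[2], 1)
  if (n_int == 0) return(seq)
  pos <- sort(sample(nchar(seq) - 1L, n_int))
  parts <- character(0)
  prev <- 0L
  for (p in pos) {
    ilen <- sample(config$intron_len_range[1]:config$intron_len_range[2], 1)
    intron <- paste0("GT", random_dna(ilen - 4L, config$gc_content), "AG")
    parts <- c(parts, substr(seq, prev + 1L, p), intron)
    prev <- p
  }
  paste0(paste(parts, collapse = ""), substr(seq, prev + 1L, nchar(seq)))
}

# place a stop codon at the codon in the middle of an ORF, respecting its
# strand; iterate until no frame holds an ORF of >= max_aa residues
induce_stops <- function(seq, n_stops, cds_start, cds_len, max_aa = 100) {
  # evenly spaced stops in the construction frame first
  n_cod <- cds_len %/% 3
  if (n_stops > 0 && n_cod > 4) {
    targets <- unique(pmin(pmax(round(seq_len(n_stops) *
                                        n_cod / (n_stops + 1)), 2L),
                           n_cod - 1L))
    chars <- strsplit(seq, "")[[1]]
    for (ci in targets) {
      at <- cds_start + 3L * (ci - 1L)
      chars[(at + 1L):(at + 3L)] <- c("T", "A", "A")
    }
    seq <- paste(chars, collapse = "")
  }
  for (iter in 1:50) {
    o <- longest_orf_one(seq)
    if (o$aa_len < max_aa) break
    mid <- o$aa_len %/% 2L
    if (o$strand == "+") {
      at <- o$nt_start + 3L * mid
      stop_cod <- c("T", "A", "A")
    } else {
      at <- o$nt_end - 3L * (mid + 1L)
      stop_cod <- c("T", "T", "A") # revcomp of TAA
    }
    chars <- strsplit(seq, "")[[1]]
    chars[(at + 1L):(at + 3L)] <- stop_cod
    seq <- paste(chars, collapse = "")
  }
  seq
}

low_complexity_seq <- function(len) {
  motif <- sample(c("AT", "TA", "AAT", "CA"), 1)
  substr(strrep(motif, ceiling(len / nchar(motif))), 1, len)
}

#' Generate a genome, transcript sets and ground truth
#'
#' Builds a gene set with paralog families and in-frame splice variants,
#' places the genes (with GT...AG introns) on genomic contigs separated by
#' intergenic spacers, withholds configurable gene subsets to create
#' RNAseq-only and predicted-only truth, embeds diverged, stop-riddled
#' pseudogene copies verbatim (intron-free) in the genome, and spikes
#' contaminants into the RNAseq transcript set.  Fully deterministic under
#' `config$seed`; the read models draw from independent streams, so read
#' parameters never perturb the genome.
#'
#' @param config A [sim_config()].
#' @return A list: `genome`, `transcripts` (the RNAseq set), `predicted`,
#'   `contaminant_dbs` (named list), and `truth` (one row per emitted
#'   sequence: `id`, `origin_gene`, `family`, `copy_index`,
#'   `variant_type`, `is_pseudogene`, `contaminant`, `status`).
#' @export
sim_transcriptome <- function(config = sim_config()) {
  with_seed_local(stream_seed(config, 1L), {
    gc <- config$gc_content
    sizes <- as.integer(names(config$paralog_family_sizes))
    fam_sizes <- integer(0)
    while (sum(fam_sizes) < config$n_genes) {
      fam_sizes <- c(fam_sizes, sample(sizes, 1,
                                       prob = config$paralog_family_sizes))
    }
    over <- sum(fam_sizes) - config$n_genes
    if (over > 0) {
      fam_sizes[length(fam_sizes)] <- fam_sizes[length(fam_sizes)] - over
    }
    fam_sizes <- fam_sizes[fam_sizes > 0]

    genes <- list()
    g <- 0L
    for (fam in seq_along(fam_sizes)) {
      n_cod <- sample(config$cds_codons_range[1]:config$cds_codons_range[2], 1)
      base_cds <- make_cds(n_cod, gc)
      for (copy in seq_len(fam_sizes[[fam]])) {
        g <- g + 1L
        cds <- if (copy == 1) {
          base_cds
        } else {
          diverge_cds(base_cds, config$paralog_divergence, gc)
        }
        utr5 <- random_dna(sample(config$utr5_range[1]:config$utr5_range[2], 1),
                           gc)
        utr3 <- random_dna(sample(config$utr3_range[1]:config$utr3_range[2], 1),
                           gc)
        genes[[g]] <- list(
          gene_id = sprintf("g%04d", g), family = fam, copy = copy,
          cds = cds, utr5 = utr5, utr3 = utr3,
          transcript = paste0(utr5, cds, utr3),
          cds_start = nchar(utr5), cds_len = nchar(cds)
        )
      }
    }
    n <- length(genes)

    status <- rep("shared", n)
    n_unpred <- round(config$frac_unpredicted * n)
    n_predonly <- round(config$frac_predicted_only * n)
    pick <- sample(n, n_unpred + n_predonly)
    status[pick[seq_len(n_unpred)]] <- "rnaseq_only"
    if (n_predonly > 0) {
      status[pick[n_unpred + seq_len(n_predonly)]] <- "predicted_only"
    }

    # pseudogenes: diverged, stop-riddled intron-free copies
    n_pseudo <- round(config$pseudogene_rate * n)
    pseudo <- list()
    if (n_pseudo > 0) {
      parents <- sample(n, n_pseudo, replace = n_pseudo > n)
      for (k in seq_len(n_pseudo)) {
        gn <- genes[[parents[[k]]]]
        seq <- substitute_bases(
          gn$transcript,
          round(config$pseudogene_divergence * nchar(gn$transcript))
        )
        seq <- induce_stops(seq, config$stop_inductions_per_pseudogene,
                            gn$cds_start, gn$cds_len)
        pseudo[[k]] <- list(
          id = sprintf("psi%03d", k), seq = seq, parent = gn$gene_id
        )
      }
    }

    # splice variants: in-frame internal CDS block deletion
    variants <- list()
    v <- 0L
    for (i in seq_len(n)) {
      if (status[[i]] == "predicted_only") next
      if (stats::runif(1) >= config$splice_variant_rate) next
      gn <- genes[[i]]
      n_cod <- gn$cds_len %/% 3
      if (n_cod < 40) next
      del_cod <- sample(10:30, 1)
      from_cod <- sample(2:(n_cod - del_cod - 1), 1)
      at <- gn$cds_start + 3L * (from_cod - 1L)
      seq <- paste0(substr(gn$transcript, 1, at),
                    substr(gn$transcript, at + 3L * del_cod + 1L,
                           nchar(gn$transcript)))
      v <- v + 1L
      variants[[v]] <- list(id = paste0(gn$gene_id, "_sv"), seq = seq,
                            gene = gn$gene_id, family = gn$family)
    }

    # genome: genes with introns + verbatim pseudogenes, on contigs
    genomic <- vapply(genes, function(gn) insert_introns(gn$transcript,
                                                         config),
                      character(1))
    elements <- c(genomic, vapply(pseudo, `[[`, character(1), "seq"))
    n_contig <- max(1L, ceiling(length(elements) / config$genes_per_contig))
    assignment <- rep(seq_len(n_contig), length.out = length(elements))
    contigs <- vapply(seq_len(n_contig), function(ci) {
      parts <- elements[assignment == ci]
      spacers <- vapply(seq_len(length(parts) + 1), function(j) {
        random_dna(sample(config$intergenic_range[1]:
                            config$intergenic_range[2], 1), gc)
      }, character(1))
      paste0(paste0(spacers[seq_along(parts)], parts, collapse = ""),
             spacers[[length(spacers)]])
    }, character(1))
    genome <- seq_tbl(sprintf("contig%03d", seq_len(n_contig)), contigs)

    # contaminants
    contaminant_dbs <- list()
    spikes <- list()
    cc <- config$contaminant_counts
    for (nm in names(cc)) {
      k <- cc[[nm]]
      if (nm == "low_complexity") {
        for (j in seq_len(k)) {
          spikes[[length(spikes) + 1]] <- list(
            id = sprintf("lc%03d", j),
            seq = low_complexity_seq(sample(150:400, 1)), label = nm
          )
        }
      } else {
        src <- vapply(seq_len(k), function(j) {
          random_dna(sample(300:900, 1), 0.45)
        }, character(1))
        ids <- sprintf("%s_src%03d", nm, seq_len(k))
        contaminant_dbs[[nm]] <- seq_tbl(ids, src)
        for (j in seq_len(k)) {
          spikes[[length(spikes) + 1]] <- list(
            id = sprintf("%s_tx%03d", nm, j), seq = src[[j]], label = nm
          )
        }
      }
    }

    gene_tbl <- tibble::tibble(
      id = vapply(genes, `[[`, character(1), "gene_id"),
      seq = vapply(genes, `[[`, character(1), "transcript"),
      family = vapply(genes, `[[`, numeric(1), "family"),
      copy = vapply(genes, `[[`, numeric(1), "copy"),
      status = status
    )

    tx_rows <- dplyr::bind_rows(
      gene_tbl |>
        dplyr::filter(.data$status != "predicted_only") |>
        dplyr::transmute(
          id = .data$id, seq = .data$seq, origin_gene = .data$id,
          family = .data$family, copy_index = .data$copy,
          variant_type = "base", is_pseudogene = FALSE,
          contaminant = NA_character_, status = .data$status
        ),
      if (length(variants) > 0) {
        tibble::tibble(
          id = vapply(variants, `[[`, character(1), "id"),
          seq = vapply(variants, `[[`, character(1), "seq"),
          origin_gene = vapply(variants, `[[`, character(1), "gene"),
          family = vapply(variants, `[[`, numeric(1), "family"),
          copy_index = NA_real_, variant_type = "splice_variant",
          is_pseudogene = FALSE, contaminant = NA_character_,
          status = NA_character_
        )
      },
      if (length(pseudo) > 0) {
        tibble::tibble(
          id = vapply(pseudo, `[[`, character(1), "id"),
          seq = vapply(pseudo, `[[`, character(1), "seq"),
          origin_gene = vapply(pseudo, `[[`, character(1), "parent"),
          family = NA_real_, copy_index = NA_real_,
          variant_type = "pseudogene", is_pseudogene = TRUE,
          contaminant = NA_character_, status = "rnaseq_only"
        )
      },
      if (length(spikes) > 0) {
        tibble::tibble(
          id = vapply(spikes, `[[`, character(1), "id"),
          seq = vapply(spikes, `[[`, character(1), "seq"),
          origin_gene = NA_character_, family = NA_real_,
          copy_index = NA_real_, variant_type = "contaminant",
          is_pseudogene = FALSE,
          contaminant = vapply(spikes, `[[`, character(1), "label"),
          status = NA_character_
        )
      }
    )

    predicted_tbl <- gene_tbl |>
      dplyr::filter(.data$status != "rnaseq_only")

    list(
      genome = genome,
      transcripts = seq_tbl(tx_rows$id, tx_rows$seq),
      predicted = seq_tbl(predicted_tbl$id, predicted_tbl$seq),
      contaminant_dbs = contaminant_dbs,
      truth = dplyr::select(tx_rows, -"seq"),
      genes = gene_tbl
    )
  })
}

#' Generate Illumina- and 454-style reads from transcripts
#'
#' Illumina reads are `read_len` nt: a random `barcode_len`-nt barcode, an
#' insert from a uniformly chosen transcript position, and — when the
#' insert runs past the 3' end (forced at `adapter_readthrough_rate`) —
#' 3'-adapter fill-in; substitution errors are applied at
#' `substitution_rate`.  454-style reads have approximately normal
#' lengths, a trans-spliced leader (ending in TAAG) prepended at
#' `leader_rate`, and +-1-base indels placed only inside homopolymer runs
#' of >= 3 nt, each run mutated with probability
#' `homopolymer_indel_rate`.
#'
#' @param transcripts A [seq_tbl()].
#' @param config A [sim_config()].
#' @return A list: `illumina` ([seq_tbl()] with qualities), `fourfivefour`
#'   ([seq_tbl()] with qualities), `truth` (per read: `id`, `platform`,
#'   `origin`, `n_subs`, `n_indels`, `has_leader`, `has_adapter`), and
#'   `indel_log` (per induced 454 indel: read id, position, run length).
#' @export
sim_reads <- function(transcripts, config = sim_config()) {
  il <- with_seed_local(stream_seed(config, 2L),
                        sim_illumina_reads(transcripts, config))
  ff <- with_seed_local(stream_seed(config, 3L),
                        sim_454_reads(transcripts, config))
  list(
    illumina = il$reads, fourfivefour = ff$reads,
    truth = dplyr::bind_rows(il$truth, ff$truth),
    indel_log = ff$indel_log
  )
}

sim_illumina_reads <- function(transcripts, config) {
  p <- config$illumina
  insert_len <- p$read_len - p$barcode_len
  n <- p$n_reads
  tx_idx <- sample(nrow(transcripts), n, replace = TRUE)
  seqs <- character(n)
  origin <- transcripts$id[tx_idx]
  n_subs <- integer(n)
  has_adapter <- logical(n)
  for (i in seq_len(n)) {
    tseq <- transcripts$seq[[tx_idx[[i]]]]
    tlen <- nchar(tseq)
    readthrough <- stats::runif(1) < p$adapter_readthrough_rate
    start <- if (readthrough && tlen > 25) {
      tlen - sample(20:min(60, tlen - 1), 1)
    } else {
      sample(max(1L, tlen - insert_len + 1L), 1)
    }
    insert <- substr(tseq, start, min(tlen, start + insert_len - 1L))
    fill <- insert_len - nchar(insert)
    if (fill > 0) {
      has_adapter[[i]] <- TRUE
      insert <- paste0(insert, substr(strrep(p$adapter_seq,
                                             ceiling(fill / nchar(p$adapter_seq))),
                                      1, fill))
    }
    read <- paste0(random_dna(p$barcode_len, 0.5), insert)
    k <- stats::rbinom(1, nchar(read), p$substitution_rate)
    n_subs[[i]] <- k
    seqs[[i]] <- substitute_bases(read, k)
  }
  qual <- lapply(seq_len(n), function(i) {
    pmin(pmax(round(stats::rnorm(nchar(seqs[[i]]), 37, 2)), 2L), 40L)
  })
  reads <- seq_tbl(sprintf("il%06d", seq_len(n)), seqs, qual = qual)
  list(reads = reads, truth = tibble::tibble(
    id = reads$id, platform = "illumina", origin = origin,
    n_subs = n_subs, n_indels = 0L, has_leader = FALSE,
    has_adapter = has_adapter
  ))
}

sim_454_reads <- function(transcripts, config) {
  p <- config$fourfivefour
  n <- p$n_reads
  tx_idx <- sample(nrow(transcripts), n, replace = TRUE)
  seqs <- character(n)
  origin <- transcripts$id[tx_idx]
  has_leader <- logical(n)
  n_indels <- integer(n)
  logs <- list()
  for (i in seq_len(n)) {
    tseq <- transcripts$seq[[tx_idx[[i]]]]
    tlen <- nchar(tseq)
    len <- min(tlen, max(60L, round(stats::rnorm(1, p$mean_len, p$sd_len))))
    start <- sample(tlen - len + 1L, 1)
    read <- substr(tseq, start, start + len - 1L)
    ind <- apply_homopolymer_indels(read, p$homopolymer_indel_rate)
    read <- ind$seq
    n_indels[[i]] <- nrow(ind$log)
    if (nrow(ind$log) > 0) {
      ind$log$read_id <- sprintf("ff%05d", i)
      logs[[length(logs) + 1]] <- ind$log
    }
    if (stats::runif(1) < p$leader_rate) {
      has_leader[[i]] <- TRUE
      read <- paste0(p$leader_seq, read)
    }
    seqs[[i]] <- read
  }
  qual <- lapply(seqs, function(s) {
    pmin(pmax(round(stats::rnorm(nchar(s), 32, 4)), 2L), 40L)
  })
  reads <- seq_tbl(sprintf("ff%05d", seq_len(n)), seqs, qual = qual)
  list(
    reads = reads,
    truth = tibble::tibble(
      id = reads$id, platform = "454", origin = origin, n_subs = 0L,
      n_indels = n_indels, has_leader = has_leader, has_adapter = FALSE
    ),
    indel_log = if (length(logs) > 0) {
      dplyr::bind_rows(logs)
    } else {
      tibble::tibble(pos = integer(), run_len = integer(), kind = character(),
                     read_id = character())
    }
  )
}

# +-1 indels inside homopolymer runs of >= 3 identical bases
apply_homopolymer_indels <- function(seq, rate) {
  r <- rle(strsplit(seq, "")[[1]])
  log <- list()
  out <- character(length(r$lengths))
  pos <- 0L
  for (k in seq_along(r$lengths)) {
    run <- r$lengths[[k]]
    base <- r$values[[k]]
    new_run <- run
    if (run >= 3 && stats::runif(1) < rate) {
      kind <- sample(c("ins", "del"), 1)
      new_run <- if (kind == "ins") run + 1L else run - 1L
      log[[length(log) + 1]] <- tibble::tibble(
        pos = pos + 1L, run_len = run, kind = kind
      )
    }
    out[[k]] <- strrep(base, new_run)
    pos <- pos + run
  }
  list(
    seq = paste(out, collapse = ""),
    log = if (length(log) > 0) {
      dplyr::bind_rows(log)
    } else {
      tibble::tibble(pos = integer(), run_len = integer(), kind = character())
    }
  )
}

#' Expand a dataset to a known redundancy factor
#'
#' Each transcript is emitted `factor` times: the original plus mutated
#' copies.  Per-copy substitutions are capped at 40% of
#' `(1 - identity_floor)` of the length, so that the pairwise identity of
#' any two copies stays strictly above the floor (two copies diverge from
#' each other at most twice as fast as from the original).
#'
#' @param transcripts A [seq_tbl()].
#' @param factor Copies per transcript (>= 1).
#' @param identity_floor Pairwise identity floor (default 0.98).
#' @param seed Integer seed.
#' @return A list: `expanded` ([seq_tbl()]) and `truth` (tibble: `id`,
#'   `origin`, `copy_index`).
#' @export
expand_redundancy <- function(transcripts, factor, identity_floor = 0.98,
                              seed = 1) {
  if (factor < 1) rlang::abort("factor must be >= 1")
  with_seed_local(seed, {
    rows <- lapply(seq_len(nrow(transcripts)), function(i) {
      len <- nchar(transcripts$seq[[i]])
      max_sub <- floor(0.4 * (1 - identity_floor) * len)
      copies <- vapply(seq_len(factor), function(k) {
        if (k == 1) {
          transcripts$seq[[i]]
        } else {
          substitute_bases(transcripts$seq[[i]], sample(0:max_sub, 1))
        }
      }, character(1))
      tibble::tibble(
        id = if (factor == 1) {
          transcripts$id[[i]]
        } else {
          paste0(transcripts$id[[i]], "_copy", seq_len(factor))
        },
        seq = copies, origin = transcripts$id[[i]],
        copy_index = seq_len(factor)
      )
    })
    flat <- dplyr::bind_rows(rows)
    list(
      expanded = seq_tbl(flat$id, flat$seq),
      truth = dplyr::select(flat, -"seq")
    )
  })
}

#' Corrupt a transcript set with fragments and frameshifts
#'
#' For redundancy-removal recovery tests: each transcript is emitted in
#' full plus `n_fragments` truncated copies (a window of 55-75% of the
#' length) and `n_frameshift` copies carrying a single-base deletion at
#' 60-80% of the transcript's longest ORF (the classic homopolymer-error
#' artifact: the deduced protein becomes a prefix of the true protein
#' followed by a short nonsense tail).  The deletion site is chosen so
#' that the shifted frame meets a stop within about two dozen codons,
#' matching the observed short nonsense polypeptides that motivate the
#' 25-residue C-terminal trim of [deduplicate()].
#'
#' @param transcripts A [seq_tbl()].
#' @param n_fragments,n_frameshift Corrupted copies per transcript.
#' @param seed Integer seed.
#' @return A list: `corrupted` ([seq_tbl()], shuffled order) and `truth`
#'   (tibble: `id`, `origin`, `variant`).
#' @export
sim_corrupt_variants <- function(transcripts, n_fragments = 1,
                                 n_frameshift = 1, seed = 1) {
  orfs <- longest_orfs(transcripts)
  with_seed_local(seed, {
    rows <- lapply(seq_len(nrow(transcripts)), function(i) {
      seq <- transcripts$seq[[i]]
      id <- transcripts$id[[i]]
      len <- nchar(seq)
      orf <- orfs[i, ]
      out <- list(tibble::tibble(id = id, seq = seq, origin = id,
                                 variant = "full"))
      for (k in seq_len(n_fragments)) {
        w <- round(len * stats::runif(1, 0.55, 0.75))
        s <- sample(len - w + 1L, 1)
        out[[length(out) + 1]] <- tibble::tibble(
          id = paste0(id, "_frag", k), seq = substr(seq, s, s + w - 1L),
          origin = id, variant = "fragment"
        )
      }
      for (k in seq_len(n_frameshift)) {
        span <- orf$nt_end - orf$nt_start
        fs <- NULL
        fallback <- NULL
        for (try in 1:25) {
          at <- orf$nt_start + round(span * stats::runif(1, 0.6, 0.8))
          at <- min(max(at, 2L), len - 1L)
          cand <- paste0(substr(seq, 1, at - 1L), substr(seq, at + 1L, len))
          o <- longest_orf_one(cand)
          # accept when the deduced ORF is still the prefix ORF and the
          # shifted frame meets a stop within ~24 codons of the deletion
          if (o$strand == orf$strand &&
              abs(o$nt_start - orf$nt_start) <= 2 &&
              o$nt_end <= at + 72) {
            fs <- cand
            break
          }
          if (is.null(fallback)) fallback <- cand
        }
        out[[length(out) + 1]] <- tibble::tibble(
          id = paste0(id, "_fs", k),
          seq = if (is.null(fs)) fallback else fs,
          origin = id, variant = "frameshift"
        )
      }
      dplyr::bind_rows(out)
    })
    flat <- dplyr::bind_rows(rows)
    flat <- flat[sample(nrow(flat)), ]
    list(
      corrupted = seq_tbl(flat$id, flat$seq),
      truth = dplyr::select(flat, -"seq")
    )
  })
}
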