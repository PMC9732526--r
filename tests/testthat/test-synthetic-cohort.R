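test_that("cohort generation is deterministic given the spec seed", {
  b1 <- generate_cohort(small_spec(seed = 11))
  b2 <- generate_cohort(small_spec(seed = 11))
  expect_identical(b1, b2)
  b3 <- generate_cohort(small_spec(seed = 12))
  expect_false(identical(b1$tpm, b3$tpm))
})

test_that("written cohorts are byte-identical across runs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(small_spec(seed = 4)), d1)
  write_cohort(generate_cohort(small_spec(seed = 4)), d2)
  f <- list.files(d1, recursive = TRUE)
  expect_setequal(f, list.files(d2, recursive = TRUE))
  h1 <- tools::md5sum(file.path(d1, f))
  h2 <- tools::md5sum(file.path(d2, f))
  expect_equal(unname(h1), unname(h2))
})

test_that("zero artifact rates yield a fusion table of true calls only", {
  b <- generate_cohort(small_spec(seed = 5, artifact_rates = c(pseudogene = 0)))
  expect_equal(nrow(b$ledger$artifact_calls), 0)
  expect_setequal(paste(b$fusion_calls$sample_id, b$fusion_calls$fusion_name),
                  paste(b$ledger$true_fusions$sample_id,
                        b$ledger$true_fusions$fusion_name))
})

test_that("planted delta-PSI is realized between risk strata", {
  ## 200 events, planted shift 0.3, ~150 samples per stratum
  b <- generate_cohort(cohort_spec(seed = 3, n_events = 200,
                                   delta_psi_planted = 0.3))
  ev <- generate_events(b$annotation)
  pq <- compute_psi(ev, b$tpm)
  strat <- setNames(b$ledger$risk$stratum, b$ledger$risk$sample_id)
  hi <- names(strat)[strat == "high"]; lo <- names(strat)[strat == "low"]
  planted <- ev$event_id[ev$gene_id %in% b$ledger$planted_dpsi_genes &
                           ev$type == "SE"]
  dps <- rowMeans(pq$psi[planted, hi], na.rm = TRUE) -
    rowMeans(pq$psi[planted, lo], na.rm = TRUE)
  expect_equal(mean(dps), 0.3, tolerance = 0.05 / 0.3)
  expect_lt(abs(mean(dps) - 0.3), 0.05)
})

test_that("planted DE genes carry the planted fold-change on average", {
  ## Monte-Carlo over 3 seeds: |log2FC| within 0.2 of the planted value
  for (s in 1:3) {
    b <- generate_cohort(small_spec(seed = s))
    kmt <- b$samples$sample_id[b$samples$fusion_group == "KMT2A-r"]
    etv <- b$samples$sample_id[b$samples$fusion_group == "ETV6-r"]
    lc <- log2(b$counts + 1)
    up <- b$ledger$de_genes$up
    lfc <- rowMeans(lc[up, kmt, drop = FALSE]) -
      rowMeans(lc[up, etv, drop = FALSE])
    expect_gte(mean(abs(lfc)), b$spec$de_log_fc - 0.2)
  }
})

test_that("high-hazard stratum relapses earlier (Kaplan-Meier ordering)", {
  b <- generate_cohort(cohort_spec(seed = 2))
  strat <- b$ledger$risk$stratum
  fit <- survival::survfit(
    survival::Surv(b$clinical$efs_time_days, b$clinical$relapse) ~ strat)
  med <- summary(fit)$table[, "median"]
  ## a median beyond follow-up (never reached) counts as +Inf
  med[is.na(med)] <- Inf
  expect_lt(med[["strat=high"]], med[["strat=low"]])
  expect_true(is.finite(med[["strat=high"]]))
})

test_that("every fusion call is attributed to exactly one ledger category", {
  b <- generate_cohort(small_spec(seed = 6))
  keys <- paste(b$fusion_calls$sample_id, b$fusion_calls$fusion_name)
  truth <- paste(b$ledger$true_fusions$sample_id,
                 b$ledger$true_fusions$fusion_name)
  art <- paste(b$ledger$artifact_calls$sample_id,
               b$ledger$artifact_calls$fusion_name)
  counts <- table(c(truth, art))
  expect_setequal(keys, names(counts))
  ## a call never sits in both categories
  expect_length(intersect(truth, art), 0)
})

test_that("the truth ledger round-trips through JSON losslessly", {
  b <- generate_cohort(small_spec(seed = 7))
  path <- withr::local_tempfile(fileext = ".json")
  write_ledger(b$ledger, path)
  lg <- read_ledger(path)
  expect_equal(lg$true_fusions, b$ledger$true_fusions)
  expect_equal(lg$artifact_calls, b$ledger$artifact_calls)
  expect_equal(lg$prognostic_genes, b$ledger$prognostic_genes)
  expect_equal(lg$planted_dpsi_genes, b$ledger$planted_dpsi_genes)
  expect_equal(lg$motif_genes, b$ledger$motif_genes)
  expect_equal(lg$risk$stratum, b$ledger$risk$stratum)
})

test_that("written standard formats round-trip through the readers", {
  b <- generate_cohort(small_spec(seed = 9))
  d <- withr::local_tempdir()
  write_cohort(b, d)
  ## GTF
  ann <- read_gtf(file.path(d, "annotation.gtf"),
                  chrom_lengths = b$annotation$chrom_lengths)
  expect_equal(ann$genes, b$annotation$genes, ignore_attr = TRUE)
  expect_setequal(ann$transcripts$tx_id, b$annotation$transcripts$tx_id)
  ex1 <- ann$exons[order(ann$exons$tx_id, ann$exons$start),
                   c("tx_id", "start", "end")]
  ex2 <- b$annotation$exons[order(b$annotation$exons$tx_id,
                                  b$annotation$exons$start),
                            c("tx_id", "start", "end")]
  expect_equal(ex1, ex2, ignore_attr = TRUE)
  ## FASTA
  genome <- read_genome_fasta(file.path(d, "genome.fa"))
  expect_identical(genome, b$annotation$genome)
  ## fusion calls (STAR-Fusion dialect)
  calls <- parse_fusion_calls(file.path(d, "fusion_calls.tsv"))
  expect_equal(calls, b$fusion_calls)
  ## knowledge tables and gene sets
  kn <- load_knowledge(file.path(d, "knowledge"))
  expect_equal(kn$pseudogenes, b$knowledge$pseudogenes)
  expect_equal(kn$known_fusions, b$knowledge$known_fusions,
               ignore_attr = TRUE)
  sets <- read_gmt(file.path(d, "gene_sets.gmt"))
  expect_equal(sets, b$gene_sets)
  ## motif DB
  db <- read_motif_db(file.path(d, "motifs"))
  expect_equal(db$kmers, b$motif_db$kmers)
})

test_that("invalid specs fail with the offending field named", {
  expect_error(cohort_spec(n_prognostic_genes = 500, n_genes = 100),
               "n_prognostic_genes")
  expect_error(cohort_spec(delta_psi_planted = 1.2), "delta_psi_planted")
  expect_error(cohort_spec(fusion_group_freqs = c("A-r" = 0.9, "B-r" = 0.3)),
               "fusion_group_freqs")
  expect_error(cohort_spec(n_cohorts = 0), "n_cohorts")
  expect_error(cohort_spec(planted_motif = "GGG"), "planted_motif")
})

test_that("sample QC applies inclusive thresholds and logs exclusions", {
  stats <- data.frame(
    sample_id = c("a", "b", "c", "d"),
    mapped_frac = c(0.30, 0.25, 0.60, 0.20),
    mapped_reads = c(6e6, 5e6, 4e6, 6e6))
  qc <- sample_qc(stats)
  expect_setequal(qc$retained, c("a", "b"))
  expect_equal(qc$log$reason[qc$log$sample_id == "c"], "mapped_reads")
  expect_equal(qc$log$reason[qc$log$sample_id == "d"], "mapped_frac")
  expect_error(sample_qc(data.frame(sample_id = "x",
                                    mapped_frac = NA_real_,
                                    mapped_reads = 1e7)), "x")
})
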