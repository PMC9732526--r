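test_that("an SE event yields eight flank windows with sane geometry", {
  ann <- seven_type_annotation()
  set.seed(1)
  genome <- c(chr1 = random_seq(10000))
  ev <- generate_events(ann)
  se <- ev[ev$type == "SE", , drop = FALSE]
  reg <- extract_event_regions(se, genome, window = 50)
  expect_equal(nrow(reg), 8)
  expect_setequal(reg$region_class,
                  c("D1_exon", "D1_intron", "A1_exon", "A1_intron",
                    "D2_exon", "D2_intron", "A2_exon", "A2_intron"))
  expect_true(all(reg$length == 50))
  expect_true(all(!reg$truncated))
  ## donor exon window ends at the splice site; intron window starts after
  d1 <- reg[reg$region_class == "D1_exon", ]
  expect_equal(d1$end, 1100)
  expect_equal(reg$start[reg$region_class == "D1_intron"], 1101)
})

test_that("minus-strand windows are the reverse complement of the locus", {
  ann <- seven_type_annotation()
  ann$genes$strand[ann$genes$gene_id == "GSE"] <- "-"
  set.seed(2)
  genome <- c(chr1 = random_seq(10000))
  ev <- generate_events(ann)
  se <- ev[ev$type == "SE" & ev$gene_id == "GSE", , drop = FALSE]
  reg <- extract_event_regions(se, genome, window = 30)
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  for (i in seq_len(nrow(reg)))
    expect_equal(reg$seq[i],
                 rc(substr(genome[["chr1"]], reg$start[i], reg$end[i])))
})

test_that("windows overrunning the contig end are truncated and flagged", {
  ann <- seven_type_annotation()
  genome <- c(chr1 = substr(random_seq(1450), 1, 1450))
  se <- generate_events(ann)
  se <- se[se$type == "SE", , drop = FALSE]
  reg <- extract_event_regions(se, genome, window = 200)
  expect_true(any(reg$truncated))
  expect_true(all(reg$end <= 1450))
  expect_error(extract_event_regions(transform(se, chrom = "chrX"), genome),
               "chrX")
})

test_that("a planted 6-mer is found exactly at its offset", {
  db <- motif_db_from_kmers(c(X = "ACGTAC"))
  reg <- data.frame(event_id = "e1", region_class = "A1_intron",
                    start = 1, end = 40, truncated = FALSE,
                    seq = paste0(strrep("T", 10), "ACGTAC", strrep("G", 24)),
                    length = 40, gc = 0.5)
  hits <- scan_motifs(reg, db, scan_pfms = FALSE)
  expect_equal(hits$n_hits, 1L)
})

test_that("one-hot PFMs reproduce the exact 6-mer hit sets", {
  set.seed(14)
  db <- motif_db_from_kmers(c(A = "GAAGAA", B = "TGCATG", C = "CCCGGG"))
  validate_motif_db(db)
  reg <- data.frame(event_id = paste0("e", 1:50),
                    region_class = "A1_intron", start = 1, end = 200,
                    truncated = FALSE,
                    seq = replicate(50, random_seq(200)),
                    length = 200, gc = 0.5, stringsAsFactors = FALSE)
  hits <- scan_motifs(reg, db, scan_pfms = TRUE)
  km <- hits[hits$motif_type == "kmer", ]
  pf <- hits[hits$motif_type == "pfm", ]
  expect_equal(pf$n_hits, km$n_hits)
})

test_that("6-mer hit counts match the closed-form expectation", {
  set.seed(15)
  db <- motif_db_from_kmers(c(X = "ACGGTA"))
  n <- 1000
  reg <- data.frame(event_id = paste0("e", 1:n), region_class = "w",
                    start = 1, end = 300, truncated = FALSE,
                    seq = replicate(n, random_seq(300)),
                    length = 300, gc = 0.5, stringsAsFactors = FALSE)
  hits <- scan_motifs(reg, db, scan_pfms = FALSE)
  expected <- 295 * 4^-6
  se <- sqrt(expected / n)
  expect_lt(abs(mean(hits$n_hits) - expected), 4 * se)
})

test_that("control matching reproduces the signal GC profile", {
  set.seed(16)
  ## bimodal GC pool; signal drawn from the high-GC mode
  n <- 300
  gc <- c(runif(n / 2, 0.3, 0.4), runif(n / 2, 0.6, 0.7))
  feats <- data.frame(event_id = paste0("e", 1:n),
                      length = rep(1600, n), gc = gc)
  signal <- paste0("e", sample((n / 2 + 1):n, 40))
  pool <- setdiff(feats$event_id, signal)
  ctrl <- match_controls(signal, pool, feats, n_samples = 50, seed = 3)
  sig_gc <- mean(feats$gc[feats$event_id %in% signal])
  ctrl_gc <- vapply(ctrl, function(ids)
    mean(feats$gc[feats$event_id %in% ids]), numeric(1))
  expect_lt(abs(mean(ctrl_gc) - sig_gc), 0.02)
  expect_true(all(lengths(ctrl) == length(signal)))
  expect_true(all(vapply(ctrl, function(ids)
    length(intersect(ids, signal)) == 0, logical(1))))
  ## determinism
  ctrl2 <- match_controls(signal, pool, feats, n_samples = 50, seed = 3)
  expect_identical(ctrl, ctrl2)
  expect_error(match_controls(feats$event_id, pool, feats), "smaller")
})

test_that("z-scores are zero in the degenerate pool == signal case", {
  set.seed(18)
  db <- motif_db_from_kmers(c(X = "GAAGAA", Y = "TTTCCA"))
  reg <- data.frame(event_id = rep(paste0("e", 1:30), each = 1),
                    region_class = "w", start = 1, end = 200,
                    truncated = FALSE,
                    seq = replicate(30, random_seq(200)),
                    length = 200, gc = 0.5, stringsAsFactors = FALSE)
  hits <- scan_motifs(reg, db, scan_pfms = FALSE)
  feats <- data.frame(event_id = reg$event_id, length = reg$length,
                      gc = reg$gc)
  signal <- reg$event_id
  ctrl <- match_controls(signal, signal, feats, n_samples = 20, seed = 1)
  enr <- enrichment_z(hits, signal, ctrl)
  expect_true(all(enr$z == 0))
  expect_true(all(!enr$enriched))
})

test_that("the planted-motif z-score rises with the planting rate", {
  set.seed(20)
  db <- motif_db_from_kmers(c(X = "GAAGAA"))
  n <- 200
  mkseq <- function(plant) {
    s <- random_seq(200)
    if (plant) s <- paste0(substr(s, 1, 80), "GAAGAA", substr(s, 87, 200))
    s
  }
  zs <- vapply(c(0.2, 0.4, 0.8), function(rate) {
    planted <- c(rep(TRUE, round(rate * 40)),
                 rep(FALSE, 40 - round(rate * 40)), rep(FALSE, n - 40))
    reg <- data.frame(event_id = paste0("e", 1:n), region_class = "w",
                      start = 1, end = 200, truncated = FALSE,
                      seq = vapply(planted, mkseq, character(1)),
                      length = 200, gc = 0.5, stringsAsFactors = FALSE)
    hits <- scan_motifs(reg, db, scan_pfms = FALSE)
    feats <- data.frame(event_id = reg$event_id, length = 200, gc = 0.5)
    signal <- paste0("e", 1:40)
    ctrl <- match_controls(signal, paste0("e", 41:n), feats,
                           n_samples = 50, seed = 2)
    enrichment_z(hits, signal, ctrl)$z
  }, numeric(1))
  expect_true(all(diff(zs) > 0))
  expect_gt(zs[3], 1.5)
})

test_that("motif databases round-trip through their text formats", {
  db <- motif_db_from_kmers(c(SRSF1 = "GGAGGA", QKI = "ACTAAC"))
  dir <- withr::local_tempdir()
  write_motif_db(db, dir)
  db2 <- read_motif_db(dir)
  expect_equal(db2$kmers, db$kmers)
  expect_equal(db2$pfms$SRSF1, db$pfms$SRSF1, tolerance = 1e-6)
})
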