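## shared fixtures: small cohort spec, toy annotations, call builders

small_spec <- function(seed = 1L, ...) {
  cohort_spec(n_cohorts = 3, patients_per_cohort = 30,
              fusion_group_freqs = c("KMT2A-r" = 0.25, "ETV6-r" = 0.25),
              n_genes = 200, n_prognostic_genes = 10, n_de_genes = 20,
              n_events = 60, n_dpsi_events = 12, seed = seed, ...)
}

## one + strand and one - strand three-exon gene with CDS and domains
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("GP", "GM"), symbol = c("GP", "GM"),
    chrom = c("chr1", "chr1"), strand = c("+", "-"),
    start = c(101L, 1101L), end = c(600L, 1600L),
    biotype = "protein_coding", stringsAsFactors = FALSE)
  transcripts <- data.frame(tx_id = c("GP.t1", "GM.t1"),
                            gene_id = c("GP", "GM"),
                            stringsAsFactors = FALSE)
  exons <- data.frame(
    tx_id = c(rep("GP.t1", 3), rep("GM.t1", 3)),
    exon_rank = NA_integer_,
    start = c(101L, 301L, 501L, 1101L, 1301L, 1501L),
    end = c(200L, 400L, 600L, 1200L, 1400L, 1600L),
    stringsAsFactors = FALSE)
  cds <- data.frame(tx_id = c("GP.t1", "GM.t1"),
                    cds_start = c(101L, 1101L), cds_end = c(600L, 1600L),
                    stringsAsFactors = FALSE)
  domains <- data.frame(
    gene_id = c("GP", "GP", "GM"),
    domain_id = c("PFA", "PFB", "PFC"),
    aa_start = c(5L, 30L, 5L), aa_end = c(20L, 60L, 20L),
    go_bp = c("RNA splicing", "translation", "RNA splicing"),
    go_cc = c("nucleus", "nucleus", "cytoplasm"),
    go_mf = c("RNA binding", "DNA binding", "RNA binding"),
    stringsAsFactors = FALSE)
  new_annotation(genes, transcripts, exons, cds, domains,
                 c(chr1 = 2000L))
}

## minimal fusion-call row builder
make_call <- function(sample_id, gene5, gene3, cohort = "C1",
                      junction = 10L, spanning = 5L, ffpm = 1,
                      anchor = "YES_LDAS", wt5 = 20L, wt3 = 20L,
                      left_bp = "chr1:1000:+", right_bp = "chr1:5000:+") {
  data.frame(sample_id = sample_id, cohort = cohort,
             fusion_name = paste0(gene5, "--", gene3),
             gene5 = gene5, gene3 = gene3,
             left_breakpoint = left_bp, right_breakpoint = right_bp,
             junction_reads = as.integer(junction),
             spanning_frags = as.integer(spanning),
             ffpm = ffpm, large_anchor = anchor,
             wt5_reads = as.integer(wt5), wt3_reads = as.integer(wt3),
             stringsAsFactors = FALSE)
}

empty_knowledge <- function() {
  list(pseudogenes = character(0),
       paralog_pairs = data.frame(gene_a = character(0),
                                  gene_b = character(0)),
       ig_hb_genes = character(0),
       normal_panel = data.frame(gene_a = character(0),
                                 gene_b = character(0)),
       known_fusions = data.frame(gene_a = character(0),
                                  gene_b = character(0),
                                  source = character(0)),
       leukemia_genes = character(0))
}

## annotation exercising all seven splicing event types (one gene each, +)
seven_type_annotation <- function() {
  g <- function(id, txs) {
    list(id = id, txs = txs)
  }
  defs <- list(
    g("GSE", list(t1 = rbind(c(1001, 1100), c(1201, 1300), c(1401, 1500)),
                  t2 = rbind(c(1001, 1100), c(1401, 1500)))),
    g("GRI", list(t1 = rbind(c(2001, 2100), c(2201, 2300)),
                  t2 = rbind(c(2001, 2300)))),
    g("GA3", list(t1 = rbind(c(3001, 3100), c(3201, 3300)),
                  t2 = rbind(c(3001, 3100), c(3231, 3300)))),
    g("GA5", list(t1 = rbind(c(4001, 4100), c(4201, 4300)),
                  t2 = rbind(c(4001, 4130), c(4201, 4300)))),
    g("GMX", list(t1 = rbind(c(5001, 5100), c(5201, 5300), c(5501, 5600)),
                  t2 = rbind(c(5001, 5100), c(5351, 5450), c(5501, 5600)))),
    g("GAF", list(t1 = rbind(c(6001, 6100), c(6401, 6500)),
                  t2 = rbind(c(6201, 6300), c(6401, 6500)))),
    g("GAL", list(t1 = rbind(c(7001, 7100), c(7201, 7300)),
                  t2 = rbind(c(7001, 7100), c(7401, 7500)))))
  genes <- transcripts <- exons <- list()
  for (d in defs) {
    allc <- do.call(rbind, d$txs)
    genes[[d$id]] <- data.frame(gene_id = d$id, symbol = d$id,
                                chrom = "chr1", strand = "+",
                                start = min(allc[, 1]), end = max(allc[, 2]),
                                biotype = "protein_coding",
                                stringsAsFactors = FALSE)
    for (tn in names(d$txs)) {
      tx <- paste0(d$id, ".", tn)
      transcripts[[tx]] <- data.frame(tx_id = tx, gene_id = d$id,
                                      stringsAsFactors = FALSE)
      exons[[tx]] <- data.frame(tx_id = tx, exon_rank = NA_integer_,
                                start = d$txs[[tn]][, 1],
                                end = d$txs[[tn]][, 2],
                                stringsAsFactors = FALSE)
    }
  }
  new_annotation(do.call(rbind, genes), do.call(rbind, transcripts),
                 do.call(rbind, exons),
                 cds = data.frame(tx_id = character(0),
                                  cds_start = integer(0),
                                  cds_end = integer(0)),
                 domains = data.frame(gene_id = character(0),
                                      domain_id = character(0),
                                      aa_start = integer(0),
                                      aa_end = integer(0),
                                      go_bp = character(0),
                                      go_cc = character(0),
                                      go_mf = character(0)),
                 chrom_lengths = c(chr1 = 10000L))
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
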