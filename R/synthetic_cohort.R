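## ---------------------------------------------------------------------------
## Synthetic multicohort B-ALL-like data with a machine-readable truth ledger.
## Every downstream stage of the package can be validated against the planted
## signals recorded here.
## ---------------------------------------------------------------------------

## predefined fusion pair mixtures per group label; proportions are realized
## deterministically (round-robin over cohort-sorted patients) so recurrence
## thresholds hold by construction
.group_pairs <- list(
  "KMT2A-r" = list(pairs = list(c("KMT2A", "AFF1"), c("KMT2A", "MLLT3")),
                   prop = c(0.7, 0.3), reciprocal = c(TRUE, FALSE)),
  "ETV6-r"  = list(pairs = list(c("ETV6", "RUNX1"), c("ETV6", "ABL1")),
                   prop = c(0.8, 0.2), reciprocal = c(FALSE, FALSE)),
  "TCF3-r"  = list(pairs = list(c("TCF3", "PBX1"), c("TCF3", "HLF")),
                   prop = c(0.75, 0.25), reciprocal = c(FALSE, FALSE)),
  "PAX5-r"  = list(pairs = list(c("PAX5", "JAK2"), c("PAX5", "ZNF521")),
                   prop = c(0.75, 0.25), reciprocal = c(FALSE, FALSE))
)

.rbp_names <- c("SRRM1", "SRSF1", "SRSF2", "SRSF7", "TRA2B", "HNRNPA1",
                "HNRNPC", "HNRNPK", "PTBP1", "ELAVL1", "RBFOX2", "QKI",
                "MBNL1", "CELF1", "TIA1", "U2AF2", "KHDRBS1", "PCBP1",
                "SRSF3", "FUS")

## fixed 6-mers per RBP; SRRM1's is replaced by the spec'd planted motif
.rbp_kmers <- c(SRRM1 = "GAAGAA", SRSF1 = "GGAGGA", SRSF2 = "GGCCTC",
                SRSF7 = "ACGACG", TRA2B = "AGAAGG", HNRNPA1 = "TAGGGT",
                HNRNPC = "TTTTTC", HNRNPK = "CCCTCC", PTBP1 = "TCTTCT",
                ELAVL1 = "ATTTTA", RBFOX2 = "TGCATG", QKI = "ACTAAC",
                MBNL1 = "GCTTGC", CELF1 = "TGTGTG", TIA1 = "TTTATT",
                U2AF2 = "TTTCCA", KHDRBS1 = "ATAAAC", PCBP1 = "CCCACC",
                SRSF3 = "CTTCGA", FUS = "GGTGGT")

.pseudogenes <- paste0("RPL7P", 1:6)
.ig_hb_genes <- c("IGHM", "IGKC", "IGLC1", "HBB", "HBA1", "HBA2")
.paralog_pairs <- data.frame(
  gene_a = c("DUX4", "NBPF10", "SMN1"),
  gene_b = c("DUX4L2", "NBPF14", "SMN2"),
  identity = c(0.95, 0.88, 0.99), stringsAsFactors = FALSE)
.normal_panel_base <- data.frame(
  gene_a = c("CTBS", "TFG"), gene_b = c("GNG5", "ADGRG7"),
  stringsAsFactors = FALSE)

#' Specification of a synthetic multicohort dataset
#'
#' Collects the generator's parameters and validates their invariants. The
#' defaults define the package's reference study conditions: five cohorts of
#' sixty patients, four mutually exclusive fusion groups, planted
#' differential-expression and prognostic signals, cassette-exon splicing
#' events with a planted PSI shift between latent risk strata, and a planted
#' purine-rich 6-mer in the flanks of differentially spliced exons.
#'
#' @param n_cohorts number of cohorts (projects).
#' @param patients_per_cohort samples per cohort.
#' @param fusion_group_freqs named probabilities per fusion-group label;
#'   the remainder are fusion-free patients.
#' @param artifact_rates named expected artifact calls per sample for classes
#'   pseudogene, paralog, immunoglobulin, promiscuous, normal_panel,
#'   single_project, low_faf, low_recurrence.
#' @param n_genes size of the background expression gene universe (planted
#'   prognostic/DE/RBP genes are drawn inside it; fusion, artifact and
#'   splicing-event genes are additional structural genes).
#' @param n_prognostic_genes planted prognostic genes.
#' @param n_de_genes planted differentially expressed genes for the
#'   KMT2A-r vs ETV6-r contrast (half up, half down).
#' @param prognostic_log_hazard log hazard ratio per SD of the prognostic
#'   expression score.
#' @param de_log_fc planted log2 fold-change for group contrasts (also the
#'   high- vs low-risk shift of prognostic genes).
#' @param n_events number of two-isoform cassette-exon genes.
#' @param n_dpsi_events events with a planted PSI shift between risk strata.
#' @param delta_psi_planted PSI shift between risk strata, in (0, 1).
#' @param planted_motif 6-mer embedded in inclusion flanks of motif-bearing
#'   events.
#' @param motif_planting_rate fraction of planted-dPSI events carrying the
#'   motif.
#' @param censoring_rate probability of independent censoring.
#' @param seed integer seed; the bundle is a deterministic function of the
#'   spec including the seed.
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_cohorts = 5, patients_per_cohort = 60,
                        fusion_group_freqs = c("KMT2A-r" = 0.22,
                                               "ETV6-r" = 0.22,
                                               "TCF3-r" = 0.12,
                                               "PAX5-r" = 0.08),
                        artifact_rates = c(pseudogene = 0.05, paralog = 0.05,
                                           immunoglobulin = 0.03,
                                           promiscuous = 0.04,
                                           normal_panel = 0.05,
                                           single_project = 0.04,
                                           low_faf = 0.04,
                                           low_recurrence = 0.02),
                        n_genes = 1000, n_prognostic_genes = 20,
                        n_de_genes = 60, prognostic_log_hazard = 1.7,
                        de_log_fc = 1.5, n_events = 200, n_dpsi_events = 40,
                        delta_psi_planted = 0.3, planted_motif = "GAAGAA",
                        motif_planting_rate = 0.6, censoring_rate = 0.3,
                        seed = 1L) {
  counts <- c(n_cohorts = n_cohorts, patients_per_cohort = patients_per_cohort,
              n_genes = n_genes, n_prognostic_genes = n_prognostic_genes,
              n_de_genes = n_de_genes, n_events = n_events,
              n_dpsi_events = n_dpsi_events)
  for (nm in names(counts))
    stop_fields(counts[[nm]] < 1 || counts[[nm]] != round(counts[[nm]]),
                "cohort_spec: field '%s' must be a count >= 1", nm)
  stop_fields(any(fusion_group_freqs < 0 | fusion_group_freqs > 1),
              "cohort_spec: field 'fusion_group_freqs' must lie in [0,1]")
  stop_fields(sum(fusion_group_freqs) > 1 + 1e-12,
              "cohort_spec: field 'fusion_group_freqs' must sum to <= 1")
  stop_fields(is.null(names(fusion_group_freqs)) ||
                any(names(fusion_group_freqs) == ""),
              "cohort_spec: field 'fusion_group_freqs' must be named")
  known <- c("pseudogene", "paralog", "immunoglobulin", "promiscuous",
             "normal_panel", "single_project", "low_faf", "low_recurrence")
  stop_fields(!all(names(artifact_rates) %in% known),
              "cohort_spec: field 'artifact_rates' has unknown classes: %s",
              paste(setdiff(names(artifact_rates), known), collapse = ", "))
  stop_fields(any(artifact_rates < 0),
              "cohort_spec: field 'artifact_rates' must be >= 0")
  stop_fields(delta_psi_planted <= 0 || delta_psi_planted >= 1,
              "cohort_spec: field 'delta_psi_planted' must lie in (0,1)")
  stop_fields(censoring_rate < 0 || censoring_rate > 1,
              "cohort_spec: field 'censoring_rate' must lie in [0,1]")
  stop_fields(n_prognostic_genes + n_de_genes + length(.rbp_names) > n_genes,
              "cohort_spec: field 'n_prognostic_genes' (+ n_de_genes + RBPs) exceeds n_genes")
  stop_fields(n_dpsi_events > n_events,
              "cohort_spec: field 'n_dpsi_events' exceeds n_events")
  stop_fields(!grepl("^[ACGT]{6}$", planted_motif),
              "cohort_spec: field 'planted_motif' must be an ACGT 6-mer")
  stop_fields(motif_planting_rate < 0 || motif_planting_rate > 1,
              "cohort_spec: field 'motif_planting_rate' must lie in [0,1]")
  structure(list(n_cohorts = as.integer(n_cohorts),
                 patients_per_cohort = as.integer(patients_per_cohort),
                 fusion_group_freqs = fusion_group_freqs,
                 artifact_rates = artifact_rates,
                 n_genes = as.integer(n_genes),
                 n_prognostic_genes = as.integer(n_prognostic_genes),
                 n_de_genes = as.integer(n_de_genes),
                 prognostic_log_hazard = prognostic_log_hazard,
                 de_log_fc = de_log_fc,
                 n_events = as.integer(n_events),
                 n_dpsi_events = as.integer(n_dpsi_events),
                 delta_psi_planted = delta_psi_planted,
                 planted_motif = planted_motif,
                 motif_planting_rate = motif_planting_rate,
                 censoring_rate = censoring_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

.cohort_names <- function(n) {
  base <- c("TARGET", "SJH", "LUND", "CHOP", "PMJCI")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("COHORT%02d", seq_len(n - length(base))))
}

## gene body builder: returns exon data.frame rows for one transcript laid
## left-to-right at `start`
.build_exons <- function(start, exon_lens, intron_lens) {
  s <- integer(length(exon_lens)); e <- integer(length(exon_lens))
  cur <- start
  for (i in seq_along(exon_lens)) {
    s[i] <- cur
    e[i] <- cur + exon_lens[i] - 1L
    cur <- e[i] + 1L + if (i < length(exon_lens)) intron_lens[i] else 0L
  }
  data.frame(start = s, end = e)
}

## assemble the full annotation for a generation plan
.build_annotation <- function(gene_def, chrom_size = 1000000L) {
  gap <- 900L
  margin <- 600L
  genes <- transcripts <- exons <- cds <- list()
  domains <- list()
  chrom_i <- 1L
  cursor <- margin
  go_bp_pool <- c("RNA splicing", "chromatin organization",
                  "transcription regulation", "translation", "cell adhesion")
  go_cc_pool <- c("nucleus", "cytoplasm", "spliceosomal complex")
  go_mf_pool <- c("DNA binding", "RNA binding", "protein kinase activity")
  for (i in seq_len(nrow(gene_def))) {
    sym <- gene_def$symbol[i]
    cat_i <- gene_def$category[i]
    strand <- if (i %% 2 == 0) "-" else "+"
    if (cat_i %in% c("fusion", "catalog")) {
      exon_lens <- rep(150L, 8L); intron_lens <- rep(500L, 7L)
    } else if (cat_i == "splicing") {
      exon_lens <- c(300L, 150L, 300L); intron_lens <- c(400L, 350L)
    } else {
      exon_lens <- c(200L, 300L, 250L); intron_lens <- c(300L, 400L)
    }
    span <- sum(exon_lens) + sum(intron_lens)
    if (cursor + span > chrom_size - margin) {
      chrom_i <- chrom_i + 1L
      cursor <- margin
    }
    chrom <- paste0("chr", chrom_i)
    ex <- .build_exons(cursor, exon_lens, intron_lens)
    gstart <- min(ex$start); gend <- max(ex$end)
    biotype <- if (cat_i == "pseudogene") "processed_pseudogene"
               else if (cat_i == "ig") "IG_C_gene" else "protein_coding"
    genes[[i]] <- data.frame(gene_id = sym, symbol = sym, chrom = chrom,
                             strand = strand, start = gstart, end = gend,
                             biotype = biotype, stringsAsFactors = FALSE)
    t1 <- paste0(sym, ".t1")
    transcripts[[i]] <- data.frame(tx_id = t1, gene_id = sym,
                                   stringsAsFactors = FALSE)
    exons[[i]] <- data.frame(tx_id = t1, exon_rank = NA_integer_,
                             start = ex$start, end = ex$end,
                             stringsAsFactors = FALSE)
    cds[[i]] <- data.frame(tx_id = t1, cds_start = gstart, cds_end = gend,
                           stringsAsFactors = FALSE)
    if (cat_i == "splicing") {
      ## second isoform skips the middle (cassette) exon
      t2 <- paste0(sym, ".t2")
      transcripts[[i]] <- rbind(transcripts[[i]],
                                data.frame(tx_id = t2, gene_id = sym,
                                           stringsAsFactors = FALSE))
      exons[[i]] <- rbind(exons[[i]],
                          data.frame(tx_id = t2, exon_rank = NA_integer_,
                                     start = ex$start[c(1, 3)],
                                     end = ex$end[c(1, 3)],
                                     stringsAsFactors = FALSE))
      cds[[i]] <- rbind(cds[[i]],
                        data.frame(tx_id = t2, cds_start = gstart,
                                   cds_end = gend, stringsAsFactors = FALSE))
    }
    if (cat_i %in% c("fusion", "catalog")) {
      ## protein length 400 aa (8 x 150 nt / 3); three domains per gene
      k <- (i %% length(go_bp_pool)) + 1L
      domains[[i]] <- data.frame(
        gene_id = sym,
        domain_id = sprintf("PF%05d", (i * 3L + 0:2)),
        aa_start = c(20L, 150L, 290L), aa_end = c(100L, 240L, 380L),
        go_bp = go_bp_pool[c(k, (k %% 5) + 1L, ((k + 1) %% 5) + 1L)],
        go_cc = go_cc_pool[c((i %% 3) + 1L, ((i + 1) %% 3) + 1L, (i %% 3) + 1L)],
        go_mf = go_mf_pool[c((i %% 3) + 1L, (i %% 3) + 1L, ((i + 2) %% 3) + 1L)],
        stringsAsFactors = FALSE)
    }
    cursor <- gend + gap
  }
  chrom_lengths <- setNames(rep(chrom_size, chrom_i), paste0("chr", seq_len(chrom_i)))
  dom <- if (length(domains)) do.call(rbind, domains) else
    data.frame(gene_id = character(0), domain_id = character(0),
               aa_start = integer(0), aa_end = integer(0),
               go_bp = character(0), go_cc = character(0),
               go_mf = character(0))
  new_annotation(do.call(rbind, genes), do.call(rbind, transcripts),
                 do.call(rbind, exons), do.call(rbind, cds), dom,
                 chrom_lengths)
}

.random_genome <- function(chrom_lengths) {
  vapply(chrom_lengths, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
}

## deterministic proportional split of group patients over fusion pairs,
## interleaved over cohort-sorted patients so every pair spans >= 2 cohorts
.assign_pairs <- function(sample_ids, cohorts, mix) {
  ord <- order(cohorts, sample_ids)
  ids <- sample_ids[ord]
  n <- length(ids)
  n_pairs <- length(mix$pairs)
  if (n < 12 || n_pairs == 1) return(setNames(rep(1L, n), ids))
  n2 <- max(5L, round(mix$prop[2] * n))
  idx2 <- unique(pmax(1L, round(seq(1, n, length.out = n2))))
  assign <- rep(1L, n)
  assign[idx2] <- 2L
  setNames(assign, ids)
}

## one synthetic caller row
.fusion_call_row <- function(sample_id, cohort, g5, g3, ann, faf_shape,
                             junction_base) {
  bp_of <- function(gene, role) {
    tx <- paste0(gene, ".t1")
    ex <- tx_exons(ann, tx)
    strand <- attr(ex, "strand")
    mid <- 2:(nrow(ex) - 1)
    k <- if (length(mid) == 1) mid else sample(mid, 1)
    inside <- runif(1) < 0.3
    if (role == "5p") {
      pos <- if (strand == "+") ex$end[k] else ex$start[k]
      if (inside) pos <- if (strand == "+") pos - sample(5:50, 1) else
        pos + sample(5:50, 1)
    } else {
      pos <- if (strand == "+") ex$start[k] else ex$end[k]
      if (inside) pos <- if (strand == "+") pos + sample(5:50, 1) else
        pos - sample(5:50, 1)
    }
    sprintf("%s:%d:%s", attr(ex, "chrom"), pos, strand)
  }
  junction <- junction_base + rpois(1, junction_base * 4)
  spanning <- 2L + rpois(1, 8)
  f5 <- rbeta(1, faf_shape[1], faf_shape[2])
  f3 <- rbeta(1, faf_shape[1], faf_shape[2])
  wt5 <- max(0L, as.integer(round(junction * (1 - f5) / f5)))
  wt3 <- max(0L, as.integer(round(junction * (1 - f3) / f3)))
  data.frame(sample_id = sample_id, cohort = cohort,
             fusion_name = paste0(g5, "--", g3),
             gene5 = g5, gene3 = g3,
             left_breakpoint = bp_of(g5, "5p"),
             right_breakpoint = bp_of(g3, "3p"),
             junction_reads = as.integer(junction),
             spanning_frags = as.integer(spanning),
             ffpm = round(runif(1, 0.3, 2), 3),
             large_anchor = "YES_LDAS",
             wt5_reads = wt5, wt3_reads = wt3,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic multicohort B-ALL-like dataset
#'
#' Produces annotation, genome sequence, fusion caller output, transcript TPM,
#' clinical and read-statistics tables, knowledge tables, a motif database,
#' PPI edges and a truth ledger, all as a deterministic function of the spec.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return an object of class \code{ball_cohort}; see the methods vignette
#'   for the component list.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(derive_seed(spec$seed, "simulate"))
  N <- spec$n_cohorts * spec$patients_per_cohort
  cohorts <- rep(.cohort_names(spec$n_cohorts), each = spec$patients_per_cohort)
  samples <- data.frame(
    sample_id = sprintf("S%04d", seq_len(N)),
    cohort = cohorts,
    sex = sample(c("M", "F"), N, replace = TRUE),
    tissue = sample(c("bone_marrow", "peripheral_blood"), N, replace = TRUE,
                    prob = c(0.7, 0.3)),
    age_years = round(runif(N, 1, 18), 1),
    stringsAsFactors = FALSE)

  ## fusion group per patient
  freqs <- spec$fusion_group_freqs
  labels <- c(names(freqs), "none")
  samples$fusion_group <- sample(labels, N, replace = TRUE,
                                 prob = c(freqs, 1 - sum(freqs)))

  ## latent risk stratum, coupled to the fusion background
  p_high <- ifelse(samples$fusion_group == "KMT2A-r", 0.85,
            ifelse(samples$fusion_group == "ETV6-r", 0.15, 0.5))
  samples$risk_stratum <- ifelse(rbinom(N, 1, p_high) == 1, "high", "low")

  ## ---- cohort-level artifact plan --------------------------------------
  rates <- spec$artifact_rates
  rate <- function(cl) if (cl %in% names(rates)) rates[[cl]] else 0
  plan_pairs <- function(class, k, prefix, base = NULL) {
    n_fus <- if (rate(class) > 0) max(1L, as.integer(round(rate(class) * N / k))) else 0L
    if (n_fus == 0L) return(NULL)
    pairs <- list()
    for (j in seq_len(n_fus)) {
      if (!is.null(base) && j <= nrow(base)) {
        pairs[[j]] <- c(base$gene_a[j], base$gene_b[j])
      } else {
        pairs[[j]] <- c(sprintf("%s%02dA", prefix, j), sprintf("%s%02dB", prefix, j))
      }
    }
    pairs
  }
  np_pairs <- plan_pairs("normal_panel", 8L, "NPG", .normal_panel_base)
  sp_pairs <- plan_pairs("single_project", 6L, "SPG")
  lf_pairs <- plan_pairs("low_faf", 8L, "LFG")
  lr_pairs <- plan_pairs("low_recurrence", 3L, "LRG")

  ## ---- gene universe ----------------------------------------------------
  custom_groups <- setdiff(names(freqs), names(.group_pairs))
  group_mix <- .group_pairs
  for (g in custom_groups) {
    root <- sub("-r$", "", g)
    group_mix[[g]] <- list(pairs = list(c(root, paste0(root, "_P1"))),
                           prop = 1, reciprocal = FALSE)
  }
  fusion_genes <- unique(unlist(lapply(group_mix[names(freqs)],
                                       function(m) unlist(m$pairs))))
  catalog_extra <- c("RUNX1T1", "TMPRSS2", "ERG", "EML4", "ALK", "CBFB",
                     "MYH11", "BCR", "IKZF1")
  promisc_pool <- sprintf("PPG%03d", 1:40)
  pseudo_partner_pool <- sprintf("XPG%03d", 1:20)
  cohort_art_genes <- unlist(c(np_pairs, sp_pairs, lf_pairs, lr_pairs))
  prog_genes <- sprintf("PRG%03d", seq_len(spec$n_prognostic_genes))
  de_genes <- sprintf("DEG%03d", seq_len(spec$n_de_genes))
  spl_genes <- sprintf("SPLG%04d", seq_len(spec$n_events))
  n_bg <- spec$n_genes - spec$n_prognostic_genes - spec$n_de_genes -
    length(.rbp_names)
  bg_genes <- sprintf("BG%04d", seq_len(n_bg))

  cohort_art_genes <- unique(c(character(0), cohort_art_genes))
  gene_def <- rbind(
    data.frame(symbol = fusion_genes, category = "fusion"),
    data.frame(symbol = catalog_extra, category = "catalog"),
    data.frame(symbol = .pseudogenes, category = "pseudogene"),
    data.frame(symbol = c(.paralog_pairs$gene_a, .paralog_pairs$gene_b),
               category = "background"),
    data.frame(symbol = .ig_hb_genes, category = "ig"),
    if (length(cohort_art_genes))
      data.frame(symbol = cohort_art_genes, category = "background"),
    data.frame(symbol = promisc_pool, category = "background"),
    data.frame(symbol = pseudo_partner_pool, category = "background"),
    data.frame(symbol = .rbp_names, category = "background"),
    data.frame(symbol = prog_genes, category = "background"),
    data.frame(symbol = de_genes, category = "background"),
    data.frame(symbol = spl_genes, category = "splicing"),
    data.frame(symbol = bg_genes, category = "background"))
  gene_def <- gene_def[!duplicated(gene_def$symbol), , drop = FALSE]
  ann <- .build_annotation(gene_def)
  ann$genome <- .random_genome(ann$chrom_lengths)

  ## ---- expression -------------------------------------------------------
  G <- nrow(ann$genes)
  gid <- ann$genes$gene_id
  base_mu <- pmin(pmax(rnorm(G, 5, 1.5), 1), 11)
  names(base_mu) <- gid
  base_mu[spl_genes] <- pmin(pmax(rnorm(length(spl_genes), 5.5, 0.8), 3), 9)
  disp <- runif(G, 0.1, 0.4)
  cohort_off <- matrix(rnorm(G * spec$n_cohorts, 0, 0.3), G,
                       dimnames = list(gid, .cohort_names(spec$n_cohorts)))
  sex_genes <- sample(bg_genes, min(30L, length(bg_genes)))
  tissue_genes <- sample(setdiff(bg_genes, sex_genes),
                         min(30L, length(bg_genes) - 30L))
  log_mu <- matrix(base_mu, G, N, dimnames = list(gid, samples$sample_id)) +
    cohort_off[, samples$cohort]
  log_mu[sex_genes, samples$sex == "M"] <-
    log_mu[sex_genes, samples$sex == "M"] + 0.8
  log_mu[tissue_genes, samples$tissue == "bone_marrow"] <-
    log_mu[tissue_genes, samples$tissue == "bone_marrow"] + 0.6
  de_up <- de_genes[seq_len(spec$n_de_genes %/% 2)]
  de_down <- setdiff(de_genes, de_up)
  in_kmt <- samples$fusion_group == "KMT2A-r"
  in_etv <- samples$fusion_group == "ETV6-r"
  log_mu[de_up, in_kmt] <- log_mu[de_up, in_kmt] + spec$de_log_fc
  log_mu[de_down, in_etv] <- log_mu[de_down, in_etv] + spec$de_log_fc
  hi <- samples$risk_stratum == "high"
  log_mu[prog_genes, hi] <- log_mu[prog_genes, hi] + spec$de_log_fc
  counts <- matrix(rnbinom(G * N, mu = 2^log_mu,
                           size = rep(1 / disp, N)), G, N,
                   dimnames = list(gid, samples$sample_id))

  ## ---- survival ---------------------------------------------------------
  ## exponential event times, log-hazard linear in the standardized
  ## prognostic expression score; baseline scaled so the low-hazard stratum
  ## is largely event-free within the administrative follow-up (~8 years),
  ## as in pediatric B-ALL event-free survival
  expr_log <- log2(counts[prog_genes, , drop = FALSE] + 1)
  score <- colMeans(expr_log)
  z <- as.numeric(scale(score))
  lambda <- log(2) / 3500 * exp(spec$prognostic_log_hazard * z)
  t_event <- rexp(N, lambda)
  cens <- ifelse(runif(N) < spec$censoring_rate, runif(N, 100, 2000), Inf)
  cens <- pmin(cens, 3000)
  samples$efs_time_days <- round(pmin(t_event, cens), 1)
  samples$relapse <- as.integer(t_event <= cens)

  ## ---- PSI and transcript TPM -------------------------------------------
  high_missing <- spl_genes[seq_len(min(4L, spec$n_events))]
  eligible <- setdiff(spl_genes, high_missing)
  dpsi_genes <- sample(eligible, spec$n_dpsi_events)
  psi_mean <- matrix(rep(runif(spec$n_events, 0.25, 0.75), N),
                     spec$n_events, N, dimnames = list(spl_genes, NULL))
  conc <- setNames(rep(15, spec$n_events), spl_genes)
  conc[dpsi_genes] <- 50
  psi_mean[dpsi_genes, ] <-
    matrix(rep(0.5 - spec$delta_psi_planted / 2, length(dpsi_genes) * N),
           length(dpsi_genes), N)
  psi_mean[dpsi_genes, hi] <- 0.5 + spec$delta_psi_planted / 2
  psi <- matrix(rbeta(spec$n_events * N,
                      psi_mean * conc[spl_genes],
                      (1 - psi_mean) * conc[spl_genes]),
                spec$n_events, N, dimnames = list(spl_genes, samples$sample_id))

  gene_len <- vapply(gid, function(g)
    spliced_length(ann, paste0(g, ".t1")), numeric(1))
  rate_mat <- counts / gene_len
  tpm_gene <- sweep(rate_mat, 2, colSums(rate_mat), "/") * 1e6

  tx_ids <- ann$transcripts$tx_id
  tx_gene_map <- setNames(ann$transcripts$gene_id, tx_ids)
  tpm <- matrix(0, length(tx_ids), N, dimnames = list(tx_ids, samples$sample_id))
  single <- !(tx_gene_map %in% spl_genes)
  tpm[single, ] <- tpm_gene[tx_gene_map[single], ]
  t1 <- paste0(spl_genes, ".t1"); t2 <- paste0(spl_genes, ".t2")
  tpm[t1, ] <- tpm_gene[spl_genes, ] * psi
  tpm[t2, ] <- tpm_gene[spl_genes, ] * (1 - psi)

  ## controlled missingness: scale event totals below the 1-TPM rule
  dropout_prone <- sample(setdiff(eligible, dpsi_genes),
                          min(10L, length(setdiff(eligible, dpsi_genes))))
  scale_total <- function(g, cols) {
    tot <- tpm[paste0(g, ".t1"), cols] + tpm[paste0(g, ".t2"), cols]
    fac <- runif(length(cols), 0.2, 0.8) / pmax(tot, 1e-9)
    tpm[paste0(g, ".t1"), cols] <<- tpm[paste0(g, ".t1"), cols] * fac
    tpm[paste0(g, ".t2"), cols] <<- tpm[paste0(g, ".t2"), cols] * fac
  }
  for (g in dropout_prone)
    scale_total(g, sample(N, max(1L, round(0.04 * N))))
  for (g in high_missing)
    scale_total(g, sample(N, round(0.15 * N)))

  ## ---- fusion calls ------------------------------------------------------
  calls <- list()
  truth <- list()
  artifacts <- list()
  push_call <- function(row, class = NULL, group = NULL) {
    calls[[length(calls) + 1L]] <<- row
    if (is.null(class)) {
      truth[[length(truth) + 1L]] <<-
        data.frame(sample_id = row$sample_id, fusion_name = row$fusion_name,
                   group = group, stringsAsFactors = FALSE)
    } else {
      artifacts[[length(artifacts) + 1L]] <<-
        data.frame(sample_id = row$sample_id, fusion_name = row$fusion_name,
                   class = class, stringsAsFactors = FALSE)
    }
  }
  for (g in names(freqs)) {
    mix <- group_mix[[g]]
    in_g <- samples$fusion_group == g
    if (!any(in_g)) next
    assign <- .assign_pairs(samples$sample_id[in_g], samples$cohort[in_g], mix)
    for (sid in names(assign)) {
      pr <- mix$pairs[[assign[[sid]]]]
      co <- samples$cohort[samples$sample_id == sid]
      push_call(.fusion_call_row(sid, co, pr[1], pr[2], ann,
                                 c(12, 28), 5L), group = g)
      recip <- mix$reciprocal[assign[[sid]]]
      if (isTRUE(recip))
        push_call(.fusion_call_row(sid, co, pr[2], pr[1], ann,
                                   c(12, 28), 5L), group = g)
    }
  }
  ## per-sample artifact classes
  for (i in seq_len(N)) {
    sid <- samples$sample_id[i]; co <- samples$cohort[i]
    for (k in seq_len(rpois(1, rate("pseudogene")))) {
      pr <- c(sample(.pseudogenes, 1), sample(pseudo_partner_pool, 1))
      push_call(.fusion_call_row(sid, co, pr[1], pr[2], ann, c(12, 28), 3L),
                class = "pseudogene")
    }
    for (k in seq_len(rpois(1, rate("paralog")))) {
      j <- sample(nrow(.paralog_pairs), 1)
      push_call(.fusion_call_row(sid, co, .paralog_pairs$gene_a[j],
                                 .paralog_pairs$gene_b[j], ann, c(12, 28), 3L),
                class = "paralog")
    }
    for (k in seq_len(rpois(1, rate("immunoglobulin")))) {
      pr <- sample(.ig_hb_genes, 2)
      push_call(.fusion_call_row(sid, co, pr[1], pr[2], ann, c(12, 28), 3L),
                class = "immunoglobulin")
    }
    for (k in seq_len(rpois(1, rate("promiscuous") / 2))) {
      trio <- sample(promisc_pool, 3)
      push_call(.fusion_call_row(sid, co, trio[1], trio[2], ann, c(12, 28), 3L),
                class = "promiscuous")
      push_call(.fusion_call_row(sid, co, trio[1], trio[3], ann, c(12, 28), 3L),
                class = "promiscuous")
    }
  }
  ## cohort-level artifact classes
  emit_recurrent <- function(pairs, class, k, one_cohort = FALSE,
                             faf_shape = c(12, 28), junction_base = 5L) {
    if (is.null(pairs)) return(invisible())
    for (pr in pairs) {
      if (one_cohort) {
        co <- sample(unique(samples$cohort), 1)
        pool <- samples$sample_id[samples$cohort == co]
        sel <- sample(pool, min(k, length(pool)))
      } else {
        ## guarantee a spread over >= 2 cohorts
        cos <- sample(unique(samples$cohort), 2)
        n1 <- ceiling(k / 2)
        sel <- c(sample(samples$sample_id[samples$cohort == cos[1]],
                        min(n1, sum(samples$cohort == cos[1]))),
                 sample(samples$sample_id[samples$cohort == cos[2]],
                        min(k - n1, sum(samples$cohort == cos[2]))))
      }
      for (sid in sel) {
        co <- samples$cohort[samples$sample_id == sid]
        push_call(.fusion_call_row(sid, co, pr[1], pr[2], ann, faf_shape,
                                   junction_base), class = class)
      }
    }
  }
  emit_recurrent(np_pairs, "normal_panel", 8L)
  emit_recurrent(sp_pairs, "single_project", 6L, one_cohort = TRUE)
  emit_recurrent(lf_pairs, "low_faf", 8L, faf_shape = c(2, 60),
                 junction_base = 2L)
  emit_recurrent(lr_pairs, "low_recurrence", 3L)
  fusion_calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(sample_id = character(0), cohort = character(0),
               fusion_name = character(0), gene5 = character(0),
               gene3 = character(0), left_breakpoint = character(0),
               right_breakpoint = character(0), junction_reads = integer(0),
               spanning_frags = integer(0), ffpm = numeric(0),
               large_anchor = character(0), wt5_reads = integer(0),
               wt3_reads = integer(0))
  rownames(fusion_calls) <- NULL

  ## ---- motif planting ----------------------------------------------------
  n_motif <- round(spec$motif_planting_rate * length(dpsi_genes))
  motif_genes <- sort(dpsi_genes)[seq_len(n_motif)]
  for (g in motif_genes) {
    ex <- tx_exons(ann, paste0(g, ".t1"))
    chrom <- attr(ex, "chrom"); strand <- attr(ex, "strand")
    motif <- spec$planted_motif
    if (strand == "+") {
      acc <- ex$start[2]          # cassette-exon acceptor
      pos <- acc - 80L            # intron side, transcription-upstream
      substr(ann$genome[[chrom]], pos, pos + 5L) <- motif
    } else {
      acc <- ex$end[2]
      pos <- acc + 75L
      substr(ann$genome[[chrom]], pos, pos + 5L) <- reverse_complement(motif)
    }
  }

  ## ---- knowledge tables --------------------------------------------------
  known_fusions <- data.frame(
    gene_a = c("KMT2A", "KMT2A", "ETV6", "ETV6", "TCF3", "TCF3", "PAX5",
               "PAX5", "RUNX1", "TMPRSS2", "EML4", "CBFB", "BCR"),
    gene_b = c("AFF1", "MLLT3", "RUNX1", "ABL1", "PBX1", "HLF", "JAK2",
               "ZNF521", "RUNX1T1", "ERG", "ALK", "MYH11", "ABL1"),
    source = c("ALL", "blood", "ALL", "ALL", "ALL", "ALL", "ALL", "ALL",
               "blood", "solid", "solid", "blood", "ALL"),
    stringsAsFactors = FALSE)
  leukemia_genes <- c("KMT2A", "AFF1", "MLLT3", "ETV6", "RUNX1", "TCF3",
                      "PBX1", "HLF", "PAX5", "JAK2", "ZNF521", "ABL1", "BCR",
                      "IKZF1")
  normal_panel <- do.call(rbind, lapply(np_pairs, function(p)
    data.frame(gene_a = p[1], gene_b = p[2], stringsAsFactors = FALSE)))
  if (is.null(normal_panel))
    normal_panel <- data.frame(gene_a = character(0), gene_b = character(0))
  knowledge <- list(pseudogenes = .pseudogenes,
                    paralog_pairs = .paralog_pairs,
                    ig_hb_genes = .ig_hb_genes,
                    normal_panel = normal_panel,
                    known_fusions = known_fusions,
                    leukemia_genes = leukemia_genes)

  ## ---- gene sets, motif DB, PPI -------------------------------------------
  third <- ceiling(spec$n_prognostic_genes / 3)
  myc_members <- prog_genes[seq_len(min(2 * third, length(prog_genes)))]
  trans_members <- prog_genes[seq(max(1, third), length(prog_genes))]
  sf_members <- prog_genes[seq(max(1, 2 * third - 1), length(prog_genes))]
  gene_sets <- list(
    MYC_TARGETS_SYN = unique(c(myc_members, sample(bg_genes, 40))),
    GO_TRANSLATION_SYN = unique(c(trans_members, sample(bg_genes, 40))),
    SF_RBP_SYN = unique(c(sf_members, .rbp_names, sample(bg_genes, 10))))

  kmers <- .rbp_kmers
  kmers["SRRM1"] <- spec$planted_motif
  motif_db <- motif_db_from_kmers(kmers)

  hub <- "SRRM1"
  hub_sig <- prog_genes[seq_len(min(6L, length(prog_genes)))]
  hub_rbps <- .rbp_names[2:6]
  bg_prot <- sample(bg_genes, 30)
  ppi <- rbind(
    data.frame(protein1 = hub, protein2 = hub_sig,
               experimental = round(runif(length(hub_sig), 200, 800)),
               combined = round(runif(length(hub_sig), 910, 995))),
    data.frame(protein1 = hub, protein2 = hub_rbps,
               experimental = round(runif(length(hub_rbps), 200, 800)),
               combined = round(runif(length(hub_rbps), 910, 995))),
    ## decoys that must not survive the PPI filter
    data.frame(protein1 = hub,
               protein2 = c(prog_genes[min(7L, length(prog_genes))],
                            .rbp_names[7]),
               experimental = c(0, 400), combined = c(950, 850)),
    data.frame(protein1 = sample(bg_prot, 20, replace = TRUE),
               protein2 = sample(bg_prot, 20, replace = TRUE),
               experimental = round(runif(20, 0, 600)),
               combined = round(runif(20, 400, 990))))
  ppi <- ppi[ppi$protein1 != ppi$protein2, , drop = FALSE]
  rownames(ppi) <- NULL

  read_stats <- data.frame(
    sample_id = samples$sample_id,
    mapped_frac = round(runif(N, 0.55, 0.95), 3),
    mapped_reads = round(runif(N, 6e6, 1.8e7)))
  read_stats$total_reads <- round(read_stats$mapped_reads / read_stats$mapped_frac)

  ledger <- list(
    true_fusions = if (length(truth)) do.call(rbind, truth) else
      data.frame(sample_id = character(0), fusion_name = character(0),
                 group = character(0)),
    artifact_calls = if (length(artifacts)) do.call(rbind, artifacts) else
      data.frame(sample_id = character(0), fusion_name = character(0),
                 class = character(0)),
    prognostic_genes = prog_genes,
    de_genes = list(up = de_up, down = de_down,
                    contrast = "KMT2A-r_vs_ETV6-r"),
    planted_dpsi_genes = sort(dpsi_genes),
    delta_psi_planted = spec$delta_psi_planted,
    motif_genes = motif_genes,
    planted_motif = spec$planted_motif,
    high_missing_genes = high_missing,
    dropout_prone_genes = sort(dropout_prone),
    risk = data.frame(sample_id = samples$sample_id,
                      stratum = samples$risk_stratum,
                      linear_predictor = round(z, 6),
                      stringsAsFactors = FALSE),
    hub_gene = hub,
    hub_signature_partners = hub_sig,
    hub_rbp_partners = hub_rbps,
    params = list(seed = spec$seed, de_log_fc = spec$de_log_fc,
                  prognostic_log_hazard = spec$prognostic_log_hazard))
  rownames(ledger$true_fusions) <- NULL
  rownames(ledger$artifact_calls) <- NULL

  clinical <- samples[, c("sample_id", "cohort", "sex", "tissue", "age_years",
                          "relapse", "efs_time_days")]
  structure(list(spec = spec, annotation = ann, samples = samples,
                 clinical = clinical, read_stats = read_stats,
                 fusion_calls = fusion_calls, counts = counts, tpm = tpm,
                 tx2gene = data.frame(tx_id = tx_ids,
                                      gene_id = unname(tx_gene_map),
                                      stringsAsFactors = FALSE),
                 psi_true = psi, knowledge = knowledge,
                 gene_sets = gene_sets, motif_db = motif_db, ppi = ppi,
                 ledger = ledger),
            class = "ball_cohort")
}

#' @export
print.ball_cohort <- function(x, ...) {
  cat("ball_cohort:", nrow(x$samples), "samples in",
      length(unique(x$samples$cohort)), "cohorts;",
      nrow(x$annotation$genes), "genes;",
      nrow(x$fusion_calls), "fusion calls (",
      nrow(x$ledger$true_fusions), "true /",
      nrow(x$ledger$artifact_calls), "artifact)\n")
  invisible(x)
}

#' Sample quality control on mapping statistics
#'
#' Retains samples with a mapped-read fraction of at least 0.25 and at least
#' five million mapped reads. Both boundaries are inclusive ("at least"), and
#' every exclusion is logged with its reason.
#'
#' @param read_stats data.frame with columns \code{sample_id},
#'   \code{mapped_frac}, \code{mapped_reads}.
#' @param min_mapped_frac minimum mapped fraction (default 0.25).
#' @param min_mapped_reads minimum mapped reads (default 5e6).
#' @return list with \code{retained} (sample ids) and \code{log} (per-sample
#'   decision with reason).
#' @export
sample_qc <- function(read_stats, min_mapped_frac = 0.25,
                      min_mapped_reads = 5e6) {
  need <- c("sample_id", "mapped_frac", "mapped_reads")
  miss <- setdiff(need, names(read_stats))
  if (length(miss)) stop("read_stats lacks columns: ", paste(miss, collapse = ", "))
  bad <- !complete.cases(read_stats[, need])
  if (any(bad)) stop("missing mapping statistics for sample(s): ",
                     paste(read_stats$sample_id[bad], collapse = ", "))
  ok_frac <- read_stats$mapped_frac >= min_mapped_frac
  ok_reads <- read_stats$mapped_reads >= min_mapped_reads
  reason <- rep("", nrow(read_stats))
  reason[!ok_frac] <- "mapped_frac"
  reason[!ok_reads] <- ifelse(reason[!ok_reads] == "", "mapped_reads",
                              "mapped_frac;mapped_reads")
  log <- data.frame(sample_id = read_stats$sample_id,
                    retained = ok_frac & ok_reads,
                    reason = reason, stringsAsFactors = FALSE)
  list(retained = read_stats$sample_id[log$retained], log = log)
}

#' Write a generated cohort bundle to a directory of standard text formats
#'
#' Writes GTF annotation, FASTA genome, fusion calls in the STAR-Fusion
#' dialect, transcript TPM and clinical/read-stat TSVs, knowledge tables,
#' GMT gene sets, motif database files, STRING-style PPI edges and the truth
#' ledger (JSON).
#'
#' @param bundle a \code{ball_cohort}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ball_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "knowledge"), showWarnings = FALSE)
  dir.create(file.path(dir, "motifs"), showWarnings = FALSE)
  write_gtf(bundle$annotation, file.path(dir, "annotation.gtf"))
  write_genome_fasta(bundle$annotation, file.path(dir, "genome.fa"))
  write_fusion_calls(bundle$fusion_calls, file.path(dir, "fusion_calls.tsv"))
  tpm <- data.frame(transcript_id = rownames(bundle$tpm),
                    bundle$tpm, check.names = FALSE)
  write_tsv(tpm, file.path(dir, "tpm.tsv"))
  write_tsv(bundle$tx2gene, file.path(dir, "tx2gene.tsv"))
  write_tsv(bundle$clinical, file.path(dir, "clinical.tsv"))
  write_tsv(bundle$read_stats, file.path(dir, "read_stats.tsv"))
  kn <- bundle$knowledge
  write_tsv(data.frame(gene = kn$pseudogenes),
            file.path(dir, "knowledge", "pseudogenes.tsv"))
  write_tsv(kn$paralog_pairs, file.path(dir, "knowledge", "paralog_pairs.tsv"))
  write_tsv(data.frame(gene = kn$ig_hb_genes),
            file.path(dir, "knowledge", "ig_hb_genes.tsv"))
  write_tsv(kn$normal_panel, file.path(dir, "knowledge", "normal_panel.tsv"))
  write_tsv(kn$known_fusions, file.path(dir, "knowledge", "known_fusions.tsv"))
  write_tsv(data.frame(gene = kn$leukemia_genes),
            file.path(dir, "knowledge", "leukemia_genes.tsv"))
  gmt <- vapply(names(bundle$gene_sets), function(s)
    paste(c(s, "synthetic", bundle$gene_sets[[s]]), collapse = "\t"),
    character(1))
  writeLines(gmt, file.path(dir, "gene_sets.gmt"))
  write_motif_db(bundle$motif_db, file.path(dir, "motifs"))
  write_tsv(bundle$ppi, file.path(dir, "ppi.tsv"))
  write_ledger(bundle$ledger, file.path(dir, "truth_ledger.json"))
  invisible(dir)
}

#' Write / read the truth ledger
#'
#' The ledger is serialized as JSON and round-trips losslessly through
#' \code{read_ledger}.
#'
#' @param ledger ledger list from \code{\link{generate_cohort}}.
#' @param path JSON file path.
#' @return \code{write_ledger}: the path invisibly; \code{read_ledger}: the
#'   ledger list.
#' @export
write_ledger <- function(ledger, path) {
  json <- jsonlite::toJSON(ledger, dataframe = "columns", auto_unbox = TRUE,
                           digits = NA, null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  lg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (nm in c("true_fusions", "artifact_calls", "risk"))
    lg[[nm]] <- as.data.frame(lg[[nm]], stringsAsFactors = FALSE)
  lg
}
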