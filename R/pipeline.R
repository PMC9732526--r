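## ---------------------------------------------------------------------------
## Pipeline orchestration: fusions -> expression/DE -> risk -> splicing ->
## motifs -> co-occurrence, with a manifest of parameters and output hashes.
## ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' Collects the synthetic-cohort spec (or a pre-generated bundle), stage
#' parameters and stage enable flags. All stage seeds derive from the global
#' seed, so stages are individually reproducible.
#'
#' @param out_dir output directory.
#' @param seed global seed.
#' @param spec a \code{\link{cohort_spec}} (defaults to the package default
#'   conditions with the given seed).
#' @param stages character vector of stages to run (subset of simulate,
#'   fusions, expression, risk, splicing, motifs, cooccur).
#' @param min_patients,median_faf_min fusion-cascade parameters.
#' @param n_perm GSEA permutations (default 200).
#' @param n_trees,mtry,k_threshold risk-model parameters.
#' @param window,n_subsamples motif parameters.
#' @param scan_pfms scan PFMs in the motif stage (default FALSE: the 6-mer
#'   scan carries the enrichment signal at half the cost; PFM scanning is
#'   available for completeness).
#' @return a \code{ball_pipeline_config}.
#' @export
pipeline_config <- function(out_dir, seed = 1L, spec = NULL,
                            stages = c("simulate", "fusions", "expression",
                                       "risk", "splicing", "motifs",
                                       "cooccur"),
                            min_patients = 5, median_faf_min = 0.1,
                            n_perm = 200, n_trees = 400, mtry = 4,
                            k_threshold = 0.7, window = 200,
                            n_subsamples = 100, scan_pfms = FALSE) {
  spec <- spec %||% cohort_spec(seed = seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), spec = spec,
                 stages = stages, min_patients = min_patients,
                 median_faf_min = median_faf_min, n_perm = n_perm,
                 n_trees = n_trees, mtry = mtry, k_threshold = k_threshold,
                 window = window, n_subsamples = n_subsamples,
                 scan_pfms = scan_pfms),
            class = "ball_pipeline_config")
}

.hash_files <- function(paths) {
  paths <- unlist(paths, use.names = FALSE)
  h <- tools::md5sum(paths)
  setNames(as.character(h), basename(paths))
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order on a generated (or
#' supplied) cohort bundle, writing stage outputs as TSV under
#' \code{out_dir} and a manifest of parameters and output-file MD5 hashes.
#' Wall-clock timings go to a separate \code{run_log.txt} so the analytic
#' outputs and the manifest are byte-identical across reruns with the same
#' configuration.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param bundle optional pre-generated \code{ball_cohort}; when absent the
#'   simulate stage generates one from \code{config$spec}.
#' @return list with the manifest, the bundle and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(config, bundle = NULL) {
  stopifnot(inherits(config, "ball_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  results <- list()
  log_lines <- character(0)
  stage_files <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- withCallingHandlers(expr, warning = function(w) {
      log_lines <<- c(log_lines, paste0("[", name, "] warning: ",
                                        conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    log_lines <<- c(log_lines,
                    sprintf("[%s] done in %.1fs", name,
                            proc.time()[["elapsed"]] - t0))
    value
  }
  enabled <- function(s) s %in% config$stages
  out_path <- function(...) file.path(config$out_dir, ...)
  record <- function(name, params, files) {
    manifest$stages[[name]] <<- list(params = params,
                                     outputs = .hash_files(files))
    stage_files[[name]] <<- files
  }

  ## ---- simulate ----------------------------------------------------------
  if (is.null(bundle)) {
    if (!enabled("simulate"))
      stop("stage 'simulate' disabled but no bundle supplied")
    bundle <- t_stage("simulate", generate_cohort(config$spec))
    cohort_dir <- out_path("cohort")
    write_cohort(bundle, cohort_dir)
    record("simulate", list(seed = config$spec$seed),
           list.files(cohort_dir, recursive = TRUE, full.names = TRUE))
  }
  qc <- sample_qc(bundle$read_stats)
  clinical <- bundle$clinical[bundle$clinical$sample_id %in% qc$retained, ]

  ## ---- fusions -----------------------------------------------------------
  if (enabled("fusions")) {
    fus <- t_stage("fusions", fusion_cascade(
      bundle$fusion_calls, bundle$knowledge,
      min_patients = config$min_patients,
      median_faf_min = config$median_faf_min,
      all_samples = clinical$sample_id))
    results$fusions <- fus
    f_cat <- out_path("fusion_catalog.tsv")
    f_trail <- out_path("fusion_trail.tsv")
    f_onco <- out_path("oncoprint.tsv")
    write_tsv(fus$records, f_cat)
    write_tsv(fus$trail, f_trail)
    write_tsv(data.frame(group = rownames(fus$oncoprint), fus$oncoprint,
                         check.names = FALSE), f_onco)
    record("fusions", list(min_patients = config$min_patients,
                           median_faf_min = config$median_faf_min),
           list(f_cat, f_trail, f_onco))
  }

  ## ---- expression --------------------------------------------------------
  if (enabled("expression")) {
    if (is.null(results$fusions))
      stop("stage 'expression' requires the 'fusions' stage")
    expr <- t_stage("expression", {
      tx_len <- setNames(
        vapply(bundle$tx2gene$tx_id, function(tx)
          spliced_length(bundle$annotation, tx), numeric(1)),
        bundle$tx2gene$tx_id)
      lib <- setNames(bundle$read_stats$mapped_reads,
                      bundle$read_stats$sample_id)
      counts <- tpm_to_gene_counts(bundle$tpm[, clinical$sample_id],
                                   bundle$tx2gene, tx_len,
                                   lib[clinical$sample_id])
      lcpm <- logcpm(counts)
      onco <- results$fusions$oncoprint
      grp <- rep(NA_character_, nrow(clinical))
      names(grp) <- clinical$sample_id
      for (g in rownames(onco))
        grp[colnames(onco)[onco[g, ] == 1]] <- g
      sel <- !is.na(grp) & grp %in% c("KMT2A-r", "ETV6-r")
      lcpm_f <- filter_expressed(lcpm)
      de <- fit_de(lcpm_f[, clinical$sample_id[sel]],
                   factor(grp[sel], levels = c("ETV6-r", "KMT2A-r")),
                   covariates = clinical[sel, c("sex", "cohort", "tissue")])
      metric <- setNames(de$rank_metric, de$gene)
      gsea <- preranked_gsea(metric, bundle$gene_sets,
                             n_perm = config$n_perm, seed = config$seed)
      list(counts = counts, lcpm = lcpm, groups = grp, de = de, gsea = gsea)
    })
    results$expression <- expr
    f_de <- out_path("de_results.tsv")
    f_rnk <- out_path("de_ranked.rnk")
    f_gsea <- out_path("gsea.tsv")
    write_tsv(expr$de, f_de)
    write_tsv(setNames(expr$de[order(-expr$de$rank_metric),
                               c("gene", "rank_metric")],
                       c("#gene", "metric")), f_rnk)
    write_tsv(expr$gsea, f_gsea)
    record("expression", list(n_perm = config$n_perm),
           list(f_de, f_rnk, f_gsea))
  }

  ## ---- risk --------------------------------------------------------------
  if (enabled("risk")) {
    if (is.null(results$expression))
      stop("stage 'risk' requires the 'expression' stage")
    risk <- t_stage("risk", {
      lcpm <- results$expression$lcpm
      sig <- build_risk_signature(lcpm, clinical,
                                  results$expression$groups,
                                  bundle$gene_sets)
      disc <- clinical[clinical$cohort == clinical$cohort[1], ]
      expr_tr <- t(lcpm[sig$signature, disc$sample_id, drop = FALSE])
      loo <- train_and_score_loo(expr_tr, disc$relapse,
                                 n_trees = config$n_trees,
                                 mtry = config$mtry,
                                 threshold = config$k_threshold,
                                 seed = config$seed)
      ev <- evaluate_risk(loo, disc$efs_time_days, disc$relapse)
      model <- train_risk_model(expr_tr, disc$relapse,
                                n_trees = config$n_trees, mtry = config$mtry,
                                threshold = config$k_threshold,
                                seed = config$seed)
      all_scores <- apply_model(model,
                                t(lcpm[sig$signature, clinical$sample_id,
                                       drop = FALSE]))
      list(signature = sig, loo = loo, evaluation = ev, model = model,
           scores = all_scores)
    })
    results$risk <- risk
    f_sig <- out_path("signature.tsv")
    f_score <- out_path("scorecard.tsv")
    f_roc <- out_path("roc_points.tsv")
    write_tsv(data.frame(gene = risk$signature$signature), f_sig)
    write_tsv(risk$scores, f_score)
    write_tsv(risk$evaluation$roc, f_roc)
    record("risk", list(n_trees = config$n_trees, mtry = config$mtry,
                        threshold = config$k_threshold),
           list(f_sig, f_score, f_roc))
  }

  ## ---- splicing ----------------------------------------------------------
  if (enabled("splicing")) {
    if (is.null(results$risk))
      stop("stage 'splicing' requires the 'risk' stage")
    spl <- t_stage("splicing", {
      events <- generate_events(bundle$annotation)
      pq <- compute_psi(events, bundle$tpm[, clinical$sample_id])
      psi <- filter_and_impute(pq$psi)
      risk_class <- setNames(results$risk$scores$class,
                             results$risk$scores$sample_id)
      grp <- factor(risk_class[colnames(psi)], levels = c("low", "high"))
      ds <- diff_splice(psi, grp,
                        covariates = clinical[match(colnames(psi),
                                                    clinical$sample_id),
                                              c("sex", "cohort", "tissue")])
      list(events = events, psi = psi, ds = ds, groups = grp)
    })
    results$splicing <- spl
    f_ev <- out_path("events.ioe.tsv")
    f_psi <- out_path("psi.tsv")
    f_ds <- out_path("diff_splice.tsv")
    write_tsv(spl$events, f_ev)
    write_tsv(data.frame(event_id = rownames(spl$psi), spl$psi,
                         check.names = FALSE), f_psi)
    write_tsv(spl$ds, f_ds)
    record("splicing", list(), list(f_ev, f_psi, f_ds))
  }

  ## ---- motifs ------------------------------------------------------------
  if (enabled("motifs")) {
    if (is.null(results$splicing))
      stop("stage 'motifs' requires the 'splicing' stage")
    mot <- t_stage("motifs", motif_enrichment(
      results$splicing$events, results$splicing$ds,
      bundle$annotation$genome, bundle$motif_db,
      window = config$window, n_subsamples = config$n_subsamples,
      seed = config$seed, scan_pfms = config$scan_pfms))
    results$motifs <- mot
    f_enr <- out_path("motif_enrichment.tsv")
    write_tsv(mot$enrichment, f_enr)
    record("motifs", list(window = config$window,
                          n_subsamples = config$n_subsamples), list(f_enr))
  }

  ## ---- co-occurrence -----------------------------------------------------
  if (enabled("cooccur")) {
    if (is.null(results$splicing))
      stop("stage 'cooccur' requires the 'splicing' stage")
    coo <- t_stage("cooccur", {
      bin <- binarize_inclusion(results$splicing$psi)
      risk_class <- setNames(results$risk$scores$class == "high",
                             results$risk$scores$sample_id)
      onco <- results$fusions$oncoprint
      grp <- rep("none", nrow(clinical))
      names(grp) <- clinical$sample_id
      for (g in rownames(onco))
        grp[colnames(onco)[onco[g, ] == 1]] <- g
      erc <- event_risk_cooccurrence(bin, risk_class, grp)
      ppi_kept <- filter_ppi(bundle$ppi)
      if (!is.null(results$motifs)) {
        enr <- results$motifs$enrichment
        enriched_rbps <- unique(enr$rbp[enr$enriched])
        ol <- interactor_overlap(enriched_rbps,
                                 results$risk$signature$signature,
                                 bundle$ledger$hub_gene, ppi_kept)
      } else {
        log_lines <- c(log_lines,
                       "[cooccur] motif stage disabled; interactor overlap skipped")
        ol <- NULL
      }
      list(cooccur = erc, ppi = ppi_kept, overlap = ol)
    })
    results$cooccur <- coo
    f_coo <- out_path("cooccurrence.tsv")
    f_ppi <- out_path("ppi_filtered.tsv")
    write_tsv(coo$cooccur$per_group, f_coo)
    write_tsv(coo$ppi, f_ppi)
    files <- list(f_coo, f_ppi)
    if (!is.null(coo$overlap)) {
      f_ol <- out_path("interactor_overlap.tsv")
      write_tsv(coo$overlap$rbp_report, f_ol)
      files <- c(files, f_ol)
    } else {
      manifest$stages$cooccur_note <- "interactor overlap skipped (motifs disabled)"
    }
    record("cooccur", list(), files)
  }

  manifest_json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                    pretty = TRUE)
  writeLines(manifest_json, out_path("manifest.json"))
  writeLines(log_lines, out_path("run_log.txt"))
  list(manifest = manifest, bundle = bundle, results = results)
}
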