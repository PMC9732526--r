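## ---------------------------------------------------------------------------
## Relapse-risk gene signature: two-contrast gate, per-gene Cox filter,
## cross-cohort variability filter, random-forest k-score with leave-one-out
## evaluation and survival-based validation.
## ---------------------------------------------------------------------------

#' Mean-expression log fold-change between two sample groups
#' @param lcpm genes x samples logCPM matrix.
#' @param samples_a,samples_b column ids of the two groups.
#' @return named numeric vector (mean A - mean B per gene).
#' @export
mean_logfc <- function(lcpm, samples_a, samples_b) {
  rowMeans(lcpm[, samples_a, drop = FALSE]) -
    rowMeans(lcpm[, samples_b, drop = FALSE])
}

#' Candidate gene gate
#'
#' Keeps genes with log fold-change above \code{lfc_min} in both contrasts
#' (relapse vs non-relapse, and KMT2A-r vs ETV6-r) that belong to at least
#' one of the configured gene sets (MYC targets, translation, splicing
#' factors / RBPs).
#'
#' @param logfc_relapse,logfc_fusion named per-gene log fold-changes.
#' @param gene_sets list of gene sets.
#' @param lfc_min threshold on both contrasts (default 0.5, strict).
#' @return character vector of candidate genes.
#' @export
select_candidates <- function(logfc_relapse, logfc_fusion, gene_sets,
                              lfc_min = 0.5) {
  genes <- intersect(names(logfc_relapse), names(logfc_fusion))
  in_set <- genes %in% unique(unlist(gene_sets))
  keep <- logfc_relapse[genes] > lfc_min & logfc_fusion[genes] > lfc_min &
    in_set
  out <- genes[keep]
  if (!length(out))
    stop("no candidate genes pass the two-contrast gate; ",
         "check effect sizes / generator settings")
  out
}

#' Per-gene Cox proportional-hazards filter
#'
#' For each candidate gene, fits event-free survival (event = first relapse)
#' on the gene's expression adjusted by age and sex (Efron tie handling) and
#' keeps genes with a Wald p-value below \code{alpha} on the expression
#' coefficient. Genes with non-convergent or non-identifiable fits are
#' flagged and excluded.
#'
#' @param candidates gene ids.
#' @param lcpm genes x samples logCPM.
#' @param clinical data.frame with sample_id, age_years, sex,
#'   efs_time_days, relapse.
#' @param alpha Wald significance level (default 0.05).
#' @return data.frame: gene, coef, hr, p, keep, note.
#' @export
cox_filter <- function(candidates, lcpm, clinical, alpha = 0.05) {
  stopifnot(all(clinical$sample_id %in% colnames(lcpm)))
  if (sum(clinical$relapse) == 0) stop("no relapse events in the cohort")
  surv <- survival::Surv(clinical$efs_time_days, clinical$relapse)
  age <- clinical$age_years
  sex <- as.factor(clinical$sex)
  res <- lapply(candidates, function(g) {
    x <- lcpm[g, clinical$sample_id]
    if (sd(x) == 0)
      return(data.frame(gene = g, coef = NA_real_, hr = NA_real_,
                        p = NA_real_, keep = FALSE,
                        note = "non-identifiable: constant expression"))
    fit <- tryCatch(
      survival::coxph(surv ~ x + age + sex, ties = "efron"),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(survival::coxph(surv ~ x + age + sex,
                                         ties = "efron"))
      })
    if (is.null(fit) || is.na(coef(fit)["x"]))
      return(data.frame(gene = g, coef = NA_real_, hr = NA_real_,
                        p = NA_real_, keep = FALSE,
                        note = "non-convergent fit"))
    sm <- summary(fit)
    p <- sm$coefficients["x", "Pr(>|z|)"]
    data.frame(gene = g, coef = unname(coef(fit)["x"]),
               hr = unname(exp(coef(fit)["x"])), p = unname(p),
               keep = !is.na(p) && p < alpha, note = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cross-cohort variability filter
#'
#' Removes genes whose cohort-mean logCPM values differ by more than
#' \code{max_logfc} between any two cohorts (dataset-driven instability).
#'
#' @param genes gene ids.
#' @param lcpm genes x samples logCPM.
#' @param cohort per-sample cohort labels aligned with columns.
#' @param max_logfc maximum allowed pairwise difference (default 3, strict).
#' @return data.frame: gene, max_diff, keep.
#' @export
variability_filter <- function(genes, lcpm, cohort, max_logfc = 3) {
  cohort <- as.factor(cohort)
  if (nlevels(cohort) < 2) stop("need at least two cohorts")
  out <- lapply(genes, function(g) {
    mns <- tapply(lcpm[g, ], cohort, mean)
    d <- max(mns) - min(mns)
    data.frame(gene = g, max_diff = unname(d), keep = d <= max_logfc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Train the k-score random-forest risk model
#'
#' A 400-tree random forest with four candidate variables per split,
#' trained on signature-gene expression against relapse labels. The k-score
#' of a sample is the fraction of trees voting relapse.
#'
#' @param expr samples x genes matrix (signature genes only).
#' @param labels binary relapse labels (0/1).
#' @param n_trees number of trees (default 400).
#' @param mtry candidate variables per split (default 4, capped at the
#'   number of genes).
#' @param threshold high-risk k-score threshold (default 0.7).
#' @param seed integer seed.
#' @return an object of class \code{ball_risk_model}.
#' @export
train_risk_model <- function(expr, labels, n_trees = 400, mtry = 4,
                             threshold = 0.7, seed = 1L) {
  y <- factor(labels, levels = c(0, 1))
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  set.seed(derive_seed(seed, "risk"))
  forest <- randomForest::randomForest(
    x = as.data.frame(expr), y = y, ntree = n_trees,
    mtry = min(mtry, ncol(expr)))
  structure(list(forest = forest, genes = colnames(expr),
                 threshold = threshold,
                 train_means = colMeans(expr),
                 n_trees = n_trees, mtry = min(mtry, ncol(expr)),
                 seed = seed, version = "1"),
            class = "ball_risk_model")
}

#' Leave-one-out k-scores
#'
#' For every sample, trains a fresh seeded forest on the remaining samples
#' and records the held-out sample's k-score (fraction of trees voting
#' relapse) and its class at the decision threshold.
#'
#' @param expr samples x genes matrix.
#' @param labels binary relapse labels aligned with rows.
#' @param n_trees,mtry,threshold,seed as in \code{\link{train_risk_model}}.
#' @return data.frame scorecard: sample_id, k_score, class, label.
#' @export
train_and_score_loo <- function(expr, labels, n_trees = 400, mtry = 4,
                                threshold = 0.7, seed = 1L) {
  n <- nrow(expr)
  if (n < 20) stop("leave-one-out evaluation needs at least 20 samples")
  y <- factor(labels, levels = c(0, 1))
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  base_seed <- derive_seed(seed, "risk")
  k <- numeric(n)
  for (i in seq_len(n)) {
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) < 2) stop("single-class training fold at sample ", i)
    set.seed((base_seed + i) %% 2147483647)
    forest <- randomForest::randomForest(
      x = as.data.frame(expr[-i, , drop = FALSE]), y = y[-i],
      ntree = n_trees, mtry = min(mtry, ncol(expr)))
    votes <- predict(forest, as.data.frame(expr[i, , drop = FALSE]),
                     type = "vote", norm.votes = TRUE)
    k[i] <- votes[, "1"]
  }
  data.frame(sample_id = rownames(expr) %||% as.character(seq_len(n)),
             k_score = k,
             class = ifelse(k >= threshold, "high", "low"),
             label = as.integer(as.character(y)),
             stringsAsFactors = FALSE)
}

#' Apply a trained risk model to new expression data
#'
#' Scores new samples with the stored forest. Up to 10\% of signature genes
#' may be absent from the new matrix (they are mean-imputed from training
#' with a warning); more is an error.
#'
#' @param model a \code{ball_risk_model}.
#' @param expr samples x genes matrix (same normalization recipe as
#'   training).
#' @return scorecard data.frame: sample_id, k_score, class.
#' @export
apply_model <- function(model, expr) {
  stopifnot(inherits(model, "ball_risk_model"))
  if (nrow(expr) == 0 || ncol(expr) == 0) stop("empty expression matrix")
  missing <- setdiff(model$genes, colnames(expr))
  if (length(missing) > 0.1 * length(model$genes))
    stop(sprintf("%d of %d signature genes missing from the matrix",
                 length(missing), length(model$genes)))
  if (length(missing)) {
    warning("mean-imputing ", length(missing), " missing signature gene(s): ",
            paste(missing, collapse = ", "))
    fill <- matrix(rep(model$train_means[missing], each = nrow(expr)),
                   nrow = nrow(expr),
                   dimnames = list(rownames(expr), missing))
    expr <- cbind(expr, fill)
  }
  expr <- expr[, model$genes, drop = FALSE]
  votes <- predict(model$forest, as.data.frame(expr), type = "vote",
                   norm.votes = TRUE)
  k <- votes[, "1"]
  data.frame(sample_id = rownames(expr) %||% as.character(seq_len(nrow(expr))),
             k_score = unname(k),
             class = ifelse(k >= model$threshold, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Evaluate a risk scorecard
#'
#' Computes the ROC curve and rank-based AUC of the k-score against relapse,
#' Kaplan-Meier curves per risk class and the two-group log-rank test at the
#' decision threshold.
#'
#' @param scorecard data.frame with k_score, class and label columns.
#' @param time,event event-free survival time and relapse indicator aligned
#'   with the scorecard (optional; omit to skip the survival part).
#' @return list with \code{auc}, \code{roc} (points), \code{accuracy} at the
#'   threshold, and (when survival data are given and both classes are
#'   non-empty) \code{km} (survfit) and \code{logrank} (chisq, df, p).
#' @export
evaluate_risk <- function(scorecard, time = NULL, event = NULL) {
  auc <- rank_auc(scorecard$k_score, scorecard$label)
  ths <- sort(unique(c(0, scorecard$k_score, 1)), decreasing = TRUE)
  roc <- t(vapply(ths, function(t) {
    pred <- scorecard$k_score >= t
    c(threshold = t,
      tpr = sum(pred & scorecard$label == 1) / max(1, sum(scorecard$label == 1)),
      fpr = sum(pred & scorecard$label == 0) / max(1, sum(scorecard$label == 0)))
  }, numeric(3)))
  acc <- mean((scorecard$class == "high") == (scorecard$label == 1))
  out <- list(auc = auc, roc = as.data.frame(roc), accuracy = acc)
  if (!is.null(time) && !is.null(event)) {
    cls <- factor(scorecard$class, levels = c("low", "high"))
    if (any(table(cls) == 0)) {
      warning("one risk class is empty; Kaplan-Meier/log-rank skipped")
    } else {
      surv <- survival::Surv(time, event)
      out$km <- survival::survfit(surv ~ cls)
      lr <- survival::survdiff(surv ~ cls)
      out$logrank <- list(chisq = unname(lr$chisq),
                          df = length(lr$n) - 1,
                          p = pchisq(lr$chisq, length(lr$n) - 1,
                                     lower.tail = FALSE))
    }
  }
  out
}

#' Build the full risk signature from cohort data
#'
#' Runs the complete signature-construction cascade: two-contrast gate
#' (relapse vs non-relapse in the discovery cohort; KMT2A-r vs ETV6-r in the
#' remaining cohorts), gene-set membership, per-gene Cox Wald filter on the
#' discovery cohort, and the cross-cohort variability filter.
#'
#' @param lcpm genes x samples logCPM (all cohorts).
#' @param clinical clinical table with sample_id, cohort, sex, age_years,
#'   relapse, efs_time_days.
#' @param fusion_groups named vector sample_id -> fusion group label (from
#'   the fusion cascade; samples without a group are absent or "none").
#' @param gene_sets list of the three candidate gene sets.
#' @param discovery_cohort cohort used for the relapse contrast and the Cox
#'   filter (default: first cohort level).
#' @param lfc_min two-contrast gate threshold (default 0.5).
#' @param cox_alpha Cox Wald threshold (default 0.05).
#' @param max_logfc variability threshold (default 3).
#' @return list with \code{signature} (gene ids), \code{candidates},
#'   \code{cox} and \code{variability} tables.
#' @export
build_risk_signature <- function(lcpm, clinical, fusion_groups, gene_sets,
                                 discovery_cohort = NULL, lfc_min = 0.5,
                                 cox_alpha = 0.05, max_logfc = 3) {
  discovery_cohort <- discovery_cohort %||% clinical$cohort[1]
  disc <- clinical[clinical$cohort == discovery_cohort, ]
  rel <- disc$sample_id[disc$relapse == 1]
  nonrel <- disc$sample_id[disc$relapse == 0]
  if (!length(rel) || !length(nonrel))
    stop("discovery cohort must contain relapse and non-relapse samples")
  logfc_relapse <- mean_logfc(lcpm, rel, nonrel)
  other <- clinical[clinical$cohort != discovery_cohort, ]
  kmt <- other$sample_id[fusion_groups[other$sample_id] %in% "KMT2A-r"]
  etv <- other$sample_id[fusion_groups[other$sample_id] %in% "ETV6-r"]
  if (!length(kmt) || !length(etv))
    stop("fusion contrast groups (KMT2A-r / ETV6-r) are empty")
  logfc_fusion <- mean_logfc(lcpm, kmt, etv)
  candidates <- select_candidates(logfc_relapse, logfc_fusion, gene_sets,
                                  lfc_min)
  cox <- cox_filter(candidates, lcpm, disc, cox_alpha)
  surv_genes <- cox$gene[cox$keep]
  if (!length(surv_genes)) stop("no genes pass the Cox filter")
  vf <- variability_filter(surv_genes, lcpm[, clinical$sample_id, drop = FALSE],
                           clinical$cohort, max_logfc)
  list(signature = vf$gene[vf$keep], candidates = candidates, cox = cox,
       variability = vf,
       logfc_relapse = logfc_relapse, logfc_fusion = logfc_fusion)
}
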