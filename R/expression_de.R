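## ---------------------------------------------------------------------------
## Expression: transcript TPM -> gene counts, TMM/logCPM, covariate-adjusted
## differential expression.
## ---------------------------------------------------------------------------

#' Convert transcript TPM to gene-level pseudo-counts
#'
#' Per sample, each transcript receives a pseudo-count proportional to
#' TPM x transcript length, scaled so the column total equals the sample's
#' library size; gene counts are sums over the gene's transcripts. This is
#' the standard abundance-to-count conversion used ahead of count-based DE
#' models.
#'
#' @param tpm transcripts x samples TPM matrix (rownames = transcript ids).
#' @param tx2gene data.frame with columns \code{tx_id}, \code{gene_id}.
#' @param tx_lengths named numeric vector of transcript lengths.
#' @param lib_sizes named numeric vector of per-sample library sizes.
#' @return genes x samples matrix of pseudo-counts; column sums equal
#'   \code{lib_sizes}.
#' @export
tpm_to_gene_counts <- function(tpm, tx2gene, tx_lengths, lib_sizes) {
  unknown <- setdiff(rownames(tpm), tx2gene$tx_id)
  if (length(unknown))
    stop("unknown transcript id(s): ", paste(head(unknown, 5), collapse = ", "))
  if (!all(rownames(tpm) %in% names(tx_lengths)))
    stop("transcript lengths missing for some transcripts")
  len <- tx_lengths[rownames(tpm)]
  if (any(len <= 0)) stop("transcript lengths must be positive")
  ls <- lib_sizes[colnames(tpm)]
  if (any(is.na(ls))) stop("library sizes missing for some samples")
  w <- tpm * len
  pseudo <- sweep(w, 2, colSums(w), "/")
  pseudo <- sweep(pseudo, 2, ls, "*")
  gene <- tx2gene$gene_id[match(rownames(tpm), tx2gene$tx_id)]
  rowsum(pseudo, group = gene)
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values factors correcting for RNA composition,
#' rescaled to geometric mean 1 (computed with edgeR's reference
#' implementation: reference sample by upper-quartile closest to the mean,
#' 30\% M / 5\% A trimming).
#'
#' @param counts genes x samples count matrix.
#' @return named numeric vector of normalization factors.
#' @export
tmm_normalize <- function(counts) {
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(colnames(counts)[zero], collapse = ", "))
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  setNames(as.numeric(f), colnames(counts))
}

#' log2 counts per million
#'
#' @param counts genes x samples counts.
#' @param norm_factors TMM factors (default: computed).
#' @param prior_count prior count for the log transform (default 0.5).
#' @return genes x samples logCPM matrix.
#' @export
logcpm <- function(counts, norm_factors = NULL, prior_count = 0.5) {
  dge <- edgeR::DGEList(counts = counts)
  dge$samples$norm.factors <- norm_factors %||% tmm_normalize(counts)
  edgeR::cpm(dge, log = TRUE, prior.count = prior_count)
}

#' Filter genes on mean logCPM
#' @param lcpm logCPM matrix.
#' @param min_mean minimum mean logCPM (default 0).
#' @return filtered matrix.
#' @export
filter_expressed <- function(lcpm, min_mean = 0) {
  lcpm[rowMeans(lcpm) >= min_mean, , drop = FALSE]
}

#' Covariate-adjusted differential expression on logCPM
#'
#' Fits a per-gene linear model of logCPM on the two-level group plus
#' covariates (typically sex, project and tissue), with optional
#' empirical-Bayes variance moderation (limma). The group coefficient is the
#' log2 fold-change of \code{levels(group)[2]} over \code{levels(group)[1]}.
#'
#' @param lcpm genes x samples logCPM matrix (pre-filtered at mean
#'   logCPM >= 0).
#' @param group two-level factor aligned with columns.
#' @param covariates data.frame of covariates, or NULL.
#' @param moderated use empirical-Bayes moderated t (default TRUE).
#' @param fdr_max,lfc_min significance thresholds (defaults 0.01 and 1).
#' @return data.frame: gene, logfc, mean_logcpm, p, fdr, rank_metric
#'   (\eqn{-\log_{10}(p)\cdot\log_2FC}), significant.
#' @export
fit_de <- function(lcpm, group, covariates = NULL, moderated = TRUE,
                   fdr_max = 0.01, lfc_min = 1) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (any(table(group) == 0)) stop("both contrast groups must be non-empty")
  dat <- data.frame(group = group)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0)
    dat <- cbind(dat, as.data.frame(covariates))
  design <- model.matrix(~ ., data = dat)
  if (qr(design)$rank < ncol(design)) {
    keep <- qr(design)$pivot[seq_len(qr(design)$rank)]
    aliased <- colnames(design)[setdiff(seq_len(ncol(design)), keep)]
    stop("confounded design: coefficient(s) aliased with the group term: ",
         paste(aliased, collapse = ", "))
  }
  fit <- limma::lmFit(lcpm, design)
  coef_name <- colnames(design)[2]
  if (moderated) {
    fit <- limma::eBayes(fit)
    p <- fit$p.value[, coef_name]
  } else {
    tstat <- fit$coefficients[, coef_name] /
      (fit$stdev.unscaled[, coef_name] * fit$sigma)
    p <- 2 * pt(-abs(tstat), df = fit$df.residual)
  }
  logfc <- fit$coefficients[, coef_name]
  fdr <- p.adjust(p, method = "BH")
  data.frame(gene = rownames(lcpm), logfc = unname(logfc),
             mean_logcpm = unname(fit$Amean), p = unname(p),
             fdr = unname(fdr),
             rank_metric = unname(-log10(p) * logfc),
             significant = unname(fdr < fdr_max & abs(logfc) > lfc_min),
             stringsAsFactors = FALSE)
}
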