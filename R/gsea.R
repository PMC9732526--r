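## ---------------------------------------------------------------------------
## Pre-ranked gene-set enrichment: weighted Kolmogorov-Smirnov running sum
## with a gene-label permutation null.
## ---------------------------------------------------------------------------

#' Enrichment score of one gene set on a ranked metric
#'
#' Genes are sorted by decreasing metric; walking down the list, hits
#' increment the running sum proportionally to \eqn{|r|^w} (normalized over
#' the set) and misses decrement it uniformly. The enrichment score is the
#' signed extremum of the running sum. With the set equal to the whole
#' universe the score is defined as 0.
#'
#' @param metric named numeric vector (the ranking metric).
#' @param set character vector of set members (intersected with the
#'   universe).
#' @param weight exponent w on \eqn{|r|} (default 1; 0 gives the unweighted
#'   classic statistic).
#' @return the enrichment score in [-1, 1].
#' @export
gsea_es <- function(metric, set, weight = 1) {
  ord <- order(metric, decreasing = TRUE)
  genes <- names(metric)[ord]
  r <- metric[ord]
  hit <- genes %in% set
  m <- sum(hit)
  n <- length(genes)
  if (m == 0 || m == n) return(0)
  wts <- abs(r)^weight
  denom <- sum(wts[hit])
  inc <- ifelse(hit, if (denom > 0) wts / denom else 1 / m, -1 / (n - m))
  if (denom == 0) inc[hit] <- 1 / m
  running <- cumsum(inc)
  running[which.max(abs(running))]
}

#' Pre-ranked gene-set enrichment with a permutation null
#'
#' Computes the enrichment score per set and a gene-label permutation null
#' (random sets of the same size), from which normalized scores (ES divided
#' by the mean absolute null ES of the same sign), permutation p-values and
#' a same-sign pooled FDR are derived.
#'
#' @param metric named numeric vector; must be finite for all genes.
#' @param gene_sets named list of character vectors.
#' @param n_perm permutations (default 1000).
#' @param weight weighting exponent (default 1).
#' @param seed integer seed for the permutation null.
#' @return data.frame: set, size, es, nes, p, fdr.
#' @export
preranked_gsea <- function(metric, gene_sets, n_perm = 1000, weight = 1,
                           seed = 1L) {
  if (any(!is.finite(metric))) stop("ranking metric must be finite")
  universe <- names(metric)
  sizes <- vapply(gene_sets, function(s) length(intersect(s, universe)),
                  integer(1))
  empty <- sizes == 0
  if (any(empty)) {
    warning("skipping empty set(s): ",
            paste(names(gene_sets)[empty], collapse = ", "))
    gene_sets <- gene_sets[!empty]
    sizes <- sizes[!empty]
  }
  if (!length(gene_sets))
    return(data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p = numeric(0), fdr = numeric(0)))
  es <- vapply(gene_sets, function(s) gsea_es(metric, s, weight), numeric(1))
  set.seed(derive_seed(seed, "gsea"))
  null_es <- lapply(unique(sizes), function(sz) {
    vapply(seq_len(n_perm), function(i)
      gsea_es(metric, sample(universe, sz), weight), numeric(1))
  })
  names(null_es) <- as.character(unique(sizes))
  norm_one <- function(e, null) {
    same <- null[sign(null) == sign(e) & null != 0]
    if (!length(same) || e == 0) return(c(nes = 0, p = 1))
    nes <- e / mean(abs(same))
    p <- (1 + sum(abs(same) >= abs(e))) / (1 + length(same))
    c(nes = nes, p = p)
  }
  stats <- t(vapply(seq_along(es), function(i)
    norm_one(es[i], null_es[[as.character(sizes[i])]]),
    c(nes = 0, p = 0)))
  nes <- stats[, "nes"]
  ## same-sign pooled FDR (GSEA-style): fraction of pooled null NES at least
  ## as extreme, relative to the fraction of observed NES at least as extreme
  null_nes <- unlist(lapply(seq_along(es), function(i) {
    null <- null_es[[as.character(sizes[i])]]
    same <- null[sign(null) == sign(es[i]) & null != 0]
    if (!length(same)) return(numeric(0))
    same / mean(abs(same))
  }))
  fdr <- vapply(seq_along(nes), function(i) {
    if (nes[i] == 0) return(1)
    null_frac <- mean(abs(null_nes[sign(null_nes) == sign(nes[i])]) >=
                        abs(nes[i]))
    obs_same <- nes[sign(nes) == sign(nes[i])]
    obs_frac <- mean(abs(obs_same) >= abs(nes[i]))
    if (is.nan(null_frac)) return(1)
    min(1, null_frac / max(obs_frac, 1e-12))
  }, numeric(1))
  data.frame(set = names(gene_sets), size = sizes, es = unname(es),
             nes = unname(nes), p = unname(stats[, "p"]), fdr = unname(fdr),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a GMT gene-set file
#' @param path GMT file (set name, description, members per line).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}
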