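## ---------------------------------------------------------------------------
## Probabilistic co-occurrence testing (exact, fixed-marginal hypergeometric
## model) and STRING-style PPI edge filtering.
## ---------------------------------------------------------------------------

#' Exact probabilistic co-occurrence test
#'
#' Under fixed marginals and random placement, the number of samples where
#' two binary traits co-occur follows the hypergeometric distribution
#' \eqn{P(j) = C(m_A, j) C(N - m_A, m_B - j) / C(N, m_B)}. The test reports
#' the exact probabilities of observing as few (\code{p_lt}) or as many
#' (\code{p_gt}) co-occurrences as seen; a pair is called positively
#' associated when \code{p_gt < alpha} and negatively (mutually exclusive)
#' when \code{p_lt < alpha}.
#'
#' @param a,b binary/logical vectors over the same samples.
#' @param alpha significance level for the call (default 0.05).
#' @return list: n, m_a, m_b, j (observed co-occurrences), expected,
#'   p_lt, p_gt, call ("positive"/"negative"/"random").
#' @export
cooccur_test <- function(a, b, alpha = 0.05) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop("vectors must have equal length")
  n <- length(a)
  if (n < 1) stop("need at least one sample")
  m_a <- sum(a); m_b <- sum(b)
  if (m_a > n || m_b > n) stop("marginal exceeds the number of samples")
  j <- sum(a & b)
  expected <- m_a * m_b / n
  ## X ~ Hypergeometric(white = m_a, black = n - m_a, drawn = m_b)
  p_lt <- phyper(j, m_a, n - m_a, m_b)
  p_gt <- phyper(j - 1, m_a, n - m_a, m_b, lower.tail = FALSE)
  call <- if (p_gt < alpha) "positive" else if (p_lt < alpha) "negative"
          else "random"
  list(n = n, m_a = m_a, m_b = m_b, j = j, expected = expected,
       p_lt = p_lt, p_gt = p_gt, call = call)
}

#' Event/high-risk co-occurrence within fusion groups
#'
#' Within each fusion group's samples, tests every binarized splicing event
#' for co-occurrence with the high-risk label, BH-corrects across events
#' within the group, and summarizes the recurrence of significant events
#' across groups.
#'
#' @param event_bin events x samples binary inclusion matrix.
#' @param risk_high named logical vector (sample -> high risk).
#' @param groups named vector sample -> fusion-group label.
#' @param alpha FDR threshold within group (default 0.05).
#' @param min_samples minimum samples per group (default 5); smaller groups
#'   are skipped with a warning.
#' @return list with \code{per_group} (data.frame event_id, group, j,
#'   expected, p_gt, fdr, significant) and \code{recurrence} (table of
#'   significant events across groups).
#' @export
event_risk_cooccurrence <- function(event_bin, risk_high, groups,
                                    alpha = 0.05, min_samples = 5) {
  res <- list()
  for (g in unique(groups)) {
    ids <- intersect(names(groups)[groups == g], colnames(event_bin))
    if (length(ids) < min_samples) {
      warning("fusion group ", g, " has fewer than ", min_samples,
              " samples; skipped")
      next
    }
    hr <- risk_high[ids]
    if (all(hr) || all(!hr)) {
      warning("fusion group ", g, " has no risk contrast; skipped")
      next
    }
    rows <- lapply(rownames(event_bin), function(ev) {
      ct <- cooccur_test(event_bin[ev, ids], hr)
      data.frame(event_id = ev, group = g, j = ct$j,
                 expected = ct$expected, p_gt = ct$p_gt,
                 stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    d$fdr <- p.adjust(d$p_gt, method = "BH")
    d$significant <- d$fdr < alpha
    res[[g]] <- d
  }
  per_group <- if (length(res)) do.call(rbind, res) else
    data.frame(event_id = character(0), group = character(0), j = integer(0),
               expected = numeric(0), p_gt = numeric(0), fdr = numeric(0),
               significant = logical(0))
  rownames(per_group) <- NULL
  sig <- per_group[per_group$significant, , drop = FALSE]
  recurrence <- if (nrow(sig)) table(sig$event_id) else table(character(0))
  list(per_group = per_group, recurrence = recurrence)
}

#' Filter STRING-style PPI edges
#'
#' Retains edges with a non-zero experimental subscore and a combined score
#' strictly above 900 (0-1000 scale). Idempotent.
#'
#' @param edges data.frame: protein1, protein2, experimental, combined.
#' @param min_combined combined-score threshold (default 900, strict).
#' @return filtered edge data.frame.
#' @export
filter_ppi <- function(edges, min_combined = 900) {
  bad <- edges$experimental < 0 | edges$experimental > 1000 |
    edges$combined < 0 | edges$combined > 1000
  if (any(bad))
    stop("PPI score out of the 0-1000 range at row ", which(bad)[1])
  edges[edges$experimental > 0 & edges$combined > min_combined, ,
        drop = FALSE]
}

#' Overlap of enriched-motif RBPs with a hub's PPI neighborhood
#'
#' For each RBP with motif enrichment, reports whether it is a direct PPI
#' neighbor of the hub splicing factor and of any signature gene, plus the
#' hub's signature-gene neighbors.
#'
#' @param enriched_rbps RBP names with enriched motifs.
#' @param signature_genes risk-signature gene ids.
#' @param hub_gene the hub RBP (e.g. SRRM1).
#' @param edges filtered PPI edges.
#' @return list with \code{rbp_report} (rbp, hub_neighbor,
#'   signature_neighbor, signature_member), \code{hub_signature_neighbors}
#'   and \code{counts}.
#' @export
interactor_overlap <- function(enriched_rbps, signature_genes, hub_gene,
                               edges) {
  neighbors <- function(g) {
    unique(c(edges$protein2[edges$protein1 == g],
             edges$protein1[edges$protein2 == g]))
  }
  hub_nb <- neighbors(hub_gene)
  if (!length(hub_nb) && nrow(edges) > 0 &&
      !hub_gene %in% c(edges$protein1, edges$protein2))
    warning("hub gene ", hub_gene, " absent from the PPI graph")
  rbp_report <- do.call(rbind, lapply(enriched_rbps, function(r) {
    nb <- neighbors(r)
    data.frame(rbp = r,
               hub_neighbor = r %in% hub_nb,
               signature_neighbor = length(intersect(nb, signature_genes)) > 0,
               signature_member = r %in% signature_genes,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rbp_report))
    rbp_report <- data.frame(rbp = character(0), hub_neighbor = logical(0),
                             signature_neighbor = logical(0),
                             signature_member = logical(0))
  hub_sig <- intersect(hub_nb, signature_genes)
  list(rbp_report = rbp_report,
       hub_signature_neighbors = hub_sig,
       counts = c(n_enriched_rbps = nrow(rbp_report),
                  n_hub_neighbors = sum(rbp_report$hub_neighbor),
                  n_hub_signature_neighbors = length(hub_sig)))
}
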