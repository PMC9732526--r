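## ---------------------------------------------------------------------------
## Alternative splicing: event generation from annotation (7 classic types),
## PSI from transcript TPM, missingness filtering + KNN imputation, and the
## logit-linear differential splicing model.
## ---------------------------------------------------------------------------

.tx_exon_table <- function(ann, tx) {
  ex <- ann$exons[ann$exons$tx_id == tx, c("start", "end")]
  ex[order(ex$start), , drop = FALSE]
}

.tx_junctions <- function(ex) {
  if (nrow(ex) < 2) return(matrix(numeric(0), ncol = 2))
  cbind(ex$end[-nrow(ex)], ex$start[-1])
}

.has_junction <- function(jn, d, a) {
  nrow(jn) > 0 && any(jn[, 1] == d & jn[, 2] == a)
}

.has_exon <- function(ex, s, e) any(ex$start == s & ex$end == e)

#' Generate alternative-splicing events from an annotation
#'
#' Enumerates the seven classic event types (SE, A3, A5, AF, AL, MX, RI) by
#' pairwise transcript comparison within each gene, using coordinate
#' signatures; events are deduplicated by signature. Inclusion/total
#' transcript sets are determined over all transcripts of the gene by the
#' presence of the event-defining junctions/exons.
#'
#' @param ann a \code{ball_annotation}.
#' @return data.frame: event_id, gene_id, type, chrom, strand,
#'   inclusion_tx, total_tx (comma-separated), span_start, span_end, coding.
#' @export
generate_events <- function(ann) {
  out <- list()
  genes <- unique(ann$transcripts$gene_id)
  for (g in genes) {
    txs <- ann$transcripts$tx_id[ann$transcripts$gene_id == g]
    if (length(txs) < 2) next
    strand <- gene_strand(ann, g)
    chrom <- ann$genes$chrom[match(g, ann$genes$gene_id)]
    ex_list <- lapply(txs, function(tx) .tx_exon_table(ann, tx))
    names(ex_list) <- txs
    bad <- vapply(ex_list, function(ex)
      nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]), logical(1))
    if (any(bad)) {
      warning("gene ", g, " has transcripts with overlapping exons; skipped")
      next
    }
    jn_list <- lapply(ex_list, .tx_junctions)
    evs <- list()
    add_event <- function(type, sig_coords, incl_pred, excl_pred, span) {
      incl <- txs[vapply(txs, incl_pred, logical(1))]
      excl <- txs[vapply(txs, excl_pred, logical(1))]
      if (!length(incl) || !length(excl)) return(invisible())
      sig <- sprintf("%s;%s:%s:%s:%s", g, type, chrom, sig_coords, strand)
      evs[[sig]] <<- list(type = type, incl = sort(incl),
                          total = sort(union(incl, excl)), span = span)
    }
    for (ia in seq_along(txs)) for (ib in seq_along(txs)) {
      if (ia == ib) next
      A <- ex_list[[ia]]; B <- ex_list[[ib]]
      jA <- jn_list[[ia]]; jB <- jn_list[[ib]]
      ## --- SE: cassette exon in A skipped by a junction in B
      if (nrow(A) >= 3) for (k in 2:(nrow(A) - 1)) {
        s <- A$start[k]; e <- A$end[k]
        p <- A$end[k - 1]; q <- A$start[k + 1]
        if (.has_junction(jB, p, q)) {
          add_event("SE", sprintf("%d-%d:%d-%d", p, s, e, q),
                    function(t) .has_junction(jn_list[[t]], p, s) &&
                      .has_junction(jn_list[[t]], e, q),
                    function(t) .has_junction(jn_list[[t]], p, q),
                    c(p, q))
        }
      }
      ## --- RI: A retains the intron between two consecutive exons of B
      if (nrow(B) >= 2) for (k in seq_len(nrow(B) - 1)) {
        s <- B$start[k]; m1 <- B$end[k]; m2 <- B$start[k + 1]; e <- B$end[k + 1]
        if (.has_exon(A, s, e)) {
          add_event("RI", sprintf("%d:%d-%d:%d", s, m1, m2, e),
                    function(t) .has_exon(ex_list[[t]], s, e),
                    function(t) .has_junction(jn_list[[t]], m1, m2),
                    c(s, e))
        }
      }
      ## --- A3/A5: junction pairs sharing one boundary
      if (nrow(jA) > 0 && nrow(jB) > 0) {
        for (r in seq_len(nrow(jA))) for (t2 in seq_len(nrow(jB))) {
          d1 <- jA[r, 1]; a1 <- jA[r, 2]
          d2 <- jB[t2, 1]; a2 <- jB[t2, 2]
          if (d1 == d2 && a1 != a2) {
            ## variable acceptor must open exons sharing their end
            endA <- A$end[A$start == a1][1]
            endB <- B$end[B$start == a2][1]
            if (!is.na(endA) && !is.na(endB) && endA == endB) {
              type <- if (strand == "+") "A3" else "A5"
              lo <- min(a1, a2); hi <- max(a1, a2)
              ## inclusion: the longer-exon (proximal splice site) form
              add_event(type, sprintf("%d-%d:%d-%d", d1, lo, d1, hi),
                        function(t) .has_junction(jn_list[[t]], d1, lo),
                        function(t) .has_junction(jn_list[[t]], d1, hi),
                        c(d1, hi))
            }
          }
          if (a1 == a2 && d1 != d2) {
            startA <- A$start[A$end == d1][1]
            startB <- B$start[B$end == d2][1]
            if (!is.na(startA) && !is.na(startB) && startA == startB) {
              type <- if (strand == "+") "A5" else "A3"
              lo <- min(d1, d2); hi <- max(d1, d2)
              add_event(type, sprintf("%d-%d:%d-%d", lo, a1, hi, a1),
                        function(t) .has_junction(jn_list[[t]], hi, a1),
                        function(t) .has_junction(jn_list[[t]], lo, a1),
                        c(lo, a1))
            }
          }
        }
      }
      ## --- MX: mutually exclusive internal exons with shared flanks
      if (nrow(A) >= 3 && nrow(B) >= 3) {
        for (k in 2:(nrow(A) - 1)) for (l in 2:(nrow(B) - 1)) {
          s1 <- A$start[k]; e1 <- A$end[k]
          s2 <- B$start[l]; e2 <- B$end[l]
          if (e1 >= s2 || s1 == s2) next       # ordered, non-overlapping
          p <- A$end[k - 1]; q <- A$start[k + 1]
          if (B$end[l - 1] == p && B$start[l + 1] == q &&
              .has_junction(jA, p, s1) && .has_junction(jA, e1, q) &&
              .has_junction(jB, p, s2) && .has_junction(jB, e2, q)) {
            add_event("MX", sprintf("%d-%d:%d-%d:%d-%d:%d-%d",
                                    p, s1, e1, q, p, s2, e2, q),
                      function(t) .has_junction(jn_list[[t]], p, s1) &&
                        .has_junction(jn_list[[t]], e1, q),
                      function(t) .has_junction(jn_list[[t]], p, s2) &&
                        .has_junction(jn_list[[t]], e2, q),
                      c(p, q))
          }
        }
      }
      ## --- AF/AL: alternative first/last exons sharing the next junction
      ## target
      if (nrow(A) >= 2 && nrow(B) >= 2) {
        ## genomic-left end (transcription first exon on +, last on -)
        fa <- c(A$start[1], A$end[1]); fb <- c(B$start[1], B$end[1])
        xa <- A$start[2]; xb <- B$start[2]
        if (fa[2] != fb[2] && xa == xb &&
            (max(fa[1], fb[1]) > min(fa[2], fb[2]))) {
          type <- if (strand == "+") "AF" else "AL"
          first <- if (fa[1] < fb[1]) fa else fb
          second <- if (fa[1] < fb[1]) fb else fa
          add_event(type, sprintf("%d:%d-%d:%d:%d-%d",
                                  first[1], first[2], xa,
                                  second[1], second[2], xa),
                    function(t) {
                      ex <- ex_list[[t]]
                      ex$start[1] == first[1] && ex$end[1] == first[2] &&
                        .has_junction(jn_list[[t]], first[2], xa)
                    },
                    function(t) {
                      ex <- ex_list[[t]]
                      ex$start[1] == second[1] && ex$end[1] == second[2] &&
                        .has_junction(jn_list[[t]], second[2], xa)
                    },
                    c(min(fa[1], fb[1]), xa))
        }
        ## genomic-right end
        na_ <- nrow(A); nb <- nrow(B)
        la <- c(A$start[na_], A$end[na_]); lb <- c(B$start[nb], B$end[nb])
        ya <- A$end[na_ - 1]; yb <- B$end[nb - 1]
        if (la[1] != lb[1] && ya == yb &&
            (max(la[1], lb[1]) > min(la[2], lb[2]))) {
          type <- if (strand == "+") "AL" else "AF"
          first <- if (la[1] < lb[1]) la else lb
          second <- if (la[1] < lb[1]) lb else la
          add_event(type, sprintf("%d-%d:%d:%d-%d:%d",
                                  ya, first[1], first[2],
                                  ya, second[1], second[2]),
                    function(t) {
                      ex <- ex_list[[t]]
                      n <- nrow(ex)
                      ex$start[n] == first[1] && ex$end[n] == first[2] &&
                        .has_junction(jn_list[[t]], ya, first[1])
                    },
                    function(t) {
                      ex <- ex_list[[t]]
                      n <- nrow(ex)
                      ex$start[n] == second[1] && ex$end[n] == second[2] &&
                        .has_junction(jn_list[[t]], ya, second[1])
                    },
                    c(ya, max(la[2], lb[2])))
        }
      }
    }
    if (!length(evs)) next
    cds_spans <- ann$cds[ann$cds$tx_id %in% txs, , drop = FALSE]
    for (sig in names(evs)) {
      ev <- evs[[sig]]
      coding <- FALSE
      if (nrow(cds_spans) > 0)
        coding <- any(cds_spans$cds_start <= ev$span[2] &
                        cds_spans$cds_end >= ev$span[1])
      out[[sig]] <- data.frame(
        event_id = sig, gene_id = g, type = ev$type, chrom = chrom,
        strand = strand,
        inclusion_tx = paste(ev$incl, collapse = ","),
        total_tx = paste(ev$total, collapse = ","),
        span_start = ev$span[1], span_end = ev$span[2],
        coding = coding, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(event_id = character(0), gene_id = character(0),
                      type = character(0), chrom = character(0),
                      strand = character(0), inclusion_tx = character(0),
                      total_tx = character(0), span_start = integer(0),
                      span_end = integer(0), coding = logical(0)))
  res <- do.call(rbind, out[sort(names(out))])
  rownames(res) <- NULL
  res
}

#' Percent spliced in (PSI) from transcript TPM
#'
#' PSI of an event in a sample is the inclusion-transcript TPM divided by
#' the total event TPM; it is missing (NA) when the total falls below
#' \code{min_tpm} (default 1 TPM).
#'
#' @param events event table from \code{\link{generate_events}}.
#' @param tpm transcripts x samples TPM matrix.
#' @param min_tpm minimum total event expression for a defined PSI.
#' @return list with \code{psi} (events x samples, NA = missing) and
#'   \code{total_tpm}.
#' @export
compute_psi <- function(events, tpm, min_tpm = 1) {
  need <- unique(unlist(strsplit(events$total_tx, ",")))
  miss <- setdiff(need, rownames(tpm))
  if (length(miss))
    stop("event transcripts missing from TPM matrix: ",
         paste(head(miss, 5), collapse = ", "))
  psi <- matrix(NA_real_, nrow(events), ncol(tpm),
                dimnames = list(events$event_id, colnames(tpm)))
  tot <- psi
  for (i in seq_len(nrow(events))) {
    incl <- strsplit(events$inclusion_tx[i], ",")[[1]]
    total <- strsplit(events$total_tx[i], ",")[[1]]
    ti <- colSums(tpm[incl, , drop = FALSE])
    tt <- colSums(tpm[total, , drop = FALSE])
    ok <- tt >= min_tpm
    psi[i, ok] <- ti[ok] / tt[ok]
    tot[i, ] <- tt
  }
  list(psi = psi, total_tpm = tot)
}

#' Missingness filter and K-nearest-neighbor imputation
#'
#' Drops events without a defined PSI in more than \code{max_missing} of the
#' samples and imputes the remaining missing entries by averaging the k
#' nearest events (Euclidean distance over co-observed samples, unweighted).
#' Observed entries are never altered.
#'
#' @param psi events x samples PSI matrix with NAs.
#' @param max_missing maximum tolerated missing fraction (default 0.10,
#'   strict).
#' @param k neighbors (default 10).
#' @return completed PSI matrix (possibly with fewer rows).
#' @export
filter_and_impute <- function(psi, max_missing = 0.10, k = 10) {
  if (k >= nrow(psi))
    stop("k (", k, ") must be smaller than the number of events (",
         nrow(psi), ")")
  frac <- rowMeans(is.na(psi))
  psi <- psi[frac <= max_missing, , drop = FALSE]
  if (!anyNA(psi)) return(psi)
  obs <- !is.na(psi)
  for (i in which(rowSums(!obs) > 0)) {
    na_cols <- which(!obs[i, ])
    d <- vapply(seq_len(nrow(psi)), function(j) {
      if (j == i) return(Inf)
      shared <- obs[i, ] & obs[j, ]
      if (!any(shared)) return(Inf)
      sqrt(mean((psi[i, shared] - psi[j, shared])^2))
    }, numeric(1))
    for (s in na_cols) {
      cand <- which(is.finite(d) & obs[, s])
      if (!length(cand)) {
        psi[i, s] <- mean(psi[i, ], na.rm = TRUE)
        next
      }
      nb <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
      psi[i, s] <- mean(psi[nb, s])
    }
  }
  psi
}

#' Differential splicing with a logit-linear model
#'
#' Removes events with a pooled standard deviation below \code{sd_min}
#' across the compared samples, then fits a per-event linear model of the
#' logit-transformed PSI on the two-level group plus covariates. Delta PSI
#' is the untransformed group-mean difference (level 2 minus level 1);
#' significance requires |dPSI| > \code{dpsi_min} and BH FDR <
#' \code{fdr_max}.
#'
#' @param psi completed events x samples PSI matrix.
#' @param group two-level factor aligned with columns.
#' @param covariates data.frame of covariates or NULL.
#' @param sd_min SD filter (default 0.1; pooled over both groups, or per
#'   group with \code{sd_scope = "within"}).
#' @param dpsi_min,fdr_max significance thresholds (defaults 0.2, 0.01).
#' @param eps logit clipping bound (default 0.01).
#' @param sd_scope "pooled" (default) or "within".
#' @return data.frame: event_id, dpsi, p, fdr, significant.
#' @export
diff_splice <- function(psi, group, covariates = NULL, sd_min = 0.1,
                        dpsi_min = 0.2, fdr_max = 0.01, eps = 0.01,
                        sd_scope = c("pooled", "within")) {
  sd_scope <- match.arg(sd_scope)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  sds <- if (sd_scope == "pooled") apply(psi, 1, sd)
         else pmax(apply(psi[, group == levels(group)[1], drop = FALSE], 1, sd),
                   apply(psi[, group == levels(group)[2], drop = FALSE], 1, sd))
  psi <- psi[sds >= sd_min, , drop = FALSE]
  if (nrow(psi) == 0)
    return(data.frame(event_id = character(0), dpsi = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      significant = logical(0)))
  dat <- data.frame(group = group)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0)
    dat <- cbind(dat, as.data.frame(covariates))
  design <- model.matrix(~ ., data = dat)
  if (qr(design)$rank < ncol(design))
    stop("confounded design: group collinear with a covariate")
  y <- clogit(psi, eps)
  fit <- limma::lmFit(y, design)
  coef_name <- colnames(design)[2]
  tstat <- fit$coefficients[, coef_name] /
    (fit$stdev.unscaled[, coef_name] * fit$sigma)
  p <- 2 * pt(-abs(tstat), df = fit$df.residual)
  g2 <- group == levels(group)[2]
  dpsi <- rowMeans(psi[, g2, drop = FALSE]) -
    rowMeans(psi[, !g2, drop = FALSE])
  fdr <- p.adjust(p, method = "BH")
  data.frame(event_id = rownames(psi), dpsi = unname(dpsi), p = unname(p),
             fdr = unname(fdr),
             significant = unname(abs(dpsi) > dpsi_min & fdr < fdr_max),
             stringsAsFactors = FALSE)
}

#' Binarize event inclusion
#'
#' An event is considered included in a sample when PSI is strictly greater
#' than 0.5.
#'
#' @param psi completed PSI matrix.
#' @return binary matrix of the same shape.
#' @export
binarize_inclusion <- function(psi) {
  (psi > 0.5) + 0L
}

#' Correlation between event PSI and host-gene expression
#'
#' @param events event table (for the host-gene mapping).
#' @param psi completed PSI matrix (events in rows).
#' @param gene_lcpm genes x samples logCPM.
#' @param r_threshold threshold for the summary fraction (default 0.5).
#' @return list with \code{per_event} (event_id, gene_id, r) and
#'   \code{fraction_above}; zero-variance pairs are excluded with a note
#'   column.
#' @export
psi_expression_correlation <- function(events, psi, gene_lcpm,
                                       r_threshold = 0.5) {
  ids <- intersect(rownames(psi), events$event_id)
  rows <- lapply(ids, function(ev) {
    g <- events$gene_id[match(ev, events$event_id)]
    if (!g %in% rownames(gene_lcpm))
      return(data.frame(event_id = ev, gene_id = g, r = NA_real_,
                        note = "host gene not in expression matrix"))
    x <- psi[ev, ]; y <- gene_lcpm[g, colnames(psi)]
    if (sd(x) == 0 || sd(y) == 0)
      return(data.frame(event_id = ev, gene_id = g, r = NA_real_,
                        note = "zero variance"))
    data.frame(event_id = ev, gene_id = g, r = cor(x, y), note = "",
               stringsAsFactors = FALSE)
  })
  per_event <- do.call(rbind, rows)
  rownames(per_event) <- NULL
  ok <- !is.na(per_event$r)
  list(per_event = per_event,
       fraction_above = if (any(ok)) mean(per_event$r[ok] > r_threshold)
                        else NA_real_)
}
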