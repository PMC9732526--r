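## ---------------------------------------------------------------------------
## Domain impact: genomic fusion breakpoints, protein-domain -> genome
## mapping, kept/lost classification, GO rollups.
## ---------------------------------------------------------------------------

.parse_breakpoint <- function(bp) {
  parts <- strsplit(bp, ":", fixed = TRUE)[[1]]
  list(chrom = parts[1], pos = as.integer(parts[2]), strand = parts[3])
}

#' Derive the genomic breakpoint used for domain analysis
#'
#' The caller-reported breakpoint is used directly when it falls inside an
#' exon of the gene's representative transcript (longest annotated CDS).
#' Otherwise the 5' partner's breakpoint moves to the last base of its last
#' retained exon and the 3' partner's to the first base of its first retained
#' exon, both in transcription orientation.
#'
#' @param ann a \code{ball_annotation}.
#' @param gene gene id.
#' @param pos caller breakpoint (genomic, 1-based).
#' @param role \code{"5p"} or \code{"3p"}.
#' @return list with \code{gene}, \code{role}, \code{chrom}, \code{pos},
#'   \code{strand}, \code{provenance} ("exonic" or "exon-boundary").
#' @export
derive_breakpoint <- function(ann, gene, pos, role = c("5p", "3p")) {
  role <- match.arg(role)
  tx <- representative_tx(ann, gene)
  ex <- tx_exons(ann, tx)
  strand <- attr(ex, "strand")
  g <- ann$genes[match(gene, ann$genes$gene_id), ]
  if (pos < g$start || pos > g$end)
    stop("breakpoint ", pos, " lies outside the span of gene ", gene)
  inside <- which(pos >= ex$start & pos <= ex$end)
  if (length(inside) > 0) {
    return(list(gene = gene, role = role, chrom = g$chrom, pos = pos,
                strand = strand, provenance = "exonic"))
  }
  ## intronic: index of the last transcription-upstream exon
  if (strand == "+") k <- max(which(ex$end < pos))
  else k <- max(which(ex$start > pos))
  new_pos <- if (role == "5p") {
    if (strand == "+") ex$end[k] else ex$start[k]
  } else {
    j <- k + 1L
    if (j > nrow(ex)) stop("no retained exon downstream of breakpoint for ", gene)
    if (strand == "+") ex$start[j] else ex$end[j]
  }
  list(gene = gene, role = role, chrom = g$chrom, pos = new_pos,
       strand = strand, provenance = "exon-boundary")
}

#' Map a protein-domain span to genomic intervals
#'
#' Converts an amino-acid span (1-based inclusive) to the CDS nucleotide span
#' \eqn{[3(a-1)+1, 3b]} and walks it across the coding exon pieces of the
#' representative transcript, strand-aware. The returned intervals are in
#' transcription order and their lengths sum to three times the amino-acid
#' length.
#'
#' @param ann a \code{ball_annotation}.
#' @param gene gene id.
#' @param aa_start,aa_end amino-acid span (1-based inclusive).
#' @param tx transcript id; defaults to the representative transcript.
#' @return data.frame with columns \code{start}, \code{end} (genomic,
#'   1-based inclusive).
#' @export
map_domain_to_genome <- function(ann, gene, aa_start, aa_end, tx = NULL) {
  tx <- tx %||% representative_tx(ann, gene)
  civ <- cds_intervals(ann, tx)
  if (is.null(civ)) stop("transcript ", tx, " has no CDS")
  strand <- attr(tx_exons(ann, tx), "strand")
  cds_len <- sum(civ$end - civ$start + 1L)
  if (cds_len %% 3 != 0) stop("CDS length of ", tx, " is not divisible by 3")
  prot_len <- cds_len %/% 3
  if (aa_start < 1 || aa_end > prot_len || aa_start > aa_end)
    stop(sprintf("aa span [%d,%d] outside protein of length %d (%s)",
                 aa_start, aa_end, prot_len, gene))
  nt1 <- 3L * (aa_start - 1L) + 1L
  nt2 <- 3L * aa_end
  out <- list()
  cum <- 0L
  for (i in seq_len(nrow(civ))) {
    w <- civ$end[i] - civ$start[i] + 1L
    lo <- max(nt1, cum + 1L)
    hi <- min(nt2, cum + w)
    if (lo <= hi) {
      o1 <- lo - cum; o2 <- hi - cum   # offsets within this exon piece
      if (strand == "+") {
        out[[length(out) + 1L]] <- c(civ$start[i] + o1 - 1L,
                                     civ$start[i] + o2 - 1L)
      } else {
        out[[length(out) + 1L]] <- c(civ$end[i] - o2 + 1L,
                                     civ$end[i] - o1 + 1L)
      }
    }
    cum <- cum + w
  }
  iv <- do.call(rbind, out)
  data.frame(start = iv[, 1], end = iv[, 2])
}

#' Classify a domain as kept or lost relative to a fusion breakpoint
#'
#' The retained side of the transcript is transcription-upstream of (and
#' including) the breakpoint for the 5' partner and downstream (inclusive)
#' for the 3' partner. The domain is kept only when all its genomic intervals
#' lie wholly on the retained side; any overlap with the breakpoint or
#' placement on the removed side classifies it as lost (disrupted).
#'
#' @param intervals data.frame of genomic intervals
#'   (\code{\link{map_domain_to_genome}}).
#' @param breakpoint_pos genomic breakpoint (1-based).
#' @param role \code{"5p"} or \code{"3p"}.
#' @param strand \code{"+"} or \code{"-"}.
#' @return \code{"kept"} or \code{"lost"}.
#' @export
classify_domain <- function(intervals, breakpoint_pos, role = c("5p", "3p"),
                            strand = c("+", "-")) {
  role <- match.arg(role); strand <- match.arg(strand)
  retained_upstream <- (role == "5p")
  kept <- if (retained_upstream == (strand == "+")) {
    all(intervals$end <= breakpoint_pos)
  } else {
    all(intervals$start >= breakpoint_pos)
  }
  if (kept) "kept" else "lost"
}

#' Assess domain impact for a set of fusion calls
#'
#' For every call, derives both partners' genomic breakpoints, maps each
#' partner's annotated protein domains to genomic coordinates and classifies
#' them kept or lost.
#'
#' @param calls fusion-call data.frame (survivors of the cascade).
#' @param ann a \code{ball_annotation} carrying a domain table.
#' @param group_of optional named vector fusion_name -> group label, added to
#'   the output for rollups.
#' @return data.frame with one row per call x partner x domain:
#'   fusion_name, sample_id, gene, role, domain_id, status, breakpoint,
#'   provenance, GO labels.
#' @export
assess_domains <- function(calls, ann, group_of = NULL) {
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    for (role in c("5p", "3p")) {
      gene <- if (role == "5p") calls$gene5[i] else calls$gene3[i]
      bp_str <- if (role == "5p") calls$left_breakpoint[i] else
        calls$right_breakpoint[i]
      if (!gene %in% ann$genes$gene_id) next
      doms <- ann$domains[ann$domains$gene_id == gene, , drop = FALSE]
      if (nrow(doms) == 0) next
      bp0 <- .parse_breakpoint(bp_str)
      bp <- derive_breakpoint(ann, gene, bp0$pos, role)
      for (j in seq_len(nrow(doms))) {
        iv <- map_domain_to_genome(ann, gene, doms$aa_start[j], doms$aa_end[j])
        st <- classify_domain(iv, bp$pos, role, bp$strand)
        rows[[length(rows) + 1L]] <- data.frame(
          fusion_name = calls$fusion_name[i],
          sample_id = calls$sample_id[i],
          gene = gene, role = role,
          domain_id = doms$domain_id[j], status = st,
          breakpoint = bp$pos, provenance = bp$provenance,
          go_bp = doms$go_bp[j], go_cc = doms$go_cc[j], go_mf = doms$go_mf[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(fusion_name = character(0), sample_id = character(0),
                      gene = character(0), role = character(0),
                      domain_id = character(0), status = character(0),
                      breakpoint = integer(0), provenance = character(0),
                      go_bp = character(0), go_cc = character(0),
                      go_mf = character(0)))
  out <- do.call(rbind, rows)
  if (!is.null(group_of)) out$group <- unname(group_of[out$fusion_name])
  out
}

#' GO-level rollup of kept/lost domain classifications
#'
#' Counts kept and lost domains per GO term within each fusion group. A
#' domain contributes once per distinct GO label attached to it; domains
#' without a label in an ontology are counted under "unannotated".
#'
#' @param classified output of \code{\link{assess_domains}} with a
#'   \code{group} column.
#' @return data.frame: group, ontology (bp/cc/mf), term, kept, lost.
#' @export
go_rollup <- function(classified) {
  if (nrow(classified) == 0)
    return(data.frame(group = character(0), ontology = character(0),
                      term = character(0), kept = integer(0),
                      lost = integer(0)))
  if (!"group" %in% names(classified)) classified$group <- "all"
  rows <- list()
  for (ont in c("bp", "cc", "mf")) {
    col <- paste0("go_", ont)
    d <- classified
    terms <- d[[col]]
    terms[is.na(terms) | terms == ""] <- "unannotated"
    ## a domain contributes once per distinct label
    key <- paste(d$group, d$fusion_name, d$sample_id, d$gene, d$domain_id,
                 terms, sep = "\r")
    keep <- !duplicated(key)
    d <- d[keep, , drop = FALSE]; terms <- terms[keep]
    tab <- table(group = d$group, term = terms, status = d$status)
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    wide <- stats::reshape(df, idvar = c("group", "term"),
                           timevar = "status", direction = "wide")
    names(wide) <- sub("^Freq\\.", "", names(wide))
    if (!"kept" %in% names(wide)) wide$kept <- 0L
    if (!"lost" %in% names(wide)) wide$lost <- 0L
    wide$ontology <- ont
    rows[[ont]] <- wide[, c("group", "ontology", "term", "kept", "lost")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[out$kept + out$lost > 0, , drop = FALSE]
}
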