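#' Annotation bundle
#'
#' A lightweight container for a gene annotation: gene table, transcript
#' table, exon table (1-based inclusive genomic intervals), CDS spans, a
#' protein-domain table and (optionally) per-chromosome sequence. All
#' coordinates are 1-based inclusive; exon rank follows transcription order
#' (rank 1 is the 5'-most exon on the transcript's strand).
#'
#' @param genes data.frame: gene_id, symbol, chrom, strand, start, end, biotype.
#' @param transcripts data.frame: tx_id, gene_id.
#' @param exons data.frame: tx_id, exon_rank, start, end.
#' @param cds data.frame: tx_id, cds_start, cds_end (genomic span; coding
#'   sequence = exon intervals intersected with the span).
#' @param domains data.frame: gene_id, domain_id, aa_start, aa_end,
#'   go_bp, go_cc, go_mf (may be empty).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param genome named character vector of chromosome sequences, or NULL.
#' @return an object of class \code{ball_annotation}.
#' @export
new_annotation <- function(genes, transcripts, exons, cds, domains,
                           chrom_lengths, genome = NULL) {
  ## basic structural invariants
  for (tx in unique(exons$tx_id)) {
    ex <- exons[exons$tx_id == tx, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))
      stop("overlapping exons in transcript ", tx)
  }
  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 cds = cds, domains = domains,
                 chrom_lengths = chrom_lengths, genome = genome),
            class = "ball_annotation")
}

#' @export
print.ball_annotation <- function(x, ...) {
  cat("ball_annotation:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons,",
      length(x$chrom_lengths), "chromosomes\n")
  invisible(x)
}

## exons of one transcript in transcription order
tx_exons <- function(ann, tx_id) {
  ex <- ann$exons[ann$exons$tx_id == tx_id, , drop = FALSE]
  if (nrow(ex) == 0) stop("unknown transcript: ", tx_id)
  gene <- ann$transcripts$gene_id[match(tx_id, ann$transcripts$tx_id)]
  strand <- ann$genes$strand[match(gene, ann$genes$gene_id)]
  ex <- ex[order(ex$start, decreasing = identical(strand, "-")), , drop = FALSE]
  ex$exon_rank <- seq_len(nrow(ex))
  attr(ex, "strand") <- strand
  attr(ex, "chrom") <- ann$genes$chrom[match(gene, ann$genes$gene_id)]
  ex
}

tx_gene <- function(ann, tx_id) {
  ann$transcripts$gene_id[match(tx_id, ann$transcripts$tx_id)]
}

gene_strand <- function(ann, gene_id) {
  ann$genes$strand[match(gene_id, ann$genes$gene_id)]
}

#' Spliced (exonic) length of a transcript
#' @param ann a \code{ball_annotation}.
#' @param tx_id transcript id.
#' @return total exon length in nucleotides.
#' @export
spliced_length <- function(ann, tx_id) {
  ex <- ann$exons[ann$exons$tx_id == tx_id, , drop = FALSE]
  sum(ex$end - ex$start + 1L)
}

## coding genomic intervals of a transcript, in transcription order
cds_intervals <- function(ann, tx_id) {
  ex <- tx_exons(ann, tx_id)
  span <- ann$cds[ann$cds$tx_id == tx_id, , drop = FALSE]
  if (nrow(span) == 0) return(NULL)
  s <- span$cds_start[1]; e <- span$cds_end[1]
  keep <- ex$end >= s & ex$start <= e
  ex <- ex[keep, , drop = FALSE]
  ex$start <- pmax(ex$start, s)
  ex$end <- pmin(ex$end, e)
  ex
}

## representative transcript for a gene: longest annotated CDS, ties broken
## by transcript id so the choice is stable across runs
representative_tx <- function(ann, gene_id) {
  txs <- ann$transcripts$tx_id[ann$transcripts$gene_id == gene_id]
  if (length(txs) == 0) stop("no transcripts for gene ", gene_id)
  cds_len <- vapply(txs, function(tx) {
    iv <- cds_intervals(ann, tx)
    if (is.null(iv)) 0L else as.integer(sum(iv$end - iv$start + 1L))
  }, integer(1))
  txs[order(-cds_len, txs)][1]
}

#' Write an annotation bundle as GTF
#'
#' Emits gene, transcript, exon and CDS features with \code{gene_id},
#' \code{gene_name}, \code{gene_biotype} and \code{transcript_id} attributes.
#'
#' @param ann a \code{ball_annotation}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_gtf <- function(ann, path) {
  attrs <- function(gene, tx = NULL) {
    g <- ann$genes[match(gene, ann$genes$gene_id), ]
    a <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                 g$gene_id, g$symbol, g$biotype)
    if (!is.null(tx)) a <- paste0(a, sprintf(' transcript_id "%s";', tx))
    a
  }
  lines <- character(0)
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    lines <- c(lines, paste(g$chrom, "ballistic", "gene", g$start, g$end, ".",
                            g$strand, ".", attrs(g$gene_id), sep = "\t"))
    txs <- ann$transcripts$tx_id[ann$transcripts$gene_id == g$gene_id]
    for (tx in txs) {
      ex <- ann$exons[ann$exons$tx_id == tx, , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      lines <- c(lines,
                 paste(g$chrom, "ballistic", "transcript", min(ex$start),
                       max(ex$end), ".", g$strand, ".",
                       attrs(g$gene_id, tx), sep = "\t"),
                 paste(g$chrom, "ballistic", "exon", ex$start, ex$end, ".",
                       g$strand, ".", attrs(g$gene_id, tx), sep = "\t"))
      span <- ann$cds[ann$cds$tx_id == tx, , drop = FALSE]
      if (nrow(span) > 0) {
        civ <- ex[ex$end >= span$cds_start[1] & ex$start <= span$cds_end[1], ,
                  drop = FALSE]
        civ$start <- pmax(civ$start, span$cds_start[1])
        civ$end <- pmin(civ$end, span$cds_end[1])
        lines <- c(lines, paste(g$chrom, "ballistic", "CDS", civ$start,
                                civ$end, ".", g$strand, "0",
                                attrs(g$gene_id, tx), sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GTF written by \code{\link{write_gtf}} back into an annotation bundle
#'
#' @param path GTF file.
#' @param chrom_lengths optional named lengths; inferred from feature extents
#'   when absent.
#' @param domains optional domain table to attach.
#' @return a \code{ball_annotation} (without sequence).
#' @export
read_gtf <- function(path, chrom_lengths = NULL, domains = NULL) {
  raw <- read.delim(path, header = FALSE, comment.char = "#", quote = "",
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "source", "feature", "start", "end",
                                  "score", "strand", "frame", "attr"))
  get_attr <- function(a, key) {
    out <- rep(NA_character_, length(a))
    has <- grepl(sprintf('%s "', key), a, fixed = TRUE)
    out[has] <- sub(sprintf('.*%s "([^"]*)".*', key), "\\1", a[has])
    out
  }
  raw$gene_id <- get_attr(raw$attr, "gene_id")
  raw$tx_id <- ifelse(grepl("transcript_id", raw$attr),
                      get_attr(raw$attr, "transcript_id"), NA_character_)
  gg <- raw[raw$feature == "gene", ]
  genes <- data.frame(gene_id = gg$gene_id,
                      symbol = get_attr(gg$attr, "gene_name"),
                      chrom = gg$chrom, strand = gg$strand,
                      start = gg$start, end = gg$end,
                      biotype = get_attr(gg$attr, "gene_biotype"),
                      stringsAsFactors = FALSE)
  tt <- raw[raw$feature == "transcript", ]
  transcripts <- data.frame(tx_id = tt$tx_id, gene_id = tt$gene_id,
                            stringsAsFactors = FALSE)
  ee <- raw[raw$feature == "exon", ]
  exons <- data.frame(tx_id = ee$tx_id, exon_rank = NA_integer_,
                      start = ee$start, end = ee$end, stringsAsFactors = FALSE)
  cc <- raw[raw$feature == "CDS", ]
  cds <- if (nrow(cc) > 0) {
    do.call(rbind, lapply(split(cc, cc$tx_id), function(d) {
      data.frame(tx_id = d$tx_id[1], cds_start = min(d$start),
                 cds_end = max(d$end), stringsAsFactors = FALSE)
    }))
  } else data.frame(tx_id = character(0), cds_start = integer(0),
                    cds_end = integer(0))
  rownames(cds) <- NULL
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(genes$end, genes$chrom, max)
    chrom_lengths <- setNames(as.integer(chrom_lengths + 1000L),
                              names(chrom_lengths))
  }
  if (is.null(domains))
    domains <- data.frame(gene_id = character(0), domain_id = character(0),
                          aa_start = integer(0), aa_end = integer(0),
                          go_bp = character(0), go_cc = character(0),
                          go_mf = character(0))
  new_annotation(genes, transcripts, exons, cds, domains, chrom_lengths)
}

#' Write the genome of an annotation bundle as FASTA
#' @param ann annotation with a \code{genome} component.
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(ann, path) {
  if (is.null(ann$genome)) stop("annotation carries no sequence")
  seqs <- Biostrings::DNAStringSet(ann$genome)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(seqs), names(seqs))
}
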