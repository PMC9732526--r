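## ---------------------------------------------------------------------------
## RBP motif enrichment: splice-site flank extraction, 6-mer and PFM
## scanning, GC/length-matched control subsampling, z-scores.
## ---------------------------------------------------------------------------

#' Build a motif database from per-RBP 6-mers
#'
#' Each RBP receives its 6-mer and a near-one-hot position frequency matrix
#' (0.91 on the consensus base, 0.03 elsewhere), so PFM scanning at the
#' default threshold reproduces the exact-match 6-mer scan.
#'
#' @param kmers named character vector (names = RBPs, values = ACGT 6-mers).
#' @return an object of class \code{motif_db} with components \code{kmers}
#'   and \code{pfms} (4 x width matrices with rows A, C, G, T).
#' @export
motif_db_from_kmers <- function(kmers) {
  stopifnot(all(grepl("^[ACGT]+$", kmers)))
  bases <- c("A", "C", "G", "T")
  pfms <- lapply(kmers, function(km) {
    chars <- strsplit(km, "")[[1]]
    m <- matrix(0.03, 4, length(chars), dimnames = list(bases, NULL))
    for (j in seq_along(chars)) m[chars[j], j] <- 0.91
    m
  })
  structure(list(kmers = kmers, pfms = pfms), class = "motif_db")
}

#' Validate a motif database
#' @param db a \code{motif_db}.
#' @return TRUE invisibly; errors on malformed content.
#' @export
validate_motif_db <- function(db) {
  stopifnot(inherits(db, "motif_db"))
  if (!all(grepl("^[ACGT]{6}$", db$kmers)))
    stop("6-mers must be uppercase ACGT of length 6")
  for (nm in names(db$pfms)) {
    cs <- colSums(db$pfms[[nm]])
    if (any(abs(cs - 1) > 1e-6))
      stop("PFM columns of ", nm, " do not sum to 1")
  }
  invisible(TRUE)
}

#' Write / read a motif database directory
#'
#' PFMs are written in JASPAR-style text (\code{>RBP} header followed by
#' four base rows); 6-mers as a two-column TSV.
#'
#' @param db a \code{motif_db}.
#' @param dir directory.
#' @return the directory (write) or a \code{motif_db} (read).
#' @export
write_motif_db <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lines <- unlist(lapply(names(db$pfms), function(nm) {
    m <- db$pfms[[nm]]
    c(paste0(">", nm),
      vapply(rownames(m), function(b)
        sprintf("%s [ %s ]", b, paste(format(m[b, ], digits = 6),
                                      collapse = " ")),
        character(1)))
  }))
  writeLines(lines, file.path(dir, "pfm.txt"))
  write_tsv(data.frame(rbp = names(db$kmers), kmer = unname(db$kmers)),
            file.path(dir, "kmers.tsv"))
  invisible(dir)
}

#' @rdname write_motif_db
#' @export
read_motif_db <- function(dir) {
  km <- read_tsv(file.path(dir, "kmers.tsv"))
  kmers <- setNames(km$kmer, km$rbp)
  lines <- readLines(file.path(dir, "pfm.txt"))
  heads <- grep("^>", lines)
  pfms <- list()
  for (i in seq_along(heads)) {
    nm <- sub("^>", "", lines[heads[i]])
    rows <- lines[(heads[i] + 1):(heads[i] + 4)]
    m <- t(vapply(rows, function(r) {
      vals <- sub("^[ACGT] \\[ ", "", sub(" \\]$", "", r))
      as.numeric(strsplit(trimws(vals), "\\s+")[[1]])
    }, numeric(nchar(kmers[[1]]))))
    rownames(m) <- substr(rows, 1, 1)
    pfms[[nm]] <- m[c("A", "C", "G", "T"), , drop = FALSE]
  }
  structure(list(kmers = kmers, pfms = pfms), class = "motif_db")
}

## splice sites of an event in transcription order; returns data.frame
## site, kind (donor/acceptor), pos
.event_sites <- function(ev) {
  coords <- as.integer(unlist(regmatches(ev$event_id,
                                         gregexpr("[0-9]+", ev$event_id))))
  ## drop the chromosome number captured from "chrN" if present
  coords <- coords[coords > 10]
  if (ev$type == "SE") {
    parts <- strsplit(ev$event_id, ":", fixed = TRUE)[[1]]
    j1 <- as.integer(strsplit(parts[3], "-")[[1]])
    j2 <- as.integer(strsplit(parts[4], "-")[[1]])
    p <- j1[1]; s <- j1[2]; e <- j2[1]; q <- j2[2]
    if (ev$strand == "+") {
      data.frame(site = c("D1", "A1", "D2", "A2"),
                 kind = c("donor", "acceptor", "donor", "acceptor"),
                 pos = c(p, s, e, q), stringsAsFactors = FALSE)
    } else {
      data.frame(site = c("D1", "A1", "D2", "A2"),
                 kind = c("donor", "acceptor", "donor", "acceptor"),
                 pos = c(q, e, s, p), stringsAsFactors = FALSE)
    }
  } else {
    data.frame(site = c("S1", "S2"), kind = c("donor", "acceptor"),
               pos = c(ev$span_start, ev$span_end), stringsAsFactors = FALSE)
  }
}

#' Extract sequence windows flanking the splice sites of events
#'
#' For each alternative splice site of an event, a window of \code{window}
#' nucleotides is taken on the exonic and the intronic side; windows of
#' minus-strand events are reverse-complemented so all sequences read in
#' transcription sense. Windows overrunning chromosome ends are truncated
#' and flagged.
#'
#' @param events event table rows (\code{\link{generate_events}}).
#' @param genome named character vector of chromosome sequences.
#' @param window window size per side (default 200).
#' @return data.frame: event_id, region_class (site_side), start, end,
#'   truncated, seq, length, gc.
#' @export
extract_event_regions <- function(events, genome, window = 200) {
  rows <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (!ev$chrom %in% names(genome))
      stop("chromosome ", ev$chrom, " absent from genome")
    chrom_seq <- genome[[ev$chrom]]
    L <- nchar(chrom_seq)
    sites <- .event_sites(ev)
    for (j in seq_len(nrow(sites))) {
      pos <- sites$pos[j]
      ## genomic window per side, oriented by strand and site kind
      exon_first <- (sites$kind[j] == "donor") == (ev$strand == "+")
      wins <- if (exon_first) {
        list(exon = c(pos - window + 1L, pos), intron = c(pos + 1L, pos + window))
      } else {
        list(intron = c(pos - window, pos - 1L), exon = c(pos, pos + window - 1L))
      }
      for (side in names(wins)) {
        w <- wins[[side]]
        trunc <- w[1] < 1L || w[2] > L
        a <- max(1L, w[1]); b <- min(L, w[2])
        s <- substr(chrom_seq, a, b)
        if (ev$strand == "-") s <- reverse_complement(s)
        rows[[length(rows) + 1L]] <- data.frame(
          event_id = ev$event_id,
          region_class = paste(sites$site[j], side, sep = "_"),
          start = a, end = b, truncated = trunc, seq = s,
          length = nchar(s), gc = gc_content(s), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scan regions for RBP motifs
#'
#' 6-mer hits are exact substring matches; PFM hits are positions whose
#' log-likelihood-ratio score (against the region's own 0-order base
#' composition, pseudocount 0.01) reaches \code{pfm_score_fraction} of the
#' maximum attainable score. Only the sense strand is scanned (RBP motifs
#' act on the pre-mRNA).
#'
#' @param regions region table from \code{\link{extract_event_regions}}.
#' @param db a \code{motif_db}.
#' @param pfm_score_fraction threshold fraction (default 0.8).
#' @param scan_pfms also scan PFMs (default TRUE; 6-mers are always
#'   scanned).
#' @return data.frame: event_id, region_class, rbp, motif_type
#'   (kmer / pfm), n_hits.
#' @export
scan_motifs <- function(regions, db, pfm_score_fraction = 0.8,
                        scan_pfms = TRUE) {
  validate_motif_db(db)
  bases <- c("A", "C", "G", "T")
  code_of <- lapply(regions$seq, function(s) match(strsplit(s, "")[[1]], bases))
  n_skipped <- sum(vapply(code_of, function(v) sum(is.na(v)), numeric(1)))
  rbps <- names(db$kmers)
  n_types <- if (scan_pfms) 2L else 1L
  total <- nrow(regions) * length(rbps) * n_types
  v_event <- character(total); v_class <- character(total)
  v_rbp <- character(total); v_type <- character(total)
  v_hits <- integer(total)
  idx <- 0L
  for (i in seq_len(nrow(regions))) {
    sq <- regions$seq[i]
    code <- code_of[[i]]
    n <- length(code)
    tab <- tabulate(code[!is.na(code)], 4)
    bg <- (tab + 0.01) / sum(tab + 0.01)
    for (r in rbps) {
      km <- db$kmers[[r]]
      g <- gregexpr(km, sq, fixed = TRUE)[[1]]
      hits_k <- if (g[1] == -1) 0L else length(g)
      idx <- idx + 1L
      v_event[idx] <- regions$event_id[i]
      v_class[idx] <- regions$region_class[i]
      v_rbp[idx] <- r; v_type[idx] <- "kmer"; v_hits[idx] <- hits_k
      if (scan_pfms) {
        pfm <- db$pfms[[r]]
        w <- ncol(pfm)
        hits_p <- 0L
        if (n >= w) {
          L <- log((pfm + 0.01) / rep(colSums(pfm + 0.01), each = 4) /
                     matrix(bg, 4, w))
          maxscore <- sum(apply(L, 2, max))
          np <- n - w + 1L
          sc <- numeric(np)
          ok <- rep(TRUE, np)
          for (k in seq_len(w)) {
            ck <- code[k:(k + np - 1L)]
            ok <- ok & !is.na(ck)
            ckf <- ifelse(is.na(ck), 1L, ck)
            sc <- sc + L[cbind(ckf, k)]
          }
          hits_p <- sum(ok & sc >= pfm_score_fraction * maxscore)
        }
        idx <- idx + 1L
        v_event[idx] <- regions$event_id[i]
        v_class[idx] <- regions$region_class[i]
        v_rbp[idx] <- r; v_type[idx] <- "pfm"; v_hits[idx] <- hits_p
      }
    }
  }
  res <- data.frame(event_id = v_event, region_class = v_class, rbp = v_rbp,
                    motif_type = v_type, n_hits = v_hits,
                    stringsAsFactors = FALSE)
  attr(res, "skipped_positions") <- n_skipped
  res
}

#' Event-level motif hit frequencies
#'
#' Collapses a hit table to the fraction of events with at least one hit,
#' per motif (RBP x motif type) and region class.
#'
#' @param hits hit table from \code{\link{scan_motifs}}.
#' @param event_ids events over which the frequency is taken.
#' @return data.frame: rbp, motif_type, region_class, frequency.
#' @export
motif_event_frequency <- function(hits, event_ids) {
  h <- hits[hits$event_id %in% event_ids, , drop = FALSE]
  key <- interaction(h$rbp, h$motif_type, h$region_class, drop = FALSE)
  agg <- tapply(seq_len(nrow(h)), key, function(ii) {
    with_hit <- unique(h$event_id[ii][h$n_hits[ii] > 0])
    length(with_hit) / length(event_ids)
  })
  parts <- do.call(rbind, strsplit(names(agg), ".", fixed = TRUE))
  data.frame(rbp = parts[, 1], motif_type = parts[, 2],
             region_class = parts[, 3],
             frequency = ifelse(is.na(as.numeric(agg)), 0, as.numeric(agg)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Draw GC/length-matched control event subsamples
#'
#' Each of \code{n_samples} control sets has the size of the signal set and
#' matches its joint length x GC distribution via stratified sampling over
#' quantile bins (4 x 4 by default), sampling without replacement within a
#' subsample. Empty strata fall back to the nearest populated bin with a
#' warning.
#'
#' @param signal_ids,pool_ids event ids of the signal set and the control
#'   pool. The caller supplies a pool disjoint from the signal (the pipeline
#'   passes the tested-but-not-significant events); it must be at least as
#'   large as the signal set. Passing the signal set itself as the pool is a
#'   degenerate case in which every subsample is a permutation of the signal
#'   and all z-scores are 0.
#' @param features data.frame with event_id, length, gc per event.
#' @param n_samples number of subsamples (default 100).
#' @param bins quantile bins per axis (default 4).
#' @param seed integer seed.
#' @return list of character vectors (one per subsample).
#' @export
match_controls <- function(signal_ids, pool_ids, features, n_samples = 100,
                           bins = 4, seed = 1L) {
  if (length(pool_ids) < length(signal_ids))
    stop("control pool smaller than signal set")
  feat <- features[match(c(signal_ids, pool_ids), features$event_id), ]
  qs_len <- unique(quantile(feat$length[feat$event_id %in% signal_ids],
                            probs = seq(0, 1, length.out = bins + 1)))
  qs_gc <- unique(quantile(feat$gc[feat$event_id %in% signal_ids],
                           probs = seq(0, 1, length.out = bins + 1)))
  ## pool events outside the signal's range land in outer pseudo-bins and
  ## are only reached through the nearest-bin fallback
  bin_of <- function(x, qs) {
    if (length(qs) < 2) return(rep(1L, length(x)))
    b <- findInterval(x, qs, rightmost.closed = TRUE)
    b[x < qs[1]] <- 0L
    b[x > qs[length(qs)]] <- length(qs)
    pmin(b, length(qs))
  }
  feat$bl <- bin_of(feat$length, qs_len)
  feat$bg <- bin_of(feat$gc, qs_gc)
  feat$stratum <- paste(feat$bl, feat$bg)
  sig_strata <- table(feat$stratum[feat$event_id %in% signal_ids])
  pool_by_stratum <- split(feat$event_id[feat$event_id %in% pool_ids],
                           feat$stratum[feat$event_id %in% pool_ids])
  set.seed(derive_seed(seed, "motifs"))
  warned <- FALSE
  draws <- lapply(seq_len(n_samples), function(s) {
    taken <- character(0)
    for (st in names(sig_strata)) {
      need <- sig_strata[[st]]
      cand <- setdiff(pool_by_stratum[[st]] %||% character(0), taken)
      if (length(cand) < need) {
        if (!warned) {
          warning("stratum ", st, " underfilled; using nearest-bin fallback")
          warned <<- TRUE
        }
        ## nearest strata by bin distance
        sb <- as.integer(strsplit(st, " ")[[1]])
        all_st <- names(pool_by_stratum)
        dist <- vapply(all_st, function(o) {
          ob <- as.integer(strsplit(o, " ")[[1]])
          sum(abs(ob - sb))
        }, numeric(1))
        for (o in all_st[order(dist)]) {
          if (length(cand) >= need) break
          cand <- union(cand, setdiff(pool_by_stratum[[o]], taken))
        }
      }
      k <- min(need, length(cand))
      if (k > 0)
        taken <- c(taken, sample(cand, k))
    }
    ## top up from anywhere if strata could not fill the quota
    if (length(taken) < length(signal_ids)) {
      rest <- setdiff(pool_ids, taken)
      taken <- c(taken, sample(rest, length(signal_ids) - length(taken)))
    }
    taken
  })
  draws
}

#' Motif enrichment z-scores against control subsamples
#'
#' For every motif x region class, compares the observed event-level hit
#' frequency in the signal set with the mean and SD of the frequencies over
#' the control subsamples: \eqn{z = (obs - mean) / SD}. When the control SD
#' is 0, z is 0 if the observed frequency equals the constant and +/-Inf
#' (with a warning) otherwise. Motifs with z > \code{z_min} are flagged
#' enriched.
#'
#' @param hits hit table over signal and pool events.
#' @param signal_ids signal event ids.
#' @param control_sets list of control id vectors
#'   (\code{\link{match_controls}}).
#' @param z_min enrichment threshold (default 1.5).
#' @return data.frame: rbp, motif_type, region_class, observed,
#'   control_mean, control_sd, z, enriched.
#' @export
enrichment_z <- function(hits, signal_ids, control_sets, z_min = 1.5) {
  obs <- motif_event_frequency(hits, signal_ids)
  ctrl <- lapply(control_sets, function(ids) motif_event_frequency(hits, ids))
  key <- function(d) paste(d$rbp, d$motif_type, d$region_class, sep = "\r")
  ok <- key(obs)
  cmat <- vapply(ctrl, function(d) d$frequency[match(ok, key(d))],
                 numeric(nrow(obs)))
  if (is.null(dim(cmat))) cmat <- matrix(cmat, nrow = nrow(obs))
  cmat[is.na(cmat)] <- 0
  cm <- rowMeans(cmat)
  csd <- apply(cmat, 1, sd)
  z <- ifelse(csd > 0, (obs$frequency - cm) / csd,
              ifelse(obs$frequency == cm, 0, Inf * sign(obs$frequency - cm)))
  if (any(is.infinite(z)))
    warning("degenerate control distribution (SD = 0) for ",
            sum(is.infinite(z)), " motif/region combination(s)")
  data.frame(rbp = obs$rbp, motif_type = obs$motif_type,
             region_class = obs$region_class, observed = obs$frequency,
             control_mean = cm, control_sd = csd, z = z,
             enriched = z > z_min, stringsAsFactors = FALSE)
}

#' End-to-end motif enrichment for a differential-splicing result
#'
#' Extracts flank regions for the tested events, scans the motif database,
#' draws GC/length-matched control subsamples from the non-significant
#' events and computes enrichment z-scores.
#'
#' @param events event table.
#' @param ds differential-splicing result (\code{\link{diff_splice}}).
#' @param genome named chromosome sequences.
#' @param db a \code{motif_db}.
#' @param window flank window (default 200).
#' @param n_subsamples control subsamples (default 100).
#' @param seed integer seed.
#' @param scan_pfms scan PFMs in addition to 6-mers (default TRUE).
#' @return list with \code{enrichment}, \code{hits}, \code{regions},
#'   \code{signal_ids}, \code{control_sets}.
#' @export
motif_enrichment <- function(events, ds, genome, db, window = 200,
                             n_subsamples = 100, seed = 1L,
                             scan_pfms = TRUE) {
  signal_ids <- ds$event_id[ds$significant]
  pool_ids <- ds$event_id[!ds$significant]
  if (!length(signal_ids)) stop("no significant events to test")
  tested <- events[events$event_id %in% c(signal_ids, pool_ids), ,
                   drop = FALSE]
  regions <- extract_event_regions(tested, genome, window)
  feats <- do.call(rbind, lapply(split(regions, regions$event_id),
                                 function(d) data.frame(
                                   event_id = d$event_id[1],
                                   length = sum(d$length),
                                   gc = mean(d$gc))))
  hits <- scan_motifs(regions, db, scan_pfms = scan_pfms)
  control_sets <- match_controls(signal_ids, pool_ids, feats,
                                 n_samples = n_subsamples, seed = seed)
  enr <- enrichment_z(hits, signal_ids, control_sets)
  list(enrichment = enr, hits = hits, regions = regions,
       signal_ids = signal_ids, control_sets = control_sets)
}
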