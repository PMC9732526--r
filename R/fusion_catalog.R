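## ---------------------------------------------------------------------------
## Fusion catalog: caller-output parsing, evidence filters, fusion allele
## frequency (FAF), artifact/recurrence/FAF cascade, classification and
## grouping.
## ---------------------------------------------------------------------------

#' STAR-Fusion-style column dialect
#'
#' Maps the package's internal fusion-call fields onto the column names of a
#' caller output table. Wild-type support can be given either as read counts
#' (\code{wt5_reads}/\code{wt3_reads}) or as per-side allele-frequency columns
#' (\code{left_af}/\code{right_af}) from which wild-type reads are inverted;
#' one of the two must be present in the file.
#'
#' @param sample_id,cohort names of the sample/cohort columns.
#' @return named list dialect usable by \code{\link{parse_fusion_calls}}.
#' @export
star_fusion_dialect <- function(sample_id = "sample_id", cohort = "cohort") {
  list(fusion_name = "#FusionName",
       junction_reads = "JunctionReadCount",
       spanning_frags = "SpanningFragCount",
       left_gene = "LeftGene", left_breakpoint = "LeftBreakpoint",
       right_gene = "RightGene", right_breakpoint = "RightBreakpoint",
       ffpm = "FFPM", large_anchor = "LargeAnchorSupport",
       wt5_reads = "LeftWtReads", wt3_reads = "RightWtReads",
       left_af = "LeftAF", right_af = "RightAF",
       sample_id = sample_id, cohort = cohort)
}

#' Write fusion calls in the STAR-Fusion dialect
#' @param calls internal fusion-call data.frame.
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
write_fusion_calls <- function(calls, path) {
  out <- data.frame(calls$fusion_name, calls$junction_reads,
                    calls$spanning_frags, calls$gene5, calls$left_breakpoint,
                    calls$gene3, calls$right_breakpoint, calls$ffpm,
                    calls$large_anchor, calls$wt5_reads, calls$wt3_reads,
                    calls$sample_id, calls$cohort, check.names = FALSE)
  names(out) <- c("#FusionName", "JunctionReadCount", "SpanningFragCount",
                  "LeftGene", "LeftBreakpoint", "RightGene",
                  "RightBreakpoint", "FFPM", "LargeAnchorSupport",
                  "LeftWtReads", "RightWtReads", "sample_id", "cohort")
  write_tsv(out, path)
}

#' Parse fusion-caller output
#'
#' Reads a caller TSV under a column dialect into the package's internal
#' fusion-call table. Orientation is preserved: reciprocal calls (B::A vs
#' A::B) stay distinct records.
#'
#' @param path TSV file.
#' @param dialect column mapping, see \code{\link{star_fusion_dialect}}.
#' @return data.frame of fusion calls (one row per caller row).
#' @export
parse_fusion_calls <- function(path, dialect = star_fusion_dialect()) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  mandatory <- c("fusion_name", "junction_reads", "spanning_frags",
                 "left_gene", "left_breakpoint", "right_gene",
                 "right_breakpoint", "ffpm", "large_anchor", "sample_id")
  miss <- mandatory[!vapply(mandatory, function(f)
    dialect[[f]] %in% names(raw), logical(1))]
  if (length(miss))
    stop("fusion table lacks mandatory column(s): ",
         paste(vapply(miss, function(f) dialect[[f]], character(1)),
               collapse = ", "))
  has_wt <- dialect$wt5_reads %in% names(raw) &&
    dialect$wt3_reads %in% names(raw)
  has_af <- dialect$left_af %in% names(raw) && dialect$right_af %in% names(raw)
  if (!has_wt && !has_af)
    stop("fusion table must carry either wild-type read counts (",
         dialect$wt5_reads, "/", dialect$wt3_reads,
         ") or per-side allele frequencies (", dialect$left_af, "/",
         dialect$right_af, ")")
  num <- function(field) {
    v <- suppressWarnings(as.numeric(raw[[dialect[[field]]]]))
    bad <- which(is.na(v) & !is.na(raw[[dialect[[field]]]]) |
                   is.na(raw[[dialect[[field]]]]))
    if (length(bad))
      stop(sprintf("non-numeric '%s' value at line %d of %s",
                   dialect[[field]], bad[1] + 1L, path))
    v
  }
  if (nrow(raw) == 0) {
    return(data.frame(sample_id = character(0), cohort = character(0),
                      fusion_name = character(0), gene5 = character(0),
                      gene3 = character(0), left_breakpoint = character(0),
                      right_breakpoint = character(0),
                      junction_reads = integer(0), spanning_frags = integer(0),
                      ffpm = numeric(0), large_anchor = character(0),
                      wt5_reads = integer(0), wt3_reads = integer(0)))
  }
  junction <- num("junction_reads")
  if (has_wt) {
    wt5 <- num("wt5_reads"); wt3 <- num("wt3_reads")
  } else {
    af_l <- num("left_af"); af_r <- num("right_af")
    wt5 <- ifelse(af_l > 0, round(junction * (1 - af_l) / af_l), 0)
    wt3 <- ifelse(af_r > 0, round(junction * (1 - af_r) / af_r), 0)
  }
  calls <- data.frame(
    sample_id = as.character(raw[[dialect$sample_id]]),
    cohort = if (dialect$cohort %in% names(raw))
      as.character(raw[[dialect$cohort]]) else NA_character_,
    fusion_name = as.character(raw[[dialect$fusion_name]]),
    gene5 = as.character(raw[[dialect$left_gene]]),
    gene3 = as.character(raw[[dialect$right_gene]]),
    left_breakpoint = as.character(raw[[dialect$left_breakpoint]]),
    right_breakpoint = as.character(raw[[dialect$right_breakpoint]]),
    junction_reads = as.integer(junction),
    spanning_frags = as.integer(num("spanning_frags")),
    ffpm = num("ffpm"),
    large_anchor = as.character(raw[[dialect$large_anchor]]),
    wt5_reads = as.integer(wt5),
    wt3_reads = as.integer(wt3),
    stringsAsFactors = FALSE)
  bad <- calls$gene5 == calls$gene3
  if (any(bad))
    stop("self-fusion (gene5 == gene3) at line ", which(bad)[1] + 1L)
  calls
}

#' Evidence filter on a fusion call
#'
#' Pass requires at least one junction read, at least one spanning fragment,
#' FFPM of at least 0.1, and large-anchor support (reads covering at least 25
#' bases on both sides of the breakpoint, \code{YES_LDAS}). Boundaries are
#' inclusive ("at least").
#'
#' @param calls fusion-call data.frame.
#' @param min_junction,min_spanning,min_ffpm thresholds.
#' @return data.frame with \code{pass} and \code{reason} ("" when passing;
#'   otherwise the first failing field).
#' @export
evidence_filter <- function(calls, min_junction = 1, min_spanning = 1,
                            min_ffpm = 0.1) {
  reason <- rep("", nrow(calls))
  reason[calls$large_anchor != "YES_LDAS"] <- "large_anchor"
  reason[calls$ffpm < min_ffpm] <- "ffpm"
  reason[calls$spanning_frags < min_spanning] <- "spanning_frags"
  reason[calls$junction_reads < min_junction] <- "junction_reads"
  data.frame(pass = reason == "", reason = reason, stringsAsFactors = FALSE)
}

#' Fusion allele frequency
#'
#' Per side, \eqn{FAF_i = F_i / (F_i + WT_i)} where \eqn{F_i} is the number of
#' reads supporting the fusion breakpoint (junction reads) and \eqn{WT_i} the
#' reads supporting the wild-type fragment of that partner; the fusion's FAF
#' is the mean of the two sides. A side with \eqn{F_i + WT_i = 0} has FAF 0.
#'
#' @param calls fusion-call data.frame.
#' @return data.frame with \code{faf_l}, \code{faf_r}, \code{faf}.
#' @export
compute_faf <- function(calls) {
  f <- calls$junction_reads
  if (any(f < 0 | calls$wt5_reads < 0 | calls$wt3_reads < 0))
    stop("negative read counts in FAF computation")
  den_l <- f + calls$wt5_reads
  den_r <- f + calls$wt3_reads
  faf_l <- ifelse(den_l == 0, 0, f / den_l)
  faf_r <- ifelse(den_r == 0, 0, f / den_r)
  data.frame(faf_l = faf_l, faf_r = faf_r, faf = (faf_l + faf_r) / 2)
}

.pair_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

.is_rescued <- function(gene5, gene3, knowledge) {
  lk <- knowledge$leukemia_genes %||% character(0)
  gene5 %in% lk | gene3 %in% lk
}

#' Artifact filters on fusion calls
#'
#' Removes calls where either partner is a pseudogene; where the unordered
#' pair is paralogous; where either partner is an immunoglobulin/hemoglobin
#' gene; and promiscuous calls: all calls of a gene within a sample where the
#' gene partners with more than one distinct other gene in that sample (the
#' exact reciprocal pair counts as a single partner, so reciprocal fusions
#' survive). Calls involving known leukemia genes bypass the promiscuity
#' filter.
#'
#' @param calls fusion-call data.frame (evidence-passing).
#' @param knowledge knowledge tables, see \code{\link{load_knowledge}}.
#' @return list with \code{calls} (survivors) and \code{trail}
#'   (per input row: pass, stage, reason).
#' @export
artifact_filters <- function(calls, knowledge) {
  n <- nrow(calls)
  reason <- rep("", n)
  ps <- knowledge$pseudogenes %||% character(0)
  hit_ps <- calls$gene5 %in% ps | calls$gene3 %in% ps
  pp <- knowledge$paralog_pairs
  par_keys <- if (!is.null(pp) && nrow(pp)) .pair_key(pp$gene_a, pp$gene_b)
              else character(0)
  hit_par <- .pair_key(calls$gene5, calls$gene3) %in% par_keys
  ig <- knowledge$ig_hb_genes %||% character(0)
  hit_ig <- calls$gene5 %in% ig | calls$gene3 %in% ig
  reason[hit_ig] <- "immunoglobulin"
  reason[hit_par] <- "paralog"
  reason[hit_ps] <- "pseudogene"
  ## promiscuity on calls surviving the identity-based filters
  alive <- reason == ""
  if (any(alive)) {
    sub <- calls[alive, , drop = FALSE]
    key <- .pair_key(sub$gene5, sub$gene3)
    promisc <- rep(FALSE, nrow(sub))
    for (s in unique(sub$sample_id)) {
      in_s <- sub$sample_id == s
      pairs <- unique(key[in_s])
      genes <- unique(c(sub$gene5[in_s], sub$gene3[in_s]))
      for (g in genes) {
        partners <- unique(c(sub$gene3[in_s & sub$gene5 == g],
                             sub$gene5[in_s & sub$gene3 == g]))
        if (length(partners) > 1)
          promisc <- promisc | (in_s & (sub$gene5 == g | sub$gene3 == g))
      }
    }
    promisc <- promisc & !.is_rescued(sub$gene5, sub$gene3, knowledge)
    idx <- which(alive)[promisc]
    reason[idx] <- "promiscuous"
  }
  trail <- data.frame(sample_id = calls$sample_id,
                      fusion_name = calls$fusion_name,
                      pass = reason == "",
                      stage = ifelse(reason == "", "", "artifact"),
                      reason = reason, stringsAsFactors = FALSE)
  list(calls = calls[reason == "", , drop = FALSE], trail = trail)
}

## per-fusion aggregation used by the record-level filters
.aggregate_records <- function(calls) {
  if (nrow(calls) == 0) {
    return(list(records = data.frame(fusion_name = character(0),
                                     gene5 = character(0),
                                     gene3 = character(0),
                                     n_patients = integer(0),
                                     n_cohorts = integer(0),
                                     median_faf = numeric(0),
                                     median_faf_l = numeric(0),
                                     median_faf_r = numeric(0)),
                calls = calls))
  }
  faf <- compute_faf(calls)
  calls$faf_l <- faf$faf_l; calls$faf_r <- faf$faf_r; calls$faf <- faf$faf
  recs <- lapply(split(calls, calls$fusion_name), function(d) {
    data.frame(fusion_name = d$fusion_name[1],
               gene5 = d$gene5[1], gene3 = d$gene3[1],
               n_patients = length(unique(d$sample_id)),
               n_cohorts = length(unique(d$cohort)),
               median_faf = median(d$faf),
               median_faf_l = median(d$faf_l),
               median_faf_r = median(d$faf_r),
               stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs)
  rownames(recs) <- NULL
  list(records = recs, calls = calls)
}

#' Recurrence filters on aggregated fusion records
#'
#' Drops fusions present in the normal-tissue panel, fusions seen in a single
#' project, and fusions supported by fewer than \code{min_patients} patients.
#' Fusions involving known leukemia genes bypass the normal-panel and
#' single-project filters, but never the patient-count rule.
#'
#' @param records aggregated records from the cascade.
#' @param knowledge knowledge tables.
#' @param min_patients minimum number of supporting patients (default 5).
#' @return records with logical columns \code{fail_normal_panel},
#'   \code{fail_single_project}, \code{fail_min_patients}, \code{rescued}.
#' @export
recurrence_filters <- function(records, knowledge, min_patients = 5) {
  if (min_patients < 1) stop("min_patients must be >= 1")
  np <- knowledge$normal_panel
  np_keys <- if (!is.null(np) && nrow(np)) .pair_key(np$gene_a, np$gene_b)
             else character(0)
  rescued <- .is_rescued(records$gene5, records$gene3, knowledge)
  records$rescued <- rescued
  records$fail_normal_panel <-
    .pair_key(records$gene5, records$gene3) %in% np_keys & !rescued
  records$fail_single_project <- records$n_cohorts < 2 & !rescued
  records$fail_min_patients <- records$n_patients < min_patients
  records
}

#' FAF threshold filter
#'
#' Keeps fusions whose median FAF across supporting patients exceeds
#' \code{median_faf_min} (strict, per the ">0.1" rule) and whose lower-FAF
#' partner has a median individual FAF of at least \code{partner_median_min}.
#'
#' @param records aggregated records.
#' @param median_faf_min median FAF threshold (default 0.1, strict).
#' @param partner_median_min partner median threshold (default 0.01,
#'   inclusive).
#' @return records with a logical column \code{fail_faf}.
#' @export
faf_threshold_filter <- function(records, median_faf_min = 0.1,
                                 partner_median_min = 0.01) {
  low_partner <- pmin(records$median_faf_l, records$median_faf_r)
  records$fail_faf <- !(records$median_faf > median_faf_min &
                          low_partner >= partner_median_min)
  records
}

#' Classify a fusion against the knowledge catalog
#'
#' Matches the unordered gene pair against the known-fusion catalog with
#' precedence ALL > blood > solid; unmatched pairs are novel.
#'
#' @param records record data.frame with gene5/gene3.
#' @param knowledge knowledge tables (\code{known_fusions} with columns
#'   gene_a, gene_b, source).
#' @return character vector of classes.
#' @export
classify_fusion <- function(records, knowledge) {
  kf <- knowledge$known_fusions
  if (is.null(kf) || nrow(kf) == 0) return(rep("novel", nrow(records)))
  keys <- .pair_key(kf$gene_a, kf$gene_b)
  qk <- .pair_key(records$gene5, records$gene3)
  vapply(qk, function(k) {
    src <- kf$source[keys == k]
    if (any(src == "ALL")) "ALL"
    else if (any(src == "blood")) "blood"
    else if (any(src == "solid")) "solid"
    else "novel"
  }, character(1), USE.NAMES = FALSE)
}

#' Group fusions by their most recurrent partner
#'
#' Each fusion is labeled \code{"<GENE>-r"} after the member gene with the
#' larger total patient count across all retained fusions; ties break
#' lexicographically.
#'
#' @param records retained records.
#' @param calls supporting calls (for patient counting).
#' @return character vector of group labels aligned with \code{records}.
#' @export
group_by_partner <- function(records, calls) {
  keep <- calls$fusion_name %in% records$fusion_name
  calls <- calls[keep, , drop = FALSE]
  gene_patients <- list()
  for (i in seq_len(nrow(calls))) {
    for (g in c(calls$gene5[i], calls$gene3[i]))
      gene_patients[[g]] <- union(gene_patients[[g]], calls$sample_id[i])
  }
  counts <- vapply(gene_patients, length, integer(1))
  vapply(seq_len(nrow(records)), function(i) {
    pair <- c(records$gene5[i], records$gene3[i])
    cnt <- counts[pair]
    cnt[is.na(cnt)] <- 0L
    win <- pair[order(-cnt, pair)][1]
    paste0(win, "-r")
  }, character(1))
}

#' Mutual-exclusivity grouping
#'
#' Tests every fusion group against every other for mutual exclusivity using
#' the exact probabilistic co-occurrence model (\code{\link{cooccur_test}}).
#' A group with no pair showing significantly fewer co-occurrences than
#' expected (P_lt < alpha) is relabeled "Other".
#'
#' @param presence binary group x sample matrix.
#' @param alpha significance level (default 0.05).
#' @return named character vector mapping each group to itself or "Other".
#' @export
exclusivity_grouping <- function(presence, alpha = 0.05) {
  stopifnot(is.matrix(presence), nrow(presence) >= 2)
  groups <- rownames(presence)
  out <- setNames(groups, groups)
  m <- rowSums(presence > 0)
  for (g in groups) {
    if (m[[g]] <= 1) {
      warning("group ", g, " present in <= 1 sample; relabeled Other")
      out[[g]] <- "Other"
      next
    }
    others <- setdiff(groups, g)
    excl <- FALSE
    for (h in others) {
      if (m[[h]] == 0) next
      res <- cooccur_test(presence[g, ] > 0, presence[h, ] > 0)
      if (res$p_lt < alpha) { excl <- TRUE; break }
    }
    if (!excl) out[[g]] <- "Other"
  }
  out
}

#' Run the full fusion-prioritization cascade
#'
#' Applies, in order: evidence filter, identity-based artifact filters
#' (pseudogene, paralog, immunoglobulin), promiscuity filter, normal-panel,
#' single-project and minimum-patient recurrence filters, and the FAF
#' threshold filter; then classifies survivors, groups them by most recurrent
#' partner, and tests group-level mutual exclusivity.
#'
#' @param calls parsed fusion-call data.frame.
#' @param knowledge knowledge tables (\code{\link{load_knowledge}}).
#' @param min_patients minimum supporting patients (default 5).
#' @param median_faf_min median-FAF threshold (default 0.1, strict).
#' @param partner_median_min lower-partner median FAF threshold (default
#'   0.01).
#' @param exclusivity_alpha alpha for mutual-exclusivity testing; set to NULL
#'   to skip the exclusivity step.
#' @param all_samples optional full sample-id vector for the oncoprint
#'   matrix (defaults to samples seen in \code{calls}).
#' @return list with \code{survivors} (calls), \code{records} (per-fusion
#'   summary with class/group/medians and per-filter outcomes), \code{trail}
#'   (per input call: removal stage and reason), \code{oncoprint}
#'   (group x sample binary matrix) and \code{group_labels} (after
#'   exclusivity relabeling).
#' @export
fusion_cascade <- function(calls, knowledge, min_patients = 5,
                           median_faf_min = 0.1, partner_median_min = 0.01,
                           exclusivity_alpha = 0.05, all_samples = NULL) {
  trail <- data.frame(sample_id = calls$sample_id,
                      fusion_name = calls$fusion_name,
                      stage = "", reason = "", stringsAsFactors = FALSE)
  ev <- evidence_filter(calls)
  trail$stage[!ev$pass] <- "evidence"
  trail$reason[!ev$pass] <- paste0("evidence:", ev$reason[!ev$pass])
  alive <- ev$pass

  af <- artifact_filters(calls[alive, , drop = FALSE], knowledge)
  idx_alive <- which(alive)
  removed <- !af$trail$pass
  trail$stage[idx_alive[removed]] <- "artifact"
  trail$reason[idx_alive[removed]] <- af$trail$reason[removed]
  alive[idx_alive[removed]] <- FALSE

  agg <- .aggregate_records(calls[alive, , drop = FALSE])
  recs <- recurrence_filters(agg$records, knowledge, min_patients)
  recs <- faf_threshold_filter(recs, median_faf_min, partner_median_min)
  ## first failing record-level filter, in cascade order
  rec_reason <- ifelse(recs$fail_normal_panel, "normal_panel",
                ifelse(recs$fail_single_project, "single_project",
                ifelse(recs$fail_min_patients, "low_recurrence",
                ifelse(recs$fail_faf, "low_faf", ""))))
  names(rec_reason) <- recs$fusion_name
  drop_rec <- rec_reason[trail$fusion_name]
  drop_rec[is.na(drop_rec)] <- ""
  rec_removed <- alive & drop_rec != ""
  trail$stage[rec_removed] <- "record"
  trail$reason[rec_removed] <- drop_rec[rec_removed]
  alive <- alive & drop_rec == ""

  survivors <- calls[alive, , drop = FALSE]
  kept <- recs[rec_reason[recs$fusion_name] == "", , drop = FALSE]
  if (nrow(kept)) {
    kept$class <- classify_fusion(kept, knowledge)
    kept$group <- group_by_partner(kept, survivors)
  } else {
    kept$class <- character(0)
    kept$group <- character(0)
  }

  samples <- all_samples %||% sort(unique(calls$sample_id))
  groups <- sort(unique(kept$group))
  onco <- matrix(0L, length(groups), length(samples),
                 dimnames = list(groups, samples))
  if (nrow(kept)) {
    grp_of <- setNames(kept$group, kept$fusion_name)
    for (i in seq_len(nrow(survivors))) {
      g <- grp_of[[survivors$fusion_name[i]]]
      onco[g, survivors$sample_id[i]] <- 1L
    }
  }
  group_labels <- setNames(groups, groups)
  if (!is.null(exclusivity_alpha) && length(groups) >= 2)
    group_labels <- exclusivity_grouping(onco, exclusivity_alpha)

  list(survivors = survivors, records = kept, all_records = recs,
       trail = trail, oncoprint = onco, group_labels = group_labels)
}

#' Load knowledge tables from a directory
#'
#' Reads the TSV knowledge tables written by \code{\link{write_cohort}}:
#' pseudogenes, paralog pairs, immunoglobulin/hemoglobin genes, the
#' normal-tissue fusion panel, the known-fusion catalog and the
#' leukemia-mutated gene list.
#'
#' @param dir directory containing the tables.
#' @return named list of knowledge tables.
#' @export
load_knowledge <- function(dir) {
  list(pseudogenes = read_tsv(file.path(dir, "pseudogenes.tsv"))$gene,
       paralog_pairs = read_tsv(file.path(dir, "paralog_pairs.tsv")),
       ig_hb_genes = read_tsv(file.path(dir, "ig_hb_genes.tsv"))$gene,
       normal_panel = read_tsv(file.path(dir, "normal_panel.tsv")),
       known_fusions = read_tsv(file.path(dir, "known_fusions.tsv")),
       leukemia_genes = read_tsv(file.path(dir, "leukemia_genes.tsv"))$gene)
}
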