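`%||%` <- function(a, b) if (is.null(a)) b else a

#' Logit with clipping
#'
#' PSI values of exactly 0 or 1 have no finite logit; values are clipped to
#' \code{[eps, 1 - eps]} before transformation.
#'
#' @param p numeric vector in [0, 1].
#' @param eps clipping bound (default 0.01).
#' @return numeric vector of logits.
#' @export
clogit <- function(p, eps = 0.01) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed from the rank-sum statistic with ties
#' averaged (equivalent to the Mann-Whitney U scaled by the number of
#' positive/negative pairs).
#'
#' @param score numeric scores (higher = more likely positive).
#' @param label binary labels (0/1, logical or two-level factor).
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(score, label) {
  label <- as.integer(as.factor(label)) - 1L
  stopifnot(all(label %in% c(0L, 1L)))
  n1 <- sum(label == 1L)
  n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) stop("rank_auc: both classes must be present")
  r <- rank(score)
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' GC content of a sequence
#' @param x character vector of ACGT strings.
#' @return numeric fraction of G+C per element.
#' @export
gc_content <- function(x) {
  n <- nchar(x)
  gc <- vapply(strsplit(toupper(x), ""), function(ch) sum(ch %in% c("G", "C")),
               integer(1))
  ifelse(n > 0, gc / n, NA_real_)
}

reverse_complement <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

#' Derive a per-stage seed from the global seed
#'
#' Fans one global seed out to stable per-stage seeds (below 2^31) so that
#' individual stages can be re-run in isolation reproducibly.
#'
#' @param seed integer global seed.
#' @param stage stage name (e.g. "simulate", "risk", "motifs").
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, fusions = 211L, expression = 307L, risk = 401L,
            splicing = 503L, motifs = 601L, cooccur = 701L, gsea = 811L)
  o <- offs[[stage]] %||% 997L
  as.integer((as.numeric(seed) * 1009 + o) %% 2147483647)
}

stop_fields <- function(cond, msg, ...) {
  if (cond) stop(sprintf(msg, ...), call. = FALSE)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE, ...)
}
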