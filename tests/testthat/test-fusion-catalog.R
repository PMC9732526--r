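test_that("caller TSV round-trips field-exact through the parser", {
  set.seed(1)
  calls <- do.call(rbind, lapply(1:10, function(i)
    make_call(sprintf("S%02d", i), paste0("G", i), paste0("H", i),
              cohort = c("C1", "C2")[1 + i %% 2],
              junction = 3L + i, spanning = 2L + i, ffpm = 0.2 * i,
              wt5 = 10L + i, wt3 = 30L - i)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fusion_calls(calls, path)
  parsed <- parse_fusion_calls(path)
  expect_equal(parsed, calls)
})

test_that("parser handles empty files and flags malformed rows and columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste("#FusionName", "JunctionReadCount", "SpanningFragCount",
               "LeftGene", "LeftBreakpoint", "RightGene", "RightBreakpoint",
               "FFPM", "LargeAnchorSupport", "LeftWtReads", "RightWtReads",
               "sample_id", "cohort", sep = "\t")
  writeLines(hdr, path)
  expect_equal(nrow(parse_fusion_calls(path)), 0)
  writeLines(c(hdr, paste("A--B", "NA", 3, "A", "chr1:5:+", "B", "chr1:9:+",
                          1, "YES_LDAS", 10, 10, "s1", "C1", sep = "\t")),
             path)
  expect_error(parse_fusion_calls(path), "line 2")
  writeLines(sub("\tJunctionReadCount", "", hdr), path)
  expect_error(parse_fusion_calls(path), "JunctionReadCount")
})

test_that("wild-type reads can be inverted from per-side allele frequencies", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste("#FusionName", "JunctionReadCount", "SpanningFragCount",
               "LeftGene", "LeftBreakpoint", "RightGene", "RightBreakpoint",
               "FFPM", "LargeAnchorSupport", "LeftAF", "RightAF",
               "sample_id", sep = "\t")
  row <- paste("A--B", 10, 3, "A", "chr1:5:+", "B", "chr1:9:+", 1,
               "YES_LDAS", 0.25, 0.5, "s1", sep = "\t")
  writeLines(c(hdr, row), path)
  parsed <- parse_fusion_calls(path)
  expect_equal(parsed$wt5_reads, 30L)  # 10 * (1 - .25)/.25
  expect_equal(parsed$wt3_reads, 10L)
})

test_that("evidence filter applies inclusive caller thresholds", {
  calls <- rbind(make_call("s", "A", "B", junction = 1, spanning = 1,
                           ffpm = 0.1),
                 make_call("s", "C", "D", junction = 5, spanning = 3,
                           ffpm = 0.05),
                 make_call("s", "E", "F", junction = 0, spanning = 9,
                           ffpm = 2.0),
                 make_call("s", "G", "H", anchor = "NO_LDAS"))
  ev <- evidence_filter(calls)
  expect_equal(ev$pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(ev$reason, c("", "ffpm", "junction_reads", "large_anchor"))
})

test_that("FAF follows the per-side read-support definition", {
  faf <- compute_faf(make_call("s", "A", "B", junction = 3, wt5 = 9, wt3 = 9))
  expect_equal(unlist(faf), c(faf_l = 0.25, faf_r = 0.25, faf = 0.25))
  faf0 <- compute_faf(make_call("s", "A", "B", junction = 0, wt5 = 50,
                                wt3 = 50))
  expect_equal(faf0$faf, 0)
  expect_error(compute_faf(make_call("s", "A", "B", wt5 = -1)), "negative")
})

test_that("FAF is bounded and invariant under swapping the partners", {
  set.seed(42)
  calls <- do.call(rbind, lapply(1:50, function(i)
    make_call("s", "A", "B", junction = sample(0:40, 1),
              wt5 = sample(0:80, 1), wt3 = sample(0:80, 1))))
  faf <- compute_faf(calls)
  expect_true(all(faf$faf >= 0 & faf$faf <= 1))
  swapped <- calls
  swapped$gene5 <- calls$gene3; swapped$gene3 <- calls$gene5
  swapped$wt5_reads <- calls$wt3_reads; swapped$wt3_reads <- calls$wt5_reads
  expect_equal(compute_faf(swapped)$faf, faf$faf)
})

test_that("promiscuity removes multi-partner genes but spares reciprocals", {
  kn <- empty_knowledge()
  calls <- rbind(make_call("s1", "A", "B"), make_call("s1", "A", "C"),
                 make_call("s2", "X", "Y"), make_call("s2", "Y", "X"))
  res <- artifact_filters(calls, kn)
  expect_setequal(res$calls$fusion_name, c("X--Y", "Y--X"))
  expect_equal(res$trail$reason[1:2], c("promiscuous", "promiscuous"))
})

test_that("identity-based artifact filters remove flagged partners", {
  kn <- empty_knowledge()
  kn$pseudogenes <- "PSG1"
  kn$paralog_pairs <- data.frame(gene_a = "P1", gene_b = "P2")
  kn$ig_hb_genes <- c("IGH", "HBB")
  calls <- rbind(make_call("s1", "PSG1", "B"), make_call("s1", "P1", "P2"),
                 make_call("s1", "IGH", "HBB"), make_call("s1", "U", "V"))
  res <- artifact_filters(calls, kn)
  expect_equal(res$calls$fusion_name, "U--V")
  expect_equal(res$trail$reason,
               c("pseudogene", "paralog", "immunoglobulin", ""))
})

test_that("artifact filtering is invariant to call order", {
  kn <- empty_knowledge()
  kn$pseudogenes <- "PSG1"
  kn$ig_hb_genes <- "IGH"
  set.seed(9)
  calls <- rbind(make_call("s1", "PSG1", "B"), make_call("s1", "IGH", "C"),
                 make_call("s1", "A", "B"), make_call("s1", "A", "C"),
                 make_call("s2", "D", "E"))
  r1 <- artifact_filters(calls, kn)
  r2 <- artifact_filters(calls[sample(nrow(calls)), ], kn)
  expect_setequal(paste(r1$calls$sample_id, r1$calls$fusion_name),
                  paste(r2$calls$sample_id, r2$calls$fusion_name))
})

test_that("recurrence filters enforce panel, project and patient rules", {
  kn <- empty_knowledge()
  kn$leukemia_genes <- "KMT2A"
  kn$normal_panel <- data.frame(gene_a = "N1", gene_b = "N2")
  calls <- rbind(
    ## known-leukemia fusion in 4 patients: still dropped (< 5 patients)
    do.call(rbind, lapply(1:4, function(i)
      make_call(paste0("a", i), "KMT2A", "AFF1",
                cohort = c("C1", "C2")[1 + i %% 2]))),
    ## 6 patients but a single cohort, not rescued
    do.call(rbind, lapply(1:6, function(i)
      make_call(paste0("b", i), "G1", "G2", cohort = "C1"))),
    ## rescued: single cohort but leukemia gene, 5 patients
    do.call(rbind, lapply(1:5, function(i)
      make_call(paste0("c", i), "KMT2A", "MLLT3", cohort = "C1"))),
    ## normal-panel pair, well supported
    do.call(rbind, lapply(1:6, function(i)
      make_call(paste0("d", i), "N1", "N2",
                cohort = c("C1", "C2")[1 + i %% 2]))))
  res <- fusion_cascade(calls, kn, exclusivity_alpha = NULL)
  expect_setequal(res$records$fusion_name, "KMT2A--MLLT3")
  reasons <- setNames(res$trail$reason, res$trail$fusion_name)
  expect_equal(unname(reasons["KMT2A--AFF1"]), "low_recurrence")
  expect_equal(unname(reasons["G1--G2"]), "single_project")
  expect_equal(unname(reasons["N1--N2"]), "normal_panel")
  expect_error(recurrence_filters(data.frame(), kn, min_patients = 0),
               "min_patients")
})

test_that("FAF threshold uses a strict median rule and a partner floor", {
  recs <- data.frame(fusion_name = c("A--B", "C--D", "E--F"),
                     gene5 = c("A", "C", "E"), gene3 = c("B", "D", "F"),
                     n_patients = 5L, n_cohorts = 2L,
                     median_faf = c(0.08, 0.25, 0.1),
                     median_faf_l = c(0.05, 0.02, 0.1),
                     median_faf_r = c(0.11, 0.4, 0.1))
  out <- faf_threshold_filter(recs)
  ## {0.05,0.08,0.09}-like median below 0.1 -> dropped; 0.25 kept;
  ## boundary exactly 0.1 -> dropped (strict >)
  expect_equal(out$fail_faf, c(TRUE, FALSE, TRUE))
  low_partner <- faf_threshold_filter(transform(recs[2, ],
                                                median_faf_l = 0.005))
  expect_true(low_partner$fail_faf)
})

test_that("classification matches unordered pairs with ALL precedence", {
  kn <- empty_knowledge()
  kn$known_fusions <- data.frame(
    gene_a = c("A", "A", "S", "R"), gene_b = c("B", "B", "T", "Q"),
    source = c("ALL", "solid", "solid", "blood"))
  recs <- data.frame(gene5 = c("A", "B", "S", "Q", "X"),
                     gene3 = c("B", "A", "T", "R", "Y"))
  expect_equal(classify_fusion(recs, kn),
               c("ALL", "ALL", "solid", "blood", "novel"))
})

test_that("partner grouping counts patients and breaks ties lexicographically", {
  calls <- rbind(
    do.call(rbind, lapply(1:80, function(i)
      make_call(paste0("k", i), "KMT2A", if (i <= 30) "AFF1" else "MLLT3"))),
    do.call(rbind, lapply(1:10, function(i)
      make_call(paste0("t", i), "XYZ", "ABC"))))
  recs <- data.frame(
    fusion_name = c("KMT2A--AFF1", "KMT2A--MLLT3", "XYZ--ABC"),
    gene5 = c("KMT2A", "KMT2A", "XYZ"),
    gene3 = c("AFF1", "MLLT3", "ABC"))
  ## KMT2A spans 80 retained patients vs AFF1's 30 / MLLT3's 50;
  ## XYZ--ABC is a 10/10 tie broken lexicographically
  expect_equal(group_by_partner(recs, calls),
               c("KMT2A-r", "KMT2A-r", "ABC-r"))
  single <- make_call("s1", "W", "Z")
  rec1 <- data.frame(fusion_name = "W--Z", gene5 = "W", gene3 = "Z")
  expect_equal(group_by_partner(rec1, single), "W-r")
})

test_that("mutual-exclusivity grouping retains exclusive groups only", {
  ## two perfectly exclusive groups covering 100 samples 50/50
  pres <- rbind(A = c(rep(1, 50), rep(0, 50)),
                B = c(rep(0, 50), rep(1, 50)))
  colnames(pres) <- paste0("s", 1:100)
  expect_equal(unname(exclusivity_grouping(pres)), c("A", "B"))
  ## a group occurring independently of the others is mostly relabeled
  set.seed(5)
  other <- replicate(30, {
    pres3 <- rbind(pres, C = rbinom(100, 1, 0.3))
    exclusivity_grouping(pres3)[["C"]] == "Other"
  })
  expect_gte(mean(other), 0.7)
  ## degenerate single-sample group
  pres2 <- rbind(A = c(1, rep(0, 19)), B = c(0, 1, rep(0, 18)))
  expect_warning(lab <- exclusivity_grouping(pres2), "Other|<= 1")
  expect_true(all(lab == "Other"))
})

test_that("every cascade filter only removes records and explains removals", {
  b <- generate_cohort(small_spec(seed = 2))
  res <- fusion_cascade(b$fusion_calls, b$knowledge)
  expect_true(all(res$survivors$fusion_name %in% b$fusion_calls$fusion_name))
  expect_lte(nrow(res$survivors), nrow(b$fusion_calls))
  removed <- res$trail[res$trail$stage != "", ]
  expect_true(all(nzchar(removed$reason)))
  kept_keys <- paste(res$survivors$sample_id, res$survivors$fusion_name)
  trail_kept <- res$trail[res$trail$stage == "", ]
  expect_setequal(kept_keys,
                  paste(trail_kept$sample_id, trail_kept$fusion_name))
})
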