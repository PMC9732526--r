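test_that("a two-isoform cassette gene yields exactly one SE event", {
  ann <- seven_type_annotation()
  ev <- generate_events(ann)
  se <- ev[ev$gene_id == "GSE", ]
  expect_equal(nrow(se), 1)
  expect_equal(se$type, "SE")
  expect_equal(se$event_id, "GSE;SE:chr1:1100-1201:1300-1401:+")
  expect_equal(se$inclusion_tx, "GSE.t1")
  expect_setequal(strsplit(se$total_tx, ",")[[1]], c("GSE.t1", "GSE.t2"))
})

test_that("all seven event types are produced with hand-written signatures", {
  ann <- seven_type_annotation()
  ev <- generate_events(ann)
  expect_equal(sort(unique(ev$type)),
               c("A3", "A5", "AF", "AL", "MX", "RI", "SE"))
  want <- c(
    "GRI;RI:chr1:2001:2100-2201:2300:+",
    "GA3;A3:chr1:3100-3201:3100-3231:+",
    "GA5;A5:chr1:4100-4201:4130-4201:+",
    "GMX;MX:chr1:5100-5201:5300-5501:5100-5351:5450-5501:+",
    "GAF;AF:chr1:6001:6100-6401:6201:6300-6401:+",
    "GAL;AL:chr1:7100-7201:7300:7100-7401:7500:+")
  for (w in want) expect_true(w %in% ev$event_id, label = w)
  ## one event per gene in this toy set
  expect_equal(nrow(ev), 7)
})

test_that("single-isoform genes produce no events and bad genes are skipped", {
  ann <- toy_annotation()     # two genes, one transcript each
  expect_equal(nrow(generate_events(ann)), 0)
  bad <- seven_type_annotation()
  bad$exons$end[bad$exons$tx_id == "GSE.t1"][1] <- 1250  # overlaps exon 2
  expect_warning(ev <- generate_events(bad), "GSE")
  expect_false(any(ev$gene_id == "GSE"))
})

test_that("event generation ignores transcript and exon input order", {
  ann <- seven_type_annotation()
  ann2 <- ann
  ann2$transcripts <- ann2$transcripts[rev(seq_len(nrow(ann2$transcripts))), ]
  ann2$exons <- ann2$exons[sample(nrow(ann2$exons)), ]
  expect_equal(generate_events(ann2), generate_events(ann))
})

test_that("PSI follows inclusion/total TPM with the 1-TPM rule", {
  ann <- seven_type_annotation()
  ev <- generate_events(ann)[1, , drop = FALSE]   # the A3 or first event
  ev <- generate_events(ann)
  se <- ev[ev$gene_id == "GSE", , drop = FALSE]
  tpm <- matrix(0, 2, 3, dimnames = list(c("GSE.t1", "GSE.t2"),
                                         c("s1", "s2", "s3")))
  tpm["GSE.t1", ] <- c(3, 0.5, 0)
  tpm["GSE.t2", ] <- c(1, 0.3, 0)
  pq <- compute_psi(se, tpm)
  expect_equal(unname(pq$psi[1, ]), c(0.75, NA, NA))
  expect_error(compute_psi(se, tpm[1, , drop = FALSE]), "missing")
})

test_that("SE PSI of two-isoform genes is complementary by construction", {
  b <- generate_cohort(small_spec(seed = 3))
  ev <- generate_events(b$annotation)
  se <- ev[ev$type == "SE", ]
  pq <- compute_psi(se, b$tpm)
  ## inclusion PSI + exclusion share = 1 exactly where defined
  for (i in sample(nrow(se), 5)) {
    incl <- strsplit(se$inclusion_tx[i], ",")[[1]]
    tot <- strsplit(se$total_tx[i], ",")[[1]]
    excl <- setdiff(tot, incl)
    share <- colSums(b$tpm[excl, , drop = FALSE]) /
      colSums(b$tpm[tot, , drop = FALSE])
    ok <- !is.na(pq$psi[i, ])
    expect_equal(unname(pq$psi[i, ok] + share[ok]), rep(1, sum(ok)))
  }
})

test_that("missingness filtering and KNN imputation follow the rules", {
  set.seed(17)
  psi <- matrix(runif(20 * 100), 20, 100,
                dimnames = list(paste0("e", 1:20), paste0("s", 1:100)))
  psi[1, 1:11] <- NA          # 11% missing -> dropped
  psi[2, 1:10] <- NA          # 10% missing -> kept and imputed
  out <- filter_and_impute(psi, k = 3)
  expect_false("e1" %in% rownames(out))
  expect_true("e2" %in% rownames(out))
  expect_false(anyNA(out))
  ## observed entries are untouched
  obs <- !is.na(psi["e2", ])
  expect_identical(out["e2", obs], psi["e2", obs])
  ## identity on complete matrices
  full <- psi[3:20, ]
  expect_identical(filter_and_impute(full, k = 3), full)
  ## forced neighbor: a duplicated row determines the imputed value
  dup <- rbind(a = psi[3, ], b = psi[3, ], psi[4:10, ])
  dup["a", 5] <- NA
  imp <- filter_and_impute(dup, k = 1)
  expect_equal(imp["a", 5], unname(psi[3, 5]))
  expect_error(filter_and_impute(psi, k = 50), "smaller")
})

test_that("imputed values stay within the neighbor range", {
  set.seed(23)
  psi <- matrix(runif(15 * 40), 15, 40,
                dimnames = list(paste0("e", 1:15), paste0("s", 1:40)))
  psi[5, 7] <- NA
  out <- filter_and_impute(psi, k = 4)
  others <- psi[-5, 7]
  expect_gte(out[5, 7], min(others))
  expect_lte(out[5, 7], max(others))
})

test_that("the logit-linear test reduces to a t-test without covariates", {
  set.seed(29)
  psi <- matrix(rbeta(10 * 60, 5, 5), 10, 60,
                dimnames = list(paste0("e", 1:10), paste0("s", 1:60)))
  grp <- factor(rep(c("low", "high"), each = 30), levels = c("low", "high"))
  ds <- diff_splice(psi, grp, sd_min = 0)
  for (i in 1:10) {
    y <- clogit(psi[i, ])
    tt <- t.test(y[grp == "high"], y[grp == "low"], var.equal = TRUE)
    expect_equal(ds$p[ds$event_id == paste0("e", i)], tt$p.value,
                 tolerance = 1e-10)
  }
  ## dPSI is reported on the raw scale
  expect_equal(ds$dpsi[1],
               mean(psi[1, grp == "high"]) - mean(psi[1, grp == "low"]),
               tolerance = 1e-12)
})

test_that("constant events are removed by the SD filter", {
  psi <- rbind(flat = rep(0.5, 40),
               var = rbeta(40, 2, 2))
  colnames(psi) <- paste0("s", 1:40)
  grp <- factor(rep(c("a", "b"), each = 20))
  ds <- diff_splice(psi, grp)
  expect_false("flat" %in% ds$event_id)
  expect_error(diff_splice(psi, grp, covariates = data.frame(x = grp)),
               "confounded")
})

test_that("significance calls are stable under the logit clipping choice", {
  set.seed(37)
  psi <- matrix(rbeta(40 * 60, 8, 8), 40, 60,
                dimnames = list(paste0("e", 1:40), paste0("s", 1:60)))
  grp <- factor(rep(c("low", "high"), each = 30), levels = c("low", "high"))
  psi[1:10, grp == "high"] <- pmin(psi[1:10, grp == "high"] + 0.35, 0.999)
  d1 <- diff_splice(psi, grp, eps = 0.01)
  d2 <- diff_splice(psi, grp, eps = 0.001)
  expect_equal(d1$significant, d2$significant)
})

test_that("binarization uses a strict 0.5 cutoff", {
  psi <- matrix(c(0.51, 0.5, 0.4, 0.4), 2, 2,
                dimnames = list(c("e1", "e2"), c("s1", "s2")))
  bin <- binarize_inclusion(psi)
  expect_equal(unname(bin[1, ]), c(1, 1) * c(1, 0))
  expect_equal(unname(bin["e2", ]), c(0, 0))
})

test_that("PSI/expression correlation matches the covariance formula", {
  set.seed(3)
  psi <- matrix(runif(3 * 30), 3, 30,
                dimnames = list(c("e1", "e2", "e3"), paste0("s", 1:30)))
  events <- data.frame(event_id = c("e1", "e2", "e3"),
                       gene_id = c("g1", "g2", "g3"))
  lcpm <- rbind(g1 = 2 * psi[1, ] + 3,          # affine -> r = 1
                g2 = rnorm(30),
                g3 = rep(1, 30))                # zero variance
  colnames(lcpm) <- colnames(psi)
  res <- psi_expression_correlation(events, psi, lcpm)
  expect_equal(res$per_event$r[1], 1, tolerance = 1e-12)
  manual <- cov(psi[2, ], lcpm["g2", ]) / (sd(psi[2, ]) * sd(lcpm["g2", ]))
  expect_equal(res$per_event$r[2], manual, tolerance = 1e-12)
  expect_true(is.na(res$per_event$r[3]))
  expect_match(res$per_event$note[3], "zero variance")
})
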