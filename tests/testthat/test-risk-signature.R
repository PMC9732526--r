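test_that("the candidate gate requires both contrasts and set membership", {
  lfc_r <- c(g1 = 0.6, g2 = 0.6, g3 = 0.7, g4 = 0.9)
  lfc_f <- c(g1 = 0.7, g2 = 0.4, g3 = 0.8, g4 = 0.9)
  sets <- list(myc = c("g1", "g2"), transl = "g3")
  ## g1: both contrasts + member; g2 fails the fusion contrast;
  ## g3 passes; g4 passes both contrasts but belongs to no set
  expect_setequal(select_candidates(lfc_r, lfc_f, sets), c("g1", "g3"))
  expect_error(select_candidates(c(g1 = 0.1), c(g1 = 0.1), sets),
               "no candidate genes")
})

test_that("Cox filter keeps prognostic genes and flags degenerate input", {
  set.seed(31)
  n <- 120
  x <- rnorm(n)
  lambda <- log(2) / 1000 * exp(log(2) * x)   # HR = 2 per unit
  t_ev <- rexp(n, lambda); cens <- runif(n, 200, 3000)
  clin <- data.frame(sample_id = paste0("s", 1:n),
                     age_years = runif(n, 1, 18),
                     sex = sample(c("M", "F"), n, TRUE),
                     efs_time_days = pmin(t_ev, cens),
                     relapse = as.integer(t_ev <= cens))
  lcpm <- rbind(strong = x, null = rnorm(n), flat = rep(1, n))
  colnames(lcpm) <- clin$sample_id
  res <- cox_filter(c("strong", "null", "flat"), lcpm, clin)
  expect_true(res$keep[res$gene == "strong"])
  expect_match(res$note[res$gene == "flat"], "constant")
  expect_false(res$keep[res$gene == "flat"])
  expect_error(cox_filter("strong", lcpm,
                          transform(clin, relapse = 0L)), "no relapse")
})

test_that("variability filter removes cross-cohort unstable genes", {
  cohort <- rep(c("A", "B", "C"), each = 10)
  mk <- function(means) {
    x <- unlist(lapply(means, rep, 10))
    x
  }
  lcpm <- rbind(unstable = mk(c(5.0, 5.5, 8.2)),
                stable = mk(c(5, 5, 5)))
  colnames(lcpm) <- paste0("s", 1:30)
  vf <- variability_filter(c("unstable", "stable"), lcpm, cohort)
  expect_equal(vf$keep, c(FALSE, TRUE))
  expect_equal(vf$max_diff[1], 3.2, tolerance = 1e-12)
})

test_that("a 39-candidate set with 2 unstable genes yields 37 survivors", {
  set.seed(55)
  cohort <- rep(c("A", "B", "C"), each = 8)
  genes <- sprintf("c%02d", 1:39)
  lcpm <- matrix(rnorm(39 * 24, 5, 0.2), 39, 24,
                 dimnames = list(genes, paste0("s", 1:24)))
  lcpm[1, cohort == "C"] <- lcpm[1, cohort == "C"] + 4
  lcpm[2, cohort == "A"] <- lcpm[2, cohort == "A"] - 3.5
  vf <- variability_filter(genes, lcpm, cohort)
  expect_equal(sum(vf$keep), 37)
  expect_setequal(vf$gene[!vf$keep], c("c01", "c02"))
})

test_that("k-scores are vote fractions with consistent classes", {
  set.seed(41)
  n <- 40
  x <- matrix(rnorm(n * 5), n, dimnames = list(paste0("s", 1:n),
                                               paste0("g", 1:5)))
  y <- as.integer(x[, 1] > 0)          # perfectly separable on g1
  x[, 1] <- x[, 1] + 3 * y             # widen the margin
  model <- train_risk_model(x, y, n_trees = 100, seed = 3)
  sc <- apply_model(model, x)
  expect_true(all(sc$k_score >= 0 & sc$k_score <= 1))
  expect_true(all((sc$k_score >= 0.7) == (sc$class == "high")))
  ## unanimous votes reach exactly 1 for clear relapse samples
  expect_equal(max(sc$k_score), 1)
})

test_that("LOO scorecard separates planted classes and respects folds", {
  set.seed(42)
  n <- 30
  x <- matrix(rnorm(n * 4), n, dimnames = list(paste0("s", 1:n),
                                               paste0("g", 1:4)))
  y <- rep(c(0L, 1L), each = n / 2)
  x[y == 1, ] <- x[y == 1, ] + 2.5
  sc <- train_and_score_loo(x, y, n_trees = 100, seed = 7)
  expect_gte(rank_auc(sc$k_score, sc$label), 0.9)
  ## determinism under the same seed
  sc2 <- train_and_score_loo(x, y, n_trees = 100, seed = 7)
  expect_identical(sc, sc2)
  expect_error(train_and_score_loo(x[1:10, ], y[1:10]), "at least 20")
})

test_that("sensitivity is non-increasing along the threshold sweep", {
  set.seed(2)
  sc <- data.frame(k_score = runif(50), label = rbinom(50, 1, 0.4))
  ths <- seq(0, 1, 0.05)
  sens <- vapply(ths, function(t)
    sum(sc$k_score >= t & sc$label == 1) / sum(sc$label == 1), numeric(1))
  expect_true(all(diff(sens) <= 1e-12))
})

test_that("evaluation returns exact AUC extremes and log-rank arithmetic", {
  sc_perfect <- data.frame(k_score = c(0.9, 0.8, 0.2, 0.1),
                           class = c("high", "high", "low", "low"),
                           label = c(1, 1, 0, 0))
  expect_equal(evaluate_risk(sc_perfect)$auc, 1)
  set.seed(19)
  sc_rand <- data.frame(k_score = runif(2000),
                        class = "low", label = rbinom(2000, 1, 0.5))
  expect_equal(evaluate_risk(sc_rand)$auc, 0.5, tolerance = 0.05)
  ## tie-averaged rank AUC agrees with the pROC reference
  skip_if_not_installed("pROC")
  sc_tie <- data.frame(k_score = sample(seq(0, 1, 0.1), 100, TRUE),
                       label = rbinom(100, 1, 0.5))
  ref <- as.numeric(pROC::auc(pROC::roc(sc_tie$label, sc_tie$k_score,
                                        direction = "<", quiet = TRUE)))
  expect_equal(rank_auc(sc_tie$k_score, sc_tie$label), ref,
               tolerance = 1e-12)
  ## six-subject worked example: log-rank statistic vs hand computation
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 1, 0, 1)
  cls <- c("high", "high", "high", "low", "low", "low")
  sc <- data.frame(k_score = c(.9, .9, .9, .1, .1, .1),
                   class = cls, label = event)
  ev <- evaluate_risk(sc, time, event)
  ## independent oracle: sum over event times of O - E for the high group
  oe <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    d <- sum(time == t & event == 1)
    n <- sum(at_risk); n1 <- sum(at_risk & cls == "high")
    o1 <- sum(time == t & event == 1 & cls == "high")
    e1 <- d * n1 / n
    oe <- oe + o1 - e1
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(ev$logrank$chisq, oe^2 / v, tolerance = 1e-10)
})

test_that("model application validates genes and imputes small gaps", {
  set.seed(43)
  x <- matrix(rnorm(600), 30, 20,
              dimnames = list(paste0("s", 1:30), paste0("g", 1:20)))
  y <- as.integer(rowMeans(x[, 1:3]) > 0)
  model <- train_risk_model(x, y, n_trees = 50, seed = 1)
  expect_error(apply_model(model, x[, 0]), "empty")
  expect_error(apply_model(model, x[, 1:15]), "missing")
  expect_warning(sc <- apply_model(model, x[, 1:19]), "mean-imputing")
  expect_equal(nrow(sc), 30)
})
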