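test_that("confusion matrices count truth rows against prediction columns", {
  cm <- confusion_matrix(sleep_stages, sleep_stages)
  expect_equal(unname(diag(cm)), rep(1L, 5))
  expect_equal(sum(cm), 5)
  cm2 <- confusion_matrix(c("W", "W"), c("N1", "N1"))
  expect_equal(cm2["W", "N1"], 2L)
  expect_equal(sum(cm2) - cm2["W", "N1"], 0L)
  expect_error(confusion_matrix("W", c("W", "N1")), "differ in length")
  # row normalisation has unit row sums for non-empty rows
  set.seed(1)
  cm3 <- confusion_matrix(sample(sleep_stages, 100, TRUE), sample(sleep_stages, 100, TRUE))
  rn <- row_normalize(cm3)
  expect_equal(unname(rowSums(rn)[rowSums(cm3) > 0]), rep(1, sum(rowSums(cm3) > 0)))
})

test_that("kappa matches its closed form and degenerate cases", {
  expect_equal(cohens_kappa(confusion_matrix(sleep_stages, sleep_stages)), 1)
  # constant predictor scores chance-level agreement exactly
  set.seed(2)
  truth <- sample(sleep_stages, 200, TRUE)
  expect_equal(cohens_kappa(confusion_matrix(truth, rep("N2", 200))), 0)
  # two-effective-class example: p_o = 0.8, p_e = 0.5 -> kappa = 0.6
  truth2 <- c(rep("W", 50), rep("N1", 50))
  pred2 <- c(rep("W", 45), rep("N1", 5), rep("W", 15), rep("N1", 35))
  expect_equal(cohens_kappa(confusion_matrix(truth2, pred2)), 0.6, tolerance = 1e-12)
  # both raters constant and identical: expected agreement is 1 and kappa
  # degenerates to 1; constant raters on different stages have p_e = 0
  expect_equal(cohens_kappa(confusion_matrix(rep("W", 4), rep("W", 4))), 1)
  expect_equal(cohens_kappa(confusion_matrix(rep("W", 4), rep("N1", 4))), 0)
})

test_that("macro-F1 averages per-class F1 with the stated edge rules", {
  truth <- c(rep("W", 50), rep("N1", 50))
  pred <- c(rep("W", 45), rep("N1", 5), rep("W", 15), rep("N1", 35))
  cm <- confusion_matrix(truth, pred)
  # per-class oracle: F1_W = 0.8182, F1_N1 = 0.7778
  f1 <- per_class_f1(cm)
  expect_equal(unname(f1["W"]), 2 * 0.75 * 0.9 / 1.65, tolerance = 1e-12)
  expect_equal(unname(f1["N1"]), 2 * 0.875 * 0.7 / 1.575, tolerance = 1e-12)
  expect_equal(macro_f1(cm), 0.7980, tolerance = 1e-4)
  expect_equal(macro_f1(confusion_matrix(sleep_stages, sleep_stages)), 1)
  # a class never predicted but present drags MF1 below accuracy
  t2 <- c(rep("N2", 90), rep("N1", 10))
  p2 <- rep("N2", 100)
  cm2 <- confusion_matrix(t2, p2)
  expect_lt(macro_f1(cm2), accuracy(cm2))
  expect_equal(unname(per_class_f1(cm2)["N1"]), 0)
})

test_that("kappa and MF1 match independent references on random matrices", {
  set.seed(99)
  for (i in 1:150) {
    n <- sample(50:400, 1)
    truth <- sample(sleep_stages, n, TRUE, prob = runif(5, 0.05, 1))
    pred <- ifelse(runif(n) < runif(1, 0.2, 0.9), truth, sample(sleep_stages, n, TRUE))
    cm <- confusion_matrix(truth, pred)
    ref_kappa <- e1071::classAgreement(unclass(cm))$kappa
    expect_equal(cohens_kappa(cm), ref_kappa, tolerance = 1e-10)
    tf <- factor(truth, levels = sleep_stages)
    pf <- factor(pred, levels = sleep_stages)
    ref_by <- caret::confusionMatrix(pf, tf)$byClass
    ref_f1 <- ref_by[, "F1"]
    ref_f1[is.na(ref_f1)] <- 0
    keep <- !(rowSums(cm) == 0 & colSums(cm) == 0)
    expect_equal(macro_f1(cm), mean(ref_f1[keep]), tolerance = 1e-10)
  }
})

test_that("metrics are invariant under a joint relabelling of stages", {
  set.seed(7)
  truth <- sample(sleep_stages, 300, TRUE)
  pred <- ifelse(runif(300) < 0.7, truth, sample(sleep_stages, 300, TRUE))
  cm <- confusion_matrix(truth, pred)
  perm <- c(W = "N3", N1 = "REM", N2 = "W", N3 = "N1", REM = "N2")
  cmp <- confusion_matrix(perm[truth], perm[pred])
  expect_equal(accuracy(cm), accuracy(cmp))
  expect_equal(cohens_kappa(cm), cohens_kappa(cmp), tolerance = 1e-12)
  expect_equal(macro_f1(cm), macro_f1(cmp), tolerance = 1e-12)
})

test_that("the stable/transitional split matches the neighbour rule", {
  expect_equal(stability_split(c("W", "W", "W", "N1", "N2", "N2", "N2")),
               c("transitional", "stable", "transitional", "transitional",
                 "transitional", "stable", "transitional"))
  const <- stability_split(rep("N2", 10))
  expect_equal(sum(const == "stable"), 8)
  expect_equal(const[c(1, 10)], rep("transitional", 2))
  alt <- stability_split(rep(c("W", "N1"), 5))
  expect_true(all(alt == "transitional"))
  # exhaustive partition for arbitrary hypnograms
  set.seed(3)
  for (i in 1:20) {
    s <- sample(sleep_stages, sample(1:50, 1), TRUE)
    f <- stability_split(s)
    expect_length(f, length(s))
    expect_true(all(f %in% c("stable", "transitional")))
  }
})

test_that("by-record metrics omit absent classes and pool additively", {
  df <- dplyr::bind_rows(
    tibble::tibble(record_id = "a", truth = c("W", "W", "N2", "N2", "N3"),
                   pred = c("W", "N2", "N2", "N2", "N3")),
    tibble::tibble(record_id = "b", truth = c("N1", "N1", "REM"),
                   pred = c("N1", "W", "REM")))
  br <- by_record_metrics(df)
  expect_equal(nrow(br), 2)
  # record "a" has no REM in truth: recall reported missing, not zero
  expect_true(is.na(br$recall_REM[br$record_id == "a"]))
  expect_equal(br$recall_W[br$record_id == "a"], 0.5)
  # single record reduces to the global by-epoch metrics
  one <- by_record_metrics(df[df$record_id == "a", ])
  expect_equal(one$accuracy, accuracy(confusion_matrix(df$truth[1:5], df$pred[1:5])))
  # pooled confusion equals by-epoch confusion on the concatenation
  cm_pool <- confusion_matrix(df$truth, df$pred)
  cm_sum <- unclass(confusion_matrix(df$truth[1:5], df$pred[1:5])) +
    unclass(confusion_matrix(df$truth[6:8], df$pred[6:8]))
  expect_equal(unclass(cm_pool), cm_sum)
})

test_that("metric reports serialise to JSON and CSV", {
  truth <- c("W", "N1", "N2", "N2", "REM")
  pred <- c("W", "N2", "N2", "N2", "REM")
  jf <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(truth, pred, jf, extra = list(split = "all"))
  rep <- jsonlite::read_json(jf)
  expect_equal(rep$schema, "nocturnet-metrics-1")
  expect_equal(rep$accuracy, 0.8)
  expect_equal(rep$split, "all")
  cf <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(confusion_matrix(truth, pred), cf)
  got <- read.csv(cf)
  expect_equal(got$truth, sleep_stages)
  expect_equal(got$N2[got$truth == "N1"], 1)
  sm <- staging_metrics(truth, pred)
  expect_equal(sm$n_epochs, 5)
  expect_true(is.na(sm$recall_N3))
})
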