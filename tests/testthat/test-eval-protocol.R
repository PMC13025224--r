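# Cross-validation splitters, metrics, majority voting, confidence intervals
# and the exact signed-rank comparison.

test_that("image-level folds are stratified exact partitions", {
  ids <- sprintf("img%03d", 1:120)
  labs <- rep(c("R", "NR"), each = 60)
  plan <- make_image_folds(ids, labs, n_folds = 6, seed = 7)
  test_sets <- lapply(plan$folds, `[[`, "test")
  expect_setequal(unlist(test_sets), ids)
  expect_identical(anyDuplicated(unlist(test_sets)), 0L)
  names(labs) <- ids
  for (f in plan$folds) {
    expect_identical(sum(labs[f$test] == "R"), 10L)
    expect_identical(sum(labs[f$test] == "NR"), 10L)
    # train/val/test partition the whole set; 90/10 of the 100 non-test
    expect_setequal(c(f$train, f$val, f$test), ids)
    expect_length(f$train, 90L)
    expect_length(f$val, 10L)
    expect_length(f$test, 20L)
  }
  expect_error(make_image_folds(ids[1:10], rep(c("R", "NR"), 5), n_folds = 6),
               "fewer images")
})

test_that("subject folds reproduce the cohort composition rules", {
  # 12R/18NR: six folds of (2R, 3NR)
  subj <- sprintf("S%02d", 1:30)
  labs <- c(rep("R", 12), rep("NR", 18))
  names(labs) <- subj
  plan <- make_subject_folds(subj, labs, n_folds = 6, seed = 1)
  for (f in plan$folds) {
    expect_identical(sum(labs[f$test] == "R"), 2L)
    expect_identical(sum(labs[f$test] == "NR"), 3L)
    expect_length(intersect(f$train, f$test), 0L)
    expect_length(intersect(f$val, f$test), 0L)
  }
  expect_setequal(unlist(lapply(plan$folds, `[[`, "test")), subj)

  # 23R/23NR: folds 1-5 test (4R, 4NR), fold 6 tests (3R, 3NR)
  subj2 <- sprintf("P%02d", 1:46)
  labs2 <- rep(c("R", "NR"), each = 23)
  names(labs2) <- subj2
  plan2 <- make_subject_folds(subj2, labs2, n_folds = 6, seed = 2)
  comp <- t(vapply(plan2$folds, function(f)
    c(R = sum(labs2[f$test] == "R"), NR = sum(labs2[f$test] == "NR")),
    c(R = 0L, NR = 0L)))
  expect_identical(comp[, "R"], c(4L, 4L, 4L, 4L, 4L, 3L))
  expect_identical(comp[, "NR"], c(4L, 4L, 4L, 4L, 4L, 3L))
  expect_identical(anyDuplicated(unlist(lapply(plan2$folds, `[[`, "test"))), 0L)

  expect_error(make_subject_folds(sprintf("S%d", 1:4), rep(c("R", "NR"), 2),
                                  n_folds = 6), "too small")
})

test_that("metrics match hand evaluation and brute-force recounts", {
  ms <- compute_metrics(confusion_counts(TP = 9, FP = 1, TN = 8, FN = 2))
  expect_equal(unclass(ms)[c("accuracy", "precision", "recall",
                             "specificity", "f1")],
               c(accuracy = 85, precision = 90, recall = 81.8181818181818,
                 specificity = 88.8888888888889, f1 = 85.7142857142857),
               tolerance = 1e-10)
  perfect <- compute_metrics(confusion_counts(5, 5, 0, 0))
  expect_true(all(unclass(perfect) == 100))
  expect_warning(
    deg <- compute_metrics(confusion_counts(TP = 0, TN = 4, FP = 0, FN = 0)),
    "undefined")
  expect_equal(deg[["recall"]], 0)
  expect_equal(deg[["specificity"]], 100)

  # 1000 random confusion tables against a recount from raw label pairs
  set.seed(10)
  for (i in 1:1000) {
    n <- sample(4:60, 1)
    truth <- sample(c("R", "NR"), n, replace = TRUE)
    pred <- sample(c("R", "NR"), n, replace = TRUE)
    ms <- suppressWarnings(compute_metrics(confusion_from_labels(truth, pred)))
    expect_equal(unclass(ms), brute_metrics(truth, pred), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("majority voting matches direct mode computation and breaks ties to NR", {
  # large-subject example: 200 of 380 images predicted R
  preds <- c(rep("R", 200), rep("NR", 180))
  v <- majority_vote(rep("S01", 380), preds)
  expect_identical(unname(v["S01"]), "R")
  # exact tie -> NR, and the tie is counted
  v2 <- majority_vote(rep(c("A", "B"), each = 4),
                      c("R", "R", "NR", "NR", "R", "R", "R", "NR"))
  expect_identical(unname(v2["A"]), "NR")
  expect_identical(unname(v2["B"]), "R")
  expect_identical(attr(v2, "n_ties"), 1L)
  # random inputs against a sort-based mode
  set.seed(11)
  for (i in 1:100) {
    subj <- sample(sprintf("S%d", 1:5), 40, replace = TRUE)
    preds <- sample(c("R", "NR"), 40, replace = TRUE)
    v <- majority_vote(subj, preds)
    for (s in unique(subj)) {
      tab <- sort(table(preds[subj == s]), decreasing = TRUE)
      want <- if (length(tab) == 2 && tab[1] == tab[2]) "NR" else names(tab)[1]
      expect_identical(unname(v[s]), want)
    }
  }
  expect_error(majority_vote(character(), character()), "at least one")
})

test_that("fold-accuracy confidence intervals match the closed-form t interval", {
  same <- subject_accuracy_ci(rep(80, 6))
  expect_equal(same$mean, 80)
  expect_equal(same$ci_low, 80)
  expect_equal(same$ci_high, 80)
  expect_equal(subject_accuracy_ci(c(100, 100, 100, 0, 0, 0))$mean, 50)
  set.seed(12)
  acc <- c(82.5, 90, 75, 80, 88, 79)
  ci <- subject_accuracy_ci(acc)
  half <- qt(0.975, 5) * sd(acc) / sqrt(6)
  expect_equal(ci$ci_low, mean(acc) - half, tolerance = 1e-12)
  expect_equal(ci$ci_high, mean(acc) + half, tolerance = 1e-12)
  single <- subject_accuracy_ci(80)
  expect_true(is.na(single$ci_low))
})

test_that("per-channel accuracy isolates the informative channel", {
  # two channels, four subjects; channel O1 predicts perfectly, Cz at chance
  subj <- rep(sprintf("S%d", 1:4), each = 6)
  truth <- rep(c("R", "R", "NR", "NR"), each = 6)
  chan <- rep(c("O1", "Cz"), 12)
  pred <- ifelse(chan == "O1", truth, rep(c("R", "NR"), 12))
  meta <- data.frame(subject_id = subj, channel = chan, truth = truth)
  pc <- per_channel_accuracy(meta, pred)
  expect_equal(unname(pc["O1"]), 100)
  expect_lt(pc["Cz"], 100)
  # single-channel input equals overall subject accuracy
  meta1 <- meta[meta$channel == "O1", ]
  pc1 <- per_channel_accuracy(meta1, pred[meta$channel == "O1"])
  votes <- majority_vote(meta1$subject_id, pred[meta$channel == "O1"])
  tr <- tapply(meta1$truth, meta1$subject_id, `[`, 1)
  expect_equal(unname(pc1["O1"]), 100 * mean(votes == tr[names(votes)]))
})

test_that("exact signed-rank p-values match enumeration and wilcox.test", {
  # six all-positive distinct differences: p = 2/2^6
  x <- c(99.1, 99.3, 99.0, 99.4, 99.2, 99.5)
  y <- x - c(0.3, 0.5, 0.2, 0.7, 0.4, 0.6)
  w <- wilcoxon_signed_rank(x, y)
  expect_equal(w$p_value, 0.03125)
  expect_true(w$exact)
  # identical vectors: p = 1 with a warning
  expect_warning(w0 <- wilcoxon_signed_rank(x, x), "zero")
  expect_equal(w0$p_value, 1)
  # two-sided symmetry under sign flip
  wf <- wilcoxon_signed_rank(y, x)
  expect_equal(wf$p_value, w$p_value)
  # against stats::wilcox.test exact p for tie-free patterns, n <= 8
  set.seed(13)
  for (i in 1:60) {
    n <- sample(5:8, 1)
    d <- sample(seq(0.1, 3, by = 0.1), n) * sample(c(-1, 1), n, replace = TRUE)
    a <- rnorm(n); b <- a - d
    mine <- wilcoxon_signed_rank(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(mine$statistic, unname(ref$statistic))
  }
})

test_that("pairwise comparison covers every unordered pair", {
  acc <- rbind(resnet18 = c(99.4, 99.2, 99.5, 99.3, 99.6, 99.1),
               mobilenet = c(98.1, 98.3, 98.0, 98.2, 98.4, 97.9),
               efficientnet = c(97.8, 98.0, 97.7, 98.1, 97.9, 97.6))
  cmp <- wilcoxon_pairwise(acc)
  expect_identical(nrow(cmp), 3L)
  expect_true(all(cmp$p_value > 0 & cmp$p_value <= 1))
  # fully separated pairs reach the n = 6 exact floor
  expect_equal(cmp$p_value[cmp$a == "resnet18" & cmp$b == "mobilenet"], 0.03125)
  expect_error(wilcoxon_pairwise(acc[, 1:4]), "at least 5")
})
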