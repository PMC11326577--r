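test_that("binary metrics on canonical tables", {
  perfect <- binary_metrics(confusion_table(1, 0, 1, 0))
  for (m in c("precision", "recall", "specificity", "accuracy", "f1", "mcc"))
    expect_equal(perfect[[m]], 1)

  chance <- binary_metrics(confusion_table(25, 25, 25, 25))
  expect_equal(chance$precision, 0.5)
  expect_equal(chance$recall, 0.5)
  expect_equal(chance$mcc, 0)

  expect_error(binary_metrics(confusion_table(0, 0, 0, 0)), "all-zero")
})

test_that("zero-denominator metrics report 0 with a flag, never NaN", {
  rep <- binary_metrics(confusion_table(0, 0, 10, 5))
  expect_equal(rep$precision, 0)
  expect_equal(rep$f1, 0)
  expect_true(all(c("precision", "f1", "mcc") %in%
                    rep$zero_denominator_flags))
  expect_false(any(is.nan(unlist(rep[c("precision", "recall",
                                       "specificity", "accuracy",
                                       "f1", "mcc")]))))
})

test_that("MCC symmetry: invariant under swap, negated under class flip", {
  set.seed(7)
  for (i in 1:50) {
    cts <- sample(0:30, 4, replace = TRUE)
    if (sum(cts) == 0) next
    base <- binary_metrics(confusion_table(cts[1], cts[2], cts[3], cts[4]))
    swap <- binary_metrics(confusion_table(cts[3], cts[4], cts[1], cts[2]))
    flip <- binary_metrics(confusion_table(cts[2], cts[1], cts[4], cts[3]))
    expect_equal(swap$mcc, base$mcc)
    expect_equal(flip$mcc, -base$mcc)
  }
})

test_that("token confusion pools residues; mismatches are named errors", {
  t1 <- c("NONE", "NONE", "NONE", "BETA_HELIX")
  p1 <- c("NONE", "NONE", "BETA_HELIX", "BETA_HELIX")
  M <- token_confusion(list(rec1 = t1), list(p1))
  expect_equal(M["NONE", "NONE"], 2)
  expect_equal(M["NONE", "BETA_HELIX"], 1)
  expect_equal(M["BETA_HELIX", "BETA_HELIX"], 1)
  expect_equal(sum(M), 4)

  ident <- token_confusion(list(t1), list(t1))
  expect_true(all(ident[upper.tri(ident)] == 0 & ident[lower.tri(ident)] == 0))

  expect_error(token_confusion(list(), list()), "no records")
  expect_error(token_confusion(list(bad_rec = t1), list(p1[-1])), "bad_rec")
})

test_that("micro token metrics: identity and oracle agreement", {
  diagM <- diag(c(5, 3, 2, 4))
  dimnames(diagM) <- list(fold_labels(), fold_labels())
  r <- micro_token_metrics(diagM)
  expect_equal(r$accuracy, 1)
  expect_equal(r$mcc, 1)

  set.seed(17)
  for (i in 1:30) {
    M <- matrix(sample(0:40, 16, replace = TRUE), 4, 4)
    if (sum(M) == 0) next
    r <- micro_token_metrics(M)
    # micro-averaging identity
    expect_equal(r$precision, r$recall)
    expect_equal(r$recall, r$accuracy)
    expect_equal(r$f1, r$accuracy)
    # flatten-and-count oracle: rebuild the token stream and count
    truth_stream <- rep(rep(1:4, each = 4), as.vector(t(M)))
    pred_stream <- rep(rep(1:4, times = 4), as.vector(t(M)))
    expect_equal(r$accuracy, mean(truth_stream == pred_stream))
    num <- sum(diag(M)) * sum(M) - sum(rowSums(M) * colSums(M))
    den <- sqrt(sum(M)^2 - sum(colSums(M)^2)) *
      sqrt(sum(M)^2 - sum(rowSums(M)^2))
    if (den > 0) expect_equal(r$mcc, num / den)
  }
})

test_that("PR AUC: separating, worked example, ties, monotone invariance", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)),
               1)
  expect_equal(pr_auc(c(0.9, 0.8, 0.7, 0.6), c(TRUE, FALSE, TRUE, FALSE)),
               (1 + 2 / 3) / 2)
  expect_equal(pr_auc(rep(0.5, 10), c(rep(TRUE, 3), rep(FALSE, 7))), 0.3)
  expect_error(pr_auc(c(0.1, 0.2), c(TRUE, TRUE)), "positive and one negative")

  set.seed(23)
  sc <- runif(30); tr <- runif(30) > 0.5
  if (length(unique(tr)) == 2) {
    a <- pr_auc(sc, tr)
    expect_equal(pr_auc(exp(3 * sc) + 2, tr), a)  # strictly monotone map
    expect_equal(pr_auc(rank(sc, ties.method = "average"), tr), a)
  }
})

test_that("benchmark reports compare tools on identical records", {
  truth <- setNames(c(rep(TRUE, 4), rep(FALSE, 6)), sprintf("g%02d", 1:10))
  good <- setNames(c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.1, 0.05, 0.01),
                   names(truth))
  rep2 <- benchmark_report(list(a = good, b = good), truth)
  expect_equal(rep2[1, -1], rep2[2, -1], ignore_attr = TRUE)

  all_neg <- setNames(rep(0, 10), names(truth))
  r <- benchmark_report(list(neg = all_neg), truth)
  expect_equal(r$recall, 0)
  expect_equal(r$specificity, 1)

  missing <- good[-3]
  expect_error(benchmark_report(list(bad = missing), truth), "g03")
})

test_that("a 3-tool benchmark fixture matches an independent hand computation", {
  set.seed(29)
  ids <- sprintf("p%02d", 1:20)
  truth <- setNames(rep(c(TRUE, FALSE), c(8, 12)), ids)
  tools <- list(
    sharp = setNames(c(runif(8, 0.6, 1), runif(12, 0, 0.4)), ids),
    dull = setNames(runif(20), ids),
    biased = setNames(c(runif(8, 0.3, 0.9), runif(12, 0.2, 0.8)), ids))
  got <- benchmark_report(tools, truth, threshold = 0.5)
  for (k in seq_along(tools)) {
    sc <- tools[[k]][ids]
    call <- sc >= 0.5
    tp <- sum(call & truth); fp <- sum(call & !truth)
    tn <- sum(!call & !truth); fn <- sum(!call & truth)
    # direct formula evaluation, independent of the package's path
    expect_equal(got$tp[k], tp)
    expect_equal(got$precision[k], if (tp + fp > 0) tp / (tp + fp) else 0)
    expect_equal(got$recall[k], tp / (tp + fn))
    expect_equal(got$specificity[k], tn / (tn + fp))
    expect_equal(got$accuracy[k], (tp + tn) / 20)
    mcc_num <- tn * tp - fn * fp
    mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (mcc_den > 0) expect_equal(got$mcc[k], mcc_num / mcc_den)
    # PR AUC via exhaustive threshold sweep
    thr <- sort(unique(sc), decreasing = TRUE)
    ap <- 0; prev <- 0
    for (t in thr) {
      pr <- sum(truth & sc >= t) / sum(sc >= t)
      rc <- sum(truth & sc >= t) / sum(truth)
      ap <- ap + (rc - prev) * pr; prev <- rc
    }
    expect_equal(got$pr_auc[k], ap)
  }
})

test_that("false-positive reassessment moves FPs to TNs and recomputes", {
  truth <- setNames(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                    sprintf("x%d", 1:6))
  calls <- setNames(c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
                    names(truth))
  tab <- binary_confusion(truth, calls)
  expect_equal(sort(tab$fp_ids), c("x3", "x4"))

  unchanged <- adjust_false_positives(tab, character(0))
  expect_equal(unchanged$counts$fp, 2)

  adj <- adjust_false_positives(tab, "x3")
  expect_equal(adj$counts$fp, 1)
  expect_equal(adj$counts$tn, 3)
  expect_equal(adj$counts$tp, 1)  # TP/FN untouched
  expect_equal(adj$counts$fn, 1)

  expect_error(adjust_false_positives(tab, "x1"), "not currently false")

  all_fp <- adjust_false_positives(tab, c("x3", "x4"))
  expect_equal(all_fp$precision, 1)
})
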