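mk_results <- function(n, kind = "paired_wilcoxon_lfc") {
  tibble::tibble(
    position = seq_len(n) * 3L, strand = rep(c("+", "-"), length.out = n),
    context = "CHH", effect = seq_len(n) / 10, p_value = 0.01,
    test_kind = kind, flagged = FALSE
  )
}

test_that("build_index copies weights verbatim and validates provenance", {
  idx <- build_index(mk_results(1), "BA")
  expect_equal(idx$entries$weight, 0.1)
  expect_equal(nrow(build_index(mk_results(105), "BA")$entries), 105)
  expect_error(build_index(mk_results(3, "age_slope"), "BA"), "test kinds")
  mixed <- mk_results(4)
  mixed$test_kind[2] <- "age_slope"
  expect_error(build_index(mixed, "BA"), "test kinds")
  expect_error(build_index(mk_results(0), "DU"), "looser alpha")
  zero <- mk_results(2)
  zero$effect[1] <- 0
  expect_error(build_index(zero, "BA"), "nonzero")
})

test_that("score_samples computes the weighted sum in percent", {
  sim <- small_dataset()
  mat <- build_matrix(sim$calls, 30, area = "NAcc")
  one <- tibble::tibble(position = mat$sites$position[1],
                        strand = mat$sites$strand[1],
                        context = mat$sites$context[1],
                        effect = 1, p_value = 0.01,
                        test_kind = "logistic_log_or", flagged = FALSE)
  idx <- build_index(one, "DU", area = "NAcc")
  sc <- score_samples(idx, mat)
  expect_equal(sc$score, unname(mat$levels[1, ]))
  # missing index site is an error naming the site
  bad <- one
  bad$position <- 999999L
  idx_bad <- build_index(bad, "DU", area = "NAcc")
  expect_error(score_samples(idx_bad, mat), "999999")
})

test_that("score_samples is linear in the weights", {
  sim <- small_dataset()
  mat <- build_matrix(sim$calls, 30, area = "NAcc")
  res <- mk_results(6, "logistic_log_or")
  res$position <- mat$sites$position[1:6]
  res$strand <- mat$sites$strand[1:6]
  res2 <- res
  res2$effect <- rev(res$effect)
  combined <- res
  combined$effect <- res$effect + res2$effect
  s1 <- score_samples(build_index(res, "DU"), mat)$score
  s2 <- score_samples(build_index(res2, "DU"), mat)$score
  s12 <- score_samples(build_index(combined, "DU"), mat)$score
  expect_equal(s12, s1 + s2, tolerance = 1e-10)
})

test_that("du_threshold implements mean + 1.96 sample SD", {
  expect_equal(du_threshold(rep(0, 5)), 0)
  scores <- c(8, 10, 12)  # mean 10, sd 2
  expect_equal(du_threshold(scores), 13.92)
  expect_error(du_threshold(5), "at least 2")
})

test_that("evaluate_classifier matches a brute-force confusion tally", {
  set.seed(66)
  scores <- rnorm(200)
  labels <- rbinom(200, 1, 0.3) == 1
  thr <- 0.2
  res <- evaluate_classifier(scores, labels, thr)
  expect_equal(res$tp, sum(scores > thr & labels))
  expect_equal(res$tn, sum(scores <= thr & !labels))
  expect_equal(res$sensitivity, sum(scores > thr & labels) / sum(labels))
  # perfectly separated scores
  sep <- evaluate_classifier(c(1, 2, 8, 9), c(FALSE, FALSE, TRUE, TRUE), 5)
  expect_equal(c(sep$sensitivity, sep$specificity, sep$ppv, sep$npv),
               c(1, 1, 1, 1))
  # nothing called positive: PPV undefined, flagged
  none <- evaluate_classifier(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE), 10)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
  expect_true(is.na(none$ppv))
  expect_true(none$undefined)
})

test_that("ties at the threshold are called negative (strict rule)", {
  res <- evaluate_classifier(c(5, 5, 6), c(FALSE, TRUE, TRUE), 5)
  expect_equal(res$tp, 1)
  expect_equal(res$fn, 1)
  expect_equal(res$tn, 1)
})

test_that("roc_auc equals the tie-adjusted Mann-Whitney statistic", {
  set.seed(99)
  for (rep in 1:5) {
    scores <- round(rnorm(60), 1)  # rounding forces ties
    labels <- rbinom(60, 1, 0.4) == 1
    if (!any(labels) || all(labels)) next
    auc <- roc_auc(scores, labels)$auc
    u <- mann_whitney(scores[labels], scores[!labels])$statistic
    expect_equal(auc, u / (sum(labels) * sum(!labels)), tolerance = 1e-12)
  }
})

test_that("roc_auc is invariant under strictly monotone score transforms", {
  set.seed(12)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.5) == 1
  base <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, base, tolerance = 1e-12)
  expect_equal(roc_auc(scores * 100 - 3, labels)$auc, base, tolerance = 1e-12)
})

test_that("roc curves run from (0,0) to (1,1) and separate perfectly when possible", {
  roc <- roc_auc(c(1, 2, 3, 10, 11), c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(roc$auc, 1)
  pts <- roc$roc_points
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  scores <- rnorm(100)
  labels <- rbinom(100, 1, 0.5)
  ours <- roc_auc(scores, labels == 1)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-10)
})

test_that("venn_overlap counts intersection cells like set algebra", {
  mk_idx <- function(pos, kind, tk) {
    build_index(tibble::tibble(position = pos, strand = "+", context = "CHH",
                               effect = 1, p_value = 0.01, test_kind = tk,
                               flagged = FALSE), kind)
  }
  a <- mk_idx(1:10, "BA", "paired_wilcoxon_lfc")
  b <- mk_idx(6:15, "DU", "logistic_log_or")
  c3 <- mk_idx(8:20, "Age", "age_slope")
  v <- venn_overlap(list(A = a, B = b, C = c3))
  cells <- setNames(v$cells$n, v$cells$cell)
  expect_equal(unname(cells["A"]), 5)        # 1..5
  expect_equal(unname(cells["A&B"]), 2)      # 6,7
  expect_equal(unname(cells["A&B&C"]), 3)    # 8,9,10
  expect_equal(unname(cells["B&C"]), 5)      # 11..15
  expect_equal(unname(cells["C"]), 5)        # 16..20
  expect_equal(v$n_shared_by_two_or_more, 10)
  # identical models overlap fully; disjoint models do not overlap
  full <- venn_overlap(list(x = a, y = a))
  expect_equal(full$cells$cell, "x&y")
  disj <- venn_overlap(list(x = a, y = mk_idx(100:105, "BA", "paired_wilcoxon_lfc")))
  expect_equal(disj$n_shared_by_two_or_more, 0)
  expect_error(venn_overlap(list(a)), "at least 2")
})

test_that("index models serialise to JSON and back", {
  idx <- build_index(mk_results(5), "BA", alpha = 0.02, area = "paired")
  path <- withr::local_tempfile(fileext = ".json")
  write_index(idx, path, overwrite = TRUE)
  back <- read_index(path)
  expect_equal(back$kind, "BA")
  expect_equal(back$entries$weight, idx$entries$weight)
  expect_equal(back$selection_alpha, 0.02)
})
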