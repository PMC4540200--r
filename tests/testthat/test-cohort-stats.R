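test_that("the RIN gate is strictly greater than 7.5", {
  s <- tibble::tibble(piece_id = c("a", "b", "c"), rin = c(7.5, 7.6, 9.1))
  out <- rin_filter(s)
  expect_equal(out$piece_id, c("b", "c"))
  expect_equal(attr(out, "n_removed"), 1L)
  empty <- rin_filter(s[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("relative expression is 2^-deltaCt", {
  expect_equal(relative_expression(25, 20), 0.03125)
  expect_equal(relative_expression(20, 20), 1)
  expect_equal(relative_expression(18, 20), 4)
})

test_that("aggregation collapses technical replicates by median, pieces by mean", {
  s <- tidyr::expand_grid(piece = 1:3, target = c("miR210", "U6"), tech_rep = 1:3) |>
    dplyr::mutate(placenta_id = "P1", group = "PE",
                  piece_id = paste0("P1.", piece),
                  ct = dplyr::case_when(
                    target == "U6" ~ 20,
                    piece == 1 ~ c(24.9, 25.0, 25.3)[tech_rep],
                    piece == 2 ~ 19,
                    TRUE ~ 18))
  per_piece <- aggregate_expression(s, "miR210", "U6", unit = "piece")
  expect_equal(nrow(per_piece), 3)
  # median of the technical replicates of piece 1 is 25.0 -> 2^-5
  expect_equal(per_piece$rel_expr[per_piece$piece_id == "P1.1"], 2^-5)
  per_pl <- aggregate_expression(s, "miR210", "U6", unit = "placenta")
  expect_equal(nrow(per_pl), 1)
  expect_equal(per_pl$rel_expr, mean(c(2^-5, 2, 4)))
  expect_error(aggregate_expression(s[s$target != "U6", ], "miR210", "U6"),
               class = "placentamir_data_error")
})

test_that("Mann-Whitney matches its printed example and handles degeneracy", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u_statistic, 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$direction, -1)
  # identical multisets: U = n^2/2, p = 1
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$u_statistic, 4.5)
  expect_equal(same$p_value, 1)
  expect_equal(mann_whitney(c(2, 2), c(2, 2))$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1), class = "placentamir_parameter_error")
  td <- tidy(res)
  expect_equal(td$u_statistic, 0)
  expect_equal(td$n1, 3L)
})

test_that("exact mode equals full enumeration for tie-free small samples", {
  withr::with_seed(5, {
    for (k in 1:60) {
      n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
      x <- sample(100, n1 + n2)  # distinct values, no ties
      a <- x[seq_len(n1)]; b <- x[-seq_len(n1)]
      expect_equal(mann_whitney(a, b, mode = "exact")$p_value,
                   mw_oracle_p(a, b), tolerance = 1e-12)
    }
  })
})

test_that("box summaries use inclusive linear-interpolation percentiles", {
  bs <- box_summary(1:100)
  expect_equal(bs$median, 50.5)
  expect_equal(bs$p5, quantile(1:100, 0.05, type = 7)[[1]])
  one <- box_summary(42)
  expect_equal(unlist(one[c("median", "q1", "q3", "p5", "p95")]),
               setNames(rep(42, 5), c("median", "q1", "q3", "p5", "p95")))
  shuffled <- box_summary(sample(1:100))
  expect_equal(shuffled, bs)
  expect_true(with(bs, p5 <= q1 && q1 <= median && median <= q3 && q3 <= p95))
  expect_error(box_summary(numeric(0)), class = "placentamir_data_error")
})

test_that("the severe-PE rule requires confirmed BP and repeated proteinuria", {
  rec <- function(bp, prot) {
    tibble::tibble(bp_readings = list(bp), proteinuria_readings = list(prot))
  }
  bp_ok <- tibble::tibble(time = c(0, 6), systolic = c(165, 166),
                          diastolic = c(105, 104))
  prot_ok <- tibble::tibble(time = c(0, 12), dipstick_grade = c(2, 2))
  expect_true(classify_severe_pe(rec(bp_ok, prot_ok)))
  # one qualifying BP reading is not confirmation
  bp_single <- tibble::tibble(time = 0, systolic = 165, diastolic = 105)
  expect_false(classify_severe_pe(rec(bp_single, prot_ok)))
  # qualifying readings less than 6 h apart do not confirm
  bp_close <- tibble::tibble(time = c(0, 5), systolic = c(165, 166),
                             diastolic = c(105, 104))
  expect_false(classify_severe_pe(rec(bp_close, prot_ok)))
  # below both thresholds
  bp_low <- tibble::tibble(time = c(0, 8), systolic = c(150, 152),
                           diastolic = c(95, 94))
  expect_false(classify_severe_pe(rec(bp_low, prot_ok)))
  # systolic alone qualifies under the "or" rule but not under "and"
  bp_sys <- tibble::tibble(time = c(0, 8), systolic = c(165, 170),
                           diastolic = c(92, 95))
  expect_true(classify_severe_pe(rec(bp_sys, prot_ok)))
  expect_false(classify_severe_pe(rec(bp_sys, prot_ok), bp_rule = "and"))
  # proteinuria readings more than 24 h apart do not qualify
  prot_far <- tibble::tibble(time = c(0, 30), dipstick_grade = c(2, 3))
  expect_false(classify_severe_pe(rec(bp_ok, prot_far)))
})

test_that("the severe-PE rule is monotone in BP and proteinuria", {
  withr::with_seed(31, {
    for (k in 1:40) {
      bp <- tibble::tibble(time = sort(runif(3, 0, 24)),
                           systolic = runif(3, 120, 180),
                           diastolic = runif(3, 70, 115))
      prot <- tibble::tibble(time = sort(runif(3, 0, 30)),
                             dipstick_grade = sample(0:4, 3, replace = TRUE))
      base <- classify_severe_pe(tibble::tibble(bp_readings = list(bp),
                                                proteinuria_readings = list(prot)))
      bp2 <- dplyr::mutate(bp, systolic = systolic + 20, diastolic = diastolic + 10)
      prot2 <- dplyr::mutate(prot, dipstick_grade = pmin(dipstick_grade + 1, 4))
      up <- classify_severe_pe(tibble::tibble(bp_readings = list(bp2),
                                              proteinuria_readings = list(prot2)))
      if (base) expect_true(up)
    }
  })
})

test_that("the ratio score combines the two Ct values in linear space", {
  expect_equal(ratio_score(24, 27), 8)
  expect_equal(ratio_score(20, 20), 1)
})

test_that("ROC AUC obeys the rank identity and matches independent routes", {
  # perfect separation
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T))$auc, 1)
  withr::with_seed(41, {
    for (k in 1:30) {
      n1 <- sample(5:15, 1); n0 <- sample(5:15, 1)
      scores <- c(rnorm(n1, 1), rnorm(n0))
      labels <- rep(c(TRUE, FALSE), c(n1, n0))
      r <- roc_auc(scores, labels)
      # AUC = U/(n1*n0) equals trapezoidal integration of the curve
      pts <- r$points[order(r$points$fpr, r$points$tpr), ]
      trapz <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
      expect_equal(r$auc, trapz, tolerance = 1e-10)
      # and the Mann-Whitney U of the positive scores
      u <- mann_whitney(scores[labels], scores[!labels])$u_statistic
      expect_equal(r$auc, u / (n1 * n0), tolerance = 1e-12)
    }
    # shuffled labels give AUC near 1/2 on average
    scores <- rnorm(40)
    aucs <- replicate(200, roc_auc(scores, sample(rep(c(TRUE, FALSE), 20)))$auc)
    expect_lt(abs(mean(aucs) - 0.5), 0.02)
  })
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), class = "placentamir_data_error")
})

test_that("ROC AUC agrees with pROC on tied and untied scores", {
  skip_if_not_installed("pROC")
  withr::with_seed(43, {
    scores <- c(rnorm(20, 1), rnorm(25))
    labels <- rep(c(1, 0), c(20, 25))
    expect_equal(roc_auc(scores, labels == 1)$auc,
                 as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
                 tolerance = 1e-12)
    tied <- round(scores)
    expect_equal(roc_auc(tied, labels == 1)$auc,
                 as.numeric(pROC::auc(pROC::roc(labels, tied, quiet = TRUE))),
                 tolerance = 1e-12)
  })
})

test_that("the full cohort comparison recovers simulated directions", {
  co <- simulate_cohort(cohort_design(seed = 77))
  r455 <- compare_cohort(co$samples, "miR455-3P")
  expect_lt(r455$p_value, 0.05)
  expect_equal(r455$direction, -1)
  r210 <- compare_cohort(co$samples, "miR210")
  expect_lt(r210$p_value, 0.05)
  expect_equal(r210$direction, 1)
  td <- tidy(r210)
  expect_equal(td$target, "miR210")
  expect_equal(td$n1 + td$n2, 29L)
  # per-piece pooling keeps more observations than per-placenta testing
  piece <- compare_cohort(co$samples, "miR210", unit = "piece")
  expect_gt(piece$n1, r210$n1)
})
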