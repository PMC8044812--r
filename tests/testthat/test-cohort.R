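test_that("percentage difference follows the stated sign convention", {
  expect_equal(percent_difference(4.0, 3.0), 25.0)
  expect_equal(percent_difference(2.0, 2.2), -10.0)
  expect_equal(percent_difference(5, 5), 0)
  expect_warning(out <- percent_difference(0, 1), "zero")
  expect_true(is.na(out))
})

test_that("signed-rank test matches brute-force enumeration for small n", {
  set.seed(17)
  for (i in 1:8) {
    n <- sample(6:10, 1)
    d <- round(rnorm(n, 0.3, 1), 3)
    d <- d[d != 0]
    if (length(d) < 5 || any(duplicated(abs(d)))) next
    ours <- wilcoxon_signed_rank(d, rep(0, length(d)))
    expect_true(ours$exact)
    expect_equal(ours$p_value, wilcoxon_brute_force(d), tolerance = 1e-12)
  }
})

test_that("degenerate paired samples give p = 1", {
  x <- c(1, 2, 3, 4, 5, 6, 7)
  out <- wilcoxon_signed_rank(x, x)
  expect_equal(out$p_value, 1)
  expect_equal(out$n_nonzero, 0L)
})

test_that("consistent one-sided shifts reach the smallest attainable p", {
  # 20 pairs, corrected always strictly below uncorrected
  set.seed(23)
  u <- runif(20, 2, 6)
  co <- u - runif(20, 0.1, 0.5)
  out <- wilcoxon_signed_rank(u, co)
  # all ranks one-signed: V = n(n+1)/2, smallest two-sided exact p = 2/2^n
  expect_equal(out$p_value, 2 / 2^20, tolerance = 1e-10)
})

test_that("Holm step-down arithmetic matches the worked example", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.20), method = "holm"),
               c(0.03, 0.04, 0.20))
  # monotone and never below the raw p
  set.seed(2)
  p <- runif(8)
  ph <- p.adjust(p, "holm")
  expect_true(all(ph >= p))
  expect_equal(order(ph[order(p)]), 1:8)
})

test_that("paired group tests apply Holm within the three-comparison family", {
  set.seed(31)
  n <- 12
  u <- runif(n, 2, 5)
  rec <- data.frame(median_rcbv = u,
                    median_rcbv_unidir = u - runif(n, 0.2, 0.6),
                    median_rcbv_bidir = u - runif(n, 0.5, 1.0))
  out <- paired_group_tests(rec)
  expect_equal(nrow(out), 3)
  expect_setequal(out$comparison,
                  c("uncorrected_vs_unidir", "uncorrected_vs_bidir",
                    "unidir_vs_bidir"))
  expect_equal(out$p_holm, p.adjust(out$p_raw, "holm"))
  expect_true(all(out$p_holm >= out$p_raw))
  expect_true(all(out$significant))
  expect_error(paired_group_tests(rec[1:4, ]), "at least 6")
  # identical maps: nothing significant
  rec0 <- data.frame(median_rcbv = u, median_rcbv_unidir = u,
                     median_rcbv_bidir = u)
  out0 <- paired_group_tests(rec0)
  expect_true(all(out0$p_raw == 1))
  expect_false(any(out0$significant))
})

test_that("Spearman grade correlation hits the monotone limits", {
  # strictly monotone, tie-free: rank correlation reaches +/-1
  rec <- data.frame(grade = 1:6,
                    median_rcbv = c(1, 1.2, 2, 2.3, 3.1, 3.5),
                    median_rcbv_unidir = c(1, 1.2, 2, 2.3, 3.1, 3.5),
                    median_rcbv_bidir = -c(1, 1.2, 2, 2.3, 3.1, 3.5))
  out <- grade_correlation(rec)
  expect_equal(out$rs[out$map == "median_rcbv"], 1)
  expect_equal(out$rs[out$map == "median_rcbv_bidir"], -1)
  # tied grades use mid-ranks, matching the base implementation
  rec$grade <- c(2, 2, 3, 3, 4, 4)
  out2 <- grade_correlation(rec)
  expect_equal(out2$rs[1],
               cor(rec$median_rcbv, rec$grade, method = "spearman"))
  expect_error(grade_correlation(rec[1:3, ]), "at least 5")
  const <- rec; const$grade <- 4
  expect_error(grade_correlation(const), "constant")
})

test_that("permuted grades show no systematic correlation", {
  set.seed(41)
  rs <- replicate(200, {
    rec <- data.frame(grade = sample(rep(2:4, each = 7)),
                      median_rcbv = rnorm(21, 2),
                      median_rcbv_unidir = rnorm(21, 2),
                      median_rcbv_bidir = rnorm(21, 2))
    grade_correlation(rec)$rs[1]
  })
  expect_lt(abs(mean(rs)), 0.05)
  # under the permutation null about 5% of |rs| exceed the 5% critical value
  expect_lt(mean(abs(rs) > 0.433), 0.12)
})

test_that("cohort table reports the documented schema", {
  set.seed(51)
  n <- 8
  mk <- function(gr) {
    u <- runif(n, 2, 5)
    data.frame(patient_id = paste0(gr, seq_len(n)), group = gr,
               grade = sample(2:4, n, TRUE),
               median_rcbv = u,
               median_rcbv_unidir = u * 0.8,
               median_rcbv_bidir = u * 0.7,
               median_k2_unidir = rnorm(n, -0.03, 0.01),
               median_k2_bidir = rnorm(n, -0.05, 0.01),
               median_kep_bidir = abs(rnorm(n, 0.02, 0.01)),
               mean_adj_r2_unidir = runif(n, 0.8, 1),
               mean_adj_r2_bidir = runif(n, 0.8, 1))
  }
  rec <- rbind(mk("enhancing"), mk("nonenhancing"))
  tab <- cohort_table(rec)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("group", "n", "rcbv_mean", "rcbv_sd",
                    "rcbv_unidir_mean", "pct_diff_unidir", "p_unidir",
                    "rcbv_bidir_mean", "pct_diff_bidir", "p_bidir",
                    "p_unidir_vs_bidir") %in% names(tab)))
  # per-patient percentage differences: here exactly 20% and 30%
  expect_equal(tab$pct_diff_unidir, c(20, 20), tolerance = 1e-10)
  expect_equal(tab$pct_diff_bidir, c(30, 30), tolerance = 1e-10)
  expect_warning(cohort_table(rec[1, ]), "single patient")
  st <- cohort_stats(rec)
  expect_named(st, c("table", "tests", "grade_correlation"))
  expect_equal(nrow(st$tests$enhancing), 3)
})
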