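test_that("fold assignment partitions, stratifies and is seed-deterministic", {
  y <- rep(c(1, 2), each = 10)
  f <- make_folds(y, k = 10, seed = 3)
  expect_equal(as.integer(table(f)), rep(2L, 10))      # balanced partition
  for (k in 1:10)                                      # one of each class
    expect_equal(sort(y[f == k]), c(1, 2))
  expect_identical(make_folds(y, k = 10, seed = 3), f)
  expect_false(identical(make_folds(y, k = 10, seed = 4), f))
  expect_warning(make_folds(rep(c(1, 2), c(18, 2)), k = 5, seed = 1),
                 "best-effort")
})

test_that("patient-grouped folds keep each patient's samples together", {
  y <- rep(c(1, 2), 12)
  pat <- rep(paste0("P", 1:8), each = 3)
  f <- make_folds(y, k = 4, group = pat, seed = 2)
  for (p in unique(pat))
    expect_length(unique(f[pat == p]), 1)
  expect_setequal(unique(f), 1:4)
})

test_that("auxiliary draws follow the equal-split size rules", {
  set.seed(1)
  pool12 <- matrix(rnorm(200), 100, 2)
  pool0 <- matrix(rnorm(200), 100, 2)
  comp <- rep(c("CE", "NE"), 50)
  a <- sample_auxiliary(pool12, pool0, 40, compartment = comp, seed = 5)
  expect_equal(nrow(a$X12), 20)
  expect_equal(nrow(a$X0), 20)
  expect_equal(sum(comp[a$idx12] == "CE"), 10)
  expect_equal(sum(comp[a$idx12] == "NE"), 10)
  # odd labeled counts: extra sample goes to the unlabeled tumoral side
  b <- sample_auxiliary(pool12, pool0, 5, compartment = comp, seed = 5)
  expect_equal(nrow(b$X12), 3)
  expect_equal(nrow(b$X0), 2)
  expect_equal(sum(comp[b$idx12] == "CE"), 2)   # odd tumoral count favors CE
  # determinism and pool-exhaustion warning
  expect_identical(sample_auxiliary(pool12, pool0, 40, comp, seed = 9),
                   sample_auxiliary(pool12, pool0, 40, comp, seed = 9))
  expect_warning(sample_auxiliary(pool12[1:3, ], pool0, 40, seed = 1),
                 "pool has only")
})

test_that("metrics match their definitions including class-0 predictions", {
  truth <- rep(c(2, 1), c(10, 10))
  pred <- c(rep(2, 8), rep(1, 2), rep(1, 9), 2)   # TP=8 FN=2 TN=9 FP=1
  m <- compute_metrics(truth, pred)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$accuracy, 0.85)
  # perfect and degenerate predictors
  expect_equal(compute_metrics(truth, truth)$accuracy, 1)
  all2 <- compute_metrics(truth, rep(2, 20))
  expect_equal(all2$sensitivity, 1)
  expect_equal(all2$specificity, 0)
  expect_equal(all2$accuracy, 0.5)
  # class-0 predictions: errors for accuracy, negative-side calls otherwise
  m0 <- compute_metrics(c(2, 2, 1, 1), c(0, 2, 0, 1))
  expect_equal(m0$accuracy, 0.5)
  expect_equal(m0$sensitivity, 0.5)
  expect_equal(m0$specificity, 1)
  # undefined metrics are NA, not 0
  expect_true(is.na(compute_metrics(c(1, 1), c(1, 1))$sensitivity))
})

test_that("metric/confusion identities hold on random confusions", {
  set.seed(8)
  for (i in 1:20) {
    truth <- sample(1:2, 30, TRUE)
    pred <- sample(0:2, 30, TRUE)
    if (length(unique(truth)) < 2) next
    m <- compute_metrics(truth, pred)
    cf <- m$confusion
    expect_equal(sum(cf), 30)
    expect_equal(m$accuracy, (cf["1", "1"] + cf["2", "2"]) / sum(cf))
    expect_equal(m$sensitivity, cf["2", "2"] / sum(cf["2", ]))
    expect_equal(m$specificity, (cf["1", "0"] + cf["1", "1"]) / sum(cf["1", ]))
  }
})

test_that("repeated CV is reproducible and near-perfect on separable cohorts", {
  ts <- generate_feature_cohort(feature_cohort_config(
    n1 = 30, n2 = 30, m12 = 30, m0 = 30, d = 5, separation = 8, seed = 31))
  r1 <- repeated_cv(ts, C1 = 1, C2 = 1, kernel_spec("rbf"),
                    n_folds = 5, n_repeats = 2, seed = 11)
  r2 <- repeated_cv(ts, C1 = 1, C2 = 1, kernel_spec("rbf"),
                    n_folds = 5, n_repeats = 2, seed = 11)
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_gte(r1$mean[["accuracy"]], 0.95)
  expect_equal(nrow(r1$per_repeat), 2)
})

test_that("two-stage tuning screens C2 then picks C1 with the tie rule", {
  ts <- generate_feature_cohort(feature_cohort_config(
    n1 = 24, n2 = 24, m12 = 24, m0 = 24, d = 4, separation = 8, seed = 17))
  tuned <- tune_wsosvm(ts, C2_grid = c(0.1, 1, 10), C1_grid = c(0.1, 1, 10),
                       n_folds = 4, n_repeats = 1, seed = 7)
  # trace covers the whole coarse grid
  expect_equal(tuned$screen_trace$C2, c(0.1, 1, 10))
  expect_equal(nrow(tuned$screen_trace), 3)
  # separable data: every C2 passes the screen, selection driven by C1 stage
  expect_true(all(tuned$screen_trace$kept))
  expect_equal(nrow(tuned$selection_trace), 9)
  # tie-break toward the smallest C1 then smallest C2 among the best
  best <- max(tuned$selection_trace$accuracy)
  cands <- tuned$selection_trace[tuned$selection_trace$accuracy >= best - 1e-12, ]
  expect_equal(tuned$C1, min(cands$C1))
  expect_equal(tuned$C2, min(cands$C2[cands$C1 == tuned$C1]))
})

test_that("exact one-sided Wilcoxon matches brute-force enumeration", {
  r <- wilcoxon_one_sided(c(3, 4, 5), c(1, 2))
  expect_equal(r$p.value, 0.1)          # 1 of C(5,2)=10 assignments as extreme
  expect_equal(r$statistic, 12)
  # identical series carry no evidence
  expect_gte(wilcoxon_one_sided(c(1, 2, 3), c(1, 2, 3))$p.value, 0.5)
  # full enumeration oracle over random no-ties splits, n <= 10
  set.seed(23)
  for (i in 1:10) {
    n <- sample(4:10, 1); na <- sample(2:(n - 2), 1)
    x <- sample(seq(0, 1, length.out = 50), n)
    a <- x[1:na]; b <- x[(na + 1):n]
    p_pkg <- wilcoxon_one_sided(a, b)$p.value
    rk <- rank(x)
    W <- sum(rk[1:na])
    combos <- combn(n, na)
    p_oracle <- mean(colSums(matrix(rk[combos], nrow = na)) >= W - 1e-9)
    expect_equal(p_pkg, p_oracle)
    # discrete-null swap identity: p(a>b) + p(b>a) = 1 + P(W = w_obs)
    p_swap <- wilcoxon_one_sided(b, a)$p.value
    p_eq <- mean(abs(colSums(matrix(rk[combos], nrow = na)) - W) < 1e-9)
    expect_equal(p_pkg + p_swap, 1 + p_eq)
    # and the no-ties exact path agrees with wilcox.test's exact p
    wt <- wilcox.test(a, b, alternative = "greater", exact = TRUE)
    expect_equal(p_pkg, wt$p.value)
  }
})

test_that("tied observations use midranks in the exact null", {
  a <- c(2, 2, 3); b <- c(1, 2)
  r <- wilcoxon_one_sided(a, b, exact = TRUE)
  rk <- rank(c(a, b))
  combos <- combn(5, 3)
  p_oracle <- mean(colSums(matrix(rk[combos], nrow = 3)) >= sum(rk[1:3]) - 1e-9)
  expect_equal(r$p.value, p_oracle)
})

test_that("large samples fall back to the tie-corrected normal approximation", {
  set.seed(4)
  a <- rnorm(30, 0.6); b <- rnorm(30)
  r <- wilcoxon_one_sided(a, b)
  expect_match(r$method, "normal approximation")
  wt <- wilcox.test(a, b, alternative = "greater", exact = FALSE)
  expect_equal(r$p.value, wt$p.value)
  expect_error(wilcoxon_one_sided(numeric(0), a), "non-empty")
})
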