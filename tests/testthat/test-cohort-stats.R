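test_that("classification table equals a direct tally and sums to cohort size", {
  co <- simulate_cohort(n_cases = 50, seed = 19)
  ct <- classification_table(co, 6)
  # independent re-count straight from the rule, bypassing the table code
  expected <- vapply(completeness_classes(), function(cl) {
    sum(classify_ablation(co$residual_pct, co$u6) == cl)
  }, integer(1))
  expect_equal(setNames(ct$table$total, ct$table$class), expected)
  expect_equal(sum(ct$table$total), nrow(co))
  expect_equal(sum(ct$table$ltp), sum(co$ltp))
  expect_error(classification_table(co, 12), "u12")
})

test_that("cumulative table is a prefix sum of the per-class table", {
  co <- simulate_cohort(n_cases = 80, seed = 23)
  for (m in c(3, 6)) {
    ct <- classification_table(co, m)$table
    cum <- cumulative_table(co, m)
    expect_equal(cum$total, c(ct$total[1], sum(ct$total[1:2]),
                              sum(ct$total[1:3]), sum(ct$total)))
    expect_equal(cum$ltp, c(ct$ltp[1], sum(ct$ltp[1:2]),
                            sum(ct$ltp[1:3]), sum(ct$ltp)))
  }
  # no-LTP cohort: all percentages zero, p-value undefined
  co0 <- co; co0$ltp <- 0L
  expect_true(all(cumulative_table(co0, 6)$ltp_pct == 0))
  expect_true(is.na(classification_table(co0, 6)$p_value))
})

test_that("association test switches to Fisher and matches enumeration", {
  expect_equal(association_test(matrix(c(5, 5, 5, 5), 2)), 1)
  # 3/0 vs 0/3: 2 of the 20 equally likely tables are as extreme
  expect_equal(association_test(matrix(c(3, 0, 0, 3), 2)), 0.1)
  # expected counts >= 5 use chi-square; cross-check a hand statistic
  tab <- matrix(c(20, 10, 15, 25), 2)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  expect_equal(association_test(tab), pchisq(stat, 1, lower.tail = FALSE))
  expect_error(association_test(matrix(c(0, 0, 3, 5), 2)), "degenerate")
  expect_error(association_test(matrix(c(1, 2, 3), 3, 1)), "2x2")
})

test_that("Fisher p equals full hypergeometric enumeration", {
  # exhaustive over all 2x2 tables with N <= 12
  mism <- 0
  for (N in 2:12) {
    parts <- expand.grid(a = 0:N, b = 0:N, c = 0:N)
    parts <- parts[rowSums(parts) <= N, ]
    for (i in seq_len(nrow(parts))) {
      tab <- matrix(c(parts$a[i], parts$b[i], parts$c[i],
                      N - sum(parts[i, ])), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      if (abs(fisher.test(tab)$p.value - fisher_enum_p(tab)) > 1e-9)
        mism <- mism + 1
    }
  }
  expect_equal(mism, 0)
  # random larger tables up to N = 40
  set.seed(41)
  for (r in 1:400) {
    tab <- matrix(rmultinom(1, sample(5:40, 1), runif(4, 0.05, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher.test(tab)$p.value, fisher_enum_p(tab),
                 tolerance = 1e-9)
  }
})

test_that("Kaplan-Meier matches hand product-limit values", {
  # no events: flat at 1
  km0 <- km_estimator(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(km0$curve$surv == 1))
  # all events: empirical survival function
  km1 <- km_estimator(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km1$curve$surv, c(2 / 3, 1 / 3, 0))
  # censoring removes from risk set without a step
  km2 <- km_estimator(c(1, 1.5, 2, 3), c(1, 0, 1, 1))
  ev <- km2$curve[km2$curve$n_event > 0, ]
  expect_equal(ev$surv, c(3 / 4, 3 / 4 * 1 / 2, 0))
  expect_equal(km_survival_at(km2, c(0.5, 1.2, 10)), c(1, 3 / 4, 0))
  # property: without censoring KM equals the empirical survivor function
  set.seed(47)
  tm <- round(rlnorm(40, 2, 0.7), 1)
  km3 <- km_estimator(tm, rep(1, 40))
  expect_equal(km3$curve$surv, hand_km(tm, rep(1, 40)))
  expect_equal(km3$curve$surv,
               vapply(km3$curve$time, function(t) mean(tm > t), numeric(1)))
  expect_error(km_estimator(numeric(0), integer(0)), "empty")
})

test_that("log-rank test matches the hand O-E statistic", {
  tm <- c(1, 2, 3, 4, 5, 6); ev <- c(1, 1, 0, 1, 1, 1)
  gr <- c(1, 1, 1, 2, 2, 2)
  lr <- logrank_test(tm, ev, gr)
  expect_equal(lr$statistic, hand_logrank_stat(tm, ev, gr))
  expect_equal(lr$p_value, pchisq(lr$statistic, 1, lower.tail = FALSE))
  # identical groups: statistic 0, p = 1
  lr0 <- logrank_test(rep(tm, 2), rep(ev, 2), rep(1:2, each = 6))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)
  # evidence grows with sample size for truly separated groups
  ps <- vapply(c(50, 100, 200), function(n) {
    co <- simulate_cohort(n_cases = n, eps = 0, seed = 500 + n)
    logrank_test(co$time_months, co$ltp, co$u6 > 10)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(logrank_test(tm, rep(0, 6), gr), "events")
})

test_that("ROC AUC equals the exhaustive concordant-pair oracle", {
  expect_equal(roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_analysis(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  set.seed(53)
  for (r in 1:20) {
    n <- sample(6:50, 1)
    vals <- round(runif(n, 0, 30), sample(0:1, 1))  # ties likely
    labs <- rbinom(n, 1, 0.4)
    if (length(unique(labs)) < 2) next
    roc <- roc_analysis(vals, labs)
    expect_equal(roc$auc, auc_pair_oracle(vals, labs))
    expect_true(all(diff(roc$sweep$sensitivity) <= 0))
    expect_true(all(diff(roc$sweep$specificity) >= 0))
  }
  expect_error(roc_analysis(1:4, c(1, 1, 1, 1)), "non-LTP")
})

test_that("ROC AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(59)
  vals <- c(rnorm(30, 12, 6), rnorm(10, 22, 6))
  labs <- rep(c(0, 1), c(30, 10))
  expect_equal(roc_analysis(vals, labs)$auc,
               as.numeric(pROC::auc(pROC::roc(labs, vals, quiet = TRUE))))
})

test_that("100%-sensitivity cut-off sits one grid step below the LTP minimum", {
  s <- sens100_threshold(c(3.3, 7.6, 20), c(1, 1, 1))
  expect_equal(s$threshold, 3.2)
  expect_equal(sens100_threshold(c(0.1, 5), c(1, 0))$threshold, 0)  # grid floor
  s2 <- sens100_threshold(c(2, 4, 11.3, 15), c(0, 0, 1, 1))
  expect_equal(s2$threshold, 11.2)
  expect_equal(s2$specificity, 1)     # both non-LTP values below 11.2
  expect_error(sens100_threshold(1:3, c(0, 0, 0)), "no LTP")
})

test_that("zone bands partition the percentage axis", {
  # LTP values from the reference profiles at 6 mm plus synthetic
  # non-LTP values whose maximum sets the upper gray bound at 19.3
  ref <- ltp_reference_cohort()
  vals <- c(ref$u6, c(0, 0, 1.2, 4.8, 8.1, 12.5, 19.3))
  labs <- c(ref$ltp, rep(0, 7))
  zb <- zone_bands(vals, labs)
  expect_equal(zb$green_upper, 11.2)
  expect_equal(zb$red_lower, 19.3)
  expect_equal(zb$gray, c(11.2, 19.3))
  # perfectly separated cohort: empty gray band
  zb2 <- zone_bands(c(1, 2, 3, 20, 25), c(0, 0, 0, 1, 1))
  expect_null(zb2$gray)
  expect_equal(zb2$green_upper, 19.9)
  expect_equal(zb2$red_lower, 3)
})

test_that("pooled t test matches hand computation and handles degeneracy", {
  r <- compare_groups_continuous(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 0.0214, tolerance = 1e-2)
  expect_equal(compare_groups_continuous(c(2, 2), c(2, 2))$p_value, 1)
  expect_equal(compare_groups_continuous(c(2, 2), c(3, 3))$p_value, 0)
  # agrees with the standard implementation on ordinary data
  set.seed(61)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  expect_equal(r2 <- compare_groups_continuous(x, y)$p_value,
               t.test(x, y, var.equal = TRUE)$p.value)
})

test_that("covariate screen builds 2x2 tables per risk factor", {
  co <- simulate_cohort(n_cases = 120, seed = 67)
  scr <- covariate_screen(co)
  expect_true(all(c("size_ge_30mm", "age_gt_60y", "vessel") %in% scr$covariate))
  expect_true(all(scr$yes_total + scr$no_total == 120))
  expect_true(all(scr$p_value >= 0 & scr$p_value <= 1))
  # a covariate identical to the outcome is maximally associated
  co$oracle_flag <- co$ltp
  p_perfect <- covariate_screen(co, "oracle_flag")$p_value
  expect_lt(p_perfect, 1e-6)
  co$const <- 1L
  expect_error(covariate_screen(co, "const"), "constant")
})

test_that("null covariates are rarely flagged (type-I behaviour)", {
  set.seed(71)
  ps <- replicate(60, {
    co <- simulate_cohort(n_cases = 100)
    covariate_screen(co, "vessel")$p_value
  })
  expect_lt(mean(ps < 0.05), 0.15)
})
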