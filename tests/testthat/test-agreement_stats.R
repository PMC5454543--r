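test_that("paired differences are FP minus board, one record per key and parameter", {
  tabs <- make_metric_tables(6, 4, 3, perturb = 0)
  d <- paired_differences(tabs$fp, tabs$board)
  expect_identical(nrow(d), 72L * 9L)
  expect_true(all(d$value == 0))
  expect_identical(sum(d$parameter == "rms_ml"), 72L)

  tabs <- make_metric_tables(3, 2, 2, perturb = 1)
  d <- paired_differences(tabs$fp, tabs$board)
  i <- which(d$subject_id == "S02" & d$device_id == "B1" &
             d$trial_index == 2 & d$parameter == "dot")
  sel <- tabs$fp$subject_id == "S02" & tabs$fp$device_id == "B1" &
    tabs$fp$trial_index == 2
  expect_equal(d$value[i], tabs$fp$dot[sel] - tabs$board$dot[sel])

  # missing trial in one table -> pairing error listing the orphan
  err <- expect_error(paired_differences(tabs$fp[-1, ], tabs$board),
                      class = "sa_pairing_error")
  expect_match(conditionMessage(err), "S01/B1/1")
})

test_that("device means aggregate trials per subject/device/parameter", {
  tabs <- make_metric_tables(6, 4, 3, perturb = 0.5)
  d <- paired_differences(tabs$fp, tabs$board)
  agg <- aggregate_by_device_mean(d)
  expect_identical(nrow(agg), 6L * 4L * 9L)  # 24 rows per parameter
  one <- d[d$subject_id == "S03" & d$device_id == "B2" &
           d$parameter == "tmv", "value"]
  expect_equal(agg$value[agg$subject_id == "S03" & agg$device_id == "B2" &
                         agg$parameter == "tmv"], mean(one))
  # single-trial input is the identity
  d1 <- d[d$trial_index == 1, ]
  agg1 <- aggregate_by_device_mean(d1)
  expect_equal(sort(agg1$value), sort(d1$value))
})

test_that("agreement limits are mean +/- 1.96 SD of the differences", {
  lim <- agreement_limits(rep(2.5, 10))
  expect_equal(lim$mean_diff, 2.5)
  expect_equal(lim$lower, 2.5)
  expect_equal(lim$upper, 2.5)

  lim <- agreement_limits(c(-1, 0, 1))
  expect_equal(lim$mean_diff, 0)
  expect_equal(lim$sd_diff, 1)
  expect_equal(lim$lower, -1.96)
  expect_equal(lim$upper, 1.96)

  # about 5% of fresh standard-normal draws fall outside the band
  set.seed(10)
  lim <- agreement_limits(rnorm(5000))
  fresh <- rnorm(50000)
  frac <- mean(fresh < lim$lower | fresh > lim$upper)
  expect_equal(frac, 0.05, tolerance = 0.2)

  expect_error(agreement_limits(c(1, 2)), class = "sa_too_short_error")
})

test_that("out-of-limit counting is strict and matches a hand count", {
  rec <- data.frame(
    subject_id = "S01", device_id = rep(c("B1", "B2"), each = 6),
    trial_index = rep(1:6, 2), parameter = "dot",
    value = c(0, 0.5, 2.5, -3, 1, 0.2,   2.0, 2.1, 0, -1, -2.6, 0.3))
  lims <- list(dot = structure(list(parameter = "dot", mean_diff = 0,
                                    sd_diff = 1, lower = -2, upper = 2,
                                    n_obs = 12),
                               class = "agreement_limits"))
  ct <- outside_limit_counts(rec, lims)
  expect_identical(ct$counts["dot", "B1"], 2L)  # 2.5 and -3
  expect_identical(ct$counts["dot", "B2"], 2L)  # 2.1 and -2.6; 2.0 is inside
  expect_equal(ct$ratios["dot", "B1"], 2 / 6)
  expect_identical(ct$total, 4L)

  # value exactly at the limit counts as inside
  rec$value <- rep(2, 12)
  ct <- outside_limit_counts(rec, lims)
  expect_identical(ct$total, 0L)
})

test_that("chi-square independence matches the expected-count oracle", {
  # perfectly proportional table: statistic 0, p 1
  tab <- outer(c(10, 20), c(3, 6)) / 10
  res <- chi_square_independence(round(tab))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  # hand-computed 2x2: all margins 30, E = 15 everywhere
  tab <- matrix(c(10, 20, 20, 10), 2, 2)
  res <- chi_square_independence(tab)
  expect_equal(res$statistic, 4 * 25 / 15, tolerance = 1e-12)
  expect_equal(unname(res$df), 1)
  expect_true(all(res$expected == 15))

  # 9x4 table: df = 24
  set.seed(12)
  tab <- matrix(rpois(36, 5) + 1, 9, 4)
  res <- chi_square_independence(tab)
  expect_equal(unname(res$df), 24)

  # permutation invariance
  res2 <- chi_square_independence(tab[sample(9), sample(4)])
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-9)

  expect_error(chi_square_independence(matrix(c(0, 0, 1, 2), 2, 2)),
               class = "sa_degenerate_error")
  expect_error(chi_square_independence(matrix(-1, 2, 2)),
               class = "sa_validation_error")
})

test_that("two-way random ICC matches the variance-components oracle", {
  # identical columns, varying rows: perfect agreement
  m <- matrix(rep(1:6, 4), 6, 4)
  ic <- icc_two_way(m, "single")
  expect_equal(ic$estimate, 1)
  expect_true(ic$degenerate)  # zero residual variance: interval undefined

  # all cells equal: defined as 1 with the degenerate flag
  ic <- icc_two_way(matrix(3, 5, 4), "single")
  expect_equal(ic$estimate, 1)
  expect_true(ic$degenerate)

  set.seed(13)
  for (i in 1:20) {
    n <- sample(c(6, 18), 1)
    m <- matrix(rnorm(n * 4), n, 4) + rnorm(n)
    for (form in c("single", "average")) {
      ic <- icc_two_way(m, form)
      expect_equal(ic$estimate, oracle_icc(m, form), tolerance = 1e-10)
      expect_lte(ic$ci_lower, ic$estimate + 1e-8)
      expect_gte(ic$ci_upper, ic$estimate - 1e-8)
    }
    # Spearman-Brown direction: average >= single when MSR > MSE
    s <- icc_two_way(m, "single"); a <- icc_two_way(m, "average")
    if (s$ms$rows > s$ms$error) expect_gte(a$estimate, s$estimate)
  }

  # large per-column offsets depress the single form far below the average
  m <- matrix(rep(rnorm(8), 3), 8, 3) +
    matrix(rep(c(0, 5, 10), each = 8), 8, 3)
  s <- icc_two_way(m, "single"); a <- icc_two_way(m, "average")
  expect_lt(s$estimate, a$estimate / 2)
  expect_lt(s$estimate, 0.2)

  expect_error(icc_two_way(matrix(c(1, NA, 2, 3), 2, 2)),
               class = "sa_validation_error")
  expect_error(icc_two_way(matrix(1:3, 3, 1)), class = "sa_validation_error")
})

test_that("ICC confidence interval achieves near-nominal coverage", {
  # two-way random model with known variance components
  set.seed(14)
  n <- 18; k <- 4
  icc_true <- 4 / (4 + 0.25 + 1)   # s2_row / (s2_row + s2_col + s2_e)
  hits <- 0; reps <- 200
  for (r in 1:reps) {
    m <- matrix(rnorm(n * k, sd = 1), n, k) +
      outer(rnorm(n, sd = 2), rep(1, k)) +
      outer(rep(1, n), rnorm(k, sd = 0.5))
    ic <- icc_two_way(m, "single")
    if (ic$ci_lower <= icc_true && icc_true <= ic$ci_upper) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.88)
  expect_lt(hits / reps, 0.995)
})

test_that("Friedman test handles ties and matches reference implementations", {
  # identical columns: statistic 0, p 1
  res <- friedman_test(matrix(rep(1:5, 3), 5, 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(15)
  for (i in 1:15) {
    m <- matrix(sample(1:4, 24, replace = TRUE), 6, 4)  # heavy ties
    res <- friedman_test(m)
    expect_equal(res$statistic, oracle_friedman_stat(m), tolerance = 1e-12)
    ref <- suppressWarnings(stats::friedman.test(m))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  }

  # invariance under strictly monotone within-block transforms
  m <- matrix(rnorm(24), 6, 4)
  res1 <- friedman_test(m)
  res2 <- friedman_test(exp(2 * m))
  expect_equal(res1$statistic, res2$statistic, tolerance = 1e-12)

  # reference-design input: 6 subjects x 4 devices -> df 3
  expect_identical(friedman_test(m)$df, 3)
})

test_that("exact Friedman permutation p matches the enumeration oracle", {
  set.seed(16)
  for (i in 1:4) {
    m <- matrix(sample(1:5, 9, replace = TRUE), 3, 3)
    res <- friedman_test(m, exact = TRUE)
    expect_identical(res$method, "exact-permutation")
    expect_equal(res$p_value, oracle_friedman_perm_p(m), tolerance = 1e-12)
  }
  # consistently dominant treatment: smallest attainable exact p
  m <- cbind(c(5, 6, 7), c(1, 2, 1.5), c(2.2, 3, 2.8))
  res <- friedman_test(m, exact = TRUE)
  expect_equal(res$p_value, oracle_friedman_perm_p(m), tolerance = 1e-12)
  expect_lt(res$p_value, 0.06)
  expect_error(friedman_test(matrix(rnorm(40), 10, 4), exact = TRUE,
                             max_perms = 1e4),
               class = "sa_validation_error")
})

test_that("Spearman correlation is midrank-then-Pearson", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_rho(x, x^3), 1)
  expect_equal(spearman_rho(x, -exp(x)), -1)

  set.seed(17)
  for (i in 1:10) {
    x <- sample(1:5, 20, replace = TRUE)  # ties
    y <- x + sample(0:3, 20, replace = TRUE)
    r <- spearman_rho(x, y)
    expect_equal(r, cor(rank(x), rank(y)), tolerance = 1e-12)
    expect_equal(r, cor(x, y, method = "spearman"), tolerance = 1e-12)
    # monotone-transform invariance
    expect_equal(spearman_rho(exp(x), y), r, tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), class = "sa_degenerate_error")
  expect_error(spearman_rho(1:3, 1:4), class = "sa_validation_error")
})

test_that("a perfect board yields the degenerate all-agreement report", {
  tabs <- make_metric_tables(6, 4, 3, perturb = 0)
  rep <- run_interchangeability_study(tabs$fp, tabs$board,
                                      design = study_design(6, 4, 3, 30))
  expect_true(all(rep$icc$estimate == 1))
  expect_true(all(rep$icc$degenerate))
  expect_true(all(rep$friedman$p_value == 1))
  expect_identical(rep$contingency$total, 0L)
  expect_true(is.na(rep$chisq$p_value))   # no informative contingency rows
  # FP and board values identical: all per-device correlations are 1
  dev_cols <- sort(unique(tabs$fp$device_id))
  expect_true(all(as.matrix(rep$spearman[dev_cols]) == 1))
})

test_that("the study battery reports both ICC granularities and errors on gaps", {
  tabs <- make_metric_tables(6, 4, 3, perturb = 0.4)
  rep <- run_interchangeability_study(tabs$fp, tabs$board,
                                      design = study_design(6, 4, 3, 30))
  expect_identical(nrow(rep$icc), 9L * 4L)
  trial_rows <- rep$icc[rep$icc$mode == "trial", ]
  expect_true(all(trial_rows$n_targets == 18))
  mean_rows <- rep$icc[rep$icc$mode == "subject_mean", ]
  expect_true(all(mean_rows$n_targets == 6))
  expect_identical(nrow(rep$limits), 9L)
  expect_true(all(rep$limits$n_obs == 72))
  expect_true(all(rep$limits$lower <= rep$limits$mean_diff))
  expect_true(all(rep$limits$mean_diff <= rep$limits$upper))
  # incomplete design
  expect_error(
    run_interchangeability_study(tabs$fp[-1, ], tabs$board[-1, ],
                                 design = study_design(6, 4, 3, 30)),
    class = "sa_validation_error")
})
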