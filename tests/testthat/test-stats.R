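# Validation statistics: ANOVA (raw and summary), exact contingency tests,
# Pearson regression, Bland-Altman, ROC AUC, ICC(2,1), paired comparison.

test_that("summary-statistics ANOVA equals raw-data ANOVA exactly", {
  set.seed(11)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    m <- runif(k, 50, 150)
    s <- runif(k, 5, 25)
    # two points per group with exactly the requested moments
    d <- purrr::map_dfr(seq_len(k), function(gi) {
      tibble::tibble(g = paste0("g", gi),
                     x = c(m[gi] - s[gi] / sqrt(2), m[gi] + s[gi] / sqrt(2)))
    })
    raw <- anova_oneway(d, x, g)
    summ <- anova_oneway_summary(
      dplyr::summarise(dplyr::group_by(d, g), n = dplyr::n(),
                       mean = mean(x), sd = sd(x), .groups = "drop")
    )
    expect_equal(raw$statistic, summ$statistic, tolerance = 1e-12)
    expect_equal(raw$p.value, summ$p.value, tolerance = 1e-12)
    # independent reference: the classical equal-variance F test
    ref <- oneway.test(x ~ g, data = d, var.equal = TRUE)
    expect_equal(raw$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(raw$p.value, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("ANOVA handles degenerate inputs explicitly", {
  same <- anova_oneway_summary(data.frame(n = c(10, 12), mean = c(5, 5),
                                          sd = c(1, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(anova_oneway_summary(data.frame(n = c(5, 5), mean = c(3, 3),
                                               sd = c(0, 0))),
               class = "lvd_error_degenerate")
  expect_error(anova_oneway_summary(data.frame(n = 5, mean = 3, sd = 1)),
               class = "lvd_error_argument")
})

test_that("Bonferroni pairwise contrasts are adjusted t tests", {
  set.seed(12)
  d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 8),
                      x = rnorm(24, rep(c(0, 1, 3), each = 8)))
  pw <- bonferroni_pairwise(d, x, g)
  expect_equal(nrow(pw), 3)
  ref <- stats::pairwise.t.test(d$x, d$g, p.adjust.method = "bonferroni")
  expect_equal(sort(pw$p.value), sort(as.vector(ref$p.value[!is.na(ref$p.value)])))
})

test_that("the exact r x c test matches brute-force enumeration", {
  expect_equal(fisher_exact_rxc(rbind(c(1, 0), c(0, 1)))$p.value, 1)
  set.seed(21)
  for (rep in 1:25) {
    tb <- matrix(rpois(6, 2.5), nrow = 2)
    if (sum(tb) == 0 || sum(tb) > 30) next
    got <- fisher_exact_rxc(tb)$p.value
    expect_equal(got, oracle_fisher_2xc(tb), tolerance = 1e-9)
    expect_gt(got, 0)
    expect_lte(got, 1)
  }
  expect_error(fisher_exact_rxc(matrix(c(1.5, 2, 3, 4), 2)),
               class = "lvd_error_argument")
})

test_that("large tables fall back to seeded Monte Carlo", {
  tb <- matrix(rep(30, 6), nrow = 2)
  res <- fisher_exact_rxc(tb, enum_limit = 100, mc_draws = 2000, seed = 5)
  expect_match(res$method, "Monte Carlo")
  expect_gt(res$p.value, 0)
  res2 <- fisher_exact_rxc(tb, enum_limit = 100, mc_draws = 2000, seed = 5)
  expect_equal(res$p.value, res2$p.value) # same seed, same estimate
})

test_that("Pearson regression matches closed-form moments", {
  d <- tibble::tibble(x = 1:10)
  d$y2 <- 2 * d$x + 1
  expect_equal(pearson_linear(d, x, y2)$estimate, 1)
  expect_equal(pearson_linear(d, x, y2)$slope, 2)
  expect_equal(pearson_linear(d, x, y2)$intercept, 1)
  d$yneg <- -d$x
  expect_equal(pearson_linear(d, x, yneg)$estimate, -1)

  set.seed(8)
  d2 <- tibble::tibble(x = rnorm(10), y = rnorm(10))
  res <- pearson_linear(d2, x, y)
  r_oracle <- sum((d2$x - mean(d2$x)) * (d2$y - mean(d2$y))) /
    sqrt(sum((d2$x - mean(d2$x))^2) * sum((d2$y - mean(d2$y))^2))
  expect_equal(res$estimate, r_oracle, tolerance = 1e-12)
  tstat <- r_oracle * sqrt((10 - 2) / (1 - r_oracle^2))
  expect_equal(res$p.value, 2 * pt(-abs(tstat), 8), tolerance = 1e-12)
  expect_equal(res$slope, r_oracle * sd(d2$y) / sd(d2$x), tolerance = 1e-12)

  expect_error(pearson_linear(tibble::tibble(x = rep(1, 5), y = rnorm(5)), x, y),
               class = "lvd_error_degenerate")
})

test_that("Bland-Altman limits are bias +/- 1.96 SD of differences", {
  ba0 <- bland_altman(1:8, 1:8)
  expect_equal(tidy(ba0)$bias, 0)
  expect_equal(tidy(ba0)$loa_low, 0)
  expect_equal(tidy(ba0)$loa_high, 0)

  bad <- bland_altman(1:8, 1:8 + 3)
  expect_equal(tidy(bad)$bias, 3)
  expect_equal(c(tidy(bad)$loa_low, tidy(bad)$loa_high), c(3, 3))

  set.seed(4)
  x <- rnorm(8, 100, 10); y <- x + rnorm(8, 1, 2)
  ba <- bland_altman(x, y)
  expect_equal(ba$bias, mean(y - x))
  expect_equal(ba$loa_high, mean(y - x) + 1.96 * sd(y - x))
  expect_equal(ba$loa_low, mean(y - x) - 1.96 * sd(y - x))
  expect_error(bland_altman(x, y, units = c("cm/s", "mL/s")),
               class = "lvd_error_units")
  expect_s3_class(ggplot2::autoplot(ba), "ggplot")
})

test_that("Bland-Altman limits cover ~95% of normal differences", {
  set.seed(99)
  x <- rnorm(10000, 50, 5)
  y <- x + rnorm(10000, 2, 3)
  ba <- bland_altman(x, y)
  cover <- mean(y - x >= ba$loa_low & y - x <= ba$loa_high)
  expect_equal(cover, 0.95, tolerance = 0.011)
})

test_that("ROC AUC equals the all-pairs rank statistic", {
  perfect <- roc_auc_with_band(c(1, 2, 3, 10, 11, 12),
                               c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$band, "excellent")

  flat <- roc_auc_with_band(rep(5, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(flat$auc, 0.5)
  expect_equal(flat$band, "poor")

  set.seed(31)
  for (rep in 1:30) {
    n <- sample(6:50, 1)
    scores <- round(rnorm(n), 1) # rounding forces ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    res <- roc_auc_with_band(scores, labels)
    expect_equal(res$auc, oracle_auc_pairs(scores, labels), tolerance = 1e-12)
    # orientation symmetry
    res_neg <- roc_auc_with_band(-scores, labels)
    expect_equal(res$auc + res_neg$auc, 1, tolerance = 1e-12)
    # lower-is-disease equals negated scores
    res_low <- roc_auc_with_band(scores, labels, direction = "lower")
    expect_equal(res_low$auc, res_neg$auc, tolerance = 1e-12)
  }
  expect_error(roc_auc_with_band(1:5, rep(TRUE, 5)),
               class = "lvd_error_degenerate_labels")
})

test_that("ROC p-values agree with the rank-sum normal approximation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  scores <- c(rnorm(30, 1), rnorm(20, 0))
  labels <- rep(c(TRUE, FALSE), c(30, 20))
  res <- roc_auc_with_band(scores, labels)
  # independent AUC cross-check
  auc_ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                            direction = "<")))
  expect_equal(res$auc, auc_ref, tolerance = 1e-10)
  wt <- suppressWarnings(stats::wilcox.test(scores[labels], scores[!labels],
                                            exact = FALSE, correct = FALSE))
  expect_equal(res$p.value, wt$p.value, tolerance = 1e-8)
})

test_that("ICC(2,1) matches the mean-squares oracle and its bands", {
  set.seed(41)
  x <- rnorm(9, 100, 15)
  dup <- cbind(x, x)
  res_dup <- icc_two_way_random(dup)
  expect_equal(res_dup$icc, 1)
  expect_equal(res_dup$band, "excellent")

  m <- matrix(c(9, 2, 5, 8, 6, 7,
                10, 4, 6, 9, 7, 8), ncol = 2)
  res <- icc_two_way_random(m)
  expect_equal(res$icc, oracle_icc21(m), tolerance = 1e-12)
  expect_equal(res$bias, tidy(bland_altman(m[, 1], m[, 2]))$bias)

  # invariance to shift and positive rescale
  expect_equal(icc_two_way_random(m + 10)$icc, res$icc, tolerance = 1e-12)
  expect_equal(icc_two_way_random(m * 3.5)$icc, res$icc, tolerance = 1e-12)

  # band cutoffs
  expect_equal(icc_band(0.89), "excellent")
  expect_equal(icc_band(0.60), "fair-to-good")
  expect_equal(icc_band(0.39), "poor")

  m_na <- m; m_na[2, 1] <- NA
  expect_error(icc_two_way_random(m_na), class = "lvd_error_incomplete_matrix")
  expect_error(icc_two_way_random(m[1:3, ]), class = "lvd_error_argument")
})

test_that("paired comparison reduces to the classical paired t test", {
  same <- paired_mean_comparison(1:6, 1:6)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  x <- c(10.2, 11.5, 9.8, 12.1, 10.9)
  y <- c(11.0, 12.2, 10.1, 13.0, 11.2)
  res <- paired_mean_comparison(x, y)
  d <- y - x
  t_oracle <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res$p.value, 2 * pt(-abs(t_oracle), 4), tolerance = 1e-12)

  set.seed(6)
  x2 <- rnorm(400, 100, 10)
  y2 <- x2 + 2.5 + rnorm(400, 0, 1)
  shift <- paired_mean_comparison(x2, y2)
  expect_equal(shift$estimate, 2.5, tolerance = 3 * 1 / sqrt(400))
})
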