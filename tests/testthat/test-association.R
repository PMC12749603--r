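# expand a counts table into a long per-sample data.frame
expand_counts <- function(var, levels_row, groups_col, counts) {
  df <- expand.grid(row = levels_row, col = groups_col, stringsAsFactors = FALSE)
  df$n <- as.vector(counts)
  out <- df[rep(seq_len(nrow(df)), df$n), c("row", "col")]
  names(out) <- c(var, "group")
  out
}

test_that("crosstab computes counts and within-column percentages", {
  # ER x necrosis with the published cohort counts
  counts <- matrix(c(292, 34, 73, 77), nrow = 2)  # rows pos/neg, cols N-/N+
  cl <- expand_counts("er", c("positive", "negative"), c("N-", "N+"), counts)
  ct <- crosstab(cl, "er", "group")
  expect_equal(ct$counts["negative", "N+"], 77)
  expect_equal(ct$percent_within_col["negative", "N+"], 51.3)
  expect_equal(ct$percent_within_col["positive", "N-"], 89.6)
  expect_equal(ct$n_used, 476)
  # percentages within a column sum to 100 up to rounding
  expect_true(all(abs(colSums(ct$percent_within_col) - 100) < 0.11))
})

test_that("crosstab excludes missing pairwise with a count", {
  cl <- data.frame(er = c("positive", "negative", "missing", "positive"),
                   group = c("a", "a", "b", "missing"))
  ct <- crosstab(cl, "er", "group")
  expect_equal(ct$n_used, 2)
  expect_equal(ct$n_missing_excluded, 2)
  expect_error(crosstab(cl, "nope", "group"), "unknown variable")
  expect_error(crosstab(data.frame(er = "missing", group = "a"), "er", "group"),
               "no complete pairs")

  # all mass in one cell -> 100%
  one <- data.frame(er = rep("positive", 4), group = rep("a", 4))
  expect_equal(unname(crosstab(one, "er", "group")$percent_within_col[1, 1]), 100)
})

test_that("chi_square is the uncorrected Pearson statistic", {
  # identical row distributions -> statistic 0, p = 1
  res <- chi_square(matrix(c(10, 10, 20, 20), nrow = 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # random r x c fixtures vs the formula oracle
  set.seed(2)
  for (i in 1:5) {
    tab <- matrix(rpois(6, 20) + 1, nrow = 2)
    res <- chi_square(tab)
    expect_equal(res$statistic, oracle_chisq_stat(tab), tolerance = 1e-12)
    expect_equal(res$df, 2)
    expect_equal(res$p_value,
                 pchisq(oracle_chisq_stat(tab), 2, lower.tail = FALSE))
  }
  expect_error(chi_square(matrix(c(0, 0, 5, 5), nrow = 2)), "zero row/column")
})

test_that("chi_square matches the closed-form 2x2 expression", {
  set.seed(3)
  for (i in 1:10) {
    t2 <- matrix(rpois(4, 15) + 1, nrow = 2)
    a <- t2[1, 1]; b <- t2[1, 2]; c_ <- t2[2, 1]; d <- t2[2, 2]
    n <- sum(t2)
    closed <- n * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    expect_equal(chi_square(t2)$statistic, closed, tolerance = 1e-12)
  }
})

test_that("mann_whitney: symmetric input gives p = 1, exact mode available", {
  res <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(res$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")

  # exact mode agrees with the exact wilcoxon distribution on small n
  set.seed(4)
  x <- rnorm(6); y <- rnorm(7) + 1
  expect_equal(mann_whitney(x, y, exact = TRUE)$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("kruskal_wallis with k = 2 matches the Mann-Whitney decision", {
  set.seed(5)
  x <- rnorm(15); y <- rnorm(12) + 0.8  # no ties
  pkw <- kruskal_wallis(list(x, y))$p_value
  pmw <- mann_whitney(x, y)$p_value
  expect_equal(pkw, pmw, tolerance = 1e-10)
  expect_error(kruskal_wallis(list(x, numeric(0))), "non-empty")
})

test_that("spearman rho is the rank correlation with a t-approximate p", {
  s <- spearman(1:10, (1:10)^2)
  expect_equal(s$rho, 1)
  expect_lt(s$p_value, 1e-6)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:3, 1:4), "equal length")

  set.seed(6)
  x <- rnorm(30); y <- x + rnorm(30)
  expect_equal(spearman(x, y)$rho, cor(x, y, method = "spearman"))
})

test_that("null type-I error of the rank tests is calibrated", {
  set.seed(7)
  reps <- 1000
  rej <- mean(replicate(reps, {
    x <- rnorm(15); y <- rnorm(15)
    mann_whitney(x, y)$p_value < 0.05
  }))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
})

test_that("logistic regression recovers a planted log-odds coefficient", {
  betas <- vapply(1:3, function(seed) {
    set.seed(seed)
    x <- rnorm(500)
    y <- rbinom(500, 1, plogis(1.5 * x))
    fit <- logistic_predict_basal(data.frame(score = x), y)
    fit$coefficients$beta[fit$coefficients$term == "score"]
  }, numeric(1))
  expect_true(all(abs(betas - 1.5) < 0.3))
})

test_that("logistic regression flags degenerate designs", {
  set.seed(8)
  # intercept-only on balanced labels -> intercept near 0
  y <- rep(c(0, 1), 100)
  fit <- logistic_predict_basal(data.frame(x = rnorm(200)), y)
  expect_lt(abs(fit$coefficients$beta[1]), 0.3)

  # duplicated feature -> collinearity error
  x <- rnorm(50)
  expect_error(logistic_predict_basal(data.frame(a = x, b = x),
                                      rbinom(50, 1, 0.5)),
               "collinear")

  # perfect separation flagged
  xs <- c(rnorm(20, -5), rnorm(20, 5))
  ys <- rep(c(0, 1), each = 20)
  expect_warning(fit2 <- logistic_predict_basal(data.frame(x = xs), ys),
                 "separation")
  expect_true(fit2$separation)
})

test_that("association battery reports one raw-p row per variable", {
  cl <- make_clinical(60, seed = 9)
  cl$score_group <- rep(c("high", "low"), 30)
  res <- suppressMessages(association_battery(cl, "score_group"))
  expect_equal(res$variable, c("er", "pr", "her2", "pam50"))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})
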