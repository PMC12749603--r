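#' Cross-tabulate two categorical clinical variables
#'
#' Builds the counts-with-percent layout of a clinico-pathological
#' association table: rows are the levels of `var_row`, columns the levels of
#' `var_col`, percentages computed within each column and rounded to one
#' decimal. Samples with a `"missing"` value in either variable are excluded
#' and counted.
#'
#' @param clinical validated clinical data.frame (or any data.frame holding
#'   the two columns).
#' @param var_row,var_col column names of the two categorical variables.
#' @return list of class `necro_crosstab`: `counts` (matrix),
#'   `percent_within_col` (matrix, one decimal), `n_used`,
#'   `n_missing_excluded`.
#' @export
crosstab <- function(clinical, var_row, var_col) {
  for (v in c(var_row, var_col)) {
    if (!v %in% names(clinical)) stop("unknown variable: ", v)
  }
  r <- as.character(clinical[[var_row]])
  c_ <- as.character(clinical[[var_col]])
  ok <- r != "missing" & c_ != "missing" & !is.na(r) & !is.na(c_)
  if (!any(ok)) stop("no complete pairs for ", var_row, " x ", var_col)
  counts <- table(r[ok], c_[ok])
  counts <- unclass(counts)
  pct <- round(100 * sweep(counts, 2, colSums(counts), "/"), 1)
  structure(list(counts = counts, percent_within_col = pct,
                 n_used = sum(ok), n_missing_excluded = sum(!ok),
                 var_row = var_row, var_col = var_col),
            class = "necro_crosstab")
}

#' @export
print.necro_crosstab <- function(x, ...) {
  cat("<crosstab> ", x$var_row, " x ", x$var_col, " (n = ", x$n_used,
      ", missing excluded = ", x$n_missing_excluded, ")\n", sep = "")
  disp <- matrix(paste0(x$counts, " (", format(x$percent_within_col, trim = TRUE), "%)"),
                 nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(disp, quote = FALSE)
  invisible(x)
}

# normalize test output to the common result record
.test_result <- function(name, statistic, df, p, n_used, n_missing = 0L) {
  data.frame(test = name,
             statistic = unname(statistic),
             df = if (is.null(df)) NA_real_ else unname(df),
             p_value = unname(p),
             n_used = n_used,
             n_missing_excluded = n_missing,
             stringsAsFactors = FALSE)
}

#' Pearson chi-square test on a contingency table
#'
#' Uncorrected Pearson statistic `sum((O - E)^2 / E)` with
#' `df = (r - 1)(c - 1)` and an upper-tail chi-square p-value; no continuity
#' correction (matching the conventional Pearson test of association
#' tables). A zero row or column margin is an error.
#'
#' @param x a `necro_crosstab`, or a counts matrix.
#' @return one-row data.frame: `test`, `statistic`, `df`, `p_value`,
#'   `n_used`, `n_missing_excluded`.
#' @export
chi_square <- function(x) {
  n_missing <- 0L
  if (inherits(x, "necro_crosstab")) {
    n_missing <- x$n_missing_excluded
    x <- x$counts
  }
  x <- as.matrix(x)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop("zero row/column margin in contingency table")
  }
  ct <- suppressWarnings(chisq.test(x, correct = FALSE))
  .test_result("Pearson chi-square", ct$statistic, ct$parameter, ct$p.value,
               sum(x), n_missing)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of a continuous variable between two groups. Default
#' is the tie-corrected normal approximation without continuity correction
#' (cohort-scale inputs); `exact = TRUE` switches to exact enumeration
#' (small samples, no ties).
#'
#' @param x,y numeric vectors, both non-empty.
#' @param exact use the exact distribution (default `FALSE`).
#' @return one-row test-result data.frame (statistic = U for `x`).
#' @export
mann_whitney <- function(x, y, exact = FALSE) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = FALSE))
  .test_result("Mann-Whitney U", wt$statistic, NULL, wt$p.value,
               length(x) + length(y))
}

#' Kruskal-Wallis H test
#'
#' Tie-corrected H statistic with a chi-square p-value on `k - 1` degrees of
#' freedom, for comparing a continuous variable across more than two groups.
#'
#' @param groups list of non-empty numeric vectors (one per group).
#' @return one-row test-result data.frame.
#' @export
kruskal_wallis <- function(groups) {
  if (any(lengths(groups) == 0)) stop("all groups must be non-empty")
  kt <- kruskal.test(groups)
  .test_result("Kruskal-Wallis H", kt$statistic, kt$parameter, kt$p.value,
               sum(lengths(groups)))
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of the (average) ranks; the p-value uses
#' the t-approximation on rho. Constant input is an error (rho undefined).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input: Spearman rho undefined")
  rho <- cor(rank(x), rank(y))
  n <- length(x)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- if (is.finite(tstat)) 2 * stats::pt(-abs(tstat), df = n - 2) else 0
  list(rho = rho, p_value = p, n = n)
}

#' Logistic regression predicting a binary phenotype from score + covariates
#'
#' Maximum-likelihood fit (IRLS via [stats::glm()]) of
#' `label ~ feature1 + feature2 + ...`, with per-feature coefficient, odds
#' ratio and Wald p-value. Perfectly collinear features are an error;
#' (quasi-)separation or non-convergence is flagged in the `converged` /
#' `separation` fields with a warning.
#'
#' @param features data.frame of numeric predictor columns (e.g. the
#'   necrosis-signature score and marker mRNA levels).
#' @param labels binary vector (logical, or 0/1, or two-level factor);
#'   `TRUE`/1/second level = the phenotype being predicted.
#' @return list: `coefficients` (data.frame term/beta/odds_ratio/se/p_value),
#'   `converged`, `separation`, `n`.
#' @export
logistic_predict_basal <- function(features, labels) {
  features <- as.data.frame(features)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels) | labels == 1)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary")
  if (length(unique(labels)) < 2) stop("labels must contain both classes")
  df <- cbind(.y = labels, features)
  mm <- stats::model.matrix(~ ., data = features)
  if (qr(mm)$rank < ncol(mm)) stop("perfectly collinear features")
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  probs <- fit$fitted.values
  separation <- any(probs > 1 - 1e-8) || any(probs < 1e-8)
  if (separation) warning("possible separation: fitted probabilities at 0/1; coefficients unreliable")
  if (!fit$converged) warning("logistic fit did not converge")
  sm <- summary(fit)$coefficients
  list(coefficients = data.frame(term = rownames(sm),
                                 beta = sm[, 1],
                                 odds_ratio = exp(sm[, 1]),
                                 se = sm[, 2],
                                 p_value = sm[, 4],
                                 row.names = NULL,
                                 stringsAsFactors = FALSE),
       converged = fit$converged,
       separation = separation,
       n = length(labels))
}

#' Run the standard association battery between a grouping and clinical variables
#'
#' For each categorical variable a crosstab + Pearson chi-square; raw
#' p-values only (no multiple-testing adjustment is applied, and that is
#' deliberate and logged).
#'
#' @param clinical clinical data.frame.
#' @param group_col name of the grouping column (e.g. necrosis status or the
#'   score's high/low group, added to the table beforehand).
#' @param variables categorical clinical columns to test (default the
#'   receptor/subtype battery).
#' @return data.frame, one row per variable, with the test results.
#' @export
association_battery <- function(clinical, group_col,
                                variables = c("er", "pr", "her2", "pam50")) {
  message("association battery reports raw p-values; no multiplicity adjustment")
  res <- lapply(variables, function(v) {
    ct <- crosstab(clinical, v, group_col)
    out <- chi_square(ct)
    out$variable <- v
    out
  })
  do.call(rbind, res)
}
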