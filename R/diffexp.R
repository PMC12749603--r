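#' Differential-expression configuration
#'
#' Parameters of the two-class SAM-style analysis. Defaults reproduce the
#' signature-derivation thresholds used throughout the package: linear-scale
#' fold change at least 2.5 in absolute value and a permutation FDR below
#' 0.008 percent (i.e. 8e-5 as a proportion).
#'
#' @param s0_mode `"median"` (median of the per-gene standard errors),
#'   `"fixed"` (use `s0_value`), or `"percentile"` (Tusher-style search over
#'   the 0,5,...,95 percentiles of s minimizing the coefficient of variation
#'   of the spread of d across s-windows).
#' @param s0_value fudge factor when `s0_mode = "fixed"`.
#' @param n_permutations number of label permutations B (>= 1).
#' @param seed integer seed; mandatory, every permutation draw derives from it.
#' @param fc_min minimum absolute linear-scale fold change (>= 1).
#' @param q_max_percent maximum permutation FDR, in percent (0-100).
#' @return list of class `de_config`.
#' @export
de_config <- function(s0_mode = c("median", "fixed", "percentile"),
                      s0_value = NULL,
                      n_permutations = 1000L,
                      seed,
                      fc_min = 2.5,
                      q_max_percent = 0.008) {
  s0_mode <- match.arg(s0_mode)
  if (missing(seed)) stop("a seed is mandatory for the permutation analysis")
  stopifnot(n_permutations >= 1, fc_min >= 1,
            q_max_percent >= 0, q_max_percent <= 100)
  if (s0_mode == "fixed" && (is.null(s0_value) || s0_value < 0)) {
    stop("s0_mode = 'fixed' requires a non-negative s0_value")
  }
  structure(list(s0_mode = s0_mode, s0_value = s0_value,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), fc_min = fc_min,
                 q_max_percent = q_max_percent),
            class = "de_config")
}

# group-1 indicator matrix -> (numerator, pooled standard error) for each
# column of `ind`; vectorized over permutations.
# X: genes x samples; ind: samples x B with exactly n1 ones per column.
.sam_core <- function(X, ind, n1, n2) {
  Tsum <- rowSums(X)
  T2 <- rowSums(X^2)
  S1 <- X %*% ind                       # genes x B sums over group 1
  m1 <- S1 / n1
  m2 <- (Tsum - S1) / n2
  ss_within <- pmax(T2 - n1 * m1^2 - n2 * m2^2, 0)  # guard fp negatives
  s <- sqrt(ss_within / (n1 + n2 - 2) * (1 / n1 + 1 / n2))
  list(num = m1 - m2, s = s)
}

# observed per-gene means / numerator / pooled SE (no s0 handling)
.sam_obs <- function(x, labels) {
  validate_expression(x)
  labels <- check_labels(x, labels)
  g1 <- labels == levels(labels)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  core <- .sam_core(x, matrix(as.numeric(g1), ncol = 1), n1, n2)
  m1 <- rowMeans(x[, g1, drop = FALSE])
  list(gene = rownames(x), mean_g1 = m1, mean_g2 = m1 - core$num[, 1],
       num = core$num[, 1], s = core$s[, 1], g1 = g1, n1 = n1, n2 = n2)
}

#' SAM modified t-statistic
#'
#' For gene *i*: `d_i = (mean_i(group1) - mean_i(group2)) / (s_i + s0)`
#' where `s_i` is the pooled two-sample standard error of the mean
#' difference. With `s0 = 0`, `d` is the classical pooled-variance
#' t-statistic. Group 1 is the necrosis-present group by convention, so
#' positive `d` means higher expression with necrosis.
#'
#' @param x log2 expression matrix (genes x samples).
#' @param labels two-level factor named by sample id; level 1 = group 1.
#' @param s0 non-negative fudge factor added to every `s_i`.
#' @return data.frame with columns `gene`, `mean_g1`, `mean_g2`, `d`, `s`.
#' @export
sam_statistic <- function(x, labels, s0) {
  stopifnot(is.numeric(s0), length(s0) == 1, s0 >= 0)
  obs <- .sam_obs(x, labels)
  if (s0 == 0 && any(obs$s == 0)) {
    stop("zero-variance gene(s) with s0 = 0 (e.g. ",
         obs$gene[which(obs$s == 0)[1]], "); use s0 > 0")
  }
  data.frame(gene = obs$gene,
             mean_g1 = obs$mean_g1,
             mean_g2 = obs$mean_g2,
             d = obs$num / (obs$s + s0),
             s = obs$s,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Estimate the SAM fudge factor s0
#'
#' @param s_values non-empty vector of non-negative per-gene standard errors.
#' @param mode `"median"`, `"fixed"`, or `"percentile"` (requires the
#'   per-gene numerators to evaluate candidate d-statistics).
#' @param value fixed s0 when `mode = "fixed"`.
#' @param numerators per-gene mean differences, required for
#'   `mode = "percentile"`.
#' @return a single non-negative s0.
#' @export
estimate_s0 <- function(s_values, mode = c("median", "fixed", "percentile"),
                        value = NULL, numerators = NULL) {
  mode <- match.arg(mode)
  if (length(s_values) == 0) stop("empty s_values")
  if (any(s_values < 0)) stop("s_values must be non-negative")
  if (mode == "median") return(median(s_values))
  if (mode == "fixed") {
    if (is.null(value) || value < 0) stop("fixed mode requires a non-negative value")
    return(value)
  }
  # Tusher-style percentile search: candidate s0 = percentiles 0,5,...,95 of
  # s; pick the candidate minimizing the coefficient of variation of the
  # spread (MAD) of d across windows of s.
  if (is.null(numerators) || length(numerators) != length(s_values)) {
    stop("percentile mode requires per-gene numerators matching s_values")
  }
  cand <- quantile(s_values, probs = seq(0, 0.95, by = 0.05), names = FALSE)
  breaks <- unique(quantile(s_values, probs = seq(0, 1, by = 0.1), names = FALSE))
  if (length(breaks) < 2) return(cand[1])  # degenerate: all s equal
  win <- cut(s_values, breaks = breaks, include.lowest = TRUE)
  cv <- vapply(cand, function(a) {
    d <- numerators / (s_values + a)
    spread <- tapply(d, win, mad)
    spread <- spread[is.finite(spread)]
    if (length(spread) < 2 || mean(spread) == 0) return(Inf)
    sd(spread) / mean(spread)
  }, numeric(1))
  if (all(!is.finite(cv))) return(median(s_values))
  cand[which.min(cv)]
}

#' Signed linear-scale fold change from log2 group means
#'
#' `r = 2^(mean_g1 - mean_g2)`; the signed fold change is `r` when `r >= 1`
#' and `-1/r` otherwise, so magnitudes are symmetric around +/-1 and a
#' negative value means lower expression in group 1 (necrosis present).
#'
#' @inheritParams sam_statistic
#' @return data.frame with columns `gene`, `mean_g1`, `mean_g2`, `fc_signed`.
#' @export
signed_fold_change <- function(x, labels) {
  validate_expression(x)
  labels <- check_labels(x, labels)
  g1 <- labels == levels(labels)[1]
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, !g1, drop = FALSE])
  r <- 2^(m1 - m2)
  data.frame(gene = rownames(x), mean_g1 = m1, mean_g2 = m2,
             fc_signed = ifelse(r >= 1, r, -1 / r),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Permutation false-discovery rate (percent) for the SAM statistic
#'
#' For each of B seeded label permutations (group sizes preserved) the
#' statistic `d*` is recomputed for every gene. For gene *i* with observed
#' `|d_i|`, the false-discovery estimate at that threshold is
#' `100 * median_b(#\{|d*_b| >= |d_i|\}) / #\{observed |d| >= |d_i|\}`
#' (pi0 fixed at 1), capped at 100. The per-gene q-value is the minimum
#' estimate over all thresholds at or below `|d_i|`, which makes q
#' non-increasing in `|d|`. On tiny cohorts where B is at least the number
#' of distinct group-1 assignments, exhaustive enumeration replaces random
#' sampling (with a message).
#'
#' @inheritParams sam_statistic
#' @param config `de_config`; supplies B, seed and the s0 rule.
#' @param s0 optional explicit s0 overriding the config rule.
#' @return data.frame `gene`, `d`, `q_percent` in the row order of `x`.
#' @export
permutation_q <- function(x, labels, config, s0 = NULL) {
  obs <- .sam_obs(x, labels)
  n1 <- obs$n1; n2 <- obs$n2; n <- n1 + n2
  if (is.null(s0)) {
    s0 <- switch(config$s0_mode,
                 median = estimate_s0(obs$s, "median"),
                 fixed = config$s0_value,
                 percentile = estimate_s0(obs$s, "percentile",
                                          numerators = obs$num))
  }
  if (s0 == 0 && any(obs$s == 0)) {
    stop("zero-variance gene(s) with s0 = 0; use s0 > 0")
  }
  d_obs <- obs$num / (obs$s + s0)

  B <- config$n_permutations
  n_distinct <- choose(n, n1)
  if (B >= n_distinct) {
    idx <- combn(n, n1)
    message("exhaustive enumeration of all ", ncol(idx),
            " group assignments (B = ", B, " >= distinct permutations)")
  } else {
    idx <- with_seed(config$seed, {
      vapply(seq_len(B), function(b) sample.int(n, n1), integer(n1))
    })
  }
  ind <- matrix(0, nrow = n, ncol = ncol(idx))
  ind[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = n1))] <- 1

  core <- .sam_core(x, ind, n1, n2)
  d_perm <- abs(core$num / (core$s + s0))

  absd <- abs(d_obs)
  G <- length(absd)
  rownames_x <- obs$gene
  # numerator: per permutation, #{|d*| >= |d_i|} pooled over all genes
  counts <- apply(d_perm, 2, function(col) {
    sc <- sort(col)
    length(sc) - findInterval(absd, sc, left.open = TRUE)
  })
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = G)
  med_count <- apply(counts, 1, median)
  # denominator: #{observed |d| >= |d_i|}
  n_ge <- G - (rank(absd, ties.method = "min") - 1L)
  fdr <- pmin(100 * med_count / n_ge, 100)
  # q_i = min FDR over thresholds at or below |d_i|
  ord <- order(absd, decreasing = TRUE)
  q_sorted <- rev(cummin(rev(fdr[ord])))
  q <- numeric(G); q[ord] <- q_sorted
  data.frame(gene = rownames_x, d = d_obs, q_percent = q,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full two-class differential-expression analysis
#'
#' Runs the modified t-statistic, signed fold change and permutation FDR in
#' one pass and labels each gene's direction against the config thresholds.
#'
#' @inheritParams permutation_q
#' @return data.frame of class `de_result`: `gene`, `mean_g1`, `mean_g2`,
#'   `fc_signed`, `d`, `s`, `q_percent`, `direction` (`UP`/`DOWN`/`none`).
#'   The s0 used is stored in the `"s0"` attribute.
#' @export
sam_de <- function(x, labels, config) {
  fc <- signed_fold_change(x, labels)
  obs <- .sam_obs(x, labels)
  s0 <- switch(config$s0_mode,
               median = estimate_s0(obs$s, "median"),
               fixed = config$s0_value,
               percentile = estimate_s0(obs$s, "percentile",
                                        numerators = obs$num))
  q <- permutation_q(x, labels, config, s0 = s0)
  out <- data.frame(gene = fc$gene,
                    mean_g1 = fc$mean_g1,
                    mean_g2 = fc$mean_g2,
                    fc_signed = fc$fc_signed,
                    d = q$d,
                    s = obs$s,
                    q_percent = q$q_percent,
                    stringsAsFactors = FALSE)
  out$direction <- ifelse(
    out$fc_signed >= config$fc_min & out$q_percent < config$q_max_percent, "UP",
    ifelse(out$fc_signed <= -config$fc_min & out$q_percent < config$q_max_percent,
           "DOWN", "none"))
  attr(out, "s0") <- s0
  class(out) <- c("de_result", class(out))
  out
}

#' Derive a directional signature from a differential-expression result
#'
#' UP = genes with `fc_signed >= fc_min` and `q_percent < q_max_percent`;
#' DOWN = genes with `fc_signed <= -fc_min` and the same FDR cut. Errors if
#' no gene passes in either direction.
#'
#' @param de `de_result` from [sam_de()].
#' @param config `de_config` with the thresholds.
#' @param name signature name.
#' @return `necro_signature`.
#' @export
derive_signature <- function(de, config, name = "NECROSIS_SIG") {
  up <- de$gene[de$fc_signed >= config$fc_min & de$q_percent < config$q_max_percent]
  down <- de$gene[de$fc_signed <= -config$fc_min & de$q_percent < config$q_max_percent]
  if (length(up) + length(down) == 0) {
    stop("no genes pass thresholds (fc_min = ", config$fc_min,
         ", q_max_percent = ", config$q_max_percent, ")")
  }
  message("derived signature '", name, "': ", length(up), " UP, ",
          length(down), " DOWN genes")
  signature_definition(name, up = up, down = down)
}

#' Write a differential-expression result as tab-separated text
#' @param de `de_result` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_result <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
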