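#' Per-sample directional sum-score
#'
#' The score of a sample is the sum of its log2 expression over the
#' signature's UP genes minus the sum over its DOWN genes. Signature genes
#' absent from the matrix are skipped (never imputed); the number and
#' identity of skipped genes are recorded in the `"missing_genes"` attribute.
#'
#' @param x log2 expression matrix (genes x samples).
#' @param sig `necro_signature`.
#' @param missing_policy `"skip"` (default) or `"error"` when any signature
#'   gene is absent from the matrix.
#' @return named numeric vector of scores (names = sample ids), with
#'   attributes `missing_genes` and `signature`.
#' @export
score_signature <- function(x, sig, missing_policy = c("skip", "error")) {
  missing_policy <- match.arg(missing_policy)
  validate_expression(x)
  up <- intersect(sig$up, rownames(x))
  down <- intersect(sig$down, rownames(x))
  missing <- setdiff(union(sig$up, sig$down), rownames(x))
  if (length(up) + length(down) == 0) {
    stop("no genes of signature '", sig$name, "' found in the matrix")
  }
  if (missing_policy == "error" && length(missing) > 0) {
    stop("signature '", sig$name, "' genes absent from matrix: ",
         paste(head(missing, 10), collapse = ", "))
  }
  up_sum <- if (length(up) > 0) colSums(x[up, , drop = FALSE]) else 0
  down_sum <- if (length(down) > 0) colSums(x[down, , drop = FALSE]) else 0
  score <- up_sum - down_sum
  names(score) <- colnames(x)
  attr(score, "missing_genes") <- missing
  attr(score, "signature") <- sig$name
  score
}

#' Dichotomize scores at zero
#'
#' Positive scores are `"high"`, zero or negative scores are `"low"`
#' (zero goes to `"low"` so that `"high"` requires strictly positive
#' evidence).
#'
#' @param scores finite numeric vector.
#' @return factor with levels `c("low", "high")`, names preserved.
#' @export
dichotomize_zero <- function(scores) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  structure(factor(ifelse(scores > 0, "high", "low"), levels = c("low", "high")),
            names = names(scores))
}

#' Split scores at the arithmetic mean
#'
#' Scores strictly above the mean are `"above"`, the rest `"below"` (so a
#' constant vector is all `"below"`).
#'
#' @param scores finite numeric vector.
#' @return factor with levels `c("below", "above")`, names preserved.
#' @export
split_mean <- function(scores) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  structure(factor(ifelse(scores > mean(scores), "above", "below"),
                   levels = c("below", "above")),
            names = names(scores))
}

#' Split scores into quartile groups Q1-Q4
#'
#' Rank-based: group = `ceiling(4 * rank / n)` with minimum ranks for ties,
#' so tied scores stay together in the lower quartile and group sizes can be
#' unequal (a message reports them). Q4 holds the highest scores. A constant
#' vector collapses into Q1 with a warning.
#'
#' @param scores finite numeric vector of length >= 4.
#' @return factor with levels `Q1`-`Q4`, names preserved.
#' @export
split_quartiles <- function(scores) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  n <- length(scores)
  if (n < 4) stop("quartile split needs at least 4 samples")
  r <- rank(scores, ties.method = "min")
  q <- ceiling(4 * r / n)
  if (length(unique(q)) == 1) warning("all scores tied: single quartile group")
  sizes <- table(factor(q, levels = 1:4))
  if (length(unique(as.integer(sizes[sizes > 0]))) > 1) {
    message("unequal quartile sizes: ", paste(sizes, collapse = "/"))
  }
  structure(factor(paste0("Q", q), levels = paste0("Q", 1:4)),
            names = names(scores))
}

#' Score a panel of signatures, z-normalized per signature
#'
#' Each signature is scored with [score_signature()] and the resulting
#' column is standardized to mean 0 and (sample) standard deviation 1 across
#' samples. A zero-variance column is left at 0 with a warning.
#'
#' @param x log2 expression matrix.
#' @param signatures list of `necro_signature` objects.
#' @return samples x signatures numeric matrix of z-scores.
#' @export
score_panel <- function(x, signatures) {
  if (length(signatures) == 0) stop("empty signature panel")
  cols <- lapply(signatures, function(s) score_signature(x, s))
  nm <- vapply(signatures, function(s) s$name, character(1))
  m <- do.call(cbind, cols)
  colnames(m) <- nm
  for (j in seq_len(ncol(m))) {
    sdv <- sd(m[, j])
    if (sdv == 0) {
      warning("signature '", colnames(m)[j], "' has zero score variance; left at 0")
      m[, j] <- 0
    } else {
      m[, j] <- (m[, j] - mean(m[, j])) / sdv
    }
  }
  m
}

#' Hierarchical clustering of a signature score table
#'
#' Agglomerative clustering with complete linkage on Euclidean distances,
#' as used to organize signature-score heatmaps. Columns (signatures) are
#' clustered; set `margin = "rows"` to cluster samples instead. Rendering is
#' out of scope: only the merge tree and leaf order are returned.
#'
#' @param score_table numeric matrix (samples x signatures), all finite.
#' @param margin `"columns"` (default) or `"rows"`.
#' @return an object of class `hclust`.
#' @export
hcluster <- function(score_table, margin = c("columns", "rows")) {
  margin <- match.arg(margin)
  if (!all(is.finite(score_table))) stop("score table must be finite")
  m <- if (margin == "columns") t(score_table) else score_table
  if (nrow(m) < 2) stop("need at least 2 items to cluster")
  hclust(dist(m, method = "euclidean"), method = "complete")
}

#' Write a per-sample score table as CSV
#'
#' One row per sample: the primary signature's score plus its zero-cut,
#' mean-split and quartile group columns, then one z-score column per panel
#' signature (if given).
#'
#' @param scores named score vector for the primary signature.
#' @param path output path.
#' @param panel optional samples x signatures z-score matrix.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path, panel = NULL) {
  df <- data.frame(sample_id = names(scores),
                   score = as.numeric(scores),
                   group_zero = as.character(dichotomize_zero(scores)),
                   group_mean = as.character(split_mean(scores)),
                   group_quartile = as.character(split_quartiles(scores)),
                   stringsAsFactors = FALSE)
  if (!is.null(panel)) df <- cbind(df, as.data.frame(panel[df$sample_id, , drop = FALSE]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
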