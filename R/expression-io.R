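#' Validate an expression matrix
#'
#' Checks the invariants assumed by every downstream computation: a numeric
#' matrix with unique, non-empty row (gene) and column (sample) names and all
#' values finite. Values are expected on the log2 scale unless a function
#' documents otherwise.
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression data must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix must have gene row names and sample column names")
  }
  if (anyDuplicated(rownames(x))) {
    dup <- unique(rownames(x)[duplicated(rownames(x))])
    stop("duplicated gene ids: ", paste(head(dup, 5), collapse = ", "),
         " (collapse probes with collapse_max_probe())")
  }
  if (anyDuplicated(colnames(x))) {
    dup <- unique(colnames(x)[duplicated(colnames(x))])
    stop("duplicated sample ids: ", paste(head(dup, 5), collapse = ", "))
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop("non-finite expression value at gene '", rownames(x)[bad[1]],
         "', sample '", colnames(x)[bad[2]], "'")
  }
  invisible(x)
}

#' Read a gene-by-sample expression matrix from tab-separated text
#'
#' Expected layout: a header row whose first field names the id column
#' (e.g. `gene_id`) followed by sample ids; one gene (or probe) per row.
#' Any non-numeric cell, including literal `NA`, is a parse error that names
#' the offending gene/sample coordinate — downstream statistics require
#' complete matrices.
#'
#' @param path path to a tab-separated text file.
#' @param allow_duplicate_ids keep duplicated row ids (probe-level data that
#'   will be collapsed with [collapse_max_probe()]). Default `FALSE`.
#' @return numeric matrix passing [validate_expression()] (row-name
#'   uniqueness is skipped when `allow_duplicate_ids = TRUE`).
#' @export
read_expression <- function(path, allow_duplicate_ids = FALSE) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed expression file: need a header row and at least one gene row")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) stop("malformed header: expected an id column plus at least one sample column")
  samples <- header[-1]
  if (anyDuplicated(samples)) {
    dup <- unique(samples[duplicated(samples)])
    stop("duplicated sample ids in header: ", paste(dup, collapse = ", "))
  }
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  nfield <- lengths(body)
  if (any(nfield != length(header))) {
    stop("row ", which(nfield != length(header))[1] + 1L,
         " has ", nfield[nfield != length(header)][1],
         " fields, expected ", length(header))
  }
  ids <- vapply(body, `[[`, character(1), 1L)
  cells <- t(vapply(body, function(f) f[-1], character(length(samples))))
  if (length(samples) == 1L) cells <- matrix(cells, ncol = 1L)
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric value '", cells[bad[1], bad[2]], "' at gene '",
         ids[bad[1]], "', sample '", samples[bad[2]], "'")
  }
  m <- matrix(vals, nrow = length(ids), ncol = length(samples),
              dimnames = list(ids, samples))
  if (!allow_duplicate_ids) validate_expression(m)
  m
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression()]: round-trips any valid matrix up to
#' numeric formatting.
#'
#' @param x numeric expression matrix.
#' @param path output path.
#' @param id_col name for the first header field (default `"gene_id"`).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, id_col = "gene_id") {
  validate_expression(x)
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2-transform a linear-scale expression matrix
#'
#' @param x numeric matrix on the linear scale.
#' @param pseudocount non-negative value added before taking log2
#'   (default 0; all `x + pseudocount` must be positive).
#' @return matrix of `log2(x + pseudocount)`.
#' @export
log2_transform <- function(x, pseudocount = 0) {
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1, pseudocount >= 0)
  shifted <- x + pseudocount
  if (any(shifted <= 0)) {
    bad <- unique(rownames(x)[which(shifted <= 0, arr.ind = TRUE)[, 1]])
    stop("log2 undefined (value + pseudocount <= 0) for genes: ",
         paste(head(bad, 10), collapse = ", "))
  }
  log2(shifted)
}

#' Collapse probe-level rows to one row per gene (max-probe rule)
#'
#' For each gene the probe with the highest mean expression across all
#' samples is retained; the other probes for that gene are dropped. Ties in
#' the probe means are broken by input order (the earlier probe wins), so the
#' result is deterministic. Output genes appear in order of first appearance.
#'
#' @param x probe-level numeric matrix (probe ids as row names; duplicates
#'   across probes of one gene expected).
#' @param probe_map named character vector mapping probe id -> gene symbol;
#'   every row of `x` must be mapped.
#' @return gene-level matrix passing [validate_expression()].
#' @export
collapse_max_probe <- function(x, probe_map) {
  if (length(probe_map) == 0) stop("empty probe map")
  if (is.null(names(probe_map))) stop("probe_map must be a named vector (probe id -> gene)")
  probes <- rownames(x)
  unmapped <- setdiff(probes, names(probe_map))
  if (length(unmapped) > 0) {
    stop("unmapped probes: ", paste(head(unmapped, 5), collapse = ", "))
  }
  genes <- unname(probe_map[probes])
  means <- rowMeans(x)
  keep <- integer(0)
  for (g in unique(genes)) {
    idx <- which(genes == g)
    keep <- c(keep, idx[which.max(means[idx])])  # which.max -> first maximum
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- genes[keep]
  validate_expression(out)
  out
}
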