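# controlled vocabulary for the clinical annotation table
.clin_levels <- list(
  necrosis   = c("present", "absent", "missing"),
  er         = c("positive", "negative", "missing"),
  pr         = c("positive", "negative", "missing"),
  her2       = c("positive", "negative", "missing"),
  pam50      = c("LumA", "LumB", "Her2", "Basal", "Normal", "missing"),
  grade      = c("1", "2", "3", "missing"),
  lymph_node = c("positive", "negative", "missing"),
  death_cause = c("disease", "other", "alive"),
  sex        = c("female", "male", "missing")
)

#' Validate a clinical annotation table
#'
#' Enforces unique sample ids, the controlled vocabulary for the categorical
#' columns, non-negative survival time, and numeric (or missing) tumor size.
#' Missing values are an explicit `"missing"` category (or `NA` for numeric
#' columns); statistical routines exclude them pairwise.
#'
#' @param clinical data.frame with columns `sample_id`, `necrosis`, `er`,
#'   `pr`, `her2`, `pam50`, `tumor_size_mm`, `grade`, `lymph_node`,
#'   `surv_time_months`, `death_cause`, `sex`.
#' @return `clinical`, invisibly.
#' @export
validate_clinical <- function(clinical) {
  required <- c("sample_id", "necrosis", "er", "pr", "her2", "pam50",
                "tumor_size_mm", "grade", "lymph_node", "surv_time_months",
                "death_cause", "sex")
  miss <- setdiff(required, names(clinical))
  if (length(miss) > 0) stop("clinical table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(clinical$sample_id)) stop("duplicated sample_id in clinical table")
  for (col in names(.clin_levels)) {
    vals <- as.character(clinical[[col]])
    bad <- setdiff(unique(vals), .clin_levels[[col]])
    if (length(bad) > 0) {
      stop("column '", col, "' has values outside the controlled vocabulary: ",
           paste(bad, collapse = ", "))
    }
  }
  if (any(!is.na(clinical$tumor_size_mm) & clinical$tumor_size_mm <= 0)) {
    stop("tumor_size_mm must be positive or NA")
  }
  if (any(clinical$surv_time_months < 0)) stop("surv_time_months must be >= 0")
  invisible(clinical)
}

#' Read a clinical annotation CSV
#'
#' @param path CSV with the clinical column names as header; `grade` may be
#'   numeric in the file and is normalized to character; empty cells in
#'   categorical columns become `"missing"`.
#' @return validated clinical data.frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in names(.clin_levels)) {
    if (col %in% names(df)) {
      v <- as.character(df[[col]])
      v[is.na(v) | v == ""] <- if (col == "death_cause") "alive" else "missing"
      df[[col]] <- v
    }
  }
  validate_clinical(df)
  df
}

#' Write a clinical annotation table as CSV
#' @param clinical validated clinical data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  validate_clinical(clinical)
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cohort filter rules
#'
#' `rule_keep` retains rows whose `field` is in `values`; `rule_drop` removes
#' rows whose `field` is in `values`. Rules are applied sequentially by
#' [filter_cohort()], and a row removed by an earlier rule is not counted
#' again by later ones.
#'
#' @param field clinical column name.
#' @param values character vector of category values.
#' @return a rule object for [filter_cohort()].
#' @export
rule_keep <- function(field, values) {
  structure(list(field = field, values = values, action = "keep"),
            class = "necro_rule")
}

#' @rdname rule_keep
#' @export
rule_drop <- function(field, values) {
  structure(list(field = field, values = values, action = "drop"),
            class = "necro_rule")
}

#' Filter a clinical cohort by a list of rules
#'
#' The defaults of the pipeline drop the Normal-like intrinsic subtype and
#' keep female patients only. Each rule's removal count is recorded in the
#' `"filter_log"` attribute of the result; applying the same rules twice is
#' idempotent.
#'
#' @param clinical validated clinical data.frame.
#' @param rules list of [rule_keep()]/[rule_drop()] objects (empty list =
#'   identity).
#' @return filtered clinical data.frame with attribute `filter_log`
#'   (data.frame: rule, field, removed).
#' @export
filter_cohort <- function(clinical, rules = list()) {
  validate_clinical(clinical)
  if (length(rules) == 0) {
    attr(clinical, "filter_log") <- data.frame(rule = character(0),
                                               field = character(0),
                                               removed = integer(0))
    return(clinical)
  }
  log <- vector("list", length(rules))
  out <- clinical
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    if (!inherits(r, "necro_rule")) stop("rules must be built with rule_keep()/rule_drop()")
    if (!r$field %in% names(out)) stop("filter rule on unknown field: ", r$field)
    vals <- as.character(out[[r$field]])
    keep <- if (r$action == "keep") vals %in% r$values else !(vals %in% r$values)
    log[[i]] <- data.frame(rule = paste(r$action, r$field),
                           field = r$field,
                           removed = sum(!keep))
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "filter_log") <- do.call(rbind, log)
  out
}

#' Default cohort filter: female patients, Normal-like subtype excluded
#' @return list of rules for [filter_cohort()].
#' @export
default_cohort_rules <- function() {
  list(rule_keep("sex", "female"), rule_drop("pam50", "Normal"))
}

#' Two-group necrosis labels for differential expression
#'
#' Builds the group factor used throughout: level 1 is necrosis-present
#' (`"N+"`, group 1) so that a positive fold change means higher expression
#' in necrotic tumors; level 2 is necrosis-absent (`"N-"`). Samples with
#' missing necrosis status are dropped.
#'
#' @param clinical validated clinical data.frame.
#' @return named factor (names = sample ids) with levels `c("N+", "N-")`.
#' @export
necrosis_labels <- function(clinical) {
  validate_clinical(clinical)
  keep <- clinical$necrosis %in% c("present", "absent")
  lab <- factor(ifelse(clinical$necrosis[keep] == "present", "N+", "N-"),
                levels = c("N+", "N-"))
  names(lab) <- clinical$sample_id[keep]
  lab
}

# check that a two-level label factor covers exactly the matrix samples
check_labels <- function(x, labels) {
  if (is.null(names(labels))) stop("group labels must be named by sample id")
  if (!setequal(names(labels), colnames(x))) {
    stop("group labels must cover exactly the matrix samples")
  }
  labels <- labels[colnames(x)]
  if (nlevels(factor(labels)) != 2) stop("exactly two groups required")
  tab <- table(labels)
  if (any(tab == 0)) stop("both groups must be non-empty")
  labels
}
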