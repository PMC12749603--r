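#' Disease-specific survival records from a clinical table
#'
#' Endpoint is death from the disease: `event = 1` iff
#' `death_cause == "disease"`; patients dying from other causes are censored
#' at the death date, and patients alive are censored at last follow-up.
#' Time is months since diagnosis.
#'
#' @param clinical validated clinical data.frame.
#' @return data.frame `sample_id`, `time`, `event`.
#' @export
dss_prepare <- function(clinical) {
  validate_clinical(clinical)
  data.frame(sample_id = clinical$sample_id,
             time = clinical$surv_time_months,
             event = as.integer(clinical$death_cause == "disease"),
             stringsAsFactors = FALSE)
}

# records: data.frame(sample_id, time, event); groups: named vector/factor
.match_groups <- function(records, groups) {
  if (is.null(names(groups))) {
    if (length(groups) != nrow(records)) {
      stop("groups must be named by sample id or match records row-for-row")
    }
    g <- factor(groups)
  } else {
    miss <- setdiff(records$sample_id, names(groups))
    if (length(miss) > 0) stop("no group label for samples: ", paste(head(miss, 5), collapse = ", "))
    g <- factor(groups[records$sample_id])
  }
  if (any(table(g) == 0)) stop("empty group")
  g
}

#' Kaplan-Meier product-limit estimate per group
#'
#' Standard product-limit estimator (ties: events before censorings at the
#' same time), returned as a tidy table rather than a plot.
#'
#' @param records data.frame `sample_id`, `time`, `event`.
#' @param groups group labels (named by sample id, or one per record); omit
#'   for a single overall curve.
#' @return data.frame `group`, `time`, `n_risk`, `n_event`, `survival`, one
#'   row per distinct observed time per group.
#' @export
km_fit <- function(records, groups = NULL) {
  if (any(records$time < 0)) stop("negative survival time")
  if (is.null(groups)) groups <- rep("all", nrow(records))
  g <- .match_groups(records, groups)
  out <- lapply(levels(g), function(lv) {
    r <- records[g == lv, , drop = FALSE]
    if (nrow(r) == 0) stop("empty group: ", lv)
    fit <- survfit(Surv(time, event) ~ 1, data = r)
    data.frame(group = lv, time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, survival = fit$surv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Log-rank test between survival groups
#'
#' Standard (unweighted) log-rank statistic, chi-square on `k - 1` degrees
#' of freedom.
#'
#' @inheritParams km_fit
#' @return one-row test-result data.frame.
#' @export
log_rank <- function(records, groups) {
  g <- .match_groups(records, groups)
  if (nlevels(g) < 2) stop("log-rank needs at least 2 groups")
  if (sum(records$event) == 0) stop("no events")
  d <- data.frame(time = records$time, event = records$event, group = g)
  sd_ <- survdiff(Surv(time, event) ~ group, data = d)
  df <- length(sd_$n) - 1
  .test_result("log-rank", sd_$chisq, df,
               pchisq(sd_$chisq, df = df, lower.tail = FALSE),
               nrow(records))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization (Newton-Raphson) over the supplied
#' covariates on complete cases only; categorical covariates enter via
#' indicator coding, continuous covariates per unit. Confidence intervals
#' are Wald: `exp(beta +/- 1.96 se)`. Ties default to the Efron
#' approximation (month-resolution data has many ties); `"breslow"` mimics
#' software using the Breslow approximation.
#'
#' @param records data.frame `sample_id`, `time`, `event`.
#' @param covariates data.frame of covariate columns, rows aligned with
#'   `records` (or with a `sample_id` column to join on).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param conf_level confidence level for the hazard-ratio interval.
#' @return list of class `necro_coxfit`: `coefficients` (data.frame
#'   term/beta/hr/ci_low/ci_high/se/p_value), `n`, `n_events`,
#'   `n_dropped_incomplete`, `ties`.
#' @export
cox_fit <- function(records, covariates, ties = c("efron", "breslow"),
                    conf_level = 0.95) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  if ("sample_id" %in% names(covariates)) {
    idx <- match(records$sample_id, covariates$sample_id)
    if (anyNA(idx)) stop("covariates missing for some samples")
    covariates <- covariates[idx, setdiff(names(covariates), "sample_id"),
                             drop = FALSE]
  }
  if (nrow(covariates) != nrow(records)) {
    stop("covariates must align with records")
  }
  cc <- complete.cases(covariates) &
    !vapply(seq_len(nrow(covariates)),
            function(i) any(covariates[i, ] == "missing"), logical(1))
  n_drop <- sum(!cc)
  d <- cbind(data.frame(time = records$time, event = records$event),
             covariates)[cc, , drop = FALSE]
  d[] <- lapply(d, function(col) if (is.character(col)) factor(col) else col)
  n_events <- sum(d$event)
  p <- ncol(covariates)
  if (n_events < p) stop("fewer events (", n_events, ") than covariates (", p, ")")
  form <- as.formula(paste("Surv(time, event) ~",
                           paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- withCallingHandlers(
    coxph(form, data = d, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w))) {
        warning("Cox fit flagged: ", conditionMessage(w), call. = FALSE)
        invokeRestart("muffleWarning")
      }
    })
  z <- qnorm(1 - (1 - conf_level) / 2)
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  res <- data.frame(term = names(beta),
                    beta = unname(beta),
                    hr = exp(unname(beta)),
                    ci_low = exp(unname(beta) - z * se),
                    ci_high = exp(unname(beta) + z * se),
                    se = unname(se),
                    p_value = 2 * pnorm(-abs(unname(beta) / se)),
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(coefficients = res, n = nrow(d), n_events = n_events,
                 n_dropped_incomplete = n_drop, ties = ties,
                 conf_level = conf_level),
            class = "necro_coxfit")
}

#' @export
print.necro_coxfit <- function(x, ...) {
  cat("<cox fit> n = ", x$n, ", events = ", x$n_events,
      ", ties = ", x$ties, "\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Write Kaplan-Meier tables or Cox results as tidy CSV
#' @param x `km_fit()` table or `necro_coxfit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survival_report <- function(x, path) {
  if (inherits(x, "necro_coxfit")) x <- x$coefficients
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
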