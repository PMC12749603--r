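#' Synthetic cohort configuration
#'
#' Defines the stated world the generator emulates: a two-group breast
#' cancer cohort with planted UP/DOWN differential genes on the log2 scale,
#' subtype labels concentrated in the necrosis-present group, survival
#' hazard proportional to the true signature score, and group-dependent
#' per-gene mutation probabilities. Defaults follow the recovery setting the
#' test suite exercises (50 vs 50 samples, 2000 genes, 20 + 20 planted genes
#' with a 2-unit log2 shift on unit-variance noise) and per-group mutation
#' rates matching the reported necrosis contrast for TP53, PIK3CA, MAP3K1,
#' CDH1 and GATA3.
#'
#' @param n_pos,n_neg samples in the necrosis-present / absent groups.
#' @param n_genes total genes.
#' @param n_up,n_down planted UP / DOWN genes (`n_up + n_down <= n_genes`).
#' @param delta log2 group difference (N+ minus N-) of planted genes: UP
#'   genes `+delta`, DOWN genes `-delta`, applied symmetrically as
#'   `+/- delta/2` around each gene's baseline mean.
#' @param noise_sd residual standard deviation on the log2 scale.
#' @param surv_beta log-hazard per unit of the standardized true score.
#' @param baseline_hazard baseline event rate per month.
#' @param censor_rate target fraction of censored cases, in `[0, 1)`.
#' @param mut_genes named list; each element `c(pos = rate_Npos, neg =
#'   rate_Nneg)` per-gene Bernoulli mutation probability by group.
#' @param subtype_mix probability of a Basal-like label given N+ / given N-.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_pos = 50, n_neg = 50, n_genes = 2000,
                       n_up = 20, n_down = 20,
                       delta = 2, noise_sd = 1,
                       surv_beta = 0.7, baseline_hazard = 0.005,
                       censor_rate = 0.2,
                       mut_genes = list(TP53 = c(pos = 0.67, neg = 0.26),
                                        PIK3CA = c(pos = 0.24, neg = 0.39),
                                        MAP3K1 = c(pos = 0.05, neg = 0.14),
                                        CDH1 = c(pos = 0.01, neg = 0.11),
                                        GATA3 = c(pos = 0.10, neg = 0.12)),
                       subtype_mix = c(pos = 0.45, neg = 0.07),
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- list(n_pos = n_pos, n_neg = n_neg, n_genes = n_genes,
              n_up = n_up, n_down = n_down, delta = delta,
              noise_sd = noise_sd, surv_beta = surv_beta,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              mut_genes = mut_genes, subtype_mix = subtype_mix,
              seed = as.integer(seed))
  if (any(c(n_pos, n_neg, n_genes, n_up, n_down) <= 0) ||
      n_up + n_down > n_genes) {
    stop("invalid counts: need positive sizes and n_up + n_down <= n_genes")
  }
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  if (noise_sd < 0 || delta < 0) stop("delta and noise_sd must be non-negative")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  structure(cfg, class = "sim_config")
}

# calibrate an independent exponential censoring rate c so that the expected
# censored fraction mean_i c/(c + lambda_i) equals the target
.censor_rate_for <- function(lambda, target) {
  if (target <= 0) return(0)
  f <- function(cr) mean(cr / (cr + lambda)) - target
  uniroot(f, lower = 1e-12, upper = 1e6, tol = 1e-10)$root
}

#' Simulate a two-group cohort with planted ground truth
#'
#' Expression: per-gene baseline means drawn from Normal(7, 1) on the log2
#' scale (microarray-like intensities), a group shift of `+/- delta` on the
#' planted genes for necrosis-present samples, and Gaussian noise. Survival:
#' exponential event times with hazard
#' `baseline_hazard * exp(surv_beta * z)` where `z` is the standardized true
#' (planted-gene) score, with independent exponential censoring calibrated
#' to the target censoring fraction; roughly a third of censored cases are
#' recorded as deaths from other causes. Mutations: per-(sample, gene)
#' Bernoulli draws at the group's configured rate. Subtype labels: Basal
#' with the group's `subtype_mix` probability, the remainder split over the
#' other subtypes with necrosis-dependent weights. Fully reproducible from
#' the seed.
#'
#' @param config `sim_config`.
#' @return list: `expression` (matrix), `clinical` (data.frame), `mutations`
#'   (`mutation_table`), `truth` (list: `up_genes`, `down_genes`, `delta`,
#'   `surv_beta`, `mut_rates`, `groups` — named necrosis factor).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_pos + cfg$n_neg
    samples <- sprintf("S%03d", seq_len(n))
    necrosis <- rep(c("present", "absent"), c(cfg$n_pos, cfg$n_neg))
    is_pos <- necrosis == "present"
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    up_genes <- genes[seq_len(cfg$n_up)]
    down_genes <- genes[cfg$n_up + seq_len(cfg$n_down)]

    baseline <- rnorm(cfg$n_genes, mean = 7, sd = 1)
    x <- matrix(baseline, nrow = cfg$n_genes, ncol = n,
                dimnames = list(genes, samples))
    # symmetric contrast: +/- delta/2 around each planted gene's baseline,
    # so the group difference is exactly delta and the directional sum-score
    # is centered near zero between the groups (DOWN genes are genuinely
    # high in the necrosis-absent group, as for e.g. ESR1 in real cohorts)
    half <- cfg$delta / 2
    x[up_genes, is_pos] <- x[up_genes, is_pos] + half
    x[up_genes, !is_pos] <- x[up_genes, !is_pos] - half
    x[down_genes, is_pos] <- x[down_genes, is_pos] - half
    x[down_genes, !is_pos] <- x[down_genes, !is_pos] + half
    if (cfg$noise_sd > 0) {
      x <- x + matrix(rnorm(length(x), sd = cfg$noise_sd), nrow = nrow(x))
    }

    # true score from the planted signature; standardized for the hazard
    true_sig <- signature_definition("TRUTH", up = up_genes, down = down_genes)
    score <- score_signature(x, true_sig)
    z <- if (sd(score) > 0) (score - mean(score)) / sd(score) else score * 0

    lambda <- cfg$baseline_hazard * exp(cfg$surv_beta * z)
    t_event <- rexp(n, rate = lambda)
    if (cfg$censor_rate > 0) {
      cr <- .censor_rate_for(lambda, cfg$censor_rate)
      t_cens <- rexp(n, rate = cr)
    } else {
      t_cens <- rep(Inf, n)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    death_cause <- ifelse(event == 1, "disease",
                          ifelse(runif(n) < 1 / 3, "other", "alive"))

    # receptor status and subtype labels concentrated by necrosis group
    er <- ifelse(runif(n) < ifelse(is_pos, 0.49, 0.90), "positive", "negative")
    pr <- ifelse(runif(n) < ifelse(is_pos, 0.38, 0.79), "positive", "negative")
    her2 <- ifelse(runif(n) < ifelse(is_pos, 0.18, 0.14), "positive", "negative")
    p_basal <- ifelse(is_pos, cfg$subtype_mix[["pos"]], cfg$subtype_mix[["neg"]])
    pam50 <- character(n)
    for (i in seq_len(n)) {
      if (runif(1) < p_basal[i]) {
        pam50[i] <- "Basal"
      } else {
        w <- if (is_pos[i]) c(LumA = 0.40, LumB = 0.31, Her2 = 0.29)
             else c(LumA = 0.60, LumB = 0.29, Her2 = 0.11)
        pam50[i] <- sample(names(w), 1, prob = w)
      }
    }

    clinical <- data.frame(
      sample_id = samples,
      necrosis = necrosis,
      er = er, pr = pr, her2 = her2,
      pam50 = pam50,
      tumor_size_mm = round(rlnorm(n, log(ifelse(is_pos, 25, 20)), 0.4), 1),
      grade = as.character(sample(1:3, n, replace = TRUE,
                                  prob = c(0.15, 0.4, 0.45))),
      lymph_node = ifelse(runif(n) < 0.45, "positive", "negative"),
      surv_time_months = round(time, 2),
      death_cause = death_cause,
      sex = "female",
      stringsAsFactors = FALSE
    )
    validate_clinical(clinical)

    mut_records <- list()
    mut_rates <- cfg$mut_genes
    for (gene in names(mut_rates)) {
      p <- ifelse(is_pos, mut_rates[[gene]][["pos"]], mut_rates[[gene]][["neg"]])
      hit <- rbinom(n, 1, p) == 1
      if (any(hit)) {
        mut_records[[gene]] <- data.frame(
          sample_id = samples[hit], gene = gene,
          variant_classification = "Missense_Mutation",
          stringsAsFactors = FALSE)
      }
    }
    records <- if (length(mut_records) > 0) {
      do.call(rbind, mut_records)
    } else {
      data.frame(sample_id = character(0), gene = character(0),
                 variant_classification = character(0))
    }
    mutations <- mutation_table(records, samples = samples)

    truth <- list(up_genes = up_genes, down_genes = down_genes,
                  delta = cfg$delta, surv_beta = cfg$surv_beta,
                  mut_rates = mut_rates,
                  groups = necrosis_labels(clinical))
    list(expression = x, clinical = clinical, mutations = mutations,
         truth = truth)
  })
}

#' Compare a derived signature against the planted truth
#'
#' @param derived `necro_signature` produced by the analysis.
#' @param truth the `truth` element of [simulate_cohort()] output.
#' @return list: `sensitivity` (planted genes recovered / planted),
#'   `precision` (recovered genes planted / recovered; `NA` when the derived
#'   signature is empty), `direction_accuracy` (fraction of recovered
#'   planted genes on the correct side; `NA` when none recovered).
#' @export
truth_report <- function(derived, truth) {
  planted <- c(truth$up_genes, truth$down_genes)
  recovered <- c(derived$up, derived$down)
  hit <- intersect(recovered, planted)
  sensitivity <- length(hit) / length(planted)
  precision <- if (length(recovered) == 0) NA_real_ else length(hit) / length(recovered)
  if (length(hit) == 0) {
    dir_acc <- NA_real_
  } else {
    correct <- length(intersect(derived$up, truth$up_genes)) +
      length(intersect(derived$down, truth$down_genes))
    dir_acc <- correct / length(hit)
  }
  list(sensitivity = sensitivity, precision = precision,
       direction_accuracy = dir_acc)
}

#' Write a simulated cohort in the formats the pipeline reads
#'
#' Emits `expression.tsv`, `clinical.csv`, `mutations.maf` and `truth.json`
#' under `dir`.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return named vector of the four file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.csv"),
             maf = file.path(dir, "mutations.maf"),
             truth = file.path(dir, "truth.json"))
  write_expression(cohort$expression, paths[["expression"]])
  write_clinical(cohort$clinical, paths[["clinical"]])
  maf <- data.frame(Hugo_Symbol = cohort$mutations$records$gene,
                    Tumor_Sample_Barcode = cohort$mutations$records$sample_id,
                    Variant_Classification = cohort$mutations$records$variant_classification)
  write.table(maf, paths[["maf"]], sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$groups <- as.list(setNames(as.character(truth$groups),
                                   names(truth$groups)))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE)
  invisible(paths)
}
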