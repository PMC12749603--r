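#' Pipeline configuration
#'
#' Collects paths and stage parameters for the end-to-end workflow
#' (derive -> score -> associate -> survive -> mutate). Every stochastic
#' stage draws from `seed`.
#'
#' @param expression path to the expression TSV (log2 unless
#'   `log2_input = FALSE`).
#' @param clinical path to the clinical CSV.
#' @param out output directory (created; each run writes its own files).
#' @param maf optional MAF path; when `NULL` the mutation stage is skipped.
#' @param signatures optional directory of panel GMT files.
#' @param pathways optional pathway GMT for the mutation stage.
#' @param seed integer seed (mandatory).
#' @param n_permutations,fc_min,q_max_percent differential-expression
#'   parameters (see [de_config()]).
#' @param grouping score grouping scheme: `"zero"`, `"mean"` or
#'   `"quartile"`.
#' @param ties Cox ties method, `"efron"` or `"breslow"`.
#' @param variant_filter `"all"` or `"nonsyn"`.
#' @param log2_input set `FALSE` if the expression file is linear scale (a
#'   log2 transform with `pseudocount` is then applied).
#' @param pseudocount pseudocount for the optional log2 transform.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, clinical, out,
                            maf = NULL, signatures = NULL, pathways = NULL,
                            seed,
                            n_permutations = 1000L, fc_min = 2.5,
                            q_max_percent = 0.008,
                            grouping = c("zero", "mean", "quartile"),
                            ties = c("efron", "breslow"),
                            variant_filter = c("all", "nonsyn"),
                            log2_input = TRUE, pseudocount = 0) {
  if (missing(seed)) stop("a seed is mandatory")
  structure(list(expression = expression, clinical = clinical, out = out,
                 maf = maf, signatures = signatures, pathways = pathways,
                 seed = as.integer(seed),
                 n_permutations = as.integer(n_permutations),
                 fc_min = fc_min, q_max_percent = q_max_percent,
                 grouping = match.arg(grouping),
                 ties = match.arg(ties),
                 variant_filter = match.arg(variant_filter),
                 log2_input = log2_input, pseudocount = pseudocount),
            class = "pipeline_config")
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; `[section]`
#' headers prefix subsequent keys as `section.key`. Values are returned as
#' strings; numeric conversion is the caller's concern.
#'
#' @param path config file path.
#' @return named list of strings.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    if (nzchar(section)) key <- paste(section, key, sep = ".")
    out[[key]] <- trimws(paste(kv[-1], collapse = "="))
  }
  out
}

.stage_file <- function(cfg, name) file.path(cfg$out, name)

#' Run the full necrosis-signature pipeline
#'
#' Stages, in order: `derive` (differential expression and signature),
#' `score` (sum-score + grouping, plus panel z-scores if a signature
#' directory was given), `associate` (chi-square battery against the score
#' group), `survive` (Kaplan-Meier tables, log-rank, Cox with the continuous
#' score per unit and per standard deviation), `mutate` (burden, per-gene
#' frequencies and tests, pathway burden; skipped with a notice when no MAF
#' path is configured). Each stage writes tidy outputs under `config$out`; a
#' `manifest.json` records input hashes, the seed, stage status, timings and
#' output hashes, so a run is exactly re-executable. Any stage error aborts
#' with the stage name; the manifest is still written with the failed stage
#' flagged.
#'
#' @param config `pipeline_config`.
#' @return the manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    seed = config$seed,
    r_version = as.character(getRversion()),
    inputs = list(),
    stages = list()
  )
  for (f in c("expression", "clinical", "maf")) {
    if (!is.null(config[[f]])) {
      manifest$inputs[[f]] <- list(path = config[[f]],
                                   md5 = unname(tools::md5sum(config[[f]])))
    }
  }
  finish <- function() {
    jsonlite::write_json(manifest, .stage_file(config, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
  }
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) e)
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res),
                                       seconds = round(elapsed, 3))
      finish()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res))
    }
    outputs <- res %||% character(0)
    manifest$stages[[name]] <<- list(
      status = "complete", seconds = round(elapsed, 3),
      outputs = lapply(outputs, function(p)
        list(path = basename(p), md5 = unname(tools::md5sum(p)))))
    res
  }

  x <- read_expression(config$expression)
  if (!config$log2_input) x <- log2_transform(x, config$pseudocount)
  clinical <- read_clinical(config$clinical)
  clinical <- clinical[clinical$sample_id %in% colnames(x), , drop = FALSE]
  labels <- necrosis_labels(clinical)
  x_lab <- x[, names(labels), drop = FALSE]

  env <- new.env()
  run_stage("derive", function() {
    decfg <- de_config(n_permutations = config$n_permutations,
                       seed = config$seed, fc_min = config$fc_min,
                       q_max_percent = config$q_max_percent)
    de <- sam_de(x_lab, labels, decfg)
    sig <- derive_signature(de, decfg)
    env$sig <- sig
    p1 <- write_de_result(de, .stage_file(config, "de_result.tsv"))
    p2 <- write_gmt(sig, .stage_file(config, "signature.gmt"))
    c(p1, p2)
  })

  run_stage("score", function() {
    scores <- score_signature(x, env$sig)
    env$scores <- scores
    env$group <- switch(config$grouping,
                        zero = dichotomize_zero(scores),
                        mean = split_mean(scores),
                        quartile = split_quartiles(scores))
    panel <- NULL
    if (!is.null(config$signatures)) {
      gmts <- list.files(config$signatures, pattern = "\\.gmt$",
                         full.names = TRUE)
      sigs <- unlist(lapply(gmts, read_gmt), recursive = FALSE)
      sigs <- Filter(function(s) {
        length(intersect(union(s$up, s$down), rownames(x))) > 0
      }, sigs)
      if (length(sigs) > 0) panel <- score_panel(x, sigs)
    }
    write_score_table(scores, .stage_file(config, "scores.csv"), panel = panel)
  })

  run_stage("associate", function() {
    cl <- clinical
    cl$score_group <- as.character(env$group[cl$sample_id])
    assoc <- association_battery(cl, "score_group")
    p <- .stage_file(config, "associations.csv")
    utils::write.csv(assoc, p, row.names = FALSE)
    p
  })

  run_stage("survive", function() {
    records <- dss_prepare(clinical)
    grp <- env$group[records$sample_id]
    km <- km_fit(records, grp)
    lr <- log_rank(records, grp)
    sc <- env$scores[records$sample_id]
    cox <- cox_fit(records,
                   data.frame(score = as.numeric(sc),
                              score_per_sd = as.numeric(scale(sc))),
                   ties = config$ties)
    p1 <- write_survival_report(km, .stage_file(config, "km.csv"))
    p2 <- .stage_file(config, "logrank.csv")
    utils::write.csv(lr, p2, row.names = FALSE)
    p3 <- write_survival_report(cox, .stage_file(config, "cox.csv"))
    c(p1, p2, p3)
  })

  if (is.null(config$maf)) {
    message("no MAF path configured; mutation stage skipped")
    manifest$stages[["mutate"]] <- list(status = "skipped",
                                        reason = "no MAF input")
  } else {
    run_stage("mutate", function() {
      mt <- read_maf(config$maf, samples = names(labels))
      burden <- mutation_burden(mt, labels,
                                variant_filter = config$variant_filter)
      freq <- gene_freq_by_group(mt, labels, top_k = 15,
                                 variant_filter = config$variant_filter)
      tests <- per_gene_test(mt, labels,
                             variant_filter = config$variant_filter)
      p1 <- .stage_file(config, "mutation_burden.csv")
      utils::write.csv(burden$per_sample, p1, row.names = FALSE)
      p2 <- .stage_file(config, "gene_frequencies.csv")
      utils::write.csv(freq, p2, row.names = FALSE)
      p3 <- .stage_file(config, "gene_tests.csv")
      utils::write.csv(tests, p3, row.names = FALSE)
      paths <- c(p1, p2, p3)
      if (!is.null(config$pathways)) {
        pmap <- read_gmt(config$pathways)
        pb <- pathway_burden(mt, pmap, labels,
                             variant_filter = config$variant_filter)
        p4 <- .stage_file(config, "pathway_burden.csv")
        utils::write.csv(pb, p4, row.names = FALSE)
        paths <- c(paths, p4)
      }
      paths
    })
  }
  finish()
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort) and `run` (end-to-end
#' pipeline). Invoke from a script as
#' `necrosig_cli(commandArgs(trailingOnly = TRUE))`; an executable wrapper
#' ships at `system.file("cli", "necrosig", package = "necrosig")`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly (0 on success).
#' @export
necrosig_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat("usage: necrosig <simulate|run> [options]\n",
        "  simulate --out DIR --seed N [--n-pos N] [--n-neg N] [--genes N]\n",
        "  run --expression TSV --clinical CSV --out DIR --seed N\n",
        "      [--maf MAF] [--signatures DIR] [--pathways GMT]\n",
        "      [--permutations B] [--fc-min F] [--q-max Q]\n",
        "      [--grouping zero|mean|quartile] [--ties efron|breslow]\n",
        "      [--variant-filter all|nonsyn] [--config FILE]\n", sep = "")
    return(invisible(0))
  }
  cmd <- args[1]
  rest <- args[-1]
  opt_list <- list(
    optparse::make_option("--expression", type = "character"),
    optparse::make_option("--clinical", type = "character"),
    optparse::make_option("--maf", type = "character"),
    optparse::make_option("--signatures", type = "character"),
    optparse::make_option("--pathways", type = "character"),
    optparse::make_option("--out", type = "character"),
    optparse::make_option("--seed", type = "integer"),
    optparse::make_option("--permutations", type = "integer", default = 1000L),
    optparse::make_option("--fc-min", dest = "fc_min", type = "double",
                          default = 2.5),
    optparse::make_option("--q-max", dest = "q_max", type = "double",
                          default = 0.008),
    optparse::make_option("--grouping", type = "character", default = "zero"),
    optparse::make_option("--ties", type = "character", default = "efron"),
    optparse::make_option("--variant-filter", dest = "variant_filter",
                          type = "character", default = "all"),
    optparse::make_option("--config", type = "character"),
    optparse::make_option("--n-pos", dest = "n_pos", type = "integer",
                          default = 50L),
    optparse::make_option("--n-neg", dest = "n_neg", type = "integer",
                          default = 50L),
    optparse::make_option("--genes", type = "integer", default = 2000L)
  )
  opts <- optparse::parse_args(optparse::OptionParser(option_list = opt_list),
                               args = rest)
  if (!is.null(opts$config)) {
    fromfile <- read_config_file(opts$config)
    for (k in names(fromfile)) {
      key <- gsub(".", "_", sub("^[^.]*\\.", "", k), fixed = TRUE)
      if (is.null(opts[[key]])) opts[[key]] <- fromfile[[k]]
    }
  }
  if (is.null(opts$seed)) stop("--seed is required")
  if (is.null(opts$out)) stop("--out is required")

  if (cmd == "simulate") {
    cohort <- simulate_cohort(sim_config(n_pos = opts$n_pos,
                                         n_neg = opts$n_neg,
                                         n_genes = opts$genes,
                                         seed = opts$seed))
    paths <- write_cohort(cohort, opts$out)
    message("cohort written: ", paste(basename(paths), collapse = ", "))
  } else if (cmd == "run") {
    if (is.null(opts$expression) || is.null(opts$clinical)) {
      stop("run requires --expression and --clinical")
    }
    cfg <- pipeline_config(expression = opts$expression,
                           clinical = opts$clinical,
                           out = opts$out, maf = opts$maf,
                           signatures = opts$signatures,
                           pathways = opts$pathways,
                           seed = opts$seed,
                           n_permutations = opts$permutations,
                           fc_min = as.numeric(opts$fc_min),
                           q_max_percent = as.numeric(opts$q_max),
                           grouping = opts$grouping, ties = opts$ties,
                           variant_filter = opts$variant_filter)
    run_pipeline(cfg)
  } else {
    stop("unknown subcommand: ", cmd)
  }
  invisible(0)
}
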