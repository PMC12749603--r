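test_that("simulation is bit-identical under the same seed", {
  cfg <- sim_config(n_genes = 100, n_up = 5, n_down = 5, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$mutations$records, b$mutations$records)
})

test_that("config validation fails before any sampling", {
  expect_error(sim_config(n_up = 60, n_down = 60, n_genes = 100, seed = 1),
               "n_up \\+ n_down")
  expect_error(sim_config(censor_rate = 1, seed = 1), "censor_rate")
  expect_error(sim_config(baseline_hazard = 0, seed = 1), "baseline_hazard")
  expect_error(sim_config(), "seed")
})

test_that("noiseless limit plants exact fold changes", {
  co <- simulate_cohort(sim_config(n_genes = 50, n_up = 3, n_down = 3,
                                   delta = 2, noise_sd = 0, seed = 7))
  fc <- signed_fold_change(co$expression, co$truth$groups)
  expect_equal(fc$fc_signed[match(co$truth$up_genes, fc$gene)], rep(4, 3))
  expect_equal(fc$fc_signed[match(co$truth$down_genes, fc$gene)], rep(-4, 3))
  others <- setdiff(fc$gene, c(co$truth$up_genes, co$truth$down_genes))
  expect_equal(fc$fc_signed[match(others, fc$gene)], rep(1, length(others)))
})

test_that("null cohorts (delta = 0) yield an empty or near-empty signature", {
  # scaled down from the 10-seed/2000-gene statement for test runtime:
  # 5 seeds x 400 genes, B = 100; the <=1% pass criterion is unchanged
  frac_pass <- vapply(1:5, function(seed) {
    co <- simulate_cohort(sim_config(n_genes = 400, n_up = 10, n_down = 10,
                                     delta = 0, seed = seed))
    cfg <- de_config(n_permutations = 100, seed = seed)
    de <- sam_de(co$expression, co$truth$groups, cfg)
    mean(de$direction != "none")
  }, numeric(1))
  expect_true(all(frac_pass <= 0.01))
})

test_that("empirical censoring tracks the configured rate", {
  co <- simulate_cohort(sim_config(n_pos = 300, n_neg = 300, n_genes = 50,
                                   n_up = 5, n_down = 5,
                                   censor_rate = 0.3, seed = 9))
  rec <- dss_prepare(co$clinical)
  expect_lt(abs(mean(rec$event == 0) - 0.3), 0.05)

  co0 <- simulate_cohort(sim_config(n_genes = 50, n_up = 5, n_down = 5,
                                    censor_rate = 0, seed = 9))
  expect_true(all(dss_prepare(co0$clinical)$event == 1))
})

test_that("realized mutation frequencies sit inside binomial 95% bounds", {
  co <- simulate_cohort(sim_config(n_pos = 200, n_neg = 200, n_genes = 50,
                                   n_up = 5, n_down = 5, seed = 10))
  freq <- gene_freq_by_group(co$mutations, co$truth$groups, top_k = Inf)
  outside <- 0L
  for (gene in names(co$truth$mut_rates)) {
    for (side in c("pos", "neg")) {
      rate <- co$truth$mut_rates[[gene]][[side]]
      n <- 200
      obs <- freq[freq$gene == gene, paste0("freq_", if (side == "pos") "N+" else "N-")]
      if (length(obs) == 0) obs <- 0  # gene absent = zero observed hits
      bound <- 1.96 * sqrt(rate * (1 - rate) / n)
      if (abs(obs - rate) >= bound) outside <- outside + 1L
    }
  }
  # 10 draws against 95% bounds: allow a single excursion
  expect_lte(outside, 1L)
})

test_that("group score separation grows with delta", {
  sep <- vapply(c(0.5, 1, 2), function(delta) {
    co <- simulate_cohort(sim_config(n_genes = 200, delta = delta, seed = 11))
    sig <- signature_definition("T", up = co$truth$up_genes,
                                down = co$truth$down_genes)
    z <- scale(score_signature(co$expression, sig))[, 1]
    is_pos <- co$clinical$necrosis == "present"
    mean(z[is_pos]) - mean(z[!is_pos])
  }, numeric(1))
  expect_true(all(diff(sep) > 0))
})

test_that("truth_report scores recovery exactly", {
  truth <- list(up_genes = paste0("u", 1:5), down_genes = paste0("d", 1:5))
  exact <- signature_definition("S", up = truth$up_genes,
                                down = truth$down_genes)
  expect_equal(truth_report(exact, truth),
               list(sensitivity = 1, precision = 1, direction_accuracy = 1))

  disjoint <- signature_definition("S", up = "x1", down = "x2")
  rep_d <- truth_report(disjoint, truth)
  expect_equal(rep_d$sensitivity, 0)
  expect_equal(rep_d$precision, 0)
  expect_true(is.na(rep_d$direction_accuracy))

  extra <- signature_definition("S", up = c(truth$up_genes, "x1"),
                                down = truth$down_genes)
  rep_e <- truth_report(extra, truth)
  expect_equal(rep_e$sensitivity, 1)
  expect_equal(rep_e$precision, 10 / 11)
})

test_that("write_cohort emits the formats the pipeline reads", {
  co <- simulate_cohort(sim_config(n_genes = 30, n_up = 3, n_down = 3,
                                   n_pos = 6, n_neg = 6, seed = 12))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_equal(read_expression(paths[["expression"]]), co$expression,
               tolerance = 1e-9)
  back <- read_clinical(paths[["clinical"]])
  expect_equal(back$necrosis, co$clinical$necrosis)
  mt <- read_maf(paths[["maf"]])
  expect_equal(nrow(mt$records), nrow(co$mutations$records))
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(unlist(truth$up_genes), co$truth$up_genes)
})
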