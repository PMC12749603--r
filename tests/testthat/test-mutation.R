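mk_mt <- function() {
  mutation_table(
    data.frame(sample_id = c("s1", "s1", "s1", "s3", "s3"),
               gene = c("TP53", "TP53", "PIK3CA", "TP53", "CDH1"),
               variant_classification = c("Missense_Mutation", "Nonsense_Mutation",
                                          "Silent", "Missense_Mutation",
                                          "Missense_Mutation")),
    samples = c("s1", "s2", "s3", "s4"))
}

grp4 <- setNames(c("N+", "N+", "N-", "N-"), c("s1", "s2", "s3", "s4"))

test_that("mutation_table enforces the sample universe", {
  expect_error(mutation_table(data.frame(sample_id = "x", gene = "g",
                                         variant_classification = "Silent"),
                              samples = "y"),
               "outside the universe")
  expect_error(mutation_table(data.frame(sample_id = "x", gene = "g")),
               "missing columns")
})

test_that("mutation burden counts records per sample, zeros included", {
  mt <- mk_mt()
  b <- mutation_burden(mt, grp4)
  expect_equal(b$per_sample$n_mutations, c(3L, 0L, 2L, 0L))
  expect_equal(b$group_means[["N+"]], 1.5)  # (3 + 0) / 2
  expect_equal(b$group_means[["N-"]], 1)    # (2 + 0) / 2
  # conservation: total counts = number of records
  expect_equal(sum(b$per_sample$n_mutations), nrow(mt$records))

  # empty table -> all zeros
  mt0 <- mutation_table(mk_mt()$records[0, ], samples = names(grp4))
  expect_true(all(mutation_burden(mt0, grp4)$per_sample$n_mutations == 0))
})

test_that("dedup flag collapses exact duplicate records", {
  rec <- rbind(mk_mt()$records, mk_mt()$records[1, ])  # duplicate row
  mt <- mutation_table(rec, samples = names(grp4))
  raw <- mutation_burden(mt, grp4)
  expect_equal(raw$per_sample$n_mutations[1], 4L)
  dd <- suppressMessages(mutation_burden(mt, grp4, dedup = TRUE))
  expect_equal(dd$per_sample$n_mutations[1], 3L)
})

test_that("variant filter drops silent records when requested", {
  mt <- mk_mt()
  b <- mutation_burden(mt, grp4, variant_filter = "nonsyn")
  expect_equal(b$per_sample$n_mutations, c(2L, 0L, 2L, 0L))
})

test_that("gene frequencies collapse multiple hits and rank by overall rate", {
  mt <- mk_mt()
  f <- gene_freq_by_group(mt, grp4, top_k = Inf)
  tp53 <- f[f$gene == "TP53", ]
  expect_equal(tp53$freq_overall, 0.5)     # s1, s3 of 4
  expect_equal(tp53$`freq_N+`, 0.5)        # s1 of {s1, s2}
  expect_equal(tp53$`freq_N-`, 0.5)
  expect_equal(f$gene[1], "TP53")          # highest overall frequency first
  expect_equal(nrow(gene_freq_by_group(mt, grp4, top_k = 2)), 2)

  # brute-force ranking check on a random fixture
  set.seed(20)
  rec <- data.frame(sample_id = sample(paste0("s", 1:10), 60, replace = TRUE),
                    gene = sample(paste0("g", 1:6), 60, replace = TRUE),
                    variant_classification = "Missense_Mutation")
  mt2 <- mutation_table(rec, samples = paste0("s", 1:10))
  g2 <- setNames(rep(c("A", "B"), each = 5), paste0("s", 1:10))
  f2 <- gene_freq_by_group(mt2, g2, top_k = Inf)
  brute <- sort(vapply(split(rec$sample_id, rec$gene),
                       function(s) length(unique(s)) / 10, numeric(1)),
                decreasing = TRUE)
  expect_equal(f2$freq_overall, unname(brute))
})

test_that("per-gene Fisher test equals hypergeometric enumeration", {
  # 8/2 mutated vs 1/9: build records to produce that 2x2
  samples <- paste0("s", 1:20)
  grp <- setNames(rep(c("A", "B"), each = 10), samples)
  mut_samples <- c(paste0("s", 1:8), "s11")  # 8 in A, 1 in B
  rec <- data.frame(sample_id = mut_samples, gene = "G1",
                    variant_classification = "Missense_Mutation")
  mt <- mutation_table(rec, samples = samples)
  res <- per_gene_test(mt, grp)
  expect_equal(res$p_value, oracle_fisher_p(8, 1, 2, 9), tolerance = 1e-12)

  # identical rates -> p = 1
  rec2 <- data.frame(sample_id = c("s1", "s11"), gene = "G1",
                     variant_classification = "Missense_Mutation")
  res2 <- per_gene_test(mutation_table(rec2, samples = samples), grp)
  expect_equal(res2$p_value, 1)
})

test_that("Fisher p is symmetric under swapping group labels", {
  mt <- mk_mt()
  p1 <- per_gene_test(mt, grp4)
  swapped <- setNames(ifelse(grp4 == "N+", "N-", "N+"), names(grp4))
  p2 <- per_gene_test(mt, swapped)
  expect_equal(p1$p_value, p2[match(p1$gene, p2$gene), "p_value"])
})

test_that("BH adjustment matches the hand step-up and its invariants", {
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  set.seed(21)
  samples <- paste0("s", 1:30)
  grp <- setNames(rep(c("A", "B"), 15), samples)
  rec <- data.frame(sample_id = sample(samples, 80, replace = TRUE),
                    gene = sample(paste0("g", 1:8), 80, replace = TRUE),
                    variant_classification = "Missense_Mutation")
  res <- per_gene_test(mutation_table(unique(rec), samples = samples), grp)
  expect_equal(res$q_value, oracle_bh(res$p_value))
  expect_true(all(diff(res$q_value[order(res$p_value)]) >= -1e-12))
  expect_gte(res$q_value[which.min(res$p_value)], min(res$p_value))
})

test_that("pathway burden is the any-member-mutated fraction with a Fisher p", {
  samples <- paste0("s", 1:20)
  grp <- setNames(rep(c("A", "B"), each = 10), samples)
  rec <- data.frame(sample_id = c("s1", "s2", "s3"), gene = "g1",
                    variant_classification = "Missense_Mutation")
  mt <- mutation_table(rec, samples = samples)
  pb <- pathway_burden(mt, list(P1 = "g1"), grp)
  expect_equal(pb$freq_A, 0.3)
  expect_equal(pb$freq_B, 0)

  # union of all genes saturates at the any-mutation fraction
  mt2 <- mk_mt()
  pb2 <- pathway_burden(mt2, list(ALL = unique(mt2$records$gene)), grp4)
  expect_equal(pb2$`freq_N+`, 0.5)
  expect_equal(pb2$`freq_N-`, 0.5)

  expect_warning(
    expect_error(pathway_burden(mt2, list(EMPTY = "absent_gene"), grp4),
                 "no pathway intersects"),
    "skipped")
})

test_that("a planted pathway rate difference is detected in most seeds", {
  hits <- vapply(1:10, function(seed) {
    set.seed(seed)
    samples <- paste0("s", 1:200)
    grp <- setNames(rep(c("A", "B"), each = 100), samples)
    mutated <- c(samples[1:100][rbinom(100, 1, 0.6) == 1],
                 samples[101:200][rbinom(100, 1, 0.2) == 1])
    rec <- data.frame(sample_id = mutated, gene = "g1",
                      variant_classification = "Missense_Mutation")
    mt <- mutation_table(rec, samples = samples)
    pathway_burden(mt, list(P = "g1"), grp)$p_value < 0.001
  }, logical(1))
  expect_gte(sum(hits), 9)
})
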