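# fixture builders and independent brute-force oracles used across tests

# random log2-scale expression matrix
make_expr <- function(n_genes, n_samples, seed = 1, mean = 7, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean, sd), nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# minimal valid clinical table
make_clinical <- function(n = 10, seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    necrosis = rep(c("present", "absent"), length.out = n),
    er = sample(c("positive", "negative"), n, replace = TRUE),
    pr = sample(c("positive", "negative"), n, replace = TRUE),
    her2 = sample(c("positive", "negative"), n, replace = TRUE),
    pam50 = sample(c("LumA", "LumB", "Her2", "Basal"), n, replace = TRUE),
    tumor_size_mm = round(runif(n, 5, 60), 1),
    grade = as.character(sample(1:3, n, replace = TRUE)),
    lymph_node = sample(c("positive", "negative"), n, replace = TRUE),
    surv_time_months = round(runif(n, 1, 120), 1),
    death_cause = sample(c("disease", "other", "alive"), n, replace = TRUE),
    sex = "female",
    stringsAsFactors = FALSE
  )
}

# two-level group factor for a matrix's samples, first n1 = group 1
make_labels <- function(x, n1) {
  lab <- factor(rep(c("N+", "N-"), c(n1, ncol(x) - n1)), levels = c("N+", "N-"))
  names(lab) <- colnames(x)
  lab
}

# oracle: classical pooled-variance two-sample t statistic, gene by gene
oracle_pooled_t <- function(x, g1) {
  vapply(seq_len(nrow(x)), function(i) {
    a <- x[i, g1]; b <- x[i, !g1]
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  }, numeric(1))
}

# oracle: Pearson chi-square statistic by the definition sum((O-E)^2/E)
oracle_chisq_stat <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# oracle: two-sided Fisher exact p by exhaustive hypergeometric enumeration
# (point-probability method) for a 2x2 table rbind(c(a, b), c(c, d))
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + c_; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# oracle: Benjamini-Hochberg step-up by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
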