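# match group labels to the mutation-table sample universe
.mut_groups <- function(mt, groups) {
  if (is.null(names(groups))) stop("groups must be named by sample id")
  miss <- setdiff(mt$samples, names(groups))
  if (length(miss) > 0) {
    stop("no group label for samples: ", paste(head(miss, 5), collapse = ", "))
  }
  factor(groups[mt$samples])
}

#' Per-sample mutation burden and per-group means
#'
#' Burden = number of mutation records per sample (all variant classes by
#' default); samples in the universe without records count 0. Exact
#' duplicate records (same sample, gene and variant class) can be collapsed
#' with `dedup = TRUE`.
#'
#' @param mt `mutation_table`.
#' @param groups named group labels covering the sample universe.
#' @param variant_filter `"all"` (default) or `"nonsyn"`.
#' @param dedup drop exact duplicate records before counting (default
#'   `FALSE`; the choice is reported in a message).
#' @return list: `per_sample` (data.frame sample_id/group/n_mutations),
#'   `group_means` (named numeric).
#' @export
mutation_burden <- function(mt, groups, variant_filter = "all", dedup = FALSE) {
  g <- .mut_groups(mt, groups)
  mt <- filter_variants(mt, variant_filter)
  rec <- mt$records
  if (dedup) {
    before <- nrow(rec)
    rec <- unique(rec)
    message("dedup: ", before - nrow(rec), " duplicate records collapsed")
  }
  counts <- table(factor(rec$sample_id, levels = mt$samples))
  per_sample <- data.frame(sample_id = mt$samples,
                           group = as.character(g),
                           n_mutations = as.integer(counts),
                           stringsAsFactors = FALSE)
  group_means <- tapply(per_sample$n_mutations, g, mean)
  list(per_sample = per_sample, group_means = c(group_means))
}

#' Per-gene mutated-sample fractions by group
#'
#' A sample counts as mutated in a gene if it has at least one qualifying
#' record for that gene (multiple hits collapse to one). Genes are ranked by
#' overall mutation frequency and the top `top_k` retained.
#'
#' @inheritParams mutation_burden
#' @param top_k number of top genes to keep (>= 1); `Inf` keeps all.
#' @return data.frame `gene`, `n_mutated_total`, `freq_overall`, then one
#'   `freq_<group>` column per group, sorted by `freq_overall` descending.
#' @export
gene_freq_by_group <- function(mt, groups, top_k = 15, variant_filter = "all") {
  if (top_k < 1) stop("top_k must be >= 1")
  g <- .mut_groups(mt, groups)
  mt <- filter_variants(mt, variant_filter)
  rec <- unique(mt$records[c("sample_id", "gene")])
  if (nrow(rec) == 0) {
    return(data.frame(gene = character(0), n_mutated_total = integer(0),
                      freq_overall = numeric(0)))
  }
  n_total <- length(mt$samples)
  group_of <- setNames(as.character(g), mt$samples)
  group_sizes <- table(g)
  genes <- unique(rec$gene)
  rows <- lapply(genes, function(gene) {
    smp <- rec$sample_id[rec$gene == gene]
    row <- data.frame(gene = gene, n_mutated_total = length(smp),
                      freq_overall = length(smp) / n_total,
                      stringsAsFactors = FALSE)
    for (lv in levels(g)) {
      row[[paste0("freq_", lv)]] <-
        sum(group_of[smp] == lv) / as.integer(group_sizes[lv])
    }
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$freq_overall, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  head(out, n = if (is.finite(top_k)) top_k else nrow(out))
}

#' Per-gene Fisher exact test of mutation rate between two groups
#'
#' For each gene a 2x2 table (mutated / not x group) is tested with the
#' two-sided Fisher exact test (hypergeometric point-probability method);
#' Benjamini-Hochberg q-values are reported across the tested genes. Genes
#' absent from all samples are skipped.
#'
#' @inheritParams mutation_burden
#' @param genes optional subset of genes to test (default: all mutated
#'   genes).
#' @return data.frame `gene`, `n_mut_<g1>`, `n_mut_<g2>`, `freq_<g1>`,
#'   `freq_<g2>`, `p_value`, `q_value`, ordered by p.
#' @export
per_gene_test <- function(mt, groups, genes = NULL, variant_filter = "all") {
  g <- .mut_groups(mt, groups)
  if (nlevels(g) != 2) stop("exactly two groups required")
  mt <- filter_variants(mt, variant_filter)
  rec <- unique(mt$records[c("sample_id", "gene")])
  all_genes <- unique(rec$gene)
  if (is.null(genes)) genes <- all_genes
  skipped <- setdiff(genes, all_genes)
  if (length(skipped) > 0) {
    message("skipping genes with no mutations: ", paste(skipped, collapse = ", "))
  }
  genes <- intersect(genes, all_genes)
  lv <- levels(g)
  n_by_group <- table(g)
  rows <- lapply(genes, function(gene) {
    smp <- rec$sample_id[rec$gene == gene]
    mut_g <- table(factor(g[match(smp, mt$samples)], levels = lv))
    tab <- rbind(mutated = as.integer(mut_g),
                 wild = as.integer(n_by_group - mut_g))
    p <- fisher.test(tab)$p.value
    data.frame(gene = gene,
               n1 = as.integer(mut_g[1]), n2 = as.integer(mut_g[2]),
               f1 = as.integer(mut_g[1]) / as.integer(n_by_group[1]),
               f2 = as.integer(mut_g[2]) / as.integer(n_by_group[2]),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- c(paste0("n_mut_", lv), paste0("freq_", lv))
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, out$gene), , drop = FALSE]
}

#' Pathway-level mutation burden by group
#'
#' A sample is "pathway-mutated" if at least one member gene carries a
#' qualifying mutation; group fractions are compared with a two-sided Fisher
#' exact test per pathway. Pathways with no member gene in the data are
#' skipped with a warning.
#'
#' @inheritParams mutation_burden
#' @param pathways named list of gene vectors, or a list of
#'   `necro_signature` objects (up and down genes pooled).
#' @return data.frame `pathway`, `n_genes_in_data`, `freq_<g1>`,
#'   `freq_<g2>`, `p_value`.
#' @export
pathway_burden <- function(mt, pathways, groups, variant_filter = "all") {
  g <- .mut_groups(mt, groups)
  if (nlevels(g) != 2) stop("exactly two groups required")
  mt <- filter_variants(mt, variant_filter)
  rec <- unique(mt$records[c("sample_id", "gene")])
  lv <- levels(g)
  n_by_group <- table(g)
  if (length(pathways) == 0) stop("empty pathway map")
  genes_of <- lapply(pathways, function(p) {
    if (inherits(p, "necro_signature")) union(p$up, p$down) else as.character(p)
  })
  if (is.null(names(genes_of))) stop("pathways must be named")
  rows <- list()
  for (nm in names(genes_of)) {
    members <- intersect(genes_of[[nm]], rec$gene)
    if (length(members) == 0) {
      warning("pathway '", nm, "' has no member gene in the data; skipped")
      next
    }
    hit_samples <- unique(rec$sample_id[rec$gene %in% members])
    hit_g <- table(factor(g[match(hit_samples, mt$samples)], levels = lv))
    tab <- rbind(hit = as.integer(hit_g), none = as.integer(n_by_group - hit_g))
    p <- fisher.test(tab)$p.value
    row <- data.frame(pathway = nm, n_genes_in_data = length(members),
                      f1 = as.integer(hit_g[1]) / as.integer(n_by_group[1]),
                      f2 = as.integer(hit_g[2]) / as.integer(n_by_group[2]),
                      p_value = p, stringsAsFactors = FALSE)
    rows[[nm]] <- row
  }
  if (length(rows) == 0) stop("no pathway intersects the mutation data")
  out <- do.call(rbind, rows)
  names(out)[3:4] <- paste0("freq_", lv)
  rownames(out) <- NULL
  out
}
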