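#' Directional gene-set (signature) definition
#'
#' A signature is a named pair of disjoint gene lists: genes expected to be
#' elevated (`up`) and reduced (`down`) in the condition of interest. The
#' per-sample score is the sum of expression over `up` minus the sum over
#' `down` (see [score_signature()]).
#'
#' @param name signature name.
#' @param up character vector of UP gene symbols (may be empty).
#' @param down character vector of DOWN gene symbols (may be empty).
#' @return object of class `necro_signature`.
#' @export
signature_definition <- function(name, up = character(0), down = character(0)) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  both <- intersect(up, down)
  if (length(both) > 0) {
    stop("genes in both UP and DOWN lists: ", paste(head(both, 5), collapse = ", "))
  }
  if (length(up) + length(down) == 0) stop("signature '", name, "' is empty")
  structure(list(name = name, up = up, down = down), class = "necro_signature")
}

#' @export
print.necro_signature <- function(x, ...) {
  cat("<necro_signature> ", x$name, ": ", length(x$up), " UP, ",
      length(x$down), " DOWN genes\n", sep = "")
  invisible(x)
}

#' Read directional signatures from a GMT file
#'
#' Standard GMT: one tab-separated line per set (`name`, `description`,
#' genes...). Lines whose names end in `_UP` and `_DN` are paired into one
#' directional signature; an unpaired `_UP`/`_DN` line, or a line with no
#' suffix, becomes a one-sided signature (with a warning for unpaired
#' suffixed lines).
#'
#' @param path GMT file path.
#' @return named list of `necro_signature` objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop("malformed GMT line ", short[1], ": need name, description, >=1 gene")
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  genes <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(genes) <- nm

  base <- sub("_(UP|DN)$", "", nm)
  sigs <- list()
  for (b in unique(base)) {
    idx <- which(base == b)
    up_i <- idx[grepl("_UP$", nm[idx])]
    dn_i <- idx[grepl("_DN$", nm[idx])]
    plain_i <- setdiff(idx, c(up_i, dn_i))
    if (length(up_i) + length(dn_i) > 0) {
      if (length(up_i) == 0 || length(dn_i) == 0) {
        warning("signature '", b, "' has only a ",
                if (length(up_i) > 0) "_UP" else "_DN",
                " set; treated as one-sided")
      }
      sigs[[b]] <- signature_definition(
        b,
        up = unlist(genes[up_i], use.names = FALSE),
        down = unlist(genes[dn_i], use.names = FALSE)
      )
    }
    for (j in plain_i) {
      sigs[[nm[j]]] <- signature_definition(nm[j], up = genes[[j]])
    }
  }
  sigs
}

#' Write signatures as GMT
#'
#' A directional signature is emitted as two lines, `NAME_UP` and `NAME_DN`;
#' a one-sided signature as a single suffixed line.
#'
#' @param sigs a `necro_signature` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sigs, path) {
  if (inherits(sigs, "necro_signature")) sigs <- list(sigs)
  lines <- character(0)
  for (s in sigs) {
    if (length(s$up) > 0) {
      lines <- c(lines, paste(c(paste0(s$name, "_UP"), "na", s$up), collapse = "\t"))
    }
    if (length(s$down) > 0) {
      lines <- c(lines, paste(c(paste0(s$name, "_DN"), "na", s$down), collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Jaccard index between the gene memberships of two signatures
#'
#' Direction is ignored: each signature contributes `up` union `down`.
#'
#' @param a,b `necro_signature` objects.
#' @return |A intersect B| / |A union B|, in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  ga <- union(a$up, a$down); gb <- union(b$up, b$down)
  length(intersect(ga, gb)) / length(union(ga, gb))
}
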