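# MAF variant classes conventionally counted as non-synonymous
.nonsyn_classes <- c("Missense_Mutation", "Nonsense_Mutation", "Splice_Site",
                     "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del",
                     "In_Frame_Ins", "Translation_Start_Site", "Nonstop_Mutation")

#' Somatic mutation table
#'
#' Wraps a record list (one row per mutation call) plus the sample universe:
#' the universe may contain mutation-free samples, which count as zeros in
#' burden and frequency computations.
#'
#' @param records data.frame with columns `sample_id`, `gene`,
#'   `variant_classification`.
#' @param samples character vector of all profiled sample ids; defaults to
#'   the samples present in `records`. Must be a superset of the record
#'   samples.
#' @return object of class `mutation_table`.
#' @export
mutation_table <- function(records, samples = NULL) {
  required <- c("sample_id", "gene", "variant_classification")
  miss <- setdiff(required, names(records))
  if (length(miss) > 0) stop("mutation records missing columns: ", paste(miss, collapse = ", "))
  records <- records[required]
  records[] <- lapply(records, as.character)
  if (is.null(samples)) samples <- unique(records$sample_id)
  extra <- setdiff(records$sample_id, samples)
  if (length(extra) > 0) {
    stop("records for samples outside the universe: ", paste(head(extra, 5), collapse = ", "))
  }
  structure(list(records = records, samples = unique(samples)),
            class = "mutation_table")
}

#' @export
print.mutation_table <- function(x, ...) {
  cat("<mutation_table> ", nrow(x$records), " records, ",
      length(unique(x$records$gene)), " genes, ", length(x$samples),
      " samples in universe\n", sep = "")
  invisible(x)
}

#' Read a Mutation Annotation Format (MAF) file
#'
#' Requires the standard `Hugo_Symbol`, `Tumor_Sample_Barcode` and
#' `Variant_Classification` columns; lines starting with `#` (MAF version
#' headers) are skipped. All variant classes are retained; filtering to
#' non-synonymous classes is done downstream via `variant_filter`.
#'
#' @param path MAF file (tab-separated text).
#' @param samples optional sample universe (ids of all profiled samples).
#' @return `mutation_table`.
#' @export
read_maf <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("MAF file not found: ", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  required <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) stop("MAF missing required columns: ", paste(miss, collapse = ", "))
  mutation_table(
    data.frame(sample_id = df$Tumor_Sample_Barcode,
               gene = df$Hugo_Symbol,
               variant_classification = df$Variant_Classification,
               stringsAsFactors = FALSE),
    samples = samples
  )
}

# apply the variant-class filter; "all" keeps every record
filter_variants <- function(mt, variant_filter = c("all", "nonsyn")) {
  variant_filter <- match.arg(variant_filter)
  if (variant_filter == "nonsyn") {
    mt$records <- mt$records[mt$records$variant_classification %in% .nonsyn_classes, ,
                             drop = FALSE]
  }
  mt
}
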