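#' @title Mutation and expression input
#' @name mutation-io
#' @description Readers for the somatic mutation table and the gene-by-sample
#'   expression table, FPKM to TPM conversion, and the expression-based
#'   mutation filter.
NULL

class_aliases <- c(
  "missense" = "missense", "missense_mutation" = "missense",
  "silent" = "silent", "synonymous" = "silent",
  "synonymous_variant" = "silent",
  "nonsense" = "nonsense", "nonsense_mutation" = "nonsense",
  "stop_gained" = "nonsense")

# Standardize a mutation data frame: canonical column names and classes,
# default f = 1, integer positions. Stops on structural problems only.
normalize_mutations <- function(m) {
  names(m)[names(m) == "class"] <- "mutation_class"
  names(m)[names(m) == "sample"] <- "sample_id"
  need <- c("gene", "isoform", "protein_position", "mutation_class")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("mutation table lacks required column(s): ",
         paste(miss, collapse = ", "))
  cls <- class_aliases[tolower(as.character(m$mutation_class))]
  if (anyNA(cls))
    stop("unknown mutation class value(s): ",
         paste(unique(m$mutation_class[is.na(cls)]), collapse = ", "))
  m$mutation_class <- unname(cls)
  m$protein_position <- as.integer(m$protein_position)
  if (!"f" %in% names(m)) m$f <- 1
  m$f[is.na(m$f)] <- 1
  if (!"sample_id" %in% names(m)) m$sample_id <- NA_character_
  if (!"cancer_type" %in% names(m)) m$cancer_type <- NA_character_
  m
}

#' Read a somatic mutation table
#'
#' Tab-separated with header; required columns `gene`, `isoform`,
#' `protein_position` (1-based), `class` (or `mutation_class`), `sample` (or
#' `sample_id`); optional `f` (subclonal fraction, defaults to 1 when absent
#' or NA), `cancer_type`, `codon`. Class names are case-insensitive and
#' MAF-style aliases (`Missense_Mutation`, `Silent`, `Nonsense_Mutation`, ...)
#' are accepted. Malformed rows (position < 1, f outside (0,1\], unknown
#' class) are rejected and collected into the `"rejected"` attribute with a
#' reason each.
#'
#' @param path File path.
#' @return Data frame of validated mutation records with attribute
#'   `"rejected"`.
#' @export
read_mutations <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  names(m)[names(m) == "class"] <- "mutation_class"
  names(m)[names(m) == "sample"] <- "sample_id"
  need <- c("gene", "isoform", "protein_position", "mutation_class",
            "sample_id")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("mutation file lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (!"f" %in% names(m)) m$f <- NA_real_
  m$f <- suppressWarnings(as.numeric(m$f))
  m$f[is.na(m$f)] <- 1
  pos <- suppressWarnings(as.integer(m$protein_position))
  cls <- class_aliases[tolower(as.character(m$mutation_class))]
  reason <- rep(NA_character_, nrow(m))
  reason[is.na(pos) | pos < 1L] <- "position must be a 1-based integer"
  reason[is.na(reason) & (m$f <= 0 | m$f > 1)] <- "f outside (0, 1]"
  reason[is.na(reason) & is.na(cls)] <- "unknown mutation class"
  bad <- !is.na(reason)
  rejected <- data.frame(row = which(bad), reason = reason[bad],
                         stringsAsFactors = FALSE)
  if (nrow(rejected))
    message(nrow(rejected), " mutation row(s) rejected (see attr 'rejected')")
  m <- m[!bad, , drop = FALSE]
  m$protein_position <- pos[!bad]
  m$mutation_class <- unname(cls[!bad])
  if (!"cancer_type" %in% names(m)) m$cancer_type <- NA_character_
  if (!"codon" %in% names(m)) m$codon <- NA_character_
  rownames(m) <- NULL
  attr(m, "rejected") <- rejected
  m
}

#' Convert FPKM expression values to TPM
#'
#' Per sample, `TPM_g = FPKM_g / sum_g(FPKM_g) * 1e6`, so each sample's TPM
#' values sum to one million. Scale-invariant per sample.
#'
#' @param x Matrix or data frame, genes in rows, samples in columns.
#' @return Matrix of TPM values with the same dimnames.
#' @export
fpkm_to_tpm <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x) || any(x < 0)) stop("FPKM values must be nonnegative")
  tot <- colSums(x)
  if (any(tot <= 0))
    stop("sample(s) with all-zero FPKM: ",
         paste(colnames(x)[tot <= 0], collapse = ", "))
  sweep(x, 2, tot, "/") * 1e6
}

#' Read a gene-by-sample expression table
#'
#' Tab-separated, genes in rows (first column `gene`), samples in columns. A
#' unit declaration line `#unit=TPM` or `#unit=FPKM` must precede the header;
#' FPKM values are converted to TPM on read.
#'
#' @param path File path.
#' @return List with `tpm` (matrix, genes x samples) and `unit` (the declared
#'   input unit).
#' @export
read_expression <- function(path) {
  first <- readLines(path, n = 1L)
  unit <- toupper(sub("^#\\s*unit\\s*=\\s*", "", first, ignore.case = TRUE))
  if (!startsWith(first, "#") || !unit %in% c("TPM", "FPKM"))
    stop("expression file must start with a unit line: '#unit=TPM' or '#unit=FPKM'")
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (names(df)[1] != "gene") stop("first expression column must be 'gene'")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene
  if (unit == "FPKM") mat <- fpkm_to_tpm(mat)
  list(tpm = mat, unit = unit)
}

#' Filter mutations by tumor-sample gene expression
#'
#' A mutation is kept iff its gene is expressed at `>= threshold` TPM in the
#' corresponding tumor sample (the paper's rule removes genes expressed at
#' `< 0.1` TPM). For samples absent from the expression table, the gene's mean
#' TPM across the other samples of the same cancer type is used. Genes absent
#' from the table pass the filter (permissive; counted in the report), as do
#' mutations with no usable expression information.
#'
#' @param mutations Mutation data frame (columns `gene`, `sample_id`, and
#'   `cancer_type` for the tissue fallback).
#' @param expression A [read_expression()] list, or a TPM matrix
#'   (genes x samples).
#' @param threshold TPM threshold (default 0.1).
#' @return Filtered mutation data frame with attribute `"filter_report"`
#'   (counts kept/removed by reason).
#' @export
expression_filter <- function(mutations, expression, threshold = 0.1) {
  tpm <- if (is.list(expression) && !is.data.frame(expression))
    expression$tpm else as.matrix(expression)
  m <- mutations
  keep <- rep(TRUE, nrow(m))
  reason <- rep("kept", nrow(m))
  sample_tissue <- unique(m[!is.na(m$sample_id),
                            c("sample_id", "cancer_type"), drop = FALSE])
  for (i in seq_len(nrow(m))) {
    g <- m$gene[i]
    if (!g %in% rownames(tpm)) { reason[i] <- "gene_not_in_expression"; next }
    s <- m$sample_id[i]
    if (!is.na(s) && s %in% colnames(tpm)) {
      if (tpm[g, s] < threshold) { keep[i] <- FALSE; reason[i] <- "low_expression" }
    } else {
      tis <- m$cancer_type[i]
      peers <- sample_tissue$sample_id[!is.na(sample_tissue$cancer_type) &
                                         sample_tissue$cancer_type %in% tis]
      peers <- intersect(setdiff(peers, s), colnames(tpm))
      if (is.na(tis) || length(peers) == 0L) {
        reason[i] <- "no_expression_information"
      } else if (mean(tpm[g, peers]) < threshold) {
        keep[i] <- FALSE; reason[i] <- "low_tissue_mean_expression"
      }
    }
  }
  out <- m[keep, , drop = FALSE]
  rownames(out) <- NULL
  report <- table(ifelse(keep, reason, paste0("removed_", reason)))
  attr(out, "filter_report") <- report
  out
}
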