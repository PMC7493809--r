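#' Per-codon missense mutability with C/G bias
#'
#' Enumerates the nine single-nucleotide substitutions of a sense codon and
#' counts, per codon position d, the substitutions that change the encoded
#' amino acid (synonymous changes and changes to stop codons are excluded).
#' Each position's count is weighted by a bias factor: 1 when the reference
#' nucleotide is A or T, `b` when it is C or G, where `b` is the relative
#' frequency of C/G versus A/T mutations in tumors (default 3.063).
#'
#' @param codon 3-letter sense codon (ACGT alphabet).
#' @param b C/G bias factor (> 0).
#' @return An object of class `codon_profile`: list with `codon`, per-position
#'   `bias`, per-position `missense_counts`, and the unnormalized mutability
#'   `lambda`.
#' @examples
#' codon_lambda("ATG")$lambda  # 1*3 + 1*3 + 3.063*3 = 15.189
#' @export
codon_lambda <- function(codon, b = 3.063) {
  codon <- toupper(codon)
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L ||
      grepl("[^ACGT]", codon))
    stop("codon must be a 3-letter ACGT string")
  if (!is.numeric(b) || b <= 0) stop("b must be positive")
  code <- Biostrings::GENETIC_CODE
  aa <- code[[codon]]
  if (aa == "*") stop("'", codon, "' is a stop codon")
  nts <- c("A", "C", "G", "T")
  ref <- strsplit(codon, "")[[1]]
  counts <- integer(3)
  for (d in 1:3) {
    for (u in setdiff(nts, ref[d])) {
      mut <- ref
      mut[d] <- u
      maa <- code[[paste(mut, collapse = "")]]
      if (maa != "*" && maa != aa) counts[d] <- counts[d] + 1L
    }
  }
  bias <- ifelse(ref %in% c("A", "T"), 1, b)
  structure(list(codon = codon, bias = bias, missense_counts = counts,
                 lambda = sum(bias * counts)),
            class = "codon_profile")
}

#' Per-position background mutability from codons
#'
#' @param codons Character vector of sense codons, one per protein position.
#' @param b C/G bias factor.
#' @return Numeric vector of unnormalized per-position mutabilities.
#' @export
position_lambda <- function(codons, b = 3.063) {
  vapply(codons, function(cd) codon_lambda(cd, b)$lambda, numeric(1),
         USE.NAMES = FALSE)
}

#' Per-position background mutability from a coding sequence
#'
#' Splits a CDS into codons (a trailing stop codon is dropped) and returns the
#' per-position mutability via [position_lambda()].
#'
#' @param cds A single nucleotide string, a `DNAStringSet` element, or a
#'   FASTA file path (first record used).
#' @param b C/G bias factor.
#' @return Numeric vector of unnormalized per-position mutabilities, one per
#'   codon.
#' @export
lambda_from_cds <- function(cds, b = 3.063) {
  if (is.character(cds) && length(cds) == 1L && file.exists(cds))
    cds <- as.character(Biostrings::readDNAStringSet(cds))[[1]]
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3 != 0)
    stop("CDS length must be divisible by 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  last <- codons[length(codons)]
  if (Biostrings::GENETIC_CODE[[last]] == "*")
    codons <- codons[-length(codons)]
  if (any(vapply(codons, function(x) Biostrings::GENETIC_CODE[[x]] == "*",
                 logical(1))))
    stop("CDS contains an internal stop codon")
  position_lambda(codons, b)
}

#' Rescale background mutabilities onto a track
#'
#' Restricts per-position mutabilities to the track's positions and
#' normalizes them to sum to 1 (the track-level background distribution).
#'
#' @param lambda Numeric vector of per-position mutabilities over the whole
#'   protein (length >= protein length), or `NULL` for a uniform background.
#' @param track A [functional_track()].
#' @return Numeric vector summing to 1, parallel to `track$positions`.
#' @export
rescale_for_track <- function(lambda, track) {
  if (is.null(lambda))
    return(rep(1 / length(track$positions), length(track$positions)))
  if (length(lambda) < track$protein_length)
    stop("lambda shorter than the protein (", length(lambda), " < ",
         track$protein_length, ")")
  lam <- lambda[track$positions]
  if (anyNA(lam) || any(lam < 0))
    stop("lambda must be nonnegative over the track positions")
  tot <- sum(lam)
  if (tot <= 0)
    stop("degenerate background: lambda is zero over all track positions")
  lam / tot
}

#' Build the whole-gene natural-variation background
#'
#' For each healthy individual, genes are min-ranked by their variant count,
#' ranks are linearly scaled to \[0,1\] as (rank-1)/(N-1), floored to
#' `bin_width` bins, and the per-gene bins are averaged across individuals.
#' A small positive floor is added before the final normalization so that no
#' gene has exactly zero background probability, and the result is scaled to
#' sum to 1 over the gene universe.
#'
#' @param variant_counts Matrix or data frame of nonnegative counts,
#'   individuals in rows, genes in columns (column names = gene ids).
#' @param bin_width Bin width for rank flooring (default 0.01).
#' @param lambda_floor Positive floor added to the averaged bins before
#'   normalization (default 1e-4); set to 0 to reproduce the raw procedure.
#' @return An object of class `natural_variation_model`: list with `genes`,
#'   `lambda` (named, sums to 1), `bin_width`, `lambda_floor`,
#'   `n_individuals`.
#' @export
build_natural_variation <- function(variant_counts, bin_width = 0.01,
                                    lambda_floor = 1e-4) {
  vc <- as.matrix(variant_counts)
  if (nrow(vc) < 1L || ncol(vc) < 2L)
    stop("variant_counts needs >= 1 individual and >= 2 genes")
  if (anyNA(vc) || any(vc < 0)) stop("variant counts must be nonnegative")
  if (is.null(colnames(vc))) stop("variant_counts must have gene column names")
  n_genes <- ncol(vc)
  bins <- t(apply(vc, 1, function(x) {
    scaled <- (rank(x, ties.method = "min") - 1) / (n_genes - 1)
    # +1e-9 guards against 0.50/0.01 evaluating to 49.999... in binary
    floor(scaled / bin_width + 1e-9) * bin_width
  }))
  avg <- colMeans(matrix(bins, ncol = n_genes,
                         dimnames = list(NULL, colnames(vc))))
  lam <- avg + lambda_floor
  structure(list(genes = colnames(vc), lambda = lam / sum(lam),
                 bin_width = bin_width, lambda_floor = lambda_floor,
                 n_individuals = nrow(vc)),
            class = "natural_variation_model")
}

#' @export
print.natural_variation_model <- function(x, ...) {
  cat(sprintf("<natural_variation_model> %d genes, %d individuals, bin width %g\n",
              length(x$genes), x$n_individuals, x$bin_width))
  invisible(x)
}
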