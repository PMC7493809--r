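#' Normalized Shannon entropy of mutations across interaction sites
#'
#' Considers all sites of a protein with nonzero interaction-track weight (the
#' union over the gene's interaction tracks) and the frequency with which
#' missense mutations hit each of them. The normalized entropy
#' `-sum(p_s log p_s) / log K` (K = number of interaction sites) is 0 when all
#' mutations pile onto one site (a hotspot) and 1 when they are spread
#' uniformly across the whole interface. The normalization makes the value
#' independent of the logarithm base.
#'
#' @param tracks List of the gene's [functional_track()]s (non-interaction
#'   tracks are ignored).
#' @param mutations Data frame of the gene's mutations.
#' @return An object of class `entropy_result`: list with `entropy`,
#'   `n_sites` (K), `n_mutations` (on interaction sites), and `site_counts`.
#' @export
interaction_entropy <- function(tracks, mutations) {
  tracks <- Filter(function(t) t$group == "interaction", tracks)
  if (length(tracks) == 0L) stop("no interaction tracks for this gene")
  sites <- sort(unique(unlist(lapply(tracks, function(t)
    t$positions[t$weights > 0]))))
  if (length(sites) == 0L)
    stop("no interaction sites (all interaction weights are zero)")
  m <- mutations
  if ("mutation_class" %in% names(m))
    m <- m[m$mutation_class == "missense", , drop = FALSE]
  m <- m[m$protein_position %in% sites, , drop = FALSE]
  if (nrow(m) == 0L)
    stop("no missense mutations on interaction sites")
  counts <- table(factor(m$protein_position, levels = sites))
  p <- as.numeric(counts) / sum(counts)
  k <- length(sites)
  h <- if (k == 1L) 0 else {
    pp <- p[p > 0]
    -sum(pp * log(pp)) / log(k)
  }
  structure(list(entropy = h, n_sites = k, n_mutations = nrow(m),
                 site_counts = counts),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("<entropy_result> normalized entropy %.4f over %d interaction sites (%d mutations)\n",
              x$entropy, x$n_sites, x$n_mutations))
  invisible(x)
}

#' Gold-standard enrichment along a gene ranking
#'
#' At each rank k, enrichment is the fraction of gold-standard genes among the
#' top k (the precision) divided by the gold-standard fraction in the whole
#' ranked set (the baseline). Gold-standard genes absent from the ranking
#' (e.g. unmutated) are excluded from both numerator and baseline. Enrichment
#' at the last rank is exactly 1.
#'
#' @param ranking Character vector of gene ids, best first (a strict
#'   ordering).
#' @param gold Character vector of gold-standard gene ids.
#' @param every Report every `every`-th rank (default 1 = all ranks).
#' @return Data frame with `rank`, `hits`, `precision`, `enrichment`;
#'   attributes `baseline` and `gold_used`.
#' @export
enrichment_curve <- function(ranking, gold, every = 1L) {
  if (anyDuplicated(ranking)) stop("ranking must not contain duplicates")
  gold_used <- intersect(gold, ranking)
  n <- length(ranking)
  hits <- cumsum(ranking %in% gold_used)
  if (length(gold_used) == 0L) {
    warning("no gold-standard genes present in the ranking")
    baseline <- 0
    enr <- rep(0, n)
  } else {
    baseline <- length(gold_used) / n
    enr <- (hits / seq_len(n)) / baseline
  }
  keep <- seq(1L, n, by = every)
  out <- data.frame(rank = keep, hits = hits[keep],
                    precision = hits[keep] / keep,
                    enrichment = enr[keep])
  attr(out, "baseline") <- baseline
  attr(out, "gold_used") <- gold_used
  out
}

#' Trapezoidal area under an enrichment curve
#'
#' @param curve A data frame from [enrichment_curve()].
#' @param top_n Integrate over ranks 1..`top_n` (default: the whole curve).
#' @return Numeric area (rank units x enrichment).
#' @export
enrichment_auc <- function(curve, top_n = max(curve$rank)) {
  cv <- curve[curve$rank <= top_n, , drop = FALSE]
  if (nrow(cv) < 2L) return(0)
  sum(diff(cv$rank) * (head(cv$enrichment, -1) + cv$enrichment[-1]) / 2)
}

#' Jaccard overlap of two gene sets
#'
#' `|A intersect B| / |A union B|`; used to compare top-ranked gene sets
#' between methods.
#'
#' @param a,b Character vectors (at least one nonempty).
#' @return Value in \[0, 1\].
#' @export
jaccard_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0L) stop("both sets are empty")
  length(intersect(a, b)) / length(u)
}

#' Per-gene perturbed-mechanism report
#'
#' For each scored gene, lists the functional tracks with Z at or above
#' `threshold`, applying display suppression rules: a domain track is shown
#' only when no interaction track of the same domain family reaches the
#' threshold (the interaction signal subsumes it), and the conservation track
#' is shown only when no track of any other group reaches the threshold.
#' Genes with no qualifying track get a single row with `NA` track fields.
#'
#' @param results A [score_cohort()] result (or its `tracks` breakdown data
#'   frame).
#' @param threshold Z threshold (default 0.5).
#' @return Data frame with `gene`, `track_id`, `group`, `ligand`, `z`.
#' @export
mechanism_report <- function(results, threshold = 0.5) {
  bd <- if (inherits(results, "gene_results")) results$tracks else results
  out <- list()
  for (g in unique(bd$gene)) {
    b <- bd[bd$gene == g & !is.na(bd$z), , drop = FALSE]
    hi <- b[b$z >= threshold, , drop = FALSE]
    rows <- hi[hi$group == "interaction", , drop = FALSE]
    dom <- hi[hi$group == "domain", , drop = FALSE]
    if (nrow(dom)) {
      int_hi_fams <- unique(track_family(
        b$track_id[b$group == "interaction" & b$z >= threshold]))
      dom <- dom[!track_family(dom$track_id) %in% int_hi_fams, , drop = FALSE]
      rows <- rbind(rows, dom)
    }
    natv <- hi[hi$group == "natural_variation", , drop = FALSE]
    rows <- rbind(rows, natv)
    cons <- hi[hi$group == "conservation", , drop = FALSE]
    other_hi <- any(hi$group != "conservation")
    if (nrow(cons) && !other_hi) rows <- rbind(rows, cons)
    if (nrow(rows) == 0L) {
      rows <- data.frame(gene = g, track_id = NA_character_,
                         group = NA_character_, ligand = NA_character_,
                         z = NA_real_, stringsAsFactors = FALSE)
    } else {
      rows <- data.frame(gene = g, track_id = rows$track_id,
                         group = rows$group, ligand = rows$ligand, z = rows$z,
                         stringsAsFactors = FALSE)
    }
    out[[g]] <- rows
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(res) <- NULL
  res
}
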