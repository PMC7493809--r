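#' Calibrate the minimum mutation count for a track's Z score
#'
#' The per-track Z score relies on the near-normality of a sum of n i.i.d.
#' draws of position weights. For each n = 1..`max_n`, `reps` random score
#' sums are drawn under the track background (f = 1) and tested for normality
#' with a Shapiro-Wilk test; the calibrated minimum n* is the smallest n from
#' which `stable` consecutive counts fail to reject normality at `alpha`.
#' Tracks whose scores never look normal within `max_n` get the
#' `never_normal` flag and are excluded from combination.
#'
#' @param track A [functional_track()].
#' @param lambda_w Track background from [rescale_for_track()].
#' @param reps Random score sums per mutation count (default 1000).
#' @param max_n Largest mutation count probed (default 500).
#' @param alpha Shapiro-Wilk rejection threshold (default 5e-5).
#' @param stable Consecutive non-rejections required (default 3); guards
#'   against single-n noise.
#' @param seed Optional integer seed; the calibration is deterministic given
#'   it and does not disturb the caller's RNG state.
#' @return An object of class `calibration_result`: list with `track_id`,
#'   `min_n` (`NA` when never normal), `never_normal`, and the protocol
#'   parameters.
#' @export
calibrate_min_mutations <- function(track, lambda_w, reps = 1000L,
                                    max_n = 500L, alpha = 5e-5,
                                    stable = 3L, seed = NULL) {
  reps <- as.integer(reps); max_n <- as.integer(max_n)
  stable <- as.integer(stable)
  if (reps < 3L) stop("reps must be >= 3 for a normality test")
  res <- list(track_id = track$track_id, min_n = NA_integer_,
              never_normal = TRUE, reps = reps, max_n = max_n,
              alpha = alpha, stable = stable, seed = seed)
  class(res) <- "calibration_result"
  if (is_degenerate_track(track)) return(res)
  mom <- track_moments(track, lambda_w)
  if (mom$degenerate) return(res)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  w <- track$weights
  streak <- 0L
  for (n in seq_len(max_n)) {
    idx <- sample.int(length(w), n * reps, replace = TRUE, prob = lambda_w)
    scores <- colSums(matrix(w[idx], nrow = n, ncol = reps))
    p <- tryCatch(shapiro.test(scores)$p.value, error = function(e) 0)
    if (p >= alpha) {
      streak <- streak + 1L
      if (streak == stable) {
        res$min_n <- n - stable + 1L
        res$never_normal <- FALSE
        return(res)
      }
    } else streak <- 0L
  }
  res
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %s: %s (reps=%d, max_n=%d, alpha=%g)\n",
              x$track_id,
              if (x$never_normal) "never normal" else paste0("n* = ", x$min_n),
              x$reps, x$max_n, x$alpha))
  invisible(x)
}

# Disk-backed calibration cache: one JSON sidecar per content hash of
# (weights, lambda, protocol), so calibrations survive across runs.
calibration_key <- function(track, lambda_w, reps, max_n, alpha, stable, seed) {
  rlang::hash(list(round(track$weights, 12), round(lambda_w, 12),
                   as.integer(reps), as.integer(max_n), alpha,
                   as.integer(stable), seed))
}

calibration_cached <- function(track, lambda_w, reps, max_n, alpha, stable,
                               seed, cache_dir = NULL) {
  if (is.null(cache_dir))
    return(calibrate_min_mutations(track, lambda_w, reps, max_n, alpha,
                                   stable, seed))
  key <- calibration_key(track, lambda_w, reps, max_n, alpha, stable, seed)
  path <- file.path(cache_dir, paste0(key, ".json"))
  if (file.exists(path)) {
    hit <- jsonlite::read_json(path, simplifyVector = TRUE)
    res <- list(track_id = track$track_id,
                min_n = if (is.null(hit$min_n) || is.na(hit$min_n)) NA_integer_
                        else as.integer(hit$min_n),
                never_normal = isTRUE(hit$never_normal),
                reps = reps, max_n = max_n, alpha = alpha, stable = stable,
                seed = seed)
    class(res) <- "calibration_result"
    return(res)
  }
  res <- calibrate_min_mutations(track, lambda_w, reps, max_n, alpha, stable,
                                 seed)
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(min_n = res$min_n,
                            never_normal = res$never_normal),
                       path, auto_unbox = TRUE, null = "null")
  res
}

#' Per-track confidence weights for the combined Z score
#'
#' Each of the four functionality groups present among the included tracks
#' contributes an equal share of the overall confidence (absent groups'
#' shares are redistributed among present groups). Within a group with
#' several tracks (interaction, domain), per-track confidence is proportional
#' to `sqrt(m)` by default (`m` = mutations at positively weighted positions),
#' or to `m` with `rule = "linear"`.
#'
#' @param groups Character vector of track groups for the included tracks.
#' @param m Nonnegative mutation counts, parallel to `groups`.
#' @param rule `"sqrt"` (default) or `"linear"` within-group weighting.
#' @return Numeric confidence vector summing to 1.
#' @export
confidence_weights <- function(groups, m, rule = c("sqrt", "linear")) {
  rule <- match.arg(rule)
  if (length(groups) == 0L) stop("no included tracks to weight")
  if (length(m) != length(groups)) stop("groups and m must be parallel")
  if (!all(groups %in% track_groups()))
    stop("unknown track group(s): ",
         paste(setdiff(groups, track_groups()), collapse = ", "))
  present <- unique(groups)
  share <- 1 / length(present)
  cw <- numeric(length(groups))
  for (g in present) {
    sel <- groups == g
    raw <- if (rule == "sqrt") sqrt(m[sel]) else m[sel]
    if (sum(raw) <= 0) raw <- rep(1, sum(sel))
    cw[sel] <- share * raw / sum(raw)
  }
  cw
}

#' Weighted Z-transform combination with correlation correction
#'
#' `Z = sum(c_i Z_i) / sqrt(sum(c_i^2) + 2 * sum_{i<j} c_i c_j r_ij)`, the
#' weighted Z-transform of correlated standard-normal statistics.
#'
#' @param z Per-track Z scores.
#' @param c Nonnegative confidence weights (at least one positive).
#' @param r Correlation matrix (unit diagonal); ignored when k = 1.
#' @return Combined Z score.
#' @export
combine_z <- function(z, c, r = diag(length(z))) {
  k <- length(z)
  if (length(c) != k) stop("z and c must have the same length")
  if (any(c < 0) || sum(c) <= 0) stop("confidences must be nonnegative, not all zero")
  if (k == 1L) return(z)
  r <- as.matrix(r)
  if (!all(dim(r) == k)) stop("r must be a k x k correlation matrix")
  if (any(abs(r) > 1 + 1e-8)) stop("correlations must lie in [-1, 1]")
  denom2 <- sum(c^2) + 2 * sum((c %o% c * r)[upper.tri(r)])
  if (denom2 <= 0)
    stop("non-positive combination variance (pathological correlation matrix); ",
         "min eigenvalue = ", format(min(eigen(r, symmetric = TRUE,
                                               only.values = TRUE)$values)))
  sum(c * z) / sqrt(denom2)
}

# Symmetrize and, if needed, project a correlation matrix to the nearest
# positive semi-definite matrix (eigenvalue clipping + unit-diagonal rescale).
condition_correlation <- function(r, tol = 1e-8) {
  r <- (r + t(r)) / 2
  ev <- eigen(r, symmetric = TRUE)
  if (min(ev$values) >= -tol) return(r)
  v <- pmax(ev$values, 0)
  m <- ev$vectors %*% (v * t(ev$vectors))
  d <- sqrt(pmax(diag(m), .Machine$double.eps))
  m <- m / (d %o% d)
  diag(m) <- 1
  dimnames(m) <- dimnames(r)
  (m + t(m)) / 2
}

#' Whole-gene mutational enrichment statistics
#'
#' The whole-gene track is a one-hot encoding over the gene universe of the
#' natural-variation background, so the score simplifies to the (subsampled)
#' sum of subclonal fractions in the gene: with subsample factor s,
#' `S = s * sum(f_i, i in gene)`, `E = s * lambda_g * sum(f)` and
#' `var = s * lambda_g * (1 - s * lambda_g) * sum(f^2)` over all n mutations
#' in the cohort. Subsampling (default `s = 1/sqrt(n)`) keeps whole-gene Z
#' scores on a scale comparable to subgene tracks.
#'
#' @param gene Gene id.
#' @param mutations Data frame of all missense mutations in the cohort (a
#'   `gene` column is required; missing `f` defaults to 1).
#' @param model A [build_natural_variation()] model.
#' @param s Subsample factor in (0, 1\]; default `1/sqrt(n)`.
#' @return A `track_statistics` object of group `"natural_variation"`, or
#'   `NULL` when the gene is absent from the model universe.
#' @export
whole_gene_z <- function(gene, mutations, model, s = NULL) {
  stopifnot(inherits(model, "natural_variation_model"))
  if (!gene %in% model$genes) return(NULL)
  m <- mutations
  if ("mutation_class" %in% names(m))
    m <- m[m$mutation_class == "missense", , drop = FALSE]
  if (!"f" %in% names(m)) m$f <- 1
  m$f[is.na(m$f)] <- 1
  n <- nrow(m)
  if (n == 0L) return(NULL)
  if (is.null(s)) s <- 1 / sqrt(n)
  if (s <= 0 || s > 1) stop("subsample factor s must lie in (0, 1]")
  lam <- unname(model$lambda[gene])
  in_gene <- m$gene == gene
  sum_f <- sum(m$f); sum_f2 <- sum(m$f^2)
  s_w <- s * sum(m$f[in_gene])
  e_s <- s * lam * sum_f
  var_s <- s * lam * (1 - s * lam) * sum_f2
  structure(list(
    track_id = paste0("whole_gene|", gene), group = "natural_variation",
    ligand = NA_character_, s_w = s_w, e_s = e_s, sd_s = sqrt(var_s),
    z = if (var_s > 0) (s_w - e_s) / sqrt(var_s) else NA_real_,
    n = sum(in_gene), m = sum(in_gene), sum_f = sum_f, sum_f2 = sum_f2,
    c_e = s * lam, c_v = s * lam * (1 - s * lam)),
    class = "track_statistics")
}

# Combine one isoform's per-track statistics into a single Z score.
# gene_stats: optional whole-gene track_statistics (zero covariance with the
# subgene tracks by construction).
combine_isoform <- function(tracks, stats, cor_mat, gene_stats = NULL,
                            min_n = NULL, positive_only = TRUE,
                            weight_rule = "sqrt") {
  k <- length(stats)
  z <- vapply(stats, `[[`, numeric(1), "z")
  n <- vapply(stats, `[[`, numeric(1), "n")
  mm <- vapply(stats, `[[`, numeric(1), "m")
  grp <- vapply(stats, `[[`, character(1), "group")
  need <- if (is.null(min_n)) rep(1, k) else min_n
  ok <- !is.na(z) & n >= 1 & is.finite(need) & n >= need
  if (positive_only) ok <- ok & z > 0
  sel_z <- z[ok]; sel_c_groups <- grp[ok]; sel_m <- mm[ok]
  sel_r <- cor_mat[ok, ok, drop = FALSE]
  if (!is.null(gene_stats) && !is.na(gene_stats$z) &&
      (!positive_only || gene_stats$z > 0)) {
    sel_z <- c(sel_z, gene_stats$z)
    sel_c_groups <- c(sel_c_groups, gene_stats$group)
    sel_m <- c(sel_m, gene_stats$m)
    kk <- length(sel_z)
    r2 <- diag(1, kk)
    if (kk > 1) r2[seq_len(kk - 1), seq_len(kk - 1)] <- sel_r
    sel_r <- r2
  }
  included <- ok
  if (length(sel_z) == 0L)
    return(list(combined_z = NA_real_, included = included, k = 0L))
  sel_r <- condition_correlation(sel_r)
  cw <- confidence_weights(sel_c_groups, sel_m, rule = weight_rule)
  list(combined_z = combine_z(sel_z, cw, sel_r), included = included,
       k = length(sel_z))
}

#' Gene-level result from per-isoform combined scores
#'
#' A gene's score is the maximum combined Z over its isoforms; ties are broken
#' by lexicographic isoform id so output is deterministic.
#'
#' @param isoform_scores Named numeric vector of combined Z scores (names =
#'   isoform ids; `NA` for unscored isoforms).
#' @return List with `combined_z` and `best_isoform` (`NA` when no isoform is
#'   scored).
#' @export
score_gene <- function(isoform_scores) {
  if (length(isoform_scores) == 0L || all(is.na(isoform_scores)))
    return(list(combined_z = NA_real_, best_isoform = NA_character_))
  ord <- order(-isoform_scores, names(isoform_scores), na.last = TRUE)
  best <- ord[1]
  list(combined_z = unname(isoform_scores[best]),
       best_isoform = names(isoform_scores)[best])
}

#' Score a mutated cohort end-to-end
#'
#' Runs the full analytic pipeline: per-track backgrounds, closed-form
#' per-track statistics, per-track minimum-mutation calibration, between-track
#' correlations, confidence-weighted combination of the per-track Z scores,
#' and per-gene maximization over isoforms.
#'
#' @param tracks List of [functional_track()]s (any number of isoforms).
#' @param mutations Data frame of mutations with columns `gene`, `isoform`,
#'   `protein_position`, `mutation_class`, and optionally `f`, `sample_id`,
#'   `cancer_type` (see [read_mutations()]). Only missense mutations are
#'   scored.
#' @param lambda Named list mapping isoform id to a per-position mutability
#'   vector (e.g. from [lambda_from_cds()]); isoforms absent from the list use
#'   a uniform background.
#' @param natvar Optional [build_natural_variation()] model adding a
#'   whole-gene track per gene in its universe.
#' @param expression Optional expression list from [read_expression()];
#'   mutations in genes expressed below `expression_threshold` TPM in the
#'   corresponding sample are excluded first.
#' @param expression_threshold TPM threshold (default 0.1).
#' @param positive_only Combine only tracks with positive Z (default TRUE,
#'   the enrichment-detection rule). With FALSE all calibrated mutated tracks
#'   are combined, which makes the combined Z a calibrated N(0,1) statistic
#'   under the null.
#' @param weight_rule Within-group confidence rule, `"sqrt"` or `"linear"`.
#' @param calibrate Run per-track minimum-mutation calibration (default TRUE).
#'   With FALSE every mutated track is eligible.
#' @param calib_reps,calib_alpha,calib_stable Calibration protocol (see
#'   [calibrate_min_mutations()]).
#' @param calib_max_n Largest mutation count probed during calibration;
#'   default: the track's observed mutation count (larger n* could never be
#'   met anyway), capped at 500.
#' @param subsample Whole-gene subsample factor s; default `1/sqrt(n)`.
#' @param seed Integer seed controlling calibration draws.
#' @param cache_dir Optional directory for the calibration cache.
#' @return An object of class `gene_results`: list with `genes` (data frame:
#'   `gene`, `best_isoform`, `combined_z`, `n_tracks_included`,
#'   `n_mutations`, ordered by decreasing score) and `tracks` (per-track
#'   breakdown: gene, isoform, track_id, group, ligand, z, n, m, min_n,
#'   included).
#' @export
score_cohort <- function(tracks, mutations,
                         lambda = NULL, natvar = NULL,
                         expression = NULL, expression_threshold = 0.1,
                         positive_only = TRUE,
                         weight_rule = c("sqrt", "linear"),
                         calibrate = TRUE, calib_reps = 1000L,
                         calib_max_n = NULL, calib_alpha = 5e-5,
                         calib_stable = 3L,
                         subsample = NULL, seed = 1L, cache_dir = NULL) {
  weight_rule <- match.arg(weight_rule)
  mutations <- normalize_mutations(mutations)
  if (!is.null(expression))
    mutations <- expression_filter(mutations, expression,
                                   threshold = expression_threshold)
  mis <- mutations[mutations$mutation_class == "missense", , drop = FALSE]
  iso_of <- vapply(tracks, `[[`, character(1), "isoform_id")
  gene_of_iso <- tapply(mis$gene, mis$isoform, function(g) g[1])
  isoforms <- intersect(unique(mis$isoform), unique(iso_of))
  total_n <- nrow(mis)
  breakdown <- list()
  iso_scores <- list()
  track_seed_base <- as.integer(seed %% 2147480000L)
  for (iso in isoforms) {
    tr <- tracks[iso_of == iso]
    lam <- if (!is.null(lambda) && iso %in% names(lambda)) lambda[[iso]] else NULL
    mut_iso <- mis[mis$isoform == iso, , drop = FALSE]
    pre <- precompute_tracks(tr, lam)
    batch <- score_batch(pre, mut_iso)
    stats <- batch$stats
    min_n <- rep(1, length(tr))
    if (calibrate) {
      for (i in seq_along(tr)) {
        obs_n <- stats[[i]]$n
        if (obs_n == 0L) { min_n[i] <- Inf; next }
        cap <- if (is.null(calib_max_n)) min(obs_n, 500L) else calib_max_n
        cal <- calibration_cached(
          tr[[i]], rescale_for_track(lam, tr[[i]]),
          reps = calib_reps, max_n = cap, alpha = calib_alpha,
          stable = calib_stable,
          seed = (track_seed_base + i * 97L) %% 2147483647L,
          cache_dir = cache_dir)
        min_n[i] <- if (cal$never_normal) Inf else cal$min_n
      }
    }
    gene <- unname(gene_of_iso[[iso]])
    gs <- if (!is.null(natvar)) whole_gene_z(gene, mis, natvar, s = subsample)
          else NULL
    comb <- combine_isoform(tr, stats, batch$cor, gene_stats = gs,
                            min_n = min_n, positive_only = positive_only,
                            weight_rule = weight_rule)
    iso_scores[[gene]] <- c(iso_scores[[gene]],
                            setNames(comb$combined_z, iso))
    all_stats <- c(stats, if (!is.null(gs)) list(gs))
    inc <- c(comb$included,
             if (!is.null(gs)) !is.na(gs$z) && (!positive_only || gs$z > 0))
    breakdown[[iso]] <- data.frame(
      gene = gene, isoform = iso,
      track_id = vapply(all_stats, `[[`, character(1), "track_id"),
      group = vapply(all_stats, `[[`, character(1), "group"),
      ligand = vapply(all_stats, `[[`, character(1), "ligand"),
      z = vapply(all_stats, `[[`, numeric(1), "z"),
      n = vapply(all_stats, `[[`, numeric(1), "n"),
      m = vapply(all_stats, `[[`, numeric(1), "m"),
      min_n = c(min_n, if (!is.null(gs)) 1),
      included = inc,
      stringsAsFactors = FALSE)
  }
  genes <- names(iso_scores)
  res <- lapply(iso_scores, score_gene)
  bd <- do.call(rbind, c(breakdown, list(make.row.names = FALSE)))
  n_mut <- table(mis$gene)
  out <- data.frame(
    gene = genes,
    best_isoform = vapply(res, `[[`, character(1), "best_isoform"),
    combined_z = vapply(res, `[[`, numeric(1), "combined_z"),
    n_tracks_included = vapply(genes, function(g)
      sum(bd$included[bd$gene == g]), numeric(1)),
    n_mutations = as.integer(n_mut[genes]),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$combined_z, out$gene, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(genes = out, tracks = bd, total_mutations = total_n),
            class = "gene_results")
}

#' @export
print.gene_results <- function(x, ...) {
  cat(sprintf("<gene_results> %d genes scored (%d missense mutations)\n",
              nrow(x$genes), x$total_mutations))
  print(head(x$genes, 10))
  if (nrow(x$genes) > 10) cat("...\n")
  invisible(x)
}

#' Write gene results to a tab-separated file
#'
#' One row per gene: `gene`, `best_isoform`, `combined_Z`, and the per-track
#' breakdown of the best isoform serialized as
#' `group:ligand:track_id=Z;n` entries joined by `"|"`.
#'
#' @param results A [score_cohort()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(inherits(results, "gene_results"))
  g <- results$genes
  ser <- vapply(seq_len(nrow(g)), function(i) {
    b <- results$tracks[results$tracks$gene == g$gene[i] &
                          results$tracks$isoform == g$best_isoform[i], ,
                        drop = FALSE]
    if (nrow(b) == 0L) return("")
    paste(sprintf("%s:%s:%s=%.6g;%d", b$group,
                  ifelse(is.na(b$ligand), ".", b$ligand),
                  b$track_id, b$z, b$n), collapse = "|")
  }, character(1))
  df <- data.frame(gene = g$gene, best_isoform = g$best_isoform,
                   combined_Z = g$combined_z, tracks = ser,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene results table written by [write_results()]
#'
#' @param path File path.
#' @return Data frame with `gene`, `best_isoform`, `combined_Z`, `tracks`.
#' @export
read_results <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
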