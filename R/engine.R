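#' @title Analytic per-track scoring engine
#' @description Closed-form per-track score moments, Z scores, and
#'   between-track covariances under a per-position background mutation
#'   model, plus the precompute-and-scale fast path.
#' @name analytic-engine
NULL

# missense mutations of a track's isoform that land in the track's position
# set W (0-weight positions of W still count toward n and sum_f)
missense_in_track <- function(track, mutations) {
  m <- mutations
  if ("isoform" %in% names(m))
    m <- m[m$isoform == track$isoform_id, , drop = FALSE]
  if ("mutation_class" %in% names(m))
    m <- m[m$mutation_class == "missense", , drop = FALSE]
  m <- m[m$protein_position %in% track$positions, , drop = FALSE]
  if (!"f" %in% names(m)) m$f <- 1
  m$f[is.na(m$f)] <- 1
  m
}

track_weight_at <- function(track, positions) {
  track$weights[match(positions, track$positions)]
}

#' Score of the observed mutations with respect to a track
#'
#' `S_W = sum_i f_i * z_i`, where `z_i` is the track weight at mutation i's
#' position and `f_i` its subclonal fraction. Only missense mutations at the
#' track's positions contribute; an empty set scores 0.
#'
#' @param track A [functional_track()].
#' @param mutations Data frame of mutations (see [read_mutations()] for
#'   columns); missing `f` defaults to 1.
#' @return Numeric score.
#' @export
track_score <- function(track, mutations) {
  m <- missense_in_track(track, mutations)
  if (nrow(m) == 0L) return(0)
  sum(m$f * track_weight_at(track, m$protein_position))
}

#' Unit moments of a track under its background
#'
#' For one mutation with f = 1, the expected track weight and its variance
#' under the track background: `C_E = sum_j lambda_j^W w_j` and
#' `C_V = sum_j lambda_j^W w_j^2 - C_E^2`. The score moments for any mutation
#' set then scale as `E[S_W] = C_E * sum(f)` and `var(S_W) = C_V * sum(f^2)`.
#'
#' @param track A [functional_track()].
#' @param lambda_w Track-level background from [rescale_for_track()].
#' @return List with `c_e`, `c_v`, and `degenerate` (TRUE when `c_v` is 0, in
#'   which case the Z score is undefined).
#' @export
track_moments <- function(track, lambda_w) {
  if (length(lambda_w) != length(track$positions))
    stop("lambda_w must be parallel to the track positions")
  if (abs(sum(lambda_w) - 1) > 1e-8)
    stop("lambda_w must sum to 1 (use rescale_for_track)")
  c_e <- sum(lambda_w * track$weights)
  c_v <- max(sum(lambda_w * track$weights^2) - c_e^2, 0)
  list(c_e = c_e, c_v = c_v, degenerate = c_v <= 1e-15)
}

#' Per-track score statistics for an observed mutation set
#'
#' Computes the observed score, its closed-form expectation and standard
#' deviation under the track background, and the resulting Z score,
#' conditional on the mutations observed to fall in the track.
#'
#' @inheritParams track_moments
#' @param mutations Data frame of mutations.
#' @return An object of class `track_statistics`: list with `track_id`,
#'   `group`, `ligand`, `s_w` (score), `e_s`, `sd_s`, `z` (`NA` when the
#'   standard deviation is 0), `n` (mutations in the track), `m` (mutations at
#'   positively weighted positions), `sum_f`, `sum_f2`, and the unit constants
#'   `c_e`, `c_v`.
#' @export
track_statistics <- function(track, lambda_w, mutations) {
  mom <- track_moments(track, lambda_w)
  m <- missense_in_track(track, mutations)
  w_at <- if (nrow(m)) track_weight_at(track, m$protein_position) else numeric(0)
  sum_f <- sum(m$f)
  sum_f2 <- sum(m$f^2)
  sd_s <- sqrt(mom$c_v * sum_f2)
  s_w <- sum(m$f * w_at)
  structure(list(
    track_id = track$track_id, group = track$group, ligand = track$ligand,
    s_w = s_w,
    e_s = mom$c_e * sum_f,
    sd_s = sd_s,
    z = if (sd_s > 0) (s_w - mom$c_e * sum_f) / sd_s else NA_real_,
    n = nrow(m),
    m = sum(w_at > 0),
    sum_f = sum_f, sum_f2 = sum_f2,
    c_e = mom$c_e, c_v = mom$c_v),
    class = "track_statistics")
}

#' Z score from track statistics
#'
#' `Z_W = (S_W - E[S_W]) / sd(S_W)`; errors when the score variance is zero.
#'
#' @param stats A `track_statistics` object from [track_statistics()].
#' @return Numeric Z score.
#' @export
track_zscore <- function(stats) {
  stopifnot(inherits(stats, "track_statistics"))
  if (!is.finite(stats$sd_s) || stats$sd_s <= 0)
    stop("Z undefined: track score has zero variance (degenerate track or no mutations)")
  (stats$s_w - stats$e_s) / stats$sd_s
}

#' @export
print.track_statistics <- function(x, ...) {
  cat(sprintf("<track_statistics> %s (%s): S=%.4g E=%.4g sd=%.4g Z=%s n=%d m=%d\n",
              x$track_id, x$group, x$s_w, x$e_s, x$sd_s,
              if (is.na(x$z)) "NA" else sprintf("%.3f", x$z), x$n, x$m))
  invisible(x)
}

#' Between-track covariance of two track scores
#'
#' Tracks sharing positions are scored by overlapping mutation sets, so their
#' scores covary. Conditional on the q mutations observed in the overlap
#' X = V intersect W, with `F = sum of f^2` over those mutations,
#' `cov(S_V, S_W) = F * (sum_j lambda_j^X v_j w_j -
#' (sum_j lambda_j^X v_j)(sum_j lambda_j^X w_j))`, where `lambda^X` is the
#' background restricted to X and renormalized. Disjoint tracks have
#' covariance 0.
#'
#' @param v,w [functional_track()]s on the same isoform.
#' @param lambda Per-position background over the whole protein (`NULL` for
#'   uniform).
#' @param mutations Data frame of mutations.
#' @return An object of class `overlap_statistics`: list with `positions`
#'   (the overlap X), `q`, `f2` (F), `cov`, `cor` (0 when either score has
#'   zero variance), and the unit constant `c_cov` such that
#'   `cov = c_cov * F`.
#' @export
track_covariance <- function(v, w, lambda, mutations) {
  if (v$isoform_id != w$isoform_id)
    stop("tracks must belong to the same isoform")
  x <- intersect(v$positions, w$positions)
  if (length(x) == 0L)
    return(structure(list(positions = integer(0), q = 0L, f2 = 0,
                          c_cov = 0, cov = 0, cor = 0),
                     class = "overlap_statistics"))
  lam_x <- if (is.null(lambda)) rep(1 / length(x), length(x)) else {
    lx <- lambda[x]
    if (sum(lx) <= 0)
      stop("degenerate background over the track overlap")
    lx / sum(lx)
  }
  vj <- track_weight_at(v, x)
  wj <- track_weight_at(w, x)
  c_cov <- sum(lam_x * vj * wj) - sum(lam_x * vj) * sum(lam_x * wj)
  mm <- missense_in_track(v, mutations)
  mm <- mm[mm$protein_position %in% x, , drop = FALSE]
  f2 <- sum(mm$f^2)
  cv <- c_cov * f2
  sv <- track_statistics(v, rescale_for_track(lambda, v), mutations)
  sw <- track_statistics(w, rescale_for_track(lambda, w), mutations)
  r <- if (sv$sd_s > 0 && sw$sd_s > 0) cv / (sv$sd_s * sw$sd_s) else 0
  structure(list(positions = x, q = nrow(mm), f2 = f2, c_cov = c_cov,
                 cov = cv, cor = min(max(r, -1), 1)),
            class = "overlap_statistics")
}

#' Precompute per-track unit constants and pairwise covariance constants
#'
#' Expectation, variance and covariance all factor as a track-fixed constant
#' times `sum(f)` or `sum(f^2)` over the observed mutations. Precomputing the
#' constants once per track set lets cohorts be scored by cheap rescaling
#' (see [score_batch()]).
#'
#' @param tracks List of [functional_track()]s on one isoform.
#' @param lambda Per-position background over the protein (`NULL` = uniform).
#' @return An object of class `track_precompute`.
#' @export
precompute_tracks <- function(tracks, lambda = NULL) {
  iso <- unique(vapply(tracks, `[[`, character(1), "isoform_id"))
  if (length(iso) != 1L) stop("all tracks must share one isoform")
  k <- length(tracks)
  mom <- lapply(tracks, function(t) track_moments(t, rescale_for_track(lambda, t)))
  c_cov <- matrix(0, k, k)
  overlap <- vector("list", k * (k - 1) / 2)
  idx <- 0L
  if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k) {
    x <- intersect(tracks[[i]]$positions, tracks[[j]]$positions)
    cc <- 0
    if (length(x)) {
      lam_x <- if (is.null(lambda)) rep(1 / length(x), length(x)) else
        lambda[x] / sum(lambda[x])
      vj <- track_weight_at(tracks[[i]], x)
      wj <- track_weight_at(tracks[[j]], x)
      cc <- sum(lam_x * vj * wj) - sum(lam_x * vj) * sum(lam_x * wj)
    }
    c_cov[i, j] <- c_cov[j, i] <- cc
    idx <- idx + 1L
    overlap[[idx]] <- list(i = i, j = j, positions = x)
  }
  structure(list(tracks = tracks, lambda = lambda,
                 c_e = vapply(mom, `[[`, numeric(1), "c_e"),
                 c_v = vapply(mom, `[[`, numeric(1), "c_v"),
                 c_cov = c_cov, overlap = overlap[seq_len(idx)]),
            class = "track_precompute")
}

#' Score a mutation batch against precomputed tracks
#'
#' Scales the precomputed unit constants by the observed `sum(f)` and
#' `sum(f^2)` per track (and per pairwise overlap), reproducing the direct
#' evaluation of the closed forms to numerical precision.
#'
#' @param pre A [precompute_tracks()] object.
#' @param mutations Data frame of mutations.
#' @return List with `stats` (list of `track_statistics`) and `cov` / `cor`
#'   (matrices over the track set).
#' @export
score_batch <- function(pre, mutations) {
  stopifnot(inherits(pre, "track_precompute"))
  k <- length(pre$tracks)
  stats <- vector("list", k)
  for (i in seq_len(k)) {
    t <- pre$tracks[[i]]
    m <- missense_in_track(t, mutations)
    w_at <- if (nrow(m)) track_weight_at(t, m$protein_position) else numeric(0)
    sum_f <- sum(m$f); sum_f2 <- sum(m$f^2)
    sd_s <- sqrt(pre$c_v[i] * sum_f2)
    s_w <- sum(m$f * w_at)
    stats[[i]] <- structure(list(
      track_id = t$track_id, group = t$group, ligand = t$ligand,
      s_w = s_w, e_s = pre$c_e[i] * sum_f, sd_s = sd_s,
      z = if (sd_s > 0) (s_w - pre$c_e[i] * sum_f) / sd_s else NA_real_,
      n = nrow(m), m = sum(w_at > 0), sum_f = sum_f, sum_f2 = sum_f2,
      c_e = pre$c_e[i], c_v = pre$c_v[i]), class = "track_statistics")
  }
  cv <- matrix(0, k, k)
  for (ov in pre$overlap) {
    if (length(ov$positions) == 0L) next
    t <- pre$tracks[[ov$i]]
    m <- missense_in_track(t, mutations)
    m <- m[m$protein_position %in% ov$positions, , drop = FALSE]
    cv[ov$i, ov$j] <- cv[ov$j, ov$i] <- pre$c_cov[ov$i, ov$j] * sum(m$f^2)
  }
  diag(cv) <- vapply(stats, function(s) s$sd_s^2, numeric(1))
  sds <- sqrt(diag(cv))
  cr <- diag(1, k)
  if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k) {
    r <- if (sds[i] > 0 && sds[j] > 0) cv[i, j] / (sds[i] * sds[j]) else 0
    cr[i, j] <- cr[j, i] <- min(max(r, -1), 1)
  }
  ids <- vapply(pre$tracks, `[[`, character(1), "track_id")
  dimnames(cv) <- dimnames(cr) <- list(ids, ids)
  list(stats = stats, cov = cv, cor = cr)
}

# Literal per-mutation evaluation of the expectation/variance sums, used to
# verify that the precompute-and-scale path is an exact algebraic rewrite.
track_moments_direct <- function(track, lambda_w, mutations) {
  m <- missense_in_track(track, mutations)
  e_z <- sum(lambda_w * track$weights)
  v_z <- sum(lambda_w * track$weights^2) - e_z^2
  e_s <- 0; var_s <- 0
  for (i in seq_len(nrow(m))) {
    e_s <- e_s + m$f[i] * e_z
    var_s <- var_s + m$f[i]^2 * v_z
  }
  list(e_s = e_s, var_s = max(var_s, 0))
}
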