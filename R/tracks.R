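#' Construct a functional track
#'
#' A track is a set of 1-based protein positions, each carrying a
#' functionality weight in \[0,1\]: ligand-binding frequencies for
#' `interaction` tracks, 0/1 membership for `domain` tracks, conservation
#' scores for `conservation` tracks, or a one-hot gene encoding for
#' `natural_variation` tracks.
#'
#' @param track_id Unique track identifier. By convention the domain family
#'   identifier is the part before the first `"|"` (see [track_family()]).
#' @param isoform_id Protein isoform the positions refer to.
#' @param group One of `"interaction"`, `"domain"`, `"conservation"`,
#'   `"natural_variation"`.
#' @param positions Integer vector of unique 1-based protein positions (the
#'   set W).
#' @param weights Numeric vector in \[0,1\], parallel to `positions`.
#' @param protein_length Protein length L; all positions must lie in \[1, L\].
#' @param ligand Optional ligand label (interaction tracks).
#' @param min_mutation_count Optional calibrated minimum mutation count n*
#'   (see [calibrate_min_mutations()]).
#' @return An object of class `functional_track`.
#' @seealso [build_interaction_track()], [build_domain_track()],
#'   [build_aggregate_tracks()], [conservation_track()]
#' @export
functional_track <- function(track_id, isoform_id, group, positions, weights,
                             protein_length, ligand = NULL,
                             min_mutation_count = NULL) {
  group <- match.arg(group, track_groups())
  positions <- as.integer(positions)
  weights <- as.numeric(weights)
  if (length(positions) == 0L)
    stop("track '", track_id, "': at least one position is required")
  if (length(positions) != length(weights))
    stop("track '", track_id, "': positions and weights differ in length")
  if (anyDuplicated(positions))
    stop("track '", track_id, "': positions must be unique")
  if (!is.numeric(protein_length) || length(protein_length) != 1L ||
      protein_length < 1)
    stop("track '", track_id, "': protein_length must be a positive integer")
  protein_length <- as.integer(protein_length)
  if (any(positions < 1L) || any(positions > protein_length))
    stop("track '", track_id, "': positions outside [1, ", protein_length,
         "]", call. = FALSE)
  if (anyNA(weights) || any(weights < 0) || any(weights > 1))
    stop("track '", track_id, "': weights must lie in [0, 1]")
  if (group == "domain" && !all(weights %in% c(0, 1)))
    stop("track '", track_id, "': domain-group tracks require 0/1 weights")
  ord <- order(positions)
  structure(
    list(track_id = as.character(track_id),
         isoform_id = as.character(isoform_id),
         group = group,
         ligand = if (is.null(ligand) || is.na(ligand) || ligand == ".")
           NA_character_ else as.character(ligand),
         positions = positions[ord],
         weights = weights[ord],
         protein_length = protein_length,
         min_mutation_count = min_mutation_count),
    class = "functional_track")
}

track_groups <- function() {
  c("interaction", "domain", "conservation", "natural_variation")
}

#' @export
print.functional_track <- function(x, ...) {
  cat(sprintf("<functional_track> %s (%s%s) isoform %s\n",
              x$track_id, x$group,
              if (!is.na(x$ligand)) paste0(", ligand ", x$ligand) else "",
              x$isoform_id))
  cat(sprintf("  %d weighted positions on protein of length %d; weights in [%.3g, %.3g]%s\n",
              length(x$positions), x$protein_length,
              min(x$weights), max(x$weights),
              if (is_degenerate_track(x)) " [degenerate]" else ""))
  invisible(x)
}

#' Is a track degenerate (constant weights)?
#'
#' A track whose weights take fewer than two distinct values has zero score
#' variance under any background, so its Z score is undefined and it is
#' excluded from combination.
#'
#' @param track A [functional_track()].
#' @return Logical.
#' @export
is_degenerate_track <- function(track) {
  length(unique(track$weights)) < 2L
}

#' Domain family identifier of a track
#'
#' Track ids built by this package are `"<family>|<qualifier>"`; the family is
#' the part before the first `"|"`. Used to pair domain tracks with the
#' interaction tracks of the same family in [mechanism_report()].
#'
#' @param track A [functional_track()] or a character track id.
#' @return Character family id.
#' @export
track_family <- function(track) {
  id <- if (inherits(track, "functional_track")) track$track_id else track
  sub("\\|.*$", "", id)
}

#' Construct a domain instance
#'
#' One hit of a domain family on a protein isoform: the 1-based positions of
#' its match states, optionally with per-state ligand binding frequencies.
#'
#' @param family_id Domain family identifier.
#' @param isoform_id Protein isoform.
#' @param positions Strictly increasing 1-based match-state positions.
#' @param binding Optional named list: ligand -> numeric vector of binding
#'   frequencies in \[0,1\], parallel to `positions`.
#' @return An object of class `domain_instance`.
#' @export
domain_instance <- function(family_id, isoform_id, positions, binding = NULL) {
  positions <- as.integer(positions)
  if (length(positions) == 0L)
    stop("domain instance requires at least one match-state position")
  if (is.unsorted(positions, strictly = TRUE))
    stop("match-state positions must be strictly increasing")
  if (any(positions < 1L))
    stop("match-state positions are 1-based and must be >= 1")
  if (!is.null(binding)) {
    if (is.null(names(binding)) || any(!nzchar(names(binding))))
      stop("binding frequencies must be a named list (ligand -> values)")
    for (lig in names(binding)) {
      bf <- binding[[lig]]
      if (length(bf) != length(positions))
        stop("binding frequencies for ligand '", lig,
             "' do not match the number of match states")
      if (anyNA(bf) || any(bf < 0) || any(bf > 1))
        stop("binding frequencies must lie in [0, 1]")
    }
  }
  structure(list(family_id = as.character(family_id),
                 isoform_id = as.character(isoform_id),
                 positions = positions,
                 binding = binding),
            class = "domain_instance")
}

#' Build an interaction track from a domain instance
#'
#' The track consists of the residues at the instance's match states, weighted
#' by the per-state binding frequencies for one ligand.
#'
#' @param instance A [domain_instance()] carrying binding frequencies.
#' @param ligand Ligand whose binding frequencies to use.
#' @param protein_length Protein length L.
#' @return A [functional_track()] of group `"interaction"`.
#' @export
build_interaction_track <- function(instance, ligand, protein_length) {
  stopifnot(inherits(instance, "domain_instance"))
  if (is.null(instance$binding) || !ligand %in% names(instance$binding))
    stop("no binding frequencies for ligand '", ligand, "' in family '",
         instance$family_id, "'", call. = FALSE)
  functional_track(
    track_id = paste(instance$family_id, min(instance$positions), ligand,
                     sep = "|"),
    isoform_id = instance$isoform_id,
    group = "interaction",
    positions = instance$positions,
    weights = instance$binding[[ligand]],
    protein_length = protein_length,
    ligand = ligand)
}

#' Build a 0/1 domain track from a domain instance
#'
#' The track spans the whole protein; positions inside the instance get
#' weight 1 and all others weight 0.
#'
#' @inheritParams build_interaction_track
#' @return A [functional_track()] of group `"domain"`.
#' @export
build_domain_track <- function(instance, protein_length) {
  stopifnot(inherits(instance, "domain_instance"))
  if (max(instance$positions) > protein_length)
    stop("match-state position ", max(instance$positions),
         " exceeds protein length ", protein_length, call. = FALSE)
  w <- numeric(protein_length)
  w[instance$positions] <- 1
  functional_track(
    track_id = paste(instance$family_id, min(instance$positions), sep = "|"),
    isoform_id = instance$isoform_id,
    group = "domain",
    positions = seq_len(protein_length),
    weights = w,
    protein_length = protein_length)
}

#' Build per-family tracks with aggregates for repeated families
#'
#' Domain families often repeat within a protein, and some interfaces are
#' mediated by the repeat as a whole rather than by single instances. For
#' every family with >= 2 instances an aggregate track is emitted whose
#' positions are the union of the instance positions (overlaps resolved by
#' maximum weight). When a family repeats at least `replace_threshold` times,
#' the individual per-instance tracks are suppressed and only the aggregate is
#' kept.
#'
#' @param instances List of [domain_instance()]s on one isoform.
#' @param protein_length Protein length L.
#' @param group `"interaction"` or `"domain"`: which kind of tracks to build.
#' @param ligand Ligand to use when `group = "interaction"`; instances lacking
#'   binding frequencies for it are skipped.
#' @param replace_threshold Instance count at and above which individual
#'   tracks are replaced by the aggregate (default 40).
#' @return List of [functional_track()]s (individual tracks followed by
#'   aggregates).
#' @export
build_aggregate_tracks <- function(instances, protein_length,
                                   group = c("interaction", "domain"),
                                   ligand = NULL, replace_threshold = 40L) {
  group <- match.arg(group)
  stopifnot(all(vapply(instances, inherits, logical(1), "domain_instance")))
  if (group == "interaction" && is.null(ligand))
    stop("interaction aggregates require a ligand")
  fams <- vapply(instances, `[[`, character(1), "family_id")
  out <- list()
  for (fam in unique(fams)) {
    inst <- instances[fams == fam]
    if (group == "interaction") {
      inst <- Filter(function(i) !is.null(i$binding) &&
                       ligand %in% names(i$binding), inst)
      if (length(inst) == 0L) next
    }
    singles <- lapply(inst, function(i) {
      if (group == "interaction")
        build_interaction_track(i, ligand, protein_length)
      else build_domain_track(i, protein_length)
    })
    tracks <- if (length(inst) >= replace_threshold) list() else singles
    if (length(inst) >= 2L) {
      agg_w <- numeric(protein_length)
      for (i in inst) {
        w <- if (group == "interaction") i$binding[[ligand]]
             else rep(1, length(i$positions))
        # overlapping instances: keep the strongest binding signal
        agg_w[i$positions] <- pmax(agg_w[i$positions], w)
      }
      pos <- sort(unique(unlist(lapply(inst, `[[`, "positions"))))
      tracks <- c(tracks, list(functional_track(
        track_id = paste(fam, "agg",
                         if (group == "interaction") ligand else NULL,
                         sep = "|"),
        isoform_id = inst[[1]]$isoform_id,
        group = group,
        positions = if (group == "domain") seq_len(protein_length) else pos,
        weights = if (group == "domain") as.numeric(agg_w > 0) else agg_w[pos],
        protein_length = protein_length,
        ligand = ligand)))
    }
    out <- c(out, tracks)
  }
  out
}

#' Background amino-acid frequencies of the BLOSUM62 substitution data
#'
#' Standard marginal frequencies of the 20 amino acids underlying the
#' BLOSUM62 matrix; used as the background distribution for conservation
#' weights. Sums to 1 exactly.
#'
#' @return Named numeric vector over the 20 standard amino acids.
#' @export
blosum62_background <- function() {
  c(A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025,
    Q = 0.034, E = 0.054, G = 0.074, H = 0.026, I = 0.068,
    L = 0.099, K = 0.058, M = 0.025, F = 0.047, P = 0.039,
    S = 0.057, T = 0.051, W = 0.013, Y = 0.032, V = 0.073)
}

#' Jensen-Shannon divergence (base 2, equal mixture weights)
#'
#' Symmetric divergence between two probability distributions, bounded in
#' \[0,1\] in base 2: `JSD(p, q) = H(m) - (H(p) + H(q))/2` with
#' `m = (p + q)/2`.
#'
#' @param p,q Probability vectors summing to 1. If both are named, they are
#'   aligned by name (missing categories get probability 0).
#' @return Divergence in \[0, 1\].
#' @export
jensen_shannon <- function(p, q) {
  if (!is.null(names(p)) && !is.null(names(q))) {
    keys <- union(names(p), names(q))
    p <- setNames(p[keys], keys); p[is.na(p)] <- 0
    q <- setNames(q[keys], keys); q[is.na(q)] <- 0
  }
  if (length(p) != length(q))
    stop("p and q must have the same categories")
  if (any(p < 0) || any(q < 0)) stop("probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8)
    stop("p and q must each sum to 1")
  m <- (p + q) / 2
  h <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  d <- h(m) - (h(p) + h(q)) / 2
  min(max(d, 0), 1)
}

#' Construct an alignment column for conservation scoring
#'
#' @param column_index 1-based protein position the column maps to.
#' @param residue_counts Named nonnegative integer counts of amino acids
#'   observed in the column (names from the 20 standard residues).
#' @param gap_count Nonnegative count of gap rows.
#' @return An object of class `conservation_column`.
#' @export
conservation_column <- function(column_index, residue_counts, gap_count = 0L) {
  if (length(residue_counts) && is.null(names(residue_counts)))
    stop("residue_counts must be named by amino acid")
  if (any(residue_counts < 0) || gap_count < 0)
    stop("counts must be nonnegative")
  if (sum(residue_counts) + gap_count == 0)
    stop("empty column: no residues and no gaps")
  structure(list(column_index = as.integer(column_index),
                 residue_counts = residue_counts,
                 gap_count = as.integer(gap_count)),
            class = "conservation_column")
}

#' Conservation weight of an alignment column
#'
#' The weight is the fraction of non-gap rows multiplied by the base-2
#' Jensen-Shannon divergence between the column's residue distribution and a
#' background amino-acid distribution (default: BLOSUM62 marginals). All-gap
#' columns get weight 0; a column distributed exactly like the background gets
#' weight 0.
#'
#' @param column A [conservation_column()].
#' @param background Named amino-acid probability vector summing to 1.
#' @return Weight in \[0, 1\].
#' @export
conservation_weight <- function(column, background = blosum62_background()) {
  stopifnot(inherits(column, "conservation_column"))
  if (abs(sum(background) - 1) > 1e-8)
    stop("background must sum to 1")
  n_res <- sum(column$residue_counts)
  total <- n_res + column$gap_count
  if (n_res == 0) return(0)
  p <- column$residue_counts / n_res
  (n_res / total) * jensen_shannon(p, background)
}

#' Build a conservation track from a multiple sequence alignment
#'
#' The first alignment row is the reference isoform; alignment columns where
#' the reference is non-gap map, in order, to protein positions 1..L. Each
#' such column is scored with [conservation_weight()] over all rows.
#' Non-standard residue letters (X, B, Z, U, O, *) are treated as gaps.
#'
#' @param alignment An `AAStringSet`/`character` of aligned sequences of equal
#'   length (first = reference), or the path of an aligned FASTA file.
#' @param isoform_id Isoform id for the resulting track.
#' @param background Background amino-acid distribution.
#' @return A [functional_track()] of group `"conservation"` spanning the
#'   reference protein.
#' @export
conservation_track <- function(alignment, isoform_id,
                               background = blosum62_background()) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment))
    alignment <- Biostrings::readAAStringSet(alignment)
  seqs <- toupper(as.character(alignment))
  if (length(seqs) < 1L) stop("alignment has no sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences must all have the same length")
  mat <- do.call(rbind, strsplit(seqs, ""))
  aa <- names(background)
  ref_cols <- which(mat[1, ] %in% aa)
  if (length(ref_cols) == 0L)
    stop("reference row contains no standard residues")
  w <- vapply(ref_cols, function(j) {
    col <- mat[, j]
    counts <- table(factor(col[col %in% aa], levels = aa))
    gaps <- sum(!col %in% aa)
    conservation_weight(
      conservation_column(j, setNames(as.integer(counts), aa), gaps),
      background)
  }, numeric(1))
  functional_track(
    track_id = "conservation|msa",
    isoform_id = isoform_id,
    group = "conservation",
    positions = seq_along(ref_cols),
    weights = w,
    protein_length = length(ref_cols))
}

#' Read tracks from a tab-separated annotation file
#'
#' One row per track with columns `isoform_id`, `track_id`, `group`, `ligand`
#' (`"."` for none), `protein_length`, and semicolon-joined `position:weight`
#' pairs (e.g. `"11:0.9;12:0.3"`). Coordinates are 1-based protein positions.
#'
#' @param path File path.
#' @return List of [functional_track()]s.
#' @export
read_tracks <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("isoform_id", "track_id", "group", "ligand", "protein_length",
            "pos_weights")
  if (!all(need %in% names(df)))
    stop("track file must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    pw <- strsplit(strsplit(df$pos_weights[i], ";", fixed = TRUE)[[1]],
                   ":", fixed = TRUE)
    functional_track(
      track_id = df$track_id[i], isoform_id = df$isoform_id[i],
      group = df$group[i], ligand = df$ligand[i],
      positions = vapply(pw, function(x) as.integer(x[1]), integer(1)),
      weights = vapply(pw, function(x) as.numeric(x[2]), numeric(1)),
      protein_length = df$protein_length[i])
  })
}

#' Write tracks to the tab-separated annotation format
#'
#' @param tracks List of [functional_track()]s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_tracks()] for the format.
#' @export
write_tracks <- function(tracks, path) {
  rows <- vapply(tracks, function(t) {
    paste(t$isoform_id, t$track_id, t$group,
          if (is.na(t$ligand)) "." else t$ligand, t$protein_length,
          paste(sprintf("%d:%.10g", t$positions, t$weights), collapse = ";"),
          sep = "\t")
  }, character(1))
  writeLines(c(paste("isoform_id", "track_id", "group", "ligand",
                     "protein_length", "pos_weights", sep = "\t"), rows),
             path)
  invisible(path)
}
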