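#' Configuration for a synthetic tumor cohort
#'
#' Describes a cohort of synthetic proteins with interaction, domain and
#' conservation tracks, a per-position background mutation model, and somatic
#' missense mutations drawn either from the background (null genes) or from a
#' background tilted toward high-weight functional sites (driver genes).
#'
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param n_genes Number of genes (one isoform each).
#' @param n_drivers Number of driver genes among them.
#' @param protein_length Length range, drawn uniformly per gene.
#' @param n_interaction,n_domain Interaction / domain-family instances per
#'   gene (each family contributes one interaction and one domain track).
#' @param weight_dist Interaction-weight distribution: `"beta"` (shape
#'   `beta_shape`), `"uniform"`, or `"binary"` (0/1 with probability 0.3 of 1).
#' @param beta_shape Two shape parameters for the beta weight distribution.
#' @param background `"codon"` (random coding sequence, mutabilities from the
#'   codon model with bias `b`) or `"uniform"`.
#' @param b C/G bias factor for the codon background.
#' @param effect Enrichment multiplier (>= 1) applied to the background mass
#'   of positions whose interaction weight is at least `effect_cutoff`, in
#'   driver genes. 1 = null cohort.
#' @param effect_cutoff Weight cutoff defining high-weight sites.
#' @param mutations_per_gene Missense mutations drawn per gene.
#' @param f_dist Subclonal fraction distribution: `"uniform"` on `f_range`
#'   (plausible read-support fractions) or `"one"` (all f = 1).
#' @param f_range Range for the uniform f distribution.
#' @param n_samples Number of tumor sample ids mutations are attributed to.
#' @param n_individuals Healthy individuals for the variant-count table
#'   (natural-variation background); 0 disables it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_genes = 100L, n_drivers = 0L,
                             protein_length = c(150L, 400L),
                             n_interaction = 2L, n_domain = 1L,
                             weight_dist = c("beta", "uniform", "binary"),
                             beta_shape = c(2, 2),
                             background = c("codon", "uniform"), b = 3.063,
                             effect = 1, effect_cutoff = 0.5,
                             mutations_per_gene = 30L,
                             f_dist = c("uniform", "one"),
                             f_range = c(0.2, 1),
                             n_samples = 50L, n_individuals = 0L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_drivers = as.integer(n_drivers),
              protein_length = as.integer(protein_length),
              n_interaction = as.integer(n_interaction),
              n_domain = as.integer(n_domain),
              weight_dist = match.arg(weight_dist),
              beta_shape = beta_shape,
              background = match.arg(background), b = b,
              effect = effect, effect_cutoff = effect_cutoff,
              mutations_per_gene = as.integer(mutations_per_gene),
              f_dist = match.arg(f_dist), f_range = f_range,
              n_samples = as.integer(n_samples),
              n_individuals = as.integer(n_individuals))
  if (cfg$n_drivers > cfg$n_genes) stop("n_drivers cannot exceed n_genes")
  if (cfg$effect < 1) stop("effect multiplier must be >= 1")
  if (length(cfg$protein_length) != 2L ||
      cfg$protein_length[1] > cfg$protein_length[2] ||
      cfg$protein_length[1] < 30L)
    stop("protein_length must be an increasing range with minimum >= 30")
  structure(cfg, class = "synthetic_config")
}

sense_codons <- function() {
  names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
}

draw_weights <- function(n, cfg) {
  switch(cfg$weight_dist,
         beta = rbeta(n, cfg$beta_shape[1], cfg$beta_shape[2]),
         uniform = runif(n),
         binary = as.numeric(runif(n) < 0.3))
}

#' Generate a synthetic cohort with known driver structure
#'
#' Builds, per gene, one isoform with interaction tracks (contiguous
#' domain-like regions with random binding weights), full-length 0/1 domain
#' tracks over the same regions, and a full-length conservation track; a
#' per-position background (codon-based or uniform); and
#' `mutations_per_gene` missense mutations whose positions are drawn from the
#' background (null genes) or from the background with `effect` times the
#' mass on positions whose interaction weight is at least `effect_cutoff`
#' (driver genes, chosen at random). Optionally also generates a healthy
#' variant-count table for the natural-variation background.
#'
#' @param config A [synthetic_config()].
#' @return List with `tracks` (list of [functional_track()]s), `mutations`
#'   (data frame), `truth` (data frame `gene`, `is_driver`), `lambda` (named
#'   list isoform -> per-position mutability), `cds` (named character, codon
#'   background only), `variant_counts` (matrix or `NULL`), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  isoforms <- sprintf("ISO%04d.1", seq_len(cfg$n_genes))
  drivers <- if (cfg$n_drivers > 0) sort(sample(genes, cfg$n_drivers)) else character(0)
  codons <- sense_codons()
  tracks <- list()
  lambda <- list()
  cds <- character(0)
  mut_rows <- vector("list", cfg$n_genes)
  samples <- sprintf("S%03d", seq_len(cfg$n_samples))
  for (gi in seq_len(cfg$n_genes)) {
    L <- sample(cfg$protein_length[1]:cfg$protein_length[2], 1L)
    iso <- isoforms[gi]
    gtracks <- list()
    # interaction + paired domain tracks over contiguous domain-like regions
    n_fam <- max(cfg$n_interaction, cfg$n_domain)
    for (k in seq_len(n_fam)) {
      dl <- sample(20:min(60L, L %/% 2), 1L)
      start <- sample.int(L - dl + 1L, 1L)
      pos <- start:(start + dl - 1L)
      fam <- sprintf("FAM%04d.%d", gi, k)
      inst <- domain_instance(fam, iso, pos,
                              binding = list(LIG = draw_weights(dl, cfg)))
      if (k <= cfg$n_interaction)
        gtracks <- c(gtracks, list(build_interaction_track(inst, "LIG", L)))
      if (k <= cfg$n_domain)
        gtracks <- c(gtracks, list(build_domain_track(inst, L)))
    }
    # conservation: full length, right-skewed continuous weights
    gtracks <- c(gtracks, list(functional_track(
      track_id = "conservation|sim", isoform_id = iso, group = "conservation",
      positions = seq_len(L), weights = rbeta(L, 1.5, 3),
      protein_length = L)))
    if (cfg$background == "codon") {
      cd <- sample(codons, L, replace = TRUE)
      cds[iso] <- paste(cd, collapse = "")
      lam <- position_lambda(cd, cfg$b)
    } else lam <- rep(1, L)
    lambda[[iso]] <- lam
    # driver genes: tilt background mass toward high-weight functional sites.
    # Sites are defined by the real-valued site-resolution tracks
    # (interaction, conservation); 0/1 domain tracks mark membership, not
    # per-site functional strength, and do not define sites.
    lam_eff <- lam
    if (genes[gi] %in% drivers && cfg$effect > 1) {
      w_max <- numeric(L)
      for (t in gtracks) if (t$group %in% c("interaction", "conservation"))
        w_max[t$positions] <- pmax(w_max[t$positions], t$weights)
      hi <- w_max >= cfg$effect_cutoff
      if (!any(hi))
        stop("impossible config: driver gene ", genes[gi],
             " has no positions with weight >= ", cfg$effect_cutoff)
      lam_eff[hi] <- lam_eff[hi] * cfg$effect
    }
    nm <- cfg$mutations_per_gene
    pos_m <- sample.int(L, nm, replace = TRUE, prob = lam_eff / sum(lam_eff))
    f <- if (cfg$f_dist == "one") rep(1, nm)
         else runif(nm, cfg$f_range[1], cfg$f_range[2])
    mut_rows[[gi]] <- data.frame(
      gene = genes[gi], isoform = iso, protein_position = pos_m,
      mutation_class = "missense", f = f,
      sample_id = sample(samples, nm, replace = TRUE),
      cancer_type = "PANCAN",
      codon = if (cfg$background == "codon")
        substring(cds[iso], 3L * (pos_m - 1L) + 1L, 3L * pos_m)
      else NA_character_,
      stringsAsFactors = FALSE)
    tracks <- c(tracks, gtracks)
  }
  variant_counts <- NULL
  if (cfg$n_individuals > 0) {
    mu <- exp(runif(cfg$n_genes, log(5), log(200)))  # gene-specific rates
    variant_counts <- matrix(
      rnbinom(cfg$n_individuals * cfg$n_genes,
              mu = rep(mu, each = cfg$n_individuals), size = 10),
      nrow = cfg$n_individuals, dimnames = list(NULL, genes))
  }
  list(tracks = tracks,
       mutations = do.call(rbind, mut_rows),
       truth = data.frame(gene = genes, is_driver = genes %in% drivers,
                          stringsAsFactors = FALSE),
       lambda = lambda,
       cds = if (cfg$background == "codon") cds else NULL,
       variant_counts = variant_counts,
       config = cfg)
}

#' Write a synthetic cohort to disk in the package's file dialects
#'
#' Emits `tracks.tsv` ([write_tracks()] format), `mutations.tsv`
#' ([read_mutations()] format), `truth.tsv`, and when present `cds.fasta`
#' (coding sequences) and `variant_counts.tsv`, so the full pipeline can be
#' run end-to-end from files.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tracks(cohort$tracks, file.path(dir, "tracks.tsv"))
  write.table(cohort$mutations, file.path(dir, "mutations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$cds))
    writeLines(as.vector(rbind(paste0(">", names(cohort$cds)), cohort$cds)),
               file.path(dir, "cds.fasta"))
  if (!is.null(cohort$variant_counts)) {
    vc <- data.frame(individual = sprintf("I%04d", seq_len(nrow(cohort$variant_counts))),
                     cohort$variant_counts, check.names = FALSE)
    write.table(vc, file.path(dir, "variant_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Monte-Carlo permutation oracle for the analytic moments
#'
#' Repeatedly assigns n mutations (with fixed subclonal fractions `f`) to
#' positions drawn from the background and recomputes every track's score.
#' The same position draw feeds all tracks containing that position, which is
#' what makes the empirical between-track covariances comparable to the
#' closed forms. Returns Monte-Carlo estimates with standard errors, for
#' checking the analytic expectation, standard deviation and covariance.
#'
#' @param tracks List of [functional_track()]s on one protein.
#' @param lambda Per-position background over the protein (`NULL` = uniform);
#'   draws are restricted to the union of track positions.
#' @param f Vector of subclonal fractions (length = number of mutations).
#' @param reps Number of shuffles (>= 1000).
#' @param seed Optional integer seed.
#' @return List with `universe` (positions sampled), per-track data frame
#'   `tracks` (`mean`, `se_mean`, `var`, `sd`, `se_sd`), matrices `cov`,
#'   `se_cov`, `cor`, and `reps`.
#' @export
permutation_oracle <- function(tracks, lambda = NULL, f, reps = 20000L,
                               seed = NULL) {
  if (reps < 1000L) stop("reps must be >= 1000")
  if (!is.null(seed)) set.seed(seed)
  universe <- sort(unique(unlist(lapply(tracks, `[[`, "positions"))))
  lam_u <- if (is.null(lambda)) rep(1, length(universe)) else lambda[universe]
  lam_u <- lam_u / sum(lam_u)
  n <- length(f)
  k <- length(tracks)
  idx <- sample.int(length(universe), n * reps, replace = TRUE, prob = lam_u)
  # zero-extended weight lookup over the sampling universe
  scores <- matrix(0, reps, k)
  for (t in seq_len(k)) {
    wt <- numeric(length(universe))
    hit <- match(tracks[[t]]$positions, universe)
    wt[hit] <- tracks[[t]]$weights
    scores[, t] <- as.vector(crossprod(matrix(wt[idx], n, reps), f))
  }
  mu <- colMeans(scores)
  ctr <- sweep(scores, 2, mu)
  vv <- colSums(ctr^2) / (reps - 1)
  m4 <- colMeans(ctr^4)
  se_var <- sqrt(pmax(m4 - vv^2, 0) / reps)
  sds <- sqrt(vv)
  se_sd <- ifelse(sds > 0, se_var / (2 * sds), 0)
  cv <- crossprod(ctr) / (reps - 1)
  se_cv <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    xy <- ctr[, i] * ctr[, j]
    se_cv[i, j] <- sqrt(max(mean(xy^2) - mean(xy)^2, 0) / reps)
  }
  ids <- vapply(tracks, `[[`, character(1), "track_id")
  dimnames(cv) <- dimnames(se_cv) <- list(ids, ids)
  list(universe = universe,
       tracks = data.frame(track_id = ids, mean = mu,
                           se_mean = sqrt(vv / reps), var = vv, sd = sds,
                           se_sd = se_sd, stringsAsFactors = FALSE),
       cov = cv, se_cov = se_cv,
       cor = stats::cov2cor(cv + diag(1e-300, k)),
       reps = reps)
}
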