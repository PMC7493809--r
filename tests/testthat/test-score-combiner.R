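test_that("the weighted Z-transform handles the textbook cases", {
  expect_equal(combine_z(c(1.2, 2.0), c(1, 1), matrix(c(1, 0, 0, 1), 2)),
               (1.2 + 2.0) / sqrt(2))
  # perfectly correlated tracks average rather than accumulate
  expect_equal(combine_z(c(1.5, 1.5), c(1, 1), matrix(c(1, 1, 1, 1), 2)), 1.5)
  expect_equal(combine_z(c(2, 1), c(1, 1), matrix(c(1, 1, 1, 1), 2)), 1.5)
  # independent tracks with arbitrary confidences
  set.seed(3)
  z <- rnorm(3); cc <- runif(3, 0.2, 1)
  expect_equal(combine_z(z, cc, diag(3)), sum(cc * z) / sqrt(sum(cc^2)))
  # k = 1 reduces to the single Z for any positive confidence
  expect_equal(combine_z(2.7, 0.25), 2.7)
  expect_equal(combine_z(2.7, 5), 2.7)
  # pathological correlation matrices are refused with diagnostics
  expect_error(combine_z(c(1, 1), c(1, 1), matrix(c(1, -1, -1, 1), 2)),
               "non-positive")
})

test_that("confidence weights split groups into equal shares", {
  # one track takes all confidence
  expect_equal(confidence_weights("interaction", 5), 1)
  # within a group, confidence scales with sqrt(m)
  expect_equal(confidence_weights(c("interaction", "interaction"), c(1, 4)),
               c(1 / 3, 2 / 3))
  # all four groups present, one track each: a quarter each
  expect_equal(
    confidence_weights(c("interaction", "domain", "conservation",
                         "natural_variation"), c(3, 9, 2, 30)),
    rep(0.25, 4))
  # absent groups redistribute: two groups -> half each
  cw <- confidence_weights(c("interaction", "conservation"), c(4, 7))
  expect_equal(cw, c(0.5, 0.5))
  # linear rule
  expect_equal(confidence_weights(c("domain", "domain"), c(1, 4),
                                  rule = "linear"), c(0.2, 0.8))
  expect_error(confidence_weights(character(0), numeric(0)), "no included")
})

test_that("whole-gene statistics follow the one-hot simplification", {
  model <- structure(list(genes = c("A", "B"),
                          lambda = c(A = 0.1, B = 0.9),
                          bin_width = 0.01, lambda_floor = 0,
                          n_individuals = 1L),
                     class = "natural_variation_model")
  muts <- data.frame(gene = rep(c("A", "B"), c(20, 80)),
                     mutation_class = "missense", f = 1)
  st <- whole_gene_z("A", muts, model, s = 1)
  expect_equal(st$s_w, 20)
  expect_equal(st$e_s, 10)
  expect_equal(st$sd_s^2, 0.1 * 0.9 * 100)
  expect_equal(st$z, 10 / 3, tolerance = 1e-12)
  # gene at exactly its expected count scores zero
  muts2 <- data.frame(gene = rep(c("A", "B"), c(10, 90)),
                      mutation_class = "missense", f = 1)
  expect_equal(whole_gene_z("A", muts2, model, s = 1)$z, 0)
  # Z shrinks monotonically toward 0 as the subsample factor shrinks
  zs <- vapply(c(1, 0.5, 0.2, 0.05), function(s)
    whole_gene_z("A", muts, model, s = s)$z, numeric(1))
  expect_true(all(diff(zs) < 0) && all(zs > 0))
  # genes outside the universe get no whole-gene track
  expect_null(whole_gene_z("C", muts, model))
})

test_that("gene scores maximize over isoforms deterministically", {
  expect_equal(score_gene(c(I1 = 1.2, I2 = 3.4)),
               list(combined_z = 3.4, best_isoform = "I2"))
  expect_equal(score_gene(c(I9 = 2.2))$best_isoform, "I9")
  tie <- score_gene(c(IB = 1.5, IA = 1.5))
  expect_identical(tie$best_isoform, "IA")
  expect_true(is.na(score_gene(c(I1 = NA_real_))$combined_z))
})

test_that("minimum-mutation calibration orders track shapes sensibly", {
  set.seed(23)
  # near-uniform real-valued weights: normality arrives within a few mutations
  smooth <- make_track(1:100, runif(100, 0.3, 0.7))
  cal_s <- calibrate_min_mutations(smooth, rescale_for_track(NULL, smooth),
                                   max_n = 100, seed = 23)
  expect_false(cal_s$never_normal)
  expect_lte(cal_s$min_n, 5)
  # the same protocol and seed reproduce the same n*
  cal_s2 <- calibrate_min_mutations(smooth, rescale_for_track(NULL, smooth),
                                    max_n = 100, seed = 23)
  expect_identical(cal_s$min_n, cal_s2$min_n)
  # heavily skewed 0/1 track: a rare high-weight position keeps scores
  # binomial-skewed far longer (never normal within the probed range)
  skew <- make_track(1:100, rep(c(1, 0), c(1, 99)), id = "SKEW")
  lam_skew <- c(0.001, rep(0.999 / 99, 99)); lam_skew <- lam_skew / sum(lam_skew)
  cal_k <- calibrate_min_mutations(skew, lam_skew, max_n = 100, seed = 23)
  nstar_k <- if (cal_k$never_normal) Inf else cal_k$min_n
  expect_gt(nstar_k, cal_s$min_n)
  # constant-weight tracks can never be calibrated
  const <- make_track(1:10, rep(1, 10))
  expect_true(calibrate_min_mutations(const, rep(0.1, 10),
                                      seed = 1)$never_normal)
})

test_that("calibration results are cached by content hash", {
  dir <- withr::local_tempdir()
  tr <- make_track(1:40, runif(40))
  lam <- rescale_for_track(NULL, tr)
  c1 <- perturbtrack:::calibration_cached(tr, lam, 1000, 50, 5e-5, 3, 42, dir)
  expect_length(list.files(dir, pattern = "json$"), 1L)
  c2 <- perturbtrack:::calibration_cached(tr, lam, 1000, 50, 5e-5, 3, 42, dir)
  expect_identical(c1$min_n, c2$min_n)
  expect_length(list.files(dir, pattern = "json$"), 1L)
})

test_that("excluding non-positive tracks never dilutes positive evidence", {
  # with the positive-only rule, adding a negative-Z track to the pool must
  # leave the combination unchanged (it is excluded, not averaged in)
  z <- c(2.5, -1.3); m <- c(6, 9)
  groups <- c("interaction", "domain")
  keep <- z > 0
  cw <- confidence_weights(groups[keep], m[keep])
  with_neg <- combine_z(z[keep], cw, diag(sum(keep)))
  expect_equal(with_neg, 2.5)
  # and combining both (no filter) would have diluted it
  cw2 <- confidence_weights(groups, m)
  expect_lt(combine_z(z, cw2, diag(2)), with_neg)
})

test_that("cohort scoring produces ranked, reproducible gene tables", {
  cfg <- synthetic_config(seed = 5, n_genes = 12, n_drivers = 3, effect = 6,
                          background = "uniform", n_individuals = 30)
  coh <- generate_cohort(cfg)
  natvar <- build_natural_variation(coh$variant_counts)
  res <- score_cohort(coh$tracks, coh$mutations, lambda = coh$lambda,
                      natvar = natvar, seed = 5)
  expect_s3_class(res, "gene_results")
  expect_identical(sort(res$genes$gene), sort(coh$truth$gene))
  expect_false(is.unsorted(rev(res$genes$combined_z), na.rm = TRUE))
  # breakdown lists every mutated track of every gene
  expect_true(all(res$genes$gene %in% res$tracks$gene))
  expect_true(all(res$tracks$included %in% c(TRUE, FALSE)))
  # identical call reproduces identical output
  res2 <- score_cohort(coh$tracks, coh$mutations, lambda = coh$lambda,
                       natvar = natvar, seed = 5)
  expect_equal(res$genes, res2$genes)
  # results table round-trips through the serialized format
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, path)
  back <- read_results(path)
  expect_equal(back$combined_Z, res$genes$combined_z, tolerance = 1e-6)
  expect_true(all(grepl("=", back$tracks[nzchar(back$tracks)])))
})
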