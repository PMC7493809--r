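test_that("track scores sum f-weighted position weights within the track", {
  tr <- make_track(c(5L, 9L), c(0.2, 1.0), L = 12)
  expect_equal(track_score(tr, make_mutations(c(5, 9), f = c(1, 0.5))), 0.7)
  expect_equal(track_score(tr, make_mutations(integer(0))), 0)
  # positions outside W contribute nothing
  expect_equal(track_score(tr, make_mutations(c(5, 3, 11), f = 1)), 0.2)
  # silent/nonsense mutations are excluded from scoring
  mm <- rbind(make_mutations(5), make_mutations(9, class = "nonsense"))
  expect_equal(track_score(tr, mm), 0.2)
})

test_that("unit moments match enumeration and flag degenerate tracks", {
  tr <- make_track(1:2, c(0.2, 1.0))
  mom <- track_moments(tr, c(0.5, 0.5))
  expect_equal(mom$c_e, 0.6)
  expect_equal(mom$c_v, 0.16)
  expect_false(mom$degenerate)

  const <- make_track(1:4, rep(0.7, 4))
  expect_true(track_moments(const, rep(0.25, 4))$degenerate)

  # 0/1 weights with background mass p on the weight-1 positions: Bernoulli
  tr01 <- make_track(1:10, rep(c(1, 0), c(3, 7)))
  lam <- rescale_for_track(NULL, tr01)
  mom01 <- track_moments(tr01, lam)
  expect_equal(mom01$c_e, 0.3)
  expect_equal(mom01$c_v, 0.3 * 0.7)
})

test_that("Z scores follow the binomial closed form on 0/1 tracks", {
  tr <- make_track(1:10, rep(c(1, 0), c(3, 7)))
  lam <- rescale_for_track(NULL, tr)
  # 5 mutations, 4 on weight-1 positions -> S = 4, E = 1.5, var = 1.05
  st <- track_statistics(tr, lam, make_mutations(c(1, 2, 3, 1, 8)))
  expect_equal(st$s_w, 4)
  expect_equal(st$e_s, 1.5)
  expect_equal(st$sd_s^2, 5 * 0.3 * 0.7)
  expect_equal(track_zscore(st), 2.5 / sqrt(1.05), tolerance = 1e-12)
  expect_equal(track_zscore(st), 2.440, tolerance = 1e-3)

  # S equal to its expectation gives Z = 0
  tr2 <- make_track(1:2, c(0, 1))
  st2 <- track_statistics(tr2, c(0.5, 0.5), make_mutations(c(1, 2)))
  expect_equal(st2$s_w, st2$e_s)
  expect_equal(track_zscore(st2), 0)

  # scaling all equal f leaves Z unchanged
  tr3 <- make_track(1:6, c(0.9, 0.1, 0.4, 0, 1, 0.3))
  lam3 <- rescale_for_track(NULL, tr3)
  z_lo <- track_statistics(tr3, lam3, make_mutations(c(1, 5, 5), f = 0.4))$z
  z_hi <- track_statistics(tr3, lam3, make_mutations(c(1, 5, 5), f = 0.8))$z
  expect_equal(z_lo, z_hi, tolerance = 1e-12)

  # degenerate track: Z undefined
  stc <- track_statistics(make_track(1:3, rep(1, 3)), rep(1 / 3, 3),
                          make_mutations(1))
  expect_true(is.na(stc$z))
  expect_error(track_zscore(stc), "zero variance")
})

test_that("between-track covariance honors overlap structure", {
  lam <- rep(1, 20)
  v <- make_track(1:10, runif(10), L = 20, id = "V")
  w_disj <- make_track(11:20, runif(10), L = 20, id = "W")
  muts <- make_mutations(c(2, 5, 13, 17))
  expect_equal(track_covariance(v, w_disj, lam, muts)$cov, 0)

  # identical tracks share all mutations: cov equals the variance, r = 1
  set.seed(31)
  v2 <- make_track(1:12, runif(12), L = 20, id = "V2")
  w2 <- make_track(1:12, v2$weights, L = 20, id = "W2")
  m2 <- make_mutations(c(1, 4, 4, 9, 12), f = runif(5, 0.3, 1))
  ov <- track_covariance(v2, w2, lam, m2)
  st <- track_statistics(v2, rescale_for_track(lam, v2), m2)
  expect_equal(ov$cov, st$sd_s^2, tolerance = 1e-12)
  expect_equal(ov$cor, 1, tolerance = 1e-12)

  # constant (zero) weights inside the overlap kill the covariance
  v3 <- make_track(1:10, c(rep(0, 5), runif(5)), L = 20, id = "V3")
  w3 <- make_track(c(1:5, 15:19), c(rep(0.8, 5), runif(5)), L = 20, id = "W3")
  expect_equal(track_covariance(v3, w3, lam, muts)$cov, 0)
})

test_that("precompute-and-scale reproduces direct evaluation exactly", {
  set.seed(91)
  for (i in 1:200) {
    L <- sample(15:120, 1)
    lam <- rgamma(L, 1.5) + 1e-6
    n_tr <- sample(2:3, 1)
    tracks <- lapply(seq_len(n_tr), function(k) {
      pos <- sort(sample.int(L, sample(5:min(40, L), 1)))
      make_track(pos, runif(length(pos)), L = L, id = paste0("T", k))
    })
    n_mut <- sample(c(0L, 3L, 25L), 1)
    muts <- make_mutations(sample.int(L, n_mut, replace = TRUE),
                           f = runif(n_mut, 0.2, 1))
    pre <- precompute_tracks(tracks, lam)
    batch <- score_batch(pre, muts)
    for (k in seq_len(n_tr)) {
      lam_w <- rescale_for_track(lam, tracks[[k]])
      direct <- perturbtrack:::track_moments_direct(tracks[[k]], lam_w, muts)
      expect_lt(abs(batch$stats[[k]]$e_s - direct$e_s), 1e-10)
      expect_lt(abs(batch$stats[[k]]$sd_s^2 - direct$var_s), 1e-10)
      full <- track_statistics(tracks[[k]], lam_w, muts)
      expect_equal(batch$stats[[k]]$z, full$z, tolerance = 1e-10)
    }
    ov <- track_covariance(tracks[[1]], tracks[[2]], lam, muts)
    expect_lt(abs(batch$cov[1, 2] - ov$cov), 1e-10)
  }
})

test_that("null Z scores are standard normal at the calibrated count", {
  set.seed(17)
  L <- 80L
  tr <- make_track(seq_len(L), runif(L), L = L)
  lam_w <- rescale_for_track(NULL, tr)
  cal <- calibrate_min_mutations(tr, lam_w, seed = 17)
  expect_false(cal$never_normal)
  n <- cal$min_n
  mom <- track_moments(tr, lam_w)
  reps <- 5000L
  idx <- sample.int(L, n * reps, replace = TRUE, prob = lam_w)
  s <- colSums(matrix(tr$weights[idx], n, reps))
  z <- (s - n * mom$c_e) / sqrt(n * mom$c_v)
  ks <- suppressWarnings(stats::ks.test(z, "pnorm"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(z)), 4 / sqrt(reps))
})

test_that("gene-level correlation matrices are symmetric and PSD", {
  set.seed(51)
  for (i in 1:30) {
    L <- 100L
    lam <- rgamma(L, 2)
    tracks <- lapply(1:4, function(k) {
      pos <- sort(sample.int(L, sample(10:60, 1)))
      make_track(pos, runif(length(pos)), L = L, id = paste0("T", k))
    })
    muts <- make_mutations(sample.int(L, 40, replace = TRUE),
                           f = runif(40, 0.2, 1))
    batch <- score_batch(precompute_tracks(tracks, lam), muts)
    r <- perturbtrack:::condition_correlation(batch$cor)
    expect_equal(r, t(r))
    ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
})
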