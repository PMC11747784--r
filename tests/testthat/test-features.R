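test_that("periodogram matches a direct DFT oracle and satisfies Parseval", {
  expect_error(periodogram_segment(numeric(0), 250), "at least 2")
  # zero in, zero out
  expect_true(all(periodogram_segment(rep(0, 250), 250)$psd == 0))

  # unit 15 Hz tone, M = 250, fs = 250, rectangular: one nonzero bin at 15
  t <- (0:249) / 250
  x <- sin(2 * pi * 15 * t)
  pg <- periodogram_segment(x, 250, window = "rectangular")
  expect_equal(pg$freqs[which.max(pg$psd)], 15)
  expect_lt(max(pg$psd[pg$freqs != 15]) / max(pg$psd), 1e-20)

  # DFT oracle for the raw textbook form |X(k)|^2 / M
  raw <- periodogram_segment(x, 250, window = "rectangular",
                             scaling = "raw", detrend = FALSE)
  k <- 0:(length(x) - 1)
  oracle <- vapply(0:125, function(f) {
    Mod(sum(x * exp(-2i * pi * f * k / 250)))^2 / 250
  }, numeric(1))
  expect_equal(raw$psd, oracle, tolerance = 1e-10)

  # Parseval: integral of the one-sided density equals the signal variance
  withr::with_seed(6, y <- rnorm(500))
  y <- y - mean(y)
  pg <- periodogram_segment(y, 250, window = "rectangular", detrend = FALSE)
  df <- pg$freqs[2] - pg$freqs[1]
  expect_equal(sum(pg$psd) * df, mean(y^2), tolerance = 0.01)
})

test_that("welch estimate is the exact mean of its segment periodograms", {
  withr::with_seed(16, x <- rnorm(2500))
  spec <- welch_psd(x, 250, nperseg = 250, overlap = 0.5)
  expect_equal(spec$n_segments, 19L)
  expect_equal(spec$freqs[2] - spec$freqs[1], 1)
  expect_true(all(spec$psd >= 0))

  manual <- Reduce(`+`, lapply(seq(0, 2250, by = 125), function(s) {
    periodogram_segment(x[(s + 1):(s + 250)], 250)$psd
  })) / 19
  expect_equal(spec$psd[1, ], manual, tolerance = 1e-12)

  expect_error(welch_psd(rnorm(100), 250, nperseg = 250), "exceeds")
})

test_that("welch averaging reduces bin variance relative to one periodogram", {
  withr::with_seed(17, {
    bins <- 10:40
    welch_vals <- single_vals <- matrix(0, 80, length(bins))
    for (i in 1:80) {
      x <- rnorm(2500)
      welch_vals[i, ] <- welch_psd(x, 250)$psd[1, bins]
      single_vals[i, ] <-
        periodogram_segment(x[1:250], 250)$psd[bins]
    }
    ratio <- mean(apply(welch_vals, 2, var) / apply(single_vals, 2, var))
    expect_lt(ratio, 0.5)
  })
})

test_that("psd_feature reads the nearest bin with lower-frequency ties", {
  spec <- welch_psd(sin(2 * pi * 15 * (0:2499) / 250), 250)
  peak <- psd_feature(spec, 15)
  expect_equal(peak, max(spec$psd[1, ]))
  expect_equal(psd_feature(spec, 15.4), peak)
  # tie at 15.5 between the 15 and 16 Hz bins breaks low
  expect_equal(psd_feature(spec, 15.5), peak)
  expect_error(psd_feature(spec, 200), "outside")

  # linear-scan oracle over a jittered grid
  withr::with_seed(18, {
    for (f in runif(20, 0, 125)) {
      expect_equal(psd_feature(spec, f),
                   spec$psd[1, which.min(abs(spec$freqs - f))])
    }
  })
})

test_that("harmonic reference banks have the 2H structure and orthogonality", {
  ref <- build_reference(15, H = 3, fs = 250, n = 2500)
  expect_equal(nrow(ref$matrix), 6L)
  expect_error(build_reference(15, H = 9, fs = 250),
               "harmonic 9 \\(135 Hz\\)")

  # integer cycle counts: rows mutually orthogonal, Gram off-diagonals ~ 0
  g <- tcrossprod(ref$matrix - rowMeans(ref$matrix))
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-10)

  r1 <- build_reference(15, H = 1, fs = 250, n = 2500)
  expect_lt(abs(sum(r1$matrix[1, ] * r1$matrix[2, ])), 1e-9)
})

test_that("single-channel CCA equals the multiple correlation, with rho = 1 in-span", {
  t <- (0:2499) / 250
  ref15 <- build_reference(15, H = 3, fs = 250, n = 2500)
  x <- sin(2 * pi * 15 * t + 0.7)
  expect_equal(cca_max_correlation(x, ref15), 1, tolerance = 1e-9)

  # third harmonic lies in the H=3 span but not the H=1 span
  x45 <- sin(2 * pi * 45 * t + 0.2)
  expect_equal(cca_max_correlation(x45, ref15), 1, tolerance = 1e-9)
  ref15_h1 <- build_reference(15, H = 1, fs = 250, n = 2500)
  expect_lt(cca_max_correlation(x45, ref15_h1), 0.05)

  # affine invariance
  withr::with_seed(19, z <- sin(2 * pi * 15 * t) + rnorm(2500))
  rho <- cca_max_correlation(z, ref15)
  expect_equal(cca_max_correlation(-3.2 * z + 40, ref15), rho,
               tolerance = 1e-9)
  expect_true(rho >= 0 && rho <= 1)
  expect_error(cca_max_correlation(rep(2, 2500), ref15), "constant")
})

test_that("CCA agrees with independent oracles on random instances", {
  # oracle 1: stats::cancor's leading canonical correlation
  withr::with_seed(20, {
    for (i in 1:20) {
      n <- 200
      f <- runif(1, 5, 40)
      ref <- build_reference(f, H = 2, fs = 250, n = n)
      x <- rnorm(n) + runif(1, 0, 2) * sin(2 * pi * f * (0:(n - 1)) / 250)
      mine <- cca_max_correlation(x, ref)
      oracle <- stats::cancor(cbind(x), t(ref$matrix))$cor[1]
      expect_equal(mine, oracle, tolerance = 1e-6)
    }
  })

  # oracle 2: brute-force maximization of corr(x, w'Y) over weight vectors
  withr::with_seed(23, {
    n <- 120
    ref <- build_reference(10, H = 1, fs = 250, n = n)
    x <- rnorm(n) + 0.8 * sin(2 * pi * 10 * (0:(n - 1)) / 250 + 1)
    obj <- function(w) -stats::cor(x, drop(w %*% ref$matrix))
    best <- -Inf
    for (rep in 1:40) {
      w0 <- rnorm(2)
      best <- max(best, -stats::optim(w0, obj, method = "BFGS")$value)
    }
    expect_equal(cca_max_correlation(x, ref), best, tolerance = 1e-6)
  })

  # multichannel mode bounds the best single channel from below
  withr::with_seed(24, {
    X <- rbind(rnorm(2500), sin(2 * pi * 15 * (0:2499) / 250) + rnorm(2500))
    ref <- build_reference(15, H = 3, fs = 250, n = 2500)
    multi <- cca_max_correlation(X, ref)
    singles <- apply(X, 1, cca_max_correlation, ref = ref)
    expect_gte(multi, max(singles) - 1e-9)
  })
})

test_that("CCA at the attended frequency rises with SSVEP amplitude", {
  amps <- c(0.5, 1.5, 3, 6)
  rhos <- vapply(seq_along(amps), function(i) {
    cfg <- sim_config(ssvep_amp = c(O1 = amps[i], O2 = amps[i],
                                    Pz = amps[i] / 2, Cz = amps[i] / 3),
                      artifact_rate = 0)
    withr::with_seed(30, m <- synthesize_trial(15, cfg))
    cca_max_correlation(m["O1", ], build_reference(15, 3, 250, 2500))
  }, numeric(1))
  expect_equal(order(rhos), seq_along(amps))  # Spearman rho = 1
})

test_that("feature vectors follow the canonical 16-entry layout", {
  pre <- small_preprocessed()
  fv <- extract_feature_vector(pre[[1]]$averages)
  expect_equal(ncol(fv), 16L)
  expect_equal(names(fv)[1:4], c("psd_O1_15", "psd_O2_15",
                                 "psd_Pz_15", "psd_Cz_15"))
  expect_equal(names(fv)[9], "cca_O1_15")
  expect_equal(names(fv)[16], "cca_Cz_18")
  psd_cols <- unlist(fv[startsWith(names(fv), "psd_")])
  cca_cols <- unlist(fv[startsWith(names(fv), "cca_")])
  expect_true(all(psd_cols >= 0))
  expect_true(all(cca_cols >= 0 & cca_cols <= 1))

  expect_error(
    extract_feature_vector(pre[[1]]$averages,
                           channels = c("O1", "O2", "Oz", "Cz")),
    "Oz")

  # noise-free subject attending per condition: near-perfect CCA
  clean <- sim_config(n_trials_per_session = 1, alpha_amp = 0,
                      noise_scale = 0, line_amp = 0, artifact_rate = 0)
  cohort <- simulate_cohort(1, 0, clean, seed = 2)
  p <- preprocess_recording(cohort$recording[[1]], n_trials_per_session = 1)
  v <- extract_feature_vector(p$averages)
  expect_true(all(unlist(v[startsWith(names(v), "cca_")]) > 0.95))
})

test_that("feature matrices are rectangular, labelled and complete", {
  cohort <- small_cohort()
  feats <- extract_features(small_preprocessed(), labels = cohort$condition)
  expect_equal(dim(feats), c(5L, 18L))
  expect_false(anyNA(feats))
  expect_equal(feats$label, cohort$condition)

  per_freq <- extract_features(small_preprocessed(),
                               labels = cohort$condition,
                               mode = "per_frequency")
  expect_equal(nrow(per_freq), 10L)          # 5 subjects x 2 frequencies
  expect_setequal(unique(per_freq$target_frequency), c(15, 18))
  expect_equal(sum(startsWith(names(per_freq), "psd_")), 4L)
  expect_equal(sum(startsWith(names(per_freq), "cca_")), 4L)
})

test_that("attended-frequency features dominate the unattended ones", {
  # paired comparison per subject and session group: the mean PSD and CCA at
  # the attended frequency exceed those at the other candidate frequency
  cohort <- small_cohort()
  pre <- small_preprocessed()
  plans <- default_session_plans()
  att_psd <- una_psd <- att_cca <- una_cca <- numeric(0)
  for (i in seq_len(nrow(cohort))) {
    for (f in c(15, 18)) {
      sess <- plans$session_id[plans$target_frequency == f]
      avg <- pre[[i]]$averages
      m <- Reduce(`+`, avg$data[avg$session_id %in% sess]) / length(sess)
      attended <- if (cohort$condition[i] == "normal") f else 33 - f
      spec <- welch_psd(m, 250)
      psd_at <- function(fq) mean(vapply(1:4, function(ch)
        psd_feature(spec, fq, ch), numeric(1)))
      cca_at <- function(fq) mean(apply(m, 1, cca_max_correlation,
        ref = build_reference(fq, 3, 250, ncol(m))))
      att_psd <- c(att_psd, psd_at(attended))
      una_psd <- c(una_psd, psd_at(33 - attended))
      att_cca <- c(att_cca, cca_at(attended))
      una_cca <- c(una_cca, cca_at(33 - attended))
    }
  }
  expect_gt(mean(att_psd - una_psd), 0)
  expect_gt(mean(att_cca - una_cca), 0)
  expect_gt(mean(att_cca > una_cca), 0.9)

  # and the combined matrix separates the two conditions on CCA features
  feats <- extract_features(pre, labels = cohort$condition)
  cca_mean <- rowMeans(feats[startsWith(names(feats), "cca_")])
  expect_gt(min(cca_mean[feats$label == "normal"]),
            max(cca_mean[feats$label == "cvd"]))
})

test_that("group PSD ratio reproduces the normal/CVD band asymmetry", {
  # identical groups give exactly 1
  spec <- welch_psd(matrix(rnorm(2500), 1), 250)
  expect_equal(psd_group_ratio(spec, spec, c(14, 16)), 1)

  # constructed spectra: doubled 15 Hz power in the normal group
  t <- (0:2499) / 250
  base <- sin(2 * pi * 15 * t)
  s_norm <- welch_psd(matrix(sqrt(2) * base, 1), 250)
  s_cvd <- welch_psd(matrix(base, 1), 250)
  expect_equal(psd_group_ratio(s_norm, s_cvd, c(14.5, 15.5)), 2,
               tolerance = 1e-6)

  # simulated cohort, sessions with a 15 Hz target: ratio > 1 in 14-16 Hz
  # and < 1 in 17-19 Hz (normals attend 15, CVD attend 18 there)
  pre <- small_preprocessed()
  cohort <- small_cohort()
  plans <- default_session_plans()
  sess15 <- plans$session_id[plans$target_frequency == 15]
  group_spec <- function(cond) {
    specs <- lapply(which(cohort$condition == cond), function(i) {
      avg <- pre[[i]]$averages
      m <- Reduce(`+`, avg$data[avg$session_id %in% sess15]) / length(sess15)
      welch_psd(m, 250)$psd
    })
    s <- welch_psd(matrix(0, 4, 2500), 250)
    s$psd <- Reduce(`+`, specs) / length(specs)
    s
  }
  sn <- group_spec("normal")
  sc <- group_spec("cvd")
  expect_gt(psd_group_ratio(sn, sc, c(14, 16)), 1)
  expect_lt(psd_group_ratio(sn, sc, c(17, 19)), 1)

  zero <- sn; zero$psd[] <- 0
  expect_error(psd_group_ratio(sn, zero, c(14, 16)), "denominator")
})
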