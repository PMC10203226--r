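# Brute-force oracle: rank with average ties, Pearson, clip, Fisher z.
oracle_dissim <- function(v1, v2) {
  r1 <- rank(v1); r2 <- rank(v2)
  rho <- sum((r1 - mean(r1)) * (r2 - mean(r2))) /
    sqrt(sum((r1 - mean(r1))^2) * sum((r2 - mean(r2))^2))
  rho <- min(max(rho, -(1 - 1e-10)), 1 - 1e-10)
  1 - atanh(rho)
}

test_that("window grids carry the printed center counts", {
  expect_length(make_window_grid(0, 2)$centers_s, 201)
  expect_length(make_window_grid(0, 3)$centers_s, 301)
  expect_equal(make_window_grid(0, 0.1, step_s = 0.05)$centers_s,
               c(0, 0.05, 0.1))
  expect_error(make_window_grid(0, 2, step_s = 0),
               class = "wm_validation_error")
  expect_error(make_window_grid(2, 0), class = "wm_validation_error")
})

test_that("window features average power and vectorize channel-major", {
  vals <- array(0, c(3, 2, 40, 100))
  vals[1, , , ] <- 2            # constant power trial
  vals[2, 1, 5, ] <- 7          # channel 1, 5 Hz only
  set.seed(1)
  vals[3, , , ] <- rnorm(2 * 40 * 100)
  pw <- power_tensor(vals, 1:40, (0:99) / 100, 100, "encoding",
                     c("h1", "h2"), c("HIP", "HIP"), 1:3, zscored = TRUE)
  fv <- window_features(pw, center_s = 0.5, width_s = 0.1)
  expect_equal(dim(fv), c(3, 80))
  expect_true(all(fv[1, ] == 2))
  # channel-major: entry for (channel 1, 5 Hz) sits at (5-1)*2 + 1
  expect_equal(fv[2, (5 - 1) * 2 + 1], 7)
  expect_equal(sum(fv[2, ] != 0), 1)
  # direct averaging oracle on the random trial
  sel <- which(pw$time_s >= 0.45 - 1e-9 & pw$time_s <= 0.55 + 1e-9)
  # channel-major flattening: channel index varies fastest
  manual <- as.vector(apply(vals[3, , , sel], c(1, 2), mean))
  expect_equal(unname(fv[3, ]), manual, tolerance = 1e-12)
  expect_error(window_features(pw, center_s = 5),
               class = "wm_validation_error")
})

test_that("pair dissimilarity matches the rank-Pearson-atanh oracle", {
  # closed forms
  expect_equal(pair_dissimilarity(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)),
               1 - atanh(cor(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9),
                             method = "spearman")))
  v <- c(1, 2, 3, 4, 5); w <- c(1, 3, 2, 5, 4)  # rho = 0.8
  expect_equal(pair_dissimilarity(v, w), 1 - atanh(0.8))
  # oracle equivalence on 1000 random pairs, including ties
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    v1 <- sample(1:8, n, replace = TRUE) + rnorm(n, sd = 0.01)
    v2 <- round(rnorm(n), 1)
    expect_equal(pair_dissimilarity(v1, v2), oracle_dissim(v1, v2),
                 tolerance = 1e-12)
  }
  # identical vectors hit the clipping bound, not infinity
  expect_equal(pair_dissimilarity(1:20, 1:20), 1 - atanh(1 - 1e-10))
  expect_error(pair_dissimilarity(rep(1, 5), 1:5),
               class = "wm_degenerate_error")
  expect_error(pair_dissimilarity(1:4, 1:5), class = "wm_validation_error")
})

test_that("trial-pair sampling is uniform, distinct and seeded", {
  p <- sample_trial_pairs(101:120, k = 100, seed = 5)
  expect_equal(dim(p), c(100, 2))
  expect_false(attr(p, "with_replacement"))
  expect_equal(anyDuplicated(paste(p[, 1], p[, 2])), 0)
  expect_true(all(p[, 1] != p[, 2]))
  expect_identical(sample_trial_pairs(101:120, k = 100, seed = 5), p)
  small <- sample_trial_pairs(1:5, k = 100, seed = 5)
  expect_true(attr(small, "with_replacement"))
  expect_error(sample_trial_pairs(7L, k = 10, seed = 1),
               class = "wm_validation_error")
})

# Power tensor whose window patterns are injected directly per trial:
# each trial's (channel x freq) pattern held constant over time + noise.
pattern_tensor <- function(patterns, noise_sd = 0, n_time = 60,
                           rate = 100, label = "encoding") {
  nt <- nrow(patterns)
  nf <- ncol(patterns)          # one channel: features = frequencies 1..nf
  vals <- array(NA_real_, c(nt, 1, nf, n_time))
  for (tr in seq_len(nt)) {
    for (s in seq_len(n_time)) {
      vals[tr, 1, , s] <- patterns[tr, ] + rnorm(nf, sd = noise_sd)
    }
  }
  power_tensor(vals, seq_len(nf), (seq_len(n_time) - 1) / rate, rate,
               label, "h1", "HIP", seq_len(nt), zscored = TRUE)
}

test_that("EED approaches its limits for shared and independent patterns", {
  set.seed(21)
  grid <- make_window_grid(0, 0.5, step_s = 0.25)
  # one shared pattern + tiny noise: dissimilarity near the clipped floor
  shared <- matrix(rep(rnorm(40), each = 20), 20, 40, byrow = FALSE)
  pw_same <- pattern_tensor(shared, noise_sd = 1e-4)
  m_same <- eed_map(pw_same, grid)
  expect_lt(mean(m_same$values), -5)
  # independent random patterns: mean dissimilarity ~ 1
  pw_ind <- pattern_tensor(matrix(rnorm(20 * 40), 20), noise_sd = 1e-3)
  m_ind <- eed_map(pw_ind, grid)
  expect_equal(mean(m_ind$values), 1, tolerance = 0.05)
  expect_equal(dim(m_ind$values), c(3, 3))
  expect_error(eed_map(pw_ind, grid, pairs = cbind(1, 99)),
               class = "wm_validation_error")
})

test_that("EED map equals a brute-force loop over pairs and windows", {
  set.seed(22)
  pw <- pattern_tensor(matrix(rnorm(5 * 40), 5), noise_sd = 0.5)
  grid <- make_window_grid(0, 0.4, step_s = 0.2)
  m <- eed_map(pw, grid)
  cmb <- t(combn(5, 2))
  manual <- matrix(0, 3, 3)
  for (w1 in 1:3) for (w2 in 1:3) {
    f1 <- window_features(pw, grid$centers_s[w1], freqs_hz = 1:40)
    f2 <- window_features(pw, grid$centers_s[w2], freqs_hz = 1:40)
    d <- mean(apply(cmb, 1, function(pr) {
      (oracle_dissim(f1[pr[1], ], f2[pr[2], ]) +
       oracle_dissim(f1[pr[2], ], f2[pr[1], ])) / 2
    }))
    manual[w1, w2] <- d
  }
  expect_equal(m$values, manual, tolerance = 1e-10)
  # averaged over symmetrized orderings the map is symmetric
  expect_equal(m$values, t(m$values), tolerance = 1e-12)
})

test_that("EMS hits its limits for persistent and independent maintenance", {
  set.seed(23)
  ge <- make_window_grid(0, 0.4, step_s = 0.2)
  gm <- make_window_grid(0, 0.4, step_s = 0.2)
  pats <- matrix(rnorm(100 * 40), 100)
  enc <- pattern_tensor(pats, noise_sd = 1e-3)
  # maintenance repeats the encoding pattern: strongly positive
  mnt_same <- pattern_tensor(pats, noise_sd = 1e-3, label = "maintenance")
  m_same <- ems_map(enc, mnt_same, ge, gm)
  expect_gt(mean(m_same$values), 5)
  # independent maintenance: similarity ~ 0
  mnt_ind <- pattern_tensor(matrix(rnorm(100 * 40), 100), noise_sd = 1e-3,
                            label = "maintenance")
  m_ind <- ems_map(enc, mnt_ind, ge, gm)
  expect_equal(mean(m_ind$values), 0, tolerance = 0.05)
  # per-trial values average to the map
  m_pt <- ems_map(enc, mnt_ind, ge, gm, per_trial = TRUE)
  expect_equal(matrix(colMeans(m_pt$trial_values), 3, 3), m_ind$values)
  # trial mismatch rejected
  enc_sub <- enc; enc_sub$trial_ids <- enc$trial_ids + 1L
  expect_error(ems_map(enc_sub, mnt_ind, ge, gm),
               class = "wm_validation_error")
})

test_that("EMS matches a brute-force within-trial loop", {
  set.seed(24)
  enc <- pattern_tensor(matrix(rnorm(4 * 40), 4), noise_sd = 0.5)
  mnt <- pattern_tensor(matrix(rnorm(4 * 40), 4), noise_sd = 0.5,
                        label = "maintenance")
  ge <- make_window_grid(0, 0.4, step_s = 0.2)
  gm <- make_window_grid(0, 0.2, step_s = 0.2)
  m <- ems_map(enc, mnt, ge, gm)
  manual <- matrix(0, 3, 2)
  for (we in 1:3) for (wm in 1:2) {
    fe <- window_features(enc, ge$centers_s[we], freqs_hz = 1:40)
    fm <- window_features(mnt, gm$centers_s[wm], freqs_hz = 1:40)
    manual[we, wm] <- mean(vapply(1:4, function(tr) {
      atanh(min(max(cor(fe[tr, ], fm[tr, ], method = "spearman"),
                    -(1 - 1e-10)), 1 - 1e-10))
    }, numeric(1)))
  }
  expect_equal(m$values, manual, tolerance = 1e-10)
})

test_that("exchangeable regions show no systematic EED difference", {
  # delta equal in both regions: the sign of the region difference is a
  # fair coin across seeds
  diffs <- vapply(1:20, function(seed) {
    mm <- region_map_means(seed + 400, n_trials_per_load = 2,
                           step_s = 0.5,
                           delta = c(AMY = 0.5, HIP = 0.5),
                           rho = c(AMY = 0.4, HIP = 0.4))
    mm[["eed_AMY"]] - mm[["eed_HIP"]]
  }, numeric(1))
  n_pos <- sum(diffs > 0)
  p <- binom.test(n_pos, length(diffs))$p.value
  expect_gt(p, 0.01)
})

test_that("mean EED rises with delta and mean EMS with rho", {
  # vary one knob at a time (delta for EED at fixed rho; rho for EMS at
  # fixed distinct patterns); 12 short sessions per level, run at a
  # clearly resolvable oscillation amplitude so the ~0.03 per-level
  # increments stand out from session noise
  levels <- c(0, 0.25, 0.5, 0.75, 1)
  eed <- ems <- numeric(length(levels))
  for (i in seq_along(levels)) {
    mm_d <- rowMeans(vapply(1:12, function(s) {
      region_map_means(s + 700 + 31 * i, n_trials_per_load = 4,
                       step_s = 0.5, osc_amplitude = 12,
                       delta = c(AMY = levels[i], HIP = levels[i]),
                       rho = c(AMY = 0.5, HIP = 0.5))
    }, numeric(4)))
    eed[i] <- mean(mm_d[c("eed_AMY", "eed_HIP")])
    mm_r <- rowMeans(vapply(1:12, function(s) {
      region_map_means(s + 900 + 31 * i, n_trials_per_load = 4,
                       step_s = 0.5, osc_amplitude = 12,
                       delta = c(AMY = 0.9, HIP = 0.9),
                       rho = c(AMY = levels[i], HIP = levels[i]))
    }, numeric(4)))
    ems[i] <- mean(mm_r[c("ems_AMY", "ems_HIP")])
  }
  expect_true(all(diff(eed) > 0))
  expect_true(all(diff(ems) > 0))
})
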