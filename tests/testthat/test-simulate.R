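test_that("generated time courses are standardized and spectrally placed", {
  tr <- 0.354
  n <- 1000
  set.seed(21)
  specs <- list(
    rsn = rsn_source(centers = list(c(3, 3, 3))),
    technical = technical_source(center_freq = 0.8, bandwidth = 0.05),
    pulsation = pulsation_source(band = c(0.6, 1.4),
                                 centers = list(c(3, 3, 3))),
    cardiac = cardiac_source(base_freq = 1.15, jitter_sd = 0.03)
  )
  for (nm in names(specs)) {
    x <- generate_source_timecourse(specs[[nm]], n, tr)
    expect_lt(abs(mean(x)), 1e-9)
    expect_lt(abs(var(x) - 1), 1e-9)
  }
  # technical: narrowband, periodogram argmax inside the band
  x <- generate_source_timecourse(specs$technical, n, tr)
  p <- periodogram(x, tr)
  expect_gte(p$freq[which.max(p$power)], 0.775)
  expect_lte(p$freq[which.max(p$power)], 0.825)
  expect_gte(sum(p$power[p$freq >= 0.775 & p$freq <= 0.825]) /
               sum(p$power), 0.8)
  # pulsation: >= 80% of power inside the stated band
  x <- generate_source_timecourse(specs$pulsation, n, tr)
  p <- periodogram(x, tr)
  expect_gte(sum(p$power[p$freq >= 0.6 & p$freq <= 1.4]) / sum(p$power), 0.8)
  # rsn: monotone decreasing band-average trend over 0.25-0.6 Hz
  x <- generate_source_timecourse(specs$rsn, n, tr)
  p <- periodogram(x, tr)
  edges <- seq(0.25, 0.6, length.out = 6)
  avg <- vapply(seq_len(5), function(i) {
    mean(p$power[p$freq >= edges[i] & p$freq < edges[i + 1]])
  }, numeric(1))
  expect_true(all(diff(avg) < 0))
})

test_that("jitter-free cardiac source is a pure oscillation on the grid", {
  set.seed(5)
  tr <- 0.354; n <- 1000
  x <- generate_source_timecourse(cardiac_source(base_freq = 1.15,
                                                 jitter_sd = 0), n, tr)
  p <- periodogram(x, tr)
  nearest <- round(1.15 * n * tr) / (n * tr)
  expect_equal(p$freq[which.max(p$power)], nearest, tolerance = 1e-12)
})

test_that("cardiac peak stays within base +/- 3 * jitter", {
  set.seed(9)
  tr <- 0.354
  for (i in 1:5) {
    x <- generate_source_timecourse(cardiac_source(base_freq = 1.15,
                                                   jitter_sd = 0.03),
                                    1000, tr)
    p <- periodogram(x, tr)
    pk <- p$freq[which.max(p$power)]
    expect_gte(pk, 1.15 - 3 * 0.03)
    expect_lte(pk, 1.15 + 3 * 0.03)
  }
})

test_that("frequencies at or above Nyquist are rejected with explanation", {
  expect_error(
    generate_source_timecourse(cardiac_source(base_freq = 1.5), 128,
                               tr = 0.354),
    "Nyquist")
  expect_error(
    generate_source_timecourse(technical_source(center_freq = 2), 128,
                               tr = 0.354),
    "Nyquist")
})

test_that("technical maps are slice-banded, constant within slices", {
  spec <- technical_source(band_period = 2, amplitude = 1)
  grid <- c(8, 8, 8)
  w <- generate_spatial_map(spec, grid)
  arr <- array(w, grid)
  slice_vals <- apply(arr, 3, function(s) unique(as.vector(s)))
  expect_true(all(lengths(slice_vals) == 1))  # constant within slice
  v <- vapply(1:8, function(z) arr[1, 1, z], numeric(1))
  expect_equal(v, c(1, 1, -1, -1, 1, 1, -1, -1))
})

test_that("blob maps overlap and degenerate radius gives one voxel", {
  grid <- c(8, 8, 8)
  a <- generate_spatial_map(rsn_source(centers = list(c(3, 3, 4)),
                                       radii = 2), grid)
  b <- generate_spatial_map(rsn_source(centers = list(c(5, 5, 4)),
                                       radii = 2), grid)
  expect_gt(sum(a > 0.1 & b > 0.1), 0)
  single <- generate_spatial_map(rsn_source(centers = list(c(4, 4, 4)),
                                            radii = 0), grid)
  expect_equal(sum(single != 0), 1)
})

test_that("simulation is deterministic and respects the mixing model", {
  cfg <- tiny_sim_config(seed = 77)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$subjects[[2]]$data, s2$subjects[[2]]$data)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$motion, s2$motion)

  # zero noise, one source: exact rank-1 outer product
  cfg1 <- sim_config(n_subjects = 1, grid_shape = c(6, 6, 4), n_volumes = 64,
                     tr_seconds = 0.354, snr = Inf,
                     seed = 3, motion_frac = 0,
                     source_specs = list(rsn_source(centers =
                                                      list(c(3, 3, 2)))))
  s <- simulate_dataset(cfg1)
  expect_equal(qr(s$subjects[[1]]$data)$rank, 1)
  expect_equal(s$subjects[[1]]$data,
               s$truth$timecourses[[1]] %*% s$truth$spatial_maps,
               tolerance = 1e-12)
})

test_that("single-subject sources appear in exactly one subject", {
  sim <- simulate_dataset(tiny_sim_config(seed = 4))
  single <- which(sim$truth$subject_scope == "single")
  for (j in single) {
    active <- vapply(sim$truth$timecourses,
                     function(m) any(m[, j] != 0), logical(1))
    expect_equal(sum(active), 1)
  }
  # shared sources active everywhere
  for (j in which(sim$truth$subject_scope == "shared")) {
    expect_true(all(vapply(sim$truth$timecourses,
                           function(m) var(m[, j]) > 0, logical(1))))
  }
})

test_that("decimation aliases oscillations to the folded frequency", {
  tr_in <- 0.1; tr_out <- 2
  n <- 4000
  t <- (0:(n - 1)) * tr_in
  x <- sin(2 * pi * 1.1 * t)
  y <- resample_long_tr(x, tr_in, tr_out)
  expect_length(y, n / 20)
  p <- periodogram(y, tr_out)
  folded <- abs(1.1 - round(1.1 * tr_out) / tr_out)
  expect_lt(abs(p$freq[which.max(p$power)] - folded), 1 / (length(y) * tr_out))

  # below the new Nyquist the peak stays put
  x_lo <- sin(2 * pi * 0.1 * t)
  p_lo <- periodogram(resample_long_tr(x_lo, tr_in, tr_out), tr_out)
  expect_equal(p_lo$freq[which.max(p_lo$power)], 0.1, tolerance = 1e-9)

  # constant series passes through; non-integer ratio errors
  expect_equal(resample_long_tr(rep(2, 10), 1, 2), rep(2, 5))
  expect_error(resample_long_tr(x, 0.3, 1), "integer multiple")
})

test_that("alias folding holds across frequencies (property)", {
  tr_in <- 0.05; tr_out <- 1
  n <- 8000
  t <- (0:(n - 1)) * tr_in
  set.seed(31)
  for (f in c(0.7, 1.3, 2.6, 4.2, 7.9)) {
    y <- resample_long_tr(sin(2 * pi * f * t + runif(1)), tr_in, tr_out)
    p <- periodogram(y, tr_out)
    folded <- abs(f - round(f * tr_out) / tr_out)
    expect_lt(abs(p$freq[which.max(p$power)] - folded),
              1 / (length(y) * tr_out) + 1e-12)
  }
})
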