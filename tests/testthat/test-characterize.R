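test_that("consistency ratio follows the sum-of-squares definition", {
  # 5 subjects, 4 time points each; build ICs with prescribed per-subject SS
  n_sub <- 5; seg <- 4
  boundaries <- tibble::tibble(subject_id = sprintf("sub-%02d", 1:n_sub),
                               row_start = seq(1, by = seg, length.out = n_sub),
                               row_end = seq(seg, by = seg, length.out = n_sub))
  make_tc <- function(ss) {
    unlist(lapply(ss, function(s) c(sqrt(s), rep(0, seg - 1))))
  }
  tc <- cbind(make_tc(c(6, 1, 1, 1, 1)),    # dominated: 6/4 = 1.5
              make_tc(rep(2, 5)),           # equal: 2/8 = 0.25
              make_tc(c(3, 0, 0, 0, 0)))    # all in one subject: Inf
  res <- consistency_filter(tc, boundaries)
  expect_equal(res$max_ratio[1], 1.5)
  expect_false(res$keep[1])
  expect_equal(res$dominant_subject[1], "sub-01")
  expect_equal(res$max_ratio[2], 0.25)
  expect_true(res$keep[2])
  expect_equal(res$max_ratio[3], Inf)
  expect_false(res$keep[3])
  # equal SS over 10 subjects gives 1/9
  b10 <- tibble::tibble(subject_id = sprintf("s%02d", 1:10),
                        row_start = seq(1, by = 2, length.out = 10),
                        row_end = seq(2, by = 2, length.out = 10))
  tc10 <- cbind(rep(1, 20))
  expect_equal(consistency_filter(tc10, b10)$max_ratio, 1 / 9)
})

test_that("single-subject input keeps components with a note", {
  tc <- cbind(rnorm(10))
  expect_message(res <- consistency_filter(tc, single_boundary(10)),
                 "single-subject")
  expect_true(res$keep)
  expect_true(is.na(res$max_ratio))
})

test_that("component spectra: single-bin and flat cases", {
  n <- 488; tr <- 0.354
  b <- single_boundary(n)
  # on-grid 0.8 Hz oscillation: all power in the 0.75-1.0 band
  bin <- round(0.8 * n * tr)
  sp <- component_spectrum(on_grid_sin(n, tr, bin), b, tr)
  fr <- sp$band_fractions$fraction
  expect_equal(fr[3], 1, tolerance = 1e-12)
  expect_equal(sum(fr[-3]), 0, tolerance = 1e-12)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  expect_equal(sp$peak_freq, bin / (n * tr), tolerance = 1e-12)

  # white noise: expected fractions proportional to band widths
  set.seed(10)
  fr1 <- replicate(100, {
    component_spectrum(rnorm(n), b, tr)$band_fractions$fraction[1]
  })
  expect_lt(abs(mean(fr1) - 0.25 / 1.15) / (0.25 / 1.15), 0.05)
})

test_that("spectra are averaged per subject segment, equal lengths enforced", {
  n <- 120; tr <- 0.354
  b2 <- tibble::tibble(subject_id = c("a", "b"),
                       row_start = c(1L, n + 1L), row_end = c(n, 2L * n))
  x1 <- rnorm(n); x2 <- rnorm(n)
  sp <- component_spectrum(c(x1, x2), b2, tr)
  avg <- (periodogram(x1, tr)$power + periodogram(x2, tr)$power) / 2
  expect_equal(sp$power, avg, tolerance = 1e-12)
  b_bad <- tibble::tibble(subject_id = c("a", "b"),
                          row_start = c(1L, 101L), row_end = c(100L, 240L))
  expect_error(component_spectrum(rnorm(240), b_bad, tr), "unequal")
})

test_that("rule cascade labels synthetic spectra of each family", {
  set.seed(14)
  tr <- 0.354; n <- 488
  b <- single_boundary(n)
  lab_of <- function(x) {
    classify_component(component_spectrum(x, b, tr))$label
  }
  tech <- generate_source_timecourse(technical_source(), n, tr)
  expect_equal(lab_of(tech), "technical")
  card <- generate_source_timecourse(cardiac_source(base_freq = 1.15,
                                                    jitter_sd = 0.02), n, tr)
  expect_equal(lab_of(card), "cardiac")
  rsn <- generate_source_timecourse(rsn_source(centers = list(c(3, 3, 3))),
                                    n, tr)
  expect_equal(lab_of(rsn), "rsn")
  # 0.45 Hz narrowband: too low for technical/cardiac, not skewed like an
  # RSN, no broadband high-frequency power - falls through to "other"
  odd <- generate_source_timecourse(technical_source(center_freq = 0.45),
                                    n, tr)
  expect_equal(lab_of(odd), "other")
})

test_that("labels, keep flags and fractions are scale invariant", {
  set.seed(15)
  n <- 488; tr <- 0.354
  b2 <- tibble::tibble(subject_id = c("a", "b"),
                       row_start = c(1L, n + 1L), row_end = c(n, 2L * n))
  # clearly subject-dominated course so the keep decision is far from the edge
  x <- c(generate_source_timecourse(technical_source(), n, tr),
         0.3 * generate_source_timecourse(technical_source(), n, tr))
  for (const in c(-3, 0.01, 7)) {
    s1 <- component_spectrum(x, b2, tr)
    s2 <- component_spectrum(const * x, b2, tr)
    expect_equal(s1$band_fractions$fraction, s2$band_fractions$fraction,
                 tolerance = 1e-9)
    expect_equal(classify_component(s1)$label, classify_component(s2)$label)
    c1 <- consistency_filter(cbind(x), b2)
    c2 <- consistency_filter(cbind(const * x), b2)
    expect_equal(c1$keep, c2$keep)
    expect_equal(c1$max_ratio, c2$max_ratio, tolerance = 1e-9)
  }
})

test_that("heart-rate estimation converts the spectral peak to bpm", {
  n <- 500; tr <- 0.2  # 1.2 Hz exactly on this grid
  b <- single_boundary(n)
  sp <- component_spectrum(on_grid_sin(n, tr, round(1.2 * n * tr)), b, tr)
  hr <- heart_rate_estimate(sp)
  expect_equal(hr$peak_hz, 1.2, tolerance = 1e-9)
  expect_equal(hr$bpm, 72, tolerance = 1e-7)
  sp1 <- component_spectrum(on_grid_sin(n, tr, round(1.0 * n * tr)), b, tr)
  expect_equal(heart_rate_estimate(sp1)$bpm, 60, tolerance = 1e-7)
  # simulated cardiac with jitter: estimate near the base rate
  set.seed(16)
  errs <- replicate(20, {
    x <- generate_source_timecourse(cardiac_source(base_freq = 1.15,
                                                   jitter_sd = 0.02),
                                    488, 0.354)
    sp <- component_spectrum(x, single_boundary(488), 0.354)
    heart_rate_estimate(sp)$peak_hz - 1.15
  })
  expect_true(all(abs(errs) <= 0.05))
})

test_that("low-frequency band table reproduces width ratios and additivity", {
  n <- 1000; tr <- 0.354
  b <- single_boundary(n)
  # power entirely below 0.1 Hz
  lowf <- on_grid_sin(n, tr, round(0.05 * n * tr))
  row <- lowfreq_band_table(lowf, b, tr)
  expect_equal(as.numeric(row), c(100, 100, 0, 0), tolerance = 1e-9)
  # flat spectrum: fractions equal band-width ratios
  set.seed(17)
  rows <- dplyr::bind_rows(replicate(100, {
    lowfreq_band_table(rnorm(n), b, tr)
  }, simplify = FALSE))
  avg <- colMeans(rows)
  expect_equal(as.numeric(avg),
               100 * c(0.24, 0.09, 0.15, 1.15) / 1.39, tolerance = 0.05)
  # additivity of the union column
  x <- rnorm(n)
  r <- lowfreq_band_table(x, b, tr)
  expect_equal(r$pct_0.01_0.25, r$pct_0.01_0.10 + r$pct_0.10_0.25,
               tolerance = 1e-9)
})

test_that("characterize assembles one labeled row per component", {
  sim <- simulate_dataset(tiny_sim_config(seed = 19))
  pre <- lapply(seq_along(sim$subjects), function(i) {
    preprocess(sim$subjects[[i]], motion = sim$motion[[i]], n_discard = 16)
  })
  d <- decompose(concatenate_subjects(pre), n_pcs = 5, n_ics = 5, seed = 2)
  ch <- characterize(d)
  expect_equal(nrow(ch), 5)
  expect_true(all(ch$label %in% c("pulsation", "rsn", "technical",
                                  "cardiac", "other")))
  fr <- as.matrix(ch[, grep("^frac_", names(ch))])
  expect_equal(rowSums(fr), rep(1, 5), tolerance = 1e-9)
  # downstream statistics invariant to component order and sign
  d_perm <- d
  perm <- c(3, 1, 5, 2, 4)
  d_perm$ic_timecourses <- d$ic_timecourses[, perm] %*% diag(c(-1, 1, -1, 1, 1))
  d_perm$spatial_maps <- diag(c(-1, 1, -1, 1, 1)) %*% d$spatial_maps[perm, ]
  ch_p <- characterize(d_perm)
  expect_equal(ch_p$label, ch$label[perm])
  expect_equal(ch_p$max_ratio, ch$max_ratio[perm], tolerance = 1e-9)
  expect_equal(as.matrix(ch_p[, grep("^frac_", names(ch_p))]),
               fr[perm, ], tolerance = 1e-9, ignore_attr = TRUE)
})
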