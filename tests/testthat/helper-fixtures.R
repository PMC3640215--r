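# shared fixtures: everything is generated in code, nothing read from disk

# sinusoid exactly on the DFT grid of an n-point series sampled at tr
on_grid_sin <- function(n, tr, bin, phase = 0) {
  sin(2 * pi * bin * (0:(n - 1)) / n + phase)
}

grid_freq <- function(n, tr, bin) bin / (n * tr)

make_vts <- function(data, tr = 0.354, id = "sub-01") {
  voxel_ts(data, tr_seconds = tr, subject_id = id)
}

single_boundary <- function(n, id = "sub-01") {
  tibble::tibble(subject_id = id, row_start = 1L, row_end = as.integer(n))
}

# all permutations of 1:n (brute-force assignment oracle)
.all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in .all_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out <- c(out, list(append(p, n, after = pos)))
    }
  }
  out
}

# small simulation used by several io/pipeline tests
tiny_sim_config <- function(seed = 11) {
  specs <- list(
    rsn_source(centers = list(c(3, 3, 3)), radii = 2, mod_freq = 0.1),
    pulsation_source(band = c(0.6, 1.3), centers = list(c(6, 5, 4)),
                     radii = 2, mod_freq = 0.1),
    cardiac_source(base_mean = 1.1, base_sd = 0.05, jitter_sd = 0.02,
                   centers = list(c(2, 6, 2), c(6, 2, 5), c(4, 7, 3)),
                   radii = 2.5, amplitude = 2)
  )
  sim_config(n_subjects = 3, grid_shape = c(8, 8, 6), n_volumes = 96,
             tr_seconds = 0.354, snr = 5, seed = seed, source_specs = specs,
             discard_volumes = 16)
}

# --- end-to-end study runs shared by the acceptance tests -------------------
# one full pipeline run on the default study conditions for a given seed,
# scored against ground truth; memoized so several tests reuse the same runs
.study_cache <- new.env(parent = emptyenv())

study_run <- function(seed) {
  key <- paste0("s", seed)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  sim <- simulate_dataset(default_sim_config(seed = seed))
  pre <- lapply(seq_along(sim$subjects), function(i) {
    preprocess(sim$subjects[[i]], motion = sim$motion[[i]], n_discard = 24,
               cutoff_hz = 0.25)
  })
  gm <- concatenate_subjects(pre)
  n_src <- length(sim$truth$labels)
  d <- decompose(gm, n_pcs = n_src, n_ics = n_src, seed = seed + 500)
  ch <- characterize(d)
  truth_tc <- do.call(rbind, lapply(sim$truth$timecourses,
                                    function(m) m[-(1:24), , drop = FALSE]))
  mt <- match_components(d$ic_timecourses, truth_tc)
  map_r <- vapply(seq_len(n_src), function(j) {
    abs(cor(d$spatial_maps[mt$component[j], ], sim$truth$spatial_maps[j, ]))
  }, numeric(1))
  res <- list(
    labels_true = sim$truth$labels,
    scope = sim$truth$subject_scope,
    tc_r = mt$r,
    map_r = map_r,
    keep = ch$keep[mt$component],
    max_ratio = ch$max_ratio[mt$component],
    labels_est = ch$label[mt$component],
    hr_est = ch$heart_rate_bpm[mt$component] / 60,
    rates_true = sim$truth$cardiac_rates
  )
  .study_cache[[key]] <- res
  res
}

study_runs <- function(seeds = 1:20) lapply(seeds, study_run)
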