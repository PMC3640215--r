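#' Source specifications for the multi-subject fMRI simulator
#'
#' A `source_spec` describes one temporally independent signal source: its
#' spectral shape (what the time course looks like in frequency space), its
#' spatial map on the voxel grid, and whether it is shared by all subjects or
#' present in a single subject only. Four families are provided, mirroring the
#' component types seen in high-frequency resting-state decompositions:
#'
#' * `rsn_source()`: network-like source with a skewed spectrum - amplitude is
#'   highest just above the high-pass cutoff and decreases continually with
#'   frequency (`power ~ f^(-2 * decay)` above `cutoff_lo`). The spatial map is
#'   a sum of smooth Gaussian blobs ("nodes").
#' * `cardiac_source()`: a frequency-modulated oscillator around a subject's
#'   heart rate. With `subject_scope = "single"`, one instance per subject is
#'   created by [simulate_dataset()], each with its own base rate drawn from
#'   `N(base_mean, base_sd)`; the slow sinusoidal frequency modulation (SD
#'   `jitter_sd` Hz) broadens the spectral peak the way heart-rate variability
#'   does.
#' * `technical_source()`: narrowband scanner artifact (center +- bandwidth/2)
#'   whose spatial map alternates sign in blocks of `band_period` slices along
#'   the slice axis, constant within each slice.
#' * `pulsation_source()`: broadband band-limited source (flat spectrum between
#'   `band[1]` and `band[2]`), spatially a set of blobs standing in for
#'   ventricles and large vessels.
#'
#' Noise-based sources (`rsn`, `technical`, `pulsation`) are generated by
#' shaping white Gaussian noise in the Fourier domain, applying a slow
#' log-normal amplitude modulation (depth `mod_depth`, modulator band
#' `<= mod_freq` Hz) and re-projecting onto the band. The modulation gives the
#' sources the bursty, super-Gaussian character of real physiological signal
#' trains; without it a band-limited Gaussian process carries no
#' higher-order structure for ICA to latch onto.
#'
#' @param centers list of numeric length-3 voxel coordinates of blob centers
#'   (1-based grid coordinates).
#' @param radii numeric vector of blob standard radii in voxels (recycled).
#' @param node_weights relative amplitude of each blob (recycled).
#' @param decay spectral decay exponent of the amplitude envelope
#'   (`power ~ f^(-2*decay)`).
#' @param cutoff_lo lower edge (Hz) of the source band.
#' @param amplitude scalar multiplier of the spatial map.
#' @param mod_depth,mod_freq amplitude-modulation depth (log-scale SD) and
#'   modulator lowpass cutoff (Hz).
#' @param subject_scope `"shared"` (every subject carries its own realization
#'   of the source on a common map) or `"single"` (present in one subject).
#' @return an object of class `source_spec`.
#' @seealso [simulate_dataset()], [generate_source_timecourse()],
#'   [generate_spatial_map()]
#' @export
rsn_source <- function(centers, radii = 3, node_weights = 1, decay = 0.75,
                       cutoff_lo = 0.25, amplitude = 1,
                       mod_depth = 0.7, mod_freq = 0.02,
                       subject_scope = "shared") {
  new_source_spec("rsn", subject_scope,
                  spectral = list(decay = decay, cutoff_lo = cutoff_lo,
                                  mod_depth = mod_depth, mod_freq = mod_freq),
                  spatial = list(centers = centers, radii = radii,
                                 node_weights = node_weights,
                                 amplitude = amplitude))
}

#' @rdname rsn_source
#' @param base_freq explicit oscillator base frequency in Hz; if `NULL`, one
#'   rate per subject is drawn from `N(base_mean, base_sd)` at simulation time.
#' @param base_mean,base_sd normal law for per-subject base rates (Hz).
#' @param base_range the rate law is truncated to this interval (Hz): resting
#'   heart rates cluster in a band around 1-1.3 Hz, and only rates below
#'   Nyquist are representable at all.
#' @param jitter_sd SD of the instantaneous-frequency modulation (Hz);
#'   0 gives a pure oscillation.
#' @export
cardiac_source <- function(base_freq = NULL, base_mean = 1.15, base_sd = 0.08,
                           base_range = c(1.0, 1.3),
                           jitter_sd = 0.03, centers = list(), radii = 3,
                           amplitude = 1, subject_scope = "single") {
  new_source_spec("cardiac", subject_scope,
                  spectral = list(base_freq = base_freq, base_mean = base_mean,
                                  base_sd = base_sd, base_range = base_range,
                                  jitter_sd = jitter_sd),
                  spatial = list(centers = centers, radii = radii,
                                 node_weights = 1, amplitude = amplitude))
}

#' @rdname rsn_source
#' @param center_freq narrowband center frequency in Hz.
#' @param bandwidth full width of the retained band in Hz.
#' @param band_period number of consecutive slices sharing a sign in the
#'   slice-banded spatial map.
#' @export
technical_source <- function(center_freq = 0.8, bandwidth = 0.05,
                             band_period = 2, amplitude = 0.45,
                             mod_depth = 0.7, mod_freq = 0.02,
                             subject_scope = "shared") {
  new_source_spec("technical", subject_scope,
                  spectral = list(center_freq = center_freq,
                                  bandwidth = bandwidth,
                                  mod_depth = mod_depth, mod_freq = mod_freq),
                  spatial = list(band_period = band_period,
                                 amplitude = amplitude))
}

#' @rdname rsn_source
#' @param band length-2 numeric, lower and upper band edge in Hz.
#' @export
pulsation_source <- function(band = c(0.6, 1.4), centers, radii = 3,
                             node_weights = 1, amplitude = 1,
                             mod_depth = 0.7, mod_freq = 0.02,
                             subject_scope = "shared") {
  stopifnot(length(band) == 2, band[1] < band[2], band[1] > 0)
  new_source_spec("pulsation", subject_scope,
                  spectral = list(band = band,
                                  mod_depth = mod_depth, mod_freq = mod_freq),
                  spatial = list(centers = centers, radii = radii,
                                 node_weights = node_weights,
                                 amplitude = amplitude))
}

new_source_spec <- function(kind, subject_scope, spectral, spatial) {
  subject_scope <- match.arg(subject_scope, c("shared", "single"))
  structure(list(kind = kind, subject_scope = subject_scope,
                 spectral = spectral, spatial = spatial),
            class = "source_spec")
}

#' @export
print.source_spec <- function(x, ...) {
  cat("<source_spec> kind:", x$kind, " scope:", x$subject_scope, "\n")
  invisible(x)
}

#' Ellipsoidal brain-like mask on a rectangular voxel grid
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param scale semi-axes of the ellipsoid as a fraction of each grid extent.
#' @return logical 3D array of dimension `grid_shape`.
#' @export
ellipsoid_mask <- function(grid_shape, scale = c(0.567, 0.567, 0.65)) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4))
  ctr <- (grid_shape + 1) / 2
  ax <- grid_shape * scale
  g <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                   z = seq_len(grid_shape[3]))
  inside <- ((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
    ((g$z - ctr[3]) / ax[3])^2 <= 1
  array(inside, dim = grid_shape)
}

#' Simulation configuration
#'
#' Bundles everything [simulate_dataset()] needs: cohort size, grid and mask,
#' acquisition length and TR, signal-to-noise ratio, the source list and the
#' RNG seed. `snr` is the ratio of total source variance to white-noise
#' variance, averaged over in-mask voxels.
#'
#' @param n_subjects number of subjects.
#' @param grid_shape integer length-3 voxel grid.
#' @param n_volumes volumes per subject (>= 64).
#' @param tr_seconds sampling interval in seconds.
#' @param snr source-to-noise variance ratio (> 0).
#' @param seed integer RNG seed; identical configs give bit-identical output.
#' @param source_specs list of [source_spec][rsn_source] objects.
#' @param mask logical 3D array; default [ellipsoid_mask()] of `grid_shape`.
#' @param motion_frac fraction of the noise variance injected as
#'   motion-correlated drift (0 disables motion coupling).
#' @param discard_volumes initial volumes the downstream pipeline is expected
#'   to drop (recorded for provenance; the simulator still writes all volumes).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_subjects, grid_shape, n_volumes, tr_seconds, snr,
                       seed, source_specs, mask = NULL, motion_frac = 0.1,
                       discard_volumes = 24) {
  stopifnot(n_subjects >= 1, length(grid_shape) == 3, all(grid_shape >= 4),
            n_volumes >= 64, tr_seconds > 0, snr > 0,
            motion_frac >= 0, discard_volumes >= 0)
  .stop_if(!length(source_specs) ||
             !all(vapply(source_specs, inherits, logical(1), "source_spec")),
           "source_specs must be a non-empty list of source_spec objects")
  if (is.null(mask)) mask <- ellipsoid_mask(grid_shape)
  stopifnot(identical(dim(mask), as.integer(grid_shape)))
  .stop_if(!any(mask), "mask has no voxels")
  structure(list(n_subjects = as.integer(n_subjects),
                 grid_shape = as.integer(grid_shape),
                 n_volumes = as.integer(n_volumes),
                 tr_seconds = tr_seconds, snr = snr, seed = as.integer(seed),
                 source_specs = source_specs, mask = mask,
                 motion_frac = motion_frac,
                 discard_volumes = as.integer(discard_volumes)),
            class = "sim_config")
}

#' Default desk-scale study configuration
#'
#' Five subjects on a 12 x 12 x 8 grid (ellipsoid mask, ~900 in-mask voxels),
#' 512 volumes at TR = 0.354 s, snr = 5, with four shared sources (two two-node
#' RSN-like networks, one 0.8 Hz slice-banded technical artifact, one broadband
#' 0.6-1.4 Hz ventricular/vessel pulsation source) plus one single-subject
#' cardiac oscillator per subject with base rates drawn from N(1.15, 0.08) Hz.
#'
#' @param seed integer RNG seed.
#' @return a [sim_config()] object.
#' @export
default_sim_config <- function(seed = 1L) {
  specs <- list(
    rsn_source(centers = list(c(3.5, 3.5, 4), c(8.5, 3.5, 5)),
               radii = c(3, 2.5)),
    rsn_source(centers = list(c(8.5, 8.5, 5), c(3.5, 8.5, 4)),
               radii = c(3, 2.5)),
    technical_source(center_freq = 0.8, bandwidth = 0.05, band_period = 2,
                     amplitude = 0.45),
    pulsation_source(band = c(0.6, 1.4),
                     centers = list(c(6, 6, 4), c(2.5, 6, 3), c(10.5, 6, 3)),
                     radii = c(2.5, 2, 2), node_weights = c(1, 0.8, 0.8)),
    cardiac_source(base_mean = 1.15, base_sd = 0.08, jitter_sd = 0.03,
                   centers = list(c(3, 6, 5), c(9, 3, 5), c(6, 3, 2),
                                  c(3, 9, 2), c(9, 6, 6)),
                   radii = 3)
  )
  sim_config(n_subjects = 5, grid_shape = c(12, 12, 8), n_volumes = 512,
             tr_seconds = 0.354, snr = 5, seed = seed, source_specs = specs)
}

# magnitude envelope of a spec on the folded two-sided DFT frequency grid
.spec_envelope <- function(spec, f_folded, nyquist) {
  sp <- spec$spectral
  switch(spec$kind,
    rsn = {
      .stop_if(sp$cutoff_lo >= nyquist,
               "rsn cutoff_lo (", sp$cutoff_lo, " Hz) must be below Nyquist (",
               round(nyquist, 4), " Hz)")
      ifelse(f_folded >= sp$cutoff_lo, (f_folded / sp$cutoff_lo)^(-sp$decay), 0)
    },
    technical = {
      .stop_if(sp$center_freq >= nyquist,
               "technical center frequency (", sp$center_freq,
               " Hz) must be below Nyquist (", round(nyquist, 4), " Hz)")
      as.numeric(abs(f_folded - sp$center_freq) <= sp$bandwidth / 2)
    },
    pulsation = {
      .stop_if(sp$band[1] >= nyquist,
               "pulsation band must start below Nyquist (",
               round(nyquist, 4), " Hz)")
      hi <- min(sp$band[2], nyquist)
      as.numeric(f_folded >= sp$band[1] & f_folded <= hi)
    },
    stop("no spectral envelope for kind ", spec$kind)
  )
}

#' Generate one source time course
#'
#' Draws a unit-variance time course from the current RNG state according to
#' the spectral law of `spec`. Noise-based kinds (`rsn`, `technical`,
#' `pulsation`) are white Gaussian noise shaped by the kind's magnitude
#' envelope in the Fourier domain, amplitude-modulated by a slow log-normal
#' envelope, re-projected onto the band and standardized. `cardiac` integrates
#' an instantaneous frequency (base rate plus slow sinusoidal modulation of SD
#' `jitter_sd`) into an oscillator phase.
#'
#' @param spec a [source_spec][rsn_source]. A `cardiac` spec must carry a
#'   concrete `base_freq`.
#' @param n_volumes number of time points.
#' @param tr sampling interval in seconds.
#' @return numeric vector of length `n_volumes`, mean 0 and variance 1.
#' @export
generate_source_timecourse <- function(spec, n_volumes, tr) {
  stopifnot(inherits(spec, "source_spec"), n_volumes >= 16, tr > 0)
  nyq <- 1 / (2 * tr)
  n <- as.integer(n_volumes)
  if (spec$kind == "cardiac") {
    sp <- spec$spectral
    base <- sp$base_freq
    .stop_if(is.null(base),
             "cardiac spec has no base_freq; per-subject rates are drawn by ",
             "simulate_dataset()")
    .stop_if(base >= nyq, "cardiac base frequency (", base,
             " Hz) must be below Nyquist (", round(nyq, 4), " Hz)")
    t <- (0:(n - 1)) * tr
    f_mod <- 0.05  # slow modulation, ~ respiratory-sinus-arrhythmia timescale
    f_inst <- base + sqrt(2) * sp$jitter_sd * sin(2 * pi * f_mod * t +
                                                    runif(1, 0, 2 * pi))
    x <- sin(2 * pi * cumsum(f_inst) * tr + runif(1, 0, 2 * pi))
  } else {
    f <- (0:(n - 1)) / (n * tr)
    f_folded <- pmin(f, 1 / tr - f)
    env <- .spec_envelope(spec, f_folded, nyq)
    .stop_if(all(env == 0), "spectral envelope of ", spec$kind,
             " source is empty on this frequency grid")
    x <- Re(fft(fft(rnorm(n)) * env, inverse = TRUE)) / n
    if (spec$spectral$mod_depth > 0) {
      # the modulator band always includes the first nonzero bin, so short
      # series still get a (slower-than-requested is impossible) modulation
      mod_cut <- max(spec$spectral$mod_freq, 1 / (n * tr))
      z <- Re(fft(fft(rnorm(n)) * (f_folded <= mod_cut),
                  inverse = TRUE)) / n
      if (sd(z) > 0) {
        z <- (z - mean(z)) / sd(z)
        x <- x * exp(spec$spectral$mod_depth * z)
        # re-project onto the band so modulation sidelobes stay inside it
        x <- Re(fft(fft(x) * (env > 0), inverse = TRUE)) / n
      }
    }
  }
  x <- x - mean(x)
  x / sd(x)
}

#' Generate a source spatial map
#'
#' Blob kinds (`rsn`, `cardiac`, `pulsation`) produce smooth localized
#' positive weights, a sum of Gaussian nodes `exp(-d^2 / (2 r^2))`; a radius of
#' 0 degenerates to a single-voxel indicator. The `technical` kind is constant
#' within each slice and alternates sign in blocks of `band_period` slices
#' along the third (slice) axis. Maps from different sources may overlap -
#' separating temporally independent sources with overlapping spatial
#' distributions is precisely what temporal ICA is for.
#'
#' @param spec a [source_spec][rsn_source].
#' @param grid_shape integer length-3 grid dimensions.
#' @param voxel_index optional V x 3 integer matrix of (1-based) voxel
#'   coordinates defining the columns; default: all grid voxels in column-major
#'   (first-axis-fastest) order.
#' @return numeric vector of weights, one per row of `voxel_index`.
#' @export
generate_spatial_map <- function(spec, grid_shape, voxel_index = NULL) {
  stopifnot(inherits(spec, "source_spec"), length(grid_shape) == 3,
            all(grid_shape >= 4))
  if (is.null(voxel_index)) {
    voxel_index <- as.matrix(expand.grid(seq_len(grid_shape[1]),
                                         seq_len(grid_shape[2]),
                                         seq_len(grid_shape[3])))
  }
  sp <- spec$spatial
  if (spec$kind == "technical") {
    block <- (voxel_index[, 3] - 1) %/% sp$band_period
    w <- sp$amplitude * (-1)^block
  } else {
    centers <- sp$centers
    .stop_if(!length(centers), spec$kind, " source has no blob centers")
    radii <- rep_len(sp$radii, length(centers))
    wts <- rep_len(sp$node_weights, length(centers))
    w <- numeric(nrow(voxel_index))
    for (i in seq_along(centers)) {
      d2 <- rowSums((voxel_index - matrix(centers[[i]], nrow(voxel_index), 3,
                                          byrow = TRUE))^2)
      if (radii[i] <= 0) {
        w <- w + wts[i] * as.numeric(d2 == min(d2) & d2 < 1)
      } else {
        w <- w + wts[i] * exp(-d2 / (2 * radii[i]^2))
      }
    }
    w <- sp$amplitude * w
  }
  .stop_if(!any(w != 0), "spatial map of ", spec$kind,
           " source has no nonzero voxel")
  w
}

# expand "single"-scope cardiac family specs into one concrete spec per subject;
# rates are drawn from a normal law truncated to the critically sampled band
.expand_specs <- function(specs, n_subjects, nyquist) {
  draw_rate <- function(mean, sd, range) {
    lo <- max(range[1], 0)
    hi <- min(range[2], 0.98 * nyquist)
    .stop_if(lo >= hi, "cardiac rate range [", range[1], ", ", range[2],
             "] Hz is incompatible with Nyquist ", round(nyquist, 4), " Hz")
    for (i in 1:1000) {
      r <- rnorm(1, mean, sd)
      if (r >= lo && r <= hi) return(r)
    }
    stop("cardiac rate law N(", mean, ", ", sd, ") never hits [",
         lo, ", ", hi, "] Hz")
  }
  out <- list(); owner <- integer(0)
  for (spec in specs) {
    if (spec$kind == "cardiac" && spec$subject_scope == "single" &&
        is.null(spec$spectral$base_freq)) {
      rates <- vapply(seq_len(n_subjects), function(i)
        draw_rate(spec$spectral$base_mean, spec$spectral$base_sd,
                  spec$spectral$base_range), numeric(1))
      centers <- spec$spatial$centers
      .stop_if(!length(centers), "cardiac family spec needs blob centers")
      for (s in seq_len(n_subjects)) {
        sp <- spec
        sp$spectral$base_freq <- rates[s]
        sp$spatial$centers <- centers[((s - 1) %% length(centers)) + 1]
        out <- c(out, list(sp)); owner <- c(owner, s)
      }
    } else {
      out <- c(out, list(spec))
      owner <- c(owner, if (spec$subject_scope == "single") 1L else NA_integer_)
    }
  }
  list(specs = out, owner = owner)
}

#' Simulate a multi-subject 4D dataset with known ground truth
#'
#' Each subject's time-by-voxel matrix is the mixing product of that subject's
#' source time courses with the (subject-invariant) spatial maps, plus white
#' Gaussian noise scaled to the configured snr and a small motion-correlated
#' drift. Shared sources get an independent realization per subject on a
#' common map - exactly the structure a temporally concatenated group ICA
#' recovers as one component with energy in every subject. Single-subject
#' sources (the cardiac family) are nonzero in exactly one subject, which is
#' what the downstream consistency criterion is designed to flag.
#'
#' @param config a [sim_config()].
#' @return an object of class `hft_simulation`: a list with `subjects` (list of
#'   [voxel_ts()] matrices), `motion` (list of T x 6 motion-parameter
#'   matrices), `truth` (ground-truth bundle: `timecourses` per subject,
#'   concatenated `timecourses_concat`, `spatial_maps` source-by-voxel,
#'   `labels`, `subject_scope`, `owner`, `cardiac_rates`, noise level `sigma`),
#'   `mask`, `voxel_index` and the `config` itself.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mask <- config$mask
  voxel_index <- which(mask, arr.ind = TRUE)
  dimnames(voxel_index) <- NULL
  V <- nrow(voxel_index)
  n_sub <- config$n_subjects
  n <- config$n_volumes
  tr <- config$tr_seconds

  ex <- .expand_specs(config$source_specs, n_sub, nyquist = 1 / (2 * tr))
  specs <- ex$specs; owner <- ex$owner
  S <- length(specs)
  maps <- do.call(rbind, lapply(specs, generate_spatial_map,
                                grid_shape = config$grid_shape,
                                voxel_index = voxel_index))
  labels <- vapply(specs, `[[`, character(1), "kind")
  scope <- vapply(specs, `[[`, character(1), "subject_scope")
  sigma <- sqrt(mean(colSums(maps^2)) / config$snr)

  subjects <- vector("list", n_sub)
  motion <- vector("list", n_sub)
  tcs <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    tc <- matrix(0, n, S)
    for (j in seq_len(S)) {
      if (scope[j] == "shared" || identical(owner[j], s)) {
        tc[, j] <- generate_source_timecourse(specs[[j]], n, tr)
      }
    }
    noise <- matrix(rnorm(n * V, 0, sigma), n, V)
    mo <- .simulate_motion(n, tr)
    data <- tc %*% maps + noise
    if (config$motion_frac > 0) {
      mo_std <- scale(mo)
      B <- matrix(rnorm(6 * V, 0, sigma * sqrt(config$motion_frac / 6)), 6, V)
      data <- data + mo_std %*% B
    }
    subjects[[s]] <- voxel_ts(data, tr_seconds = tr, voxel_index = voxel_index,
                              subject_id = sprintf("sub-%02d", s))
    motion[[s]] <- mo
    tcs[[s]] <- tc
  }
  rates <- vapply(specs, function(sp)
    if (sp$kind == "cardiac") sp$spectral$base_freq else NA_real_, numeric(1))
  truth <- list(timecourses = tcs,
                timecourses_concat = do.call(rbind, tcs),
                spatial_maps = maps, labels = labels, subject_scope = scope,
                owner = owner,
                cardiac_rates = rates[labels == "cardiac"],
                sigma = sigma)
  structure(list(subjects = subjects, motion = motion, truth = truth,
                 mask = mask, voxel_index = voxel_index, config = config),
            class = "hft_simulation")
}

#' @export
print.hft_simulation <- function(x, ...) {
  cat("<hft_simulation>", length(x$subjects), "subjects,",
      nrow(x$voxel_index), "in-mask voxels,", x$config$n_volumes,
      "volumes @ TR", x$config$tr_seconds, "s\n")
  cat("  sources:", paste(x$truth$labels, collapse = ", "), "\n")
  invisible(x)
}

# smooth 6-column random-walk motion parameters (3 translations, 3 rotations)
.simulate_motion <- function(n, tr) {
  lowpass <- function(x, cutoff = 0.1) {
    f <- (0:(n - 1)) / (n * tr)
    keep <- pmin(f, 1 / tr - f) <= cutoff
    Re(fft(fft(x) * keep, inverse = TRUE)) / n
  }
  scales <- c(rep(0.05, 3), rep(5e-4, 3))  # mm, radians
  mo <- vapply(scales, function(sc) lowpass(cumsum(rnorm(n, 0, sc))),
               numeric(n))
  colnames(mo) <- c("trans_x", "trans_y", "trans_z",
                    "rot_x", "rot_y", "rot_z")
  mo
}

#' Decimate a time series to a longer TR
#'
#' Keeps every k-th sample, where `k = tr_out / tr_in` must be an integer:
#' the discrete analogue of scanning the same signal at a long TR. Any
#' oscillation above the new Nyquist frequency shows up at its folded alias
#' `|f - round(f * tr_out) / tr_out|`.
#'
#' @param series numeric vector sampled at `tr_in`.
#' @param tr_in,tr_out original and target sampling intervals (s).
#' @return numeric vector of every k-th sample.
#' @export
resample_long_tr <- function(series, tr_in, tr_out) {
  stopifnot(is.numeric(series), tr_in > 0, tr_out > 0)
  k <- tr_out / tr_in
  .stop_if(abs(k - round(k)) > 1e-8,
           "tr_out must be an integer multiple of tr_in (ratio ", k, ")")
  series[seq(1, length(series), by = round(k))]
}
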