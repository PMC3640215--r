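#' Subject-consistency variance-ratio filter
#'
#' For every component time course, computes each subject's sum of squares and
#' the ratio of the largest subject's sum of squares to the summed sum of
#' squares of all other subjects. A component is discarded when that ratio
#' exceeds 1 - i.e. when a single subject contributes more variance to the
#' component than all other subjects combined, the signature of a
#' subject-specific (typically cardiac) source in a group decomposition.
#'
#' @param d an [hft_decomposition][fastica_temporal] (or a plain time-by-IC
#'   matrix).
#' @param boundaries subject-boundaries tibble (`subject_id`, `row_start`,
#'   `row_end`); taken from `d` when omitted.
#' @return tibble with one row per component: `component`, `max_ratio`,
#'   `dominant_subject`, `keep`, and a list-column `per_subject_ss`.
#' @export
consistency_filter <- function(d, boundaries = NULL) {
  tc <- if (inherits(d, "hft_decomposition")) d$ic_timecourses else as.matrix(d)
  if (is.null(boundaries) && inherits(d, "hft_decomposition")) {
    boundaries <- d$boundaries
  }
  .stop_if(is.null(boundaries), "subject boundaries are required")
  .stop_if(max(boundaries$row_end) != nrow(tc) ||
             min(boundaries$row_start) != 1,
           "boundaries do not cover all ", nrow(tc), " rows")
  n_sub <- nrow(boundaries)
  ss <- vapply(seq_len(n_sub), function(s) {
    rows <- boundaries$row_start[s]:boundaries$row_end[s]
    colSums(tc[rows, , drop = FALSE]^2)
  }, numeric(ncol(tc)))
  ss <- matrix(ss, ncol = n_sub)  # components x subjects
  if (n_sub == 1) {
    message("single-subject input: consistency ratio undefined; ",
            "components kept")
    return(tibble::tibble(component = seq_len(ncol(tc)),
                          max_ratio = NA_real_,
                          dominant_subject = boundaries$subject_id[1],
                          keep = TRUE,
                          per_subject_ss = asplit(ss, 1)))
  }
  tot <- rowSums(ss)
  ratio <- ss / (tot - ss)     # Inf when one subject holds all the variance
  max_idx <- max.col(ratio, ties.method = "first")
  max_ratio <- ratio[cbind(seq_len(nrow(ratio)), max_idx)]
  tibble::tibble(component = seq_len(ncol(tc)),
                 max_ratio = max_ratio,
                 dominant_subject = boundaries$subject_id[max_idx],
                 keep = max_ratio <= 1,
                 per_subject_ss = asplit(ss, 1))
}

#' Segment-averaged power spectrum of a component time course
#'
#' Splits a concatenated component time course at the subject boundaries,
#' computes the raw periodogram of each (equal-length) segment, and averages
#' across subjects on the common frequency grid. Averaging per segment avoids
#' the spurious broadband energy that the discontinuities at concatenation
#' boundaries would inject into a single long transform. Band fractions are
#' normalized by the total power inside `[band_edges[1],
#' band_edges[length(band_edges)]]`.
#'
#' @param tc numeric vector: a concatenated component time course.
#' @param boundaries subject-boundaries tibble.
#' @param tr sampling interval in seconds.
#' @param band_edges ordered band edges in Hz.
#' @return object of class `hft_spectrum`: `freq`, `power`, `band_edges`,
#'   `band_fractions` (tibble from [band_fractions()]), `peak_freq` (argmax
#'   inside the analyzed range), `tr`.
#' @export
component_spectrum <- function(tc, boundaries, tr,
                               band_edges = c(0.25, 0.5, 0.75, 1, 1.25, 1.4)) {
  tc <- as.numeric(tc)
  .stop_if(max(boundaries$row_end) != length(tc),
           "boundaries do not match the time course length")
  lens <- boundaries$row_end - boundaries$row_start + 1
  .stop_if(length(unique(lens)) != 1,
           "subject segments have unequal lengths: ",
           paste(unique(lens), collapse = ", "))
  .stop_if(lens[1] < 2 * (length(band_edges) - 1) * 2,
           "segments too short for the requested band resolution")
  pg <- lapply(seq_len(nrow(boundaries)), function(s) {
    periodogram(tc[boundaries$row_start[s]:boundaries$row_end[s]], tr)
  })
  freq <- pg[[1]]$freq
  power <- Reduce(`+`, lapply(pg, `[[`, "power")) / length(pg)
  bf <- band_fractions(freq, power, band_edges)
  rng <- freq >= band_edges[1] & freq <= band_edges[length(band_edges)]
  peak <- freq[rng][which.max(power[rng])]
  structure(list(freq = freq, power = power, band_edges = band_edges,
                 band_fractions = bf, peak_freq = peak, tr = tr),
            class = "hft_spectrum")
}

#' @export
print.hft_spectrum <- function(x, ...) {
  cat("<hft_spectrum> peak", round(x$peak_freq, 3), "Hz; band fractions:\n")
  print(x$band_fractions)
  invisible(x)
}

#' Default classification thresholds
#'
#' All thresholds of the rule cascade in [classify_component()], exposed so
#' they can be tuned. Defaults encode the qualitative spectral signatures of
#' the four component families: technical artifacts concentrate nearly all
#' power in 0.75-1.0 Hz as a sharp peak; cardiac components peak at the heart
#' rate (1.0-1.35 Hz); RSN-like components have skewed spectra with strictly
#' decreasing band fractions; pulsation components are broadband above 0.6 Hz.
#'
#' @param technical_band_min minimum fraction in 0.75-1.0 Hz for `technical`.
#' @param technical_sharpness minimum max/median power ratio for `technical`.
#' @param cardiac_peak_range heart-rate peak window in Hz.
#' @param cardiac_band_min minimum fraction in 1.0-1.4 Hz for `cardiac`.
#' @param rsn_first_band_min minimum fraction in the lowest band for `rsn`.
#' @param rsn_tie_tol one non-decrease between adjacent bands is tolerated if
#'   within this relative amount (a "tie").
#' @param pulsation_hi_min minimum fraction above 0.6 Hz for `pulsation`.
#' @return named list of thresholds.
#' @export
classification_rules <- function(technical_band_min = 0.5,
                                 technical_sharpness = 10,
                                 cardiac_peak_range = c(1.0, 1.35),
                                 cardiac_band_min = 0.4,
                                 rsn_first_band_min = 0.35,
                                 rsn_tie_tol = 0.05,
                                 pulsation_hi_min = 0.5) {
  as.list(environment())
}

#' Rule-based component classification
#'
#' Deterministic cascade over the component's spectral fingerprint, evaluated
#' on the five-band high-frequency fractions (0.25-0.5, 0.5-0.75, 0.75-1.0,
#' 1.0-1.25, 1.25-1.4 Hz):
#'
#' 1. `technical` - fraction in 0.75-1.0 Hz at least `technical_band_min` and
#'    spectral sharpness (max power / median power over the analyzed range) at
#'    least `technical_sharpness`;
#' 2. `cardiac` - peak frequency inside `cardiac_peak_range` and fraction
#'    above 1.0 Hz at least `cardiac_band_min`;
#' 3. `rsn` - band fractions decreasing across the five bands (one tie within
#'    `rsn_tie_tol` relative tolerated) and lowest-band fraction at least
#'    `rsn_first_band_min`;
#' 4. `pulsation` - fraction above 0.6 Hz at least `pulsation_hi_min`;
#' 5. `other` otherwise.
#'
#' @param spec an [hft_spectrum][component_spectrum] computed on the
#'   five-band high-frequency edges.
#' @param map optional spatial map (accepted for interface symmetry; the
#'   default cascade is purely spectral).
#' @param rules a [classification_rules()] list.
#' @return tibble with `label` and evidence columns (`frac_band3`,
#'   `sharpness`, `peak_freq`, `frac_above_1`, `frac_above_0.6`,
#'   `monotone_decreasing`).
#' @export
classify_component <- function(spec, map = NULL,
                               rules = classification_rules()) {
  stopifnot(inherits(spec, "hft_spectrum"))
  bf <- spec$band_fractions$fraction
  .stop_if(length(bf) != 5,
           "classification expects the five-band high-frequency edges")
  edges <- spec$band_edges
  rng <- spec$freq >= edges[1] & spec$freq <= edges[length(edges)]
  p <- spec$power[rng]; f <- spec$freq[rng]
  sharpness <- if (median(p) > 0) max(p) / median(p) else Inf
  frac_hi1 <- bf[4] + bf[5]
  frac_06 <- sum(p[f >= 0.6]) / sum(p)
  d <- diff(bf)
  n_up <- sum(d >= 0)
  monotone <- n_up == 0 ||
    (n_up == 1 && d[d >= 0] <= rules$rsn_tie_tol * bf[c(d >= 0, FALSE)])
  label <- if (bf[3] >= rules$technical_band_min &&
               sharpness >= rules$technical_sharpness) {
    "technical"
  } else if (spec$peak_freq >= rules$cardiac_peak_range[1] &&
             spec$peak_freq <= rules$cardiac_peak_range[2] &&
             frac_hi1 >= rules$cardiac_band_min) {
    "cardiac"
  } else if (monotone && bf[1] >= rules$rsn_first_band_min) {
    "rsn"
  } else if (frac_06 >= rules$pulsation_hi_min) {
    "pulsation"
  } else {
    "other"
  }
  tibble::tibble(label = label, frac_band3 = bf[3], sharpness = sharpness,
                 peak_freq = spec$peak_freq, frac_above_1 = frac_hi1,
                 frac_above_0.6 = frac_06, monotone_decreasing = monotone)
}

#' Heart-rate estimate from a cardiac component spectrum
#'
#' Locates the spectral peak in the physiologically plausible window
#' (0.8 Hz to Nyquist) and converts it to beats per minute.
#'
#' @param spec an [hft_spectrum][component_spectrum].
#' @param lo lower bound of the search window in Hz.
#' @return tibble with `peak_hz` and `bpm`.
#' @export
heart_rate_estimate <- function(spec, lo = 0.8) {
  stopifnot(inherits(spec, "hft_spectrum"))
  sel <- spec$freq >= lo
  .stop_if(!any(sel) || all(spec$power[sel] <= 0),
           "no spectral peak above ", lo, " Hz")
  p <- spec$power[sel]
  i <- which.max(p)
  # require a genuine local maximum, not a monotone edge artifact
  .stop_if(i == 1 && length(p) > 1 && p[1] <= spec$power[which(sel)[1] - 1],
           "no local spectral maximum above ", lo, " Hz")
  peak <- spec$freq[sel][i]
  tibble::tibble(peak_hz = peak, bpm = 60 * peak)
}

#' Low-frequency band-fraction table for an unfiltered run
#'
#' For decompositions run without the high-pass filter, summarizes each
#' component's power distribution over 0.01-0.10, 0.10-0.25 and
#' 0.25-Nyquist Hz, plus the union 0.01-0.25 Hz, as percentages of the total
#' power in the analyzed range (0.01 Hz to the top edge). The union column
#' equals the sum of its two sub-bands.
#'
#' @param tc concatenated component time course.
#' @param boundaries subject-boundaries tibble.
#' @param tr sampling interval in seconds.
#' @param top upper edge of the analyzed range in Hz (default 1.4).
#' @return one-row tibble with percentage columns `pct_0.01_0.25`,
#'   `pct_0.01_0.10`, `pct_0.10_0.25`, `pct_0.25_top`.
#' @export
lowfreq_band_table <- function(tc, boundaries, tr, top = 1.4) {
  spec <- component_spectrum(tc, boundaries, tr,
                             band_edges = c(0.01, 0.10, 0.25, top))
  fr <- spec$band_fractions$fraction
  tibble::tibble(pct_0.01_0.25 = 100 * (fr[1] + fr[2]),
                 pct_0.01_0.10 = 100 * fr[1],
                 pct_0.10_0.25 = 100 * fr[2],
                 pct_0.25_top = 100 * fr[3])
}

#' Characterize every component of a decomposition
#'
#' Runs the consistency filter, the segment-averaged spectrum, the rule-based
#' classifier and (for cardiac-labeled components) the heart-rate estimate
#' over all components, returning one summary row per component.
#'
#' @param d an [hft_decomposition][fastica_temporal] with boundaries and TR.
#' @param band_edges five-band high-frequency edges in Hz.
#' @param rules a [classification_rules()] list.
#' @return object of class `hft_characterization`: a tibble with `component`,
#'   `keep`, `max_ratio`, `dominant_subject`, `peak_freq`, `label`,
#'   `heart_rate_bpm`, and one `frac_<lo>_<hi>` column per band; the list of
#'   spectra is attached as attribute `spectra`.
#' @export
characterize <- function(d, band_edges = c(0.25, 0.5, 0.75, 1, 1.25, 1.4),
                         rules = classification_rules()) {
  stopifnot(inherits(d, "hft_decomposition"))
  .stop_if(is.null(d$boundaries) || is.null(d$tr_seconds),
           "decomposition lacks subject boundaries or TR")
  cons <- consistency_filter(d)
  specs <- lapply(seq_len(d$n_ics), function(i) {
    component_spectrum(d$ic_timecourses[, i], d$boundaries, d$tr_seconds,
                       band_edges)
  })
  cls <- dplyr::bind_rows(lapply(seq_along(specs), function(i) {
    classify_component(specs[[i]], d$spatial_maps[i, ], rules)
  }))
  hr <- vapply(seq_along(specs), function(i) {
    if (cls$label[i] == "cardiac") heart_rate_estimate(specs[[i]])$bpm
    else NA_real_
  }, numeric(1))
  fr <- do.call(rbind, lapply(specs, function(s) s$band_fractions$fraction))
  colnames(fr) <- sprintf("frac_%g_%g", band_edges[-length(band_edges)],
                          band_edges[-1])
  out <- dplyr::bind_cols(
    tibble::tibble(component = cons$component, keep = cons$keep,
                   max_ratio = cons$max_ratio,
                   dominant_subject = cons$dominant_subject,
                   peak_freq = cls$peak_freq, label = cls$label,
                   heart_rate_bpm = hr),
    tibble::as_tibble(fr))
  attr(out, "spectra") <- specs
  class(out) <- c("hft_characterization", class(out))
  out
}
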