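#' Pipeline configuration
#'
#' Everything needed to run the full analysis: per-subject input paths (or
#' in-memory [voxel_ts()] objects), mask, preprocessing parameters,
#' decomposition dimensions and characterization settings. With
#' `cutoff_hz = NA` the high-pass filter is disabled, giving the
#' low-frequency reference analysis.
#'
#' @param subjects either a list of `list(fmri = path, motion = path)` entries
#'   or a list of [voxel_ts()] objects (with `motion_tables` supplied
#'   separately).
#' @param mask path to the mask NIfTI (ignored for in-memory input).
#' @param motion_tables optional list of time-by-6 matrices for in-memory
#'   input.
#' @param tr_seconds TR override in seconds (default: from NIfTI headers).
#' @param discard_volumes initial volumes to drop per subject.
#' @param cutoff_hz high-pass cutoff in Hz, or `NA` to disable filtering.
#' @param fwhm_voxels spatial smoothing FWHM in voxels (0 = off).
#' @param n_pcs,n_ics decomposition dimensions.
#' @param band_edges five-band high-frequency edges for characterization.
#' @param rules [classification_rules()] thresholds.
#' @param seed integer seed for the ICA initialization.
#' @param out_dir optional output directory; when given, component maps, time
#'   courses, the component summary TSV and the JSON run report are written.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(subjects, mask = NULL, motion_tables = NULL,
                            tr_seconds = NULL, discard_volumes = 24,
                            cutoff_hz = 0.25, fwhm_voxels = 0,
                            n_pcs = 76, n_ics = 75,
                            band_edges = c(0.25, 0.5, 0.75, 1, 1.25, 1.4),
                            rules = classification_rules(), seed = 1L,
                            out_dir = NULL) {
  stopifnot(length(subjects) >= 1, n_ics <= n_pcs)
  structure(list(subjects = subjects, mask = mask,
                 motion_tables = motion_tables, tr_seconds = tr_seconds,
                 discard_volumes = discard_volumes, cutoff_hz = cutoff_hz,
                 fwhm_voxels = fwhm_voxels, n_pcs = n_pcs, n_ics = n_ics,
                 band_edges = band_edges, rules = rules,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with fields matching the [pipeline_config()]
#'   arguments (`subjects` as a list of `fmri`/`motion` path pairs).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  if (!is.null(args$band_edges)) args$band_edges <- as.numeric(args$band_edges)
  if (!is.null(args$cutoff_hz) && identical(args$cutoff_hz, "none")) {
    args$cutoff_hz <- NA
  }
  do.call(pipeline_config, args)
}

.run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full high-frequency tICA pipeline
#'
#' Executes preprocess (discard, motion regression, standardization, optional
#' smoothing, high-pass), temporal concatenation, truncated-SVD prewhitening,
#' FastICA, and component characterization (consistency filter, spectra, band
#' fractions, classification). Identical configuration and seed give
#' identical outputs. Any stage error aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return object of class `hft_run`: `summary` (the
#'   [characterize()] tibble), `decomposition`, `report` (JSON-serializable
#'   provenance: per-stage parameters and counts, seed, timings).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  report <- list(seed = config$seed, stages = list())

  loaded <- .run_stage("load", {
    if (all(vapply(config$subjects, inherits, logical(1), "voxel_ts"))) {
      list(subjects = config$subjects, motion = config$motion_tables)
    } else {
      subs <- lapply(config$subjects, function(s) {
        load_masked_4d(s$fmri, config$mask, tr_seconds = config$tr_seconds)
      })
      mot <- lapply(config$subjects, function(s) {
        if (is.null(s$motion)) NULL
        else as.matrix(read.table(s$motion, header = TRUE))
      })
      list(subjects = subs, motion = mot)
    }
  })
  report$stages$load <- list(n_subjects = length(loaded$subjects),
                             n_voxels = ncol(loaded$subjects[[1]]$data),
                             n_volumes = nrow(loaded$subjects[[1]]$data))

  pre <- .run_stage("preprocess", {
    lapply(seq_along(loaded$subjects), function(i) {
      preprocess(loaded$subjects[[i]],
                 motion = if (is.null(loaded$motion)) NULL
                          else loaded$motion[[i]],
                 n_discard = config$discard_volumes,
                 cutoff_hz = config$cutoff_hz,
                 fwhm_voxels = config$fwhm_voxels)
    })
  })
  report$stages$preprocess <- list(
    discard_volumes = config$discard_volumes,
    cutoff_hz = config$cutoff_hz,
    fwhm_voxels = config$fwhm_voxels,
    n_constant_voxels = vapply(pre, function(m)
      as.integer(attr(m, "provenance")$n_constant_voxels), integer(1)))

  gm <- .run_stage("concatenate", concatenate_subjects(pre))
  report$stages$concatenate <- list(rows = nrow(gm$data),
                                    voxels = ncol(gm$data))

  n_pcs <- min(config$n_pcs, min(dim(gm$data)) - 1)
  n_ics <- min(config$n_ics, n_pcs)
  d <- .run_stage("decompose",
                  decompose(gm, n_pcs = n_pcs, n_ics = n_ics,
                            seed = config$seed))
  report$stages$decompose <- list(n_pcs = n_pcs, n_ics = n_ics,
                                  iterations = d$convergence$iterations)

  summary <- .run_stage("characterize",
                        characterize(d, band_edges = config$band_edges,
                                     rules = config$rules))
  report$stages$characterize <- list(
    n_kept = sum(summary$keep), n_discarded = sum(!summary$keep),
    labels = table(summary$label))
  report$elapsed_seconds <- as.numeric(difftime(Sys.time(), t0,
                                                units = "secs"))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    smry <- summary
    attr(smry, "spectra") <- NULL
    write.table(format(as.data.frame(smry), digits = 10, trim = TRUE),
                file.path(config$out_dir, "components.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_timecourses(d, file.path(config$out_dir, "timecourses.tsv"))
    if (!is.null(gm$voxel_index)) {
      grid <- apply(gm$voxel_index, 2, max)
      write_component_maps(d, gm$voxel_index, grid,
                           file.path(config$out_dir, "component_maps.nii.gz"),
                           tr_seconds = gm$tr_seconds)
    }
    write.table(data.frame(singular_value = d$singular_values),
                file.path(config$out_dir, "singular_values.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  structure(list(summary = summary, decomposition = d, report = report),
            class = "hft_run")
}

#' @export
print.hft_run <- function(x, ...) {
  cat("<hft_run>", x$decomposition$n_ics, "components;",
      sum(x$summary$keep), "kept by the consistency criterion\n")
  print(dplyr::count(x$summary, .data$label))
  invisible(x)
}
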