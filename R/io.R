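#' Load a masked 4D NIfTI run as a voxel time-series matrix
#'
#' Reads a 4D functional image and a 3D mask on the same grid and extracts the
#' in-mask voxel time courses as a time-by-voxel matrix. Columns follow mask
#' scan order (first axis fastest), and the voxel-to-grid mapping is retained
#' so spatial maps can be written back to volumes. TR is taken from the fourth
#' pixdim entry of the header unless overridden.
#'
#' @param fmri_path path to a 4D NIfTI (.nii or .nii.gz).
#' @param mask_path path to a 3D mask NIfTI on the same grid (nonzero = in).
#' @param tr_seconds optional TR override in seconds.
#' @param subject_id label; default: the file name without extensions.
#' @return a [voxel_ts()].
#' @export
load_masked_4d <- function(fmri_path, mask_path, tr_seconds = NULL,
                           subject_id = NULL) {
  img <- RNifti::readNifti(fmri_path)
  msk <- RNifti::readNifti(mask_path)
  .stop_if(length(dim(img)) != 4, fmri_path, " is not a 4D image")
  .stop_if(length(dim(msk)) != 3, mask_path, " is not a 3D mask")
  .stop_if(!identical(dim(img)[1:3], dim(msk)),
           "grid mismatch: data ", paste(dim(img)[1:3], collapse = "x"),
           " vs mask ", paste(dim(msk), collapse = "x"))
  mask <- array(msk != 0, dim = dim(msk))
  .stop_if(!any(mask), "mask contains no voxels")
  if (is.null(tr_seconds)) tr_seconds <- RNifti::pixdim(img)[4]
  .stop_if(!is.finite(tr_seconds) || tr_seconds <= 0,
           "TR from header is ", tr_seconds, "; pass tr_seconds explicitly")
  voxel_index <- which(mask, arr.ind = TRUE)
  dimnames(voxel_index) <- NULL
  n_t <- dim(img)[4]
  flat <- matrix(img, prod(dim(img)[1:3]), n_t)
  data <- t(flat[as.vector(mask), , drop = FALSE])
  .stop_if(!all(is.finite(data)), "non-finite values inside the mask")
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(fmri_path))
  }
  voxel_ts(data, tr_seconds = tr_seconds, voxel_index = voxel_index,
           subject_id = subject_id)
}

# assemble an in-mask vector (or IC-by-voxel matrix) into a (4D) volume array
.maps_to_array <- function(maps, voxel_index, grid_shape) {
  maps <- rbind(maps)
  arr <- array(0, c(grid_shape, nrow(maps)))
  for (i in seq_len(nrow(maps))) {
    vol <- array(0, grid_shape)
    vol[voxel_index] <- maps[i, ]
    arr[, , , i] <- vol
  }
  arr
}

#' Write component spatial maps as a 4D NIfTI
#'
#' One volume per independent component, voxels outside the mask set to 0.
#'
#' @param d an [hft_decomposition][fastica_temporal].
#' @param voxel_index V x 3 voxel coordinates of the map columns.
#' @param grid_shape 3D grid dimensions.
#' @param path output file (.nii or .nii.gz).
#' @param tr_seconds stored in the fourth pixdim slot for provenance.
#' @return `path`, invisibly.
#' @export
write_component_maps <- function(d, voxel_index, grid_shape, path,
                                 tr_seconds = 1) {
  arr <- .maps_to_array(d$spatial_maps, voxel_index, grid_shape)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, tr_seconds)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write IC time courses as TSV with a JSON sidecar
#'
#' Rows are time points of the concatenated group time axis, one column per
#' component; subject boundaries, TR and convergence details go to a JSON
#' sidecar next to the table.
#'
#' @param d an [hft_decomposition][fastica_temporal].
#' @param path output TSV path; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(d, path) {
  tc <- d$ic_timecourses
  colnames(tc) <- sprintf("IC%02d", seq_len(ncol(tc)))
  write.table(format(tc, digits = 10, trim = TRUE, scientific = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(
    list(tr_seconds = d$tr_seconds,
         boundaries = d$boundaries,
         n_pcs = d$n_pcs, n_ics = d$n_ics,
         convergence = d$convergence),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a simulated dataset to disk
#'
#' Produces the on-disk layout the pipeline consumes: per-subject 4D NIfTI
#' volumes, a 3D mask, 6-column motion TSVs, plus a ground-truth bundle
#' (source time courses as TSV, spatial maps as 4D NIfTI, metadata as JSON).
#'
#' @param sim an [hft_simulation][simulate_dataset].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "hft_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- sim$config$grid_shape
  tr <- sim$config$tr_seconds
  mask_img <- RNifti::asNifti(array(as.numeric(sim$mask), grid))
  RNifti::writeNifti(mask_img, file.path(dir, "mask.nii.gz"))
  for (s in seq_along(sim$subjects)) {
    vts <- sim$subjects[[s]]
    arr <- array(0, c(grid, nrow(vts$data)))
    for (t in seq_len(nrow(vts$data))) {
      vol <- array(0, grid)
      vol[sim$voxel_index] <- vts$data[t, ]
      arr[, , , t] <- vol
    }
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(1, 1, 1, tr)
    RNifti::writeNifti(img, file.path(dir, sprintf("%s.nii.gz",
                                                   vts$subject_id)))
    write.table(format(sim$motion[[s]], digits = 8, trim = TRUE),
                file.path(dir, sprintf("%s_motion.tsv", vts$subject_id)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    tcs <- sim$truth$timecourses[[s]]
    colnames(tcs) <- sprintf("source%02d", seq_len(ncol(tcs)))
    write.table(format(tcs, digits = 10, trim = TRUE, scientific = TRUE),
                file.path(dir, sprintf("%s_truth_timecourses.tsv",
                                       vts$subject_id)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  maps_img <- RNifti::asNifti(.maps_to_array(sim$truth$spatial_maps,
                                             sim$voxel_index, grid))
  RNifti::writeNifti(maps_img, file.path(dir, "truth_maps.nii.gz"))
  jsonlite::write_json(
    list(n_subjects = sim$config$n_subjects, grid_shape = grid,
         n_volumes = sim$config$n_volumes, tr_seconds = tr,
         snr = sim$config$snr, seed = sim$config$seed,
         labels = sim$truth$labels, subject_scope = sim$truth$subject_scope,
         cardiac_rates = sim$truth$cardiac_rates, sigma = sim$truth$sigma,
         voxel_order = "column-major, first axis fastest, 0-based",
         discard_volumes = sim$config$discard_volumes),
    file.path(dir, "truth_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
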