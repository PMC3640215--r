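#' Temporally concatenate subjects into a group matrix
#'
#' Stacks per-subject time-by-voxel matrices in input order, recording where
#' each subject's rows start and end. All subjects must share the same voxel
#' columns (mask) and TR.
#'
#' @param matrices list of [voxel_ts()] objects.
#' @return object of class `group_matrix`: `data` (total-time-by-voxel),
#'   `boundaries` (tibble: `subject_id`, `row_start`, `row_end`, 1-based
#'   inclusive), `tr_seconds`, `voxel_index`.
#' @export
concatenate_subjects <- function(matrices) {
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, inherits, logical(1), "voxel_ts")))
  ref <- matrices[[1]]
  for (m in matrices[-1]) {
    .stop_if(ncol(m$data) != ncol(ref$data),
             "subject ", m$subject_id, " has ", ncol(m$data),
             " voxels but ", ref$subject_id, " has ", ncol(ref$data))
    .stop_if(!isTRUE(all.equal(m$tr_seconds, ref$tr_seconds)),
             "subject ", m$subject_id, " has TR ", m$tr_seconds,
             " but ", ref$subject_id, " has TR ", ref$tr_seconds)
    if (!is.null(m$voxel_index) && !is.null(ref$voxel_index)) {
      .stop_if(!identical(unname(m$voxel_index), unname(ref$voxel_index)),
               "subject ", m$subject_id, " uses a different mask than ",
               ref$subject_id)
    }
  }
  rows <- vapply(matrices, function(m) nrow(m$data), integer(1))
  ends <- cumsum(rows)
  boundaries <- tibble::tibble(
    subject_id = vapply(matrices, `[[`, character(1), "subject_id"),
    row_start = c(1L, head(ends, -1) + 1L),
    row_end = ends)
  structure(list(data = do.call(rbind, lapply(matrices, `[[`, "data")),
                 boundaries = boundaries, tr_seconds = ref$tr_seconds,
                 voxel_index = ref$voxel_index),
            class = "group_matrix")
}

#' @export
print.group_matrix <- function(x, ...) {
  cat("<group_matrix>", nrow(x$data), "rows (", nrow(x$boundaries),
      "subjects ) x", ncol(x$data), "voxels @ TR", x$tr_seconds, "s\n")
  invisible(x)
}

#' Top-k singular triplets of a tall data matrix
#'
#' Computes the leading k singular values and vectors through an
#' eigendecomposition of the Gram matrix on the smaller side - exact at desk
#' scale, where the voxel-by-voxel (or time-by-time) Gram matrix fits in
#' memory comfortably. Returned bases are checked for orthonormality to `tol`.
#'
#' @param x numeric matrix or [group_matrix][concatenate_subjects].
#' @param k number of triplets, `k < min(dim(x))`.
#' @param tol orthonormality tolerance for the returned bases.
#' @return list with `u` (rows x k), `d` (nonincreasing singular values),
#'   `v` (cols x k).
#' @export
truncated_svd <- function(x, k, tol = 1e-8) {
  if (inherits(x, "group_matrix")) x <- x$data
  x <- as.matrix(x)
  stopifnot(k >= 1, k < min(dim(x)))
  # subspace from the Gram eigendecomposition on the smaller side, then a
  # Rayleigh-Ritz refinement (dense SVD of the k-column projection) to recover
  # full precision on small singular values, which the squared problem loses
  if (ncol(x) <= nrow(x)) {
    e <- eigen(crossprod(x), symmetric = TRUE)
    v0 <- e$vectors[, seq_len(k), drop = FALSE]
    sb <- svd(x %*% v0)
    u <- sb$u
    d <- sb$d
    v <- v0 %*% sb$v
  } else {
    e <- eigen(tcrossprod(x), symmetric = TRUE)
    u0 <- e$vectors[, seq_len(k), drop = FALSE]
    sb <- svd(crossprod(x, u0))
    u <- u0 %*% sb$v
    d <- sb$d
    v <- sb$u
  }
  ortho_err <- max(abs(crossprod(u) - diag(k)), abs(crossprod(v) - diag(k)))
  .stop_if(ortho_err > max(tol, 1e-6),
           "singular bases failed orthonormality (residual ",
           format(ortho_err), "); the requested rank may be degenerate")
  list(u = u, d = d, v = v)
}

#' Prewhiten via the PCA basis
#'
#' Projects the data onto its top-k principal components and rescales so the
#' reduced temporal matrix has identity sample covariance. The PC basis and
#' singular values are retained for back-projection of spatial maps. Because
#' every voxel column of the group matrix is (per-subject) mean-centered, the
#' whitened columns have exactly zero mean.
#'
#' @param sv output of [truncated_svd()].
#' @param k number of components to keep (`<= length(sv$d)`).
#' @return object of class `whitened`: `z` (n x k whitened matrix), `d`,
#'   `v` (PC basis, cols x k), `n` (rows).
#' @export
whiten <- function(sv, k = length(sv$d)) {
  stopifnot(k >= 1, k <= length(sv$d))
  .stop_if(any(sv$d[seq_len(k)] <= .Machine$double.eps * sv$d[1] * 100),
           "zero singular value among the top ", k,
           " components: degenerate dimension")
  n <- nrow(sv$u)
  z <- sqrt(n - 1) * sv$u[, seq_len(k), drop = FALSE]
  mu <- colMeans(z)
  if (max(abs(mu)) > 1e-6) {
    warning("whitened columns deviate from zero mean (max |mean| = ",
            format(max(abs(mu))), "); input columns may not be centered")
  }
  structure(list(z = z, d = sv$d[seq_len(k)],
                 v = sv$v[, seq_len(k), drop = FALSE], n = n),
            class = "whitened")
}

# one symmetric FastICA pass; returns NULL on non-convergence
.fastica_core <- function(z, n_ics, contrast, alpha, tol, max_iter) {
  n <- nrow(z); k <- ncol(z)
  g_fun <- switch(contrast,
    logcosh = function(u) {
      gu <- tanh(alpha * u)
      list(g = gu, gprime_mean = alpha * colMeans(1 - gu^2))
    },
    exp = function(u) {
      eu <- exp(-u^2 / 2)
      list(g = u * eu, gprime_mean = colMeans((1 - u^2) * eu))
    },
    cube = function(u) list(g = u^3, gprime_mean = colMeans(3 * u^2)))
  sym_decorrelate <- function(W) {
    e <- eigen(tcrossprod(W), symmetric = TRUE)
    if (any(e$values < 1e-12)) return(NULL)  # degenerate: caller restarts
    (e$vectors %*% diag(1 / sqrt(e$values), n_ics) %*% t(e$vectors)) %*% W
  }
  W <- sym_decorrelate(matrix(rnorm(n_ics * k), n_ics, k))
  if (is.null(W)) {
    return(list(W = NULL, iterations = 0, delta = Inf, converged = FALSE))
  }
  for (it in seq_len(max_iter)) {
    u <- z %*% t(W)
    gg <- g_fun(u)
    W_new <- crossprod(gg$g, z) / n - diag(gg$gprime_mean, n_ics) %*% W
    W_new <- sym_decorrelate(W_new)
    if (is.null(W_new)) {
      return(list(W = W, iterations = it, delta = Inf, converged = FALSE))
    }
    delta <- max(abs(1 - abs(rowSums(W_new * W))))
    W <- W_new
    if (delta < tol) {
      return(list(W = W, iterations = it, delta = delta, converged = TRUE))
    }
  }
  list(W = W, iterations = max_iter, delta = delta, converged = FALSE)
}

#' Temporal FastICA on whitened data
#'
#' Extracts `n_ics` temporally independent components by symmetric
#' (parallel-update) fixed-point iteration on the whitened temporal matrix.
#' The unmixing matrix is orthonormal in whitened space, so the component time
#' courses come out uncorrelated with unit variance. Spatial maps are obtained
#' by composing the mixing matrix with the stored PC basis - the projection of
#' each component back from principal-component space into voxel space.
#'
#' Component sign is canonicalized so each spatial map has positive skewness
#' (falling back to making the largest-magnitude voxel weight positive), and
#' components are ordered by the variance they explain in the original data,
#' descending. Given the same seed, the result is deterministic. If the
#' iteration fails to converge it is restarted with a derived seed, up to
#' `restarts` times.
#'
#' @param wh a [whiten()]ed object.
#' @param n_ics number of independent components (`<= ncol(wh$z)`).
#' @param seed integer seed for the random orthonormal initialization.
#' @param contrast FastICA nonlinearity: `"logcosh"` (default), `"exp"` or
#'   `"cube"`.
#' @param alpha logcosh slope parameter in `[1, 2]`.
#' @param tol convergence tolerance on the unmixing update.
#' @param max_iter iteration budget per restart.
#' @param restarts seeded restarts before giving up.
#' @param boundaries optional subject-boundaries tibble carried through for
#'   downstream consistency analysis.
#' @param tr_seconds optional sampling interval carried through.
#' @return object of class `hft_decomposition`: `n_pcs`, `n_ics`,
#'   `singular_values`, `pc_basis` (k x V), `ic_timecourses` (n x n_ics, unit
#'   variance), `spatial_maps` (n_ics x V), `unmixing`, `convergence`,
#'   `boundaries`, `tr_seconds`.
#' @export
fastica_temporal <- function(wh, n_ics, seed = 1L,
                             contrast = c("logcosh", "exp", "cube"),
                             alpha = 1, tol = 1e-6, max_iter = 1000,
                             restarts = 5, boundaries = NULL,
                             tr_seconds = NULL) {
  stopifnot(inherits(wh, "whitened"))
  contrast <- match.arg(contrast)
  k <- ncol(wh$z)
  .stop_if(n_ics > k, "n_ics (", n_ics, ") exceeds the whitened dimension (",
           k, ")")
  fit <- NULL
  for (r in 0:restarts) {
    set.seed(as.integer(seed) + r)
    fit <- .fastica_core(wh$z, n_ics, contrast, alpha, tol, max_iter)
    if (fit$converged) break
  }
  .stop_if(!fit$converged,
           "FastICA did not converge in ", max_iter, " iterations over ",
           restarts + 1, " starts (last delta ", format(fit$delta), ")")
  W <- fit$W
  S <- wh$z %*% t(W)
  maps <- W %*% diag(wh$d, k) %*% t(wh$v) / sqrt(wh$n - 1)
  # sign: positive map skewness, falling back to the largest-|weight| voxel
  for (i in seq_len(n_ics)) {
    sk <- .skewness(maps[i, ])
    flip <- if (abs(sk) > 1e-8) sk < 0 else maps[i, which.max(abs(maps[i, ]))] < 0
    if (flip) {
      maps[i, ] <- -maps[i, ]
      S[, i] <- -S[, i]
      W[i, ] <- -W[i, ]
    }
  }
  ord <- order(rowSums(maps^2), decreasing = TRUE)
  structure(list(n_pcs = k, n_ics = n_ics, singular_values = wh$d,
                 pc_basis = t(wh$v), ic_timecourses = S[, ord, drop = FALSE],
                 spatial_maps = maps[ord, , drop = FALSE],
                 unmixing = W[ord, , drop = FALSE],
                 convergence = list(iterations = fit$iterations,
                                    delta = fit$delta,
                                    contrast = contrast, seed = seed),
                 boundaries = boundaries, tr_seconds = tr_seconds),
            class = "hft_decomposition")
}

#' @export
print.hft_decomposition <- function(x, ...) {
  cat("<hft_decomposition>", x$n_ics, "ICs from", x$n_pcs, "PCs;",
      nrow(x$ic_timecourses), "time points x", ncol(x$spatial_maps),
      "voxels\n")
  cat("  converged in", x$convergence$iterations, "iterations (",
      x$convergence$contrast, "contrast )\n")
  invisible(x)
}

#' Group decomposition in one call
#'
#' Truncated SVD, prewhitening and temporal FastICA chained on a concatenated
#' group matrix.
#'
#' @param gm a [group_matrix][concatenate_subjects].
#' @param n_pcs principal components retained for prewhitening.
#' @param n_ics independent components extracted (`<= n_pcs`).
#' @param seed integer seed passed to [fastica_temporal()].
#' @param ... further arguments to [fastica_temporal()].
#' @return an `hft_decomposition`.
#' @export
decompose <- function(gm, n_pcs = 76, n_ics = 75, seed = 1L, ...) {
  stopifnot(inherits(gm, "group_matrix"))
  sv <- truncated_svd(gm, k = n_pcs)
  wh <- whiten(sv, k = n_pcs)
  fastica_temporal(wh, n_ics = n_ics, seed = seed,
                   boundaries = gm$boundaries, tr_seconds = gm$tr_seconds, ...)
}
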