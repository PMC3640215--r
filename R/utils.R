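#' One-sided periodogram of a time series
#'
#' Raw periodogram on the DFT grid, excluding the DC bin. Only relative power
#' matters downstream (band fractions, peak locations), so no windowing or
#' density scaling is applied.
#'
#' @param x numeric vector.
#' @param tr sampling interval in seconds.
#' @return a tibble with columns `freq` (Hz, in `(0, Nyquist]`) and `power`.
#' @examples
#' p <- periodogram(sin(2 * pi * 0.5 * (0:511) * 0.354), tr = 0.354)
#' p$freq[which.max(p$power)]
#' @export
periodogram <- function(x, tr) {
  stopifnot(is.numeric(x), length(x) >= 4, tr > 0)
  n <- length(x)
  m <- n %/% 2
  p <- Mod(fft(x))^2 / n
  tibble::tibble(freq = (1:m) / (n * tr), power = p[2:(m + 1)])
}

#' Fraction of spectral power per frequency band
#'
#' Bins a periodogram into consecutive bands `[edges[i], edges[i+1])` (the last
#' band is closed above) and normalizes by the total power inside
#' `[edges[1], edges[length(edges)]]`, so the fractions sum to one over the
#' analyzed range.
#'
#' @param freq,power numeric vectors as returned by [periodogram()].
#' @param edges ordered numeric vector of band edges in Hz (length >= 2).
#' @return tibble with columns `band_lo`, `band_hi`, `fraction`.
#' @export
band_fractions <- function(freq, power, edges) {
  stopifnot(length(edges) >= 2, !is.unsorted(edges, strictly = TRUE),
            length(freq) == length(power), all(power >= 0))
  in_range <- freq >= edges[1] & freq <= edges[length(edges)]
  total <- sum(power[in_range])
  if (total <= 0) stop("no spectral power inside the analyzed range [",
                       edges[1], ", ", edges[length(edges)], "] Hz")
  nb <- length(edges) - 1
  frac <- vapply(seq_len(nb), function(i) {
    hi_ok <- if (i == nb) freq <= edges[i + 1] else freq < edges[i + 1]
    sum(power[freq >= edges[i] & hi_ok]) / total
  }, numeric(1))
  tibble::tibble(band_lo = edges[-length(edges)], band_hi = edges[-1],
                 fraction = frac)
}

#' Optimal assignment between estimated and reference components
#'
#' Solves the linear assignment problem that maximizes the summed absolute
#' correlation between component time courses (or maps) and reference sources,
#' i.e. the permutation/sign matching step used to score blind source
#' separation against ground truth.
#'
#' @param est matrix with one estimated component per column.
#' @param ref matrix with one reference source per column (same row count).
#' @return tibble with one row per reference column: `source`, `component`
#'   (matched column of `est`), `r` (absolute correlation) and `sign`.
#' @export
match_components <- function(est, ref) {
  est <- as.matrix(est); ref <- as.matrix(ref)
  stopifnot(nrow(est) == nrow(ref), ncol(est) >= ncol(ref))
  cc <- suppressWarnings(cor(ref, est))
  cc[!is.finite(cc)] <- 0
  asg <- solve_assignment(1 - abs(cc))
  tibble::tibble(
    source = seq_len(ncol(ref)),
    component = asg,
    r = abs(cc)[cbind(seq_len(ncol(ref)), asg)],
    sign = sign(cc[cbind(seq_len(ncol(ref)), asg)])
  )
}

#' Minimum-cost assignment (exact, small problems)
#'
#' Exact solver by dynamic programming over column subsets; cost matrices up to
#' 20 columns are supported, which covers component-matching at desk scale.
#'
#' @param cost numeric matrix, rows <= cols; entry (i, j) is the cost of
#'   assigning row i to column j.
#' @return integer vector: the column assigned to each row.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n >= 1, n <= m, m <= 20, all(is.finite(cost)))
  nset <- bitwShiftL(1L, m)
  dp <- rep(Inf, nset)
  dp[1] <- 0
  choice <- integer(nset)
  nbits <- vapply(0:(nset - 1), function(s) sum(bitwAnd(s, bitwShiftL(1L, 0:(m - 1))) != 0), numeric(1))
  for (s in 0:(nset - 1)) {
    if (!is.finite(dp[s + 1])) next
    i <- nbits[s + 1] + 1
    if (i > n) next
    for (j in seq_len(m)) {
      bit <- bitwShiftL(1L, j - 1)
      if (bitwAnd(s, bit) == 0) {
        ns <- bitwOr(s, bit)
        val <- dp[s + 1] + cost[i, j]
        if (val < dp[ns + 1]) {
          dp[ns + 1] <- val
          choice[ns + 1] <- j
        }
      }
    }
  }
  # pick best terminal subset with n bits, then backtrack
  terms <- which(nbits == n) - 1
  best <- terms[which.min(dp[terms + 1])]
  asg <- integer(n)
  s <- best
  for (i in n:1) {
    j <- choice[s + 1]
    asg[i] <- j
    s <- bitwAnd(s, bitwNot(bitwShiftL(1L, j - 1)))
  }
  asg
}

# skewness used for component sign canonicalization
.skewness <- function(x) {
  x <- x - mean(x)
  s <- sd(x)
  if (s == 0) return(0)
  mean(x^3) / s^3
}

.stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)
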