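# One-sided raw periodogram. Power normalized so that the sum over all
# non-DC ordinates equals t * population variance (discrete Parseval).
periodogram <- function(x, tr) {
  t <- length(x)
  X <- fft(x)
  half <- floor(t / 2)
  p_full <- Mod(X)^2 / t
  freqs <- (0:half) / (t * tr)
  pow <- p_full[1:(half + 1)]
  # fold the negative frequencies onto the positive half
  if (t %% 2 == 0) {
    if (half >= 2) pow[2:half] <- pow[2:half] + rev(p_full[(half + 2):t])
  } else {
    pow[2:(half + 1)] <- pow[2:(half + 1)] + rev(p_full[(half + 2):t])
  }
  list(freqs = freqs, power = pow)
}

band_fraction <- function(freqs, power, band) {
  pos <- freqs > 0
  inb <- pos & freqs >= band[1] & freqs <= band[2]
  tot <- sum(power[pos])
  if (tot <= 0) stop_rsn("degenerate spectrum: series has no power")
  sum(power[inb]) / tot
}

#' Spectral summary of a network's averaged time-course
#'
#' Raw periodogram of the voxel-averaged series over the full detectable
#' range (0 to Nyquist); relative power is the periodogram divided by its
#' maximum; the band contribution is the fraction of total (non-DC)
#' spectral energy lying in the low-frequency band. Input should be
#' regressed but NOT band-pass filtered, since the summary spans the whole
#' spectrum.
#'
#' @param ts An `rsn_ts` (regressed).
#' @param band Low-frequency band in Hz, default `c(0.01, 0.08)`.
#' @param falff_mode Passed to [falff()].
#' @return An `rsn_spectrum`: `freqs`, `relative_power` (max 1),
#'   `band_contribution`, `falff`, plus labels.
#' @export
band_power_summary <- function(ts, band = c(0.01, 0.08),
                               falff_mode = c("power", "amplitude")) {
  stopifnot(inherits(ts, "rsn_ts"))
  nyq <- 1 / (2 * ts$tr)
  assert_that(band[1] > 0 && band[1] < band[2] && band[2] <= nyq,
              "band must lie within (0, Nyquist]")
  avg <- colMeans(ts$data)
  if (all(abs(avg - mean(avg)) < 1e-14))
    stop_rsn("degenerate spectrum: averaged series is constant")
  pg <- periodogram(avg - mean(avg), ts$tr)
  structure(
    list(network = ts$network, subject_id = ts$subject_id,
         freqs = pg$freqs, relative_power = pg$power / max(pg$power),
         band_contribution = band_fraction(pg$freqs, pg$power, band),
         falff = falff(ts, band, match.arg(falff_mode))),
    class = "rsn_spectrum"
  )
}

#' @export
print.rsn_spectrum <- function(x, ...) {
  cat(sprintf("<rsn_spectrum> %s/%s: band contribution %.3f, fALFF %.3f\n",
              x$subject_id, x$network, x$band_contribution, x$falff))
  invisible(x)
}

#' Tidy a spectral summary into a frequency table
#'
#' @param x An `rsn_spectrum`.
#' @param ... Unused.
#' @return Tibble with `subject_id`, `network`, `freq`, `relative_power`.
#' @export
tidy.rsn_spectrum <- function(x, ...) {
  tibble::tibble(subject_id = x$subject_id, network = x$network,
                 freq = x$freqs, relative_power = x$relative_power)
}

#' Fractional low-frequency power (fALFF)
#'
#' Computed voxel-wise on each voxel's own periodogram, then averaged over
#' the network's voxels. `mode = "power"` uses the power ratio;
#' `mode = "amplitude"` uses the square-root-amplitude ratio convention.
#'
#' @param ts An `rsn_ts` (regressed, unfiltered).
#' @param band Low-frequency band in Hz.
#' @param mode `"power"` (default) or `"amplitude"`.
#' @return A proportion in `[0, 1]`.
#' @export
falff <- function(ts, band = c(0.01, 0.08),
                  mode = c("power", "amplitude")) {
  stopifnot(inherits(ts, "rsn_ts"))
  mode <- match.arg(mode)
  vals <- apply(ts$data, 1, function(x) {
    x <- x - mean(x)
    if (all(abs(x) < 1e-14))
      stop_rsn("degenerate spectrum: constant voxel series")
    pg <- periodogram(x, ts$tr)
    if (mode == "power") {
      band_fraction(pg$freqs, pg$power, band)
    } else {
      pos <- pg$freqs > 0
      inb <- pos & pg$freqs >= band[1] & pg$freqs <= band[2]
      sum(sqrt(pg$power[inb])) / sum(sqrt(pg$power[pos]))
    }
  })
  mean(vals)
}

#' Cross-network correlation matrix
#'
#' Pearson correlations between the cleaned, voxel-averaged time-courses of
#' all networks, per subject, plus the across-subject mean matrix. In real
#' resting data the higher-cognitive networks are anti-correlated with the
#' perceptual ones; the generator reproduces that sign structure.
#'
#' @param ts_by_subject List over subjects; each element a named list of
#'   cleaned `rsn_ts`, one per network (same networks for every subject).
#' @return An `rsn_xcor`: `networks`, mean `matrix`, and `per_subject`
#'   array (network x network x subject).
#' @export
rsn_cross_correlation <- function(ts_by_subject) {
  assert_that(length(ts_by_subject) >= 1, "need at least one subject")
  nets <- names(ts_by_subject[[1]])
  assert_that(!is.null(nets) && length(nets) >= 2,
              "each subject needs a named list of at least two networks")
  per <- vapply(ts_by_subject, function(tl) {
    avg <- vapply(tl[nets], function(ts) colMeans(ts$data),
                  numeric(ncol(tl[[1]]$data)))
    if (any(apply(avg, 2, sd) < 1e-14))
      stop_rsn("constant network-average series")
    cor(avg)
  }, matrix(0, length(nets), length(nets)))
  m <- apply(per, c(1, 2), mean)
  dimnames(m) <- list(nets, nets)
  structure(list(networks = nets, matrix = m, per_subject = per),
            class = "rsn_xcor")
}

#' @export
print.rsn_xcor <- function(x, ...) {
  cat("<rsn_xcor> mean cross-network correlation over",
      dim(x$per_subject)[3], "subjects\n")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Tidy the cross-network correlation into long form
#'
#' @param x An `rsn_xcor`.
#' @param ... Unused.
#' @return Tibble `network_a`, `network_b`, `r`.
#' @export
tidy.rsn_xcor <- function(x, ...) {
  m <- x$matrix
  tibble::tibble(
    network_a = rep(rownames(m), times = ncol(m)),
    network_b = rep(colnames(m), each = nrow(m)),
    r = as.vector(m)
  )
}
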