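#' Exclusive voxel sets after overlap exclusion
#'
#' Voxels belonging to more than one network are dropped from every network,
#' so the returned sets are pairwise disjoint subsets of the originals.
#'
#' @param atlas An `rsn_atlas`.
#' @return Named list of integer voxel-index vectors.
#' @export
exclude_overlap <- function(atlas) {
  stopifnot(inherits(atlas, "rsn_atlas"))
  all_vox <- unlist(atlas$masks, use.names = FALSE)
  multi <- unique(all_vox[duplicated(all_vox)])
  out <- lapply(atlas$masks, function(v) setdiff(v, multi))
  empty <- names(out)[lengths(out) == 0]
  if (length(empty) > 0)
    stop_rsn(paste("network(s) left empty after overlap exclusion:",
                   paste(empty, collapse = ", ")))
  out
}

# 1D Gaussian kernel matrix (dim x dim) with truncated, renormalized tails
# so constants stay constant at the edges.
gauss_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- ceiling(3 * sigma_vox)
  w <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    keep <- j >= 1 & j <= n
    K[i, j[keep]] <- w[keep] / sum(w[keep])
  }
  K
}

#' Spatially smooth a dataset's volumes
#'
#' Separable 3D Gaussian convolution applied volume by volume, with
#' `sigma = fwhm / (2 sqrt(2 log 2))` per axis in voxel units. `fwhm_mm = 0`
#' is the identity. Used for the with/without-smoothing sensitivity
#' comparison; the synthetic default pipeline runs unsmoothed.
#'
#' @param dataset An `rsn_bold`.
#' @param fwhm_mm Kernel full width at half maximum, millimetres.
#' @param voxel_size_mm Isotropic voxel size, millimetres.
#' @return The dataset with smoothed volumes.
#' @export
smooth_volumes <- function(dataset, fwhm_mm, voxel_size_mm = 3) {
  stopifnot(inherits(dataset, "rsn_bold"))
  assert_that(fwhm_mm >= 0, "fwhm_mm must be non-negative")
  assert_that(voxel_size_mm > 0, "voxel_size_mm must be positive")
  if (fwhm_mm == 0) return(dataset)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  d <- dim(dataset$volumes)
  Kx <- gauss_kernel_matrix(d[1], sigma)
  Ky <- gauss_kernel_matrix(d[2], sigma)
  Kz <- gauss_kernel_matrix(d[3], sigma)
  out <- dataset$volumes
  for (tt in seq_len(d[4])) {
    v <- out[, , , tt]
    # axis 1
    v <- array(Kx %*% matrix(v, nrow = d[1]), dim = d[1:3])
    # axis 2
    v <- aperm(array(Ky %*% matrix(aperm(v, c(2, 1, 3)), nrow = d[2]),
                     dim = d[c(2, 1, 3)]), c(2, 1, 3))
    # axis 3
    v <- aperm(array(Kz %*% matrix(aperm(v, c(3, 1, 2)), nrow = d[3]),
                     dim = d[c(3, 1, 2)]), c(2, 3, 1))
    out[, , , tt] <- v
  }
  dataset$volumes <- out
  dataset
}

#' Extract a network's voxel-by-time matrix
#'
#' @param dataset An `rsn_bold`.
#' @param voxel_ids Integer linear voxel indices (typically one entry of
#'   [exclude_overlap()]).
#' @param network Network label carried along.
#' @return An `rsn_ts` object: matrix `data` (voxels x time), `voxel_ids`,
#'   `tr`, `subject_id`, `network` and `cleaned` flags.
#' @export
extract_timeseries <- function(dataset, voxel_ids, network) {
  stopifnot(inherits(dataset, "rsn_bold"))
  d <- dim(dataset$volumes)
  m <- matrix(dataset$volumes, nrow = prod(d[1:3]))[voxel_ids, ,
                                                    drop = FALSE]
  structure(
    list(network = network, subject_id = dataset$subject_id,
         voxel_ids = voxel_ids, data = m, tr = dataset$tr,
         cleaned = c(regressed = FALSE, filtered = FALSE)),
    class = "rsn_ts"
  )
}

#' @export
print.rsn_ts <- function(x, ...) {
  cat(sprintf("<rsn_ts> %s/%s: %d voxels x %d volumes (regressed=%s, filtered=%s)\n",
              x$subject_id, x$network, nrow(x$data), ncol(x$data),
              x$cleaned[["regressed"]], x$cleaned[["filtered"]]))
  invisible(x)
}

#' Build the nuisance regression design
#'
#' Nineteen columns: an intercept, nine sources (six motion parameters,
#' white-matter, ventricular and global signals), and the backward-difference
#' temporal derivative of each source (first entry 0). All columns except
#' the intercept are mean-centered.
#'
#' @param dataset An `rsn_bold`.
#' @return An `rsn_design`: `columns` (time x 19 matrix), `column_names`.
#' @export
build_nuisance_design <- function(dataset) {
  stopifnot(inherits(dataset, "rsn_bold"))
  t <- dim(dataset$volumes)[4]
  for (nm in c("motion", "wm_signal", "ventricle_signal", "global_signal"))
    if (is.null(dataset[[nm]]))
      stop_rsn(paste("missing nuisance regressor:", nm))
  assert_that(ncol(dataset$motion) == 6, "motion table must have 6 columns")
  src <- cbind(dataset$motion, wm = dataset$wm_signal,
               ventricle = dataset$ventricle_signal,
               global = dataset$global_signal)
  assert_that(nrow(src) == t, "regressor length must equal volume count")
  deriv <- apply(src, 2, function(x) c(0, diff(x)))
  colnames(deriv) <- paste0("d_", colnames(src))
  X <- cbind(intercept = 1, scale(cbind(src, deriv), center = TRUE,
                                  scale = FALSE))
  structure(list(columns = X, column_names = colnames(X)),
            class = "rsn_design")
}

#' Remove nuisance variance by linear regression
#'
#' Each voxel row is replaced by its least-squares residual against the
#' full design; residuals are orthogonal to every design column. A
#' rank-deficient design is handled by the Moore-Penrose pseudoinverse with
#' a warning.
#'
#' @param ts An `rsn_ts`.
#' @param design An `rsn_design` with as many rows as `ts` has timepoints.
#' @return `ts` with residual data and `regressed = TRUE`.
#' @export
regress_nuisance <- function(ts, design) {
  stopifnot(inherits(ts, "rsn_ts"), inherits(design, "rsn_design"))
  X <- design$columns
  assert_that(nrow(X) == ncol(ts$data),
              "design rows must equal time length")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    warning("rank-deficient nuisance design; using pseudoinverse")
    beta <- MASS::ginv(X) %*% t(ts$data)
    res <- t(ts$data) - X %*% beta
  } else {
    res <- qr.resid(qr_x, t(ts$data))
  }
  ts$data <- t(res)
  ts$cleaned[["regressed"]] <- TRUE
  ts
}

#' Band-pass filter voxel time-series
#'
#' Zero-phase (forward-backward) Butterworth filter of order 2, the
#' standard resting-state realization: passband gain above 0.9 at band
#' center, stopband gain below 0.1 one octave outside either edge, no
#' phase distortion.
#'
#' @param ts An `rsn_ts`.
#' @param low_hz,high_hz Band edges in Hz; `0 <= low < high <= 1/(2 tr)`.
#' @return `ts` filtered, `filtered = TRUE`.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(ts, "rsn_ts"))
  nyq <- 1 / (2 * ts$tr)
  assert_that(low_hz >= 0 && low_hz < high_hz && high_hz <= nyq,
              sprintf("band must satisfy 0 <= low < high <= Nyquist (%.3g Hz)",
                      nyq))
  bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  # remove DC analytically before filtering: it lies outside any passband
  # and would otherwise leak through filtfilt's edge transients
  ts$data <- t(apply(ts$data, 1, function(x)
    signal::filtfilt(bf, x - mean(x))))
  ts$cleaned[["filtered"]] <- TRUE
  ts
}

#' Preprocess one subject end-to-end
#'
#' Overlap exclusion, optional smoothing, per-network extraction, nuisance
#' regression with temporal derivatives, band-pass filtering — in that fixed
#' order.
#'
#' @param dataset An `rsn_bold`.
#' @param atlas The matching `rsn_atlas`.
#' @param band Band edges in Hz.
#' @param smooth_fwhm_mm Optional smoothing FWHM (0 = off, the default).
#' @param voxel_size_mm Voxel size for smoothing.
#' @param filter Set `FALSE` to stop after regression (spectral analysis
#'   consumes regressed-but-unfiltered series).
#' @return Named list of cleaned `rsn_ts`, one per network.
#' @export
preprocess_subject <- function(dataset, atlas, band = c(0.01, 0.08),
                               smooth_fwhm_mm = 0, voxel_size_mm = 3,
                               filter = TRUE) {
  excl <- exclude_overlap(atlas)
  if (smooth_fwhm_mm > 0)
    dataset <- smooth_volumes(dataset, smooth_fwhm_mm, voxel_size_mm)
  design <- build_nuisance_design(dataset)
  out <- lapply(names(excl), function(nm) {
    ts <- extract_timeseries(dataset, excl[[nm]], nm)
    ts <- regress_nuisance(ts, design)
    if (filter) ts <- bandpass(ts, band[1], band[2])
    ts
  })
  stats::setNames(out, names(excl))
}
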