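#' Describe one synthetic resting-state network
#'
#' A network spec fixes the size and correlation architecture of one
#' synthetic RSN: how many voxels it occupies, how many temporally coherent
#' communities those voxels split into, the target Pearson correlation
#' between voxels of the same community (`within_community_r`) and of
#' different communities (`between_community_r`), and the fraction of the
#' clean signal's spectral power lying in the 0.01-0.08 Hz band
#' (`low_freq_fraction`). A small fraction of each community's voxels act as
#' "bridges" mixing two adjacent community signals, which emulates the
#' spatial autocorrelation of real voxel data and keeps the graph connected
#' at conservative correlation thresholds.
#'
#' @param name Network label, e.g. `"DMN"`.
#' @param group `"cognitive"` or `"perceptual"`.
#' @param n_voxels Number of voxels the network occupies.
#' @param n_communities Number of coherent sub-communities (>= 1).
#' @param within_community_r Target Pearson r between voxels of the same
#'   community, in (0, 1).
#' @param between_community_r Target Pearson r between voxels of different
#'   communities of the same network, in `[0, within_community_r)`.
#' @param low_freq_fraction Fraction of clean-signal spectral power in the
#'   low-frequency band, in (0, 1).
#' @param bridge_fraction Fraction of each community's voxels mixing the
#'   adjacent community's signal.
#' @return A one-row tibble.
#' @export
network_spec <- function(name, group, n_voxels = 200L, n_communities = 4L,
                         within_community_r = 0.8,
                         between_community_r = 0.3,
                         low_freq_fraction = 0.65,
                         bridge_fraction = 0.15) {
  group <- match.arg(group, c("cognitive", "perceptual"))
  assert_that(n_voxels >= n_communities,
              "n_voxels must be at least n_communities")
  assert_that(within_community_r > 0 && within_community_r < 1,
              "within_community_r must lie in (0, 1)")
  assert_that(between_community_r >= 0 &&
                between_community_r < within_community_r,
              "between_community_r must lie in [0, within_community_r)")
  assert_that(low_freq_fraction > 0 && low_freq_fraction < 1,
              "low_freq_fraction must lie in (0, 1)")
  assert_that(bridge_fraction >= 0 && bridge_fraction < 0.5,
              "bridge_fraction must lie in [0, 0.5)")
  tibble::tibble(
    name = as.character(name), group = group,
    n_voxels = as.integer(n_voxels),
    n_communities = as.integer(n_communities),
    within_community_r = within_community_r,
    between_community_r = between_community_r,
    low_freq_fraction = low_freq_fraction,
    bridge_fraction = bridge_fraction
  )
}

#' Default six-network layout
#'
#' Three higher-cognitive networks (CEN, DAN, DMN) and three perceptual
#' networks (SMN, AN, VN). Cognitive networks get more, less inter-connected
#' communities and a larger low-frequency power fraction; perceptual
#' networks are fewer-community and more homogeneous. These defaults are
#' chosen so that the default cohort reproduces the qualitative
#' cognitive/perceptual dichotomy (higher sigma, gamma, lambda and band
#' power; lower clustering coefficient for cognitive networks).
#'
#' @return A six-row tibble of network specs.
#' @export
default_networks <- function() {
  dplyr::bind_rows(
    network_spec("CEN", "cognitive", 210L, 6L, 0.85, 0.15, 0.75),
    network_spec("DAN", "cognitive", 220L, 6L, 0.85, 0.15, 0.75),
    network_spec("DMN", "cognitive", 260L, 7L, 0.85, 0.15, 0.78),
    network_spec("SMN", "perceptual", 160L, 3L, 0.85, 0.20, 0.58),
    network_spec("AN",  "perceptual", 170L, 3L, 0.85, 0.20, 0.55),
    network_spec("VN",  "perceptual", 180L, 3L, 0.85, 0.20, 0.62)
  )
}

#' Configuration for the synthetic BOLD generator
#'
#' Bundles acquisition constants (250 retained volumes at TR = 2 s by
#' default), the network layout, the spatial grid, nuisance-signal
#' amplitudes and the root seed.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param n_timepoints Volumes per subject (>= 16).
#' @param tr Repetition time in seconds.
#' @param networks Tibble of network specs (see [network_spec()]).
#' @param overlap_fraction Per-network fraction of voxels shared with an
#'   adjacent network, in `[0, 0.5]`.
#' @param noise_sd Standard deviation of independent voxel noise, in signal
#'   units. `0` gives noise-free voxels (clean path).
#' @param nuisance_amplitudes Named numeric amplitudes for
#'   `motion`, `wm`, `ventricle`, `global` injections; any may be 0.
#' @param grid_dim 3-vector of grid dimensions in voxels.
#' @param group_coupling Weight coupling network signals to a cohort-level
#'   latent with opposite sign for the two groups, producing the
#'   cognitive-versus-perceptual anti-correlation seen in real data.
#' @param seed Integer root seed.
#' @return An object of class `rsn_generator_config`.
#' @export
generator_config <- function(n_subjects = 12L, n_timepoints = 250L, tr = 2,
                             networks = default_networks(),
                             overlap_fraction = 0.1, noise_sd = 1,
                             nuisance_amplitudes = c(motion = 0.2, wm = 0.3,
                                                     ventricle = 0.3,
                                                     global = 0.4),
                             grid_dim = c(24L, 24L, 12L),
                             group_coupling = 0.1, seed = 1L) {
  assert_that(n_timepoints >= 16, "n_timepoints must be at least 16")
  assert_that(tr > 0, "tr must be positive")
  assert_that(overlap_fraction >= 0 && overlap_fraction <= 0.5,
              "overlap_fraction must lie in [0, 0.5]")
  assert_that(noise_sd >= 0, "noise_sd must be non-negative")
  assert_that(length(grid_dim) == 3 && all(grid_dim >= 2),
              "grid_dim must be three dimensions >= 2")
  assert_that(is.data.frame(networks) && nrow(networks) >= 2,
              "networks must be a spec tibble with at least two rows")
  req <- c("motion", "wm", "ventricle", "global")
  missing <- setdiff(req, names(nuisance_amplitudes))
  assert_that(length(missing) == 0,
              paste("nuisance_amplitudes missing:",
                    paste(missing, collapse = ", ")))
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_timepoints = as.integer(n_timepoints), tr = tr,
         networks = networks, overlap_fraction = overlap_fraction,
         noise_sd = noise_sd,
         nuisance_amplitudes = nuisance_amplitudes[req],
         grid_dim = as.integer(grid_dim),
         group_coupling = group_coupling, seed = as.integer(seed)),
    class = "rsn_generator_config"
  )
}

# Coordinates (n x 3) of every voxel in a grid, column-major order.
grid_coords <- function(dim3) {
  as.matrix(expand.grid(x = seq_len(dim3[1]), y = seq_len(dim3[2]),
                        z = seq_len(dim3[3])))
}

# Ring of blob centers for k networks, spread over the grid interior.
network_centers <- function(dim3, k) {
  ang <- 2 * pi * (seq_len(k) - 1) / k
  cx <- dim3[1] / 2 + 0.32 * dim3[1] * cos(ang)
  cy <- dim3[2] / 2 + 0.32 * dim3[2] * sin(ang)
  cz <- ifelse(seq_len(k) %% 2 == 0, dim3[3] * 0.7, dim3[3] * 0.35)
  cbind(cx, cy, cz)
}

#' Generate a labelled synthetic atlas
#'
#' Places each network as a compact blob of voxels around a center on a
#' ring, with a configured fraction of voxels shared pairwise between
#' ring-adjacent networks (those voxels carry two labels, mirroring the
#' partial overlap of real RSN maps). Deterministic for a fixed config.
#'
#' @param config An [generator_config()] object.
#' @return An object of class `rsn_atlas`: grid dimensions, one voxel-index
#'   set per network, and the network-to-group map.
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "rsn_generator_config"))
  nets <- config$networks
  k <- nrow(nets)
  dim3 <- config$grid_dim
  coords <- grid_coords(dim3)
  centers <- network_centers(dim3, k)
  taken <- rep(FALSE, nrow(coords))
  masks <- stats::setNames(vector("list", k), nets$name)

  # claim the n nearest unclaimed voxels to a point (ties by index)
  claim <- function(point, n, what) {
    d <- sqrt(colSums((t(coords) - point)^2))
    ord <- order(d, seq_along(d))
    free <- ord[!taken[ord]]
    if (length(free) < n)
      stop_rsn(sprintf(
        "grid %s too small to host %d voxels for %s",
        paste(dim3, collapse = "x"), n, what))
    idx <- free[seq_len(n)]
    taken[idx] <<- TRUE
    idx
  }

  # shared blobs between ring-adjacent pairs, sized so each network's
  # multi-label fraction is close to overlap_fraction
  shared <- vector("list", k)
  if (config$overlap_fraction > 0 && k >= 2) {
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      if (k == 2 && i == 2) break  # one pair only
      n_sh <- round(config$overlap_fraction *
                      (nets$n_voxels[i] + nets$n_voxels[j]) / 4)
      if (n_sh > 0) {
        mid <- (centers[i, ] + centers[j, ]) / 2
        shared[[i]] <- claim(mid, n_sh,
                             paste0(nets$name[i], "/", nets$name[j]))
      }
    }
  }
  for (i in seq_len(k)) {
    j_prev <- if (i == 1L) k else i - 1L
    sh <- c(shared[[i]], if (j_prev != i) shared[[j_prev]])
    n_core <- nets$n_voxels[i] - length(sh)
    if (n_core < 1)
      stop_rsn(sprintf("network %s smaller than its shared overlap",
                       nets$name[i]))
    core <- claim(centers[i, ], n_core, nets$name[i])
    masks[[i]] <- sort(c(core, sh))
  }
  structure(
    list(dim = dim3, masks = masks,
         groups = stats::setNames(nets$group, nets$name)),
    class = "rsn_atlas"
  )
}

#' @export
print.rsn_atlas <- function(x, ...) {
  cat("<rsn_atlas> grid", paste(x$dim, collapse = "x"), "\n")
  for (nm in names(x$masks))
    cat(sprintf("  %-4s %-10s %4d voxels\n", nm, x$groups[[nm]],
                length(x$masks[[nm]])))
  invisible(x)
}

#' Tidy an atlas into a voxel-label table
#'
#' @param x An `rsn_atlas`.
#' @param ... Unused.
#' @return A tibble with columns `voxel` (linear grid index), `network`,
#'   `group`. Overlap voxels appear once per label.
#' @export
tidy.rsn_atlas <- function(x, ...) {
  purrr::imap_dfr(x$masks, function(v, nm)
    tibble::tibble(voxel = v, network = nm, group = unname(x$groups[[nm]])))
}

# Unit-variance series whose periodogram puts exactly `frac` of its
# (non-DC) power in `band`: fixed per-bin amplitudes, random phases.
shaped_latent <- function(t, tr, frac, band = c(0.01, 0.08)) {
  k <- seq_len(floor((t - 1) / 2))       # positive frequency bins
  f <- k / (t * tr)
  inb <- f >= band[1] & f <= band[2]
  assert_that(any(inb) && any(!inb),
              "time-series too short to shape the requested band")
  pow <- numeric(length(k))
  pow[inb] <- frac / sum(inb)
  pow[!inb] <- (1 - frac) / sum(!inb)
  amp <- sqrt(2 * pow)                   # var of a*cos = a^2/2
  phase <- runif(length(k), 0, 2 * pi)
  tt <- seq_len(t) - 1
  x <- amp * cos(outer(2 * pi * f * tr, tt) + phase)
  colSums(x)
}

# Smooth bounded random walk used for motion traces.
motion_trace <- function(t) {
  w <- cumsum(rnorm(t))
  w <- w - mean(w)
  w / max(sd(w), 1e-12)
}

#' Generate a synthetic multi-subject BOLD cohort
#'
#' Per network, voxel signals are a shared community latent plus
#' independent voxel noise; the latent amplitude is solved from the target
#' within-community correlation at unit noise (`alpha = sqrt(r / (1 - r))`,
#' so that `alpha^2 / (alpha^2 + noise_sd^2) = r` when `noise_sd = 1`, the
#' default). Raising `noise_sd` above 1 lowers the realized correlation;
#' `noise_sd = 0` gives perfectly correlated communities (clean path).
#' Community latents share a network latent with weight
#' `between_community_r / within_community_r`, and bridge voxels mix two
#' ring-adjacent community latents. Latents are spectrally shaped so the
#' clean signal's 0.01-0.08 Hz energy fraction equals `low_freq_fraction`.
#' Motion-like, white-matter-like, ventricle-like and global nuisance
#' signals are injected with per-voxel random loadings at the configured
#' amplitudes and recorded as regressor channels.
#'
#' @param config An [generator_config()].
#' @param atlas The matching [generate_atlas()] output.
#' @return A list of `rsn_bold` datasets, one per subject. Each carries the
#'   4D volume array, TR, the 6-column motion table, wm/ventricle/global
#'   channels, and (as `latents`) the clean community latents used.
#' @export
generate_cohort <- function(config, atlas) {
  stopifnot(inherits(config, "rsn_generator_config"),
            inherits(atlas, "rsn_atlas"))
  nets <- config$networks
  assert_that(identical(sort(names(atlas$masks)), sort(nets$name)),
              "atlas networks do not match config networks")
  t <- config$n_timepoints
  with_seed(substream_seed(config$seed, "cohort"), {
    lapply(seq_len(config$n_subjects), function(s)
      generate_subject(config, atlas, sprintf("sub-%02d", s)))
  })
}

# One subject; relies on the caller's RNG stream.
generate_subject <- function(config, atlas, subject_id) {
  nets <- config$networks
  t <- config$n_timepoints
  tr <- config$tr
  noise_sd <- config$noise_sd
  amps <- config$nuisance_amplitudes
  nvox_grid <- prod(config$grid_dim)

  # cohort-level latent couples the two groups with opposite signs
  coh <- shaped_latent(t, tr, mean(nets$low_freq_fraction))
  h <- config$group_coupling

  latents <- list()
  comm_of <- list()     # per network: community index per voxel

  # clean voxel signals per network
  net_signals <- list()
  for (i in seq_len(nrow(nets))) {
    sp <- nets[i, ]
    sgn <- if (sp$group == "cognitive") 1 else -1
    own <- shaped_latent(t, tr, sp$low_freq_fraction)
    lnet <- sqrt(h) * sgn * coh + sqrt(1 - h) * own
    g <- sp$between_community_r / sp$within_community_r
    K <- sp$n_communities
    lcom <- sapply(seq_len(K), function(k)
      sqrt(g) * lnet + sqrt(1 - g) * shaped_latent(t, tr,
                                                   sp$low_freq_fraction))
    lcom <- matrix(lcom, ncol = K)
    vox <- atlas$masks[[sp$name]]
    n <- length(vox)
    # contiguous community blocks in voxel order
    comm <- sort(rep(seq_len(K), length.out = n))
    sigs <- matrix(0, nrow = n, ncol = t)
    for (k in seq_len(K)) {
      idx <- which(comm == k)
      nb <- if (K > 1) floor(sp$bridge_fraction * length(idx)) else 0L
      core_idx <- if (nb > 0) idx[seq_len(length(idx) - nb)] else idx
      sigs[core_idx, ] <- matrix(lcom[, k], nrow = length(core_idx),
                                 ncol = t, byrow = TRUE)
      if (nb > 0) {
        k2 <- if (k == K) 1L else k + 1L
        br <- (lcom[, k] + lcom[, k2]) / sqrt(2 + 2 * g)
        bridge_idx <- idx[seq(length(idx) - nb + 1, length(idx))]
        sigs[bridge_idx, ] <- matrix(br, nrow = nb, ncol = t, byrow = TRUE)
      }
    }
    latents[[sp$name]] <- t(lcom)
    comm_of[[sp$name]] <- comm
    net_signals[[sp$name]] <- sigs
  }

  # latent amplitude solved from the target within-community r for
  # unit-variance voxel noise: alpha^2 / (alpha^2 + 1) = r. Calibrated at
  # noise_sd = 1 (the default), so extra noise lowers realized r and
  # noise-free runs give r = 1.
  alpha_of <- function(r) sqrt(r / (1 - r))

  # nuisance sources (recorded channels)
  motion <- sapply(seq_len(6), function(j) motion_trace(t))
  colnames(motion) <- paste0("mot", 1:6)
  wm <- shaped_latent(t, tr, 0.5)
  ventricle <- shaped_latent(t, tr, 0.5)
  globalsig <- shaped_latent(t, tr, 0.6)

  # paint voxels; overlap voxels average the signals of their networks
  acc <- matrix(0, nrow = nvox_grid, ncol = t)
  cnt <- integer(nvox_grid)
  for (i in seq_len(nrow(nets))) {
    sp <- nets[i, ]
    vox <- atlas$masks[[sp$name]]
    a <- alpha_of(sp$within_community_r)
    acc[vox, ] <- acc[vox, ] + a * net_signals[[sp$name]]
    cnt[vox] <- cnt[vox] + 1L
  }
  painted <- which(cnt > 0)
  sig <- acc[painted, , drop = FALSE] / cnt[painted]
  if (noise_sd > 0)
    sig <- sig + matrix(rnorm(length(painted) * t, sd = noise_sd),
                        ncol = t)
  # nuisance injection with per-voxel loadings
  np <- length(painted)
  inject <- function(src, amp) {
    if (amp == 0) return(NULL)
    sig <<- sig + outer(rnorm(np), src * amp)
  }
  for (j in seq_len(6)) inject(motion[, j], amps[["motion"]])
  inject(wm, amps[["wm"]])
  inject(ventricle, amps[["ventricle"]])
  inject(globalsig, amps[["global"]])

  vol_mat <- matrix(0, nrow = nvox_grid, ncol = t)
  vol_mat[painted, ] <- sig
  vol <- array(vol_mat, dim = c(config$grid_dim, t))

  structure(
    list(subject_id = subject_id, volumes = vol, tr = tr,
         motion = motion, wm_signal = wm, ventricle_signal = ventricle,
         global_signal = globalsig, latents = latents,
         communities = comm_of),
    class = "rsn_bold"
  )
}

#' @export
print.rsn_bold <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("<rsn_bold> %s: %dx%dx%d grid, %d volumes, TR %.3gs\n",
              x$subject_id, d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}
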