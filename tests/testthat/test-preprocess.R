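make_atlas <- function(masks, groups) {
  structure(list(dim = c(10L, 10L, 5L), masks = masks, groups = groups),
            class = "rsn_atlas")
}

test_that("overlap exclusion returns disjoint subsets", {
  atlas <- make_atlas(list(A = c(1L, 2L, 3L), B = c(3L, 4L)),
                      c(A = "cognitive", B = "perceptual"))
  ex <- exclude_overlap(atlas)
  expect_equal(ex$A, c(1L, 2L))
  expect_equal(ex$B, 4L)

  # disjoint input is returned unchanged
  atlas2 <- make_atlas(list(A = c(1L, 2L), B = c(5L, 6L)),
                       c(A = "cognitive", B = "perceptual"))
  expect_equal(exclude_overlap(atlas2), atlas2$masks)

  # emptied network errors with its name
  atlas3 <- make_atlas(list(A = c(1L, 2L), B = c(1L, 2L)),
                       c(A = "cognitive", B = "perceptual"))
  expect_error(exclude_overlap(atlas3), "A")
})

test_that("overlap exclusion counts match a label census on random atlases", {
  cfg <- tiny_config(seed = 31)
  cfg$overlap_fraction <- 0.2
  atlas <- generate_atlas(cfg)
  labels <- tidy(atlas)
  census <- table(labels$voxel)
  multi <- as.integer(names(census)[census > 1])
  ex <- exclude_overlap(atlas)
  for (nm in names(atlas$masks)) {
    n_multi <- sum(atlas$masks[[nm]] %in% multi)
    expect_equal(length(ex[[nm]]), length(atlas$masks[[nm]]) - n_multi)
    expect_true(all(ex[[nm]] %in% atlas$masks[[nm]]))
  }
  # pairwise disjoint
  all_ids <- unlist(ex)
  expect_equal(anyDuplicated(all_ids), 0)
})

test_that("gaussian smoothing matches its separable closed form", {
  cfg <- tiny_config(n_subjects = 1, seed = 4)
  atlas <- generate_atlas(cfg)
  ds <- generate_cohort(cfg, atlas)[[1]]

  # fwhm 0 is the identity
  expect_identical(smooth_volumes(ds, 0)$volumes, ds$volumes)

  # unit impulse: center value equals the product of the three 1D kernel
  # centers (independently computed normalized discrete Gaussian)
  dsi <- ds
  dsi$volumes <- array(0, dim = dim(ds$volumes))
  dsi$volumes[8, 8, 5, 1] <- 1
  sm <- smooth_volumes(dsi, 8, voxel_size_mm = 3)
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 3
  r <- ceiling(3 * sigma)
  w <- exp(-(-r:r)^2 / (2 * sigma^2))
  w <- w / sum(w)
  expect_equal(sm$volumes[8, 8, 5, 1], w[r + 1]^3, tolerance = 1e-10)

  # constant volume stays constant (kernel mass preserved, incl. edges)
  dsc <- ds
  dsc$volumes <- array(7, dim = dim(ds$volumes))
  smc <- smooth_volumes(dsc, 8, voxel_size_mm = 3)
  expect_equal(max(abs(smc$volumes - 7)), 0, tolerance = 1e-10)

  expect_error(smooth_volumes(ds, 8, voxel_size_mm = 0), "voxel_size")
})

test_that("nuisance design has 19 ordered, centered columns", {
  cfg <- tiny_config(n_subjects = 1, seed = 6)
  atlas <- generate_atlas(cfg)
  ds <- generate_cohort(cfg, atlas)[[1]]
  X <- build_nuisance_design(ds)
  expect_equal(dim(X$columns), c(cfg$n_timepoints, 19))
  expect_equal(X$column_names[1], "intercept")
  expect_equal(sum(grepl("^d_", X$column_names)), 9)
  # non-intercept columns are centered
  expect_true(all(abs(colMeans(X$columns[, -1])) < 1e-10))

  # constant source: derivative identically zero; ramp: constant derivative
  ds2 <- ds
  ds2$motion[, 1] <- 5
  ds2$wm_signal <- seq_len(cfg$n_timepoints) * 0.5
  X2 <- build_nuisance_design(ds2)
  d_mot1 <- X2$columns[, which(X2$column_names == "d_mot1")]
  expect_true(all(abs(d_mot1) < 1e-12))
  d_wm <- X2$columns[, which(X2$column_names == "d_wm")]
  expect_lt(max(abs(d_wm[-1] - d_wm[2])), 1e-12)

  ds3 <- ds
  ds3$wm_signal <- NULL
  expect_error(build_nuisance_design(ds3), "wm_signal")
})

test_that("nuisance regression removes exactly the design span", {
  cfg <- tiny_config(n_subjects = 1, seed = 12)
  atlas <- generate_atlas(cfg)
  ds <- generate_cohort(cfg, atlas)[[1]]
  design <- build_nuisance_design(ds)
  t_len <- cfg$n_timepoints

  # a voxel equal to the global signal regresses to ~0
  ts <- make_ts(rbind(ds$global_signal, rnorm(t_len)), tr = cfg$tr)
  res <- regress_nuisance(ts, design)
  expect_lt(max(abs(res$data[1, ])), 1e-8)

  # residuals orthogonal to every design column
  g <- res$data %*% design$columns
  norms <- sqrt(rowSums(res$data^2)) %o% sqrt(colSums(design$columns^2))
  expect_true(all(abs(g) < 1e-8 * pmax(norms, 1)))

  # a series orthogonal to all columns is unchanged
  set.seed(1)
  y <- rnorm(t_len)
  y <- qr.resid(qr(design$columns), y)
  res2 <- regress_nuisance(make_ts(matrix(y, 1), tr = cfg$tr), design)
  expect_equal(as.numeric(res2$data), y, tolerance = 1e-10)

  # small random case matches the normal-equations oracle
  set.seed(2)
  Y <- matrix(rnorm(5 * 20), 5, 20)
  X <- cbind(1, matrix(rnorm(20 * 3), 20, 3))
  dsg <- structure(list(columns = X,
                        column_names = paste0("c", 1:4)),
                   class = "rsn_design")
  got <- regress_nuisance(make_ts(Y, tr = 2), dsg)$data
  beta <- solve(t(X) %*% X, t(X) %*% t(Y))
  expected <- t(t(Y) - X %*% beta)
  expect_equal(got, expected, tolerance = 1e-10)

  # regression on residuals is a no-op
  res3 <- regress_nuisance(res, design)
  expect_equal(res3$data, res$data, tolerance = 1e-8)

  # rank-deficient design falls back to the pseudoinverse with a warning
  Xdef <- cbind(1, rnorm(20), rnorm(20))
  Xdef <- cbind(Xdef, Xdef[, 2] * 2)
  ddef <- structure(list(columns = Xdef, column_names = paste0("c", 1:4)),
                    class = "rsn_design")
  expect_warning(rdef <- regress_nuisance(make_ts(Y, tr = 2), ddef),
                 "rank-deficient")
  expect_true(all(abs(rdef$data %*% Xdef) < 1e-6))
})

test_that("band-pass filter honors its gain contract", {
  t_len <- 250
  tr <- 2
  tm <- seq(0, by = tr, length.out = t_len)
  mk <- function(f) make_ts(matrix(sin(2 * pi * f * tm), 1), tr = tr)
  rms_mid <- function(x) sqrt(mean(x[30:220]^2))

  inband <- bandpass(mk(0.04))
  expect_gte(rms_mid(inband$data[1, ]) / rms_mid(mk(0.04)$data[1, ]), 0.9)

  highf <- bandpass(mk(0.2))
  expect_lte(rms_mid(highf$data[1, ]) / rms_mid(mk(0.2)$data[1, ]), 0.1)

  dc <- bandpass(make_ts(matrix(1, 1, t_len), tr = tr))
  expect_lt(max(abs(dc$data)), 1e-6)

  # length preserved, no NaN
  expect_equal(ncol(inband$data), t_len)
  expect_false(any(is.na(inband$data)))

  expect_error(bandpass(mk(0.04), low_hz = 0.01, high_hz = 0.3), "Nyquist")
})

test_that("with zero nuisance amplitudes regression barely changes variance", {
  cfg <- tiny_config(n_subjects = 1, seed = 23,
                     nuisance_amplitudes = c(motion = 0, wm = 0,
                                             ventricle = 0, global = 0))
  atlas <- generate_atlas(cfg)
  ds <- generate_cohort(cfg, atlas)[[1]]
  ex <- exclude_overlap(atlas)
  ts <- extract_timeseries(ds, ex[[1]], names(ex)[1])
  v_before <- apply(ts$data, 1, var)
  res <- regress_nuisance(ts, build_nuisance_design(ds))
  v_after <- apply(res$data, 1, var)
  expect_true(all(v_after / v_before > 0.8))
  expect_true(all(v_after / v_before <= 1 + 1e-10))
})

test_that("preprocess_subject runs the fixed stage order", {
  cfg <- tiny_config(n_subjects = 1, seed = 14)
  atlas <- generate_atlas(cfg)
  ds <- generate_cohort(cfg, atlas)[[1]]
  out <- preprocess_subject(ds, atlas)
  expect_named(out, cfg$networks$name)
  for (ts in out) {
    expect_true(ts$cleaned[["regressed"]])
    expect_true(ts$cleaned[["filtered"]])
    expect_false(any(is.na(ts$data)))
  }
  # voxel sets are the exclusive ones
  ex <- exclude_overlap(atlas)
  expect_equal(out[[1]]$voxel_ids, ex[[1]])
})
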