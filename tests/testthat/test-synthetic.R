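test_that("atlas respects overlap settings and sizing", {
  cfg0 <- tiny_config()
  cfg0$overlap_fraction <- 0
  atlas0 <- generate_atlas(cfg0)
  labels0 <- tidy(atlas0)
  expect_equal(max(table(labels0$voxel)), 1)
  expect_equal(lengths(atlas0$masks),
               stats::setNames(cfg0$networks$n_voxels, cfg0$networks$name))

  # six networks of 100 voxels, overlap 0.1: per-network multi-label
  # fraction close to 0.1
  nets <- dplyr::bind_rows(lapply(1:6, function(i)
    network_spec(paste0("n", i), if (i <= 3) "cognitive" else "perceptual",
                 100L, 2L, 0.8, 0.2, 0.6)))
  cfg <- generator_config(networks = nets, overlap_fraction = 0.1,
                          grid_dim = c(20L, 20L, 10L), seed = 3)
  atlas <- generate_atlas(cfg)
  labels <- tidy(atlas)
  multi <- as.integer(names(which(table(labels$voxel) > 1)))
  for (nm in names(atlas$masks)) {
    frac <- mean(atlas$masks[[nm]] %in% multi)
    expect_gte(frac, 0.07)
    expect_lte(frac, 0.13)
  }

  # an impossible request errors and names the network
  big <- generator_config(
    networks = dplyr::bind_rows(
      network_spec("huge", "cognitive", 5000L, 2L, 0.8, 0.2, 0.6),
      network_spec("tiny", "perceptual", 10L, 2L, 0.8, 0.2, 0.6)),
    grid_dim = c(8L, 8L, 8L), seed = 1)
  expect_error(generate_atlas(big), "huge")
})

test_that("generator is deterministic for a fixed seed", {
  cfg <- tiny_config(seed = 9)
  a1 <- generate_atlas(cfg)
  a2 <- generate_atlas(cfg)
  expect_identical(a1, a2)
  c1 <- generate_cohort(cfg, a1)
  c2 <- generate_cohort(cfg, a1)
  expect_identical(c1, c2)
  # a different seed changes the data
  cfg2 <- tiny_config(seed = 10)
  c3 <- generate_cohort(cfg2, generate_atlas(cfg2))
  expect_false(identical(c1[[1]]$volumes, c3[[1]]$volumes))
})

test_that("noise-free single-community network has unit pairwise r", {
  nets <- dplyr::bind_rows(
    network_spec("one", "cognitive", 30L, 1L, 0.8, 0, 0.7),
    network_spec("two", "perceptual", 30L, 1L, 0.8, 0, 0.5))
  cfg <- generator_config(n_subjects = 1, networks = nets,
                          overlap_fraction = 0, noise_sd = 0,
                          nuisance_amplitudes = c(motion = 0, wm = 0,
                                                  ventricle = 0, global = 0),
                          grid_dim = c(12L, 12L, 8L), seed = 5)
  atlas <- generate_atlas(cfg)
  ds <- generate_cohort(cfg, atlas)[[1]]
  ts <- extract_timeseries(ds, atlas$masks$one, "one")
  r <- cor(t(ts$data))
  expect_true(all(abs(r - 1) < 1e-10))
})

test_that("clean latents carry the requested band fraction", {
  cfg <- tiny_config(n_subjects = 3, seed = 21)
  atlas <- generate_atlas(cfg)
  cohort <- generate_cohort(cfg, atlas)
  fr <- sapply(names(atlas$masks), function(nm) {
    target <- cfg$networks$low_freq_fraction[cfg$networks$name == nm]
    got <- sapply(cohort, function(ds) {
      mean(apply(ds$latents[[nm]], 1, function(x) {
        ts <- make_ts(matrix(x, nrow = 1), tr = cfg$tr)
        band_power_summary(ts)$band_contribution
      }))
    })
    abs(mean(got) - target)
  })
  expect_lt(mean(fr), 0.05)
})

test_that("realized within-community correlation tracks the target", {
  nets <- dplyr::bind_rows(
    network_spec("a", "cognitive", 40L, 2L, 0.7, 0.1, 0.7,
                 bridge_fraction = 0),
    network_spec("b", "perceptual", 40L, 2L, 0.5, 0.1, 0.5,
                 bridge_fraction = 0))
  cfg <- generator_config(n_subjects = 4, networks = nets,
                          overlap_fraction = 0,
                          nuisance_amplitudes = c(motion = 0, wm = 0,
                                                  ventricle = 0, global = 0),
                          grid_dim = c(14L, 14L, 8L), seed = 8)
  atlas <- generate_atlas(cfg)
  cohort <- generate_cohort(cfg, atlas)
  for (nm in c("a", "b")) {
    target <- nets$within_community_r[nets$name == nm]
    got <- sapply(cohort, function(ds) {
      ts <- extract_timeseries(ds, atlas$masks[[nm]], nm)
      comm <- ds$communities[[nm]]
      r <- cor(t(ts$data))
      same <- outer(comm, comm, "==") & upper.tri(r)
      mean(r[same])
    })
    expect_lt(abs(mean(got) - target), 0.1)
  }
})

test_that("more voxel noise means lower realized correlation", {
  nets <- network_spec("a", "cognitive", 30L, 1L, 0.6, 0, 0.7)
  nets <- dplyr::bind_rows(nets,
                           network_spec("b", "perceptual", 30L, 1L, 0.6, 0,
                                        0.5))
  mean_r <- sapply(c(0.5, 1, 2), function(ns) {
    vals <- sapply(1:10, function(rep) {
      cfg <- generator_config(n_subjects = 1, networks = nets,
                              overlap_fraction = 0, noise_sd = ns,
                              nuisance_amplitudes = c(motion = 0, wm = 0,
                                                      ventricle = 0,
                                                      global = 0),
                              grid_dim = c(12L, 12L, 8L),
                              seed = 100 + rep)
      atlas <- generate_atlas(cfg)
      ds <- generate_cohort(cfg, atlas)[[1]]
      ts <- extract_timeseries(ds, atlas$masks$a, "a")
      r <- cor(t(ts$data))
      mean(r[upper.tri(r)])
    })
    mean(vals)
  })
  expect_true(all(diff(mean_r) < 0))
})

test_that("band fraction of clean latents is monotone in the target", {
  fr <- sapply(c(0.3, 0.55, 0.8), function(f) {
    nets <- dplyr::bind_rows(
      network_spec("a", "cognitive", 20L, 1L, 0.6, 0, f),
      network_spec("b", "perceptual", 20L, 1L, 0.6, 0, f))
    cfg <- generator_config(n_subjects = 2, networks = nets,
                            overlap_fraction = 0,
                            grid_dim = c(10L, 10L, 8L), seed = 17)
    cohort <- generate_cohort(cfg, generate_atlas(cfg))
    mean(sapply(cohort, function(ds)
      band_power_summary(make_ts(ds$latents$a[1, , drop = FALSE],
                                 tr = cfg$tr))$band_contribution))
  })
  expect_true(all(diff(fr) > 0))
})

test_that("datasets carry well-formed nuisance channels and volumes", {
  cfg <- tiny_config(seed = 2)
  atlas <- generate_atlas(cfg)
  ds <- generate_cohort(cfg, atlas)[[1]]
  expect_equal(dim(ds$volumes)[4], cfg$n_timepoints)
  expect_false(any(is.na(ds$volumes)))
  expect_equal(ncol(ds$motion), 6)
  expect_equal(length(ds$global_signal), cfg$n_timepoints)
  expect_s3_class(ds, "rsn_bold")
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(network_spec("x", "cognitive", between_community_r = 0.9,
                            within_community_r = 0.8),
               "between_community_r")
  expect_error(network_spec("x", "cognitive", within_community_r = 1.2),
               "within_community_r")
  expect_error(generator_config(n_timepoints = 8), "n_timepoints")
  expect_error(generator_config(overlap_fraction = 0.7), "overlap_fraction")
  expect_error(generator_config(nuisance_amplitudes = c(motion = 1)),
               "wm")
})
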