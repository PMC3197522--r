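#' Pipeline configuration
#'
#' One object driving the full simulate - preprocess - spectral - graph -
#' null - stats chain.
#'
#' @param generator A [generator_config()].
#' @param band Low-frequency band in Hz.
#' @param grid Correlation-threshold grid (18 values by default).
#' @param n_null Rewired null-ensemble size per graph.
#' @param threshold_sweep Compute metrics over the whole grid (set `FALSE`
#'   to evaluate the analysis threshold only).
#' @param equalize Also compute node-equalized metrics.
#' @param equalize_draws Subsample draws when equalizing.
#' @param smooth_fwhm_mm Optional spatial smoothing FWHM (0 = off).
#' @param voxel_size_mm Voxel size used by smoothing.
#' @param seed Root seed for rewiring/equalization substreams (data
#'   generation uses the generator's own seed).
#' @return An `rsn_pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            band = c(0.01, 0.08),
                            grid = threshold_grid(), n_null = 30,
                            threshold_sweep = TRUE,
                            equalize = FALSE, equalize_draws = 10,
                            smooth_fwhm_mm = 0, voxel_size_mm = 3,
                            seed = generator$seed) {
  stopifnot(inherits(generator, "rsn_generator_config"))
  nyq <- 1 / (2 * generator$tr)
  assert_that(band[1] > 0 && band[1] < band[2] && band[2] <= nyq,
              "band must lie within (0, Nyquist]")
  assert_that(all(grid > 0 & grid < 1), "grid thresholds must be in (0,1)")
  structure(
    list(generator = generator, band = band, grid = grid,
         n_null = as.integer(n_null),
         threshold_sweep = isTRUE(threshold_sweep),
         equalize = isTRUE(equalize),
         equalize_draws = as.integer(equalize_draws),
         smooth_fwhm_mm = smooth_fwhm_mm, voxel_size_mm = voxel_size_mm,
         seed = as.integer(seed)),
    class = "rsn_pipeline_config"
  )
}

# Metrics + small-world indices for one voxel subset of a correlation
# matrix at one threshold.
metrics_with_null <- function(cm, threshold, m_null, seed) {
  g <- threshold_graph(cm, threshold)
  met <- graph_metrics(g)
  sw <- small_world_indices(met, g, m = m_null, seed = seed)
  dplyr::bind_cols(glance(met),
                   glance(sw)[, c("gamma", "lambda", "sigma",
                                  "c_rand", "l_rand", "m")])
}

#' Run the full analysis pipeline
#'
#' Generates the synthetic cohort, preprocesses every subject (overlap
#' exclusion, optional smoothing, nuisance regression, band-pass), computes
#' spectral summaries on the regressed series, sweeps the binary-graph
#' metrics over the threshold grid, evaluates small-world indices against
#' rewired null ensembles at the data-driven analysis threshold, and runs
#' the group-level statistics. Deterministic for a fixed config.
#'
#' @param config An [pipeline_config()].
#' @param verbose Print stage progress to stderr.
#' @return An `rsn_results` bundle of tibbles: `spectral_table`,
#'   `cross_rsn`, `metrics_by_threshold`, `metrics_at_analysis_threshold`,
#'   optionally `metrics_equalized`, `stats_report`, `group_tests`, and
#'   `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "rsn_pipeline_config"))
  gen <- config$generator
  say <- function(...) if (verbose) message(...)

  say("stage: simulate")
  atlas <- generate_atlas(gen)
  cohort <- generate_cohort(gen, atlas)
  groups <- atlas$groups
  excl <- exclude_overlap(atlas)

  say("stage: preprocess")
  regressed <- lapply(cohort, function(ds)
    preprocess_subject(ds, atlas, band = config$band,
                       smooth_fwhm_mm = config$smooth_fwhm_mm,
                       voxel_size_mm = config$voxel_size_mm,
                       filter = FALSE))
  cleaned <- lapply(regressed, function(tl)
    lapply(tl, bandpass, low_hz = config$band[1],
           high_hz = config$band[2]))

  say("stage: spectral")
  spectral_table <- purrr::map_dfr(regressed, function(tl)
    purrr::map_dfr(tl, function(ts) {
      sp <- band_power_summary(ts, band = config$band)
      tibble::tibble(subject_id = ts$subject_id, network = ts$network,
                     group = unname(groups[[ts$network]]),
                     band_contribution = sp$band_contribution,
                     falff = sp$falff)
    }))
  xcor <- rsn_cross_correlation(cleaned)

  say("stage: correlation graphs")
  corrs <- lapply(cleaned, function(tl) lapply(tl, correlation_matrix))

  sweep <- NULL
  if (config$threshold_sweep) {
    sweep <- purrr::map_dfr(corrs, function(cl)
      purrr::map_dfr(cl, function(cm)
        purrr::map_dfr(config$grid, function(T)
          glance(graph_metrics(threshold_graph(cm, T))))))
    sweep$group <- unname(groups[sweep$network])
  }

  say("stage: null models at analysis threshold")
  t_star <- analysis_threshold(max(lengths(excl)), gen$n_timepoints,
                               config$grid)
  at_t <- purrr::map_dfr(corrs, function(cl)
    purrr::map_dfr(cl, function(cm)
      metrics_with_null(cm, t_star, config$n_null,
                        substream_seed(config$seed,
                                       paste("rewire", cm$subject_id,
                                             cm$network)))))
  at_t$group <- unname(groups[at_t$network])

  equalized <- NULL
  if (config$equalize) {
    say("stage: node equalization")
    draws <- equalize_nodes(excl, n_draws = config$equalize_draws,
                            seed = substream_seed(config$seed, "equalize"))
    eq_rows <- purrr::imap_dfr(draws, function(sets, d)
      purrr::map_dfr(corrs, function(cl)
        purrr::map_dfr(names(sets), function(nm) {
          cm <- cl[[nm]]
          keep <- match(sets[[nm]], cm$voxel_ids)
          sub <- cm
          sub$r <- cm$r[keep, keep]
          sub$voxel_ids <- cm$voxel_ids[keep]
          res <- metrics_with_null(
            sub, t_star, config$n_null,
            substream_seed(config$seed,
                           paste("eq", d, cm$subject_id, nm)))
          res$draw <- d
          res
        })))
    equalized <- eq_rows |>
      dplyr::group_by(.data$subject_id, .data$network) |>
      dplyr::summarise(dplyr::across(c("N", "E", "C", "L", "lcc_fraction",
                                       "gamma", "lambda", "sigma"), mean),
                       n_draws = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(threshold = t_star,
                    group = unname(groups[.data$network]))
  }

  say("stage: statistics")
  metric_tbls <- list(
    C = at_t[, c("subject_id", "network", "group")] |>
      dplyr::mutate(value = at_t$C),
    L = at_t[, c("subject_id", "network", "group")] |>
      dplyr::mutate(value = at_t$L),
    gamma = at_t[, c("subject_id", "network", "group")] |>
      dplyr::mutate(value = at_t$gamma),
    lambda = at_t[, c("subject_id", "network", "group")] |>
      dplyr::mutate(value = at_t$lambda),
    sigma = at_t[, c("subject_id", "network", "group")] |>
      dplyr::mutate(value = at_t$sigma),
    band_contribution = spectral_table[, c("subject_id", "network",
                                           "group")] |>
      dplyr::mutate(value = spectral_table$band_contribution),
    falff = spectral_table[, c("subject_id", "network", "group")] |>
      dplyr::mutate(value = spectral_table$falff)
  )
  n_metrics <- length(metric_tbls)
  gtests <- purrr::imap(metric_tbls, function(tbl, nm)
    group_stats(tbl, nm, vs_unity = nm %in% c("gamma", "lambda", "sigma"),
                unity_family = 18, group_family = n_metrics))
  stats_report <- purrr::map_dfr(gtests, tidy)

  structure(
    list(spectral_table = spectral_table, cross_rsn = xcor,
         metrics_by_threshold = sweep,
         metrics_at_analysis_threshold = at_t,
         metrics_equalized = equalized,
         group_tests = gtests, stats_report = stats_report,
         analysis_threshold = t_star,
         provenance = list(
           config = config, seed = config$seed,
           version = as.character(utils::packageVersion("rsntopo")))),
    class = "rsn_results"
  )
}

#' @export
print.rsn_results <- function(x, ...) {
  cat("<rsn_results>\n")
  cat(sprintf("  analysis threshold T* = %.3f\n", x$analysis_threshold))
  s <- x$metrics_at_analysis_threshold |>
    dplyr::group_by(.data$network, .data$group) |>
    dplyr::summarise(dplyr::across(c("C", "L", "sigma", "gamma", "lambda"),
                                   mean), .groups = "drop")
  print(as.data.frame(s), digits = 3)
  invisible(x)
}

#' Glance at a results bundle
#' @param x An `rsn_results`.
#' @param ... Unused.
#' @return One-row tibble of headline quantities.
#' @export
glance.rsn_results <- function(x, ...) {
  at <- x$metrics_at_analysis_threshold
  cog <- at$group == "cognitive"
  tibble::tibble(
    n_subjects = length(unique(at$subject_id)),
    n_networks = length(unique(at$network)),
    analysis_threshold = x$analysis_threshold,
    sigma_cognitive = mean(at$sigma[cog]),
    sigma_perceptual = mean(at$sigma[!cog]),
    C_cognitive = mean(at$C[cog]),
    C_perceptual = mean(at$C[!cog]),
    min_lcc_fraction = min(at$lcc_fraction)
  )
}

#' Tidy a results bundle
#' @param x An `rsn_results`.
#' @param ... Unused.
#' @return The per-subject metrics table at the analysis threshold.
#' @export
tidy.rsn_results <- function(x, ...) {
  tibble::as_tibble(x$metrics_at_analysis_threshold)
}
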