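#' Write a synthetic cohort to disk
#'
#' Emits NIfTI-1 4D volumes (one per subject), one binary NIfTI mask volume
#' per network (so overlapping labels are representable), per-subject
#' nuisance regressors as TSV (columns `mot1..mot6, wm, ventricle,
#' global`), and a YAML echo of the generator configuration.
#'
#' @param cohort List of `rsn_bold` from [generate_cohort()].
#' @param atlas The `rsn_atlas`.
#' @param config The `rsn_generator_config`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, atlas, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(atlas$masks)) {
    m <- array(0L, dim = atlas$dim)
    m[atlas$masks[[nm]]] <- 1L
    RNifti::writeNifti(RNifti::asNifti(m),
                       file.path(dir, paste0("mask-", nm, ".nii")))
  }
  for (ds in cohort) {
    RNifti::writeNifti(RNifti::asNifti(ds$volumes, pixdim = c(3, 3, 3, ds$tr)),
                       file.path(dir, paste0(ds$subject_id, "_bold.nii")))
    reg <- tibble::as_tibble(as.data.frame(ds$motion))
    names(reg) <- paste0("mot", 1:6)
    reg$wm <- ds$wm_signal
    reg$ventricle <- ds$ventricle_signal
    reg$global <- ds$global_signal
    readr::write_tsv(reg, file.path(dir,
                                    paste0(ds$subject_id, "_confounds.tsv")))
  }
  cfg <- list(n_subjects = config$n_subjects,
              n_timepoints = config$n_timepoints, tr = config$tr,
              overlap_fraction = config$overlap_fraction,
              noise_sd = config$noise_sd,
              nuisance_amplitudes = as.list(config$nuisance_amplitudes),
              grid_dim = config$grid_dim,
              group_coupling = config$group_coupling, seed = config$seed,
              networks = lapply(seq_len(nrow(config$networks)), function(i)
                as.list(config$networks[i, ])),
              groups = as.list(atlas$groups))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory produced by [write_cohort()].
#' @return List with `cohort` (list of `rsn_bold`), `atlas` (`rsn_atlas`)
#'   and `config` (the YAML echo as a list).
#' @export
read_cohort <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  masks <- list()
  for (f in sort(list.files(dir, pattern = "^mask-.*\\.nii$"))) {
    nm <- sub("^mask-(.*)\\.nii$", "\\1", f)
    vol <- as.array(RNifti::readNifti(file.path(dir, f)))
    masks[[nm]] <- which(vol > 0)
  }
  groups <- unlist(cfg$groups)
  atlas <- structure(list(dim = unlist(cfg$grid_dim),
                          masks = masks[names(groups)],
                          groups = groups),
                     class = "rsn_atlas")
  subs <- sort(list.files(dir, pattern = "_bold\\.nii$"))
  cohort <- lapply(subs, function(f) {
    sid <- sub("_bold\\.nii$", "", f)
    vol <- as.array(RNifti::readNifti(file.path(dir, f)))
    reg <- readr::read_tsv(file.path(dir, paste0(sid, "_confounds.tsv")),
                           show_col_types = FALSE)
    structure(
      list(subject_id = sid, volumes = vol, tr = cfg$tr,
           motion = as.matrix(reg[, paste0("mot", 1:6)]),
           wm_signal = reg$wm, ventricle_signal = reg$ventricle,
           global_signal = reg$global),
      class = "rsn_bold")
  })
  list(cohort = cohort, atlas = atlas, config = cfg)
}

#' Write the result tables of a pipeline run as TSV
#'
#' @param results An `rsn_results`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "rsn_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(results$spectral_table,
                   file.path(dir, "spectral_table.tsv"))
  if (!is.null(results$metrics_by_threshold))
    readr::write_tsv(results$metrics_by_threshold,
                     file.path(dir, "metrics_by_threshold.tsv"))
  readr::write_tsv(results$metrics_at_analysis_threshold,
                   file.path(dir, "metrics_at_analysis_threshold.tsv"))
  if (!is.null(results$metrics_equalized))
    readr::write_tsv(results$metrics_equalized,
                     file.path(dir, "metrics_equalized.tsv"))
  readr::write_tsv(results$stats_report, file.path(dir, "stats_report.tsv"))
  xc <- tidy(results$cross_rsn)
  readr::write_tsv(xc, file.path(dir, "cross_rsn_correlation.tsv"))
  invisible(dir)
}
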