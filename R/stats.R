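#' One-sample t test of a metric against 1
#'
#' Two-sided one-sample t test of per-subject index values (gamma, lambda,
#' sigma) against the random-graph reference value 1, with Bonferroni
#' correction over the analysis family (default 18 = 6 networks x 3
#' indices).
#'
#' @param values Numeric vector of per-subject values (>= 3).
#' @param family Bonferroni family size.
#' @return One-row tibble: `mean`, `sd`, `t`, `df`, `p_raw`, `p_corrected`,
#'   `degenerate`.
#' @export
test_vs_unity <- function(values, family = 18) {
  assert_that(length(values) >= 3, "need at least 3 values")
  if (sd(values) < 1e-14) {
    if (abs(mean(values) - 1) < 1e-14) {
      return(tibble::tibble(mean = 1, sd = 0, t = 0,
                            df = length(values) - 1, p_raw = 1,
                            p_corrected = 1, degenerate = TRUE))
    }
    return(tibble::tibble(mean = mean(values), sd = 0, t = Inf,
                          df = length(values) - 1, p_raw = 0,
                          p_corrected = 0, degenerate = TRUE))
  }
  tt <- t.test(values, mu = 1)
  tibble::tibble(mean = mean(values), sd = sd(values),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_raw = tt$p.value,
                 p_corrected = min(1, tt$p.value * family),
                 degenerate = FALSE)
}

#' One-way ANOVA of a metric across networks
#'
#' Network as the single factor, subjects as replicates.
#'
#' @param tbl Tibble with columns `subject_id`, `network`, `value`, one row
#'   per subject-network cell (balanced).
#' @return One-row tibble `F`, `df1`, `df2`, `p`.
#' @export
anova_networks <- function(tbl) {
  assert_that(all(c("subject_id", "network", "value") %in% names(tbl)),
              "tbl needs subject_id, network, value columns")
  counts <- table(tbl$network)
  assert_that(length(counts) >= 2, "need at least 2 networks")
  assert_that(length(unique(counts)) == 1 && all(counts >= 2),
              "unbalanced or missing subject-network cells")
  fit <- aov(value ~ network, data = tbl)
  s <- summary(fit)[[1]]
  tibble::tibble(F = s[["F value"]][1], df1 = s[["Df"]][1],
                 df2 = s[["Df"]][2], p = s[["Pr(>F)"]][1])
}

#' Two-way ANOVA of the cognitive/perceptual group effect
#'
#' Factors: group (2 levels) and network nested within group; subjects are
#' replicates. The group main effect is reported, Bonferroni-corrected over
#' the number of metrics tested. `subject_block = TRUE` adds subject as an
#' additive blocking factor (repeated-measures variant, which changes the
#' error degrees of freedom).
#'
#' @param tbl Tibble with columns `subject_id`, `network`, `group`,
#'   `value`.
#' @param family Bonferroni family (number of metrics tested).
#' @param subject_block Use subject as a blocking factor.
#' @return One-row tibble: `F_group`, `df1`, `df2`, `p_raw`, `p_corrected`,
#'   and `direction` (sign of cognitive mean minus perceptual mean).
#' @export
anova_groups <- function(tbl, family = 1, subject_block = FALSE) {
  assert_that(all(c("subject_id", "network", "group", "value") %in%
                    names(tbl)),
              "tbl needs subject_id, network, group, value columns")
  tbl$group <- factor(tbl$group)
  tbl$network <- factor(tbl$network)
  assert_that(nlevels(tbl$group) == 2, "need exactly two groups")
  per_group <- table(tbl$group)
  assert_that(all(per_group >= 2), "singleton group")
  fit <- if (subject_block) {
    aov(value ~ factor(subject_id) + group + group / network, data = tbl)
  } else {
    aov(value ~ group + group / network, data = tbl)
  }
  s <- summary(fit)[[1]]
  rn <- trimws(rownames(s))
  gi <- which(rn == "group")
  ri <- which(rn == "Residuals")
  mg <- tapply(tbl$value, tbl$group, mean)
  dir_cog <- unname(mg[["cognitive"]] - mg[["perceptual"]])
  p <- s[["Pr(>F)"]][gi]
  tibble::tibble(F_group = s[["F value"]][gi], df1 = s[["Df"]][gi],
                 df2 = s[["Df"]][ri], p_raw = p,
                 p_corrected = min(1, p * family),
                 direction = sign(dir_cog))
}

#' Full inferential summary for one metric
#'
#' Runs the one-sample tests against 1 per network (for the small-world
#' indices), the one-way ANOVA across networks, and the two-way group
#' ANOVA, assembling a tidy report.
#'
#' @param tbl Tibble with `subject_id`, `network`, `group`, `value`.
#' @param metric Metric label.
#' @param vs_unity Also test each network's values against 1.
#' @param unity_family Bonferroni family for the one-sample tests.
#' @param group_family Bonferroni family for the group ANOVA.
#' @return An `rsn_groupstats` list with `per_network`, `vs_unity`,
#'   `anova_networks`, `anova_groups` tibbles.
#' @export
group_stats <- function(tbl, metric, vs_unity = FALSE, unity_family = 18,
                        group_family = 1) {
  per_network <- tbl |>
    dplyr::group_by(.data$network, .data$group) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(metric = metric, .before = 1)
  unity <- NULL
  if (vs_unity) {
    unity <- tbl |>
      dplyr::group_by(.data$network) |>
      dplyr::reframe(test_vs_unity(.data$value, family = unity_family)) |>
      dplyr::mutate(metric = metric, .before = 1)
  }
  structure(
    list(metric = metric, per_network = per_network, vs_unity = unity,
         anova_networks = anova_networks(tbl),
         anova_groups = anova_groups(tbl, family = group_family)),
    class = "rsn_groupstats"
  )
}

#' @export
print.rsn_groupstats <- function(x, ...) {
  cat(sprintf("<rsn_groupstats> %s: group F=%.2f p_corr=%.3g (direction %+d)\n",
              x$metric, x$anova_groups$F_group, x$anova_groups$p_corrected,
              x$anova_groups$direction))
  invisible(x)
}

#' Tidy a group-stats result
#' @param x An `rsn_groupstats`.
#' @param ... Unused.
#' @return Long tibble of test rows (scope, statistic, df, p values).
#' @export
tidy.rsn_groupstats <- function(x, ...) {
  rows <- list(
    tibble::tibble(metric = x$metric, scope = "networks_anova",
                   term = "network", statistic = x$anova_networks$F,
                   df1 = x$anova_networks$df1, df2 = x$anova_networks$df2,
                   p_raw = x$anova_networks$p, p_corrected = NA_real_),
    tibble::tibble(metric = x$metric, scope = "group_anova",
                   term = "group", statistic = x$anova_groups$F_group,
                   df1 = x$anova_groups$df1, df2 = x$anova_groups$df2,
                   p_raw = x$anova_groups$p_raw,
                   p_corrected = x$anova_groups$p_corrected)
  )
  if (!is.null(x$vs_unity)) {
    rows <- c(rows, list(
      tibble::tibble(metric = x$metric,
                     scope = paste0("vs_unity:", x$vs_unity$network),
                     term = "mean-1", statistic = x$vs_unity$t,
                     df1 = x$vs_unity$df, df2 = NA_real_,
                     p_raw = x$vs_unity$p_raw,
                     p_corrected = x$vs_unity$p_corrected)))
  }
  dplyr::bind_rows(rows)
}
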