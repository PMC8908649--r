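# Seeded synthetic cohorts with the statistical structure the analysis
# assumes: two Fazekas-graded groups, modular inter-regional covariance
# with attenuated within-module coupling in the high-WMH group,
# band-limited series, and cognition scores coupled to a designated
# node's connectivity.

# published group medians / IQRs used as simulation anchors
.anchor <- list(
  wmh_median = c(A = 1.31, B = 7.84), wmh_iqr = c(A = 1.94, B = 7.08),
  age_median = c(A = 65, B = 69), age_iqr = c(A = 7, B = 13),
  female_prop = 0.69, moca_baseline = 24, mmse_baseline = 29)

#' Cohort simulation parameters
#'
#' Defaults describe the emulated study population: 64 low-severity
#' (Fazekas total 1-2) and 46 high-severity (3-6) subjects, 90 AAL
#' regions, TR = 2 s resting-state series of 230 analysis-ready volumes,
#' six equal covariance modules with within-module correlation 0.6 and
#' between-module correlation 0.1, within-module coupling attenuated by
#' 40% in the high-severity group, and MoCA scores positively coupled to
#' the designated node's connectivity strength.
#'
#' @param n_group_a,n_group_b group sizes.
#' @param n_regions number of network nodes (default 90).
#' @param n_timepoints analysis-ready series length T.
#' @param tr_seconds repetition time (s).
#' @param n_modules number of equal-size covariance modules.
#' @param within_module_r within-module correlation in (0, 1).
#' @param between_module_r between-module correlation in
#'   `[0, within_module_r)`.
#' @param group_b_attenuation factor in `[0, 1)` multiplying group B's
#'   within-module coupling (as `1 - attenuation`).
#' @param cognition_effect slope linking the designated node's coupling
#'   modifier to simulated MoCA points.
#' @param cognition_node node index whose connectivity carries the
#'   cognition signal (default 47, the left lingual gyrus in AAL-90).
#' @param noise_sd SD of the MoCA noise term (points).
#' @param band_limited filter the generated series to 0.01-0.08 Hz.
#' @param seed master seed; identical seeds give bit-identical cohorts.
#' @return List of class `cohort_params`.
#' @export
cohort_params <- function(n_group_a = 64L, n_group_b = 46L,
                          n_regions = 90L, n_timepoints = 230L,
                          tr_seconds = 2, n_modules = 6L,
                          within_module_r = 0.6, between_module_r = 0.1,
                          group_b_attenuation = 0.4,
                          cognition_effect = 1.5,
                          cognition_node = NULL, noise_sd = 2,
                          band_limited = TRUE, seed = 1L) {
  p <- list(n_group_a = as.integer(n_group_a),
            n_group_b = as.integer(n_group_b),
            n_regions = as.integer(n_regions),
            n_timepoints = as.integer(n_timepoints),
            tr_seconds = tr_seconds, n_modules = as.integer(n_modules),
            within_module_r = within_module_r,
            between_module_r = between_module_r,
            group_b_attenuation = group_b_attenuation,
            cognition_effect = cognition_effect,
            cognition_node = if (is.null(cognition_node))
              min(47L, as.integer(n_regions)) else as.integer(cognition_node),
            noise_sd = noise_sd, band_limited = isTRUE(band_limited),
            seed = as.integer(seed))
  with(p, {
    if (n_group_a < 0 || n_group_b < 0 || n_group_a + n_group_b < 1)
      stop_wmhnet("group sizes must be nonnegative, at least one subject")
    if (n_regions < n_modules || n_modules < 1)
      stop_wmhnet("need n_regions >= n_modules >= 1")
    if (!(within_module_r > 0 && within_module_r < 1))
      stop_wmhnet("within_module_r must lie in (0, 1)")
    if (!(between_module_r >= 0 && between_module_r < within_module_r))
      stop_wmhnet("need 0 <= between_module_r < within_module_r")
    if (!(group_b_attenuation >= 0 && group_b_attenuation < 1))
      stop_wmhnet("group_b_attenuation must lie in [0, 1)")
    if (within_module_r * (1 - group_b_attenuation) <= between_module_r)
      stop_wmhnet("attenuated within-module coupling (",
                  within_module_r * (1 - group_b_attenuation),
                  ") must still exceed between_module_r (",
                  between_module_r, ")")
    if (noise_sd <= 0) stop_wmhnet("noise_sd must be positive")
    if (p$cognition_node < 1 || p$cognition_node > n_regions)
      stop_wmhnet("cognition_node out of range")
  })
  structure(p, class = "cohort_params")
}

#' Fazekas total score and severity group
#'
#' Adds the periventricular and deep white-matter Fazekas grades; totals
#' of 1-2 define group A (low severity), 3-6 group B (high severity),
#' and 0 is returned as `"ungrouped"` (WMH-negative subjects are not
#' enrolled).
#'
#' @param pvh_grade,dwmh_grade integer grades in 0-3.
#' @return List with `fazekas_total` and `group` (`"A"`, `"B"` or
#'   `"ungrouped"`).
#' @export
#' @examples
#' fazekas_group(1, 1)  # total 2, group A
#' fazekas_group(3, 3)  # total 6, group B
fazekas_group <- function(pvh_grade, dwmh_grade) {
  for (g in c(pvh_grade, dwmh_grade))
    if (!is.numeric(g) || length(g) != 1 || g != round(g) || g < 0 || g > 3)
      stop_wmhnet("Fazekas grades must be integers in 0-3")
  total <- as.integer(pvh_grade + dwmh_grade)
  group <- if (total == 0L) "ungrouped" else if (total <= 2L) "A" else "B"
  list(fazekas_total = total, group = group)
}

# sample (pvh, dwmh) uniformly over the pairs admissible for a group
sample_grades <- function(group) {
  totals <- if (group == "A") 1:2 else 3:6
  pairs <- expand.grid(pvh = 0:3, dwmh = 0:3)
  pairs <- pairs[(pairs$pvh + pairs$dwmh) %in% totals, ]
  pairs[sample.int(nrow(pairs), 1L), ]
}

# module assignment: contiguous, sizes as equal as possible
module_assignment <- function(n_regions, n_modules) {
  sizes <- rep(n_regions %/% n_modules, n_modules)
  extra <- n_regions %% n_modules
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(n_modules), times = sizes)
}

# block-constant correlation matrix, with the designated node's
# within-module correlations scaled by `node_scale`
build_covariance <- function(params, within_r, node_scale = 1) {
  mod <- module_assignment(params$n_regions, params$n_modules)
  same <- outer(mod, mod, "==")
  sigma <- matrix(params$between_module_r, params$n_regions,
                  params$n_regions)
  sigma[same] <- within_r
  j <- params$cognition_node
  in_mod <- same[j, ]
  sigma[j, in_mod] <- within_r * node_scale
  sigma[in_mod, j] <- within_r * node_scale
  diag(sigma) <- 1
  sigma
}

chol_or_fail <- function(sigma, params, what) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch))
    stop_wmhnet(sprintf(
      paste0("implied covariance for %s is not positive definite ",
             "(within_module_r = %g, between_module_r = %g, ",
             "group_b_attenuation = %g)"),
      what, params$within_module_r, params$between_module_r,
      params$group_b_attenuation))
  ch
}

#' Generate a synthetic cohort
#'
#' Draws, for each subject, a zero-mean Gaussian ROI time series with the
#' block (module) covariance implied by the parameters -- group B's
#' within-module coupling scaled by `1 - group_b_attenuation` -- band-pass
#' filtered to the resting-state band; Fazekas grades sampled uniformly
#' within each group's admissible totals; lognormal WMH volumes anchored
#' to published group medians; and MoCA coupled to a per-subject
#' coupling modifier of the designated node
#' (`moca = baseline + cognition_effect * u + noise`, clamped to 0-30).
#'
#' @param params a [cohort_params()].
#' @return A `cohort`: list with `subjects` (data frame), `timeseries`
#'   (list of T x N matrices), `node_labels`, `params`.
#' @export
generate_cohort <- function(params = cohort_params()) {
  if (!inherits(params, "cohort_params"))
    stop_wmhnet("expected cohort_params")
  # validate base covariances up front so errors name the parameters
  for (gw in list(c("group A", params$within_module_r),
                  c("group B", params$within_module_r *
                      (1 - params$group_b_attenuation))))
    chol_or_fail(build_covariance(params, as.numeric(gw[2])), params, gw[1])

  n_tot <- params$n_group_a + params$n_group_b
  groups <- rep(c("A", "B"), c(params$n_group_a, params$n_group_b))
  seeds <- derive_seeds(params$seed, n_tot + 1L)
  labels <- if (params$n_regions == 90) aal90_labels() else
    paste0("node_", seq_len(params$n_regions))

  subjects <- vector("list", n_tot)
  series <- vector("list", n_tot)
  for (s in seq_len(n_tot)) {
    g <- groups[s]
    drawn <- with_seed(seeds[s], {
      gr <- sample_grades(g)
      fz <- fazekas_group(gr$pvh, gr$dwmh)
      med <- .anchor$wmh_median[[g]]
      # lognormal sdlog matched to the published median and IQR
      sdlog <- asinh(.anchor$wmh_iqr[[g]] / med / 2) / qnorm(0.75)
      wmh <- rlnorm(1, meanlog = log(med), sdlog = sdlog)
      age <- max(55, round(rnorm(1, .anchor$age_median[[g]],
                                 .anchor$age_iqr[[g]] / 1.349)))
      sex <- if (rbinom(1, 1, .anchor$female_prop) == 1) "F" else "M"
      edu <- max(0, round(rnorm(1, 9, 3)))
      # per-subject coupling modifier of the designated node; carries
      # the cognition signal and scales that node's within-module r
      u <- max(-2, min(2, rnorm(1)))
      within_r <- params$within_module_r *
        (if (g == "B") 1 - params$group_b_attenuation else 1)
      node_scale <- 1 + 0.15 * u
      sigma <- build_covariance(params, within_r, node_scale)
      ch <- chol_or_fail(sigma, params, sprintf("subject %d", s))
      x <- matrix(rnorm(params$n_timepoints * params$n_regions),
                  params$n_timepoints) %*% ch
      ts <- roi_timeseries(x, params$tr_seconds, labels)
      if (params$band_limited) ts <- bandpass(ts)
      moca <- round(.anchor$moca_baseline + params$cognition_effect * u +
                      rnorm(1, 0, params$noise_sd))
      mmse <- round(.anchor$mmse_baseline + rnorm(1, 0, 1))
      rec <- data.frame(subject_id = sprintf("sub-%03d", s),
                        pvh = gr$pvh, dwmh = gr$dwmh,
                        fazekas_total = fz$fazekas_total, group = fz$group,
                        wmh_volume_ml = wmh, age = age, sex = sex,
                        education_years = edu,
                        moca = max(0L, min(30L, as.integer(moca))),
                        mmse = max(0L, min(30L, as.integer(mmse))))
      list(rec = rec, ts = ts$data)
    })
    subjects[[s]] <- drawn$rec
    series[[s]] <- drawn$ts
  }
  subjects <- do.call(rbind, subjects)
  names(series) <- subjects$subject_id
  structure(list(subjects = subjects, timeseries = series,
                 node_labels = labels, params = params),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (A: %d, B: %d), %d regions, T = %d\n",
              nrow(x$subjects), sum(x$subjects$group == "A"),
              sum(x$subjects$group == "B"), length(x$node_labels),
              nrow(x$timeseries[[1]])))
  invisible(x)
}
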