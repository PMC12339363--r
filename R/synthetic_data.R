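#' Specification of a synthetic fiber bundle
#'
#' Describes abstract test anatomy: `n_streamlines` smooth perturbations of a
#' common centerline, dispersed laterally with Gaussian SD `lateral_sd` and
#' resampled at `step` mm spacing. The perturbation is a stationary
#' piecewise-linear Gaussian field: offsets are drawn independently at the
#' centerline control points, interpolated linearly along arc length, and
#' variance-normalized so every point's marginal offset SD equals
#' `lateral_sd` exactly.
#'
#' @param name bundle identifier.
#' @param centerline m x 3 matrix of world-mm control points, m >= 2.
#' @param n_streamlines number of streamlines (>= 1).
#' @param lateral_sd Gaussian dispersion around the centerline, mm (>= 0).
#' @param step point spacing along each streamline, mm (> 0).
#' @param seed integer RNG seed.
#' @return An object of class `bundle_spec`.
#' @export
bundle_spec <- function(name, centerline, n_streamlines = 100L,
                        lateral_sd = 2, step = 1, seed = 1L) {
  centerline <- as.matrix(centerline)
  assert_that(is.character(name) && length(name) == 1L, "parameter_error",
              "name must be a single string")
  assert_that(nrow(centerline) >= 2L && ncol(centerline) == 3L &&
              all(is.finite(centerline)), "parameter_error",
              "centerline needs >= 2 finite 3D control points")
  assert_that(is_number(n_streamlines) && n_streamlines >= 1, "parameter_error",
              "n_streamlines must be >= 1")
  assert_that(is_number(lateral_sd) && lateral_sd >= 0, "parameter_error",
              "lateral_sd must be >= 0")
  assert_that(is_number(step) && step > 0, "parameter_error", "step must be > 0")
  structure(list(name = name, centerline = centerline,
                 n_streamlines = as.integer(n_streamlines),
                 lateral_sd = lateral_sd, step = step, seed = as.integer(seed)),
            class = "bundle_spec")
}

#' Generate a synthetic fiber bundle
#'
#' Deterministic given the spec's seed. With `lateral_sd = 0` every
#' streamline equals the resampled centerline.
#'
#' @param spec a [bundle_spec()].
#' @return A [tractogram()] with `spec$n_streamlines` streamlines.
#' @export
generate_bundle <- function(spec) {
  assert_that(inherits(spec, "bundle_spec"), "parameter_error",
              "spec must be a bundle_spec")
  set.seed(spec$seed)
  base <- resample_polyline(spec$centerline, spec$step)
  # arc-length position of each resampled point, mapped onto the control
  # point parameterization for offset interpolation
  seg <- sqrt(rowSums((spec$centerline[-1L, , drop = FALSE] -
                       spec$centerline[-nrow(spec$centerline), , drop = FALSE])^2))
  knots <- c(0, cumsum(seg))
  segb <- sqrt(rowSums((base[-1L, , drop = FALSE] -
                        base[-nrow(base), , drop = FALSE])^2))
  s <- c(0, cumsum(segb))
  streamlines <- lapply(seq_len(spec$n_streamlines), function(i) {
    if (spec$lateral_sd == 0) return(base)
    g <- matrix(stats::rnorm(length(knots) * 3L, sd = spec$lateral_sd),
                ncol = 3L)
    off <- interp_offsets(knots, g, s)
    base + off
  })
  tractogram(streamlines)
}

# Linear interpolation of per-knot offsets with per-point variance
# normalization: between knots i and i+1 at fraction w, the raw offset
# (1-w) g_i + w g_{i+1} has SD proportional to sqrt((1-w)^2 + w^2); dividing
# by that factor keeps the marginal SD constant along the streamline.
interp_offsets <- function(knots, g, s) {
  s <- pmin(pmax(s, knots[1L]), knots[length(knots)])
  idx <- findInterval(s, knots, rightmost.closed = TRUE)
  idx <- pmin(idx, length(knots) - 1L)
  w <- (s - knots[idx]) / (knots[idx + 1L] - knots[idx])
  norm <- sqrt((1 - w)^2 + w^2)
  out <- ((1 - w) * g[idx, , drop = FALSE] + w * g[idx + 1L, , drop = FALSE]) / norm
  out
}

#' Specification of a synthetic patient cohort
#'
#' Emulates a bilateral DBS cohort: each patient receives one effective
#' contact per hemisphere, placed at the hemisphere's target with Gaussian
#' jitter, stimulated with a truncated-Gaussian current. Baseline Y-BOCS
#' scores are truncated Gaussians on [8, 40]; marginal improvements are
#' drawn from a Gaussian truncated to at most 1 (improvement is the relative
#' Y-BOCS reduction (baseline - followup)/baseline, so 1 means symptom-free).
#' Follow-up scores are rounded to integers (clinician scale) and the
#' improvement recomputed from the rounded scores.
#'
#' @param name cohort identifier.
#' @param n_patients number of patients (>= 2).
#' @param target_left,target_right world-mm hemisphere targets.
#' @param placement_sd contact placement jitter SD, mm (>= 0).
#' @param current_mean,current_sd stimulation current distribution, mA
#'   (truncated to > 0).
#' @param baseline_mean,baseline_sd baseline Y-BOCS distribution (truncated
#'   to [8, 40]).
#' @param improvement_mean,improvement_sd marginal improvement distribution
#'   (truncated to <= 1), used by [generate_cohort()] when outcomes are not
#'   simulated from a density.
#' @param effect_slope improvement per unit activation, used by
#'   [simulate_outcomes()].
#' @param noise_sd improvement noise SD for [simulate_outcomes()], or `NULL`
#'   for the pipeline's automatic calibration.
#' @param seed integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(name, n_patients = 12L,
                        target_left = c(-10, 0, 0), target_right = c(10, 0, 0),
                        placement_sd = 1, current_mean = 3, current_sd = 0.5,
                        baseline_mean = 34.3, baseline_sd = 4.4,
                        improvement_mean = 0.44, improvement_sd = 0.25,
                        effect_slope = 1, noise_sd = NULL, seed = 1L) {
  assert_that(is.character(name) && length(name) == 1L, "parameter_error",
              "name must be a single string")
  assert_that(is_number(n_patients) && n_patients >= 2, "parameter_error",
              "n_patients must be >= 2")
  assert_that(is_point3(target_left) && is_point3(target_right),
              "parameter_error", "targets must be finite 3D points")
  assert_that(is_number(placement_sd) && placement_sd >= 0, "parameter_error",
              "placement_sd must be >= 0")
  assert_that(is_number(current_mean) && current_mean > 0 &&
              is_number(current_sd) && current_sd >= 0, "parameter_error",
              "current distribution must have positive mean and sd >= 0")
  assert_that(is_number(baseline_mean) && is_number(baseline_sd) &&
              baseline_sd >= 0, "parameter_error", "invalid baseline distribution")
  structure(list(name = name, n_patients = as.integer(n_patients),
                 target_left = target_left, target_right = target_right,
                 placement_sd = placement_sd,
                 current_mean = current_mean, current_sd = current_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 improvement_mean = improvement_mean,
                 improvement_sd = improvement_sd,
                 effect_slope = effect_slope, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Rejection sampling from N(mean, sd) truncated to [lo, hi].
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  out <- numeric(0L)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic cohort: contact and outcome tables
#'
#' Deterministic given the spec's seed. The outcome table carries marginal
#' improvements drawn from the spec's improvement distribution; to generate
#' outcomes that are instead linear in a bundle's activation score, pass the
#' contact table on to [simulate_outcomes()].
#'
#' @param spec a [cohort_spec()].
#' @return list with `contacts` (one row per patient-hemisphere:
#'   `patient_id`, `hemisphere`, `x_mm`, `y_mm`, `z_mm`, `current_mA`) and
#'   `outcomes` (`patient_id`, `ybocs_baseline`, `ybocs_followup`,
#'   `improvement`).
#' @export
generate_cohort <- function(spec) {
  assert_that(inherits(spec, "cohort_spec"), "parameter_error",
              "spec must be a cohort_spec")
  set.seed(spec$seed)
  n <- spec$n_patients
  ids <- sprintf("%s-%02d", spec$name, seq_len(n))
  targets <- list(L = spec$target_left, R = spec$target_right)
  contacts <- do.call(rbind, lapply(c("L", "R"), function(h) {
    jit <- matrix(stats::rnorm(3L * n, sd = spec$placement_sd), ncol = 3L)
    ctr <- sweep(jit, 2L, targets[[h]], `+`)
    data.frame(patient_id = ids, hemisphere = h,
               x_mm = ctr[, 1L], y_mm = ctr[, 2L], z_mm = ctr[, 3L],
               current_mA = rtrunc_norm(n, spec$current_mean, spec$current_sd,
                                        lo = .Machine$double.eps),
               stringsAsFactors = FALSE)
  }))
  contacts <- contacts[order(contacts$patient_id, contacts$hemisphere), ]
  rownames(contacts) <- NULL
  baseline <- round(rtrunc_norm(n, spec$baseline_mean, spec$baseline_sd, 8, 40))
  improvement <- rtrunc_norm(n, spec$improvement_mean, spec$improvement_sd,
                             hi = 1)
  outcomes <- finalize_outcomes(ids, baseline, improvement)
  list(contacts = contacts, outcomes = outcomes)
}

# Round follow-up to the clinician integer scale, clamp to [0, 40], and
# recompute improvement from the rounded scores.
finalize_outcomes <- function(ids, baseline, improvement) {
  followup <- round(baseline * (1 - improvement))
  followup <- pmin(pmax(followup, 0), 40)
  data.frame(patient_id = ids, ybocs_baseline = baseline,
             ybocs_followup = followup,
             improvement = (baseline - followup) / baseline,
             stringsAsFactors = FALSE)
}

#' Simulate outcomes linear in a bundle's activation score
#'
#' Per patient, the (pre-rounding) improvement is
#' `intercept + effect_slope * mean bilateral activation + N(0, noise_sd)`,
#' where activation is the mean density inside each hemisphere's VAT (see
#' [bundle_activation()]). Follow-up scores are rounded to integers and the
#' reported improvement recomputed, as in [generate_cohort()].
#'
#' @param contacts contact table as produced by [generate_cohort()].
#' @param density a [density_volume()] of the effect-carrying bundle; must
#'   cover all activation spheres.
#' @param effect_slope improvement per unit activation.
#' @param noise_sd Gaussian noise SD on the improvement scale.
#' @param seed integer RNG seed.
#' @param intercept improvement at zero activation (default 0).
#' @param baseline optional vector of baseline Y-BOCS scores per patient
#'   (sorted patient order); drawn from the default baseline distribution
#'   when omitted.
#' @param params a [vat_params()].
#' @param round_scores if `TRUE`, round follow-up scores to the clinician
#'   integer scale and recompute improvement (as [generate_cohort()] does);
#'   default `FALSE` keeps the simulated improvement exact, so a noiseless
#'   simulation is exactly linear in activation.
#' @return outcome table as in [generate_cohort()].
#' @export
simulate_outcomes <- function(contacts, density, effect_slope, noise_sd,
                              seed = 1L, intercept = 0, baseline = NULL,
                              params = vat_params(), round_scores = FALSE) {
  assert_that(is_number(noise_sd) && noise_sd >= 0, "parameter_error",
              "noise_sd must be >= 0")
  sites <- build_sites(contacts, params)
  act <- vapply(seq_len(nrow(sites)), function(i) {
    bundle_activation(density,
                      list(center = unlist(sites[i, c("x_mm", "y_mm", "z_mm")]),
                           radius = sites$radius_mm[i]))
  }, numeric(1))
  set.seed(seed)
  ids <- sort(unique(contacts$patient_id))
  act_pat <- vapply(ids, function(p) mean(act[sites$patient_id == p]), numeric(1))
  improvement <- intercept + effect_slope * act_pat +
    stats::rnorm(length(ids), sd = noise_sd)
  improvement <- pmin(improvement, 1)
  if (is.null(baseline))
    baseline <- round(rtrunc_norm(length(ids), 34.3, 4.4, 8, 40))
  if (round_scores) return(finalize_outcomes(ids, baseline, improvement))
  data.frame(patient_id = ids, ybocs_baseline = baseline,
             ybocs_followup = baseline * (1 - improvement),
             improvement = improvement, stringsAsFactors = FALSE)
}
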