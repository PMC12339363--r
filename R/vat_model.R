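#' Volume-of-activated-tissue (VAT) model parameters
#'
#' The VAT around an electrode contact is modelled as an exact sphere derived
#' from a Coulomb-law point-source field in a homogeneous medium: the field
#' exceeds the activation threshold `e_threshold` out to a radius that grows
#' with the square root of the injected current. Defaults are the standard
#' values for grey/white matter stimulation modelling: conductivity
#' sigma = 0.1 S/m and activation threshold E = 0.2 V/mm.
#'
#' @param sigma tissue conductivity in S/m (> 0).
#' @param e_threshold activation threshold in V/mm (> 0).
#' @return An object of class `vat_params`.
#' @export
vat_params <- function(sigma = 0.1, e_threshold = 0.2) {
  assert_that(is_number(sigma) && sigma > 0, "parameter_error", "sigma must be > 0")
  assert_that(is_number(e_threshold) && e_threshold > 0, "parameter_error",
              "e_threshold must be > 0")
  structure(list(sigma = sigma, e_threshold = e_threshold), class = "vat_params")
}

#' Activation radius of a stimulation current
#'
#' Evaluates r = sqrt(I / (4 * pi * sigma * E)) with the current converted
#' from mA to A and the threshold from V/mm to V/m; the result is returned
#' in mm. All unit conversions happen here and nowhere else. The radius is
#' strictly increasing and continuous in the current, with the scaling law
#' r(4 I) = 2 r(I).
#'
#' @param current stimulation current in mA (vectorized, each >= 0).
#' @param params a [vat_params()].
#' @return activation radius in mm (same length as `current`).
#' @examples
#' activation_radius(1, vat_params())   # ~1.9947 mm at the default constants
#' @export
activation_radius <- function(current, params = vat_params()) {
  assert_that(is.numeric(current) && all(is.finite(current)), "parameter_error",
              "current must be finite")
  assert_that(all(current >= 0), "parameter_error", "current must be >= 0 mA")
  I_si <- current * 1e-3                     # mA -> A
  E_si <- params$e_threshold * 1e3           # V/mm -> V/m
  1e3 * sqrt(I_si / (4 * pi * params$sigma * E_si))   # m -> mm
}

#' Effective center of the active contacts
#'
#' When several contacts on one lead are active, the stimulation site is
#' taken as their geometric center (arithmetic mean of the contact
#' coordinates).
#'
#' @param contacts n x 3 matrix (or length-3 vector) of world-mm contact
#'   coordinates, n >= 1.
#' @return length-3 world-mm coordinate.
#' @export
effective_center <- function(contacts) {
  contacts <- rbind(contacts)
  assert_that(nrow(contacts) >= 1L && ncol(contacts) == 3L &&
              all(is.finite(contacts)), "parameter_error",
              "contacts must be a non-empty n x 3 matrix of finite coordinates")
  colMeans(contacts)
}

#' Build stimulation sites from an electrode-contact table
#'
#' Aggregates a contact table (one row per active contact) into one
#' stimulation site per patient and hemisphere: the effective center of that
#' hemisphere's active contacts plus the current-derived activation radius.
#' Every patient must have contacts in both hemispheres (bilateral
#' stimulation).
#'
#' @param contacts data frame with columns `patient_id`, `hemisphere`
#'   (`"L"`/`"R"`), `x_mm`, `y_mm`, `z_mm`, `current_mA`.
#' @param params a [vat_params()].
#' @return data frame of sites: `patient_id`, `hemisphere`, `x_mm`, `y_mm`,
#'   `z_mm`, `current_mA`, `radius_mm`, sorted by patient then hemisphere.
#' @export
build_sites <- function(contacts, params = vat_params()) {
  need <- c("patient_id", "hemisphere", "x_mm", "y_mm", "z_mm", "current_mA")
  missing_cols <- setdiff(need, names(contacts))
  assert_that(length(missing_cols) == 0L, "validation_error",
              "contact table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  assert_that(all(contacts$hemisphere %in% c("L", "R")), "validation_error",
              "hemisphere must be 'L' or 'R'")
  assert_that(all(contacts$current_mA > 0), "parameter_error",
              "currents must be > 0 mA")
  hemi_count <- table(unique(contacts[, c("patient_id", "hemisphere")])$patient_id)
  incomplete <- names(hemi_count)[hemi_count < 2L]
  assert_that(length(incomplete) == 0L, "validation_error",
              "missing hemisphere for patient(s): %s",
              paste(incomplete, collapse = ", "))
  key <- interaction(contacts$patient_id, contacts$hemisphere, drop = TRUE)
  rows <- lapply(split(contacts, key), function(g) {
    ctr <- effective_center(as.matrix(g[, c("x_mm", "y_mm", "z_mm")]))
    cur <- mean(g$current_mA)
    data.frame(patient_id = g$patient_id[1L], hemisphere = g$hemisphere[1L],
               x_mm = ctr[1L], y_mm = ctr[2L], z_mm = ctr[3L],
               current_mA = cur, radius_mm = activation_radius(cur, params),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id, out$hemisphere), , drop = FALSE]
  rownames(out) <- NULL
  out
}

site_centers <- function(sites) as.matrix(sites[, c("x_mm", "y_mm", "z_mm")])
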