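#' DBS lead geometry
#'
#' A linear four-contact lead. `tip_position` is the center of the deepest
#' contact (contact 0); contacts 1..3 lie at `spacing` mm intervals back
#' along the implant direction (i.e. shallower). The default geometry
#' (2.0 mm center-to-center spacing, 0.635 mm contact radius) is a
#' conventional cylindrical DBS lead.
#'
#' @param tip_position World mm position of the deepest contact center.
#' @param direction Unit implant direction (entry toward tip); default
#'   straight down (0, 0, -1).
#' @param n_contacts Number of contacts.
#' @param spacing Center-to-center contact spacing, mm.
#' @param contact_radius Contact radius, mm (caps the field singularity).
#' @param label Free-text lead label, e.g. "VIM" or "VOp".
#' @return A `lead_model`.
#' @export
lead_model <- function(tip_position, direction = c(0, 0, -1), n_contacts = 4L,
                       spacing = 2.0, contact_radius = 0.635, label = "") {
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-9) {
    if (nrm < 1e-12) stop("`direction` must be nonzero", call. = FALSE)
    direction <- direction / nrm
  }
  tip_position <- as.numeric(tip_position)
  centers <- t(vapply(seq_len(n_contacts) - 1L,
                      function(k) tip_position - k * spacing * direction,
                      numeric(3)))
  structure(list(tip_position = tip_position, direction = direction,
                 contact_centers = centers, spacing = spacing,
                 contact_radius = contact_radius, label = label),
            class = "lead_model")
}

#' Stimulation setting
#'
#' Active contacts and their signed currents. Negative current = cathode.
#' Monopolar settings (`case_return = TRUE`) return current at infinity
#' (the implanted pulse generator case); bipolar settings must have signed
#' currents summing to zero. In voltage mode, amplitudes are volts and are
#' converted to current through a fixed impedance before field evaluation.
#' Pulse width and frequency are recorded as metadata only: the field model
#' is amplitude-driven.
#'
#' @param active Data frame (or list coercible to one) with columns
#'   `contact` (0-based index) and `amplitude` (mA in current mode, V in
#'   voltage mode; signed, negative = cathode).
#' @param mode "current" or "voltage".
#' @param case_return TRUE for monopolar stimulation.
#' @param pulse_width_us,frequency_hz Metadata, ignored by the field model.
#' @return A `stim_setting`.
#' @export
stim_setting <- function(active, mode = c("current", "voltage"),
                         case_return = TRUE, pulse_width_us = 60,
                         frequency_hz = 130) {
  mode <- match.arg(mode)
  active <- as.data.frame(active)
  stopifnot(all(c("contact", "amplitude") %in% names(active)))
  if (!case_return && nrow(active) > 0 &&
      abs(sum(active$amplitude)) > 1e-9)
    stop("configuration error: bipolar signed currents must sum to 0",
         call. = FALSE)
  structure(list(active = active, mode = mode, case_return = case_return,
                 pulse_width_us = pulse_width_us, frequency_hz = frequency_hz),
            class = "stim_setting")
}

#' Tissue conductivity and VTA threshold parameters
#'
#' @param sigma_s_per_m Isotropic conductivity, S/m (default 0.14).
#' @param efield_threshold_v_per_mm Activation threshold on the electric
#'   field magnitude, V/mm (default 0.2).
#' @param impedance_ohm Impedance used only for voltage-to-current
#'   conversion (default 1000 Ohm).
#' @return A `conductivity_params`.
#' @export
conductivity_params <- function(sigma_s_per_m = 0.14,
                                efield_threshold_v_per_mm = 0.2,
                                impedance_ohm = 1000) {
  stopifnot(sigma_s_per_m > 0, efield_threshold_v_per_mm > 0,
            impedance_ohm > 0)
  structure(list(sigma_s_per_m = sigma_s_per_m,
                 efield_threshold_v_per_mm = efield_threshold_v_per_mm,
                 impedance_ohm = impedance_ohm),
            class = "conductivity_params")
}

stim_currents_amps <- function(stim, cond) {
  amp <- stim$active$amplitude
  if (stim$mode == "voltage") amp <- amp / cond$impedance_ohm # V / Ohm = A
  else amp <- amp * 1e-3                                      # mA -> A
  amp
}

#' Electric-field vectors of a lead at arbitrary points
#'
#' Point-source superposition in an infinite homogeneous isotropic medium:
#' each active contact contributes I_c (v - p_c) / (4 pi sigma |v - p_c|^3).
#' Distances closer than the contact radius are clamped to the contact
#' surface, capping the singularity at the surface value.
#'
#' @param lead A `lead_model`.
#' @param stim A `stim_setting`.
#' @param cond A `conductivity_params`.
#' @param points n x 3 matrix of world mm points.
#' @return n x 3 matrix of field vectors in V/mm.
#' @export
efield_vectors <- function(lead, stim, cond, points) {
  points <- rbind_coords(points)
  out <- matrix(0, nrow(points), 3)
  if (nrow(stim$active) == 0) return(out)
  amps <- stim_currents_amps(stim, cond)
  r0 <- lead$contact_radius * 1e-3 # m
  for (k in seq_len(nrow(stim$active))) {
    I <- amps[k]
    if (I == 0) next
    p <- lead$contact_centers[stim$active$contact[k] + 1L, ]
    d <- sweep(points, 2, p) * 1e-3 # mm -> m
    r <- sqrt(rowSums(d^2))
    # at the contact center the direction is arbitrary but the capped
    # magnitude is continuous: place the point on the contact surface
    at0 <- r == 0
    if (any(at0)) { d[at0, 1] <- r0; r[at0] <- r0 }
    r_eff <- pmax(r, r0)
    scale <- I / (4 * pi * cond$sigma_s_per_m * r_eff^2 * r)
    out <- out + d * scale
  }
  out * 1e-3 # V/m -> V/mm
}

#' Electric-field magnitude image
#'
#' Evaluates [efield_vectors()] at every voxel center of `grid` and takes
#' the magnitude. The field is linear in the currents: scaling all
#' amplitudes by k scales the magnitude by |k|.
#'
#' @inheritParams efield_vectors
#' @param grid Template `image_volume` defining the output grid.
#' @return An `image_volume` of field magnitude, V/mm.
#' @export
efield_magnitude <- function(lead, stim, cond, grid) {
  if (nrow(stim$active) == 0)
    stop("configuration error: at least one active contact required",
         call. = FALSE)
  vec <- efield_vectors(lead, stim, cond, grid_coordinates(grid))
  mag <- sqrt(rowSums(vec^2))
  out <- empty_like(grid)
  out$data <- array(mag, dim(grid$data))
  out
}

#' Threshold an electric-field image to a binary VTA
#'
#' A voxel belongs to the volume of tissue activated iff the field magnitude
#' at its center is at least the activation threshold. Monotone: raising the
#' threshold never grows the VTA.
#'
#' @param efield `image_volume` of field magnitude (V/mm).
#' @param cond A `conductivity_params` (supplies the threshold).
#' @return Binary `image_volume`.
#' @export
threshold_vta <- function(efield, cond) {
  out <- efield
  out$data <- array(as.numeric(efield$data >= cond$efield_threshold_v_per_mm),
                    dim(efield$data))
  out
}

#' Union of the VIM-lead and VOp-lead VTAs
#'
#' The aggregate volume treats the two unilateral leads as a single
#' stimulation volume (voxelwise union).
#'
#' @param vta_vim,vta_vop Binary `image_volume`s on the same grid.
#' @return Binary `image_volume`.
#' @export
aggregate_vta <- function(vta_vim, vta_vop) {
  if (!same_grid(vta_vim, vta_vop))
    stop("VTAs must share grid and affine", call. = FALSE)
  out <- vta_vim
  out$data <- array(as.numeric(vta_vim$data != 0 | vta_vop$data != 0),
                    dim(vta_vim$data))
  out
}

#' Closed-form activation radius of a monopolar point source
#'
#' Inverts E = I / (4 pi sigma r^2) at the activation threshold:
#' r* = sqrt(I / (4 pi sigma E)). With 1 mA, 0.14 S/m and 0.2 V/mm this is
#' about 1.69 mm.
#'
#' @param current_ma Absolute current, mA.
#' @param cond A `conductivity_params`.
#' @return Radius in mm.
#' @export
monopolar_vta_radius <- function(current_ma, cond) {
  I <- abs(current_ma) * 1e-3
  E <- cond$efield_threshold_v_per_mm * 1e3 # V/mm -> V/m
  sqrt(I / (4 * pi * cond$sigma_s_per_m * E)) * 1e3 # m -> mm
}
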