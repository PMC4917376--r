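# Parametric model of the photon beam at the chamber plane: geometric
# projection, off-center ratios (OCR), output factors (OF) and deliberate
# detuning of the profile shoulder.

# Field sizes are specified at this source-to-axis distance (mm); the chamber
# sits closer to the source, so nominal diameters are scaled before use.
NOMINAL_SAD_MM <- 800

# Scale factor for the sigmoid field edge, chosen so that the penumbra
# parameter p equals the 80%-20% penumbra width of the profile.
PENUMBRA_K <- sqrt(2) * stats::qnorm(0.8)

#' Clinical aperture diameters
#'
#' The variable-aperture collimator is clinically restricted to 12 field
#' sizes, specified as diameters at the nominal source-to-axis distance of
#' 800 mm.
#'
#' @return Numeric vector of the 12 clinical diameters in mm.
#' @export
clinical_diameters <- function() {
  c(5, 7.5, 10, 12.5, 15, 20, 25, 30, 35, 40, 50, 60)
}

#' Collimator aperture
#'
#' @param diameter_mm Nominal aperture diameter in mm at SAD 800 mm.
#'   Arbitrary positive diameters are allowed (e.g. perturbed apertures
#'   `d +/- 0.2`); set `clinical = TRUE` to restrict to the clinical set.
#' @param kind `"iris"` for the variable aperture, `"fixed"` for a fixed cone.
#' @param clinical If `TRUE`, the diameter must belong to
#'   [clinical_diameters()].
#'
#' @return An object of class `aperture_spec`.
#' @export
aperture_spec <- function(diameter_mm, kind = c("iris", "fixed"),
                          clinical = FALSE) {
  kind <- match.arg(kind)
  if (!is.numeric(diameter_mm) || length(diameter_mm) != 1L ||
      !is.finite(diameter_mm) || diameter_mm <= 0) {
    stop("`diameter_mm` must be a single positive number", call. = FALSE)
  }
  if (clinical && !any(abs(clinical_diameters() - diameter_mm) < 1e-9)) {
    stop(sprintf("diameter %.3g mm is not in the clinical aperture set",
                 diameter_mm), call. = FALSE)
  }
  structure(list(diameter_mm = diameter_mm, kind = kind),
            class = "aperture_spec")
}

as_diameter <- function(aperture) {
  if (inherits(aperture, "aperture_spec")) return(aperture$diameter_mm)
  if (is.numeric(aperture) && length(aperture) == 1L && is.finite(aperture) &&
      aperture > 0) {
    return(as.numeric(aperture))
  }
  stop("`aperture` must be an aperture_spec or a single positive diameter in mm",
       call. = FALSE)
}

#' Large-area chamber geometry
#'
#' Defaults describe a Bragg-peak-type parallel-plate chamber with an active
#' area of diameter 81.6 mm, mounted with its plane at SAD 791 mm.
#'
#' @param active_diameter_mm Diameter of the sensitive area in mm.
#' @param plane_sad_mm Source-to-chamber distance in mm.
#' @param window_mm Entrance window thickness in mm (metadata only).
#'
#' @return An object of class `chamber_spec` with element `r_max_mm`, the
#'   radius of the sensitive area.
#' @export
chamber_spec <- function(active_diameter_mm = 81.6, plane_sad_mm = 791,
                         window_mm = 3.47) {
  if (active_diameter_mm <= 0 || plane_sad_mm <= 0) {
    stop("chamber dimensions must be positive", call. = FALSE)
  }
  structure(list(r_max_mm = active_diameter_mm / 2,
                 active_diameter_mm = active_diameter_mm,
                 plane_sad_mm = plane_sad_mm,
                 window_mm = window_mm),
            class = "chamber_spec")
}

#' Project a nominal diameter onto the chamber plane
#'
#' Field sizes are specified at SAD 800 mm; the chamber plane is nearer the
#' source, so the field diameter there is scaled by `plane_sad / 800`.
#'
#' @param aperture An [aperture_spec()] or a diameter in mm.
#' @param chamber A [chamber_spec()].
#'
#' @return Projected diameter in mm at the chamber plane.
#' @export
project_diameter <- function(aperture, chamber = chamber_spec()) {
  d <- as_diameter(aperture)
  if (chamber$plane_sad_mm <= 0) stop("plane SAD must be positive", call. = FALSE)
  d * chamber$plane_sad_mm / NOMINAL_SAD_MM
}

#' Radially symmetric beam-profile model
#'
#' The off-center ratio is modelled as a flat (optionally slightly horned)
#' core with an error-function-shaped penumbra centred on the projected field
#' edge,
#' \deqn{OCR(r) = (1 + f\,(\min(r,R)/R)^2)\; \tfrac12\,
#'   \mathrm{erfc}\!\left(k\,(r-R)/p\right) \; s(r),}
#' where \eqn{R} is the projected field radius, \eqn{p} the 80%-20% penumbra
#' width, \eqn{f} a flatness parameter and \eqn{s(r)} a shoulder-depression
#' factor controlled by the detuning level. `penumbra_mm = 0` selects an
#' ideal step profile (1 inside the field, 1/2 on the edge, 0 outside).
#'
#' @param penumbra_mm 80%-20% penumbra width at the chamber plane, in mm.
#' @param flatness Dimensionless horn amplitude of the core (0 = flat).
#' @param detune_level Dimensionless detuning level; level 1 depresses the
#'   profile shoulder by approximately 4% (see [detune()]).
#'
#' @return An object of class `beam_profile`.
#' @export
beam_profile <- function(penumbra_mm = 3, flatness = 0, detune_level = 0) {
  if (penumbra_mm < 0) stop("`penumbra_mm` must be >= 0", call. = FALSE)
  if (flatness < 0) stop("`flatness` must be >= 0", call. = FALSE)
  if (detune_level < 0) stop("`detune_level` must be >= 0", call. = FALSE)
  structure(list(penumbra_mm = penumbra_mm, flatness = flatness,
                 detune_level = detune_level),
            class = "beam_profile")
}

# Smoothstep ramp: 0 below a, 1 above b, C1 in between.
smoothstep <- function(x, a, b) {
  t <- pmin(pmax((x - a) / (b - a), 0), 1)
  t * t * (3 - 2 * t)
}

# Shoulder weight: 1 on [0.5 R, 0.9 R], smooth shoulders over 0.05 R on
# either side, 0 elsewhere. Detuning multiplies the OCR by (1 - 0.04 level w).
shoulder_weight <- function(r, R) {
  x <- r / R
  smoothstep(x, 0.45, 0.5) * (1 - smoothstep(x, 0.9, 0.95))
}

#' Off-center ratio of the beam profile
#'
#' @param model A [beam_profile()].
#' @param aperture An [aperture_spec()] or a diameter in mm.
#' @param r Radial distance(s) from the beam axis at the chamber plane, mm.
#' @param chamber A [chamber_spec()]; sets the projection of the nominal
#'   diameter onto the chamber plane.
#'
#' @return OCR value(s), normalized to 1 on the central axis.
#' @export
ocr <- function(model, aperture, r, chamber = chamber_spec()) {
  stopifnot(inherits(model, "beam_profile"))
  if (any(r < 0)) stop("`r` must be >= 0", call. = FALSE)
  R <- project_diameter(aperture, chamber) / 2
  p <- model$penumbra_mm
  if (p == 0) {
    edge <- ifelse(r < R, 1, ifelse(r == R, 0.5, 0))
  } else {
    # 0.5 * erfc(k (r - R) / p) written via the normal CDF, renormalized to
    # its on-axis value so that OCR(0) = 1 holds even when the penumbra is
    # not small against the field radius
    edge <- stats::pnorm(-sqrt(2) * PENUMBRA_K * (r - R) / p) /
      stats::pnorm(sqrt(2) * PENUMBRA_K * R / p)
  }
  core <- 1 + model$flatness * (pmin(r, R) / R)^2
  depress <- 1 - 0.04 * model$detune_level * shoulder_weight(r, R)
  edge * core * depress
}

#' Detune the beam profile
#'
#' Emulates a deliberate mis-tune of beam symmetry/homogeneity whose effect
#' on the profile is a decrease of the dose in the shoulder region (between
#' 0.5 and 0.9 of the field radius) by approximately 4% per unit level,
#' leaving the central axis normalized to 1.
#'
#' @param model A [beam_profile()].
#' @param level Detuning level; 0 returns the model unchanged, 1 reproduces
#'   the worst-case clinically tolerated mis-tune.
#'
#' @return A `beam_profile` with the requested detuning level.
#' @export
detune <- function(model, level) {
  stopifnot(inherits(model, "beam_profile"))
  if (level < 0) stop("`level` must be >= 0", call. = FALSE)
  model$detune_level <- level
  model
}

#' Output-factor table
#'
#' @param diameter_mm Strictly increasing aperture diameters in mm.
#' @param of Output factors (central-axis dose per MU relative to the
#'   reference aperture); positive and non-decreasing in diameter.
#' @param synthetic Flag carried into reports: `TRUE` marks a stand-in table
#'   not measured on a machine.
#'
#' @return A data frame of class `of_table` with columns `diameter_mm`, `of`.
#' @export
of_table <- function(diameter_mm, of, synthetic = FALSE) {
  if (length(diameter_mm) != length(of) || length(of) < 2L) {
    stop("`diameter_mm` and `of` must have equal length >= 2", call. = FALSE)
  }
  if (any(diff(diameter_mm) <= 0)) {
    stop("diameters must be strictly increasing", call. = FALSE)
  }
  if (any(of <= 0)) stop("output factors must be positive", call. = FALSE)
  if (any(diff(of) < 0)) {
    stop("output factors must be non-decreasing in diameter", call. = FALSE)
  }
  structure(data.frame(diameter_mm = as.numeric(diameter_mm),
                       of = as.numeric(of)),
            synthetic = isTRUE(synthetic),
            class = c("of_table", "data.frame"))
}

#' Synthetic default output-factor table
#'
#' A monotone, saturating curve evaluated at the 12 clinical diameters and
#' normalized to 1 at the 60 mm aperture:
#' \eqn{OF(d) \propto 1 - A e^{-d/\tau}} with \eqn{A = 0.4545},
#' \eqn{\tau = 15} mm, giving OF(5) of about 0.68 rising to 1.0. This is a
#' stand-in with a plausible small-field shape, not machine data, and is
#' flagged `synthetic` so that reports carry the mark.
#'
#' @return An [of_table()] flagged synthetic.
#' @export
default_of_table <- function() {
  d <- clinical_diameters()
  raw <- 1 - 0.4545 * exp(-d / 15)
  of_table(d, raw / raw[length(raw)], synthetic = TRUE)
}

#' Interpolate an output factor at an arbitrary diameter
#'
#' Piecewise-linear interpolation between adjacent tabulated diameters.
#' Beyond the largest diameter the endpoint value is used (the OF plateaus
#' at large apertures); below the smallest diameter the first segment is
#' extended linearly (the OF gradient keeps steepening toward small fields,
#' which is what makes the negative small-aperture limit larger in magnitude
#' than pure area scaling). Either extrapolation is allowed only up to
#' 0.2 mm outside the tabulated range.
#'
#' @param table An [of_table()].
#' @param d Diameter(s) in mm.
#'
#' @return Interpolated output factor(s) `OF'(d)`.
#' @export
interpolate_of <- function(table, d) {
  stopifnot(inherits(table, "of_table"))
  lo <- table$diameter_mm[1L]
  hi <- table$diameter_mm[nrow(table)]
  if (any(d < lo - 0.2 - 1e-12) || any(d > hi + 0.2 + 1e-12)) {
    stop(sprintf(
      "diameter outside the tabulated range [%.6g, %.6g] mm by more than 0.2 mm",
      lo, hi), call. = FALSE)
  }
  out <- stats::approx(table$diameter_mm, table$of,
                       xout = pmin(pmax(d, lo), hi), method = "linear")$y
  below <- d < lo
  if (any(below)) {
    slope <- (table$of[2L] - table$of[1L]) /
      (table$diameter_mm[2L] - table$diameter_mm[1L])
    out[below] <- pmax(table$of[1L] + (d[below] - lo) * slope, 0)
  }
  out
}
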