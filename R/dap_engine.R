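# Dose-area products by deterministic quadrature of the beam profile over
# the chamber's sensitive area, aligned and misaligned, and the tolerance
# limits derived from the model.

integrate_checked <- function(f, lower, upper, rel.tol, what) {
  res <- stats::integrate(f, lower, upper, rel.tol = rel.tol, abs.tol = 0,
                          subdivisions = 500L, stop.on.error = FALSE)
  if (!res$message %in% c("OK", "the integral is probably divergent") ||
      !is.finite(res$value)) {
    stop(sprintf("quadrature failed in %s: %s", what, res$message),
         call. = FALSE)
  }
  res$value
}

#' Dose-area product for an aligned chamber
#'
#' Radial integration of the off-center ratio over the chamber's sensitive
#' area, weighted with the output factor:
#' \deqn{DAP = OF \int_0^{r_{max}} OCR(r, d)\, 2\pi r\, dr.}
#'
#' @param model A [beam_profile()].
#' @param aperture An [aperture_spec()] or a diameter in mm.
#' @param of Output factor weight (dimensionless).
#' @param chamber A [chamber_spec()].
#'
#' @return DAP in model units (nC-equivalent).
#' @export
dap_radial <- function(model, aperture, of, chamber = chamber_spec()) {
  stopifnot(inherits(model, "beam_profile"))
  if (of == 0) return(0)
  r_max <- chamber$r_max_mm
  R <- project_diameter(aperture, chamber) / 2
  f <- function(r) ocr(model, aperture, r, chamber) * 2 * pi * r
  if (model$penumbra_mm == 0) {
    # step edge: the profile is identically zero beyond R, so integrate only
    # the smooth part inside the field
    upper <- min(R, r_max)
    val <- integrate_checked(f, 0, upper, rel.tol = 1e-10, what = "dap_radial")
  } else {
    val <- integrate_checked(f, 0, r_max, rel.tol = 1e-10, what = "dap_radial")
  }
  of * val
}

# Area of the intersection of a disk of radius R (beam) and a disk of radius
# r_max (chamber) whose centers are a distance s apart.
lens_area <- function(R, r_max, s) {
  if (s >= R + r_max) return(0)
  if (s <= abs(r_max - R)) return(pi * min(R, r_max)^2)
  d1 <- (s^2 + R^2 - r_max^2) / (2 * s)
  d2 <- s - d1
  R^2 * acos(pmin(pmax(d1 / R, -1), 1)) +
    r_max^2 * acos(pmin(pmax(d2 / r_max, -1), 1)) -
    0.5 * sqrt(pmax((-s + R + r_max) * (s + R - r_max) *
                      (s - R + r_max) * (s + R + r_max), 0))
}

#' Dose-area product for a misaligned chamber
#'
#' Integral of the beam profile over a disk of radius `r_max` whose center is
#' offset from the beam axis, computed by nested deterministic quadrature in
#' polar coordinates centred on the chamber (the integrand is smooth there).
#' At `shift = 0` this agrees with [dap_radial()] to better than 1e-6
#' relative; the computation is still performed by 2-D quadrature so the
#' agreement is a genuine cross-check, not an aliased code path.
#'
#' @param model A [beam_profile()].
#' @param aperture An [aperture_spec()] or a diameter in mm.
#' @param of Output factor weight.
#' @param chamber A [chamber_spec()].
#' @param shift Offset of the chamber center from the beam axis, mm (>= 0).
#'
#' @return DAP in model units.
#' @export
dap_offset <- function(model, aperture, of, chamber = chamber_spec(),
                       shift = 0) {
  stopifnot(inherits(model, "beam_profile"))
  if (shift < 0) stop("`shift` must be >= 0", call. = FALSE)
  if (of == 0) return(0)
  r_max <- chamber$r_max_mm
  R <- project_diameter(aperture, chamber) / 2
  if (model$penumbra_mm == 0) {
    if (model$flatness != 0 || model$detune_level != 0) {
      stop("offset integration of a step profile supports only flatness 0 and no detuning",
           call. = FALSE)
    }
    return(of * lens_area(R, r_max, shift))
  }
  inner <- function(rho) {
    if (rho == 0) return(0)
    g <- function(phi) {
      r <- sqrt(rho^2 + shift^2 + 2 * rho * shift * cos(phi))
      ocr(model, aperture, r, chamber)
    }
    # the integrand is even in phi: integrate half the circle
    2 * integrate_checked(g, 0, pi, rel.tol = 1e-9, what = "dap_offset (angular)") * rho
  }
  val <- integrate_checked(function(rho) vapply(rho, inner, numeric(1)),
                           0, r_max, rel.tol = 1e-8,
                           what = "dap_offset (radial)")
  of * val
}

#' Quotient of two dose-area products
#'
#' The core QA statistic: the DAP of a variable aperture relative to the DAP
#' of the fixed 60 mm reference aperture,
#' \eqn{\theta(d) = DAP_{Iris}(d) / DAP_{Fixed}(60\,mm)}.
#'
#' @param dap_iris DAP of the aperture under test.
#' @param dap_fixed DAP of the fixed reference aperture (> 0).
#'
#' @return Dimensionless quotient(s).
#' @export
theta <- function(dap_iris, dap_fixed) {
  if (any(dap_fixed <= 0)) {
    stop("reference DAP must be positive", call. = FALSE)
  }
  dap_iris / dap_fixed
}

#' Calculated tolerance limits from the beam model
#'
#' Converts the aperture reproducibility specification (+/- `perturbation`
#' mm on the nominal diameter) into percentage limits on the QA quotient by
#' the analytical route: the baseline DAP is computed from the model, the
#' perturbed DAP uses a field radius rescaled to the perturbed diameter and
#' an output factor interpolated at that diameter, and the limit is the
#' percentage ratio
#' \eqn{\delta_{calc,\pm0.2}(d) = (\theta_{\pm0.2}/\theta_{baseline} - 1)\cdot 100}.
#' The fixed-reference denominator cancels in the ratio.
#'
#' @param model A [beam_profile()].
#' @param table An [of_table()].
#' @param apertures Diameters in mm (default: the clinical set).
#' @param chamber A [chamber_spec()].
#' @param perturbation Diameter perturbation in mm (default 0.2, the
#'   manufacturer's reproducibility specification).
#'
#' @return A [tolerance_limits()] data frame with `source = "calculated"`.
#' @export
calculated_limits <- function(model, table, apertures = clinical_diameters(),
                              chamber = chamber_spec(), perturbation = 0.2) {
  stopifnot(inherits(model, "beam_profile"), inherits(table, "of_table"))
  if (perturbation < 0) stop("`perturbation` must be >= 0", call. = FALSE)
  one <- function(d) {
    base <- dap_radial(model, d, interpolate_of(table, d), chamber)
    pert <- function(sgn) {
      dp <- d + sgn * perturbation
      dap_radial(model, dp, interpolate_of(table, dp), chamber)
    }
    c(plus = (pert(+1) / base - 1) * 100,
      minus = (pert(-1) / base - 1) * 100)
  }
  lim <- t(vapply(apertures, one, numeric(2)))
  tolerance_limits(apertures, lim[, "plus"], lim[, "minus"],
                   source = "calculated")
}

#' Tolerance limits container
#'
#' Per-aperture positive and negative percentage limits on the QA deviation,
#' tagged with their provenance (derived by model calculation or by
#' deliberate-perturbation measurement).
#'
#' @param aperture_mm Aperture diameters in mm.
#' @param delta_plus Positive limits in percent (> 0).
#' @param delta_minus Negative limits in percent (< 0).
#' @param source `"calculated"` or `"measured"`.
#'
#' @return A data frame of class `tolerance_limits`.
#' @export
tolerance_limits <- function(aperture_mm, delta_plus, delta_minus,
                             source = c("calculated", "measured")) {
  source <- match.arg(source)
  if (any(delta_plus <= 0) || any(delta_minus >= 0)) {
    stop("tolerance limits must satisfy delta_plus > 0 > delta_minus",
         call. = FALSE)
  }
  structure(data.frame(aperture_mm = as.numeric(aperture_mm),
                       delta_plus = as.numeric(delta_plus),
                       delta_minus = as.numeric(delta_minus)),
            source = source,
            class = c("tolerance_limits", "data.frame"))
}
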