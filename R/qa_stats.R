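# QA statistics of the dose-area-product method: percentage deviations,
# percent <-> millimetre conversion, tolerance limits from perturbation
# measurements, characterization fits, the error budget, and the
# reproducibility / stability / long-term QA summaries.

#' Percentage deviation of the QA quotient from baseline
#'
#' \eqn{\delta(d) = (\theta(d)/\theta_{baseline}(d) - 1)\cdot 100}.
#'
#' @param theta Quotient(s) measured in a QA session.
#' @param theta_baseline Commissioning baseline quotient(s) (> 0).
#'
#' @return Deviation(s) in percent on the 0-100 scale.
#' @export
delta <- function(theta, theta_baseline) {
  if (any(theta_baseline <= 0)) {
    stop("baseline quotient must be positive", call. = FALSE)
  }
  (theta / theta_baseline - 1) * 100
}

#' Deviation of the quotient under chamber misalignment
#'
#' Same ratio-minus-one contract as [delta()], comparing a misaligned to an
#' aligned measurement of the quotient.
#'
#' @param theta_misaligned,theta_aligned Quotients (> 0 denominator).
#' @return Deviation in percent.
#' @export
misalign_error <- function(theta_misaligned, theta_aligned) {
  delta(theta_misaligned, theta_aligned)
}

#' Deviation of the quotient under a primary-beam change
#'
#' @param theta_detuned,theta_unmodified Quotients (> 0 denominator).
#' @return Deviation in percent.
#' @export
beamchange_error <- function(theta_detuned, theta_unmodified) {
  delta(theta_detuned, theta_unmodified)
}

#' Convert a percentage quotient deviation into a diameter change
#'
#' Because the DAP scales with the field area, a quotient deviation of
#' \eqn{\delta} percent at nominal diameter \eqn{d} corresponds to a diameter
#' change \eqn{\Delta d = d(\sqrt{1 + \delta/100} - 1)} mm. Output-factor
#' variation is deliberately excluded from this conversion: it is a pure
#' area-scaling rule.
#'
#' @param delta Deviation(s) in percent; must exceed -100.
#' @param d Nominal aperture diameter(s) in mm.
#'
#' @return Equivalent diameter change(s) in mm, signed like `delta`.
#' @export
delta_to_mm <- function(delta, d) {
  if (any(delta <= -100)) stop("`delta` must be > -100 %", call. = FALSE)
  if (any(d <= 0)) stop("`d` must be positive", call. = FALSE)
  d * (sqrt(1 + delta / 100) - 1)
}

#' Convert a diameter change into a percentage quotient deviation
#'
#' Exact inverse of [delta_to_mm()]:
#' \eqn{\delta = ((d + \Delta d)^2/d^2 - 1)\cdot 100}.
#'
#' @param dd Diameter change(s) in mm.
#' @param d Nominal aperture diameter(s) in mm; `d + dd` must stay positive.
#'
#' @return Deviation(s) in percent.
#' @export
mm_to_delta <- function(dd, d) {
  if (any(d <= 0) || any(d + dd <= 0)) {
    stop("diameters must stay positive", call. = FALSE)
  }
  ((d + dd)^2 / d^2 - 1) * 100
}

#' Commissioning baseline of QA quotients
#'
#' @param aperture_mm Clinical aperture diameters in mm (sorted increasing).
#' @param theta_baseline Baseline quotient per aperture; positive and
#'   strictly increasing with aperture area.
#' @param date Acquisition date (ISO-8601 string).
#' @param n_repeats Number of repeat readings behind each mean.
#'
#' @return A data frame of class `baseline_record`.
#' @export
baseline_record <- function(aperture_mm, theta_baseline,
                            date = NA_character_, n_repeats = NA_integer_) {
  ord <- order(aperture_mm)
  aperture_mm <- aperture_mm[ord]
  theta_baseline <- theta_baseline[ord]
  if (any(theta_baseline <= 0)) {
    stop("baseline quotients must be positive", call. = FALSE)
  }
  if (any(diff(theta_baseline) <= 0)) {
    stop("baseline quotients must increase strictly with aperture area",
         call. = FALSE)
  }
  structure(data.frame(aperture_mm = as.numeric(aperture_mm),
                       theta_baseline = as.numeric(theta_baseline)),
            date = date, n_repeats = n_repeats,
            class = c("baseline_record", "data.frame"))
}

#' Noise-free baseline from the beam model
#'
#' Computes the deterministic quotient \eqn{\theta(d)} for every clinical
#' aperture directly from the beam model, as a stand-in for a commissioning
#' run.
#'
#' @param model A [beam_profile()].
#' @param table An [of_table()].
#' @param chamber A [chamber_spec()].
#' @param apertures Diameters in mm (default: the clinical set).
#'
#' @return A [baseline_record()].
#' @export
model_baseline <- function(model, table, chamber = chamber_spec(),
                           apertures = clinical_diameters()) {
  ref <- dap_radial(model, 60, interpolate_of(table, 60), chamber)
  th <- vapply(apertures, function(d) {
    theta(dap_radial(model, d, interpolate_of(table, d), chamber), ref)
  }, numeric(1))
  baseline_record(apertures, th, date = NA_character_, n_repeats = NA_integer_)
}

#' Measured tolerance limits from deliberate perturbation runs
#'
#' The aperture reproducibility specification is converted into limits by
#' measurement: the field size is deliberately changed by +/- 0.2 mm, the
#' quotient is measured, and the limit per aperture and sign is
#' \eqn{\delta_{meas,\pm0.2}(d) =
#'   (\theta_{meas,\pm0.2mm}(d)/\theta_{baseline}(d) - 1)\cdot 100}.
#'
#' @param theta_plus,theta_minus Data frames with columns `aperture_mm` and
#'   `theta`: mean quotients measured with the aperture set to `d + 0.2` and
#'   `d - 0.2` mm respectively.
#' @param baseline A [baseline_record()] covering the same apertures.
#'
#' @return A [tolerance_limits()] data frame with `source = "measured"`.
#' @export
measured_limits <- function(theta_plus, theta_minus, baseline) {
  stopifnot(inherits(baseline, "baseline_record"))
  need <- baseline$aperture_mm
  for (nm in list(theta_plus, theta_minus)) {
    if (!all(c("aperture_mm", "theta") %in% names(nm))) {
      stop("perturbed inputs need columns `aperture_mm` and `theta`",
           call. = FALSE)
    }
    missing <- setdiff(need, nm$aperture_mm)
    if (length(missing)) {
      stop(sprintf("missing perturbed quotients for aperture(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  tp <- theta_plus$theta[match(need, theta_plus$aperture_mm)]
  tm <- theta_minus$theta[match(need, theta_minus$aperture_mm)]
  tolerance_limits(need,
                   delta(tp, baseline$theta_baseline),
                   delta(tm, baseline$theta_baseline),
                   source = "measured")
}

#' Power-law characterization fit of DAP versus diameter
#'
#' Least-squares fit of \eqn{DAP = b\, d^c} performed in log-log space, the
#' scale-free weighting appropriate for data spanning a 50-fold dynamic
#' range. `log_space = FALSE` selects raw nonlinear least squares instead.
#'
#' @param d Aperture diameters in mm (>= 3 points).
#' @param dap DAP values (> 0).
#' @param log_space Fit in log-log space (default) or by raw nonlinear LS.
#'
#' @return A list with elements `b`, `c`, `fitted` and `residuals` (residuals
#'   on the fitting scale).
#' @export
fit_dap_power_law <- function(d, dap, log_space = TRUE) {
  if (length(d) != length(dap) || length(d) < 3L) {
    stop("need at least 3 (d, DAP) points", call. = FALSE)
  }
  if (any(d <= 0) || any(dap <= 0)) {
    stop("diameters and DAP values must be positive", call. = FALSE)
  }
  if (log_space) {
    fit <- stats::lm(log(dap) ~ log(d))
    b <- exp(unname(stats::coef(fit)[1L]))
    cc <- unname(stats::coef(fit)[2L])
    list(b = b, c = cc, fitted = b * d^cc,
         residuals = unname(stats::residuals(fit)))
  } else {
    start <- fit_dap_power_law(d, dap, log_space = TRUE)
    fit <- stats::nls(dap ~ b * d^c,
                      start = list(b = start$b, c = start$c),
                      control = stats::nls.control(maxiter = 200,
                                                   scaleOffset = 1))
    est <- stats::coef(fit)
    list(b = unname(est["b"]), c = unname(est["c"]),
         fitted = unname(stats::fitted(fit)),
         residuals = unname(stats::residuals(fit)))
  }
}

#' Through-origin linear fit of the quotient versus aperture area
#'
#' Least-squares slope of \eqn{\theta = b \cdot area} constrained through the
#' origin: \eqn{b = \sum x y / \sum x^2}.
#'
#' @param area_cm2 Aperture areas in cm^2.
#' @param theta Quotients.
#'
#' @return The slope `b` (per cm^2).
#' @export
fit_theta_linear <- function(area_cm2, theta) {
  if (length(area_cm2) != length(theta) || length(area_cm2) < 1L) {
    stop("need matching (area, theta) points", call. = FALSE)
  }
  sxx <- sum(area_cm2^2)
  if (sxx == 0) stop("all areas are zero", call. = FALSE)
  sum(area_cm2 * theta) / sxx
}

#' Error budget of the method
#'
#' Combines the independent error components that contribute to the quotient
#' (output variation, MU-delivery uncertainty, chamber misalignment, the
#' chamber's inherent uncertainty) in quadrature. Because the combination
#' rule used for the published working value is a conservative envelope
#' rather than a plain quadrature sum, both numbers are reported side by
#' side and neither replaces the other.
#'
#' @param output Output-variation component, percent (>= 0).
#' @param mu MU-delivery component, percent (>= 0).
#' @param misalign Misalignment component, percent (>= 0).
#' @param lac Chamber component, percent (>= 0, default 0: negligible).
#' @param envelope Conservative working value reported alongside the
#'   quadrature sum, percent (default 0.2).
#'
#' @return A list of class `error_budget` with the components, `quadrature`
#'   (the root-sum-square) and `envelope`.
#' @export
error_budget <- function(output = 0.04, mu = 0.04, misalign = 0.10, lac = 0,
                         envelope = 0.2) {
  comp <- c(output = output, mu = mu, misalign = misalign, lac = lac)
  if (any(comp < 0)) stop("error components must be >= 0", call. = FALSE)
  structure(list(components = comp,
                 quadrature = sqrt(sum(comp^2)),
                 envelope = envelope),
            class = "error_budget")
}

fmt_ap <- function(d) sprintf("%.1f", d)

split_sessions <- function(sessions) {
  if (is.data.frame(sessions)) {
    sessions <- split(sessions, sessions$session_id)
  }
  if (!is.list(sessions) || !length(sessions)) {
    stop("`sessions` must be a measurement session or a list of them",
         call. = FALSE)
  }
  sessions
}

session_means <- function(session) {
  key <- interaction(session$collimator, fmt_ap(session$aperture_mm),
                     drop = TRUE)
  parts <- split(session, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    data.frame(collimator = p$collimator[1L],
               aperture_mm = p$aperture_mm[1L],
               n = nrow(p),
               mean = mean(p$reading_nC),
               sd = if (nrow(p) > 1L) stats::sd(p$reading_nC) else NA_real_)
  }))
  rownames(out) <- NULL
  out[order(out$collimator, out$aperture_mm), , drop = FALSE]
}

fixed_reference_mean <- function(means) {
  ref <- means$collimator == "fixed" & abs(means$aperture_mm - 60) < 1e-9
  if (!any(ref)) {
    stop("session lacks the fixed 60 mm reference aperture", call. = FALSE)
  }
  means$mean[ref][1L]
}

# Quotients of every non-reference record against the fixed 60 mm reference.
session_thetas <- function(session) {
  means <- session_means(session)
  ref <- fixed_reference_mean(means)
  keep <- !(means$collimator == "fixed" & abs(means$aperture_mm - 60) < 1e-9)
  data.frame(collimator = means$collimator[keep],
             aperture_mm = means$aperture_mm[keep],
             theta = theta(means$mean[keep], ref))
}

#' Reproducibility summary of repeated DAP readings
#'
#' For every aperture, the sample standard deviation of the repeat readings
#' within each session is expressed in percent of the session mean; the
#' median and first/third quartiles of these per-session values across
#' sessions summarize reproducibility, and the median is also translated
#' into an equivalent diameter change via [delta_to_mm()].
#'
#' @param sessions A list of measurement sessions (or one data frame holding
#'   several `session_id`s); every aperture needs >= 2 repeats per session
#'   and >= 2 sessions.
#'
#' @return A data frame of class `series_summary` with per-aperture columns
#'   `sd_q1_pct`, `sd_median_pct`, `sd_q3_pct` and their mm equivalents.
#' @export
reproducibility_summary <- function(sessions) {
  sessions <- split_sessions(sessions)
  if (length(sessions) < 2L) stop("need >= 2 sessions", call. = FALSE)
  per <- lapply(sessions, function(s) {
    m <- session_means(s)
    if (any(m$n < 2L)) {
      stop("every aperture needs >= 2 repeat readings per session",
           call. = FALSE)
    }
    m$sd_pct <- m$sd / m$mean * 100
    m[, c("collimator", "aperture_mm", "sd_pct")]
  })
  all <- do.call(rbind, per)
  key <- interaction(all$collimator, fmt_ap(all$aperture_mm), drop = TRUE)
  out <- do.call(rbind, lapply(split(all, key), function(g) {
    q <- stats::quantile(g$sd_pct, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(collimator = g$collimator[1L],
               aperture_mm = g$aperture_mm[1L],
               n_sessions = nrow(g),
               sd_q1_pct = q[1L], sd_median_pct = q[2L], sd_q3_pct = q[3L])
  }))
  rownames(out) <- NULL
  out$sd_q1_mm <- delta_to_mm(out$sd_q1_pct, out$aperture_mm)
  out$sd_median_mm <- delta_to_mm(out$sd_median_pct, out$aperture_mm)
  out$sd_q3_mm <- delta_to_mm(out$sd_q3_pct, out$aperture_mm)
  out <- out[order(out$collimator, out$aperture_mm), , drop = FALSE]
  structure(out, class = c("series_summary", "data.frame"))
}

#' Stability of the QA quotient across sessions
#'
#' For every aperture (measured against the fixed 60 mm reference), the
#' standard deviation of \eqn{\theta} across sessions in percent of its mean
#' and in mm, plus a linear trend statistic (slope of \eqn{\theta} versus
#' session index with its standard error) supporting a no-drift check.
#'
#' @param sessions A list of >= 2 measurement sessions (or one data frame
#'   holding several `session_id`s), in chronological order.
#'
#' @return A data frame of class `series_summary` with columns `theta_mean`,
#'   `theta_sd_pct`, `theta_sd_mm`, `trend_slope`, `trend_se`.
#' @export
stability_summary <- function(sessions) {
  sessions <- split_sessions(sessions)
  if (length(sessions) < 2L) stop("need >= 2 sessions", call. = FALSE)
  per <- lapply(seq_along(sessions), function(i) {
    th <- session_thetas(sessions[[i]])
    th$session_index <- i
    th
  })
  all <- do.call(rbind, per)
  key <- interaction(all$collimator, fmt_ap(all$aperture_mm), drop = TRUE)
  out <- do.call(rbind, lapply(split(all, key), function(g) {
    m <- mean(g$theta)
    s <- stats::sd(g$theta)
    fit <- stats::lm(theta ~ session_index, data = g)
    # a constant series is a legitimate (perfect) fit; the slope SE is then 0
    sm <- suppressWarnings(summary(fit))$coefficients
    data.frame(collimator = g$collimator[1L],
               aperture_mm = g$aperture_mm[1L],
               n_sessions = nrow(g),
               theta_mean = m,
               theta_sd_pct = s / m * 100,
               trend_slope = sm["session_index", "Estimate"],
               trend_se = sm["session_index", "Std. Error"])
  }))
  rownames(out) <- NULL
  out$theta_sd_mm <- delta_to_mm(out$theta_sd_pct, out$aperture_mm)
  out <- out[order(out$collimator, out$aperture_mm), , drop = FALSE]
  structure(out, class = c("series_summary", "data.frame"))
}

#' Evaluate a QA session against baseline and tolerance limits
#'
#' Computes the quotient \eqn{\theta(d)} from the session means for every
#' clinical aperture, its percentage deviation \eqn{\delta(d)} from the
#' commissioning baseline, the equivalent diameter change in mm, and a
#' per-aperture pass/fail against the tolerance limits. A deviation exactly
#' on a limit counts as a pass (the specification is stated inclusively).
#' An aperture missing from the session is reported as failed with a reason,
#' never silently skipped; a missing fixed 60 mm reference is an error.
#'
#' @param session A measurement session data frame.
#' @param baseline A [baseline_record()].
#' @param limits A [tolerance_limits()] covering the baseline apertures.
#'
#' @return An object of class `qa_result`: a list with the per-aperture
#'   `table`, `session_id`, `date` and overall `pass`.
#' @export
evaluate_qa <- function(session, baseline, limits) {
  stopifnot(inherits(baseline, "baseline_record"),
            inherits(limits, "tolerance_limits"))
  means <- session_means(session)
  ref <- fixed_reference_mean(means)
  iris <- means[means$collimator == "iris", , drop = FALSE]
  rows <- lapply(seq_len(nrow(baseline)), function(i) {
    d <- baseline$aperture_mm[i]
    tb <- baseline$theta_baseline[i]
    il <- limits[abs(limits$aperture_mm - d) < 1e-9, , drop = FALSE]
    if (!nrow(il)) {
      stop(sprintf("no tolerance limits for aperture %s mm", fmt_ap(d)),
           call. = FALSE)
    }
    hit <- abs(iris$aperture_mm - d) < 1e-9
    if (!any(hit)) {
      return(data.frame(aperture_mm = d, theta = NA_real_,
                        theta_baseline = tb, delta_pct = NA_real_,
                        delta_mm = NA_real_,
                        delta_plus = il$delta_plus[1L],
                        delta_minus = il$delta_minus[1L],
                        pass = FALSE, reason = "aperture missing from session"))
    }
    th <- theta(iris$mean[hit][1L], ref)
    dl <- delta(th, tb)
    data.frame(aperture_mm = d, theta = th, theta_baseline = tb,
               delta_pct = dl, delta_mm = delta_to_mm(dl, d),
               delta_plus = il$delta_plus[1L], delta_minus = il$delta_minus[1L],
               pass = il$delta_minus[1L] <= dl & dl <= il$delta_plus[1L],
               reason = NA_character_)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 session_id = session$session_id[1L],
                 date = session$date[1L],
                 pass = all(tab$pass)),
            class = "qa_result")
}

#' Aggregate measured sessions into a commissioning baseline
#'
#' Means of the per-session quotients \eqn{\theta(d)} across sessions, for
#' the iris apertures present in all sessions.
#'
#' @param sessions A list of measurement sessions (or one data frame).
#'
#' @return A [baseline_record()] (date: the first session's date).
#' @export
baseline_from_sessions <- function(sessions) {
  sessions <- split_sessions(sessions)
  th <- lapply(sessions, session_thetas)
  iris <- lapply(th, function(x) x[x$collimator == "iris", , drop = FALSE])
  aps <- Reduce(intersect, lapply(iris, function(x) x$aperture_mm))
  if (!length(aps)) stop("sessions share no iris apertures", call. = FALSE)
  mean_th <- vapply(sort(aps), function(d) {
    mean(vapply(iris, function(x) x$theta[abs(x$aperture_mm - d) < 1e-9][1L],
                numeric(1)))
  }, numeric(1))
  n_rep <- max(vapply(sessions, function(s)
    max(table(interaction(s$collimator, fmt_ap(s$aperture_mm)))), numeric(1)))
  baseline_record(sort(aps), mean_th,
                  date = as.character(sessions[[1L]]$date[1L]),
                  n_repeats = as.integer(n_rep))
}

#' @export
print.qa_result <- function(x, ...) {
  cat(sprintf("QA session %s (%s): %s\n", x$session_id, x$date,
              if (x$pass) "PASS" else "FAIL"))
  tab <- x$table
  tab$theta <- signif(tab$theta, 6)
  tab$delta_pct <- round(tab$delta_pct, 3)
  tab$delta_mm <- round(tab$delta_mm, 3)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' @export
print.error_budget <- function(x, ...) {
  cat("Error budget (percent of the QA quotient):\n")
  for (nm in names(x$components)) {
    cat(sprintf("  %-9s %.4g\n", nm, x$components[[nm]]))
  }
  cat(sprintf("  quadrature sum: %.4g %%\n", x$quadrature))
  cat(sprintf("  conservative envelope: %.4g %%\n", x$envelope))
  invisible(x)
}
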