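# Synthetic measurement sessions with the noise structure of repeated
# 100-MU exposures: output drift, MU-delivery noise, aperture-size jitter,
# chamber misalignment, deliberate detuning and systematic aperture offsets.

#' Simulation configuration
#'
#' Defaults reproduce the documented study conditions: repeated 100-MU
#' exposures of the 12 clinical iris apertures plus the fixed 60 mm
#' reference, with an output variation of 0.04%, an MU-delivery uncertainty
#' of 0.04%, and an aperture-size repeatability well below the 0.2 mm
#' specification (jitter SD 0.02 mm).
#'
#' @param seed Integer RNG seed; a fixed seed makes sessions bit-reproducible.
#' @param n_repeats Repeat readings per aperture (default 5).
#' @param mu Monitor units per exposure (default 100).
#' @param output_drift_sd SD of the linac output variation, percent.
#' @param mu_delivery_sd SD of the MU-delivery uncertainty, percent.
#' @param aperture_jitter_sd SD of the iris aperture-size jitter, mm
#'   (fixed cones get no size jitter).
#' @param misalignment Chamber offset from the beam axis, mm.
#' @param detune_level Beam detuning level passed to [detune()].
#' @param aperture_offsets Systematic true aperture-size errors in mm:
#'   a single number applied to every iris aperture, or a vector named by
#'   diameter formatted with one decimal (e.g. `"7.5"`).
#' @param calibration_drift Linear drift of the aperture offsets across a
#'   long-term series, mm per session (default 0).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_repeats = 5L, mu = 100,
                       output_drift_sd = 0.04, mu_delivery_sd = 0.04,
                       aperture_jitter_sd = 0.02, misalignment = 0,
                       detune_level = 0, aperture_offsets = 0,
                       calibration_drift = 0) {
  if (n_repeats < 1L) stop("`n_repeats` must be >= 1", call. = FALSE)
  if (mu <= 0) stop("`mu` must be positive", call. = FALSE)
  for (v in c(output_drift_sd, mu_delivery_sd, aperture_jitter_sd,
              misalignment, detune_level)) {
    if (v < 0) stop("noise SDs, misalignment and detuning must be >= 0",
                    call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_repeats = as.integer(n_repeats),
                 mu = mu, output_drift_sd = output_drift_sd,
                 mu_delivery_sd = mu_delivery_sd,
                 aperture_jitter_sd = aperture_jitter_sd,
                 misalignment = misalignment, detune_level = detune_level,
                 aperture_offsets = aperture_offsets,
                 calibration_drift = calibration_drift),
            class = "sim_config")
}

offset_for <- function(offsets, d) {
  if (length(offsets) == 1L && is.null(names(offsets))) return(offsets)
  key <- fmt_ap(d)
  if (key %in% names(offsets)) return(unname(offsets[[key]]))
  0
}

#' Simulate one measurement session
#'
#' Each exposure draws a true aperture diameter (nominal + systematic offset
#' + normal jitter, iris only), evaluates the deterministic chamber reading
#' from the beam model (misaligned if configured), and multiplies it by
#' independent output-drift and MU-delivery noise factors. With all SDs at
#' zero the readings equal the model DAPs exactly. The RNG state is saved
#' and restored, and draws follow a fixed order (jitter, drift, MU noise per
#' exposure; apertures in clinical order, then the fixed reference), so a
#' fixed seed yields a bit-reproducible session.
#'
#' @param model A [beam_profile()] (the configured detuning level is applied
#'   on top).
#' @param table An [of_table()].
#' @param chamber A [chamber_spec()].
#' @param config A [sim_config()].
#' @param session_id Identifier string for the session.
#' @param date ISO-8601 date string.
#'
#' @return A measurement session: a data frame of class
#'   `measurement_session` with columns `session_id`, `date`, `collimator`,
#'   `aperture_mm`, `mu`, `repeat_index`, `reading_nC`.
#' @export
simulate_session <- function(model, table, chamber = chamber_spec(),
                             config = sim_config(), session_id = "S001",
                             date = "2023-01-01") {
  stopifnot(inherits(model, "beam_profile"), inherits(table, "of_table"),
            inherits(config, "sim_config"))
  model <- detune(model, config$detune_level)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  lo <- table$diameter_mm[1L] - 0.2
  hi <- table$diameter_mm[nrow(table)] + 0.2
  dap_cache <- new.env(parent = emptyenv())
  dap_at <- function(true_d) {
    key <- sprintf("%.12g", true_d)
    if (!is.null(dap_cache[[key]])) return(dap_cache[[key]])
    of <- interpolate_of(table, min(max(true_d, lo), hi))
    v <- if (config$misalignment > 0) {
      dap_offset(model, true_d, of, chamber, shift = config$misalignment)
    } else {
      dap_radial(model, true_d, of, chamber)
    }
    dap_cache[[key]] <- v
    v
  }

  records <- rbind(
    data.frame(collimator = "iris", aperture_mm = clinical_diameters()),
    data.frame(collimator = "fixed", aperture_mm = 60)
  )
  rows <- vector("list", nrow(records) * config$n_repeats)
  k <- 0L
  for (i in seq_len(nrow(records))) {
    kind <- records$collimator[i]
    d <- records$aperture_mm[i]
    for (rep_i in seq_len(config$n_repeats)) {
      if (kind == "iris") {
        jitter <- rnorm(1L, 0, config$aperture_jitter_sd)
        true_d <- d + offset_for(config$aperture_offsets, d) + jitter
      } else {
        true_d <- d
      }
      drift <- rnorm(1L, 0, config$output_drift_sd)
      mu_noise <- rnorm(1L, 0, config$mu_delivery_sd)
      reading <- dap_at(true_d) * (1 + drift / 100) * (1 + mu_noise / 100) *
        config$mu / 100
      k <- k + 1L
      rows[[k]] <- data.frame(session_id = session_id, date = date,
                              collimator = kind, aperture_mm = d,
                              mu = config$mu, repeat_index = rep_i,
                              reading_nC = reading)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("measurement_session", "data.frame")
  out
}

#' Simulate a long-term QA series
#'
#' Generates independent sessions with fresh noise draws. Session seeds are
#' split deterministically from the master seed
#' (`(seed + i * 1000003) mod (2^31 - 1)` for session `i`), so the whole
#' series is reproducible. An optional linear calibration drift shifts the
#' systematic aperture offsets by `calibration_drift` mm per session.
#' Sessions are dated 21 days apart, emulating a roughly monthly QA schedule.
#'
#' @param model A [beam_profile()].
#' @param table An [of_table()].
#' @param chamber A [chamber_spec()].
#' @param config A [sim_config()].
#' @param n_sessions Number of sessions (>= 1).
#' @param start_date First session date (ISO-8601).
#'
#' @return A list of measurement sessions.
#' @export
simulate_longterm <- function(model, table, chamber = chamber_spec(),
                              config = sim_config(), n_sessions = 31L,
                              start_date = "2023-01-01") {
  if (n_sessions < 1L) stop("`n_sessions` must be >= 1", call. = FALSE)
  start <- as.Date(start_date)
  lapply(seq_len(n_sessions), function(i) {
    cfg_i <- config
    cfg_i$seed <- as.integer((config$seed + i * 1000003) %% 2147483647)
    cfg_i$aperture_offsets <- config$aperture_offsets +
      config$calibration_drift * (i - 1L)
    simulate_session(model, table, chamber, cfg_i,
                     session_id = sprintf("S%03d", i),
                     date = as.character(start + (i - 1L) * 21L))
  })
}
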