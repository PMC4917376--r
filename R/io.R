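# Readers and writers for measurement sessions (CSV), baselines and
# tolerance limits (plain-text key-value + table), QA reports (JSON) and
# the beam-model configuration (YAML).

SESSION_HEADER <- c("session_id", "date", "collimator", "aperture_mm", "mu",
                    "repeat_index", "reading_nC")

num17 <- function(x) formatC(x, digits = 17, format = "g")

#' Fingerprint of a configuration or file
#'
#' A 31-bit polynomial rolling hash over the UTF-8 bytes of `text`, printed
#' as 8 hex digits. Used to stamp reports with the configuration they were
#' produced from.
#'
#' @param text A character vector (concatenated with newlines before
#'   hashing).
#' @return An 8-character hex string.
#' @export
config_fingerprint <- function(text) {
  bytes <- as.integer(charToRaw(paste(text, collapse = "\n")))
  h <- 0
  m <- 2147483647
  for (b in bytes) h <- (h * 31 + b) %% m
  sprintf("%08x", h)
}

#' Write a measurement session to CSV
#'
#' One row per exposure; aperture diameters are formatted with one decimal
#' (exact string keys, no float drift) and readings with 17 significant
#' digits so that [read_session()] round-trips losslessly.
#'
#' @param session A measurement session data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  if (!all(SESSION_HEADER %in% names(session))) {
    stop("session is missing required columns", call. = FALSE)
  }
  out <- data.frame(session_id = session$session_id,
                    date = session$date,
                    collimator = session$collimator,
                    aperture_mm = fmt_ap(session$aperture_mm),
                    mu = num17(session$mu),
                    repeat_index = session$repeat_index,
                    reading_nC = num17(session$reading_nC))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement session from CSV
#'
#' Validates the exact header, numeric fields, collimator kinds, duplicate
#' `(collimator, aperture, repeat_index)` keys and the presence of the fixed
#' 60 mm reference aperture; all malformed rows are reported together with
#' their line numbers.
#'
#' @param path CSV file path.
#' @return A data frame of class `measurement_session`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), SESSION_HEADER)) {
    stop(sprintf("session header must be exactly: %s",
                 paste(SESSION_HEADER, collapse = ",")), call. = FALSE)
  }
  problems <- character(0)
  line <- seq_len(nrow(raw)) + 1L
  ap <- suppressWarnings(as.numeric(raw$aperture_mm))
  mu <- suppressWarnings(as.numeric(raw$mu))
  rep_i <- suppressWarnings(as.integer(raw$repeat_index))
  reading <- suppressWarnings(as.numeric(raw$reading_nC))
  bad <- function(cond, what) {
    if (any(cond)) {
      problems <<- c(problems, sprintf("line %d: %s", line[cond], what))
    }
  }
  bad(!raw$collimator %in% c("iris", "fixed"),
      "collimator must be 'iris' or 'fixed'")
  bad(is.na(ap) | ap <= 0, "aperture_mm must be a positive number")
  bad(is.na(mu) | mu <= 0, "mu must be a positive number")
  bad(is.na(rep_i) | rep_i < 1L, "repeat_index must be a positive integer")
  bad(is.na(reading) | reading <= 0, "reading_nC must be a positive number")
  key <- paste(raw$session_id, raw$collimator, raw$aperture_mm, rep_i)
  bad(duplicated(key), "duplicate (aperture, repeat_index)")
  if (length(problems)) {
    stop(paste(c("malformed session file:", problems), collapse = "\n  "),
         call. = FALSE)
  }
  out <- data.frame(session_id = raw$session_id, date = raw$date,
                    collimator = raw$collimator, aperture_mm = ap,
                    mu = mu, repeat_index = rep_i, reading_nC = reading)
  if (!any(out$collimator == "fixed" & abs(out$aperture_mm - 60) < 1e-9)) {
    stop("session file lacks the required fixed 60 mm reference aperture",
         call. = FALSE)
  }
  class(out) <- c("measurement_session", "data.frame")
  out
}

write_kv_table <- function(path, format, meta, table) {
  lines <- c(sprintf("format: %s", format),
             vapply(names(meta), function(k) sprintf("%s: %s", k, meta[[k]]),
                    character(1)),
             "",
             paste(names(table), collapse = "\t"))
  body <- apply(table, 1L, function(row) paste(row, collapse = "\t"))
  writeLines(c(lines, body), path)
  invisible(path)
}

read_kv_table <- function(path, format) {
  lines <- readLines(path)
  blank <- which(lines == "")[1L]
  if (is.na(blank)) stop("malformed file: no header/table separator",
                         call. = FALSE)
  head <- lines[seq_len(blank - 1L)]
  kv <- strsplit(head, ": ", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  if (!identical(unname(meta[["format"]]), format)) {
    stop(sprintf("expected a '%s' file", format), call. = FALSE)
  }
  tab_lines <- lines[(blank + 1L):length(lines)]
  cols <- strsplit(tab_lines[1L], "\t", fixed = TRUE)[[1L]]
  cells <- strsplit(tab_lines[-1L], "\t", fixed = TRUE)
  tab <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
  names(tab) <- cols
  list(meta = meta, table = tab)
}

#' Write / read a commissioning baseline file
#'
#' Plain-text format: a key-value header (format tag, acquisition date,
#' repeat count) and a tab-separated table of baseline quotients per
#' aperture, written at full precision so that the round trip is lossless.
#'
#' @param baseline A [baseline_record()].
#' @param path File path.
#' @return `write_baseline`: `path` invisibly; `read_baseline`: a
#'   [baseline_record()].
#' @export
write_baseline <- function(baseline, path) {
  stopifnot(inherits(baseline, "baseline_record"))
  write_kv_table(path, "lacqa-baseline-v1",
                 list(date = as.character(attr(baseline, "date")),
                      n_repeats = as.character(attr(baseline, "n_repeats"))),
                 data.frame(aperture_mm = fmt_ap(baseline$aperture_mm),
                            theta_baseline = num17(baseline$theta_baseline)))
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  got <- read_kv_table(path, "lacqa-baseline-v1")
  n_rep <- got$meta[["n_repeats"]]
  baseline_record(as.numeric(got$table$aperture_mm),
                  as.numeric(got$table$theta_baseline),
                  date = got$meta[["date"]],
                  n_repeats = if (identical(n_rep, "NA")) NA_integer_
                              else as.integer(n_rep))
}

#' Write / read a tolerance-limits file
#'
#' Plain-text key-value header (format tag and the `source` of the limits:
#' calculated or measured) plus a tab-separated per-aperture table.
#'
#' @param limits A [tolerance_limits()].
#' @param path File path.
#' @return `write_limits`: `path` invisibly; `read_limits`: a
#'   [tolerance_limits()].
#' @export
write_limits <- function(limits, path) {
  stopifnot(inherits(limits, "tolerance_limits"))
  write_kv_table(path, "lacqa-limits-v1",
                 list(source = attr(limits, "source")),
                 data.frame(aperture_mm = fmt_ap(limits$aperture_mm),
                            delta_plus = num17(limits$delta_plus),
                            delta_minus = num17(limits$delta_minus)))
}

#' @rdname write_limits
#' @export
read_limits <- function(path) {
  got <- read_kv_table(path, "lacqa-limits-v1")
  tolerance_limits(as.numeric(got$table$aperture_mm),
                   as.numeric(got$table$delta_plus),
                   as.numeric(got$table$delta_minus),
                   source = got$meta[["source"]])
}

#' Write / read a QA report
#'
#' JSON report carrying the tool version, a fingerprint of the configuration
#' used, the per-aperture results (quotients to 6 significant figures,
#' percentages on the 0-100 scale, mm equivalents to 3 decimals) and the
#' overall verdict. When the output-factor table is a synthetic stand-in the
#' report says so.
#'
#' @param result A `qa_result` from [evaluate_qa()].
#' @param path File path.
#' @param config_text Character vector fingerprinted into the report.
#' @param of_synthetic Whether the OF table behind the evaluation is a
#'   synthetic stand-in.
#' @return `write_report`: `path` invisibly; `read_report`: a list.
#' @export
write_report <- function(result, path, config_text = "", of_synthetic = FALSE) {
  stopifnot(inherits(result, "qa_result"))
  tab <- result$table
  report <- list(
    tool = "lacqa",
    version = as.character(utils::packageVersion("lacqa")),
    config_hash = config_fingerprint(config_text),
    session_id = result$session_id,
    date = result$date,
    of_table_synthetic = isTRUE(of_synthetic),
    pass = result$pass,
    apertures = data.frame(
      aperture_mm = tab$aperture_mm,
      theta = signif(tab$theta, 6),
      theta_baseline = signif(tab$theta_baseline, 6),
      delta_pct = round(tab$delta_pct, 4),
      delta_mm = round(tab$delta_mm, 3),
      delta_plus = round(tab$delta_plus, 4),
      delta_minus = round(tab$delta_minus, 4),
      pass = tab$pass,
      reason = tab$reason))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read / write a beam-model configuration
#'
#' YAML configuration with blocks `chamber` (`active_diameter_mm`,
#' `plane_sad_mm`, `window_mm`), `profile` (`penumbra_mm`, `flatness`,
#' `detune_level`), `of_table` (list of `[diameter_mm, of]` pairs, plus an
#' `of_table_synthetic` flag) and an optional `simulation` block mapping to
#' [sim_config()] fields.
#'
#' @param path YAML file path.
#' @return `read_beam_config`: a list with elements `chamber`, `model`,
#'   `of_table` and (if present) `sim`; `write_beam_config`: `path`
#'   invisibly.
#' @export
read_beam_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ch <- cfg$chamber
  chamber <- chamber_spec(
    active_diameter_mm = ch$active_diameter_mm %||% 81.6,
    plane_sad_mm = ch$plane_sad_mm %||% 791,
    window_mm = ch$window_mm %||% 3.47)
  pr <- cfg$profile
  model <- beam_profile(penumbra_mm = pr$penumbra_mm %||% 3,
                        flatness = pr$flatness %||% 0,
                        detune_level = pr$detune_level %||% 0)
  if (is.null(cfg$of_table)) stop("config lacks `of_table`", call. = FALSE)
  pairs <- do.call(rbind, lapply(cfg$of_table, unlist))
  table <- of_table(pairs[, 1L], pairs[, 2L],
                    synthetic = isTRUE(cfg$of_table_synthetic))
  sim <- NULL
  if (!is.null(cfg$simulation)) {
    sim <- do.call(sim_config, cfg$simulation)
  }
  list(chamber = chamber, model = model, of_table = table, sim = sim)
}

#' @rdname read_beam_config
#' @param config A list as returned by [read_beam_config()].
#' @export
write_beam_config <- function(config, path) {
  out <- list(
    chamber = list(active_diameter_mm = config$chamber$active_diameter_mm,
                   plane_sad_mm = config$chamber$plane_sad_mm,
                   window_mm = config$chamber$window_mm),
    profile = list(penumbra_mm = config$model$penumbra_mm,
                   flatness = config$model$flatness,
                   detune_level = config$model$detune_level),
    of_table_synthetic = isTRUE(attr(config$of_table, "synthetic")),
    of_table = lapply(seq_len(nrow(config$of_table)), function(i) {
      list(config$of_table$diameter_mm[i], config$of_table$of[i])
    }))
  if (!is.null(config$sim)) {
    out$simulation <- unclass(config$sim)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
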