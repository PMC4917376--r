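test_that("percentage deviation from baseline follows the ratio contract", {
  expect_equal(delta(0.25, 0.25), 0)
  expect_equal(delta(1.0363 * 0.007, 0.007), 3.63, tolerance = 1e-9)
  expect_equal(delta(0.5, 1), -50)
  expect_error(delta(1, 0), "positive")
  # misalignment and beam-change deviations share the contract
  expect_equal(misalign_error(1.0126, 1), 1.26, tolerance = 1e-9)
  expect_equal(misalign_error(1.0010, 1), 0.10, tolerance = 1e-9)
  expect_equal(beamchange_error(1, 1), 0)
  expect_equal(beamchange_error(1.0002, 1), 0.02, tolerance = 1e-9)
})

test_that("percent <-> mm conversion reproduces the published equivalents", {
  expect_equal(round(delta_to_mm(3.63, 5), 3), 0.090)
  expect_equal(round(delta_to_mm(0.63, 60), 3), 0.189)
  expect_equal(round(delta_to_mm(-0.82, 20), 3), -0.082)
  expect_equal(delta_to_mm(0, 25), 0)
  expect_equal(round(mm_to_delta(0.1, 7.5), 1), 2.7)
  expect_lt(abs(mm_to_delta(0.1, 60) - 0.34), 0.01)
  expect_error(delta_to_mm(-100, 5), "-100")
  expect_error(mm_to_delta(-6, 5), "positive")
})

test_that("percent <-> mm conversions are exact inverses", {
  for (d in c(5, 7.5, 20, 60)) {
    for (dl in c(-50, -5, -0.5, 0, 0.5, 5, 50, 100)) {
      expect_equal(mm_to_delta(delta_to_mm(dl, d), d), dl,
                   tolerance = 1e-12)
    }
    for (dd in c(-0.5, -0.2, 0, 0.2, 0.5)) {
      expect_equal(delta_to_mm(mm_to_delta(dd, d), d), dd,
                   tolerance = 1e-12)
    }
  }
})

test_that("baseline records demand positive, area-monotone quotients", {
  expect_error(baseline_record(c(5, 10), c(0.02, 0.01)), "increase")
  expect_error(baseline_record(c(5, 10), c(-0.1, 0.1)), "positive")
  bl <- model_baseline(sigmoid_profile, default_of_table(), chamber_default)
  expect_true(all(diff(bl$theta_baseline) > 0))
  expect_equal(bl$theta_baseline[12], 1, tolerance = 1e-9)
})

test_that("measured limits equal the closed form under pure area scaling", {
  bl <- model_baseline(step_profile, flat_of, chamber_default)
  pert <- function(dd) {
    th <- vapply(bl$aperture_mm, function(d) {
      theta(dap_radial(step_profile, d + dd, 1, chamber_default),
            dap_radial(step_profile, 60, 1, chamber_default))
    }, numeric(1))
    data.frame(aperture_mm = bl$aperture_mm, theta = th)
  }
  lim <- measured_limits(pert(+0.2), pert(-0.2), bl)
  expect_equal(lim$delta_plus, mm_to_delta(0.2, bl$aperture_mm),
               tolerance = 1e-9)
  expect_equal(lim$delta_minus, mm_to_delta(-0.2, bl$aperture_mm),
               tolerance = 1e-9)
  expect_equal(round(lim$delta_plus[bl$aperture_mm == 30], 2), 1.34)
  expect_identical(attr(lim, "source"), "measured")
  # unperturbed input would give zero limits, which the container rejects
  expect_error(measured_limits(pert(0), pert(0), bl), "delta_plus")
  # a missing aperture is a validation error
  expect_error(measured_limits(pert(0.2)[-1, ], pert(-0.2), bl), "missing")
})

test_that("power-law characterization fit recovers exponents", {
  d <- clinical_diameters()
  # exact quadratic data
  fit <- fit_dap_power_law(d, d^2)
  expect_equal(fit$c, 2, tolerance = 1e-9)
  expect_equal(fit$b, 1, tolerance = 1e-9)
  # the three printed DAP means give an exponent near the published 12-point
  # fit
  fit3 <- fit_dap_power_law(c(7.5, 30, 60), c(2.41, 35.88, 136.33))
  expect_equal(fit3$c, 1.9417, tolerance = 1e-4)
  expect_lt(abs(fit3$c / 1.935 - 1), 0.01)
  # scale equivariance: b scales, c does not
  fitk <- fit_dap_power_law(c(7.5, 30, 60), 3.7 * c(2.41, 35.88, 136.33))
  expect_equal(fitk$c, fit3$c, tolerance = 1e-12)
  expect_equal(fitk$b, 3.7 * fit3$b, tolerance = 1e-9)
  # nonlinear-least-squares option agrees with the log-space route
  dap_noisy <- 0.05 * d^1.9 * (1 + 0.01 * sin(seq_along(d)))
  fit_nls <- fit_dap_power_law(d, dap_noisy, log_space = FALSE)
  expect_equal(fit_nls$c, 1.9, tolerance = 0.01)
  expect_equal(fit_nls$c, fit_dap_power_law(d, dap_noisy)$c, tolerance = 0.01)
  expect_error(fit_dap_power_law(c(5, 10), c(1, 2)), "3")
})

test_that("through-origin linear fit of theta vs area", {
  # ideal model: theta = area / area(60 mm), so the slope is 1/(pi * 3^2 cm^2)
  d <- clinical_diameters()
  area <- pi * (d / 20)^2  # cm^2
  th <- (d / 60)^2
  expect_equal(fit_theta_linear(area, th), 1 / (pi * 9), tolerance = 1e-12)
  # printed triple is close to the published 12-point slope
  b <- fit_theta_linear(c(1.77, 28.27, 113.1), c(0.0168, 0.2503, 0.9509))
  expect_equal(b, 0.008434, tolerance = 1e-4)
  expect_lt(abs(b / 0.00846 - 1), 0.01)
  # single point degenerates to y/x
  expect_equal(fit_theta_linear(4, 0.02), 0.005)
  expect_error(fit_theta_linear(0, 0), "zero")
})

test_that("error budget combines components in quadrature", {
  eb <- error_budget(0.04, 0.04, 0, 0)
  expect_equal(eb$quadrature, sqrt(2 * 0.04^2), tolerance = 1e-12)
  expect_equal(error_budget(0.07, 0, 0, 0)$quadrature, 0.07)
  eb3 <- error_budget(0.04, 0.04, 0.10, 0)
  expect_equal(eb3$quadrature, sqrt(0.04^2 + 0.04^2 + 0.10^2),
               tolerance = 1e-12)
  expect_equal(eb3$envelope, 0.2)
  # permutation invariance and the triangle property
  comp <- c(0.04, 0.1, 0.02, 0.07)
  perms <- list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3), c(3, 1, 4, 2))
  q <- vapply(perms, function(p) {
    error_budget(comp[p[1]], comp[p[2]], comp[p[3]], comp[p[4]])$quadrature
  }, numeric(1))
  expect_true(all(abs(q - q[1]) < 1e-15))
  expect_gte(q[1], max(comp))
  expect_lte(q[1], sum(comp))
  expect_error(error_budget(-0.1, 0, 0, 0), ">= 0")
})

test_that("reproducibility summary recovers injected reading noise", {
  m <- step_profile
  tab <- flat_of
  # identical readings -> all zero SDs
  quiet <- simulate_longterm(m, tab, chamber_default, quiet_config(seed = 4),
                             n_sessions = 2)
  rs0 <- reproducibility_summary(quiet)
  expect_true(all(rs0$sd_median_pct == 0))
  # two sessions with known per-session SDs: median is their mean and the
  # quartiles bracket it
  s1 <- quiet[[1]]
  s2 <- quiet[[2]]
  base <- s1$reading_nC[1]
  s1$reading_nC <- rep(c(base * 0.99, base * 1.01),
                       length.out = nrow(s1))  # per-session SD a
  s2$reading_nC <- rep(c(base * 0.98, base * 1.02),
                       length.out = nrow(s2))  # per-session SD b > a
  rs2 <- reproducibility_summary(list(s1, s2))
  one <- rs2[rs2$collimator == "iris" & rs2$aperture_mm == 5, ]
  expect_equal(one$sd_median_pct,
               mean(c(sd(s1$reading_nC[1:5]) / mean(s1$reading_nC[1:5]),
                      sd(s2$reading_nC[1:5]) / mean(s2$reading_nC[1:5]))) * 100,
               tolerance = 1e-9)
  expect_lte(one$sd_q1_pct, one$sd_median_pct)
  expect_gte(one$sd_q3_pct, one$sd_median_pct)
  # injected reading SD of 0.5% is recovered across 31 sessions x 5 repeats;
  # the sample SD of 5 repeats is biased, so compare to the theoretical
  # median of a chi-distributed sample SD
  noisy <- simulate_longterm(m, tab, chamber_default,
                             sim_config(seed = 11, output_drift_sd = 0.5,
                                        mu_delivery_sd = 0,
                                        aperture_jitter_sd = 0),
                             n_sessions = 31)
  rs <- reproducibility_summary(noisy)
  expected_median <- 0.5 * sqrt(qchisq(0.5, df = 4) / 4)
  got <- rs$sd_median_pct[rs$collimator == "fixed"]
  se <- 1.25 * 0.5 / sqrt(2 * 4) / sqrt(31)
  expect_lt(abs(got - expected_median), 3 * se)
  # mm equivalents are consistent with the percent values
  expect_equal(rs$sd_median_mm,
               delta_to_mm(rs$sd_median_pct, rs$aperture_mm))
  expect_error(reproducibility_summary(quiet[1]), "2 sessions")
})

test_that("stability summary measures between-session quotient spread", {
  m <- step_profile
  quiet <- simulate_longterm(m, flat_of, chamber_default, quiet_config(seed = 5),
                             n_sessions = 3)
  st0 <- stability_summary(quiet)
  expect_true(all(st0$theta_sd_pct == 0))
  expect_true(all(abs(st0$trend_slope) < 1e-15))
  # sessions with alternating +/-1% quotient jitter in the numerator
  jit <- c(-1, 1)
  sessions <- lapply(1:10, function(i) {
    s <- quiet[[1]]
    s$session_id <- sprintf("J%02d", i)
    num <- s$collimator == "iris"
    s$reading_nC[num] <- s$reading_nC[num] * (1 + jit[(i %% 2) + 1] / 100)
    s
  })
  st <- stability_summary(sessions)
  # balanced +/-1% jitter: relative SD equals the SD of the jitter values
  expect_equal(st$theta_sd_pct[st$aperture_mm == 5], sd(rep(jit, 5)),
               tolerance = 1e-6)
  # a deliberate linear drift is picked up by the trend statistic
  drifted <- lapply(1:12, function(i) {
    s <- quiet[[1]]
    s$session_id <- sprintf("D%02d", i)
    num <- s$collimator == "iris"
    s$reading_nC[num] <- s$reading_nC[num] *
      (1 + 0.002 * i + 1e-5 * sin(i))
    s
  })
  std <- stability_summary(drifted)
  row <- std[std$aperture_mm == 30, ]
  expect_gt(row$trend_slope / row$trend_se, 3)
})

test_that("QA evaluation round-trips, flags and converts consistently", {
  m <- sigmoid_profile
  tab <- default_of_table()
  bl <- model_baseline(m, tab, chamber_default)
  lim <- calculated_limits(m, tab, chamber = chamber_default)
  # noiseless session regenerated from the model: all deviations vanish
  s0 <- simulate_session(m, tab, chamber_default, quiet_config(seed = 2))
  r0 <- evaluate_qa(s0, bl, lim)
  expect_true(r0$pass)
  expect_lt(max(abs(r0$table$delta_pct)), 1e-10)
  # delta equals delta(theta, baseline) with no hidden recomputation
  expect_equal(r0$table$delta_pct,
               delta(r0$table$theta, r0$table$theta_baseline))
  expect_equal(r0$table$delta_mm,
               delta_to_mm(r0$table$delta_pct, r0$table$aperture_mm),
               tolerance = 1e-9)
  # the published worst case sits well inside measured-style +/-10% limits
  wide <- tolerance_limits(bl$aperture_mm, rep(10, 12), rep(-9.51, 12),
                           source = "measured")
  s363 <- s0
  num <- s363$collimator == "iris" & s363$aperture_mm == 5
  s363$reading_nC[num] <- s363$reading_nC[num] * 1.0363
  r363 <- evaluate_qa(s363, bl, wide)
  expect_equal(r363$table$delta_pct[1], 3.63, tolerance = 1e-6)
  expect_true(r363$table$pass[1])
  # a session missing an aperture fails that aperture with a reason
  smiss <- s0[!(s0$collimator == "iris" & s0$aperture_mm == 25), ]
  rmiss <- evaluate_qa(smiss, bl, lim)
  row <- rmiss$table[rmiss$table$aperture_mm == 25, ]
  expect_false(row$pass)
  expect_match(row$reason, "missing")
  expect_false(rmiss$pass)
  # missing fixed reference is an error
  snoref <- s0[s0$collimator != "fixed", ]
  expect_error(evaluate_qa(snoref, bl, lim), "reference")
})

test_that("a boundary deviation counts as a pass (inclusive tie rule)", {
  bl <- baseline_record(c(5, 10), c(0.01, 0.04))
  quiet <- simulate_session(step_profile, flat_of, chamber_default,
                            quiet_config(seed = 3))
  # craft a session whose 5 mm deviation is about +8.16% (the +0.2 mm limit)
  s <- quiet
  ref <- mean(s$reading_nC[s$collimator == "fixed"])
  i5 <- s$collimator == "iris" & s$aperture_mm == 5
  s$reading_nC[i5] <- 0.01 * (1 + 8.16 / 100) * ref
  i10 <- s$collimator == "iris" & s$aperture_mm == 10
  s$reading_nC[i10] <- 0.04 * ref
  s <- s[i5 | i10 | s$collimator == "fixed", ]
  wide <- tolerance_limits(c(5, 10), c(30, 30), c(-30, -30), "measured")
  dl5 <- evaluate_qa(s, bl, wide)$table$delta_pct[1]
  expect_equal(dl5, 8.16, tolerance = 1e-9)
  # limits set to the exact computed deviation: the tie passes
  lim <- tolerance_limits(c(5, 10), c(dl5, 4.04), c(-7.84, -3.96),
                          source = "measured")
  r <- evaluate_qa(s, bl, lim)
  expect_equal(r$table$delta_pct[1], dl5)
  expect_true(r$table$pass[1])
  # just beyond the limit fails
  lim2 <- tolerance_limits(c(5, 10), c(dl5 - 1e-9, 4.04), c(-7.84, -3.96),
                           source = "measured")
  expect_false(evaluate_qa(s, bl, lim2)$table$pass[1])
})

test_that("simulated aperture offsets are recovered as mean deviations", {
  # constant OF isolates pure area scaling, so the mean deviation at a true
  # offset x mm must approach mm_to_delta(x, d)
  m <- step_profile
  bl <- model_baseline(m, flat_of, chamber_default)
  lim <- tolerance_limits(bl$aperture_mm, rep(30, 12), rep(-30, 12),
                          source = "measured")
  for (x in c(-0.2, 0, 0.2)) {
    cfg <- sim_config(seed = 20 + round(10 * x), aperture_offsets = x)
    sessions <- simulate_longterm(m, flat_of, chamber_default, cfg,
                                  n_sessions = 31)
    deltas <- sapply(sessions, function(s) {
      evaluate_qa(s, bl, lim)$table$delta_pct
    })
    for (d in c(5, 30, 60)) {
      i <- which(bl$aperture_mm == d)
      got <- mean(deltas[i, ])
      se <- sd(deltas[i, ]) / sqrt(ncol(deltas))
      expect_lt(abs(got - mm_to_delta(x, d)), 3 * se + 1e-6)
    }
  }
})
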