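test_that("wet/dry classification respects the threshold", {
  expect_equal(classify_wet_dry(c(0, 0.05, 0.3), 0.1), c(0L, 0L, 1L))
  expect_equal(classify_wet_dry(c(0, 0.01, 2), 0), c(1L, 1L, 1L))
  expect_equal(classify_wet_dry(rep(0, 4), 0.1), rep(0L, 4))
  expect_error(classify_wet_dry(c(-1, 0)), "negative")
})

test_that("seasons follow meteorological months", {
  expect_equal(as.character(assign_season(15)), "DJF")
  expect_equal(as.character(assign_season(100)), "MAM")
  expect_equal(as.character(assign_season(200)), "JJA")
  expect_equal(as.character(assign_season(290)), "SON")
  expect_equal(as.character(assign_season(350)), "DJF")
})

test_that("per-DOY bias ratios average the obs/est ratio across years", {
  doy <- rep(1:5, 2)
  obs <- rep(10, 10)
  tab <- doy_bias_ratios(obs, obs, doy)
  expect_equal(tab$mean_ratio[1:5], rep(1, 5))
  expect_equal(tab$count[1:5], rep(2L, 5))
  expect_true(all(is.na(tab$mean_ratio[6:366])))
  tab2 <- doy_bias_ratios(obs, obs / 2, doy)
  expect_equal(tab2$mean_ratio[1:5], rep(2, 5))
  # nonpositive estimates are excluded and counted
  est <- c(-1, rep(10, 9))
  tab3 <- doy_bias_ratios(obs, est, doy)
  expect_equal(attr(tab3, "n_nonpositive"), 1L)
  expect_equal(tab3$count[1], 1L)
})

test_that("stage-2 Fourier fit recovers an orthogonal-basis pattern", {
  doy <- 1:365
  tab <- doy_bias_ratios(rep(1, 365), rep(1, 365), doy)
  expect_equal(unname(fit_fs(tab, 2)), rep(0, 4), tolerance = 1e-12)
  # ratios 1 + 0.1 cos(2 pi i / 365): d = 0.1, the rest ~0
  obs <- 1 + 0.1 * cos(2 * pi * doy / 365)
  tab <- doy_bias_ratios(obs, rep(1, 365), doy)
  fs <- fit_fs(tab, 2)
  # brute-force regression oracle
  x <- 2 * pi * doy / 365
  oracle <- coef(lm((obs - 1) ~ 0 + cos(x) + sin(x) + cos(2 * x) +
                      sin(2 * x)))
  expect_equal(unname(fs), unname(oracle), tolerance = 1e-10)
  expect_equal(unname(fs["d"]), 0.1, tolerance = 1e-8)
  expect_lt(max(abs(fs[c("e", "f", "g")])), 1e-8)
})

test_that("a first-order series cannot express a 4-pi harmonic", {
  doy <- 1:365
  obs <- 1 + 0.15 * cos(4 * pi * doy / 365)
  tab <- doy_bias_ratios(obs, rep(1, 365), doy)
  fs1 <- fit_fs(tab, 1)
  fs2 <- fit_fs(tab, 2)
  resid1 <- obs - fs_series(fs1, doy)
  resid2 <- obs - fs_series(fs2, doy)
  expect_gt(sd(resid1), 10 * sd(resid2))
  expect_equal(unname(fs2["f"]), 0.15, tolerance = 1e-8)
})

test_that("stage-1 recovers noise-free generating parameters", {
  tp <- parameter_set(0.73, list(all = c(f = 0.45, g = 0.12, n = 2.285)),
                      q = 0.18)
  cfg <- synthetic_config(n_years = 3, true_params = tp, rs_noise_sd = 0,
                          spec = "1-2-1-4", seed = 21)
  sim <- generate_weather(cfg)
  fit <- fit_stage_one(sim$ws, "1-2-1-4", sim$metadata)
  got <- fit$params
  expect_equal(got$tau_coeffs[1], 0.73, tolerance = 1e-3)
  expect_equal(unname(got$fcd_groups$all["f"]), 0.45, tolerance = 1e-3)
  expect_equal(unname(got$fcd_groups$all["g"]), 0.12, tolerance = 1e-3)
  expect_equal(got$q, 0.18, tolerance = 1e-3)
  expect_true(fit$diagnostics$converged)
})

test_that("frozen parameters pass through the fit unchanged", {
  sim <- make_sim(n_years = 2, seed = 8)
  spec <- parse_variant("1-2-1-4")
  spec$frozen <- c("f", "g")
  fit <- fit_stage_one(sim$ws, spec, sim$metadata,
                       frozen_values = c(f = 0.476, g = 0.106))
  expect_identical(unname(fit$params$fcd_groups$all["f"]), 0.476)
  expect_identical(unname(fit$params$fcd_groups$all["g"]), 0.106)
  expect_error(fit_stage_one(sim$ws, spec, sim$metadata),
               "frozen")
})

test_that("calibration requires observed radiation and enough days", {
  sim <- make_sim(n_years = 2, seed = 8)
  ws <- sim$ws
  ws$rs_obs <- NA_real_
  expect_error(fit_stage_one(ws, "1-2-1-4", sim$metadata), "usable days")
  short <- sim$ws[1:100, ]
  class(short) <- class(sim$ws)
  expect_error(fit_stage_one(short, "1-2-1-4", sim$metadata), "usable days")
})

test_that("without an Fs term, calibrate is exactly the stage-1 fit", {
  sim <- make_sim(n_years = 2, seed = 13)
  res <- calibrate(sim$ws, "1-3-0", sim$metadata)
  fit <- fit_stage_one(sim$ws, "1-3-0", sim$metadata)
  expect_equal(res$params$tau_coeffs, fit$params$tau_coeffs)
  expect_equal(res$params$fcd_groups, fit$params$fcd_groups)
  expect_length(res$params$fs_coeffs, 0)
  expect_equal(unclass(res$stage1_indices), unclass(res$final_indices))
})

test_that("calibration is deterministic for a fixed seed and config", {
  sim <- make_sim(n_years = 2, seed = 17)
  a <- calibrate(sim$ws, "1-2-1-4", sim$metadata)
  b <- calibrate(sim$ws, "1-2-1-4", sim$metadata)
  expect_identical(a$params, b$params)
  expect_identical(unclass(a$final_indices), unclass(b$final_indices))
})

test_that("double-step fit removes an injected seasonal bias", {
  cfg <- synthetic_config(n_years = 10, seed = 19,
                          bias_coeffs = c(0, 0.15))
  res <- recovery_experiment(cfg, spec = "1-2-1-4")
  expect_lt(res$final_pi_doy, res$stage1_pi_doy / 2)
  expect_equal(unname(res$fitted$params$fs_coeffs["e"]), 0.15,
               tolerance = 0.15)
})

test_that("wet/dry split calibration fits separate curve groups", {
  tp <- parameter_set(0.73, list(dry = c(f = 0.35, g = 0.10, n = 2.285),
                                 wet = c(f = 0.55, g = 0.14, n = 2.285)))
  cfg <- synthetic_config(n_years = 4, true_params = tp, rs_noise_sd = 0,
                          spec = "1-22-0", seed = 23)
  sim <- generate_weather(cfg)
  fit <- fit_stage_one(sim$ws, "1-22-0", sim$metadata)
  expect_equal(unname(fit$params$fcd_groups$dry["f"]), 0.35,
               tolerance = 0.02)
  expect_equal(unname(fit$params$fcd_groups$wet["f"]), 0.55,
               tolerance = 0.02)
})

test_that("regional parameters reproduce the published arithmetic", {
  md <- site_metadata(latitude = 40, dt_avg = 12)
  expect_equal(regional_tau(12), 0.74672)
  ps <- regional_parameters(md)
  expect_equal(ps$tau_coeffs[1], 0.74672)
  expect_equal(unname(ps$fcd_groups$all[c("f", "g", "n")]),
               c(0.476, 0.106, 2.285))
  expect_equal(ps$q, 2.25)
  expect_equal(unname(ps$fs_coeffs),
               c(-0.259, -0.00377 * 12 + 0.0312, -0.00341 * 12 + 0.0597,
                 -0.00076 * 12 + 0.0320))
  # the alternative regression for the last coefficient
  ps2 <- regional_parameters(md, use_alt_g = TRUE)
  expect_equal(unname(ps2$fs_coeffs["g"]), -0.0036 * 12 + 0.0755)
  expect_error(regional_parameters(site_metadata(40)), "dt_avg")
})

test_that("rule building separates stable and covariate-driven parameters", {
  base <- regional_parameters(site_metadata(40, dt_avg = 11))
  mk <- function(dt, lat) {
    p <- regional_parameters(site_metadata(lat, dt_avg = dt))
    list(metadata = site_metadata(lat, altitude = 200, t_avg = 12,
                                  dt_avg = dt, p_annual = 800),
         params = p)
  }
  # latitudes deliberately not collinear with dt_avg
  sites <- list(mk(9, 42), mk(11, 38), mk(13, 44), mk(15, 40))
  rules <- build_regional_rules(sites, cv_threshold = 0.2)
  # a, b, c, d identical across sites: mean rules
  for (p in c("a", "b", "c", "d")) {
    expect_equal(rules[[p]]$type, "mean")
  }
  # e is an exact linear function of dt_avg: regression recovered, |r| = 1
  expect_equal(rules$e$type, "linear")
  expect_equal(rules$e$covariate, "dt_avg")
  expect_equal(rules$e$slope, -0.00377, tolerance = 1e-10)
  expect_equal(abs(rules$e$r), 1, tolerance = 1e-10)
  # an infinite threshold forces mean rules everywhere
  rules_inf <- build_regional_rules(sites, cv_threshold = Inf)
  expect_true(all(vapply(rules_inf[names(rules_inf) != "g_alt"],
                         function(r) r$type, "") == "mean"))
  expect_error(build_regional_rules(sites[1:2]), "3")
  # identical parameters across sites: all mean rules
  same <- list(mk(11, 38), mk(11, 40), mk(11, 42))
  rules_same <- build_regional_rules(same, cv_threshold = 0.2)
  expect_true(all(vapply(rules_same[setdiff(names(rules_same), "g_alt")],
                         function(r) r$type, "") == "mean"))
  # rules round-trip through regional_parameters
  ps <- regional_parameters(site_metadata(41, dt_avg = 12), rules = rules)
  expect_equal(unname(ps$fs_coeffs["e"]), -0.00377 * 12 + 0.0312,
               tolerance = 1e-8)
})
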