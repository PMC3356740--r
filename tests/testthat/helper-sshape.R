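# tiny deterministic series builders used across the tests

# n consecutive days of one non-leap year with given fields
make_series <- function(tmax, tmin, prcp = 0, rs_obs = NULL,
                        year = 2001L, doy_start = 1L) {
  n <- length(tmax)
  weather_series(year = year, doy = doy_start + seq_len(n) - 1L,
                 tmax = tmax, tmin = rep_len(tmin, n),
                 prcp = rep_len(prcp, n), rs_obs = rs_obs)
}

# a full synthetic station, small by default
make_sim <- function(n_years = 3, seed = 42, ...) {
  generate_weather(synthetic_config(n_years = n_years, seed = seed, ...))
}

test_metadata <- function(latitude = 40, dt_avg = 11)
  site_metadata(latitude = latitude, dt_avg = dt_avg)
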