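Package: sshape
Title: S-Shape Daily Global Solar Radiation Estimation from Temperature and Precipitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates daily global solar radiation from routinely measured
    weather variables (maximum and minimum temperature, precipitation) for
    crop-model and water-balance applications. Implements the S-shape model
    family, in which the fraction of clear day is an S-shaped (van Genuchten
    or Brutsaert type) function of the diurnal temperature range, together
    with a double-step site-specific calibration (nonlinear stage-1 fit plus
    a Fourier-series correction of the per-day-of-year bias ratio), four
    temperature and precipitation based reference models (Donatelli-Campbell,
    Donatelli-Bellocchi, Hunt-Kuchar-Swanton, Liu-Scott), accuracy,
    correlation and pattern error indices including the day-of-year and
    minimum-temperature pattern indices, a metadata-only regionalization that
    needs no site radiation record, and a seeded stochastic daily weather
    generator for end-to-end testing without station data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
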