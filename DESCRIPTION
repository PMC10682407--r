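Package: thermidx
Title: Rational Thermal Comfort Indices and Mean Radiant Temperature for
    Human Biometeorology
Version: 0.1.0
Authors@R:
    person("Thermidx", "Developers", email = "thermidx@posteo.net",
           role = c("aut", "cre"))
Description: Computes the rational human thermal indices PMV (predicted
    mean vote), SET* (outdoor standard effective temperature), PET
    (physiologically equivalent temperature), mPET (modified PET with a
    multi-node physiology and adaptive clothing) and UTCI (universal
    thermal climate index, operational polynomial) from point
    meteorological records.  Includes auxiliary conversions between
    vapour pressure and relative humidity, a power-law wind height
    reduction to the biometeorological reference height of 1.1 m, and a
    mean radiant temperature model that assembles short- and long-wave
    radiation fluxes from site coordinates, time, cloud cover and
    optional measured global radiation.  A batch interface reads station
    CSV time series, and a deterministic synthetic-weather generator
    provides test fixtures for mid-latitude diurnal series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
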