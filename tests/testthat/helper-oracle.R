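# Independent oracles used across the suite.

# Solar-position oracle: Spencer Fourier-series declination and
# equation of time (a published algorithm independent of the package's
# almanac ephemeris).  Returns the zenith angle in degrees.
oracle_zenith <- function(lat, lon, doy, hour, tz) {
  g <- 2 * pi * (doy - 1 + (hour - 12) / 24) / 365
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  tst <- hour * 60 + eqtime + 4 * (lon - 15 * tz)
  ha <- (tst / 4 - 180) * pi / 180
  latr <- lat * pi / 180
  cosz <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)
  acos(pmin(1, pmax(-1, cosz))) * 180 / pi
}

# standard clothing insulation of the SET* standard environment for a
# given metabolic rate in met units
standard_clo <- function(met_units) 1.52 / (met_units + 0.6944) - 0.1835

# metabolic rate of a subject in met units (same definition the
# engines use, recomputed here for test readability)
met_units_of <- function(subj) {
  metabolic_rate(subj) / dubois_area(subj) / 58.2
}

ref_record <- function(Ta) {
  suppressWarnings(meteo_record(Ta = Ta, VP = 12, v = 0.1, Tmrt = Ta))
}
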