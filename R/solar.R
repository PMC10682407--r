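# Solar geometry: site/time container and sun position from an
# Astronomical-Almanac-style low-precision ephemeris.

.DEG <- pi / 180

# Inputs carry day-of-year but no calendar year; solar geometry is
# evaluated in a fixed non-leap reference year so results are
# reproducible (documented in the vignette).
.SOLAR_REF_JD0 <- 2459945.5  # 2023-01-01 00:00 UT

#' Construct a site/time descriptor
#'
#' Geographic position plus calendar/clock fields that drive solar
#' geometry.  When `day_of_year`, `hour_of_day` or `timezone_offset` are
#' omitted, the current system local time is used ("now" default); the
#' resolved values are stored in the returned object so the call is
#' reproducible.
#'
#' @param longitude Degrees, positive east, in \[-180, 180\].
#' @param latitude Degrees, positive north, in \[-90, 90\].
#' @param sea_level_height Elevation above sea level, m.
#' @param day_of_year 1-366.
#' @param hour_of_day Local clock time in floating hours, \[0, 24).
#' @param timezone_offset Hours ahead of UTC.
#' @return An object of class `site_time`.
#' @export
site_time <- function(longitude, latitude, sea_level_height = 0,
                      day_of_year = NULL, hour_of_day = NULL,
                      timezone_offset = NULL) {
  if (abs(longitude) > 180) stop("longitude must lie in [-180, 180]")
  if (abs(latitude) > 90) stop("latitude must lie in [-90, 90]")
  if (is.null(day_of_year) || is.null(hour_of_day) ||
      is.null(timezone_offset)) {
    now <- as.POSIXlt(Sys.time())
    if (is.null(day_of_year)) day_of_year <- now$yday + 1
    if (is.null(hour_of_day)) {
      hour_of_day <- now$hour + now$min / 60 + now$sec / 3600
    }
    if (is.null(timezone_offset)) {
      off <- now$gmtoff
      timezone_offset <- if (is.null(off) || is.na(off)) 0 else off / 3600
    }
    message(sprintf(
      "site_time: 'now' default resolved to day_of_year=%d hour_of_day=%.3f timezone_offset=%.2f",
      day_of_year, hour_of_day, timezone_offset))
  }
  if (day_of_year < 1 || day_of_year > 366) stop("day_of_year must be 1-366")
  if (hour_of_day < 0 || hour_of_day >= 24) {
    stop("hour_of_day must lie in [0, 24)")
  }
  structure(list(longitude = longitude, latitude = latitude,
                 sea_level_height = sea_level_height,
                 day_of_year = day_of_year, hour_of_day = hour_of_day,
                 timezone_offset = timezone_offset),
            class = "site_time")
}

#' Solar position
#'
#' Zenith and azimuth of the sun plus the seasonal earth-sun distance
#' factor \eqn{(r_0/r)^2}, from the low-precision solar ephemeris of the
#' Astronomical Almanac (mean longitude/anomaly, ecliptic longitude,
#' right ascension/declination, sidereal hour angle), accurate to about
#' 0.01 degrees over recent decades.
#'
#' @param site A [site_time()].
#' @return List with `zenith` (deg, 0-180), `azimuth` (deg from north,
#'   clockwise, \[0, 360)) and `earth_sun_factor` (dimensionless).
#' @export
solar_position <- function(site) {
  stopifnot(inherits(site, "site_time"))
  ut <- site$hour_of_day - site$timezone_offset  # hours UT
  jd <- .SOLAR_REF_JD0 + (site$day_of_year - 1) + ut / 24
  n <- jd - 2451545.0

  mnlong <- (280.460 + 0.9856474 * n) %% 360
  mnanom <- ((357.528 + 0.9856003 * n) %% 360) * .DEG
  eclong <- ((mnlong + 1.915 * sin(mnanom) + 0.020 * sin(2 * mnanom)) %%
               360) * .DEG
  oblqec <- (23.439 - 0.0000004 * n) * .DEG

  ra <- atan2(cos(oblqec) * sin(eclong), cos(eclong))
  dec <- asin(sin(oblqec) * sin(eclong))

  gmst <- (6.697375 + 0.0657098242 * n + ut) %% 24
  lmst <- (gmst + site$longitude / 15) %% 24
  ha <- lmst * 15 * .DEG - ra
  ha <- atan2(sin(ha), cos(ha))  # wrap to (-pi, pi]

  lat <- site$latitude * .DEG
  sinel <- sin(dec) * sin(lat) + cos(dec) * cos(lat) * cos(ha)
  el <- asin(pmin(1, pmax(-1, sinel)))
  zenith <- 90 - el / .DEG

  az <- atan2(-sin(ha), cos(lat) * tan(dec) - sin(lat) * cos(ha))
  azimuth <- (az / .DEG) %% 360

  # earth-sun distance factor (r0/r)^2, Spencer Fourier fit
  g <- 2 * pi * (site$day_of_year - 1 + (site$hour_of_day - 12) / 24) / 365
  esf <- 1.000110 + 0.034221 * cos(g) + 0.001280 * sin(g) +
    0.000719 * cos(2 * g) + 0.000077 * sin(2 * g)

  list(zenith = zenith, azimuth = azimuth, earth_sun_factor = esf)
}
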