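# Mean radiant temperature model: clear-sky shortwave, cloud attenuation,
# surface/atmospheric longwave, and the flux composition on a standing
# person.  Formula dialect (Kasten air mass, Kasten-Czeplak cloud law,
# Angstrom-type sky emissivity) is frozen and documented in the vignette.

.SIGMA <- 5.67e-8      # Stefan-Boltzmann, W/(m^2 K^4)
.SOLAR_CONST <- 1367   # W/m^2
.EPS_SURF <- 0.97      # emissivity of natural surfaces
.EPS_BODY <- 0.97      # longwave emissivity of the clothed human body

#' Radiation model configuration
#'
#' Optional inputs and defaults of the Tmrt simulation.
#'
#' @param N Cloud cover, octas 0-8.
#' @param G Measured global radiation override, W/m^2, or `NULL`.
#' @param DGratio Diffuse-to-global ratio override, or `NULL` (cloud and
#'   zenith based split).
#' @param Tob Surface temperature override, degC, or `NULL` (surface
#'   energy balance estimate).
#' @param ltf Linke turbidity factor.
#' @param OmegaF Sky view factor, 0-1.
#' @param alb Albedo of the surroundings.
#' @param albhum Albedo of the human body.
#' @param RedGChk Logical: reduce a preset `G` by the obstacle (sky view)
#'   factor.
#' @param foglimit RH threshold (%) above which all shortwave is treated
#'   as diffuse.
#' @param bowen Bowen ratio (sensible/latent) of the surface.
#' @return An object of class `radiation_config`.
#' @export
radiation_config <- function(N = 0, G = NULL, DGratio = NULL, Tob = NULL,
                             ltf = 3, OmegaF = 1.0, alb = 0.3, albhum = 0.3,
                             RedGChk = FALSE, foglimit = 90, bowen = 1.0) {
  if (N < 0 || N > 8) stop("N must lie in [0, 8] octas")
  if (OmegaF < 0 || OmegaF > 1) stop("OmegaF must lie in [0, 1]")
  if (alb < 0 || alb > 1 || albhum < 0 || albhum > 1) {
    stop("albedos must lie in [0, 1]")
  }
  if (!is.null(DGratio) && (DGratio < 0 || DGratio > 1)) {
    stop("DGratio must lie in [0, 1]")
  }
  if (bowen <= 0) stop("bowen must be > 0")
  if (ltf <= 0) stop("ltf must be > 0")
  structure(list(N = N, G = G, DGratio = DGratio, Tob = Tob, ltf = ltf,
                 OmegaF = OmegaF, alb = alb, albhum = albhum,
                 RedGChk = isTRUE(RedGChk), foglimit = foglimit,
                 bowen = bowen),
            class = "radiation_config")
}

#' Clear-sky shortwave fluxes
#'
#' Direct beam from the solar constant attenuated by Beer-type
#' extinction with Kasten-Young relative air mass, Kasten Rayleigh
#' optical thickness scaled by the Linke turbidity, and an elevation
#' pressure correction exp(-z/8434 m).  Diffuse is a fixed fraction
#' (0.3) of the extinguished irradiance projected on the horizontal.
#'
#' @param zenith Solar zenith angle, deg.
#' @param earth_sun_factor Seasonal distance factor \eqn{(r_0/r)^2}.
#' @param sea_level_height Site elevation, m.
#' @param ltf Linke turbidity factor.
#' @param VP Vapour pressure, hPa.  Accepted for interface completeness;
#'   water-vapour extinction is carried by `ltf` (see vignette).
#' @return List `Imax` (beam normal), `Gmax`, `Dmax` (horizontal), all
#'   W/m^2; all zero for `zenith >= 90`.
#' @export
clear_sky_fluxes <- function(zenith, earth_sun_factor = 1,
                             sea_level_height = 0, ltf = 3, VP = 12) {
  if (zenith >= 90) {
    return(list(Imax = 0, Gmax = 0, Dmax = 0))
  }
  cosz <- cos(zenith * .DEG)
  m_rel <- 1 / (cosz + 0.50572 * (96.07995 - zenith) ^ (-1.6364))
  m <- m_rel * exp(-sea_level_height / 8434)
  delta_r <- 1 / (6.6296 + 1.7513 * m - 0.1202 * m ^ 2 +
                    0.0065 * m ^ 3 - 0.00013 * m ^ 4)
  i0 <- .SOLAR_CONST * earth_sun_factor
  trans <- exp(-0.8662 * ltf * m * delta_r)
  Imax <- i0 * trans
  Dmax <- 0.3 * (1 - trans) * i0 * cosz
  list(Imax = Imax, Gmax = Imax * cosz + Dmax, Dmax = Dmax)
}

#' Actual shortwave fluxes under cloud or a measured global radiation
#'
#' Precedence: a measured `G_override` wins (optionally reduced by the
#' sky-view factor when `RedGChk`), split into direct/diffuse by
#' `DGratio` if given, else by the cloud/zenith split of the clear-sky
#' model.  Without an override the Kasten-Czeplak cloud attenuation
#' `Gtat = Gmax (1 - 0.75 (N/8)^3.4)` applies.  When `RH >= foglimit`
#' all shortwave is treated as diffuse.
#'
#' @param clear Clear-sky triple from [clear_sky_fluxes()].
#' @param N Cloud cover, octas.
#' @param G_override Measured global radiation, W/m^2, or `NULL`.
#' @param DGratio Diffuse fraction of the override, or `NULL`.
#' @param RH Relative humidity, %.
#' @param foglimit RH threshold for full diffuse, %.
#' @param RedGChk Logical; reduce preset G by `OmegaF`.
#' @param zenith Solar zenith angle, deg.
#' @param OmegaF Sky view factor (used only with `RedGChk`).
#' @return List `Itat` (beam normal), `Gtat`, `Dtat` (horizontal), W/m^2,
#'   satisfying `Gtat = Itat cos(zenith) + Dtat`.
#' @export
actual_fluxes <- function(clear, N = 0, G_override = NULL, DGratio = NULL,
                          RH = 50, foglimit = 90, RedGChk = FALSE,
                          zenith = 0, OmegaF = 1) {
  cosz <- if (zenith < 90) cos(zenith * .DEG) else 0
  cloud8 <- N / 8
  # diffuse fraction: clear-sky share rising to 1 under full overcast
  fd0 <- if (clear$Gmax > 0) clear$Dmax / clear$Gmax else 1
  fd <- fd0 + (1 - fd0) * cloud8

  if (!is.null(G_override)) {
    if (G_override < 0) stop("G_override must be >= 0 W/m^2")
    Gtat <- G_override
    if (isTRUE(RedGChk)) Gtat <- Gtat * OmegaF
    if (clear$Gmax > 0 && Gtat > 1.2 * clear$Gmax) {
      warning(sprintf(
        "G_override (%.0f W/m^2) exceeds 1.2 x clear-sky Gmax (%.0f); value retained",
        G_override, clear$Gmax))
    }
    if (!is.null(DGratio)) fd <- DGratio
  } else {
    Gtat <- clear$Gmax * (1 - 0.75 * cloud8 ^ 3.4)
  }

  if (RH >= foglimit) fd <- 1

  Dtat <- fd * Gtat
  Itat <- if (cosz > 1e-6) (Gtat - Dtat) / cosz else 0
  if (cosz <= 1e-6) Dtat <- Gtat
  # direct beam cannot exceed the clear-sky beam; excess goes diffuse
  if (clear$Imax > 0 && Itat > clear$Imax) {
    Dtat <- Dtat + (Itat - clear$Imax) * cosz
    Itat <- clear$Imax
  }
  list(Itat = Itat, Gtat = Gtat, Dtat = Dtat)
}

#' Atmospheric and surface longwave fluxes plus surface temperature
#'
#' Clear-sky atmospheric emissivity from an Angstrom-type fit
#' `0.82 - 0.25 * 10^(-0.094 VP)` with cloud enhancement
#' `(1 + 0.22 (N/8)^2)`, capped at 1.  The surface temperature `Tob`
#' solves a linearised energy balance: absorbed shortwave
#' `(1 - alb) Gtat` plus absorbed sky longwave against surface emission
#' and turbulent loss partitioned by the Bowen ratio (at most 10 Newton
#' steps to 0.01 K).
#'
#' @param Ta Air temperature, degC.
#' @param VP Vapour pressure, hPa.
#' @param N Cloud cover, octas.
#' @param Gtat Current global radiation, W/m^2.
#' @param Itat Current beam radiation, W/m^2 (unused by the balance but
#'   part of the stage contract).
#' @param zenith Solar zenith, deg.
#' @param alb Surface albedo.
#' @param bowen Bowen ratio.
#' @param v Wind speed, m/s (turbulent exchange coefficient).
#' @param Tob_override Measured surface temperature, degC, or `NULL`.
#' @return List `A`, `Eu`, `Es` (W/m^2) and `Tob` (degC).  `Es` is the
#'   lateral longwave from surroundings at the mean of air and surface
#'   temperature.
#' @export
surface_and_longwave <- function(Ta, VP, N = 0, Gtat = 0, Itat = 0,
                                 zenith = 90, alb = 0.3, bowen = 1.0,
                                 v = 0.1, Tob_override = NULL) {
  eps_a <- min(1, (0.82 - 0.25 * 10 ^ (-0.094 * VP)) *
                 (1 + 0.22 * (N / 8) ^ 2))
  A <- eps_a * .SIGMA * (Ta + 273.15) ^ 4

  if (is.null(Tob_override)) {
    hs <- (5.9 + 4.1 * v) * (1 + 1 / bowen)
    Tob <- Ta
    for (i in seq_len(10)) {
      tk <- Tob + 273.15
      f <- (1 - alb) * Gtat + .EPS_SURF * (A - .SIGMA * tk ^ 4) -
        hs * (Tob - Ta)
      df <- -4 * .EPS_SURF * .SIGMA * tk ^ 3 - hs
      step <- f / df
      Tob <- Tob - step
      if (abs(step) < 0.01) break
    }
  } else {
    Tob <- Tob_override
  }

  Eu <- .EPS_SURF * .SIGMA * (Tob + 273.15) ^ 4
  Es <- .EPS_SURF * .SIGMA * ((Ta + Tob) / 2 + 273.15) ^ 4
  list(A = A, Eu = Eu, Es = Es, Tob = Tob)
}

# projected-area factor of a standing person as a function of solar
# altitude (deg): 0.308 cos(alt (0.998 - alt^2/50000))
.fproj_standing <- function(altitude) {
  if (altitude <= 0) return(0)
  0.308 * cos(altitude * (0.998 - altitude ^ 2 / 50000) * .DEG)
}

#' Compose the mean radiant temperature from component fluxes
#'
#' Absorbed mean flux density on a standing person:
#' shortwave `ak (fp I + 0.5 (OmegaF D + alb G))` with absorptivity
#' `ak = 1 - albhum` and projected-area factor `fp` of the standing
#' body, plus longwave weighted by angle factors `fup = 0.3` (sky,
#' scaled by `OmegaF`; the obstructed share is replaced by `L_obst`),
#' `fdown = 0.3` (ground) and `fside = 0.4` (lateral).  Inverted through
#' Stefan-Boltzmann with body emissivity 0.97, so an isothermal
#' enclosure of emissivity 0.97 returns its own temperature exactly.
#'
#' @param Itat Beam normal irradiance, W/m^2.
#' @param Dtat Diffuse horizontal irradiance, W/m^2.
#' @param Gtat Global horizontal irradiance, W/m^2.
#' @param A Atmospheric longwave, W/m^2.
#' @param Eu Longwave from the ground surface, W/m^2.
#' @param Es Longwave from the sides, W/m^2.
#' @param zenith Solar zenith, deg.
#' @param OmegaF Sky view factor.
#' @param alb Surface albedo (ground-reflected shortwave).
#' @param albhum Human body albedo.
#' @param L_obst Longwave radiance of obstacles replacing the
#'   obstructed sky share; defaults to `Es`.
#' @return Mean radiant temperature, degC.
#' @export
tmrt_compose <- function(Itat, Dtat, Gtat, A, Eu, Es, zenith,
                         OmegaF = 1, alb = 0.3, albhum = 0.3,
                         L_obst = Es) {
  if (any(c(Itat, Dtat, Gtat, A, Eu, Es) < 0)) {
    stop("all component fluxes must be >= 0")
  }
  ak <- 1 - albhum
  fp <- .fproj_standing(90 - zenith)
  sw <- ak * (fp * Itat + 0.5 * (OmegaF * Dtat + alb * Gtat))
  lw <- 0.3 * (OmegaF * A + (1 - OmegaF) * L_obst) + 0.3 * Eu + 0.4 * Es
  # longwave radiances already carry the 0.97 surface emissivity; the
  # inversion divides it back out so an isothermal enclosure returns
  # its own temperature exactly
  sstr <- sw + lw
  if (sstr < 0) stop("composed mean radiant flux is negative")
  (sstr / (.EPS_BODY * .SIGMA)) ^ 0.25 - 273.15
}

#' Simulate mean radiant temperature and its radiation budget
#'
#' Orchestrates [solar_position()], [clear_sky_fluxes()],
#' [actual_fluxes()], [surface_and_longwave()] and [tmrt_compose()].
#' Obstacles that replace the obstructed sky share (when `OmegaF < 1`)
#' are assumed to radiate at air temperature.
#'
#' @param Ta Air temperature, degC.
#' @param RH Relative humidity, % (one of `RH`/`VP` required).
#' @param VP Vapour pressure, hPa.
#' @param v Wind speed at 1.1 m, m/s.
#' @param site A [site_time()]; coordinates are mandatory.
#' @param config A [radiation_config()].
#' @return An object of class `radiation_budget`: list with `Tmrt`,
#'   `VP`, `Imax`, `Gmax`, `Dmax`, `Itat`, `Gtat`, `Dtat`, `A`, `Eu`,
#'   `Es`, `Tob` plus `zenith` and `azimuth`.
#' @examples
#' st <- site_time(121.5, 23.5, 30, day_of_year = 210, hour_of_day = 15.8,
#'                 timezone_offset = 8)
#' tmrt_calc(Ta = 20, RH = 50, v = 0.1, site = st,
#'           config = radiation_config(N = 6))
#' @export
tmrt_calc <- function(Ta, RH = NULL, VP = NULL, v = 0.1, site,
                      config = radiation_config()) {
  if (missing(site) || !inherits(site, "site_time")) {
    stop("site coordinates are required (a site_time object)")
  }
  if (is.null(RH) && is.null(VP)) stop("one of RH or VP is required")
  if (!is.null(RH) && !is.null(VP)) {
    if (abs(RH - suppressWarnings(vp_rh_exchange(Ta, VP = VP))) >= 0.01) {
      stop("VP and RH are inconsistent through the saturation curve at Ta")
    }
  }
  if (is.null(VP)) VP <- vp_rh_exchange(Ta, RH = RH)
  if (is.null(RH)) RH <- vp_rh_exchange(Ta, VP = VP)

  sp <- solar_position(site)
  clear <- clear_sky_fluxes(sp$zenith, sp$earth_sun_factor,
                            site$sea_level_height, config$ltf, VP)
  act <- actual_fluxes(clear, N = config$N, G_override = config$G,
                       DGratio = config$DGratio, RH = RH,
                       foglimit = config$foglimit,
                       RedGChk = config$RedGChk, zenith = sp$zenith,
                       OmegaF = config$OmegaF)
  lw <- surface_and_longwave(Ta, VP, N = config$N, Gtat = act$Gtat,
                             Itat = act$Itat, zenith = sp$zenith,
                             alb = config$alb, bowen = config$bowen,
                             v = v, Tob_override = config$Tob)
  l_obst <- .EPS_SURF * .SIGMA * (Ta + 273.15) ^ 4
  tmrt <- tmrt_compose(act$Itat, act$Dtat, act$Gtat, lw$A, lw$Eu, lw$Es,
                       zenith = sp$zenith, OmegaF = config$OmegaF,
                       alb = config$alb, albhum = config$albhum,
                       L_obst = l_obst)
  structure(list(Tmrt = tmrt, VP = VP, Imax = clear$Imax,
                 Gmax = clear$Gmax, Dmax = clear$Dmax, Itat = act$Itat,
                 Gtat = act$Gtat, Dtat = act$Dtat, A = lw$A, Eu = lw$Eu,
                 Es = lw$Es, Tob = lw$Tob, zenith = sp$zenith,
                 azimuth = sp$azimuth),
            class = "radiation_budget")
}

#' @export
print.radiation_budget <- function(x, ...) {
  cat(sprintf("radiation_budget: Tmrt=%.2f degC (zenith=%.1f deg)\n",
              x$Tmrt, x$zenith))
  cat(sprintf("  shortwave W/m^2: Imax=%.1f Gmax=%.1f Dmax=%.1f | Itat=%.1f Gtat=%.1f Dtat=%.1f\n",
              x$Imax, x$Gmax, x$Dmax, x$Itat, x$Gtat, x$Dtat))
  cat(sprintf("  longwave  W/m^2: A=%.1f Eu=%.1f Es=%.1f | Tob=%.2f degC\n",
              x$A, x$Eu, x$Es, x$Tob))
  invisible(x)
}
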