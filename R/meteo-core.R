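# Shared meteorological primitives: saturation curve, humidity exchange,
# wind profile, and the record/subject containers used by every index engine.

# Magnus constants over liquid water (no ice branch; see vignette).
.MAGNUS_E0 <- 6.107
.MAGNUS_A <- 7.5
.MAGNUS_B <- 237.3

#' Saturation vapour pressure over water
#'
#' Magnus-form saturation curve \eqn{e_s(T_a) = 6.107 \cdot
#' 10^{7.5 T_a / (237.3 + T_a)}} in hPa.  A single liquid-water branch is
#' used for all temperatures; there is no ice branch.
#'
#' @param Ta Air temperature in degrees Celsius, within \[-60, 80\].
#' @return Saturation vapour pressure in hPa (vectorised over `Ta`).
#' @examples
#' saturation_vapor_pressure(0)   # 6.107
#' saturation_vapor_pressure(20)  # about 23.38
#' @export
saturation_vapor_pressure <- function(Ta) {
  if (!is.numeric(Ta) || any(!is.finite(Ta))) {
    stop("Ta must be finite numeric")
  }
  if (any(Ta < -60) || any(Ta > 80)) {
    stop("Ta outside supported range [-60, 80] degC")
  }
  .MAGNUS_E0 * 10 ^ (.MAGNUS_A * Ta / (.MAGNUS_B + Ta))
}

#' Exchange vapour pressure and relative humidity
#'
#' Converts between vapour pressure VP (hPa) and relative humidity RH (%)
#' through the saturation curve at `Ta`.  Exactly one of `VP`/`RH` must be
#' supplied; the missing one is returned.  Supersaturated input
#' (`VP > es(Ta)`) yields a warning and RH capped at 100 rather than an
#' error, because station archives contain such records.
#'
#' @param Ta Air temperature, degrees Celsius.
#' @param VP Vapour pressure, hPa (optional).
#' @param RH Relative humidity, percent in \[0, 100\] (optional).
#' @return The missing humidity variable (numeric, vectorised).
#' @examples
#' vp_rh_exchange(Ta = 20, RH = 50)   # about 11.69 hPa
#' vp_rh_exchange(Ta = 20, VP = 12.5) # about 53.5 %
#' @export
vp_rh_exchange <- function(Ta, VP = NULL, RH = NULL) {
  if (is.null(VP) == is.null(RH)) {
    stop("supply exactly one of VP or RH")
  }
  es <- saturation_vapor_pressure(Ta)
  if (!is.null(RH)) {
    if (any(RH < 0) || any(RH > 100)) stop("RH must lie in [0, 100] %")
    return(RH * es / 100)
  }
  if (any(VP < 0)) stop("VP must be >= 0 hPa")
  rh <- 100 * VP / es
  if (any(rh > 100)) {
    warning("VP exceeds saturation at Ta; RH capped at 100 %")
    rh <- pmin(rh, 100)
  }
  rh
}

#' Wind speed at another height (power-law profile)
#'
#' Reduces (or raises) a wind speed measured at `height` to
#' `target_height` with the power-law profile
#' \eqn{v_t = v (z_t/z)^{p}}.  The default exponent 0.12 corresponds to
#' open terrain and is shared package-wide, including the internal
#' 1.1 m to 10 m conversion used by [utci_calc()].
#'
#' @param WS Wind speed at `height`, m/s (>= 0).
#' @param height Measurement height, m (> 0).
#' @param target_height Target height, m (> 0); default 1.1 m, the
#'   biometeorological reference height.
#' @param exponent Profile exponent, dimensionless.
#' @return Wind speed at `target_height`, m/s.
#' @examples
#' wind_at_height(8.5, 60)  # about 5.26 m/s at 1.1 m
#' @export
wind_at_height <- function(WS, height, target_height = 1.1, exponent = 0.12) {
  if (any(WS < 0)) stop("WS must be >= 0")
  if (any(height <= 0) || any(target_height <= 0)) {
    stop("heights must be > 0 m")
  }
  WS * (target_height / height) ^ exponent
}

#' Construct a meteorological record
#'
#' Bundles one time-point of environmental drivers.  Both humidity
#' representations are carried: whichever of `VP`/`RH` was supplied, the
#' other is filled through [vp_rh_exchange()], so each index engine can
#' take its preferred form (PMV/PET/mPET/UTCI consume VP, SET* consumes
#' RH).  If both are supplied they must be mutually consistent.
#'
#' @param Ta Air temperature, degrees Celsius.
#' @param VP Vapour pressure, hPa (optional if `RH` given).
#' @param RH Relative humidity, % (optional if `VP` given).
#' @param v Wind speed at 1.1 m, m/s (>= 0).
#' @param Tmrt Mean radiant temperature, degrees Celsius.  Finite, not
#'   clamped: sunlit Tmrt may exceed Ta by tens of kelvin.
#' @return An object of class `meteo_record`.
#' @export
meteo_record <- function(Ta, VP = NULL, RH = NULL, v, Tmrt) {
  stopifnot(length(Ta) == 1, length(v) == 1, length(Tmrt) == 1)
  if (!is.finite(Ta) || !is.finite(v) || !is.finite(Tmrt)) {
    stop("Ta, v and Tmrt must be finite")
  }
  if (v < 0) stop("v must be >= 0 m/s")
  if (is.null(VP) && is.null(RH)) stop("one of VP or RH is required")
  if (!is.null(VP) && !is.null(RH)) {
    rh_chk <- suppressWarnings(vp_rh_exchange(Ta, VP = VP))
    if (abs(RH - rh_chk) >= 0.01) {
      stop("VP and RH are inconsistent through the saturation curve at Ta")
    }
  } else if (is.null(VP)) {
    VP <- vp_rh_exchange(Ta, RH = RH)
  } else {
    RH <- vp_rh_exchange(Ta, VP = VP)
  }
  if (VP < 0 || RH < 0 || RH > 100) stop("humidity out of physical range")
  structure(list(Ta = Ta, VP = VP, RH = RH, v = v, Tmrt = Tmrt),
            class = "meteo_record")
}

#' @export
print.meteo_record <- function(x, ...) {
  cat(sprintf(
    "meteo_record: Ta=%.2f degC  VP=%.2f hPa  RH=%.1f %%  v=%.2f m/s  Tmrt=%.2f degC\n",
    x$Ta, x$VP, x$RH, x$v, x$Tmrt))
  invisible(x)
}

#' Construct a subject profile
#'
#' Thermo-physiological and textile parameters shared by the index
#' engines.  `icl = NULL` means "use the engine's own default": 0.6 clo
#' for PMV, 0.9 clo for SET*/PET/mPET (for mPET only when
#' `auto_clo = FALSE`).
#'
#' @param icl Clothing insulation, clo, or `NULL` for the per-index
#'   default.
#' @param work Activity load above basal metabolism, W.
#' @param ht Body height, m.
#' @param mbody Body mass, kg.
#' @param age Age, years.
#' @param sex 1 = male, 2 = female.  `gender` is accepted as an alias.
#' @param pos Posture code: 1 standing, 2 sitting, 3 lying.
#' @param auto_clo Logical; mPET only.  `TRUE` selects Ta-adaptive
#'   clothing via [auto_clothing()].
#' @param gender Alias for `sex` (ignored when `sex` is given
#'   explicitly).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(icl = NULL, work = 80, ht = 1.75, mbody = 75,
                            age = 35, sex = 1, pos = 1, auto_clo = TRUE,
                            gender = NULL) {
  if (!is.null(gender) && missing(sex)) sex <- gender
  if (!is.null(icl) && (!is.finite(icl) || icl <= 0)) {
    stop("icl must be > 0 clo")
  }
  if (work < 0) stop("work must be >= 0 W")
  if (ht <= 0 || mbody <= 0 || age <= 0) {
    stop("ht, mbody and age must be > 0")
  }
  if (!sex %in% c(1, 2)) stop("sex must be 1 (male) or 2 (female)")
  if (!pos %in% c(1, 2, 3)) stop("pos must be 1 (stand), 2 (sit) or 3 (lie)")
  structure(list(icl = icl, work = work, ht = ht, mbody = mbody, age = age,
                 sex = sex, pos = pos, auto_clo = isTRUE(auto_clo)),
            class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "subject_profile: icl=%s clo  work=%g W  ht=%g m  mbody=%g kg  age=%g  sex=%d  pos=%d  auto_clo=%s\n",
    if (is.null(x$icl)) "engine default" else format(x$icl), x$work, x$ht,
    x$mbody, x$age, x$sex, x$pos, x$auto_clo))
  invisible(x)
}

#' DuBois body surface area
#'
#' \eqn{A_{Du} = 0.203\, m^{0.425}\, h^{0.725}} in square metres.
#'
#' @param subj A [subject_profile()].
#' @return Body surface area, m^2.
#' @export
dubois_area <- function(subj) {
  0.203 * subj$mbody ^ 0.425 * subj$ht ^ 0.725
}

#' Basal plus activity metabolic rate
#'
#' Basal metabolism from the Harris-Benedict-type fit used by the MEMI
#' tradition (sex-, age-, height- and mass-dependent), plus the activity
#' load `work`.  Returned as total watts for the whole body.
#'
#' @param subj A [subject_profile()].
#' @return Metabolic rate, W (whole body).
#' @export
metabolic_rate <- function(subj) {
  ht_cm <- subj$ht * 100
  if (subj$sex == 1) {
    basal <- 3.45 * subj$mbody ^ 0.75 *
      (1 + 0.004 * (30 - subj$age) +
         0.010 * (ht_cm / subj$mbody ^ (1 / 3) - 43.4))
  } else {
    basal <- 3.19 * subj$mbody ^ 0.75 *
      (1 + 0.004 * (30 - subj$age) +
         0.018 * (ht_cm / subj$mbody ^ (1 / 3) - 42.1))
  }
  basal + subj$work
}
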