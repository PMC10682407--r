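# Gagge two-node thermoregulation and the standard effective
# temperature SET*.  Control-law constants follow the classical
# two-node publication; the full set is tabulated in the vignette.

.TN <- list(
  tsk0 = 33.7, tcr0 = 36.8, tb0 = 36.49,
  skbf0 = 6.3,                # L/(m^2 h)
  csw = 170,                  # sweating gain, g/(m^2 h K)
  cdil = 120, cstr = 0.5,     # vasomotor gains
  cshiv = 19.4,               # shivering gain, W/m^2 per K^2
  met_factor = 58.2,          # W/m^2 per met
  sbc = 5.6697e-8
)

# saturation vapour pressure in torr (two-node native unit)
.psat_torr <- function(t) exp(18.6686 - 4030.183 / (t + 235))

# convective coefficient, W/(m^2 K); includes the metabolic pumping term
.tn_chc <- function(v, met_units) {
  max(3, 8.600001 * v ^ 0.53,
      if (met_units > 0.85) 5.66 * (met_units - 0.85) ^ 0.39 else 0)
}

.two_node_core <- function(Ta, Tmrt, v, RH, met_units, clo, minutes,
                           subj) {
  p <- .TN
  adu <- dubois_area(subj)
  mbody <- subj$mbody
  vel <- max(v, 0.1)
  pa <- RH / 100 * .psat_torr(Ta)              # torr

  rm <- met_units * p$met_factor               # W/m^2, fixed component
  m <- rm
  tsk <- p$tsk0
  tcr <- p$tcr0
  skbf <- p$skbf0
  alpha <- 0.1
  esk <- 0.1 * rm
  mrsw <- 0
  pwet <- 0.06

  wmax <- if (clo < 1e-6) 0.38 * vel ^ (-0.29) else 0.59 * vel ^ (-0.08)
  wmax <- min(wmax, 1)
  iclo <- 0.45                                 # clothing permeation efficiency
  lr <- 2.2                                    # Lewis relation, degC/torr
  rcl <- 0.155 * clo
  facl <- 1 + 0.15 * clo
  chr <- 4.7
  dry <- 0
  emax <- 1

  if (minutes > 0) {
    for (minute in seq_len(minutes)) {
      chc <- .tn_chc(vel, m / p$met_factor)
      ctc <- chr + chc
      ra <- 1 / (facl * ctc)
      top <- (chr * Tmrt + chc * Ta) / ctc
      # clothing surface temperature / radiative coefficient fixed point
      tcl <- (ra * tsk + rcl * top) / (ra + rcl)
      for (i in 1:20) {
        chr <- 4 * 0.72 * p$sbc * ((tcl + Tmrt) / 2 + 273.15) ^ 3
        ctc <- chr + chc
        ra <- 1 / (facl * ctc)
        top <- (chr * Tmrt + chc * Ta) / ctc
        tcl_new <- (ra * tsk + rcl * top) / (ra + rcl)
        if (abs(tcl_new - tcl) < 0.01) {
          tcl <- tcl_new
          break
        }
        tcl <- tcl_new
      }
      dry <- (tsk - top) / (ra + rcl)
      hfcs <- (tcr - tsk) * (5.28 + 1.163 * skbf)
      eres <- 0.0023 * m * (44 - pa)
      cres <- 0.0014 * m * (34 - Ta)
      scr <- m - hfcs - eres - cres
      ssk <- hfcs - dry - esk
      tcsk <- 0.97 * alpha * mbody
      tccr <- 0.97 * (1 - alpha) * mbody
      dtsk <- ssk * adu / (tcsk * 60)
      dtcr <- scr * adu / (tccr * 60)
      if (abs(dtsk) > 5 || abs(dtcr) > 5) {
        stop("two-node step instability: |dT| > 5 K/min")
      }
      tsk <- tsk + dtsk
      tcr <- tcr + dtcr
      tb <- alpha * tsk + (1 - alpha) * tcr

      warms <- max(tsk - p$tsk0, 0)
      colds <- max(p$tsk0 - tsk, 0)
      warmc <- max(tcr - p$tcr0, 0)
      coldc <- max(p$tcr0 - tcr, 0)
      warmb <- max(tb - p$tb0, 0)

      skbf <- (p$skbf0 + p$cdil * warmc) / (1 + p$cstr * colds)
      skbf <- min(max(skbf, 0.5), 90)
      mrsw <- min(p$csw * warmb * exp(warms / 10.7), 500)
      ersw <- 0.68 * mrsw
      rea <- 1 / (lr * facl * chc)
      recl <- rcl / (lr * iclo)
      emax <- (.psat_torr(tsk) - pa) / (rea + recl)
      if (emax > 0) {
        prsw <- ersw / emax
        pwet <- 0.06 + 0.94 * prsw
        edif <- pwet * emax - ersw
        if (pwet > wmax) {
          pwet <- wmax
          prsw <- wmax / 0.94
          ersw <- prsw * emax
          edif <- pwet * emax - ersw
        }
        esk <- ersw + edif
      } else {
        # condensation regime: skin fully wet
        pwet <- wmax
        ersw <- 0
        edif <- 0
        esk <- emax
      }
      mshiv <- p$cshiv * colds * coldc
      m <- rm + mshiv
      # skin-mass fraction; the raw fit exceeds 0.35 under strong
      # vasoconstriction, clamp to the physiological band
      alpha <- min(max(0.0417737 + 0.7451833 / (skbf + 0.585417),
                       0.04), 0.35)
    }
  }

  list(Tcore = tcr, Tsk = tsk, skin_blood_flow = skbf, sweat_rate = mrsw,
       w = pwet, alpha = alpha, dry = dry, esk = esk, m = m, chr = chr,
       pa = pa, emax = emax, adu = adu)
}

#' Simulate the two-node (core/skin) thermoregulation model
#'
#' Explicit 1-minute stepping from the neutral start (Tcore 36.8 degC,
#' Tsk 33.7 degC): vasodilation/constriction from core and skin error
#' signals, regulatory sweating from the body-temperature error,
#' shivering metabolism from cold signals.
#'
#' @param met A [meteo_record()] (RH is consumed; default clothing
#'   0.9 clo).
#' @param subj A [subject_profile()].
#' @param minutes Exposure, minutes (default 60); `minutes = 0` returns
#'   the neutral start state.
#' @return An object of class `two_node_state`: `Tcore`, `Tsk` (degC),
#'   `skin_blood_flow` (L/(m^2 h)), `sweat_rate` (g/(m^2 h)), `w`
#'   (wettedness, 0.06-1) and `alpha` (skin mass fraction).
#' @export
two_node_simulate <- function(met, subj = subject_profile(), minutes = 60) {
  stopifnot(inherits(met, "meteo_record"))
  clo <- if (is.null(subj$icl)) 0.9 else subj$icl
  met_units <- metabolic_rate(subj) / dubois_area(subj) / .TN$met_factor
  st <- .two_node_core(met$Ta, met$Tmrt, met$v, met$RH, met_units, clo,
                       minutes, subj)
  structure(st[c("Tcore", "Tsk", "skin_blood_flow", "sweat_rate", "w",
                 "alpha")],
            class = "two_node_state")
}

#' Outdoor standard effective temperature (SET*)
#'
#' SET* is the air temperature of the standard environment
#' (Tmrt = Ta, still air 0.15 m/s, RH 50 %, standard clothing for the
#' activity `icl_std = 1.52/(met + 0.6944) - 0.1835` clo) in which a
#' standard subject with the actual skin temperature and wettedness
#' loses the same total heat.  The standard-environment heat-loss curve
#' is solved by bisection to 0.01 K.
#'
#' @param met A [meteo_record()] (RH consumed; default clothing
#'   0.9 clo).
#' @param subj A [subject_profile()].
#' @param minutes Exposure horizon for the two-node state, minutes.
#' @param details Logical; return the matched-balance diagnostics
#'   (`SET`, `residual` of the standard-environment heat-loss match in
#'   W/m^2, `hsk`, `Tsk`, `w`) instead of the bare scalar.
#' @return SET*, degC (or a diagnostics list when `details = TRUE`).
#' @examples
#' set_star(meteo_record(Ta = 20, RH = 50, v = 0.1, Tmrt = 20))
#' @export
set_star <- function(met, subj = subject_profile(), minutes = 60,
                     details = FALSE) {
  stopifnot(inherits(met, "meteo_record"))
  p <- .TN
  clo <- if (is.null(subj$icl)) 0.9 else subj$icl
  met_units <- metabolic_rate(subj) / dubois_area(subj) / p$met_factor
  st <- .two_node_core(met$Ta, met$Tmrt, met$v, met$RH, met_units, clo,
                       minutes, subj)

  hsk <- st$dry + st$esk                       # total skin heat loss, W/m^2
  pwet <- st$w
  tsk <- st$Tsk
  pssk <- .psat_torr(tsk)
  lr <- 2.2

  met_final <- st$m / p$met_factor
  chrs <- st$chr
  chcs <- max(3, if (met_final > 0.85) 5.66 * (met_final - 0.85) ^ 0.39
              else 0)
  ctcs <- chrs + chcs
  clo_s <- 1.52 / (met_final + 0.6944) - 0.1835
  rcl_s <- 0.155 * clo_s
  facl_s <- 1 + 0.25 * clo_s                   # k_clo = 0.25 in the standard
  fcl_s <- 1 / (1 + 0.155 * facl_s * ctcs * clo_s)
  im_s <- 0.45
  icl_s <- im_s * chcs / ctcs * (1 - fcl_s) / (chcs / ctcs - fcl_s * im_s)
  ra_s <- 1 / (facl_s * ctcs)
  rea_s <- 1 / (lr * facl_s * chcs)
  recl_s <- rcl_s / (lr * icl_s)
  hd_s <- 1 / (ra_s + rcl_s)
  he_s <- 1 / (rea_s + recl_s)

  balance <- function(set) {
    hsk - hd_s * (tsk - set) -
      pwet * he_s * (pssk - 0.5 * .psat_torr(set))
  }
  lo <- -40
  hi <- 80
  f_lo <- balance(lo)
  f_hi <- balance(hi)
  if (f_lo * f_hi > 0) {
    stop(sprintf(
      "SET* bisection bracket [-40, 80] degC does not enclose a root (f(lo)=%.1f, f(hi)=%.1f)",
      f_lo, f_hi))
  }
  while (hi - lo > 0.01) {
    mid <- (lo + hi) / 2
    if (balance(mid) * f_lo <= 0) hi <- mid else lo <- mid
  }
  set <- (lo + hi) / 2
  if (details) {
    list(SET = set, residual = balance(set), hsk = hsk, Tsk = tsk,
         w = pwet)
  } else {
    set
  }
}

#' @export
print.two_node_state <- function(x, ...) {
  cat(sprintf(
    "two_node_state: Tcore=%.2f Tsk=%.2f degC  skbf=%.1f L/(m^2 h)  sweat=%.0f g/(m^2 h)  w=%.2f  alpha=%.3f\n",
    x$Tcore, x$Tsk, x$skin_blood_flow, x$sweat_rate, x$w, x$alpha))
  invisible(x)
}
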