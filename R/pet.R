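# Munich energy-balance model for individuals (MEMI) steady state and
# the physiologically-equivalent-temperature mapping.  Sign convention:
# gains to the body are positive, losses negative, so at steady state
# h + Ere + csum + rsum + Ed + Esw = 0.

.MEMI <- list(
  po = 1013.25,          # reference pressure, hPa
  cair = 1010,           # specific heat of air, J/(kg K)
  evap = 2.42e6,         # latent heat of vaporisation, J/kg
  emsk = 0.99, emcl = 0.95,
  sigm = 5.67e-8,
  rdsk = 0.79e7,         # skin vapour diffusion resistance, s/m
  rdcl_per_rcl = 5.24e6  # clothing vapour resistance per unit rcl
)

# reference climate of the equivalence mapping (frozen)
.PET_REF <- list(v = 0.1, VP = 12, icl = 0.9, work = 80)

# bisection for the equivalence mapping on a monotone increasing f.
# Endpoints where the reference model has no physiological solution
# (extreme cold) are probed safely and the bracket shrunk to the
# feasible band before bisecting.
.equiv_bisect <- function(f, lo_limit, hi_limit, tol, what) {
  probe <- function(x) tryCatch(f(x), error = function(e) NA_real_)
  lo <- NA_real_
  f_lo <- NA_real_
  for (x in seq(21, lo_limit, by = -7)) {
    v <- probe(x)
    if (is.na(v)) break
    lo <- x
    f_lo <- v
    if (v < 0) break
  }
  hi <- NA_real_
  f_hi <- NA_real_
  for (x in seq(28, hi_limit, by = 7)) {
    v <- probe(x)
    if (is.na(v)) break
    hi <- x
    f_hi <- v
    if (v > 0) break
  }
  if (is.na(lo) || is.na(hi) || f_lo > 0 || f_hi < 0) {
    stop(sprintf(
      "%s equivalence root not bracketed in [%g, %g] degC (feasible band [%s, %s])",
      what, lo_limit, hi_limit, format(lo), format(hi)))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

.memi_psat <- function(t) 6.11 * 10 ^ (7.45 * t / (235 + t))

# state and flux decomposition for a fixed skin temperature; solves the
# core and clothing balances internally
.memi_at_tsk <- function(tsk, Ta, VP, v, Tmrt, icl, subj, p = 1013.25) {
  k <- .MEMI
  adu <- dubois_area(subj)
  M <- metabolic_rate(subj)
  h <- M                                      # eta = 0: all load internal

  # respiration
  tex <- 0.47 * Ta + 21.0
  rtv <- 1.44e-6 * M
  eres <- k$cair * (Ta - tex) * rtv
  vpex <- .memi_psat(tex)
  erel <- 0.623 * k$evap / p * (VP - vpex) * rtv
  ere <- eres + erel

  # clothing geometry
  facl <- min(1, (-2.36 + 173.51 * icl - 100.76 * icl ^ 2 +
                    19.28 * icl ^ 3) / 100)
  facl <- max(facl, 0.02)
  fcl <- 1 + 0.15 * icl
  acl <- adu * facl + adu * (fcl - 1)
  ht <- subj$ht
  y <- if (icl >= 2) 1
  else if (icl > 0.6) (ht - 0.2) / ht
  else if (icl > 0.3) 0.5
  else 0.1
  r2 <- adu * (fcl - 1 + facl) / (2 * pi * ht * y)
  r1 <- facl * adu / (2 * pi * ht * y)
  di <- r2 - r1
  rcl <- icl / 6.45
  htcl <- 6.28 * ht * y * di / (rcl * log(r2 / r1) * acl)

  feff <- c(0.725, 0.696, 0.67)[subj$pos]
  hc <- (2.67 + 6.5 * v ^ 0.67) * (p / k$po) ^ 0.55

  tmrt_k4 <- (Tmrt + 273.15) ^ 4
  tsk_k4 <- (tsk + 273.15) ^ 4

  # core temperature from the core balance h + ere - Fcs(tcr) = 0
  transport <- function(tcr) {
    vb2 <- max(tcr - 36.6, 0)
    vb1 <- max(34 - tsk, 0)
    vb <- min(max((6.3 + 75 * vb2) / (1 + 0.5 * vb1), 0.5), 90)
    adu * (tcr - tsk) * (5.28 + 1.163 * vb)
  }
  fcore <- function(tcr) h + ere - transport(tcr)
  lo <- tsk - 3
  hi <- 48
  if (fcore(lo) < 0 || fcore(hi) > 0) {
    stop("core balance has no root in the physiological bracket")
  }
  tcr <- stats::uniroot(fcore, c(lo, hi), tol = 1e-7)$root

  # clothing surface temperature from the clothing balance
  fclo <- function(tcl) {
    htcl * acl * (tsk - tcl) + hc * (Ta - tcl) * acl +
      feff * acl * k$emcl * k$sigm * (tmrt_k4 - (tcl + 273.15) ^ 4)
  }
  tcl <- stats::uniroot(fclo, c(-80, 130), tol = 1e-7)$root

  cbare <- hc * (Ta - tsk) * adu * (1 - facl)
  cclo <- hc * (Ta - tcl) * acl
  rbare <- feff * adu * (1 - facl) * k$emsk * k$sigm * (tmrt_k4 - tsk_k4)
  rclo <- feff * acl * k$emcl * k$sigm * (tmrt_k4 - (tcl + 273.15) ^ 4)

  # evaporation: regulatory sweating capped by the wettedness limit,
  # plus passive diffusion over the dry skin fraction
  vpts <- .memi_psat(tsk)
  tbody <- 0.1 * tsk + 0.9 * tcr
  swm <- 304.94 * max(tbody - 36.6, 0) * adu / 3600000   # kg/s
  if (subj$sex == 2) swm <- swm * 0.7
  esw <- -k$evap * swm                                    # W, <= 0
  fec <- 1 / (1 + 0.92 * hc * rcl)
  he <- 0.633 * hc / (p * k$cair)
  emax <- k$evap * he * (VP - vpts) * adu * fec           # W, < 0 normally
  if (emax >= 0) {
    # ambient vapour pressure above skin saturation: no evaporative loss
    esw <- 0
    wetsk <- 1
  } else if (esw < emax) {
    esw <- emax
    wetsk <- 1
  } else {
    wetsk <- if (emax < 0) esw / emax else 0
  }
  ed <- k$evap / (k$rdsk + k$rdcl_per_rcl * rcl) * adu * (1 - wetsk) *
    (VP - vpts)

  kclo <- htcl * acl * (tsk - tcl)
  transport_val <- h + ere                     # core balance at root
  skin_residual <- transport_val + cbare + rbare + ed + esw - kclo

  list(residual = skin_residual, Tcore = tcr, Tsk = tsk, Tcl = tcl,
       wetsk = wetsk, h = h, Ere = ere, csum = cbare + cclo,
       rsum = rbare + rclo, Ed = ed, Esw = esw)
}

#' Solve the MEMI steady-state energy balance
#'
#' Coupled steady-state balance of core, skin and clothing-surface
#' temperatures with vasomotor blood-flow adjustment, regulatory
#' sweating with a wettedness cap, passive skin diffusion, and
#' respiratory fluxes.  Solved by nested 1-D root finding (clothing and
#' core balances inside a skin-temperature root) to a residual below
#' 0.1 W.
#'
#' @param met A [meteo_record()] (VP consumed).
#' @param subj A [subject_profile()]; clothing defaults to the PET
#'   convention of 0.9 clo when `icl` is `NULL`.
#' @param icl Clothing insulation override, clo.
#' @param tsk_bracket Skin-temperature search bracket, degC.  The
#'   default is the physiological band; [pet_calc()] extends it
#'   downward for the reference-climate construct under strong cold
#'   stress (classical PET convention).
#' @return List with `Tcore`, `Tsk`, `Tcl` (degC), `wetsk` (0-1) and
#'   the flux decomposition `h`, `Ere`, `csum`, `rsum`, `Ed`, `Esw`
#'   (W, gains positive), closing to < 0.1 W.
#' @export
memi_solve <- function(met, subj = subject_profile(), icl = NULL,
                       tsk_bracket = c(0.5, 45)) {
  stopifnot(inherits(met, "meteo_record"))
  if (is.null(icl)) icl <- if (is.null(subj$icl)) 0.9 else subj$icl
  f <- function(tsk) {
    .memi_at_tsk(tsk, met$Ta, met$VP, met$v, met$Tmrt, icl, subj)$residual
  }
  lo <- tsk_bracket[1]
  hi <- tsk_bracket[2]
  f_lo <- f(lo)
  f_hi <- f(hi)
  if (f_lo * f_hi > 0) {
    # scan for a sign change before giving up
    grid <- seq(lo, hi, by = 1)
    vals <- vapply(grid, f, numeric(1))
    idx <- which(vals[-1] * vals[-length(vals)] <= 0)
    if (length(idx) == 0) {
      stop(sprintf(
        "no skin-temperature root in [%g, %g] degC (residual %.1f..%.1f W)",
        tsk_bracket[1], tsk_bracket[2], f_lo, f_hi))
    }
    lo <- grid[idx[1]]
    hi <- grid[idx[1] + 1]
  }
  tsk <- stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
  st <- .memi_at_tsk(tsk, met$Ta, met$VP, met$v, met$Tmrt, icl, subj)
  st$residual <- NULL
  st
}

#' Physiologically equivalent temperature (PET)
#'
#' PET is the air temperature of the reference climate (Tmrt = Ta_ref,
#' v = 0.1 m/s, VP = 12 hPa, work = 80 W, icl = 0.9 clo) at which the
#' reference-climate MEMI solution reproduces the actual skin
#' temperature; the core temperature of the matched reference solution
#' is verified against the actual one and a mismatch above 0.2 K logs a
#' warning (the classical 1-D equivalence ambiguity).  Found by
#' bisection on \[-50, 80\] degC to 0.01 K.  The returned fluxes and
#' temperatures are those of the actual environment.
#'
#' @param met A [meteo_record()] (VP consumed).
#' @param subj A [subject_profile()]; `icl` is fixed at 0.9 clo per the
#'   PET convention (a user value is accepted for the actual-environment
#'   solve but the reference run always wears 0.9 clo).
#' @return An object of class `pet_result`: `PET` (degC) plus the
#'   11-field actual-environment solution (`Tcore`, `Tsk`, `Tcl`,
#'   `wetsk`, `metabolic_rate`, `respiratory_flux`, `convective_flux`,
#'   `radiative_flux`, `diffuse_flux`, `sweating_flux`).
#' @examples
#' pet_calc(meteo_record(Ta = 20, VP = 12.5, v = 0.1, Tmrt = 20))
#' @export
pet_calc <- function(met, subj = subject_profile()) {
  stopifnot(inherits(met, "meteo_record"))
  actual <- memi_solve(met, subj)

  ref <- .PET_REF
  ref_subj <- subject_profile(icl = ref$icl, work = ref$work, ht = subj$ht,
                              mbody = subj$mbody, age = subj$age,
                              sex = subj$sex, pos = subj$pos)
  ref_solve <- function(ta_ref) {
    # reference VP of 12 hPa is supersaturated below ~9.7 degC; the
    # capped-RH warning is expected there
    rec <- suppressWarnings(meteo_record(Ta = ta_ref, VP = ref$VP,
                                         v = ref$v, Tmrt = ta_ref))
    memi_solve(rec, ref_subj, tsk_bracket = c(-35, 45))
  }
  f <- function(ta_ref) ref_solve(ta_ref)$Tsk - actual$Tsk
  pet <- .equiv_bisect(f, lo_limit = -50, hi_limit = 80, tol = 0.01,
                       what = "PET")
  ref_state <- ref_solve(pet)
  if (abs(ref_state$Tcore - actual$Tcore) > 0.2) {
    warning(sprintf(
      "PET equivalence: reference core temperature differs from actual by %.2f K",
      ref_state$Tcore - actual$Tcore))
  }
  structure(list(PET = pet, Tcore = actual$Tcore, Tsk = actual$Tsk,
                 Tcl = actual$Tcl, wetsk = actual$wetsk,
                 metabolic_rate = actual$h, respiratory_flux = actual$Ere,
                 convective_flux = actual$csum,
                 radiative_flux = actual$rsum, diffuse_flux = actual$Ed,
                 sweating_flux = actual$Esw),
            class = "pet_result")
}

#' @export
print.pet_result <- function(x, ...) {
  cat(sprintf("PET = %.2f degC\n", x$PET))
  cat(sprintf("  Tcore=%.2f Tsk=%.2f Tcl=%.2f degC  wetsk=%.2f\n",
              x$Tcore, x$Tsk, x$Tcl, x$wetsk))
  cat(sprintf(
    "  fluxes W (gains +): M=%.1f Ere=%.1f C=%.1f R=%.1f Ed=%.1f Esw=%.1f\n",
    x$metabolic_rate, x$respiratory_flux, x$convective_flux,
    x$radiative_flux, x$diffuse_flux, x$sweating_flux))
  invisible(x)
}
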