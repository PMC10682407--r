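# Modified PET: a compact multi-node, semi-steady-state
# thermophysiological model (head / trunk / arms / legs as concentric
# core-muscle-fat-skin cylinders coupled to a central blood pool) with
# humidity-sensitive clothing vapour transfer and Ta-adaptive clothing
# insulation.  Geometry and control constants are tabulated in the
# vignette.

.MN <- local({
  seg <- c("head", "trunk", "arms", "legs")
  a_frac <- c(0.07, 0.36, 0.19, 0.38)          # DuBois area fractions
  m_frac <- c(0.07, 0.50, 0.12, 0.31)          # mass fractions (ex blood)
  # layer mass fractions within a segment (core, muscle, fat, skin)
  layer_frac <- rbind(
    head  = c(0.80, 0.05, 0.05, 0.10),
    trunk = c(0.55, 0.30, 0.10, 0.05),
    arms  = c(0.30, 0.50, 0.10, 0.10),
    legs  = c(0.30, 0.55, 0.08, 0.07))
  list(
    seg = seg, a_frac = a_frac, m_frac = m_frac, layer_frac = layer_frac,
    cp_tissue = 3500, cp_blood = 3850, blood_frac = 0.05,
    k_cm = 13, k_mf = 16, k_fs = 21,           # inter-layer conductance W/(m^2 K)
    basal_seg = c(0.16, 0.56, 0.10, 0.18),     # basal met distribution
    basal_layer = c(0.85, 0.13, 0.01, 0.01),   # within-segment split
    work_seg = c(0.00, 0.30, 0.10, 0.60),      # activity load to muscle
    w_core = 45, w_musc = 6, w_fat = 1.5,      # perfusion, L/(m^2 h)
    skbf0 = 6.3, cdil = 75, cstr = 0.5,        # skin vasomotor law
    csw = 304.94 / 3.6e6,                      # sweating gain, kg/(s K) per m^2... total below
    cshiv = 19.4,                              # shivering, W/m^2 per K^2
    im = 0.38,                                 # clothing moisture permeability
    icl_head = 0.1,                            # near-bare head, clo
    emcl = 0.95, feff = 0.725,
    lewis = 1.65,                              # K/hPa
    evap = 2.42e6, sigm = 5.67e-8,
    dt = 60, horizon = 480, dT_crit = 0.01, eb_crit = 1.0
  )
})

#' Air-temperature-adaptive clothing insulation
#'
#' Monotone non-increasing, continuous mapping from air temperature to
#' clothing insulation, bounded to \[0.3, 2.6\] clo and pinned so that
#' `auto_clothing(20) = 0.9` clo, matching the fixed PET clothing at
#' mild conditions.  Slope -0.0425 clo/K.
#'
#' @param Ta Air temperature, degC.
#' @return Clothing insulation, clo (vectorised).
#' @examples
#' auto_clothing(c(-15, 20, 35))
#' @export
auto_clothing <- function(Ta) {
  if (any(!is.finite(Ta))) stop("Ta must be finite")
  pmin(2.6, pmax(0.3, 0.9 - 0.0425 * (Ta - 20)))
}

# one explicit-Euler step; state is list(T = 4x4 matrix, Tb = scalar)
# env: list(Ta, VP, RH, v, Tmrt); pars precomputed geometry
.mn_step <- function(state, env, pars) {
  p <- .MN
  T <- state$T                     # seg x layer (core, muscle, fat, skin)
  Tb <- state$Tb
  A <- pars$A_seg                  # m^2 per segment
  tsk <- T[, 4]
  tsk_mm <- sum(tsk * p$a_frac)
  tcore <- T[2, 1]                 # trunk core is the central core signal

  # central control signals
  warmc <- max(tcore - 36.8, 0)
  coldc <- max(36.8 - tcore, 0)
  colds <- max(33.7 - tsk_mm, 0)
  skbf <- min(max((p$skbf0 + p$cdil * warmc) / (1 + p$cstr * colds),
                  0.5), 90)
  mshiv_area <- p$cshiv * colds * coldc        # W/m^2
  tbody <- 0.1 * tsk_mm + 0.9 * tcore
  sw_total <- 304.94 * max(tbody - 36.6, 0) * pars$adu / 3.6e6  # kg/s

  # clothing node (quasi-steady) per segment
  hc <- 2.67 + 6.5 * env$v ^ 0.67
  tcl <- state$Tcl
  hr <- p$feff * 4 * p$emcl * p$sigm * ((tcl + env$Tmrt) / 2 + 273.15) ^ 3
  rcl <- pars$rcl_seg
  fcl <- pars$fcl_seg
  tcl <- (tsk / rcl + fcl * (hc * env$Ta + hr * env$Tmrt)) /
    (1 / rcl + fcl * (hc + hr))
  q_dry_gain <- A * (tcl - tsk) / rcl          # W into skin
  csum <- sum(A * fcl * hc * (env$Ta - tcl))
  rsum <- sum(A * fcl * hr * (env$Tmrt - tcl))

  # evaporation per segment: sweating demand vs maximum through
  # humidity-sensitive clothing
  im_eff <- p$im * (1 - 0.25 * env$RH / 100)
  he_air <- p$lewis * hc * fcl
  he_cl <- p$lewis * im_eff / rcl
  u_e <- 1 / (1 / he_air + 1 / he_cl)          # W/(m^2 hPa)
  psk <- .memi_psat(tsk)
  emax <- u_e * (psk - env$VP)                 # W/m^2, loss when positive
  ersw <- p$evap * sw_total * p$a_frac / A     # W/m^2 demand
  w_seg <- ifelse(emax > 0,
                  pmin(1, 0.06 + 0.94 * ersw / emax),
                  1)
  esk <- ifelse(emax > 0, w_seg * emax, emax)  # condensation gains if < 0
  wet_sum <- -sum(esk * A)

  # respiration from the trunk core (MEMI formulation)
  M_total <- pars$M_total + mshiv_area * pars$adu
  tex <- 0.47 * env$Ta + 21.0
  rtv <- 1.44e-6 * M_total
  ere <- 1010 * (env$Ta - tex) * rtv +
    0.623 * p$evap / 1013.25 * (env$VP - .memi_psat(tex)) * rtv

  # metabolic heat per node
  q_met <- pars$q_met_basal                    # seg x layer, W
  q_met[, 2] <- q_met[, 2] + mshiv_area * pars$adu * pars$shiv_split

  # perfusion conductances, W/K
  g_perf <- 1.163 * A * cbind(rep(p$w_core, 4), rep(p$w_musc, 4),
                              rep(p$w_fat, 4), rep(skbf, 4))

  # conduction between layers, W
  q_cm <- p$k_cm * A * (T[, 1] - T[, 2])
  q_mf <- p$k_mf * A * (T[, 2] - T[, 3])
  q_fs <- p$k_fs * A * (T[, 3] - T[, 4])

  dT <- matrix(0, 4, 4)
  dT[, 1] <- q_met[, 1] - q_cm + g_perf[, 1] * (Tb - T[, 1])
  dT[2, 1] <- dT[2, 1] + ere
  dT[, 2] <- q_met[, 2] + q_cm - q_mf + g_perf[, 2] * (Tb - T[, 2])
  dT[, 3] <- q_met[, 3] + q_mf - q_fs + g_perf[, 3] * (Tb - T[, 3])
  dT[, 4] <- q_met[, 4] + q_fs + g_perf[, 4] * (Tb - T[, 4]) +
    q_dry_gain - esk * A
  dTb <- sum(g_perf * (T - Tb))

  T_new <- T + p$dt * dT / pars$C
  Tb_new <- Tb + p$dt * dTb / pars$Cb

  # whole-body residual, gains positive; wet_gain is the (negative)
  # total evaporative gain
  wet_gain <- -sum(esk * A)
  eb <- M_total + ere + csum + rsum + wet_gain

  list(T = T_new, Tb = Tb_new, Tcl = tcl, w_seg = w_seg,
       dT_max = max(abs(c(T_new - T, Tb_new - Tb))),
       eb = eb, csum = csum, rsum = rsum, ere = ere,
       wet_sum = wet_gain, M_total = M_total, skbf = skbf)
}

.mn_pars <- function(subj, icl) {
  p <- .MN
  adu <- dubois_area(subj)
  A_seg <- p$a_frac * adu
  mass_seg <- p$m_frac * subj$mbody * (1 - p$blood_frac)
  C <- p$layer_frac * mass_seg * p$cp_tissue   # seg x layer, J/K
  Cb <- p$blood_frac * subj$mbody * p$cp_blood
  M_basal <- metabolic_rate(subject_profile(
    work = 0, ht = subj$ht, mbody = subj$mbody, age = subj$age,
    sex = subj$sex, pos = subj$pos))
  q_met_basal <- outer(p$basal_seg, p$basal_layer) * M_basal
  q_met_basal[, 2] <- q_met_basal[, 2] + p$work_seg * subj$work
  icl_seg <- c(p$icl_head, icl, icl, icl)
  shiv_split <- p$work_seg + 0.05              # shivering mostly in limbs
  shiv_split[1] <- 0
  shiv_split <- shiv_split / sum(shiv_split)
  list(adu = adu, A_seg = A_seg, C = C, Cb = Cb,
       M_total = M_basal + subj$work, q_met_basal = q_met_basal,
       rcl_seg = 0.155 * icl_seg, fcl_seg = 1 + 0.15 * icl_seg,
       shiv_split = shiv_split)
}

.mn_neutral_state <- function() {
  T <- matrix(36.8, 4, 4)
  T[, 2] <- 36.3
  T[, 3] <- 35.0
  T[, 4] <- 33.7
  list(T = T, Tb = 36.8, Tcl = rep(30, 4))
}

#' Converge the multi-node model to its semi-steady state
#'
#' Steps the segmental bioheat equations (layer conduction, blood-pool
#' coupling, quasi-steady clothing with humidity-dependent vapour
#' transfer, central sweating/vasomotor/shivering control) on a 1-minute
#' grid until the semi-steady criterion holds (max |dT/dt| over all
#' nodes < 0.01 K/min and whole-body flux residual < 1 W) or 480
#' simulated minutes elapse, in which case a warning is issued and the
#' state returned with `converged = FALSE`.
#'
#' @param met A [meteo_record()] (VP consumed).
#' @param subj A [subject_profile()]; clothing from [auto_clothing()]
#'   when `auto_clo` is `TRUE`, else the user `icl` (default 0.9 clo).
#' @param icl Clothing override, clo (bypasses the auto rule).
#' @param init Optional initial state (warm start); defaults to the
#'   neutral state.
#' @return An object of class `multi_node_state`: segment-layer
#'   temperature matrix `T`, blood-pool `Tb`, per-segment clothing
#'   temperatures `Tcl`, wettedness `w_seg`, the flux bookkeeping and a
#'   `converged` flag.
#' @export
mpet_converge <- function(met, subj = subject_profile(), icl = NULL,
                          init = NULL) {
  stopifnot(inherits(met, "meteo_record"))
  p <- .MN
  if (is.null(icl)) {
    icl <- if (subj$auto_clo) auto_clothing(met$Ta)
    else if (is.null(subj$icl)) 0.9 else subj$icl
  }
  pars <- .mn_pars(subj, icl)
  env <- list(Ta = met$Ta, VP = met$VP, RH = met$RH, v = max(met$v, 0.05),
              Tmrt = met$Tmrt)
  state <- if (is.null(init)) .mn_neutral_state() else init
  converged <- FALSE
  minutes <- 0
  last <- NULL
  for (i in seq_len(p$horizon)) {
    last <- .mn_step(state, env, pars)
    state <- list(T = last$T, Tb = last$Tb, Tcl = last$Tcl)
    minutes <- i
    if (last$dT_max < p$dT_crit && abs(last$eb) < p$eb_crit) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf(
      "multi-node model not semi-steady after %d min (max dT %.3f K/min, residual %.1f W)",
      p$horizon, last$dT_max, last$eb))
  }
  tsk_mm <- sum(state$T[, 4] * p$a_frac)
  structure(list(
    T = state$T, Tb = state$Tb, Tcl = state$Tcl, w_seg = last$w_seg,
    Tcore = state$T[2, 1], Tsk_mm = tsk_mm,
    Tcl_mm = sum(state$Tcl * p$a_frac),
    icl = icl, minutes = minutes, converged = converged,
    fluxes = list(M = last$M_total, Ere = last$ere, csum = last$csum,
                  rsum = last$rsum, wet_sum = last$wet_sum,
                  eb = last$eb)),
    class = "multi_node_state")
}

#' Modified physiologically equivalent temperature (mPET)
#'
#' mPET is the air temperature of the PET reference climate
#' (Tmrt = Ta_ref, v = 0.1 m/s, VP = 12 hPa, work = 80 W; clothing in
#' the reference run chosen by the same auto/fixed rule as the actual
#' run) whose converged multi-node state matches the actual mean skin
#' temperature, found by bisection on \[-50, 80\] degC to 0.01 K.  The
#' returned fields carry the actual-environment means and the residual
#' `energy_balance`.
#'
#' @param met A [meteo_record()] (VP consumed).
#' @param subj A [subject_profile()]; `auto_clo = TRUE` (default)
#'   selects Ta-adaptive clothing, otherwise the user `icl` is worn in
#'   both the actual and the reference run.
#' @param icl Clothing override, clo (implies a fixed-clothing run, as
#'   the worked-call convention `icl = 1.8, clo_auto = FALSE`).
#' @return An object of class `mpet_result` with 14 fields: `mPET`,
#'   `Tcore`, `Tsk_mm`, `Tcl`, `vpts`, `wetsk`, `icl`, `sk_wetted_mm`,
#'   `metabolic_rate`, `wet_sum`, `convective_flux`, `radiative_flux`,
#'   `respiratory_flux`, `energy_balance`.
#' @examples
#' \donttest{
#' mpet_calc(meteo_record(Ta = 20, VP = 12.5, v = 0.1, Tmrt = 20))
#' }
#' @export
mpet_calc <- function(met, subj = subject_profile(), icl = NULL) {
  stopifnot(inherits(met, "meteo_record"))
  p <- .MN
  if (!is.null(icl)) {
    subj <- subject_profile(icl = icl, work = subj$work, ht = subj$ht,
                            mbody = subj$mbody, age = subj$age,
                            sex = subj$sex, pos = subj$pos,
                            auto_clo = FALSE)
  }
  actual <- mpet_converge(met, subj)

  # the clothing ensemble is a property of the subject, chosen once
  # from the ACTUAL environment (auto rule at the actual Ta, or the
  # fixed user value) and worn unchanged in the reference run; this
  # keeps the reference identity exact while adaptive dress damps the
  # sensitivity to the outdoor extremes
  ref_subj <- subject_profile(icl = actual$icl, work = 80,
                              ht = subj$ht, mbody = subj$mbody,
                              age = subj$age, sex = subj$sex,
                              pos = subj$pos, auto_clo = FALSE)
  warm <- NULL
  ref_tsk <- function(ta_ref) {
    rec <- suppressWarnings(
      meteo_record(Ta = ta_ref, VP = .PET_REF$VP, v = .PET_REF$v,
                   Tmrt = ta_ref))
    st <- suppressWarnings(mpet_converge(rec, ref_subj, init = warm))
    warm <<- list(T = st$T, Tb = st$Tb, Tcl = st$Tcl)
    st$Tsk_mm
  }
  f <- function(ta_ref) ref_tsk(ta_ref) - actual$Tsk_mm
  mpet <- .equiv_bisect(f, lo_limit = -50, hi_limit = 80, tol = 0.01,
                        what = "mPET")

  tsk <- actual$T[, 4]
  psk <- .memi_psat(tsk)
  vp_skin <- met$VP + actual$w_seg * (psk - met$VP)
  fx <- actual$fluxes
  structure(list(
    mPET = mpet, Tcore = actual$Tcore, Tsk_mm = actual$Tsk_mm,
    Tcl = actual$Tcl_mm, vpts = sum(vp_skin * p$a_frac),
    wetsk = sum((actual$w_seg >= 0.99) * p$a_frac), icl = actual$icl,
    sk_wetted_mm = sum(actual$w_seg * p$a_frac),
    metabolic_rate = fx$M, wet_sum = fx$wet_sum,
    convective_flux = fx$csum, radiative_flux = fx$rsum,
    respiratory_flux = fx$Ere, energy_balance = fx$eb,
    converged = actual$converged),
    class = "mpet_result")
}

#' @export
print.multi_node_state <- function(x, ...) {
  cat(sprintf(
    "multi_node_state (%s after %d min): Tcore=%.2f Tsk_mm=%.2f Tb=%.2f degC  icl=%.2f clo\n",
    if (x$converged) "semi-steady" else "NOT converged", x$minutes,
    x$Tcore, x$Tsk_mm, x$Tb, x$icl))
  invisible(x)
}

#' @export
print.mpet_result <- function(x, ...) {
  cat(sprintf("mPET = %.2f degC  (icl = %.2f clo)\n", x$mPET, x$icl))
  cat(sprintf(
    "  Tcore=%.2f Tsk_mm=%.2f Tcl=%.2f degC  vpts=%.1f hPa  wetted=%.2f  saturated=%.2f\n",
    x$Tcore, x$Tsk_mm, x$Tcl, x$vpts, x$sk_wetted_mm, x$wetsk))
  cat(sprintf(
    "  fluxes W (gains +): M=%.1f Ere=%.1f C=%.1f R=%.1f E=%.1f  residual=%.2f\n",
    x$metabolic_rate, x$respiratory_flux, x$convective_flux,
    x$radiative_flux, x$wet_sum, x$energy_balance))
  invisible(x)
}
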