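# Fanger predicted mean vote with the three-field output
# {PMV, Teq, hclo}.

# thermal load L (W/m^2) and clothing state for a uniform or split
# (Ta, Tmrt) environment; pa in Pa
.fanger_load <- function(Ta, Tmrt, v, pa, M, icl_clo,
                         max_iter = 150, tol = 1e-3) {
  icl <- 0.155 * icl_clo                       # m^2 K/W
  fcl <- if (icl <= 0.078) 1 + 1.29 * icl else 1.05 + 0.645 * icl
  hcf <- 12.1 * sqrt(v)
  tsk <- 35.7 - 0.028 * M
  # clothing-temperature iteration in the standard averaged form
  # (linear in xf^4, unconditionally contracting)
  taa <- Ta + 273
  tra <- Tmrt + 273
  p1 <- icl * fcl
  p2 <- p1 * 3.96
  p3 <- p1 * 100
  p4 <- p1 * taa
  p5 <- 308.7 - 0.028 * M + p2 * (tra / 100) ^ 4
  xn <- (taa + (35.5 - Ta) / (3.5 * icl + 0.1)) / 100
  xf <- xn
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    xf <- (xf + xn) / 2
    hcn <- 2.38 * abs(100 * xf - taa) ^ 0.25
    hc <- max(hcn, hcf)
    xn <- (p5 + p4 * hc - p2 * xf ^ 4) / (100 + p3 * hc)
    if (abs(xn - xf) < tol / 100) {
      converged <- TRUE
      break
    }
  }
  tcl <- 100 * xn - 273
  if (!converged) {
    stop(sprintf(
      "clothing-temperature iteration did not converge after %d iterations (last Tcl=%.3f)",
      max_iter, tcl))
  }
  hc <- max(2.38 * abs(tcl - Ta) ^ 0.25, hcf)
  rad <- 3.96e-8 * fcl * ((tcl + 273) ^ 4 - (Tmrt + 273) ^ 4)
  conv <- fcl * hc * (tcl - Ta)
  L <- M -
    3.05e-3 * (5733 - 6.99 * M - pa) -
    0.42 * max(M - 58.15, 0) -
    1.7e-5 * M * (5867 - pa) -
    0.0014 * M * (34 - Ta) -
    rad - conv
  list(L = L, tcl = tcl, tsk = tsk, icl = icl)
}

#' Predicted mean vote (PMV) with equivalent temperature and clothing
#' heat loss
#'
#' Fanger's steady-state comfort equation.  The clothing surface
#' temperature is solved by damped fixed-point iteration of the clothing
#' heat balance (|delta Tcl| < 1e-3 K, at most 150 iterations), then
#' `PMV = (0.303 exp(-0.036 M) + 0.028) L` with `L` the six-term thermal
#' load.  `Teq` is the uniform temperature (Ta = Tmrt, same wind and RH)
#' at which the load vanishes, found by bisection on \[-40, 60\] degC to
#' 0.01 K.  `hclo` is the dry heat flow through the clothing at the
#' converged state.
#'
#' @param met A [meteo_record()] (VP is consumed; default clothing
#'   0.6 clo).
#' @param subj A [subject_profile()]; metabolic rate is basal plus
#'   `work`, normalised by the DuBois area, unless `met_rate` overrides
#'   it.
#' @param met_rate Optional metabolic rate override, W/m^2 (useful for
#'   comfort-standard conventions where M is prescribed directly).
#' @return An object of class `pmv_result`: list `PMV` (dimensionless),
#'   `Teq` (degC), `hclo` (W/m^2).
#' @examples
#' rec <- meteo_record(Ta = 20, VP = 12.5, v = 0.1, Tmrt = 20)
#' pmv_calc(rec, subject_profile())
#' @export
pmv_calc <- function(met, subj = subject_profile(), met_rate = NULL) {
  stopifnot(inherits(met, "meteo_record"))
  icl_clo <- if (is.null(subj$icl)) 0.6 else subj$icl
  M <- if (is.null(met_rate)) metabolic_rate(subj) / dubois_area(subj) else
    met_rate
  pa <- met$VP * 100                           # hPa -> Pa
  st <- .fanger_load(met$Ta, met$Tmrt, met$v, pa, M, icl_clo)
  pmv <- (0.303 * exp(-0.036 * M) + 0.028) * st$L
  hclo <- (st$tsk - st$tcl) / st$icl

  rh <- met$RH
  load_at <- function(T) {
    pa_t <- rh / 100 * saturation_vapor_pressure(T) * 100
    .fanger_load(T, T, met$v, pa_t, M, icl_clo)$L
  }
  lo <- -40
  hi <- 60
  teq <- NA_real_
  f_lo <- load_at(lo)
  f_hi <- load_at(hi)
  if (f_lo * f_hi <= 0) {
    while (hi - lo > 0.01) {
      mid <- (lo + hi) / 2
      if (load_at(mid) * f_lo <= 0) hi <- mid else lo <- mid
    }
    teq <- (lo + hi) / 2
  }
  structure(list(PMV = pmv, Teq = teq, hclo = hclo), class = "pmv_result")
}

#' @export
print.pmv_result <- function(x, ...) {
  cat(sprintf("PMV = %.2f   Teq = %.2f degC   hclo = %.1f W/m^2\n",
              x$PMV, x$Teq, x$hclo))
  invisible(x)
}
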