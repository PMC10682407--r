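test_that("auto_clothing: pinned, bounded, monotone", {
  expect_equal(auto_clothing(20), 0.9)
  expect_lt(abs(auto_clothing(35) - 0.3), 0.1)
  expect_gte(auto_clothing(-15), 2.0)
  ta <- seq(-30, 45, by = 0.5)
  icl <- auto_clothing(ta)
  expect_true(all(diff(icl) <= 0))
  expect_true(all(icl >= 0.3 & icl <= 2.6))
})

test_that("multi-node model converges to a physiological neutral state", {
  st <- mpet_converge(meteo_record(Ta = 23, VP = 12, v = 0.1, Tmrt = 23))
  expect_true(st$converged)
  expect_true(st$Tcore > 36.4 && st$Tcore < 37.2)
  expect_lt(abs(st$fluxes$eb), 1)
  # area-weighted mean consistency
  expect_equal(st$Tsk_mm, sum(st$T[, 4] * c(0.07, 0.36, 0.19, 0.38)),
               tolerance = 1e-6)
  expect_equal(st$Tcl_mm, sum(st$Tcl * c(0.07, 0.36, 0.19, 0.38)),
               tolerance = 1e-6)
})

test_that("semi-steady state is independent of the initial condition", {
  rec <- meteo_record(Ta = 8, VP = 8, v = 1, Tmrt = 8)
  warm <- mpet_converge(rec)
  cold_init <- list(T = matrix(c(rep(35, 8), rep(30, 4), rep(20, 4)),
                               4, 4), Tb = 35, Tcl = rep(10, 4))
  cold <- mpet_converge(rec, init = cold_init)
  expect_lt(abs(warm$Tsk_mm - cold$Tsk_mm), 0.05)
  expect_lt(abs(warm$Tcore - cold$Tcore), 0.05)
})

test_that("extreme cold at the horizon returns a flagged state, no error", {
  rec <- meteo_record(Ta = -40, RH = 70, v = 10, Tmrt = -40)
  expect_warning(st <- mpet_converge(rec), "not semi-steady")
  expect_false(st$converged)
  expect_true(all(is.finite(st$T)))
})

test_that("mPET is the identity on the reference manifold (auto clothing)", {
  for (ta in seq(0, 35, by = 7)) {
    m <- suppressWarnings(mpet_calc(ref_record(ta)))
    expect_lt(abs(m$mPET - ta), 0.5)
  }
})

test_that("fixed clothing is passed through exactly; determinism holds", {
  rec <- meteo_record(Ta = 20, VP = 12.5, v = 0.1, Tmrt = 20)
  m <- suppressWarnings(mpet_calc(rec, icl = 1.8))
  expect_identical(m$icl, 1.8)
  m2 <- suppressWarnings(mpet_calc(rec, icl = 1.8))
  expect_identical(m[], m2[])      # bit-identical outputs
})

test_that("mPET increases with Tmrt and closes the energy balance", {
  ms <- vapply(c(20, 40, 60), function(tmrt) {
    suppressWarnings(
      mpet_calc(meteo_record(Ta = 25, VP = 15, v = 0.5,
                             Tmrt = tmrt)))$mPET
  }, numeric(1))
  expect_true(all(diff(ms) > 0))

  set.seed(9)
  for (i in 1:10) {
    rec <- meteo_record(Ta = stats::runif(1, -5, 35),
                        RH = stats::runif(1, 25, 90),
                        v = stats::runif(1, 0.1, 4),
                        Tmrt = stats::runif(1, -5, 55))
    st <- suppressWarnings(mpet_converge(rec))
    if (st$converged) expect_lt(abs(st$fluxes$eb), 1)
    expect_true(all(st$w_seg >= 0 & st$w_seg <= 1))
  }
})

test_that("adaptive clothing damps the Ta response relative to PET", {
  ta_grid <- seq(-10, 30, by = 10)
  recs <- lapply(ta_grid, function(ta) {
    meteo_record(Ta = ta, RH = 70, v = 1, Tmrt = ta)
  })
  pet <- vapply(recs, function(r) {
    suppressWarnings(pet_calc(r))$PET
  }, numeric(1))
  mpet <- vapply(recs, function(r) {
    suppressWarnings(mpet_calc(r))$mPET
  }, numeric(1))
  # mean equivalent-temperature change per unit Ta is smaller for the
  # adaptive-clothing model over the same records
  expect_lt(diff(range(mpet)), diff(range(pet)))
})
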