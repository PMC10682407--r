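sigma <- 5.67e-8

test_that("clear-sky fluxes: night, no-atmosphere limit, daytime bracket", {
  expect_equal(clear_sky_fluxes(120, 1, 0, 3, 12),
               list(Imax = 0, Gmax = 0, Dmax = 0))
  expect_equal(clear_sky_fluxes(90, 1, 0, 3, 12)$Imax, 0)
  # ltf -> 0 limit: beam approaches the solar constant x distance factor
  top <- clear_sky_fluxes(0, 1.02, 0, ltf = 1e-9, 12)$Imax
  expect_equal(top, 1367 * 1.02, tolerance = 1e-6)
  cs <- clear_sky_fluxes(30, 1, 0, ltf = 3, 12)
  expect_true(cs$Gmax > 700 && cs$Gmax < 1000)
  expect_true(cs$Dmax / cs$Gmax > 0.05 && cs$Dmax / cs$Gmax < 0.35)
  # elevation thins the atmosphere: stronger beam
  expect_gt(clear_sky_fluxes(30, 1, 2000, 3, 12)$Imax, cs$Imax)
})

test_that("cloud attenuation follows 1 - 0.75 (N/8)^3.4 exactly", {
  cs <- clear_sky_fluxes(35, 1, 100, 3, 12)
  for (N in 0:8) {
    act <- actual_fluxes(cs, N = N, RH = 50, zenith = 35)
    expect_equal(act$Gtat / cs$Gmax, 1 - 0.75 * (N / 8) ^ 3.4,
                 tolerance = 1e-9)
  }
  # N = 0 reproduces the clear-sky triple
  act0 <- actual_fluxes(cs, N = 0, RH = 50, zenith = 35)
  expect_equal(act0$Itat, cs$Imax, tolerance = 1e-9)
  expect_equal(act0$Gtat, cs$Gmax, tolerance = 1e-9)
  expect_equal(act0$Dtat, cs$Dmax, tolerance = 1e-9)
})

test_that("actual fluxes: decomposition, fog rule, override handling", {
  cs <- clear_sky_fluxes(42, 1, 0, 3.5, 15)
  cosz <- cos(42 * pi / 180)
  for (N in c(0, 3, 6, 8)) {
    a <- actual_fluxes(cs, N = N, RH = 60, zenith = 42)
    expect_equal(a$Gtat, a$Itat * cosz + a$Dtat, tolerance = 0.5)
    expect_lte(a$Itat, cs$Imax + 1e-9)
  }
  # fog: everything diffuse
  fog <- actual_fluxes(cs, N = 2, RH = 95, foglimit = 90, zenith = 42)
  expect_equal(fog$Itat, 0)
  expect_equal(fog$Dtat, fog$Gtat)
  # G override wins and splits by DGratio
  ov <- actual_fluxes(cs, N = 2, G_override = 200, DGratio = 0.4,
                      RH = 50, zenith = 42)
  expect_equal(ov$Gtat, 200)
  expect_equal(ov$Dtat, 80)
  expect_error(actual_fluxes(cs, G_override = -5, RH = 50, zenith = 42),
               ">= 0")
  expect_warning(actual_fluxes(cs, G_override = 5 * cs$Gmax, RH = 50,
                               zenith = 42), "retained")
  # RedGChk reduces the preset by the sky-view factor
  red <- actual_fluxes(cs, G_override = 200, RH = 50, zenith = 42,
                       RedGChk = TRUE, OmegaF = 0.6)
  expect_equal(red$Gtat, 120)
})

test_that("longwave stage: Stefan-Boltzmann anchors and cloud enhancement", {
  # night with surface pinned at Ta
  lw <- surface_and_longwave(Ta = 10, VP = 9, N = 0, Gtat = 0,
                             Tob_override = 10)
  expect_equal(lw$Eu, 0.97 * sigma * 283.15 ^ 4)
  expect_equal(lw$Es, lw$Eu)   # (Ta+Tob)/2 = Ta
  # clouds enhance atmospheric emission
  a0 <- surface_and_longwave(Ta = 20, VP = 11.7, N = 0, Gtat = 0)$A
  a8 <- surface_and_longwave(Ta = 20, VP = 11.7, N = 8, Gtat = 0)$A
  expect_gt(a8, a0)
  expect_true(a0 > 280 && a0 < 360)  # clear-sky emissivity bracket
  # strong sun heats the surface above air temperature
  hot <- surface_and_longwave(Ta = 25, VP = 15, N = 0, Gtat = 800,
                              zenith = 20)
  expect_gt(hot$Tob, 25)
})

test_that("tmrt_compose: isothermal identity, monotonicity, reduction", {
  f20 <- 0.97 * sigma * 293.15 ^ 4
  expect_equal(tmrt_compose(0, 0, 0, f20, f20, f20, zenith = 40), 20,
               tolerance = 1e-6)
  base <- tmrt_compose(0, 0, 0, f20, f20, f20, zenith = 40)
  expect_gt(tmrt_compose(100, 0, 0, f20, f20, f20, zenith = 40), base)
  # monotone in every flux component
  args0 <- list(Itat = 200, Dtat = 80, Gtat = 250, A = 330, Eu = 420,
                Es = 400, zenith = 45)
  t0 <- do.call(tmrt_compose, args0)
  for (nm in c("Itat", "Dtat", "A", "Eu", "Es")) {
    args <- args0
    args[[nm]] <- args[[nm]] + 60
    expect_gt(do.call(tmrt_compose, args), t0)
  }
  expect_error(tmrt_compose(-1, 0, 0, 300, 300, 300, zenith = 45),
               ">= 0")
})

test_that("tmrt_calc: paper-style worked calls and night behaviour", {
  st <- site_time(121.5, 23.5, 30, day_of_year = 210, hour_of_day = 15.8,
                  timezone_offset = 8)
  b <- tmrt_calc(Ta = 20, RH = 50, v = 0.1, site = st,
                 config = radiation_config(N = 6))
  fields <- c("Tmrt", "VP", "Imax", "Gmax", "Dmax", "Itat", "Gtat",
              "Dtat", "A", "Eu", "Es", "Tob")
  expect_true(all(fields %in% names(b)))
  expect_true(all(vapply(b[fields], is.finite, logical(1))))
  expect_true(all(unlist(b[c("Imax", "Gmax", "Dmax", "Itat", "Gtat",
                             "Dtat", "A", "Eu", "Es")]) >= 0))
  expect_lt(b$Gtat, b$Gmax)            # N = 6 attenuates
  expect_equal(b$VP, vp_rh_exchange(20, RH = 50))

  # midnight: longwave only, Tmrt at or below air temperature
  stn <- site_time(121.5, 23.5, 30, day_of_year = 210, hour_of_day = 0,
                   timezone_offset = 8)
  bn <- tmrt_calc(Ta = 20, RH = 50, v = 0.1, site = stn)
  expect_equal(bn$Itat + bn$Gtat + bn$Dtat, 0)
  expect_lte(bn$Tmrt, 21)

  # reduced sky view lowers Tmrt under clear noon sky
  noon <- site_time(121.5, 23.5, 30, day_of_year = 210,
                    hour_of_day = 12.2, timezone_offset = 8)
  t1 <- tmrt_calc(Ta = 20, RH = 50, v = 0.1, site = noon)$Tmrt
  t5 <- tmrt_calc(Ta = 20, RH = 50, v = 0.1, site = noon,
                  config = radiation_config(OmegaF = 0.5))$Tmrt
  expect_lt(t5, t1)

  expect_error(tmrt_calc(Ta = 20, RH = 50, v = 0.1), "site")
  expect_error(tmrt_calc(Ta = 20, RH = 50, VP = 20, v = 0.1, site = st),
               "inconsistent")
})
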