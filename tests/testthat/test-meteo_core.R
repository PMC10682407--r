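test_that("saturation vapour pressure: anchors, monotonicity, convexity", {
  expect_equal(saturation_vapor_pressure(0), 6.107)
  # hand evaluation of the Magnus formula: 6.107 * 10^(150/257.3)
  expect_equal(saturation_vapor_pressure(20), 6.107 * 10 ^ (150 / 257.3))
  expect_equal(saturation_vapor_pressure(20), 23.378, tolerance = 1e-4)
  expect_gt(saturation_vapor_pressure(30), saturation_vapor_pressure(20))

  ta <- seq(-30, 50, by = 0.5)
  es <- saturation_vapor_pressure(ta)
  expect_true(all(diff(es) > 0))
  expect_true(all(diff(diff(es)) > 0))  # convex (finite differences)

  expect_error(saturation_vapor_pressure(-61), "-60")
  expect_error(saturation_vapor_pressure(85), "80")
})

test_that("vp_rh_exchange: worked values, edge cases, round trip", {
  expect_equal(vp_rh_exchange(Ta = 20, RH = 50),
               saturation_vapor_pressure(20) / 2)
  expect_equal(vp_rh_exchange(Ta = 20, RH = 50), 11.69, tolerance = 1e-3)
  expect_equal(vp_rh_exchange(Ta = 13, RH = 0), 0)
  expect_error(vp_rh_exchange(20), "exactly one")
  expect_error(vp_rh_exchange(20, VP = 10, RH = 50), "exactly one")
  expect_warning(out <- vp_rh_exchange(Ta = 10, VP = 30), "capped")
  expect_equal(out, 100)

  set.seed(42)
  ta <- stats::runif(1000, -30, 45)
  rh <- stats::runif(1000, 0, 100)
  back <- vp_rh_exchange(ta, VP = vp_rh_exchange(ta, RH = rh))
  expect_equal(back, rh, tolerance = 1e-6)
})

test_that("wind_at_height: worked value, identities, composition", {
  expect_equal(wind_at_height(8.5, 60), 8.5 * (1.1 / 60) ^ 0.12)
  expect_equal(wind_at_height(8.5, 60), 5.26, tolerance = 1e-2)
  expect_equal(wind_at_height(3.0, 1.1), 3.0)
  expect_equal(wind_at_height(0, 25), 0)
  expect_error(wind_at_height(2, 0), "> 0")

  v60_10 <- wind_at_height(7, 60, target_height = 10)
  expect_equal(wind_at_height(v60_10, 10), wind_at_height(7, 60),
               tolerance = 1e-9)
})

test_that("meteo_record fills the missing humidity form and validates", {
  r <- meteo_record(Ta = 20, RH = 50, v = 1, Tmrt = 25)
  expect_equal(r$VP, vp_rh_exchange(20, RH = 50))
  r2 <- meteo_record(Ta = 20, VP = 12.5, v = 1, Tmrt = 25)
  expect_equal(r2$RH, 100 * 12.5 / saturation_vapor_pressure(20))
  expect_error(meteo_record(Ta = 20, VP = 20, RH = 30, v = 1, Tmrt = 20),
               "inconsistent")
  expect_error(meteo_record(Ta = 20, v = 1, Tmrt = 20), "VP or RH")
  expect_error(meteo_record(Ta = 20, RH = 50, v = -1, Tmrt = 20), "v must")
})

test_that("subject_profile defaults and validation follow the contract", {
  s <- subject_profile()
  expect_equal(s[c("work", "ht", "mbody", "age", "sex", "pos")],
               list(work = 80, ht = 1.75, mbody = 75, age = 35, sex = 1,
                    pos = 1))
  expect_null(s$icl)
  expect_true(s$auto_clo)
  expect_equal(subject_profile(gender = 2)$sex, 2)
  expect_error(subject_profile(sex = 3), "sex")
  expect_error(subject_profile(mbody = -1), "> 0")
  # DuBois area of the default subject
  expect_equal(dubois_area(s), 0.203 * 75 ^ 0.425 * 1.75 ^ 0.725)
})
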