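test_that("two-node stays near neutral in a neutral environment", {
  rec <- meteo_record(Ta = 28.5, RH = 50, v = 0.1, Tmrt = 28.5)
  st <- two_node_simulate(rec)
  expect_lt(abs(st$Tsk - 33.7), 1.5)
  expect_true(st$Tcore > 36.3 && st$Tcore < 37.5)
})

test_that("extreme heat saturates wettedness at the cap; minutes = 0 is identity", {
  rec <- meteo_record(Ta = 45, RH = 80, v = 0.1, Tmrt = 45)
  st <- two_node_simulate(rec)
  wmax <- 0.59 * 0.1 ^ (-0.08)     # clothed wettedness cap of the model
  expect_gte(st$w, 0.99 * min(wmax, 1))

  st0 <- two_node_simulate(rec, minutes = 0)
  expect_equal(st0$Tcore, 36.8)
  expect_equal(st0$Tsk, 33.7)
  expect_equal(st0$skin_blood_flow, 6.3)
})

test_that("state invariants hold across a range of environments", {
  set.seed(3)
  for (i in 1:20) {
    rec <- meteo_record(Ta = stats::runif(1, -5, 40), RH = stats::runif(1, 20, 95),
                        v = stats::runif(1, 0.1, 3),
                        Tmrt = stats::runif(1, -5, 60))
    st <- two_node_simulate(rec)
    expect_true(st$w >= 0.06 && st$w <= 1)
    expect_true(st$alpha >= 0.04 && st$alpha <= 0.35)
    if (rec$Ta <= 28 && rec$Tmrt <= 28) expect_gt(st$Tcore, st$Tsk)
  }
})

test_that("SET* reflexivity: standard environment maps near itself", {
  subj0 <- subject_profile()
  clo_s <- standard_clo(met_units_of(subj0))
  for (ta in c(18, 22, 25, 28, 32)) {
    rec <- meteo_record(Ta = ta, RH = 50, v = 0.15, Tmrt = ta)
    s <- set_star(rec, subject_profile(icl = clo_s))
    expect_lt(abs(s - ta), 0.5)
  }
})

test_that("SET* is finite, bracketed and monotone in radiant load", {
  rec <- meteo_record(Ta = 20, RH = 50, v = 0.1, Tmrt = 20)
  s <- set_star(rec)
  expect_true(is.finite(s) && s > 10 && s < 25)
  s_hot <- set_star(meteo_record(Ta = 20, RH = 50, v = 0.1, Tmrt = 40))
  expect_gt(s_hot, s)
})

test_that("SET* monotone in Ta and continuous (no > 2 K jumps per 0.1 K)", {
  ta <- seq(10, 35, by = 0.5)
  s <- vapply(ta, function(t) {
    set_star(meteo_record(Ta = t, RH = 50, v = 0.3, Tmrt = t))
  }, numeric(1))
  expect_true(all(diff(s) > 0))
  # continuity at finer resolution around a mid-range point
  ta_f <- seq(24, 26, by = 0.1)
  s_f <- vapply(ta_f, function(t) {
    set_star(meteo_record(Ta = t, RH = 50, v = 0.3, Tmrt = t))
  }, numeric(1))
  expect_lt(max(abs(diff(s_f))), 2)
})
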