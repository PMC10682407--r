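# comfort-standard validation rows (Ta = Tmrt unless stated; M in met,
# icl in clo); expected PMV from the published standard's table,
# confirmed before the build
iso_rows <- data.frame(
  ta = c(22, 27, 27, 19, 23.5),
  v = c(0.10, 0.10, 0.30, 0.10, 0.30),
  rh = c(60, 60, 60, 40, 40),
  met = c(1.2, 1.2, 1.2, 1.2, 1.2),
  clo = c(0.5, 0.5, 0.5, 1.0, 1.0),
  pmv = c(-0.75, 0.77, 0.44, -0.60, 0.12))

test_that("PMV matches the comfort-standard validation rows to 0.1", {
  for (i in seq_len(nrow(iso_rows))) {
    r <- iso_rows[i, ]
    rec <- meteo_record(Ta = r$ta, RH = r$rh, v = r$v, Tmrt = r$ta)
    p <- pmv_calc(rec, subject_profile(icl = r$clo),
                  met_rate = r$met * 58.15)
    expect_lt(abs(p$PMV - r$pmv), 0.1)
  }
})

test_that("paper-style call returns a finite cool-side vote", {
  p <- pmv_calc(meteo_record(Ta = 20, VP = 12.5, v = 0.1, Tmrt = 20))
  expect_true(all(vapply(p[c("PMV", "Teq", "hclo")], is.finite,
                         logical(1))))
  expect_lt(p$PMV, 0)   # 20 degC, 0.6 clo, light activity is cool-side
})

test_that("Teq is the zero of the load: re-feeding gives PMV ~ 0", {
  set.seed(11)
  for (i in 1:50) {
    ta <- stats::runif(1, 5, 35)
    tmrt <- ta + stats::runif(1, -5, 15)
    v <- stats::runif(1, 0.1, 2)
    rh <- stats::runif(1, 25, 85)
    rec <- meteo_record(Ta = ta, RH = rh, v = v, Tmrt = tmrt)
    p <- pmv_calc(rec, subject_profile(icl = 0.8))
    rec_eq <- meteo_record(Ta = p$Teq, RH = rh, v = v, Tmrt = p$Teq)
    p_eq <- pmv_calc(rec_eq, subject_profile(icl = 0.8))
    expect_lt(abs(p_eq$PMV), 0.05)
  }
})

test_that("PMV monotone in Ta and Tmrt; wind cools below skin temperature", {
  base <- function(ta = 22, tmrt = 22, v = 0.15) {
    pmv_calc(meteo_record(Ta = ta, RH = 50, v = v, Tmrt = tmrt))$PMV
  }
  expect_gt(base(ta = 26), base(ta = 22))
  expect_gt(base(tmrt = 30), base(tmrt = 22))
  expect_lt(base(v = 1.5), base(v = 0.15))
})

test_that("hclo is a positive dry flow in the cold and continuous in icl", {
  rec <- meteo_record(Ta = 5, RH = 60, v = 0.5, Tmrt = 5)
  p <- pmv_calc(rec, subject_profile(icl = 1.2))
  expect_gt(p$hclo, 0)
  h1 <- pmv_calc(rec, subject_profile(icl = 1.2))$hclo
  h2 <- pmv_calc(rec, subject_profile(icl = 1.201))$hclo
  expect_lt(abs(h1 - h2), 1)
})
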