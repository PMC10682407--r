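closure <- function(st) {
  st$h + st$Ere + st$csum + st$rsum + st$Ed + st$Esw
}

test_that("memi_solve closes the energy balance in the reference climate", {
  st <- memi_solve(ref_record(21))
  expect_lt(abs(closure(st)), 0.1)
  expect_true(all(vapply(st, function(x) all(is.finite(x)), logical(1))))
})

test_that("hot radiant and cold environments show the expected physiology", {
  hot <- memi_solve(meteo_record(Ta = 30, VP = 21, v = 1.0, Tmrt = 60))
  expect_gt(hot$Tsk, 34)
  expect_lt(hot$Esw, 0)
  expect_gt(hot$wetsk, 0.2)

  cold1 <- memi_solve(meteo_record(Ta = -5, VP = 3, v = 1, Tmrt = -5))
  cold3 <- memi_solve(meteo_record(Ta = -5, VP = 3, v = 3, Tmrt = -5))
  expect_lt(cold1$csum, 0)
  expect_gt(abs(cold3$csum), abs(cold1$csum))
})

test_that("PET is the identity on the reference manifold", {
  for (ta in seq(-10, 40, by = 5)) {
    p <- suppressWarnings(pet_calc(ref_record(ta)))
    expect_lt(abs(p$PET - ta), 0.2)
  }
})

test_that("PET matches the source publication's hot radiant example to 1 K", {
  # tabulated worked example of the PET source model:
  # Ta=30, Tmrt=60, v=1.0, VP=21 -> PET ~ 43 degC
  p <- suppressWarnings(
    pet_calc(meteo_record(Ta = 30, VP = 21, v = 1.0, Tmrt = 60)))
  expect_lt(abs(p$PET - 43), 1)
})

test_that("PET is insensitive to small VP changes near reference", {
  p12 <- suppressWarnings(
    pet_calc(meteo_record(Ta = 22, VP = 12, v = 0.1, Tmrt = 22)))
  p125 <- suppressWarnings(
    pet_calc(meteo_record(Ta = 22, VP = 12.5, v = 0.1, Tmrt = 22)))
  expect_lt(abs(p12$PET - p125$PET), 0.3)
})

test_that("PET strictly increases with Tmrt at fixed Ta", {
  pets <- vapply(c(20, 35, 50, 65), function(tmrt) {
    suppressWarnings(
      pet_calc(meteo_record(Ta = 24, VP = 15, v = 0.5, Tmrt = tmrt)))$PET
  }, numeric(1))
  expect_true(all(diff(pets) > 0))
})

test_that("flux closure holds on random in-range conditions", {
  set.seed(5)
  for (i in 1:25) {
    rec <- meteo_record(Ta = stats::runif(1, -10, 35),
                        RH = stats::runif(1, 20, 95),
                        v = stats::runif(1, 0.1, 5),
                        Tmrt = stats::runif(1, -10, 60))
    st <- memi_solve(rec)
    expect_lt(abs(closure(st)), 0.5)
    expect_gte(st$Tcore, st$Tsk - 1)
    expect_true(st$wetsk >= 0 && st$wetsk <= 1)
  }
})
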