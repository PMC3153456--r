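test_that("channel rates keep the fast/slow ratio structural", {
  r <- channelRates(defaultParameters())
  expect_identical(r[["beta_fast_1"]] / r[["beta_slow_1"]], 10)
  expect_identical(r[["beta_fast_2"]] / r[["beta_slow_2"]], 10)

  r1 <- channelRates(kineticParameters(rate_ratio_fast_slow = 1))
  expect_identical(r1[["beta_fast_1"]], r1[["beta_slow_1"]])
  expect_identical(r1[["beta_fast_2"]], r1[["beta_slow_2"]])

  p <- defaultParameters()
  doubled <- kineticParameters(beta_slow_2 = 2 * p@beta_slow_2)
  expect_identical(channelRates(doubled)[["beta_fast_2"]],
                   2 * channelRates(p)[["beta_fast_2"]])
})

test_that("no synthesis happens without RP; dis-synthesis still returns complexes", {
  st <- cellState(dsb = 200, rdsbc = 10, mdsbc = 4)
  out <- stepDsbc(st, defaultParameters())
  expect_identical(out$synth_fast_1 + out$synth_fast_2 +
                     out$synth_slow_1 + out$synth_slow_2, 0)
  expect_gt(out$rdsbc_dissynth, 0)
  expect_gt(out$mdsbc_dissynth, 0)
  expect_equal(dsbTotal(out$state),
               200 + out$rdsbc_dissynth + out$mdsbc_dissynth,
               tolerance = 1e-12)
})

test_that("dis-synthesis follows the closed-form decay and refills DSB and RP", {
  p <- kineticParameters(delta_r = 0.1)
  st <- cellState(rdsbc = 5, params = p)
  out <- stepDsbc(st, p)
  expected <- 5 * (1 - exp(-0.1))
  expect_equal(out$rdsbc_dissynth, expected, tolerance = 1e-12)
  expect_equal(dsbTotal(out$state), expected, tolerance = 1e-12)
  expect_equal(out$state@rp, expected, tolerance = 1e-12)
  expect_equal(out$state@rdsbc, 5 - expected, tolerance = 1e-12)
})

test_that("misrepair split and flux sum are conserved per step", {
  st <- cellState(dsb = 500, rp = 300)
  out <- stepDsbc(st, defaultParameters())
  total <- out$synth_fast_1 + out$synth_fast_2 + out$synth_slow_1 +
    out$synth_slow_2
  expect_equal(out$rdsbc_gain + out$mdsbc_gain, total, tolerance = 1e-12)
  expect_gt(total, 0)
  expect_lte(total, 300 + 1e-12)          # bounded by available RP
  expect_lte(total, 500 + 1e-12)          # and by available DSBs
})

test_that("second-order flux is quadratic in cohort size at fixed RP share", {
  # all DSBs slow, only the second-order channel active, RP effectively
  # unlimited so the share factor is ~1
  p <- kineticParameters(f_fast = 0, beta_slow_1 = 0, beta_slow_2 = 1e-5,
                         delta_r = 0, delta_m = 0)
  flux2 <- function(n) {
    st <- cellState(dsb = n, rp = 1e12, params = p)
    stepDsbc(st, p)$synth_slow_2
  }
  expect_equal(flux2(200) / flux2(100), 4, tolerance = 1e-6)
  expect_equal(flux2(1000) / flux2(500), 4, tolerance = 1e-6)
})

test_that("synthesis is monotone in RP at fixed DSB and in DSB at fixed RP", {
  p <- defaultParameters()
  totalSynth <- function(dsb, rp) {
    out <- stepDsbc(cellState(dsb = dsb, rp = rp, params = p), p)
    out$synth_fast_1 + out$synth_fast_2 + out$synth_slow_1 + out$synth_slow_2
  }
  by_rp <- vapply(c(0, 1, 10, 100, 1000, 1e4), totalSynth, numeric(1),
                  dsb = 400)
  expect_true(all(diff(by_rp) >= 0))
  by_dsb <- vapply(c(0, 10, 100, 500, 2000), totalSynth, numeric(1),
                   rp = 500)
  expect_true(all(diff(by_dsb) >= 0))
})

test_that("a 1000-DSB bolus routes 70% through the fast kinetics", {
  b <- repairBolus(1000, defaultParameters())
  expect_equal(b$fast_fraction, 0.70, tolerance = 1e-9)
  expect_equal(b$fast_repaired + b$slow_repaired, 1000, tolerance = 1e-6)
})
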