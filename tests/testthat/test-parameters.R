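test_that("default parameter set is valid and carries the anchored values", {
  p <- defaultParameters()
  expect_length(validateParameters(p), 0)
  expect_identical(p@a_ir, 35)
  expect_identical(p@f_fast, 0.70)
  expect_identical(p@rate_ratio_fast_slow, 10)
  r <- channelRates(p)
  expect_identical(r[["beta_fast_1"]] / r[["beta_slow_1"]], 10)
  expect_identical(r[["beta_fast_2"]] / r[["beta_slow_2"]], 10)
})

test_that("validation reports violations by field without raising", {
  bad <- kineticParameters(f_fast = 1.3)
  v <- validateParameters(bad)
  expect_length(v, 1)
  expect_match(v, "f_fast")

  v <- validateParameters(kineticParameters(d_mrna = -0.1))
  expect_match(v, "d_mrna", all = FALSE)

  v <- validateParameters(kineticParameters(p_misrepair_slow_2 = 2))
  expect_match(v, "p_misrepair_slow_2", all = FALSE)

  # an externally supplied rate mapping with equal fast and slow rates
  # breaks the structural ratio constraint
  p <- defaultParameters()
  rates <- channelRates(p)
  rates[["beta_fast_1"]] <- rates[["beta_slow_1"]]
  v <- validateParameters(p, rates = rates)
  expect_length(v, 1)
  expect_match(v, "rate_ratio_fast_slow")
})

test_that("unknown or unnamed parameter overrides are rejected", {
  expect_error(kineticParameters(not_a_field = 1), "unknown parameter")
  expect_error(kineticParameters(1), "named")
})

test_that("configuration files round-trip field for field", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  p <- kineticParameters(beta_slow_1 = 0.123, lambda_tox = 4.5e-7,
                         new_dna_feedback = TRUE)
  writeConfig(p, cellType(gamma_dna = 0.6), cfg)
  back <- readConfig(cfg)
  for (s in slotNames("KineticParameters"))
    expect_identical(slot(back$params, s), slot(p, s), label = s)
  expect_identical(back$cell@gamma_dna, 0.6)
  expect_identical(back$cell@gamma_gene, 0.8)
})

test_that("unknown config keys error and missing keys warn with defaults", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines("a_ir: 35\nbogus_key: 1", cfg)
  expect_error(readConfig(cfg), "bogus_key")

  writeLines("a_ir: 40\nf_fast: 0.5", cfg)
  expect_warning(back <- readConfig(cfg), "missing")
  expect_identical(back$params@a_ir, 40)
  expect_identical(back$params@f_fast, 0.5)
  expect_identical(back$params@theta_rp, defaultParameters()@theta_rp)
})

test_that("cell-type coefficients are bounded in [0, 1]", {
  expect_error(cellType(gamma_dna = 1.4), "0, 1")
  expect_identical(cellType()@gamma_gene, 0.8)
})
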