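test_that("DSB induction is Poisson with mean k_t * a_ir * dose", {
  p <- defaultParameters()
  expect_identical(sampleDsbCount(0, p, mode = "mean-field"), 0)
  set.seed(1)
  expect_identical(sampleDsbCount(0, p), 0L)
  expect_identical(sampleDsbCount(8, p, mode = "mean-field"), 280)
  expect_identical(sampleDsbCount(8, kineticParameters(k_t = 0.5),
                                  mode = "mean-field"), 140)
  expect_error(sampleDsbCount(-1, p), "non-negative")

  set.seed(42)
  x <- sampleDsbCount(1, p, n = 20000)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 35), 3 * se)
})

test_that("the empirical damage mean scales linearly with dose", {
  p <- defaultParameters()
  set.seed(7)
  m2 <- mean(sampleDsbCount(2, p, n = 20000))
  m4 <- mean(sampleDsbCount(4, p, n = 20000))
  se <- sqrt(2 * 35 / 20000 + 4 * 35 / 20000)  # SE of m4 - 2 m2 is larger;
  expect_lt(abs(m4 - 2 * m2), 6 * se)          # conservative allowance
  expect_lt(abs(m4 / m2 - 2), 0.05)
})

test_that("a zero-dose damage step leaves the state unchanged", {
  st <- cellState(dsb = 10, rp = 5)
  r <- stepDamage(st, 0, defaultParameters(), cellType())
  expect_identical(r$new_dsbs, 0L)
  expect_identical(r$dna_destroyed, 0)
  expect_identical(r$gene_destroyed, 0)
  for (s in slotNames("CellState"))
    expect_identical(slot(r$state, s), slot(st, s), label = s)
})

test_that("repair gene decays monotonically toward zero and never returns", {
  res <- runSimulation(doseProfile(8, 400), mode = "mean-field")
  gene <- trajectory(res)$repair_gene
  expect_true(all(diff(gene) < 0))
  expect_true(all(gene >= 0))
  expect_lt(gene[length(gene)], gene[1])
})

test_that("without repair, DSBs and DNA accumulate and the generation ledger equals the pool", {
  p <- kineticParameters(beta_slow_1 = 0, beta_slow_2 = 0,
                         delta_r = 0, delta_m = 0)
  res <- runSimulation(doseProfile(8, 200), params = p,
                       initial = cellState(params = p), mode = "mean-field")
  tr <- trajectory(res)
  expect_equal(tr$dsb, tr$cum_dsb_generated, tolerance = 1e-12)
  expect_true(all(diff(tr$dsb) > 0))
  expect_true(all(diff(tr$dna) > 0))
})

test_that("new DNA feeds back into the breakable substrate only when enabled", {
  p_off <- defaultParameters()
  p_on <- kineticParameters(new_dna_feedback = TRUE)
  r_off <- stepDamage(cellState(params = p_off), 8, p_off, cellType(),
                      mode = "mean-field")
  r_on <- stepDamage(cellState(params = p_on), 8, p_on, cellType(),
                     mode = "mean-field")
  expect_identical(r_off$state@dna, r_on$state@dna)
  expect_lt(r_off$state@dna_intact, r_on$state@dna_intact)
})
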