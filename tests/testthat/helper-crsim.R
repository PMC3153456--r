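# Shared fixtures for the crsim suite. Everything is generated in code.

# Parameter set with fast-relaxing enzyme pools (time constants ~20
# time-scales) so fixed-point burn-ins converge in a few hundred steps.
fastRelaxParams <- function(...) {
  kineticParameters(d_mrna = 0.05, d_rp = 0.05, ...)
}

# Closed-form zero-IR fixed point of the enzyme kinetics: with no DSBs the
# production/degradation balance gives mrna* = k_mrna_basal G / d_mrna and
# rp* = k_rp_basal mrna* / d_rp.
zeroIrFixedPoint <- function(params, gene) {
  mrna <- params@k_mrna_basal * gene / params@d_mrna
  rp <- params@k_rp_basal * mrna / params@d_rp
  list(mrna = mrna, rp = rp)
}

# Brute-force scan oracles for the detection operations; deliberately
# plain loops, independent of the vectorized implementations.
bruteFirstBelow <- function(series, epsilon, after = 0) {
  for (i in seq_along(series)) {
    t <- i - 1
    if (t >= after && series[i] < epsilon) return(t)
  }
  NA_real_
}

bruteSignChange <- function(deltas, window = 1, after = 0) {
  n <- length(deltas)
  if (n == 0) return(NA_real_)
  sm <- numeric(n)
  for (i in seq_len(n)) sm[i] <- mean(deltas[max(1, i - window + 1):i])
  pos_seen <- FALSE
  for (i in seq_len(n)) {
    if (pos_seen && sm[i] < 0 && i - 1 >= after) return(i - 1)
    if (sm[i] > 0) pos_seen <- TRUE
  }
  NA_real_
}

# Ledger residuals that must vanish at every recorded step of any run.
ledgerResiduals <- function(result) {
  tr <- trajectory(result)
  first <- tr[1, ]
  dsb_res <- (first$dsb + tr$cum_dsb_generated + tr$cum_dissynthesized) -
    (tr$dsb + tr$cum_synthesized)
  rp_res <- (first$rp + tr$cum_rp_produced - tr$cum_rp_degraded -
               (tr$rdsbc + tr$mdsbc - first$rdsbc - first$mdsbc)) - tr$rp
  list(dsb = dsb_res, rp = rp_res,
       scale = pmax(1, tr$cum_dsb_generated + tr$cum_rp_produced))
}
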