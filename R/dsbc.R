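#' Realized DSBC synthesis channel rates
#'
#' The four synthesis channels combine the fast/slow kinetics with the
#' first-order (ends of the same DSB rejoined; flux linear in cohort size)
#' and second-order (ends of two different DSBs rejoined; flux quadratic)
#' processes. The fast rates are derived structurally from the slow ones,
#' so \code{beta_fast_j / beta_slow_j == rate_ratio_fast_slow} holds
#' exactly for both orders.
#'
#' @param params a \code{\linkS4class{KineticParameters}}.
#' @return named numeric with elements \code{beta_fast_1},
#'   \code{beta_fast_2}, \code{beta_slow_1}, \code{beta_slow_2}.
#' @examples
#' r <- channelRates(defaultParameters())
#' r[["beta_fast_1"]] / r[["beta_slow_1"]]   # exactly 10
#' @export
channelRates <- function(params) {
  c(beta_fast_1 = params@rate_ratio_fast_slow * params@beta_slow_1,
    beta_fast_2 = params@rate_ratio_fast_slow * params@beta_slow_2,
    beta_slow_1 = params@beta_slow_1,
    beta_slow_2 = params@beta_slow_2)
}

# Internal DSBC synthesis / dis-synthesis update on a plain list state.
#
# Raw channel demands are beta_i1 * cohort + beta_i2 * cohort^2 (times the
# global RP-DSB encounter coefficient). RP limitation is a saturating
# share rp / (rp + total demand); the realized fluxes are then capped so
# no cohort and not more RP than available is consumed. One RP binds per
# DSB in a complex; dis-synthesis releases exactly one of each, which
# keeps the DSB-pairing and RP ledgers exact. DSBs returned by
# dis-synthesis re-enter the free pool and are re-routed fast/slow at
# f_fast, consistent with cohort assignment at (re)generation time.
.step_dsbc <- function(s, params) {
  rt <- channelRates(params)
  e <- params@eta_rp_dsb
  d_f1 <- e * rt[["beta_fast_1"]] * s$dsb_fast
  d_f2 <- e * rt[["beta_fast_2"]] * s$dsb_fast^2
  d_s1 <- e * rt[["beta_slow_1"]] * s$dsb_slow
  d_s2 <- e * rt[["beta_slow_2"]] * s$dsb_slow^2
  raw <- d_f1 + d_f2 + d_s1 + d_s2
  share <- if (raw > 0) s$rp / (s$rp + raw) else 0
  f1 <- d_f1 * share; f2 <- d_f2 * share
  s1 <- d_s1 * share; s2 <- d_s2 * share
  # never consume more than a cohort holds
  tot_f <- f1 + f2
  if (tot_f > s$dsb_fast && tot_f > 0) {
    k <- s$dsb_fast / tot_f; f1 <- f1 * k; f2 <- f2 * k
  }
  tot_s <- s1 + s2
  if (tot_s > s$dsb_slow && tot_s > 0) {
    k <- s$dsb_slow / tot_s; s1 <- s1 * k; s2 <- s2 * k
  }
  total <- f1 + f2 + s1 + s2
  if (total > s$rp && total > 0) {
    k <- s$rp / total
    f1 <- f1 * k; f2 <- f2 * k; s1 <- s1 * k; s2 <- s2 * k
    total <- s$rp
  }
  mg <- params@p_misrepair_fast_1 * f1 + params@p_misrepair_fast_2 * f2 +
    params@p_misrepair_slow_1 * s1 + params@p_misrepair_slow_2 * s2
  rg <- total - mg
  rdis <- s$rdsbc * (1 - exp(-params@delta_r))
  mdis <- s$mdsbc * (1 - exp(-params@delta_m))
  returned <- rdis + mdis

  s$dsb_fast <- s$dsb_fast - (f1 + f2) + params@f_fast * returned
  s$dsb_slow <- s$dsb_slow - (s1 + s2) + (1 - params@f_fast) * returned
  s$rp <- s$rp - total + returned
  s$rdsbc <- s$rdsbc + rg - rdis
  s$mdsbc <- s$mdsbc + mg - mdis
  s$cum_synthesized <- s$cum_synthesized + total
  s$cum_dissynthesized <- s$cum_dissynthesized + returned
  s$cum_synth_fast <- s$cum_synth_fast + f1 + f2
  s$cum_synth_slow <- s$cum_synth_slow + s1 + s2
  list(state = s, synth_fast_1 = f1, synth_fast_2 = f2,
       synth_slow_1 = s1, synth_slow_2 = s2,
       rdsbc_gain = rg, mdsbc_gain = mg,
       rdsbc_dissynth = rdis, mdsbc_dissynth = mdis)
}

#' Apply one time-scale of DSBC synthesis and dis-synthesis
#'
#' Synthesizes DSB-protein complexes from the free DSB cohorts and the RP
#' pool through the four channels of \code{\link{channelRates}}, splits
#' each channel's flux into correctly repaired (rDSBC) and misrepaired
#' (mDSBC) complexes by the per-channel misrepair fractions, and returns
#' dis-synthesized complexes (\code{delta_r}, \code{delta_m}) to the free
#' DSB and RP pools. Synthesis consumes equal amounts of DSB and RP and is
#' limited by whichever is scarce; with no RP at all, only dis-synthesis
#' fluxes can be non-zero.
#'
#' @param state a \code{\linkS4class{CellState}}.
#' @param params a \code{\linkS4class{KineticParameters}}.
#' @return a list with elements \code{state} (updated \code{CellState}),
#'   per-channel fluxes \code{synth_fast_1}, \code{synth_fast_2},
#'   \code{synth_slow_1}, \code{synth_slow_2}, the outcome split
#'   \code{rdsbc_gain}, \code{mdsbc_gain}, and the dis-synthesis fluxes
#'   \code{rdsbc_dissynth}, \code{mdsbc_dissynth}.
#' @examples
#' st <- cellState(dsb = 100, rp = 50)
#' stepDsbc(st, defaultParameters())
#' @export
stepDsbc <- function(state, params) {
  validObject(state)
  r <- .step_dsbc(.state_as_list(state), params)
  r$state <- .state_from_list(r$state)
  r
}

#' Route a DSB bolus to exhaustion through the repair channels
#'
#' Mean-field experiment isolating the fast/slow routing: an initial bolus
#' of DSBs is split into cohorts at \code{f_fast}, RP is clamped abundant
#' (so the RP share is effectively 1), dis-synthesis is disabled so the
#' free pool can actually empty, and synthesis is iterated until the free
#' DSB pool falls below \code{tol}. The per-cohort synthesis ledgers then
#' give the fraction of the bolus repaired through the fast kinetics,
#' which equals \code{f_fast} by construction of cohort assignment.
#'
#' @param n_dsb bolus size (default 1000).
#' @param params a \code{\linkS4class{KineticParameters}}.
#' @param tol free-DSB exhaustion threshold.
#' @param max_steps safety cap on the number of time-scales iterated.
#' @return a list with \code{fast_fraction} (fraction of synthesized
#'   complexes that came from the fast cohort), \code{fast_repaired},
#'   \code{slow_repaired}, \code{steps}.
#' @examples
#' repairBolus(1000, defaultParameters())$fast_fraction   # 0.70
#' @export
repairBolus <- function(n_dsb = 1000, params = defaultParameters(),
                        tol = 1e-6, max_steps = 100000L) {
  params@delta_r <- 0
  params@delta_m <- 0
  rp_clamp <- 1e9 * (n_dsb + 1)
  s <- .state_as_list(cellState(dsb = n_dsb, rp = rp_clamp,
                                params = params))
  steps <- 0L
  while (s$dsb_fast + s$dsb_slow >= tol && steps < max_steps) {
    s <- .step_dsbc(s, params)$state
    s$rp <- rp_clamp
    steps <- steps + 1L
  }
  if (s$dsb_fast + s$dsb_slow >= tol)
    warning("bolus not exhausted within max_steps")
  list(fast_fraction = s$cum_synth_fast /
         (s$cum_synth_fast + s$cum_synth_slow),
       fast_repaired = s$cum_synth_fast,
       slow_repaired = s$cum_synth_slow,
       steps = steps)
}
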