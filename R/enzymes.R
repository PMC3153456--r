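# Saturation factor for threshold-limited production: 1 up to the
# threshold, then (theta / (theta + (x - theta)))^2. The square makes the
# interaction flux x * sat(x) peak at the threshold and decay toward 0
# beyond it (a first-power factor would only plateau), so production
# genuinely collapses under damage overload.
.sat <- function(x, theta) {
  if (theta <= 0) return(as.numeric(x <= theta))
  (theta / (theta + pmax(0, x - theta)))^2
}

# Exact one-step update of x' = P - d * x over one time-scale with P held
# constant (exponential-Euler). Returns the new pool plus the effective
# produced/degraded amounts, whose difference is exactly the pool change.
.exp_euler <- function(x, P, d) {
  if (d <= 0) return(list(x = x + P, produced = P, degraded = 0))
  a <- exp(-d)
  list(x = x * a + P * (1 - a) / d,
       produced = P * (1 - a) / d,
       degraded = x * (1 - a))
}

#' Repair-mRNA transcription rate
#'
#' Instantaneous transcription flux of repair mRNA from the repair gene:
#' a basal term \code{k_mrna_basal * gene} plus a mass-action encounter
#' term \code{eta_gene_dsb * gene * dsb} damped by a saturation factor that
#' equals 1 up to \code{theta_mrna} DSBs and decreases beyond it, modelling
#' the fall-off of transcription once damage overruns the threshold the
#' machinery can respond to. At \code{dsb = 0} the flux is exactly the
#' basal term; it is never below it.
#'
#' @param dsb free DSB count (>= 0).
#' @param gene repair-gene abundance (>= 0).
#' @param params a \code{\linkS4class{KineticParameters}}.
#' @return transcription flux (molecules per time-scale).
#' @examples
#' p <- defaultParameters()
#' transcriptionFlux(0, 100, p)     # basal: k_mrna_basal * 100
#' transcriptionFlux(500, 100, p)
#' @export
transcriptionFlux <- function(dsb, gene, params) {
  if (any(dsb < 0) || any(gene < 0)) stop("dsb and gene must be >= 0")
  params@k_mrna_basal * gene +
    params@eta_gene_dsb * gene * dsb * .sat(dsb, params@theta_mrna)
}

#' Repair-protein translation rate
#'
#' Instantaneous translation flux of RP from repair mRNA: basal term
#' \code{k_rp_basal * mrna} plus the mRNA-DSB encounter term damped beyond
#' \code{theta_rp}, structured exactly as \code{\link{transcriptionFlux}}.
#'
#' @param dsb free DSB count (>= 0).
#' @param mrna repair-mRNA abundance (>= 0).
#' @param params a \code{\linkS4class{KineticParameters}}.
#' @return translation flux (molecules per time-scale).
#' @export
translationFlux <- function(dsb, mrna, params) {
  if (any(dsb < 0) || any(mrna < 0)) stop("dsb and mrna must be >= 0")
  params@k_rp_basal * mrna +
    params@eta_mrna_dsb * mrna * dsb * .sat(dsb, params@theta_rp)
}

# Internal enzyme-kinetics update on a plain list state. Production fluxes
# are held constant over the step at their start-of-step values; each pool
# then evolves by the exact linear production/degradation solution, so the
# zero-IR fixed point of the discrete scheme coincides with the
# continuous-time balance mrna* = k_mrna_basal G / d_mrna,
# rp* = k_rp_basal mrna* / d_rp.
.step_enzymes <- function(s, params) {
  dsb <- s$dsb_fast + s$dsb_slow
  tf <- transcriptionFlux(dsb, s$repair_gene, params)
  up_m <- .exp_euler(s$mrna, tf, params@d_mrna)
  lf <- translationFlux(dsb, s$mrna, params)
  up_r <- .exp_euler(s$rp, lf, params@d_rp)
  s$mrna <- up_m$x
  s$rp <- up_r$x
  s$cum_rp_produced <- s$cum_rp_produced + up_r$produced
  s$cum_rp_degraded <- s$cum_rp_degraded + up_r$degraded
  list(state = s, mrna_produced = up_m$produced,
       mrna_degraded = up_m$degraded, rp_produced = up_r$produced,
       rp_degraded = up_r$degraded)
}

#' Apply one time-scale of repair-enzyme kinetics
#'
#' Advances the repair-mRNA and RP pools by one time-scale: production at
#' the start-of-step \code{\link{transcriptionFlux}} and
#' \code{\link{translationFlux}} rates, first-order self-degradation at
#' \code{d_mrna} and \code{d_rp}, integrated exactly for the linear
#' production/degradation system so pools can never go negative. The RP
#' production/degradation ledgers are updated with the realized per-step
#' amounts.
#'
#' @param state a \code{\linkS4class{CellState}}.
#' @param params a \code{\linkS4class{KineticParameters}}.
#' @return a list with elements \code{state} (updated \code{CellState}) and
#'   the per-step fluxes \code{mrna_produced}, \code{mrna_degraded},
#'   \code{rp_produced}, \code{rp_degraded}.
#' @examples
#' st <- cellState(repair_gene = 100)
#' stepEnzymes(st, defaultParameters())
#' @export
stepEnzymes <- function(state, params) {
  validObject(state)
  r <- .step_enzymes(.state_as_list(state), params)
  r$state <- .state_from_list(r$state)
  r
}
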