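#' Sample the number of DSBs induced in one time-scale
#'
#' The number of double-strand breaks induced per time-scale is Poisson
#' with mean \code{k_t * a_ir * dose}: the mean is linear in dose, with
#' \code{a_ir} breaks per Gy (default 35, within the measured 30-40
#' DSBs/Gy) and \code{k_t} a per-time-scale scaling. In mean-field mode the
#' draw is replaced by its expectation.
#'
#' @param dose IR dose in Gy (scalar, >= 0).
#' @param params a \code{\linkS4class{KineticParameters}}.
#' @param mode \code{"stochastic"} (Poisson draw from the current RNG
#'   stream) or \code{"mean-field"}.
#' @param n number of draws.
#' @return numeric vector of length \code{n}; integer-valued in stochastic
#'   mode.
#' @examples
#' sampleDsbCount(8, defaultParameters(), mode = "mean-field")  # 280
#' set.seed(1); sampleDsbCount(1, defaultParameters(), n = 5)
#' @export
sampleDsbCount <- function(dose, params, mode = c("stochastic", "mean-field"),
                           n = 1L) {
  mode <- match.arg(mode)
  if (!is.numeric(dose) || length(dose) != 1L || is.na(dose) || dose < 0)
    stop("dose must be a single non-negative number (Gy)")
  m <- params@k_t * params@a_ir * dose
  if (mode == "mean-field") rep(m, n) else stats::rpois(n, m)
}

# Internal per-step damage update on a plain list state. Returns the
# updated list plus the realized fluxes. The destruction fluxes use
# survival-fraction updates pool * (1 - exp(-gamma * mu * dose)) so no pool
# can go negative at any rate or dose. New DNA from DSBs credits the
# displayed DNA ledger; it re-enters the breakable substrate only when
# params@new_dna_feedback is TRUE.
.step_damage <- function(s, dose, params, cell, mode) {
  new_dsbs <- sampleDsbCount(dose, params, mode)
  dna_destroyed <- s$dna_intact * (1 - exp(-cell@gamma_dna *
                                             params@mu_dna_rate * dose))
  gene_destroyed <- s$repair_gene * (1 - exp(-cell@gamma_gene *
                                               params@mu_gene_rate * dose))
  new_dna <- params@nu_new_dna * new_dsbs
  s$dna_intact <- s$dna_intact - dna_destroyed +
    if (params@new_dna_feedback) new_dna else 0
  s$dna <- s$dna - dna_destroyed + new_dna
  s$repair_gene <- s$repair_gene - gene_destroyed
  s$dsb_fast <- s$dsb_fast + params@f_fast * new_dsbs
  s$dsb_slow <- s$dsb_slow + (1 - params@f_fast) * new_dsbs
  s$cum_dsb_generated <- s$cum_dsb_generated + new_dsbs
  list(state = s, new_dsbs = new_dsbs, dna_destroyed = dna_destroyed,
       gene_destroyed = gene_destroyed)
}

#' Apply one time-scale of radiation damage
#'
#' Draws the stochastic DSB count for the step (see
#' \code{\link{sampleDsbCount}}), destroys DNA and repair gene with
#' cell-type-scaled survival fractions, credits each resulting DSB to the
#' DNA ledger as a new DNA, and routes the new DSBs into the fast/slow
#' repair cohorts (fraction \code{f_fast} fast). Destroyed repair gene is
#' permanently removed: the model has no gene synthesis, so the gene pool
#' is non-increasing.
#'
#' @param state a \code{\linkS4class{CellState}}.
#' @param dose IR dose in Gy for this time-scale.
#' @param params a \code{\linkS4class{KineticParameters}}.
#' @param cell a \code{\linkS4class{CellTypeCoefficients}}.
#' @param mode \code{"stochastic"} or \code{"mean-field"}.
#' @return a list with elements \code{state} (updated
#'   \code{CellState}), \code{new_dsbs}, \code{dna_destroyed} and
#'   \code{gene_destroyed}.
#' @examples
#' st <- cellState()
#' stepDamage(st, 8, defaultParameters(), cellType(), mode = "mean-field")
#' @export
stepDamage <- function(state, dose, params, cell,
                       mode = c("stochastic", "mean-field")) {
  mode <- match.arg(mode)
  validObject(state)
  r <- .step_damage(.state_as_list(state), dose, params, cell, mode)
  r$state <- .state_from_list(r$state)
  r
}
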