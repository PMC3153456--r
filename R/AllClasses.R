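#' @import methods
NULL

.scalar <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

#' Cell-type radiosensitivity coefficients
#'
#' The cell type enters the model as two dimensionless sensitivities in
#' \eqn{[0, 1]} that scale the destruction of genomic DNA and of the repair
#' gene under ionizing radiation. A radioresistant cell type has small
#' coefficients, a sensitive one values near 1; the reference cell type used
#' throughout is 0.8 for both.
#'
#' @slot gamma_dna sensitivity of DNA destruction under IR.
#' @slot gamma_gene sensitivity of repair-gene destruction under IR.
#' @exportClass CellTypeCoefficients
setClass("CellTypeCoefficients",
  representation(gamma_dna = "numeric", gamma_gene = "numeric"),
  prototype(gamma_dna = 0.8, gamma_gene = 0.8),
  validity = function(object) {
    msg <- character()
    for (s in c("gamma_dna", "gamma_gene")) {
      v <- slot(object, s)
      if (!.scalar(v)) msg <- c(msg, paste0(s, " must be a single numeric"))
      else if (v < 0 || v > 1) msg <- c(msg, paste0(s, " must lie in [0, 1]"))
    }
    if (length(msg)) msg else TRUE
  }
)

# Numeric scalar slots of KineticParameters, in config-file order.
.kp_fields <- c(
  "k_t", "a_ir",
  "mu_dna_rate", "mu_gene_rate", "nu_new_dna",
  "k_mrna_basal", "k_rp_basal", "d_mrna", "d_rp",
  "eta_gene_dsb", "eta_mrna_dsb", "eta_rp_dsb",
  "theta_mrna", "theta_rp",
  "f_fast", "rate_ratio_fast_slow",
  "beta_slow_1", "beta_slow_2",
  "p_misrepair_fast_1", "p_misrepair_fast_2",
  "p_misrepair_slow_1", "p_misrepair_slow_2",
  "delta_r", "delta_m",
  "theta_tox", "lambda_tox", "s0"
)

#' Rate constants and thresholds of the cellular repair system
#'
#' Container for every kinetic constant of the model. All rates are per
#' time-scale (the abstract discrete simulation unit); abundances are
#' molecule counts. The four DSBC synthesis channel rates are parameterized
#' by the two slow-channel rates plus \code{rate_ratio_fast_slow}, so the
#' fast/slow rate ratio is structural: \code{beta_fast_j} is always derived
#' as \code{rate_ratio_fast_slow * beta_slow_j} (see
#' \code{\link{channelRates}}).
#'
#' @slot k_t per-time-scale DSB-count scaling of the Poisson damage mean.
#' @slot a_ir mean DSBs induced per Gy of IR dose.
#' @slot mu_dna_rate external interaction rate of DNA with IR (per Gy per
#'   time-scale).
#' @slot mu_gene_rate external interaction rate of the repair gene with IR.
#' @slot nu_new_dna DNA-ledger credit per resulting DSB (each break is
#'   counted as a new DNA).
#' @slot k_mrna_basal basal transcription rate of repair mRNA per repair
#'   gene.
#' @slot k_rp_basal basal induction rate of RP per repair mRNA.
#' @slot d_mrna,d_rp first-order self-degradation rates of mRNA and RP.
#' @slot eta_gene_dsb,eta_mrna_dsb,eta_rp_dsb encounter-rate coefficients of
#'   the gene-DSB, mRNA-DSB and RP-DSB binary interactions.
#' @slot theta_mrna,theta_rp DSB-count thresholds past which transcription
#'   and translation rates begin to fall off.
#' @slot f_fast fraction of newly generated DSBs routed to the fast repair
#'   kinetics.
#' @slot rate_ratio_fast_slow fast/slow channel rate ratio.
#' @slot beta_slow_1,beta_slow_2 slow-channel first- and second-order
#'   synthesis rates.
#' @slot p_misrepair_fast_1,p_misrepair_fast_2,p_misrepair_slow_1,p_misrepair_slow_2
#'   per-channel fractions of synthesis flux yielding misrepaired complexes.
#' @slot delta_r,delta_m dis-synthesis rates of rDSBC and mDSBC back into a
#'   free DSB plus RP.
#' @slot theta_tox toxin burden a cell can carry without loss of genome
#'   stability.
#' @slot lambda_tox rate at which excess toxins erode genome stability.
#' @slot s0 initial genome-stability level.
#' @slot new_dna_feedback logical; if \code{TRUE}, DSB-derived new DNA also
#'   re-enters the breakable substrate pool (default \code{FALSE}: ledger
#'   only).
#' @seealso \code{\link{defaultParameters}}, \code{\link{validateParameters}}
#' @exportClass KineticParameters
setClass("KineticParameters",
  representation = do.call(representation, c(
    as.list(setNames(rep("numeric", length(.kp_fields)), .kp_fields)),
    list(new_dna_feedback = "logical")
  )),
  validity = function(object) {
    msg <- character()
    for (s in .kp_fields) {
      if (!.scalar(slot(object, s)))
        msg <- c(msg, paste0(s, " must be a single non-missing numeric"))
    }
    if (length(object@new_dna_feedback) != 1L || is.na(object@new_dna_feedback))
      msg <- c(msg, "new_dna_feedback must be a single logical")
    if (length(msg)) msg else TRUE
  }
)

#' Ionizing-radiation dose profile
#'
#' A piecewise-constant dose schedule over discrete time-scales: segment
#' \code{i} applies \code{dose[i]} Gy for \code{n_steps[i]} consecutive
#' time-scales. A constant-dose run is a single segment.
#'
#' @slot n_steps integer vector of segment lengths (time-scales).
#' @slot dose numeric vector of per-segment doses (Gy, >= 0).
#' @seealso \code{\link{doseProfile}}, \code{\link{doseVector}}
#' @exportClass DoseProfile
setClass("DoseProfile",
  representation(n_steps = "integer", dose = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@n_steps) != length(object@dose))
      msg <- c(msg, "n_steps and dose must have equal length")
    if (any(is.na(object@n_steps)) || any(object@n_steps < 0L))
      msg <- c(msg, "all segment lengths must be non-negative integers")
    if (any(is.na(object@dose)) || any(object@dose < 0))
      msg <- c(msg, "all doses must be >= 0 Gy")
    if (length(msg)) msg else TRUE
  }
)

# Scalar slots of CellState. dsb is carried as the fast/slow cohorts
# assigned at generation time; dna_intact is the breakable substrate while
# dna is the displayed ledger (substrate plus DSB-derived new DNA).
.cs_fields <- c(
  "dna", "dna_intact", "repair_gene", "dsb_fast", "dsb_slow",
  "mrna", "rp", "rdsbc", "mdsbc", "toxins", "stability",
  "cum_dsb_generated", "cum_synthesized", "cum_dissynthesized",
  "cum_rp_produced", "cum_rp_degraded", "cum_synth_fast", "cum_synth_slow"
)

#' Instantaneous state of the cellular repair system
#'
#' Abundances of all active particles of the two sub-populations (DNA
#' damage: DNA, DSB, rDSBC, mDSBC; repair enzyme: repair gene, repair mRNA,
#' RP), the derived toxin burden and genome stability, and the cumulative
#' conservation ledgers that the integrator keeps exact. Abundances are
#' real-valued (mean-field continuous kinetics); only the stochastic DSB
#' draw is integer.
#'
#' @slot dna displayed DNA count (substrate plus DSB-derived new DNA).
#' @slot dna_intact breakable DNA substrate.
#' @slot repair_gene repair-gene abundance; destroyed gene never returns.
#' @slot dsb_fast,dsb_slow free DSBs in the fast and slow repair cohorts.
#' @slot mrna,rp repair mRNA and repair protein pools.
#' @slot rdsbc,mdsbc correctly repaired and misrepaired DSB-protein
#'   complexes.
#' @slot toxins mDSBC plus intact DSB burden.
#' @slot stability genome stability in \code{[0, s0]}, non-increasing.
#' @slot cum_dsb_generated,cum_synthesized,cum_dissynthesized,cum_rp_produced,cum_rp_degraded
#'   non-decreasing conservation ledgers.
#' @slot cum_synth_fast,cum_synth_slow per-cohort synthesis ledgers.
#' @seealso \code{\link{cellState}}, \code{\link{advanceState}}
#' @exportClass CellState
setClass("CellState",
  representation = do.call(representation,
    as.list(setNames(rep("numeric", length(.cs_fields)), .cs_fields))),
  validity = function(object) {
    msg <- character()
    for (s in .cs_fields) {
      v <- slot(object, s)
      if (!.scalar(v)) msg <- c(msg, paste0(s, " must be a single numeric"))
      else if (v < -1e-12) msg <- c(msg, paste0(s, " must be >= 0"))
    }
    if (length(msg)) msg else TRUE
  }
)

#' Specification of a complete simulation run
#'
#' Bundles everything a run needs: the dose profile, kinetic parameters,
#' cell-type coefficients, initial state, RNG seed, integration mode and
#' recording stride.
#'
#' @slot profile a \code{\linkS4class{DoseProfile}}.
#' @slot params a \code{\linkS4class{KineticParameters}}.
#' @slot cell a \code{\linkS4class{CellTypeCoefficients}}.
#' @slot initial a \code{\linkS4class{CellState}}.
#' @slot seed integer RNG seed (\code{NA} allowed in mean-field mode).
#' @slot mode \code{"stochastic"} or \code{"mean-field"}.
#' @slot record_every positive integer recording stride.
#' @seealso \code{\link{runSpec}}, \code{\link{runSimulation}}
#' @exportClass RunSpec
setClass("RunSpec",
  representation(profile = "DoseProfile", params = "KineticParameters",
                 cell = "CellTypeCoefficients", initial = "CellState",
                 seed = "integer", mode = "character",
                 record_every = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("stochastic", "mean-field"))
      msg <- c(msg, "mode must be 'stochastic' or 'mean-field'")
    if (length(object@record_every) != 1L || is.na(object@record_every) ||
        object@record_every < 1L)
      msg <- c(msg, "record_every must be a positive integer")
    if (identical(object@mode, "stochastic") &&
        (length(object@seed) != 1L || is.na(object@seed)))
      msg <- c(msg, "stochastic mode requires an integer seed")
    if (length(msg)) msg else TRUE
  }
)

#' Result of a simulation run
#'
#' The recorded trajectory (one row per recorded time-scale, including
#' t = 0), the realized per-step stochastic DSB draws, and the full run
#' specification needed to reproduce it bit for bit.
#'
#' @slot trajectory data.frame of the recorded state time-series.
#' @slot dsb_draws numeric vector of realized per-step DSB counts (length
#'   \code{totalSteps(profile)}).
#' @slot params,cell,profile the run inputs.
#' @slot seed integer seed used (\code{NA} in mean-field mode).
#' @slot mode \code{"stochastic"} or \code{"mean-field"}.
#' @seealso \code{\link{runSimulation}}, \code{\link{trajectory}},
#'   \code{\link{indicatorReport}}
#' @exportClass SimulationResult
setClass("SimulationResult",
  representation(trajectory = "data.frame", dsb_draws = "numeric",
                 params = "KineticParameters",
                 cell = "CellTypeCoefficients",
                 profile = "DoseProfile", seed = "integer",
                 mode = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("stochastic", "mean-field"))
      msg <- c(msg, "mode must be 'stochastic' or 'mean-field'")
    if (nrow(object@trajectory) < 1L)
      msg <- c(msg, "trajectory must contain at least the initial state")
    if (length(msg)) msg else TRUE
  }
)

#' Derived indicator report
#'
#' Indicator tracks read off a simulation (repair capability = RP
#' available; cellular activity = per-step rDSBC synthesis flux; toxin
#' burden; genome stability) together with detected threshold times.
#' Detected times are time-scale indices, or \code{NA} when the event never
#' occurs within the run.
#'
#' @slot tracks data.frame with columns \code{t}, \code{rp_available},
#'   \code{rdsbc_flux}, \code{toxins}, \code{stability}.
#' @slot t_mrna_zero first time-scale (at or after the mRNA peak) at which
#'   repair mRNA falls below \code{epsilon}.
#' @slot t_rp_peak time-scale of the RP maximum.
#' @slot t_rdsbc_sign_change first time-scale at which the smoothed change
#'   of the rDSBC synthesis flux turns negative after having been positive.
#' @slot t_stability_half first time-scale with stability below half its
#'   initial level.
#' @slot epsilon near-zero threshold used for \code{t_mrna_zero}.
#' @slot window smoothing window (time-scales) used for the sign-change
#'   detection.
#' @seealso \code{\link{indicatorReport}}, \code{\link{detectedTimes}}
#' @exportClass IndicatorReport
setClass("IndicatorReport",
  representation(tracks = "data.frame", t_mrna_zero = "numeric",
                 t_rp_peak = "numeric", t_rdsbc_sign_change = "numeric",
                 t_stability_half = "numeric", epsilon = "numeric",
                 window = "numeric"),
  validity = function(object) {
    if (nrow(object@tracks) < 1L) "tracks must be non-empty" else TRUE
  }
)
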