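#' Construct a cell state
#'
#' Builds the initial (or any) state of the cellular repair system. A free
#' DSB count given through \code{dsb} is split into the fast/slow cohorts
#' at \code{params@f_fast}; the toxin burden is derived as
#' \code{mdsbc + dsb}; stability defaults to \code{params@s0}; all
#' conservation ledgers start at zero.
#'
#' @param dna initial DNA count (breakable substrate).
#' @param repair_gene initial repair-gene abundance.
#' @param dsb initial free DSB count (split into cohorts at
#'   \code{f_fast}).
#' @param mrna,rp,rdsbc,mdsbc initial enzyme and complex pools.
#' @param stability initial genome stability; defaults to \code{params@s0}.
#' @param params a \code{\linkS4class{KineticParameters}} (used for the
#'   cohort split and the stability default).
#' @return a \code{\linkS4class{CellState}}.
#' @examples
#' cellState()                        # default initial cell
#' cellState(dsb = 1000, rp = 500)
#' @export
cellState <- function(dna = 10000, repair_gene = 100, dsb = 0, mrna = 0,
                      rp = 0, rdsbc = 0, mdsbc = 0, stability = NULL,
                      params = defaultParameters()) {
  new("CellState",
      dna = dna, dna_intact = dna, repair_gene = repair_gene,
      dsb_fast = params@f_fast * dsb, dsb_slow = (1 - params@f_fast) * dsb,
      mrna = mrna, rp = rp, rdsbc = rdsbc, mdsbc = mdsbc,
      toxins = mdsbc + dsb,
      stability = if (is.null(stability)) params@s0 else stability,
      cum_dsb_generated = 0, cum_synthesized = 0, cum_dissynthesized = 0,
      cum_rp_produced = 0, cum_rp_degraded = 0,
      cum_synth_fast = 0, cum_synth_slow = 0)
}

#' @rdname CellState-class
#' @aliases dsbTotal,CellState-method
#' @export
setMethod("dsbTotal", "CellState", function(x) x@dsb_fast + x@dsb_slow)

#' @describeIn CellState-class display method.
#' @export
setMethod("show", "CellState", function(object) {
  cat("CellState\n")
  cat(sprintf("  dna %.6g  repair_gene %.6g  dsb %.6g (fast %.6g / slow %.6g)\n",
              object@dna, object@repair_gene, dsbTotal(object),
              object@dsb_fast, object@dsb_slow))
  cat(sprintf("  mrna %.6g  rp %.6g  rdsbc %.6g  mdsbc %.6g\n",
              object@mrna, object@rp, object@rdsbc, object@mdsbc))
  cat(sprintf("  toxins %.6g  stability %.6g\n",
              object@toxins, object@stability))
  invisible(NULL)
})

# CellState <-> plain list. The hot integration loop works on lists; the
# S4 object appears only at API boundaries.
.state_as_list <- function(state) {
  setNames(lapply(.cs_fields, slot, object = state), .cs_fields)
}

.state_from_list <- function(s) {
  # absorb sub-1e-12 float drift before validity kicks in
  s <- lapply(s, function(v) if (v < 0 && v > -1e-9) 0 else v)
  do.call(new, c(list("CellState"), s))
}

# One full time-scale on a plain list state: damage -> enzymes -> DSBC
# synthesis -> toxins/stability (fixed operator-splitting order). Toxins
# are the instantaneous burden mdsbc + free DSB; stability decays
# multiplicatively by exp(-lambda_tox * excess over theta_tox), which
# keeps it in [0, s0] without clipping.
.advance <- function(s, dose, params, cell, mode) {
  dmg <- .step_damage(s, dose, params, cell, mode)
  s <- .step_enzymes(dmg$state, params)$state
  dc <- .step_dsbc(s, params)
  s <- dc$state
  s$toxins <- s$mdsbc + s$dsb_fast + s$dsb_slow
  s$stability <- s$stability *
    exp(-params@lambda_tox * max(0, s$toxins - params@theta_tox))
  bad <- vapply(s, function(v) !is.finite(v) || v < -1e-9, logical(1))
  if (any(bad))
    stop("integrator error: non-finite or negative pool(s): ",
         paste(names(s)[bad], collapse = ", "))
  list(state = s, new_dsbs = dmg$new_dsbs, rdsbc_flux = dc$rdsbc_gain)
}

#' Advance a cell state by one time-scale
#'
#' Composes the three process stages in fixed order -- radiation damage
#' (\code{\link{stepDamage}}), enzyme kinetics (\code{\link{stepEnzymes}}),
#' DSBC synthesis/dis-synthesis (\code{\link{stepDsbc}}) -- then updates
#' the toxin burden (misrepaired complexes plus intact DSBs) and decays
#' genome stability by the excess of toxins over \code{theta_tox} at rate
#' \code{lambda_tox}. Stability is non-increasing and stays in
#' \code{[0, s0]} by construction.
#'
#' @param state a \code{\linkS4class{CellState}}.
#' @param dose IR dose in Gy for this time-scale.
#' @param params a \code{\linkS4class{KineticParameters}}.
#' @param cell a \code{\linkS4class{CellTypeCoefficients}}.
#' @param mode \code{"stochastic"} or \code{"mean-field"}.
#' @return the updated \code{\linkS4class{CellState}}.
#' @examples
#' advanceState(cellState(), 8, defaultParameters(), cellType(),
#'              mode = "mean-field")
#' @export
advanceState <- function(state, dose, params, cell,
                         mode = c("stochastic", "mean-field")) {
  mode <- match.arg(mode)
  validObject(state)
  .state_from_list(
    .advance(.state_as_list(state), dose, params, cell, mode)$state)
}

#' Construct a run specification
#'
#' @param profile a \code{\linkS4class{DoseProfile}}.
#' @param params a \code{\linkS4class{KineticParameters}}.
#' @param cell a \code{\linkS4class{CellTypeCoefficients}}.
#' @param initial initial \code{\linkS4class{CellState}}.
#' @param seed integer RNG seed. Required for reproducible stochastic
#'   runs; if omitted in stochastic mode a seed is drawn and reported in a
#'   message.
#' @param mode \code{"stochastic"} or \code{"mean-field"}.
#' @param record_every recording stride in time-scales.
#' @return a \code{\linkS4class{RunSpec}}.
#' @examples
#' runSpec(doseProfile(8, 100), seed = 1)
#' @export
runSpec <- function(profile, params = defaultParameters(),
                    cell = cellType(),
                    initial = cellState(params = params), seed = NULL,
                    mode = c("stochastic", "mean-field"),
                    record_every = 1L) {
  mode <- match.arg(mode)
  if (is.null(seed)) {
    if (mode == "stochastic") {
      seed <- as.integer(Sys.time()) %% .Machine$integer.max
      message("no seed supplied; drew seed ", seed)
    } else {
      seed <- NA_integer_
    }
  }
  new("RunSpec", profile = profile, params = params, cell = cell,
      initial = initial, seed = as.integer(seed), mode = mode,
      record_every = as.integer(record_every))
}

#' Run a complete simulation
#'
#' Iterates \code{\link{advanceState}} over the dose profile, recording
#' the state at \code{t = 0} and every \code{record_every}-th time-scale
#' (the final step is always recorded), together with the realized
#' per-step DSB draws. Identical specifications with identical seeds give
#' bit-identical results; mean-field runs are seed-independent.
#'
#' @param x a \code{\linkS4class{RunSpec}}, or a
#'   \code{\linkS4class{DoseProfile}} plus the named arguments of
#'   \code{\link{runSpec}}.
#' @param ... passed to \code{\link{runSpec}} when \code{x} is a
#'   \code{DoseProfile}.
#' @return a \code{\linkS4class{SimulationResult}}.
#' @examples
#' res <- runSimulation(doseProfile(8, 50), seed = 1)
#' head(trajectory(res))
#' @export
setGeneric("runSimulation", function(x, ...) standardGeneric("runSimulation"))

#' @rdname runSimulation
#' @aliases runSimulation,DoseProfile-method
#' @export
setMethod("runSimulation", "DoseProfile", function(x, ...) {
  runSimulation(runSpec(profile = x, ...))
})

.traj_cols <- c("t", "dose_gy", "dna", "repair_gene", "dsb", "mrna", "rp",
                "rdsbc", "mdsbc", "toxins", "stability",
                "cum_dsb_generated", "cum_synthesized",
                "cum_dissynthesized", "dsb_fast", "dsb_slow", "dna_intact",
                "new_dsbs", "rdsbc_flux", "cum_rp_produced",
                "cum_rp_degraded", "cum_synth_fast", "cum_synth_slow")

.traj_row <- function(s, t, dose, new_dsbs, rdsbc_flux) {
  c(t, dose, s$dna, s$repair_gene, s$dsb_fast + s$dsb_slow, s$mrna, s$rp,
    s$rdsbc, s$mdsbc, s$toxins, s$stability, s$cum_dsb_generated,
    s$cum_synthesized, s$cum_dissynthesized, s$dsb_fast, s$dsb_slow,
    s$dna_intact, new_dsbs, rdsbc_flux, s$cum_rp_produced,
    s$cum_rp_degraded, s$cum_synth_fast, s$cum_synth_slow)
}

#' @rdname runSimulation
#' @aliases runSimulation,RunSpec-method
#' @export
setMethod("runSimulation", "RunSpec", function(x, ...) {
  validObject(x)
  stopifnot(length(validateParameters(x@params)) == 0L)
  doses <- doseVector(x@profile)
  n <- length(doses)
  stochastic <- identical(x@mode, "stochastic")
  if (stochastic) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(x@seed)
  }
  rec <- unique(c(0L, seq_len(n)[seq_len(n) %% x@record_every == 0L], n))
  rec <- sort(rec[rec <= n])
  out <- matrix(NA_real_, nrow = length(rec), ncol = length(.traj_cols),
                dimnames = list(NULL, .traj_cols))
  draws <- numeric(n)
  s <- .state_as_list(x@initial)
  ri <- 1L
  out[ri, ] <- .traj_row(s, 0L, 0, 0, 0)
  for (t in seq_len(n)) {
    st <- tryCatch(.advance(s, doses[t], x@params, x@cell, x@mode),
                   error = function(e)
                     stop("at time-scale ", t, ": ", conditionMessage(e)))
    s <- st$state
    draws[t] <- st$new_dsbs
    if (t %in% rec) {
      ri <- ri + 1L
      out[ri, ] <- .traj_row(s, t, doses[t], st$new_dsbs, st$rdsbc_flux)
    }
  }
  new("SimulationResult", trajectory = as.data.frame(out),
      dsb_draws = draws, params = x@params, cell = x@cell,
      profile = x@profile, seed = x@seed, mode = x@mode)
})

#' @rdname SimulationResult-class
#' @aliases trajectory,SimulationResult-method
#' @export
setMethod("trajectory", "SimulationResult", function(x) x@trajectory)

#' @rdname SimulationResult-class
#' @aliases dsbDraws,SimulationResult-method
#' @export
setMethod("dsbDraws", "SimulationResult", function(x) x@dsb_draws)

#' @describeIn SimulationResult-class display method.
#' @export
setMethod("show", "SimulationResult", function(object) {
  tr <- object@trajectory
  last <- tr[nrow(tr), ]
  cat("SimulationResult:", object@mode, "run,",
      totalSteps(object@profile), "time-scales",
      if (!is.na(object@seed)) paste0("(seed ", object@seed, ")") else "",
      "\n")
  cat(sprintf("  final: dsb %.4g  rp %.4g  rdsbc %.4g  toxins %.4g  stability %.4g\n",
              last$dsb, last$rp, last$rdsbc, last$toxins, last$stability))
  invisible(NULL)
})
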