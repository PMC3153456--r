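#' First time a series falls below a threshold
#'
#' Scans a per-time-scale series (position \code{i} of the vector is
#' time-scale \code{i - 1}) for the first time-scale at or after
#' \code{after} whose value is strictly below \code{epsilon}. Supports
#' reading "tends to zero" times off simulation tracks.
#'
#' @param series numeric vector indexed by time-scale (first element is
#'   time-scale 0).
#' @param epsilon strictly positive threshold.
#' @param after earliest time-scale (0-based) eligible for detection.
#' @return the detected time-scale (0-based), or \code{NA} if the series
#'   never falls below \code{epsilon} at or after \code{after}.
#' @examples
#' firstBelow(c(3, 2, 1, 0.05), 0.1)   # 3
#' firstBelow(c(3, 2, 1), 0.1)         # NA
#' @export
firstBelow <- function(series, epsilon, after = 0) {
  stopifnot(epsilon > 0)
  hit <- which(series < epsilon & seq_along(series) - 1 >= after)
  if (length(hit)) hit[1] - 1 else NA_real_
}

#' First positive-to-negative sign change of a smoothed delta series
#'
#' Applies a right-aligned moving average of width \code{window} to a
#' series of per-time-scale changes and returns the first index (0-based)
#' at which the smoothed delta is negative after having been positive at
#' some earlier index. Supports reading "increases until t*, then
#' decreases" turning points off noisy tracks.
#'
#' @param deltas numeric vector of per-step changes.
#' @param window moving-average window in steps (>= 1). Positions with
#'   fewer than \code{window} predecessors average what is available.
#' @param after earliest index (0-based) eligible for detection; the
#'   positive stretch may lie before it.
#' @return 0-based index of the detected sign change, or \code{NA} if the
#'   smoothed series never turns negative after a positive stretch.
#' @examples
#' signChangeTime(c(1, 2, 1, -1, -2), 1)   # 3
#' signChangeTime(c(1, 2, 3), 1)           # NA
#' @export
signChangeTime <- function(deltas, window = 1L, after = 0) {
  stopifnot(window >= 1)
  n <- length(deltas)
  if (n == 0L) return(NA_real_)
  cs <- cumsum(deltas)
  i <- seq_len(n)
  lo <- pmax(i - window, 0L)
  sm <- (cs - c(0, cs)[lo + 1L]) / (i - lo)
  seen_pos <- cumsum(sm > 0) > 0
  hit <- which(sm < 0 & c(FALSE, seen_pos[-n]) & i - 1 >= after)
  if (length(hit)) hit[1] - 1 else NA_real_
}

#' Derive the indicator report of a simulation
#'
#' Extracts the three indicator tracks the model is read through --
#' repair capability (RP available), cellular activity (per-step rDSBC
#' synthesis flux) and genome burden (toxins, stability) -- and detects
#' the characteristic times: the post-peak near-zero crossing of repair
#' mRNA, the RP peak, the turning point of the rDSBC flux, and the
#' half-stability time. The report is a pure function of the result.
#'
#' @param result a \code{\linkS4class{SimulationResult}} recorded at
#'   stride 1 (\code{record_every = 1}).
#' @param epsilon near-zero threshold for the mRNA collapse; defaults to
#'   1\% of the mRNA track maximum.
#' @param window smoothing window (time-scales) for the rDSBC turning
#'   point; default 25.
#' @return an \code{\linkS4class{IndicatorReport}}.
#' @examples
#' res <- runSimulation(doseProfile(8, 200), seed = 1)
#' detectedTimes(indicatorReport(res))
#' @export
indicatorReport <- function(result, epsilon = NULL, window = 25L) {
  tr <- trajectory(result)
  if (nrow(tr) < 2L) stop("result must contain at least one step")
  if (any(diff(tr$t) != 1))
    stop("indicator detection needs a stride-1 trajectory (record_every = 1)")
  if (is.null(epsilon)) {
    epsilon <- 0.01 * max(tr$mrna)
    if (epsilon <= 0) epsilon <- .Machine$double.eps
  }
  tracks <- data.frame(t = tr$t, rp_available = tr$rp,
                       rdsbc_flux = tr$rdsbc_flux, toxins = tr$toxins,
                       stability = tr$stability)
  mrna_peak <- tr$t[which.max(tr$mrna)]
  # anchor the turning-point search at the climax of the smoothed flux so
  # transient wiggles during the ramp-up are not mistaken for the decline
  flux_sm <- stats::filter(tr$rdsbc_flux, rep(1 / window, window),
                           sides = 1)
  flux_sm[seq_len(min(window - 1, length(flux_sm)))] <- NA
  peak_i <- if (all(is.na(flux_sm))) 1L else which.max(flux_sm)
  d0 <- signChangeTime(diff(tr$rdsbc_flux), window, after = peak_i - 1L)
  new("IndicatorReport", tracks = tracks,
      t_mrna_zero = firstBelow(tr$mrna, epsilon, after = mrna_peak),
      t_rp_peak = tr$t[which.max(tr$rp)],
      t_rdsbc_sign_change = if (is.na(d0)) NA_real_ else tr$t[d0 + 2],
      t_stability_half = firstBelow(tr$stability,
                                    0.5 * result@params@s0, after = 0),
      epsilon = epsilon, window = as.numeric(window))
}

#' @rdname IndicatorReport-class
#' @aliases detectedTimes,IndicatorReport-method
#' @export
setMethod("detectedTimes", "IndicatorReport", function(x) {
  c(t_mrna_zero = x@t_mrna_zero, t_rp_peak = x@t_rp_peak,
    t_rdsbc_sign_change = x@t_rdsbc_sign_change,
    t_stability_half = x@t_stability_half)
})

#' @rdname IndicatorReport-class
#' @aliases indicatorTracks,IndicatorReport-method
#' @export
setMethod("indicatorTracks", "IndicatorReport", function(x) x@tracks)

#' @describeIn IndicatorReport-class display method.
#' @export
setMethod("show", "IndicatorReport", function(object) {
  cat("IndicatorReport over", nrow(object@tracks) - 1, "time-scales\n")
  print(detectedTimes(object))
  invisible(NULL)
})
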