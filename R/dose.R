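#' Construct a dose profile
#'
#' A dose profile is a piecewise-constant schedule of IR dose over discrete
#' time-scales. \code{doseProfile(8, 2500)} is 2500 time-scales of constant
#' 8 Gy; \code{doseProfile(c(8, 0), c(100, 400))} is 100 time-scales at
#' 8 Gy followed by 400 unirradiated ones.
#'
#' @param dose numeric vector of per-segment doses (Gy, >= 0).
#' @param n_steps integer vector of segment lengths (time-scales),
#'   recycled against \code{dose}.
#' @return a \code{\linkS4class{DoseProfile}}.
#' @examples
#' p <- doseProfile(8, 2500)
#' totalSteps(p)
#' doseAt(p, 1)
#' @export
doseProfile <- function(dose, n_steps) {
  if (length(dose) == 0L) stop("dose profile needs at least one segment")
  n <- as.integer(n_steps)
  if (length(n) != length(dose)) {
    if (length(n) == 1L) n <- rep(n, length(dose))
    else if (length(dose) == 1L) dose <- rep(dose, length(n))
    else stop("dose and n_steps lengths differ")
  }
  new("DoseProfile", n_steps = n, dose = as.numeric(dose))
}

#' @rdname DoseProfile-class
#' @aliases totalSteps,DoseProfile-method
#' @export
setMethod("totalSteps", "DoseProfile", function(x) sum(x@n_steps))

#' @rdname DoseProfile-class
#' @aliases doseVector,DoseProfile-method
#' @export
setMethod("doseVector", "DoseProfile",
          function(x) rep(x@dose, times = x@n_steps))

#' @rdname DoseProfile-class
#' @aliases doseAt,DoseProfile,numeric-method
#' @export
setMethod("doseAt", signature("DoseProfile", "numeric"), function(x, t) {
  n <- totalSteps(x)
  if (any(t < 1 | t > n)) stop("time-scale index out of range [1, ", n, "]")
  doseVector(x)[t]
})

#' @describeIn DoseProfile-class display method.
#' @export
setMethod("show", "DoseProfile", function(object) {
  cat("DoseProfile:", length(object@dose), "segment(s),",
      totalSteps(object), "time-scales\n")
  for (i in seq_along(object@dose))
    cat(sprintf("  %d steps @ %g Gy\n", object@n_steps[i], object@dose[i]))
  invisible(NULL)
})
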