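# Mandatory TSV schema, one row per recorded time-scale.
.tsv_cols <- c("t", "dose_gy", "dna", "repair_gene", "dsb", "mrna", "rp",
               "rdsbc", "mdsbc", "toxins", "stability",
               "cum_dsb_generated", "cum_synthesized", "cum_dissynthesized")

#' Write and read simulation time-series as TSV
#'
#' \code{writeTimeseries} exports the recorded trajectory with one row per
#' recorded time-scale and the fixed column set \code{t, dose_gy, dna,
#' repair_gene, dsb, mrna, rp, rdsbc, mdsbc, toxins, stability,
#' cum_dsb_generated, cum_synthesized, cum_dissynthesized} (header row,
#' UTF-8, "." decimal). \code{readTimeseries} reads such a file back into
#' a data.frame.
#'
#' @param result a \code{\linkS4class{SimulationResult}}.
#' @param path output (input) file path.
#' @return \code{writeTimeseries}: \code{path}, invisibly.
#'   \code{readTimeseries}: a data.frame with the schema columns.
#' @examples
#' res <- runSimulation(doseProfile(8, 20), seed = 1)
#' tsv <- tempfile(fileext = ".tsv")
#' writeTimeseries(res, tsv)
#' head(readTimeseries(tsv))
#' @export
writeTimeseries <- function(result, path) {
  tr <- trajectory(result)[, .tsv_cols]
  utils::write.table(tr, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeTimeseries
#' @export
readTimeseries <- function(path) {
  tr <- utils::read.delim(path, fileEncoding = "UTF-8")
  missing <- setdiff(.tsv_cols, names(tr))
  if (length(missing))
    stop("time-series file lacks column(s): ", paste(missing, collapse = ", "))
  tr
}

#' Write an indicator report as JSON
#'
#' Serializes the detected threshold times and detection settings of an
#' \code{\linkS4class{IndicatorReport}}; absent detections are written as
#' JSON null.
#'
#' @param report an \code{\linkS4class{IndicatorReport}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path) {
  times <- as.list(detectedTimes(report))
  times <- lapply(times, function(v) if (is.na(v)) NULL else v)
  out <- list(detected_times = times,
              epsilon = report@epsilon, window = report@window,
              final = as.list(report@tracks[nrow(report@tracks),
                                            c("t", "rp_available",
                                              "toxins", "stability")]))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
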