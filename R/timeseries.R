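#' Measurement time series
#'
#' A thin data.frame wrapper holding a sampled trajectory: times in hours
#' (strictly increasing), nonnegative values (cells or pg/mL) and an
#' optional per-point spread.
#'
#' @param times sampling times (h), strictly increasing
#' @param values measured or simulated values (cells or pg/mL)
#' @param sd optional per-point standard deviation
#' @return a data.frame of class `ang_series` with columns `time_h`,
#'   `value` and `sd`
#' @export
ang_series <- function(times, values, sd = NULL) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(values)) || any(values < -1e-9))
    stop("values must be finite and nonnegative")
  if (is.null(sd)) sd <- rep(NA_real_, length(times))
  if (length(sd) != length(times)) stop("sd length mismatch")
  structure(data.frame(time_h = times, value = pmax(values, 0), sd = sd),
            class = c("ang_series", "data.frame"))
}

#' Read or write a time series as CSV
#'
#' CSV layout is `time_h,value,sd`.
#'
#' @param path file path
#' @param x an [ang_series()]
#' @return `read_series` returns an `ang_series`; `write_series` returns
#'   `path` invisibly
#' @export
read_series <- function(path) {
  d <- read.csv(path)
  ang_series(d$time_h, d$value, if ("sd" %in% names(d)) d$sd else NULL)
}

#' @rdname read_series
#' @export
write_series <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
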