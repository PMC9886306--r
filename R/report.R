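#' Relative error in percent
#'
#' `|model - data| / |data| * 100`, the convention used throughout the
#' calibration error tables. A zero data value yields `NA` with a
#' warning (such cells are flagged rather than reported, since the
#' relative error would blow up).
#'
#' @param model_value,data_value numeric vectors (recycled)
#' @return relative errors (%)
#' @export
relative_error <- function(model_value, data_value) {
  out <- abs(model_value - data_value) / abs(data_value) * 100
  if (any(data_value == 0)) {
    warning("zero data value: relative error undefined, returning NA")
    out[data_value == 0] <- NA_real_
  }
  out
}

#' Mean and sample standard deviation of per-day errors
#'
#' The summary convention of the error tables: arithmetic mean and the
#' n-1 (sample) standard deviation.
#'
#' @param errors numeric vector of per-day error percentages
#' @return named vector `c(mean, sd)`
#' @export
error_summary <- function(errors) {
  errors <- errors[!is.na(errors)]
  if (!length(errors)) stop("no errors to summarize")
  c(mean = mean(errors),
    sd = if (length(errors) >= 2) sd(errors) else NA_real_)
}

#' Assemble a per-day error table with a summary row
#'
#' Rounds for display with half-up rounding at one decimal place (the
#' printed convention); full precision is retained in the returned
#' `values` attribute.
#'
#' @param days day labels
#' @param ... named numeric columns of per-day error percentages
#' @return data.frame with one row per day plus an `Average` row
#' @export
error_table <- function(days, ...) {
  cols <- list(...)
  stopifnot(length(cols) >= 1, !is.null(names(cols)))
  round_half_up <- function(x, d = 1) floor(x * 10^d + 0.5) / 10^d
  out <- data.frame(day = as.character(days))
  for (nm in names(cols)) out[[nm]] <- round_half_up(cols[[nm]])
  avg <- vapply(cols, function(x) round_half_up(mean(x, na.rm = TRUE)), 0)
  out <- rbind(out, c(day = "Average", as.list(avg)))
  attr(out, "values") <- cols
  out
}

#' Write an error table as CSV or Markdown
#'
#' @param tab output of [error_table()]
#' @param path destination; `.md` extension emits a Markdown pipe table,
#'   anything else CSV
#' @return `path`, invisibly
#' @export
write_error_table <- function(tab, path) {
  if (grepl("\\.md$", path)) {
    hdr <- paste0("| ", paste(names(tab), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
    rows <- apply(tab, 1, function(r)
      paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(hdr, sep, rows), path)
  } else {
    write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}
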