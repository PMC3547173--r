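# Spectral data container and text-format I/O.

#' Single-channel power spectrum
#'
#' The unit of fitting: a frequency grid (Hz) with non-negative real
#' power values and a free-text label.
#'
#' @param freqs Strictly increasing temporal frequencies (Hz).
#' @param power Non-negative finite power values, one per frequency.
#' @param label Free-text label (subject/condition).
#' @return An object of class `spectral_data` (a list with elements
#'   `freqs`, `power`, `label`).
#' @export
spectral_data <- function(freqs, power, label = "") {
  freqs <- as.numeric(freqs)
  power <- as.numeric(power)
  if (length(freqs) != length(power))
    stop("freqs and power must have equal length")
  if (any(diff(freqs) <= 0)) stop("freqs must be strictly increasing")
  if (any(!is.finite(power)) || any(power < 0))
    stop("power must be finite and non-negative")
  structure(list(freqs = freqs, power = power, label = as.character(label)),
            class = "spectral_data")
}

#' @export
print.spectral_data <- function(x, ...) {
  cat(sprintf("Power spectrum%s: %d bins, %g-%g Hz\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' @export
as.data.frame.spectral_data <- function(x, ...) {
  data.frame(frequency_hz = x$freqs, power = x$power)
}

#' @export
plot.spectral_data <- function(x, ..., xlab = "frequency (Hz)",
                               ylab = "power", type = "l") {
  graphics::plot(x$freqs, x$power, type = type, xlab = xlab, ylab = ylab,
                 main = x$label, ...)
  invisible(x)
}

#' Read / write spectra as CSV, TSV or JSON
#'
#' Text round-trip with header columns `frequency_hz`, `power`
#' (CSV/TSV), or a JSON object with the same fields plus `label`.
#' Numbers are written with full precision so the textual representation
#' round-trips bit-stably.
#'
#' @param path File path; format chosen by extension (`.csv`, `.tsv`,
#'   `.json`).
#' @param label Label to attach when the format does not carry one.
#' @return A `spectral_data` object (`read_spectrum`) or `path`
#'   invisibly (`write_spectrum`).
#' @export
read_spectrum <- function(path, label = "") {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$frequency_hz) || is.null(obj$power))
      stop("malformed spectrum JSON: need fields frequency_hz, power")
    return(spectral_data(obj$frequency_hz, obj$power,
                         label = if (!is.null(obj$label)) obj$label else label))
  }
  sep <- if (ext == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("frequency_hz", "power") %in% names(df)))
    stop("malformed spectrum table: need columns frequency_hz, power")
  spectral_data(df$frequency_hz, df$power, label = label)
}

#' @rdname read_spectrum
#' @param x A `spectral_data` object.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "spectral_data"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(list(frequency_hz = x$freqs, power = x$power,
                              label = x$label),
                         path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  sep <- if (ext == "tsv") "\t" else ","
  df <- data.frame(frequency_hz = sprintf("%.17g", x$freqs),
                   power = sprintf("%.17g", x$power))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
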