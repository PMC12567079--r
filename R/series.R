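#' Display time series
#'
#' Container for the 1-D vertical-position trace of the edge male at a fixed
#' sampling rate. Positions are raw raster pixel coordinates (the image y-axis
#' points downward, so a higher flight is a *smaller* y). This is the object
#' all recurrence quantification operates on.
#'
#' @param y Numeric vector of vertical positions (pixels, raster orientation).
#' @param fps Sampling rate in frames per second.
#' @param t0 Time of the first sample in seconds.
#' @param meta Named list of provenance fields (court id, display id,
#'   `n_males`, source, ...). Free-form.
#'
#' @return An object of class `display_series`.
#' @export
display_series <- function(y, fps, t0 = 0, meta = list()) {
  y <- as.numeric(y)
  if (length(y) < 2L) stop("a display series needs at least 2 samples")
  if (anyNA(y)) stop("display series must not contain missing values")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("`fps` must be a single positive number")
  structure(list(y = y, fps = fps, t0 = t0, meta = meta),
            class = "display_series")
}

#' @export
print.display_series <- function(x, ...) {
  cat(sprintf("<display_series> %d samples @ %g fps (%.2f s)\n",
              length(x$y), x$fps, length(x$y) / x$fps))
  cat(sprintf("  y range: [%.1f, %.1f] px\n", min(x$y), max(x$y)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.display_series <- function(x) length(x$y)

#' @export
as.data.frame.display_series <- function(x, ...) {
  data.frame(time_s = x$t0 + (seq_along(x$y) - 1) / x$fps, y_px = x$y)
}

#' Duration of a display series in seconds
#' @param series A `display_series`.
#' @return Length of the recording in seconds (`n / fps`).
#' @export
series_duration <- function(series) {
  stopifnot(inherits(series, "display_series"))
  length(series$y) / series$fps
}

#' Read / write a display series as CSV
#'
#' The on-disk format is a two-column CSV (`time_s`, `y_px`); the sampling
#' rate is recovered from the median time step on read. A JSON sidecar
#' (`<path>.json`) carries `fps`, `t0` and the meta fields so a round trip is
#' lossless.
#'
#' @param series A `display_series`.
#' @param path CSV file path.
#' @return `write_series_csv` returns `path` invisibly; `read_series_csv`
#'   returns a `display_series`.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "display_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  sidecar <- list(fps = series$fps, t0 = series$t0, meta = series$meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "y_px") %in% names(d)))
    stop("series CSV must have columns `time_s` and `y_px`")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    display_series(d$y_px, fps = side$fps, t0 = side$t0 %||% 0,
                   meta = as.list(side$meta))
  } else {
    dt <- stats::median(diff(d$time_s))
    if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate from ", path)
    display_series(d$y_px, fps = 1 / dt, t0 = d$time_s[1])
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a stage/child seed from a user seed; kept below 2^31 so it is a
## valid R integer.
derive_seed <- function(seed, salt) {
  as.integer((as.double(seed) * 69069 + as.double(salt) * 10007) %% 2147483629)
}
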