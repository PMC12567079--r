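## Local maxima of a numeric vector with topographic prominence.
## Plateaus count once (at their midpoint). For each peak, prominence is
## peak height minus the higher of the two minima separating it from the
## nearest higher ground (or the series edge).
find_peaks <- function(x) {
  n <- length(x)
  if (n < 3L) return(data.frame(index = integer(0), prominence = numeric(0)))
  ## collapse plateaus, remembering original index ranges
  r <- rle(x)
  vals <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(vals)
  if (k < 3L) return(data.frame(index = integer(0), prominence = numeric(0)))
  is_peak <- c(FALSE, vals[2:(k - 1)] > vals[1:(k - 2)] &
                 vals[2:(k - 1)] > vals[3:k], FALSE)
  pk <- which(is_peak)
  if (!length(pk)) return(data.frame(index = integer(0),
                                     prominence = numeric(0)))
  prom <- vapply(pk, function(i) {
    h <- vals[i]
    left <- if (i > 1) vals[seq_len(i - 1)] else numeric(0)
    higher <- which(left >= h)
    lmin <- min(if (length(higher)) left[(max(higher) + 1):(i - 1)] else left)
    right <- if (i < k) vals[(i + 1):k] else numeric(0)
    higher <- which(right >= h)
    rmin <- min(if (length(higher)) right[seq_len(min(higher) - 1)] else right)
    h - max(lmin, rmin)
  }, numeric(1))
  data.frame(index = as.integer((starts[pk] + ends[pk]) %/% 2L),
             prominence = prom)
}

#' Cartwheel flight frequency of a display series
#'
#' Each vertical oscillation of the edge male is one cartwheel flight, so
#' the display frequency is the number of upward excursions per second.
#' Peaks are counted towards the "up" direction (smaller raster y) and
#' must have topographic prominence of at least `prominence_frac` times
#' the series range, which makes the count robust to baseline drift from
#' imperfect tracking. A constant series has no flights.
#'
#' @param series A [display_series()] (or numeric vector with `fps`).
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   series range (default 0.25).
#' @param fps Sampling rate, required only for bare numeric input.
#' @return Frequency in Hz (flights per second).
#' @export
cartwheel_frequency <- function(series, prominence_frac = 0.25, fps = NULL) {
  if (inherits(series, "display_series")) {
    y <- series$y; fps <- series$fps
  } else {
    y <- as.numeric(series)
    if (is.null(fps)) stop("`fps` required for bare numeric input")
  }
  if (fps <= 0) stop("`fps` must be positive")
  if (length(y) < 2L) stop("series must have at least 2 samples")
  rng <- diff(range(y))
  duration <- length(y) / fps
  if (rng == 0) return(0)
  pk <- find_peaks(-y)                     # up = smaller raster y
  n_flights <- sum(pk$prominence >= prominence_frac * rng)
  n_flights / duration
}

#' Court record
#'
#' Per-court observation unit for the female-choice stage: recording time
#' and the counts of female visits and copulations seen at the perch.
#'
#' @param court_id Court identifier.
#' @param recording_hours Total recording time in hours (> 0).
#' @param n_visits,n_copulations Event counts (>= 0).
#' @param displays Optional list of per-display data (series or metrics).
#' @return A list of class `court_record`.
#' @export
court_record <- function(court_id, recording_hours, n_visits, n_copulations,
                         displays = list()) {
  if (recording_hours <= 0) stop("`recording_hours` must be positive")
  if (n_visits < 0 || n_copulations < 0) stop("counts must be >= 0")
  structure(list(court_id = court_id, recording_hours = recording_hours,
                 n_visits = n_visits, n_copulations = n_copulations,
                 displays = displays),
            class = "court_record")
}

#' Female visitation and copulation rates
#'
#' Event counts divided by the court's total recording time.
#'
#' @param record A [court_record()], or a list with `recording_hours`,
#'   `n_visits`, `n_copulations`.
#' @return Named numeric vector `c(visits_per_hour, copulations_per_hour)`.
#' @export
female_rates <- function(record) {
  if (is.null(record$recording_hours) || record$recording_hours <= 0)
    stop("`recording_hours` must be positive")
  c(visits_per_hour = record$n_visits / record$recording_hours,
    copulations_per_hour = record$n_copulations / record$recording_hours)
}
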