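#' Simulate the vertical-position series of a cartwheel display
#'
#' Builds the ground-truth trace the tracker is meant to recover: a
#' baseline perch height with one smooth vertical excursion per flight.
#' Flights form a queue over the males with nominal inter-flight interval
#' `1/flight_rate`; intervals are jittered by `timing_noise_sd` (inflated
#' with group size when `group_jitter_per_male > 0`, emulating imprecise
#' queue handoffs in larger courts), flight heights by `height_noise_sd`,
#' and every sample by `motion_noise_sd` (fine-motor wobble along the
#' path). Each excursion is a raised-cosine bump: the head
#' rises from `baseline_y` to `baseline_y - height` and returns over one
#' nominal interval. The trace never encodes which male flies — like the
#' field series, it is identity-free.
#'
#' @param params A [display_params()] object.
#' @return A list with elements `series` (a [display_series()] of length
#'   `round(duration * fps)`) and `events` (data frame of per-flight start
#'   time, peak time and height).
#' @export
simulate_display_series <- function(params) {
  stopifnot(inherits(params, "display_params"))
  p <- params
  n <- round(p$duration * p$fps)
  nominal <- 1 / p$flight_rate
  if (p$duration + 1e-9 < nominal)
    stop("`duration` too short to contain a single flight (needs >= 1/flight_rate)")

  withr::with_seed(p$seed, {
    ## Draw a fixed-size jitter stream first so the draws (and hence the
    ## trace when the group factor is 0) are identical across n_males.
    n_max <- ceiling(p$duration * p$flight_rate * 2) + 2L
    raw_jit <- stats::rnorm(n_max)
    raw_hgt <- stats::rnorm(n_max)

    sd_eff <- p$timing_noise_sd *
      (1 + p$group_jitter_per_male * (p$n_males - 1L))
    starts <- numeric(0)
    t_k <- 0
    k <- 0L
    while (t_k + nominal <= p$duration + 1e-9 && k < n_max) {
      k <- k + 1L
      starts[k] <- t_k
      gap <- nominal + raw_jit[k] * sd_eff
      t_k <- t_k + max(gap, 0.1 * nominal)
    }
    ## keep the head inside the frame: 1 <= y <= baseline
    heights <- pmin(pmax(p$hop_amplitude +
                           raw_hgt[seq_len(k)] * p$height_noise_sd, 1),
                    p$baseline_y - 1)
    wobble <- if (p$motion_noise_sd > 0)
      stats::rnorm(n, 0, p$motion_noise_sd) else numeric(n)
  })

  t <- (seq_len(n) - 1) / p$fps
  y <- rep(p$baseline_y, n)
  excur <- numeric(n)
  for (k in seq_along(starts)) {
    idx <- which(t >= starts[k] & t <= starts[k] + nominal)
    if (!length(idx)) next
    phase <- (t[idx] - starts[k]) / nominal
    bump <- heights[k] * 0.5 * (1 - cos(2 * pi * phase))
    excur[idx] <- pmax(excur[idx], bump)
  }
  y <- pmin(pmax(y - excur + wobble, 1), p$frame_size[2] - 1)
  events <- data.frame(start_s = starts, peak_s = starts + nominal / 2,
                       height_px = heights)
  series <- display_series(y, fps = p$fps,
                           meta = list(n_males = p$n_males,
                                       source = "synthetic"))
  list(series = series, events = events)
}
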