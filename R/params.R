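#' Parameters for a simulated cartwheel display
#'
#' Describes one cooperative display: a row of males taking turns performing
#' vertical hover ("cartwheel") flights in front of an optional female. The
#' defaults reflect the field conditions the package emulates: courts of a
#' few males flying at about 1.9 flights per second, recorded at 30 fps.
#'
#' @param n_males Number of males in the display (field courts hold 2-6).
#' @param flight_rate Nominal flight rate in Hz (flights per second).
#' @param hop_amplitude Height of a flight excursion in pixels.
#' @param baseline_y Perch height of the heads in raster pixels (y grows
#'   downward; the flight moves towards smaller y).
#' @param timing_noise_sd SD (seconds) of the jitter on inter-flight
#'   intervals.
#' @param height_noise_sd SD (pixels) of the per-flight jitter on flight
#'   heights (amplitude imprecision between flights).
#' @param motion_noise_sd SD (pixels) of per-sample jitter on the head
#'   position (fine-motor wobble along the flight path); this is the
#'   imprecision the microstate entropy is sensitive to.
#' @param duration Display length in seconds.
#' @param fps Frames per second of the rendered scene.
#' @param frame_size `c(width, height)` of the frame in pixels.
#' @param female_present Logical; render a (red-free) female blob.
#' @param dance_direction `"left"` or `"right"`: the side of the row where
#'   the active (edge) male flies; the female, when present, sits just
#'   beyond that side.
#' @param group_jitter_per_male Per-handoff inflation of the timing jitter:
#'   the effective SD is `timing_noise_sd * (1 + group_jitter_per_male *
#'   (n_males - 1))`, so larger queues hand off less precisely. Set to 0 for
#'   the null in which group size has no effect on timing.
#' @param seed RNG seed making the display reproducible.
#'
#' @return A validated list of class `display_params`.
#' @export
display_params <- function(n_males = 3, flight_rate = 1.89,
                           hop_amplitude = 50, baseline_y = 120,
                           timing_noise_sd = 0.05, height_noise_sd = 4,
                           motion_noise_sd = 0,
                           duration = 30, fps = 30,
                           frame_size = c(240, 160),
                           female_present = TRUE,
                           dance_direction = c("right", "left"),
                           group_jitter_per_male = 0.25,
                           seed = 1L) {
  dance_direction <- match.arg(dance_direction)
  p <- list(n_males = as.integer(n_males), flight_rate = flight_rate,
            hop_amplitude = hop_amplitude, baseline_y = baseline_y,
            timing_noise_sd = timing_noise_sd,
            height_noise_sd = height_noise_sd,
            motion_noise_sd = motion_noise_sd,
            duration = duration, fps = fps,
            frame_size = as.integer(frame_size),
            female_present = isTRUE(female_present),
            dance_direction = dance_direction,
            group_jitter_per_male = group_jitter_per_male,
            seed = as.integer(seed))
  if (p$n_males < 1L) stop("`n_males` must be >= 1")
  if (p$fps <= 0) stop("`fps` must be positive")
  if (p$duration <= 0) stop("`duration` must be positive")
  if (p$flight_rate <= 0) stop("`flight_rate` must be positive")
  if (p$timing_noise_sd < 0 || p$height_noise_sd < 0 ||
      p$motion_noise_sd < 0)
    stop("noise SDs must be >= 0")
  if (length(p$frame_size) != 2L || any(p$frame_size < 8L))
    stop("`frame_size` must be c(width, height) in pixels")
  if (p$hop_amplitude <= 0) stop("`hop_amplitude` must be positive")
  class(p) <- "display_params"
  p
}

#' Parameters for a simulated multi-court dataset
#'
#' Describes the data-generating process for the court-level experiment:
#' per-display RQA-like metrics whose log-means are linear in the number of
#' males, and per-display female visit / copulation counts drawn from a
#' Poisson with log-rate linear in the standardized predictors, with a
#' shared normal random intercept per court. Effect-size defaults echo the
#' signs and magnitudes of the field analysis (entropy rising ~0.04 per
#' male on the log scale; visitation increasing with recurrence rate and
#' decreasing with entropy).
#'
#' @param n_courts Number of courts (the random-effect grouping factor).
#' @param displays_per_court Displays recorded per court.
#' @param beta_entropy_vs_males Slope of log-mean microstate entropy on the
#'   number of males.
#' @param beta_rate_vs_rr,beta_rate_vs_entropy,beta_rate_vs_males Effects
#'   (log scale, per SD of the predictor) of recurrence rate, entropy and
#'   male count on the female visit/copulation rates.
#' @param court_sd SD of the normal court random intercept (applied, with
#'   independent draws, to both the predictor and the rate linear scales).
#' @param recording_hours Recording time per court in hours (the rate
#'   denominator and Poisson exposure).
#' @param visit_log_rate,copulation_log_rate Baseline log-rates (per hour)
#'   of female visits and copulations at average predictor values.
#' @param mcentr_shape,metric_shape Gamma shape parameters for the entropy
#'   metric and the remaining metrics (larger = less display-to-display
#'   noise).
#' @param freq_shape Gamma shape for cartwheel frequency; the default 14
#'   gives a coefficient of variation of about 27%.
#' @param det_lam_rho,det_entropy_rho Weights of (log) laminarity and
#'   entropy in the construction of determinism, which is generated as a
#'   near-linear blend of the two so that the collinearity screen has a
#'   real redundancy to find (echoing the strong field correlation between
#'   determinism and laminarity).
#' @param seed RNG seed.
#'
#' @return A validated list of class `court_sim_params`.
#' @export
court_sim_params <- function(n_courts = 6, displays_per_court = 10,
                             beta_entropy_vs_males = 0.04,
                             beta_rate_vs_rr = 0.18,
                             beta_rate_vs_entropy = -0.16,
                             beta_rate_vs_males = -0.04,
                             court_sd = 0.3, recording_hours = 5,
                             visit_log_rate = 0.05,
                             copulation_log_rate = -2.98,
                             mcentr_shape = 40, metric_shape = 40,
                             freq_shape = 14, det_lam_rho = 0.85,
                             det_entropy_rho = -0.45,
                             seed = 1L) {
  p <- list(n_courts = as.integer(n_courts),
            displays_per_court = as.integer(displays_per_court),
            beta_entropy_vs_males = beta_entropy_vs_males,
            beta_rate_vs_rr = beta_rate_vs_rr,
            beta_rate_vs_entropy = beta_rate_vs_entropy,
            beta_rate_vs_males = beta_rate_vs_males,
            court_sd = court_sd, recording_hours = recording_hours,
            visit_log_rate = visit_log_rate,
            copulation_log_rate = copulation_log_rate,
            mcentr_shape = mcentr_shape, metric_shape = metric_shape,
            freq_shape = freq_shape, det_lam_rho = det_lam_rho,
            det_entropy_rho = det_entropy_rho,
            seed = as.integer(seed))
  if (p$n_courts < 1L || p$displays_per_court < 1L)
    stop("court and display counts must be >= 1")
  if (p$court_sd < 0) stop("`court_sd` must be >= 0")
  if (p$recording_hours <= 0) stop("`recording_hours` must be positive")
  if (abs(p$det_lam_rho) >= 1) stop("`det_lam_rho` must be in (-1, 1)")
  if (p$det_lam_rho^2 + p$det_entropy_rho^2 > 1)
    stop("`det_lam_rho`^2 + `det_entropy_rho`^2 must be <= 1")
  class(p) <- "court_sim_params"
  p
}

#' Tracker configuration
#'
#' Settings for the colour-range quadrant tracker. A pixel is "red" when
#' each RGB channel lies inside `[color_lo, color_hi]`; a quadrant registers
#' a male when at least `coverage_threshold` of its area is red.
#'
#' @param color_lo,color_hi Lower/upper RGB bounds (0-255) of the tracked
#'   colour; the defaults bracket the red head plumage.
#' @param coverage_threshold Fraction of a quadrant that must be covered for
#'   a detection (the calibrated default is 0.40).
#' @param grid `c(n_cols, n_rows)` of the quadrant grid, or `NULL` to derive
#'   it from `cell_px`.
#' @param cell_px Target quadrant size in pixels when `grid` is `NULL`. The
#'   quadrant should be saturable by a single head, so the default is about
#'   half the rendered head diameter.
#' @param target_fps Output sampling rate; the source rate must be an
#'   integer multiple.
#' @param dance_direction `"left"`, `"right"` or `"auto"`: which side of the
#'   frame holds the edge of the dance when no female column is given.
#' @param female_column Optional pixel x of the female; the edge male is the
#'   detection closest to her.
#' @param max_gap Longest detection dropout (frames) bridged by carrying the
#'   last position forward.
#' @param handoff_eps Hysteresis (px) a rival detection must exceed before
#'   tracking hands off to it; 0 = strict passing.
#'
#' @return A validated list of class `tracker_config`.
#' @export
tracker_config <- function(color_lo = c(150, 0, 0),
                           color_hi = c(255, 100, 100),
                           coverage_threshold = 0.40,
                           grid = NULL, cell_px = 8L,
                           target_fps = 15,
                           dance_direction = c("auto", "left", "right"),
                           female_column = NULL,
                           max_gap = 3L, handoff_eps = 0) {
  dance_direction <- match.arg(dance_direction)
  cfg <- list(color_lo = as.numeric(color_lo),
              color_hi = as.numeric(color_hi),
              coverage_threshold = coverage_threshold,
              grid = if (!is.null(grid)) as.integer(grid),
              cell_px = as.integer(cell_px),
              target_fps = target_fps,
              dance_direction = dance_direction,
              female_column = female_column,
              max_gap = as.integer(max_gap),
              handoff_eps = handoff_eps)
  if (length(cfg$color_lo) != 3L || length(cfg$color_hi) != 3L)
    stop("colour bounds must be RGB triples")
  if (any(cfg$color_lo > cfg$color_hi))
    stop("`color_lo` must be <= `color_hi` componentwise")
  if (cfg$coverage_threshold <= 0 || cfg$coverage_threshold > 1)
    stop("`coverage_threshold` must be in (0, 1]")
  if (cfg$max_gap < 0L) stop("`max_gap` must be >= 0")
  class(cfg) <- "tracker_config"
  cfg
}
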