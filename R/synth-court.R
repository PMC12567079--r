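## Gamma draw parameterised by mean and shape.
rgamma_mean <- function(n, mean, shape) {
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' Simulate a multi-court display dataset
#'
#' Generates the observation table the inference stage consumes, with known
#' ground truth. Each metric (and the rate linear predictor) gets its own
#' independent normal court random intercept with SD `court_sd`. For each
#' display the number of males is uniform on 2-6; the RQA-like metrics
#' are Gamma with log-mean linear in the male count (slope
#' `beta_entropy_vs_males` for the entropy metric, 0 for the others);
#' determinism is generated as a near-linear blend of the realized
#' laminarity and entropy (weights `det_lam_rho` and `det_entropy_rho` on
#' the log scale), reproducing the collinearity the screen must detect
#' and drop. Visit and copulation counts are Poisson with exposure
#' `recording_hours` and log-rate linear in the within-dataset
#' standardized predictors (male count, recurrence rate, entropy), and are
#' divided by the recording time to give per-hour rates.
#'
#' @param params A [court_sim_params()] object.
#' @return A data frame of class `court_dataset` with one row per display:
#'   `court` (factor), `display_id`, `n_males`, `frequency`, `rr`, `det`,
#'   `lam`, `mcentr`, `r_sel`, `visits`, `copulations`, `visit_rate`,
#'   `copulation_rate`, `recording_hours`. The true effect parameters are
#'   attached as attribute `truth`.
#' @export
simulate_court_dataset <- function(params) {
  stopifnot(inherits(params, "court_sim_params"))
  p <- params
  n <- p$n_courts * p$displays_per_court
  court <- factor(rep(seq_len(p$n_courts), each = p$displays_per_court))

  withr::with_seed(p$seed, {
    ## each metric gets its own court intercept (the grouping structure the
    ## mixed models must absorb); the rate linear predictor gets another
    u_mc <- stats::rnorm(p$n_courts, 0, p$court_sd)
    u_rr <- stats::rnorm(p$n_courts, 0, p$court_sd)
    u_lam <- stats::rnorm(p$n_courts, 0, p$court_sd)
    u_rate <- stats::rnorm(p$n_courts, 0, p$court_sd)
    ci <- as.integer(court)

    n_males <- sample(2:6, n, replace = TRUE)

    ## metric scales chosen to resemble field displays: RR/DET/LAM in
    ## percent, entropy in nats (max ln 16 ~ 2.77), radius in px
    mcentr <- rgamma_mean(n, exp(log(1.4) + p$beta_entropy_vs_males *
                                   (n_males - 4) + u_mc[ci]), p$mcentr_shape)
    rr <- rgamma_mean(n, exp(log(30) + u_rr[ci]), p$metric_shape)
    lam <- rgamma_mean(n, exp(log(55) + u_lam[ci]), p$metric_shape)
    ## determinism is built as a near-linear blend of the realized
    ## laminarity and entropy (log scale), so it is the redundant metric
    ## the collinearity screen must single out
    zz <- function(x) (x - mean(x)) / stats::sd(x)
    a <- p$det_lam_rho; b <- p$det_entropy_rho
    resid_sd <- sqrt(max(1 - a^2 - b^2, 0.05))
    z_det <- a * zz(log(lam)) + b * zz(log(mcentr)) +
      resid_sd * stats::rnorm(n)
    det <- exp(log(70) + 0.15 * z_det)
    r_sel <- rgamma_mean(n, 12, p$metric_shape)
    frequency <- rgamma_mean(n, 1.89, p$freq_shape)

    zs <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x)
      else x * 0
    lin <- p$beta_rate_vs_males * zs(n_males) +
      p$beta_rate_vs_rr * zs(rr) +
      p$beta_rate_vs_entropy * zs(mcentr) + u_rate[ci]
    visits <- stats::rpois(n, p$recording_hours *
                             exp(p$visit_log_rate + lin))
    copulations <- stats::rpois(n, p$recording_hours *
                                  exp(p$copulation_log_rate + lin))
  })

  out <- data.frame(court = court,
                    display_id = seq_len(n),
                    n_males = n_males,
                    frequency = frequency,
                    rr = rr, det = det, lam = lam, mcentr = mcentr,
                    r_sel = r_sel,
                    visits = visits, copulations = copulations,
                    visit_rate = visits / p$recording_hours,
                    copulation_rate = copulations / p$recording_hours,
                    recording_hours = p$recording_hours)
  attr(out, "truth") <- p
  class(out) <- c("court_dataset", "data.frame")
  out
}
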