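test_that("spearman matrix basics and known rank dependence", {
  set.seed(1)
  x <- rnorm(50)
  d <- data.frame(a = x, b = -x, c = runif(50))
  rho <- spearman_matrix(d)
  expect_equal(diag(rho), c(a = 1, b = 1, c = 1))
  expect_equal(rho["a", "b"], -1)
  expect_identical(rho, t(rho))
  ## Gaussian copula with correlation 0.8: population Spearman is
  ## (6/pi) asin(rho/2) ~= 0.786
  set.seed(2)
  z1 <- rnorm(500); z2 <- 0.8 * z1 + sqrt(1 - 0.64) * rnorm(500)
  big <- data.frame(u = qgamma(pnorm(z1), 3), v = exp(z2))
  expect_lt(abs(spearman_matrix(big)["u", "v"] - (6 / pi) * asin(0.4)),
            0.05)
  expect_warning(spearman_matrix(data.frame(a = x, k = rep(1, 50))),
                 "constant")
  expect_error(spearman_matrix(d[1:2, ]), "3 rows")
})

test_that("VIF screen drops constructed collinearity and spares the rest", {
  set.seed(3)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  ## near-orthogonal design: all VIFs ~1, nothing dropped
  v0 <- vif_screen(data.frame(x1, x2, x3))
  expect_equal(v0$retained, c("x1", "x2", "x3"))
  expect_true(all(v0$vif < 1.5))
  ## duplicate column: infinite VIF, one copy dropped
  vdup <- vif_screen(data.frame(x1, x1b = x1, x2))
  expect_length(vdup$dropped, 1L)
  expect_true(vdup$dropped %in% c("x1", "x1b"))
  ## predictor that is 95% explained by the others: VIF = 20 -> dropped
  noise <- rnorm(n)
  lin <- x1 + x2
  x4 <- lin + noise * sd(lin) * sqrt(0.05 / 0.95)
  v <- vif_screen(data.frame(x1, x2, x4))
  first <- v$trace[v$trace$step == 1, ]
  expect_gt(first$vif[first$predictor == "x4"], 10)
  expect_true("x4" %in% v$dropped)
  expect_true(all(v$vif[v$retained] < 3.5))
  expect_error(vif_screen(data.frame(x1)), "2 predictors")
})

test_that("in-package VIFs agree with car::vif", {
  skip_if_not_installed("car")
  d <- simulate_court_dataset(court_sim_params(n_courts = 20,
                                               displays_per_court = 10,
                                               seed = 23))
  preds <- c("n_males", "frequency", "rr", "det", "lam", "mcentr")
  v <- vif_screen(d[preds], threshold = Inf)   # no dropping, just VIFs
  fit <- lm(visit_rate ~ n_males + frequency + rr + det + lam + mcentr,
            data = d)
  expect_equal(v$vif[preds], car::vif(fit)[preds], tolerance = 1e-8)
})

test_that("gamma mixed fit honours its numerical contracts", {
  d <- simulate_court_dataset(court_sim_params(n_courts = 12,
                                               displays_per_court = 10,
                                               seed = 5))
  f <- fit_gamma_glmm(d, "mcentr", c("n_males", "rr"), standardize = FALSE)
  expect_s3_class(f, "gamma_glmm")
  expect_true(f$converged)
  ## Wald chi-square is (estimate / se)^2, row by row
  expect_equal(f$coefficients$chisq,
               (f$coefficients$estimate / f$coefficients$se)^2)
  expect_true(all(f$coefficients$se > 0))
  expect_gte(f$ranef_variance, 0)
  ## standardization is a reparameterisation: identical log-likelihood
  fs <- fit_gamma_glmm(d, "mcentr", c("n_males", "rr"), standardize = TRUE)
  expect_equal(f$logLik, fs$logLik, tolerance = 1e-4)
  ## and the standardized slope is the raw slope times the predictor SD
  raw <- f$coefficients$estimate[f$coefficients$term == "n_males"]
  std <- fs$coefficients$estimate[fs$coefficients$term == "n_males"]
  expect_equal(std, raw * sd(d$n_males), tolerance = 1e-3)
})

test_that("glmmTMB estimates agree with an lme4 cross-fit", {
  skip_if_not_installed("lme4")
  d <- simulate_court_dataset(court_sim_params(n_courts = 20,
                                               displays_per_court = 10,
                                               seed = 17))
  f <- fit_gamma_glmm(d, "mcentr", "n_males", standardize = FALSE)
  ref <- suppressWarnings(lme4::glmer(
    mcentr ~ n_males + (1 | court), data = d,
    family = Gamma(link = "log")))
  b_ref <- lme4::fixef(ref)["n_males"]
  b <- f$coefficients$estimate[f$coefficients$term == "n_males"]
  expect_equal(b, unname(b_ref), tolerance = 0.02)
})

test_that("zero responses are shifted, all-zero responses error", {
  d <- simulate_court_dataset(court_sim_params(n_courts = 10,
                                               displays_per_court = 8,
                                               seed = 11))
  d$copulation_rate[1:5] <- 0
  f <- suppressWarnings(fit_gamma_glmm(d, "copulation_rate", "n_males"))
  expect_gt(f$zero_shift, 0)
  d$copulation_rate <- 0
  expect_error(fit_gamma_glmm(d, "copulation_rate", "n_males"),
               "no positive values")
})

test_that("single-court data falls back to a fixed-effects GLM, flagged", {
  d <- simulate_court_dataset(court_sim_params(n_courts = 1,
                                               displays_per_court = 20,
                                               seed = 9))
  expect_warning(f <- fit_gamma_glmm(d, "mcentr", "n_males"),
                 "single level")
  expect_equal(f$engine, "glm")
  expect_equal(f$n_groups, 1L)
})

test_that("group-size analysis flags only the entropy metric", {
  hits <- sapply(1:5, function(s) {
    d <- simulate_court_dataset(court_sim_params(
      n_courts = 30, displays_per_court = 10, seed = 500 + s))
    gs <- suppressWarnings(run_group_size_analysis(d))
    tab <- gs$summary
    c(mcentr_sig = tab$p[tab$response == "mcentr"] < 0.05,
      others_null = mean(tab$p[!tab$response %in% "mcentr"] >= 0.05))
  })
  expect_true(all(hits["mcentr_sig", ] == 1))
  expect_gte(mean(hits["others_null", ]), 0.8)
})

test_that("female-choice analysis recovers effect signs and drops DET", {
  sg <- sapply(1:5, function(s) {
    d <- simulate_court_dataset(court_sim_params(
      n_courts = 30, displays_per_court = 10, seed = 700 + s))
    fc <- suppressWarnings(run_female_choice_analysis(d))
    cv <- fc$visitation$coefficients
    cc <- fc$copulation$coefficients
    c(det_dropped = "det" %in% fc$vif$dropped,
      signs = mean(c(cv$estimate[cv$term == "rr"] > 0,
                     cv$estimate[cv$term == "mcentr"] < 0,
                     cc$estimate[cc$term == "rr"] > 0,
                     cc$estimate[cc$term == "mcentr"] < 0)))
  })
  expect_gte(mean(sg["det_dropped", ]), 0.8)
  expect_gte(mean(sg["signs", ]), 0.8)
})

test_that("with standardized predictors the intercept is the log mean", {
  d <- simulate_court_dataset(court_sim_params(
    n_courts = 25, displays_per_court = 10, court_sd = 0,
    beta_rate_vs_rr = 0, beta_rate_vs_entropy = 0, beta_rate_vs_males = 0,
    seed = 13))
  f <- suppressWarnings(
    fit_gamma_glmm(d, "visit_rate", c("n_males", "rr", "mcentr")))
  b0 <- f$coefficients$estimate[f$coefficients$term == "(Intercept)"]
  y <- d$visit_rate
  y[y == 0] <- min(y[y > 0]) / 2
  expect_lt(abs(b0 - log(mean(y))), 0.1)
})
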