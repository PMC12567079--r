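#' Spearman correlation matrix of display metrics
#'
#' Pairwise Spearman rank correlations among metric columns; pairs
#' involving a constant column are undefined and returned as `NA` with a
#' warning.
#'
#' @param metrics A data frame (numeric columns are used).
#' @return A symmetric correlation matrix with unit diagonal and attribute
#'   `undefined` listing any constant columns.
#' @export
spearman_matrix <- function(metrics) {
  x <- as.data.frame(metrics)
  x <- x[vapply(x, is.numeric, logical(1))]
  if (nrow(x) < 3L) stop("need at least 3 rows for a correlation matrix")
  const <- names(x)[vapply(x, function(c) stats::sd(c) == 0, logical(1))]
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  diag(rho) <- 1
  if (length(const)) {
    warning("constant column(s) give undefined correlations: ",
            paste(const, collapse = ", "))
    rho[const, ] <- NA; rho[, const] <- NA
    for (cc in const) rho[cc, cc] <- 1
  }
  attr(rho, "undefined") <- const
  rho
}

#' Iterative variance-inflation-factor screen
#'
#' Computes `VIF_k = 1 / (1 - R^2_k)` from regressing each predictor on
#' the others; while any VIF exceeds `threshold`, the predictor with the
#' largest VIF is dropped and the VIFs are recomputed. Perfectly collinear
#' predictors have infinite VIF and are dropped first.
#'
#' @param predictors Data frame of numeric predictors (>= 2 columns, more
#'   rows than columns).
#' @param threshold VIF above which a predictor is dropped (default 3.5).
#' @return List with `retained` (character), `dropped` (character, in drop
#'   order), `vif` (named vector for the retained set) and `trace` (data
#'   frame of step, predictor, vif, dropped).
#' @export
vif_screen <- function(predictors, threshold = 3.5) {
  x <- as.data.frame(predictors)
  x <- x[vapply(x, is.numeric, logical(1))]
  if (ncol(x) < 2L) stop("need at least 2 predictors")
  if (nrow(x) <= ncol(x)) stop("need more rows than predictors")

  vif_of <- function(d) {
    vapply(names(d), function(k) {
      fit <- stats::lm(stats::reformulate(setdiff(names(d), k), k), data = d)
      ## a perfect fit warns in summary.lm; it is handled as infinite VIF
      r2 <- suppressWarnings(summary(fit)$r.squared)
      if (r2 >= 1 - 1e-10) Inf else 1 / (1 - r2)
    }, numeric(1))
  }

  dropped <- character(0)
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    v <- vif_of(x)
    worst <- names(v)[which.max(v)]
    drop_now <- max(v) > threshold && ncol(x) > 1L
    trace[[step]] <- data.frame(step = step, predictor = names(v),
                                vif = unname(v),
                                dropped = names(v) == worst & drop_now)
    if (!drop_now) break
    dropped <- c(dropped, worst)
    x <- x[setdiff(names(x), worst)]
    if (ncol(x) < 2L) { v <- stats::setNames(1, names(x)); break }
  }
  list(retained = names(x), dropped = dropped, vif = v,
       trace = do.call(rbind, trace))
}

#' Fit a Gamma log-link mixed model
#'
#' Fits `response ~ predictors + (1 | group)` with a Gamma distribution
#' and log link. Zero responses (possible for copulation rates) are
#' shifted to half the smallest positive observed value, recorded in the
#' result. Predictors are optionally centred and scaled by their SD, in
#' which case coefficients are per-SD effects. Wald chi-squared statistics
#' are `(estimate / se)^2` on 1 d.f. If the grouping factor has a single
#' level, or the mixed fit fails to converge, the model falls back to a
#' fixed-effects Gamma GLM with a warning and the result is flagged.
#'
#' @param data Data frame.
#' @param response Response column name (must be non-negative with at
#'   least one positive value).
#' @param predictors Character vector of predictor column names.
#' @param group Grouping-factor column name (default `"court"`).
#' @param standardize Centre/scale predictors (default `TRUE`).
#' @return An object of class `gamma_glmm`: `coefficients` (data frame of
#'   term, estimate, se, chisq, df, p), `ranef_variance`, `ranef_sd`,
#'   `converged`, `singular`, `engine`, `n_obs`, `n_groups`,
#'   `zero_shift`, `logLik`, and the fitted model in `fit`.
#' @export
fit_gamma_glmm <- function(data, response, predictors, group = "court",
                           standardize = TRUE) {
  d <- as.data.frame(data)
  stopifnot(response %in% names(d), all(predictors %in% names(d)),
            group %in% names(d))
  y <- d[[response]]
  if (any(y < 0)) stop("response `", response, "` has negative values")
  if (!any(y > 0))
    stop("response `", response, "` has no positive values; a Gamma model ",
         "cannot be fit")
  zero_shift <- 0
  if (any(y == 0)) {
    zero_shift <- min(y[y > 0]) / 2
    y[y == 0] <- zero_shift
  }
  d$.y <- y
  d$.g <- factor(d[[group]])
  scaled <- FALSE
  for (p in predictors) {
    if (standardize && stats::sd(d[[p]]) > 0) {
      d[[p]] <- (d[[p]] - mean(d[[p]])) / stats::sd(d[[p]])
      scaled <- TRUE
    }
  }

  n_groups <- nlevels(d$.g)
  rhs <- paste(predictors, collapse = " + ")
  use_mixed <- n_groups >= 2L
  engine <- "glmmTMB"
  fit <- NULL
  converged <- FALSE
  if (use_mixed) {
    form <- stats::as.formula(paste(".y ~", rhs, "+ (1 | .g)"))
    fit <- suppressWarnings(tryCatch(
      glmmTMB::glmmTMB(form, data = d, family = Gamma(link = "log")),
      error = function(e) NULL))
    if (!is.null(fit))
      converged <- isTRUE(fit$fit$convergence == 0) &&
        isTRUE(fit$sdr$pdHess)
  }
  if (is.null(fit) || !converged) {
    if (use_mixed)
      warning("mixed fit did not converge; falling back to a fixed-effects ",
              "Gamma GLM")
    else
      warning("grouping factor has a single level; fitting a fixed-effects ",
              "Gamma GLM")
    engine <- "glm"
    form <- stats::as.formula(paste(".y ~", rhs))
    fit <- stats::glm(form, data = d, family = Gamma(link = "log"))
    converged <- fit$converged
  }

  if (engine == "glmmTMB") {
    co <- summary(fit)$coefficients$cond
    vc <- glmmTMB::VarCorr(fit)$cond$.g
    rv <- as.numeric(vc[1, 1])
    ll <- as.numeric(stats::logLik(fit))
  } else {
    co <- summary(fit)$coefficients
    rv <- NA_real_
    ll <- as.numeric(stats::logLik(fit))
  }
  est <- co[, 1]; se <- co[, 2]
  chisq <- (est / se)^2
  res <- data.frame(term = rownames(co), estimate = unname(est),
                    se = unname(se), chisq = unname(chisq), df = 1,
                    p = stats::pchisq(unname(chisq), df = 1,
                                      lower.tail = FALSE),
                    row.names = NULL)
  res$p[res$term == "(Intercept)"] <- NA

  structure(list(coefficients = res,
                 ranef_variance = rv,
                 ranef_sd = if (is.na(rv)) NA_real_ else sqrt(rv),
                 converged = converged,
                 singular = if (is.na(rv)) NA else rv < 1e-8,
                 engine = engine,
                 n_obs = nrow(d), n_groups = n_groups,
                 zero_shift = zero_shift,
                 standardized = scaled,
                 logLik = ll,
                 response = response,
                 fit = fit),
            class = "gamma_glmm")
}

#' @export
print.gamma_glmm <- function(x, ...) {
  cat(sprintf("<gamma_glmm> %s ~ ... (%s), %d obs / %d groups%s\n",
              x$response, x$engine, x$n_obs, x$n_groups,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(x$coefficients, digits = 4)
  if (!is.na(x$ranef_variance))
    cat(sprintf("  random intercept: variance %.4g (sd %.4g)%s\n",
                x$ranef_variance, x$ranef_sd,
                if (isTRUE(x$singular)) " [singular]" else ""))
  if (x$zero_shift > 0)
    cat(sprintf("  zero responses shifted to %.4g\n", x$zero_shift))
  invisible(x)
}

#' 95% Wald confidence intervals for the fixed effects
#' @param fit A `gamma_glmm`.
#' @param level Confidence level (default 0.95).
#' @return Data frame of term, lower, upper.
#' @export
wald_ci <- function(fit, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  with(fit$coefficients,
       data.frame(term = term, lower = estimate - z * se,
                  upper = estimate + z * se))
}

#' Group-size analysis
#'
#' One Gamma log-link mixed model per display metric (cartwheel frequency
#' and the RQA metrics) with the number of males as the predictor and a
#' court random intercept. Predictors are left on their natural scale so
#' slopes read as per-additional-male effects on the log mean.
#'
#' @param dataset A `court_dataset` (or compatible data frame).
#' @param responses Metric columns to model; defaults to those present.
#' @return A list of `gamma_glmm` fits (one per response) with a `summary`
#'   data frame of the `n_males` rows, class `group_size_analysis`.
#' @export
run_group_size_analysis <- function(dataset,
                                    responses = c("frequency", "rr", "det",
                                                  "lam", "mcentr", "r_sel")) {
  responses <- intersect(responses, names(dataset))
  if (!length(responses)) stop("no metric columns found in `dataset`")
  fits <- lapply(responses, function(resp)
    fit_gamma_glmm(dataset, resp, "n_males", standardize = FALSE))
  names(fits) <- responses
  tab <- do.call(rbind, lapply(responses, function(r) {
    cf <- fits[[r]]$coefficients
    row <- cf[cf$term == "n_males", ]
    data.frame(response = r, estimate = row$estimate, se = row$se,
               chisq = row$chisq, p = row$p,
               engine = fits[[r]]$engine)
  }))
  structure(list(fits = fits, summary = tab), class = "group_size_analysis")
}

#' @export
print.group_size_analysis <- function(x, ...) {
  cat("<group_size_analysis> effect of n_males per response:\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Female-choice analysis
#'
#' Models female visitation and copulation rates against the number of
#' males, cartwheel frequency and the RQA metrics, with a court random
#' intercept and standardized predictors. Predictors are first passed
#' through the collinearity screen ([vif_screen()]), which with field-like
#' data drops determinism for its redundancy with laminarity.
#'
#' @param dataset A `court_dataset` (or compatible data frame with
#'   `visit_rate` / `copulation_rate` columns).
#' @param predictors Candidate predictor columns.
#' @param vif_threshold Passed to [vif_screen()].
#' @return List of class `female_choice_analysis`: `visitation` and
#'   `copulation` (`gamma_glmm` fits), `vif` (screen report), and
#'   `predictors` (retained set).
#' @export
run_female_choice_analysis <- function(dataset,
                                       predictors = c("n_males", "frequency",
                                                      "rr", "det", "lam",
                                                      "mcentr", "r_sel"),
                                       vif_threshold = 3.5) {
  predictors <- intersect(predictors, names(dataset))
  if (length(predictors) < 2L) stop("need at least 2 candidate predictors")
  screen <- vif_screen(dataset[predictors], threshold = vif_threshold)
  keep <- screen$retained
  structure(list(
    visitation = fit_gamma_glmm(dataset, "visit_rate", keep,
                                standardize = TRUE),
    copulation = fit_gamma_glmm(dataset, "copulation_rate", keep,
                                standardize = TRUE),
    vif = screen, predictors = keep),
    class = "female_choice_analysis")
}

#' @export
print.female_choice_analysis <- function(x, ...) {
  cat("<female_choice_analysis>\n")
  if (length(x$vif$dropped))
    cat("  dropped by VIF screen:", paste(x$vif$dropped, collapse = ", "),
        "\n")
  cat("-- visitation rate --\n"); print(x$visitation)
  cat("-- copulation rate --\n"); print(x$copulation)
  invisible(x)
}
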