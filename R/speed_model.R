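#' Fit the log-log spacing-to-speed mixed model
#'
#' Random-intercept Gaussian model on the natural-log scale,
#' `log(speed_ij) = beta0 + beta1 log(spacing_ij) + u_i + e_ij`, with
#' whale identity as the random intercept to absorb repeated measurements
#' per individual. Fitted by REML (default) or ML; explanatory power is
#' summarised by the Nakagawa--Schielzeth marginal and conditional
#' R-squared, where the fixed-effect variance is the variance of the
#' fixed-effect linear predictor over the data. Body length can be added
#' as a second fixed effect behind a flag; it is excluded from the default
#' model. With a single whale the random intercept is unidentifiable and
#' the fit degenerates to OLS with a warning.
#'
#' @param events Data frame with columns `whale_id`, `mean_spacing` (m),
#'   `speed` (m/s), and `body_length` when `include_body_length = TRUE`.
#'   Spacings and speeds must be strictly positive.
#' @param estimation `"REML"` (default) or `"ML"` (use ML when comparing
#'   fixed-effect structures).
#' @param include_body_length Add `log(body_length)` as a fixed effect.
#' @return An object of class `lmm_fit` with `beta0`, `beta1` (and their
#'   SEs), `fixef_vcov`, `sigma_u2`, `sigma_e2`, `r2_marginal`,
#'   `r2_conditional`, `n_events`, `n_whales`, `estimation`,
#'   `converged`, and the underlying fitted model in `$model`.
#' @export
fit_loglog_lmm <- function(events, estimation = c("REML", "ML"),
                           include_body_length = FALSE) {
  estimation <- match.arg(estimation)
  d <- as.data.frame(events)
  stopifnot(all(c("whale_id", "mean_spacing", "speed") %in% names(d)))
  if (any(d$mean_spacing <= 0) || any(d$speed <= 0)) {
    stop("spacings and speeds must be strictly positive", call. = FALSE)
  }
  d$log_speed <- log(d$speed)
  d$log_spacing <- log(d$mean_spacing)
  n_whales <- length(unique(d$whale_id))
  if (n_whales < 1 || nrow(d) < 3) {
    stop("need >= 3 events from >= 1 whale", call. = FALSE)
  }
  fixed <- "log_speed ~ log_spacing"
  if (include_body_length) {
    stopifnot("body_length" %in% names(d), all(d$body_length > 0))
    d$log_body_length <- log(d$body_length)
    fixed <- paste(fixed, "+ log_body_length")
  }

  if (n_whales == 1) {
    warning("single whale: random intercept unidentifiable, fitting OLS")
    ols <- stats::lm(stats::as.formula(fixed), data = d)
    sm <- summary(ols)
    beta <- stats::coef(ols)
    V <- stats::vcov(ols)
    sigma_e2 <- sm$sigma^2
    sigma_u2 <- 0
  } else {
    form <- stats::as.formula(paste(fixed, "+ (1 | whale_id)"))
    fit <- lme4::lmer(form, data = d, REML = estimation == "REML",
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore"))
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    vc <- lme4::VarCorr(fit)
    sigma_u2 <- as.numeric(vc$whale_id[1, 1])
    sigma_e2 <- attr(vc, "sc")^2
    ols <- fit
  }
  X <- stats::model.matrix(stats::as.formula(paste("~", sub(".*~", "", fixed))),
                           data = d)
  eta <- drop(X %*% beta)
  sigma_f2 <- mean((eta - mean(eta))^2)
  tot <- sigma_f2 + sigma_u2 + sigma_e2
  se <- sqrt(diag(V))
  structure(
    list(beta0 = unname(beta[1]), beta0_se = unname(se[1]),
         beta1 = unname(beta[2]), beta1_se = unname(se[2]),
         coefficients = beta,
         fixef_vcov = V,
         sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
         sigma_f2 = sigma_f2,
         r2_marginal = sigma_f2 / tot,
         r2_conditional = (sigma_f2 + sigma_u2) / tot,
         n_events = nrow(d), n_whales = n_whales,
         estimation = estimation,
         include_body_length = include_body_length,
         converged = if (inherits(ols, "merMod"))
           length(ols@optinfo$conv$lme4$messages %||% character()) == 0
         else TRUE,
         model = ols),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Log-log spacing-to-speed mixed model (%s; %d events, %d whales)\n",
              x$estimation, x$n_events, x$n_whales))
  cat(sprintf("  log(speed) = %.4f + %.4f log(spacing) [SE %.4f, %.4f]\n",
              x$beta0, x$beta1, x$beta0_se, x$beta1_se))
  cat(sprintf("  sigma_u^2 = %.5f, sigma_e^2 = %.5f\n", x$sigma_u2, x$sigma_e2))
  cat(sprintf("  R2 marginal %.3f, conditional %.3f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' Predict swimming speed from flukeprint spacing in a still image
#'
#' New-whale prediction from the fixed effects: on the log scale
#' `eta = beta0 + beta1 log(spacing)` with total predictive variance
#' `v = x' V x + sigma_u^2 + sigma_e^2` (fixed-effect uncertainty plus
#' random-intercept and residual variance, the whale being unknown).
#' Back-transformed quantities: median `exp(eta)`, bias-corrected mean
#' `exp(eta + (sigma_u^2 + sigma_e^2) / 2)` (log-normal mean correction),
#' and the 95% prediction interval `exp(eta +/- 1.96 sqrt(v))`.
#'
#' @param fit An `lmm_fit` from [fit_loglog_lmm()] (default model, no
#'   body-length term).
#' @param spacing Flukeprint spacing(s) in metres, > 0 (vectorised).
#' @param level Prediction level (default 0.95; the normal quantile is
#'   used without a degrees-of-freedom correction).
#' @return Data frame with `spacing`, `median_speed`,
#'   `mean_speed_bias_corrected`, `pi_low`, `pi_high`.
#' @export
predict_still <- function(fit, spacing, level = 0.95) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (fit$include_body_length) {
    stop("still-image prediction uses the spacing-only model", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be positive and finite", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  X <- cbind(1, log(spacing))
  eta <- drop(X %*% c(fit$beta0, fit$beta1))
  v_fix <- rowSums((X %*% fit$fixef_vcov) * X)
  v <- v_fix + fit$sigma_u2 + fit$sigma_e2
  correction <- (fit$sigma_u2 + fit$sigma_e2) / 2
  data.frame(spacing = spacing,
             median_speed = exp(eta),
             mean_speed_bias_corrected = exp(eta + correction),
             pi_low = exp(eta - z * sqrt(v)),
             pi_high = exp(eta + z * sqrt(v)))
}

#' Leave-one-whale-out cross-validation of the spacing-to-speed model
#'
#' Withholds all surfacing events of one whale at a time, refits the
#' model on the remainder, and predicts the held-out events at the
#' population level (random intercept 0 -- the left-out whale's intercept
#' is unknown by construction). Predictions are generated in log space
#' and back-transformed (median). Reports original-scale RMSE and MAPE
#' and the percentage of observed speeds inside the propagated 95%
#' prediction intervals.
#'
#' @param events As in [fit_loglog_lmm()]; needs >= 3 whales.
#' @param estimation Passed through to the per-fold fits.
#' @return An object of class `cv_report` with `rmse`, `mape`,
#'   `pi_coverage` (%), `n_folds`, `n_skipped`, and the per-event
#'   `predictions` table (`whale_id`, `observed`, `predicted`, `pi_low`,
#'   `pi_high`).
#' @export
loocv_by_whale <- function(events, estimation = "REML") {
  d <- as.data.frame(events)
  whales <- unique(d$whale_id)
  if (length(whales) < 3) stop("need >= 3 whales for LOOCV", call. = FALSE)
  preds <- vector("list", length(whales))
  skipped <- 0L
  for (i in seq_along(whales)) {
    w <- whales[i]
    train <- d[d$whale_id != w, ]
    test <- d[d$whale_id == w, ]
    fit <- tryCatch(fit_loglog_lmm(train, estimation = estimation),
                    error = function(e) {
                      warning("fold for whale ", w, " skipped: ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(fit)) { skipped <- skipped + 1L; next }
    p <- predict_still(fit, test$mean_spacing)
    preds[[i]] <- data.frame(whale_id = w, observed = test$speed,
                             predicted = p$median_speed,
                             pi_low = p$pi_low, pi_high = p$pi_high,
                             stringsAsFactors = FALSE)
  }
  pr <- do.call(rbind, preds)
  if (is.null(pr) || nrow(pr) == 0) stop("all LOOCV folds failed", call. = FALSE)
  err <- pr$observed - pr$predicted
  structure(
    list(rmse = sqrt(mean(err^2)),
         mape = 100 * mean(abs(err) / pr$observed),
         pi_coverage = 100 * mean(pr$observed >= pr$pi_low &
                                    pr$observed <= pr$pi_high),
         n_folds = length(whales), n_skipped = skipped,
         predictions = pr),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Leave-one-whale-out CV over %d whales (%d skipped)\n",
              x$n_folds, x$n_skipped))
  cat(sprintf("  RMSE %.3f m/s, MAPE %.1f%%, 95%% PI coverage %.1f%%\n",
              x$rmse, x$mape, x$pi_coverage))
  invisible(x)
}

#' Calibration of still-image speed predictions
#'
#' Deming regression (equal error variances, lambda = 1) of predicted
#' against observed speeds, testing whether the slope differs from unity
#' and the intercept from zero -- the hypotheses of an unbiased,
#' well-calibrated predictor.
#'
#' @param predicted,observed Paired speeds, m/s (>= 3 pairs).
#' @param lambda Error variance ratio, passed to [deming_regression()].
#' @return A `deming_fit`.
#' @export
calibrate_predictions <- function(predicted, observed, lambda = 1) {
  deming_regression(observed, predicted, lambda = lambda)
}
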