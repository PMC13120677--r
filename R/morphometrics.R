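#' Per-individual morphometric summaries
#'
#' Computes one record per whale from an annotation table: mean flukeprint
#' width (from width-endpoint pairs), mean body length (rostrum tip to
#' fluke notch) and mean fluke span (tip to tip). Widths enter the mean
#' only when measured at the earliest clearly defined print boundary --
#' within 5 s of fluke emergence -- and not flagged as degraded; degraded
#' prints stay in the annotation table for movement analyses. Whales with
#' no valid width measurement are dropped with a warning. World
#' coordinates are used when present, otherwise pixel coordinates are
#' scaled through the supplied camera and flight context.
#'
#' @param annotations Annotation table ([read_annotations()] schema).
#' @param cam,ctx Optional [camera_model()] and [flight_context()] used
#'   when only pixel coordinates are available.
#' @param max_emergence_s Width-measurement quality window, seconds.
#' @return Data frame with `whale_id`, `age_class` (when the annotations
#'   carry it), `mean_flukeprint_width`, `mean_body_length`,
#'   `mean_fluke_span`, `n_measurements`.
#' @export
summarize_individuals <- function(annotations, cam = NULL, ctx = NULL,
                                  max_emergence_s = 5) {
  an <- as.data.frame(annotations)
  need <- c("record_type", "whale_id", "event_id", "sensor")
  if (!all(need %in% names(an))) {
    stop("annotation table lacks required columns: ",
         paste(setdiff(need, names(an)), collapse = ", "), call. = FALSE)
  }
  pair_len <- function(type_a, type_b, keys) {
    a <- an[an$record_type == type_a, ]
    b <- an[an$record_type == type_b, ]
    ka <- do.call(paste, c(a[keys], sep = "\r"))
    kb <- do.call(paste, c(b[keys], sep = "\r"))
    m <- match(ka, kb)
    a <- a[!is.na(m), ]; b <- b[m[!is.na(m)], ]
    if (nrow(a) == 0) return(NULL)
    len <- point_distance(a, b, cam, ctx)
    cbind(a[c("whale_id", intersect(c("degraded", "emergence_offset_s"),
                                    names(a)))],
          length_m = len)
  }
  widths <- pair_len("print_width_left", "print_width_right",
                     c("whale_id", "event_id", "print_id"))
  if (!is.null(widths)) {
    keep <- rep(TRUE, nrow(widths))
    if ("emergence_offset_s" %in% names(widths)) {
      keep <- keep & (is.na(widths$emergence_offset_s) |
                        widths$emergence_offset_s <= max_emergence_s)
    }
    if ("degraded" %in% names(widths)) {
      keep <- keep & !isTRUE_vec(widths$degraded)
    }
    widths <- widths[keep, ]
  }
  lengths <- pair_len("rostrum", "fluke_notch",
                      c("whale_id", "event_id", "timestamp"))
  spans <- pair_len("fluke_tip_left", "fluke_tip_right",
                    c("whale_id", "event_id", "timestamp"))

  ids <- unique(an$whale_id)
  mean_for <- function(tab, id) {
    if (is.null(tab)) return(c(NA_real_, 0))
    v <- tab$length_m[tab$whale_id == id]
    if (length(v) == 0) c(NA_real_, 0) else c(mean(v), length(v))
  }
  out <- do.call(rbind, lapply(ids, function(id) {
    w <- mean_for(widths, id); l <- mean_for(lengths, id)
    s <- mean_for(spans, id)
    data.frame(whale_id = id,
               mean_flukeprint_width = w[1],
               mean_body_length = l[1],
               mean_fluke_span = s[1],
               n_measurements = w[2],
               stringsAsFactors = FALSE)
  }))
  if ("age_class" %in% names(an)) {
    out$age_class <- an$age_class[match(out$whale_id, an$whale_id)]
    out <- out[c("whale_id", "age_class", setdiff(names(out),
                                                  c("whale_id", "age_class")))]
  }
  bad <- out$n_measurements == 0
  if (any(bad)) {
    warning(sum(bad), " whale(s) excluded: no valid width measurement (",
            paste(out$whale_id[bad], collapse = ", "), ")")
    out <- out[!bad, ]
  }
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) !is.na(x) & x %in% c(TRUE, "TRUE", "true", 1)

point_distance <- function(a, b, cam, ctx) {
  have_world <- all(c("x_m", "y_m") %in% names(a)) &&
    !anyNA(a$x_m) && !anyNA(b$x_m)
  if (have_world) {
    return(sqrt((a$x_m - b$x_m)^2 + (a$y_m - b$y_m)^2))
  }
  if (is.null(cam) || is.null(ctx)) {
    stop("pixel-only annotations need a camera model and flight context",
         call. = FALSE)
  }
  vapply(seq_len(nrow(a)), function(i) {
    cx <- if (!is.null(a$altitude_m) && is.finite(a$altitude_m[i])) {
      flight_context(a$altitude_m[i], ctx$altitude_sd, ctx$nadir)
    } else ctx
    measure_length(c(a$x_px[i], a$y_px[i]), c(b$x_px[i], b$y_px[i]), cam, cx)
  }, numeric(1))
}

#' Linear scaling models between flukeprint width and body size
#'
#' Ordinary least squares regressions of a size response (mean body length
#' or mean fluke span) on mean flukeprint width: pooled across classes,
#' within a single class, or the interaction model
#' `response ~ width * age_class` whose width-by-class interaction F test
#' asks whether the scaling slope differs between calves and adults.
#'
#' @param summaries Per-whale table from [summarize_individuals()] with an
#'   `age_class` column.
#' @param response `"body_length"` or `"fluke_span"`.
#' @param scope `"pooled"`, `"adult"`, `"calf"` or `"interaction"`.
#' @return An object of class `scaling_fit`: the underlying `lm`, its
#'   coefficient table, `adj_r2`, and for the interaction scope
#'   `interaction_F`, `interaction_df`, `interaction_p`.
#' @export
fit_scaling <- function(summaries,
                        response = c("body_length", "fluke_span"),
                        scope = c("pooled", "adult", "calf", "interaction")) {
  response <- match.arg(response)
  scope <- match.arg(scope)
  d <- scaling_frame(summaries, response, scope)
  if (nrow(d) < 3) stop("need at least 3 whales in scope", call. = FALSE)
  if (scope == "interaction") {
    if (length(unique(d$age_class)) < 2) {
      stop("invalid design: interaction model needs both age classes",
           call. = FALSE)
    }
    fit <- stats::lm(y ~ width * age_class, data = d)
    av <- stats::anova(fit)
    i <- grep("width:age_class", rownames(av))
    int_F <- av[i, "F value"]; int_p <- av[i, "Pr(>F)"]
    int_df <- c(av[i, "Df"], av["Residuals", "Df"])
  } else {
    fit <- stats::lm(y ~ width, data = d)
    int_F <- int_p <- NULL; int_df <- NULL
  }
  sm <- summary(fit)
  structure(
    list(response = response, scope = scope, model = fit,
         coefficients = sm$coefficients,
         adj_r2 = sm$adj.r.squared, r2 = sm$r.squared,
         n = nrow(d),
         interaction_F = int_F, interaction_df = int_df,
         interaction_p = int_p),
    class = "scaling_fit")
}

scaling_frame <- function(summaries, response, scope) {
  s <- as.data.frame(summaries)
  ycol <- paste0("mean_", response)
  stopifnot(all(c("mean_flukeprint_width", ycol) %in% names(s)))
  d <- data.frame(width = s$mean_flukeprint_width, y = s[[ycol]],
                  age_class = if ("age_class" %in% names(s)) s$age_class
                              else NA_character_,
                  stringsAsFactors = FALSE)
  d <- d[stats::complete.cases(d[c("width", "y")]), ]
  if (scope %in% c("adult", "calf")) d <- d[d$age_class == scope, ]
  d
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Scaling fit: %s ~ flukeprint width [%s, n = %d]\n",
              x$response, x$scope, x$n))
  stats::printCoefmat(x$coefficients, digits = 4)
  cat(sprintf("  adjusted R2 = %.3f\n", x$adj_r2))
  if (!is.null(x$interaction_F)) {
    cat(sprintf("  width x class interaction: F(%d,%d) = %.3f, p = %.3g\n",
                x$interaction_df[1], x$interaction_df[2],
                x$interaction_F, x$interaction_p))
  }
  invisible(x)
}

#' K-fold cross-validation of a scaling model
#'
#' Random (unstratified) folds under a fixed seed; the scope's model is
#' refitted on each training set and held-out predictions are pooled to
#' give RMSE and R-squared (`1 - SSE/SST` over the held-out pool). When
#' fewer observations than folds are available, k is reduced to n with a
#' warning.
#'
#' @inheritParams fit_scaling
#' @param k Number of folds (default 10).
#' @param seed RNG seed controlling fold assignment.
#' @return List with `cv_rmse`, `cv_r2`, `k`, `n`.
#' @export
crossvalidate_scaling <- function(summaries,
                                  response = c("body_length", "fluke_span"),
                                  scope = c("pooled", "adult", "calf",
                                            "interaction"),
                                  k = 10, seed = 1L) {
  response <- match.arg(response)
  scope <- match.arg(scope)
  d <- scaling_frame(summaries, response, scope)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 whales in scope", call. = FALSE)
  if (n < k) {
    warning("fewer observations (", n, ") than folds; reducing k to n")
    k <- n
  }
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  pred <- numeric(n)
  form <- if (scope == "interaction") y ~ width * age_class else y ~ width
  for (f in seq_len(k)) {
    fit <- stats::lm(form, data = d[fold != f, ])
    pred[fold == f] <- stats::predict(fit, newdata = d[fold == f, ])
  }
  sse <- sum((d$y - pred)^2)
  sst <- sum((d$y - mean(d$y))^2)
  list(cv_rmse = sqrt(sse / n), cv_r2 = 1 - sse / sst, k = k, n = n)
}

#' Logistic age-class discrimination from flukeprint width
#'
#' Fits a logistic regression of age class (adult = positive) on mean
#' flukeprint width, flags complete separation (residual deviance
#' essentially zero, as expected when the class width distributions do
#' not overlap), computes the ROC directly over width thresholds
#' (monotone-equivalent to probability thresholds for a single monotone
#' predictor), and selects the Youden-optimal threshold. Among thresholds
#' attaining the maximal J the smallest is taken, placed at the midpoint
#' of the gap between the neighbouring observed widths. A confusion
#' matrix and accuracy at the selected threshold are reported. Class
#' labels are used only for fitting and evaluation, never for prediction.
#'
#' @param summaries Per-whale table with `age_class` and
#'   `mean_flukeprint_width`; both classes need >= 2 whales.
#' @return An object of class `classifier_fit` with `glm_coefficients`,
#'   `separation_flag`, `residual_deviance`, `roc` (threshold,
#'   sensitivity, specificity data frame), `auc`, `youden_threshold`,
#'   `youden_J`, `sensitivity`, `specificity`, `confusion` (2x2),
#'   `accuracy`.
#' @export
classify_age <- function(summaries) {
  s <- as.data.frame(summaries)
  stopifnot(all(c("age_class", "mean_flukeprint_width") %in% names(s)))
  s <- s[stats::complete.cases(s[c("age_class", "mean_flukeprint_width")]), ]
  tab <- table(s$age_class)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("invalid design: both age classes need at least 2 whales",
         call. = FALSE)
  }
  adult <- s$age_class == "adult"
  w <- s$mean_flukeprint_width
  fit <- suppressWarnings(
    stats::glm(adult ~ w, family = stats::binomial(),
               control = stats::glm.control(maxit = 50)))
  dev <- fit$deviance
  separated <- dev < 1e-6

  # ROC over width thresholds: classify adult when width > threshold
  u <- sort(unique(w))
  thr <- c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  sens <- vapply(thr, function(t) mean(w[adult] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(w[!adult] <= t), numeric(1))
  J <- sens + spec - 1
  best <- which(J == max(J))[1] # smallest threshold among ties
  roc <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  # AUC by trapezoid over (FPR, TPR), equals the Mann-Whitney statistic
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(sens)]) / 2)

  pred_adult <- w > thr[best]
  confusion <- table(predicted = factor(pred_adult, c(FALSE, TRUE),
                                        c("calf", "adult")),
                     actual = factor(adult, c(FALSE, TRUE),
                                     c("calf", "adult")))
  structure(
    list(glm_coefficients = stats::coef(fit),
         separation_flag = separated,
         residual_deviance = dev,
         roc = roc, auc = auc,
         youden_threshold = thr[best], youden_J = J[best],
         sensitivity = sens[best], specificity = spec[best],
         confusion = confusion,
         accuracy = mean(pred_adult == adult),
         n = length(w)),
    class = "classifier_fit")
}

#' @export
print.classifier_fit <- function(x, ...) {
  cat(sprintf("Age-class classifier on flukeprint width (n = %d)\n", x$n))
  if (x$separation_flag) {
    cat("  complete separation: residual deviance ~ 0\n")
  }
  cat(sprintf("  AUC %.3f; Youden threshold %.3f m (J = %.3f)\n",
              x$auc, x$youden_threshold, x$youden_J))
  cat(sprintf("  sensitivity %.3f, specificity %.3f, accuracy %.3f\n",
              x$sensitivity, x$specificity, x$accuracy))
  print(x$confusion)
  invisible(x)
}
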