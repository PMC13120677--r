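annotation_record_types <- c(
  "rostrum", "fluke_notch", "fluke_tip_left", "fluke_tip_right",
  "print_centroid", "print_width_left", "print_width_right",
  "print_posterior", "print_anterior", "tail")

annotation_mandatory <- c("record_type", "whale_id", "event_id",
                          "timestamp", "sensor")

#' Read an annotation table
#'
#' Comma-separated table with one row per annotated landmark. Mandatory
#' columns: `record_type`, `whale_id`, `event_id`, `timestamp`, `sensor`;
#' each row must carry pixel (`x_px`, `y_px`) or world (`x_m`, `y_m`)
#' coordinates (or both); flukeprint records (`print_*` types) must carry
#' `print_id`. Unknown columns are preserved. Rows with missing
#' coordinates are dropped and collected into the `errors` attribute with
#' a warning; a print record without a `print_id` is a schema error
#' naming the offending row.
#'
#' @param path Path to a CSV file.
#' @return Data frame of validated annotation records, with an `errors`
#'   attribute (possibly empty data frame of dropped rows).
#' @export
read_annotations <- function(path) {
  an <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_annotations(an)
}

validate_annotations <- function(an) {
  missing_cols <- setdiff(annotation_mandatory, names(an))
  if (length(missing_cols) > 0) {
    stop("annotation schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  has_px <- all(c("x_px", "y_px") %in% names(an))
  has_m <- all(c("x_m", "y_m") %in% names(an))
  if (!has_px && !has_m) {
    stop("annotation schema error: need pixel (x_px,y_px) or world (x_m,y_m) coordinates",
         call. = FALSE)
  }
  if (nrow(an) == 0) {
    attr(an, "errors") <- an
    return(an)
  }
  bad_type <- !an$record_type %in% annotation_record_types
  is_print <- grepl("^print_", an$record_type)
  no_pid <- is_print & (!"print_id" %in% names(an) | is.na(an$print_id %||% NA))
  if (any(no_pid)) {
    stop("annotation schema error: print record(s) lacking print_id at row(s) ",
         paste(which(no_pid), collapse = ", "), call. = FALSE)
  }
  ok_px <- if (has_px) is.finite(an$x_px) & is.finite(an$y_px) else FALSE
  ok_m <- if (has_m) is.finite(an$x_m) & is.finite(an$y_m) else FALSE
  bad_coord <- !(ok_px | ok_m)
  bad_ts <- !is.finite(an$timestamp) | an$timestamp < 0
  bad <- bad_type | bad_coord | bad_ts
  if (any(bad)) {
    warning(sum(bad), " malformed annotation row(s) dropped; see attr(x, 'errors')")
  }
  out <- an[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "errors") <- an[bad, , drop = FALSE]
  out
}

#' Write an annotation table
#'
#' Inverse of [read_annotations()]: plain CSV, no row names.
#'
#' @param annotations Annotation data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(as.data.frame(annotations), path, row.names = FALSE)
  invisible(path)
}

KNOT_MS <- 0.514444  # 1 international knot in m/s

#' Convert between measurement units
#'
#' Supported pairs: `"m_s"` <-> `"knots"` (1 knot = 0.514444 m/s) and
#' `"m"` <-> `"px"` through a ground sample distance. Conversions are
#' exact and mutually inverse.
#'
#' @param value Numeric value(s).
#' @param from,to Unit labels: `"m_s"`, `"knots"`, `"m"`, `"px"`.
#' @param gsd Ground sample distance (m/px), required for m <-> px.
#' @return Converted numeric value(s).
#' @examples
#' convert_units(4.1, "m_s", "knots") # about 8 knots
#' @export
convert_units <- function(value, from, to, gsd = NULL) {
  key <- paste(from, to, sep = "->")
  needs_gsd <- key %in% c("m->px", "px->m")
  if (needs_gsd && (is.null(gsd) || gsd <= 0)) {
    stop("m <-> px conversion needs a positive ground sample distance",
         call. = FALSE)
  }
  switch(key,
         "m_s->knots" = value / KNOT_MS,
         "knots->m_s" = value * KNOT_MS,
         "m->px" = value / gsd,
         "px->m" = value * gsd,
         "m_s->m_s" = value, "knots->knots" = value,
         "m->m" = value, "px->px" = value,
         stop("unsupported unit conversion: ", key, call. = FALSE))
}

#' Read a run configuration file
#'
#' Structured YAML with optional blocks `cameras` (RGB/TIR intrinsics),
#' `flight` (altitude, altitude_sd), `simulation` (arguments of
#' [sim_config()]), and `analysis` (seed, cv_folds, lambda, pi_level,
#' frame_stride).
#'
#' @param path Path to a YAML file.
#' @return A named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

build_sim_config <- function(config, seed = NULL) {
  simargs <- config$simulation %||% list()
  if (!is.null(seed)) simargs$seed <- seed
  for (side in c("rgb", "tir")) {
    blk <- config$cameras[[side]]
    if (!is.null(blk)) {
      simargs[[paste0(side, "_camera")]] <- do.call(camera_model, c(
        list(sensor_label = toupper(side)), blk))
    }
  }
  if (!is.null(config$flight$altitude)) {
    simargs$altitude <- config$flight$altitude
  }
  if (!is.null(config$flight$altitude_sd)) {
    simargs$altitude_sd <- config$flight$altitude_sd
  }
  do.call(sim_config, simargs)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages on a simulated survey (or a supplied
#' annotation table): photogrammetric summaries, morphometric scaling and
#' age classification, dual-sensor speed agreement, the spacing-to-speed
#' mixed model with leave-one-whale-out validation and calibration, and
#' heading agreement. Fully deterministic given the seeds in the
#' configuration. Stage failures abort with the stage name; completed
#' stage outputs are kept in the returned bundle.
#'
#' @param config A `run_config` list (see [read_run_config()]), a path to
#'   a YAML file, or `NULL` for defaults.
#' @param annotations Optional annotation table; when `NULL` the
#'   simulation stage generates one.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "morphometrics", "speed", "orientation")`.
#' @param out Optional directory; when given, writes `report.json`, the
#'   annotation table and per-stage CSV tables there.
#' @return A list (class `pipeline_report`) with one element per stage
#'   plus `tables` (annotation and event tables).
#' @export
run_pipeline <- function(config = NULL, annotations = NULL,
                         stages = c("simulate", "morphometrics", "speed",
                                    "orientation"),
                         out = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- config %||% list()
  stages <- match.arg(stages, several.ok = TRUE)
  analysis <- config$analysis %||% list()
  seed <- analysis$seed %||% config$simulation$seed %||% 1L
  cfg <- build_sim_config(config, seed = seed)
  report <- list(seed = seed)
  tables <- list()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  whales_truth <- NULL
  speed_obs <- NULL
  if ("simulate" %in% stages && is.null(annotations)) {
    sim <- run_stage("simulate", {
      pop <- simulate_population(cfg)
      ann <- simulate_tracks_and_prints(cfg, pop$states)
      obs <- generate_speed_observations(cfg, pop$states)
      list(pop = pop, ann = ann, obs = obs)
    })
    annotations <- sim$ann
    whales_truth <- sim$pop$whales
    speed_obs <- sim$obs
    report$simulate <- list(
      n_whales = nrow(sim$pop$whales),
      n_adults = sum(sim$pop$whales$age_class == "adult"),
      n_calves = sum(sim$pop$whales$age_class == "calf"),
      n_events = nrow(sim$pop$states),
      n_annotation_rows = nrow(annotations))
    tables$true_whales <- whales_truth
    tables$speed_observations <- speed_obs
  }
  if (is.null(annotations)) {
    stop("configuration error: no annotations supplied and simulation not requested",
         call. = FALSE)
  }
  annotations <- validate_annotations(as.data.frame(annotations))
  tables$annotations <- annotations

  if ("morphometrics" %in% stages) {
    morph <- run_stage("morphometrics", {
      summaries <- summarize_individuals(annotations)
      cls <- classify_age(summaries)
      fits <- lapply(c(pooled = "pooled", interaction = "interaction",
                       adult = "adult", calf = "calf"), function(sc) {
        f <- fit_scaling(summaries, "body_length", sc)
        keep <- list(slope = unname(f$coefficients["width", "Estimate"]),
                     slope_se = unname(f$coefficients["width", "Std. Error"]),
                     adj_r2 = f$adj_r2, n = f$n)
        if (!is.null(f$interaction_F)) {
          keep$interaction_F <- f$interaction_F
          keep$interaction_p <- f$interaction_p
        }
        keep
      })
      cv <- crossvalidate_scaling(summaries, "body_length", "adult",
                                  k = analysis$cv_folds %||% 10,
                                  seed = seed)
      list(summaries = summaries,
           report = list(
             n_whales = nrow(summaries),
             scaling = fits,
             cv_adult_body_length = cv[c("cv_rmse", "cv_r2", "k")],
             classifier = list(
               youden_threshold = cls$youden_threshold,
               sensitivity = cls$sensitivity,
               specificity = cls$specificity,
               auc = cls$auc, accuracy = cls$accuracy,
               separation_flag = cls$separation_flag)))
    })
    tables$whale_summaries <- morph$summaries
    report$morphometrics <- morph$report
  }

  if ("speed" %in% stages) {
    sp <- run_stage("speed", {
      es <- event_speeds(annotations,
                         stride = analysis$frame_stride %||% 1L)
      pairs <- pair_events(es$rgb, es$tir)
      agr <- agreement_stats(pairs)
      ev <- if (!is.null(speed_obs)) {
        data.frame(whale_id = speed_obs$whale_id,
                   mean_spacing = speed_obs$mean_spacing,
                   speed = speed_obs$speed)
      } else {
        data.frame(whale_id = pairs$whale_id,
                   mean_spacing = pairs$mean_spacing,
                   speed = pairs$tir_speed)
      }
      fit <- fit_loglog_lmm(ev)
      cv <- loocv_by_whale(ev)
      cal <- calibrate_predictions(cv$predictions$predicted,
                                   cv$predictions$observed,
                                   lambda = analysis$lambda %||% 1)
      list(pairs = pairs,
           report = list(
             agreement = unclass_report(agr),
             lmm = list(beta0 = fit$beta0, beta0_se = fit$beta0_se,
                        beta1 = fit$beta1, beta1_se = fit$beta1_se,
                        sigma_u2 = fit$sigma_u2, sigma_e2 = fit$sigma_e2,
                        r2_marginal = fit$r2_marginal,
                        r2_conditional = fit$r2_conditional,
                        n_events = fit$n_events, n_whales = fit$n_whales),
             loocv = list(rmse = cv$rmse, mape = cv$mape,
                          pi_coverage = cv$pi_coverage),
             calibration = list(slope = cal$slope, intercept = cal$intercept,
                                slope_p = cal$slope_test$p,
                                intercept_p = cal$intercept_test$p),
             frame_stride = analysis$frame_stride %||% 1L))
    })
    tables$paired_events <- sp$pairs
    report$speed <- sp$report
  }

  if ("orientation" %in% stages) {
    ori <- run_stage("orientation", {
      hp <- heading_pairs(annotations)
      ha <- heading_agreement_report(hp)
      ds <- ha$difference_summary
      list(pairs = hp,
           report = list(
             n_pairs = ha$n_pairs,
             mean_offset = wrap_difference(ds$circ_mean, 0),
             circ_sd_deg = ds$circ_sd_deg,
             rayleigh_p = ds$rayleigh_p,
             circular_correlation = ha$correlation$r,
             correlation_p = ha$correlation$p_value,
             category_proportions = ha$category_proportions,
             mean_abs_error = ha$mean_abs_error,
             pct_under_20deg = ha$pct_under_20deg))
    })
    tables$heading_pairs <- ori$pairs
    report$orientation <- ori$report
  }

  bundle <- structure(list(report = report, tables = tables),
                      class = "pipeline_report")
  if (!is.null(out)) write_report_bundle(bundle, out)
  bundle
}

unclass_report <- function(agr) {
  lapply(unclass(agr), function(v) if (is.numeric(v)) unname(v) else v)
}

#' Write a pipeline report bundle to disk
#'
#' `report.json` (all floating point at 6 significant digits) plus one
#' CSV per table.
#'
#' @param bundle A `pipeline_report` from [run_pipeline()].
#' @param out Output directory (created if needed).
#' @return `out`, invisibly.
#' @export
write_report_bundle <- function(bundle, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  json <- jsonlite::toJSON(round_sig(bundle$report, 6), auto_unbox = TRUE,
                           pretty = TRUE, digits = NA, na = "null")
  writeLines(json, file.path(out, "report.json"))
  for (nm in names(bundle$tables)) {
    utils::write.csv(bundle$tables[[nm]],
                     file.path(out, paste0(nm, ".csv")), row.names = FALSE)
  }
  invisible(out)
}

round_sig <- function(x, digits) {
  if (is.list(x)) return(lapply(x, round_sig, digits = digits))
  if (is.numeric(x)) return(signif(x, digits))
  x
}

#' @export
print.pipeline_report <- function(x, ...) {
  r <- x$report
  cat("Pipeline report (seed", r$seed, ")\n")
  if (!is.null(r$simulate)) {
    cat(sprintf("  simulated %d whales (%d adults, %d calves), %d events\n",
                r$simulate$n_whales, r$simulate$n_adults,
                r$simulate$n_calves, r$simulate$n_events))
  }
  if (!is.null(r$morphometrics)) {
    cl <- r$morphometrics$classifier
    cat(sprintf("  age classifier: threshold %.2f m, sens %.2f, spec %.2f\n",
                cl$youden_threshold, cl$sensitivity, cl$specificity))
  }
  if (!is.null(r$speed)) {
    cat(sprintf("  speed agreement: bias %.3f m/s, RMSE %.3f, ICC %.3f\n",
                r$speed$agreement$bias, r$speed$agreement$rmse,
                r$speed$agreement$icc_a1))
    cat(sprintf("  LMM: beta1 %.3f (SE %.3f), R2 marg %.2f / cond %.2f; LOOCV coverage %.1f%%\n",
                r$speed$lmm$beta1, r$speed$lmm$beta1_se,
                r$speed$lmm$r2_marginal, r$speed$lmm$r2_conditional,
                r$speed$loocv$pi_coverage))
  }
  if (!is.null(r$orientation)) {
    cat(sprintf("  orientation: offset %.2f deg, circular r %.3f, %.1f%% under 20 deg\n",
                r$orientation$mean_offset, r$orientation$circular_correlation,
                r$orientation$pct_under_20deg))
  }
  invisible(x)
}
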