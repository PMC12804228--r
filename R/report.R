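#' Pipeline configuration for a simulated study
#'
#' Bundles every tunable the analysis stages use, with the study's
#' published values as defaults where they exist (loads 2/3/4 N, 40 Hz
#' force sampling, 0.01 s RMS windows, 120-160 kHz band, 90th/95th
#' percentiles, smoothing thresholds, alpha 0.05, 3 repeats, panel of 8)
#' and desk-scale simulation sizes elsewhere (recording duration, AE rate,
#' stroke count — see the methods vignette). The configuration round-trips
#' losslessly through its JSON representation.
#'
#' @param materials named list of [material_spec()] objects.
#' @param loads target loads, N.
#' @param repeats recordings per material x load.
#' @param duration recording length, s.
#' @param n_strokes strokes per recording.
#' @param force_rate force sampling rate, Hz.
#' @param ae_rate AE sampling rate, Sa/s.
#' @param ae include the AE stages.
#' @param window_seconds AE RMS window, s.
#' @param band AE band of interest, Hz.
#' @param band_pct in-band spectral percentile.
#' @param static_pct static-region percentile.
#' @param min_normal COF mask threshold, N.
#' @param hysteresis stroke-segmentation hysteresis, N.
#' @param min_duration minimum stroke duration, s.
#' @param trim_frac trailing trim fraction of the dynamic region.
#' @param alpha significance level.
#' @param n_panellists sensory panel size.
#' @param sensory_noise_sd panellist noise, rating units.
#' @param seed master seed; per-trial seeds are derived from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(materials = default_materials(),
                            loads = c(2, 3, 4), repeats = 3,
                            duration = 6, n_strokes = 8,
                            force_rate = 40, ae_rate = 5e5, ae = TRUE,
                            window_seconds = 0.01, band = c(120e3, 160e3),
                            band_pct = 90, static_pct = 95,
                            min_normal = 0.2, hysteresis = 0.05,
                            min_duration = 0.25, trim_frac = 0.05,
                            alpha = 0.05, n_panellists = 8,
                            sensory_noise_sd = 0.8, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> %d materials x loads {%s} x %d repeats, %g s @ %g Hz / %g Sa/s, seed %d\n",
              length(x$materials), paste(x$loads, collapse = ","), x$repeats,
              x$duration, x$force_rate, x$ae_rate, x$seed))
  invisible(x)
}

# JSON-serializable view of the resolved configuration
config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$materials <- lapply(cfg$materials, function(m) {
    u <- unclass(m)
    u$sensory_profile <- as.list(u$sensory_profile)
    u
  })
  out
}

#' Run the full simulated study end to end
#'
#' simulate -> friction -> acoustic -> sensory -> statistics. For every
#' material x load x repeat cell one trial is simulated (per-trial seed
#' derived from the master seed), friction and AE stroke features are
#' extracted, the in-band spectral percentile is computed per trial, a
#' simulated questionnaire is generated and validated, and the statistical
#' layer is run: per-material box-plot summaries, Tukey-Kramer tables for
#' dynamic COF, dynamic AE RMS and the band percentile, a covariance PCA
#' of the sensory data with per-material 95% concentration ellipsoids, and
#' the combined tribology PCA with supplementary sensory vectors. All
#' tables are written as CSV/JSON to `out_dir` together with a run log and
#' the resolved configuration; the run is deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` computes
#'   everything without writing.
#' @return (invisibly) list with `friction_features`, `ae_features`,
#'   `band_table`, `friction_summary`, `tukey_cof`, `tukey_rms`,
#'   `tukey_band`, `sensory`, `sensory_validation`, `sensory_pca`,
#'   `ellipsoids`, `combined`, `log`.
#' @export
run_report <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  note("run_report: %d materials, loads {%s}, %d repeats, seed %d",
       length(config$materials), paste(config$loads, collapse = ","),
       config$repeats, config$seed)
  if (!config$ae) note("AE stages skipped: force-only report")

  fr_rows <- list(); ae_rows <- list(); band_rows <- list()
  trial <- 0L; cell <- 0L
  for (m in config$materials) {
    cell <- 0L
    for (load in config$loads) for (rep_i in seq_len(config$repeats)) {
      trial <- trial + 1L
      cell <- cell + 1L
      # the same (load, repeat) cell shares one random stream across
      # materials: paired sessions, as when one participant strokes every
      # material under the same conditions
      plan <- trial_plan(target_load = load, duration = config$duration,
                         n_strokes = config$n_strokes,
                         force_rate = config$force_rate,
                         ae_rate = config$ae_rate,
                         seed = config$seed + 1000L * cell)
      sim <- tryCatch(
        simulate_trial(m, plan, ae = config$ae),
        error = function(e) stop(sprintf(
          "stage simulate failed for trial %d (%s, %g N, repeat %d): %s",
          trial, m$name, load, rep_i, conditionMessage(e)), call. = FALSE))

      ff <- tryCatch(
        friction_features(sim$force$recording, min_normal = config$min_normal,
                          hysteresis = config$hysteresis,
                          min_duration = config$min_duration,
                          trim_frac = config$trim_frac),
        error = function(e) stop(sprintf(
          "stage friction failed for trial %d (%s, %g N, repeat %d): %s",
          trial, m$name, load, rep_i, conditionMessage(e)), call. = FALSE))
      f <- ff$features
      f$target_load <- load; f$repeat_id <- rep_i
      fr_rows[[trial]] <- f
      note("trial %d (%s, %g N, rep %d): %d strokes, %d masked COF samples",
           trial, m$name, load, rep_i, nrow(ff$strokes),
           sum(!ff$series$valid))

      if (config$ae) {
        af <- tryCatch(
          ae_features(sim$ae, strokes = ff$strokes,
                      force_rate = config$force_rate, mode = "transfer",
                      band = config$band,
                      window_seconds = config$window_seconds),
          error = function(e) stop(sprintf(
            "stage acoustic failed for trial %d (%s, %g N, repeat %d): %s",
            trial, m$name, load, rep_i, conditionMessage(e)), call. = FALSE))
        a <- af$features
        a$target_load <- load; a$repeat_id <- rep_i
        ae_rows[[trial]] <- a
        band_rows[[trial]] <- data.frame(material = m$name,
                                         target_load = load,
                                         repeat_id = rep_i,
                                         band_p90 = af$band_p90)
        note("trial %d: band P%g = %.4g, %d spectral peaks removed",
             trial, config$band_pct, af$band_p90,
             attr(af$spectrum, "n_removed") %||% 0L)
      }
    }
  }
  friction_feats <- do.call(rbind, fr_rows)
  ae_feats <- if (config$ae) do.call(rbind, ae_rows) else NULL
  band_table <- if (config$ae) do.call(rbind, band_rows) else NULL

  friction_summary <- summarize_features(friction_feats, "dynamic_cof",
                                         "material")
  tukey_cof <- tukey_kramer(friction_feats$dynamic_cof,
                            friction_feats$material, alpha = config$alpha)
  tukey_rms <- if (config$ae)
    tukey_kramer(ae_feats$dynamic_rms, ae_feats$material,
                 alpha = config$alpha) else NULL
  tukey_band <- if (config$ae && config$repeats * length(config$loads) >= 2)
    tukey_kramer(band_table$band_p90, band_table$material,
                 alpha = config$alpha) else NULL

  sens <- generate_sensory_responses(config$materials,
                                     n_panellists = config$n_panellists,
                                     noise_sd = config$sensory_noise_sd,
                                     seed = config$seed)
  sens_val <- validate_questionnaire(sens)
  wide <- sensory_wide(sens)
  sens_pca <- run_pca(as.matrix(wide[sensory_attributes()]),
                      mode = "covariance")
  dims <- min(3L, ncol(sens_pca$scores))
  ellipsoids <- lapply(split(seq_len(nrow(wide)), wide$material), function(i)
    concentration_ellipsoid(sens_pca$scores[i, , drop = FALSE], dims = dims))

  combined <- NULL
  if (config$ae) {
    trib <- stats::aggregate(
      friction_feats[c("static_cof", "dynamic_cof")],
      by = list(material = friction_feats$material), FUN = mean)
    trib_ae <- stats::aggregate(
      ae_feats[c("static_rms", "dynamic_rms")],
      by = list(material = ae_feats$material), FUN = mean)
    trib <- merge(trib, trib_ae, by = "material")
    sens_means <- stats::aggregate(
      wide[sensory_attributes()], by = list(material = wide$material),
      FUN = mean)
    combined <- combined_pca(trib, sens_means)
  }

  result <- list(friction_features = friction_feats, ae_features = ae_feats,
                 band_table = band_table, friction_summary = friction_summary,
                 tukey_cof = tukey_cof, tukey_rms = tukey_rms,
                 tukey_band = tukey_band, sensory = sens,
                 sensory_validation = sens_val, sensory_pca = sens_pca,
                 ellipsoids = ellipsoids, combined = combined,
                 log = log_lines)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, name) if (!is.null(df))
      utils::write.csv(as.data.frame(df), file.path(out_dir, name),
                       row.names = FALSE)
    w(friction_feats, "friction_features.csv")
    w(ae_feats, "ae_stroke_features.csv")
    w(band_table, "band_percentiles.csv")
    w(friction_summary, "friction_summary.csv")
    w(tukey_cof, "tukey_dynamic_cof.csv")
    w(tukey_rms, "tukey_dynamic_rms.csv")
    w(tukey_band, "tukey_band_p90.csv")
    write_sensory_csv(sens, file.path(out_dir, "sensory_ratings.csv"))
    w(variance_table(sens_pca), "sensory_pca_variance.csv")
    w(data.frame(attribute = rownames(sens_pca$loadings),
                 round(sens_pca$loadings[, seq_len(dims), drop = FALSE], 6)),
      "sensory_pca_loadings.csv")
    w(data.frame(wide[c("panellist", "material")],
                 round(sens_pca$scores[, seq_len(dims), drop = FALSE], 6)),
      "sensory_pca_scores.csv")
    jsonlite::write_json(lapply(ellipsoids, unclass),
                         file.path(out_dir, "ellipsoids.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(combined)) {
      w(variance_table(combined), "combined_pca_variance.csv")
      w(data.frame(attribute = rownames(combined$overlays),
                   round(combined$overlays, 6)), "combined_pca_overlays.csv")
    }
    jsonlite::write_json(config_as_list(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
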