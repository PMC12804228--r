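#' Uniform reciprocating stroke schedule
#'
#' Tiles the recording with `n_strokes` equal sliding movements of
#' alternating direction (+1 = left-to-right first), emulating continuous
#' reciprocal finger sliding.
#'
#' @param plan a [trial_plan()].
#' @param min_stroke_s minimum physically sensible stroke duration, s.
#' @return data frame with columns `start_time`, `end_time` (s) and
#'   `direction` (+1/-1); strokes tile `[0, duration]`.
#' @export
generate_stroke_schedule <- function(plan, min_stroke_s = 0.25) {
  stopifnot(inherits(plan, "trial_plan"))
  if (plan$n_strokes * min_stroke_s > plan$duration)
    stop(sprintf("invalid plan: %d strokes of >= %g s do not fit in %g s",
                 plan$n_strokes, min_stroke_s, plan$duration), call. = FALSE)
  edges <- seq(0, plan$duration, length.out = plan$n_strokes + 1L)
  data.frame(start_time = edges[-length(edges)], end_time = edges[-1L],
             direction = rep_len(c(1, -1), plan$n_strokes))
}

# Normalized COF envelope of one stroke over n samples: linear ramp over the
# first 20% of the stroke up to the static peak mu_s, kinetic plateau at mu_d
# (optionally modulated by 8 Hz stick-slip), linear decay over the trailing 5%
# before reversal. The ramp starts and the decay ends at a small positive
# fraction of the respective level so the lateral-force sign stays equal to
# the stroke direction throughout.
stroke_cof_envelope <- function(n, mu_s, mu_d, rate,
                                stick_slip = FALSE, stick_slip_amplitude = 0,
                                ramp_frac = 0.2, trim_frac = 0.05,
                                onset_frac = 0.05, stick_slip_hz = 8) {
  n_ramp <- max(2L, as.integer(ceiling(ramp_frac * n)))
  n_plateau_end <- n - as.integer(floor(trim_frac * n))  # same formula as the splitter's trim
  env <- numeric(n)
  env[seq_len(n_ramp)] <- mu_s * (onset_frac + (1 - onset_frac) *
                                    (seq_len(n_ramp) - 1) / (n_ramp - 1))
  if (n_plateau_end > n_ramp) {
    idx <- (n_ramp + 1L):n_plateau_end
    plateau <- rep(mu_d, length(idx))
    if (stick_slip && stick_slip_amplitude > 0) {
      t_local <- (idx - 1) / rate
      plateau <- plateau * (1 + stick_slip_amplitude *
                              sin(2 * pi * stick_slip_hz * t_local))
    }
    env[idx] <- plateau
  }
  if (n > n_plateau_end) {
    idx <- (n_plateau_end + 1L):n
    env[idx] <- mu_d * seq(1, onset_frac, length.out = length(idx) + 1L)[-1L]
  }
  env
}

# Map schedule times to 1-based sample index spans at a given rate.
schedule_to_spans <- function(schedule, rate, n_total) {
  start_idx <- pmin(n_total, floor(schedule$start_time * rate) + 1L)
  end_idx <- c(start_idx[-1L] - 1L, n_total)
  data.frame(start = as.integer(start_idx), end = as.integer(end_idx),
             direction = schedule$direction)
}

#' Simulate a force-plate recording with planted friction ground truth
#'
#' The normal channel tracks the target load with Gaussian error (sd 5% of
#' load) plus a slow sinusoidal drift (0.1 Hz, amplitude 5%, random phase
#' per trial), emulating an experimenter holding a prompted load. The
#' lateral channel follows, per stroke, a linear static ramp to
#' `mu_static * load`, a kinetic plateau at `mu_dynamic * load` (with
#' optional stick-slip), a short terminal decay, additive Gaussian noise,
#' and a sign equal to the sliding direction.
#'
#' @param material a [material_spec()].
#' @param plan a [trial_plan()].
#' @param noise if `FALSE`, all noise and drift are switched off so the
#'   planted coefficients are recoverable exactly.
#' @param load_noise_sd,drift_amplitude,lateral_noise_sd noise magnitudes as
#'   fractions of the target load.
#' @param drift_freq drift frequency, Hz.
#' @param reseed if `TRUE` (default) the RNG is seeded from `plan$seed`;
#'   [simulate_trial()] seeds once and passes `FALSE`.
#' @return list with `recording` (a [force_recording()]) and `strokes`
#'   (ground-truth spans: `start`, `end` 1-based inclusive sample indices,
#'   `direction`, `ramp_end` = index of the planted static peak).
#' @export
synthesize_force_recording <- function(material, plan, noise = TRUE,
                                       load_noise_sd = 0.05,
                                       drift_amplitude = 0.05,
                                       drift_freq = 0.1,
                                       lateral_noise_sd = 0.02,
                                       reseed = TRUE) {
  stopifnot(inherits(material, "material_spec"), inherits(plan, "trial_plan"))
  if (reseed) set.seed(plan$seed)
  if (!noise) load_noise_sd <- drift_amplitude <- lateral_noise_sd <- 0

  schedule <- generate_stroke_schedule(plan)
  n <- as.integer(round(plan$duration * plan$force_rate))
  time <- (seq_len(n) - 1) / plan$force_rate
  load <- plan$target_load

  phase <- if (drift_amplitude > 0) stats::runif(1, 0, 2 * pi) else 0
  normal <- load * (1 + drift_amplitude * sin(2 * pi * drift_freq * time + phase))
  if (load_noise_sd > 0) normal <- normal + stats::rnorm(n, 0, load_noise_sd * load)

  spans <- schedule_to_spans(schedule, plan$force_rate, n)
  lateral <- numeric(n)
  ramp_end <- integer(nrow(spans))
  for (k in seq_len(nrow(spans))) {
    idx <- spans$start[k]:spans$end[k]
    env <- stroke_cof_envelope(length(idx), material$mu_static,
                               material$mu_dynamic, plan$force_rate,
                               stick_slip = material$stick_slip,
                               stick_slip_amplitude = material$stick_slip_amplitude)
    lateral[idx] <- spans$direction[k] * load * env
    ramp_end[k] <- spans$start[k] + max(2L, as.integer(ceiling(0.2 * length(idx)))) - 1L
  }
  if (lateral_noise_sd > 0) lateral <- lateral + stats::rnorm(n, 0, lateral_noise_sd * load)

  rec <- force_recording(time = time, normal_force = normal,
                         lateral_force = lateral, rate = plan$force_rate,
                         meta = list(material = material$name,
                                     target_load = load, seed = plan$seed))
  spans$ramp_end <- ramp_end
  list(recording = rec, strokes = spans)
}

#' Simulate an acoustic-emission waveform following the friction envelope
#'
#' Produces band-limited noise (white noise masked in the frequency domain
#' to 120-160 kHz) whose amplitude envelope follows each stroke's friction
#' envelope, at the material's in-band level, plus an unfiltered broadband
#' floor; both are enveloped so the waveform is near-zero at stroke
#' reversals.
#'
#' @inheritParams synthesize_force_recording
#' @param strokes ground-truth stroke schedule from the same plan (the
#'   `data.frame` returned by [generate_stroke_schedule()]); defaults to the
#'   plan's own schedule.
#' @param band AE band of interest, Hz.
#' @return an [ae_recording()].
#' @export
synthesize_ae_recording <- function(material, plan, strokes = NULL,
                                    band = c(120e3, 160e3), reseed = TRUE) {
  stopifnot(inherits(material, "material_spec"), inherits(plan, "trial_plan"))
  if (plan$ae_rate < 2 * band[2])
    stop(sprintf("ae_rate %g < %g Hz: band %g-%g kHz not representable (Nyquist)",
                 plan$ae_rate, 2 * band[2], band[1] / 1e3, band[2] / 1e3),
         call. = FALSE)
  if (reseed) set.seed(plan$seed)
  if (is.null(strokes)) strokes <- generate_stroke_schedule(plan)

  n <- as.integer(round(plan$duration * plan$ae_rate))
  spans <- schedule_to_spans(strokes, plan$ae_rate, n)
  env <- numeric(n)
  for (k in seq_len(nrow(spans))) {
    idx <- spans$start[k]:spans$end[k]
    env[idx] <- stroke_cof_envelope(length(idx), 1,
                                    material$mu_dynamic / material$mu_static,
                                    plan$ae_rate,
                                    stick_slip = material$stick_slip,
                                    stick_slip_amplitude = material$stick_slip_amplitude)
  }

  x <- numeric(n)
  if (material$ae_band_level > 0)
    x <- x + material$ae_band_level * band_limited_noise(n, plan$ae_rate, band)
  if (material$ae_out_of_band_level > 0)
    x <- x + material$ae_out_of_band_level * stats::rnorm(n)
  ae_recording(samples = env * x, rate = plan$ae_rate,
               meta = list(material = material$name,
                           target_load = plan$target_load, seed = plan$seed))
}

# Unit-variance white noise masked in the frequency domain to [band].
band_limited_noise <- function(n, rate, band) {
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  freqs <- (seq_len(n) - 1) * rate / n
  # two-sided mask: positive-frequency band and its mirrored conjugate part
  keep <- (freqs >= band[1] & freqs <= band[2]) |
    (freqs >= rate - band[2] & freqs <= rate - band[1])
  spec[!keep] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Simulate questionnaire responses for a panel
#'
#' Each panellist rates each material on the six tactile attributes: the
#' material's planted sensory profile plus Gaussian panellist noise, then a
#' monotone rescaling per panellist and attribute so the extreme grades 1
#' and 10 are each used at least once (the anchoring rule given to the
#' panel), which also keeps all ratings inside the scale.
#'
#' @param materials list of [material_spec()] objects (>= 2, each with a
#'   sensory profile).
#' @param n_panellists panel size (study panel: 8).
#' @param noise_sd panellist noise, rating units.
#' @param seed integer seed.
#' @return a [sensory_table()] in long format.
#' @export
generate_sensory_responses <- function(materials, n_panellists = 8,
                                       noise_sd = 0.8, seed = 1L) {
  if (length(materials) < 2L)
    stop("need at least 2 materials for anchored ratings", call. = FALSE)
  stopifnot_scalar(n_panellists, "n_panellists", lower = 1)
  profiles <- vapply(materials, function(m) {
    if (is.null(m$sensory_profile))
      stop(sprintf("material '%s' has no sensory profile", m$name), call. = FALSE)
    m$sensory_profile
  }, numeric(6L))  # attributes x materials
  mat_names <- vapply(materials, `[[`, character(1L), "name")
  set.seed(seed)
  out <- vector("list", n_panellists)
  for (p in seq_len(n_panellists)) {
    raw <- profiles + stats::rnorm(length(profiles), 0, noise_sd)
    scaled <- t(apply(raw, 1L, function(r) {
      if (diff(range(r)) == 0) return(rep(5.5, length(r)))
      pmin(10, pmax(1, 1 + 9 * (r - min(r)) / (max(r) - min(r))))
    }))
    out[[p]] <- data.frame(
      panellist = sprintf("P%02d", p),
      material = rep(mat_names, each = 6L),
      attribute = rep(sensory_attributes(), times = length(materials)),
      rating = as.vector(scaled))
  }
  sensory_table(do.call(rbind, out))
}

#' Simulate one full trial (force + AE) from a single random stream
#'
#' Seeds the RNG once from `plan$seed` and draws the force recording and the
#' AE waveform sequentially from that stream, so one integer reproduces the
#' whole trial bit-identically.
#'
#' @inheritParams synthesize_force_recording
#' @param ae if `FALSE`, skip AE synthesis (force-only trial).
#' @return list with `force` (recording + ground-truth strokes), `ae`
#'   (an [ae_recording()] or `NULL`) and `schedule`.
#' @export
simulate_trial <- function(material, plan, noise = TRUE, ae = TRUE) {
  set.seed(plan$seed)
  schedule <- generate_stroke_schedule(plan)
  force <- synthesize_force_recording(material, plan, noise = noise,
                                      reseed = FALSE)
  ae_rec <- if (ae) synthesize_ae_recording(material, plan, strokes = schedule,
                                            reseed = FALSE) else NULL
  list(force = force, ae = ae_rec, schedule = schedule)
}
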