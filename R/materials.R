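#' Material specification for the synthetic generator
#'
#' Describes one test surface by its planted tribological, acoustic and
#' sensory ground truth: static and dynamic friction coefficients, optional
#' stick-slip modulation of the kinetic plateau (seen on smooth planar
#' substrates), acoustic-emission energy inside and outside the 120-160 kHz
#' band of interest, and the mean sensory profile on the 1-10 scale.
#'
#' @param name material label.
#' @param mu_static static coefficient of friction (>= mu_dynamic >= 0).
#' @param mu_dynamic dynamic (kinetic) coefficient of friction.
#' @param stick_slip logical; modulate the plateau with an 8 Hz oscillation.
#' @param stick_slip_amplitude relative amplitude of the stick-slip
#'   oscillation (fraction of the plateau force).
#' @param ae_band_level AE magnitude (arbitrary units) in the 120-160 kHz
#'   band during sliding.
#' @param ae_out_of_band_level broadband AE floor outside the band.
#' @param sensory_profile named numeric vector of the six attribute means
#'   (`slippery`, `soft`, `rough`, `thick`, `greasy`, `pleasant`), each in
#'   \[1, 10\].
#' @return an object of class `material_spec`.
#' @seealso [default_materials()] for the six built-in presets.
#' @export
material_spec <- function(name, mu_static, mu_dynamic,
                          stick_slip = FALSE, stick_slip_amplitude = 0,
                          ae_band_level = 0, ae_out_of_band_level = 0,
                          sensory_profile = NULL) {
  stopifnot_scalar(mu_static, "mu_static", 0)
  stopifnot_scalar(mu_dynamic, "mu_dynamic", 0)
  if (mu_static < mu_dynamic)
    stop("mu_static must be >= mu_dynamic", call. = FALSE)
  stopifnot_flag(stick_slip, "stick_slip")
  stopifnot_scalar(stick_slip_amplitude, "stick_slip_amplitude", 0)
  stopifnot_scalar(ae_band_level, "ae_band_level", 0)
  stopifnot_scalar(ae_out_of_band_level, "ae_out_of_band_level", 0)
  if (!is.null(sensory_profile)) {
    if (!is.numeric(sensory_profile) || length(sensory_profile) != 6L ||
        any(sensory_profile < 1 | sensory_profile > 10))
      stop("sensory_profile must be six values in [1, 10]", call. = FALSE)
    if (is.null(names(sensory_profile)))
      names(sensory_profile) <- sensory_attributes()
    if (!setequal(names(sensory_profile), sensory_attributes()))
      stop("sensory_profile names must be the six canonical attributes",
           call. = FALSE)
    sensory_profile <- sensory_profile[sensory_attributes()]
  }
  structure(list(name = as.character(name), mu_static = mu_static,
                 mu_dynamic = mu_dynamic, stick_slip = stick_slip,
                 stick_slip_amplitude = stick_slip_amplitude,
                 ae_band_level = ae_band_level,
                 ae_out_of_band_level = ae_out_of_band_level,
                 sensory_profile = sensory_profile),
            class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material_spec> %s: mu_s=%.3f mu_d=%.3f%s AE band=%.3g floor=%.3g\n",
              x$name, x$mu_static, x$mu_dynamic,
              if (x$stick_slip) sprintf(" stick-slip(%.0f%%)",
                                        100 * x$stick_slip_amplitude) else "",
              x$ae_band_level, x$ae_out_of_band_level))
  invisible(x)
}

#' Built-in material presets
#'
#' Six presets emulating the study surfaces: three fabrics (cotton terry,
#' polycotton knit, cotton woven) and three planar substrates (PET film,
#' glazed ceramic "enamel", PTFE tape). Dynamic-COF medians are ordered
#' PET > enamel > PTFE ~ terry > knit ~ woven with all fabrics below 0.5,
#' and the 120-160 kHz AE levels are ordered inversely (woven > knit >
#' terry > PTFE > enamel > PET); knit and woven are deliberately given
#' nearly identical friction so that the COF comparison cannot separate
#' them while the AE features can. The numeric values are simulator
#' fixtures, not measurements.
#'
#' @return named list of [material_spec()] objects.
#' @export
default_materials <- function() {
  prof <- function(...) {
    p <- c(...)
    names(p) <- sensory_attributes()
    p
  }
  list(
    terry = material_spec("terry", 0.55, 0.420,
                          ae_band_level = 0.30, ae_out_of_band_level = 0.03,
                          sensory_profile = prof(3.0, 6.5, 8.5, 8.0, 2.0, 4.0)),
    knit = material_spec("knit", 0.42, 0.334,
                         ae_band_level = 0.50, ae_out_of_band_level = 0.03,
                         sensory_profile = prof(5.5, 8.5, 3.5, 5.0, 2.5, 6.5)),
    woven = material_spec("woven", 0.41, 0.330,
                          ae_band_level = 0.72, ae_out_of_band_level = 0.03,
                          sensory_profile = prof(5.0, 8.0, 4.5, 4.5, 2.5, 6.0)),
    PET = material_spec("PET", 1.30, 1.050, stick_slip = TRUE,
                        stick_slip_amplitude = 0.15,
                        ae_band_level = 0.06, ae_out_of_band_level = 0.02,
                        sensory_profile = prof(7.5, 2.5, 2.0, 2.0, 6.5, 8.0)),
    enamel = material_spec("enamel", 1.05, 0.850, stick_slip = TRUE,
                           stick_slip_amplitude = 0.12,
                           ae_band_level = 0.10, ae_out_of_band_level = 0.02,
                           sensory_profile = prof(8.5, 2.0, 1.5, 3.0, 5.5, 7.5)),
    PTFE = material_spec("PTFE", 0.58, 0.450, stick_slip = TRUE,
                         stick_slip_amplitude = 0.10,
                         ae_band_level = 0.20, ae_out_of_band_level = 0.03,
                         sensory_profile = prof(9.0, 3.5, 2.5, 2.5, 7.5, 7.0))
  )
}

#' Trial plan for one simulated recording
#'
#' Defaults mirror the study protocol: a target applied load of 2, 3 or 4 N,
#' 30 s recordings, force channels sampled at 40 Hz, AE sampled at 2 MSa/s.
#' The stroke count per recording is not part of the protocol; 10 strokes
#' (3 s per sliding movement) is the package default.
#'
#' @param target_load target normal load in newtons (2, 3 or 4 in the study;
#'   any positive value accepted).
#' @param duration recording length in seconds.
#' @param n_strokes number of reciprocating sliding movements.
#' @param force_rate force-plate sampling rate, Hz.
#' @param ae_rate AE sampling rate, samples/s (must exceed 2 x 160 kHz for
#'   the band of interest to be representable).
#' @param seed integer seed; one seed drives every random draw of the trial.
#' @return an object of class `trial_plan`.
#' @export
trial_plan <- function(target_load = 2, duration = 30, n_strokes = 10,
                       force_rate = 40, ae_rate = 2e6, seed = 1L) {
  stopifnot_scalar(target_load, "target_load", lower = 1e-9)
  stopifnot_scalar(duration, "duration", lower = 1e-9)
  stopifnot_scalar(n_strokes, "n_strokes", lower = 1)
  stopifnot_scalar(force_rate, "force_rate", lower = 1e-9)
  stopifnot_scalar(ae_rate, "ae_rate", lower = 1e-9)
  stopifnot_scalar(seed, "seed")
  structure(list(target_load = target_load, duration = duration,
                 n_strokes = as.integer(n_strokes), force_rate = force_rate,
                 ae_rate = ae_rate, seed = as.integer(seed)),
            class = "trial_plan")
}

#' @export
print.trial_plan <- function(x, ...) {
  cat(sprintf("<trial_plan> load=%g N, %g s, %d strokes, force %g Hz, AE %g Sa/s, seed %d\n",
              x$target_load, x$duration, x$n_strokes, x$force_rate, x$ae_rate,
              x$seed))
  invisible(x)
}
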