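#' Force-plate recording container
#'
#' Synchronized normal (vertical) and lateral (horizontal, signed) force
#' channels from a reciprocating finger-sliding trial.
#'
#' @param time sample times, s, strictly increasing.
#' @param normal_force normal force, N.
#' @param lateral_force signed lateral force, N (sign encodes sliding
#'   direction).
#' @param rate sampling rate, Hz (study rig: 40 Hz).
#' @param meta named list of trial metadata (participant, material,
#'   target_load, repeat, ...).
#' @return object of class `force_recording`.
#' @export
force_recording <- function(time, normal_force, lateral_force, rate = 40,
                            meta = list()) {
  n <- length(time)
  if (n < 2L || length(normal_force) != n || length(lateral_force) != n)
    stop("channels must have equal length >= 2", call. = FALSE)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  stopifnot_scalar(rate, "rate", lower = 1e-12)
  structure(list(time = as.numeric(time), normal_force = as.numeric(normal_force),
                 lateral_force = as.numeric(lateral_force), rate = rate,
                 meta = meta),
            class = "force_recording")
}

#' @export
print.force_recording <- function(x, ...) {
  cat(sprintf("<force_recording> %d samples @ %g Hz (%.2f s)%s\n",
              length(x$time), x$rate, diff(range(x$time)),
              if (length(x$meta)) paste0(", ",
                paste(names(x$meta), unlist(x$meta), sep = "=", collapse = " "))
              else ""))
  invisible(x)
}

#' @export
plot.force_recording <- function(x, ...) {
  graphics::matplot(x$time, cbind(x$normal_force, x$lateral_force),
                    type = "l", lty = 1, col = c("black", "firebrick"),
                    xlab = "time (s)", ylab = "force (N)", ...)
  graphics::legend("topright", c("normal", "lateral"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}

#' Instantaneous coefficient of friction
#'
#' COF = |lateral| / normal per sample, masked (flagged invalid) wherever
#' the normal force falls below `min_normal` — this prevents COF blow-up at
#' finger lift-off while preserving genuinely high COF values at contact
#' loads.
#'
#' @param rec a [force_recording()].
#' @param min_normal minimum normal force, N, for a valid COF sample.
#' @return object of class `cof_series`: `time`, `cof` (NA where masked),
#'   `valid`, `mask_reason` (`"valid"` or `"low-normal-force"`).
#' @export
compute_cof_series <- function(rec, min_normal = 0.2) {
  stopifnot(inherits(rec, "force_recording"))
  stopifnot_scalar(min_normal, "min_normal", lower = 1e-12)
  valid <- rec$normal_force >= min_normal
  if (!any(valid))
    stop(sprintf("all %d samples masked: normal force never reaches %g N",
                 length(valid), min_normal), call. = FALSE)
  cof <- ifelse(valid, abs(rec$lateral_force) / rec$normal_force, NA_real_)
  structure(list(time = rec$time, cof = cof, valid = valid,
                 mask_reason = ifelse(valid, "valid", "low-normal-force"),
                 rate = rec$rate, meta = rec$meta),
            class = "cof_series")
}

#' @export
print.cof_series <- function(x, ...) {
  cat(sprintf("<cof_series> %d samples (%d masked), COF range [%.3f, %.3f]\n",
              length(x$cof), sum(!x$valid),
              min(x$cof, na.rm = TRUE), max(x$cof, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.cof_series <- function(x, ...) {
  graphics::plot(x$time, x$cof, type = "l", xlab = "time (s)", ylab = "COF", ...)
  invisible(x)
}

#' Segment a recording into single sliding strokes
#'
#' One stroke is one finger sliding movement between direction reversals.
#' Strokes are maximal runs of consistent lateral-force sign after
#' hysteresis debouncing: the direction state only switches when the
#' lateral force exceeds the hysteresis band with the opposite sign, which
#' suppresses zero-crossing chatter at reversals. Runs shorter than the
#' minimum stroke duration are merged into the preceding stroke (or dropped
#' at the edges) and reported via the `n_dropped` attribute.
#'
#' @param rec a [force_recording()].
#' @param hysteresis half-width of the sign hysteresis band, N.
#' @param min_duration minimum stroke duration, s.
#' @return data frame of class `stroke_table`: 1-based inclusive sample
#'   spans `start`, `end` and `direction` (+1/-1).
#' @export
segment_strokes <- function(rec, hysteresis = 0.05, min_duration = 0.25) {
  stopifnot(inherits(rec, "force_recording"))
  lat <- rec$lateral_force
  n <- length(lat)
  min_len <- max(1L, as.integer(round(min_duration * rec$rate)))
  if (n < min_len)
    stop(sprintf("recording (%d samples) shorter than one minimum stroke (%d)",
                 n, min_len), call. = FALSE)

  # hysteresis state machine over the sign of the lateral force
  state <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (lat[i] > hysteresis) cur <- 1L
    else if (lat[i] < -hysteresis) cur <- -1L
    state[i] <- cur
  }
  first <- which(state != 0L)
  if (!length(first))
    stop("no strokes: lateral force never exceeds the hysteresis band",
         call. = FALSE)
  state[seq_len(first[1L])] <- state[first[1L]]  # backfill leading idle samples

  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  spans <- data.frame(start = starts, end = ends, direction = r$values)

  # merge sub-minimum runs into the previous stroke; drop a short first run
  n_dropped <- 0L
  keep <- spans
  repeat {
    short <- which((keep$end - keep$start + 1L) < min_len)
    if (!length(short)) break
    i <- short[1L]
    if (i == 1L && nrow(keep) > 1L) {
      keep$start[2L] <- keep$start[1L]
      keep <- keep[-1L, , drop = FALSE]
    } else if (i > 1L) {
      keep$end[i - 1L] <- keep$end[i]
      keep <- keep[-i, , drop = FALSE]
    } else break  # single short run: keep it rather than return nothing
    n_dropped <- n_dropped + 1L
  }
  rownames(keep) <- NULL
  keep$stroke_id <- seq_len(nrow(keep))
  structure(keep[, c("stroke_id", "start", "end", "direction")],
            n_dropped = n_dropped, class = c("stroke_table", "data.frame"))
}

#' Split each stroke into static and dynamic regions
#'
#' The static region runs from the stroke start to the first sample
#' attaining the stroke's maximum COF (the static-friction peak); the
#' dynamic region is the remainder minus a trailing trim fraction that
#' excludes the deceleration into the direction reversal. Strokes with too
#' few valid samples are flagged unusable.
#'
#' @param strokes a `stroke_table` from [segment_strokes()].
#' @param series a [compute_cof_series()] result (or any list with a
#'   numeric `cof` element aligned to the recording, e.g. an AE RMS profile
#'   via [segment_rms_strokes()]).
#' @param trim_frac trailing fraction of each stroke excluded from the
#'   dynamic region.
#' @param min_valid minimum number of valid samples for a usable stroke.
#' @return the stroke table with `static_start`, `static_end`,
#'   `dynamic_start`, `dynamic_end`, `usable` columns.
#' @export
split_static_dynamic <- function(strokes, series, trim_frac = 0.05,
                                 min_valid = 4L) {
  stopifnot(is.data.frame(strokes))
  cof <- series$cof
  out <- strokes
  out$static_start <- out$static_end <- NA_integer_
  out$dynamic_start <- out$dynamic_end <- NA_integer_
  out$usable <- FALSE
  for (k in seq_len(nrow(out))) {
    idx <- out$start[k]:out$end[k]
    v <- cof[idx]
    ok <- which(!is.na(v))
    if (length(ok) < min_valid) next
    n <- length(idx)
    peak <- ok[which.max(v[ok])]           # first index attaining the max
    dyn_end <- n - as.integer(floor(trim_frac * n))
    if (peak >= dyn_end) {                 # degenerate: peak inside the trim
      if (peak >= n) next
      dyn_end <- n
    }
    out$static_start[k] <- out$start[k]
    out$static_end[k] <- out$start[k] + peak - 1L
    out$dynamic_start[k] <- out$start[k] + peak
    out$dynamic_end[k] <- out$start[k] + dyn_end - 1L
    out$usable[k] <- out$dynamic_end[k] >= out$dynamic_start[k]
  }
  out
}

#' Per-stroke static and dynamic COF statistics
#'
#' Static COF = 95th percentile of the COF over the static region; dynamic
#' COF = median over the dynamic region. Both use the package-wide
#' linear-interpolation percentile convention ([pctl()]).
#'
#' @param strokes output of [split_static_dynamic()].
#' @param series the matching [compute_cof_series()] result.
#' @param static_pct percentile used for the static statistic.
#' @return data frame with one row per usable stroke: `stroke_id`,
#'   `direction`, `static_cof`, `dynamic_cof` plus recording metadata.
#' @export
extract_stroke_cof <- function(strokes, series, static_pct = 95) {
  rows <- lapply(seq_len(nrow(strokes)), function(k) {
    if (!isTRUE(strokes$usable[k])) return(NULL)
    st <- series$cof[strokes$static_start[k]:strokes$static_end[k]]
    dy <- series$cof[strokes$dynamic_start[k]:strokes$dynamic_end[k]]
    st <- st[!is.na(st)]; dy <- dy[!is.na(dy)]
    if (!length(st) || !length(dy)) return(NULL)
    data.frame(stroke_id = strokes$stroke_id[k],
               direction = strokes$direction[k],
               static_cof = pctl(st, static_pct),
               dynamic_cof = pctl(dy, 50))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no usable strokes: every span was empty or invalid", call. = FALSE)
  meta <- series$meta
  for (f in c("participant", "material", "target_load", "repeat"))
    if (!is.null(meta[[f]])) out[[f]] <- meta[[f]]
  rownames(out) <- NULL
  out
}

#' Full friction feature pipeline for one recording
#'
#' Convenience wrapper: COF series, stroke segmentation, static/dynamic
#' split, per-stroke feature extraction.
#'
#' @inheritParams compute_cof_series
#' @inheritParams segment_strokes
#' @inheritParams split_static_dynamic
#' @return list with `series`, `strokes` and `features`.
#' @export
friction_features <- function(rec, min_normal = 0.2, hysteresis = 0.05,
                              min_duration = 0.25, trim_frac = 0.05) {
  series <- compute_cof_series(rec, min_normal = min_normal)
  strokes <- segment_strokes(rec, hysteresis = hysteresis,
                             min_duration = min_duration)
  strokes <- split_static_dynamic(strokes, series, trim_frac = trim_frac)
  list(series = series, strokes = strokes,
       features = extract_stroke_cof(strokes, series))
}

#' Grouped box-plot summaries of stroke features
#'
#' Per group: n, median, quartiles, whiskers by the 1.5 x IQR rule and the
#' retained outliers — the statistics behind per-material box plots. No
#' values are discarded.
#'
#' @param features data frame of per-stroke features.
#' @param value name of the value column (e.g. `"dynamic_cof"`).
#' @param group_by character vector of grouping columns.
#' @return data frame with one row per non-empty group.
#' @export
summarize_features <- function(features, value = "dynamic_cof",
                               group_by = "material") {
  stopifnot(value %in% names(features), all(group_by %in% names(features)))
  key <- interaction(features[group_by], drop = TRUE, sep = "/")
  groups <- split(features[[value]], key)
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]][!is.na(groups[[g]])]
    if (!length(x)) {
      warning(sprintf("group '%s' is empty; omitted", g), call. = FALSE)
      return(NULL)
    }
    s <- boxplot_stats(x)
    data.frame(group = g, n = s$n, median = s$median, q1 = s$q1,
               q3 = s$q3, whisker_low = s$whisker_low,
               whisker_high = s$whisker_high, n_outliers = s$n_outliers)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no non-empty groups", call. = FALSE)
  # split the compound key back into its grouping columns
  parts <- do.call(rbind, strsplit(out$group, "/", fixed = TRUE))
  for (j in seq_along(group_by)) out[[group_by[j]]] <- parts[, j]
  rownames(out) <- NULL
  out[, c(group_by, "n", "median", "q1", "q3", "whisker_low", "whisker_high",
          "n_outliers")]
}
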