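#' Read and write force recordings as CSV
#'
#' Column layout: `time_s`, `normal_N`, `lateral_N` (header required).
#' Metadata, if present, travels in a JSON sidecar written next to the CSV.
#'
#' @param rec a [force_recording()].
#' @param path CSV path.
#' @param meta_sidecar also write `<path>.json` with rate and metadata.
#' @return `write_force_csv`: the path, invisibly. `read_force_csv`: a
#'   [force_recording()].
#' @export
write_force_csv <- function(rec, path, meta_sidecar = TRUE) {
  stopifnot(inherits(rec, "force_recording"))
  utils::write.csv(data.frame(time_s = rec$time, normal_N = rec$normal_force,
                              lateral_N = rec$lateral_force),
                   path, row.names = FALSE)
  if (meta_sidecar)
    jsonlite::write_json(list(rate = rec$rate, meta = rec$meta),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_force_csv
#' @param rate sampling rate, Hz; taken from the sidecar when present.
#' @export
read_force_csv <- function(path, rate = NULL) {
  df <- utils::read.csv(path)
  req <- c("time_s", "normal_N", "lateral_N")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  bad <- which(!stats::complete.cases(df[req]))
  if (length(bad))
    stop(sprintf("%s: malformed row(s) at line(s) %s", path,
                 paste(utils::head(bad + 1L, 5L), collapse = ", ")),
         call. = FALSE)
  if (any(diff(df$time_s) <= 0))
    stop(sprintf("%s: time_s must be strictly increasing", path), call. = FALSE)
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(rate)) rate <- sc$rate
    if (!is.null(sc$meta)) meta <- as.list(sc$meta)
  }
  if (is.null(rate)) rate <- 1 / stats::median(diff(df$time_s))
  force_recording(df$time_s, df$normal_N, df$lateral_N, rate = rate,
                  meta = meta)
}

#' Read and write AE recordings as WAV or raw float32
#'
#' `write_ae_wav`/`read_ae_wav` use a minimal single-channel RIFF WAVE
#' container (IEEE float32 on write; float32, float64 and 16-bit PCM on
#' read), carrying the sample rate in the header.
#' `write_ae_raw`/`read_ae_raw` store little-endian float32 samples plus a
#' JSON sidecar `{rate, units, meta}`.
#'
#' @param rec an [ae_recording()].
#' @param path output path.
#' @return writers: the path, invisibly; readers: an [ae_recording()].
#' @export
write_ae_wav <- function(rec, path) {
  stopifnot(inherits(rec, "ae_recording"))
  n <- length(rec$samples)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 4L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")            # IEEE float
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(rec$rate), con, size = 4, endian = "little")
  writeBin(as.integer(rec$rate * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")            # block align
  writeBin(32L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(rec$samples, con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_ae_wav
#' @param meta metadata list attached to the recording on read.
#' @export
read_ae_wav <- function(path, meta = list()) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop(path, ": not a RIFF file", call. = FALSE)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop(path, ": not a WAVE file", call. = FALSE)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!nzchar(id)) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(code = readBin(con, integer(), size = 2, endian = "little"),
                  channels = readBin(con, integer(), size = 2, endian = "little"),
                  rate = readBin(con, integer(), size = 4, endian = "little"))
      readBin(con, integer(), size = 4, endian = "little")  # byte rate
      readBin(con, integer(), size = 2, endian = "little")  # block align
      fmt$bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16L) readBin(con, raw(), n = size - 16L)
    } else if (id == "data") {
      if (is.null(fmt)) stop(path, ": data chunk before fmt", call. = FALSE)
      samples <- readBin(con, raw(), n = size)
      break
    } else readBin(con, raw(), n = size)
  }
  if (is.null(fmt) || is.null(samples))
    stop(path, ": missing fmt or data chunk", call. = FALSE)
  if (fmt$channels != 1L)
    stop(path, ": only single-channel WAV supported", call. = FALSE)
  x <- switch(as.character(fmt$code),
              "3" = {
                bytes <- if (fmt$bits == 64) 8L else 4L
                readBin(samples, numeric(), n = length(samples) %/% bytes,
                        size = bytes, endian = "little")
              },
              "1" = readBin(samples, integer(), n = length(samples) / 2L,
                            size = 2, signed = TRUE,
                            endian = "little") / 32768,
              stop(path, ": unsupported WAV format code ", fmt$code,
                   call. = FALSE))
  ae_recording(x, rate = fmt$rate, meta = meta)
}

#' @rdname write_ae_wav
#' @export
write_ae_raw <- function(rec, path) {
  stopifnot(inherits(rec, "ae_recording"))
  con <- file(path, "wb")
  writeBin(rec$samples, con, size = 4, endian = "little")
  close(con)
  jsonlite::write_json(list(rate = rec$rate, units = "V", meta = rec$meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ae_wav
#' @export
read_ae_raw <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop(path, ": missing JSON sidecar ", sidecar, call. = FALSE)
  sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n <- file.size(path) / 4L
  con <- file(path, "rb")
  x <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  close(con)
  ae_recording(x, rate = sc$rate,
               meta = if (is.null(sc$meta)) list() else as.list(sc$meta))
}

#' Read and write sensory tables as long-format CSV
#'
#' Columns: `panellist`, `material`, `attribute`, `rating`.
#'
#' @param t a [sensory_table()].
#' @param path CSV path.
#' @return writer: the path, invisibly; reader: a [sensory_table()].
#' @export
write_sensory_csv <- function(t, path) {
  stopifnot(inherits(t, "sensory_table"))
  utils::write.csv(as.data.frame(t), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensory_csv
#' @export
read_sensory_csv <- function(path) {
  df <- utils::read.csv(path)
  sensory_table(df)
}
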