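#' Canonical sensory attribute vocabulary
#'
#' The six tactile attributes rated on a 1-10 interval scale, in their fixed
#' order. These are the labels of the quantitative loadings table; the
#' questionnaire prose names them differently ([attribute_aliases()]).
#'
#' @return character vector of the six attributes.
#' @export
sensory_attributes <- function() {
  c("slippery", "soft", "rough", "thick", "greasy", "pleasant")
}

#' Alias map from questionnaire prose names to canonical attributes
#'
#' The correspondence is a renaming only; no rating values are inverted
#' (in particular, "stickiness" maps onto the slipperiness axis without
#' reversing the scale).
#'
#' @return named character vector: prose name -> canonical attribute.
#' @export
attribute_aliases <- function() {
  c(stickiness = "slippery", softness = "soft", roughness = "rough",
    thickness = "thick", greasiness = "greasy",
    "overall feeling" = "pleasant", pleasantness = "pleasant")
}

#' Sensory questionnaire table
#'
#' Long-format panellist x material x attribute ratings on the 1-10
#' interval scale. Ratings are stored as real numbers (panellists place
#' marks on a continuous scale). Prose attribute names are mapped to the
#' canonical vocabulary; anything outside it is rejected, never coerced.
#'
#' @param df data frame with columns `panellist`, `material`, `attribute`,
#'   `rating`.
#' @return object of class `sensory_table` (a data frame).
#' @export
sensory_table <- function(df) {
  req <- c("panellist", "material", "attribute", "rating")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- df[req]
  df$panellist <- as.character(df$panellist)
  df$material <- as.character(df$material)
  attr_in <- tolower(trimws(as.character(df$attribute)))
  aliases <- attribute_aliases()
  hit <- attr_in %in% names(aliases)
  attr_in[hit] <- aliases[attr_in[hit]]
  unknown <- setdiff(unique(attr_in), sensory_attributes())
  if (length(unknown))
    stop("unknown attribute(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  df$attribute <- attr_in
  df$rating <- as.numeric(df$rating)
  key <- paste(df$panellist, df$material, df$attribute)
  if (anyDuplicated(key))
    stop("duplicate (panellist, material, attribute) record(s): ",
         paste(utils::head(key[duplicated(key)], 3L), collapse = "; "),
         call. = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("sensory_table", "data.frame"))
}

#' Validate a questionnaire against the rating protocol
#'
#' Checks, per panellist and attribute: scale bounds (1-10; error),
#' completeness over the material set (error), and the anchoring rule that
#' at least one material sits on each extreme grade (warning only — real
#' panellists may deviate from the instruction; the synthetic generator
#' enforces it by construction).
#'
#' @param t a [sensory_table()].
#' @param tol numeric slack on the extreme grades.
#' @return object of class `sensory_validation`: list with `errors`,
#'   `warnings` (character vectors) and `ok` (no errors).
#' @export
validate_questionnaire <- function(t, tol = 1e-8) {
  stopifnot(inherits(t, "sensory_table"))
  errors <- character()
  warnings <- character()
  bad <- which(is.na(t$rating) | t$rating < 1 | t$rating > 10)
  for (i in bad)
    errors <- c(errors, sprintf(
      "rating out of [1, 10]: panellist %s, material %s, attribute %s = %s",
      t$panellist[i], t$material[i], t$attribute[i], format(t$rating[i])))
  materials <- sort(unique(t$material))
  for (p in unique(t$panellist)) {
    tp <- t[t$panellist == p, ]
    for (a in sensory_attributes()) {
      r <- tp$rating[tp$attribute == a]
      miss <- setdiff(materials, tp$material[tp$attribute == a])
      if (length(miss))
        errors <- c(errors, sprintf(
          "panellist %s, attribute %s: missing rating for %s", p, a,
          paste(miss, collapse = ", ")))
      if (!length(r)) next
      if (min(r) > 1 + tol)
        warnings <- c(warnings, sprintf(
          "panellist %s, attribute %s: extreme grade 1 unused", p, a))
      if (max(r) < 10 - tol)
        warnings <- c(warnings, sprintf(
          "panellist %s, attribute %s: extreme grade 10 unused", p, a))
    }
  }
  structure(list(ok = !length(errors), errors = errors, warnings = warnings),
            class = "sensory_validation")
}

#' @export
print.sensory_validation <- function(x, ...) {
  cat(sprintf("<sensory_validation> %s: %d error(s), %d warning(s)\n",
              if (x$ok) "OK" else "FAILED", length(x$errors),
              length(x$warnings)))
  for (e in utils::head(x$errors, 10L)) cat("  error: ", e, "\n", sep = "")
  for (w in utils::head(x$warnings, 10L)) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Radar profile of one panellist's ratings
#'
#' One attribute-ordered six-vector per material, the data behind a radar
#' chart of a panellist's questionnaire response. Attribute order is the
#' canonical [sensory_attributes()] order; the result is independent of
#' input record order.
#'
#' @param t a [sensory_table()].
#' @param panellist panellist label.
#' @return materials x attributes numeric matrix.
#' @export
radar_profile <- function(t, panellist) {
  stopifnot(inherits(t, "sensory_table"))
  tp <- t[t$panellist == panellist, ]
  if (!nrow(tp)) stop(sprintf("panellist '%s' not present", panellist),
                      call. = FALSE)
  materials <- sort(unique(tp$material))
  attrs <- sensory_attributes()
  m <- matrix(NA_real_, length(materials), length(attrs),
              dimnames = list(materials, attrs))
  for (i in seq_len(nrow(tp)))
    m[tp$material[i], tp$attribute[i]] <- tp$rating[i]
  if (anyNA(m)) {
    hole <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing rating: material %s, attribute %s",
                 rownames(m)[hole[1L]], colnames(m)[hole[2L]]), call. = FALSE)
  }
  m
}

#' Radar chart of one panellist's material profiles
#'
#' @inheritParams radar_profile
#' @param ... passed to [graphics::lines()].
#' @return the profile matrix, invisibly.
#' @export
plot_radar <- function(t, panellist, ...) {
  m <- radar_profile(t, panellist)
  k <- ncol(m)
  ang <- pi / 2 - 2 * pi * (seq_len(k) - 1) / k
  graphics::plot(NA, xlim = c(-11, 11), ylim = c(-11, 11), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("panellist %s", panellist))
  for (r in c(1, 4, 7, 10))
    graphics::polygon(r * cos(ang), r * sin(ang), border = "grey80")
  graphics::text(10.8 * cos(ang), 10.8 * sin(ang), colnames(m), cex = 0.8)
  cols <- grDevices::hcl.colors(nrow(m), "Dark 3")
  for (i in seq_len(nrow(m)))
    graphics::polygon(m[i, ] * cos(ang), m[i, ] * sin(ang), border = cols[i],
                      lwd = 2, ...)
  graphics::legend("bottomleft", rownames(m), col = cols, lwd = 2, bty = "n",
                   cex = 0.8)
  invisible(m)
}

#' Long/wide conversion of sensory tables
#'
#' `sensory_wide()` pivots to one row per panellist x material with one
#' column per attribute; `sensory_long()` inverts it. The round-trip is
#' lossless.
#'
#' @param t a [sensory_table()].
#' @return `sensory_wide`: data frame `panellist`, `material`, then the six
#'   attribute columns.
#' @export
sensory_wide <- function(t) {
  stopifnot(inherits(t, "sensory_table"))
  keys <- unique(t[c("panellist", "material")])
  keys <- keys[order(keys$panellist, keys$material), ]
  out <- keys
  for (a in sensory_attributes()) {
    ta <- t[t$attribute == a, ]
    idx <- match(paste(keys$panellist, keys$material),
                 paste(ta$panellist, ta$material))
    out[[a]] <- ta$rating[idx]
  }
  rownames(out) <- NULL
  out
}

#' @rdname sensory_wide
#' @param w a wide-format data frame as produced by `sensory_wide()`.
#' @export
sensory_long <- function(w) {
  attrs <- intersect(sensory_attributes(), names(w))
  rows <- lapply(attrs, function(a)
    data.frame(panellist = w$panellist, material = w$material, attribute = a,
               rating = w[[a]]))
  sensory_table(do.call(rbind, rows))
}
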