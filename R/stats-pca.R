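#' Principal component analysis with a variance-contribution table
#'
#' Eigendecomposition of the centered (covariance mode) or centered and
#' standardized (correlation mode) data. Covariance mode is the default:
#' applied to raw 1-10 ratings it yields eigenvalues on the rating-variance
#' scale of the published variance-contribution tables. Components are sign
#' -fixed so that each component's largest-magnitude loading is positive,
#' making the output deterministic.
#'
#' @param x numeric matrix or data frame, observations x variables.
#' @param mode `"covariance"` (center only) or `"correlation"` (center and
#'   scale to unit variance).
#' @return object of class `pca_model`: `eigenvalues` (descending),
#'   `variance_pct`, `cumulative_pct`, `loadings` (variables x components,
#'   orthonormal columns), `scores` (observations x components), `center`,
#'   `scale`, `mode`.
#' @export
run_pca <- function(x, mode = c("covariance", "correlation")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric", call. = FALSE)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need >= 2 observations and >= 2 variables", call. = FALSE)
  if (anyNA(x)) stop("missing cells are not allowed", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (mode == "correlation") {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0))
      stop("constant variable(s) in correlation mode: ",
           paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = (mode == "correlation"))
  ncomp <- length(pc$sdev)
  loadings <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  scores <- pc$x[, seq_len(ncomp), drop = FALSE]
  # sign convention: largest-magnitude loading positive per component
  for (j in seq_len(ncomp)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2
  model <- list(eigenvalues = ev,
                variance_pct = 100 * ev / sum(ev),
                cumulative_pct = cumsum(100 * ev / sum(ev)),
                loadings = loadings, scores = scores,
                center = pc$center,
                scale = if (mode == "correlation") pc$scale else NULL,
                mode = mode, n = nrow(x))
  class(model) <- "pca_model"
  model
}

#' @export
print.pca_model <- function(x, digits = 4, ...) {
  cat(sprintf("<pca_model> %s mode, %d observations, %d components\n",
              x$mode, x$n, length(x$eigenvalues)))
  tab <- variance_table(x)
  print(format(tab, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.pca_model <- function(object, ...) {
  cat("Variance contribution rates\n")
  print(format(variance_table(object), digits = 4), row.names = FALSE)
  cat("\nVariable loadings (first 3 components)\n")
  k <- min(3L, ncol(object$loadings))
  print(round(object$loadings[, seq_len(k), drop = FALSE], 4))
  invisible(object)
}

#' Variance-contribution table of a PCA model
#'
#' @param model a [run_pca()] result (or any list with `eigenvalues`,
#'   `variance_pct`, `cumulative_pct`).
#' @return data frame with `pc`, `eigenvalue`, `variance_pct`,
#'   `cumulative_pct`.
#' @export
variance_table <- function(model) {
  data.frame(pc = paste0("PC", seq_along(model$eigenvalues)),
             eigenvalue = model$eigenvalues,
             variance_pct = model$variance_pct,
             cumulative_pct = model$cumulative_pct)
}

#' 3-D biplot / score plot of a PCA model
#'
#' Plots the first two components with loading arrows and optional group
#' ellipses (2-D sections of the concentration ellipsoids).
#'
#' @param x a [run_pca()] result.
#' @param groups optional factor over observations; draws one 95%
#'   concentration ellipse per group.
#' @param ... passed to [graphics::plot()].
#' @return the model, invisibly.
#' @export
plot.pca_model <- function(x, groups = NULL, ...) {
  s <- x$scores[, 1:2, drop = FALSE]
  graphics::plot(s, xlab = sprintf("PC1 (%.1f%%)", x$variance_pct[1]),
                 ylab = sprintf("PC2 (%.1f%%)", x$variance_pct[2]),
                 pch = 19, col = if (is.null(groups)) "grey40"
                 else as.integer(factor(groups)), ...)
  sc <- 0.8 * max(abs(s)) / max(abs(x$loadings[, 1:2]))
  graphics::arrows(0, 0, sc * x$loadings[, 1], sc * x$loadings[, 2],
                   length = 0.08, col = "steelblue")
  graphics::text(1.07 * sc * x$loadings[, 1], 1.07 * sc * x$loadings[, 2],
                 rownames(x$loadings), col = "steelblue", cex = 0.8)
  if (!is.null(groups)) {
    for (g in unique(groups)) {
      pts <- s[groups == g, , drop = FALSE]
      if (nrow(pts) < 3L) next
      ell <- concentration_ellipsoid(pts, dims = 2L)
      if (ell$degenerate) next
      th <- seq(0, 2 * pi, length.out = 100)
      xy <- cbind(ell$radii[1] * cos(th), ell$radii[2] * sin(th)) %*% t(ell$axes)
      graphics::lines(xy[, 1] + ell$center[1], xy[, 2] + ell$center[2],
                      col = as.integer(factor(g, levels = unique(groups))))
    }
  }
  invisible(x)
}

#' Concentration ellipsoid of a score cloud
#'
#' The 95% data ellipsoid of one group's component scores: centered on the
#' group mean, axes from the eigendecomposition of the group score
#' covariance, radii scaled by the chi-square quantile at the level
#' (population-ellipse convention). The F-based confidence region for the
#' mean is available as an alternative scaling.
#'
#' @param scores numeric matrix, points x dims (dims columns are used).
#' @param level coverage probability.
#' @param dims number of leading dimensions.
#' @param scaling `"chisq"` (data ellipsoid, default) or `"f"` (confidence
#'   region for the group mean).
#' @return object of class `ellipsoid`: `center`, `axes` (orthonormal
#'   columns), `radii`, `level`, `n`, `degenerate`.
#' @export
concentration_ellipsoid <- function(scores, level = 0.95, dims = 3,
                                    scaling = c("chisq", "f")) {
  scaling <- match.arg(scaling)
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L) stop("need >= 2 points", call. = FALSE)
  dims <- min(dims, ncol(scores))
  s <- scores[, seq_len(dims), drop = FALSE]
  n <- nrow(s)
  center <- colMeans(s)
  degenerate <- n < dims + 1L
  cv <- stats::cov(s)
  eg <- eigen(cv, symmetric = TRUE)
  eg$values[eg$values < 0] <- 0
  if (all(eg$values == 0)) degenerate <- TRUE
  c2 <- switch(scaling,
               chisq = stats::qchisq(level, df = dims),
               f = dims * (n - 1) / (n * (n - dims)) *
                 stats::qf(level, dims, n - dims))
  structure(list(center = center, axes = eg$vectors,
                 radii = sqrt(pmax(eg$values, 0) * c2), level = level,
                 n = n, dims = dims, scaling = scaling,
                 degenerate = degenerate),
            class = "ellipsoid")
}

#' @export
print.ellipsoid <- function(x, ...) {
  cat(sprintf("<ellipsoid> %d-D, level %.2f, n=%d%s, radii: %s\n",
              x$dims, x$level, x$n,
              if (x$degenerate) " (degenerate)" else "",
              paste(sprintf("%.3g", x$radii), collapse = ", ")))
  invisible(x)
}

#' Point membership in a concentration ellipsoid
#'
#' @param ell an [concentration_ellipsoid()] result.
#' @param points numeric matrix, points x dims.
#' @return logical vector: point inside (or on) the ellipsoid.
#' @export
ellipsoid_contains <- function(ell, points) {
  points <- as.matrix(points)[, seq_len(ell$dims), drop = FALSE]
  d <- sweep(points, 2L, ell$center) %*% ell$axes
  r <- ifelse(ell$radii > 0, ell$radii, Inf)
  rowSums(sweep(d, 2L, r, "/")^2) <= 1
}

#' PCA of tribological features with supplementary sensory vectors
#'
#' Runs a PCA on the four tribology variables (mean static/dynamic COF and
#' static/dynamic AE RMS per material x participant cell) as active
#' variables; the sensory attribute means for the same cells are overlaid
#' as supplementary vectors — the correlation of each attribute with the
#' component scores — without influencing the decomposition. This is the
#' combined instrument-panel view relating measured friction and acoustic
#' emission to perceived attributes.
#'
#' @param tribology data frame with key columns (`material`, optionally
#'   `participant`) and the four feature columns `static_cof`,
#'   `dynamic_cof`, `static_rms`, `dynamic_rms`.
#' @param sensory_means data frame with the same key columns and one column
#'   per sensory attribute.
#' @param mode passed to [run_pca()]; correlation mode is the default here
#'   because the four active variables are on unrelated physical scales.
#' @return a `pca_model` with an extra `overlays` element (attributes x
#'   components correlation matrix).
#' @export
combined_pca <- function(tribology, sensory_means,
                         mode = c("correlation", "covariance")) {
  mode <- match.arg(mode)
  keys <- intersect(c("material", "participant"), names(tribology))
  if (!length(keys)) stop("tribology needs a 'material' key column", call. = FALSE)
  if (!all(keys %in% names(sensory_means)))
    stop("sensory_means lacks key column(s): ",
         paste(setdiff(keys, names(sensory_means)), collapse = ", "),
         call. = FALSE)
  kt <- do.call(paste, tribology[keys])
  ks <- do.call(paste, sensory_means[keys])
  if (anyDuplicated(kt) || anyDuplicated(ks))
    stop("keys must be unique per table", call. = FALSE)
  missing_keys <- union(setdiff(kt, ks), setdiff(ks, kt))
  if (length(missing_keys))
    stop("key mismatch between tables: ",
         paste(utils::head(missing_keys, 5L), collapse = "; "), call. = FALSE)
  sensory_means <- sensory_means[match(kt, ks), , drop = FALSE]

  active_vars <- c("static_cof", "dynamic_cof", "static_rms", "dynamic_rms")
  active_vars <- intersect(active_vars, names(tribology))
  if (length(active_vars) < 2L)
    stop("need at least two tribology feature columns", call. = FALSE)
  model <- run_pca(as.matrix(tribology[active_vars]), mode = mode)

  sup_vars <- setdiff(names(sensory_means), keys)
  overlays <- matrix(NA_real_, length(sup_vars), ncol(model$scores),
                     dimnames = list(sup_vars, colnames(model$scores)))
  for (v in sup_vars)
    for (j in seq_len(ncol(model$scores))) {
      sc <- model$scores[, j]
      overlays[v, j] <- if (stats::sd(sc) == 0 ||
                            stats::sd(sensory_means[[v]]) == 0) 0
        else stats::cor(sensory_means[[v]], sc)
    }
  model$overlays <- overlays
  model$supplementary <- as.matrix(sensory_means[sup_vars])
  model
}

#' Signed correlations between model variables
#'
#' Reports the signed correlation and a qualitative label (positive /
#' negative / near-zero at |r| < `near_zero`) for each requested pair of
#' variables: active variables, supplementary (overlay) variables, or one
#' of each. Used to read relationships such as an inverse association
#' between AE level and perceived pleasantness off a fitted model.
#'
#' @param model a [run_pca()] or [combined_pca()] result.
#' @param pairs character matrix or list of length-2 vectors of variable
#'   names; default: all pairs.
#' @param near_zero |r| threshold for the near-zero label.
#' @return data frame `var1`, `var2`, `r`, `label`.
#' @export
correlation_signs <- function(model, pairs = NULL, near_zero = 0.2) {
  stopifnot(inherits(model, "pca_model"))
  # reconstruct variable values in score space: active variables from the
  # loadings back-projection, supplementary variables as stored
  active <- model$scores %*% t(model$loadings)
  colnames(active) <- rownames(model$loadings)
  vals <- active
  if (!is.null(model$supplementary))
    vals <- cbind(vals, model$supplementary)
  vars <- colnames(vals)
  if (is.null(pairs)) {
    cmb <- utils::combn(vars, 2L)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  if (is.matrix(pairs))
    pairs <- lapply(seq_len(nrow(pairs)), function(i) pairs[i, ])
  rows <- lapply(pairs, function(p) {
    if (!all(p %in% vars))
      stop("unknown variable(s): ", paste(setdiff(p, vars), collapse = ", "),
           call. = FALSE)
    r <- stats::cor(vals[, p[1L]], vals[, p[2L]])
    data.frame(var1 = p[1L], var2 = p[2L], r = r,
               label = if (abs(r) < near_zero) "near-zero"
               else if (r > 0) "positive" else "negative")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
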