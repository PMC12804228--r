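test_that("run_pca matches a direct eigendecomposition of the covariance", {
  set.seed(2)
  x <- matrix(rnorm(200 * 5), 200, 5) %*% matrix(runif(25, -1, 1), 5, 5)
  colnames(x) <- paste0("v", 1:5)
  model <- run_pca(x, mode = "covariance")
  eg <- eigen(cov(x), symmetric = TRUE)
  expect_equal(model$eigenvalues, eg$values, tolerance = 1e-10)
  # loadings span the same axes (up to sign)
  for (j in 1:5)
    expect_equal(abs(sum(model$loadings[, j] * eg$vectors[, j])), 1,
                 tolerance = 1e-8)
  # sign convention: largest-magnitude loading positive
  for (j in 1:5)
    expect_gt(model$loadings[which.max(abs(model$loadings[, j])), j], 0)
})

test_that("PCA invariants hold: variance normalisation, orthonormality, reconstruction", {
  set.seed(3)
  x <- matrix(rnorm(60 * 4), 60, 4)
  for (mode in c("covariance", "correlation")) {
    m <- run_pca(x, mode = mode)
    expect_equal(sum(m$variance_pct), 100, tolerance = 1e-9)
    expect_equal(m$variance_pct,
                 100 * m$eigenvalues / sum(m$eigenvalues), tolerance = 1e-12)
    expect_equal(m$cumulative_pct[length(m$cumulative_pct)], 100,
                 tolerance = 1e-6)
    expect_true(all(diff(m$cumulative_pct) >= -1e-12))
    expect_equal(crossprod(m$loadings), diag(4), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # back-projection reproduces the centered (scaled) data
    xc <- scale(x, center = TRUE, scale = (mode == "correlation"))
    expect_equal(m$scores %*% t(m$loadings), xc, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # collinear data: all variance on PC1
  line <- cbind(1:50, 2 * (1:50), -0.5 * (1:50))
  ml <- run_pca(line, mode = "covariance")
  expect_equal(ml$variance_pct, c(100, 0, 0), tolerance = 1e-8)
  expect_error(run_pca(cbind(a = rep(1, 10), b = rnorm(10)),
                       mode = "correlation"), "constant")
})

test_that("the published sensory variance table satisfies the PCA invariants", {
  ref <- reference_pca_table()
  ev <- ref$variance$eigenvalue
  expect_equal(100 * ev / sum(ev), ref$variance$variance_pct,
               tolerance = 5e-4)
  expect_equal(cumsum(100 * ev / sum(ev)), ref$variance$cumulative_pct,
               tolerance = 5e-4)
  expect_equal(ref$variance$cumulative_pct[3], 82.01)  # first three components
  # printed loadings columns are orthonormal to printed precision
  g <- crossprod(ref$loadings)
  expect_equal(g, diag(3), tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("concentration ellipsoids recover known covariances", {
  # isotropic: radii ~ sqrt(chi-square quantile)
  set.seed(8)
  z <- matrix(rnorm(2000 * 3), 2000, 3)
  e <- concentration_ellipsoid(z, level = 0.95, dims = 3)
  expect_equal(e$radii, rep(sqrt(qchisq(0.95, 3)), 3), tolerance = 0.1)
  # degenerate cloud
  same <- matrix(1, 5, 3)
  ed <- concentration_ellipsoid(same, dims = 3)
  expect_true(ed$degenerate)
  expect_equal(ed$radii, rep(0, 3))
  expect_error(concentration_ellipsoid(matrix(1, 1, 3)), "2 points")
  # anisotropic recovery
  S <- diag(c(4, 1, 0.25))
  x <- z %*% chol(S)
  ea <- concentration_ellipsoid(x, dims = 3)
  expect_equal(sort(ea$radii),
               sort(sqrt(diag(S) * qchisq(0.95, 3))), tolerance = 0.1)
})

test_that("tukey_kramer agrees with the equal-n HSD and base TukeyHSD", {
  set.seed(4)
  y <- rnorm(60, rep(c(0, 1, 3), each = 20))
  g <- rep(c("a", "b", "c"), each = 20)
  tk <- tukey_kramer(y, g)
  # independent equal-n computation from the classical formula
  fit <- aov(y ~ factor(g))
  mse <- sum(residuals(fit)^2) / fit$df.residual
  means <- tapply(y, g, mean)
  q_ab <- abs(means["a"] - means["b"]) / sqrt(mse / 20)
  expect_equal(tk$q[tk$group_i == "a" & tk$group_j == "b"], unname(q_ab),
               tolerance = 1e-8)
  # p-values agree with stats::TukeyHSD
  hsd <- TukeyHSD(fit)$`factor(g)`
  expect_equal(sort(tk$p), sort(unname(hsd[, "p adj"])), tolerance = 1e-8)

  # identical groups: q = 0, p = 1
  t0 <- tukey_kramer(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(t0$q, 0)
  expect_equal(t0$p, 1)
  expect_false(t0$significant)

  expect_error(tukey_kramer(1:5, c("a", "a", "a", "a", "b")), ">= 2 values")
  expect_error(tukey_kramer(1:4, rep("a", 4)), "2 groups")
})

test_that("separated means are detected, equal means are not", {
  set.seed(10)
  sd0 <- 1
  y <- c(rnorm(30, 0, sd0), rnorm(30, 0, sd0), rnorm(30, 10 * sd0, sd0))
  g <- rep(c("a", "b", "c"), each = 30)
  tk <- tukey_kramer(y, g)
  sig <- tk$significant
  names(sig) <- paste(tk$group_i, tk$group_j)
  expect_false(sig[["a b"]])
  expect_true(sig[["a c"]])
  expect_true(sig[["b c"]])
  # permutation oracle for the a-c pair: observed |diff| far in the tail
  obs <- abs(mean(y[g == "a"]) - mean(y[g == "c"]))
  perm <- replicate(200, {
    sh <- sample(y[g %in% c("a", "c")])
    abs(mean(sh[1:30]) - mean(sh[31:60]))
  })
  expect_gt(obs, max(perm))
})

test_that("unequal group sizes use the Kramer standard error", {
  set.seed(12)
  y <- c(rnorm(10), rnorm(25, 1))
  g <- rep(c("a", "b"), c(10, 25))
  tk <- tukey_kramer(y, g)
  mse <- attr(tk, "mse")
  expect_equal(tk$se, sqrt((mse / 2) * (1 / 10 + 1 / 25)), tolerance = 1e-12)
})

test_that("combined PCA overlays supplementary sensory vectors faithfully", {
  set.seed(15)
  n <- 24
  trib <- data.frame(material = sprintf("m%02d", 1:n),
                     static_cof = runif(n, 0.3, 1.2),
                     dynamic_cof = runif(n, 0.2, 1.0),
                     static_rms = runif(n, 0.1, 0.6),
                     dynamic_rms = runif(n, 0.1, 0.6))
  sens <- data.frame(material = trib$material,
                     pleasant = -trib$dynamic_rms * 3 + rnorm(n, sd = 0.05),
                     rough = rnorm(n))
  model <- combined_pca(trib, sens)
  # supplementary vector of a variable equal to an active one aligns with it
  sens2 <- sens
  sens2$copycat <- trib$dynamic_cof
  m2 <- combined_pca(trib, sens2)
  active_dir <- m2$loadings["dynamic_cof", ]
  # correlation pattern of the copy points along the active variable's
  # loading direction (cosine ~ 1; not exact because the overlay is a
  # correlation, i.e. the loading row scaled per component by its sdev)
  ov <- m2$overlays["copycat", ]
  cosang <- sum(ov * active_dir) / sqrt(sum(ov^2) * sum(active_dir^2))
  expect_gt(abs(cosang), 0.9)
  # and equals the direct correlation with the scores, component by component
  expect_equal(unname(ov),
               unname(cor(trib$dynamic_cof, m2$scores)[1, ]),
               tolerance = 1e-10)
  # planted anti-correlation shows as a negative sign
  cs <- correlation_signs(model, pairs = list(c("dynamic_rms", "pleasant")))
  expect_equal(cs$label, "negative")
  expect_lt(cs$r, -0.9)
  # row order does not matter
  perm <- sample(n)
  m3 <- combined_pca(trib[perm, ], sens)
  expect_equal(abs(m3$loadings), abs(model$loadings), tolerance = 1e-8)
  # key mismatch is reported
  expect_error(combined_pca(trib, sens[-1, ]), "key mismatch")
})

test_that("correlation signs recover planted correlations", {
  set.seed(16)
  n <- 200
  a <- rnorm(n)
  b <- 0.8 * a + sqrt(1 - 0.64) * rnorm(n)
  x <- cbind(a = a, b = b, c = rnorm(n), d = -a)
  model <- run_pca(x, mode = "covariance")
  cs <- correlation_signs(model, pairs = list(c("a", "a"), c("a", "d"),
                                              c("a", "b")))
  expect_equal(cs$r[1], 1, tolerance = 1e-10)
  expect_equal(cs$r[2], -1, tolerance = 1e-10)
  expect_equal(cs$r[3], 0.8, tolerance = 0.1)
  expect_error(correlation_signs(model, pairs = list(c("a", "zz"))),
               "unknown variable")
})
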