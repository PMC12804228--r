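# shared fixtures: small materials and plans used across test files

fab <- function(mu_s = 0.6, mu_d = 0.4, band = 0.5, oob = 0.05,
                name = "fab") {
  material_spec(name, mu_s, mu_d, ae_band_level = band,
                ae_out_of_band_level = oob,
                sensory_profile = stats::setNames(c(5, 6, 4, 5, 3, 7),
                                                  sensory_attributes()))
}

quick_plan <- function(seed = 1, load = 2, duration = 4, n_strokes = 6,
                       ae_rate = 5e5) {
  trial_plan(target_load = load, duration = duration, n_strokes = n_strokes,
             ae_rate = ae_rate, seed = seed)
}

# independent sort-and-interpolate order-statistic oracle (linear
# interpolation between closest order statistics), written from the
# definition rather than via stats::quantile
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1L) return(x)
  h <- (n - 1) * (p / 100) + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# brute-force windowed RMS straight from the defining equation
oracle_rms <- function(x, w) {
  nw <- length(x) %/% w
  vapply(seq_len(nw), function(k) {
    seg <- x[((k - 1) * w + 1):(k * w)]
    sqrt(sum(seg^2) / w)
  }, numeric(1))
}
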