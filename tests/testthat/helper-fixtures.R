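# Shared fixtures, built in code at test time.

# Monotone toy curve with mild wiggles, covering the full analysis window.
toy_curve <- function(slope = 1, wiggle_amp = 20, wiggle_period = 500,
                      sigma = 15, span = c(0, 15000)) {
  make_toy_calcurve(span = span, slope = slope, wiggle_amp = wiggle_amp,
                    wiggle_period = wiggle_period, sigma = sigma)
}

# Small well-formed date table.
toy_dates <- function(n = 6) {
  c14_dates(lab_id = sprintf("L%03d", seq_len(n)),
            c14_age = seq(4000, by = 450, length.out = n),
            c14_error = rep(c(40, 60), length.out = n),
            site_id = rep(c("s1", "s2"), length.out = n),
            lat = -10, lon = -60, elevation = 100,
            country = "Brazil", admin1 = "Amazonas")
}

# Draw an observed SPD straight from a density over the window through the
# back-calibration engine (years ~ density; 14C via curve error model;
# errors from err_fn), one date per bin. Mirrors what the null simulator
# does, with a chosen generative density.
engine_spd <- function(density_fn, n_bins, curve, seed,
                       window = c(2000, 12000), step = 5,
                       err_fn = default_error_model) {
  prep <- paleodem:::sim_prep(curve, window, step)
  dens <- density_fn(prep$calbp)
  withr::with_seed(seed, {
    years <- sample(prep$calbp, n_bins, replace = TRUE, prob = dens)
    c14 <- uncalibrate_sample(years, curve)
    err <- err_fn(n_bins)
    v <- paleodem:::sum_dates_fast(c14, err, prep)
  })
  out <- paleodem:::spd_from_values(prep$calbp, v, n_bins = n_bins,
                                    normalised_input = TRUE)
  attr(out, "errors") <- err
  out
}

expect_same_spd <- function(a, b, tol = 1e-12) {
  expect_equal(a$calbp, b$calbp)
  expect_equal(a$value, b$value, tolerance = tol)
}

# Independent brute-force oracle: evaluate the calibration Gaussian on a
# fine sub-grid over the whole curve, aggregate to coarse cells by plain
# loops, normalise. Shares no code with calibrate().
brute_calibrate <- function(c14_age, c14_error, curve, step = 1, fine = 0.1) {
  nsub <- round(step / fine)
  offs <- seq(-step / 2 + fine / 2, step / 2 - fine / 2, length.out = nsub)
  calbp <- seq(ceiling(min(curve$calbp) / step) * step,
               floor(max(curve$calbp) / step) * step, by = step)
  mass <- numeric(length(calbp))
  for (i in seq_along(calbp)) {
    acc <- 0
    for (o in offs) {
      t <- calbp[i] + o
      if (t < min(curve$calbp) || t > max(curve$calbp)) next
      mu <- approx(curve$calbp, curve$mu, t)$y
      sg <- approx(curve$calbp, curve$sigma, t)$y
      acc <- acc + dnorm(c14_age, mu, sqrt(c14_error^2 + sg^2))
    }
    mass[i] <- acc / nsub
  }
  mass / sum(mass)
}

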