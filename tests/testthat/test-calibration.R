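test_that("an identity curve reproduces the Gaussian measurement error", {
  cv <- make_toy_calcurve(span = c(3000, 7000), slope = 1, sigma = 0)
  d <- calibrate(5000, 20, cv, normalise = TRUE, trim_tail = 0)
  expect_equal(d$calbp[which.max(d$mass)], 5000)
  m <- sum(d$calbp * d$mass)
  s <- sqrt(sum((d$calbp - m)^2 * d$mass))
  expect_equal(m, 5000, tolerance = 1e-6)
  expect_equal(s, 20, tolerance = 1e-3)
  # analytic change of variables: identical to the normalised Gaussian
  ref <- dnorm(d$calbp, 5000, 20)
  expect_equal(d$mass, ref / sum(ref), tolerance = 1e-9)
})

test_that("change of variables holds for any monotone noiseless curve", {
  cv <- make_toy_calcurve(span = c(2000, 12000), slope = 1.4, sigma = 0)
  d <- calibrate(9100, 35, cv, normalise = TRUE, trim_tail = 0)
  ref <- dnorm(d$calbp, 9100 / 1.4, 35 / 1.4)
  expect_equal(d$mass, ref / sum(ref), tolerance = 1e-9)
})

test_that("normalised densities sum to one; unnormalised keep global scaling", {
  cv <- toy_curve()
  for (err in c(25, 80, 160)) {
    dn <- calibrate(6000, err, cv, normalise = TRUE)
    expect_equal(sum(dn$mass), 1, tolerance = 1e-12)
    du <- calibrate(6000, err, cv, normalise = FALSE, trim_tail = 1e-5)
    expect_lt(sum(du$mass), 1)          # trimmed tail mass is simply absent
    expect_gt(sum(du$mass), 1 - 1e-3)
    full <- calibrate(6000, err, cv, normalise = FALSE, trim_tail = 0)
    expect_equal(sum(full$mass), 1, tolerance = 1e-12)
  }
})

test_that("calibration matches the fine-grid brute-force oracle on a plateau", {
  # curve with genuine reversals (a plateau), like real calibration wiggles
  cv <- make_toy_calcurve(span = c(4000, 8000), slope = 1, wiggle_amp = 120,
                          wiggle_period = 450, sigma = 10, monotone = FALSE)
  d <- calibrate(6005, 30, cv, step = 1, normalise = TRUE, trim_tail = 0,
                 fine = 0.1)
  ref <- brute_calibrate(6005, 30, cv, step = 1, fine = 0.1)
  grid <- seq(4000, 8000, by = 1)
  full <- numeric(length(grid))
  full[match(d$calbp, grid)] <- d$mass
  expect_lt(max(abs(full - ref)), 1e-10)
  # genuinely multimodal: several local maxima carrying real mass
  peaks <- which(diff(sign(diff(full))) == -2) + 1
  expect_gt(sum(full[peaks] > 0.2 * max(full)), 1)
})

test_that("density mode is stable under grid refinement 5 -> 1", {
  cv <- toy_curve()
  d5 <- calibrate(7300, 45, cv, step = 5, normalise = TRUE)
  d1 <- calibrate(7300, 45, cv, step = 1, normalise = TRUE)
  m5 <- d5$calbp[which.max(d5$mass)]
  m1 <- d1$calbp[which.max(d1$mass)]
  expect_lte(abs(m5 - m1), 2.5)  # within one coarse cell
})

test_that("dates outside the curve support raise a calibration error", {
  cv <- make_toy_calcurve(span = c(3000, 7000), slope = 1, sigma = 10)
  expect_error(calibrate(20000, 40, cv), "outside curve support")
})

test_that("reservoir correction shifts age and inflates error in quadrature", {
  marine <- toy_dates(2)
  marine$material <- "marine"
  same <- apply_reservoir(marine, 0, 0)
  expect_equal(same$c14_age, marine$c14_age)
  expect_equal(same$c14_error, marine$c14_error)

  one <- c14_dates("M1", 4000, 40, "s", material = "marine")
  adj <- apply_reservoir(one, 100, 30)
  expect_equal(adj$c14_age, 3900)
  expect_equal(adj$c14_error, 50)

  expect_error(apply_reservoir(toy_dates(1), 100, 30), "marine")
})

test_that("reservoir offset moves the calibrated mode by delta_r / slope", {
  slope <- 2
  cv <- make_toy_calcurve(span = c(1000, 9000), slope = slope, sigma = 5)
  one <- c14_dates("M1", 8000, 40, "s", material = "marine")
  adj <- apply_reservoir(one, 300, 0)
  mode_of <- function(age, err) {
    d <- calibrate(age, err, cv, normalise = TRUE)
    sum(d$calbp * d$mass)  # mean of a symmetric density = mode
  }
  shift <- mode_of(one$c14_age, one$c14_error) -
    mode_of(adj$c14_age, adj$c14_error)
  expect_equal(shift, 300 / slope, tolerance = 0.02)
})

test_that("nearest delta-R site lookup matches an exhaustive scan", {
  at_site <- data.frame(lat = c(-12, -33), lon = c(-77, -71.6),
                        delta_r = c(190, 220), delta_r_error = c(40, 55))
  class(at_site) <- c("delta_r_sites", "data.frame")
  expect_equal(nearest_delta_r(-33, -71.6, at_site)$delta_r, 220)

  tie <- data.frame(lat = c(0, 0), lon = c(-1, 1),
                    delta_r = c(10, 20), delta_r_error = c(50, 30))
  class(tie) <- c("delta_r_sites", "data.frame")
  expect_equal(nearest_delta_r(0, 0, tie)$delta_r, 20)  # smaller error wins

  set.seed(11)
  sites <- data.frame(lat = runif(20, -40, 5), lon = runif(20, -80, -40),
                      delta_r = round(runif(20, -100, 400)),
                      delta_r_error = round(runif(20, 20, 90)))
  class(sites) <- c("delta_r_sites", "data.frame")
  for (q in 1:10) {
    qlat <- runif(1, -40, 5); qlon <- runif(1, -80, -40)
    d <- geosphere::distHaversine(c(qlon, qlat), cbind(sites$lon, sites$lat))
    expect_equal(nearest_delta_r(qlat, qlon, sites)$delta_r,
                 sites$delta_r[which.min(d)])
  }
  empty <- sites[0, ]
  class(empty) <- c("delta_r_sites", "data.frame")
  expect_error(nearest_delta_r(0, -60, empty), "empty")
})

test_that("back-calibration sampling follows the curve error model", {
  noiseless <- make_toy_calcurve(span = c(1000, 9000), slope = 1.2, sigma = 0)
  expect_equal(uncalibrate_sample(c(4000, 6000), noiseless),
               c(4800, 7200))

  cv <- make_toy_calcurve(span = c(1000, 9000), slope = 1.2, sigma = 25)
  withr::with_seed(5, {
    draws <- uncalibrate_sample(rep(5000, 1e5), cv)
  })
  se <- 25 / sqrt(1e5)
  expect_lt(abs(mean(draws) - 5000 * 1.2), 3 * se)

  withr::with_seed(6, {
    a <- uncalibrate_sample(rep(5000, 1e5), cv)
    b <- uncalibrate_sample(rep(5100, 1e5), cv)
  })
  expect_equal(mean(b) - mean(a), 100 * 1.2, tolerance = 3 * sqrt(2) * se / 100)

  expect_error(uncalibrate_sample(99999, cv), "outside curve support")
})

test_that("calibrating the expected 14C age recovers the calendar year", {
  cv <- toy_curve(sigma = 10)
  for (year in c(4000, 7550, 11200)) {
    mu <- approx(cv$calbp, cv$mu, year)$y
    d <- calibrate(mu, 30, cv, normalise = TRUE)
    expect_lte(abs(d$calbp[which.max(d$mass)] - year), 2)
  }
})

test_that("marine dates are calibrated against the marine curve with delta-R", {
  terr <- make_toy_calcurve(span = c(1000, 9000), slope = 1, sigma = 8,
                            name = "terr")
  # marine curve offset by a 400-year reservoir
  mar <- cal_curve(terr$calbp, terr$mu + 400, terr$sigma, name = "mar")
  sites <- data.frame(lat = 0, lon = -60, delta_r = 100, delta_r_error = 0)
  class(sites) <- c("delta_r_sites", "data.frame")
  d <- c14_dates(c("T1", "M1"), c(5000, 5500), c(30, 30), "s",
                 lat = 0, lon = -60, material = c("terrestrial", "marine"))
  dens <- calibrate_dates(d, terr, mar, sites, normalise = TRUE)
  mode_t <- dens$T1$calbp[which.max(dens$T1$mass)]
  mode_m <- dens$M1$calbp[which.max(dens$M1$mass)]
  expect_equal(mode_t, 5000, tolerance = 2)
  # 5500 - deltaR 100 = 5400 on a curve offset by +400 -> 5000 cal BP
  expect_equal(mode_m, 5000, tolerance = 2)
})
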