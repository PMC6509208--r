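mk_spd <- function(calbp, value) paleodem:::spd_from_values(calbp, value)

test_that("growth-model fitting recovers exact generative parameters", {
  t <- seq(2000, 12000, by = 5)
  y <- 0.8 * exp(-2e-4 * t)
  m <- fit_growth_model(mk_spd(t, y), "exponential")
  expect_equal(unname(m$params["a"]), 0.8, tolerance = 1e-6)
  expect_equal(unname(m$params["b"]), -2e-4, tolerance = 1e-6)
  expect_equal(m$gof_r2, 1, tolerance = 1e-9)
  expect_equal(predict(m, c(5000, 9000)), 0.8 * exp(-2e-4 * c(5000, 9000)),
               tolerance = 1e-6)

  flat <- fit_growth_model(mk_spd(t, rep(3, length(t))), "linear")
  expect_equal(unname(flat$params["b"]), 0, tolerance = 1e-12)

  lg <- 2 / (1 + exp(0.002 * (t - 7000)))
  ml <- fit_growth_model(mk_spd(t, lg), "logistic")
  expect_equal(unname(ml$params["K"]), 2, tolerance = 1e-4)
  expect_equal(unname(ml$params["r"]), -0.002, tolerance = 1e-4)
  expect_equal(unname(ml$params["t0"]), 7000, tolerance = 1)
})

test_that("AIC prefers the generative family on noisy exponential data", {
  t <- seq(2000, 12000, by = 10)
  wins <- 0
  set.seed(9)
  for (r in 1:100) {
    y <- 1.5 * exp(-3e-4 * t) + rnorm(length(t), 0, 0.01)
    spd <- mk_spd(t, pmax(y, 0))
    me <- fit_growth_model(spd, "exponential")
    ml <- fit_growth_model(spd, "linear")
    if (me$ic < ml$ic) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("model_test finds no deviation when observed equals the null mean", {
  cv <- toy_curve()
  m <- fit_growth_model(mk_spd(seq(2000, 12000, 5),
                               0.5 * exp(-2e-4 * seq(2000, 12000, 5))),
                        "exponential")
  env <- simulate_null(m, n_bins = 200, error_pool = rep(c(40, 80), 50),
                       curve = cv, runs = 100, seed = 21)
  obs <- paleodem:::spd_from_values(env$calbp, env$mean)
  res <- model_test(obs, env)
  expect_equal(nrow(res$segments), 0)
  expect_gt(res$global_p, 0.9)
  # plus-one rule: p can never be zero and never below 1/(runs+1)
  expect_gte(res$global_p, 1 / 101)
})

test_that("the null envelope collapses onto a degenerate curve's density", {
  # noiseless curve + single-cell support: every run is the same density
  cv <- make_toy_calcurve(span = c(4000, 6000), slope = 1, sigma = 0)
  t <- seq(4000, 6000, 5)
  spike <- ifelse(t == 5000, 1, 0)
  m <- list(family = "linear", params = c(a = 0, b = 0))
  class(m) <- "growth_model"
  # degenerate density via a custom model: use a linear model fitted to the
  # spike is pointless; instead call the engine directly
  prep <- paleodem:::sim_prep(cv, c(4000, 6000), 5)
  withr::with_seed(1, {
    v1 <- paleodem:::sum_dates_fast(uncalibrate_sample(5000, cv), 30, prep)
    v2 <- paleodem:::sum_dates_fast(uncalibrate_sample(5000, cv), 30, prep)
  })
  expect_identical(v1, v2)
  expect_equal(sum(v1), 1, tolerance = 1e-9)
  expect_equal(prep$calbp[which.max(v1)], 5000)
})

test_that("simulate_null demands a seed and is byte-reproducible under one", {
  cv <- toy_curve()
  m <- fit_growth_model(mk_spd(seq(2000, 12000, 5),
                               rep(1, 2001)), "linear")
  expect_error(simulate_null(m, 50, c(40, 60), cv, runs = 5), "seed")
  e1 <- simulate_null(m, 50, c(40, 60), cv, runs = 20, seed = 33)
  e2 <- simulate_null(m, 50, c(40, 60), cv, runs = 20, seed = 33)
  expect_identical(e1, e2)
})

test_that("doubling runs moves the band by less than the Monte Carlo error", {
  cv <- toy_curve()
  m <- fit_growth_model(mk_spd(seq(2000, 12000, 5),
                               0.5 * exp(-2e-4 * seq(2000, 12000, 5))),
                        "exponential")
  e250 <- simulate_null(m, 150, c(40, 80, 120), cv, runs = 250, seed = 1)
  e500 <- simulate_null(m, 150, c(40, 80, 120), cv, runs = 500, seed = 2)
  # z-space bands sit near +-2; the 2.5% quantile SE at 250 runs is ~0.15z
  mid <- e250$calbp > 3000 & e250$calbp < 11000
  expect_lt(stats::median(abs(e250$lo[mid] - e500$lo[mid])), 0.35)
  expect_lt(stats::median(abs(e250$hi[mid] - e500$hi[mid])), 0.35)
})

test_that("an injected deep trough yields a below segment and a tiny p", {
  cv <- toy_curve()
  dens_fn <- function(t) 0.5 + 1e-4 * (12000 - t)
  obs <- engine_spd(function(t) dens_fn(t) *
                      ifelse(t <= 7500 & t > 7000, 0.1, 1),
                    n_bins = 800, curve = cv, seed = 41)
  m <- fit_growth_model(obs, "linear")
  env <- simulate_null(m, 800, attr(obs, "errors"), cv, runs = 200, seed = 42)
  res <- model_test(obs, env)
  below <- res$segments[res$segments$sign == "below", ]
  expect_gte(nrow(below), 1)
  covering <- below[below$start_calbp >= 7200 & below$end_calbp <= 7400, ]
  expect_gte(nrow(covering), 1)
  expect_lte(res$global_p, 0.01)
})

test_that("breakpoint sweep recovers a planted regime shift", {
  t <- seq(2000, 12000, 5)
  base <- 0.5 + 1e-4 * (12000 - t)
  y <- ifelse(t > 8600, base, base * 0.3)
  bp <- breakpoint_sweep(mk_spd(t, y), family = "linear")
  expect_equal(bp$calbp, 8600)
  expect_true(bp$distinct)
  # invariant to candidate order
  bp2 <- breakpoint_sweep(mk_spd(t, y),
                          candidates = seq(8000, 10000, by = 100),
                          family = "linear")
  expect_equal(bp2$calbp, 8600)

  # no change point: flat profile flagged as not distinct
  smooth <- mk_spd(t, base)
  expect_false(breakpoint_sweep(smooth, family = "linear")$distinct)

  expect_error(breakpoint_sweep(mk_spd(t, y),
                                candidates = c(2100, 2200)), "500 years")
  expect_error(breakpoint_sweep(mk_spd(t, y), candidates = 9000),
               "at least 2")
})

test_that("conditioned test fits on the pre-breakpoint window only", {
  cv <- toy_curve()
  obs <- engine_spd(crash_density(crashes = three_phase_crashes()),
                    n_bins = 600, curve = cv, seed = 51)
  res <- conditioned_test(obs, 600, attr(obs, "errors"), cv,
                          breakpoint = 8600, runs = 100, seed = 52)
  expect_equal(res$model$fit_window, c(8600, 12000))
  expect_true(all(res$post_segments$end_calbp <= 8600))
  expect_gte(res$global_p, 1 / 101)
  expect_error(conditioned_test(obs, 600, attr(obs, "errors"), cv,
                                breakpoint = 500, runs = 10, seed = 1),
               "window")
})
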