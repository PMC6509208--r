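# Synthetic-data generators. Everything here is a pure function of its
# parameters and seed, so every pipeline stage can be exercised against a
# known ground truth without any external download.

#' Toy calibration curve with controllable wiggles
#'
#' Builds a synthetic calibration curve `mu(t) = slope * t + wiggle_amp *
#' sin(2 * pi * t / wiggle_period)` with constant curve error. With
#' `monotone = TRUE` (the default) the parameter combination must satisfy
#' `slope > 2 * pi * wiggle_amp / wiggle_period`, which guarantees a
#' strictly increasing mean and hence an invertible curve.
#'
#' @param span `(min, max)` cal BP.
#' @param slope 14C years per calendar year (default 1).
#' @param wiggle_amp,wiggle_period sine wiggle amplitude (years) and period
#'   (years).
#' @param sigma constant 1-sigma curve error, years.
#' @param knot_step knot spacing, years (default 5).
#' @param monotone enforce the monotonicity constraint.
#' @param name curve name.
#' @return a [cal_curve].
#' @export
make_toy_calcurve <- function(span = c(0, 15000), slope = 1.0,
                              wiggle_amp = 0, wiggle_period = 500,
                              sigma = 20, knot_step = 5, monotone = TRUE,
                              name = "toy") {
  stopifnot(length(span) == 2, span[2] > span[1], sigma >= 0, knot_step > 0)
  if (monotone && wiggle_amp > 0 &&
      slope <= 2 * pi * wiggle_amp / wiggle_period) {
    stop("non-monotone parameter combination: need slope > 2*pi*amp/period (",
         signif(2 * pi * wiggle_amp / wiggle_period, 4), ")")
  }
  t <- seq(span[1], span[2], by = knot_step)
  mu <- slope * t + wiggle_amp * sin(2 * pi * t / wiggle_period)
  cal_curve(t, mu, rep(sigma, length(t)), name = name)
}

#' Demographic scenario for the date simulator
#'
#' Bundles everything the radiocarbon date simulator needs: a relative
#' population density over calendar time, sample sizes, site structure,
#' region proportions, the measurement-error model and the marine fraction.
#'
#' @param name scenario label.
#' @param density_fn function of cal BP returning relative population
#'   (>= 0).
#' @param n_dates number of determinations to draw.
#' @param n_sites number of sites; dates are allocated to sites with a
#'   Zipf(1.2) size bias so some sites are heavily over-dated, exercising
#'   the 200-year binning.
#' @param region_mix named proportions over
#'   `c(highlands, lowlands, southern_cone)`; must sum to 1.
#' @param error_model function(n) returning n 1-sigma errors; default
#'   log-normal with median 60 years, truncated at 200 years to respect the
#'   error filter.
#' @param material_mix probability that a date is marine (default 0).
#' @param window `(min, max)` cal BP sampling support.
#' @return object of class `demographic_scenario`.
#' @export
demographic_scenario <- function(name, density_fn, n_dates, n_sites,
                                 region_mix = c(highlands = 0.35,
                                                lowlands = 0.4,
                                                southern_cone = 0.25),
                                 error_model = default_error_model,
                                 material_mix = 0,
                                 window = c(2000, 12000)) {
  stopifnot(is.function(density_fn), n_dates >= 0, n_sites >= 1,
            abs(sum(region_mix) - 1) < 1e-9,
            material_mix >= 0, material_mix <= 1)
  structure(list(name = name, density_fn = density_fn, n_dates = n_dates,
                 n_sites = n_sites, region_mix = region_mix,
                 error_model = error_model, material_mix = material_mix,
                 window = window),
            class = "demographic_scenario")
}

#' Default empirical-style measurement-error model
#'
#' Log-normal 1-sigma errors with median 60 years (log-scale SD 0.45),
#' truncated at 200 years by resampling, mimicking the error structure of
#' large archaeological compilations while respecting the >200-year filter.
#'
#' @param n number of errors to draw.
#' @return numeric vector of errors (years).
#' @export
default_error_model <- function(n) {
  out <- numeric(0)
  while (length(out) < n) {
    e <- stats::rlnorm(n, meanlog = log(60), sdlog = 0.45)
    out <- c(out, e[e <= 200])
  }
  round(pmax(out[seq_len(n)], 15))
}

# Region-consistent site metadata templates, so assign_region() reproduces
# the scenario's labels.
.region_templates <- list(
  highlands = list(country = "Peru", admin1 = "Cusco",
                   lat = c(-14, -6), lon = c(-73, -70), elev = c(2500, 4000)),
  lowlands = list(country = "Brazil", admin1 = "Amazonas",
                  lat = c(-8, 0), lon = c(-65, -55), elev = c(30, 250)),
  southern_cone = list(country = "Argentina", admin1 = "Neuquén",
                       lat = c(-42, -30), lon = c(-70, -62), elev = c(100, 280))
)

#' Simulate an archaeological radiocarbon date table
#'
#' Draws calendar years in proportion to the scenario's population density,
#' back-calibrates each through the calibration curve's error model
#' ([uncalibrate_sample()]), attaches measurement errors from the error
#' model, allocates dates to sites with a Zipf(1.2) size bias, and fills
#' region-consistent metadata. Fully reproducible under `seed`.
#'
#' @param scenario a [demographic_scenario].
#' @param curve terrestrial [cal_curve].
#' @param marine_curve marine [cal_curve] (required if `material_mix > 0`).
#' @param seed mandatory RNG seed.
#' @return a `c14_dates` data frame with attribute `true_cal_years` (the
#'   ground-truth calendar years, cal BP).
#' @export
simulate_dates <- function(scenario, curve, marine_curve = NULL, seed) {
  if (missing(seed) || is.null(seed)) stop("simulate_dates: a seed is required")
  if (scenario$material_mix > 0 && is.null(marine_curve)) {
    stop("material_mix > 0 requires a marine curve")
  }
  n <- scenario$n_dates
  if (n == 0) {
    out <- c14_dates(character(0), numeric(0), numeric(0), character(0))
    attr(out, "true_cal_years") <- numeric(0)
    return(out)
  }
  grid <- seq(min(scenario$window), max(scenario$window), by = 1)
  dens <- scenario$density_fn(grid)
  if (any(dens < 0) || all(dens == 0)) {
    stop("scenario density must be >= 0 and not identically zero")
  }
  withr::with_seed(seed, {
    years <- sample(grid, n, replace = TRUE, prob = dens)
    material <- ifelse(stats::runif(n) < scenario$material_mix,
                       "marine", "terrestrial")
    c14 <- numeric(n)
    terr <- material == "terrestrial"
    if (any(terr)) c14[terr] <- uncalibrate_sample(years[terr], curve)
    if (any(!terr)) c14[!terr] <- uncalibrate_sample(years[!terr], marine_curve)
    err <- scenario$error_model(n)
    # Zipf(1.2) site-size bias
    site_w <- (seq_len(scenario$n_sites))^-1.2
    site_i <- sample.int(scenario$n_sites, n, replace = TRUE, prob = site_w)
    # sites get regions per region_mix
    site_region <- sample(names(scenario$region_mix), scenario$n_sites,
                          replace = TRUE, prob = scenario$region_mix)
    site_meta <- lapply(seq_len(scenario$n_sites), function(s) {
      tpl <- .region_templates[[site_region[s]]]
      list(lat = stats::runif(1, tpl$lat[1], tpl$lat[2]),
           lon = stats::runif(1, tpl$lon[1], tpl$lon[2]),
           elev = round(stats::runif(1, tpl$elev[1], tpl$elev[2])),
           country = tpl$country, admin1 = tpl$admin1)
    })
    meta <- function(field) {
      vapply(site_i, function(s) site_meta[[s]][[field]],
             if (field %in% c("country", "admin1")) character(1) else numeric(1))
    }
    out <- c14_dates(
      lab_id = sprintf("%s-%05d", toupper(substr(scenario$name, 1, 3)),
                       seq_len(n)),
      c14_age = round(c14), c14_error = err,
      site_id = sprintf("site%04d", site_i),
      lat = meta("lat"), lon = meta("lon"), elevation = meta("elev"),
      country = meta("country"), admin1 = meta("admin1"),
      material = material, region = site_region[site_i])
  })
  attr(out, "true_cal_years") <- years
  out
}

#' Piecewise demographic density: linear growth with planted crashes
#'
#' Builds a density function for [demographic_scenario()]: linear relative
#' population growth toward the present, optionally multiplied by a crash
#' factor inside given intervals. Suitable for planting step drops (e.g. a
#' 70% crash after 8600 cal BP) or multi-phase crash/recovery structures.
#'
#' @param base_at_start relative population at the old end of the window.
#' @param growth linear increase per calendar year toward the present.
#' @param crashes data frame with columns `from`, `to` (cal BP, `from` >
#'   `to`) and `level` (multiplier in (0, 1]); outside all intervals the
#'   base trend applies.
#' @param window `(min, max)` cal BP support.
#' @return function of cal BP.
#' @export
crash_density <- function(base_at_start = 1, growth = 2e-4, crashes = NULL,
                          window = c(2000, 12000)) {
  force(base_at_start); force(growth); force(crashes); force(window)
  function(t) {
    v <- base_at_start + growth * (max(window) - t)
    v[t < min(window) | t > max(window)] <- 0
    if (!is.null(crashes)) {
      for (i in seq_len(nrow(crashes))) {
        inside <- t <= crashes$from[i] & t > crashes$to[i]
        v[inside] <- v[inside] * crashes$level[i]
      }
    }
    pmax(v, 0)
  }
}

#' Three-phase mid-Holocene crash scenario
#'
#' The package's reference synthetic scenario: quasi-stable weakly linear
#' growth through the early Holocene, then three phases of deep population
#' decline beginning at 8.6, 7.7 and 6.9 k cal BP, separated by 200-year
#' recoveries, with full recovery after 6.2 k cal BP.
#'
#' @param level crash-phase population as a fraction of the base trend
#'   (default 0.3).
#' @param window `(min, max)` cal BP.
#' @return data frame of crash intervals, usable with [crash_density()].
#' @export
three_phase_crashes <- function(level = 0.3, window = c(2000, 12000)) {
  data.frame(from = c(8600, 7700, 6900),
             to = c(7900, 7100, 6200),
             level = level)
}

#' Simulate a palaeoclimate proxy record with planted anomalies
#'
#' Generates a regularly sampled proxy series: optional smooth trend plus
#' Gaussian noise plus spikes of given amplitude at given ages (snapped to
#' the nearest sample age). The ground-truth anomaly ages are retained for
#' detector scoring.
#'
#' @param record_id,source_id identifiers.
#' @param resolution sampling interval, years (> 0).
#' @param span `(min, max)` cal BP.
#' @param noise_sd Gaussian noise SD (proxy units).
#' @param anomalies data frame with columns `age` (cal BP, inside `span`)
#'   and `amplitude` (proxy units, sign preserved); or `NULL`.
#' @param trend_fn optional function of age giving the smooth trend.
#' @param seed mandatory RNG seed.
#' @return a [climate_record] with attribute `true_anomaly_ages` (snapped
#'   ages of the planted spikes).
#' @export
simulate_climate_record <- function(record_id, source_id = "s1", resolution,
                                    span = c(2000, 12000), noise_sd = 1,
                                    anomalies = NULL, trend_fn = NULL, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("simulate_climate_record: a seed is required")
  }
  stopifnot(resolution > 0)
  ages <- seq(min(span), max(span), by = resolution)
  trend <- if (is.null(trend_fn)) numeric(length(ages)) else trend_fn(ages)
  withr::with_seed(seed, {
    values <- trend + stats::rnorm(length(ages), 0, noise_sd)
  })
  true_ages <- numeric(0)
  if (!is.null(anomalies) && nrow(anomalies)) {
    if (any(anomalies$age < min(span) | anomalies$age > max(span))) {
      stop("anomaly age outside record span")
    }
    idx <- vapply(anomalies$age, function(a) which.min(abs(ages - a)),
                  integer(1))
    values[idx] <- values[idx] + anomalies$amplitude
    true_ages <- ages[idx]
  }
  rec <- climate_record(record_id, source_id, ages, values)
  attr(rec, "true_anomaly_ages") <- true_ages
  rec
}
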