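#' Construct a calibration curve
#'
#' A calibration curve maps calendar age (cal BP) to the expected
#' radiocarbon age and its 1-sigma curve error. Values between knots are
#' linearly interpolated.
#'
#' @param calbp calendar ages of the knots (strictly monotone after sorting).
#' @param mu expected 14C age (14C BP) at each knot.
#' @param sigma 1-sigma curve error (years) at each knot, all > 0.
#' @param name curve name.
#' @return object of class `cal_curve`.
#' @export
cal_curve <- function(calbp, mu, sigma, name = "curve") {
  if (length(calbp) != length(mu) || length(calbp) != length(sigma)) {
    stop("calbp, mu and sigma must have equal length")
  }
  o <- order(calbp)
  calbp <- as.numeric(calbp[o]); mu <- as.numeric(mu[o])
  sigma <- as.numeric(sigma[o])
  if (any(diff(calbp) <= 0)) stop("cal BP grid is not strictly monotone")
  if (any(sigma < 0)) stop("curve sigma must be >= 0")
  structure(list(name = name, calbp = calbp, mu = mu, sigma = sigma),
            class = "cal_curve")
}

#' @export
print.cal_curve <- function(x, ...) {
  cat("Calibration curve '", x$name, "': ", length(x$calbp), " knots, ",
      sprintf("%.0f-%.0f cal BP\n", min(x$calbp), max(x$calbp)), sep = "")
  invisible(x)
}

# Interpolate curve mean and error at arbitrary calendar ages.
curve_at <- function(curve, calbp) {
  list(mu = stats::approx(curve$calbp, curve$mu, xout = calbp, rule = 1)$y,
       sigma = stats::approx(curve$calbp, curve$sigma, xout = calbp, rule = 1)$y)
}

# Curve resampled on a regular calendar grid over a window; the workhorse
# representation for calibration and simulation. Clips the window to the
# curve support.
curve_grid <- function(curve, window, step = 1) {
  lo <- max(min(window), min(curve$calbp))
  hi <- min(max(window), max(curve$calbp))
  if (lo >= hi) stop("window does not intersect curve support")
  calbp <- seq(ceiling(lo / step) * step, floor(hi / step) * step, by = step)
  g <- curve_at(curve, calbp)
  list(calbp = calbp, mu = g$mu, sigma = g$sigma, step = step)
}

#' Calibrate a radiocarbon determination
#'
#' Converts a 14C age and its 1-sigma error into a probability mass over
#' calendar years. For each grid year `t` the Gaussian density
#' `phi(c14_age; mu(t), sqrt(c14_error^2 + sigma(t)^2))` is evaluated, with
#' `mu` and `sigma` linearly interpolated from the curve. The density vector
#' is scaled by its total over the full curve support (computed before any
#' trimming); with `normalise = TRUE` the trimmed vector is rescaled to sum
#' exactly 1, otherwise it keeps the global scaling (so the trimmed tail
#' mass is simply absent).
#'
#' @param c14_age uncalibrated age, 14C BP.
#' @param c14_error 1-sigma measurement error, years (> 0).
#' @param curve a [cal_curve].
#' @param step calendar grid step, years (1 or 5 are the intended values).
#' @param normalise rescale the trimmed density to sum 1.
#' @param trim_tail drop leading/trailing cells whose density is below this
#'   fraction of the peak; 0 disables trimming.
#' @param fine sub-cell quadrature step in years. The default (`fine =
#'   step`) evaluates the density at the cell centre; smaller values average
#'   the density over a regular sub-grid inside each cell (e.g. `fine = 0.1`
#'   for 0.1-year quadrature).
#' @param lab_id optional identifier carried on the result.
#' @return object of class `cal_density`: list with `calbp` (trimmed grid),
#'   `mass`, `normalised`, `step`, `lab_id`.
#' @export
calibrate <- function(c14_age, c14_error, curve, step = 1, normalise = FALSE,
                      trim_tail = 1e-5, fine = step, lab_id = NULL) {
  stopifnot(length(c14_age) == 1, c14_error > 0, fine <= step)
  rng <- range(curve$mu)
  slack <- 5 * sqrt(c14_error^2 + max(curve$sigma)^2)
  if (c14_age < rng[1] - slack || c14_age > rng[2] + slack) {
    stop("14C age ", c14_age, " outside curve support [",
         rng[1], ", ", rng[2], "] (with 5-sigma slack)")
  }
  g <- curve_grid(curve, range(curve$calbp), step = step)
  # 8-sigma support window: density outside is < 1e-14 of the peak, so the
  # windowed total equals the full-support total to floating-point accuracy.
  smax <- sqrt(c14_error^2 + max(g$sigma)^2)
  hit <- which(abs(g$mu - c14_age) <= 8 * smax)
  if (!length(hit)) stop("14C age outside curve support")
  keep <- seq(min(hit), max(hit))  # contiguous span keeps the grid regular
  calbp <- g$calbp[keep]
  if (fine < step) {
    nsub <- round(step / fine)
    offs <- seq(-step / 2 + fine / 2, step / 2 - fine / 2, length.out = nsub)
    sub <- rep(calbp, each = nsub) + rep(offs, times = length(calbp))
    cg <- curve_at(curve, sub)
    ok <- !is.na(cg$mu)
    d <- numeric(length(sub))
    d[ok] <- stats::dnorm(c14_age, cg$mu[ok],
                          sqrt(c14_error^2 + cg$sigma[ok]^2))
    dens <- colMeans(matrix(d, nrow = nsub))
  } else {
    dens <- stats::dnorm(c14_age, g$mu[keep],
                         sqrt(c14_error^2 + g$sigma[keep]^2))
  }
  total <- sum(dens)
  if (total <= 0) stop("degenerate calibrated density (total mass 0)")
  mass <- dens / total
  if (trim_tail > 0) {
    big <- which(dens >= trim_tail * max(dens))
    idx <- min(big):max(big)
    calbp <- calbp[idx]
    mass <- mass[idx]
  }
  if (normalise) mass <- mass / sum(mass)
  structure(list(calbp = calbp, mass = mass, normalised = normalise,
                 step = step, lab_id = lab_id),
            class = "cal_density")
}

#' @export
print.cal_density <- function(x, ...) {
  mode_at <- x$calbp[which.max(x$mass)]
  cat("Calibrated density", if (!is.null(x$lab_id)) paste0("[", x$lab_id, "]"),
      sprintf("- %d cells (step %g), mode %g cal BP, mass %.6f\n",
              length(x$calbp), x$step, mode_at, sum(x$mass)))
  invisible(x)
}

#' Calibrate a table of radiocarbon dates
#'
#' Batch driver over [calibrate()]. Marine dates are reservoir-corrected
#' with the nearest Delta-R site (when `delta_r_sites` is given) and
#' calibrated against `marine_curve`; terrestrial dates use `curve`.
#'
#' @param dates a `c14_dates` data frame.
#' @param curve terrestrial [cal_curve].
#' @param marine_curve marine [cal_curve]; required if any date is marine.
#' @param delta_r_sites optional `delta_r_sites` table for local reservoir
#'   offsets.
#' @param ... passed to [calibrate()] (`step`, `normalise`, `trim_tail`, ...).
#' @return named list of `cal_density`, keyed by `lab_id`.
#' @export
calibrate_dates <- function(dates, curve, marine_curve = NULL,
                            delta_r_sites = NULL, ...) {
  if (any(dates$material == "marine") && is.null(marine_curve)) {
    stop("marine dates present but no marine curve supplied")
  }
  out <- vector("list", nrow(dates))
  for (i in seq_len(nrow(dates))) {
    age <- dates$c14_age[i]; err <- dates$c14_error[i]
    cv <- curve
    if (dates$material[i] == "marine") {
      cv <- marine_curve
      if (!is.null(delta_r_sites)) {
        dr <- nearest_delta_r(dates$lat[i], dates$lon[i], delta_r_sites)
        age <- age - dr$delta_r
        err <- sqrt(err^2 + dr$delta_r_error^2)
      }
    }
    out[[i]] <- calibrate(age, err, cv, lab_id = dates$lab_id[i], ...)
  }
  names(out) <- dates$lab_id
  out
}

#' Apply a marine reservoir offset (Delta-R) to marine dates
#'
#' Subtracts the local Delta-R from the 14C age and inflates the error in
#' quadrature, in preparation for calibration against the marine curve.
#'
#' @param dates a `c14_dates` data frame, all rows marine.
#' @param delta_r local reservoir offset, years.
#' @param delta_r_error 1-sigma error of the offset, years (>= 0).
#' @return the adjusted `c14_dates`.
#' @export
apply_reservoir <- function(dates, delta_r, delta_r_error) {
  if (any(dates$material != "marine")) {
    stop("apply_reservoir: all dates must be marine")
  }
  stopifnot(all(delta_r_error >= 0))
  dates$c14_age <- dates$c14_age - delta_r
  dates$c14_error <- sqrt(dates$c14_error^2 + delta_r_error^2)
  dates
}

#' Nearest Delta-R sampling site by great-circle distance
#'
#' @param lat,lon query coordinates, decimal degrees (WGS84).
#' @param sites a `delta_r_sites` data frame (see [read_delta_r()]).
#' @return list with `delta_r` and `delta_r_error` of the site minimising
#'   great-circle distance; ties broken by smaller error, then input order.
#' @export
nearest_delta_r <- function(lat, lon, sites) {
  if (is.null(sites) || nrow(sites) == 0) stop("empty delta-R site table")
  d <- geosphere::distHaversine(c(lon, lat), cbind(sites$lon, sites$lat))
  best <- order(d, sites$delta_r_error)[1]
  list(delta_r = sites$delta_r[best], delta_r_error = sites$delta_r_error[best])
}

#' Back-calibrate: sample 14C ages for given calendar years
#'
#' Draws one 14C age per calendar year from the curve's Gaussian error
#' model, `Normal(mu(t), sigma(t))` with linear interpolation. Uses the
#' current RNG stream; callers own seeding.
#'
#' @param cal_year calendar year(s), cal BP, inside the curve support.
#' @param curve a [cal_curve].
#' @return numeric vector of sampled 14C ages, one per input year.
#' @export
uncalibrate_sample <- function(cal_year, curve) {
  g <- curve_at(curve, cal_year)
  if (anyNA(g$mu)) stop("calendar year outside curve support")
  stats::rnorm(length(cal_year), g$mu, g$sigma)
}

# ---- fast simulation engine -------------------------------------------------
#
# Sums Gaussian calibrated densities of many dates on a shared regular grid
# in one vectorised pass. Requires the interpolated curve mean to be
# monotone in calendar age over the window (true for the real curves over
# the study interval and enforced for toy curves), which lets each date's
# 8-sigma support be located with findInterval rather than a full scan.
# Each date's density is scaled by its own windowed total, so every date
# contributes unit mass; grids are untrimmed.

sim_prep <- function(curve, window, step) {
  g <- curve_grid(curve, window, step)
  if (is.unsorted(g$mu) && is.unsorted(rev(g$mu))) {
    stop("simulation engine requires a monotone curve over the window")
  }
  if (g$mu[1] > g$mu[length(g$mu)]) {
    g$flip <- TRUE
  } else {
    g$flip <- FALSE
  }
  g$smax <- max(g$sigma)
  g
}

# Summed density of dates (c14, err) on the prepared grid. Returns the SPD
# vector (length(prep$calbp)); each date contributes total mass 1 (dates
# whose support falls outside the window contribute what overlaps it).
sum_dates_fast <- function(c14, err, prep) {
  n <- length(c14)
  mu <- prep$mu
  if (prep$flip) mu <- rev(mu)
  s7 <- 7 * sqrt(err^2 + prep$smax^2)   # tail below 1e-11 of the peak
  a <- findInterval(c14 - s7, mu) + 1L
  b <- findInterval(c14 + s7, mu)
  a <- pmax(a, 1L); b <- pmin(b, length(mu))
  len <- pmax(b - a + 1L, 0L)
  use <- which(len > 0L)
  if (!length(use)) return(numeric(length(prep$calbp)))
  idx <- sequence(len[use], from = a[use])
  did <- rep(use, len[use])
  if (prep$flip) idx <- length(mu) - idx + 1L
  st <- sqrt(err[did]^2 + prep$sigma[idx]^2)
  z <- (c14[did] - prep$mu[idx]) / st
  dens <- exp(-0.5 * z * z) / st
  # per-date totals: entries of one date are contiguous, so block sums
  # come from one cumulative sum
  ends <- cumsum(len[use])
  cs <- cumsum(dens)
  tot_map <- numeric(n)
  tot_map[use] <- cs[ends] - c(0, cs[ends[-length(ends)]])
  good <- tot_map[did] > 0
  w <- dens[good] / tot_map[did[good]]
  acc <- rowsum(w, idx[good], reorder = FALSE)
  out <- numeric(length(prep$calbp))
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}
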