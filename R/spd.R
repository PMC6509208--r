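#' Aggregate same-site dates into bins
#'
#' Intensively dated sites would otherwise dominate a summed probability
#' distribution, so same-site dates whose uncalibrated ages fall within `h`
#' years of each other are grouped into one bin; downstream, each bin
#' contributes one date-equivalent of mass. Two grouping rules are offered:
#' complete-linkage agglomerative clustering of the 14C ages cut at height
#' `h` (default), or fixed-width intervals of `h` years.
#'
#' @param dates a `c14_dates` data frame.
#' @param h bin sensitivity, uncalibrated years (default 200).
#' @param method `"cluster"` (complete linkage, cut at `h`) or `"fixed"`
#'   (intervals `[k*h, (k+1)*h)`).
#' @return data frame with columns `lab_id`, `site_id`, `bin_id`; dates at
#'   different sites never share a bin.
#' @export
bin_dates <- function(dates, h = 200, method = c("cluster", "fixed")) {
  stopifnot(h > 0)
  method <- match.arg(method)
  bin <- character(nrow(dates))
  for (s in unique(dates$site_id)) {
    i <- which(dates$site_id == s)
    ages <- dates$c14_age[i]
    if (method == "fixed") {
      cl <- as.integer(factor(floor(ages / h)))
    } else if (length(i) == 1L) {
      cl <- 1L
    } else {
      hc <- stats::hclust(stats::dist(ages), method = "complete")
      cl <- stats::cutree(hc, h = h)
    }
    bin[i] <- paste(s, cl, sep = "_")
  }
  data.frame(lab_id = dates$lab_id, site_id = dates$site_id, bin_id = bin,
             stringsAsFactors = FALSE)
}

#' Sum calibrated densities into an SPD
#'
#' Within each bin, member densities are averaged cell-wise so every bin
#' contributes one date-equivalent of probability mass; bin curves are then
#' summed on a regular calendar grid restricted to `window`.
#'
#' @param densities named list of `cal_density` (keys = lab_id), all on the
#'   same grid step.
#' @param bins bin table from [bin_dates()]; if `NULL`, every date is its
#'   own bin.
#' @param window `(min, max)` cal BP analysis window.
#' @return object of class `spd`: list with `calbp`, `value`, `n_dates`,
#'   `n_bins`, `normalised_input`, `window`, `step`.
#' @export
sum_probabilities <- function(densities, bins = NULL, window = c(2000, 12000)) {
  if (!length(densities)) stop("no densities supplied")
  steps <- unique(vapply(densities, `[[`, numeric(1), "step"))
  if (length(steps) != 1) stop("densities have mismatched grid steps")
  step <- steps
  if (is.null(bins)) {
    bins <- data.frame(lab_id = names(densities),
                       bin_id = names(densities), stringsAsFactors = FALSE)
  }
  missing_d <- setdiff(bins$lab_id, names(densities))
  if (length(missing_d)) {
    stop("no calibrated density for: ", paste(utils::head(missing_d, 5), collapse = ", "))
  }
  grid <- seq(ceiling(min(window) / step) * step,
              floor(max(window) / step) * step, by = step)
  value <- numeric(length(grid))
  size <- table(bins$bin_id)
  # canonical accumulation order: the sum is exactly invariant to input order
  for (k in order(bins$bin_id, bins$lab_id)) {
    d <- densities[[bins$lab_id[k]]]
    w <- 1 / size[[bins$bin_id[k]]]
    pos <- round((d$calbp - grid[1]) / step) + 1
    ok <- pos >= 1 & pos <= length(grid)
    if (any(ok)) value[pos[ok]] <- value[pos[ok]] + d$mass[ok] * w
  }
  norm_in <- all(vapply(densities[bins$lab_id], `[[`, logical(1), "normalised"))
  structure(list(calbp = grid, value = value,
                 n_dates = length(unique(bins$lab_id)),
                 n_bins = length(unique(bins$bin_id)),
                 normalised_input = norm_in,
                 window = c(min(window), max(window)), step = step),
            class = "spd")
}

# Build an spd object directly from a value vector on a known grid.
spd_from_values <- function(calbp, value, n_bins = NA_integer_,
                            n_dates = n_bins, normalised_input = NA) {
  step <- unique(round(diff(calbp), 10))
  stopifnot(length(step) == 1)
  structure(list(calbp = calbp, value = value, n_dates = n_dates,
                 n_bins = n_bins, normalised_input = normalised_input,
                 window = range(calbp), step = step),
            class = "spd")
}

#' @export
print.spd <- function(x, ...) {
  cat(sprintf(
    "SPD: %d cells (step %g) over %g-%g cal BP, %s dates in %s bins, total %.4f\n",
    length(x$calbp), x$step, x$window[1], x$window[2],
    ifelse(is.na(x$n_dates), "?", x$n_dates),
    ifelse(is.na(x$n_bins), "?", x$n_bins), sum(x$value)))
  invisible(x)
}

#' Centred rolling mean of an SPD
#'
#' Smooths out calibration-curve artefacts with a centred moving average;
#' the window is truncated symmetrically at the series edges so the output
#' grid is unchanged.
#'
#' @param spd an `spd` object.
#' @param window smoothing window, years (default 100); must be at least
#'   the grid step.
#' @return the smoothed `spd`.
#' @export
rolling_mean <- function(spd, window = 100) {
  stopifnot(window >= spd$step)
  h <- floor(round(window / spd$step) / 2)
  spd$value <- roll_mean_vec(spd$value, h)
  spd
}

# Centred moving average with half-width h, symmetric truncation at edges.
roll_mean_vec <- function(x, h) {
  n <- length(x)
  if (h == 0 || n == 0) return(x)
  cs <- cumsum(c(0, x))
  e <- pmin(h, seq_len(n) - 1L, n - seq_len(n))
  lo <- seq_len(n) - e
  hi <- seq_len(n) + e
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
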