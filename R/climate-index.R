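#' Rolling-MAD outlier detection in a palaeoclimate record
#'
#' Flags extreme hydroclimatic anomalies in a proxy time series with a
#' robust rolling rule: a point is an anomaly when it deviates from the
#' median of its centred window by more than `k` times the window's rolling
#' MAD (median absolute deviation scaled by the usual 1.4826 Gaussian
#' consistency constant, as in [stats::mad()], so `k = 3` is an
#' approximately 3-sigma — conservative — threshold). The window
#' is scaled to the record's resolution so that it approximates
#' `target_window` years — `max(3, round(target_window / resolution))`
#' points — which keeps the rule comparable across records of different
#' sampling density. Records too coarse to put at least 3 points in the
#' target window are rejected.
#'
#' Edge windows are truncated; a truncated window with fewer than 3 points
#' cannot flag its centre. A window with zero MAD flags any centre that
#' deviates from the window median at all (the threshold degenerates to
#' 0+), so a constant record yields no flags.
#'
#' @param record a [climate_record].
#' @param k MAD multiplier (default 3).
#' @param target_window target window width, years (default 100).
#' @param include_centre include the evaluated point in its own window
#'   (default TRUE; excluding it increases sensitivity).
#' @param mad_constant scale factor applied to the raw median absolute
#'   deviation (default `1.4826`, the Gaussian consistency constant; set to
#'   1 for the raw MAD).
#' @return object of class `anomaly_series`: `record_id`, `source_id`,
#'   `flagged_ages` (cal BP), `window_points`, `n_points`.
#' @export
rolling_mad_outliers <- function(record, k = 3, target_window = 100,
                                 include_centre = TRUE,
                                 mad_constant = 1.4826) {
  if (record$resolution > target_window / 3) {
    stop("record ", record$record_id, "/", record$source_id,
         " too coarse: resolution ", record$resolution,
         " yr allows fewer than 3 points per ", target_window, "-yr window",
         call. = FALSE)
  }
  n <- length(record$values)
  w <- max(3, round(target_window / record$resolution))
  half <- floor(w / 2)
  flagged <- logical(n)
  x <- record$values
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    idx <- lo:hi
    if (!include_centre) idx <- setdiff(idx, i)
    if (length(idx) < 3) next
    m <- stats::median(x[idx])
    d <- mad_constant * stats::median(abs(x[idx] - m))
    dev <- abs(x[i] - m)
    flagged[i] <- if (d == 0) dev > 0 else dev > k * d
  }
  structure(list(record_id = record$record_id, source_id = record$source_id,
                 flagged_ages = record$ages[flagged],
                 window_points = w, n_points = n),
            class = "anomaly_series")
}

#' @export
print.anomaly_series <- function(x, ...) {
  cat(sprintf("Anomaly series %s/%s: %d flags (window %d points)\n",
              x$record_id, x$source_id, length(x$flagged_ages),
              x$window_points))
  invisible(x)
}

#' Detect anomalies across a set of climate records
#'
#' List-level driver over [rolling_mad_outliers()]: records too coarse for
#' the window rule are skipped and logged, and multiple sources of the same
#' record are analysed separately and then combined with
#' [combine_sources()].
#'
#' @param records list of [climate_record].
#' @param ... passed to [rolling_mad_outliers()].
#' @return list of `anomaly_series`, one per record_id; attribute
#'   `rejected` lists skipped record/source pairs.
#' @export
climate_outliers <- function(records, ...) {
  rejected <- character(0)
  series <- list()
  for (r in records) {
    a <- tryCatch(rolling_mad_outliers(r, ...), error = function(e) {
      message(conditionMessage(e))
      NULL
    })
    if (is.null(a)) {
      rejected <- c(rejected, paste(r$record_id, r$source_id, sep = "/"))
      next
    }
    series[[length(series) + 1]] <- a
  }
  ids <- vapply(series, `[[`, character(1), "record_id")
  out <- lapply(split(series, ids), function(g) {
    if (length(g) == 1) g[[1]] else combine_sources(g)
  })
  attr(out, "rejected") <- rejected
  out
}

#' Combine anomaly series from multiple sources of one record
#'
#' Where one physical record is represented by several archives (e.g. two
#' speleothems from one cave), outliers are detected per source and then
#' merged: the union of flagged ages is taken, and flags within
#' `merge_within` years of each other are collapsed to one event (the
#' lowest cal BP age of the cluster is kept).
#'
#' @param series list of `anomaly_series` sharing one `record_id`.
#' @param merge_within merge tolerance, years (default 10).
#' @return a combined `anomaly_series` (source_id `"combined"`).
#' @export
combine_sources <- function(series, merge_within = 10) {
  ids <- unique(vapply(series, `[[`, character(1), "record_id"))
  if (length(ids) != 1) {
    stop("combine_sources: mismatched record ids: ", paste(ids, collapse = ", "))
  }
  ages <- sort(unique(unlist(lapply(series, `[[`, "flagged_ages"))))
  if (length(ages) > 1) {
    new_event <- c(TRUE, diff(ages) > merge_within)
    ages <- ages[new_event]
  }
  structure(list(record_id = ids, source_id = "combined",
                 flagged_ages = ages,
                 window_points = max(vapply(series, `[[`, numeric(1),
                                            "window_points")),
                 n_points = sum(vapply(series, `[[`, numeric(1), "n_points"))),
            class = "anomaly_series")
}

#' Bin anomalies into a continental climate-variability index
#'
#' Sums flagged anomalies from all records into 100-year bins on a common
#' cal BP time scale. Only incidence is counted — not magnitude, sign or
#' spatial position. Bins whose count exceeds the dataset mean by more than
#' two standard deviations mark intervals of significantly above-normal
#' climatic variability.
#'
#' @param series list of `anomaly_series` (typically from
#'   [climate_outliers()]).
#' @param bin_width bin width, years (default 100); bins are half-open
#'   `[edge, edge + width)` and aligned to multiples of the width.
#' @param window `(min, max)` cal BP; mean/SD and flags are computed over
#'   bins inside this window.
#' @return object of class `anomaly_index`: `bin_start`, `bin_end`,
#'   `count`, `mean_count`, `sd_count`, `flagged` (logical per bin).
#' @export
bin_anomalies <- function(series, bin_width = 100, window = c(2000, 12000)) {
  edges <- seq(floor(min(window) / bin_width) * bin_width,
               ceiling(max(window) / bin_width) * bin_width - bin_width,
               by = bin_width)
  ages <- unlist(lapply(series, `[[`, "flagged_ages"))
  counts <- integer(length(edges))
  if (length(ages)) {
    b <- floor(ages / bin_width) * bin_width
    tab <- table(b[b >= edges[1] & b <= edges[length(edges)]])
    counts[match(as.numeric(names(tab)), edges)] <- as.integer(tab)
  }
  m <- mean(counts)
  s <- stats::sd(counts)
  structure(list(bin_start = edges, bin_end = edges + bin_width,
                 count = counts, mean_count = m, sd_count = s,
                 flagged = counts > m + 2 * s,
                 bin_width = bin_width, window = c(min(window), max(window)),
                 n_records = length(series)),
            class = "anomaly_index")
}

#' @export
print.anomaly_index <- function(x, ...) {
  cat(sprintf(
    "Climate variability index: %d bins of %g yr, %d anomalies from %d record(s)\n",
    length(x$count), x$bin_width, sum(x$count), x$n_records))
  cat(sprintf("  mean %.2f, sd %.2f; %d bin(s) above mean + 2 SD", x$mean_count,
              x$sd_count, sum(x$flagged)))
  if (any(x$flagged)) {
    cat(":", paste(x$bin_start[x$flagged], collapse = ", "), "cal BP")
  }
  cat("\n")
  invisible(x)
}

#' Export an anomaly index as a data frame
#'
#' @param x an `anomaly_index`.
#' @param ... unused.
#' @export
as.data.frame.anomaly_index <- function(x, ...) {
  data.frame(bin_start = x$bin_start, bin_end = x$bin_end, count = x$count,
             flagged = x$flagged)
}
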