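# Canonical column set for radiocarbon date tables. lab_id, c14_age,
# c14_error and site_id are mandatory; the rest are needed only by the
# operations that consume them (regional assignment, marine calibration).
.c14_fields <- c("lab_id", "c14_age", "c14_error", "site_id",
                 "lat", "lon", "elevation", "country", "admin1",
                 "material", "region")
.c14_required <- c("lab_id", "c14_age", "c14_error", "site_id")

#' Default column mapping for radiocarbon date tables
#'
#' Maps the package's canonical field names to the column names expected in
#' an input CSV. Override entries to adapt to a foreign schema, e.g.
#' `c14_schema(lab_id = "LabCode", c14_age = "C14Age")`.
#'
#' @param ... named overrides, `canonical_field = "column name in file"`.
#' @return named character vector mapping canonical fields to file columns.
#' @export
c14_schema <- function(...) {
  schema <- stats::setNames(.c14_fields, .c14_fields)
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .c14_fields)
    if (length(bad)) stop("unknown schema field(s): ", paste(bad, collapse = ", "))
    schema[names(dots)] <- dots
  }
  schema
}

#' Read a radiocarbon date table from CSV
#'
#' Reads and validates a table of radiocarbon determinations. Rows violating
#' basic invariants (non-positive 1-sigma error, negative 14C age,
#' out-of-range coordinates, unknown material) are rejected, never silently
#' dropped: the returned object carries a load report listing every
#' rejection and its reason.
#'
#' @param path CSV file with a header row.
#' @param schema column mapping from [c14_schema()].
#' @return a `c14_dates` data frame (one row per retained determination,
#'   canonical column names) with attribute `load_report`: a list with
#'   `n_read`, `n_rejected` and a `rejections` data frame (row, lab_id,
#'   reason).
#' @export
read_c14_table <- function(path, schema = c14_schema()) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(schema[.c14_required], names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- lapply(.c14_fields, function(f) {
    col <- schema[[f]]
    if (col %in% names(raw)) raw[[col]] else rep(NA, nrow(raw))
  })
  names(df) <- .c14_fields
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (f in c("c14_age", "c14_error", "lat", "lon", "elevation")) {
    df[[f]] <- suppressWarnings(as.numeric(df[[f]]))
  }
  for (f in c("lab_id", "site_id", "country", "admin1", "material", "region")) {
    df[[f]] <- as.character(df[[f]])
  }
  validate_c14(df, n_read = nrow(raw))
}

# Shared row validation; returns a c14_dates object with a load report.
validate_c14 <- function(df, n_read = nrow(df)) {
  reason <- rep(NA_character_, nrow(df))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[cond & is.na(reason)] <<- why
  }
  flag(is.na(df$c14_age) | is.na(df$c14_error), "unparseable age or error")
  flag(df$c14_error <= 0, "nonpositive error")
  flag(df$c14_age < 0, "negative c14 age")
  flag(!is.na(df$lat) & (df$lat < -90 | df$lat > 90), "latitude out of range")
  flag(!is.na(df$lon) & (df$lon < -180 | df$lon > 180), "longitude out of range")
  flag(!is.na(df$material) & !(df$material %in% c("terrestrial", "marine")),
       "unknown material")
  keep <- is.na(reason)
  rejections <- data.frame(row = which(!keep),
                           lab_id = df$lab_id[!keep],
                           reason = reason[!keep],
                           stringsAsFactors = FALSE)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$material[is.na(out$material)] <- "terrestrial"
  class(out) <- c("c14_dates", "data.frame")
  attr(out, "load_report") <- list(n_read = n_read,
                                   n_retained = nrow(out),
                                   n_rejected = sum(!keep),
                                   rejections = rejections)
  if (nrow(rejections)) {
    message(nrow(rejections), " row(s) rejected: ",
            paste(unique(rejections$reason), collapse = "; "))
  }
  out
}

#' Construct a validated radiocarbon date table from in-memory vectors
#'
#' @param lab_id,c14_age,c14_error,site_id mandatory fields.
#' @param lat,lon,elevation,country,admin1,material,region optional metadata.
#' @return a `c14_dates` data frame (see [read_c14_table()]).
#' @export
c14_dates <- function(lab_id, c14_age, c14_error, site_id,
                      lat = NA_real_, lon = NA_real_, elevation = NA_real_,
                      country = NA_character_, admin1 = NA_character_,
                      material = "terrestrial", region = NA_character_) {
  n <- length(lab_id)
  df <- data.frame(lab_id = as.character(lab_id),
                   c14_age = as.numeric(rep_len(c14_age, n)),
                   c14_error = as.numeric(rep_len(c14_error, n)),
                   site_id = as.character(rep_len(site_id, n)),
                   lat = as.numeric(rep_len(lat, n)),
                   lon = as.numeric(rep_len(lon, n)),
                   elevation = as.numeric(rep_len(elevation, n)),
                   country = as.character(rep_len(country, n)),
                   admin1 = as.character(rep_len(admin1, n)),
                   material = as.character(rep_len(material, n)),
                   region = as.character(rep_len(region, n)),
                   stringsAsFactors = FALSE)
  validate_c14(df)
}

#' Write a radiocarbon date table to CSV
#'
#' Inverse of [read_c14_table()] under the default schema; round-trips all
#' canonical fields.
#'
#' @param dates a `c14_dates` data frame.
#' @param path output file.
#' @export
write_c14_table <- function(dates, path) {
  utils::write.csv(as.data.frame(dates)[, .c14_fields], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Filter radiocarbon dates on error and 14C age range
#'
#' Retains dates with a 1-sigma error of at most `max_error` years (the
#' exclusion is strict on "greater than": a 200-year error is retained) and
#' an uncalibrated age inside `[min_c14_age, max_c14_age]` 14C BP. These are
#' the standard screening rules for continental-scale SPD compilations:
#' large-error dates smear the sum, and dates outside the study interval add
#' nothing but edge effects.
#'
#' @param dates a `c14_dates` data frame.
#' @param max_error maximum 1-sigma error retained (years), default 200.
#' @param max_c14_age,min_c14_age retained 14C age range (14C BP).
#' @return the filtered `c14_dates` (idempotent).
#' @export
filter_dates <- function(dates, max_error = 200,
                         max_c14_age = 12000, min_c14_age = 2000) {
  stopifnot(max_error > 0, max_c14_age > min_c14_age)
  keep <- dates$c14_error <= max_error &
    dates$c14_age >= min_c14_age & dates$c14_age <= max_c14_age
  out <- dates[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("filter_dates: no dates retained")
  class(out) <- c("c14_dates", "data.frame")
  out
}

# Region rule constants. The highland/southern split runs along the
# Peru-Chile border; sites above the elevation contour (or on the Pacific
# coast west of it) north of this latitude are "highlands", south of it
# "southern_cone".
PERU_CHILE_BORDER_LAT <- -18.35
REGION_ELEV_CUTOFF <- 300
PACIFIC_LON_CUTOFF <- -74.5

.bolivia_highland <- c("La Paz", "Oruro", "Cochabamba")
.bolivia_southern <- c("Chuquisaca", "Tarija", "Potosí", "Potosi")
.southern_countries <- c("Uruguay", "Argentina", "Paraguay")
.brazil_southern <- c("Paraná", "Parana", "Rio Grande do Sul",
                      "Santa Catarina")
.pacific_countries <- c("Chile", "Peru", "Ecuador")

#' Assign macro-regions to radiocarbon dates
#'
#' Partitions South American sites into three macro-regions — tropical
#' `highlands`, tropical `lowlands`, and the `southern_cone` — using
#' elevation, country and first-level administrative unit:
#' \itemize{
#'   \item Bolivian departments La Paz / Oruro / Cochabamba are highlands;
#'     Chuquisaca / Tarija / Potosí are southern cone.
#'   \item Uruguay, Argentina and Paraguay, and the Brazilian states Paraná,
#'     Rio Grande do Sul and Santa Catarina, are southern cone.
#'   \item Remaining sites above the 300 m contour split at the Peru–Chile
#'     border latitude (−18.35°): north is highlands, south is southern cone.
#'   \item Pacific-coast sites below the contour (Chile, and Peru/Ecuador
#'     west of longitude −74.5°) follow the same latitudinal split.
#'   \item Everything else below 300 m is lowlands.
#' }
#'
#' @param dates a `c14_dates` data frame.
#' @param border_lat latitude of the Peru–Chile border used for the
#'   north/south split of the Andean chain.
#' @return `dates` with its `region` column filled with one of
#'   `"highlands"`, `"lowlands"`, `"southern_cone"`.
#' @export
assign_region <- function(dates, border_lat = PERU_CHILE_BORDER_LAT) {
  n <- nrow(dates)
  region <- rep(NA_character_, n)
  need <- function(field, i) {
    v <- dates[[field]][i]
    if (is.na(v) || (is.character(v) && !nzchar(v))) {
      stop("assign_region: missing '", field, "' for lab_id ",
           dates$lab_id[i], call. = FALSE)
    }
    v
  }
  lat_block <- function(i) {
    if (need("lat", i) >= border_lat) "highlands" else "southern_cone"
  }
  for (i in seq_len(n)) {
    country <- need("country", i)
    if (country == "Bolivia") {
      admin1 <- need("admin1", i)
      if (admin1 %in% .bolivia_highland) { region[i] <- "highlands"; next }
      if (admin1 %in% .bolivia_southern) { region[i] <- "southern_cone"; next }
    }
    if (country %in% .southern_countries) { region[i] <- "southern_cone"; next }
    if (country == "Brazil") {
      admin1 <- need("admin1", i)
      if (admin1 %in% .brazil_southern) { region[i] <- "southern_cone"; next }
    }
    elev <- need("elevation", i)
    if (elev > REGION_ELEV_CUTOFF) { region[i] <- lat_block(i); next }
    if (country %in% .pacific_countries &&
        (country == "Chile" || need("lon", i) <= PACIFIC_LON_CUTOFF)) {
      region[i] <- lat_block(i)
      next
    }
    region[i] <- "lowlands"
  }
  dates$region <- region
  dates
}

#' Read a calibration curve in `.14c` text format
#'
#' Parses the standard calibration-curve dialect: comment lines starting
#' with `#`, then comma- or whitespace-delimited columns (cal BP, 14C age,
#' 1-sigma error, further columns ignored). The grid is sorted to ascending
#' cal BP on read; duplicate cal BP entries are a format error.
#'
#' @param path curve file.
#' @param name curve name; defaults to the file name.
#' @return a [cal_curve] object.
#' @export
read_calcurve <- function(path, name = sub("\\.14c$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty calibration curve file: ", path)
  fields <- strsplit(trimws(lines), "[,\\s]+")
  ncol_min <- min(lengths(fields))
  if (ncol_min < 3) stop("calibration curve needs >= 3 columns: ", path)
  m <- vapply(fields, function(x) as.numeric(x[1:3]), numeric(3))
  if (anyNA(m)) stop("non-numeric entries in calibration curve: ", path)
  calbp <- m[1, ]; mu <- m[2, ]; sig <- m[3, ]
  if (anyDuplicated(calbp)) stop("duplicate cal BP entries in curve: ", path)
  o <- order(calbp)
  cal_curve(calbp[o], mu[o], sig[o], name = name)
}

#' Write a calibration curve in `.14c` text format
#'
#' @param curve a [cal_curve].
#' @param path output file.
#' @export
write_calcurve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", curve$name), con)
  writeLines("# cal BP, 14C age BP, error", con)
  writeLines(sprintf("%s,%s,%s",
                     format(curve$calbp, trim = TRUE, scientific = FALSE),
                     format(curve$mu, trim = TRUE, scientific = FALSE),
                     format(curve$sigma, trim = TRUE, scientific = FALSE)),
             con)
  invisible(path)
}

#' Read a table of marine reservoir offset (Delta-R) sampling sites
#'
#' @param path CSV with columns `lat`, `lon`, `delta_r`, `delta_r_error`.
#' @return data frame of class `delta_r_sites`.
#' @export
read_delta_r <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("lat", "lon", "delta_r", "delta_r_error")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("delta-R table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(df$delta_r_error < 0)) stop("negative delta_r_error")
  class(df) <- c("delta_r_sites", "data.frame")
  df
}

#' Read palaeoclimate proxy records from CSV
#'
#' One file may hold many records and sources; rows are grouped by
#' `(record_id, source_id)`. A record's resolution is derived as the median
#' of successive age differences.
#'
#' @param path CSV with columns `age_calBP`, `value`, `record_id`,
#'   `source_id`.
#' @return a list of [climate_record] objects.
#' @export
read_climate_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("age_calBP", "value", "record_id", "source_id")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("climate table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  key <- paste(df$record_id, df$source_id, sep = "\r")
  lapply(split(df, key), function(g) {
    climate_record(record_id = g$record_id[1], source_id = g$source_id[1],
                   ages = g$age_calBP, values = g$value)
  })
}

#' Write palaeoclimate proxy records to CSV
#'
#' @param records list of [climate_record] objects.
#' @param path output file.
#' @export
write_climate_records <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r) {
    data.frame(age_calBP = r$ages, value = r$values,
               record_id = r$record_id, source_id = r$source_id,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Construct a palaeoclimate proxy record
#'
#' @param record_id identifier of the site/record (shared across sources).
#' @param source_id one physical archive (e.g. one speleothem).
#' @param ages sample ages, cal BP (ordered on construction).
#' @param values proxy values, same length as `ages`.
#' @return object of class `climate_record` with derived `resolution`
#'   (median successive age difference, years).
#' @export
climate_record <- function(record_id, source_id, ages, values) {
  if (length(ages) != length(values)) stop("ages and values differ in length")
  if (length(ages) < 3) stop("a climate record needs at least 3 points")
  o <- order(ages)
  ages <- as.numeric(ages[o]); values <- as.numeric(values[o])
  res <- stats::median(diff(ages))
  if (!is.finite(res) || res <= 0) stop("degenerate age axis (resolution <= 0)")
  structure(list(record_id = as.character(record_id),
                 source_id = as.character(source_id),
                 ages = ages, values = values, resolution = res),
            class = "climate_record")
}

#' @export
print.climate_record <- function(x, ...) {
  cat("Climate record", x$record_id, "/", x$source_id, "-",
      length(x$ages), "points,",
      sprintf("%.0f-%.0f cal BP, resolution %.1f yr\n",
              min(x$ages), max(x$ages), x$resolution))
  invisible(x)
}
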