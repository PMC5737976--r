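# Reading the weekly environmental database, monthly aggregation, and the
# long-term record filter.

#' Parser configuration for the weekly environmental database
#'
#' The weekly database is a delimited text file with one row per station
#' visit. The default dialect is tab-separated with an `NA` missing-value
#' token and a header row naming the columns `station`, `date`,
#' `temperature`, `salinity`, `secchi`. All of this is configurable for
#' files that use other separators, tokens, column names or date formats.
#'
#' @param sep Field separator (default tab).
#' @param na_token Missing-value token (default `"NA"`).
#' @param date_format Date format string passed to [base::as.Date()].
#' @param columns Named character vector mapping the canonical roles
#'   `station`, `date`, `temperature`, `salinity`, `secchi` to the column
#'   names used in the file.
#' @return A list of class `weekly_dialect`.
#' @export
weekly_dialect <- function(sep = "\t", na_token = "NA",
                           date_format = "%Y-%m-%d",
                           columns = c(station = "station", date = "date",
                                       temperature = "temperature",
                                       salinity = "salinity",
                                       secchi = "secchi")) {
  required <- c("station", "date", "temperature", "salinity", "secchi")
  if (!all(required %in% names(columns)))
    stop("dialect columns must map all of: ",
         paste(required, collapse = ", "))
  structure(list(sep = sep, na_token = na_token, date_format = date_format,
                 columns = columns),
            class = "weekly_dialect")
}

# physically plausible ranges for field measurements; values outside are
# treated as recording errors, flagged and excluded
.temp_range <- c(10, 40)

#' Parse the weekly environmental database
#'
#' Reads a delimited text file of weekly station measurements (water
#' temperature in deg C, salinity, Secchi distance in m) into a tidy
#' observation table. Rows with unparseable dates or with all three
#' measurements missing are counted and dropped. Temperatures outside
#' 10--40 deg C and non-positive Secchi distances are treated as recording
#' errors: they are set to missing with a warning rather than aborting the
#' parse, since long multi-operator field datasets inevitably contain typos.
#'
#' @param path Path to the delimited text file.
#' @param dialect A [weekly_dialect()] describing the file layout.
#' @param metadata Optional station metadata table (see
#'   [read_station_metadata()]); station codes in the data but not in the
#'   metadata trigger a warning listing the unknown codes.
#' @return A list with components:
#'   \describe{
#'     \item{observations}{data.frame with columns `station_id`, `date`,
#'       `temperature`, `salinity`, `secchi`.}
#'     \item{report}{list with `rows_read`, `rows_kept`, `rows_dropped`,
#'       `values_flagged` (out-of-range values set to missing) and
#'       `station_counts` (named integer vector).}
#'   }
#' @export
parse_weekly_database <- function(path, dialect = weekly_dialect(),
                                  metadata = NULL) {
  if (!file.exists(path)) stop("weekly database file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           na.strings = dialect$na_token,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  cols <- dialect$columns
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols))
    stop("columns missing from file: ", paste(missing_cols, collapse = ", "))

  rows_read <- nrow(raw)
  obs <- data.frame(
    station_id = raw[[cols[["station"]]]],
    date = as.Date(raw[[cols[["date"]]]], format = dialect$date_format),
    temperature = suppressWarnings(as.numeric(raw[[cols[["temperature"]]]])),
    salinity = suppressWarnings(as.numeric(raw[[cols[["salinity"]]]])),
    secchi = suppressWarnings(as.numeric(raw[[cols[["secchi"]]]])),
    stringsAsFactors = FALSE
  )

  flagged <- 0L
  bad_temp <- !is.na(obs$temperature) &
    (obs$temperature < .temp_range[1] | obs$temperature > .temp_range[2])
  if (any(bad_temp)) {
    flagged <- flagged + sum(bad_temp)
    obs$temperature[bad_temp] <- NA_real_
  }
  bad_secchi <- !is.na(obs$secchi) & obs$secchi <= 0
  if (any(bad_secchi)) {
    flagged <- flagged + sum(bad_secchi)
    obs$secchi[bad_secchi] <- NA_real_
  }
  if (flagged > 0)
    warning(flagged, " out-of-range value(s) set to missing ",
            "(temperature outside [", .temp_range[1], ", ", .temp_range[2],
            "] or non-positive Secchi)")

  keep <- !is.na(obs$date) &
    (!is.na(obs$temperature) | !is.na(obs$salinity) | !is.na(obs$secchi))
  dropped <- sum(!keep)
  obs <- obs[keep, , drop = FALSE]
  rownames(obs) <- NULL
  if (nrow(obs) == 0L) stop("zero parseable rows in ", path)

  if (!is.null(metadata)) {
    unknown <- setdiff(unique(obs$station_id), metadata$station_id)
    if (length(unknown))
      warning("station code(s) not in metadata: ",
              paste(sort(unknown), collapse = ", "))
  }

  report <- list(
    rows_read = rows_read,
    rows_kept = nrow(obs),
    rows_dropped = dropped,
    values_flagged = flagged,
    station_counts = table(obs$station_id)
  )
  list(observations = obs, report = report)
}

#' Read a station metadata table
#'
#' Station metadata is a CSV with columns `station_id`, `country`, `site`,
#' `habitat` (one of `reef`, `seagrass`, `mangrove`), `latitude`,
#' `longitude`, and optionally `first_date`/`last_date` (ISO dates bounding
#' the record).
#'
#' @param path CSV file path.
#' @return data.frame of validated station metadata.
#' @export
read_station_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_station_metadata(md)
}

#' Validate station metadata
#'
#' Checks habitat labels, coordinate ranges and station-id uniqueness.
#'
#' @param md data.frame with at least `station_id`, `habitat`, `latitude`,
#'   `longitude`.
#' @return The validated data.frame, invisibly unchanged.
#' @export
validate_station_metadata <- function(md) {
  needed <- c("station_id", "habitat", "latitude", "longitude")
  miss <- setdiff(needed, names(md))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$station_id))
    stop("duplicate station_id in metadata: ",
         paste(unique(md$station_id[duplicated(md$station_id)]),
               collapse = ", "))
  bad_hab <- setdiff(unique(md$habitat), c("reef", "seagrass", "mangrove"))
  if (length(bad_hab))
    stop("habitat must be reef, seagrass or mangrove; found: ",
         paste(bad_hab, collapse = ", "))
  if (any(md$latitude < -90 | md$latitude > 90))
    stop("latitude out of [-90, 90]")
  if (any(md$longitude < -180 | md$longitude > 180))
    stop("longitude out of [-180, 180]")
  md
}

#' Aggregate weekly observations to monthly means
#'
#' Computes, per station and calendar month, the arithmetic mean of the
#' non-missing weekly values of one variable. Months with no data are
#' simply absent (a gap), never zero-filled. The month index `t` counts
#' months elapsed since the station's first populated month, so series
#' with gaps have non-consecutive `t`.
#'
#' @param obs Observation data.frame as returned by
#'   [parse_weekly_database()] (components `station_id`, `date` and the
#'   measurement columns).
#' @param variable One of `"temperature"`, `"salinity"`, `"secchi"`.
#' @return A tidy data.frame (`monthly_series`) with columns `station_id`,
#'   `variable`, `year`, `month`, `t`, `value`, ordered by station and `t`.
#' @export
aggregate_monthly <- function(obs, variable = c("temperature", "salinity",
                                                "secchi")) {
  variable <- match.arg(variable)
  empty <- data.frame(station_id = character(), variable = character(),
                      year = integer(), month = integer(), t = integer(),
                      value = numeric(), stringsAsFactors = FALSE)
  if (nrow(obs) == 0L) return(empty)
  v <- obs[[variable]]
  ok <- !is.na(v)
  if (!any(ok)) return(empty)
  d <- obs$date[ok]
  key <- data.frame(station_id = obs$station_id[ok],
                    year = as.integer(format(d, "%Y")),
                    month = as.integer(format(d, "%m")))
  agg <- stats::aggregate(list(value = v[ok]), by = key, FUN = mean)
  # absolute month number makes gap-aware t arithmetic trivial
  agg$.m <- agg$year * 12L + agg$month
  agg <- agg[order(agg$station_id, agg$.m), , drop = FALSE]
  first <- tapply(agg$.m, agg$station_id, min)
  agg$t <- agg$.m - as.integer(first[agg$station_id])
  out <- data.frame(station_id = agg$station_id,
                    variable = if (variable == "secchi") "visibility" else variable,
                    year = agg$year, month = agg$month, t = agg$t,
                    value = agg$value, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter monthly series to long-term records
#'
#' A station's series for a variable is retained if and only if it spans at
#' least `min_years` years (counting whole months from first to last
#' populated month, inclusive) and contains at least `min_records` monthly
#' records. Both thresholds are inclusive.
#'
#' @param monthly A tidy monthly-series data.frame from
#'   [aggregate_monthly()].
#' @param min_years Minimum record span in years (default 3).
#' @param min_records Minimum number of monthly records (default 30).
#' @return A list with `retained` (the filtered data.frame), `summary`
#'   (one row per station-variable: `n_records`, `span_months`, `retained`,
#'   `reason`) and `retained_fraction`.
#' @export
filter_long_term <- function(monthly, min_years = 3, min_records = 30) {
  stopifnot(min_years > 0, min_records > 0)
  if (nrow(monthly) == 0L)
    return(list(retained = monthly,
                summary = data.frame(station_id = character(),
                                     variable = character(),
                                     n_records = integer(),
                                     span_months = integer(),
                                     retained = logical(),
                                     reason = character()),
                retained_fraction = NaN))
  key <- paste(monthly$station_id, monthly$variable, sep = "\r")
  n_records <- tapply(monthly$t, key, length)
  span <- tapply(monthly$t, key, function(t) max(t) - min(t) + 1L)
  ids <- names(n_records)
  ok_span <- span >= 12 * min_years
  ok_n <- n_records >= min_records
  retained_flag <- ok_span & ok_n
  reason <- rep("", length(ids))
  reason[!ok_span] <- "span below threshold"
  reason[!ok_n] <- ifelse(reason[!ok_n] == "", "too few records",
                          "span below threshold; too few records")
  parts <- do.call(rbind, strsplit(ids, "\r", fixed = TRUE))
  summary <- data.frame(station_id = parts[, 1], variable = parts[, 2],
                        n_records = as.integer(n_records),
                        span_months = as.integer(span),
                        retained = as.logical(retained_flag),
                        reason = reason, stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  keep_keys <- ids[retained_flag]
  retained <- monthly[key %in% keep_keys, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, summary = summary,
       retained_fraction = mean(retained_flag))
}

#' Write / read monthly series as CSV
#'
#' The on-disk format is the tidy table itself (`station_id`, `variable`,
#' `year`, `month`, `t`, `value`); values are written with full precision
#' so a round trip reproduces `(t, value)` pairs exactly.
#'
#' @param monthly Monthly-series data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); the data.frame (reader).
#' @export
write_monthly_csv <- function(monthly, path) {
  df <- monthly
  df$value <- sprintf("%.17g", df$value)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_monthly_csv
#' @export
read_monthly_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$value <- as.numeric(df$value)
  df
}
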