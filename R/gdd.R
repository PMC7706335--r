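#' Growing degree days from hourly temperature records
#'
#' Accumulates thermal time from sowing as
#' \deqn{GDD_{DAS} = \sum_{d=1}^{DAS} \sum_{h=1}^{24} \max(T_{d,h} - T_{base}, 0) / 24,}
#' i.e. hourly temperatures above a base temperature, averaged per day and
#' summed over days after sowing (DAS). Days with fewer than 24 hourly
#' records are rejected rather than rescaled, because the daily divisor is
#' fixed at 24.
#'
#' @param temps A data frame with columns `timestamp` (POSIXct or ISO-8601
#'   character, hourly instants, strictly increasing) and `temp_c`
#'   (air temperature, degrees Celsius).
#' @param sowing_date Sowing date (`Date` or `"YYYY-MM-DD"`). Accumulation
#'   starts the day after sowing (DAS 1).
#' @param t_base Base temperature in degrees Celsius. Default 0.
#'
#' @return A tibble with columns `das` (integer days after sowing), `date`,
#'   and `gdd` (cumulative degree days, nondecreasing).
#' @examples
#' h <- seq(as.POSIXct("2019-03-02 00:00", tz = "UTC"), by = "hour", length.out = 24)
#' compute_gdd(data.frame(timestamp = h, temp_c = 24), sowing_date = "2019-03-01")
#' @export
compute_gdd <- function(temps, sowing_date, t_base = 0) {
  stopifnot(is.data.frame(temps), all(c("timestamp", "temp_c") %in% names(temps)))
  if (!is.numeric(t_base) || length(t_base) != 1 || is.na(t_base) || t_base < -50) {
    stop("`t_base` must be a single temperature above -50 degrees C", call. = FALSE)
  }
  ts <- temps$timestamp
  if (!inherits(ts, "POSIXct")) ts <- as.POSIXct(ts, tz = "UTC")
  if (anyNA(ts)) stop("unparseable timestamps in `temps`", call. = FALSE)
  if (any(diff(as.numeric(ts)) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  sow <- as.Date(sowing_date)
  day <- as.Date(ts, tz = attr(ts, "tzone") %||% "UTC")
  keep <- day > sow
  day <- day[keep]
  temp <- temps$temp_c[keep]
  if (length(temp) == 0L) stop("no records after the sowing date", call. = FALSE)

  per_day <- tibble::tibble(date = day, temp_c = temp) |>
    dplyr::group_by(date) |>
    dplyr::summarise(
      n_h = dplyr::n(),
      gdd_day = sum(pmax(temp_c - t_base, 0)) / 24,
      .groups = "drop"
    )
  bad <- per_day$date[per_day$n_h != 24L]
  if (length(bad) > 0L) {
    stop("day(s) without exactly 24 hourly records: ",
         paste(format(bad), collapse = ", "), call. = FALSE)
  }
  per_day |>
    dplyr::mutate(das = as.integer(date - sow), gdd = cumsum(gdd_day)) |>
    dplyr::select(das, date, gdd)
}

#' Thermal time relative to the beginning of stem elongation
#'
#' Offsets a cumulative GDD axis by a plot's GS30 anchor:
#' \eqn{\Delta GDD_{GS30} = GDD - GDD_{GS30}}. Negative values are time
#' points before, positive values after, the beginning of stem elongation.
#'
#' @param gdd A numeric vector of cumulative GDD values, or a tibble from
#'   [compute_gdd()] (a `dgdd` column is then appended).
#' @param gdd_gs30 The GDD at which the plot reaches GS30 (finite, > 0).
#' @return A numeric vector of offsets, or the input tibble with a `dgdd`
#'   column.
#' @examples
#' delta_gdd(c(400, 600, 800), gdd_gs30 = 600)
#' @export
delta_gdd <- function(gdd, gdd_gs30) {
  if (!is.numeric(gdd_gs30) || length(gdd_gs30) != 1 || !is.finite(gdd_gs30) ||
      gdd_gs30 <= 0) {
    stop("`gdd_gs30` must be a single finite positive value", call. = FALSE)
  }
  if (is.data.frame(gdd)) {
    stopifnot("gdd" %in% names(gdd))
    return(dplyr::mutate(gdd, dgdd = .data$gdd - gdd_gs30))
  }
  gdd - gdd_gs30
}

#' Read an hourly temperature CSV
#'
#' Expects columns `timestamp` (ISO-8601) and `temp_c`.
#'
#' @param path Path to the CSV file.
#' @return A tibble with parsed `timestamp` and numeric `temp_c`.
#' @export
read_temperature_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("timestamp", "temp_c") %in% names(x)))
  ts <- as.POSIXct(gsub("T", " ", x$timestamp), tz = "UTC")
  if (anyNA(ts)) stop("unparseable timestamps in ", path, call. = FALSE)
  tibble::tibble(timestamp = ts, temp_c = as.numeric(x$temp_c))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
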