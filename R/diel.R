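#' Sunrise and sunset from NOAA solar geometry
#'
#' Computes geometric sunrise and sunset (UTC) for each date from the NOAA
#' solar-position algorithm: the Julian-century solar ephemeris (mean
#' longitude and anomaly, equation of centre, apparent longitude, corrected
#' obliquity) giving the equation of time and solar declination, and the
#' hour angle at the standard refraction-corrected zenith of 90.833
#' degrees. The solar angles are first evaluated at local solar noon and
#' then re-evaluated at the event time itself, which matters near the
#' equinoxes when declination moves ~0.4 degrees per day. An alternative
#' zenith of 96 degrees (`twilight = "civil"`) moves the day/night boundary
#' to civil twilight.
#'
#' Accuracy is well within a minute of high-precision ephemerides for mid
#' latitudes, far below the one-hour bin width used downstream.
#'
#' @param dates a `Date` vector.
#' @param lat,lon site coordinates, decimal degrees (north / east positive).
#'   Defaults are the study spawning ground at 49.578497 N, 15.251671 E.
#' @param twilight `"official"` (zenith 90.833, default) or `"civil"`
#'   (zenith 96).
#' @return a `data.frame` with `date`, `sunrise`, `sunset` (POSIXct UTC).
#' @export
solar_times <- function(dates, lat = 49.578497, lon = 15.251671,
                        twilight = c("official", "civil")) {
  twilight <- match.arg(twilight)
  zenith <- if (twilight == "civil") 96 else 90.833
  if (abs(lat) >= 66)
    stop("unsupported latitude (polar day/night not handled): ", lat)
  dates <- as.Date(dates)
  d2r <- pi / 180
  jd0 <- as.numeric(dates) + 2440587.5  # Julian day at 00:00 UTC
  event_minutes <- function(minutes_utc) {
    jc <- (jd0 + minutes_utc / 1440 - 2451545) / 36525
    # solar ephemeris in Julian centuries from J2000
    ml <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
    ma <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
    ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
    ctr <- (sin(ma * d2r) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
              sin(2 * ma * d2r) * (0.019993 - 0.000101 * jc) +
              sin(3 * ma * d2r) * 0.000289)
    omega <- (125.04 - 1934.136 * jc) * d2r
    app_long <- ml + ctr - 0.00569 - 0.00478 * sin(omega)
    obliq <- (23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60 +
                0.00256 * cos(omega))
    decl <- asin(sin(obliq * d2r) * sin(app_long * d2r))
    y <- tan(obliq / 2 * d2r)^2
    eqtime <- 4 / d2r * (y * sin(2 * ml * d2r) - 2 * ecc * sin(ma * d2r) +
                           4 * ecc * y * sin(ma * d2r) * cos(2 * ml * d2r) -
                           0.5 * y^2 * sin(4 * ml * d2r) -
                           1.25 * ecc^2 * sin(2 * ma * d2r))
    cos_ha <- (cos(zenith * d2r) / (cos(lat * d2r) * cos(decl))
               - tan(lat * d2r) * tan(decl))
    if (any(abs(cos_ha) > 1))
      stop("sun does not rise/set on some requested dates at latitude ", lat)
    ha <- acos(cos_ha) / d2r
    list(sunrise = 720 - 4 * (lon + ha) - eqtime,
         sunset = 720 - 4 * (lon - ha) - eqtime)
  }
  # evaluate at local solar noon, then refine at the event times (the
  # declination moves ~0.4 deg/day near the equinoxes)
  first <- event_minutes(720 - 4 * lon)
  sunrise_min <- event_minutes(first$sunrise)$sunrise
  sunset_min <- event_minutes(first$sunset)$sunset
  midnight <- as.POSIXct(paste(dates), tz = "UTC")
  data.frame(date = dates,
             sunrise = midnight + sunrise_min * 60,
             sunset = midnight + sunset_min * 60)
}

#' Label time bins day or night
#'
#' For each bin, the day fraction is the share of the bin lying between the
#' sunrise and sunset of the bin's UTC date; the night fraction is its
#' complement, so the two always sum to one. The binary `period` label
#' (used as a model covariate) is the majority label; the fractional weights
#' are retained for boundary-unbiased share computations.
#'
#' @param bins grid from [make_bins()] (whole-hour UTC bins never straddle
#'   midnight).
#' @param lat,lon,twilight passed to [solar_times()].
#' @return `bins` with `day_frac`, `night_frac` and `period`
#'   (`"day"`/`"night"`) columns added.
#' @export
label_bins <- function(bins, lat = 49.578497, lon = 15.251671,
                       twilight = "official") {
  .check_grid(bins)
  d <- as.Date(bins$bin_start, tz = "UTC")
  win <- solar_times(sort(unique(d)), lat = lat, lon = lon, twilight = twilight)
  i <- match(d, win$date)
  s <- as.numeric(bins$bin_start)
  e <- as.numeric(bins$bin_end)
  day_s <- pmax(0, pmin(e, as.numeric(win$sunset[i])) -
                   pmax(s, as.numeric(win$sunrise[i])))
  bins$day_frac <- day_s / (e - s)
  bins$night_frac <- 1 - bins$day_frac
  bins$period <- ifelse(bins$day_frac >= 0.5, "day", "night")
  bins
}

#' Hour-of-day profile of a binned series
#'
#' Averages an hourly series by UTC hour of day across all season days,
#' giving the 24-hour distribution shape (and the share of the total that
#' falls in each hour).
#'
#' @param bin_start POSIXct UTC hourly bin starts.
#' @param value numeric value per bin.
#' @return a `data.frame` with `hour` (0-23), `mean` (mean value at that
#'   hour), and `share` (fraction of the series total in that hour; `NA`
#'   when the total is zero).
#' @export
diel_profile <- function(bin_start, value) {
  stopifnot(length(bin_start) == length(value))
  hour <- as.POSIXlt(bin_start, tz = "UTC")$hour
  m <- vapply(0:23, function(h) {
    v <- value[hour == h]
    if (length(v)) mean(v) else 0
  }, numeric(1))
  tot <- sum(value)
  data.frame(hour = 0:23, mean = m,
             share = if (tot > 0) m / sum(m) else NA_real_)
}
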