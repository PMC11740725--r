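#' Solar zenith angle and daylight flag
#'
#' Computes the apparent solar position for a local timestamp using the NOAA
#' solar-calculator formulation (a truncation of Meeus' algorithms, accurate to
#' well under 0.5 degrees over 1900--2100). The zenith angle feeds the
#' direct-beam term of the globe-temperature energy balance, where the incident
#' shortwave on a sphere scales with `1/(2 cos Z)`.
#'
#' @param latitude Degrees north, in `[-90, 90]`.
#' @param longitude Degrees east (west negative).
#' @param timestamp_local `POSIXct` timestamp(s); the timezone attached to the
#'   timestamp defines local clock time.
#' @param tz_offset_hours Hours east of UTC for `timestamp_local` (e.g. -7 for
#'   PDT). If `NULL`, taken from the timestamp's own timezone.
#' @return A data.frame with `zenith_deg` in `[0, 180]` and `daylight`
#'   (`TRUE` iff the sun centre is above the horizon, i.e. zenith < 90).
#' @examples
#' noon <- as.POSIXct("2020-08-15 12:00:00", tz = "Etc/GMT+7")
#' solar_geometry(37.62, -122.38, noon)
#' @export
solar_geometry <- function(latitude, longitude, timestamp_local,
                           tz_offset_hours = NULL) {
  if (any(!is.finite(latitude)) || any(latitude < -90) || any(latitude > 90)) {
    stop("latitude must be finite and in [-90, 90]")
  }
  if (!inherits(timestamp_local, "POSIXct")) {
    timestamp_local <- as.POSIXct(timestamp_local, tz = "UTC")
  }
  if (any(is.na(timestamp_local))) stop("invalid timestamp")
  if (is.null(tz_offset_hours)) {
    tz_offset_hours <- as.numeric(format(timestamp_local, "%z")) / 100
    tz_offset_hours <- trunc(tz_offset_hours) +
      (tz_offset_hours - trunc(tz_offset_hours)) * 100 / 60
  }

  deg2rad <- pi / 180
  # Julian day from the UTC instant; POSIXct is seconds since 1970-01-01 UTC
  jd <- as.numeric(timestamp_local) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525

  L0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  M  <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  e  <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  C  <- sin(M * deg2rad) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
        sin(2 * M * deg2rad) * (0.019993 - 0.000101 * jc) +
        sin(3 * M * deg2rad) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * jc
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega * deg2rad)

  eps0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  eps  <- eps0 + 0.00256 * cos(omega * deg2rad)

  decl <- asin(sin(eps * deg2rad) * sin(app_long * deg2rad)) / deg2rad

  y <- tan(eps / 2 * deg2rad)^2
  eq_time <- 4 / deg2rad * (
    y * sin(2 * L0 * deg2rad) - 2 * e * sin(M * deg2rad) +
      4 * e * y * sin(M * deg2rad) * cos(2 * L0 * deg2rad) -
      0.5 * y^2 * sin(4 * L0 * deg2rad) - 1.25 * e^2 * sin(2 * M * deg2rad)
  )  # minutes

  local_minutes <- as.numeric(format(timestamp_local, "%H")) * 60 +
    as.numeric(format(timestamp_local, "%M")) +
    as.numeric(format(timestamp_local, "%S")) / 60
  true_solar <- (local_minutes + eq_time + 4 * longitude -
                   60 * tz_offset_hours) %% 1440
  hour_angle <- ifelse(true_solar / 4 < 0, true_solar / 4 + 180,
                       true_solar / 4 - 180)

  cos_zen <- sin(latitude * deg2rad) * sin(decl * deg2rad) +
    cos(latitude * deg2rad) * cos(decl * deg2rad) * cos(hour_angle * deg2rad)
  cos_zen <- pmin(1, pmax(-1, cos_zen))
  zen <- acos(cos_zen) / deg2rad

  data.frame(zenith_deg = zen, daylight = zen < 90)
}
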