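#' Configure a synthetic meteorological campaign
#'
#' Builds the configuration for a seeded synthetic hourly campaign that emulates
#' the statistical shape of high-resolution mesoscale-model output over an
#' airport campus: a sinusoidal diurnal air-temperature cycle, anti-correlated
#' relative humidity, lognormal wind, clear-sky short/longwave radiation, and a
#' midday-peaked air-temperature cooling signal per albedo scenario.
#'
#' Scenario series differ from baseline only through a cooling profile
#' `delta_Ta(h) = peak_cooling * Kdown(h) / max(Kdown)`, so cooling is largest
#' near solar noon and zero at night.
#'
#' @param n_locations Number of monitoring locations (default 10).
#' @param year,month Campaign month (default August 2020, 31 days).
#' @param latitude,longitude Campus coordinates in degrees (default SFO).
#' @param tz_offset_hours Local offset from UTC in hours (default -7, PDT).
#' @param seed Integer RNG seed; identical seed and config give byte-identical
#'   output.
#' @param Ta_mean,Ta_amplitude Mean and semi-amplitude of the diurnal air
#'   temperature cycle, degrees C.
#' @param Ta_peak_hour Local hour of maximum air temperature.
#' @param RH_mean,RH_amplitude Mean and semi-amplitude of relative humidity
#'   (percent); RH is anti-correlated with the temperature cycle and clamped to
#'   `[5, 99]` percent, the validity window of the Stull wet-bulb fit.
#' @param wind_meanlog,wind_sdlog Lognormal wind-speed parameters (m/s);
#'   defaults give a median of 3.5 m/s so both the windy and calm shade
#'   branches of the WBGT formula are exercised.
#' @param cloudless Clear-sky flag (only clear sky is modelled).
#' @param scenario_peak_cooling Named vector of peak midday air-temperature
#'   reductions (degrees C, positive = cooling) per scenario. Must contain
#'   `baseline = 0`; defaults 0.9 / 1.25 / 1.6 for low / moderate / high.
#' @param F_clear Direct-beam fraction of total horizontal shortwave under
#'   clear sky for zenith < 80 degrees; linearly tapered to 0 at 90 degrees.
#' @param ground_albedo Broadband surface albedo used for upwelling shortwave.
#' @param location_sd_Ta,noise_sd_Ta Between-location offset and hourly noise
#'   standard deviations for air temperature (degrees C). Both perturbations
#'   are centred across locations at every hour, so the across-location mean
#'   equals the deterministic diurnal cycle exactly for any seed.
#' @return A `campaign_config` list.
#' @export
campaign_config <- function(n_locations = 10,
                            year = 2020, month = 8,
                            latitude = 37.62, longitude = -122.38,
                            tz_offset_hours = -7,
                            seed = 1L,
                            Ta_mean = 21, Ta_amplitude = 8, Ta_peak_hour = 14,
                            RH_mean = 65, RH_amplitude = 22,
                            wind_meanlog = log(3.5), wind_sdlog = 0.45,
                            cloudless = TRUE,
                            scenario_peak_cooling = c(baseline = 0, low = 0.9,
                                                      moderate = 1.25, high = 1.6),
                            F_clear = 0.85,
                            ground_albedo = 0.20,
                            location_sd_Ta = 0.6, noise_sd_Ta = 0.35) {
  if (n_locations < 1) stop("n_locations must be >= 1")
  if (Ta_amplitude < 0 || RH_amplitude < 0) stop("amplitudes must be >= 0")
  if (is.null(names(scenario_peak_cooling)) ||
      !"baseline" %in% names(scenario_peak_cooling)) {
    stop("scenario_peak_cooling must be named and contain 'baseline'")
  }
  if (scenario_peak_cooling[["baseline"]] != 0) {
    stop("baseline peak cooling must be 0")
  }
  ord <- intersect(c("low", "moderate", "high"), names(scenario_peak_cooling))
  if (length(ord) > 1 && is.unsorted(scenario_peak_cooling[ord])) {
    stop("peak cooling must be non-decreasing across low -> moderate -> high")
  }
  structure(list(
    n_locations = as.integer(n_locations), year = year, month = month,
    latitude = latitude, longitude = longitude,
    tz_offset_hours = tz_offset_hours, seed = as.integer(seed),
    Ta_mean = Ta_mean, Ta_amplitude = Ta_amplitude, Ta_peak_hour = Ta_peak_hour,
    RH_mean = RH_mean, RH_amplitude = RH_amplitude,
    wind_meanlog = wind_meanlog, wind_sdlog = wind_sdlog,
    cloudless = cloudless,
    scenario_peak_cooling = scenario_peak_cooling,
    F_clear = F_clear, ground_albedo = ground_albedo,
    location_sd_Ta = location_sd_Ta, noise_sd_Ta = noise_sd_Ta
  ), class = "campaign_config")
}

#' Generate a synthetic hourly meteorological campaign
#'
#' Produces one hourly series per (location, scenario) for every hour of the
#' configured month. Samples are instantaneous top-of-hour values in local
#' time. Shortwave follows a clear-sky cosine-of-zenith shape (zero at night),
#' longwave components are blackbody fluxes at near-surface temperatures, and
#' each scenario subtracts a midday-peaked cooling profile from the baseline
#' air temperature. Per-location perturbations are seeded and centred across
#' locations at every hour.
#'
#' @param config A [campaign_config()] object.
#' @return A data.frame with columns `location_id, timestamp_local, Ta_C,
#'   RH_pct, u_ms, Kdown_Wm2, Kup_Wm2, Ldown_Wm2, Lup_Wm2, F_frac, zenith_deg,
#'   scenario`; rows ordered by scenario, location, time.
#' @export
generate_campaign <- function(config) {
  stopifnot(inherits(config, "campaign_config"))
  set.seed(config$seed)
  sigma_sb <- 5.670374419e-8

  tz <- sprintf("Etc/GMT%+d", -config$tz_offset_hours)  # Etc zones flip sign
  n_days <- days_in_month(config$year, config$month)
  t0 <- as.POSIXct(sprintf("%04d-%02d-01 00:00:00", config$year, config$month),
                   tz = tz)
  times <- t0 + 3600 * seq_len(n_days * 24) - 3600
  nh <- length(times)
  hours <- as.numeric(format(times, "%H"))

  sol <- solar_geometry(config$latitude, config$longitude, times,
                        tz_offset_hours = config$tz_offset_hours)
  cosz <- cos(sol$zenith_deg * pi / 180)
  # clear-sky transmittance 0.75, solar constant 1361 W/m2
  Kdown <- ifelse(sol$daylight, 1361 * 0.75 * pmax(cosz, 0), 0)
  F_frac <- ifelse(Kdown > 0,
                   config$F_clear *
                     pmin(1, pmax(0, (90 - sol$zenith_deg) / 10)),
                   0)
  Knorm <- if (max(Kdown) > 0) Kdown / max(Kdown) else Kdown

  Ta_cycle <- config$Ta_mean + config$Ta_amplitude *
    cos(2 * pi * (hours - config$Ta_peak_hour) / 24)
  RH_cycle <- config$RH_mean - if (config$Ta_amplitude > 0) {
    config$RH_amplitude * (Ta_cycle - config$Ta_mean) / config$Ta_amplitude
  } else 0

  nl <- config$n_locations
  # centred perturbations: across-location mean is the deterministic cycle
  loc_off <- stats::rnorm(nl, 0, config$location_sd_Ta)
  loc_off <- loc_off - mean(loc_off)
  noise <- matrix(stats::rnorm(nh * nl, 0, config$noise_sd_Ta), nh, nl)
  noise <- noise - rowMeans(noise)
  u_mat <- matrix(stats::rlnorm(nh * nl, config$wind_meanlog, config$wind_sdlog),
                  nh, nl)

  # scenario series differ from baseline only through the Ta cooling profile;
  # radiative and wind fields are shared (the cooling signal emulates the
  # post-processed 2-m air temperature response, not a re-run of the surface
  # energy budget)
  scen_names <- names(config$scenario_peak_cooling)
  out <- vector("list", length(scen_names) * nl)
  k <- 0
  RH <- pmin(99, pmax(5, RH_cycle))
  for (loc in seq_len(nl)) {
    Ta0 <- Ta_cycle + loc_off[loc] + noise[, loc]
    Ts <- Ta0 + 2 + 6 * Knorm  # surface skin warmer than air, midday-peaked
    Ldown <- 0.75 * sigma_sb * (Ta0 + 273.15)^4
    Lup <- 0.97 * sigma_sb * (Ts + 273.15)^4
    for (scen in scen_names) {
      dTa <- config$scenario_peak_cooling[[scen]] * Knorm
      k <- k + 1
      out[[k]] <- data.frame(
        location_id = sprintf("loc%02d", loc),
        timestamp_local = times,
        Ta_C = Ta0 - dTa, RH_pct = RH, u_ms = u_mat[, loc],
        Kdown_Wm2 = Kdown,
        Kup_Wm2 = config$ground_albedo * Kdown,
        Ldown_Wm2 = Ldown,
        Lup_Wm2 = Lup,
        F_frac = F_frac, zenith_deg = sol$zenith_deg,
        scenario = scen,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%04d-%02d-01", year, month))
  as.integer(seq(first, by = "1 month", length.out = 2)[2] - first)
}

#' Write / read the hourly meteorology CSV
#'
#' Plain CSV with the campaign schema; timestamps are written in ISO-8601 with
#' the local UTC offset so round-trips are exact and byte-stable.
#'
#' @param met Campaign data.frame from [generate_campaign()].
#' @param path Output file path.
#' @return `write_met_csv` returns `path` invisibly; `read_met_csv` returns the
#'   campaign data.frame with parsed `POSIXct` timestamps.
#' @export
write_met_csv <- function(met, path) {
  out <- met
  out$timestamp_local <- format(met$timestamp_local, "%Y-%m-%dT%H:%M:%S%z")
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.8g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_met_csv
#' @export
read_met_csv <- function(path) {
  met <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("location_id", "timestamp_local", "Ta_C", "RH_pct", "u_ms",
            "Kdown_Wm2", "Kup_Wm2", "Ldown_Wm2", "Lup_Wm2", "F_frac",
            "zenith_deg", "scenario")
  missing <- setdiff(need, names(met))
  if (length(missing)) {
    stop("met CSV is missing columns: ", paste(missing, collapse = ", "))
  }
  off <- substr(met$timestamp_local, 20, 24)
  tzh <- unique(as.integer(substr(off, 1, 3)))
  tz <- if (length(tzh) == 1 && !is.na(tzh)) {
    sprintf("Etc/GMT%+d", -tzh)
  } else "UTC"
  met$timestamp_local <- as.POSIXct(met$timestamp_local,
                                    format = "%Y-%m-%dT%H:%M:%S%z", tz = tz)
  met
}
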