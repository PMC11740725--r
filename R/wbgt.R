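#' Stull wet-bulb temperature approximation
#'
#' Closed-form natural wet-bulb temperature from air temperature and relative
#' humidity, via Stull's arctangent fit to psychrometric calculations at
#' standard sea-level pressure:
#'
#' `Tw = Ta*atan(0.151977*sqrt(RH + 8.313659)) + atan(Ta + RH)
#'       - atan(RH - 1.676331) + 0.00391838*RH^1.5*atan(0.023101*RH)
#'       - 4.686035`
#'
#' The fit is valid for RH in 5--99 percent and Ta in about -20--50 degrees C;
#' outside that window the value is still returned but a warning is raised and
#' the `out_of_range` attribute flags the offending elements.
#'
#' @param Ta Air temperature, degrees C.
#' @param RH Relative humidity, percent (0--100 scale).
#' @return Wet-bulb temperature, degrees C (vectorized).
#' @examples
#' wet_bulb_stull(20, 50)  # ~ 13.7
#' @export
wet_bulb_stull <- function(Ta, RH) {
  if (any(is.na(Ta)) || any(is.na(RH))) stop("Ta and RH must be non-missing")
  oor <- RH < 5 | RH > 99 | Ta < -20 | Ta > 50
  if (any(oor)) {
    warning(sum(oor), " input(s) outside the fit validity window ",
            "(RH 5-99%, Ta -20..50 C); values evaluated anyway")
  }
  Tw <- Ta * atan(0.151977 * sqrt(RH + 8.313659)) +
    atan(Ta + RH) - atan(RH - 1.676331) +
    0.00391838 * RH^1.5 * atan(0.023101 * RH) -
    4.686035
  if (any(oor)) attr(Tw, "out_of_range") <- which(oor)
  Tw
}

#' Globe-temperature solver settings and physical constants
#'
#' Parameters of the 15 cm black-globe energy balance: globe emissivity and
#' albedo, diameter, the Stefan-Boltzmann constant, the fixed-point iteration
#' tolerance and damping, and the wind clamp applied before the calm-branch
#' `log10(u)` term.
#'
#' @param epsilon_g Globe emissivity (default 0.95).
#' @param alpha_g Globe shortwave albedo (default 0.05).
#' @param diameter Globe diameter in metres (default 0.15).
#' @param sigma Stefan-Boltzmann constant, W m^-2 K^-4.
#' @param tolerance Convergence tolerance on successive globe-temperature
#'   iterates, degrees C (default 0.02).
#' @param max_iterations Iteration cap before the bisection fallback.
#' @param damping Successive-substitution damping factor in (0, 1].
#' @param cosz_floor Lower bound applied to `cos Z` in the direct-beam
#'   denominator, to avoid sunrise/sunset blow-up.
#' @param sun_kdown_threshold Shortwave threshold (W/m2) above which a daytime
#'   hour is treated as sun-exposed.
#' @param u_min Wind-speed clamp (m/s) applied before `log10(u)`.
#' @return A `globe_params` list.
#' @export
globe_params <- function(epsilon_g = 0.95, alpha_g = 0.05, diameter = 0.15,
                         sigma = 5.670374419e-8, tolerance = 0.02,
                         max_iterations = 50L, damping = 0.5,
                         cosz_floor = 0.02, sun_kdown_threshold = 25,
                         u_min = 0.13) {
  stopifnot(epsilon_g > 0, epsilon_g <= 1, alpha_g >= 0, alpha_g < 1,
            tolerance > 0, damping > 0, damping <= 1)
  structure(list(epsilon_g = epsilon_g, alpha_g = alpha_g, diameter = diameter,
                 sigma = sigma, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 damping = damping, cosz_floor = cosz_floor,
                 sun_kdown_threshold = sun_kdown_threshold, u_min = u_min),
            class = "globe_params")
}

# Convective heat-transfer coefficient for a sphere in forced convection:
# Nu = 2 + 0.6 Re^0.5 Pr^(1/3), with dry-air properties evaluated at the film
# temperature (Sutherland viscosity, ideal-gas density at 101.325 kPa).
hc_sphere <- function(u, diameter, T_film_K) {
  k_air <- 0.02624 * (T_film_K / 300)^0.8646          # W m-1 K-1
  mu <- 1.458e-6 * T_film_K^1.5 / (T_film_K + 110.4)  # Pa s
  rho <- 101325 / (287.05 * T_film_K)                 # kg m-3
  Re <- pmax(u, 0.05) * diameter * rho / mu
  Pr <- 0.71
  Nu <- 2 + 0.6 * sqrt(Re) * Pr^(1 / 3)
  Nu * k_air / diameter
}

# Right-hand side of the globe energy balance, Kelvin^4:
#   Tg^4 = (Ldn+Lup)/(2s) - hc (Tg-Ta)/(eg s)
#          + Kdn (1-ag)/(2 eg s) (1 - F + F/(2 cos Z)) + (1-ag)/(2 eg s) Kup
globe_rhs <- function(TgK, TaK, u, Kdown, Kup, Ldown, Lup, Ffrac, cosz, p) {
  hc <- hc_sphere(u, p$diameter, (TgK + TaK) / 2)
  (Ldown + Lup) / (2 * p$sigma) -
    hc * (TgK - TaK) / (p$epsilon_g * p$sigma) +
    Kdown * (1 - p$alpha_g) / (2 * p$epsilon_g * p$sigma) *
      (1 - Ffrac + Ffrac / (2 * cosz)) +
    (1 - p$alpha_g) / (2 * p$epsilon_g * p$sigma) * Kup
}

#' Black-globe temperature from the radiative-convective energy balance
#'
#' Solves the globe energy balance by damped successive substitution on the
#' globe temperature in Kelvin, iterating `Tg <- (1-d)*Tg + d*RHS^(1/4)` until
#' successive iterates differ by less than `tolerance` (default 0.02 C).
#' Samples that fail to converge within `max_iterations` fall back to
#' bracketing bisection of the energy-balance residual over
#' `[Ta - 5, Ta + 80]` degrees C.
#'
#' All radiative algebra is in Kelvin internally; interfaces are in Celsius.
#'
#' @param Ta Air temperature, degrees C (vectorized; all arguments recycle).
#' @param u Wind speed, m/s.
#' @param Kdown,Kup Downwelling / upwelling shortwave, W/m2.
#' @param Ldown,Lup Downwelling / upwelling longwave, W/m2.
#' @param F_frac Direct-beam fraction of total horizontal shortwave, 0--1.
#' @param zenith_deg Solar zenith angle, degrees; `cos Z` is floored at
#'   `params$cosz_floor` in the beam denominator.
#' @param params A [globe_params()] object.
#' @return A data.frame with `Tg_C`, `iterations`, and `fallback` (TRUE where
#'   bisection was used).
#' @export
globe_temperature <- function(Ta, u, Kdown, Kup, Ldown, Lup, F_frac,
                              zenith_deg, params = globe_params()) {
  n <- max(length(Ta), length(u), length(Kdown), length(Kup),
           length(Ldown), length(Lup), length(F_frac), length(zenith_deg))
  Ta <- rep_len(Ta, n); u <- rep_len(u, n)
  Kdown <- rep_len(Kdown, n); Kup <- rep_len(Kup, n)
  Ldown <- rep_len(Ldown, n); Lup <- rep_len(Lup, n)
  F_frac <- rep_len(F_frac, n); zenith_deg <- rep_len(zenith_deg, n)

  TaK <- Ta + 273.15
  cosz <- pmax(cos(zenith_deg * pi / 180), params$cosz_floor)

  TgK <- TaK  # start at air temperature
  iters <- integer(n)
  active <- rep(TRUE, n)
  for (it in seq_len(params$max_iterations)) {
    if (!any(active)) break
    rhs <- globe_rhs(TgK[active], TaK[active], u[active], Kdown[active],
                     Kup[active], Ldown[active], Lup[active], F_frac[active],
                     cosz[active], params)
    TgK_new <- (1 - params$damping) * TgK[active] +
      params$damping * pmax(rhs, 1)^0.25
    delta <- abs(TgK_new - TgK[active])
    TgK[active] <- TgK_new
    iters[active] <- it
    done <- delta < params$tolerance
    active[active] <- !done
  }

  fallback <- active
  if (any(fallback)) {
    idx <- which(fallback)
    TgK[idx] <- vapply(idx, function(i) {
      resid <- function(tgk) {
        tgk^4 - globe_rhs(tgk, TaK[i], u[i], Kdown[i], Kup[i], Ldown[i],
                          Lup[i], F_frac[i], cosz[i], params)
      }
      lo <- TaK[i] - 5
      hi <- TaK[i] + 80
      flo <- resid(lo); fhi <- resid(hi)
      if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
        stop(sprintf(paste0("globe temperature bisection failed: no sign ",
                            "change on [Ta-5, Ta+80] (Ta=%.2f C, u=%.2f m/s, ",
                            "Kdown=%.1f W/m2)"), Ta[i], u[i], Kdown[i]))
      }
      while (hi - lo > 1e-3) {
        mid <- (lo + hi) / 2
        if (resid(lo) * resid(mid) <= 0) hi <- mid else lo <- mid
      }
      (lo + hi) / 2
    }, numeric(1))
  }

  data.frame(Tg_C = TgK - 273.15, iterations = iters, fallback = fallback)
}

#' Shade / night WBGT
#'
#' For hours with no sun exposure the index uses wet-bulb and air temperature
#' only, with a wind branch at 3 m/s:
#' `0.7 Tw + 0.3 Ta` when `u > 3`, else
#' `0.67 Tw + 0.33 Ta - 0.048 log10(u) (Ta - Tw)`.
#' Wind is clamped below at `u_min` before the logarithm (the calm branch
#' diverges as u -> 0); clamping is a data-hygiene rule, never an error.
#'
#' @param Tw Wet-bulb temperature, degrees C.
#' @param Ta Air temperature, degrees C.
#' @param u Wind speed, m/s.
#' @param u_min Lower wind clamp, m/s.
#' @return A data.frame with `WBGT_C` and `branch` (`no_sun_windy` /
#'   `no_sun_calm`).
#' @export
wbgt_no_sun <- function(Tw, Ta, u, u_min = 0.13) {
  u <- pmax(u, u_min)
  windy <- u > 3
  WBGT <- ifelse(windy,
                 0.7 * Tw + 0.3 * Ta,
                 0.67 * Tw + 0.33 * Ta - 0.048 * log10(u) * (Ta - Tw))
  data.frame(WBGT_C = WBGT,
             branch = ifelse(windy, "no_sun_windy", "no_sun_calm"))
}

#' Sun-exposed WBGT
#'
#' The standard outdoor index `0.7 Tw + 0.2 Tg + 0.1 Ta`.
#'
#' @param Tw Wet-bulb temperature, degrees C.
#' @param Tg Globe temperature, degrees C.
#' @param Ta Air temperature, degrees C.
#' @return WBGT, degrees C.
#' @export
wbgt_sun <- function(Tw, Tg, Ta) {
  stopifnot(all(is.finite(Tw)), all(is.finite(Tg)), all(is.finite(Ta)))
  0.7 * Tw + 0.2 * Tg + 0.1 * Ta
}

#' Hourly WBGT for a meteorological series
#'
#' Applies the sun rule per hour: an hour is sun-exposed iff downwelling
#' shortwave exceeds `params$sun_kdown_threshold` (default 25 W/m2) and the
#' sun is above the horizon; those hours get the sun form with the globe
#' temperature solved from the energy balance, all other hours the shade/night
#' form. One record per input sample, order preserved.
#'
#' @param met Data.frame with the hourly met schema (see [generate_campaign()]),
#'   chronologically sorted within each (location, scenario) series.
#' @param params A [globe_params()] object.
#' @return Data.frame with `location_id, timestamp_local, scenario, Tw_C, Tg_C
#'   (NA for no-sun hours), WBGT_C, branch, iterations`.
#' @export
compute_wbgt_series <- function(met, params = globe_params()) {
  key <- interaction(met$location_id, met$scenario, drop = TRUE)
  unsorted <- tapply(as.numeric(met$timestamp_local), key, is.unsorted)
  if (any(unlist(unsorted))) {
    stop("met series must be chronologically sorted within each ",
         "(location, scenario) group")
  }

  Tw <- suppressWarnings(wet_bulb_stull(met$Ta_C, met$RH_pct))
  attr(Tw, "out_of_range") <- NULL
  sun <- met$Kdown_Wm2 > params$sun_kdown_threshold & met$zenith_deg < 90

  Tg <- rep(NA_real_, nrow(met))
  iters <- rep(NA_integer_, nrow(met))
  if (any(sun)) {
    g <- globe_temperature(met$Ta_C[sun], met$u_ms[sun], met$Kdown_Wm2[sun],
                           met$Kup_Wm2[sun], met$Ldown_Wm2[sun],
                           met$Lup_Wm2[sun], met$F_frac[sun],
                           met$zenith_deg[sun], params)
    Tg[sun] <- g$Tg_C
    iters[sun] <- g$iterations
  }

  WBGT <- numeric(nrow(met))
  branch <- character(nrow(met))
  if (any(sun)) {
    WBGT[sun] <- wbgt_sun(Tw[sun], Tg[sun], met$Ta_C[sun])
    branch[sun] <- "sun"
  }
  if (any(!sun)) {
    ns <- wbgt_no_sun(Tw[!sun], met$Ta_C[!sun], met$u_ms[!sun],
                      u_min = params$u_min)
    WBGT[!sun] <- ns$WBGT_C
    branch[!sun] <- ns$branch
  }

  data.frame(
    location_id = met$location_id,
    timestamp_local = met$timestamp_local,
    scenario = met$scenario,
    Tw_C = as.numeric(Tw), Tg_C = Tg, WBGT_C = WBGT,
    branch = branch, iterations = iters,
    stringsAsFactors = FALSE
  )
}

#' Write / read the hourly WBGT CSV
#'
#' @param wbgt Data.frame from [compute_wbgt_series()].
#' @param path File path.
#' @return `write_wbgt_csv` returns `path` invisibly; `read_wbgt_csv` the
#'   parsed data.frame.
#' @export
write_wbgt_csv <- function(wbgt, path) {
  out <- wbgt
  out$timestamp_local <- format(wbgt$timestamp_local, "%Y-%m-%dT%H:%M:%S%z")
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) ifelse(is.na(x), "",
                                                  sprintf("%.8g", x)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_wbgt_csv
#' @export
read_wbgt_csv <- function(path) {
  wbgt <- utils::read.csv(path, stringsAsFactors = FALSE)
  off <- substr(wbgt$timestamp_local, 20, 24)
  tzh <- unique(as.integer(substr(off, 1, 3)))
  tz <- if (length(tzh) == 1 && !is.na(tzh)) sprintf("Etc/GMT%+d", -tzh) else "UTC"
  wbgt$timestamp_local <- as.POSIXct(wbgt$timestamp_local,
                                     format = "%Y-%m-%dT%H:%M:%S%z", tz = tz)
  wbgt
}
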