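# Independent oracles used across the suite. Each is written from scratch
# against the underlying definition, not by calling package internals.

# Solar zenith via the Astronomical Almanac low-precision formulae
# (Michalsky-style), independent of the NOAA formulation in the package.
oracle_zenith <- function(latitude, longitude, timestamp_local, tz_offset) {
  d2r <- pi / 180
  jd <- as.numeric(timestamp_local) / 86400 + 2440587.5
  n <- jd - 2451545
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- (357.528 + 0.9856003 * n) %% 360
  lambda <- L + 1.915 * sin(g * d2r) + 0.020 * sin(2 * g * d2r)
  eps <- 23.439 - 0.0000004 * n
  decl <- asin(sin(eps * d2r) * sin(lambda * d2r))
  ra <- atan2(cos(eps * d2r) * sin(lambda * d2r), cos(lambda * d2r))
  ut_hours <- ((jd - 0.5) %% 1) * 24
  gmst <- (6.697375 + 0.0657098242 * (jd - 2451545 - ut_hours / 24) +
             1.0027379 * ut_hours) %% 24
  lmst <- (gmst + longitude / 15) %% 24
  ha <- (lmst * 15 - ra / d2r)
  ha <- ((ha + 180) %% 360) - 180
  cosz <- sin(latitude * d2r) * sin(decl) +
    cos(latitude * d2r) * cos(decl) * cos(ha * d2r)
  acos(pmin(1, pmax(-1, cosz))) / d2r
}

# Globe temperature by bracketing bisection of the energy-balance residual,
# with its own convective-coefficient and air-property code.
oracle_globe_bisect <- function(Ta, u, Kdown, Kup, Ldown, Lup, F_frac,
                                zenith_deg, eps_g = 0.95, alpha_g = 0.05,
                                D = 0.15, sigma = 5.670374419e-8,
                                cosz_floor = 0.02, tol = 1e-4) {
  TaK <- Ta + 273.15
  cosz <- max(cos(zenith_deg * pi / 180), cosz_floor)
  hc_of <- function(TgK) {
    Tf <- (TgK + TaK) / 2
    k <- 0.02624 * (Tf / 300)^0.8646
    mu <- 1.458e-6 * Tf^1.5 / (Tf + 110.4)
    rho <- 101325 / (287.05 * Tf)
    Re <- max(u, 0.05) * D * rho / mu
    (2 + 0.6 * sqrt(Re) * 0.71^(1 / 3)) * k / D
  }
  resid <- function(TgK) {
    TgK^4 - ((Ldown + Lup) / (2 * sigma) -
               hc_of(TgK) * (TgK - TaK) / (eps_g * sigma) +
               Kdown * (1 - alpha_g) / (2 * eps_g * sigma) *
                 (1 - F_frac + F_frac / (2 * cosz)) +
               (1 - alpha_g) / (2 * eps_g * sigma) * Kup)
  }
  lo <- TaK - 5
  hi <- TaK + 80
  stopifnot(resid(lo) * resid(hi) <= 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (resid(lo) * resid(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2 - 273.15
}

# Work loss through the logistic identity 60 * plogis(p * log(W / W50)),
# an algebraically independent route to the same response.
oracle_work_loss <- function(WBGT) {
  ifelse(WBGT > 0, 60 * stats::plogis(6.33 * (log(WBGT) - log(33.63))), 0)
}

# Shift totals by an explicit triple loop over (day, hour-of-day, location).
oracle_shift_totals <- function(records, schedule = shift_schedule()) {
  records$work_loss_min <- as.numeric(work_loss(records$WBGT_C))
  days <- sort(unique(format(records$timestamp_local, "%Y-%m-%d")))
  locs <- unique(records$location_id)
  hr <- as.integer(format(records$timestamp_local, "%H"))
  dy <- format(records$timestamp_local, "%Y-%m-%d")
  out <- list()
  for (scen in unique(records$scenario)) {
    for (i in seq_len(nrow(schedule))) {
      s <- schedule$start_hour[i]; e <- schedule$end_hour[i]
      hours <- if (s < e) s:(e - 1) else c(s:23, 0:(e - 1))
      tot <- 0; wb <- c()
      for (d in days) {
        for (h in hours) {
          cell <- c()
          for (l in locs) {
            sel <- records$scenario == scen & dy == d & hr == h &
              records$location_id == l
            cell <- c(cell, records$work_loss_min[sel])
          }
          tot <- tot + mean(cell) / 60
          wb <- c(wb, mean(records$WBGT_C[records$scenario == scen &
                                            dy == d & hr == h]))
        }
      }
      out[[paste(scen, schedule$shift[i])]] <-
        data.frame(scenario = scen, shift = schedule$shift[i],
                   lost_hours = tot, mean_wbgt_C = mean(wb))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Piecewise-linear integral by explicit pairwise accumulation.
oracle_trapz <- function(y, dt = 1) {
  a <- 0
  for (i in seq_len(length(y) - 1)) a <- a + (y[i] + y[i + 1]) / 2 * dt
  a
}

# Small random daytime met samples; longwave fluxes are tied to the air and
# (warmer) surface temperatures so the globe equilibrium stays physical.
random_globe_samples <- function(n, seed = 1) {
  set.seed(seed)
  sigma <- 5.670374419e-8
  Ta <- runif(n, 5, 40)
  data.frame(
    Ta = Ta,
    u = runif(n, 0.2, 12),
    Kdown = runif(n, 30, 1000),
    F_frac = runif(n, 0, 0.9),
    zenith = runif(n, 5, 85),
    Ldown = runif(n, 0.80, 0.95) * sigma * (Ta + 273.15)^4,
    Lup = sigma * (Ta + runif(n, 5, 15) + 273.15)^4
  ) |> transform(Kup = 0.2 * Kdown)
}

# An hourly WBGT record table with randomized temperatures over one month.
random_month_records <- function(seed, n_locations = 2, scenarios = "baseline",
                                 year = 2020, month = 8) {
  set.seed(seed)
  n_days <- as.integer(seq(as.Date(sprintf("%d-%02d-01", year, month)),
                           by = "1 month", length.out = 2)[2] -
                         as.Date(sprintf("%d-%02d-01", year, month)))
  t0 <- as.POSIXct(sprintf("%d-%02d-01 00:00:00", year, month),
                   tz = "Etc/GMT+7")
  times <- t0 + 3600 * (seq_len(n_days * 24) - 1)
  expand.grid(
    timestamp_local = times,
    location_id = sprintf("loc%02d", seq_len(n_locations)),
    scenario = scenarios,
    stringsAsFactors = FALSE
  ) |> transform(WBGT_C = runif(n_days * 24 * n_locations * length(scenarios),
                                5, 38))
}
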