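test_that("Stull wet bulb matches frozen high-precision spot values", {
  expect_equal(wet_bulb_stull(20, 50), 13.699341968988140, tolerance = 1e-9)
  expect_equal(wet_bulb_stull(30, 60), 23.995518612319442, tolerance = 1e-9)
  # near saturation the wet bulb approaches the dry bulb
  expect_lt(30 - wet_bulb_stull(30, 99), 1.0)
})

test_that("Stull wet bulb stays below the dry bulb and flags range violations", {
  grid <- expand.grid(Ta = seq(-15, 45, by = 5), RH = seq(5, 99, by = 10))
  Tw <- wet_bulb_stull(grid$Ta, grid$RH)
  expect_true(all(Tw <= grid$Ta + 0.5))

  expect_warning(out <- wet_bulb_stull(25, 2), "validity window")
  expect_identical(attr(out, "out_of_range"), 1L)
  expect_error(wet_bulb_stull(NaN, 50), "non-missing")
})

test_that("globe temperature has the analytic radiative fixed point", {
  sig <- 5.670374419e-8
  Ta <- c(10, 25, 38)
  L <- sig * (Ta + 273.15)^4
  g <- globe_temperature(Ta, u = 4, Kdown = 0, Kup = 0, Ldown = L, Lup = L,
                         F_frac = 0, zenith_deg = 45)
  expect_equal(g$Tg_C, Ta, tolerance = 1e-9)
  expect_true(all(g$iterations == 1))
})

test_that("globe temperature increases with shortwave load", {
  base <- globe_temperature(28, 3, 400, 80, 350, 450, 0.8, 30)
  hot <- globe_temperature(28, 3, 800, 160, 350, 450, 0.8, 30)
  expect_gt(hot$Tg_C, base$Tg_C)
})

test_that("globe solver agrees with an independent bisection oracle", {
  s <- random_globe_samples(100, seed = 3)
  got <- globe_temperature(s$Ta, s$u, s$Kdown, s$Kup, s$Ldown, s$Lup,
                           s$F_frac, s$zenith)
  want <- mapply(oracle_globe_bisect, s$Ta, s$u, s$Kdown, s$Kup, s$Ldown,
                 s$Lup, s$F_frac, s$zenith)
  expect_lt(max(abs(got$Tg_C - want)), 0.04)
})

test_that("shade/night WBGT reproduces the branch arithmetic", {
  windy <- wbgt_no_sun(20, 30, 5)
  expect_equal(windy$WBGT_C, 23.0, tolerance = 1e-12)
  expect_identical(windy$branch, "no_sun_windy")

  calm1 <- wbgt_no_sun(20, 30, 1)
  expect_equal(calm1$WBGT_C, 23.3, tolerance = 1e-12)
  expect_identical(calm1$branch, "no_sun_calm")

  calm01 <- wbgt_no_sun(20, 30, 0.13)
  expect_equal(calm01$WBGT_C,
               0.67 * 20 + 0.33 * 30 - 0.048 * log10(0.13) * 10,
               tolerance = 1e-12)
  # sub-clamp winds are clamped, never an error
  expect_identical(wbgt_no_sun(20, 30, 0)$WBGT_C, calm01$WBGT_C)
})

test_that("sun WBGT is the exact weighted sum", {
  expect_equal(wbgt_sun(25, 25, 25), 25, tolerance = 1e-15)
  expect_equal(wbgt_sun(20, 40, 30), 25, tolerance = 1e-15)
  expect_equal(wbgt_sun(18.5, 45, 28), 24.75, tolerance = 1e-15)
})

test_that("the u = 3 branch discontinuity is bounded as documented", {
  set.seed(8)
  Tw <- runif(50, 5, 30)
  Ta <- Tw + runif(50, 0, 12)
  eq1 <- 0.7 * Tw + 0.3 * Ta
  eq2 <- wbgt_no_sun(Tw, Ta, rep(3, 50))$WBGT_C
  bound <- 0.048 * log10(3) * (Ta - Tw) + 0.03 * abs(Ta - Tw) + 0.03 * abs(Tw)
  expect_true(all(abs(eq1 - eq2) <= bound + 1e-12))
})

test_that("WBGT is non-decreasing in each component in the physical regime", {
  set.seed(9)
  Tw <- runif(30, 5, 28)
  Ta <- Tw + runif(30, 0, 10)
  Tg <- Ta + runif(30, 0, 25)
  u <- runif(30, 0.2, 8)
  d <- 0.5
  expect_true(all(wbgt_sun(Tw + d, Tg, Ta) >= wbgt_sun(Tw, Tg, Ta)))
  expect_true(all(wbgt_sun(Tw, Tg + d, Ta) >= wbgt_sun(Tw, Tg, Ta)))
  expect_true(all(wbgt_sun(Tw, Tg, Ta + d) >= wbgt_sun(Tw, Tg, Ta)))
  # within each shade branch (u fixed), raising Tw or Ta raises the index
  for (uu in c(1, 5)) {
    expect_true(all(wbgt_no_sun(Tw + d, Ta + d, uu)$WBGT_C >=
                      wbgt_no_sun(Tw, Ta, uu)$WBGT_C))
  }
})

test_that("series computation matches composing the scalar operations", {
  cfg <- campaign_config(n_locations = 1, seed = 5,
                         scenario_peak_cooling = c(baseline = 0))
  met <- generate_campaign(cfg)
  params <- globe_params()
  out <- compute_wbgt_series(met, params)

  expect_equal(nrow(out), nrow(met))
  sun <- met$Kdown_Wm2 > params$sun_kdown_threshold & met$zenith_deg < 90
  expect_identical(out$branch == "sun", sun)
  expect_true(all(is.na(out$Tg_C[!sun])))

  Tw <- wet_bulb_stull(met$Ta_C, met$RH_pct)
  ns <- wbgt_no_sun(Tw[!sun], met$Ta_C[!sun], met$u_ms[!sun])
  expect_equal(out$WBGT_C[!sun], ns$WBGT_C, tolerance = 1e-12)
  g <- globe_temperature(met$Ta_C[sun], met$u_ms[sun], met$Kdown_Wm2[sun],
                         met$Kup_Wm2[sun], met$Ldown_Wm2[sun],
                         met$Lup_Wm2[sun], met$F_frac[sun],
                         met$zenith_deg[sun], params)
  expect_equal(out$WBGT_C[sun], wbgt_sun(Tw[sun], g$Tg_C, met$Ta_C[sun]),
               tolerance = 1e-12)
})

test_that("an all-night series never solves the globe", {
  cfg <- campaign_config(n_locations = 1, seed = 5,
                         scenario_peak_cooling = c(baseline = 0))
  met <- generate_campaign(cfg)
  night <- met[met$zenith_deg >= 90, ]
  out <- compute_wbgt_series(night)
  expect_true(all(is.na(out$Tg_C)))
  expect_true(all(out$branch %in% c("no_sun_windy", "no_sun_calm")))

  windy <- night
  windy$u_ms <- 5
  ow <- compute_wbgt_series(windy)
  Tw <- wet_bulb_stull(windy$Ta_C, windy$RH_pct)
  expect_equal(ow$WBGT_C, 0.7 * Tw + 0.3 * windy$Ta_C, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("unsorted series are rejected", {
  cfg <- campaign_config(n_locations = 1, seed = 5,
                         scenario_peak_cooling = c(baseline = 0))
  met <- generate_campaign(cfg)
  expect_error(compute_wbgt_series(met[rev(seq_len(nrow(met))), ]),
               "chronologically sorted")
})
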