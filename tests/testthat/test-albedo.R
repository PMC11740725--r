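mk_stack <- function(value = 0.2, nr = 4, nc = 5, mask = NULL) {
  bands <- setNames(
    lapply(c("B2", "B3", "B4", "B8", "B11", "B12"),
           function(b) matrix(value, nr, nc)),
    c("B2", "B3", "B4", "B8", "B11", "B12"))
  band_stack(bands, resolution = 10, mask = mask)
}

test_that("broadband conversion is the weighted sum, with clipping", {
  coeffs <- albedo_coefficients()
  # all-zero reflectance with zero offset -> zero albedo
  z <- narrowband_to_broadband(mk_stack(0), coeffs)
  expect_true(all(z$values == 0))

  # uniform reflectance v with weights summing to S -> v*S + offset
  S <- sum(coeffs$weights)
  u <- narrowband_to_broadband(mk_stack(0.3), coeffs)
  expect_equal(as.numeric(u$values), rep(0.3 * S, 20), tolerance = 1e-12)

  # weighted sums above 1 clip to exactly 1, below 0 to exactly 0
  hot <- narrowband_to_broadband(mk_stack(1.4), coeffs)
  expect_true(all(hot$values == 1))
  neg <- narrowband_to_broadband(mk_stack(0.1),
                                 albedo_coefficients(offset = -0.5))
  expect_true(all(neg$values == 0))
})

test_that("clipping is idempotent", {
  st <- mk_stack(1.4)
  once <- narrowband_to_broadband(st)
  again <- pmax(pmin(once$values, 1), 0)
  expect_identical(once$values, again)
})

test_that("masks propagate and malformed stacks are rejected", {
  m <- matrix(TRUE, 4, 5)
  m[1, 1] <- FALSE
  alb <- narrowband_to_broadband(mk_stack(0.3, mask = m))
  expect_true(is.na(alb$values[1, 1]))
  expect_equal(sum(is.na(alb$values)), 1)

  bad <- list(B2 = matrix(0, 2, 2), B3 = matrix(0, 3, 3))
  expect_error(band_stack(bad), "identical dimensions")
  st <- mk_stack(0.2)
  st$bands$B12 <- NULL
  expect_error(narrowband_to_broadband(st), "missing from stack")
})

test_that("campus summary matches a brute-force accumulation", {
  const <- narrowband_to_broadband(mk_stack(0.3 / sum(albedo_coefficients()$weights)))
  s <- campus_summary(const)
  expect_equal(s$mean, 0.3, tolerance = 1e-12)
  expect_equal(s$min, 0.3, tolerance = 1e-12)
  expect_equal(s$max, 0.3, tolerance = 1e-12)

  two <- structure(list(values = matrix(c(0.1, 0.5), 1), mask = NULL),
                   class = "albedo_raster")
  s2 <- campus_summary(two)
  expect_equal(c(s2$mean, s2$min, s2$max), c(0.3, 0.1, 0.5), tolerance = 1e-12)

  set.seed(31)
  vals <- matrix(runif(200), 10, 20)
  rast <- structure(list(values = vals, mask = NULL), class = "albedo_raster")
  bnd <- matrix(runif(200) > 0.3, 10, 20)
  s3 <- campus_summary(rast, boundary = bnd)
  acc <- 0; cnt <- 0
  for (i in 1:10) for (j in 1:20) if (bnd[i, j]) {
    acc <- acc + vals[i, j]; cnt <- cnt + 1
  }
  expect_equal(s3$mean, acc / cnt, tolerance = 1e-12)
  expect_equal(s3$n, cnt)
  expect_error(campus_summary(rast, boundary = bnd & FALSE), "no unmasked")
})

test_that("scenario remapping reproduces every scenario-table cell", {
  tab <- scenario_table()
  for (ty in tab$surface_type) {
    for (sc in c("baseline", "low", "moderate", "high")) {
      mono <- matrix(ty, 3, 3)
      out <- apply_scenario(mono, tab, scenario = sc)
      expect_true(all(out$values == tab[[sc]][tab$surface_type == ty]))
    }
  }
  # integer-coded map with a legend
  leg <- setNames(tab$surface_type, seq_len(nrow(tab)))
  imap <- matrix(c(1L, 6L, 6L, 1L), 2, 2)
  out <- apply_scenario(imap, tab, scenario = "high", legend = leg)
  expect_equal(as.numeric(out$values), c(0.85, 0.30, 0.30, 0.85))
})

test_that("unknown surface types error unless passed through at baseline", {
  tab <- scenario_table()
  mp <- matrix(c("roofs", "gravel"), 1, 2)
  expect_error(apply_scenario(mp, tab, scenario = "low"), "unknown surface")
  base <- structure(list(values = matrix(c(0.28, 0.08), 1, 2), mask = NULL),
                    class = "albedo_raster")
  out <- apply_scenario(mp, tab, scenario = "low", passthrough = TRUE,
                        baseline_raster = base)
  expect_equal(as.numeric(out$values), c(0.63, 0.08))
})

test_that("mean campus albedo is monotone across scenarios for any surface map", {
  tab <- scenario_table()
  set.seed(41)
  for (rep in 1:5) {
    mp <- matrix(sample(tab$surface_type, 30, replace = TRUE), 5, 6)
    means <- vapply(c("baseline", "low", "moderate", "high"), function(sc) {
      campus_summary(apply_scenario(mp, tab, scenario = sc))$mean
    }, numeric(1))
    expect_true(all(diff(means) >= -1e-12))
  }
})

test_that("scenario table defaults validate and bad tables are rejected", {
  tab <- scenario_table()
  expect_true(all(tab$baseline <= tab$low & tab$low <= tab$moderate &
                    tab$moderate <= tab$high))
  bad <- tab
  bad$low[1] <- 0.1  # below baseline
  expect_error(scenario_table(bad), "baseline <= low")
  bad2 <- tab
  bad2$high[2] <- 1.2
  expect_error(scenario_table(bad2), "\\[0, 1\\]")
})

test_that("the delimited band reader round-trips a matrix", {
  m <- matrix(runif(12), 3, 4)
  f <- withr::local_tempfile(fileext = ".txt")
  write.table(m, f, row.names = FALSE, col.names = FALSE)
  expect_equal(unname(read_band_matrix(f)), m, tolerance = 1e-12)
})
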