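#' Narrow-to-broadband conversion coefficients for Sentinel-2-like bands
#'
#' Per-band weights and offset used to combine the blue, green, red (B2, B3,
#' B4), near-infrared (B8) and shortwave-infrared (B11, B12) surface
#' reflectances into a broadband shortwave albedo. The default set is the
#' published Sentinel-2 narrow-to-broadband regression of Bonafoni and
#' Sekertekin (weights 0.2266, 0.1236, 0.1573, 0.3417, 0.1170, 0.0338; zero
#' offset). Coefficients live in configuration, not code, so alternative
#' sensor sets can be swapped in.
#'
#' @param weights Named numeric vector of per-band weights.
#' @param offset Additive offset.
#' @return List with `weights` and `offset`.
#' @export
albedo_coefficients <- function(weights = c(B2 = 0.2266, B3 = 0.1236,
                                            B4 = 0.1573, B8 = 0.3417,
                                            B11 = 0.1170, B12 = 0.0338),
                                offset = 0) {
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("weights must be a named vector of band weights")
  }
  list(weights = weights, offset = offset)
}

#' Assemble a multiband reflectance stack
#'
#' @param bands Named list of numeric matrices (one per band), identical
#'   dimensions; values are unitless surface reflectances.
#' @param resolution Metres per pixel (metadata only).
#' @param mask Optional logical matrix, `TRUE` = valid pixel (cloud-free,
#'   in-scene). Defaults to all valid.
#' @return A `band_stack` list.
#' @export
band_stack <- function(bands, resolution = 10, mask = NULL) {
  if (!length(bands) || is.null(names(bands))) stop("bands must be a named list")
  dims <- lapply(bands, dim)
  if (any(vapply(dims, is.null, logical(1))) ||
      !all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all bands must be matrices with identical dimensions")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(bands[[1]]), ncol(bands[[1]]))
  if (!identical(dim(mask), dims[[1]])) stop("mask dimensions must match bands")
  structure(list(bands = bands, resolution = resolution, mask = mask),
            class = "band_stack")
}

#' Broadband albedo from narrowband reflectances
#'
#' Per-pixel weighted sum `offset + sum_b w_b * reflectance_b`, then clipped:
#' values above 1 (sensor noise, highly reflective materials) are set to 1
#' and values below 0 to 0. Masked pixels propagate as `NA`.
#'
#' @param stack A [band_stack()].
#' @param coefficients A coefficient set from [albedo_coefficients()]; every
#'   named band must be present in the stack.
#' @return An `albedo_raster` list with `values` (matrix, clipped to
#'   `[0, 1]`), `resolution`, `mask`.
#' @export
narrowband_to_broadband <- function(stack, coefficients = albedo_coefficients()) {
  stopifnot(inherits(stack, "band_stack"))
  missing <- setdiff(names(coefficients$weights), names(stack$bands))
  if (length(missing)) {
    stop("band(s) missing from stack: ", paste(missing, collapse = ", "))
  }
  alb <- matrix(coefficients$offset, nrow(stack$bands[[1]]),
                ncol(stack$bands[[1]]))
  for (b in names(coefficients$weights)) {
    alb <- alb + coefficients$weights[[b]] * stack$bands[[b]]
  }
  alb <- pmax(pmin(alb, 1), 0)  # matrix first: pmin/pmax keep its dims
  alb[!stack$mask] <- NA_real_
  structure(list(values = alb, resolution = stack$resolution,
                 mask = stack$mask),
            class = "albedo_raster")
}

#' Summary statistics of an albedo raster over a boundary
#'
#' Unweighted mean, minimum, maximum and a histogram over the unmasked pixels
#' inside the boundary.
#'
#' @param raster An `albedo_raster` from [narrowband_to_broadband()] or
#'   [apply_scenario()].
#' @param boundary Optional logical matrix selecting in-boundary pixels;
#'   defaults to the whole scene.
#' @param breaks Histogram breaks passed to [graphics::hist()] semantics via
#'   [base::cut()]; default 20 equal bins on `[0, 1]`.
#' @return List with `mean`, `min`, `max`, `n`, and `histogram` (counts per
#'   bin).
#' @export
campus_summary <- function(raster, boundary = NULL,
                           breaks = seq(0, 1, by = 0.05)) {
  stopifnot(inherits(raster, "albedo_raster"))
  v <- raster$values
  if (!is.null(boundary)) {
    if (!identical(dim(boundary), dim(v))) stop("boundary must match raster")
    v[!boundary] <- NA_real_
  }
  v <- v[!is.na(v)]
  if (!length(v)) stop("no unmasked pixels inside the boundary")
  counts <- table(cut(v, breaks = breaks, include.lowest = TRUE))
  list(mean = mean(v), min = min(v), max = max(v), n = length(v),
       histogram = counts)
}

#' Surface-type albedo scenarios
#'
#' The scenario table maps the six campus surface types to broadband albedos
#' under the current baseline and three hypothetical modification levels.
#' Defaults are the study scenarios: e.g. roofs 0.28 at baseline rising to
#' 0.85 under high modification, runways 0.15 rising to 0.30. Per surface
#' type the albedo is non-decreasing from baseline through low, moderate and
#' high.
#'
#' @param table Data.frame with columns `surface_type, baseline, low,
#'   moderate, high`, all albedos in `[0, 1]`.
#' @return Validated scenario table.
#' @export
scenario_table <- function(table = NULL) {
  if (is.null(table)) {
    table <- data.frame(
      surface_type = c("roofs", "aprons", "parking",
                       "roadways_shoulders_taxiways",
                       "unclassified_pavements", "runways"),
      baseline = c(0.28, 0.21, 0.18, 0.18, 0.19, 0.15),
      low      = c(0.63, 0.30, 0.30, 0.30, 0.35, 0.20),
      moderate = c(0.75, 0.35, 0.35, 0.35, 0.40, 0.25),
      high     = c(0.85, 0.40, 0.40, 0.40, 0.45, 0.30),
      stringsAsFactors = FALSE
    )
  }
  need <- c("surface_type", "baseline", "low", "moderate", "high")
  if (!all(need %in% names(table))) {
    stop("scenario table needs columns: ", paste(need, collapse = ", "))
  }
  vals <- as.matrix(table[, c("baseline", "low", "moderate", "high")])
  if (any(vals < 0 | vals > 1)) stop("all albedos must be in [0, 1]")
  if (any(apply(vals, 1, is.unsorted))) {
    stop("per surface type, albedo must satisfy baseline <= low <= moderate <= high")
  }
  table
}

#' Remap a surface-type map to scenario albedos
#'
#' Every pixel's albedo becomes the scenario albedo of its surface type.
#' Pixels whose type is not in the table either keep their baseline albedo
#' (`passthrough = TRUE`, requires `baseline_raster`) or raise an error.
#'
#' @param surface_map Character or integer matrix of surface types (integers
#'   are looked up in `legend`).
#' @param table Scenario table from [scenario_table()].
#' @param scenario One of `"baseline", "low", "moderate", "high"`.
#' @param legend Named character vector mapping integer codes to surface-type
#'   names (required for integer maps).
#' @param passthrough Keep unknown-type pixels at their baseline albedo.
#' @param baseline_raster `albedo_raster` supplying passthrough values.
#' @return An `albedo_raster`.
#' @export
apply_scenario <- function(surface_map, table = scenario_table(),
                           scenario = c("baseline", "low", "moderate", "high"),
                           legend = NULL, passthrough = FALSE,
                           baseline_raster = NULL) {
  scenario <- match.arg(scenario)
  table <- scenario_table(table)
  types <- surface_map
  if (is.numeric(types)) {
    if (is.null(legend)) stop("integer surface maps need a legend")
    types <- matrix(unname(legend[as.character(surface_map)]),
                    nrow(surface_map), ncol(surface_map))
  }
  known <- types %in% table$surface_type
  if (any(!known & !is.na(types)) && !passthrough) {
    stop("unknown surface type(s): ",
         paste(unique(types[!known & !is.na(types)]), collapse = ", "),
         " (set passthrough = TRUE to keep baseline values)")
  }
  vals <- matrix(NA_real_, nrow(types), ncol(types))
  idx <- match(types, table$surface_type)
  vals[] <- table[[scenario]][idx]
  if (passthrough && any(!known)) {
    if (is.null(baseline_raster)) {
      stop("passthrough requires a baseline_raster for unknown-type pixels")
    }
    vals[!known] <- baseline_raster$values[!known]
  }
  structure(list(values = vals, resolution = NULL,
                 mask = !is.na(vals)),
            class = "albedo_raster")
}

#' Read a single band as a matrix
#'
#' Reads either a plain whitespace/comma-delimited numeric matrix (the
#' text fallback used in tests and small scenes) or, when the `tiff` package
#' is available, a single-band TIFF raster.
#'
#' @param path File path; `.tif`/`.tiff` extensions dispatch to the TIFF
#'   reader, anything else to the delimited reader.
#' @return Numeric matrix of reflectances.
#' @export
read_band_matrix <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF bands requires the 'tiff' package")
    }
    m <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(m)) == 3) m <- m[, , 1]
    return(m)
  }
  as.matrix(utils::read.table(path, header = FALSE, sep = ""))
}
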