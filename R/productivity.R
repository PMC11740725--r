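#' Heat-induced work loss per working hour
#'
#' Logistic exposure-response between WBGT and physical work capacity (PWC),
#' fit to fixed-heart-rate chamber trials of unacclimatized workers performing
#' moderate-to-heavy work in normal attire:
#'
#' `work_loss = 60 - 60 / (1 + (33.63 / WBGT)^(-6.33))`
#'
#' i.e. minutes lost per hour out of 60. At WBGT = 33.63 C capacity is exactly
#' half (30 min/h lost); the response is strictly increasing in WBGT.
#' Non-positive WBGT returns 0 minutes lost (the expression is undefined
#' there and cold stress is out of scope) with the indices flagged in the
#' `nonpositive` attribute.
#'
#' @param WBGT Wet bulb globe temperature, degrees C (vectorized).
#' @return Minutes of work lost per hour, in `[0, 60]`.
#' @examples
#' work_loss(33.63)  # 30
#' @export
work_loss <- function(WBGT) {
  if (any(is.na(WBGT))) stop("WBGT must be non-missing")
  r <- WBGT / 33.63
  loss <- ifelse(WBGT > 0, 60 * r^6.33 / (1 + r^6.33), 0)
  loss <- pmin(60, pmax(0, loss))
  if (any(WBGT <= 0)) attr(loss, "nonpositive") <- which(WBGT <= 0)
  loss
}

#' Worker shift schedule
#'
#' The three 8-hour outdoor shifts: first 07-15, second 15-23, third 23-07
#' local time (start inclusive, end exclusive; the third shift crosses
#' midnight). The shifts partition the 24-hour day.
#'
#' @return Data.frame with `shift`, `start_hour`, `end_hour`.
#' @export
shift_schedule <- function() {
  data.frame(shift = c("first", "second", "third"),
             start_hour = c(7L, 15L, 23L),
             end_hour = c(15L, 23L, 7L),
             stringsAsFactors = FALSE)
}

# Map hour-of-day to shift name under a schedule; NA where uncovered.
assign_shift <- function(hour, schedule = shift_schedule()) {
  out <- rep(NA_character_, length(hour))
  for (i in seq_len(nrow(schedule))) {
    s <- schedule$start_hour[i]; e <- schedule$end_hour[i]
    sel <- if (s < e) hour >= s & hour < e else hour >= s | hour < e
    out[sel] <- schedule$shift[i]
  }
  out
}

#' Per-hour productivity records
#'
#' Attaches the work-loss response to an hourly WBGT table: minutes lost per
#' hour and the percent physical work capacity `100 * (1 - loss/60)`.
#'
#' @param wbgt Data.frame from [compute_wbgt_series()] (or any table with
#'   `WBGT_C`).
#' @return The input with `work_loss_min` and `pwc_pct` columns appended.
#' @export
productivity_records <- function(wbgt) {
  loss <- work_loss(wbgt$WBGT_C)
  attr(loss, "nonpositive") <- NULL
  wbgt$work_loss_min <- as.numeric(loss)
  wbgt$pwc_pct <- 100 * (1 - wbgt$work_loss_min / 60)
  wbgt
}

#' Aggregate hourly work loss to shifts over a month
#'
#' The response is applied to each hourly, per-location WBGT first; locations
#' are then averaged unweighted within each (day, hour) cell, and cells are
#' summed over the shift's hours and the month's days:
#' `lost_hours = sum over cells( mean over locations(work_loss) ) / 60`.
#' Because aggregation covers every day of the month, assembling the
#' midnight-crossing third shift is equivalent to binning samples by
#' hour-of-day, which is what is done. Mean WBGT is the unweighted mean over
#' the same cells. Missing hours are an error (no silent imputation).
#'
#' @param records Data.frame with `timestamp_local, location_id, scenario,
#'   WBGT_C` (work loss recomputed internally if absent).
#' @param schedule Shift schedule data.frame, see [shift_schedule()].
#' @return Data.frame with one row per (scenario, shift): `mean_wbgt_C`,
#'   `lost_hours`, `n_cells`, plus a `total` row per scenario covering all
#'   24 hours.
#' @export
shift_aggregate <- function(records, schedule = shift_schedule()) {
  if (!"work_loss_min" %in% names(records)) {
    records <- productivity_records(records)
  }
  hours <- as.integer(format(records$timestamp_local, "%H"))
  day <- format(records$timestamp_local, "%Y-%m-%d")

  # coverage check: every (location, scenario) must have every hour exactly once
  cover <- table(records$location_id, records$scenario, day, hours)
  if (any(cover != 1)) {
    bad <- which(cover != 1, arr.ind = TRUE)
    dn <- dimnames(cover)
    gaps <- apply(utils::head(bad, 10), 1, function(r) {
      sprintf("%s/%s %s %02d:00 (count %d)", dn[[1]][r[1]], dn[[2]][r[2]],
              dn[[3]][r[3]], as.integer(dn[[4]][r[4]]),
              cover[r[1], r[2], r[3], r[4]])
    })
    stop("incomplete hourly coverage; first gaps/duplicates:\n  ",
         paste(gaps, collapse = "\n  "))
  }

  records$shift <- assign_shift(hours, schedule)
  # mean over locations within each (scenario, day, hour) cell
  cell <- stats::aggregate(
    cbind(work_loss_min, WBGT_C) ~ scenario + day + hours + shift,
    data = cbind(records, day = day, hours = hours), FUN = mean)

  agg_one <- function(df, label) {
    data.frame(scenario = df$scenario[1], shift = label,
               mean_wbgt_C = mean(df$WBGT_C),
               lost_hours = sum(df$work_loss_min) / 60,
               n_cells = nrow(df), stringsAsFactors = FALSE)
  }
  parts <- lapply(split(cell, list(cell$scenario, cell$shift), drop = TRUE),
                  function(df) agg_one(df, df$shift[1]))
  totals <- lapply(split(cell, cell$scenario), function(df) agg_one(df, "total"))
  out <- do.call(rbind, c(parts, totals))
  rownames(out) <- NULL
  shift_order <- c(schedule$shift, "total")
  out[order(match(out$scenario, unique(records$scenario)),
            match(out$shift, shift_order)), , drop = FALSE]
}

#' Hours of productivity gained versus baseline
#'
#' Per shift: `gained = lost_hours(baseline) - lost_hours(scenario)`; the
#' total row is the sum over shifts. Negative values mean the scenario is
#' hotter than baseline.
#'
#' @param report Shift report from [shift_aggregate()] covering the baseline
#'   and at least one other scenario.
#' @param baseline Name of the reference scenario (default `"baseline"`).
#' @return Data.frame with one row per (scenario, shift) excluding the
#'   baseline itself: `hours_gained`, plus baseline and scenario mean WBGT.
#' @export
hours_gained <- function(report, baseline = "baseline") {
  if (!baseline %in% report$scenario) {
    stop("baseline scenario '", baseline, "' not present in report")
  }
  base <- report[report$scenario == baseline, ]
  scens <- setdiff(unique(report$scenario), baseline)
  out <- lapply(scens, function(sc) {
    r <- report[report$scenario == sc, ]
    m <- merge(base, r, by = "shift", suffixes = c("_baseline", "_scenario"))
    if (nrow(m) != nrow(base) || nrow(m) != nrow(r) ||
        any(m$n_cells_baseline != m$n_cells_scenario)) {
      stop("scenario '", sc, "' coverage does not match baseline")
    }
    data.frame(scenario = sc, shift = m$shift,
               mean_wbgt_baseline_C = m$mean_wbgt_C_baseline,
               mean_wbgt_scenario_C = m$mean_wbgt_C_scenario,
               hours_gained = m$lost_hours_baseline - m$lost_hours_scenario,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  shift_order <- c(setdiff(unique(report$shift), "total"), "total")
  out <- out[order(match(out$scenario, scens),
                   match(out$shift, shift_order)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Productivity area under the curve
#'
#' Trapezoidal integral of a chronological percent-PWC series: the sum over
#' consecutive pairs of `(pwc_i + pwc_{i+1})/2 * dt`, in percent-hours.
#'
#' @param pwc_pct Percent physical work capacity series (chronological).
#' @param times Optional `POSIXct` or numeric-hour timestamps; hourly spacing
#'   assumed when omitted.
#' @return Area in percent-hours.
#' @export
productivity_auc <- function(pwc_pct, times = NULL) {
  n <- length(pwc_pct)
  if (n < 2) stop("need at least two points for a trapezoidal area")
  dt <- if (is.null(times)) {
    rep(1, n - 1)
  } else {
    if (length(times) != n) stop("times must match pwc_pct length")
    d <- diff(as.numeric(times))
    if (inherits(times, "POSIXct")) d <- d / 3600
    if (any(d <= 0)) stop("times must be strictly increasing")
    d
  }
  sum((pwc_pct[-n] + pwc_pct[-1]) / 2 * dt)
}
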