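# Relative sea-level rise from annual tide-gauge series: 60-yr OLS trends,
# a 30->60-yr bridging regression for short records, and nearest-gauge
# assignment to sites.

#' Fit a linear sea-level trend over the most recent window
#'
#' Ordinary least squares of annual mean sea level on calendar year over the
#' most recent `window_years` of the record. A gauge must cover at least
#' `min_coverage` of the window with non-missing annual values; otherwise a
#' classed error (`tidalcarbon_trend_unavailable`) signals that the trend is
#' unavailable, distinct from any numerical failure.
#'
#' @param series A list or one-row data frame with `gauge_id`, `lat`, `lon`
#'   and parallel numeric vectors `years` and `msl` (mm; `NA` gaps allowed).
#' @param window_years Trend window length in years (default 60).
#' @param min_coverage Minimum fraction of the window with data (default 0.8,
#'   i.e. at least 48 of 60 years).
#' @return A `linear_trend` list: `gauge_id`, `lat`, `lon`, `slope` (mm
#'   yr^-1), `intercept` (mm, at year 0), `slope_se`, `n_years`, `window`
#'   (start/end years), `bridged = FALSE`.
#' @export
#' @examples
#' s <- list(gauge_id = "g1", lat = 40, lon = -74,
#'           years = 1960:2019, msl = 3 * (1960:2019) + 10)
#' fit_gauge_trend(s)$slope # 3
fit_gauge_trend <- function(series, window_years = 60, min_coverage = 0.8) {
  years <- series$years
  msl <- series$msl
  if (is.list(years)) years <- years[[1]]
  if (is.list(msl)) msl <- msl[[1]]
  stopifnot(length(years) == length(msl))
  end <- max(years[!is.na(msl)])
  start <- end - window_years + 1
  inwin <- years >= start & years <= end & !is.na(msl)
  n <- sum(inwin)
  if (n < min_coverage * window_years) {
    stop(errorCondition(
      sprintf("gauge %s: %d of %d annual values in window; need >= %.0f",
              series$gauge_id %||% "?", n, window_years,
              min_coverage * window_years),
      class = c("tidalcarbon_trend_unavailable", "error")))
  }
  fit <- lm(msl[inwin] ~ years[inwin])
  # noise-free series trip the "essentially perfect fit" warning; the
  # zero SE they produce is exactly what we want
  sm <- suppressWarnings(summary(fit))
  structure(list(
    gauge_id = series$gauge_id %||% NA_character_,
    lat = series$lat %||% NA_real_, lon = series$lon %||% NA_real_,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    slope_se = unname(sm$coefficients[2, 2]),
    n_years = n, window = c(start, end), bridged = FALSE),
    class = "linear_trend")
}

#' Rescale short-record trends to the 60-yr basis
#'
#' Gauges with only ~30 yr of record are brought onto the 60-yr scale through
#' an OLS bridge `trend60 ~ trend30` (with intercept) trained on gauges that
#' support both windows. Bridged slopes are flagged, and their standard error
#' combines the mapped gauge-level SE with the bridge's residual SE in
#' quadrature.
#'
#' @param pairs A data frame with columns `trend30` and `trend60` (mm yr^-1),
#'   one row per long-record training gauge; at least 3 rows.
#' @param shorts A list of `linear_trend` objects fitted on the 30-yr window.
#' @return A list of `linear_trend` objects on the 60-yr basis with
#'   `bridged = TRUE`; the bridge fit is attached as attribute `bridge`.
#' @export
bridge_short_records <- function(pairs, shorts) {
  stopifnot(is.data.frame(pairs))
  if (!all(c("trend30", "trend60") %in% names(pairs))) {
    stop("pairs must have columns trend30 and trend60", call. = FALSE)
  }
  if (nrow(pairs) < 3) {
    stop(errorCondition(
      sprintf("need >= 3 training pairs to bridge, got %d", nrow(pairs)),
      class = c("tidalcarbon_bridging_unavailable", "error")))
  }
  fit <- lm(trend60 ~ trend30, data = pairs)
  # exact training pairs trip the perfect-fit warning; sigma 0 is correct
  sigma <- suppressWarnings(summary(fit)$sigma)
  b <- coef(fit)
  out <- lapply(shorts, function(tr) {
    stopifnot(inherits(tr, "linear_trend"))
    tr$slope <- unname(b[1] + b[2] * tr$slope)
    tr$slope_se <- unname(sqrt((b[2] * tr$slope_se)^2 + sigma^2))
    tr$bridged <- TRUE
    tr
  })
  attr(out, "bridge") <- list(intercept = unname(b[1]), slope = unname(b[2]),
                              sigma = sigma, n_pairs = nrow(pairs))
  out
}

#' Assign the nearest gauge's RSLR trend to a site
#'
#' Haversine-nearest gauge among the usable trends; ties in distance are
#' broken toward the lexicographically smaller `gauge_id`.
#'
#' @param site A list or one-row data frame with `lat` and `lon`.
#' @param trends A list of `linear_trend` objects carrying `lat`/`lon`.
#' @return A list with `rslr` (mm yr^-1), `gauge_id`, `distance_km`,
#'   `bridged`.
#' @export
assign_rslr <- function(site, trends) {
  if (length(trends) == 0) {
    stop("no usable gauge trends to assign from", call. = FALSE)
  }
  lat <- vapply(trends, function(t) t$lat, numeric(1))
  lon <- vapply(trends, function(t) t$lon, numeric(1))
  ids <- vapply(trends, function(t) as.character(t$gauge_id), character(1))
  d <- haversine_km(site$lat, site$lon, lat, lon)
  ord <- order(d, ids)
  k <- ord[1]
  list(rslr = trends[[k]]$slope, gauge_id = ids[k], distance_km = d[k],
       bridged = trends[[k]]$bridged)
}

#' Fit trends for a whole gauge table and bridge short records
#'
#' Convenience wrapper over [fit_gauge_trend()] and [bridge_short_records()]:
#' gauges supporting the long window get a direct 60-yr trend (never a
#' bridged one); gauges supporting only the short window are bridged using
#' training pairs built from the long-record gauges.
#'
#' @param gauges A data frame in the long gauge schema (`gauge_id`, `lat`,
#'   `lon`, `year`, `msl_mm`).
#' @param window_long,window_short Long and short window lengths (60 / 30).
#' @param min_coverage Coverage fraction required within a window.
#' @return A list of `linear_trend` objects (60-yr basis), one per usable
#'   gauge.
#' @export
fit_all_gauges <- function(gauges, window_long = 60, window_short = 30,
                           min_coverage = 0.8) {
  stopifnot(is.data.frame(gauges))
  split_g <- split(gauges, gauges$gauge_id)
  to_series <- function(g) list(gauge_id = g$gauge_id[1], lat = g$lat[1],
                                lon = g$lon[1], years = g$year, msl = g$msl_mm)
  long <- list(); short <- list(); pairs <- list()
  for (g in split_g) {
    s <- to_series(g)
    t60 <- tryCatch(fit_gauge_trend(s, window_long, min_coverage),
                    tidalcarbon_trend_unavailable = function(e) NULL)
    t30 <- tryCatch(fit_gauge_trend(s, window_short, min_coverage),
                    tidalcarbon_trend_unavailable = function(e) NULL)
    if (!is.null(t60)) {
      long[[s$gauge_id]] <- t60
      if (!is.null(t30)) {
        pairs[[s$gauge_id]] <- data.frame(trend30 = t30$slope,
                                          trend60 = t60$slope)
      }
    } else if (!is.null(t30)) {
      short[[s$gauge_id]] <- t30
    }
  }
  if (length(short) > 0) {
    pairs_df <- do.call(rbind, pairs)
    bridged <- bridge_short_records(pairs_df, unname(short))
    long <- c(long, bridged)
  }
  unname(long)
}

#' Attach RSLR to every site in a table
#'
#' @param sites A sites data frame with `lat`/`lon`.
#' @param trends A list of `linear_trend` objects.
#' @return `sites` with columns `rslr_mm_yr`, `rslr_gauge_id`,
#'   `rslr_distance_km` overwritten/added.
#' @export
assign_rslr_sites <- function(sites, trends) {
  res <- lapply(seq_len(nrow(sites)), function(i) {
    assign_rslr(list(lat = sites$lat[i], lon = sites$lon[i]), trends)
  })
  sites$rslr_mm_yr <- vapply(res, `[[`, numeric(1), "rslr")
  sites$rslr_gauge_id <- vapply(res, `[[`, character(1), "gauge_id")
  sites$rslr_distance_km <- vapply(res, `[[`, numeric(1), "distance_km")
  sites
}
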