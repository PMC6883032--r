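# Upscaling site CAR to a polygon inventory: 100-km-radius interpolation
# with regional fallback, per-polygon fluxes, quadrature error propagation
# for sums, and the two simpler national estimators.

#' Sites within a radius of a polygon centroid
#'
#' Haversine distance on the 6371-km sphere; the boundary is inclusive (a
#' site at exactly `radius_km` counts as a neighbor).
#'
#' @param polygon A list or one-row data frame with `lat` and `lon`.
#' @param sites A sites data frame with `lat`/`lon`.
#' @param radius_km Search radius in km (> 0; default 100).
#' @return The subset of `sites` within the radius, with a `distance_km`
#'   column appended.
#' @export
neighbors_within <- function(polygon, sites, radius_km = 100) {
  assert_number(radius_km, "radius_km", lower = 1e-9)
  d <- haversine_km(polygon$lat, polygon$lon, sites$lat, sites$lon)
  keep <- d <= radius_km
  out <- sites[keep, , drop = FALSE]
  out$distance_km <- d[keep]
  out
}

#' Regional CAR summary statistics from a site table
#'
#' Mean, standard error of the mean, and n of CAR per region, the fallback
#' statistics for polygons with fewer than two neighboring sites.
#'
#' @param sites Sites data frame with `region` and `car_gC_m2_yr`.
#' @return A tibble with `region`, `car_mean`, `car_se`, `n`.
#' @export
regional_car_stats <- function(sites) {
  sites |>
    dplyr::filter(!is.na(.data$car_gC_m2_yr)) |>
    dplyr::group_by(region = .data$region) |>
    dplyr::summarise(car_mean = mean(.data$car_gC_m2_yr),
                     car_se = sd(.data$car_gC_m2_yr) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
}

#' Interpolate CAR onto one wetland polygon
#'
#' With at least two sites inside the radius, the polygon takes the
#' unweighted mean of neighbor CARs with SE = sample SD / sqrt(n). Polygons
#' with no or only one neighbor fall back to their region's mean CAR and the
#' regional mean's SE. `ci95 = 1.96 * car_se` throughout.
#'
#' @param polygon A one-row data frame or list with `polygon_id`, `lat`,
#'   `lon`, `area_km2`, `region` (and optionally `vegetation`, `state`).
#' @param sites Sites data frame with coordinates and `car_gC_m2_yr`.
#' @param regional_stats Output of [regional_car_stats()] (or any table with
#'   `region`, `car_mean`, `car_se`).
#' @param radius_km Interpolation radius, km (default 100).
#' @return A one-row tibble: `polygon_id`, `car_mean`, `car_se`, `ci95`,
#'   `n_neighbors`, `method`, `flux` and `flux_se` (Tg yr^-1).
#' @export
interpolate_car <- function(polygon, sites, regional_stats, radius_km = 100) {
  nb <- neighbors_within(polygon, sites, radius_km)
  nb <- nb[!is.na(nb$car_gC_m2_yr), , drop = FALSE]
  n <- nrow(nb)
  if (n >= 2) {
    car_mean <- mean(nb$car_gC_m2_yr)
    car_se <- sd(nb$car_gC_m2_yr) / sqrt(n)
    method <- "interpolated"
  } else {
    row <- regional_stats[regional_stats$region == polygon$region, ]
    if (nrow(row) != 1) {
      stop("regional_stats has no row for region '", polygon$region, "'",
           call. = FALSE)
    }
    car_mean <- row$car_mean
    car_se <- row$car_se
    method <- "regional_fallback"
  }
  tibble::tibble(
    polygon_id = polygon$polygon_id, region = polygon$region,
    state = polygon$state %||% NA_character_,
    vegetation = polygon$vegetation %||% NA_character_,
    area_km2 = polygon$area_km2,
    car_mean = car_mean, car_se = car_se, ci95 = 1.96 * car_se,
    n_neighbors = n, method = method,
    flux = car_mean * polygon$area_km2 * 1e-6,
    flux_se = car_se * polygon$area_km2 * 1e-6)
}

#' Upscale CAR onto a whole polygon inventory
#'
#' Vectorized driver for [interpolate_car()]: one distance computation per
#' polygon-site pair, then the neighbor-mean / regional-fallback rule.
#'
#' @param polygons Inventory data frame (`polygon_id`, `lat`, `lon`,
#'   `area_km2`, `vegetation`, `region`, `state`).
#' @inheritParams interpolate_car
#' @return A tibble of per-polygon estimates, one row per polygon, same
#'   columns as [interpolate_car()].
#' @export
upscale_inventory <- function(polygons, sites, regional_stats = NULL,
                              radius_km = 100) {
  assert_number(radius_km, "radius_km", lower = 1e-9)
  if (is.null(regional_stats)) regional_stats <- regional_car_stats(sites)
  ok <- !is.na(sites$car_gC_m2_yr)
  s <- sites[ok, , drop = FALSE]
  # npoly x nsites distance matrix; inventories here are small enough that
  # the dense matrix is cheaper than per-polygon scans
  dm <- geosphere::distm(cbind(polygons$lon, polygons$lat),
                         cbind(s$lon, s$lat),
                         fun = function(p1, p2)
                           geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  within <- dm <= radius_km
  n_nb <- rowSums(within)
  car_mean <- car_se <- numeric(nrow(polygons))
  for (i in seq_len(nrow(polygons))) {
    if (n_nb[i] >= 2) {
      v <- s$car_gC_m2_yr[within[i, ]]
      car_mean[i] <- mean(v)
      car_se[i] <- sd(v) / sqrt(length(v))
    } else {
      row <- regional_stats[regional_stats$region == polygons$region[i], ]
      if (nrow(row) != 1) {
        stop("regional_stats has no row for region '", polygons$region[i],
             "'", call. = FALSE)
      }
      car_mean[i] <- row$car_mean
      car_se[i] <- row$car_se
    }
  }
  tibble::tibble(
    polygon_id = polygons$polygon_id, region = polygons$region,
    state = polygons$state, vegetation = polygons$vegetation,
    area_km2 = polygons$area_km2,
    car_mean = car_mean, car_se = car_se, ci95 = 1.96 * car_se,
    n_neighbors = n_nb,
    method = ifelse(n_nb >= 2, "interpolated", "regional_fallback"),
    flux = car_mean * polygons$area_km2 * 1e-6,
    flux_se = car_se * polygons$area_km2 * 1e-6)
}

#' Per-polygon carbon flux from a CAR estimate
#'
#' `flux (Tg yr^-1) = CAR (g C m^-2 yr^-1) x area (km^2) x 1e-6`.
#'
#' @param car_mean,car_se CAR mean and SE, g C m^-2 yr^-1.
#' @param area_km2 Polygon area, km^2.
#' @return A list with `flux` and `flux_se` in Tg yr^-1.
#' @export
#' @examples
#' polygon_flux(100, 0, 1)$flux # 1e-4 Tg yr^-1
polygon_flux <- function(car_mean, car_se = 0, area_km2) {
  assert_number(area_km2, "area_km2", lower = 0)
  list(flux = car_mean * area_km2 * 1e-6, flux_se = car_se * area_km2 * 1e-6)
}

#' Aggregate polygon fluxes with quadrature error propagation
#'
#' Sums fluxes within groups at the requested level and propagates standard
#' errors assuming independent polygon errors:
#' `se_sum = sqrt(sum(se_i^2))`, `ci95 = z * se_sum`.
#'
#' @param estimates Per-polygon estimate table (needs `flux`, `flux_se` and
#'   the grouping column for the chosen level).
#' @param level One of `"national"`, `"region"`, `"state"`, `"vegetation"`.
#' @param z CI multiplier (default 1.96 for 95%).
#' @return A tibble with `level`, `label`, `total_flux`, `flux_se`, `ci95`,
#'   `n_polygons`.
#' @export
aggregate_flux <- function(estimates, level = c("national", "region", "state",
                                                "vegetation"), z = 1.96) {
  level <- match.arg(level)
  if (nrow(estimates) == 0) {
    warning("no estimates to aggregate; returning zero totals", call. = FALSE)
    return(tibble::tibble(level = level, label = NA_character_,
                          total_flux = 0, flux_se = 0, ci95 = 0,
                          n_polygons = 0L))
  }
  key <- switch(level, national = NULL, region = "region", state = "state",
                vegetation = "vegetation")
  grouped <- if (is.null(key)) {
    dplyr::mutate(estimates, .label = "CONUS")
  } else {
    dplyr::mutate(estimates, .label = .data[[key]])
  }
  grouped |>
    dplyr::group_by(label = .data$.label) |>
    dplyr::summarise(total_flux = sum(.data$flux),
                     flux_se = sqrt(sum(.data$flux_se^2)),
                     n_polygons = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(level = level, ci95 = z * .data$flux_se) |>
    dplyr::select("level", "label", "total_flux", "flux_se", "ci95",
                  "n_polygons")
}

#' National totals by the uniform and stratified estimators
#'
#' `upscale_uniform()` applies one mean CAR to the whole wetland area;
#' `upscale_stratified()` multiplies group means (per region or vegetation)
#' by their areas and sums.
#'
#' @param mean_car Mean CAR, g C m^-2 yr^-1.
#' @param total_area Total wetland area, km^2.
#' @return Total flux in Tg yr^-1.
#' @export
#' @examples
#' upscale_uniform(161.8, 25892) # 4.189 -> the ~4.19 Tg national figure
upscale_uniform <- function(mean_car, total_area) {
  assert_number(mean_car, "mean_car", lower = 0)
  assert_number(total_area, "total_area", lower = 0)
  mean_car * sum(total_area) * 1e-6
}

#' @rdname upscale_uniform
#' @param group_means Named numeric vector of group mean CARs.
#' @param group_areas Named numeric vector of group areas, km^2; names must
#'   match `group_means`.
#' @export
upscale_stratified <- function(group_means, group_areas) {
  if (is.null(names(group_means)) || is.null(names(group_areas)) ||
      !setequal(names(group_means), names(group_areas))) {
    stop("group_means and group_areas must share the same names",
         call. = FALSE)
  }
  areas <- group_areas[names(group_means)]
  sum(group_means * areas) * 1e-6
}

#' Relative underestimation of a group mean by a reference mean
#'
#' `100 * (group_mean - reference_mean) / group_mean`: how much of a group's
#' CAR is missed when a coarser (e.g. national) mean is used in its place.
#'
#' @param group_mean Group mean CAR (> 0).
#' @param reference_mean The coarser reference mean.
#' @param digits Rounding for reporting; `NULL` (default) returns full
#'   precision.
#' @return Percent underestimation.
#' @export
#' @examples
#' underestimation_pct(271.9, 161.8, digits = 0) # 40
underestimation_pct <- function(group_mean, reference_mean, digits = NULL) {
  assert_number(group_mean, "group_mean", lower = 1e-12)
  assert_number(reference_mean, "reference_mean")
  out <- 100 * (group_mean - reference_mean) / group_mean
  if (!is.null(digits)) out <- round(out, digits)
  out
}
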