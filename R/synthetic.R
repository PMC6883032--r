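# Synthetic study system: site networks, tide-gauge records, polygon
# inventories and scenario trajectories with the statistical structure the
# analysis assumes, so every downstream stage is testable offline.

#' Default regional and vegetation parameter tables
#'
#' The regional table carries per-region CAR and SAR means, standard errors
#' and sample sizes, the regional RSLR, and wetland area; the vegetation
#' table carries per-class carbon density statistics and areas. These are
#' the generator defaults and the printed inputs for the aggregate checks.
#'
#' @return A tibble.
#' @export
default_region_table <- function() {
  tibble::tibble(
    region = c("Mid Atlantic", "New England", "South Atlantic-Gulf",
               "Lower Mississippi", "Texas-Gulf", "California",
               "Pacific Northwest"),
    car_mean = c(176.5, 151.3, 123.6, 271.9, 237.8, 103.8, 110.2),
    car_se = c(14, 11, 11, 18, 16, 8, 6),
    car_n = c(85, 64, 69, 43, 2, 36, 11),
    sar_mean = c(4.46, 3.72, 3.95, 8.89, 5.30, 4.79, 3.27),
    sar_se = c(0.33, 0.22, 0.34, 0.44, 0.9, 0.43, 0.39),
    sar_n = c(90, 78, 68, 43, 2, 40, 11),
    rslr = c(3.82, 2.78, 2.95, 8.91, 6.59, 1.98, 0.98),
    area_km2 = c(3844, 512, 10359, 8193, 2340, 269, 373))
}

#' @rdname default_region_table
#' @export
default_vegetation_table <- function() {
  tibble::tibble(
    vegetation = c("tidal_freshwater", "brackish", "salt_marsh", "mangrove"),
    cdensity_mean = c(0.038, 0.042, 0.035, 0.046),
    cdensity_se = c(0.003, 0.002, 0.001, 0.002),
    cdensity_n = c(44, 86, 175, 28),
    area_km2 = c(4828.8, 5233.5, 13157.3, 2672.4))
}

#' Configuration for the synthetic study system
#'
#' Defaults reproduce the regional and vegetation summary structure of the
#' national compilation: regional CAR / SAR means and standard errors (with
#' their sample sizes), regional RSLR and wetland areas, vegetation-level
#' carbon densities and area shares, and a target CAR-RSLR correlation of
#' 0.40. Site-level spread is `se * sqrt(n)`, so regional sample means
#' recover the configured values at the configured precision.
#'
#' @param seed Root seed; all generators draw from named substreams of it.
#' @param n_sites_per_region Sites generated per region.
#' @param n_polygons_per_region Inventory polygons per region.
#' @param n_gauges Number of tide gauges.
#' @param regions Regional parameter table (columns `region`, `car_mean`,
#'   `car_se`, `car_n`, `sar_mean`, `sar_se`, `sar_n`, `rslr`, `area_km2`).
#' @param vegetation Vegetation parameter table (columns `vegetation`,
#'   `cdensity_mean`, `cdensity_se`, `cdensity_n`, `area_km2`).
#' @param car_rslr_corr Target Pearson correlation between site CAR and RSLR.
#' @param polygon_area_lognorm_mu,polygon_area_lognorm_sigma Log-km^2
#'   parameters of the raw polygon-area distribution (rescaled per region to
#'   the configured regional total).
#' @param gauge_trend_range Width (mm yr^-1) of the uniform spread of gauge
#'   true trends around their region's RSLR.
#' @param gauge_noise_sd Annual sea-level noise SD, mm.
#' @param short_gauge_fraction Fraction of gauges with only the most recent
#'   30 annual values.
#' @param source_sd SD (g C m^-2 yr^-1) of a shared within-source CAR
#'   offset; 0 (default) means sites are independent across sources.
#' @param rslr_jitter_sd SD (mm yr^-1) of site-level RSLR around the
#'   regional value.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1, n_sites_per_region = 50,
                         n_polygons_per_region = 60, n_gauges = 40,
                         regions = default_region_table(),
                         vegetation = default_vegetation_table(),
                         car_rslr_corr = 0.40,
                         polygon_area_lognorm_mu = 2,
                         polygon_area_lognorm_sigma = 1.2,
                         gauge_trend_range = 2, gauge_noise_sd = 20,
                         short_gauge_fraction = 0.25, source_sd = 0,
                         rslr_jitter_sd = 0.3) {
  if (n_sites_per_region <= 0 || n_polygons_per_region < 0 || n_gauges <= 0) {
    stop("counts must be positive", call. = FALSE)
  }
  stopifnot(is.data.frame(regions), is.data.frame(vegetation))
  if (any(regions$car_se < 0) || any(regions$sar_se < 0) ||
      any(vegetation$cdensity_se < 0)) {
    stop("standard errors must be >= 0", call. = FALSE)
  }
  share <- vegetation$area_km2 / sum(vegetation$area_km2)
  if (abs(sum(share) - 1) > 1e-9) stop("vegetation shares must sum to 1")
  assert_number(car_rslr_corr, "car_rslr_corr", lower = -1, upper = 1)
  assert_number(short_gauge_fraction, "short_gauge_fraction", 0, 1)
  assert_number(gauge_noise_sd, "gauge_noise_sd", lower = 0)
  assert_number(source_sd, "source_sd", lower = 0)
  structure(list(
    seed = as.integer(seed), n_sites_per_region = as.integer(n_sites_per_region),
    n_polygons_per_region = as.integer(n_polygons_per_region),
    n_gauges = as.integer(n_gauges), regions = regions,
    vegetation = vegetation, veg_area_share = setNames(share,
                                                       vegetation$vegetation),
    car_rslr_corr = car_rslr_corr,
    polygon_area_lognorm_mu = polygon_area_lognorm_mu,
    polygon_area_lognorm_sigma = polygon_area_lognorm_sigma,
    gauge_trend_range = gauge_trend_range, gauge_noise_sd = gauge_noise_sd,
    short_gauge_fraction = short_gauge_fraction, source_sd = source_sd,
    rslr_jitter_sd = rslr_jitter_sd), class = "synth_config")
}

#' Schematic coastal geography for the seven regions
#'
#' Bounding boxes in decimal degrees approximating the real coastal
#' positions of the seven watershed groups (so that haversine distances are
#' realistic), with `n_clusters` cluster centres per region used to place
#' sites and polygons. The geography is schematic: the analysis needs
#' distances and labels, not real shapes.
#'
#' @param n_clusters Cluster centres per region.
#' @param seed Seed for the centre placement.
#' @return A tibble with `region`, box edges, and list-columns of cluster
#'   centre coordinates.
#' @export
region_layout <- function(n_clusters = 5, seed = 42) {
  boxes <- tibble::tibble(
    region = c("New England", "Mid Atlantic", "South Atlantic-Gulf",
               "Lower Mississippi", "Texas-Gulf", "California",
               "Pacific Northwest"),
    lon_min = c(-73.5, -77.5, -82.5, -92.0, -97.5, -123.0, -124.6),
    lon_max = c(-67.0, -73.5, -76.0, -88.5, -93.5, -117.0, -122.0),
    lat_min = c(41.0, 37.0, 25.0, 29.0, 26.0, 32.5, 42.0),
    lat_max = c(45.0, 41.0, 35.0, 31.0, 29.5, 38.5, 48.5),
    states = list(c("MA", "ME", "CT"), c("NJ", "MD", "VA"),
                  c("NC", "GA", "FL"), c("LA", "MS"), c("TX"),
                  c("CA"), c("OR", "WA")))
  withr::with_seed(seed, {
    boxes$centers <- lapply(seq_len(nrow(boxes)), function(i) {
      cbind(lon = runif(n_clusters, boxes$lon_min[i], boxes$lon_max[i]),
            lat = runif(n_clusters, boxes$lat_min[i], boxes$lat_max[i]))
    })
  })
  boxes
}

# place n points near a region's cluster centres, clipped to the box
place_in_region <- function(n, box_row, jitter_sd = 0.3) {
  centers <- box_row$centers[[1]]
  pick <- sample.int(nrow(centers), n, replace = TRUE)
  lon <- centers[pick, "lon"] + rnorm(n, 0, jitter_sd)
  lat <- centers[pick, "lat"] + rnorm(n, 0, jitter_sd)
  tibble::tibble(
    lon = pmin(pmax(lon, box_row$lon_min), box_row$lon_max),
    lat = pmin(pmax(lat, box_row$lat_min), box_row$lat_max))
}

state_from_latitude <- function(lat, box_row) {
  states <- box_row$states[[1]]
  breaks <- seq(box_row$lat_min, box_row$lat_max,
                length.out = length(states) + 1)
  states[pmin(findInterval(lat, breaks, rightmost.closed = TRUE),
              length(states))]
}

rtruncnorm0 <- function(n, mean, sd, lower = 0) {
  pmax(rnorm(n, mean, sd), lower)
}

# Noise component that moves cor(car0 + noise, rslr) to the target: adds
# independent noise when the realized correlation overshoots, or an
# RSLR-aligned component when it falls short.
calibrate_car_noise <- function(car0, rslr, rho_target) {
  s0 <- sd(car0)
  if (s0 < 1e-12 || sd(rslr) < 1e-12) return(numeric(length(car0)))
  rho0 <- cor(car0, rslr)
  if (abs(rho0 - rho_target) < 0.005) return(numeric(length(car0)))
  if (abs(rho0) > abs(rho_target) && sign(rho0) == sign(rho_target)) {
    sigma <- s0 * sqrt((rho0 / rho_target)^2 - 1)
    return(rnorm(length(car0), 0, sigma))
  }
  z <- rslr - mean(rslr)
  f <- function(lam) cor(car0 + lam * z, rslr) - rho_target
  hi <- 10 * s0 / sd(rslr)
  lam <- tryCatch(uniroot(f, c(0, hi))$root, error = function(e) hi)
  lam * z
}

#' Generate a synthetic site network
#'
#' Per region, sites get a sediment accretion rate drawn around the regional
#' mean (SD = se * sqrt(n)), a site RSLR jittered around the regional value,
#' a vegetation class sampled by area share with a carbon density drawn per
#' vegetation, and a salinity consistent with the class boundaries. CAR is
#' the identity `c_density * SAR * 1000` plus a stored noise term
#' (`car_noise`): within each region CAR is standardized to the configured
#' regional mean and SD, then one calibration component brings the realized
#' all-site Pearson correlation between CAR and RSLR to the configured
#' target, and CAR is floored at zero. Sites carry a `source_id` grouping
#' label of 5-10 sites each.
#'
#' @param config A [synth_config()].
#' @return A tibble in the sites schema (see [read_sites()]); the invariant
#'   `car_gC_m2_yr == c_density_gC_cm3 * sar_mm_yr * 1000 + car_noise` holds
#'   exactly.
#' @export
generate_sites <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  layout <- region_layout()
  veg <- config$vegetation
  withr::with_seed(substream_seed(config$seed, "sites"), {
    per_region <- lapply(seq_len(nrow(config$regions)), function(i) {
      rg <- config$regions[i, ]
      box <- layout[layout$region == rg$region, ]
      n <- config$n_sites_per_region
      coords <- place_in_region(n, box)
      sar_sd <- rg$sar_se * sqrt(rg$sar_n)
      sar <- rtruncnorm0(n, rg$sar_mean, sar_sd, lower = 0.1)
      vclass <- sample(veg$vegetation, n, replace = TRUE,
                       prob = config$veg_area_share)
      vi <- match(vclass, veg$vegetation)
      cd_sd <- veg$cdensity_se[vi] * sqrt(veg$cdensity_n[vi])
      cd <- pmin(pmax(rnorm(n, veg$cdensity_mean[vi], cd_sd), 0.005), 0.59)
      salinity <- numeric(n)
      salinity[vclass == "tidal_freshwater"] <-
        runif(sum(vclass == "tidal_freshwater"), 0, 0.49)
      salinity[vclass == "brackish"] <- runif(sum(vclass == "brackish"),
                                              0.5, 18)
      salinity[vclass == "salt_marsh"] <- runif(sum(vclass == "salt_marsh"),
                                                18.1, 35)
      salinity[vclass == "mangrove"] <- runif(sum(vclass == "mangrove"),
                                              18, 36)
      rslr <- rg$rslr + rnorm(n, 0, config$rslr_jitter_sd)
      tibble::tibble(
        region = rg$region, state = state_from_latitude(coords$lat, box),
        lat = coords$lat, lon = coords$lon, vegetation = vclass,
        marsh_zone = ifelse(vclass == "salt_marsh",
                            sample(c("high", "low"), n, replace = TRUE),
                            NA_character_),
        salinity_ppt = salinity, sar_mm_yr = sar, c_density_gC_cm3 = cd,
        rslr_mm_yr = rslr,
        car_target_mean = rg$car_mean,
        car_target_sd = rg$car_se * sqrt(rg$car_n))
    })
    sites <- dplyr::bind_rows(per_region)
    base <- sites$c_density_gC_cm3 * sites$sar_mm_yr * 1000
    # standardize within region to the configured CAR mean/SD (degenerate
    # configs with zero spread keep the raw identity value)
    car0 <- base
    for (r in unique(sites$region)) {
      idx <- sites$region == r
      m <- mean(base[idx]); s <- sd(base[idx])
      tgt_sd <- sites$car_target_sd[idx][1]
      if (s > 1e-9 && tgt_sd > 0) {
        car0[idx] <- sites$car_target_mean[idx][1] +
          tgt_sd * (base[idx] - m) / s
      }
    }
    n_all <- nrow(sites)
    # source-of-reference grouping: chunks of 5-10 consecutive sites
    src_sizes <- c()
    while (sum(src_sizes) < n_all) {
      src_sizes <- c(src_sizes, sample(5:10, 1))
    }
    source_id <- rep(sprintf("src%03d", seq_along(src_sizes)),
                     times = src_sizes)[seq_len(n_all)]
    src_eff <- if (config$source_sd > 0) {
      eff <- rnorm(length(unique(source_id)), 0, config$source_sd)
      eff[match(source_id, unique(source_id))]
    } else {
      numeric(n_all)
    }
    recenter_floor <- function(car) {
      # flooring at zero drags low-CAR regions upward; re-center each
      # region on its configured mean (clipped mass is small, so a few
      # passes converge)
      for (pass in 1:4) {
        for (r in unique(sites$region)) {
          idx <- sites$region == r
          tgt <- config$regions$car_mean[config$regions$region == r]
          car[idx] <- car[idx] + (tgt - mean(car[idx]))
        }
        car <- pmax(car, 0)
      }
      car
    }
    noise_free <- all(config$regions$car_se == 0) &&
      all(config$regions$sar_se == 0) &&
      all(config$vegetation$cdensity_se == 0) && config$source_sd == 0
    car <- car0 + src_eff
    if (!noise_free && sd(car) > 1e-9) {
      car <- recenter_floor(pmax(car, 0))
      # iterate calibration because the floor + re-centering shift the
      # realized correlation slightly
      for (it in 1:3) {
        if (abs(cor(car, sites$rslr_mm_yr) - config$car_rslr_corr) < 0.015)
          break
        car <- recenter_floor(
          car + calibrate_car_noise(car, sites$rslr_mm_yr,
                                    config$car_rslr_corr))
      }
    } else {
      car <- pmax(car, 0)
    }
    sites$car_gC_m2_yr <- car
    sites$car_noise <- car - base
    sites$source_id <- source_id
    sites$site_id <- sprintf("site%04d", seq_len(n_all))
    sites$tair_c <- 26 - 0.5 * sites$lat + rnorm(n_all, 0, 1)
    sites$prcp_mm_yr <- rtruncnorm0(n_all, 1300 - 8 * abs(sites$lon + 95),
                                    150, lower = 100)
    sites$dating_method <- sample(c("Pb210", "Cs137", "SET"), n_all,
                                  replace = TRUE, prob = c(0.5, 0.42, 0.08))
    sites$car_target_mean <- NULL
    sites$car_target_sd <- NULL
    dplyr::select(sites, "site_id", "source_id", "lat", "lon", "region",
                  "state", "vegetation", "marsh_zone", "salinity_ppt",
                  "sar_mm_yr", "c_density_gC_cm3", "car_gC_m2_yr",
                  "car_noise", "rslr_mm_yr", "tair_c", "prcp_mm_yr",
                  "dating_method")
  })
}

#' Generate synthetic tide-gauge records
#'
#' Each gauge is a linear trend (stored as ground truth `true_trend_mm_yr`)
#' plus i.i.d. Gaussian annual noise. Gauge true trends sit within
#' `gauge_trend_range` of their region's RSLR. A configured fraction of
#' gauges has only the most recent 30 annual values; the rest span 60 years
#' (1960-2019).
#'
#' @param config A [synth_config()].
#' @return A tibble in the long gauge schema: `gauge_id`, `lat`, `lon`,
#'   `year`, `msl_mm`, `true_trend_mm_yr`.
#' @export
generate_gauges <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  layout <- region_layout()
  withr::with_seed(substream_seed(config$seed, "gauges"), {
    reg_idx <- rep_len(seq_len(nrow(config$regions)), config$n_gauges)
    rows <- lapply(seq_len(config$n_gauges), function(g) {
      rg <- config$regions[reg_idx[g], ]
      box <- layout[layout$region == rg$region, ]
      coords <- place_in_region(1, box)
      trend <- rg$rslr + runif(1, -0.5, 0.5) * config$gauge_trend_range
      short <- runif(1) < config$short_gauge_fraction
      years <- if (short) 1990:2019 else 1960:2019
      msl <- 7000 + trend * (years - 1990) +
        rnorm(length(years), 0, config$gauge_noise_sd)
      tibble::tibble(gauge_id = sprintf("gauge%03d", g),
                     lat = coords$lat, lon = coords$lon, year = years,
                     msl_mm = msl, true_trend_mm_yr = trend)
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate a synthetic wetland polygon inventory
#'
#' Polygon centroids cluster near the same regional cluster centres as the
#' sites (so radius queries find neighbors), raw areas are log-normal and
#' then rescaled so each region's total equals the configured regional area
#' exactly (the inventory emulates a fixed wetland-inventory extraction, not
#' a random total), vegetation is assigned by area share, and states follow
#' the coordinate rule.
#'
#' @param config A [synth_config()].
#' @return A tibble in the inventory schema: `polygon_id`, `lat`, `lon`,
#'   `area_km2`, `vegetation`, `region`, `state`.
#' @export
generate_inventory <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  layout <- region_layout()
  withr::with_seed(substream_seed(config$seed, "inventory"), {
    rows <- lapply(seq_len(nrow(config$regions)), function(i) {
      rg <- config$regions[i, ]
      n <- config$n_polygons_per_region
      if (n == 0) return(NULL)
      box <- layout[layout$region == rg$region, ]
      coords <- place_in_region(n, box)
      raw <- rlnorm(n, config$polygon_area_lognorm_mu,
                    config$polygon_area_lognorm_sigma)
      area <- raw * rg$area_km2 / sum(raw)
      tibble::tibble(
        region = rg$region, lat = coords$lat, lon = coords$lon,
        area_km2 = area,
        vegetation = sample(config$vegetation$vegetation, n, replace = TRUE,
                            prob = config$veg_area_share),
        state = state_from_latitude(coords$lat, box))
    })
    inv <- dplyr::bind_rows(rows)
    if (nrow(inv) == 0) {
      return(tibble::tibble(polygon_id = character(), lat = numeric(),
                            lon = numeric(), area_km2 = numeric(),
                            vegetation = character(), region = character(),
                            state = character()))
    }
    inv$polygon_id <- sprintf("poly%05d", seq_len(nrow(inv)))
    dplyr::select(inv, "polygon_id", "lat", "lon", "area_km2", "vegetation",
                  "region", "state")
  })
}

#' Generate a scenario specification
#'
#' One coastal segment per region, with the regional CAR mean/SE, regional
#' RSLR and area as the baseline. The decadal RSLR path (2020-2100) is a
#' monotone non-decreasing power curve whose added rise by 2100 grows with
#' RCP severity (+2 / +4 / +8 mm yr^-1 for RCP 2.6 / 4.5 / 8.5); the
#' decadal area-fraction path starts at exactly 1 in 2020 and moves
#' linearly to an endpoint set by the population-density threshold for
#' lateral accommodation space (5 -> 0.75, 20 -> 0.90, 150 -> 1.20,
#' 300 -> 1.50), with a small per-segment jitter.
#'
#' @param config A [synth_config()].
#' @param rcp One of `"RCP2.6"`, `"RCP4.5"`, `"RCP8.5"`.
#' @param pop_threshold One of 5, 20, 150, 300 (people km^-2).
#' @return A list of class `scenario_spec` with `rcp`, `pop_threshold`,
#'   `segments` (baseline tibble) and `paths` (long decadal tibble).
#' @export
generate_scenarios <- function(config = synth_config(), rcp = "RCP8.5",
                               pop_threshold = 300) {
  stopifnot(inherits(config, "synth_config"))
  rcp <- match.arg(rcp, c("RCP2.6", "RCP4.5", "RCP8.5"))
  if (!pop_threshold %in% c(5, 20, 150, 300)) {
    stop("pop_threshold must be one of 5, 20, 150, 300", call. = FALSE)
  }
  rise_2100 <- c("RCP2.6" = 2, "RCP4.5" = 4, "RCP8.5" = 8)[[rcp]]
  frac_2100 <- c("5" = 0.75, "20" = 0.90, "150" = 1.20,
                 "300" = 1.50)[[as.character(pop_threshold)]]
  decades <- seq(2020, 2100, by = 10)
  rg <- config$regions
  segments <- tibble::tibble(
    segment_id = rg$region, car0 = rg$car_mean, car0_se = rg$car_se,
    rslr0 = rg$rslr, area0_km2 = rg$area_km2)
  withr::with_seed(substream_seed(config$seed, "scenarios"), {
    jitter <- runif(nrow(rg), -0.03, 0.03)
  })
  paths <- tidyr::expand_grid(segment_id = rg$region, decade = decades) |>
    dplyr::left_join(segments, by = "segment_id") |>
    dplyr::mutate(
      frac_time = (.data$decade - 2020) / 80,
      rslr_mm_yr = .data$rslr0 + rise_2100 * .data$frac_time^1.5,
      area_fraction = pmax(0.05, 1 + (frac_2100 - 1 +
        jitter[match(.data$segment_id, rg$region)]) * .data$frac_time)) |>
    dplyr::mutate(area_fraction = ifelse(.data$decade == 2020, 1,
                                         .data$area_fraction)) |>
    dplyr::select("segment_id", "decade", "rslr_mm_yr", "area_fraction")
  structure(list(rcp = rcp, pop_threshold = pop_threshold,
                 segments = segments, paths = paths),
            class = "scenario_spec")
}
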