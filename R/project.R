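# Decadal projection of CAR and national C sequestration to 2100 under RCP
# scenarios, with a critical-RSLR cap and a Monte-Carlo uncertainty band.

#' Projection parameters
#'
#' @param critical_rslr Critical RSLR rate in mm yr^-1 beyond which accretion
#'   no longer keeps pace and CAR stops increasing (default 10; 12 is the
#'   reported limit for southeast US marshes).
#' @param n_draws Monte-Carlo draws for the uncertainty band (default 10000;
#'   at least 1000 for reported bands).
#' @param seed Seed for the Monte-Carlo draws.
#' @return A list of class `projection_params`.
#' @export
projection_params <- function(critical_rslr = 10, n_draws = 10000, seed = 1) {
  assert_number(critical_rslr, "critical_rslr", lower = 1e-9)
  assert_number(n_draws, "n_draws", lower = 1)
  structure(list(critical_rslr = critical_rslr,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "projection_params")
}

#' Project CAR under a future RSLR value
#'
#' Applies the CAR~RSLR slope to the RSLR difference between the current
#' (2010s) rate and a future rate, capping both at the critical RSLR so that
#' sites at or beyond the critical rate gain no further CAR, and flooring
#' the result at zero:
#' `CAR_t = max(0, car0 + slope * (min(rslr_t, crit) - min(rslr0, crit)))`.
#'
#' @param car0 Baseline CAR, g C m^-2 yr^-1.
#' @param rslr0 Baseline (2010s) RSLR, mm yr^-1.
#' @param rslr_t Future RSLR, mm yr^-1.
#' @param model A [fit_car_rslr()] model (only `slope` is used here).
#' @param params A [projection_params()] object.
#' @return Projected CAR, g C m^-2 yr^-1.
#' @export
#' @examples
#' m <- structure(list(slope = 20), class = "car_rslr_model")
#' project_car(100, 4, 7, m)   # 160
#' project_car(100, 4, 14, m)  # 220: capped at the critical 10 mm yr^-1
project_car <- function(car0, rslr0, rslr_t, model,
                        params = projection_params()) {
  slope <- model$slope
  eff_t <- pmin(rslr_t, params$critical_rslr)
  eff_0 <- pmin(rslr0, params$critical_rslr)
  pmax(0, car0 + slope * (eff_t - eff_0))
}

#' Project national C sequestration under one scenario
#'
#' Per decade and coastal segment, flux = projected CAR x baseline area x
#' area fraction x 1e-6 (Tg yr^-1); the national path sums the segments.
#' The uncertainty band perturbs the baseline CAR of each segment
#' (`Normal(car0, car0_se^2)`) and the model slope
#' (`Normal(slope, slope_se^2)`) over `n_draws` Monte-Carlo replicates,
#' flooring CAR at zero; projected RSLR paths are treated as fixed mean
#' trajectories.
#'
#' @param spec A `scenario_spec` (see [generate_scenarios()] or
#'   [read_scenarios()]).
#' @param model A [fit_car_rslr()] model with `slope` and `slope_se`.
#' @param params A [projection_params()] object.
#' @return A list of class `projection_result`: `path` (tibble with
#'   `decade`, `flux_mean`, `flux_lo`, `flux_hi` in Tg yr^-1,
#'   `flux_deterministic`), `segment_car` (tibble of per-segment projected
#'   CAR), and `provenance` (seed, n_draws, critical_rslr, rcp, threshold).
#' @export
project_national <- function(spec, model, params = projection_params()) {
  stopifnot(inherits(spec, "scenario_spec"))
  seg <- spec$segments
  paths <- spec$paths
  decades <- sort(unique(paths$decade))
  full <- paths |>
    dplyr::count(.data$segment_id) |>
    dplyr::pull(.data$n)
  if (length(unique(full)) != 1 || unique(full) != length(decades)) {
    stop("every segment needs a value for every decade", call. = FALSE)
  }
  wide <- paths |>
    dplyr::left_join(seg, by = "segment_id") |>
    dplyr::arrange(.data$decade, .data$segment_id)
  det_car <- project_car(wide$car0, wide$rslr0, wide$rslr_mm_yr, model, params)
  wide$flux_det <- det_car * wide$area0_km2 * wide$area_fraction * 1e-6
  det_path <- wide |>
    dplyr::group_by(decade = .data$decade) |>
    dplyr::summarise(flux = sum(.data$flux_det), .groups = "drop")

  nseg <- nrow(seg)
  draws <- withr::with_seed(params$seed, {
    car0_draw <- matrix(rnorm(params$n_draws * nseg, mean = seg$car0,
                              sd = seg$car0_se), nrow = nseg)
    car0_draw <- pmax(car0_draw, 0)
    slope_draw <- rnorm(params$n_draws, model$slope,
                        model$slope_se %||% 0)
    list(car0 = car0_draw, slope = slope_draw)
  })
  seg_idx <- match(wide$segment_id, seg$segment_id)
  dec_f <- factor(wide$decade, levels = decades)
  eff_diff <- pmin(wide$rslr_mm_yr, params$critical_rslr) -
    pmin(wide$rslr0, params$critical_rslr)
  area_w <- wide$area0_km2 * wide$area_fraction * 1e-6
  flux_mat <- matrix(0, nrow = length(decades), ncol = params$n_draws,
                     dimnames = list(decades, NULL))
  for (k in seq_len(params$n_draws)) {
    car_k <- pmax(0, draws$car0[seg_idx, k] + draws$slope[k] * eff_diff)
    flux_mat[, k] <- tapply(car_k * area_w, dec_f, sum)
  }
  band <- apply(flux_mat, 1, quantile, probs = c(0.025, 0.975), names = FALSE)
  path <- tibble::tibble(
    decade = decades,
    flux_mean = unname(rowMeans(flux_mat)),
    flux_lo = unname(band[1, ]), flux_hi = unname(band[2, ]),
    flux_deterministic = det_path$flux)
  segment_car <- tibble::tibble(segment_id = wide$segment_id,
                                decade = wide$decade, car = det_car)
  structure(list(path = path, segment_car = segment_car,
                 provenance = list(seed = params$seed,
                                   n_draws = params$n_draws,
                                   critical_rslr = params$critical_rslr,
                                   rcp = spec$rcp,
                                   pop_threshold = spec$pop_threshold)),
            class = "projection_result")
}

#' Compare projection results across scenarios
#'
#' Long-format table of the decadal flux paths of several scenarios, with a
#' ratio-to-baseline column (each scenario's flux divided by its own flux in
#' the first decade).
#'
#' @param results A named list of `projection_result` objects.
#' @return A tibble: `scenario`, `threshold`, `decade`, `mean`, `lo`, `hi`,
#'   `ratio_to_baseline`.
#' @export
compare_scenarios <- function(results) {
  stopifnot(length(results) >= 1)
  grids <- lapply(results, function(r) r$path$decade)
  if (length(unique(lapply(grids, identity))) > 1 &&
      !all(vapply(grids, identical, logical(1), grids[[1]]))) {
    stop("scenarios use inconsistent decade grids", call. = FALSE)
  }
  rows <- lapply(results, function(r) {
    base <- r$path$flux_mean[which.min(r$path$decade)]
    tibble::tibble(
      scenario = r$provenance$rcp %||% NA_character_,
      threshold = r$provenance$pop_threshold %||% NA_real_,
      decade = r$path$decade, mean = r$path$flux_mean,
      lo = r$path$flux_lo, hi = r$path$flux_hi,
      ratio_to_baseline = r$path$flux_mean / base)
  })
  dplyr::bind_rows(rows)
}

#' Plot projected national flux paths
#'
#' Ribbon-and-line plot of the decadal national flux with its 95% band, one
#' colour per scenario. Requires \pkg{ggplot2}.
#'
#' @param results A named list of `projection_result` objects.
#' @return A ggplot object.
#' @export
plot_projection <- function(results) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- compare_scenarios(results)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$decade, y = .data$mean,
                                   colour = .data$scenario,
                                   fill = .data$scenario)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Decade", y = "National C flux (Tg yr⁻¹)",
                  colour = "Scenario", fill = "Scenario") +
    ggplot2::theme_minimal()
}
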