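# Radius interpolation, flux arithmetic, and quadrature aggregation.

test_that("radius neighborhood is boundary-inclusive and matches a distance-scan oracle", {
  sites <- toy_sites(cars = c(100, 200), lats = c(39, 39), lons = c(-74, -75))
  poly <- toy_polygon(lat = 39, lon = -74)
  nb <- neighbors_within(poly, sites, 100)
  expect_true("s01" %in% nb$site_id)
  expect_equal(nb$distance_km[nb$site_id == "s01"], 0)
  # a site at exactly the radius is included
  d <- haversine_km(39, -74, 39, -75)
  nb2 <- neighbors_within(poly, sites, radius_km = d)
  expect_true("s02" %in% nb2$site_id)
  nb3 <- neighbors_within(poly, sites, radius_km = d - 0.001)
  expect_false("s02" %in% nb3$site_id)
  set.seed(51)
  sites_r <- toy_sites(cars = runif(40, 50, 300),
                       lats = runif(40, 25, 45), lons = runif(40, -95, -70))
  for (rep in 1:5) {
    poly_r <- toy_polygon(lat = runif(1, 25, 45), lon = runif(1, -95, -70))
    got <- neighbors_within(poly_r, sites_r, 300)$site_id
    want <- sites_r$site_id[haversine_km(poly_r$lat, poly_r$lon,
                                         sites_r$lat, sites_r$lon) <= 300]
    expect_setequal(got, want)
  }
})

test_that("interpolation uses the neighbor mean with SD/sqrt(n) and falls back below 2 neighbors", {
  sites3 <- toy_sites(cars = c(200, 200, 200), lats = c(39, 39.1, 39.2),
                      lons = rep(-74, 3))
  est <- interpolate_car(toy_polygon(39.1, -74), sites3,
                         toy_regional_stats())
  expect_equal(est$car_mean, 200)
  expect_equal(est$car_se, 0)
  expect_equal(est$method, "interpolated")
  sites_mix <- toy_sites(cars = c(100, 200, 300), lats = c(39, 39.1, 39.2),
                         lons = rep(-74, 3))
  est2 <- interpolate_car(toy_polygon(39.1, -74), sites_mix,
                          toy_regional_stats())
  expect_equal(est2$car_mean, 200)
  expect_equal(est2$car_se, sd(c(100, 200, 300)) / sqrt(3))
  expect_equal(est2$car_se, 57.735, tolerance = 1e-4)
  expect_equal(est2$ci95, 1.96 * est2$car_se)
  # exactly one neighbor -> regional fallback with the regional mean's SE
  lone <- toy_sites(cars = 250, lats = 39, lons = -74)
  est3 <- interpolate_car(toy_polygon(39, -74), lone, toy_regional_stats())
  expect_equal(est3$method, "regional_fallback")
  expect_equal(est3$car_mean, 176.5)
  expect_equal(est3$car_se, 14)
  expect_equal(est3$n_neighbors, 1)
  # exactly two neighbors interpolate
  two <- toy_sites(cars = c(100, 300), lats = c(39, 39.1), lons = rep(-74, 2))
  expect_equal(interpolate_car(toy_polygon(39, -74), two,
                               toy_regional_stats())$method, "interpolated")
  expect_error(interpolate_car(toy_polygon(39, -74, region = "Atlantis"),
                               lone, toy_regional_stats()), "Atlantis")
})

test_that("polygon flux is the 1e-6 unit bridge from CAR x area", {
  expect_equal(polygon_flux(100, 0, 1)$flux, 1e-4)
  expect_equal(polygon_flux(161.8, 0, 25892)$flux, 4.189, tolerance = 1e-3)
  expect_equal(polygon_flux(60, 0, 24945.9)$flux, 1.497, tolerance = 1e-3)
  expect_equal(polygon_flux(100, 10, 50)$flux_se, 10 * 50 * 1e-6)
})

test_that("aggregation sums fluxes and propagates SEs in quadrature", {
  est <- tibble::tibble(polygon_id = sprintf("p%d", 1:4),
                        region = "Mid Atlantic", state = "NJ",
                        vegetation = "salt_marsh", area_km2 = 1,
                        car_mean = 100, car_se = 1, ci95 = 1.96,
                        n_neighbors = 3, method = "interpolated",
                        flux = c(1, 2, 3, 4), flux_se = 1)
  agg <- aggregate_flux(est, "national")
  expect_equal(agg$total_flux, 10)
  expect_equal(agg$flux_se, 2) # sqrt(4 x 1)
  expect_equal(agg$ci95, 3.92)
  single <- aggregate_flux(est[2, ], "national")
  expect_equal(single$total_flux, 2)
  expect_equal(single$flux_se, 1)
  # permutation invariance and additivity over a disjoint partition
  perm <- aggregate_flux(est[sample(4), ], "national")
  expect_equal(perm$total_flux, agg$total_flux)
  expect_equal(perm$flux_se, agg$flux_se)
  part1 <- aggregate_flux(est[1:2, ], "national")
  part2 <- aggregate_flux(est[3:4, ], "national")
  expect_equal(part1$total_flux + part2$total_flux, agg$total_flux)
  expect_equal(sqrt(part1$flux_se^2 + part2$flux_se^2), agg$flux_se)
  expect_warning(empty <- aggregate_flux(est[0, ], "national"), "no estimates")
  expect_equal(empty$total_flux, 0)
})

test_that("quadrature SE of a sum matches a Monte-Carlo oracle", {
  set.seed(61)
  k <- 50
  flux <- runif(k, 0.001, 0.1)
  flux_se <- runif(k, 0.0005, 0.02)
  analytic <- sqrt(sum(flux_se^2))
  draws <- matrix(rnorm(k * 20000, flux, flux_se), nrow = k)
  mc <- sd(colSums(draws))
  expect_equal(mc, analytic, tolerance = 0.03)
})

test_that("uniform and stratified estimators agree with each other and the reference arithmetic", {
  expect_equal(upscale_uniform(161.8, 25892), 4.189, tolerance = 1e-3)
  # stratified with one group equals uniform on that group
  expect_equal(upscale_stratified(c(a = 161.8), c(a = 25892)),
               upscale_uniform(161.8, 25892))
  expect_error(upscale_stratified(c(a = 1), c(b = 1)), "names")
  # name alignment is by key, not position
  expect_equal(upscale_stratified(c(a = 100, b = 200),
                                  c(b = 2000, a = 1000)),
               (100 * 1000 + 200 * 2000) * 1e-6)
})

test_that("all three estimators coincide on a spatially homogeneous field", {
  cfg <- small_config(seed = 13)
  sites <- generate_sites(cfg)
  sites$car_gC_m2_yr <- 150 # homogeneous CAR everywhere
  inv <- generate_inventory(cfg)
  est <- upscale_inventory(inv, sites)
  total_area <- sum(inv$area_km2)
  want <- 150 * total_area * 1e-6
  expect_equal(aggregate_flux(est, "national")$total_flux, want)
  expect_equal(upscale_uniform(150, total_area), want)
  areas <- tapply(inv$area_km2, inv$region, sum)
  means <- setNames(rep(150, length(areas)), names(areas))
  expect_equal(upscale_stratified(means, setNames(as.numeric(areas),
                                                  names(areas))), want)
})

test_that("when every polygon falls back regionally, aggregation equals stratified upscaling", {
  cfg <- small_config(seed = 17)
  sites <- generate_sites(cfg)
  inv <- generate_inventory(cfg)
  # push all sites out of range so each polygon uses its regional mean
  far_sites <- sites
  far_sites$lat <- 5
  far_sites$lon <- -150
  reg <- regional_car_stats(sites)
  est <- upscale_inventory(inv, far_sites, reg)
  expect_true(all(est$method == "regional_fallback"))
  by_region <- aggregate_flux(est, "region")
  areas <- tapply(inv$area_km2, inv$region, sum)
  means <- setNames(reg$car_mean, reg$region)
  expect_equal(sum(by_region$total_flux),
               upscale_stratified(means[names(areas)],
                                  setNames(as.numeric(areas), names(areas))))
})

test_that("relative underestimation of a group mean is reported in percent", {
  expect_equal(underestimation_pct(271.9, 161.8, digits = 0), 40)
  expect_equal(underestimation_pct(150, 150), 0)
  expect_equal(underestimation_pct(200, 100), 50)
  expect_error(underestimation_pct(0, 100))
})
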