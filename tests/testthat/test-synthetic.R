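test_that("generate_country tiles a rectangle into the requested districts", {
  cfg <- synthetic_config(grid_nx = 4, grid_ny = 5, cell_km = c(20, 30, 40),
                          seed = 1)
  map <- generate_country(cfg)
  expect_equal(length(map$district_id), 20)
  areas <- vapply(map$polygons, polygon_area_km2, numeric(1))
  # partition: cell areas sum to the bounding rectangle's area
  bb <- t(vapply(map$polygons, geomaskr:::geom_bbox, numeric(4)))
  whole <- cbind(lon = c(min(bb[, 1]), max(bb[, 3]), max(bb[, 3]), min(bb[, 1])),
                 lat = c(min(bb[, 2]), min(bb[, 2]), max(bb[, 4]), max(bb[, 4])))
  expect_equal(sum(areas), polygon_area_km2(whole), tolerance = 1e-6)
  # every cell centroid locates to its own district
  for (id in map$district_id) {
    b <- geomaskr:::geom_bbox(map$polygons[[id]])
    expect_equal(locate_point(map, (b[1] + b[3]) / 2, (b[2] + b[4]) / 2), id)
  }
})

test_that("row-varying cell sizes produce a wide district area spread", {
  cfg <- synthetic_config(grid_nx = 3, grid_ny = 3, cell_km = c(15, 30, 60),
                          seed = 1)
  areas <- vapply(generate_country(cfg)$polygons, polygon_area_km2, numeric(1))
  expect_gt(max(areas) / min(areas), 3)
})

test_that("true cluster locations fall inside their true districts with valid weights", {
  cfg <- synthetic_config(grid_nx = 3, grid_ny = 3, clusters_per_district = 4,
                          households_per_cluster = 5, seed = 2)
  map <- generate_country(cfg)
  sv <- generate_survey(map, cfg)
  expect_equal(nrow(sv$clusters), 9 * 4)
  expect_identical(locate_point(map, sv$clusters$lon, sv$clusters$lat),
                   sv$clusters$true_district)
  expect_true(all(sv$clusters$weight > 0))
  expect_true(all(sv$indicators$y %in% c(0, 1)))
})

test_that("zero prevalence yields all-zero outcomes", {
  cfg <- synthetic_config(grid_nx = 2, grid_ny = 2, clusters_per_district = 3,
                          households_per_cluster = 8,
                          prevalence = list(water = rep(0, 4)), seed = 3)
  map <- generate_country(cfg)
  sv <- generate_survey(map, cfg)
  expect_true(all(sv$indicators$y == 0))
})

test_that("national weighted prevalence recovers the design value", {
  # cluster_sd = 0 makes the weighted design prevalence exact
  cfg <- synthetic_config(grid_nx = 2, grid_ny = 2, cell_km = 30,
                          clusters_per_district = 20,
                          households_per_cluster = 125, cluster_sd = 0,
                          prevalence = list(water = c(0.2, 0.4, 0.5, 0.7)),
                          seed = 4)
  map <- generate_country(cfg)
  sv <- generate_survey(map, cfg)   # 10,000 household records
  ind <- sv$indicators
  p_hat <- sum(ind$weight * ind$y) / sum(ind$weight)
  w_d <- tapply(ind$weight, ind$cluster_id, sum)
  d_of <- sv$clusters$true_district[match(names(w_d), sv$clusters$cluster_id)]
  prev <- c(0.2, 0.4, 0.5, 0.7)[match(d_of, map$district_id)]
  p_design <- sum(unname(w_d) * prev) / sum(w_d)
  mc_se <- sqrt(p_design * (1 - p_design) / nrow(ind))
  expect_lt(abs(p_hat - p_design), 3 * mc_se)
})

test_that("cluster_sd = 0 leaves only binomial between-cluster variation", {
  cfg <- synthetic_config(grid_nx = 1, grid_ny = 1, clusters_per_district = 100,
                          households_per_cluster = 25, cluster_sd = 0,
                          prevalence = list(water = 0.4), seed = 5)
  map <- generate_country(cfg)
  sv <- generate_survey(map, cfg)
  means <- tapply(sv$indicators$y, sv$indicators$cluster_id, mean)
  p <- mean(sv$indicators$y)
  ratio <- var(as.numeric(means)) / (p * (1 - p) / 25)
  # variance ratio ~ chi2_99 / 99 under the null: 0.6-1.5 is ~4 sigma
  expect_gt(ratio, 0.6)
  expect_lt(ratio, 1.5)
})

test_that("a positive cluster_sd produces detectable overdispersion", {
  cfg <- synthetic_config(grid_nx = 1, grid_ny = 1, clusters_per_district = 100,
                          households_per_cluster = 25, cluster_sd = 0.6,
                          prevalence = list(water = 0.4), seed = 6)
  sv <- generate_survey(generate_country(cfg), cfg)
  means <- tapply(sv$indicators$y, sv$indicators$cluster_id, mean)
  p <- mean(sv$indicators$y)
  expect_gt(var(as.numeric(means)) / (p * (1 - p) / 25), 1.8)
})

test_that("eligibility thinning reproduces the indicator precision hierarchy", {
  fx <- recovery_fixture()
  n_by <- table(fx$survey$indicators$indicator)
  expect_gt(n_by[["water"]], n_by[["stunting"]])
  expect_gt(n_by[["stunting"]], n_by[["breastfeeding"]])
})

test_that("zero caps leave locations unchanged and geomasking is deterministic", {
  fx <- recovery_fixture()
  cl <- fx$survey$clusters[1:10, ]
  none <- apply_geomask(cl, sim_config(d_max_urban_km = 0,
                                       d_max_rural_km = 0, seed = 1))
  expect_equal(none$lon, cl$lon)
  expect_equal(none$lat, cl$lat)
  g1 <- apply_geomask(cl, sim_config(seed = 9), fx$map)
  g2 <- apply_geomask(cl, sim_config(seed = 9), fx$map)
  expect_identical(g1, g2)
  disp <- geodesic_distance_km(g1$true_lon, g1$true_lat, g1$lon, g1$lat)
  caps <- ifelse(g1$urban, 2, 5)
  expect_true(all(disp <= caps))
})

test_that("district-constrained geomasking never crosses a boundary", {
  fx <- recovery_fixture()
  cl <- fx$survey$clusters[seq(1, 500, by = 10), ]
  g <- apply_geomask(cl, sim_config(seed = 10), fx$map,
                     constrain_within_district = TRUE)
  expect_identical(locate_point(fx$map, g$lon, g$lat), g$true_district)
})

test_that("unconstrained geomasking does cross boundaries for near-boundary clusters", {
  map <- two_rect_map()
  off <- 0.5 / (111.1949 * cos(-15 * pi / 180))   # 0.5 km west of boundary
  cl <- data.frame(cluster_id = paste0("nb", 1:40), lon = 35 - off,
                   lat = seq(-15.5, -14.5, length.out = 40), urban = FALSE,
                   stratum_id = "s", weight = 1, true_district = "west")
  g <- apply_geomask(cl, sim_config(seed = 11), map)
  crossed <- locate_point(map, g$lon, g$lat) != "west"
  # analytic crossing probability ~0.42 at a = 0.5, d = 5
  expect_gt(sum(crossed), 5)
})

test_that("method C accuracy is monotone as the geomask caps shrink", {
  fx <- recovery_fixture()
  cl <- fx$survey$clusters[seq(1, 500, by = 5), ]   # 100 clusters
  acc <- vapply(c(5, 2, 1, 0.5, 0), function(cap) {
    cfg <- sim_config(d_max_urban_km = max(cap * 2 / 5, 0),
                      d_max_rural_km = cap, seed = 12)
    g <- apply_geomask(cl, cfg, fx$map, constrain_within_country = cap > 0)
    asg <- assign_clusters(g, fx$map, "C")
    mean(asg$district_id == cl$true_district)
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
  expect_equal(acc[5], 1)
})
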