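make_assignment <- function(df, method) {
  structure(df, method = method,
            class = c("district_assignment", "data.frame"))
}

test_that("record building applies the likelihood-times-weight rule", {
  asgA <- make_assignment(data.frame(
    cluster_id = c("c1", "c1", "c2"),
    district_id = c("D1", "D2", "D1"),
    proportion = c(0.4, 0.6, 1)), "A")
  ind <- data.frame(cluster_id = c("c1", "c2"), record_id = c("r1", "r2"),
                    indicator = "water", y = c(1, 0), weight = 2.5)
  clusters <- data.frame(cluster_id = c("c1", "c2"), stratum_id = "s1")
  recs <- build_district_records(ind, asgA, clusters)
  r1d1 <- recs[recs$record_id == "r1" & recs$district_id == "D1", ]
  expect_equal(r1d1$weight, 1.0)   # 0.4 x 2.5
  r1d2 <- recs[recs$record_id == "r1" & recs$district_id == "D2", ]
  expect_equal(r1d2$weight, 1.5)
  # method A conserves each record's base weight across districts
  tot <- tapply(recs$weight, recs$record_id, sum)
  expect_equal(as.numeric(tot), c(2.5, 2.5), tolerance = 1e-9)
  # zero-proportion districts carry no records
  expect_equal(nrow(recs[recs$record_id == "r2" & recs$district_id == "D2", ]), 0)
})

test_that("records with missing y are dropped and single-district weights pass through", {
  asgC <- make_assignment(data.frame(cluster_id = "c1", district_id = "D1",
                                     proportion = 1), "C")
  ind <- data.frame(cluster_id = "c1", record_id = c("r1", "r2"),
                    indicator = "water", y = c(1, NA), weight = 2.5)
  clusters <- data.frame(cluster_id = "c1", stratum_id = "s1")
  recs <- build_district_records(ind, asgC, clusters)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$weight, 2.5)
  # a record whose cluster has no assignment is a consistency error
  bad <- data.frame(cluster_id = "c9", record_id = "r9", indicator = "water",
                    y = 1, weight = 1)
  expect_error(build_district_records(bad, asgC, clusters),
               "without assignment")
})

test_that("Taylor SE reduces to the classical formula in the degenerate design", {
  # single stratum, unit weights, every record its own cluster
  rec <- data.frame(stratum_id = "s", cluster_id = paste0("c", 1:4),
                    weight = 1, y = c(1, 0, 1, 1))
  est <- estimate_proportion(rec)
  expect_equal(est$p_hat, 0.75)
  expect_equal(est$se, 0.25)   # sqrt(p(1-p)/(n-1)) exactly
  # and for arbitrary binary data
  set.seed(6)
  y <- rbinom(40, 1, 0.3)
  rec2 <- data.frame(stratum_id = "s", cluster_id = paste0("c", 1:40),
                     weight = 1, y = y)
  est2 <- estimate_proportion(rec2)
  p <- mean(y)
  expect_equal(est2$se, sqrt(p * (1 - p) / 39), tolerance = 1e-12)
})

test_that("weighted point estimate and extreme-proportion CI contract", {
  rec <- data.frame(stratum_id = "s", cluster_id = c("c1", "c2"),
                    weight = c(1, 3), y = c(1, 0))
  expect_equal(estimate_proportion(rec)$p_hat, 0.25)
  zero <- data.frame(stratum_id = "s", cluster_id = paste0("c", 1:5),
                     weight = 1, y = 0)
  est <- estimate_proportion(zero)
  expect_equal(est$p_hat, 0)
  expect_false(est$ci_estimable)         # "95% confidence not estimable"
  expect_true(is.na(est$ci_low) && is.na(est$ci_high))
  expect_equal(est$se, 0)
  expect_error(estimate_proportion(zero[0, ]), "empty")
})

test_that("logit CI stays in (0,1), contains the estimate, and Wald is available", {
  rec <- make_records(n_clusters = 12, m = 15, p = 0.2, seed = 14)
  est <- estimate_proportion(rec)
  expect_true(est$ci_low > 0 && est$ci_high < 1)
  expect_true(est$ci_low < est$p_hat && est$p_hat < est$ci_high)
  expect_equal(est$df, est$n_clusters - 2)
  w <- estimate_proportion(rec, ci = "wald")
  expect_equal(w$p_hat, est$p_hat)
  expect_false(identical(w$ci_low, est$ci_low))
})

test_that("Taylor SE matches a rescaling cluster bootstrap on a realistic district", {
  rec <- make_records(n_clusters = 24, m = 20, p = 0.4, seed = 42)
  taylor <- estimate_proportion(rec)$se
  set.seed(42)
  boot <- bootstrap_se(rec, n_boot = 1000)
  expect_lt(abs(taylor - boot) / taylor, 0.05)
})

test_that("singleton strata follow the centered rule by default", {
  rec <- data.frame(
    stratum_id = c("s1", "s1", "s1", "s2"),
    cluster_id = c("c1", "c2", "c3", "c4"),
    weight = 1, y = c(1, 0, 1, 1)
  )
  cent <- estimate_proportion(rec)
  cert <- estimate_proportion(rec, singleton = "certainty")
  expect_gt(cent$se, cert$se)   # centered is the conservative choice
  # certainty ignores the singleton: variance comes from s1 alone
  W <- 4; p <- 3 / 4
  z <- (rec$y - p) / W
  v_s1 <- 3 / 2 * sum((z[1:3] - mean(z[1:3]))^2)
  expect_equal(cert$se, sqrt(v_s1), tolerance = 1e-12)
  v_cent <- v_s1 + (z[4] - mean(z))^2
  expect_equal(cent$se, sqrt(v_cent), tolerance = 1e-12)
})

test_that("adding positive cases never decreases the estimate", {
  rec <- make_records(n_clusters = 8, m = 10, p = 0.3, seed = 21)
  p0 <- estimate_proportion(rec)$p_hat
  for (extra_w in c(0.5, 1, 5)) {
    rec2 <- rbind(rec, data.frame(stratum_id = "s1", cluster_id = "new",
                                  weight = extra_w, y = 1))
    expect_gte(estimate_proportion(rec2)$p_hat, p0)
  }
})

test_that("methods agree exactly when every cluster is unambiguous", {
  map <- two_rect_map()
  set.seed(17)
  clusters <- data.frame(
    cluster_id = paste0("k", 1:8),
    lon = runif(8, 34.2, 34.8), lat = runif(8, -15.8, -14.2),
    urban = FALSE, stratum_id = "s1", weight = runif(8, 0.5, 2)
  )
  ind <- data.frame(cluster_id = rep(clusters$cluster_id, each = 10),
                    record_id = paste0("r", 1:80), indicator = "water",
                    y = rbinom(80, 1, 0.4),
                    weight = rep(clusters$weight, each = 10))
  cfg <- sim_config(n_sims = 100, seed = 4)
  ests <- lapply(c("A", "B", "C"), function(m)
    estimate_coverage(ind, assign_clusters(clusters, map, m, cfg), clusters))
  strip <- function(d) {
    d <- as.data.frame(d)
    attr(d, "method") <- NULL
    attr(d, "level") <- NULL
    d
  }
  for (m in 2:3) expect_identical(strip(ests[[1]]), strip(ests[[m]]))
})

test_that("between-survey change uses the integer-percent convention", {
  e1 <- data.frame(district_id = "Blantyre", indicator = "water",
                   p_hat = 0.34)
  e2 <- data.frame(district_id = "Blantyre", indicator = "water",
                   p_hat = 0.15)
  ch <- estimate_change(e1, e2)
  expect_equal(ch$change_pp, -19)
  expect_equal(estimate_change(e1, e1)$change_pp, 0)
  e3 <- data.frame(district_id = "Blantyre", indicator = "water",
                   p_hat = 0.001)
  e4 <- data.frame(district_id = "Blantyre", indicator = "water",
                   p_hat = 0.051)
  expect_equal(estimate_change(e3, e4)$change_pp, 5)
  other <- data.frame(district_id = "Zomba", indicator = "water", p_hat = 0.2)
  expect_error(estimate_change(e1, other), "no matching")
})
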