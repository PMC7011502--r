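# Fixtures and independent oracles shared across test files.

# Two large rectangles sharing the meridian lon = 35 as a long straight
# boundary; each extends far beyond any geomask displacement.
two_rect_map <- function() {
  west <- cbind(lon = c(34.0, 35.0, 35.0, 34.0),
                lat = c(-16, -16, -14, -14))
  east <- cbind(lon = c(35.0, 36.0, 36.0, 35.0),
                lat = c(-16, -16, -14, -14))
  district_map(c("east", "west"), list(east, west))
}

# A small map with a triangle, an L-shape (concave) and a square, used to
# exercise point location on non-rectangular geometry.
mixed_map <- function() {
  tri <- cbind(lon = c(0, 2, 0), lat = c(0, 0, 2))
  ell <- cbind(lon = c(2, 4, 4, 3, 3, 2), lat = c(0, 0, 1, 1, 2, 2))
  sq <- cbind(lon = c(0, 2, 2, 0), lat = c(2, 2, 4, 4))
  district_map(c("tri", "ell", "sq"), list(tri, ell, sq))
}

# Independent point-in-polygon oracle: winding number (signed angle sum),
# a different algorithm from the package's even-odd crossing test.
winding_inside <- function(ring, px, py) {
  n <- nrow(ring)
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    a1 <- atan2(ring[i, 2] - py, ring[i, 1] - px)
    a2 <- atan2(ring[j, 2] - py, ring[j, 1] - px)
    d <- a2 - a1
    if (d > pi) d <- d - 2 * pi
    if (d < -pi) d <- d + 2 * pi
    total <- total + d
  }
  abs(total) > pi
}

# Analytic probability that a geomask displacement from a point at
# perpendicular distance a from an infinite straight boundary crosses it,
# under distance ~ U(0, d_max) and uniform bearing:
#   P = (1 / (pi * d_max)) * integral_a^d_max arccos(a / r) dr
cross_prob_straight_boundary <- function(a, d_max) {
  if (a >= d_max) return(0)
  stats::integrate(function(r) acos(pmin(1, a / r)), a, d_max)$value /
    (pi * d_max)
}

# Rao-Wu rescaling cluster bootstrap SE for the weighted proportion:
# within each stratum resample n_h - 1 clusters with replacement and scale
# their weights by n_h / (n_h - 1).
bootstrap_se <- function(records, n_boot = 1000) {
  strata <- split(records, records$stratum_id)
  reps <- vapply(seq_len(n_boot), function(b) {
    parts <- lapply(strata, function(s) {
      cl <- unique(s$cluster_id)
      nh <- length(cl)
      take <- sample(cl, nh - 1, replace = TRUE)
      do.call(rbind, lapply(take, function(id) {
        r <- s[s$cluster_id == id, , drop = FALSE]
        r$weight <- r$weight * nh / (nh - 1)
        r
      }))
    })
    r <- do.call(rbind, parts)
    sum(r$weight * r$y) / sum(r$weight)
  }, numeric(1))
  stats::sd(reps)
}

# Jackknife (leave-one-pair-out) CI for the CCC on Fisher's z scale.
jackknife_ccc_ci <- function(x, y, level = 0.95) {
  n <- length(x)
  z_full <- atanh(ccc(x, y))
  z_i <- vapply(seq_len(n), function(i) atanh(ccc(x[-i], y[-i])), numeric(1))
  ps <- n * z_full - (n - 1) * z_i
  se <- stats::sd(ps) / sqrt(n)
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(mean(ps) + c(-1, 1) * q * se)
}

# A small single-district record set under a stratified cluster design.
make_records <- function(n_clusters = 20, m = 20, p = 0.4, seed = 42,
                         strata = 2, icc_sd = 0.4) {
  set.seed(seed)
  rows <- lapply(seq_len(n_clusters), function(c) {
    u <- stats::rnorm(1, 0, icc_sd)
    data.frame(
      stratum_id = paste0("s", 1 + (c %% strata)),
      cluster_id = paste0("c", c),
      weight = stats::runif(m, 0.5, 2),
      y = as.numeric(stats::runif(m) < stats::plogis(stats::qlogis(p) + u))
    )
  })
  do.call(rbind, rows)
}

# Default-conditions synthetic study (5x5 country, 20 clusters/district,
# 25 households/cluster), shared by the parameter-recovery tests and the
# method-ranking check. Cached per session: generation is deterministic in
# the seed.
recovery_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- synthetic_config(seed = 42)
    map <- generate_country(cfg)
    sv <- generate_survey(map, cfg)
    gm <- apply_geomask(sv$clusters, sim_config(seed = 42), map)
    cache <<- list(cfg = cfg, map = map, survey = sv, masked = gm)
    cache
  }
})
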