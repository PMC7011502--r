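# The DHS geomask displacement model and its Monte-Carlo inversion.
#
# DHS displaces each released cluster centroid by a two-step draw: a
# uniform distance up to a cap (2 km urban, 5 km rural; a 1% rural tail up
# to 10 km exists in the protocol but is off by default here) and an
# independent uniform bearing. Distance is uniform in *distance*, not in
# area: the displacement density is higher near the true location than a
# "dart board" (area-uniform) draw would give.

#' Simulation configuration for geomask inversion
#'
#' @param n_sims Number of simulated re-displacements per cluster.
#' @param d_max_urban_km,d_max_rural_km Displacement caps in km.
#' @param seed Integer seed. Each cluster gets its own stream derived from
#'   `(seed, cluster_id)`, so results are independent of cluster order.
#' @param include_one_percent_rule If `TRUE`, each rural draw uses a 10 km
#'   cap with probability 0.01 (the documented DHS long-displacement rule).
#'   Off by default.
#' @param area_uniform If `TRUE`, draw distances area-uniformly
#'   (`d_max * sqrt(U)`) instead of distance-uniformly; provided for
#'   sensitivity analysis only.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_sims = 1000, d_max_urban_km = 2, d_max_rural_km = 5,
                       seed = 1L, include_one_percent_rule = FALSE,
                       area_uniform = FALSE) {
  # caps of exactly 0 are allowed as the degenerate no-displacement model
  stopifnot(n_sims >= 1, d_max_urban_km >= 0, d_max_rural_km >= 0)
  structure(
    list(n_sims = as.integer(n_sims),
         d_max_urban_km = d_max_urban_km,
         d_max_rural_km = d_max_rural_km,
         seed = as.integer(seed),
         include_one_percent_rule = isTRUE(include_one_percent_rule),
         area_uniform = isTRUE(area_uniform)),
    class = "sim_config"
  )
}

# Deterministic per-cluster seed from the global seed and the cluster id
# (polynomial string hash mod a prime below 2^31), so per-cluster results
# do not depend on processing order.
derive_seed <- function(seed, cluster_id) {
  codes <- utf8ToInt(as.character(cluster_id))
  h <- as.double(seed %% 2147483647L)
  for (ch in codes) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw geomask displacements
#'
#' Draws `n` independent (distance, bearing) pairs from the DHS geomask
#' model: distance uniform on `[0, d_max_km]` and bearing uniform on
#' `[0, 2*pi)`, independent. Uses the current RNG state.
#'
#' @param n Number of draws.
#' @param d_max_km Displacement cap in km (nonnegative).
#' @param area_uniform If `TRUE`, distance is area-uniform
#'   (`d_max * sqrt(U)`) for sensitivity analysis.
#' @return A data.frame with columns `bearing` (radians, clockwise from
#'   north) and `distance` (km).
#' @export
draw_displacement <- function(n, d_max_km, area_uniform = FALSE) {
  if (length(d_max_km) != 1 || is.na(d_max_km) || d_max_km < 0)
    stop("invalid parameter: d_max_km must be a single nonnegative number")
  # distance first, then angle; the order is immaterial for independent draws
  u <- stats::runif(n)
  distance <- if (area_uniform) d_max_km * sqrt(u) else d_max_km * u
  bearing <- stats::runif(n, 0, 2 * pi)
  data.frame(bearing = bearing, distance = distance)
}

#' Simulate possible origin locations for a geomasked cluster
#'
#' Enumerates, by Monte Carlo, locations from which a geomasked cluster
#' could have originated: the released coordinate is re-displaced `n_sims`
#' times under the geomask model (because the displacement distribution is
#' radially symmetric, re-displacing the released point samples the origin
#' likelihood). A pure function of `(cluster, config$seed)`.
#'
#' @param cluster A list or one-row data.frame with `cluster_id`, `lon`,
#'   `lat`, and logical/0-1 `urban`.
#' @param config A [sim_config()].
#' @return A data.frame of `n_sims` rows with columns `lon`, `lat`,
#'   `distance` (the drawn displacement, km).
#' @export
simulate_cluster_locations <- function(cluster, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  urban <- as.logical(cluster$urban)
  d_max <- if (urban) config$d_max_urban_km else config$d_max_rural_km
  with_seed(derive_seed(config$seed, cluster$cluster_id), {
    draws <- draw_displacement(config$n_sims, d_max,
                               area_uniform = config$area_uniform)
    if (!urban && config$include_one_percent_rule) {
      long <- stats::runif(config$n_sims) < 0.01
      if (any(long))
        draws$distance[long] <- stats::runif(sum(long), 0, 10)
    }
    pts <- offset_point(cluster$lon, cluster$lat, draws$bearing, draws$distance)
    pts$distance <- draws$distance
    pts
  })
}

#' Read a cluster table from CSV
#'
#' Expected columns: `cluster_id`, `lon`, `lat`, `urban` (0/1 or logical),
#' `stratum_id`, `weight`.
#'
#' @param path Path to a CSV file.
#' @return A data.frame of cluster records.
#' @export
read_clusters <- function(path) {
  cl <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clusters(cl)
}

validate_clusters <- function(cl) {
  need <- c("cluster_id", "lon", "lat", "urban", "stratum_id", "weight")
  miss <- setdiff(need, names(cl))
  if (length(miss))
    stop("cluster table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(cl$cluster_id))
    stop("duplicate cluster_id in cluster table")
  if (any(!is.finite(cl$weight)) || any(cl$weight <= 0))
    stop("cluster weights must be positive")
  if (any(abs(cl$lat) > 90) || any(abs(cl$lon) > 180))
    stop("cluster coordinates outside WGS84 bounds")
  cl$urban <- as.logical(cl$urban)
  cl
}
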