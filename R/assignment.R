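# District assignment for geomasked clusters.
#
# Method A: fractional assignment — re-displace the released coordinate
#   n_sims times under the geomask model, locate every simulated point, and
#   assign each district the fraction of located simulations falling in it.
#   Simulated points outside every district (sea, neighboring country) are
#   dropped and the fractions renormalized: the true origin must lie in
#   some district, so renormalization is the maximum-likelihood treatment
#   under the displacement model.
# Method B: the modal district of the method-A simulation.
# Method C: the district containing the released geomasked coordinate.

#' Method A: fractional district assignment
#'
#' @param cluster A list/one-row data.frame with `cluster_id`, `lon`,
#'   `lat`, `urban`.
#' @param map A [district_map()].
#' @param config A [sim_config()].
#' @return A list with `cluster_id` and `proportions`, a named numeric
#'   vector over districts that received at least one simulated point,
#'   summing to 1.
#' @export
assign_method_A <- function(cluster, map, config = sim_config()) {
  pts <- simulate_cluster_locations(cluster, config)
  d <- locate_point(map, pts$lon, pts$lat)
  d <- d[!is.na(d)]
  if (!length(d))
    stop("assignment failure: all simulated points for cluster '",
         cluster$cluster_id, "' fall outside every district")
  tab <- table(d)
  prop <- as.numeric(tab) / sum(tab)
  names(prop) <- names(tab)
  list(cluster_id = as.character(cluster$cluster_id), proportions = prop)
}

#' Method B: modal simulated district
#'
#' Selects the district with the largest method-A proportion. Ties are
#' broken toward the district containing the released geomasked point when
#' it is among the tied set (consistent with method C), otherwise toward
#' the smallest district id.
#'
#' @param assignment_a A method-A assignment (see [assign_method_A()]).
#' @param map A [district_map()] (needed only to resolve ties).
#' @param lon,lat The released geomasked coordinate (used only for ties).
#' @return A list with `cluster_id`, `district_id`, `method = "B"`.
#' @export
assign_method_B <- function(assignment_a, map = NULL, lon = NULL, lat = NULL) {
  p <- assignment_a$proportions
  top <- names(p)[p >= max(p) - 1e-12]
  if (length(top) > 1 && !is.null(map) && !is.null(lon)) {
    home <- locate_point(map, lon, lat)
    if (!is.na(home) && home %in% top) top <- home
  }
  list(cluster_id = assignment_a$cluster_id,
       district_id = sort(top, method = "radix")[1], method = "B")
}

#' Method C: district containing the geomasked point
#'
#' Locates the released coordinate directly; if it falls outside every
#' district, snaps to the nearest boundary within `snap_km`.
#'
#' @param cluster A list/one-row data.frame with `cluster_id`, `lon`, `lat`.
#' @param map A [district_map()].
#' @param snap_km Snap tolerance in km (default 0.5).
#' @return A list with `cluster_id`, `district_id`, `method = "C"`.
#' @export
assign_method_C <- function(cluster, map, snap_km = 0.5) {
  d <- locate_point(map, cluster$lon, cluster$lat)
  if (is.na(d)) d <- snap_to_district(map, cluster$lon, cluster$lat, snap_km)
  if (is.na(d))
    stop("assignment failure: cluster '", cluster$cluster_id,
         "' is farther than ", snap_km, " km from every district")
  list(cluster_id = as.character(cluster$cluster_id), district_id = d,
       method = "C")
}

#' Assign all clusters by one method
#'
#' Runs method A, B, or C over a cluster table and returns a long
#' assignment table. Methods B and C yield one row per cluster; method A
#' yields one row per (cluster, district) with a positive proportion.
#'
#' @param clusters Cluster data.frame with `cluster_id`, `lon`, `lat`,
#'   `urban` (and any other columns, carried along by id downstream).
#' @param map A [district_map()].
#' @param method `"A"`, `"B"`, or `"C"`.
#' @param config A [sim_config()] (methods A and B).
#' @param snap_km Snap tolerance for method C.
#' @return A data.frame of class `district_assignment` with columns
#'   `cluster_id`, `district_id`, `proportion` (1 for B/C) and attribute
#'   `method`.
#' @export
assign_clusters <- function(clusters, map, method = c("C", "A", "B"),
                            config = sim_config(), snap_km = 0.5) {
  method <- match.arg(method)
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    switch(method,
      A = {
        a <- assign_method_A(cl, map, config)
        data.frame(cluster_id = a$cluster_id,
                   district_id = names(a$proportions),
                   proportion = unname(a$proportions))
      },
      B = {
        a <- assign_method_A(cl, map, config)
        b <- assign_method_B(a, map, cl$lon, cl$lat)
        data.frame(cluster_id = b$cluster_id, district_id = b$district_id,
                   proportion = 1)
      },
      C = {
        cc <- assign_method_C(cl, map, snap_km)
        data.frame(cluster_id = cc$cluster_id, district_id = cc$district_id,
                   proportion = 1)
      })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, method = method, class = c("district_assignment",
                                            "data.frame"))
}

#' @export
print.district_assignment <- function(x, ...) {
  m <- attr(x, "method")
  ncl <- length(unique(x$cluster_id))
  cat("district_assignment (method ", m, "): ", ncl, " clusters, ",
      length(unique(x$district_id)), " districts\n", sep = "")
  if (m == "A") {
    split_n <- sum(tapply(x$proportion, x$cluster_id, length) > 1)
    cat("  clusters with >1 possible district of origin:", split_n, "\n")
  }
  print(utils::head(as.data.frame(x), 8), row.names = FALSE)
  if (nrow(x) > 8) cat("  ...", nrow(x) - 8, "more rows\n")
  invisible(x)
}

#' Count assigned clusters per district
#'
#' For methods B and C, an integer cluster count per district. For method
#' A, two columns per district: `whole` counts clusters assigned with
#' proportion 1 (geomask radius entirely within the district) and
#' `partial` counts clusters assigned with a fractional proportion there.
#'
#' @param assignments A `district_assignment` from [assign_clusters()].
#' @return A data.frame keyed by `district_id`.
#' @export
count_clusters_per_district <- function(assignments) {
  m <- attr(assignments, "method")
  ids <- sort(unique(assignments$district_id), method = "radix")
  if (identical(m, "A")) {
    whole <- integer(length(ids)); partial <- integer(length(ids))
    names(whole) <- names(partial) <- ids
    for (cl in split(assignments, assignments$cluster_id)) {
      if (nrow(cl) == 1 && cl$proportion >= 1 - 1e-12) {
        whole[cl$district_id] <- whole[cl$district_id] + 1L
      } else {
        partial[cl$district_id] <- partial[cl$district_id] + 1L
      }
    }
    data.frame(district_id = ids, whole = unname(whole),
               partial = unname(partial))
  } else {
    tab <- table(assignments$district_id)
    data.frame(district_id = ids, n_clusters = as.integer(tab[ids]))
  }
}

# Shannon entropy (nats) of each cluster's method-A proportions; a
# diagnostic for assignment ambiguity (0 = unambiguous).
assignment_entropy <- function(assignments) {
  vapply(split(assignments$proportion, assignments$cluster_id),
         function(p) -sum(p * log(p)), numeric(1))
}
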