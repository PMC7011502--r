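# District-level coverage estimation under the complex survey design.
#
# The estimator is the weighted proportion (a ratio estimator) with
# clusters as PSUs and design strata; variance by Taylor linearization.
# Method A contributes fractional records: a record whose cluster has
# district proportion p_d enters district d with weight p_d * base weight,
# keeping its original cluster/stratum identity for variance purposes (the
# same cluster may therefore contribute to several districts).

#' Build per-district record sets
#'
#' Joins indicator records to a district assignment. Methods B/C place each
#' record in exactly one district with its base weight; method A places a
#' record in every district its cluster has positive proportion in, with
#' adjusted weight = proportion x base weight (the product of the district
#' likelihood and the sampling weight). Records with missing `y` are
#' dropped listwise.
#'
#' @param indicators Data.frame with columns `cluster_id`, `record_id`,
#'   `indicator`, `y` (0/1/NA), `weight` (positive).
#' @param assignments A `district_assignment` from [assign_clusters()].
#' @param clusters Cluster table supplying `stratum_id` per `cluster_id`.
#' @return A data.frame with columns `district_id`, `indicator`,
#'   `stratum_id`, `cluster_id`, `record_id`, `weight`, `y`.
#' @export
build_district_records <- function(indicators, assignments, clusters) {
  need <- c("cluster_id", "record_id", "indicator", "y", "weight")
  miss <- setdiff(need, names(indicators))
  if (length(miss))
    stop("indicator table missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(indicators$cluster_id), unique(assignments$cluster_id))
  if (length(bad))
    stop("data consistency error: cluster(s) without assignment: ",
         paste(utils::head(bad, 5), collapse = ", "))
  ind <- indicators[!is.na(indicators$y), , drop = FALSE]
  if (any(ind$weight <= 0)) stop("record weights must be positive")
  strat <- clusters[, c("cluster_id", "stratum_id")]
  asg <- as.data.frame(assignments)[, c("cluster_id", "district_id",
                                        "proportion")]
  m <- merge(ind, asg, by = "cluster_id")
  m <- merge(m, strat, by = "cluster_id")
  out <- data.frame(district_id = m$district_id, indicator = m$indicator,
                    stratum_id = m$stratum_id, cluster_id = m$cluster_id,
                    record_id = m$record_id,
                    weight = m$weight * m$proportion, y = m$y)
  out[out$weight > 0, , drop = FALSE]
}

#' Weighted proportion with Taylor linearized variance
#'
#' Estimates p-hat = sum(w y) / sum(w) and its standard error by Taylor
#' linearization with clusters as PSUs within strata: for linearized
#' scores z_k = w_k (y_k - p) / W summed to cluster totals z_hc,
#' V = sum_h n_h / (n_h - 1) * sum_c (z_hc - zbar_h)^2. The confidence
#' interval is a logit-scale Wald interval with a t critical value on
#' df = (#clusters) - (#strata), which keeps the interval inside (0, 1);
#' a plain Wald interval is available. Extreme estimates (p-hat 0 or 1)
#' have no estimable interval and are flagged.
#'
#' Strata reduced to a single cluster (common after district
#' disaggregation) contribute, under the default `"centered"` rule, a
#' squared deviation of their cluster total about the mean cluster total
#' across all clusters in the district, with factor 1; `"certainty"`
#' treats them as sampled with certainty (zero contribution).
#'
#' @param records Data.frame with `stratum_id`, `cluster_id`, `weight`,
#'   `y` for one district x indicator.
#' @param level Confidence level (default 0.95).
#' @param ci `"logit"` (default) or `"wald"`.
#' @param singleton Singleton-stratum rule, `"centered"` or `"certainty"`.
#' @return One-row data.frame: `p_hat`, `se`, `ci_low`, `ci_high`,
#'   `ci_estimable`, `n_clusters`, `n_obs`, `df`.
#' @export
estimate_proportion <- function(records, level = 0.95,
                                ci = c("logit", "wald"),
                                singleton = c("centered", "certainty")) {
  ci <- match.arg(ci)
  singleton <- match.arg(singleton)
  if (is.null(records) || nrow(records) == 0) stop("empty record set")
  stopifnot(all(records$weight > 0), all(records$y %in% c(0, 1)))
  w <- records$weight
  y <- records$y
  W <- sum(w)
  p <- sum(w * y) / W
  z <- w * (y - p) / W
  cl_key <- interaction(records$stratum_id, records$cluster_id, drop = TRUE)
  z_hc <- tapply(z, cl_key, sum)
  strata_of <- tapply(as.character(records$stratum_id), cl_key, `[`, 1)
  n_clusters <- length(z_hc)
  n_strata <- length(unique(strata_of))
  zbar_all <- mean(z_hc)
  V <- 0
  for (h in unique(strata_of)) {
    zh <- z_hc[strata_of == h]
    nh <- length(zh)
    if (nh > 1) {
      V <- V + nh / (nh - 1) * sum((zh - mean(zh))^2)
    } else if (singleton == "centered") {
      V <- V + (zh - zbar_all)^2
    }  # certainty: contributes 0
  }
  se <- sqrt(max(V, 0))
  df <- n_clusters - n_strata
  estimable <- p > 0 && p < 1 && se > 0 && df >= 1
  ci_low <- ci_high <- NA_real_
  if (estimable) {
    tcrit <- stats::qt(1 - (1 - level) / 2, df)
    if (ci == "logit") {
      lg <- stats::qlogis(p)
      se_lg <- se / (p * (1 - p))
      ci_low <- stats::plogis(lg - tcrit * se_lg)
      ci_high <- stats::plogis(lg + tcrit * se_lg)
    } else {
      ci_low <- max(0, p - tcrit * se)
      ci_high <- min(1, p + tcrit * se)
    }
  }
  data.frame(p_hat = p, se = se, ci_low = ci_low, ci_high = ci_high,
             ci_estimable = estimable, n_clusters = n_clusters,
             n_obs = nrow(records), df = df)
}

#' District coverage estimates for one assignment method
#'
#' Builds district record sets from an assignment and estimates each
#' district x indicator weighted proportion with its design-based
#' uncertainty.
#'
#' @inheritParams build_district_records
#' @inheritParams estimate_proportion
#' @return A data.frame of class `district_estimates`: one row per
#'   district x indicator with the columns of [estimate_proportion()] plus
#'   `district_id` and `indicator`; attribute `method`.
#' @export
estimate_coverage <- function(indicators, assignments, clusters,
                              level = 0.95, ci = c("logit", "wald"),
                              singleton = c("centered", "certainty")) {
  recs <- build_district_records(indicators, assignments, clusters)
  keys <- unique(recs[, c("district_id", "indicator")])
  keys <- keys[order(keys$district_id, keys$indicator), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- recs$district_id == keys$district_id[i] &
      recs$indicator == keys$indicator[i]
    est <- estimate_proportion(recs[sel, , drop = FALSE], level = level,
                               ci = ci, singleton = singleton)
    cbind(keys[i, , drop = FALSE], est)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, method = attr(assignments, "method"), level = level,
            class = c("district_estimates", "data.frame"))
}

#' @export
print.district_estimates <- function(x, digits = 3, ...) {
  cat("district_estimates (method ", attr(x, "method"), ", ",
      100 * attr(x, "level"), "% CI): ", nrow(x), " district x indicator\n",
      sep = "")
  df <- as.data.frame(x)
  num <- c("p_hat", "se", "ci_low", "ci_high")
  df[num] <- lapply(df[num], round, digits)
  print(utils::head(df, 12), row.names = FALSE)
  if (nrow(df) > 12) cat("  ...", nrow(df) - 12, "more rows\n")
  invisible(x)
}

#' Between-survey change in percentage points
#'
#' Matches two estimate tables (e.g. two survey rounds) on district and
#' indicator and reports the change as a difference of integer percents,
#' `round(100 p2) - round(100 p1)`, the convention of published coverage
#' tables (estimates are carried at full precision and rounded only here).
#'
#' @param est_t1,est_t2 `district_estimates` tables for the earlier and
#'   later survey.
#' @return A data.frame with `district_id`, `indicator`, `pct_t1`,
#'   `pct_t2`, `change_pp`.
#' @export
estimate_change <- function(est_t1, est_t2) {
  key <- c("district_id", "indicator")
  a <- as.data.frame(est_t1)[, c(key, "p_hat")]
  b <- as.data.frame(est_t2)[, c(key, "p_hat")]
  m <- merge(a, b, by = key, suffixes = c("_t1", "_t2"))
  if (nrow(m) == 0)
    stop("no matching district x indicator pairs between the two tables")
  pct1 <- round(100 * m$p_hat_t1)
  pct2 <- round(100 * m$p_hat_t2)
  data.frame(district_id = m$district_id, indicator = m$indicator,
             pct_t1 = pct1, pct_t2 = pct2, change_pp = pct2 - pct1)
}
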