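# Agreement between two sets of district estimates: Lin's concordance
# correlation coefficient (CCC), rho_c = 2 s_xy / (s_x^2 + s_y^2 +
# (xbar - ybar)^2), which penalizes both imprecision (scatter about the
# best-fit line) and inaccuracy (departure from the identity line).

#' Lin's concordance correlation coefficient
#'
#' Computed with biased (divide-by-n) moments, per Lin's original
#' definition; set `bias_correction = TRUE` for (n-1)-denominator moments.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), no missing values.
#' @param bias_correction Use (n-1) moment denominators.
#' @return The CCC, in `[-1, 1]`.
#' @export
ccc <- function(x, y, bias_correction = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired values")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  den <- if (bias_correction) n - 1 else n
  sx2 <- sum((x - mean(x))^2) / den
  sy2 <- sum((y - mean(y))^2) / den
  sxy <- sum((x - mean(x)) * (y - mean(y))) / den
  d2 <- (mean(x) - mean(y))^2
  if (sx2 + sy2 + d2 == 0)
    stop("CCC undefined: both vectors constant with equal means")
  2 * sxy / (sx2 + sy2 + d2)
}

#' CCC with a Fisher-z confidence interval
#'
#' The CCC estimate with the standard asymptotic confidence interval:
#' Fisher's z transform of rho_c, Lin's variance for the z-transformed
#' estimate, normal quantiles, back-transformed by tanh. With |rho_c| = 1
#' (exact agreement/reversal) the z variance is not finite; the result is
#' flagged degenerate and carries no interval.
#'
#' @param x,y Numeric vectors of equal length (n >= 4 for an interval).
#' @param level Confidence level.
#' @param bias_correction Passed to [ccc()].
#' @return An object of class `ccc` with fields `ccc`, `ci_low`,
#'   `ci_high`, `n`, `level`, `degenerate`.
#' @export
concordance <- function(x, y, level = 0.95, bias_correction = FALSE) {
  rc <- ccc(x, y, bias_correction = bias_correction)
  n <- length(x)
  out <- list(ccc = rc, ci_low = NA_real_, ci_high = NA_real_, n = n,
              level = level, degenerate = FALSE)
  if (abs(rc) >= 1 - 1e-12) {
    out$degenerate <- TRUE
    return(structure(out, class = "ccc"))
  }
  if (n < 4) stop("need at least 4 pairs for a confidence interval")
  r <- stats::cor(x, y)
  sx <- sqrt(sum((x - mean(x))^2) / n)
  sy <- sqrt(sum((y - mean(y))^2) / n)
  u <- (mean(x) - mean(y)) / sqrt(sx * sy)
  # Lin's asymptotic variance of atanh(rho_c)
  vz <- ((1 - r^2) * rc^2 / ((1 - rc^2) * r^2) +
         2 * rc^3 * (1 - rc) * u^2 / (r * (1 - rc^2)^2) -
         rc^4 * u^4 / (2 * r^2 * (1 - rc^2)^2)) / (n - 2)
  z <- atanh(rc)
  q <- stats::qnorm(1 - (1 - level) / 2)
  half <- q * sqrt(max(vz, 0))
  out$ci_low <- tanh(z - half)
  out$ci_high <- tanh(z + half)
  structure(out, class = "ccc")
}

#' @export
print.ccc <- function(x, digits = 3, ...) {
  cat("Lin's concordance correlation coefficient\n")
  cat("  ccc =", format(round(x$ccc, digits)), " (n =", x$n, "pairs)\n")
  if (x$degenerate) {
    cat("  exact agreement/reversal: no finite-interval z variance\n")
  } else {
    cat("  ", 100 * x$level, "% CI: [", format(round(x$ci_low, digits)),
        ", ", format(round(x$ci_high, digits)), "]\n", sep = "")
  }
  invisible(x)
}

#' Agreement between two district estimate tables
#'
#' Matches two `district_estimates` tables (or plain data.frames with
#' `district_id` and `p_hat`) on district (and indicator when present) and
#' computes the CCC with its confidence interval per indicator.
#'
#' @param est_x,est_y Estimate tables to compare.
#' @param level Confidence level.
#' @return A data.frame with one row per indicator: `indicator`, `ccc`,
#'   `ci_low`, `ci_high`, `n`.
#' @export
agreement <- function(est_x, est_y, level = 0.95) {
  a <- as.data.frame(est_x)
  b <- as.data.frame(est_y)
  key <- intersect(c("district_id", "indicator"), intersect(names(a), names(b)))
  m <- merge(a[, c(key, "p_hat")], b[, c(key, "p_hat")], by = key,
             suffixes = c("_x", "_y"))
  by_ind <- if ("indicator" %in% key) split(m, m$indicator) else list(all = m)
  rows <- lapply(names(by_ind), function(ind) {
    g <- by_ind[[ind]]
    cc <- concordance(g$p_hat_x, g$p_hat_y, level = level)
    data.frame(indicator = ind, ccc = cc$ccc, ci_low = cc$ci_low,
               ci_high = cc$ci_high, n = cc$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
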