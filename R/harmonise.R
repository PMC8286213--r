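#' Aggregate image-quality results across scanners
#'
#' Per-sphere, per-metric mean and sample standard deviation over a set of
#' `iq_result`s from different scanners/sites.
#'
#' @param results List of `iq_result` objects with matching sphere sets.
#' @param metrics Metric columns to aggregate.
#' @return Object of class `ensemble_summary`: data frame with `diameter`,
#'   `metric`, `mean`, `sd`, `n`.
#' @export
aggregate_iq <- function(results, metrics = c("RC_max", "RC_mean", "RC_peak")) {
  if (length(results) < 2) stop_nemaiq("insufficient_data", "need at least 2 results")
  diam <- results[[1]]$recovery$diameter
  for (r in results) {
    if (!identical(r$recovery$diameter, diam)) {
      stop_nemaiq("incompatible_results", "sphere sets differ between results")
    }
  }
  rows <- list()
  for (m in metrics) {
    vals <- sapply(results, function(r) r$recovery[[m]])  # spheres x scanners
    rows[[m]] <- data.frame(diameter = diam, metric = m,
                            mean = apply(vals, 1, mean),
                            sd = apply(vals, 1, sd),
                            n = length(results))
  }
  structure(do.call(rbind, c(rows, make.row.names = FALSE)),
            class = c("ensemble_summary", "data.frame"))
}

#' Derive specification limits from an ensemble
#'
#' Acceptance bounds per sphere and metric, `mean +/- k * SD` across the
#' contributing scanners (k = 2 by default, i.e. the two-standard-deviation
#' band used to define multi-centre specification limits).
#'
#' @param summary An [aggregate_iq()] result.
#' @param k Half-width in standard deviations (default 2).
#' @param family Label for the reconstruction family the limits apply to.
#' @return A `limits_table`: data frame `family`, `metric`, `diameter_mm`,
#'   `lower`, `upper`. Zero-SD rows yield degenerate limits and a warning.
#' @export
derive_limits <- function(summary, k = 2, family = "advanced") {
  if (any(!is.finite(summary$sd))) stop_nemaiq("invalid_parameter", "non-finite SD")
  out <- data.frame(family = family, metric = summary$metric,
                    diameter_mm = summary$diameter,
                    lower = summary$mean - k * summary$sd,
                    upper = summary$mean + k * summary$sd)
  if (k > 0 && any(summary$sd == 0)) {
    warning("degenerate limits: zero between-scanner SD for some entries")
  }
  structure(out, class = c("limits_table", "data.frame"))
}

#' Shipped Gallium-68 specification limits
#'
#' The proposed per-sphere RC acceptance bands for Gallium-68 multi-centre
#' trials, for conventional (OSEM/OSEM+TOF) and advanced (PSF/BPL)
#' reconstruction families, as transcribed in
#' `inst/extdata/limits_ga68_table2.csv`. The source table prints the columns
#' as SUV_max/SUV_mean/SUV_peak; they are RC-type bounds and are labelled
#' RC_* here. Alternative limit files in the same schema (columns `family`,
#' `metric`, `diameter_mm`, `lower`, `upper`) can be loaded with
#' [read_limits()].
#'
#' @return A `limits_table` data frame.
#' @export
ga68_limits <- function() {
  read_limits(system.file("extdata", "limits_ga68_table2.csv", package = "nemaiq"))
}

#' Read or write a limits table
#'
#' CSV schema: columns `family`, `metric`, `diameter_mm`, `lower`, `upper`.
#'
#' @param path File path.
#' @param limits A `limits_table` (for writing).
#' @return `read_limits`: a `limits_table`; `write_limits`: `path`, invisibly.
#' @export
read_limits <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("family", "metric", "diameter_mm", "lower", "upper")
  if (!all(need %in% names(df))) {
    stop_nemaiq("invalid_limits", "limits file must have columns %s",
                paste(need, collapse = ", "))
  }
  if (any(df$lower >= df$upper)) stop_nemaiq("invalid_limits", "lower must be < upper")
  structure(df[need], class = c("limits_table", "data.frame"))
}

#' @rdname read_limits
#' @export
write_limits <- function(limits, path) {
  write.csv(limits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.limits_table <- function(x, ...) {
  cat(sprintf("<limits_table: %d entries, families %s>\n", nrow(x),
              paste(unique(x$family), collapse = ", ")))
  NextMethod()
}

#' Check a result against specification limits
#'
#' Pass iff `lower <= value <= upper` (closed interval) for every
#' sphere/metric covered by the limits table.
#'
#' @param result An `iq_result`.
#' @param limits A `limits_table`; if it contains several families, pick one
#'   with `family`.
#' @param family Reconstruction family to check against (default: the only
#'   family present).
#' @return Object of class `compliance_report`: data frame with `diameter`,
#'   `metric`, `value`, `lower`, `upper`, `pass` and `deviation_pct` (percent
#'   beyond the violated bound; 0 when passing).
#' @export
check_compliance <- function(result, limits, family = NULL) {
  if (is.null(family)) {
    fams <- unique(limits$family)
    if (length(fams) > 1) stop_nemaiq("invalid_parameter",
                                      "limits contain several families; pick one")
    family <- fams
  }
  lim <- limits[limits$family == family, ]
  rows <- list()
  for (i in seq_len(nrow(lim))) {
    d <- lim$diameter_mm[i]; m <- lim$metric[i]
    j <- which(result$recovery$diameter == d)
    if (!length(j) || !m %in% names(result$recovery)) {
      stop_nemaiq("incomplete_limits",
                  "result has no value for %s at %g mm", m, d)
    }
    v <- result$recovery[[m]][j]
    pass <- v >= lim$lower[i] & v <= lim$upper[i]
    dev <- if (pass) 0 else if (v < lim$lower[i]) {
      100 * (v - lim$lower[i]) / lim$lower[i]
    } else {
      100 * (v - lim$upper[i]) / lim$upper[i]
    }
    rows[[i]] <- data.frame(diameter = d, metric = m, value = v,
                            lower = lim$lower[i], upper = lim$upper[i],
                            pass = pass, deviation_pct = dev)
  }
  structure(do.call(rbind, rows), class = c("compliance_report", "data.frame"))
}

#' @export
print.compliance_report <- function(x, ...) {
  cat(sprintf("<compliance: %d/%d pass>\n", sum(x$pass), nrow(x)))
  if (any(!x$pass)) {
    bad <- x[!x$pass, c("diameter", "metric", "value", "lower", "upper", "deviation_pct")]
    print(format(bad, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Percentage difference between two recovery values
#'
#' `100 * (rc_a - rc_b) / rc_b`, the percent deviation of `rc_a` from the
#' reference `rc_b` (e.g. BPL_beta against PSF_6.4).
#'
#' @param rc_a Value(s) to compare.
#' @param rc_b Reference value(s), > 0.
#' @return Percent difference.
#' @export
pct_difference <- function(rc_a, rc_b) {
  if (any(rc_b <= 0)) stop_nemaiq("invalid_reference", "reference must be > 0")
  100 * (rc_a - rc_b) / rc_b
}

#' Welch's unequal-variance t test
#'
#' Two-sided Welch t test with the Welch-Satterthwaite degrees of freedom,
#' as used to compare contrast recovery between isotopes.
#'
#' @param group_a,group_b Numeric vectors (each of length >= 2).
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_nemaiq("insufficient_data", "each group needs at least 2 values")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    eq <- mean(group_a) == mean(group_b)
    return(list(t = if (eq) 0 else sign(mean(group_a) - mean(group_b)) * Inf,
                df = length(group_a) + length(group_b) - 2,
                p = if (eq) 1 else 0))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}
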