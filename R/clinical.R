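#' Bland-Altman agreement of paired lesion uptake values
#'
#' Differences of (natural-)log-transformed paired SUVs, their mean and
#' sample SD, and the 95% limits of agreement `mean +/- 1.96 * SD`. The
#' count of pairs strictly outside the limits and the paired-t p value are
#' included. On the log scale the limits back-transform to ratio limits.
#'
#' @param suv_a,suv_b Paired per-lesion values (same lesions, same order),
#'   all > 0; at least 3 pairs.
#' @param log Log-transform before differencing (default `TRUE`).
#' @return Object of class `bland_altman` with `mean_diff`, `sd_diff`,
#'   `loa` (length 2), `differences`, `means`, `n_outside`, `t`, `df`, `p`.
#' @export
bland_altman <- function(suv_a, suv_b, log = TRUE) {
  if (length(suv_a) != length(suv_b)) {
    stop_nemaiq("invalid_parameter", "inputs must be paired (equal length)")
  }
  if (length(suv_a) < 3) stop_nemaiq("insufficient_pairs", "need at least 3 pairs")
  if (log) {
    if (any(suv_a <= 0) || any(suv_b <= 0)) {
      stop_nemaiq("invalid_suv", "SUVs must be > 0 for the log transform")
    }
    a <- base::log(suv_a); b <- base::log(suv_b)
  } else {
    a <- suv_a; b <- suv_b
  }
  d <- a - b
  md <- mean(d); sdd <- sd(d)
  loa <- md + c(-1.96, 1.96) * sdd
  tt <- paired_t_test(suv_a, suv_b, on_log = log)
  structure(list(mean_diff = md, sd_diff = sdd, loa = loa,
                 differences = d, means = (a + b) / 2,
                 n_outside = sum(abs(d - md) > 1.96 * sdd),
                 t = tt$t, df = tt$df, p = tt$p, log = log),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman (n = %d%s): mean diff %.4f, LoA [%.4f, %.4f], %d outside, p = %.3g>\n",
              length(x$differences), if (x$log) ", log scale" else "",
              x$mean_diff, x$loa[1], x$loa[2], x$n_outside, x$p))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences,
                 xlab = if (x$log) "mean of log SUVs" else "mean",
                 ylab = if (x$log) "difference of log SUVs" else "difference", ...)
  graphics::abline(h = x$mean_diff)
  graphics::abline(h = x$loa, lty = 2)
  invisible(x)
}

#' Paired t test on (log-transformed) lesion values
#'
#' Standard paired two-sided t test with n - 1 degrees of freedom, on log
#' differences by default.
#'
#' @param suv_a,suv_b Paired values; at least 3 pairs.
#' @param on_log Log-transform first (default `TRUE`).
#' @return List with `t`, `df`, `p`.
#' @export
paired_t_test <- function(suv_a, suv_b, on_log = TRUE) {
  if (length(suv_a) != length(suv_b)) {
    stop_nemaiq("invalid_parameter", "inputs must be paired (equal length)")
  }
  n <- length(suv_a)
  if (n < 3) stop_nemaiq("insufficient_pairs", "need at least 3 pairs")
  if (on_log) {
    if (any(suv_a <= 0) || any(suv_b <= 0)) {
      stop_nemaiq("invalid_suv", "SUVs must be > 0 for the log transform")
    }
    d <- base::log(suv_a) - base::log(suv_b)
  } else {
    d <- suv_a - suv_b
  }
  # essentially-constant differences (e.g. an exactly constant ratio): the
  # t statistic degenerates to 0 or +/-Inf
  if (sd(d) <= 1e-10 * (abs(mean(d)) + 1e-300)) {
    eq <- abs(mean(d)) <= 1e-12 * max(abs(c(suv_a, suv_b, 1)))
    return(list(t = if (eq) 0 else sign(mean(d)) * Inf, df = n - 1,
                p = if (eq) 1 else 0))
  }
  ht <- stats::t.test(d)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Default reconstruction-bias curve for the lesion generator
#'
#' Multiplicative SUV bias of each reconstruction relative to the PSF_6.4
#' reference: 1.0 for the reference and `exp(0.12 * (900 - beta) / 700)` for
#' BPL_beta — monotone decreasing in beta and passing through 1.0 between
#' beta = 800 and 1000, with about +13% at beta = 200.
#'
#' @param betas Penalisation factors to include.
#' @return Named numeric vector of biases.
#' @export
default_recon_bias <- function(betas = seq(200, 1200, by = 200)) {
  b <- exp(0.12 * (900 - betas) / 700)
  stats::setNames(c(1, b), c("PSF_6.4", sprintf("BPL_%d", betas)))
}

#' Generate a synthetic per-lesion SUV cohort
#'
#' Stands in for a clinical cohort of delineated lesions: per-lesion baseline
#' SUV_max values are drawn lognormally around site-specific medians
#' (prostate 8, lymph node 6, bone 5 g/ml), and each reconstruction's
#' measurement multiplies the baseline by its bias and by lognormal
#' measurement noise (`sd_log` on the log scale). SUV_mean and SUV_peak are
#' generated as fixed fractions (0.65 and 0.8) of SUV_max with small
#' independent jitter, capped at SUV_max. Deterministic under a fixed seed.
#'
#' @param n_lesions Number of lesions (>= 1); overridden by `sum(site_mix)`
#'   when `site_mix` is given as counts.
#' @param site_mix Named integer counts per site (default 13 prostate,
#'   9 lymph node, 2 bone).
#' @param bias_by_recon Named vector of multiplicative biases per
#'   reconstruction label; see [default_recon_bias()].
#' @param sd_log Per-reconstruction measurement noise, SD of log SUV.
#' @param sd_lesion Between-lesion spread, SD of log baseline (default 0.5).
#' @param seed Integer seed.
#' @return Data frame with columns `lesion_id`, `site`, `recon_label`,
#'   `suv_max`, `suv_mean`, `suv_peak` (long format, one row per lesion and
#'   reconstruction).
#' @export
generate_synthetic_lesions <- function(n_lesions = 24,
                                       site_mix = c(prostate = 13, lymph_node = 9, bone = 2),
                                       bias_by_recon = default_recon_bias(),
                                       sd_log = 0.06, sd_lesion = 0.5, seed = 1) {
  if (sd_log < 0) stop_nemaiq("invalid_parameter", "sd_log must be >= 0")
  sites <- rep(names(site_mix), times = site_mix)
  if (length(sites) != n_lesions) {
    sites <- rep(names(site_mix), length.out = n_lesions)
  }
  baseline <- c(prostate = 8, lymph_node = 6, bone = 5)[sites]
  state <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(state)) assign(".Random.seed", state, globalenv()), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max),
           kind = "Mersenne-Twister", normal.kind = "Inversion")
  base_max <- baseline * exp(rnorm(length(sites), 0, sd_lesion))
  out <- list()
  for (r in names(bias_by_recon)) {
    mx <- base_max * bias_by_recon[[r]] * exp(rnorm(length(sites), 0, sd_log))
    mn <- pmin(0.65 * mx * exp(rnorm(length(sites), 0, 0.05)), mx)
    pk <- pmin(0.80 * mx * exp(rnorm(length(sites), 0, 0.04)), mx)
    out[[r]] <- data.frame(lesion_id = seq_along(sites), site = sites,
                           recon_label = r, suv_max = mx, suv_mean = mn,
                           suv_peak = pk)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  rownames(res) <- NULL
  res
}

#' Bland-Altman comparison of every reconstruction against a reference
#'
#' @param lesions Long-format lesion table from
#'   [generate_synthetic_lesions()] or [read.csv()] in the same schema.
#' @param reference Reference reconstruction label (default `"PSF_6.4"`).
#' @param metric Which SUV column to compare.
#' @return Named list of [bland_altman()] results, one per non-reference
#'   reconstruction.
#' @export
compare_to_reference <- function(lesions, reference = "PSF_6.4",
                                 metric = "suv_max") {
  labs <- setdiff(unique(lesions$recon_label), reference)
  ref <- lesions[lesions$recon_label == reference, ]
  ref <- ref[order(ref$lesion_id), ]
  out <- lapply(labs, function(l) {
    x <- lesions[lesions$recon_label == l, ]
    x <- x[order(x$lesion_id), ]
    if (!identical(x$lesion_id, ref$lesion_id)) {
      stop_nemaiq("invalid_parameter", "lesion sets differ between reconstructions")
    }
    bland_altman(ref[[metric]], x[[metric]])
  })
  stats::setNames(out, labs)
}
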