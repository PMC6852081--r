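# Plot-level aggregation of census-interval rates and weighted category
# statistics with bootstrap confidence intervals.

#' Mean biomass change rate of a permanent plot
#'
#' The plot-level rate is the plain arithmetic mean of its census-interval
#' rates (intervals are not length-weighted by default; see
#' \code{\link{permanent_plot_summaries}}).
#'
#' @param rates Numeric vector of census-interval rates, Mg ha^-1 yr^-1
#'   (any sign), length \eqn{\ge} 1.
#' @param interval_years Optional interval lengths; used only when
#'   \code{weight_by_interval} is TRUE.
#' @param weight_by_interval Weight census rates by interval length
#'   (off by default).
#' @return Plot mean rate, Mg ha^-1 yr^-1.
#' @export
plot_mean_rate <- function(rates, interval_years = NULL,
                           weight_by_interval = FALSE) {
  if (length(rates) < 1) stop("a plot needs at least one census interval")
  if (weight_by_interval) {
    if (is.null(interval_years)) stop("interval_years required for weighting")
    weighted_mean(rates, interval_years)
  } else {
    mean(rates)
  }
}

#' Weight of a permanent plot
#'
#' Default scheme: plot area times total monitoring length
#' (ha \eqn{\times} yr). When every plot in a category shares identical area
#' and monitoring period the weights are set to 1 (handled by
#' \code{\link{permanent_plot_summaries}}); alternative schemes use area or
#' years alone, or equal weights.
#'
#' @param area_ha Plot area, ha (> 0).
#' @param monitoring_years Total monitoring period, years (> 0).
#' @param scheme One of \code{"area_x_years"} (default), \code{"area_only"},
#'   \code{"years_only"}, \code{"equal"}.
#' @return Nonnegative weight(s).
#' @export
plot_weight <- function(area_ha, monitoring_years,
                        scheme = c("area_x_years", "area_only",
                                   "years_only", "equal")) {
  scheme <- match.arg(scheme)
  if (any(area_ha <= 0) || any(monitoring_years <= 0)) {
    stop("area_ha and monitoring_years must be > 0")
  }
  switch(scheme,
         area_x_years = area_ha * monitoring_years,
         area_only = area_ha + 0 * monitoring_years,
         years_only = monitoring_years + 0 * area_ha,
         equal = rep(1, max(length(area_ha), length(monitoring_years))))
}

#' Weighted mean and weighted standard deviation
#'
#' \code{weighted_mean} is \eqn{\sum w_i x_i / \sum w_i}. The weighted SD
#' uses the frequency-style estimator
#' \deqn{\sqrt{\frac{\sum w_i (x_i - \bar x_w)^2}{\frac{M-1}{M}\sum w_i}}}
#' with \eqn{M} the number of nonzero weights, which reduces to the ordinary
#' sample SD under equal weights and is invariant to rescaling all weights.
#'
#' @param x Numeric rates.
#' @param w Nonnegative weights, same length; \eqn{\sum w > 0}.
#' @return Scalar, Mg ha^-1 yr^-1.
#' @export
weighted_mean <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0))
  if (sum(w) <= 0) stop("weights sum to zero")
  sum(w * x) / sum(w)
}

#' @rdname weighted_mean
#' @export
weighted_sd <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0))
  sw <- sum(w)
  if (sw <= 0) stop("weights sum to zero")
  m <- sum(w > 0)
  if (m < 2) return(0)
  xbar <- sum(w * x) / sw
  sqrt(sum(w * (x - xbar)^2) / ((m - 1) / m * sw))
}

#' Percentile bootstrap confidence interval for a weighted mean
#'
#' Plots are the independent resampling units: (rate, weight) pairs are
#' resampled jointly with replacement, the weighted mean is recomputed per
#' replicate, and the CI is the percentile interval of the replicate
#' distribution. Deterministic given \code{seed}.
#'
#' @param rates Plot-level rates (length \eqn{\ge} 2).
#' @param weights Nonnegative plot weights.
#' @param reps Number of bootstrap repetitions (default 1000).
#' @param seed Integer seed; \code{NULL} uses the current RNG stream.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Named numeric \code{c(low, high)}, Mg ha^-1 yr^-1.
#' @export
bootstrap_ci <- function(rates, weights = rep(1, length(rates)),
                         reps = 1000, seed = NULL, level = 0.95) {
  n <- length(rates)
  if (n < 2) stop("bootstrap requires at least 2 plots")
  stopifnot(length(weights) == n, reps >= 1, level > 0, level < 1)
  if (sum(weights) <= 0) stop("weights sum to zero")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  idx <- matrix(sample.int(n, n * reps, replace = TRUE), nrow = n)
  num <- colSums(matrix(weights[idx] * rates[idx], nrow = n))
  den <- colSums(matrix(weights[idx], nrow = n))
  stat <- num / den
  alpha <- (1 - level) / 2
  ci <- unname(quantile(stat, c(alpha, 1 - alpha), type = 7, na.rm = TRUE))
  c(low = ci[1], high = ci[2])
}

#' Summarise permanent-plot censuses into weighted plot rates
#'
#' Aggregates a census-interval table (one row per interval) to one row per
#' plot: the plot mean rate, total monitoring years, and the plot weight
#' under the chosen scheme. Within each continent x ecozone x status
#' category, if every plot has identical area and monitoring period all
#' weights collapse to 1.
#'
#' @param censuses Census table from \code{\link{read_permanent_plot_csv}}.
#' @param scheme Weighting scheme, see \code{\link{plot_weight}}.
#' @param weight_by_interval Weight census rates by interval length when
#'   averaging within a plot (off by default).
#' @return Data frame: \code{plot_id, continent, ecozone, status, rate,
#'   weight, n_censuses, monitoring_years, area_ha}.
#' @export
permanent_plot_summaries <- function(censuses, scheme = "area_x_years",
                                     weight_by_interval = FALSE) {
  rate_col <- if ("rate_agb" %in% names(censuses)) "rate_agb" else "rate"
  parts <- split(censuses, censuses$plot_id)
  rows <- lapply(parts, function(p) {
    area <- unique(p$area_ha)
    if (length(area) != 1) {
      stop("plot ", p$plot_id[1], " has inconsistent area_ha across censuses")
    }
    data.frame(
      plot_id = p$plot_id[1], continent = p$continent[1],
      ecozone = p$ecozone[1], status = p$status[1],
      rate = plot_mean_rate(p[[rate_col]], p$interval_years,
                            weight_by_interval),
      n_censuses = nrow(p),
      monitoring_years = sum(p$interval_years),
      area_ha = area, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$weight <- plot_weight(out$area_ha, out$monitoring_years, scheme)
  # uniform-category rule: identical area and monitoring period -> weight 1
  cat_key <- paste(out$continent, out$ecozone, out$status)
  for (k in unique(cat_key)) {
    sel <- cat_key == k
    if (length(unique(out$area_ha[sel])) == 1 &&
        length(unique(out$monitoring_years[sel])) == 1) {
      out$weight[sel] <- 1
    }
  }
  out <- out[order(out$plot_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
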