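# Category-level default-rate table assembly: pooling, minimum-data rules,
# the donor-continent recommendation ladder and IPCC-2006 fallback.

#' Normal-approximation confidence interval for a category mean
#'
#' \eqn{\bar x \pm z_{1-\alpha/2}\, SD/\sqrt{n}} with \eqn{z = 1.959964} at
#' the default 95\% level. This z-based interval is the normative rule for
#' secondary-forest categories (it reproduces the published refined default
#' tables at 1-decimal rounding, which a t-based interval does not).
#'
#' @param mean Category mean, Mg ha^-1 yr^-1.
#' @param sd Category SD (\eqn{\ge} 0).
#' @param n Number of sites (\eqn{\ge} 2).
#' @param level Confidence level, default 0.95.
#' @return Named numeric \code{c(low, high)}.
#' @export
normal_ci <- function(mean, sd, n, level = 0.95) {
  if (n < 2) stop("normal_ci requires n >= 2")
  if (sd < 0) stop("sd must be >= 0")
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sd / sqrt(n)
  c(low = mean - half, high = mean + half)
}

category_estimate <- function(continent, ecozone, forest_type, mean = NA_real_,
                              median = NA_real_, sd = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_,
                              n_sites = 0L, ci_method = NA_character_,
                              status = NA_character_, donor = NA_character_) {
  data.frame(continent = continent, ecozone = ecozone,
             forest_type = forest_type, mean = mean, median = median,
             sd = sd, ci_low = ci_low, ci_high = ci_high,
             n_sites = as.integer(n_sites), ci_method = ci_method,
             status = status, donor = donor, stringsAsFactors = FALSE)
}

#' Estimate a secondary-forest category from site rates
#'
#' Younger- and older-secondary categories pool site-specific rates
#' unweighted: the estimate is the arithmetic mean, median and sample SD
#' with a z-based 95\% CI (\code{\link{normal_ci}}). At least two site rates
#' are required; smaller categories return an empty estimate to be handled
#' by \code{\link{fill_gaps}}.
#'
#' @param rates Numeric site rates, Mg ha^-1 yr^-1.
#' @param continent,ecozone,forest_type Category labels.
#' @param level Confidence level, default 0.95.
#' @return One-row \code{CategoryEstimate} data frame.
#' @export
estimate_secondary_category <- function(rates, continent, ecozone,
                                        forest_type, level = 0.95) {
  if (length(rates) < 2) {
    return(category_estimate(continent, ecozone, forest_type,
                             n_sites = length(rates)))
  }
  m <- mean(rates)
  s <- sd(rates)
  ci <- normal_ci(m, s, length(rates), level)
  category_estimate(continent, ecozone, forest_type,
                    mean = m, median = median(rates), sd = s,
                    ci_low = ci[["low"]], ci_high = ci[["high"]],
                    n_sites = length(rates), ci_method = "analytic_z",
                    status = "derived")
}

#' Estimate an old-growth category from weighted plot rates
#'
#' Old-growth categories use the weighted mean and weighted SD of plot-level
#' rates (weights from plot area and monitoring length) and a percentile
#' bootstrap CI (plots resampled with replacement; 1,000 repetitions by
#' default). The median is unweighted.
#'
#' @param rates Plot-level mean rates, Mg ha^-1 yr^-1.
#' @param weights Nonnegative plot weights.
#' @param continent,ecozone Category labels.
#' @param reps Bootstrap repetitions, default 1000.
#' @param seed Integer seed for the bootstrap (deterministic given seed).
#' @param level Confidence level, default 0.95.
#' @return One-row \code{CategoryEstimate} data frame.
#' @export
estimate_og_category <- function(rates, weights = rep(1, length(rates)),
                                 continent = NA_character_,
                                 ecozone = NA_character_,
                                 reps = 1000, seed = NULL, level = 0.95) {
  if (length(rates) < 2) {
    return(category_estimate(continent, ecozone, "old_growth",
                             n_sites = length(rates)))
  }
  ci <- bootstrap_ci(rates, weights, reps = reps, seed = seed, level = level)
  category_estimate(continent, ecozone, "old_growth",
                    mean = weighted_mean(rates, weights),
                    median = median(rates),
                    sd = weighted_sd(rates, weights),
                    ci_low = ci[["low"]], ci_high = ci[["high"]],
                    n_sites = length(rates), ci_method = "bootstrap",
                    status = "derived")
}

#' Pool managed/logged plot rates into the older-secondary category
#'
#' Managed/logged forest data, when available, are combined with the
#' older-secondary forest type of the same continent and ecozone: each
#' managed plot contributes its plot-mean rate as one additional site-level
#' observation, and the pooled category is then estimated unweighted with
#' \code{\link{estimate_secondary_category}}.
#'
#' @param os_site_rates Numeric older-secondary site rates.
#' @param managed_plot_rates Numeric managed/logged plot-mean rates (may be
#'   empty).
#' @return Numeric vector of pooled site-level rates.
#' @export
pool_managed_into_os <- function(os_site_rates, managed_plot_rates) {
  c(os_site_rates, managed_plot_rates)
}

#' Fill empty categories by the recommendation ladder
#'
#' Empty cells of the category table are filled in a fixed order:
#' \enumerate{
#'   \item one donor continent has a derived rate for the same ecozone and
#'     forest type: copy it (\code{status = "recommended_from_donor"});
#'   \item both other continents have derived rates: choose the donor whose
#'     mean lies closest (mean absolute difference) to the derived means of
#'     the \emph{other} forest types in the target continent and ecozone;
#'     ties break to the donor with more sites, then to the fixed continent
#'     order Africa, NorthSouthAmerica, Asia;
#'   \item no donor anywhere: use the user-supplied IPCC-2006 default
#'     (\code{status = "ipcc2006_fallback"}), with older-secondary and
#'     old-growth both mapped to the 2006 ">20 years" class.
#' }
#' Derived cells are never overwritten and the operation is idempotent.
#'
#' @param table Category table covering the full continent x ecozone x
#'   forest-type universe (empty cells have \code{NA} status).
#' @param ipcc2006 IPCC-2006 fallback config: a data frame or list of
#'   records with \code{ecozone}, \code{continent}, \code{secondary_le20},
#'   \code{gt20} (see \code{\link{read_ipcc2006_config}}). May be
#'   \code{NULL} if no rung-3 cell occurs.
#' @return The completed table.
#' @export
fill_gaps <- function(table, ipcc2006 = NULL) {
  ipcc2006 <- normalize_ipcc2006(ipcc2006)
  derived <- table[!is.na(table$status) & table$status == "derived", ,
                   drop = FALSE]
  empty <- which(is.na(table$status))
  for (i in empty) {
    tgt <- table[i, ]
    donors <- derived[derived$ecozone == tgt$ecozone &
                        derived$forest_type == tgt$forest_type &
                        derived$continent != tgt$continent, , drop = FALSE]
    if (nrow(donors) >= 1) {
      donor <- if (nrow(donors) == 1) donors else {
        pick_aligned_donor(donors, derived, tgt)
      }
      table$mean[i] <- donor$mean
      table$median[i] <- donor$median
      table$sd[i] <- donor$sd
      table$ci_low[i] <- donor$ci_low
      table$ci_high[i] <- donor$ci_high
      table$n_sites[i] <- donor$n_sites
      table$ci_method[i] <- donor$ci_method
      table$status[i] <- "recommended_from_donor"
      table$donor[i] <- donor$continent
    } else {
      val <- ipcc2006_value(ipcc2006, tgt$ecozone, tgt$continent,
                            tgt$forest_type)
      table$mean[i] <- val
      table$status[i] <- "ipcc2006_fallback"
    }
  }
  table
}

# rung 2: donor whose mean best aligns with the target cell's other
# forest-type means; ties -> larger n_sites -> continent order
pick_aligned_donor <- function(donors, derived, tgt) {
  others <- derived[derived$ecozone == tgt$ecozone &
                      derived$continent == tgt$continent &
                      derived$forest_type != tgt$forest_type, , drop = FALSE]
  score <- if (nrow(others)) {
    vapply(donors$mean, function(m) mean(abs(m - others$mean)), numeric(1))
  } else {
    rep(0, nrow(donors))  # no reference values: fall through to tie-breaks
  }
  ord <- order(score, -donors$n_sites, match(donors$continent, CONTINENTS))
  donors[ord[1], , drop = FALSE]
}

normalize_ipcc2006 <- function(cfg) {
  if (is.null(cfg)) return(NULL)
  if (is.data.frame(cfg)) return(cfg)
  if (is.list(cfg)) {
    recs <- cfg$rates %||% cfg
    df <- do.call(rbind, lapply(recs, function(r) {
      data.frame(ecozone = r$ecozone, continent = r$continent,
                 secondary_le20 = as.numeric(r$secondary_le20),
                 gt20 = as.numeric(r$gt20), stringsAsFactors = FALSE)
    }))
    return(df)
  }
  stop("unrecognized ipcc2006 config")
}

ipcc2006_value <- function(cfg, ecozone, continent, forest_type) {
  cell <- paste(continent, ecozone, forest_type, sep = " / ")
  if (is.null(cfg)) {
    stop("no IPCC-2006 fallback configured, required for cell: ", cell)
  }
  row <- cfg[cfg$ecozone == ecozone & cfg$continent == continent, ,
             drop = FALSE]
  if (nrow(row) == 0) {
    stop("IPCC-2006 config has no entry for cell: ", cell)
  }
  if (forest_type == "younger_secondary") row$secondary_le20[1] else
    row$gt20[1]  # older-secondary and old-growth collapse to ">20 years"
}

#' Read an IPCC-2006 fallback configuration (YAML)
#'
#' The fallback table is user-supplied, one record per ecozone x continent
#' with \code{secondary_le20} and \code{gt20} rates (Mg ha^-1 yr^-1) under a
#' top-level \code{rates:} key.
#'
#' @param path Path to the YAML file.
#' @return Data frame with columns \code{ecozone, continent,
#'   secondary_le20, gt20}.
#' @export
read_ipcc2006_config <- function(path) {
  normalize_ipcc2006(yaml::read_yaml(path))
}

#' Render the default-rate table
#'
#' Formats a category table IPCC-style: one row per continent x ecozone x
#' forest type with all rates rounded half-away-from-zero to one decimal
#' (rounding is applied only here; the pipeline keeps full precision).
#'
#' @param table Completed category table (\code{\link{fill_gaps}} output).
#' @return Data frame with rounded numeric columns, ordered by ecozone,
#'   continent, forest type; class \code{"default_rate_table"} so that
#'   printing shows an aligned text table.
#' @export
render_table <- function(table) {
  out <- table
  for (col in c("mean", "median", "sd", "ci_low", "ci_high")) {
    out[[col]] <- round_half_away(out[[col]], 1)
  }
  out <- out[order(match(out$ecozone, ECOZONES),
                   match(out$continent, CONTINENTS),
                   match(out$forest_type, FOREST_TYPES)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("default_rate_table", "data.frame")
  out
}

#' @export
print.default_rate_table <- function(x, ...) {
  ft_code <- c(younger_secondary = "YS", older_secondary = "OS",
               old_growth = "OG")
  df <- data.frame(
    Ecozone = x$ecozone, Continent = x$continent,
    Type = ft_code[x$forest_type],
    Mean = fmt1(x$mean), Median = fmt1(x$median), SD = fmt1(x$sd),
    `CI (95%)` = ifelse(is.na(x$ci_low), "",
                        paste0(fmt1(x$ci_low), ", ", fmt1(x$ci_high))),
    n = ifelse(x$n_sites > 0, x$n_sites, ""),
    Status = x$status, check.names = FALSE
  )
  print.data.frame(df, row.names = FALSE, right = FALSE)
  invisible(x)
}

fmt1 <- function(x) ifelse(is.na(x), "", sprintf("%.1f", x))

#' Derive the full default-rate table from plot data
#'
#' The end-to-end pipeline: validates and filters chronosequence records,
#' groups proximate sites per continent, fits the growth models and extracts
#' site rates, aggregates permanent-plot censuses, pools managed/logged
#' plots into older-secondary categories, estimates every category with
#' sufficient data (\eqn{\ge} 2 sites/plots), fills the remaining cells by
#' the recommendation ladder, and renders the table.
#'
#' @param chrono Chronosequence records (data frame or CSV path).
#' @param plots Permanent-plot census table (data frame or CSV path); may
#'   be \code{NULL}.
#' @param ipcc2006 IPCC-2006 fallback config (data frame, list, or YAML
#'   path); may be \code{NULL}.
#' @param seed Integer seed for the old-growth bootstraps (default
#'   20190816).
#' @param reps Bootstrap repetitions, default 1000.
#' @param level Confidence level, default 0.95.
#' @param scheme Plot weighting scheme, see \code{\link{plot_weight}}.
#' @param cells Optional data frame (\code{continent}, \code{ecozone})
#'   restricting the category universe; defaults to every continent x
#'   ecozone combination observed in the input data.
#' @return List: \code{table} (full-precision category table),
#'   \code{rendered} (rounded display table), \code{site_rates},
#'   \code{plot_rates}, \code{report} (filter and grouping counts).
#' @export
derive_rates <- function(chrono, plots = NULL, ipcc2006 = NULL,
                         seed = 20190816, reps = 1000, level = 0.95,
                         scheme = "area_x_years", cells = NULL) {
  records <- if (is.character(chrono)) read_chronosequence_csv(chrono) else
    as_chrono_records(chrono)
  records <- apply_inclusion_filters(records)
  filter_report <- attr(records, "filter_report")

  grouped <- list()
  group_report <- list()
  for (ct in intersect(CONTINENTS, unique(records$continent))) {
    g <- group_proximate_sites(records[records$continent == ct, ,
                                       drop = FALSE], ct)
    group_report[[ct]] <- attr(g, "group_report")
    grouped[[ct]] <- g
  }
  grouped <- if (length(grouped)) do.call(rbind, grouped) else
    cbind(records[0, ], chrono_id = character(0))

  chrono_res <- chronosequence_site_rates(grouped)
  srates <- chrono_res$rates

  censuses <- if (is.null(plots)) NULL else if (is.character(plots)) {
    read_permanent_plot_csv(plots)
  } else {
    as_census_records(plots)
  }
  prates <- if (is.null(censuses) || nrow(censuses) == 0) {
    data.frame(plot_id = character(0), continent = character(0),
               ecozone = character(0), status = character(0),
               rate = numeric(0), weight = numeric(0))
  } else {
    permanent_plot_summaries(censuses, scheme)
  }

  if (is.character(ipcc2006)) ipcc2006 <- read_ipcc2006_config(ipcc2006)

  if (is.null(cells)) {
    cells <- unique(rbind(
      if (nrow(srates)) srates[c("continent", "ecozone")] else NULL,
      if (nrow(prates)) prates[c("continent", "ecozone")] else NULL
    ))
  }
  universe <- merge(cells, data.frame(forest_type = FOREST_TYPES))
  universe <- universe[order(match(universe$ecozone, ECOZONES),
                             match(universe$continent, CONTINENTS),
                             match(universe$forest_type, FOREST_TYPES)), ]

  rows <- vector("list", nrow(universe))
  for (i in seq_len(nrow(universe))) {
    u <- universe[i, ]
    if (u$forest_type == "old_growth") {
      sel <- prates$continent == u$continent & prates$ecozone == u$ecozone &
        prates$status == "old_growth"
      rows[[i]] <- estimate_og_category(
        prates$rate[sel], prates$weight[sel], u$continent, u$ecozone,
        reps = reps, seed = seed + i, level = level)
    } else {
      sel <- srates$continent == u$continent & srates$ecozone == u$ecozone &
        srates$forest_type == u$forest_type
      r <- if (nrow(srates)) srates$rate[sel] else numeric(0)
      if (u$forest_type == "older_secondary") {
        msel <- prates$continent == u$continent &
          prates$ecozone == u$ecozone & prates$status == "managed_logged"
        r <- pool_managed_into_os(r, prates$rate[msel])
      }
      rows[[i]] <- estimate_secondary_category(r, u$continent, u$ecozone,
                                               u$forest_type, level)
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  table <- fill_gaps(table, ipcc2006)

  list(table = table, rendered = render_table(table),
       site_rates = srates, plot_rates = prates,
       report = list(filters = filter_report, grouping = group_report))
}

#' Write derive_rates outputs to disk
#'
#' @param result A \code{\link{derive_rates}} result.
#' @param table_csv Path for the rounded table CSV.
#' @param report_json Optional path for the JSON filter/grouping report.
#' @return Invisibly, \code{table_csv}.
#' @export
write_rate_table <- function(result, table_csv, report_json = NULL) {
  out <- result$rendered
  out <- out[c("ecozone", "continent", "forest_type", "mean", "median",
               "sd", "ci_low", "ci_high", "n_sites", "ci_method", "status",
               "donor")]
  names(out)[names(out) == "n_sites"] <- "n"
  write.csv(out, table_csv, row.names = FALSE, na = "")
  if (!is.null(report_json)) write_filter_report(result$report, report_json)
  invisible(table_csv)
}
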