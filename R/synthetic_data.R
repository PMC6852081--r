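# Generators for chronosequence and permanent-plot datasets with known
# ground truth, mirroring the generative assumptions of the analysis.

with_seed_local <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Parameters for the chronosequence generator
#'
#' The generator mirrors the analysis model: per site \eqn{i}, deviations
#' \eqn{(b_{0i}, b_{1i})} are drawn from a bivariate normal with the given
#' SDs and correlation, plot ages are drawn over \code{age_range} (uniform,
#' or log-uniform to emulate the typical skew toward young stands), and
#' \deqn{AGB = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i})\ln(age) +
#'   N(0, \sigma_{resid}),}
#' floored at 0 (with the flooring count reported).
#'
#' @param n_sites Number of chronosequence sites.
#' @param plots_per_site Plots per site: a count, or a \code{c(min, max)}
#'   range sampled uniformly.
#' @param age_range Stand-age range in years, within (0, 100].
#' @param beta0,beta1 Fixed intercept and ln-age slope, Mg/ha.
#' @param sd_b0,sd_b1 SDs of the site random intercept and slope, Mg/ha.
#' @param corr_b0b1 Correlation of the random effects, in [-1, 1].
#' @param sd_resid Residual SD, Mg/ha.
#' @param continent,ecozone Category labels for the generated records.
#' @param age_sampling \code{"uniform"} or \code{"log_uniform"}.
#' @param seed Integer seed (reproducible: same params + seed give
#'   identical output).
#' @return A validated parameter list of class \code{chrono_sim_params}.
#' @export
chrono_sim_params <- function(n_sites = 30, plots_per_site = 8,
                              age_range = c(1, 80), beta0 = 10, beta1 = 35,
                              sd_b0 = 10, sd_b1 = 5, corr_b0b1 = 0,
                              sd_resid = 10,
                              continent = "NorthSouthAmerica",
                              ecozone = "tropical_rainforest",
                              age_sampling = c("uniform", "log_uniform"),
                              seed = 1L) {
  age_sampling <- match.arg(age_sampling)
  stopifnot(n_sites >= 1, all(plots_per_site >= 1),
            length(age_range) == 2, age_range[1] > 0,
            age_range[2] <= 100, age_range[1] <= age_range[2],
            sd_b0 >= 0, sd_b1 >= 0, abs(corr_b0b1) <= 1, sd_resid >= 0,
            continent %in% CONTINENTS, ecozone %in% ECOZONES)
  structure(as.list(environment()), class = "chrono_sim_params")
}

#' Simulate chronosequence plot records with known truth
#'
#' @param params A \code{\link{chrono_sim_params}} object.
#' @param site_prefix Prefix for generated site ids.
#' @return List with \code{records} (the chronosequence CSV schema),
#'   \code{truth} (per-site intercept/slope and analytic younger- and
#'   older-secondary rates between the realised anchors) and
#'   \code{n_floored} (AGB values floored at 0).
#' @export
simulate_chronosequences <- function(params, site_prefix = "site") {
  stopifnot(inherits(params, "chrono_sim_params"))
  p <- params
  with_seed_local(p$seed, {
    n <- p$n_sites
    # bivariate normal site deviations
    z1 <- rnorm(n); z2 <- rnorm(n)
    b0 <- p$sd_b0 * z1
    b1 <- p$sd_b1 * (p$corr_b0b1 * z1 + sqrt(1 - p$corr_b0b1^2) * z2)
    npl <- if (length(p$plots_per_site) == 2) {
      sample(seq(p$plots_per_site[1], p$plots_per_site[2]), n, replace = TRUE)
    } else rep(p$plots_per_site, n)

    site_ids <- sprintf("%s%03d", site_prefix, seq_len(n))
    # synthetic grid coordinates, spaced so no proximity grouping triggers
    lat <- ((seq_len(n) - 1) %% 17) * 5 - 40
    lon <- (((seq_len(n) - 1) %/% 17) * 5) %% 160 - 20

    recs <- vector("list", n)
    truth <- vector("list", n)
    floored <- 0L
    for (i in seq_len(n)) {
      ages <- switch(p$age_sampling,
        uniform = runif(npl[i], p$age_range[1], p$age_range[2]),
        log_uniform = exp(runif(npl[i], log(p$age_range[1]),
                                log(p$age_range[2]))))
      mu <- (p$beta0 + b0[i]) + (p$beta1 + b1[i]) * log(ages)
      agb <- mu + rnorm(npl[i], 0, p$sd_resid)
      floored <- floored + sum(agb < 0)
      agb <- pmax(agb, 0)
      recs[[i]] <- data.frame(
        record_id = sprintf("%s_p%02d", site_ids[i], seq_len(npl[i])),
        site_id = site_ids[i], continent = p$continent,
        ecozone = p$ecozone, lat = lat[i], lon = lon[i],
        stand_age = ages, value = agb, value_type = "agb",
        carbon_fraction = NA_real_, in_continental_us = FALSE,
        stringsAsFactors = FALSE
      )
      slope <- p$beta1 + b1[i]
      intercept <- p$beta0 + b0[i]
      min_age <- min(ages); max_age <- max(ages)
      anchor_low <- if (min_age <= 20) 20 else min_age
      truth[[i]] <- data.frame(
        chrono_id = site_ids[i], b0 = b0[i], b1 = b1[i],
        intercept = intercept, slope = slope,
        min_age = min_age, max_age = max_age,
        ys_rate_true = if (min_age <= 20) {
          (intercept + slope * log(20)) / 20
        } else NA_real_,
        os_anchor_low = anchor_low,
        os_rate_true = if (max_age > anchor_low) {
          slope * (log(max_age) - log(anchor_low)) / (max_age - anchor_low)
        } else NA_real_,
        stringsAsFactors = FALSE
      )
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(records = records, truth = truth, n_floored = floored)
  })
}

#' Parameters for the permanent-plot generator
#'
#' Plot true rates are drawn \eqn{N(\mu, \sigma_{plot})}; census-interval
#' rates around the plot truth with SD \eqn{\sigma_{census}}; plot areas and
#' monitoring spans uniform over their ranges; the monitoring span is split
#' evenly across the plot's census intervals. Negative \eqn{\mu} is legal
#' (declining old-growth stands occur).
#'
#' @param n_plots Number of plots.
#' @param mu_rate True category mean rate, Mg ha^-1 yr^-1 (any sign).
#' @param sd_plot Between-plot SD of true rates.
#' @param sd_census Within-plot census-to-census SD.
#' @param censuses_per_plot A count or \code{c(min, max)} range.
#' @param area_range Plot area range, ha.
#' @param years_range Total monitoring period range, years.
#' @param status \code{"old_growth"} or \code{"managed_logged"}.
#' @param continent,ecozone Category labels.
#' @param seed Integer seed.
#' @return A validated parameter list of class \code{plot_sim_params}.
#' @export
plot_sim_params <- function(n_plots = 30, mu_rate = 1.0, sd_plot = 2.0,
                            sd_census = 1.0, censuses_per_plot = c(1, 5),
                            area_range = c(0.25, 10),
                            years_range = c(5, 30),
                            status = "old_growth",
                            continent = "NorthSouthAmerica",
                            ecozone = "tropical_rainforest", seed = 1L) {
  stopifnot(n_plots >= 1, sd_plot >= 0, sd_census >= 0,
            all(censuses_per_plot >= 1), all(area_range > 0),
            all(years_range > 0),
            status %in% c("old_growth", "managed_logged"),
            continent %in% CONTINENTS, ecozone %in% ECOZONES)
  structure(as.list(environment()), class = "plot_sim_params")
}

#' Simulate permanent-plot census records with known truth
#'
#' @param params A \code{\link{plot_sim_params}} object.
#' @param plot_prefix Prefix for generated plot ids.
#' @return List with \code{censuses} (the permanent-plot CSV schema, one row
#'   per census interval) and \code{truth} (\code{mu_rate} plus each plot's
#'   true rate).
#' @export
simulate_permanent_plots <- function(params, plot_prefix = "plot") {
  stopifnot(inherits(params, "plot_sim_params"))
  p <- params
  with_seed_local(p$seed, {
    n <- p$n_plots
    true_rate <- rnorm(n, p$mu_rate, p$sd_plot)
    ncen <- if (length(p$censuses_per_plot) == 2) {
      sample(seq(p$censuses_per_plot[1], p$censuses_per_plot[2]), n,
             replace = TRUE)
    } else rep(p$censuses_per_plot, n)
    area <- runif(n, p$area_range[1], p$area_range[2])
    years <- runif(n, p$years_range[1], p$years_range[2])
    ids <- sprintf("%s%03d", plot_prefix, seq_len(n))
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      rows[[i]] <- data.frame(
        plot_id = ids[i], continent = p$continent, ecozone = p$ecozone,
        status = p$status, area_ha = area[i],
        interval_years = rep(years[i] / ncen[i], ncen[i]),
        rate = rnorm(ncen[i], true_rate[i], p$sd_census),
        value_type = "agb", carbon_fraction = NA_real_,
        stringsAsFactors = FALSE
      )
    }
    censuses <- do.call(rbind, rows)
    rownames(censuses) <- NULL
    truth <- data.frame(plot_id = ids, true_rate = true_rate,
                        area_ha = area, monitoring_years = years,
                        stringsAsFactors = FALSE)
    list(censuses = censuses,
         truth = list(mu_rate = p$mu_rate, plots = truth))
  })
}

#' Build the end-to-end study fixture
#'
#' A small synthetic two-ecozone dataset exercising every stage of the
#' pipeline, with a documented truth ledger:
#' \itemize{
#'   \item tropical rainforest chronosequences on all three continents
#'     (the Asian ones only \eqn{\le} 20 yr old, so their older-secondary
#'     cell is empty and must be filled from two donor continents);
#'   \item tropical moist forest chronosequences in Africa only (the
#'     American and Asian moist cells fall to the single-donor rung);
#'   \item old-growth rainforest plots on all continents, but no moist
#'     old-growth anywhere (those cells fall to the IPCC-2006 fallback);
#'   \item managed/logged rainforest plots in the Americas and Africa
#'     (pooled into older-secondary);
#'   \item one record in the continental US and one secondary record aged
#'     101 yr, each dropped by an inclusion filter.
#' }
#'
#' @param seed Integer seed.
#' @return List: \code{chrono} (records), \code{plots} (censuses),
#'   \code{ipcc2006} (fallback config data frame), \code{cells} (the
#'   category universe to evaluate), \code{truth} (generator truth ledgers
#'   and the expected gap-filling outcome per empty cell).
#' @export
make_study_fixture <- function(seed = 20190816) {
  groups <- list(
    rf_africa = chrono_sim_params(
      n_sites = 8, plots_per_site = 6, age_range = c(1, 80),
      beta0 = 15, beta1 = 45, sd_b0 = 8, sd_b1 = 6, sd_resid = 15,
      continent = "Africa", ecozone = "tropical_rainforest",
      seed = seed + 1),
    rf_americas = chrono_sim_params(
      n_sites = 12, plots_per_site = 6, age_range = c(1, 80),
      beta0 = 10, beta1 = 36, sd_b0 = 8, sd_b1 = 5, sd_resid = 12,
      continent = "NorthSouthAmerica", ecozone = "tropical_rainforest",
      seed = seed + 2),
    rf_asia = chrono_sim_params(
      n_sites = 8, plots_per_site = 5, age_range = c(1, 20),
      beta0 = 8, beta1 = 20, sd_b0 = 6, sd_b1 = 4, sd_resid = 8,
      continent = "Asia", ecozone = "tropical_rainforest",
      seed = seed + 3),
    moist_africa = chrono_sim_params(
      n_sites = 12, plots_per_site = 6, age_range = c(1, 80),
      beta0 = 8, beta1 = 18, sd_b0 = 6, sd_b1 = 3, sd_resid = 10,
      continent = "Africa", ecozone = "tropical_moist_forest",
      seed = seed + 4)
  )
  chrono_parts <- list()
  chrono_truth <- list()
  for (nm in names(groups)) {
    sim <- simulate_chronosequences(groups[[nm]],
                                    site_prefix = paste0(nm, "_s"))
    chrono_parts[[nm]] <- sim$records
    chrono_truth[[nm]] <- sim$truth
  }
  chrono <- do.call(rbind, chrono_parts)
  rownames(chrono) <- NULL

  # records that must be dropped by the inclusion filters
  extra <- data.frame(
    record_id = c("us_record", "overage_record"),
    site_id = c("us_site", "moist_africa_s001"),
    continent = c("NorthSouthAmerica", "Africa"),
    ecozone = c("tropical_rainforest", "tropical_moist_forest"),
    lat = c(35, -5), lon = c(-100, 20),
    stand_age = c(15, 101), value = c(60, 250), value_type = "agb",
    carbon_fraction = NA_real_, in_continental_us = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  chrono <- rbind(chrono, extra)

  plot_groups <- list(
    og_rf_africa = plot_sim_params(
      n_plots = 20, mu_rate = 1.3, sd_plot = 2.0, sd_census = 1.0,
      continent = "Africa", ecozone = "tropical_rainforest",
      status = "old_growth", seed = seed + 11),
    og_rf_americas = plot_sim_params(
      n_plots = 20, mu_rate = 1.0, sd_plot = 2.0, sd_census = 1.0,
      continent = "NorthSouthAmerica", ecozone = "tropical_rainforest",
      status = "old_growth", seed = seed + 12),
    og_rf_asia = plot_sim_params(
      n_plots = 20, mu_rate = 0.7, sd_plot = 2.0, sd_census = 1.0,
      continent = "Asia", ecozone = "tropical_rainforest",
      status = "old_growth", seed = seed + 13),
    ml_rf_americas = plot_sim_params(
      n_plots = 10, mu_rate = 1.6, sd_plot = 1.5, sd_census = 1.0,
      continent = "NorthSouthAmerica", ecozone = "tropical_rainforest",
      status = "managed_logged", seed = seed + 14),
    ml_rf_africa = plot_sim_params(
      n_plots = 10, mu_rate = 1.2, sd_plot = 1.5, sd_census = 1.0,
      continent = "Africa", ecozone = "tropical_rainforest",
      status = "managed_logged", seed = seed + 15)
  )
  plot_parts <- list()
  plot_truth <- list()
  for (nm in names(plot_groups)) {
    sim <- simulate_permanent_plots(plot_groups[[nm]],
                                    plot_prefix = paste0(nm, "_p"))
    plot_parts[[nm]] <- sim$censuses
    plot_truth[[nm]] <- sim$truth
  }
  plots <- do.call(rbind, plot_parts)
  rownames(plots) <- NULL

  ipcc2006 <- expand.grid(continent = CONTINENTS,
                          ecozone = c("tropical_rainforest",
                                      "tropical_moist_forest"),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ipcc2006$secondary_le20 <- c(10, 7, 9, 6, 7, 5.5)
  ipcc2006$gt20 <- c(3.1, 1.3, 2.2, 2.0, 1.8, 1.4)

  expected_gap_fills <- data.frame(
    continent = c("Asia", "NorthSouthAmerica", "NorthSouthAmerica", "Asia",
                  "Asia", "Africa", "NorthSouthAmerica", "Asia"),
    ecozone = c("tropical_rainforest", rep("tropical_moist_forest", 2),
                rep("tropical_moist_forest", 2),
                rep("tropical_moist_forest", 3)),
    forest_type = c("older_secondary", "younger_secondary",
                    "older_secondary", "younger_secondary",
                    "older_secondary", "old_growth", "old_growth",
                    "old_growth"),
    expected_status = c("recommended_from_donor", rep("recommended_from_donor", 4),
                        rep("ipcc2006_fallback", 3)),
    expected_donor = c(NA, "Africa", "Africa", "Africa", "Africa",
                       NA, NA, NA),
    stringsAsFactors = FALSE
  )

  cells <- expand.grid(continent = CONTINENTS,
                       ecozone = c("tropical_rainforest",
                                   "tropical_moist_forest"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  list(chrono = chrono, plots = plots, ipcc2006 = ipcc2006, cells = cells,
       truth = list(chrono = chrono_truth, plots = plot_truth,
                    params = list(chrono = groups, plots = plot_groups),
                    expected_gap_fills = expected_gap_fills))
}

#' Write a study fixture to a directory
#'
#' Writes \code{chrono.csv}, \code{plots.csv}, \code{ipcc2006.yaml} and
#' \code{truth.json} in the schemas the readers expect.
#'
#' @param fixture A \code{\link{make_study_fixture}} result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
write_study_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(fixture$chrono, file.path(dir, "chrono.csv"), row.names = FALSE)
  write.csv(fixture$plots, file.path(dir, "plots.csv"), row.names = FALSE)
  yaml::write_yaml(
    list(rates = lapply(seq_len(nrow(fixture$ipcc2006)), function(i) {
      as.list(fixture$ipcc2006[i, ])
    })),
    file.path(dir, "ipcc2006.yaml"))
  jsonlite::write_json(fixture$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
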