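test_that("z-based normal CI reproduces published category intervals after rounding", {
  ci <- normal_ci(7.6, 5.9, 15)
  expect_equal(round_half_away(ci, 1), c(low = 4.6, high = 10.6))
  ci2 <- normal_ci(2.7, 3.1, 2)
  expect_equal(round_half_away(ci2, 1), c(low = -1.6, high = 7.0))
  expect_equal(normal_ci(3, 0, 10), c(low = 3, high = 3))
  expect_error(normal_ci(1, 1, 1), "n >= 2")
  # symmetry: low + high = 2 * mean
  set.seed(3)
  for (i in 1:25) {
    m <- rnorm(1); s <- runif(1, 0, 4); n <- sample(2:50, 1)
    ci <- normal_ci(m, s, n)
    expect_equal(ci[["low"]] + ci[["high"]], 2 * m, tolerance = 1e-9)
  }
})

test_that("secondary category estimates use mean/median/sample SD and analytic CI", {
  est <- estimate_secondary_category(c(2.9 - 1 / sqrt(2), 2.9 + 1 / sqrt(2)),
                                     "Africa", "tropical_moist_forest",
                                     "younger_secondary")
  expect_equal(est$mean, 2.9)
  expect_equal(est$sd, 1.0)
  expect_equal(round_half_away(c(est$ci_low, est$ci_high), 1), c(1.5, 4.3))
  expect_identical(est$ci_method, "analytic_z")
  expect_identical(est$status, "derived")

  est2 <- estimate_secondary_category(c(5, 5, 5), "Asia",
                                      "tropical_rainforest",
                                      "older_secondary")
  expect_equal(c(est2$mean, est2$sd, est2$ci_low, est2$ci_high),
               c(5, 0, 5, 5))

  est3 <- estimate_secondary_category(1:4, "Asia", "tropical_rainforest",
                                      "younger_secondary")
  expect_equal(est3$mean, 2.5)
  expect_equal(est3$median, 2.5)
  expect_equal(est3$sd, sd(1:4), tolerance = 1e-9)

  # fewer than two rates: empty estimate forwarded to gap filling
  e <- estimate_secondary_category(2.2, "Asia", "tropical_rainforest",
                                   "younger_secondary")
  expect_true(is.na(e$status))
  expect_equal(e$n_sites, 1L)
})

test_that("old-growth estimates combine weighted stats with a bootstrap CI", {
  est <- estimate_og_category(c(0, 2), continent = "Asia",
                              ecozone = "tropical_rainforest", seed = 9)
  expect_equal(est$mean, 1.0)
  expect_gte(est$ci_low, 0)
  expect_lte(est$ci_high, 2)
  expect_identical(est$ci_method, "bootstrap")

  est2 <- estimate_og_category(rep(1.7, 5), weights = c(1, 2, 3, 4, 5),
                               seed = 1)
  expect_equal(c(est2$mean, est2$sd, est2$ci_low, est2$ci_high),
               c(1.7, 0, 1.7, 1.7))

  # simulation: estimate close to the generating mean at n = 250
  sim <- simulate_permanent_plots(plot_sim_params(
    n_plots = 250, mu_rate = 1.0, sd_plot = 2.0, sd_census = 0.5,
    seed = 31))
  sm <- permanent_plot_summaries(as_census_records(sim$censuses))
  est3 <- estimate_og_category(sm$rate, sm$weight, seed = 7)
  expect_lt(abs(est3$mean - 1.0), 2 * 2 / sqrt(250) + 0.1)
})

test_that("managed/logged rates pool into older-secondary unweighted", {
  pooled <- pool_managed_into_os(c(2, 2, 2), 5)
  expect_length(pooled, 4)
  expect_equal(mean(pooled), 2.75)
  expect_equal(pool_managed_into_os(c(1, 2), numeric(0)), c(1, 2))
  est <- estimate_secondary_category(pooled, "Africa",
                                     "tropical_rainforest",
                                     "older_secondary")
  expect_equal(est$n_sites, 4L)
})

test_that("the gap-filling ladder fills by donor, alignment, then IPCC-2006 fallback", {
  tab <- rbind(
    # target continent has YS derived; OS empty with one donor
    estimate_secondary_category(c(4, 6), "Africa", "tropical_dry_forest",
                                "younger_secondary"),
    deltagb:::category_estimate("Africa", "tropical_dry_forest", "older_secondary"),
    estimate_secondary_category(c(1.5, 2.5), "NorthSouthAmerica",
                                "tropical_dry_forest", "older_secondary"),
    # rung 2 target: YS empty, two donors with different distances to the
    # target's other-type mean (OS mean 2.0)
    deltagb:::category_estimate("NorthSouthAmerica", "tropical_dry_forest",
                      "younger_secondary"),
    estimate_secondary_category(c(1.9, 2.1), "Asia", "tropical_dry_forest",
                                "younger_secondary"),
    # rung 3 target: no old-growth data anywhere
    deltagb:::category_estimate("Africa", "tropical_dry_forest", "old_growth")
  )
  cfg <- data.frame(ecozone = "tropical_dry_forest", continent = "Africa",
                    secondary_le20 = 4.5, gt20 = 1.2,
                    stringsAsFactors = FALSE)
  out <- fill_gaps(tab, cfg)

  os_afr <- out[out$continent == "Africa" &
                  out$forest_type == "older_secondary", ]
  expect_identical(os_afr$status, "recommended_from_donor")
  expect_identical(os_afr$donor, "NorthSouthAmerica")
  expect_equal(os_afr$mean, 2.0)

  # rung 2: donors Africa YS (5.0) and Asia YS (2.0); the Americas' own OS
  # mean is 2.0, so the Asia donor aligns better (|2-2| < |5-2|)
  ys_na <- out[out$continent == "NorthSouthAmerica" &
                 out$forest_type == "younger_secondary", ]
  expect_identical(ys_na$donor, "Asia")
  expect_equal(ys_na$mean, 2.0)

  # rung 3: old-growth falls back to the config's >20-years class
  og <- out[out$forest_type == "old_growth", ]
  expect_identical(og$status, "ipcc2006_fallback")
  expect_equal(og$mean, 1.2)

  # derived cells untouched; idempotent
  expect_identical(out$mean[1], tab$mean[1])
  expect_identical(fill_gaps(out, cfg), out)

  # missing config entry is a hard error naming the cell
  tab2 <- rbind(tab[1:5, ],
                deltagb:::category_estimate("Asia", "tropical_dry_forest",
                                            "old_growth"))
  expect_error(fill_gaps(tab2, cfg), "Asia / tropical_dry_forest")
})

test_that("rung-2 alignment is computed by brute force over both donors", {
  # enumerate both donor choices against the target's other-type means
  donors <- data.frame(continent = c("Africa", "Asia"), mean = c(2.0, 6.0))
  other_means <- c(2.5, 3.0)
  scores <- vapply(donors$mean,
                   function(m) mean(abs(m - other_means)), numeric(1))
  best <- donors$continent[which.min(scores)]
  expect_identical(best, "Africa")

  tab <- rbind(
    estimate_secondary_category(c(1.9, 2.1), "Africa",
                                "tropical_shrubland", "younger_secondary"),
    estimate_secondary_category(c(5.9, 6.1), "Asia",
                                "tropical_shrubland", "younger_secondary"),
    estimate_secondary_category(c(2.4, 2.6), "NorthSouthAmerica",
                                "tropical_shrubland", "older_secondary"),
    estimate_og_category(c(2.8, 3.2), continent = "NorthSouthAmerica",
                         ecozone = "tropical_shrubland", seed = 2),
    deltagb:::category_estimate("NorthSouthAmerica", "tropical_shrubland",
                      "younger_secondary")
  )
  out <- fill_gaps(tab)
  filled <- out[out$status == "recommended_from_donor", ]
  expect_identical(filled$donor, best)
  expect_equal(filled$mean, 2.0)
})

test_that("rendering rounds half away from zero and round-trips at 1 decimal", {
  tab <- rbind(
    estimate_secondary_category(c(5.945, 5.945), "Africa",
                                "tropical_rainforest", "younger_secondary"),
    estimate_secondary_category(c(2.7, 2.8), "Asia",
                                "tropical_rainforest", "older_secondary")
  )
  tab$status <- "derived"
  out <- render_table(tab)
  expect_equal(out$mean, c(5.9, 2.8))  # 5.945 -> 5.9, 2.75 -> 2.8
  expect_equal(round_half_away(-1.596, 1), -1.6)
  expect_equal(round_half_away(c(-0.05, 0.05, 2.75, -2.75), 1),
               c(-0.1, 0.1, 2.8, -2.8))
  # CSV round trip preserves the 1-decimal values
  res <- list(rendered = out,
              report = list())
  path <- withr::local_tempfile(fileext = ".csv")
  write_rate_table(res, path)
  rt <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(rt$mean, out$mean)
  expect_equal(rt$ci_low, out$ci_low)
})

test_that("published-table fixture: YS >= OS >= OG within complete categories", {
  pub <- published_table()
  key <- paste(pub$ecozone, pub$continent)
  for (k in unique(key)) {
    sub <- pub[key == k, ]
    if (all(c("younger_secondary", "older_secondary", "old_growth") %in%
            sub$forest_type)) {
      m <- setNames(sub$mean, sub$forest_type)
      expect_gte(m[["younger_secondary"]], m[["older_secondary"]])
      expect_gte(m[["older_secondary"]], m[["old_growth"]])
    }
  }
})

test_that("derive_rates runs end to end on the study fixture with correct ladder statuses", {
  fx <- make_study_fixture(17)
  res <- derive_rates(fx$chrono, fx$plots, fx$ipcc2006, seed = 17,
                      reps = 200, cells = fx$cells)
  tab <- res$table
  expect_equal(nrow(tab), 18)  # 3 continents x 2 ecozones x 3 types
  expect_true(all(!is.na(tab$status)))
  for (i in seq_len(nrow(fx$truth$expected_gap_fills))) {
    e <- fx$truth$expected_gap_fills[i, ]
    row <- tab[tab$continent == e$continent & tab$ecozone == e$ecozone &
                 tab$forest_type == e$forest_type, ]
    expect_identical(row$status, e$expected_status)
    if (!is.na(e$expected_donor)) {
      expect_identical(row$donor, e$expected_donor)
    }
  }
  # derived cells satisfy the CategoryEstimate invariants
  der <- tab[tab$status == "derived", ]
  expect_true(all(der$ci_low <= der$ci_high))
  expect_true(all(der$n_sites >= 2))
  expect_true(all((der$ci_method == "bootstrap") ==
                    (der$forest_type == "old_growth")))
})
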