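test_that("carbon-to-biomass conversion inverts multiplication by the carbon fraction", {
  expect_equal(convert_to_agb(47, is_carbon = TRUE), 100)
  expect_equal(convert_to_agb(80, is_carbon = FALSE), 80)
  expect_equal(convert_to_agb(25, is_carbon = TRUE, cf = 0.5), 50)

  set.seed(42)
  for (i in 1:50) {
    agb <- runif(1, 0, 400)
    cf <- runif(1, 0.01, 1)
    expect_equal(convert_to_agb(agb * cf, TRUE, cf), agb,
                 tolerance = 1e-9)
  }
  expect_error(convert_to_agb(-1, FALSE, record_id = "bad1"), "bad1")
  expect_error(convert_to_agb(10, TRUE, cf = 1.2, record_id = "bad2"),
               "bad2")
})

test_that("forest-type classification respects the 20/100-year cut-offs and is exclusive", {
  expect_equal(classify_forest_type(stand_age = 20), "younger_secondary")
  expect_equal(classify_forest_type(stand_age = 20.5), "older_secondary")
  expect_equal(classify_forest_type(last_disturbance = 150), "old_growth")
  expect_equal(classify_forest_type(stand_age = 40,
                                    intervention = "partial"),
               "managed_logged")
  expect_error(classify_forest_type(), "at least one")
  expect_error(classify_forest_type(last_disturbance = 150,
                                    intervention = "partial"),
               "contradictory")

  # total and mutually exclusive on a grid of valid inputs
  for (age in c(0.5, 1, 19.9, 20, 20.1, 99, 100)) {
    out <- classify_forest_type(stand_age = age)
    expect_length(out, 1)
    expect_true(out %in% c("younger_secondary", "older_secondary"))
    expect_identical(out, if (age <= 20) "younger_secondary" else
      "older_secondary")
  }
})

test_that("inclusion filters drop US and over-age records and report counts", {
  df <- as_chrono_records(chrono_df(
    site_id = paste0("s", 1:5), stand_age = c(10, 101, 30, 50, 15),
    value = 100, in_continental_us = c(FALSE, FALSE, TRUE, FALSE, FALSE)))
  out <- apply_inclusion_filters(df)
  rep <- attr(out, "filter_report")
  expect_equal(nrow(out), 3)
  expect_equal(rep$us, 1)
  expect_equal(rep$age_gt_100, 1)
  expect_equal(rep$us + rep$age_gt_100, rep$n_in - rep$n_out)

  empty <- apply_inclusion_filters(df[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "filter_report")$us, 0)
})

test_that("validation rejects bad records instead of dropping them", {
  expect_error(as_chrono_records(chrono_df("s1", stand_age = 0, value = 10)),
               "stand_age")
  expect_error(as_chrono_records(chrono_df("s1", stand_age = 10,
                                           value = NA)), "missing AGB")
  expect_error(as_chrono_records(chrono_df("s1", 10, 10, lat = 95)),
               "lat")
  expect_warning(
    as_chrono_records(cbind(chrono_df("s1", 10, 10), extra_col = 1)),
    "unknown column")
})

test_that("proximity grouping merges by single linkage under continental thresholds", {
  # two African sites 1.4 degrees apart: merged
  df <- as_chrono_records(chrono_df(
    site_id = c("a", "a", "b", "b"), stand_age = c(5, 10, 15, 22),
    value = c(30, 60, 80, 95), lat = c(0, 0, 1.4, 1.4), lon = 0))
  g <- group_proximate_sites(df, "Africa")
  expect_equal(length(unique(g$chrono_id)), 1)
  expect_setequal(g$site_id, c("a", "b"))

  # 1.6 degrees apart: not merged (each site still has 2 distinct ages)
  df2 <- as_chrono_records(chrono_df(
    site_id = c("a", "a", "b", "b"), stand_age = c(5, 10, 15, 22),
    value = c(30, 60, 80, 95), lat = c(0, 0, 1.6, 1.6), lon = 0))
  g2 <- group_proximate_sites(df2, "Africa")
  expect_equal(length(unique(g2$chrono_id)), 2)

  # Asian chain A-B 3, B-C 3, A-C 6: one component via single linkage
  df3 <- as_chrono_records(chrono_df(
    site_id = rep(c("A", "B", "C"), each = 2),
    stand_age = rep(c(5, 15), 3), value = rep(c(40, 70), 3),
    lat = rep(c(0, 3, 6), each = 2), lon = 0, continent = "Asia"))
  g3 <- group_proximate_sites(df3, "Asia")
  expect_equal(length(unique(g3$chrono_id)), 1)
  # brute-force oracle: connected component over all below-threshold pairs
  coords <- c(A = 0, B = 3, C = 6)
  adj <- abs(outer(coords, coords, "-")) < 4.0
  expect_true(all(adj[c("A", "B"), c("B", "C")][c(1, 4)]))

  # idempotence: regrouping the output changes nothing
  g3b <- group_proximate_sites(g3[names(df3)], "Asia")
  expect_equal(g3b$chrono_id, g3$chrono_id)

  expect_error(group_proximate_sites(rbind(df, df3)), "single continent")
})

test_that("Americas chronosequences need >= 3 plots; Africa/Asia need 2 distinct ages", {
  df <- as_chrono_records(chrono_df(
    site_id = c("a", "a", "a", "b", "b"), stand_age = c(5, 10, 20, 5, 10),
    value = 50, continent = "NorthSouthAmerica",
    lat = c(0, 0, 0, 30, 30)))
  g <- group_proximate_sites(df, "NorthSouthAmerica")
  expect_setequal(unique(g$chrono_id), "a")
  expect_equal(attr(g, "group_report")$dropped, 1)

  # African site with a single distinct age is dropped even unmerged
  df2 <- as_chrono_records(chrono_df(
    site_id = c("x", "x"), stand_age = c(7, 7), value = c(40, 45),
    lat = c(0, 0)))
  g2 <- group_proximate_sites(df2, "Africa")
  expect_equal(nrow(g2), 0)
})

test_that("CSV round trips preserve validated records", {
  df <- chrono_df(site_id = c("s1", "s1", "s2", "s2"),
                  stand_age = c(4, 18, 33, 60),
                  value = c(20, 90, 47, 120),
                  value_type = c("agb", "agb", "carbon", "agb"))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  rt <- read_chronosequence_csv(path)
  expect_equal(rt$stand_age, df$stand_age)
  expect_equal(rt$agb, c(20, 90, 47 / 0.47, 120))

  cen <- data.frame(plot_id = c("p1", "p1", "p2"), continent = "Asia",
                    ecozone = "tropical_rainforest", status = "old_growth",
                    area_ha = c(1, 1, 0.5), interval_years = c(5, 5, 10),
                    rate = c(1.2, -0.4, 0.94), value_type = c("agb", "agb",
                                                              "carbon"),
                    carbon_fraction = NA_real_, stringsAsFactors = FALSE)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(cen, path2, row.names = FALSE)
  rt2 <- read_permanent_plot_csv(path2)
  expect_equal(rt2$rate_agb, c(1.2, -0.4, 2), tolerance = 1e-12)
  expect_error(as_census_records(transform(cen, area_ha = 0)), "area_ha")
})
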