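# shared helpers: tiny in-code fixtures and oracles

chrono_df <- function(site_id, stand_age, value, continent = "Africa",
                      ecozone = "tropical_rainforest", lat = 0, lon = 0,
                      value_type = "agb", carbon_fraction = NA_real_,
                      in_continental_us = FALSE) {
  n <- max(length(site_id), length(stand_age))
  data.frame(
    record_id = paste0("r", seq_len(n)),
    site_id = rep_len(site_id, n), continent = rep_len(continent, n),
    ecozone = rep_len(ecozone, n), lat = rep_len(lat, n),
    lon = rep_len(lon, n), stand_age = rep_len(stand_age, n),
    value = rep_len(value, n), value_type = rep_len(value_type, n),
    carbon_fraction = rep_len(carbon_fraction, n),
    in_continental_us = rep_len(in_continental_us, n),
    stringsAsFactors = FALSE
  )
}

# exact log-linear chronosequence records (no noise) for k sites
loglinear_records <- function(intercepts, slopes, ages) {
  rows <- lapply(seq_along(intercepts), function(i) {
    data.frame(chrono_id = paste0("s", i), stand_age = ages,
               agb = intercepts[i] + slopes[i] * log(ages),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# brute-force weighted statistics oracle (naive loops, independent of the
# vectorised implementation)
oracle_weighted_mean <- function(x, w) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + w[i] * x[i]
    den <- den + w[i]
  }
  num / den
}
oracle_weighted_sd <- function(x, w) {
  m <- 0
  for (wi in w) if (wi > 0) m <- m + 1
  if (m < 2) return(0)
  xb <- oracle_weighted_mean(x, w)
  s <- 0
  for (i in seq_along(x)) s <- s + w[i] * (x[i] - xb)^2
  sqrt(s / ((m - 1) / m * sum(w)))
}

published_table <- function() {
  read.csv(system.file("extdata", "refined_rates_2019.csv",
                       package = "deltagb"), stringsAsFactors = FALSE)
}
agb20_table <- function() {
  read.csv(system.file("extdata", "agb_at_20_2019.csv",
                       package = "deltagb"), stringsAsFactors = FALSE)
}
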