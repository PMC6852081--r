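# Reading, validation, classification and filtering of plot-level inputs.

CHRONO_COLUMNS <- c(
  "record_id", "site_id", "continent", "ecozone", "lat", "lon",
  "stand_age", "value", "value_type", "carbon_fraction", "in_continental_us"
)
PLOT_COLUMNS <- c(
  "plot_id", "continent", "ecozone", "status", "area_ha",
  "interval_years", "rate", "value_type", "carbon_fraction"
)

#' Convert aboveground carbon to aboveground biomass
#'
#' Values reported as aboveground carbon (Mg C/ha, or Mg C/ha/yr for change
#' rates) are converted to dry biomass by dividing by the carbon fraction
#' cited in the original source or, when none is given, by the IPCC default
#' fraction of 0.47. Values already reported as biomass pass through
#' unchanged.
#'
#' @param value Numeric vector, Mg/ha (biomass or carbon). Must be
#'   non-negative for stocks; change rates may be negative (see
#'   \code{allow_negative}).
#' @param is_carbon Logical vector: is the value aboveground carbon?
#' @param cf Carbon fraction(s) in (0, 1]; \code{NA} means "not cited", in
#'   which case 0.47 is used.
#' @param allow_negative Permit negative values (for change rates).
#' @param record_id Optional ids used in error messages.
#' @return Numeric vector of AGB values, Mg/ha.
#' @examples
#' convert_to_agb(47, is_carbon = TRUE)        # 100
#' convert_to_agb(25, is_carbon = TRUE, cf = 0.5)  # 50
#' @export
convert_to_agb <- function(value, is_carbon, cf = NA_real_,
                           allow_negative = FALSE, record_id = NULL) {
  n <- max(length(value), length(is_carbon))
  value <- rep_len(value, n)
  is_carbon <- rep_len(is_carbon, n)
  cf <- rep_len(cf, n)
  ids <- rep_len(record_id %||% as.character(seq_len(n)), n)

  bad_val <- !is.finite(value) | (!allow_negative & value < 0)
  if (any(bad_val)) {
    stop("invalid value (negative or non-finite) for record(s): ",
         paste(ids[bad_val], collapse = ", "))
  }
  bad_cf <- !is.na(cf) & (cf <= 0 | cf > 1)
  if (any(bad_cf)) {
    stop("carbon_fraction outside (0, 1] for record(s): ",
         paste(ids[bad_cf], collapse = ", "))
  }
  cf_use <- ifelse(is.na(cf), IPCC_CARBON_FRACTION, cf)
  ifelse(is_carbon, value / cf_use, value)
}

#' Classify a stand into an IPCC forest type
#'
#' Stands are classified from stand age, time since last anthropogenic
#' disturbance, and/or the kind of intervention recorded:
#' \itemize{
#'   \item stand age \eqn{\le} 20 yr: \code{younger_secondary};
#'   \item 20 < age \eqn{\le} 100 yr: \code{older_secondary};
#'   \item no recorded anthropogenic disturbance for \eqn{\ge} 100 yr:
#'     \code{old_growth};
#'   \item partial stand disturbance (selective logging, silvicultural
#'     treatment): \code{managed_logged}.
#' }
#'
#' @param stand_age Years since stand initiation, or \code{NA}.
#' @param last_disturbance Years since last anthropogenic disturbance, or
#'   \code{NA}.
#' @param intervention One of \code{"none"}, \code{"partial"} (selective
#'   logging / silviculture), or \code{NA}.
#' @return One of \code{"younger_secondary"}, \code{"older_secondary"},
#'   \code{"old_growth"}, \code{"managed_logged"}.
#' @export
classify_forest_type <- function(stand_age = NA_real_,
                                 last_disturbance = NA_real_,
                                 intervention = NA_character_) {
  stopifnot(length(stand_age) == 1, length(last_disturbance) == 1,
            length(intervention) == 1)
  if (is.na(stand_age) && is.na(last_disturbance) && is.na(intervention)) {
    stop("at least one of stand_age, last_disturbance or intervention ",
         "must be provided")
  }
  if (!is.na(intervention) && !intervention %in% c("none", "partial")) {
    stop("unknown intervention: ", intervention)
  }
  partial <- !is.na(intervention) && intervention == "partial"
  undisturbed_100 <- (!is.na(last_disturbance) && last_disturbance >= 100) ||
    (!is.na(stand_age) && stand_age > 100 &&
       (is.na(intervention) || intervention == "none"))
  if (partial && undisturbed_100) {
    stop("contradictory metadata: partial intervention recorded for a stand ",
         "flagged undisturbed for >= 100 years")
  }
  if (partial) return("managed_logged")
  # age since disturbance doubles as stand age for secondary stands
  age <- if (!is.na(stand_age)) stand_age else last_disturbance
  if (undisturbed_100) return("old_growth")
  if (!is.na(age)) {
    if (age <= 20) return("younger_secondary")
    if (age <= 100) return("older_secondary")
  }
  stop("cannot classify: age ", age, " with no disturbance record")
}

validate_chrono_records <- function(df) {
  problems <- character(0)
  chk <- function(cond, msg) {
    if (any(cond)) {
      problems <<- c(problems, paste0(
        msg, ": ", paste(df$record_id[cond], collapse = ", ")))
    }
  }
  chk(is.na(df$stand_age) | df$stand_age <= 0, "stand_age missing or <= 0")
  chk(is.na(df$value), "missing AGB value")
  chk(!is.na(df$lat) & abs(df$lat) > 90, "|lat| > 90")
  chk(!is.na(df$lon) & abs(df$lon) > 180, "|lon| > 180")
  chk(!df$continent %in% CONTINENTS, "unknown continent")
  chk(!df$ecozone %in% ECOZONES, "unknown ecozone")
  chk(!df$value_type %in% c("agb", "carbon"), "value_type not agb|carbon")
  if (length(problems)) {
    stop("invalid chronosequence records:\n  ",
         paste(problems, collapse = "\n  "))
  }
  invisible(df)
}

#' Read and validate a chronosequence CSV
#'
#' Expected columns: \code{record_id, site_id, continent, ecozone, lat, lon,
#' stand_age, value, value_type, carbon_fraction, in_continental_us}. Carbon
#' values are converted to AGB on read. Unknown columns are dropped with a
#' warning; records with non-positive age or missing values are rejected with
#' an error (not silently dropped).
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A data frame of validated records with an \code{agb} column
#'   (Mg/ha).
#' @export
read_chronosequence_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_chrono_records(df)
}

#' Validate an in-memory chronosequence table
#'
#' @param df Data frame with the chronosequence CSV columns.
#' @return Validated record data frame with computed \code{agb}.
#' @rdname read_chronosequence_csv
#' @export
as_chrono_records <- function(df) {
  unknown <- setdiff(names(df), CHRONO_COLUMNS)
  if (length(unknown)) {
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "))
    df <- df[intersect(names(df), CHRONO_COLUMNS)]
  }
  missing <- setdiff(setdiff(CHRONO_COLUMNS, c("carbon_fraction",
                                               "in_continental_us")),
                     names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(df$carbon_fraction)) df$carbon_fraction <- NA_real_
  if (is.null(df$in_continental_us)) df$in_continental_us <- FALSE
  df$record_id <- as.character(df$record_id)
  df$site_id <- as.character(df$site_id)
  df$in_continental_us <- as.logical(df$in_continental_us)
  validate_chrono_records(df)
  df$agb <- convert_to_agb(df$value, df$value_type == "carbon",
                           df$carbon_fraction, record_id = df$record_id)
  df
}

#' Apply the study-design inclusion filters
#'
#' Drops records located in the continental United States and secondary-stand
#' records older than 100 years. The counts removed by each rule are attached
#' as the \code{"filter_report"} attribute (and satisfy
#' \code{sum(report) == nrow(in) - nrow(out)}).
#'
#' @param records Validated chronosequence records
#'   (\code{\link{read_chronosequence_csv}}).
#' @return Filtered records with a \code{filter_report} attribute listing
#'   \code{us} and \code{age_gt_100} counts.
#' @export
apply_inclusion_filters <- function(records) {
  us <- !is.na(records$in_continental_us) & records$in_continental_us
  over_age <- !us & records$stand_age > 100
  out <- records[!(us | over_age), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- list(
    us = sum(us), age_gt_100 = sum(over_age),
    n_in = nrow(records), n_out = nrow(out)
  )
  out
}

#' Group proximate chronosequence sites
#'
#' In Africa and Asia, sites in the same ecozone closer than a continental
#' threshold (1.5 and 4.0 decimal degrees respectively; Euclidean distance on
#' latitude/longitude) are merged into single chronosequences via
#' single-linkage (connected components of the below-threshold graph). In the
#' Americas no merging occurs, and chronosequences with fewer than 3 plots
#' are excluded; in Africa/Asia a (merged) chronosequence must retain at
#' least 2 plots at distinct stand ages to support a slope.
#'
#' @param records Validated, filtered chronosequence records, all from one
#'   continent.
#' @param continent Continent of the records; defaulted from the data.
#' @return The records that survive, with a \code{chrono_id} column naming
#'   the (possibly merged) chronosequence each plot belongs to, plus a
#'   \code{"group_report"} attribute (counts of merged sites and dropped
#'   chronosequences).
#' @export
group_proximate_sites <- function(records,
                                  continent = unique(records$continent)) {
  if (length(continent) != 1) {
    stop("records must all belong to a single continent; got: ",
         paste(continent, collapse = ", "))
  }
  if (nrow(records) == 0) {
    records$chrono_id <- character(0)
    attr(records, "group_report") <- list(merged_sites = 0, dropped = 0)
    return(records)
  }
  stopifnot(all(records$continent == continent))

  # site representative coordinates (sites are points; mean guards dupes)
  sites <- unique(records$site_id)
  lat <- tapply(records$lat, records$site_id, mean)[sites]
  lon <- tapply(records$lon, records$site_id, mean)[sites]
  zone <- tapply(records$ecozone, records$site_id,
                 function(z) z[[1]])[sites]

  chrono_of <- setNames(sites, sites)
  if (continent %in% names(PROXIMITY_THRESHOLD)) {
    thr <- PROXIMITY_THRESHOLD[[continent]]
    for (ez in unique(zone)) {
      idx <- which(zone == ez)
      if (length(idx) < 2) next
      d <- as.matrix(dist(cbind(lat[idx], lon[idx])))
      comp <- connected_components(d < thr)
      for (k in unique(comp)) {
        members <- sites[idx[comp == k]]
        chrono_of[members] <- paste(sort(members), collapse = "+")
      }
    }
  }
  records$chrono_id <- unname(chrono_of[records$site_id])

  # minimum-size rules
  keep <- rep(TRUE, nrow(records))
  dropped <- 0L
  for (id in unique(records$chrono_id)) {
    sel <- records$chrono_id == id
    ok <- if (continent == "NorthSouthAmerica") {
      sum(sel) >= 3
    } else {
      length(unique(records$stand_age[sel])) >= 2
    }
    if (!ok) {
      keep[sel] <- FALSE
      dropped <- dropped + 1L
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "group_report") <- list(
    merged_sites = sum(chrono_of != names(chrono_of)),
    dropped = dropped
  )
  out
}

# connected components of an undirected adjacency matrix (single linkage)
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n)
  current <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    current <- current + 1L
    frontier <- i
    comp[i] <- current
    while (length(frontier)) {
      nb <- which(adj[frontier[1], ] & comp == 0L)
      comp[nb] <- current
      frontier <- c(frontier[-1], nb)
    }
  }
  comp
}

#' Read a permanent-plot census CSV
#'
#' One row per census interval. Expected columns: \code{plot_id, continent,
#' ecozone, status, area_ha, interval_years, rate, value_type,
#' carbon_fraction}. Carbon change rates are converted to biomass change on
#' read (negative rates are legal: old-growth stands may lose biomass).
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A data frame of census intervals with a \code{rate_agb} column
#'   (Mg ha^-1 yr^-1).
#' @export
read_permanent_plot_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_census_records(df)
}

#' @rdname read_permanent_plot_csv
#' @param df Data frame with the permanent-plot CSV columns.
#' @export
as_census_records <- function(df) {
  unknown <- setdiff(names(df), PLOT_COLUMNS)
  if (length(unknown)) {
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "))
    df <- df[intersect(names(df), PLOT_COLUMNS)]
  }
  missing <- setdiff(setdiff(PLOT_COLUMNS, "carbon_fraction"), names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(df$carbon_fraction)) df$carbon_fraction <- NA_real_
  df$plot_id <- as.character(df$plot_id)
  problems <- character(0)
  chk <- function(cond, msg) {
    if (any(cond)) {
      problems <<- c(problems,
                     paste0(msg, ": ", paste(df$plot_id[cond], collapse = ", ")))
    }
  }
  chk(is.na(df$area_ha) | df$area_ha <= 0, "area_ha missing or <= 0")
  chk(is.na(df$interval_years) | df$interval_years <= 0,
      "interval_years missing or <= 0")
  chk(is.na(df$rate), "missing rate")
  chk(!df$status %in% c("old_growth", "managed_logged"),
      "status not old_growth|managed_logged")
  chk(!df$continent %in% CONTINENTS, "unknown continent")
  chk(!df$ecozone %in% ECOZONES, "unknown ecozone")
  if (length(problems)) {
    stop("invalid census records:\n  ", paste(problems, collapse = "\n  "))
  }
  df$rate_agb <- convert_to_agb(df$rate, df$value_type == "carbon",
                                df$carbon_fraction, allow_negative = TRUE,
                                record_id = df$plot_id)
  df
}

#' Write a filter/grouping report as JSON
#'
#' @param report A named list of counts (e.g. the \code{filter_report}
#'   attribute).
#' @param path Output path for the JSON file.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
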