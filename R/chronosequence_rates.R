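# Mixed-effects AGB ~ ln(stand age) growth curves and site-specific
# secondary-forest biomass change rates.

#' Fit the AGB--ln(stand age) mixed-effects growth model
#'
#' Fits, by REML,
#' \deqn{AGB_{ij} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i})\,\ln(age_{ij}) +
#'   \varepsilon_{ij}}
#' with correlated site-level random intercepts \eqn{b_{0i}} and slopes
#' \eqn{b_{1i}}, one model per continent-by-ecozone stratum of
#' chronosequences. Site-specific curves are the fixed effects plus the
#' shrunken (BLUP) site deviations.
#'
#' When the full model fails to converge or is singular, the fit degrades in
#' a fixed order: drop the random-effect correlation, then drop the random
#' slope, then fall back to independent per-site ordinary least squares. The
#' structure actually used is recorded in \code{fit_method} /
#' \code{ranef_structure} and \code{converged} is set honestly.
#'
#' @param records Data frame with columns \code{chrono_id}, \code{stand_age}
#'   (> 0) and \code{agb} (output of \code{\link{group_proximate_sites}}, or
#'   any table with those columns).
#' @return An object of class \code{growth_model_fit}: fixed effects
#'   \code{beta0}, \code{beta1}; \code{site_effects} (per-chronosequence
#'   intercept/slope deviations); \code{var_components} (\code{sd_b0},
#'   \code{sd_b1}, \code{corr_b0b1}, \code{sd_resid}); \code{converged};
#'   \code{fit_method}; and a per-site age summary used by
#'   \code{\link{site_rates}}.
#' @export
fit_growth_model <- function(records) {
  stopifnot(all(c("chrono_id", "stand_age", "agb") %in% names(records)))
  if (any(records$stand_age <= 0)) stop("stand ages must be > 0")
  ids <- unique(records$chrono_id)

  # every site with all-identical ages is unusable for a slope
  degenerate <- vapply(ids, function(id) {
    ages <- records$stand_age[records$chrono_id == id]
    length(unique(ages)) < 2
  }, logical(1))
  if (all(degenerate)) {
    stop("rank-deficient input: every chronosequence has a single distinct ",
         "stand age; cannot identify a slope")
  }

  dat <- data.frame(
    chrono_id = factor(records$chrono_id, levels = ids),
    ln_age = log(records$stand_age),
    agb = records$agb
  )

  fit <- NULL
  structure_used <- NA_character_
  converged <- FALSE
  if (length(ids) >= 2) {
    forms <- list(
      corr_slope = agb ~ ln_age + (1 + ln_age | chrono_id),
      uncorr_slope = agb ~ ln_age + (1 + ln_age || chrono_id),
      intercept_only = agb ~ ln_age + (1 | chrono_id)
    )
    for (nm in names(forms)) {
      cand <- try_lmer(forms[[nm]], dat)
      if (!is.null(cand)) {
        fit <- cand
        structure_used <- nm
        converged <- TRUE
        break
      }
    }
  }

  if (is.null(fit)) {
    return(fit_per_site_ols(dat, ids, converged = FALSE))
  }

  fe <- lme4::fixef(fit)
  re <- lme4::ranef(fit)$chrono_id
  b0 <- if ("(Intercept)" %in% colnames(re)) re[ids, "(Intercept)"] else
    rep(0, length(ids))
  b1 <- if ("ln_age" %in% colnames(re)) re[ids, "ln_age"] else
    rep(0, length(ids))
  vc <- lme4::VarCorr(fit)
  vdf <- as.data.frame(vc)
  pick <- function(v1, v2 = NA) {
    row <- vdf$grp != "Residual" & vdf$var1 %in% v1 &
      (if (is.na(v2)) is.na(vdf$var2) else vdf$var2 %in% v2)
    if (any(row)) vdf$sdcor[row][1] else 0
  }
  var_components <- list(
    sd_b0 = pick("(Intercept)"),
    sd_b1 = pick("ln_age"),
    corr_b0b1 = if (structure_used == "corr_slope")
      pick("(Intercept)", "ln_age") else 0,
    sd_resid = vdf$sdcor[vdf$grp == "Residual"][1]
  )

  new_growth_model_fit(
    beta0 = unname(fe[["(Intercept)"]]),
    beta1 = unname(fe[["ln_age"]]),
    site_effects = data.frame(chrono_id = ids, b0 = unname(b0),
                              b1 = unname(b1), stringsAsFactors = FALSE),
    var_components = var_components,
    converged = converged,
    fit_method = "REML",
    ranef_structure = structure_used,
    records = records
  )
}

# attempt one lmer structure; NULL on error, warning, or singular fit
try_lmer <- function(formula, dat) {
  res <- tryCatch(
    withCallingHandlers(
      lme4::lmer(formula, data = dat, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE)),
      warning = function(w) invokeRestart("muffleWarning"),
      message = function(m) invokeRestart("muffleMessage")
    ),
    error = function(e) NULL
  )
  if (is.null(res)) return(NULL)
  msgs <- unlist(res@optinfo$conv$lme4$messages)
  if (length(msgs) || lme4::isSingular(res, tol = 1e-5)) return(NULL)
  res
}

# independent OLS per site; fixed effects are the pooled OLS line
fit_per_site_ols <- function(dat, ids, converged) {
  pooled <- lm(agb ~ ln_age, data = dat)
  beta <- coef(pooled)
  eff <- lapply(ids, function(id) {
    d <- dat[dat$chrono_id == id, ]
    if (length(unique(d$ln_age)) < 2) {
      # slope unidentifiable: keep pooled slope, refit intercept
      c(mean(d$agb) - beta[[2]] * mean(d$ln_age), beta[[2]])
    } else {
      coef(lm(agb ~ ln_age, data = d))
    }
  })
  eff <- do.call(rbind, eff)
  site_slopes <- eff[, 2]
  new_growth_model_fit(
    beta0 = unname(beta[[1]]),
    beta1 = unname(beta[[2]]),
    site_effects = data.frame(chrono_id = ids,
                              b0 = unname(eff[, 1] - beta[[1]]),
                              b1 = unname(site_slopes - beta[[2]]),
                              stringsAsFactors = FALSE),
    var_components = list(
      sd_b0 = if (length(ids) > 1) sd(eff[, 1]) else 0,
      sd_b1 = if (length(ids) > 1) sd(site_slopes) else 0,
      corr_b0b1 = 0,
      sd_resid = summary(pooled)$sigma
    ),
    converged = converged,
    fit_method = "fallback_per_site_OLS",
    ranef_structure = "per_site_OLS",
    records = dat_to_records(dat)
  )
}

dat_to_records <- function(dat) {
  data.frame(chrono_id = as.character(dat$chrono_id),
             stand_age = exp(dat$ln_age), agb = dat$agb,
             stringsAsFactors = FALSE)
}

new_growth_model_fit <- function(beta0, beta1, site_effects, var_components,
                                 converged, fit_method, ranef_structure,
                                 records) {
  ages <- split(records$stand_age, records$chrono_id)
  ages <- ages[site_effects$chrono_id]
  site_summary <- data.frame(
    chrono_id = site_effects$chrono_id,
    n_plots = vapply(ages, length, integer(1)),
    min_age = vapply(ages, min, numeric(1)),
    max_age = vapply(ages, max, numeric(1)),
    stringsAsFactors = FALSE
  )
  structure(
    list(beta0 = beta0, beta1 = beta1, site_effects = site_effects,
         var_components = var_components, converged = converged,
         fit_method = fit_method, ranef_structure = ranef_structure,
         site_summary = site_summary),
    class = "growth_model_fit"
  )
}

#' @export
print.growth_model_fit <- function(x, ...) {
  cat("Growth model fit: AGB ~ ln(stand age)\n")
  cat(sprintf("  fixed effects: beta0 = %.3f, beta1 = %.3f\n",
              x$beta0, x$beta1))
  cat(sprintf("  sites: %d | method: %s (%s) | converged: %s\n",
              nrow(x$site_effects), x$fit_method, x$ranef_structure,
              x$converged))
  v <- x$var_components
  cat(sprintf("  sd(b0) = %.3f, sd(b1) = %.3f, corr = %.2f, sd(resid) = %.3f\n",
              v$sd_b0, v$sd_b1, v$corr_b0b1, v$sd_resid))
  invisible(x)
}

site_coefs <- function(fit, chrono_id) {
  i <- match(chrono_id, fit$site_effects$chrono_id)
  if (is.na(i)) stop("unknown chrono_id: ", chrono_id)
  c(intercept = fit$beta0 + fit$site_effects$b0[i],
    slope = fit$beta1 + fit$site_effects$b1[i])
}

#' Predict AGB for a chronosequence at a given stand age
#'
#' Evaluates the site-specific curve
#' \eqn{(\beta_0 + b_{0i}) + (\beta_1 + b_{1i}) \ln(age)}. Predictions may
#' be negative at small ages; they are returned unclamped (callers may flag
#' them).
#'
#' @param fit A \code{\link{fit_growth_model}} result.
#' @param chrono_id Chronosequence id present in the fit.
#' @param age Stand age in years, > 0.
#' @return Predicted AGB, Mg/ha.
#' @export
predict_site_agb <- function(fit, chrono_id, age) {
  stopifnot(inherits(fit, "growth_model_fit"), all(age > 0))
  cf <- site_coefs(fit, chrono_id)
  unname(cf["intercept"] + cf["slope"] * log(age))
}

#' Younger-secondary biomass change rate for one chronosequence
#'
#' The regrowth rate over the first 20 years of succession: predicted AGB at
#' 20 years divided by 20 (a chord from the origin, i.e. assuming linear
#' accumulation over 0--20 yr). A site only contributes if it has at least
#' one plot aged \eqn{\le} 20 years.
#'
#' @inheritParams predict_site_agb
#' @return One-row data frame (a \code{SiteRate}): \code{chrono_id},
#'   \code{forest_type}, \code{rate} (Mg ha^-1 yr^-1), anchors and predicted
#'   AGB at the anchors; or \code{NULL} with a message if the site has no
#'   plot \eqn{\le} 20 yr.
#' @export
ys_rate <- function(fit, chrono_id) {
  s <- fit$site_summary[fit$site_summary$chrono_id == chrono_id, ]
  if (nrow(s) == 0) stop("unknown chrono_id: ", chrono_id)
  if (s$min_age > 20) {
    message("site ", chrono_id,
            ": no plot aged <= 20 yr; contributes no younger-secondary rate")
    return(NULL)
  }
  agb20 <- predict_site_agb(fit, chrono_id, 20)
  data.frame(
    chrono_id = chrono_id, forest_type = "younger_secondary",
    rate = agb20 / 20, anchor_low_age = 0, anchor_high_age = 20,
    predicted_agb_low = 0, predicted_agb_high = agb20,
    fit_method = fit$fit_method, stringsAsFactors = FALSE
  )
}

#' Older-secondary biomass change rate for one chronosequence
#'
#' The chord slope of the fitted curve between 20 years (or the youngest age
#' available after 20 years) and the maximum stand age available at the
#' site:
#' \deqn{rate = \frac{AGB(t_{max}) - AGB(t_{low})}{t_{max} - t_{low}}.}
#' Sites whose oldest plot is \eqn{\le} 20 yr contribute no older-secondary
#' rate. No extrapolation beyond the site's maximum observed age is
#' performed.
#'
#' @inheritParams predict_site_agb
#' @param max_age Maximum stand age observed at the site (years, in (20,
#'   100]); defaulted from the fitted data.
#' @param youngest_age Youngest stand age observed (years); defaulted from
#'   the fitted data.
#' @return One-row \code{SiteRate} data frame, or \code{NULL} with a message
#'   when the site cannot contribute.
#' @export
os_rate <- function(fit, chrono_id, max_age = NULL, youngest_age = NULL) {
  s <- fit$site_summary[fit$site_summary$chrono_id == chrono_id, ]
  if (nrow(s) == 0) stop("unknown chrono_id: ", chrono_id)
  max_age <- max_age %||% s$max_age
  youngest_age <- youngest_age %||% s$min_age
  anchor_low <- if (youngest_age <= 20) 20 else youngest_age
  if (max_age <= anchor_low) {
    message("site ", chrono_id, ": maximum age ", max_age,
            " <= anchor ", anchor_low,
            "; contributes no older-secondary rate")
    return(NULL)
  }
  if (max_age > 100) stop("older-secondary anchor beyond 100 yr: ", max_age)
  lo <- predict_site_agb(fit, chrono_id, anchor_low)
  hi <- predict_site_agb(fit, chrono_id, max_age)
  data.frame(
    chrono_id = chrono_id, forest_type = "older_secondary",
    rate = (hi - lo) / (max_age - anchor_low),
    anchor_low_age = anchor_low, anchor_high_age = max_age,
    predicted_agb_low = lo, predicted_agb_high = hi,
    fit_method = fit$fit_method, stringsAsFactors = FALSE
  )
}

#' Site-specific rates for every chronosequence in a fit
#'
#' Applies \code{\link{ys_rate}} and \code{\link{os_rate}} to every fitted
#' chronosequence; sites contribute a younger-secondary rate only when they
#' have a plot aged \eqn{\le} 20 yr, and an older-secondary rate only when
#' their age span extends beyond the low anchor.
#'
#' @param fit A \code{\link{fit_growth_model}} result.
#' @return Data frame of \code{SiteRate} rows (possibly zero rows).
#' @export
site_rates <- function(fit) {
  ids <- fit$site_effects$chrono_id
  rows <- list()
  for (id in ids) {
    rows <- c(rows, list(
      suppressMessages(ys_rate(fit, id)),
      suppressMessages(os_rate(fit, id))
    ))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(chrono_id = character(0), forest_type = character(0),
                      rate = numeric(0), anchor_low_age = numeric(0),
                      anchor_high_age = numeric(0),
                      predicted_agb_low = numeric(0),
                      predicted_agb_high = numeric(0),
                      fit_method = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit growth models and extract site rates for all strata
#'
#' Splits grouped chronosequence records by continent and ecozone, fits one
#' mixed model per stratum (falling back to per-site OLS when a stratum has
#' a single chronosequence), and collects all site-specific younger- and
#' older-secondary rates.
#'
#' @param records Grouped records with \code{chrono_id}, \code{continent},
#'   \code{ecozone}, \code{stand_age}, \code{agb}.
#' @return List with \code{rates} (SiteRate data frame including
#'   \code{continent} and \code{ecozone}) and \code{fits} (named list of
#'   \code{growth_model_fit} per stratum).
#' @export
chronosequence_site_rates <- function(records) {
  if (nrow(records) == 0) {
    return(list(rates = data.frame(), fits = list()))
  }
  strata <- split(records,
                  list(records$continent, records$ecozone), drop = TRUE)
  fits <- list()
  rates <- list()
  for (nm in sort(names(strata))) {
    st <- strata[[nm]]
    fit <- fit_growth_model(st)
    fits[[nm]] <- fit
    r <- site_rates(fit)
    if (nrow(r)) {
      r$continent <- st$continent[1]
      r$ecozone <- st$ecozone[1]
      rates[[nm]] <- r
    }
  }
  rates <- if (length(rates)) do.call(rbind, rates) else data.frame()
  rownames(rates) <- NULL
  list(rates = rates, fits = fits)
}
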