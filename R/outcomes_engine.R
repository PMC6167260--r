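#' Natural-history parameters for a condition
#'
#' @param m_nocare_u5 Fraction of affected livebirths dying before age 5
#'   without care.
#' @param m_care_u5 Same with optimal care; must not exceed `m_nocare_u5`.
#' @param sb_frac Stillbirth fraction among non-terminated affected
#'   pregnancies.
#' @param shares_nocare,shares_care Named triples `(cured, mild_moderate,
#'   severe)` of fractions over survivors at age 5, each summing to 1.
#' @param death_age_bands Data frame (`age`, `share`): midpoint age in
#'   years of each under-5 death band and its share of deaths; shares sum
#'   to 1.
#' @return A list of class `natural_history`.
#' @export
natural_history <- function(m_nocare_u5, m_care_u5, sb_frac,
                            shares_nocare, shares_care,
                            death_age_bands = data.frame(age = 0.5,
                                                         share = 1)) {
  stopifnot(m_care_u5 >= 0, m_care_u5 <= m_nocare_u5, m_nocare_u5 <= 1,
            sb_frac >= 0, sb_frac <= 1)
  for (s in list(shares_nocare, shares_care)) {
    stopifnot(length(s) == 3, all(s >= 0))
    if (abs(sum(s) - 1) > 1e-9)
      stop("survivor shares must sum to 1", call. = FALSE)
  }
  names(shares_nocare) <- names(shares_care) <-
    c("cured", "mild_moderate", "severe")
  if (abs(sum(death_age_bands$share) - 1) > 1e-9)
    stop("death age band shares must sum to 1", call. = FALSE)
  structure(list(m_nocare_u5 = m_nocare_u5, m_care_u5 = m_care_u5,
                 sb_frac = sb_frac, shares_nocare = shares_nocare,
                 shares_care = shares_care,
                 death_age_bands = death_age_bands),
            class = "natural_history")
}

#' Birth outcomes of affected pregnancies
#'
#' Allocates post-prevention affected pregnancies to termination,
#' stillbirth and livebirth; the three components sum exactly to the
#' affected prevalence (the conserved envelope).
#'
#' @param post_prevention_prevalence Affected pregnancies per 1000 births
#'   after primary prevention.
#' @param terminations Terminations per 1000 births; must not exceed the
#'   prevalence.
#' @param nh A [natural_history()].
#' @return List with `affected_post_prevention`, `terminations`,
#'   `stillbirths`, `livebirths` (all per 1000 births).
#' @export
birth_outcome_envelope <- function(post_prevention_prevalence, terminations,
                                   nh) {
  stopifnot(inherits(nh, "natural_history"),
            post_prevention_prevalence >= 0, terminations >= 0)
  if (terminations > post_prevention_prevalence + 1e-12)
    stop("terminations exceed affected prevalence", call. = FALSE)
  continuing <- post_prevention_prevalence - terminations
  list(affected_post_prevention = post_prevention_prevalence,
       terminations = terminations,
       stillbirths = continuing * nh$sb_frac,
       livebirths = continuing * (1 - nh$sb_frac))
}

#' Under-5 outcomes of affected livebirths under binary access
#'
#' Access to care is binary at the individual level: the population splits
#' into a with-care stratum (fraction `access`) experiencing `m_care_u5`
#' and the care-specific survivor shares, and a without-care stratum
#' experiencing `m_nocare_u5` and the no-care shares. Survivor disability
#' shares are therefore mixed with survivor-mass weights from each stratum,
#' not with the raw population access fraction.
#'
#' @param livebirths_per_1000 Affected livebirths per 1000 births.
#' @param access Fraction of the population with access to optimal care.
#' @param nh A [natural_history()].
#' @return List with `u5_deaths`, `cured`, `mild_moderate`, `severe`
#'   (per 1000 births; they sum to the livebirths).
#' @export
under5_outcomes <- function(livebirths_per_1000, access, nh) {
  stopifnot(inherits(nh, "natural_history"),
            livebirths_per_1000 >= 0, access >= 0, access <= 1)
  L <- livebirths_per_1000
  surv_care <- L * access * (1 - nh$m_care_u5)
  surv_nocare <- L * (1 - access) * (1 - nh$m_nocare_u5)
  deaths <- L - surv_care - surv_nocare
  out <- surv_care * nh$shares_care + surv_nocare * nh$shares_nocare
  list(u5_deaths = deaths,
       cured = unname(out["cured"]),
       mild_moderate = unname(out["mild_moderate"]),
       severe = unname(out["severe"]))
}

#' Mean age at death of under-5 deaths
#'
#' Share-weighted mean of the death-band midpoint ages; independent of the
#' number of deaths. Returns `NA` when there are no deaths.
#'
#' @param u5_deaths Under-5 deaths per 1000 births.
#' @param bands Data frame (`age`, `share`) with shares summing to 1.
#' @return Mean age at death in years, or `NA` for zero deaths.
#' @export
mean_age_at_death <- function(u5_deaths, bands) {
  if (u5_deaths == 0) return(NA_real_)
  if (is.null(bands) || nrow(bands) == 0)
    stop("death age bands required when deaths are nonzero", call. = FALSE)
  if (abs(sum(bands$share) - 1) > 1e-9)
    stop("death age band shares must sum to 1", call. = FALSE)
  sum(bands$age * bands$share)
}

#' Full conserved outcome envelope for one country-condition
#'
#' @param post_prevention_prevalence Affected pregnancies per 1000 births
#'   after prevention.
#' @param terminations Terminations per 1000 births.
#' @param access Access to optimal care (fraction).
#' @param nh A [natural_history()].
#' @return One-row data frame with all envelope fields; both conservation
#'   identities hold to numerical precision.
#' @export
outcome_envelope <- function(post_prevention_prevalence, terminations,
                             access, nh) {
  birth <- birth_outcome_envelope(post_prevention_prevalence, terminations,
                                  nh)
  u5 <- under5_outcomes(birth$livebirths, access, nh)
  data.frame(affected_post_prevention = birth$affected_post_prevention,
             terminations = birth$terminations,
             stillbirths = birth$stillbirths,
             livebirths = birth$livebirths,
             u5_deaths = u5$u5_deaths,
             cured = u5$cured,
             mild_moderate = u5$mild_moderate,
             severe = u5$severe,
             mean_age_at_death_years =
               mean_age_at_death(u5$u5_deaths, nh$death_age_bands))
}

#' Births-weighted aggregation of country estimates to regions
#'
#' Per-1000 rates and access fractions aggregate as livebirths-weighted
#' means; absolute counts as sums. A `World` row (the weighted mean over
#' all countries, equivalently over the regional rows) is appended.
#'
#' @param estimates Data frame with one row per country(-condition),
#'   including a region column and a weight column.
#' @param rate_cols Names of per-1000 / fraction columns to weight-average.
#' @param count_cols Names of absolute-count columns to sum.
#' @param region_col,weight_col Column names for region and livebirths.
#' @param world_row Append the all-country row labelled `"World"`?
#' @return Data frame with one row per region (plus World).
#' @export
aggregate_regions <- function(estimates, rate_cols,
                              count_cols = character(),
                              region_col = "region",
                              weight_col = "livebirths",
                              world_row = TRUE) {
  w <- estimates[[weight_col]]
  stopifnot(all(w >= 0))
  if (sum(w) == 0) stop("total weight is zero", call. = FALSE)
  agg_one <- function(df, label) {
    ww <- df[[weight_col]]
    row <- data.frame(region = label, livebirths = sum(ww))
    for (col in rate_cols)
      row[[col]] <- sum(df[[col]] * ww) / sum(ww)
    for (col in count_cols)
      row[[col]] <- sum(df[[col]])
    row
  }
  regions <- split(estimates, estimates[[region_col]])
  out <- do.call(rbind, lapply(names(regions),
                               function(r) agg_one(regions[[r]], r)))
  if (world_row) out <- rbind(out, agg_one(estimates, "World"))
  rownames(out) <- NULL
  out
}
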