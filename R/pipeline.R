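#' Run the full country-by-condition estimation pipeline
#'
#' For every country-condition pair: estimate access to optimal care from
#' the (consanguinity/HIV-adjusted) infant mortality rate; apply the
#' primary-prevention model matching the condition class (folic-acid
#' fortification for NTDs, anti-D prophylaxis for Rh disease, genetic risk
#' information for recessive disorders); apply the prenatal-diagnosis/TOP
#' assumptions of the country's policy group to malformation, chromosomal
#' and NTD classes; and allocate the remainder to the conserved outcome
#' envelope. Recessive-disorder terminations are embedded in the
#' counselling model and therefore counted as prevented, not as population
#' TOPs, to avoid double counting.
#'
#' @param countries Validated country table (see [read_country_table()]).
#' @param conditions Validated condition table.
#' @param config Configuration list (see [default_config()]).
#' @param observed_top Optional data frame (`iso3`, `condition_id`,
#'   `top_per_1000`) of registry TOP rates for group-A countries; absent
#'   entries default to 0 with a message.
#' @param verbose Emit per-stage messages?
#' @return List with `access` (per-country access estimates), `estimates`
#'   (one row per country-condition with the prevention decomposition and
#'   full envelope) and `regional` (births-weighted regional summary).
#' @export
#' @examples
#' fx <- generate_fixtures(5, seed = 1)
#' res <- run_pipeline(fx$countries, fx$conditions)
#' head(res$estimates)
run_pipeline <- function(countries, conditions, config = default_config(),
                         observed_top = NULL, verbose = FALSE) {
  countries <- validate_country_table(countries)
  conditions <- validate_condition_table(conditions)
  say <- function(...) if (verbose) message(...)

  say("fitting access curve")
  curve <- fit_access_curve(m_lo = config$access$m_lo,
                            m_hi = config$access$m_hi,
                            anchors = config$access$anchors)
  cmodel <- consanguinity_model(e_nocare = config$consanguinity$e_nocare,
                                rho = config$consanguinity$rho,
                                n_iter = config$consanguinity$n_iter,
                                imr_floor = config$consanguinity$imr_floor)
  fconst <- folate_constants(
    sb_anenc_floor = config$folate$sb_anenc_floor,
    enceph_share = config$folate$enceph_share,
    total_floor = config$folate$total_floor,
    k_dose = config$folate$k_dose,
    ofc_max_effect = config$folate$ofc_max_effect,
    chd_max_effect = config$folate$chd_max_effect,
    dose_response_table = config$folate$dose_response_table)
  uptake_tab <- top_uptake_table(
    uptakes = stats::setNames(conditions$eurocat_top_uptake,
                              conditions$condition_id),
    restricted_conditions =
      conditions$condition_id[conditions$restricted_flag],
    restricted_multiplier = config$top$restricted_multiplier)

  say("estimating access for ", nrow(countries), " countries")
  ests <- lapply(seq_len(nrow(countries)), function(i)
    estimate_access(countries$imr[i], countries$alpha[i],
                    countries$hiv_imr[i], curve, cmodel))
  access_tab <- data.frame(
    iso3 = countries$iso3, year = countries$year, imr = countries$imr,
    c_imr = vapply(ests, `[[`, numeric(1), "consanguinity_imr"),
    hiv_imr = countries$hiv_imr,
    final_adjusted_imr = vapply(ests, `[[`, numeric(1),
                                "final_adjusted_imr"),
    access_unadjusted_pct = round(100 * vapply(ests, `[[`, numeric(1),
                                               "access_unadjusted"), 1),
    access_final_pct = round(100 * vapply(ests, `[[`, numeric(1),
                                          "access_final"), 1))
  access_final <- vapply(ests, `[[`, numeric(1), "access_final")

  rows <- vector("list", nrow(countries) * nrow(conditions))
  idx <- 0
  for (i in seq_len(nrow(countries))) {
    ctry <- countries[i, ]
    acc <- access_final[i]
    policy_args <- list(group = ctry$top_group,
                        universal_screening = ctry$universal_screening)
    fpolicy <- fortification_policy(ctry$fortification_mandatory,
                                    ctry$fortification_dose_ppm,
                                    ctry$fortification_reach)
    for (j in seq_len(nrow(conditions))) {
      cond <- conditions[j, ]
      baseline <- if (cond$condition_class == "single_gene_recessive" &&
                      !is.na(cond$q)) {
        1000 * hardy_weinberg_prevalence(cond$q, ctry$alpha)
      } else {
        cond$baseline_prevalence_per_1000
      }

      post <- baseline
      if (cond$condition_class == "ntd" && cond$folate_preventable_flag) {
        post <- post_fortification_prevalence(baseline, fpolicy, fconst)
      } else if (cond$condition_class == "rh_disease") {
        actx <- antid_context(acc, ctry$anc4,
                              ctry$antid_standard_practice,
                              config$antid$efficacy)
        post <- baseline - antid_prevented_per_1000(baseline, actx)
      } else if (cond$condition_class == "single_gene_recessive") {
        pnd_ok <- ctry$top_group %in% c("A", "B", "C")
        rctx <- counselling_context(
          family_size_norm = max(1, ctry$tfr),
          pnd_available = pnd_ok,
          pnd_uptake = if (pnd_ok) cond$eurocat_top_uptake else 0,
          retro_coverage = acc,
          pro_coverage = ctry$prospective_screening_coverage,
          p_affected = config$reproductive$p_affected)
        post <- counselling_adjusted_prevalence(baseline, rctx)
      }

      tops <- 0
      if (cond$condition_class %in% c("malformation", "chromosomal",
                                      "ntd")) {
        if (ctry$top_group == "A") {
          obs <- 0
          if (!is.null(observed_top)) {
            hit <- observed_top$iso3 == ctry$iso3 &
              observed_top$condition_id == cond$condition_id
            if (any(hit)) obs <- observed_top$top_per_1000[which(hit)[1]]
          }
          policy <- do.call(top_policy,
                            c(policy_args,
                              list(observed_top_rate_per_1000 = obs)))
          tops <- terminations_per_1000(post, acc, 0, policy)
        } else {
          policy <- do.call(top_policy, policy_args)
          upt <- top_uptake(cond$condition_id, policy, uptake_tab)
          if (is.na(upt)) upt <- 0
          tops <- terminations_per_1000(post, acc, upt, policy)
        }
      }

      nh <- natural_history(
        m_nocare_u5 = cond$m_nocare_u5, m_care_u5 = cond$m_care_u5,
        sb_frac = cond$sb_frac,
        shares_nocare = c(cond$share_cured_nocare, cond$share_mild_nocare,
                          cond$share_severe_nocare),
        shares_care = c(cond$share_cured_care, cond$share_mild_care,
                        cond$share_severe_care))
      env <- outcome_envelope(post, tops, acc, nh)
      # envelope 'livebirths' is per-1000; renamed so it cannot clash with
      # the absolute livebirths weight column
      names(env)[names(env) == "livebirths"] <- "livebirths_rate"

      idx <- idx + 1
      rows[[idx]] <- cbind(
        data.frame(iso3 = ctry$iso3, region = ctry$region,
                   year = ctry$year, livebirths = ctry$livebirths,
                   condition_id = cond$condition_id,
                   condition_class = cond$condition_class,
                   access_final = acc,
                   baseline_per_1000 = baseline,
                   prevented_per_1000 = baseline - post),
        env)
    }
    say("country ", ctry$iso3, " done")
  }
  estimates <- do.call(rbind, rows)

  say("aggregating to regions")
  rate_cols <- c("access_final", "baseline_per_1000", "prevented_per_1000",
                 "affected_post_prevention", "terminations", "stillbirths",
                 "livebirths_rate", "u5_deaths", "cured", "mild_moderate",
                 "severe")
  regional <- aggregate_regions(estimates, rate_cols)

  list(access = access_tab, estimates = estimates, regional = regional)
}
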