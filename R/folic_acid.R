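#' Folate model constants
#'
#' Floor constants and dose-response calibration for the effect of mandatory
#' folic-acid flour fortification on neural tube defect (NTD) birth
#' prevalence. The spina-bifida-plus-anencephaly floor of 0.7 per 1000 and
#' the 11.5% encephalocoele share motivate a total non-folate-preventable
#' NTD rate of 0.77 per 1000; the total floor is carried as an independent
#' constant rather than recomputed from the other two.
#'
#' @param sb_anenc_floor Post-fortification spina bifida + anencephaly rate
#'   per 1000 births.
#' @param enceph_share Encephalocoele share of total NTDs.
#' @param total_floor Non-folate-preventable total NTD rate per 1000 births.
#' @param k_dose Exponential dose coefficient per ppm; the default 1.65 is
#'   the smallest round value for which 2 ppm at full reach brings every
#'   baseline up to 6.5 per 1000 below 1 per 1000.
#' @param ofc_max_effect,chd_max_effect Maximal proportional reductions of
#'   orofacial clefts / congenital heart disease at saturating dose. The
#'   evidence supports only a "small" effect; 0.05 is a configurable
#'   placeholder.
#' @param dose_response_table Optional data frame (`ppm`, `residual_ratio`)
#'   overriding the exponential form by piecewise-linear interpolation.
#' @return A list of class `folate_constants`.
#' @export
folate_constants <- function(sb_anenc_floor = 0.7, enceph_share = 0.115,
                             total_floor = 0.77, k_dose = 1.65,
                             ofc_max_effect = 0.05, chd_max_effect = 0.05,
                             dose_response_table = NULL) {
  stopifnot(total_floor >= sb_anenc_floor, enceph_share >= 0,
            enceph_share < 1, k_dose > 0,
            ofc_max_effect >= 0, ofc_max_effect <= 0.2,
            chd_max_effect >= 0, chd_max_effect <= 0.2)
  if (!is.null(dose_response_table)) {
    dose_response_table <- as.data.frame(dose_response_table)
    stopifnot(all(c("ppm", "residual_ratio") %in% names(dose_response_table)))
  }
  structure(list(sb_anenc_floor = sb_anenc_floor, enceph_share = enceph_share,
                 total_floor = total_floor, k_dose = k_dose,
                 ofc_max_effect = ofc_max_effect,
                 chd_max_effect = chd_max_effect,
                 dose_response_table = dose_response_table),
            class = "folate_constants")
}

#' Fortification policy for one country
#'
#' @param mandatory Is flour fortification mandated?
#' @param dose_ppm Folic acid dose in parts per million (mg per kg flour).
#' @param reach Fraction of the population consuming fortified flour.
#' @param voluntary_or_supplementation_only Voluntary fortification or
#'   supplementation programmes only; treated as having no population
#'   effect.
#' @return A list of class `fortification_policy`.
#' @export
fortification_policy <- function(mandatory = FALSE, dose_ppm = 0, reach = 0,
                                 voluntary_or_supplementation_only = FALSE) {
  stopifnot(dose_ppm >= 0, reach >= 0, reach <= 1)
  structure(list(mandatory = isTRUE(mandatory), dose_ppm = dose_ppm,
                 reach = reach,
                 voluntary_or_supplementation_only =
                   isTRUE(voluntary_or_supplementation_only)),
            class = "fortification_policy")
}

#' Residual ratio of folate-preventable NTDs at a fortification dose
#'
#' Fraction of folate-preventable cases remaining at full population reach:
#' RR(d) = exp(-k_dose * d), or linear interpolation of a supplied
#' dose-response table. RR(0) = 1 and RR is strictly decreasing in dose.
#'
#' @param dose_ppm Dose in ppm (>= 0); vectorised.
#' @param constants A [folate_constants()].
#' @return Residual ratio(s) in (0, 1\].
#' @export
#' @examples
#' residual_ratio(2)   # exp(-3.3) ~ 0.0369
residual_ratio <- function(dose_ppm, constants = folate_constants()) {
  stopifnot(inherits(constants, "folate_constants"), all(dose_ppm >= 0))
  tab <- constants$dose_response_table
  if (!is.null(tab)) {
    return(stats::approx(tab$ppm, tab$residual_ratio, xout = dose_ppm,
                         rule = 2)$y)
  }
  exp(-constants$k_dose * dose_ppm)
}

#' Post-fortification NTD birth prevalence
#'
#' Only mandatory fortification has an effect; voluntary fortification and
#' supplementation are treated as having none. The folate-preventable
#' portion of the baseline (the excess over the non-preventable floor) is
#' reduced by the dose-dependent factor (1 - RR(d)) in the fraction of the
#' population reached. When an observed post-fortification prevalence is
#' supplied it takes precedence over the model.
#'
#' @param baseline_per_1000 Pre-fortification total NTD birth prevalence
#'   (per 1000 births).
#' @param policy A [fortification_policy()].
#' @param constants A [folate_constants()].
#' @param observed_post_per_1000 Optional observed post-fortification
#'   prevalence; returned as-is when present.
#' @return Post-fortification prevalence per 1000, never below the floor
#'   and never above the baseline.
#' @export
#' @examples
#' post_fortification_prevalence(3.0, fortification_policy(TRUE, 2, 1))
post_fortification_prevalence <- function(baseline_per_1000, policy,
                                          constants = folate_constants(),
                                          observed_post_per_1000 = NULL) {
  stopifnot(inherits(policy, "fortification_policy"),
            all(baseline_per_1000 >= 0))
  if (!is.null(observed_post_per_1000)) return(observed_post_per_1000)
  if (!policy$mandatory || policy$voluntary_or_supplementation_only)
    return(baseline_per_1000)
  floor <- constants$total_floor
  rr <- residual_ratio(policy$dose_ppm, constants)
  post <- baseline_per_1000 -
    policy$reach * (baseline_per_1000 - floor) * (1 - rr)
  post <- pmin(pmax(post, floor), baseline_per_1000)
  # baselines already below the floor are left untouched
  post[baseline_per_1000 <= floor] <- baseline_per_1000[baseline_per_1000 <= floor]
  post
}

#' Split a total NTD prevalence into subtypes
#'
#' Fortification is assumed to act equally on all NTDs, so any total is
#' allocated proportionally to the baseline subtype shares.
#'
#' @param total_per_1000 Total NTD prevalence per 1000.
#' @param baseline_shares Named numeric over `anencephaly`, `spina_bifida`,
#'   `encephalocoele`, summing to 1.
#' @return Named numeric of per-1000 rates summing to the total.
#' @export
split_ntd_subtypes <- function(total_per_1000,
                               baseline_shares = c(anencephaly = 0.45,
                                                   spina_bifida = 0.435,
                                                   encephalocoele = 0.115)) {
  stopifnot(total_per_1000 >= 0)
  if (abs(sum(baseline_shares) - 1) > 1e-9)
    stop("baseline subtype shares must sum to 1", call. = FALSE)
  total_per_1000 * baseline_shares
}

#' Collateral reduction of non-NTD malformations from fortification
#'
#' Small proportional reductions of orofacial clefts and congenital heart
#' disease under mandatory fortification, scaled by reach and by how much
#' of the maximal dose effect is realised.
#'
#' @param condition_class `"orofacial_cleft"` or `"congenital_heart"`.
#' @param policy A [fortification_policy()].
#' @param constants A [folate_constants()].
#' @return Proportional reduction in \[0, 1\]; zero unless mandatory.
#' @export
collateral_reduction <- function(condition_class, policy,
                                 constants = folate_constants()) {
  condition_class <- match.arg(condition_class,
                               c("orofacial_cleft", "congenital_heart"))
  stopifnot(inherits(policy, "fortification_policy"))
  if (!policy$mandatory || policy$voluntary_or_supplementation_only)
    return(0)
  max_effect <- switch(condition_class,
                       orofacial_cleft = constants$ofc_max_effect,
                       congenital_heart = constants$chd_max_effect)
  policy$reach * max_effect * (1 - residual_ratio(policy$dose_ppm, constants))
}
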