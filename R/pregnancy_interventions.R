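#' Termination-of-pregnancy policy group for a country
#'
#' Groups encode data availability and legal status of termination of
#' pregnancy (TOP) for fetal impairment: A — legal with registry data (use
#' observed rates); B — legal, no data (model prenatal-diagnosis access via
#' the optimal-care curve, EUROCAT-average uptake); C — status unclear but
#' evidence of widespread availability (treated as B); D — illegal (no
#' terminations).
#'
#' @param group One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param universal_screening Explicit universal prenatal screening policy?
#'   When absent, uptake for restricted conditions (Down syndrome, spina
#'   bifida) is halved.
#' @param observed_top_rate_per_1000 Observed TOP rate (group A only).
#' @return A list of class `top_policy`.
#' @export
top_policy <- function(group, universal_screening = FALSE,
                       observed_top_rate_per_1000 = NULL) {
  group <- match.arg(group, c("A", "B", "C", "D"))
  if (group == "A" && is.null(observed_top_rate_per_1000))
    stop("group A requires an observed TOP rate", call. = FALSE)
  if (group != "A" && !is.null(observed_top_rate_per_1000))
    stop("observed TOP rates apply to group A only", call. = FALSE)
  structure(list(group = group,
                 universal_screening = isTRUE(universal_screening),
                 observed_top_rate_per_1000 = observed_top_rate_per_1000),
            class = "top_policy")
}

#' Condition-level TOP uptake table
#'
#' @param uptakes Named numeric: EUROCAT-average uptake fraction among
#'   prenatally diagnosed pregnancies, per condition id.
#' @param restricted_conditions Conditions subject to the 50% rule in the
#'   absence of universal screening.
#' @param restricted_multiplier Multiplier applied to restricted conditions
#'   without universal screening.
#' @return A list of class `top_uptake_table`.
#' @export
top_uptake_table <- function(uptakes,
                             restricted_conditions = c("down_syndrome",
                                                       "spina_bifida"),
                             restricted_multiplier = 0.5) {
  stopifnot(is.numeric(uptakes), !is.null(names(uptakes)),
            all(uptakes >= 0), all(uptakes <= 1),
            restricted_multiplier >= 0, restricted_multiplier <= 1)
  structure(list(uptakes = uptakes,
                 restricted_conditions = restricted_conditions,
                 restricted_multiplier = restricted_multiplier),
            class = "top_uptake_table")
}

#' TOP uptake applied to a condition under a policy group
#'
#' Group D yields zero. Groups B and C use the EUROCAT-average uptake,
#' multiplied by the restricted multiplier for Down syndrome and spina
#' bifida unless the country has an explicit universal screening policy.
#' Group A bypasses the uptake path entirely (observed rates are used);
#' `NA` is returned as the signal.
#'
#' @param condition_id Condition identifier present in `table`.
#' @param policy A [top_policy()].
#' @param table A [top_uptake_table()].
#' @return Uptake fraction, 0 for group D, `NA` for group A.
#' @export
#' @examples
#' tab <- top_uptake_table(c(down_syndrome = 0.6))
#' top_uptake("down_syndrome", top_policy("B"), tab)   # 0.30
top_uptake <- function(condition_id, policy, table) {
  stopifnot(inherits(policy, "top_policy"), inherits(table, "top_uptake_table"))
  if (!condition_id %in% names(table$uptakes))
    stop("unknown condition: ", condition_id, call. = FALSE)
  if (policy$group == "D") return(0)
  if (policy$group == "A") return(NA_real_)
  uptake <- unname(table$uptakes[[condition_id]])
  if (condition_id %in% table$restricted_conditions &&
      !policy$universal_screening)
    uptake <- uptake * table$restricted_multiplier
  uptake
}

#' Terminations of pregnancy per 1000 births
#'
#' Group A passes through the observed rate (capped at the affected
#' prevalence, with a warning). Other groups multiply the affected
#' prevalence by modelled prenatal-diagnosis access and the condition
#' uptake.
#'
#' @param affected_prevalence_per_1000 Affected pregnancies per 1000 births.
#' @param pnd_access Fraction with access to prenatal diagnosis (modelled
#'   as access to optimal care).
#' @param uptake Uptake fraction from [top_uptake()] (ignored for groups A
#'   and D).
#' @param policy A [top_policy()].
#' @return Terminations per 1000 births, never above the prevalence.
#' @export
terminations_per_1000 <- function(affected_prevalence_per_1000, pnd_access,
                                  uptake, policy) {
  stopifnot(inherits(policy, "top_policy"),
            affected_prevalence_per_1000 >= 0,
            pnd_access >= 0, pnd_access <= 1)
  if (policy$group == "A") {
    obs <- policy$observed_top_rate_per_1000
    if (is.null(obs)) stop("group A requires an observed TOP rate",
                           call. = FALSE)
    if (obs > affected_prevalence_per_1000) {
      warning("observed TOP rate exceeds affected prevalence; capped",
              call. = FALSE)
      obs <- affected_prevalence_per_1000
    }
    return(obs)
  }
  if (policy$group == "D") return(0)
  stopifnot(uptake >= 0, uptake <= 1)
  affected_prevalence_per_1000 * pnd_access * uptake
}

#' Anti-D coverage context
#'
#' @param access Estimated access to optimal care (fraction).
#' @param anc4_coverage Coverage of four or more antenatal care visits.
#' @param standard_practice Is Rh screening plus anti-D considered standard
#'   obstetric practice in the country?
#' @param efficacy Efficacy of prophylaxis in preventing an affected
#'   pregnancy (default 1).
#' @return A list of class `antid_context`.
#' @export
antid_context <- function(access, anc4_coverage = 0,
                          standard_practice = FALSE, efficacy = 1) {
  stopifnot(access >= 0, access <= 1, anc4_coverage >= 0, anc4_coverage <= 1,
            efficacy >= 0, efficacy <= 1)
  structure(list(access = access, anc4_coverage = anc4_coverage,
                 standard_practice = isTRUE(standard_practice),
                 efficacy = efficacy),
            class = "antid_context")
}

#' Anti-D prophylaxis coverage
#'
#' Coverage is at minimum the estimated access to optimal care; where
#' screening and anti-D are standard obstetric practice, it rises to the
#' coverage of four antenatal care visits when that is higher.
#'
#' @param ctx An [antid_context()].
#' @return Coverage fraction, never below `access`.
#' @export
antid_coverage <- function(ctx) {
  stopifnot(inherits(ctx, "antid_context"))
  if (ctx$standard_practice) max(ctx$access, ctx$anc4_coverage) else ctx$access
}

#' Rh-disease births prevented by anti-D prophylaxis
#'
#' @param baseline_rh_per_1000 Baseline Rh haemolytic disease prevalence
#'   per 1000 births.
#' @param ctx An [antid_context()].
#' @return Prevented cases per 1000 births.
#' @export
antid_prevented_per_1000 <- function(baseline_rh_per_1000, ctx) {
  stopifnot(all(baseline_rh_per_1000 >= 0))
  baseline_rh_per_1000 * antid_coverage(ctx) * ctx$efficacy
}
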