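#' Baseline birth prevalence of a recessive disorder
#'
#' Hardy-Weinberg prevalence augmented for consanguinity: the probability a
#' birth is affected is q^2 + alpha * q * (1 - q), where q is the
#' pathogenic allele frequency and alpha the population mean coefficient of
#' consanguinity (the extra term is the excess homozygosity from identity
#' by descent).
#'
#' @param q Pathogenic allele frequency, in \[0, 0.5\].
#' @param alpha Mean coefficient of consanguinity.
#' @return Affected births per birth (a fraction). Vectorised.
#' @export
#' @examples
#' hardy_weinberg_prevalence(0.05)            # 0.0025
#' hardy_weinberg_prevalence(0.05, 0.0625)    # 0.00546875
hardy_weinberg_prevalence <- function(q, alpha = 0) {
  if (any(q < 0) || any(q > 0.5)) stop("q must lie in [0, 0.5]", call. = FALSE)
  if (any(alpha < 0) || any(alpha > 0.0625))
    stop("alpha must lie in [0, 0.0625]", call. = FALSE)
  q^2 + alpha * q * (1 - q)
}

#' Counselling context for genetic risk information
#'
#' @param family_size_norm Mean final family size N (births per couple,
#'   >= 1); real-valued, typically the country's total fertility rate.
#' @param pnd_available Is prenatal diagnosis available?
#' @param pnd_uptake Fraction of diagnosed at-risk pregnancies terminated.
#' @param retro_coverage Fraction of affected children diagnosed with the
#'   parents counselled (retrospective identification).
#' @param pro_coverage Fraction of at-risk couples identified before any
#'   affected birth (prospective screening); zero by default.
#' @param p_affected Probability an at-risk couple's birth is affected
#'   (1/4 for an autosomal recessive disorder).
#' @return A list of class `counselling_context`.
#' @export
counselling_context <- function(family_size_norm, pnd_available = FALSE,
                                pnd_uptake = 0, retro_coverage = 0,
                                pro_coverage = 0, p_affected = 0.25) {
  stopifnot(family_size_norm >= 1,
            pnd_uptake >= 0, pnd_uptake <= 1,
            retro_coverage >= 0, retro_coverage <= 1,
            pro_coverage >= 0, pro_coverage <= 1,
            p_affected > 0, p_affected < 1)
  structure(list(family_size_norm = family_size_norm,
                 pnd_available = isTRUE(pnd_available),
                 pnd_uptake = pnd_uptake, retro_coverage = retro_coverage,
                 pro_coverage = pro_coverage, p_affected = p_affected),
            class = "counselling_context")
}

# Expected affected births for a couple stopping at the first affected
# birth, against an N-birth norm, as a proportional fall from baseline N*p.
retro_fall_closed <- function(N, p = 0.25) {
  pmax(0, 1 - (1 - (1 - p)^N) / (N * p))
}

#' Proportional fall in affected births from retrospective risk information
#'
#' Maximum-effect model: counselled couples either stop reproducing at the
#' first affected birth (no prenatal diagnosis), or continue to the family
#' norm with post-first-affected affected pregnancies terminated and
#' replaced with probability `pnd_uptake`. The fall is expressed relative
#' to the uncounselled baseline of N/4 affected births per couple and is
#' continuous in real-valued N.
#'
#' @param ctx A [counselling_context()].
#' @return Fraction in \[0, 1).
#' @export
#' @examples
#' retrospective_fall(counselling_context(6))     # ~0.452
#' retrospective_fall(counselling_context(2.5))   # ~0.179
retrospective_fall <- function(ctx) {
  stopifnot(inherits(ctx, "counselling_context"))
  base <- retro_fall_closed(ctx$family_size_norm, ctx$p_affected)
  if (ctx$pnd_available) ctx$pnd_uptake * base else base
}

#' Proportional fall in affected births from prospective risk information
#'
#' Couples identified before any affected birth are modelled as limiting
#' their family to two healthy children (without prenatal diagnosis), which
#' yields an expected 2 * p/(1-p) affected births per couple (negative
#' binomial), compared with the N * p baseline; the information is taken to
#' have no effect when the family-size norm is below 2/(1-p) births (below
#' 3 for p = 1/4). With prenatal diagnosis every affected pregnancy is
#' diagnosable, and the fall equals the termination uptake.
#'
#' @param ctx A [counselling_context()].
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' prospective_fall(counselling_context(6))    # ~0.556
#' prospective_fall(counselling_context(2))    # 0
prospective_fall <- function(ctx) {
  stopifnot(inherits(ctx, "counselling_context"))
  if (ctx$pnd_available) return(ctx$pnd_uptake)
  p <- ctx$p_affected
  expected_affected <- 2 * p / (1 - p)   # stop at two healthy children
  max(0, 1 - expected_affected / (ctx$family_size_norm * p))
}

#' Birth prevalence after genetic counselling
#'
#' Mixes the prospective and retrospective effects over their population
#' coverages: prospectively identified couples (coverage p) realise the
#' prospective fall; the remainder realise the retrospective fall in the
#' fraction r of couples actually reached after a first affected child.
#'
#' @param baseline_per_1000 Baseline affected birth prevalence per 1000.
#' @param ctx A [counselling_context()].
#' @return Adjusted prevalence per 1000, in \[0, baseline\].
#' @export
counselling_adjusted_prevalence <- function(baseline_per_1000, ctx) {
  stopifnot(inherits(ctx, "counselling_context"), all(baseline_per_1000 >= 0))
  p <- ctx$pro_coverage
  r <- ctx$retro_coverage
  f_pro <- prospective_fall(ctx)
  f_retro <- retrospective_fall(ctx)
  baseline_per_1000 * (p * (1 - f_pro) + (1 - p) * (1 - r * f_retro))
}

#' Simulate reproductive stopping rules for at-risk couples
#'
#' Direct Monte-Carlo simulation of the behavioural rules underlying
#' [retrospective_fall()] and [prospective_fall()], used as an independent
#' cross-check of the closed forms. Retrospective: couples plan `N` births;
#' at the first affected birth they either stop (no prenatal diagnosis) or
#' carry on with each subsequent affected pregnancy terminated and replaced
#' by an unaffected birth with probability `pnd_uptake`. Prospective:
#' couples reproduce until they have two healthy children (no prenatal
#' diagnosis), or plan `N` births with every affected pregnancy terminated
#' and replaced with probability `pnd_uptake`.
#'
#' @param rule `"retrospective"` or `"prospective"`.
#' @param N Family-size norm (integer number of births).
#' @param pnd_uptake `NULL` for no prenatal diagnosis, else the termination
#'   probability per diagnosed affected pregnancy.
#' @param n_couples Number of simulated couples.
#' @param p_affected Per-birth probability of an affected child.
#' @param seed Integer seed (local RNG; the caller's RNG state is restored).
#' @return A list with the empirical `fall`, its standard error `se`, and
#'   the mean affected births per couple.
#' @export
simulate_reproductive_outcomes <- function(rule = c("retrospective",
                                                    "prospective"),
                                           N, pnd_uptake = NULL,
                                           n_couples = 1e5,
                                           p_affected = 0.25, seed = 1L) {
  rule <- match.arg(rule)
  stopifnot(N >= 1, N == round(N))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  p <- p_affected
  u <- if (is.null(pnd_uptake)) NA_real_ else pnd_uptake

  if (rule == "retrospective") {
    # number of births up to and including the first affected one
    first <- ceiling(log(stats::runif(n_couples)) / log(1 - p))
    any_aff <- first <= N
    if (is.null(pnd_uptake)) {
      affected <- as.numeric(any_aff)
    } else {
      post_slots <- ifelse(any_aff, N - first, 0)
      # each later slot is an affected birth unless diagnosed and terminated
      later <- stats::rbinom(n_couples, size = post_slots, prob = p * (1 - u))
      affected <- as.numeric(any_aff) + later
    }
  } else {
    if (is.null(pnd_uptake)) {
      # reproduce until two healthy children; affecteds are the failures
      affected <- stats::rnbinom(n_couples, size = 2, prob = 1 - p)
    } else {
      affected <- stats::rbinom(n_couples, size = N, prob = p * (1 - u))
    }
  }
  baseline <- N * p
  fall <- 1 - mean(affected) / baseline
  list(fall = fall,
       se = stats::sd(affected) / (sqrt(n_couples) * baseline),
       mean_affected = mean(affected))
}
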