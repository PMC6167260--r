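#' Generate synthetic country and condition tables
#'
#' Deterministic (seeded) fixture generator spanning the indicator ranges
#' the estimation framework is designed for: IMR log-uniform on 2-120 per
#' 1000 (covering all five access bands, including the steep 10-35 zone),
#' consanguinity coefficient zero for half the countries and uniform
#' 0.005-0.04 for the rest (an Eastern-Mediterranean-like pattern), total
#' fertility rising with IMR, antenatal-care coverage falling with IMR,
#' HIV-attributable infant mortality for a flagged subset, and TOP policy
#' groups sampled over A-D. The condition table ships one NTD, one
#' chromosomal, one recessive (allele frequency supplied) and one
#' Rh-disease row with plausible synthetic natural-history parameters.
#'
#' @param n_countries Number of country rows (>= 1).
#' @param seed Integer seed; the same seed yields byte-identical tables.
#' @return List with `countries` and `conditions` data frames, both
#'   passing their schema validators.
#' @export
#' @examples
#' fx <- generate_fixtures(10, seed = 42)
#' nrow(fx$countries)
generate_fixtures <- function(n_countries, seed = 42L) {
  stopifnot(n_countries >= 1)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- n_countries

  imr <- exp(stats::runif(n, log(2), log(120)))
  consang <- stats::runif(n) < 0.5
  alpha <- ifelse(consang, stats::runif(n, 0.005, 0.04), 0)
  # fertility rises and antenatal coverage falls along the development axis
  devax <- (log(imr) - log(2)) / (log(120) - log(2))
  tfr <- pmin(7, pmax(1.2, 1.2 + 5.0 * devax + stats::rnorm(n, 0, 0.4)))
  anc4 <- pmin(1, pmax(0, 0.97 - 0.75 * devax + stats::rnorm(n, 0, 0.05)))
  hiv_flag <- stats::runif(n) < 0.2
  hiv_imr <- ifelse(hiv_flag, stats::runif(n, 0.1, 1) * pmin(0.2 * imr, 8), 0)
  nmr <- 0.6 * imr * stats::runif(n, 0.9, 1.1)
  top_group <- sample(c("A", "B", "C", "D"), n, replace = TRUE,
                      prob = c(0.2, 0.35, 0.15, 0.3))
  mandatory <- stats::runif(n) < 0.4
  regions <- c("AFR", "AMR", "EMR", "EUR", "SEAR", "WPR")

  grid <- expand.grid(a = LETTERS, b = LETTERS, c = LETTERS,
                      stringsAsFactors = FALSE)
  iso3 <- paste0(grid$c, grid$b, grid$a)[seq_len(n)]

  countries <- data.frame(
    iso3 = iso3,
    region = sample(regions, n, replace = TRUE),
    year = 2010L,
    livebirths = round(exp(stats::runif(n, log(1e4), log(3e6)))),
    imr = imr,
    nmr = nmr,
    hiv_imr = hiv_imr,
    alpha = alpha,
    tfr = tfr,
    anc4 = anc4,
    fortification_mandatory = mandatory,
    fortification_dose_ppm = ifelse(mandatory,
                                    stats::runif(n, 0.5, 3), 0),
    fortification_reach = ifelse(mandatory, stats::runif(n, 0.3, 1), 0),
    top_group = top_group,
    universal_screening = top_group %in% c("A", "B") &
      stats::runif(n) < 0.4,
    antid_standard_practice = stats::runif(n) < 0.5,
    prospective_screening_coverage =
      ifelse(stats::runif(n) < 0.15, stats::runif(n, 0.2, 0.9), 0),
    stringsAsFactors = FALSE
  )

  # Synthetic condition parameters: values are field-plausible but invented
  # (EUROCAT uptakes and natural-history shares are inputs in production).
  conditions <- data.frame(
    condition_id = c("spina_bifida", "down_syndrome", "beta_thalassaemia",
                     "rh_disease"),
    condition_class = c("ntd", "chromosomal", "single_gene_recessive",
                        "rh_disease"),
    baseline_prevalence_per_1000 = c(2.0, 1.6, NA, 0.6),
    q = c(NA, NA, 0.02, NA),
    eurocat_top_uptake = c(0.6, 0.6, 0.9, 0),
    restricted_flag = c(TRUE, TRUE, FALSE, FALSE),
    sb_frac = c(0.05, 0.05, 0.0, 0.15),
    m_nocare_u5 = c(0.80, 0.45, 0.90, 0.70),
    m_care_u5 = c(0.10, 0.05, 0.05, 0.02),
    share_cured_care = c(0.30, 0.00, 0.10, 0.80),
    share_mild_care = c(0.45, 0.60, 0.70, 0.15),
    share_severe_care = c(0.25, 0.40, 0.20, 0.05),
    share_cured_nocare = c(0.05, 0.00, 0.00, 0.40),
    share_mild_nocare = c(0.35, 0.40, 0.30, 0.35),
    share_severe_nocare = c(0.60, 0.60, 0.70, 0.25),
    folate_preventable_flag = c(TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )

  list(countries = validate_country_table(countries),
       conditions = validate_condition_table(conditions))
}

#' Write fixture tables to CSV
#'
#' @param fixtures Output of [generate_fixtures()].
#' @param dir Output directory (created if needed).
#' @return Paths of the two files written, invisibly.
#' @export
write_fixtures <- function(fixtures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cpath <- file.path(dir, "countries.csv")
  dpath <- file.path(dir, "conditions.csv")
  utils::write.csv(fixtures$countries, cpath, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8", na = "")
  utils::write.csv(fixtures$conditions, dpath, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(c(countries = cpath, conditions = dpath))
}
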