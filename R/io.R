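# Country and condition table schemas: name -> validator. Extra columns are
# rejected by name so that schema drift is caught at the door.

country_schema <- function() {
  frac <- function(x) is.numeric(x) & x >= 0 & x <= 1
  list(
    iso3 = function(x) is.character(x) & nchar(x) == 3,
    region = function(x) is.character(x) & nchar(x) > 0,
    year = function(x) is.numeric(x) & x == round(x),
    livebirths = function(x) is.numeric(x) & x >= 0,
    imr = function(x) is.numeric(x) & is.finite(x) & x >= 0,
    nmr = function(x) is.numeric(x) & x >= 0,
    hiv_imr = function(x) is.numeric(x) & x >= 0,
    alpha = function(x) is.numeric(x) & x >= 0 & x <= 0.0625,
    tfr = function(x) is.numeric(x) & x >= 0,
    anc4 = frac,
    fortification_mandatory = is.logical,
    fortification_dose_ppm = function(x) is.numeric(x) & x >= 0,
    fortification_reach = frac,
    top_group = function(x) x %in% c("A", "B", "C", "D"),
    universal_screening = is.logical,
    antid_standard_practice = is.logical,
    prospective_screening_coverage = frac
  )
}

condition_schema <- function() {
  frac <- function(x) is.na(x) | (is.numeric(x) & x >= 0 & x <= 1)
  list(
    condition_id = function(x) is.character(x) & nchar(x) > 0,
    condition_class = function(x) x %in% c("malformation", "chromosomal",
                                           "single_gene_recessive",
                                           "rh_disease", "ntd"),
    baseline_prevalence_per_1000 = function(x)
      is.na(x) | (is.numeric(x) & x >= 0),
    q = function(x) is.na(x) | (is.numeric(x) & x >= 0 & x <= 0.5),
    eurocat_top_uptake = frac,
    restricted_flag = is.logical,
    sb_frac = frac,
    m_nocare_u5 = frac,
    m_care_u5 = frac,
    share_cured_care = frac,
    share_mild_care = frac,
    share_severe_care = frac,
    share_cured_nocare = frac,
    share_mild_nocare = frac,
    share_severe_nocare = frac,
    folate_preventable_flag = is.logical
  )
}

schema_error <- function(msg) {
  structure(class = c("cdburden_schema_error", "error", "condition"),
            list(message = msg, call = NULL))
}

validate_table <- function(df, schema, what) {
  missing <- setdiff(names(schema), names(df))
  if (length(missing))
    stop(schema_error(paste0(what, ": missing column(s): ",
                             paste(missing, collapse = ", "))))
  extra <- setdiff(names(df), names(schema))
  if (length(extra))
    stop(schema_error(paste0(what, ": unexpected column(s): ",
                             paste(extra, collapse = ", "))))
  for (col in names(schema)) {
    ok <- schema[[col]](df[[col]])
    if (any(!ok)) {
      bad <- which(!ok)[1]
      stop(schema_error(sprintf(
        "%s: invalid value in column '%s', row %d: %s",
        what, col, bad, format(df[[col]][bad]))))
    }
  }
  df
}

#' Validate a country-year table
#'
#' Checks exact schema columns, types, ranges and enums, naming the first
#' offending cell; also enforces cross-field invariants (HIV-attributable
#' IMR cannot exceed IMR).
#'
#' @param df Data frame of country-year records.
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_country_table <- function(df) {
  validate_table(df, country_schema(), "country table")
  bad <- which(df$hiv_imr > df$imr)
  if (length(bad))
    stop(schema_error(sprintf(
      "country table: hiv_imr exceeds imr in row %d", bad[1])))
  df
}

#' Validate a condition-parameter table
#'
#' Recessive rows must carry an allele frequency `q` or a baseline
#' prevalence, not both; all other rows need a baseline.
#'
#' @param df Data frame of condition profiles.
#' @return The validated data frame.
#' @export
validate_condition_table <- function(df) {
  validate_table(df, condition_schema(), "condition table")
  rec <- df$condition_class == "single_gene_recessive"
  both <- rec & !is.na(df$q) & !is.na(df$baseline_prevalence_per_1000)
  neither <- rec & is.na(df$q) & is.na(df$baseline_prevalence_per_1000)
  if (any(both | neither))
    stop(schema_error(sprintf(
      "condition table: recessive row %d must carry q or a baseline, not both/neither",
      which(both | neither)[1])))
  if (any(!rec & is.na(df$baseline_prevalence_per_1000)))
    stop(schema_error("condition table: non-recessive rows need a baseline prevalence"))
  for (suffix in c("care", "nocare")) {
    s <- df[[paste0("share_cured_", suffix)]] +
      df[[paste0("share_mild_", suffix)]] +
      df[[paste0("share_severe_", suffix)]]
    if (any(abs(s - 1) > 1e-9))
      stop(schema_error(sprintf(
        "condition table: %s survivor shares must sum to 1 (row %d)",
        suffix, which(abs(s - 1) > 1e-9)[1])))
  }
  if (any(df$m_care_u5 > df$m_nocare_u5))
    stop(schema_error("condition table: m_care_u5 exceeds m_nocare_u5"))
  df
}

#' Read and validate a country-year CSV
#'
#' UTF-8, comma-separated, header row, '.' decimal separator.
#'
#' @param path File path.
#' @return Validated data frame of country-year records.
#' @export
read_country_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  for (col in c("fortification_mandatory", "universal_screening",
                "antid_standard_practice"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  validate_country_table(df)
}

#' Read and validate a condition-parameter CSV
#'
#' @param path File path.
#' @return Validated data frame of condition profiles.
#' @export
read_condition_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  for (col in c("restricted_flag", "folate_preventable_flag"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  validate_condition_table(df)
}

#' Write an estimates table as CSV
#'
#' Numeric columns are written with 15 significant digits so that a write
#' followed by a read is lossless to at least 12 significant digits.
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_estimates <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}
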