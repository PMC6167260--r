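#' Built-in model configuration
#'
#' All tunable model constants with their defaults, as a nested list.
#' Values loaded from a YAML or JSON file override these; explicit
#' function arguments override both (precedence: argument > file >
#' built-in).
#'
#' @return Nested list of configuration values.
#' @export
default_config <- function() {
  list(
    access = list(
      m_lo = 9,
      m_hi = 100,
      anchors = data.frame(imr = c(17, 39.5, 77),
                           access = c(0.50, 0.15, 0.05))
    ),
    consanguinity = list(
      e_nocare = 30,
      rho = 0.8,
      n_iter = 2L,
      imr_floor = 1
    ),
    folate = list(
      sb_anenc_floor = 0.7,
      enceph_share = 0.115,
      total_floor = 0.77,
      k_dose = 1.65,
      ofc_max_effect = 0.05,
      chd_max_effect = 0.05,
      dose_response_table = NULL
    ),
    reproductive = list(
      p_affected = 0.25,
      mc_oracle_n = 1e5,
      seed = 1L
    ),
    top = list(
      restricted_multiplier = 0.5,
      restricted_conditions = c("down_syndrome", "spina_bifida")
    ),
    antid = list(
      efficacy = 1.0
    )
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.data.frame(base[[nm]]) && !is.data.frame(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a configuration file over the built-in defaults
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for the
#'   defaults alone.
#' @param overrides Optional nested list applied on top of the file.
#' @return Full configuration list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    ext <- tolower(tools::file_ext(path))
    file_cfg <- switch(ext,
      yaml = ,
      yml = yaml::read_yaml(path),
      json = jsonlite::fromJSON(path, simplifyVector = TRUE),
      stop("config must be YAML or JSON, got .", ext, call. = FALSE))
    cfg <- merge_config(cfg, file_cfg)
  }
  merge_config(cfg, overrides)
}
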