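#' Stepped CHERG access-to-care reference table
#'
#' The five-band mapping from infant mortality rate (IMR, infant deaths per
#' 1000 livebirths) to the estimated proportion of the population with access
#' to optimal care, derived from the CHERG neonatal mortality groups. Bands
#' are half-open real intervals so that the printed integer ranges
#' (<= 9, 10-24, 25-54, 55-99, 100+) cover all real-valued IMRs without gaps.
#'
#' @return A data frame of class `stepped_access_table` with columns
#'   `imr_low` (inclusive), `imr_high` (exclusive, `Inf` for the last band)
#'   and `access` (fraction in \[0, 1\], non-increasing).
#' @export
#' @examples
#' stepped_access_table()
stepped_access_table <- function() {
  tab <- data.frame(
    imr_low  = c(0, 10, 25, 55, 100),
    imr_high = c(10, 25, 55, 100, Inf),
    access   = c(1.0, 0.50, 0.15, 0.05, 0.0)
  )
  class(tab) <- c("stepped_access_table", "data.frame")
  tab
}

validate_stepped_table <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("imr_low", "imr_high", "access") %in% names(table)))
  if (table$imr_low[1] != 0 || !is.infinite(table$imr_high[nrow(table)]))
    stop("stepped access table must cover [0, Inf)", call. = FALSE)
  if (any(table$imr_high[-nrow(table)] != table$imr_low[-1]))
    stop("stepped access table bands must be contiguous", call. = FALSE)
  if (is.unsorted(rev(table$access)))
    stop("access must be non-increasing across bands", call. = FALSE)
  if (table$access[1] != 1 || table$access[nrow(table)] != 0)
    stop("first band access must be 1 and last band 0", call. = FALSE)
  invisible(table)
}

#' Stepped access to optimal care from infant mortality
#'
#' Maps IMR onto the access fraction of the band containing it.
#'
#' @param imr Infant deaths per 1000 livebirths; finite, non-negative.
#'   Vectorised.
#' @param table Band table, see [stepped_access_table()].
#' @return Access fraction(s) in \[0, 1\].
#' @export
#' @examples
#' stepped_access(c(8, 17, 120))   # 1.00, 0.50, 0.00
stepped_access <- function(imr, table = stepped_access_table()) {
  validate_stepped_table(table)
  if (any(!is.finite(imr)) || any(imr < 0))
    stop("imr must be finite and >= 0", call. = FALSE)
  idx <- findInterval(imr, table$imr_low)
  table$access[idx]
}

#' Fit the smooth access-to-care curve
#'
#' Replaces the stepped band mapping with a continuous, monotone curve based
#' on the Beta family: access(m) = 1 for m <= m_lo, 0 for m >= m_hi, and
#' otherwise 1 - I((m - m_lo)/(m_hi - m_lo); a, b), where I is the
#' regularized incomplete beta function. The two positive shape parameters
#' are chosen by least squares at the interior band midpoints of the stepped
#' table; the fit must land within `tol` of every anchor or a calibration
#' error is raised.
#'
#' @param table Stepped reference table (defines the endpoints' semantics).
#' @param m_lo IMR at and below which access is exactly 1 (per 1000).
#' @param m_hi IMR at and above which access is exactly 0 (per 1000).
#' @param anchors Two-column matrix or data frame of (imr, access)
#'   calibration points; defaults to the interior band midpoints of the
#'   printed integer ranges: (17, 0.50), (39.5, 0.15), (77, 0.05).
#' @param tol Maximum permitted absolute miss at any anchor.
#' @return An object of class `access_curve` with fields `m_lo`, `m_hi`,
#'   `shape_a`, `shape_b`, `anchors`.
#' @export
#' @examples
#' curve <- fit_access_curve()
#' access_from_imr(c(9, 17, 100), curve)
fit_access_curve <- function(table = stepped_access_table(),
                             m_lo = 9, m_hi = 100,
                             anchors = NULL, tol = 0.05) {
  validate_stepped_table(table)
  if (is.null(anchors))
    anchors <- data.frame(imr = c(17, 39.5, 77), access = c(0.50, 0.15, 0.05))
  anchors <- as.data.frame(anchors)
  names(anchors) <- c("imr", "access")
  if (m_lo >= m_hi) stop("m_lo must be < m_hi", call. = FALSE)

  x <- (anchors$imr - m_lo) / (m_hi - m_lo)
  sse <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    sum((1 - stats::pbeta(x, a, b) - anchors$access)^2)
  }
  fit <- stats::optim(c(0, 0), sse, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  shape_a <- exp(fit$par[1]); shape_b <- exp(fit$par[2])
  resid <- (1 - stats::pbeta(x, shape_a, shape_b)) - anchors$access
  if (max(abs(resid)) > tol) {
    stop(calibration_error(sprintf(
      "access curve calibration failed: max anchor miss %.4f > %.4f (a=%.4g, b=%.4g)",
      max(abs(resid)), tol, shape_a, shape_b)))
  }
  structure(
    list(m_lo = m_lo, m_hi = m_hi, shape_a = shape_a, shape_b = shape_b,
         anchors = anchors, anchor_residuals = resid),
    class = "access_curve"
  )
}

calibration_error <- function(msg) {
  structure(class = c("cdburden_calibration_error", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Evaluate the access curve at given infant mortality rates
#'
#' @param imr IMR values (per 1000); vectorised.
#' @param curve An [fit_access_curve()] object.
#' @return Access fractions in \[0, 1\]; exactly 1 at or below `m_lo` and
#'   exactly 0 at or above `m_hi`.
#' @export
access_from_imr <- function(imr, curve) {
  stopifnot(inherits(curve, "access_curve"))
  if (any(!is.finite(imr)) || any(imr < 0))
    stop("imr must be finite and >= 0", call. = FALSE)
  x <- (imr - curve$m_lo) / (curve$m_hi - curve$m_lo)
  out <- 1 - stats::pbeta(x, curve$shape_a, curve$shape_b)
  out[imr <= curve$m_lo] <- 1
  out[imr >= curve$m_hi] <- 0
  out
}

#' @export
print.access_curve <- function(x, ...) {
  cat(sprintf(
    "Access-to-care curve: 1 - I((m - %g)/%g; a = %.4f, b = %.4f) on (%g, %g)\n",
    x$m_lo, x$m_hi - x$m_lo, x$shape_a, x$shape_b, x$m_lo, x$m_hi))
  invisible(x)
}

#' Consanguinity excess-mortality model parameters
#'
#' @param e_nocare Excess consanguinity-associated infant deaths per 1000
#'   livebirths at the first-cousin reference level (alpha = 0.0625) in the
#'   absence of care.
#' @param rho Fraction of those excess deaths avertable with optimal care.
#' @param n_iter Number of fixed-point iterations of the IMR adjustment; the
#'   default of 2 is the point at which further iterations change the
#'   adjusted IMR negligibly.
#' @param imr_floor Minimum permitted adjusted IMR (per 1000).
#' @param f_ref Reference inbreeding coefficient (first-cousin offspring).
#' @return A list of class `consanguinity_model`.
#' @export
consanguinity_model <- function(e_nocare = 30, rho = 0.8, n_iter = 2L,
                                imr_floor = 1, f_ref = 0.0625) {
  stopifnot(e_nocare >= 0, rho >= 0, rho <= 1, n_iter >= 1, imr_floor > 0,
            f_ref > 0)
  structure(list(e_nocare = e_nocare, rho = rho, n_iter = as.integer(n_iter),
                 imr_floor = imr_floor, f_ref = f_ref),
            class = "consanguinity_model")
}

#' Consanguinity-associated infant mortality (cIMR)
#'
#' Excess infant deaths attributable to consanguinity-associated recessive
#' disorders, scaled linearly in the population mean coefficient of
#' consanguinity and attenuated by access to care: with access, a fraction
#' `rho` of the excess deaths is averted.
#'
#' @param alpha Mean coefficient of consanguinity, in \[0, 0.0625\].
#' @param access Fraction of the population with access to optimal care.
#' @param model A [consanguinity_model()].
#' @return cIMR, infant deaths per 1000 livebirths. Vectorised over `alpha`
#'   and `access`.
#' @export
#' @examples
#' consanguinity_imr(0.02, 0.5, consanguinity_model(e_nocare = 30, rho = 0.8))
consanguinity_imr <- function(alpha, access, model = consanguinity_model()) {
  stopifnot(inherits(model, "consanguinity_model"))
  if (any(alpha < 0) || any(alpha > model$f_ref))
    stop("alpha must lie in [0, ", model$f_ref, "]", call. = FALSE)
  if (any(access < 0) || any(access > 1))
    stop("access must lie in [0, 1]", call. = FALSE)
  (alpha / model$f_ref) * model$e_nocare *
    ((1 - access) + access * (1 - model$rho))
}

#' Iterative consanguinity adjustment of IMR
#'
#' The first subtraction of cIMR (computed at the access level implied by
#' the unadjusted IMR) over-states consanguinity-associated mortality,
#' because the reduced IMR implies better access and hence fewer
#' consanguinity-associated deaths. The adjustment is therefore iterated:
#' access is re-evaluated on the adjusted IMR and cIMR recomputed, a fixed
#' number of times (default 2, after which changes are negligible).
#'
#' @param imr Unadjusted IMR (per 1000), scalar.
#' @param alpha Mean coefficient of consanguinity.
#' @param curve Access curve from [fit_access_curve()].
#' @param model A [consanguinity_model()].
#' @return A list with `adjusted_imr`, `consanguinity_imr` (the final cIMR),
#'   `access_unadjusted`, `clamped` (whether the floor bound), and `trace`,
#'   a data frame with one row per iteration (`iter`, `c_imr`,
#'   `adjusted_imr`, `access`).
#' @export
adjust_imr_consanguinity <- function(imr, alpha, curve,
                                     model = consanguinity_model()) {
  stopifnot(length(imr) == 1, length(alpha) == 1)
  if (!is.finite(imr) || imr < 0)
    stop("imr must be finite and >= 0", call. = FALSE)
  a <- access_from_imr(imr, curve)
  access_unadjusted <- a
  trace <- data.frame(iter = integer(), c_imr = numeric(),
                      adjusted_imr = numeric(), access = numeric())
  imr_k <- imr
  c_imr <- 0
  clamped <- FALSE
  for (k in seq_len(model$n_iter)) {
    c_imr <- consanguinity_imr(alpha, a, model)
    imr_k <- imr - c_imr
    if (imr_k < model$imr_floor) {
      imr_k <- model$imr_floor
      clamped <- TRUE
    }
    a <- access_from_imr(imr_k, curve)
    trace <- rbind(trace, data.frame(iter = k, c_imr = c_imr,
                                     adjusted_imr = imr_k, access = a))
  }
  list(adjusted_imr = imr_k, consanguinity_imr = c_imr,
       access_unadjusted = access_unadjusted, clamped = clamped,
       trace = trace)
}

#' HIV adjustment of the consanguinity-adjusted IMR
#'
#' Subtracts HIV-attributable infant mortality; the result is floored at
#' `imr_floor`, with a warning when the subtraction would go below it.
#'
#' @param consanguinity_adjusted_imr Consanguinity-adjusted IMR (per 1000).
#' @param hiv_imr HIV-attributable infant deaths per 1000 livebirths.
#' @param imr_floor Minimum permitted adjusted IMR (per 1000).
#' @return Final adjusted IMR (per 1000).
#' @export
#' @examples
#' final_adjusted_imr(41.25, 0.05)   # 41.2
final_adjusted_imr <- function(consanguinity_adjusted_imr, hiv_imr,
                               imr_floor = 1) {
  stopifnot(all(consanguinity_adjusted_imr >= 0), all(hiv_imr >= 0))
  out <- consanguinity_adjusted_imr - hiv_imr
  low <- out < imr_floor
  if (any(low)) {
    warning("adjusted IMR clamped at floor ", imr_floor, " per 1000 for ",
            sum(low), " value(s)", call. = FALSE)
    out[low] <- imr_floor
  }
  out
}

#' Estimate access to optimal care with consanguinity and HIV adjustments
#'
#' Composes the iterative consanguinity adjustment and the HIV subtraction,
#' then evaluates the access curve on the final adjusted IMR. Because both
#' adjustments lower the IMR and the curve is non-increasing, the final
#' access estimate is never below the unadjusted one.
#'
#' @param imr Unadjusted IMR (per 1000), scalar.
#' @param alpha Mean coefficient of consanguinity.
#' @param hiv_imr HIV-attributable IMR (per 1000); must not exceed `imr`.
#' @param curve Access curve from [fit_access_curve()].
#' @param model A [consanguinity_model()].
#' @return A list of class `access_estimate` with `access_unadjusted`,
#'   `consanguinity_imr`, `adjusted_imr`, `final_adjusted_imr`,
#'   `access_final` and the per-iteration `trace`.
#' @export
#' @examples
#' curve <- fit_access_curve()
#' estimate_access(45, alpha = 0.03, hiv_imr = 0, curve = curve)
estimate_access <- function(imr, alpha = 0, hiv_imr = 0, curve,
                            model = consanguinity_model()) {
  if (hiv_imr > imr)
    stop("hiv_imr must not exceed imr", call. = FALSE)
  adj <- adjust_imr_consanguinity(imr, alpha, curve, model)
  fin <- final_adjusted_imr(adj$adjusted_imr, hiv_imr, model$imr_floor)
  structure(
    list(imr = imr,
         access_unadjusted = adj$access_unadjusted,
         consanguinity_imr = adj$consanguinity_imr,
         adjusted_imr = adj$adjusted_imr,
         final_adjusted_imr = fin,
         access_final = access_from_imr(fin, curve),
         clamped = adj$clamped,
         trace = adj$trace),
    class = "access_estimate"
  )
}

#' @export
print.access_estimate <- function(x, ...) {
  cat(sprintf(
    "IMR %.2f -> adjusted %.2f (cIMR %.2f) -> final %.2f; access %.1f%% -> %.1f%%\n",
    x$imr, x$adjusted_imr, x$consanguinity_imr, x$final_adjusted_imr,
    100 * x$access_unadjusted, 100 * x$access_final))
  invisible(x)
}

#' Access estimates for a table of country-years
#'
#' @param countries Validated country table (see [read_country_table()]).
#' @param curve Access curve; fitted with defaults when omitted.
#' @param model A [consanguinity_model()].
#' @return Data frame with one row per input row: `iso3`, `year`, `imr`,
#'   `c_imr`, `hiv_imr`, `final_adjusted_imr`, `access_unadjusted_pct`,
#'   `access_final_pct` (percent, 1 decimal).
#' @export
estimate_access_table <- function(countries, curve = fit_access_curve(),
                                  model = consanguinity_model()) {
  rows <- lapply(seq_len(nrow(countries)), function(i) {
    est <- estimate_access(countries$imr[i], countries$alpha[i],
                           countries$hiv_imr[i], curve, model)
    data.frame(iso3 = countries$iso3[i], year = countries$year[i],
               imr = countries$imr[i], c_imr = est$consanguinity_imr,
               hiv_imr = countries$hiv_imr[i],
               final_adjusted_imr = est$final_adjusted_imr,
               access_unadjusted_pct = round(100 * est$access_unadjusted, 1),
               access_final_pct = round(100 * est$access_final, 1))
  })
  do.call(rbind, rows)
}
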