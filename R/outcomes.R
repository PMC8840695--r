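#' Altitude adjustment of haemoglobin
#'
#' Applies the CDC polynomial adjustment used by the DHS program:
#' with `A` the altitude in thousands of feet, the adjustment subtracted from
#' the measured haemoglobin is `-0.032*A + 0.022*A^2`, clamped at zero so the
#' adjustment is never negative (it only becomes positive above ~1450 ft).
#'
#' @param hb_gdl Measured haemoglobin, g/dl.
#' @param altitude_m Altitude in metres; `NA` skips adjustment for that
#'   record (the caller is expected to log the count).
#' @return Adjusted haemoglobin, g/dl (same length as input).
#' @export
adjust_hb_for_altitude <- function(hb_gdl, altitude_m) {
  stopifnot(length(hb_gdl) == length(altitude_m) || length(altitude_m) == 1)
  A <- altitude_m * 3.2808399 / 1000  # thousands of feet
  adj <- pmax(0, -0.032 * A + 0.022 * A^2)
  adj[is.na(altitude_m)] <- 0
  hb_gdl - adj
}

#' Classify anaemia from adjusted haemoglobin
#'
#' Binary flag is `adjusted_hb < cutoff` (strict). Severity uses the WHO
#' bands for children 6-59 months, interpreted as half-open intervals so
#' they partition the anaemic range: severe `< 7`, moderate `[7, 9)`, mild
#' `[9, cutoff)`.
#'
#' @param adjusted_hb Altitude-adjusted haemoglobin, g/dl.
#' @param cutoff Anaemia cutoff, g/dl (default 11).
#' @return Data frame with integer `anaemic` and factor `severity`
#'   (`none < mild < moderate < severe`).
#' @export
classify_anaemia <- function(adjusted_hb, cutoff = 11) {
  severity <- rep(NA_character_, length(adjusted_hb))
  ok <- !is.na(adjusted_hb)
  severity[ok] <- "none"
  severity[ok & adjusted_hb < cutoff] <- "mild"
  severity[ok & adjusted_hb < 9] <- "moderate"
  severity[ok & adjusted_hb < 7] <- "severe"
  data.frame(
    anaemic = ifelse(is.na(adjusted_hb), NA_integer_,
                     as.integer(adjusted_hb < cutoff)),
    severity = factor(severity, levels = c("none", "mild", "moderate", "severe"),
                      ordered = TRUE)
  )
}

#' Classify stunting from height-for-age z score
#'
#' Stunted if and only if `haz < cutoff` (strict), default cutoff -2 SD.
#'
#' @param haz Height-for-age z score.
#' @param cutoff Cutoff in SD units (default -2).
#' @return Integer vector (1 stunted, 0 not, NA missing).
#' @export
classify_stunting <- function(haz, cutoff = -2) {
  ifelse(is.na(haz), NA_integer_, as.integer(haz < cutoff))
}

#' Flag severe stunting
#'
#' Conventional severe cutoff of -3 SD; informational only, the joint model
#' consumes the binary indicator from [classify_stunting()].
#'
#' @inheritParams classify_stunting
#' @export
classify_severe_stunting <- function(haz, cutoff = -3) {
  classify_stunting(haz, cutoff)
}

#' Derive both binary outcomes on a record table
#'
#' Adjusts haemoglobin for altitude, classifies anaemia and stunting, and
#' writes the `anaemic`, `anaemia_severity` and `stunted` columns. Children
#' younger than 6 months (where `age_months` is available) are excluded from
#' anaemia derivation and flagged missing, mirroring the survey protocol.
#'
#' @param records Validated child records carrying `hb_gdl`, `altitude_m`,
#'   `haz` (and optionally `age_months`).
#' @param config An [analysis_config()].
#' @return Records with derived outcome columns; attributes
#'   `n_missing_altitude` (adjustment skipped) and `n_under6_excluded`.
#' @export
derive_outcomes <- function(records, config = analysis_config()) {
  hb <- if ("hb_gdl" %in% names(records)) records$hb_gdl else rep(NA_real_, nrow(records))
  alt <- if ("altitude_m" %in% names(records)) records$altitude_m else rep(NA_real_, nrow(records))
  adj <- adjust_hb_for_altitude(hb, alt)
  an <- classify_anaemia(adj, config$anaemia_cutoff)
  under6 <- if ("age_months" %in% names(records)) {
    !is.na(records$age_months) & records$age_months < 6
  } else rep(FALSE, nrow(records))
  an$anaemic[under6] <- NA_integer_
  an$severity[under6] <- NA
  records$anaemic <- an$anaemic
  records$anaemia_severity <- an$severity
  haz <- if ("haz" %in% names(records)) records$haz else rep(NA_real_, nrow(records))
  records$stunted <- classify_stunting(haz, config$stunting_cutoff)
  attr(records, "n_missing_altitude") <- sum(!is.na(hb) & is.na(alt))
  attr(records, "n_under6_excluded") <- sum(under6 & !is.na(hb))
  records
}
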