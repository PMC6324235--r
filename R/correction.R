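# Two-step evolutionary-rate correction of Ks distributions, and linear
# dating of polyploidy events against the hexaploidization calibration.
#
# Step 1 aligns every lineage's peak of ECH-produced duplicates to the
# grape peak (grape evolved slowest): c1 = mu_grape / mu_lineage, applied
# multiplicatively; cross-lineage samples use the algebraic mean of the two
# lineages' coefficients.  Step 2 removes the residual elevation that step 1
# leaves on the fast (cotton) lineage by aligning the cotton-outgroup
# distribution to the durian-outgroup distribution: c2 = mu_dc / mu_cc.
# For a cross-species sample only one of the two path halves runs through
# the elevated lineage, so c2 = 2/(1 + r) for residual rate r; a
# within-lineage duplicate pair has both halves elevated, and its
# equivalent coefficient is 1/r = c2/(2 - c2).

#' Step-1 correction coefficient for one lineage
#'
#' @param mu_grape fitted Ks peak of grape's ECH duplicates
#' @param mu_lineage fitted Ks peak of the lineage's ECH duplicates
#' @return coefficient c1 = mu_grape / mu_lineage; multiplying the
#'   lineage's Ks values by c1 moves its ECH peak onto grape's
#' @export
step1_coefficient <- function(mu_grape, mu_lineage) {
  if (!is.finite(mu_grape) || !is.finite(mu_lineage) ||
      mu_grape <= 0 || mu_lineage <= 0)
    stop("peak means must be positive")
  mu_grape / mu_lineage
}

#' Correct a cross-genome Ks sample with two lineage coefficients
#'
#' Applies the algebraic mean of the two lineages' step-1 coefficients:
#' Ks' = Ks (c_i + c_j)/2.  When one genome is grape, its coefficient is 1.
#'
#' @param ks numeric Ks values
#' @param c_i,c_j step-1 coefficients of the two lineages
#' @return corrected Ks values
#' @export
correct_between <- function(ks, c_i, c_j) {
  if (c_i <= 0 || c_j <= 0) stop("coefficients must be positive")
  ks * (c_i + c_j) / 2
}

#' Step-2 correction of cotton-lineage Ks samples
#'
#' Computes c2 = `mu_slow_outgroup` / `mu_fast_outgroup` from the two
#' step-1-corrected outgroup distributions (durian-cacao and cotton-cacao
#' in the default four-taxon setting) and applies it to a Ks sample from
#' the fast lineage.  `sample_type = "cross"` (fast-lineage x other-genome
#' orthologs) multiplies by c2 itself; `sample_type = "duplicate"`
#' (within-fast-lineage duplicate pairs, e.g. the decaploidy paralogs)
#' multiplies by the equivalent duplicate-pair coefficient c2/(2 - c2),
#' because both halves of a duplicate pair's path are rate-elevated while
#' only one half of a cross-species path is.
#'
#' @param ks Ks values to correct (already step-1 corrected)
#' @param mu_fast_outgroup step-1-corrected peak of fast-lineage vs
#'   outgroup orthologs
#' @param mu_slow_outgroup step-1-corrected peak of slow-lineage vs
#'   outgroup orthologs
#' @param sample_type `"duplicate"` or `"cross"`
#' @return list with `ks` (corrected values), `c2`, and the coefficient
#'   actually applied (`applied`)
#' @export
step2_correction <- function(ks, mu_fast_outgroup, mu_slow_outgroup,
                             sample_type = c("duplicate", "cross")) {
  sample_type <- match.arg(sample_type)
  if (!is.finite(mu_fast_outgroup) || !is.finite(mu_slow_outgroup) ||
      mu_fast_outgroup <= 0 || mu_slow_outgroup <= 0)
    stop("peak means must be positive")
  c2 <- mu_slow_outgroup / mu_fast_outgroup
  applied <- if (sample_type == "cross") c2 else c2 / (2 - c2)
  list(ks = ks * applied, c2 = c2, applied = applied,
       sample_type = sample_type)
}

#' Build a correction model from fitted peaks
#'
#' Convenience wrapper collecting the step-1 coefficients of all lineages
#' and the step-2 coefficient of the fast lineage.
#'
#' @param ech_peaks named numeric: fitted ECH-duplicate peak per lineage;
#'   must include `grape`
#' @param mu_fast_outgroup,mu_slow_outgroup step-1-corrected outgroup
#'   ortholog peaks for the step-2 contrast (optional)
#' @param fast_lineage lineage the step-2 coefficient applies to
#' @return object of class `correction_model`
#' @export
correction_model <- function(ech_peaks, mu_fast_outgroup = NULL,
                             mu_slow_outgroup = NULL,
                             fast_lineage = "cotton") {
  if (!"grape" %in% names(ech_peaks))
    stop("ech_peaks must include a 'grape' entry")
  c1 <- vapply(ech_peaks, function(mu)
    step1_coefficient(ech_peaks[["grape"]], mu), numeric(1))
  c2 <- NULL
  if (!is.null(mu_fast_outgroup) && !is.null(mu_slow_outgroup))
    c2 <- mu_slow_outgroup / mu_fast_outgroup
  structure(list(step1 = c1, step2 = c2, fast_lineage = fast_lineage,
                 ech_peaks = ech_peaks), class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat("Evolutionary-rate correction model\n  step-1 coefficients:\n")
  for (nm in names(x$step1))
    cat(sprintf("    %-7s %.4f\n", nm, x$step1[[nm]]))
  if (!is.null(x$step2))
    cat(sprintf("  step-2 coefficient (%s): %.4f\n", x$fast_lineage, x$step2))
  invisible(x)
}

#' Date an event by linear scaling against the ECH calibration
#'
#' @param corrected_peak rate-corrected Ks peak of the event's duplicates
#' @param ech_peak rate-corrected Ks peak of the calibrating
#'   hexaploidization
#' @param t_lo,t_hi calibration age range of the ECH in million years
#' @param event label
#' @return object of class `event_date`: list with the inferred age range
#'   `date_mya = corrected_peak / ech_peak * c(t_lo, t_hi)`
#' @export
date_event <- function(corrected_peak, ech_peak, t_lo = 115, t_hi = 130,
                       event = "event") {
  if (ech_peak <= 0 || corrected_peak < 0) stop("peaks must be positive")
  if (t_lo > t_hi) stop("calibration range must be ordered")
  if (corrected_peak > ech_peak)
    warning("event peak exceeds the calibration peak (older than the ECH)")
  structure(list(event = event, corrected_peak = corrected_peak,
                 ech_peak = ech_peak, calibration_mya = c(t_lo, t_hi),
                 date_mya = corrected_peak / ech_peak * c(t_lo, t_hi)),
            class = "event_date")
}

#' @export
print.event_date <- function(x, ...) {
  cat(sprintf("%s: Ks peak %.3f (calibration %.3f = %g-%g mya) -> %.1f-%.1f mya\n",
              x$event, x$corrected_peak, x$ech_peak,
              x$calibration_mya[1], x$calibration_mya[2],
              x$date_mya[1], x$date_mya[2]))
  invisible(x)
}

#' Percent rate elevation of a fast lineage over a slow one
#'
#' Computed from the two lineages' Ks peaks against a common outgroup:
#' 100 (mu_fast - mu_slow) / mu_slow.
#'
#' @param mu_fast_outgroup,mu_slow_outgroup ortholog Ks peaks vs the
#'   common outgroup
#' @return percent elevation
#' @export
rate_elevation <- function(mu_fast_outgroup, mu_slow_outgroup) {
  if (mu_fast_outgroup <= 0 || mu_slow_outgroup <= 0)
    stop("peak means must be positive")
  100 * (mu_fast_outgroup - mu_slow_outgroup) / mu_slow_outgroup
}
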