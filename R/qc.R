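# Matrix-level sample QC. Of the twelve quality parameters used for
# Affymetrix arrays, five are computable from an expression matrix
# (negative values, >16-bit saturation, average intensity, GAPDH and
# ACTB 3'/5' ratios); the remaining seven need probe/CEL-level data
# (spike-in controls, border controls, centre of intensity, RNA
# degradation slope, present calls) and are reported as not-evaluable
# placeholders so the report format keeps their slots.

QC_CEL_LEVEL_CHECKS <- c(
  "poly_a_spike_controls", "labeled_crna_spike_controls",
  "center_of_intensity", "positive_border_controls",
  "negative_border_controls", "rna_degradation_slope",
  "percent_present_calls"
)

#' QC configuration
#'
#' Thresholds and control-probeset identifiers for [run_qc()]. The
#' defaults follow platform convention (no claim of reproducing any
#' published cut-offs): mean intensity within \[20, 20000\] on the
#' linear scale and 3'/5' control ratios at most 3.
#'
#' @param mean_band Length-2 numeric: admissible band for the mean of
#'   all probeset intensities (linear scale).
#' @param ratio_cap Maximum admissible GAPDH / ACTB 3'/5' ratio.
#' @param gapdh_3,gapdh_5,actb_3,actb_5 Control probeset IDs for the
#'   3'/5' degradation checks (e.g. the AFFX GAPDH/ACTB 3' and 5'
#'   probesets); `NULL` leaves the check not-evaluable.
#' @param strict When `TRUE`, not-evaluable checks fail the sample
#'   instead of being ignored in the overall verdict.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(mean_band = c(20, 20000), ratio_cap = 3,
                      gapdh_3 = NULL, gapdh_5 = NULL,
                      actb_3 = NULL, actb_5 = NULL,
                      strict = FALSE) {
  stopifnot(length(mean_band) == 2, mean_band[1] < mean_band[2],
            ratio_cap > 0)
  structure(
    list(mean_band = mean_band, ratio_cap = ratio_cap,
         gapdh_3 = gapdh_3, gapdh_5 = gapdh_5,
         actb_3 = actb_3, actb_5 = actb_5, strict = strict),
    class = "qc_config"
  )
}

#' 3'/5' control probeset ratio
#'
#' Ratio of the 3'-end to the 5'-end control probeset intensity of a
#' housekeeping gene (GAPDH, ACTB); values well above 1 indicate RNA
#' degradation or inefficient labelling. Returns `NA` (not evaluable)
#' when either probeset is absent/missing or the 5' intensity is not
#' positive.
#'
#' @param intensities Named numeric vector keyed by probeset ID.
#' @param probeset_3,probeset_5 IDs of the 3' and 5' control probesets.
#' @return The ratio, or `NA_real_` when not evaluable.
#' @export
three_prime_ratio <- function(intensities, probeset_3, probeset_5) {
  if (is.null(probeset_3) || is.null(probeset_5) ||
      !(probeset_3 %in% names(intensities)) ||
      !(probeset_5 %in% names(intensities))) {
    return(NA_real_)
  }
  x3 <- unname(intensities[[probeset_3]])
  x5 <- unname(intensities[[probeset_5]])
  if (is.na(x3) || is.na(x5) || x5 <= 0 || x3 <= 0) return(NA_real_)
  x3 / x5
}

qc_one_sample <- function(sample_id, intensities, config) {
  obs <- intensities[!is.na(intensities)]
  if (length(obs) == 0) {
    abort_pathact(paste0("sample ", sample_id, " has no observed intensities"))
  }
  gapdh <- three_prime_ratio(intensities, config$gapdh_3, config$gapdh_5)
  actb <- three_prime_ratio(intensities, config$actb_3, config$actb_5)
  checks <- tibble::tibble(
    check = c("no_negative_values", "no_saturated_values",
              "mean_intensity_in_band", "gapdh_3prime_5prime_ratio",
              "actb_3prime_5prime_ratio", QC_CEL_LEVEL_CHECKS),
    value = c(sum(obs < 0), sum(obs > 65535), mean(obs), gapdh, actb,
              rep(NA_real_, length(QC_CEL_LEVEL_CHECKS))),
    threshold_description = c(
      "no intensity below 0",
      "no intensity above 65535 (16-bit)",
      sprintf("mean intensity in [%g, %g]", config$mean_band[1],
              config$mean_band[2]),
      sprintf("GAPDH 3'/5' ratio <= %g", config$ratio_cap),
      sprintf("ACTB 3'/5' ratio <= %g", config$ratio_cap),
      rep("requires CEL-level data (not evaluable from a matrix)",
          length(QC_CEL_LEVEL_CHECKS))
    )
  )
  checks$passed <- c(
    sum(obs < 0) == 0,
    sum(obs > 65535) == 0,
    mean(obs) >= config$mean_band[1] && mean(obs) <= config$mean_band[2],
    if (is.na(gapdh)) NA else gapdh <= config$ratio_cap,
    if (is.na(actb)) NA else actb <= config$ratio_cap,
    rep(NA, length(QC_CEL_LEVEL_CHECKS))
  )
  checks$sample_id <- sample_id
  checks[, c("sample_id", "check", "value", "threshold_description", "passed")]
}

#' Run sample quality control on an expression matrix
#'
#' Executes the matrix-level checks for every sample: no negative
#' intensities, no saturated (>65535) intensities, mean intensity inside
#' the configured band, and GAPDH/ACTB 3'/5' ratios below the configured
#' cap (not-evaluable when control probesets are absent). CEL-level
#' checks are reported as not-evaluable placeholder rows.
#'
#' @param data Expression tibble.
#' @param config A [qc_config()].
#' @return Tidy tibble, one row per sample x check: `sample_id`,
#'   `check`, `value`, `threshold_description`, `passed` (`NA` = not
#'   evaluable). Summarise with [qc_overall()].
#' @export
run_qc <- function(data, config = qc_config()) {
  check_expression(data)
  stopifnot(inherits(config, "qc_config"))
  sample_ids <- setdiff(names(data), "probeset_id")
  purrr::map_dfr(sample_ids, function(sid) {
    qc_one_sample(sid, stats::setNames(data[[sid]], data$probeset_id), config)
  })
}

#' Per-sample overall QC verdict
#'
#' A sample passes when every evaluable check passes; in strict mode a
#' not-evaluable check also fails the sample.
#'
#' @param qc Output of [run_qc()].
#' @param strict Treat not-evaluable checks as failures.
#' @return Tibble `sample_id`, `overall_pass`.
#' @export
qc_overall <- function(qc, strict = FALSE) {
  stopifnot(is.data.frame(qc),
            all(c("sample_id", "passed") %in% names(qc)))
  qc |>
    dplyr::group_by(sample_id = .data$sample_id) |>
    dplyr::summarise(
      overall_pass = if (strict) {
        all(!is.na(.data$passed) & .data$passed)
      } else {
        all(.data$passed[!is.na(.data$passed)])
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$sample_id, unique(qc$sample_id)))
}

#' Drop samples that failed quality control
#'
#' @param data Expression tibble.
#' @param qc Output of [run_qc()] covering exactly the samples of
#'   `data`.
#' @param strict Passed to [qc_overall()].
#' @return `data` restricted to passing samples, column order preserved.
#' @export
filter_by_qc <- function(data, qc, strict = FALSE) {
  check_expression(data)
  sample_ids <- setdiff(names(data), "probeset_id")
  overall <- qc_overall(qc, strict = strict)
  if (!setequal(overall$sample_id, sample_ids)) {
    abort_pathact("QC report and expression data cover different samples")
  }
  keep <- overall$sample_id[overall$overall_pass]
  data[, c("probeset_id", sample_ids[sample_ids %in% keep])]
}
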