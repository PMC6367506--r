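# PI3K-FOXO interpretation. The FOXO model reads out PI3K pathway
# activity inversely, but only while FOXO acts in its growth-control
# mode. Under cellular oxidative stress FOXO is alternatively
# phosphorylated and switches to transcribing stress-protective targets
# such as SOD2; an elevated SOD2 level therefore invalidates the
# inverse readout and the PI3K call becomes indeterminate.

#' Assess oxidative stress from SOD2 expression
#'
#' Compares a sample's SOD2 expression against a reference set of
#' normal (non-stressed) tissue values. The stress threshold is the
#' reference mean plus two reference standard deviations (sample SD,
#' n - 1 denominator); the sample is flagged stressed only when its
#' level strictly exceeds the threshold (a level exactly at the
#' threshold is non-stressed).
#'
#' @param sod2_level SOD2 expression of the sample. When the SOD2 level
#'   is measured by several probesets, pass their mean (see
#'   [sod2_level()]).
#' @param reference Numeric vector (length >= 2) of SOD2 levels in
#'   normal tissue, same units as `sod2_level`.
#' @return A one-row tibble: `sod2_level`, `reference_mean`,
#'   `reference_sd`, `threshold`, `stressed`.
#' @examples
#' assess_oxidative_stress(8, c(4, 5, 6)) # threshold 7 -> stressed
#' @export
assess_oxidative_stress <- function(sod2_level, reference) {
  if (length(reference) < 2 || any(!is.finite(reference))) {
    abort_pathact("`reference` needs at least 2 finite values")
  }
  if (length(sod2_level) != 1 || !is.finite(sod2_level)) {
    abort_pathact("`sod2_level` must be a single finite value")
  }
  m <- mean(reference)
  s <- stats::sd(reference)
  thr <- m + 2 * s
  tibble::tibble(
    sod2_level = sod2_level,
    reference_mean = m,
    reference_sd = s,
    threshold = thr,
    stressed = sod2_level > thr
  )
}

#' Aggregate SOD2 probeset intensities for a sample
#'
#' The SOD2 level entering [assess_oxidative_stress()] is the mean of
#' the designated SOD2 probesets' intensities (configurable list;
#' missing values dropped).
#'
#' @param intensities Named numeric vector of intensities keyed by
#'   probeset ID.
#' @param sod2_probesets Character vector of SOD2 probeset IDs.
#' @return The mean intensity, or `NA` if none observed.
#' @export
sod2_level <- function(intensities, sod2_probesets) {
  x <- intensities[names(intensities) %in% sod2_probesets]
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  mean(x)
}

#' Interpret a FOXO activity score as a PI3K pathway readout
#'
#' In the absence of oxidative stress, PI3K pathway activity is the
#' inverse of FOXO transcriptional activity:
#' `pi3k_log2odds = -foxo_log2odds`, with the qualitative call made
#' against `threshold` by [call_activity()]. When the sample is
#' oxidative-stressed, FOXO activity no longer reads out PI3K activity:
#' no PI3K score is produced and the call is `"indeterminate"`.
#'
#' @param foxo Either an `activity_result` from the FOXO model or a bare
#'   log2odds value.
#' @param stress A one-row tibble from [assess_oxidative_stress()].
#' @param threshold Decision threshold on the PI3K log2odds scale
#'   (default 0).
#' @return A one-row tibble: `foxo_log2odds`, `stressed`,
#'   `pi3k_log2odds` (`NA` when stressed), `call`.
#' @export
interpret_pi3k <- function(foxo, stress, threshold = 0) {
  foxo_l2o <- if (inherits(foxo, "activity_result")) foxo$log2odds else foxo
  if (length(foxo_l2o) != 1 || !is.finite(foxo_l2o)) {
    abort_pathact("`foxo` must supply a single finite log2odds value")
  }
  if (!is.data.frame(stress) || !("stressed" %in% names(stress))) {
    abort_pathact("`stress` must come from assess_oxidative_stress()")
  }
  stressed <- isTRUE(stress$stressed[1])
  if (stressed) {
    tibble::tibble(
      foxo_log2odds = foxo_l2o, stressed = TRUE,
      pi3k_log2odds = NA_real_, call = "indeterminate"
    )
  } else {
    pi3k <- -foxo_l2o
    tibble::tibble(
      foxo_log2odds = foxo_l2o, stressed = FALSE,
      pi3k_log2odds = pi3k, call = call_activity(pi3k, threshold)
    )
  }
}

#' Combine per-pathway scores into a per-sample report
#'
#' Builds the wide multi-pathway table used to present individual
#' samples: one row per sample with its QC status, annotation, and one
#' log2odds column per pathway. Pathways missing for a sample appear as
#' explicit `NA` cells; a duplicated sample/pathway pair is an error.
#'
#' @param results Long tibble with columns `sample_id`, `pathway`,
#'   `log2odds`, and optionally `qc_pass` (logical) and `annotation`
#'   (character), e.g. row-bound outputs of [score_samples()].
#' @return Wide tibble: `sample_id`, `qc_pass`, `annotation`, then one
#'   column per pathway (alphabetical), sample order preserved.
#' @export
multi_pathway_report <- function(results) {
  stopifnot(is.data.frame(results))
  needed <- c("sample_id", "pathway", "log2odds")
  if (!all(needed %in% names(results))) {
    abort_pathact("`results` must have columns sample_id, pathway, log2odds")
  }
  if (nrow(results) == 0) abort_pathact("`results` is empty")
  dup <- duplicated(results[, c("sample_id", "pathway")])
  if (any(dup)) {
    abort_pathact(paste0(
      "duplicated sample/pathway combination(s): ",
      paste(unique(results$sample_id[dup]), collapse = ", ")
    ))
  }
  if (!("qc_pass" %in% names(results))) results$qc_pass <- NA
  if (!("annotation" %in% names(results))) results$annotation <- NA_character_
  meta <- results |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      qc_pass = .data$qc_pass[1],
      annotation = .data$annotation[1],
      .groups = "drop"
    )
  wide <- results |>
    dplyr::select("sample_id", "pathway", "log2odds") |>
    tidyr::pivot_wider(names_from = "pathway", values_from = "log2odds")
  pathways <- sort(unique(results$pathway))
  out <- dplyr::left_join(meta, wide, by = "sample_id")
  out <- out[, c("sample_id", "qc_pass", "annotation", pathways)]
  # preserve first-appearance sample order
  out[match(unique(results$sample_id), out$sample_id), ]
}

#' Write a multi-pathway report as TSV
#'
#' @param report Output of [multi_pathway_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  stopifnot(is.data.frame(report))
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
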