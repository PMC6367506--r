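# Calibration on ground-truth labeled samples. The latent gene state is
# hard-assigned from the sample label and the gene's regulation
# direction (no EM): an active-labeled sample puts up-regulated genes in
# the "up" state and down-regulated genes in the "down" state; an
# inactive label does the reverse.

check_calibration <- function(data, labels) {
  check_expression(data)
  if (!is.data.frame(labels) ||
      !all(c("sample_id", "label") %in% names(labels))) {
    abort_pathact("`labels` must have columns `sample_id` and `label`")
  }
  if (!all(labels$label %in% c("active", "inactive"))) {
    abort_pathact("labels must be `active` or `inactive`")
  }
  if (anyDuplicated(labels$sample_id)) {
    abort_pathact("duplicate sample IDs in labels")
  }
  sample_ids <- setdiff(names(data), "probeset_id")
  missing <- setdiff(labels$sample_id, sample_ids)
  if (length(missing) > 0) {
    abort_pathact(paste0(
      "labeled sample(s) absent from the expression data: ",
      paste(missing, collapse = ", ")
    ))
  }
  for (cls in c("active", "inactive")) {
    if (sum(labels$label == cls) == 0) {
      abort_pathact(paste0("calibration needs at least one `", cls, "` sample"))
    }
  }
  invisible(labels)
}

# log2(x+1) values of one probeset across a set of samples, NAs dropped
probeset_log2 <- function(data, probeset_id, sample_ids) {
  row <- which(data$probeset_id == probeset_id)[1]
  x <- vapply(sample_ids, function(s) data[[s]][row], numeric(1))
  log2(x[!is.na(x)] + 1)
}

check_probesets_observed <- function(model, data) {
  absent <- setdiff(model$probesets$probeset_id, data$probeset_id)
  if (length(absent) > 0) {
    abort_pathact(paste0(
      "model probeset(s) absent from the calibration data: ",
      paste(absent, collapse = ", ")
    ))
  }
  sample_cols <- setdiff(names(data), "probeset_id")
  for (id in model$probesets$probeset_id) {
    row <- which(data$probeset_id == id)[1]
    vals <- vapply(sample_cols, function(s) data[[s]][row], numeric(1))
    if (all(is.na(vals))) {
      abort_pathact(paste0("probeset ", id, " has no observed value in any sample"))
    }
  }
  invisible(model)
}

#' Set probeset discretization thresholds from labeled samples
#'
#' For each probeset the high/low cut on the log2(intensity + 1) scale
#' is placed at the midpoint between the per-class medians of the
#' calibration samples. Probesets whose class medians coincide get a
#' threshold equal to that common median and end up uninformative after
#' CPT fitting.
#'
#' @param model An unfrozen `pathway_model`.
#' @param data Expression tibble containing every model probeset.
#' @param labels Tibble `sample_id`, `label` (`active`/`inactive`), one
#'   or more samples per class.
#' @return The model with updated `log2_threshold` per probeset.
#' @export
set_discretization_thresholds <- function(model, data, labels) {
  stopifnot(inherits(model, "pathway_model"))
  check_unfrozen(model, "updating discretization thresholds")
  check_calibration(data, labels)
  check_probesets_observed(model, data)
  act <- labels$sample_id[labels$label == "active"]
  ina <- labels$sample_id[labels$label == "inactive"]
  thr <- vapply(model$probesets$probeset_id, function(id) {
    m_act <- stats::median(probeset_log2(data, id, act))
    m_ina <- stats::median(probeset_log2(data, id, ina))
    (m_act + m_ina) / 2
  }, numeric(1))
  if (any(!is.finite(thr))) {
    abort_pathact("a probeset has no observed value in one of the classes")
  }
  model$probesets$log2_threshold <- unname(thr)
  validate_pathway_model(model)
}

#' Fit probeset conditional probabilities from labeled samples
#'
#' Estimates, for every probeset, `P(high | gene up)` and
#' `P(high | gene down)` by Laplace-smoothed counting. A sample's latent
#' gene state is hard-assigned from its ground-truth label and the
#' gene's regulation direction; a probeset observation counts as "high"
#' when `log2(intensity + 1)` exceeds the probeset's discretization
#' threshold. With `n` concordant samples of which `k` are high,
#' `P(high | up) = (k + pseudocount) / (n + 2 * pseudocount)`, so fitted
#' probabilities are always strictly inside (0, 1).
#'
#' @inheritParams set_discretization_thresholds
#' @param pseudocount Positive Laplace smoothing constant (default 1).
#' @return The model with fitted `p_high_given_up` / `p_high_given_down`.
#' @export
fit_probeset_cpts <- function(model, data, labels, pseudocount = 1) {
  stopifnot(inherits(model, "pathway_model"))
  check_unfrozen(model, "refitting conditional probabilities")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    abort_pathact("`pseudocount` must be a single positive number")
  }
  check_calibration(data, labels)
  check_probesets_observed(model, data)

  act <- labels$sample_id[labels$label == "active"]
  ina <- labels$sample_id[labels$label == "inactive"]
  ps <- model$probesets
  for (i in seq_len(nrow(ps))) {
    up_first <- ps$direction[i] == "up_regulated"
    # samples whose hard-assigned gene state is "up" / "down"
    up_samples <- if (up_first) act else ina
    down_samples <- if (up_first) ina else act
    x_up <- probeset_log2(data, ps$probeset_id[i], up_samples)
    x_down <- probeset_log2(data, ps$probeset_id[i], down_samples)
    thr <- ps$log2_threshold[i]
    ps$p_high_given_up[i] <-
      (sum(x_up > thr) + pseudocount) / (length(x_up) + 2 * pseudocount)
    ps$p_high_given_down[i] <-
      (sum(x_down > thr) + pseudocount) / (length(x_down) + 2 * pseudocount)
  }
  model$probesets <- ps
  validate_pathway_model(model)
}

#' Calibrate a pathway model on ground-truth samples
#'
#' Convenience wrapper running [set_discretization_thresholds()] then
#' [fit_probeset_cpts()], optionally freezing the result so later
#' datasets are scored with exactly the same model.
#'
#' @inheritParams fit_probeset_cpts
#' @param freeze Freeze the calibrated model (default `TRUE`).
#' @return A calibrated `pathway_model`.
#' @export
calibrate_model <- function(model, data, labels, pseudocount = 1,
                            freeze = TRUE) {
  model <- set_discretization_thresholds(model, data, labels)
  model <- fit_probeset_cpts(model, data, labels, pseudocount = pseudocount)
  if (freeze) model <- freeze(model)
  model
}

#' Recalibrate a decision threshold on labeled scores
#'
#' Scans every candidate threshold (midpoints between adjacent sorted
#' scores, plus one candidate below and above the score range) for the
#' cut maximising the chosen objective, with samples called active when
#' their score strictly exceeds the cut. Ties are broken toward the
#' candidate nearest 0, so perfectly separated symmetric scores yield a
#' threshold of 0. Intended for adapting a frozen model to a new
#' cell/tissue type: only the threshold moves, the model itself is
#' unchanged.
#'
#' @param scores Numeric log2odds scores.
#' @param labels Character vector, `"active"`/`"inactive"`, aligned with
#'   `scores`; both classes must be present.
#' @param objective `"accuracy"` (fraction correct) or `"youden"`
#'   (sensitivity + specificity - 1).
#' @return The selected threshold (a single number).
#' @export
recalibrate_threshold <- function(scores, labels,
                                  objective = c("accuracy", "youden")) {
  objective <- match.arg(objective)
  if (length(scores) != length(labels)) {
    abort_pathact("`scores` and `labels` must have the same length")
  }
  if (!all(labels %in% c("active", "inactive"))) {
    abort_pathact("labels must be `active` or `inactive`")
  }
  if (!all(c("active", "inactive") %in% labels)) {
    abort_pathact("both classes must be present to recalibrate a threshold")
  }
  if (any(!is.finite(scores))) abort_pathact("scores must be finite")

  s <- sort(unique(scores))
  candidates <- c(min(s) - 1,
                  if (length(s) > 1) (s[-length(s)] + s[-1]) / 2,
                  max(s) + 1)
  is_active <- labels == "active"
  obj <- vapply(candidates, function(t) {
    pred <- scores > t
    if (objective == "accuracy") {
      mean(pred == is_active)
    } else {
      sens <- sum(pred & is_active) / sum(is_active)
      spec <- sum(!pred & !is_active) / sum(!is_active)
      sens + spec - 1
    }
  }, numeric(1))
  best <- which(obj >= max(obj) - 1e-12)
  # ties: nearest 0, then smallest value, for determinism
  best <- best[order(abs(candidates[best]), candidates[best])]
  candidates[best[1]]
}

EVIDENCE_CATEGORIES <- c(
  "response_element_motif", "promoter_functionality",
  "tf_binding_in_vivo", "tf_binding_in_vitro", "differential_expression"
)

#' Rank candidate target genes by direct evidence score
#'
#' Candidate direct target genes of a transcription factor are scored by
#' a weighted sum of experimental-evidence categories (response-element
#' motif in the promoter, promoter functionality, in-vivo and in-vitro
#' transcription-factor binding, differential expression upon pathway
#' activation) plus a corroboration bonus per independent cell type and
#' research group, then ranked.
#'
#' @param records Tibble with columns `gene_symbol`, the five category
#'   columns (non-negative scores), `n_cell_types`, `n_groups`.
#' @param weights Named non-negative weights covering every category
#'   present (default 1 each).
#' @param bonus Bonus per corroborating cell type / research group
#'   (default 0.5).
#' @return Tibble `gene_symbol`, `total_score`, sorted by descending
#'   score with alphabetical tie-break.
#' @export
rank_candidate_genes <- function(records,
                                 weights = stats::setNames(
                                   rep(1, length(EVIDENCE_CATEGORIES)),
                                   EVIDENCE_CATEGORIES),
                                 bonus = 0.5) {
  stopifnot(is.data.frame(records), "gene_symbol" %in% names(records))
  categories <- intersect(EVIDENCE_CATEGORIES, names(records))
  if (length(categories) == 0) {
    abort_pathact("`records` contains no evidence-category column")
  }
  uncovered <- setdiff(categories, names(weights))
  if (length(uncovered) > 0) {
    abort_pathact(paste0("`weights` must cover categories: ",
                         paste(uncovered, collapse = ", ")))
  }
  if (any(weights < 0) || bonus < 0) {
    abort_pathact("weights and bonus must be non-negative")
  }
  for (cat in categories) {
    if (any(records[[cat]] < 0)) {
      abort_pathact(paste0("negative component score in `", cat, "`"))
    }
  }
  n_cell <- if ("n_cell_types" %in% names(records)) records$n_cell_types else 0
  n_grp <- if ("n_groups" %in% names(records)) records$n_groups else 0
  total <- rep(0, nrow(records))
  for (cat in categories) total <- total + weights[[cat]] * records[[cat]]
  total <- total + bonus * (n_cell + n_grp)
  tibble::tibble(gene_symbol = records$gene_symbol, total_score = total) |>
    dplyr::arrange(dplyr::desc(.data$total_score), .data$gene_symbol)
}
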