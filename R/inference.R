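# Exact inference on the three-layer network.
#
# The network is a tree: TC -> gene_j -> probeset_jk. Conditional on the
# TC state the genes are independent, and conditional on a gene state its
# probesets are independent, so the evidence likelihood factorises over
# genes:
#   L(state) = prod_j [ P(up|state) * prod_k f_k(up) +
#                       P(down|state) * prod_k f_k(down) ]
# where f_k(s) = w_k P(high|s) + (1-w_k) P(low|s) is the soft-evidence
# likelihood of probeset k and unobserved probesets contribute 1.
# Computation is in log space; per-gene log likelihood-ratio terms are
# returned as additive log2 contributions.

# probability clamp for the log2odds transform; caps the score at
# +/- log2((1-eps)/eps) ~ +/- 39.86
PATHACT_EPS <- 1e-12

#' Infer pathway activity from probeset evidence
#'
#' Performs exact Bayesian inference of the probability `P` that the
#' pathway's transcription complex is actively transcribing its target
#' genes, given per-probeset evidence of the "high" state. `P` is
#' reported together with the log2odds activity score
#' `log2(P / (1 - P))`, the qualitative call against the model's
#' threshold, and the additive per-gene log2 contributions (prior
#' log2odds + sum of contributions = log2odds).
#'
#' Evidence weights are soft: a weight of 1 means the probeset is
#' certainly high, 0 certainly low, intermediate values express
#' uncertainty. Probesets absent from `evidence` are unobserved and are
#' marginalised out (a gene with no observed probeset contributes
#' nothing). Use [evidence_weights()] to map continuous intensities to
#' weights.
#'
#' @param model A `pathway_model`.
#' @param evidence Named numeric vector of weights in \[0, 1\] keyed by
#'   probeset ID, or a data frame with columns `probeset_id` and
#'   `weight`. Every key must exist in the model.
#' @param context Threshold context label used for the call.
#' @param scale_range Optional length-2 numeric `c(lo, hi)`; when given,
#'   the log2odds score is also mapped to a 0–100 scale via
#'   [to_scaled_score()].
#' @return An object of class `activity_result`; see [tidy.activity_result()]
#'   and [glance.activity_result()].
#' @examples
#' m <- pathway_model(
#'   tibble::tibble(gene = "G1", direction = "up_regulated", probeset_id = "PS",
#'                  p_high_given_up = 0.9, p_high_given_down = 0.1),
#'   pathway = "demo"
#' )
#' infer_activity(m, c(PS = 1))$probability_active  # 0.82
#' @export
infer_activity <- function(model, evidence = numeric(), context = "default",
                           scale_range = NULL) {
  stopifnot(inherits(model, "pathway_model"))
  w <- as_evidence(evidence, model)

  ps <- model$probesets
  obs <- ps[ps$probeset_id %in% names(w), , drop = FALSE]
  ww <- unname(w[obs$probeset_id])

  # log soft-evidence likelihood per observed probeset, for both gene states
  log_f_up <- log(ww * obs$p_high_given_up + (1 - ww) * (1 - obs$p_high_given_up))
  log_f_down <- log(ww * obs$p_high_given_down + (1 - ww) * (1 - obs$p_high_given_down))

  genes <- dplyr::distinct(ps, .data$gene, .data$p_up_given_active,
                           .data$p_up_given_inactive)
  sum_up <- vapply(genes$gene, function(g) sum(log_f_up[obs$gene == g]),
                   numeric(1))
  sum_down <- vapply(genes$gene, function(g) sum(log_f_down[obs$gene == g]),
                     numeric(1))

  log_l_active <- log_sum_exp2(log(genes$p_up_given_active) + sum_up,
                               log1p(-genes$p_up_given_active) + sum_down)
  log_l_inactive <- log_sum_exp2(log(genes$p_up_given_inactive) + sum_up,
                                 log1p(-genes$p_up_given_inactive) + sum_down)

  contrib <- (log_l_active - log_l_inactive) / log(2)
  names(contrib) <- genes$gene

  prior_l2o <- log2(model$prior_active / (1 - model$prior_active))
  cap <- log2((1 - PATHACT_EPS) / PATHACT_EPS)
  l2o <- min(max(prior_l2o + sum(contrib), -cap), cap)
  p <- 1 / (1 + 2^(-l2o))

  threshold <- get_threshold(model, context)
  structure(
    list(
      pathway = model$pathway,
      probability_active = p,
      log2odds = l2o,
      scaled_score = if (is.null(scale_range)) NULL else
        to_scaled_score(l2o, scale_range[1], scale_range[2]),
      call = call_activity(l2o, threshold),
      gene_contributions = contrib,
      prior_log2odds = prior_l2o,
      threshold = threshold,
      context = context
    ),
    class = "activity_result"
  )
}

# logsumexp of two aligned vectors
log_sum_exp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

as_evidence <- function(evidence, model) {
  if (is.data.frame(evidence)) {
    if (!all(c("probeset_id", "weight") %in% names(evidence))) {
      abort_pathact("evidence data frame needs columns `probeset_id` and `weight`")
    }
    w <- stats::setNames(as.numeric(evidence$weight),
                         as.character(evidence$probeset_id))
  } else {
    w <- evidence
  }
  if (length(w) == 0) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(w)) || any(names(w) == "")) {
    abort_pathact("evidence must be keyed by probeset ID")
  }
  if (anyDuplicated(names(w))) {
    abort_pathact("duplicated probeset IDs in evidence")
  }
  unknown <- setdiff(names(w), model$probesets$probeset_id)
  if (length(unknown) > 0) {
    abort_pathact(paste0(
      "evidence names probeset(s) not in the model: ",
      paste(unknown, collapse = ", ")
    ))
  }
  if (any(!is.finite(w) | w < 0 | w > 1)) {
    abort_pathact("evidence weights must lie in [0, 1]")
  }
  w
}

#' @export
print.activity_result <- function(x, ...) {
  cat("<activity_result> ", x$pathway, "\n", sep = "")
  cat("  P(active) = ", format(x$probability_active),
      "   log2odds = ", format(x$log2odds), "\n", sep = "")
  cat("  call: ", x$call, " (threshold ", format(x$threshold),
      ", context \"", x$context, "\")\n", sep = "")
  invisible(x)
}

#' Tidy per-gene contributions of an activity result
#'
#' @param x An `activity_result`.
#' @param ... Unused.
#' @return A tibble with one row per target gene and its additive log2
#'   contribution to the activity score.
#' @exportS3Method generics::tidy
tidy.activity_result <- function(x, ...) {
  tibble::tibble(
    gene = names(x$gene_contributions),
    log2_contribution = unname(x$gene_contributions)
  )
}

#' One-row summary of an activity result
#'
#' @param x An `activity_result`.
#' @param ... Unused.
#' @return A one-row tibble: pathway, probability, log2odds, optional
#'   scaled score, call and threshold.
#' @exportS3Method generics::glance
glance.activity_result <- function(x, ...) {
  tibble::tibble(
    pathway = x$pathway,
    probability_active = x$probability_active,
    log2odds = x$log2odds,
    scaled_score = if (is.null(x$scaled_score)) NA_real_ else x$scaled_score,
    call = x$call,
    threshold = x$threshold,
    context = x$context
  )
}

#' Brute-force inference oracle by joint enumeration
#'
#' Computes `P(TC = active | evidence)` by explicit summation over every
#' joint configuration of the transcription complex, all gene states and
#' all observed probeset states — no factorisation tricks. Exponential in
#' model size; intended for testing exact inference on small networks.
#'
#' @param model A `pathway_model`.
#' @param evidence As in [infer_activity()].
#' @param max_states Cap on the joint hidden-state count
#'   `2 * 2^genes * 2^probesets`; models above it are rejected.
#' @return The posterior probability that the pathway is active.
#' @export
joint_enumeration_oracle <- function(model, evidence = numeric(),
                                     max_states = 2^20) {
  stopifnot(inherits(model, "pathway_model"))
  w <- as_evidence(evidence, model)
  ps <- model$probesets
  genes <- dplyr::distinct(ps, .data$gene, .data$p_up_given_active,
                           .data$p_up_given_inactive)
  n_g <- nrow(genes)
  n_p <- nrow(ps)
  n_states <- 2 * 2^n_g * 2^n_p
  if (n_states > max_states) {
    abort_pathact(paste0(
      "joint state space (", n_states, ") exceeds max_states (", max_states, ")"
    ))
  }

  obs_idx <- which(ps$probeset_id %in% names(w))
  gene_of_ps <- match(ps$gene, genes$gene)

  # enumerate gene states (rows of a logical matrix: TRUE = up) and, for
  # each, sum P(state) * P(evidence | state) over every probeset
  # configuration (rows of ps_states: TRUE = high)
  gene_states <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), n_g)))
  ps_states <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), n_p)))
  ev_factor <- rep(1, nrow(ps_states))
  if (length(obs_idx) > 0) {
    ww <- unname(w[ps$probeset_id[obs_idx]])
    for (k in seq_along(obs_idx)) {
      ev_factor <- ev_factor *
        ifelse(ps_states[, obs_idx[k]], ww[k], 1 - ww[k])
    }
  }

  total <- c(active = 0, inactive = 0)
  for (tc in c("active", "inactive")) {
    p_up <- if (tc == "active") genes$p_up_given_active else genes$p_up_given_inactive
    prior <- if (tc == "active") model$prior_active else 1 - model$prior_active
    for (i in seq_len(nrow(gene_states))) {
      up <- gene_states[i, ]
      p_genes <- prod(ifelse(up, p_up, 1 - p_up))
      p_high <- ifelse(up[gene_of_ps], ps$p_high_given_up, ps$p_high_given_down)
      ph_mat <- matrix(p_high, nrow = nrow(ps_states), ncol = n_p, byrow = TRUE)
      prob_mat <- ifelse(ps_states, ph_mat, 1 - ph_mat)
      acc <- sum(exp(rowSums(log(prob_mat))) * ev_factor)
      total[tc] <- total[tc] + prior * p_genes * acc
    }
  }
  unname(total["active"] / sum(total))
}

#' Convert a probability to a log2odds activity score
#'
#' The activity score is `log2(p / (1 - p))`, showing more detail than
#' `p` itself when `p` is close to 0 or 1. To keep the score finite, `p`
#' is clamped to `[1e-12, 1 - 1e-12]`, capping the score at about
#' ±39.86.
#'
#' @param p Probability (vectorised), each in \[0, 1\].
#' @return log2odds value(s).
#' @examples
#' to_log2odds(0.5) # 0, the default decision threshold
#' to_log2odds(0.8) # 2
#' @export
to_log2odds <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    abort_pathact("`p` must lie in [0, 1]")
  }
  cap <- log2((1 - PATHACT_EPS) / PATHACT_EPS)
  pmin(pmax(log2(p / (1 - p)), -cap), cap)
}

#' Map a log2odds score onto a 0–100 scale
#'
#' Affine standardisation `100 * (x - lo) / (hi - lo)`, clipped to
#' \[0, 100\].
#'
#' @param log2odds Score(s) to map.
#' @param lo,hi Scores mapped to 0 and 100 respectively (`lo < hi`).
#' @return Scaled score(s) in \[0, 100\].
#' @export
to_scaled_score <- function(log2odds, lo, hi) {
  if (!(is.finite(lo) && is.finite(hi) && lo < hi)) {
    abort_pathact("`lo` must be strictly less than `hi`")
  }
  pmin(pmax(100 * (log2odds - lo) / (hi - lo), 0), 100)
}

#' Qualitative activity call from a log2odds score
#'
#' Active iff the score strictly exceeds the threshold; a score equal to
#' the threshold is called inactive (conservative, deterministic tie
#' rule). The default threshold 0 corresponds to probability 0.5.
#'
#' @param log2odds Score(s), finite.
#' @param threshold Decision threshold on the log2odds scale.
#' @return Character vector, `"active"` or `"inactive"`.
#' @export
call_activity <- function(log2odds, threshold = 0) {
  if (any(!is.finite(log2odds)) || !is.finite(threshold)) {
    abort_pathact("`log2odds` and `threshold` must be finite")
  }
  ifelse(log2odds > threshold, "active", "inactive")
}

#' Soft (or hard) evidence weights from probeset intensities
#'
#' Maps continuous linear-scale hybridization intensities to the weight
#' of the "high" probeset state. In `"soft"` mode the weight is
#' `plogis((log2(intensity + 1) - log2_threshold) * soft_scale)`; as
#' `soft_scale` grows this approaches the `"hard"` mode, a 0/1 cut of
#' `log2(intensity + 1)` at the probeset's discretization threshold.
#' Missing intensities and probesets not in the model yield no evidence.
#'
#' @param model A `pathway_model` (supplies per-probeset thresholds and
#'   soft scales).
#' @param intensities Named numeric vector of linear-scale intensities
#'   keyed by probeset ID.
#' @param mode `"soft"` (default) or `"hard"`.
#' @return Named weight vector suitable for [infer_activity()].
#' @export
evidence_weights <- function(model, intensities, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "pathway_model"))
  ps <- model$probesets
  keep <- names(intensities)[names(intensities) %in% ps$probeset_id &
                               !is.na(intensities)]
  if (length(keep) == 0) return(stats::setNames(numeric(0), character(0)))
  x <- intensities[keep]
  i <- match(keep, ps$probeset_id)
  z <- log2(x + 1) - ps$log2_threshold[i]
  w <- if (mode == "soft") {
    stats::plogis(z * ps$soft_scale[i])
  } else {
    as.numeric(z > 0)
  }
  stats::setNames(unname(w), keep)
}

#' Score every sample of an expression matrix
#'
#' Data-frame-first front door for inference: converts each sample's
#' intensities into evidence weights and runs [infer_activity()],
#' returning one row per sample.
#'
#' @param data Expression tibble: `probeset_id` column plus one numeric
#'   column per sample (linear-scale intensities, `NA` = missing).
#' @param model A `pathway_model`.
#' @param mode Evidence mode, `"soft"` or `"hard"` (see
#'   [evidence_weights()]).
#' @param context Threshold context for the qualitative call.
#' @param scale_range Optional `c(lo, hi)` for a 0–100 scaled score
#'   column.
#' @return A tibble: `sample_id`, `pathway`, `probability_active`,
#'   `log2odds`, (`scaled_score`,) `call`.
#' @export
score_samples <- function(data, model, mode = c("soft", "hard"),
                          context = "default", scale_range = NULL) {
  mode <- match.arg(mode)
  check_expression(data)
  sample_ids <- setdiff(names(data), "probeset_id")
  rows <- purrr::map_dfr(sample_ids, function(sid) {
    x <- stats::setNames(data[[sid]], data$probeset_id)
    res <- infer_activity(model, evidence_weights(model, x, mode = mode),
                          context = context, scale_range = scale_range)
    dplyr::bind_cols(tibble::tibble(sample_id = sid), glance(res))
  })
  if (is.null(scale_range)) rows$scaled_score <- NULL
  rows
}
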