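#' Construct a pathway activity model
#'
#' Builds the tree-structured Bayesian network that links a latent
#' transcription complex (TC, active/inactive) to its direct target genes
#' (up/down) and to the microarray probesets measuring each gene
#' (high/low with continuous soft evidence). The network is specified at
#' the probeset level: one row of `probesets` per probeset, carrying the
#' gene it belongs to and the conditional probabilities of both causal
#' layers.
#'
#' Gene-level conditional probabilities (`p_up_given_active`,
#' `p_up_given_inactive`) describe how a target gene responds to the
#' transcription complex. They are literature-derived model inputs, not
#' fitted quantities; when omitted they default to 0.90/0.10 for
#' up-regulated genes and 0.10/0.90 for down-regulated genes.
#' Probeset-level probabilities (`p_high_given_up`, `p_high_given_down`)
#' are normally fitted from ground-truth calibration samples via
#' [fit_probeset_cpts()]; their pre-calibration defaults (0.80/0.20) are
#' placeholders only.
#'
#' @param probesets Data frame with one row per probeset. Required
#'   columns: `gene`, `direction` (`"up_regulated"` or
#'   `"down_regulated"`), `probeset_id`. Optional columns (defaults
#'   applied per the Details): `p_up_given_active`, `p_up_given_inactive`,
#'   `p_high_given_up`, `p_high_given_down`, `log2_threshold` (default 7,
#'   log2-intensity units), `soft_scale` (default 1, steepness of the
#'   soft-evidence logistic).
#' @param pathway Pathway name, e.g. `"AR"` or `"HH"`.
#' @param prior_active Prior probability that the pathway is active,
#'   strictly inside (0, 1). Default 0.5 (symmetric ignorance).
#' @param thresholds Named numeric vector of decision thresholds on the
#'   log2odds scale, one per tissue/context label. Must contain
#'   `"default"`.
#'
#' @return An object of class `pathway_model`: a list with elements
#'   `pathway`, `prior_active`, `thresholds`, `frozen` and the validated
#'   probeset-level tibble `probesets`.
#'
#' @examples
#' m <- pathway_model(
#'   tibble::tibble(
#'     gene = "GLI1", direction = "up_regulated", probeset_id = "206646_at"
#'   ),
#'   pathway = "HH"
#' )
#' m
#' @seealso [infer_activity()], [calibrate_model()], [freeze()]
#' @export
pathway_model <- function(probesets, pathway, prior_active = 0.5,
                          thresholds = c(default = 0)) {
  stopifnot(is.data.frame(probesets))
  ps <- tibble::as_tibble(probesets)
  required <- c("gene", "direction", "probeset_id")
  missing_cols <- setdiff(required, names(ps))
  if (length(missing_cols) > 0) {
    abort_pathact(paste0(
      "`probesets` is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(ps) == 0) {
    abort_pathact("a pathway model needs at least one target gene with one probeset")
  }
  if (!all(ps$direction %in% c("up_regulated", "down_regulated"))) {
    abort_pathact("`direction` must be \"up_regulated\" or \"down_regulated\"")
  }

  ps <- fill_probeset_defaults(ps)
  ps <- ps[, c(
    "gene", "direction", "p_up_given_active", "p_up_given_inactive",
    "probeset_id", "p_high_given_up", "p_high_given_down",
    "log2_threshold", "soft_scale"
  )]

  model <- structure(
    list(
      pathway = as.character(pathway)[1],
      prior_active = as.numeric(prior_active)[1],
      thresholds = thresholds,
      frozen = FALSE,
      probesets = ps
    ),
    class = "pathway_model"
  )
  validate_pathway_model(model)
}

fill_probeset_defaults <- function(ps) {
  up <- ps$direction == "up_regulated"
  if (!"p_up_given_active" %in% names(ps)) {
    ps$p_up_given_active <- ifelse(up, 0.9, 0.1)
  }
  if (!"p_up_given_inactive" %in% names(ps)) {
    ps$p_up_given_inactive <- ifelse(up, 0.1, 0.9)
  }
  if (!"p_high_given_up" %in% names(ps)) ps$p_high_given_up <- 0.8
  if (!"p_high_given_down" %in% names(ps)) ps$p_high_given_down <- 0.2
  if (!"log2_threshold" %in% names(ps)) ps$log2_threshold <- 7
  if (!"soft_scale" %in% names(ps)) ps$soft_scale <- 1
  ps
}

validate_pathway_model <- function(model) {
  ps <- model$probesets
  p <- model$prior_active
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p <= 0 || p >= 1) {
    abort_pathact("`prior_active` must lie strictly between 0 and 1")
  }
  if (anyDuplicated(ps$probeset_id)) {
    dup <- unique(ps$probeset_id[duplicated(ps$probeset_id)])
    abort_pathact(paste0(
      "probeset IDs must be unique across the model; duplicated: ",
      paste(dup, collapse = ", ")
    ))
  }
  for (col in c("p_up_given_active", "p_up_given_inactive",
                "p_high_given_up", "p_high_given_down")) {
    check_probability(ps[[col]], col)
  }
  if (any(!is.finite(ps$log2_threshold))) {
    abort_pathact("`log2_threshold` must be finite")
  }
  if (any(!is.finite(ps$soft_scale) | ps$soft_scale <= 0)) {
    abort_pathact("`soft_scale` must be positive and finite")
  }
  # gene-level fields must agree across a gene's probesets
  gene_tab <- dplyr::distinct(
    ps, .data$gene, .data$direction,
    .data$p_up_given_active, .data$p_up_given_inactive
  )
  if (anyDuplicated(gene_tab$gene)) {
    abort_pathact("gene-level fields (direction, p_up_*) must be identical across a gene's probesets")
  }
  up <- gene_tab$direction == "up_regulated"
  bad_up <- up & !(gene_tab$p_up_given_active > gene_tab$p_up_given_inactive)
  bad_dn <- !up & !(gene_tab$p_up_given_active < gene_tab$p_up_given_inactive)
  if (any(bad_up | bad_dn)) {
    abort_pathact(paste0(
      "gene(s) violate the direction constraint on p_up_given_active vs ",
      "p_up_given_inactive: ",
      paste(gene_tab$gene[bad_up | bad_dn], collapse = ", ")
    ))
  }
  if (!("default" %in% names(model$thresholds))) {
    abort_pathact("`thresholds` must contain a \"default\" entry")
  }
  if (any(!is.finite(model$thresholds))) {
    abort_pathact("all thresholds must be finite")
  }
  model
}

check_probability <- function(x, name) {
  if (any(!is.finite(x) | x <= 0 | x >= 1)) {
    abort_pathact(paste0(
      "`", name, "` must lie strictly between 0 and 1 (no degenerate 0/1 entries)"
    ))
  }
  invisible(x)
}

abort_pathact <- function(message, class = character()) {
  rlang::abort(message, class = c(class, "pathact_error"))
}

#' @export
print.pathway_model <- function(x, ...) {
  genes <- unique(x$probesets$gene)
  cat("<pathway_model> ", x$pathway, "\n", sep = "")
  cat("  target genes: ", length(genes),
      "  probesets: ", nrow(x$probesets), "\n", sep = "")
  cat("  prior P(active): ", format(x$prior_active),
      "   frozen: ", x$frozen, "\n", sep = "")
  thr <- paste0(names(x$thresholds), "=", format(unname(x$thresholds)))
  cat("  thresholds (log2odds): ", paste(thr, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Freeze a calibrated pathway model
#'
#' After calibration the model's probabilities are locked: subsequent
#' refitting is rejected, so every later dataset is scored by exactly the
#' same model and scores stay directly comparable. Decision thresholds
#' remain adjustable per tissue context via [set_threshold()] — moving
#' the cut keeps the model itself untouched.
#'
#' Freezing an already frozen model is a no-op.
#'
#' @param model A `pathway_model`.
#' @return The model with `frozen = TRUE`.
#' @export
freeze <- function(model) {
  stopifnot(inherits(model, "pathway_model"))
  model$frozen <- TRUE
  model
}

#' @rdname freeze
#' @export
is_frozen <- function(model) {
  stopifnot(inherits(model, "pathway_model"))
  isTRUE(model$frozen)
}

check_unfrozen <- function(model, what) {
  if (is_frozen(model)) {
    abort_pathact(
      paste0("model \"", model$pathway, "\" is frozen; ", what,
             " is not allowed (thresholds may still be set)"),
      class = "pathact_frozen_error"
    )
  }
  invisible(model)
}

#' Set a decision threshold for a tissue context
#'
#' Thresholds on the log2odds activity score translate the continuous
#' score into an active/inactive call. The default threshold is 0
#' (probability 0.5); other tissue types may need their own cut (for
#' instance a higher cut for Hedgehog activity in brain tissue), which
#' can be added without touching — or unfreezing — the model.
#'
#' @param model A `pathway_model` (frozen or not).
#' @param value Threshold on the log2odds scale.
#' @param context Context label, e.g. `"default"` or `"brain"`.
#' @return The updated model.
#' @export
set_threshold <- function(model, value, context = "default") {
  stopifnot(inherits(model, "pathway_model"))
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value)) {
    abort_pathact("threshold `value` must be a single finite number")
  }
  model$thresholds[[context]] <- value
  model
}

get_threshold <- function(model, context) {
  if (!(context %in% names(model$thresholds))) {
    abort_pathact(paste0(
      "no threshold for context \"", context, "\"; available: ",
      paste(names(model$thresholds), collapse = ", ")
    ))
  }
  unname(model$thresholds[[context]])
}

#' Tidy a pathway model into its probeset-level table
#'
#' Returns the flat probeset-level tibble the model was built from: one
#' row per probeset with gene membership, regulation direction and both
#' layers of conditional probabilities. `pathway_model(tidy(m), ...)`
#' reconstructs the network.
#'
#' @param x A `pathway_model`.
#' @param ... Unused.
#' @return A tibble with one row per probeset.
#' @exportS3Method generics::tidy
tidy.pathway_model <- function(x, ...) {
  x$probesets
}

#' Summarise a pathway model in one row
#'
#' @param x A `pathway_model`.
#' @param ... Unused.
#' @return A one-row tibble: pathway, gene/probeset counts, prior,
#'   frozen flag and default threshold.
#' @exportS3Method generics::glance
glance.pathway_model <- function(x, ...) {
  tibble::tibble(
    pathway = x$pathway,
    n_genes = length(unique(x$probesets$gene)),
    n_probesets = nrow(x$probesets),
    prior_active = x$prior_active,
    frozen = x$frozen,
    default_threshold = get_threshold(x, "default")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Generate a random pathway model
#'
#' Draws a small random network: gene directions, relation-(i) and
#' relation-(ii) conditional probabilities uniform on a non-degenerate
#' band, and random discretization thresholds. Used for property testing
#' and benchmarking exact inference against brute-force enumeration, so
#' the total number of binary hidden nodes (1 + genes + probesets) is
#' kept at or below `max_nodes`.
#'
#' @param n_genes Number of target genes (default drawn from 1–6).
#' @param probesets_per_gene Vector of probeset counts per gene (default
#'   drawn from 1–3, trimmed to respect `max_nodes`).
#' @param max_nodes Cap on 1 + genes + probesets (default 19, keeping
#'   full joint enumeration below 2^20 states).
#' @return A `pathway_model`.
#' @export
random_pathway_model <- function(n_genes = sample(1:6, 1),
                                 probesets_per_gene = sample(1:3, n_genes, replace = TRUE),
                                 max_nodes = 19) {
  stopifnot(n_genes >= 1, length(probesets_per_gene) == n_genes)
  # trim probeset counts so the joint state space stays enumerable
  while (1 + n_genes + sum(probesets_per_gene) > max_nodes) {
    i <- which.max(probesets_per_gene)
    if (probesets_per_gene[i] <= 1) break
    probesets_per_gene[i] <- probesets_per_gene[i] - 1
  }
  rows <- purrr::map_dfr(seq_len(n_genes), function(g) {
    up <- stats::runif(1) < 0.5
    p_hi <- stats::runif(1, 0.6, 0.95)
    p_lo <- stats::runif(1, 0.05, 0.4)
    tibble::tibble(
      gene = sprintf("G%02d", g),
      direction = if (up) "up_regulated" else "down_regulated",
      p_up_given_active = if (up) p_hi else p_lo,
      p_up_given_inactive = if (up) p_lo else p_hi,
      probeset_id = sprintf("G%02d_PS%d", g, seq_len(probesets_per_gene[g])),
      p_high_given_up = stats::runif(probesets_per_gene[g], 0.55, 0.95),
      p_high_given_down = stats::runif(probesets_per_gene[g], 0.05, 0.45),
      log2_threshold = stats::runif(probesets_per_gene[g], 5, 9),
      soft_scale = stats::runif(probesets_per_gene[g], 0.5, 3)
    )
  })
  pathway_model(rows, pathway = "random",
                prior_active = stats::runif(1, 0.2, 0.8))
}
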