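# Generative counterpart of the network: ancestral sampling from the
# transcription-complex state down to probeset intensities. Intensities
# follow a two-component Gaussian on the log2 scale (one component per
# probeset state), emitted on the linear scale as 2^x - 1, matching the
# log2(x + 1) transform used downstream. This emulates the two-class
# latent structure of real arrays, not probe-level CEL structure, batch
# effects or cross-hybridization.

#' Simulate a labeled expression dataset from a pathway model
#'
#' For every sample the transcription-complex state is set by its label;
#' each target gene's up/down state is drawn from the gene's
#' conditional probabilities given that state; each probeset's high/low
#' state is drawn from its conditional probabilities given the gene
#' state; and the linear-scale intensity is emitted as `2^x - 1` with
#' `x ~ Normal(mu_high, sigma)` for high probesets and
#' `Normal(mu_low, sigma)` for low ones. Optional dropout replaces
#' values with `NA` (missing measurements).
#'
#' The defaults (`mu_low = 6`, `mu_high = 10`, `sigma = 1` on the log2
#' scale) emulate well-separated low/high hybridization signals on a
#' MAS5-like intensity scale.
#'
#' @param model A `pathway_model`.
#' @param n_active,n_inactive Number of samples per class.
#' @param mu_low,mu_high Log2-intensity means of the low and high
#'   probeset states (`mu_high > mu_low`).
#' @param sigma Log2-intensity standard deviation (> 0; 0 is allowed as
#'   a degenerate noiseless limit).
#' @param dropout_rate Probability in \[0, 1) that a value is missing.
#' @param seed Optional integer seed; the whole dataset is reproducible
#'   from it (a single generator stream drives every draw).
#' @return A list: `expression` (tibble, `probeset_id` + one column per
#'   sample) and `labels` (tibble `sample_id`, `label`).
#' @export
simulate_dataset <- function(model, n_active = 25, n_inactive = 25,
                             mu_low = 6, mu_high = 10, sigma = 1,
                             dropout_rate = 0, seed = NULL) {
  stopifnot(inherits(model, "pathway_model"))
  if (n_active < 0 || n_inactive < 0 || n_active + n_inactive < 1) {
    abort_pathact("need at least one sample to simulate")
  }
  if (!(mu_high > mu_low)) abort_pathact("`mu_high` must exceed `mu_low`")
  if (sigma < 0) abort_pathact("`sigma` must be non-negative")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort_pathact("`dropout_rate` must lie in [0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)

  ps <- model$probesets
  genes <- dplyr::distinct(ps, .data$gene, .data$p_up_given_active,
                           .data$p_up_given_inactive)
  gene_of_ps <- match(ps$gene, genes$gene)
  labels <- tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(n_active + n_inactive)),
    label = rep(c("active", "inactive"), c(n_active, n_inactive))
  )

  mat <- matrix(NA_real_, nrow = nrow(ps), ncol = nrow(labels),
                dimnames = list(NULL, labels$sample_id))
  for (j in seq_len(nrow(labels))) {
    p_up <- if (labels$label[j] == "active") genes$p_up_given_active
            else genes$p_up_given_inactive
    up <- stats::runif(nrow(genes)) < p_up
    p_high <- ifelse(up[gene_of_ps], ps$p_high_given_up, ps$p_high_given_down)
    high <- stats::runif(nrow(ps)) < p_high
    x <- stats::rnorm(nrow(ps), mean = ifelse(high, mu_high, mu_low),
                      sd = sigma)
    val <- 2^x - 1
    if (dropout_rate > 0) {
      val[stats::runif(nrow(ps)) < dropout_rate] <- NA_real_
    }
    mat[, j] <- val
  }
  expression <- dplyr::bind_cols(
    tibble::tibble(probeset_id = ps$probeset_id),
    tibble::as_tibble(mat)
  )
  list(expression = expression, labels = labels)
}
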