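# Shared fixtures, all built in code.

# one up-regulated gene with a single strongly informative probeset
tiny_model <- function(prior = 0.5) {
  pathway_model(
    tibble::tibble(
      gene = "G1", direction = "up_regulated", probeset_id = "PS",
      p_high_given_up = 0.9, p_high_given_down = 0.1
    ),
    pathway = "tiny", prior_active = prior
  )
}

# multi-gene model with informative defaults, mixed directions
demo_model <- function(n_genes = 4, ps_per_gene = 2) {
  rows <- purrr::map_dfr(seq_len(n_genes), function(g) {
    tibble::tibble(
      gene = sprintf("G%d", g),
      direction = if (g %% 2 == 0) "down_regulated" else "up_regulated",
      probeset_id = sprintf("G%d_PS%d", g, seq_len(ps_per_gene))
    )
  })
  pathway_model(rows, pathway = "demo")
}

# generative model emulating calibration-grade ground-truth classes
# (near-concordant target-gene response with strongly informative
# probesets, as in ligand-stimulated vs deprived cell lines). Hard
# label-based gene-state assignment estimates P(high | TC state), which
# differs from the probeset CPT by the gene-layer mixing bias
# (1 - p_up|active) * (p_high|up - p_high|down); near-deterministic
# concordance keeps that bias well inside the recovery tolerance.
demo_calibration_model <- function(n_genes = 3, ps_per_gene = 2) {
  m <- demo_model(n_genes, ps_per_gene)
  up <- m$probesets$direction == "up_regulated"
  m$probesets$p_up_given_active <- ifelse(up, 0.995, 0.005)
  m$probesets$p_up_given_inactive <- ifelse(up, 0.005, 0.995)
  m$probesets$p_high_given_up <- 0.95
  m$probesets$p_high_given_down <- 0.05
  m
}

# mean hold-out accuracy over several label shuffles: a single shuffle
# leaves a shared residual signal across samples, so only the average
# is near chance
null_control_accuracy <- function(model, train, holdout, n_shuffles = 10) {
  vapply(seq_len(n_shuffles), function(i) {
    shuffled <- train$labels
    shuffled$label <- sample(shuffled$label)
    null_model <- calibrate_model(model, train$expression, shuffled)
    scores <- score_samples(holdout$expression, null_model) |>
      dplyr::left_join(holdout$labels, by = "sample_id")
    mean((scores$log2odds > 0) == (scores$label == "active"))
  }, numeric(1)) |> mean()
}

# expression tibble from a named list sample_id -> named intensity vector
expr_from_list <- function(values) {
  ids <- unique(unlist(lapply(values, names)))
  cols <- lapply(values, function(v) unname(v[ids]))
  dplyr::bind_cols(tibble::tibble(probeset_id = ids),
                   tibble::as_tibble(cols))
}

labels_tbl <- function(sample_ids, label) {
  tibble::tibble(sample_id = sample_ids, label = label)
}

# minimal GEO series-matrix text fixture
series_matrix_lines <- function(quoted = TRUE, truncated = FALSE) {
  q <- function(x) if (quoted) paste0('"', x, '"') else x
  lines <- c(
    "!Series_title\t\"toy series\"",
    paste0("!Sample_title\t", q("tumour A"), "\t", q("normal B")),
    paste0("!Sample_geo_accession\t", q("GSM0001"), "\t", q("GSM0002")),
    "!series_matrix_table_begin",
    paste0(q("ID_REF"), "\t", q("GSM0001"), "\t", q("GSM0002")),
    paste0(q("1007_s_at"), "\t120.5\t98.25"),
    paste0(q("1053_at"), "\t37\t"),
    "!series_matrix_table_end"
  )
  if (truncated) lines <- lines[seq_len(length(lines) - 1)]
  lines
}

# independent enumeration oracle for the exact rank-sum p-value:
# assigns every subset of the observed midranks to group a
oracle_rank_sum_p <- function(a, b, sided = "two_sided") {
  n_a <- length(a)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n_a)])
  combos <- utils::combn(length(r), n_a)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  p_ge <- mean(w_all >= w - 1e-9)
  p_le <- mean(w_all <= w + 1e-9)
  switch(sided,
    two_sided = min(1, 2 * min(p_ge, p_le)),
    greater = p_ge,
    less = p_le
  )
}
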