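# intensity whose log2(x+1) equals v
lin <- function(v) 2^v - 1

test_that("CPT fitting reproduces the Laplace count formula", {
  m <- pathway_model(
    tibble::tibble(gene = "G1", direction = "up_regulated",
                   probeset_id = "PS", log2_threshold = 7),
    pathway = "p"
  )
  # 10 active samples: 9 high (log2 = 8), 1 low (log2 = 6);
  # 2 inactive samples: both low
  vals <- c(rep(list(c(PS = lin(8))), 9), list(c(PS = lin(6))),
            rep(list(c(PS = lin(6))), 2))
  names(vals) <- sprintf("S%02d", seq_along(vals))
  data <- expr_from_list(vals)
  labels <- labels_tbl(names(vals), rep(c("active", "inactive"), c(10, 2)))

  fit <- fit_probeset_cpts(m, data, labels, pseudocount = 1)
  expect_equal(fit$probesets$p_high_given_up, 10 / 12)
  expect_equal(fit$probesets$p_high_given_down, 1 / 4)

  # symmetric counts leave the probeset uninformative: (n+1)/(n+2) both
  all_high <- expr_from_list(stats::setNames(
    rep(list(c(PS = lin(8))), 4), sprintf("T%d", 1:4)))
  lab2 <- labels_tbl(sprintf("T%d", 1:4),
                     rep(c("active", "inactive"), each = 2))
  fit2 <- fit_probeset_cpts(m, all_high, lab2, pseudocount = 1)
  expect_equal(fit2$probesets$p_high_given_up, 3 / 4)
  expect_equal(fit2$probesets$p_high_given_down, 3 / 4)

  # heavy smoothing pulls both probabilities to 1/2
  fit3 <- fit_probeset_cpts(m, data, labels, pseudocount = 1e9)
  expect_equal(fit3$probesets$p_high_given_up, 0.5, tolerance = 1e-6)
  expect_equal(fit3$probesets$p_high_given_down, 0.5, tolerance = 1e-6)
})

test_that("CPT fitting rejects invalid calibration sets", {
  m <- tiny_model()
  data <- expr_from_list(list(S1 = c(PS = 10), S2 = c(PS = 10)))
  expect_error(
    fit_probeset_cpts(m, data, labels_tbl(c("S1", "S2"), c("active", "active"))),
    "inactive", class = "pathact_error"
  )
  # a model probeset never observed is named in the rejection
  m2 <- pathway_model(
    tibble::tibble(gene = "G1", direction = "up_regulated",
                   probeset_id = c("PS", "GHOST")),
    pathway = "p"
  )
  expect_error(
    fit_probeset_cpts(m2, data, labels_tbl(c("S1", "S2"),
                                           c("active", "inactive"))),
    "GHOST", class = "pathact_error"
  )
  expect_error(fit_probeset_cpts(m, data,
                                 labels_tbl(c("S1", "S2"),
                                            c("active", "inactive")),
                                 pseudocount = 0),
               class = "pathact_error")
})

test_that("discretization thresholds sit midway between class medians", {
  m <- pathway_model(
    tibble::tibble(gene = "G1", direction = "up_regulated",
                   probeset_id = "PS"),
    pathway = "p"
  )
  data <- expr_from_list(list(
    A1 = c(PS = lin(8)), A2 = c(PS = lin(8)),
    I1 = c(PS = lin(6)), I2 = c(PS = lin(6))
  ))
  labels <- labels_tbl(c("A1", "A2", "I1", "I2"),
                       rep(c("active", "inactive"), each = 2))
  thr <- set_discretization_thresholds(m, data, labels)
  expect_equal(thr$probesets$log2_threshold, 7)

  # single sample per class, intensities 3 and 15: (log2 4 + log2 16)/2 = 3
  d2 <- expr_from_list(list(A = c(PS = 3), I = c(PS = 15)))
  thr2 <- set_discretization_thresholds(
    m, d2, labels_tbl(c("A", "I"), c("active", "inactive")))
  expect_equal(thr2$probesets$log2_threshold, 3)

  # identical class medians collapse to that median
  d3 <- expr_from_list(list(A = c(PS = lin(5)), I = c(PS = lin(5))))
  thr3 <- set_discretization_thresholds(
    m, d3, labels_tbl(c("A", "I"), c("active", "inactive")))
  expect_equal(thr3$probesets$log2_threshold, 5)
})

test_that("freezing locks probabilities but not thresholds", {
  m <- tiny_model()
  data <- expr_from_list(list(A = c(PS = lin(8)), I = c(PS = lin(6))))
  labels <- labels_tbl(c("A", "I"), c("active", "inactive"))
  frozen <- freeze(fit_probeset_cpts(m, data, labels))
  expect_true(is_frozen(frozen))
  expect_error(fit_probeset_cpts(frozen, data, labels),
               class = "pathact_frozen_error")
  expect_error(set_discretization_thresholds(frozen, data, labels),
               class = "pathact_frozen_error")
  # redefining a threshold keeps exactly the same (frozen) model
  with_brain <- set_threshold(frozen, 5, context = "brain")
  expect_equal(with_brain$thresholds[["brain"]], 5)
  expect_true(is_frozen(with_brain))
  expect_identical(with_brain$probesets, frozen$probesets)
  # idempotence
  expect_identical(freeze(frozen), frozen)
})

test_that("CPT fitting is invariant to sample order", {
  set.seed(11)
  m <- demo_model()
  sim <- simulate_dataset(m, 20, 20, seed = 3)
  fit1 <- calibrate_model(m, sim$expression, sim$labels, freeze = FALSE)
  perm <- sample(nrow(sim$labels))
  shuffled_expr <- sim$expression[, c(1, 1 + perm)]
  shuffled_labels <- sim$labels[perm, ]
  fit2 <- calibrate_model(m, shuffled_expr, shuffled_labels, freeze = FALSE)
  expect_equal(fit1$probesets, fit2$probesets)
})

test_that("calibration recovers the generating CPTs from simulated samples", {
  m <- demo_calibration_model(n_genes = 3, ps_per_gene = 2)
  truth <- m$probesets
  sim <- simulate_dataset(m, 500, 500, sigma = 0.5, seed = 314)
  fit <- calibrate_model(m, sim$expression, sim$labels, freeze = FALSE)
  expect_true(all(abs(fit$probesets$p_high_given_up -
                        truth$p_high_given_up) <= 0.05))
  expect_true(all(abs(fit$probesets$p_high_given_down -
                        truth$p_high_given_down) <= 0.05))
})

test_that("calibration separates the classes it was fitted on", {
  m <- demo_model(n_genes = 3, ps_per_gene = 2) # 6 informative probesets
  sim <- simulate_dataset(m, 30, 30, seed = 21)
  fit <- calibrate_model(m, sim$expression, sim$labels)
  scores <- score_samples(sim$expression, fit) |>
    dplyr::left_join(sim$labels, by = "sample_id")
  mean_by <- tapply(scores$log2odds, scores$label, mean)
  expect_gt(mean_by[["active"]], mean_by[["inactive"]])
})

test_that("threshold recalibration maximises its objective over all cuts", {
  # well separated: any cut in (-2, 4); tie rule picks the one nearest 0
  expect_equal(
    recalibrate_threshold(c(-3, -2, 4, 5),
                          c("inactive", "inactive", "active", "active")),
    1
  )
  # symmetric perfect separation around 0 gives exactly 0
  expect_equal(
    recalibrate_threshold(c(-2, -1, 1, 2),
                          c("inactive", "inactive", "active", "active")),
    0
  )
  expect_error(recalibrate_threshold(c(1, 2), c("active", "active")),
               class = "pathact_error")

  # exhaustive grid scan as an independent check, interleaved classes
  set.seed(8)
  for (i in 1:10) {
    scores <- round(stats::rnorm(12), 2)
    labels <- sample(c("active", "inactive"), 12, replace = TRUE,
                     prob = c(0.5, 0.5))
    if (length(unique(labels)) < 2) next
    for (objective in c("accuracy", "youden")) {
      t_star <- recalibrate_threshold(scores, labels, objective)
      obj <- function(t) {
        pred <- scores > t
        act <- labels == "active"
        if (objective == "accuracy") mean(pred == act)
        else sum(pred & act) / sum(act) + sum(!pred & !act) / sum(!act) - 1
      }
      grid <- seq(min(scores) - 1, max(scores) + 1, length.out = 2001)
      expect_gte(obj(t_star) + 1e-12, max(vapply(grid, obj, numeric(1))))
    }
  }
})

test_that("candidate gene ranking is a weighted sum with corroboration bonus", {
  rec <- tibble::tibble(
    gene_symbol = "AXIN2",
    response_element_motif = 1, promoter_functionality = 1,
    tf_binding_in_vivo = 1, tf_binding_in_vitro = 1,
    differential_expression = 1, n_cell_types = 0, n_groups = 0
  )
  expect_equal(rank_candidate_genes(rec)$total_score, 5)

  recs <- tibble::tibble(
    gene_symbol = c("B", "A", "C"),
    response_element_motif = c(2, 1, 1),
    promoter_functionality = 0, tf_binding_in_vivo = 0,
    tf_binding_in_vitro = 0, differential_expression = 0,
    n_cell_types = c(0, 0, 0), n_groups = c(0, 2, 0)
  )
  # zero weights, zero bonus: all tied, alphabetical order
  zero_w <- stats::setNames(rep(0, 5), c(
    "response_element_motif", "promoter_functionality", "tf_binding_in_vivo",
    "tf_binding_in_vitro", "differential_expression"
  ))
  expect_equal(rank_candidate_genes(recs, weights = zero_w, bonus = 0)$gene_symbol,
               c("A", "B", "C"))
  # A's 2-group bonus ties it with B at 2; alphabetical tie-break
  ranked <- rank_candidate_genes(recs)
  expect_equal(ranked$gene_symbol, c("A", "B", "C"))
  expect_equal(ranked$total_score, c(2, 2, 1))
  more_groups <- dplyr::mutate(recs, n_groups = c(0, 5, 0))
  expect_equal(rank_candidate_genes(more_groups)$gene_symbol[1], "A")
  expect_error(rank_candidate_genes(recs, weights = -zero_w - 1),
               class = "pathact_error")
})
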