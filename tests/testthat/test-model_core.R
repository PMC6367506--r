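test_that("model construction enforces the network invariants", {
  base <- tibble::tibble(gene = "G1", direction = "up_regulated",
                         probeset_id = "PS")
  expect_s3_class(pathway_model(base, pathway = "p"), "pathway_model")

  expect_error(pathway_model(base, pathway = "p", prior_active = 1),
               class = "pathact_error")
  expect_error(pathway_model(base, pathway = "p", prior_active = 0),
               class = "pathact_error")
  expect_error(
    pathway_model(dplyr::bind_rows(base, base), pathway = "p"),
    "unique", class = "pathact_error"
  )
  expect_error(
    pathway_model(dplyr::mutate(base, p_high_given_up = 1), pathway = "p"),
    class = "pathact_error"
  )
  # direction must order the gene-level probabilities
  expect_error(
    pathway_model(
      dplyr::mutate(base, p_up_given_active = 0.2, p_up_given_inactive = 0.8),
      pathway = "p"
    ),
    "direction constraint", class = "pathact_error"
  )
  expect_silent(
    pathway_model(
      tibble::tibble(gene = "G1", direction = "down_regulated",
                     probeset_id = "PS", p_up_given_active = 0.2,
                     p_up_given_inactive = 0.8),
      pathway = "p"
    )
  )
  expect_error(pathway_model(base, pathway = "p", thresholds = c(brain = 5)),
               "default", class = "pathact_error")
})

test_that("inference matches hand-computed posteriors on the 1-gene model", {
  m <- tiny_model()
  # enumeration over the 8 joint states gives P(active | PS high) = 0.82
  expect_equal(infer_activity(m, c(PS = 1))$probability_active, 0.82,
               tolerance = 1e-12)
  expect_equal(joint_enumeration_oracle(m, c(PS = 1)), 0.82,
               tolerance = 1e-12)
  # no evidence leaves the prior untouched
  expect_equal(infer_activity(m)$probability_active, 0.5)
  expect_equal(infer_activity(tiny_model(prior = 0.3))$probability_active, 0.3)
  # an uninformative probeset has likelihood ratio 1
  flat <- pathway_model(
    tibble::tibble(gene = "G1", direction = "up_regulated",
                   probeset_id = "PS", p_high_given_up = 0.6,
                   p_high_given_down = 0.6),
    pathway = "flat", prior_active = 0.37
  )
  for (w in c(0, 0.25, 1)) {
    expect_equal(infer_activity(flat, c(PS = w))$probability_active, 0.37,
                 tolerance = 1e-12)
  }
})

test_that("evidence is validated against the model", {
  m <- tiny_model()
  expect_error(infer_activity(m, c(NOPE = 1)), "NOPE",
               class = "pathact_error")
  expect_error(infer_activity(m, c(PS = 1.2)), class = "pathact_error")
  expect_error(infer_activity(m, c(PS = -0.1)), class = "pathact_error")
  # data-frame evidence is equivalent to a named vector
  df_ev <- tibble::tibble(probeset_id = "PS", weight = 0.7)
  expect_equal(infer_activity(m, df_ev)$probability_active,
               infer_activity(m, c(PS = 0.7))$probability_active)
})

test_that("exact inference agrees with joint enumeration on random models", {
  set.seed(20240917)
  for (i in 1:30) {
    m <- random_pathway_model()
    w <- stats::setNames(stats::runif(nrow(m$probesets)),
                         m$probesets$probeset_id)
    # random subset observed; the rest marginalised out
    w <- w[stats::runif(length(w)) < 0.8]
    expect_equal(infer_activity(m, w)$probability_active,
                 joint_enumeration_oracle(m, w), tolerance = 1e-10)
  }
})

test_that("oracle rejects models whose joint state space exceeds the cap", {
  m <- demo_model(n_genes = 4, ps_per_gene = 2) # 2 * 2^4 * 2^8 = 2^13
  expect_error(joint_enumeration_oracle(m, max_states = 2^12),
               "max_states", class = "pathact_error")
})

test_that("per-gene contributions are additive on the log2odds scale", {
  set.seed(42)
  m <- random_pathway_model(n_genes = 4)
  w <- stats::setNames(stats::runif(nrow(m$probesets)),
                       m$probesets$probeset_id)
  r <- infer_activity(m, w)
  expect_equal(r$prior_log2odds + sum(r$gene_contributions), r$log2odds,
               tolerance = 1e-9)
  expect_named(r$gene_contributions, unique(m$probesets$gene))
  # tidy()/glance() expose the same numbers
  expect_equal(sum(tidy(r)$log2_contribution), sum(r$gene_contributions))
  expect_equal(glance(r)$log2odds, r$log2odds)
})

test_that("more 'high' evidence on an up-regulated gene never lowers the posterior", {
  set.seed(7)
  m <- demo_model()
  ps_up <- m$probesets$probeset_id[m$probesets$direction == "up_regulated"][1]
  weights <- seq(0, 1, by = 0.1)
  p <- vapply(weights, function(w) {
    infer_activity(m, stats::setNames(w, ps_up))$probability_active
  }, numeric(1))
  expect_true(all(diff(p) >= -1e-12))
})

test_that("flipping all labels mirrors the posterior", {
  set.seed(99)
  for (i in 1:10) {
    m <- random_pathway_model(n_genes = 3)
    w <- stats::setNames(stats::runif(nrow(m$probesets)),
                         m$probesets$probeset_id)
    flipped <- m
    flipped$prior_active <- 1 - m$prior_active
    tmp <- flipped$probesets$p_up_given_active
    flipped$probesets$p_up_given_active <- flipped$probesets$p_up_given_inactive
    flipped$probesets$p_up_given_inactive <- tmp
    # bypass the direction-consistency check: flip direction labels too
    flipped$probesets$direction <- ifelse(
      flipped$probesets$direction == "up_regulated",
      "down_regulated", "up_regulated"
    )
    expect_equal(infer_activity(flipped, w)$probability_active,
                 1 - infer_activity(m, w)$probability_active,
                 tolerance = 1e-10)
  }
})

test_that("an unobserved probeset behaves as if absent from the model", {
  set.seed(5)
  m <- demo_model(n_genes = 2, ps_per_gene = 2)
  drop_id <- m$probesets$probeset_id[2]
  w_all <- stats::setNames(stats::runif(nrow(m$probesets)),
                           m$probesets$probeset_id)
  w_partial <- w_all[setdiff(names(w_all), drop_id)]
  reduced <- pathway_model(
    m$probesets[m$probesets$probeset_id != drop_id, ],
    pathway = m$pathway, prior_active = m$prior_active
  )
  expect_equal(infer_activity(m, w_partial)$probability_active,
               infer_activity(reduced, w_partial)$probability_active,
               tolerance = 1e-12)
})

test_that("log2odds transform anchors, caps and symmetry hold", {
  expect_identical(to_log2odds(0.5), 0) # probability 0.5 <-> log2odds 0
  expect_equal(to_log2odds(0.8), 2)
  cap <- log2((1 - 1e-12) / 1e-12)
  expect_equal(to_log2odds(1), cap)
  expect_equal(to_log2odds(0), -cap)
  expect_true(is.finite(to_log2odds(1)))
  expect_error(to_log2odds(1.01), class = "pathact_error")
  expect_error(to_log2odds(-0.01), class = "pathact_error")
  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(to_log2odds(p)) > 0))
  expect_equal(to_log2odds(1 - p), -to_log2odds(p), tolerance = 1e-9)
})

test_that("scaled score maps and clips as an affine 0-100 standardisation", {
  expect_equal(to_scaled_score(-10, -10, 10), 0)
  expect_equal(to_scaled_score(10, -10, 10), 100)
  expect_equal(to_scaled_score(0, -10, 10), 50)
  expect_equal(to_scaled_score(-15, -10, 10), 0)
  expect_equal(to_scaled_score(15, -10, 10), 100)
  expect_error(to_scaled_score(0, 5, 5), class = "pathact_error")
})

test_that("activity calls use strict exceedance with inactive ties", {
  expect_identical(call_activity(0.1, 0), "active")
  expect_identical(call_activity(4, 5), "inactive") # brain-type higher cut
  expect_identical(call_activity(0, 0), "inactive")
  expect_identical(call_activity(c(-1, 2), 0), c("inactive", "active"))
})
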