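# Group comparison and correlation statistics for pathway activity
# scores. Small-sample p-values are exact: rank-sum tests enumerate all
# assignments of the observed (mid)ranks to the two groups, signed-rank
# tests enumerate all sign configurations, so ties are handled exactly
# too. Above the exact cutoff the usual normal approximation with
# midranks, tie-corrected variance and continuity correction is used.
# Two-sided p-values are twice the smaller tail, capped at 1.

#' Compare pathway activity scores between two groups
#'
#' Wilcoxon tests on activity scores: the unpaired rank-sum test (one-
#' or two-sided) and the paired two-sided signed-rank test. For small
#' samples p-values come from full enumeration of the exact permutation
#' distribution (including midranks under ties); larger samples use the
#' tie-corrected normal approximation with continuity correction. No
#' multiple-testing correction is applied by default; pass the returned
#' p-values to [stats::p.adjust()] if needed.
#'
#' The reported statistic is the rank sum `W` of `scores_a` (rank-sum
#' tests) or the positive-difference rank sum `V` of `a - b`
#' (signed-rank). One-sided rank-sum tests with
#' `alternative = "greater"` test whether `scores_a` tends larger.
#' A paired test whose differences are all zero is not evaluable
#' (`p_value = NA` with an explanatory note).
#'
#' @param scores_a,scores_b Numeric score vectors (equal length for the
#'   paired test).
#' @param test One of `"rank_sum_two_sided"`, `"rank_sum_one_sided"`,
#'   `"wilcoxon_signed_rank_two_sided"`.
#' @param alternative Direction for the one-sided rank-sum test:
#'   `"greater"` (default) or `"less"`, referring to `scores_a`.
#' @param exact_cutoff Exact enumeration is used when both group sizes
#'   (rank-sum) or the number of non-zero differences (signed-rank) are
#'   at most this (defaults 10 and 14).
#' @return One-row tibble: `test`, `n_a`, `n_b`, `statistic`,
#'   `p_value`, `exact`, `note`.
#' @export
compare_groups <- function(scores_a, scores_b,
                           test = c("rank_sum_two_sided",
                                    "rank_sum_one_sided",
                                    "wilcoxon_signed_rank_two_sided"),
                           alternative = c("greater", "less"),
                           exact_cutoff = NULL) {
  test <- match.arg(test)
  alternative <- match.arg(alternative)
  a <- as.numeric(scores_a)
  b <- as.numeric(scores_b)
  if (length(a) < 1 || length(b) < 1 || any(!is.finite(c(a, b)))) {
    abort_pathact("both groups need at least one finite observation")
  }
  if (test == "wilcoxon_signed_rank_two_sided") {
    if (length(a) != length(b)) {
      abort_pathact("the paired signed-rank test requires equal-length groups")
    }
    res <- signed_rank_test(a, b, exact_cutoff %||% 14)
  } else {
    sided <- if (test == "rank_sum_two_sided") "two_sided" else alternative
    res <- rank_sum_test(a, b, sided, exact_cutoff %||% 10)
  }
  tibble::tibble(
    test = test, n_a = length(a), n_b = length(b),
    statistic = res$statistic, p_value = res$p, exact = res$exact,
    note = res$note
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

rank_sum_test <- function(a, b, sided, exact_cutoff) {
  n_a <- length(a)
  n <- n_a + length(b)
  r <- rank(c(a, b)) # midranks under ties
  w <- sum(r[seq_len(n_a)])
  if (n_a <= exact_cutoff && length(b) <= exact_cutoff) {
    # all assignments of n_a of the observed midranks to group a
    combos <- utils::combn(n, n_a)
    w_all <- colSums(matrix(r[combos], nrow = n_a))
    tol <- 1e-9
    p_ge <- mean(w_all >= w - tol)
    p_le <- mean(w_all <= w + tol)
    p <- switch(sided,
      two_sided = min(1, 2 * min(p_ge, p_le)),
      greater = p_ge,
      less = p_le
    )
    list(statistic = w, p = p, exact = TRUE, note = NA_character_)
  } else {
    mu <- n_a * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n_a * length(b) / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z_num <- w - mu
    cc <- 0.5 # continuity correction toward the null
    p <- switch(sided,
      two_sided = 2 * stats::pnorm(-(abs(z_num) - cc) / sqrt(sigma2)),
      greater = stats::pnorm(-(z_num - cc) / sqrt(sigma2)),
      less = stats::pnorm((z_num + cc) / sqrt(sigma2))
    )
    list(statistic = w, p = min(1, max(0, p)), exact = FALSE,
         note = "normal approximation")
  }
}

signed_rank_test <- function(a, b, exact_cutoff) {
  d <- a - b
  nz <- d[d != 0]
  n_zero <- sum(d == 0)
  if (length(nz) == 0) {
    return(list(statistic = NA_real_, p = NA_real_, exact = NA,
                note = "not evaluable: all paired differences are zero"))
  }
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  note <- if (n_zero > 0) {
    paste0(n_zero, " zero difference(s) dropped")
  } else {
    NA_character_
  }
  n <- length(nz)
  if (n <= exact_cutoff) {
    # enumerate all 2^n sign configurations of the observed midranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.vector(signs %*% r)
    tol <- 1e-9
    p <- min(1, 2 * min(mean(v_all >= v - tol), mean(v_all <= v + tol)))
    list(statistic = v, p = p, exact = TRUE, note = note)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    p <- 2 * stats::pnorm(-(abs(v - mu) - 0.5) / sqrt(sigma2))
    list(statistic = v, p = min(1, max(0, p)), exact = FALSE,
         note = paste(c(note, "normal approximation"), collapse = "; "))
  }
}

#' Correlate two pathways' activity scores
#'
#' Computes both the Pearson correlation and the Spearman rank
#' correlation with their p-values (via [stats::cor.test()]). Reports
#' surface the Pearson coefficient by default; the Spearman column is
#' there to confirm rank-level agreement. Constant input makes the
#' correlation undefined: the result is returned with `NA` coefficients
#' and a note rather than an error.
#'
#' @param scores_x,scores_y Equal-length numeric vectors, `n >= 3`.
#' @return One-row tibble: `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `n`, `note`.
#' @export
correlate_pathways <- function(scores_x, scores_y) {
  x <- as.numeric(scores_x)
  y <- as.numeric(scores_y)
  if (length(x) != length(y)) {
    abort_pathact("`scores_x` and `scores_y` must have the same length")
  }
  if (length(x) < 3) abort_pathact("correlation needs n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort_pathact("scores must be finite")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(
      pearson_r = NA_real_, pearson_p = NA_real_,
      spearman_rho = NA_real_, spearman_p = NA_real_,
      n = length(x), note = "not evaluable: constant input"
    ))
  }
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  tibble::tibble(
    pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
    spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
    n = length(x), note = NA_character_
  )
}
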