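#' Max-t permutation test for a group difference across algorithm variants
#'
#' For one network measure observed under K tracking-algorithm variants,
#' computes the pooled-variance two-sample t statistic per variant and takes
#' the maximum of |t| over variants as the test statistic, controlling the
#' family-wise error of the K simultaneous comparisons. The null
#' distribution is obtained by permuting group labels: exactly, by
#' enumerating all `choose(nA + nB, nA)` label assignments when that count
#' is at most 20,000 (the default "auto" rule), or by Monte-Carlo sampling
#' of `n_perm` assignments otherwise. The identity assignment is always
#' counted in both numerator and denominator, so p > 0. The test is
#' two-sided via |t|; a variant with zero pooled variance under some
#' assignment contributes t = 0 there (logged once).
#'
#' @param group_a,group_b Numeric matrices (subjects x variants) or data
#'   frames; both groups must have the same number of variant columns.
#' @param mode `"auto"` (exact when feasible), `"exact"`, or `"mc"`.
#' @param n_perm Monte-Carlo draws (ignored in exact mode).
#' @param seed Integer seed (Monte-Carlo mode).
#' @param exact_limit Largest assignment count for which "auto" enumerates.
#' @return An object of class `maxt_test`: list with `t_obs` (per-variant t,
#'   group A minus group B), `max_t` (observed max |t|), `p`, `mode`,
#'   `n_assignments` (denominator), `perm_max_t` (the permutation
#'   distribution) and `seed`.
#' @export
#' @examples
#' a <- matrix(rnorm(18, mean = 1), 6, 3)
#' b <- matrix(rnorm(18), 6, 3)
#' maxt_permutation_test(a, b)
maxt_permutation_test <- function(group_a, group_b,
                                  mode = c("auto", "exact", "mc"),
                                  n_perm = 2000, seed = 1L,
                                  exact_limit = 20000) {
  mode <- match.arg(mode)
  A <- as.matrix(group_a)
  B <- as.matrix(group_b)
  if (ncol(A) != ncol(B)) abort("Both groups must have the same variant columns.")
  nA <- nrow(A); nB <- nrow(B)
  if (nA < 2 || nB < 2) abort("Each group needs at least 2 subjects.")
  X <- rbind(A, B)
  n <- nA + nB
  n_total <- choose(n, nA)
  if (mode == "auto") mode <- if (n_total <= exact_limit) "exact" else "mc"
  if (mode == "exact" && n_total > exact_limit) {
    abort(sprintf("Exact mode would enumerate %g assignments; use mode = 'mc'.",
                  n_total))
  }

  if (mode == "exact") {
    assign_idx <- combn(n, nA)          # columns are index sets for group A
  } else {
    assign_idx <- with_seed_if(seed, {
      draws <- replicate(n_perm, sample.int(n, nA))
      cbind(seq_len(nA), draws)         # identity assignment first
    })
  }
  P <- ncol(assign_idx)
  Ind <- matrix(0, P, n)
  Ind[cbind(rep(seq_len(P), each = nA), as.vector(assign_idx))] <- 1

  X2 <- X^2
  sumA <- Ind %*% X                     # P x K group-A sums
  sumA2 <- Ind %*% X2
  tot <- matrix(colSums(X), P, ncol(X), byrow = TRUE)
  tot2 <- matrix(colSums(X2), P, ncol(X), byrow = TRUE)
  mA <- sumA / nA
  mB <- (tot - sumA) / nB
  ssA <- sumA2 - nA * mA^2
  ssB <- (tot2 - sumA2) - nB * mB^2
  sp2 <- (ssA + ssB) / (n - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  tmat <- (mA - mB) / se
  zero_var <- se <= 0 | !is.finite(tmat)
  if (any(zero_var)) {
    message(sprintf("t set to 0 for %d assignment-variant pair(s) with zero pooled variance.",
                    sum(zero_var)))
    tmat[zero_var] <- 0
  }
  perm_max <- apply(abs(tmat), 1L, max)

  # observed statistic from the true labels (= identity assignment)
  id_row <- if (mode == "exact") {
    which(colSums(assign_idx == seq_len(nA)) == nA)[1L]
  } else 1L
  t_obs <- tmat[id_row, ]
  names(t_obs) <- colnames(A) %||% paste0("alg", seq_len(ncol(A)))
  max_obs <- max(abs(t_obs))
  p <- sum(perm_max >= max_obs - 1e-12) / P

  structure(
    list(t_obs = t_obs, max_t = max_obs, p = p, mode = mode,
         n_assignments = P, perm_max_t = perm_max,
         seed = if (mode == "mc") as.integer(seed) else NA_integer_),
    class = "maxt_test"
  )
}

#' @export
print.maxt_test <- function(x, ...) {
  cat(sprintf("<maxt_test> max |t| = %.3f, p = %.4g (%s, %d assignments)\n",
              x$max_t, x$p, x$mode, x$n_assignments))
  cat("  per-variant t:", paste(sprintf("%s = %.3f", names(x$t_obs), x$t_obs),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Max-t permutation tests for every measure of a metric table
#'
#' Runs [maxt_permutation_test()] once per measure, with subjects-by-variant
#' matrices assembled from the long metric table.
#'
#' @param metrics Long tibble (columns `subject_id`, `group`, `algorithm`,
#'   `measure`, `value`).
#' @param measures Measures to test (default: canonical six present).
#' @inheritParams maxt_permutation_test
#' @return Tibble with one row per measure: `measure`, `max_t`, `p`, `mode`,
#'   and a `test` list column with the full `maxt_test` objects.
#' @export
maxt_test_table <- function(metrics, measures = NULL,
                            mode = c("auto", "exact", "mc"),
                            n_perm = 2000, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot("group" %in% names(metrics))
  if (is.null(measures)) {
    measures <- intersect(MEASURE_ORDER, unique(metrics$measure))
  }
  groups <- levels(factor(metrics$group))
  tests <- lapply(measures, function(m) {
    sp <- build_space(metrics[metrics$measure == m, ], measures = m)
    A <- sp$X[sp$labels == groups[1L], , drop = FALSE]
    B <- sp$X[sp$labels == groups[2L], , drop = FALSE]
    maxt_permutation_test(A, B, mode = mode, n_perm = n_perm, seed = seed)
  })
  tibble(
    measure = measures,
    max_t = vapply(tests, `[[`, numeric(1), "max_t"),
    p = vapply(tests, `[[`, numeric(1), "p"),
    mode = vapply(tests, `[[`, character(1), "mode"),
    test = tests
  )
}
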