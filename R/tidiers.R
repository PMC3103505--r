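#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-subject posteriors of a leave-one-out LDA
#'
#' @param x An `lda_loocv` object.
#' @param ... Unused.
#' @return Tibble with one row per subject: `subject`, `truth`, `posterior`
#'   (probability of the positive class), `predicted`, `correct`.
#' @exportS3Method generics::tidy
tidy.lda_loocv <- function(x, ...) {
  x$posteriors
}

#' One-row summary of a leave-one-out LDA
#'
#' @param x An `lda_loocv` object.
#' @param ... Unused.
#' @return Tibble with `accuracy` (percent), `n` (subjects), `positive`,
#'   `ridge` and, when selection ran, the selected measures collapsed into
#'   `selected`.
#' @exportS3Method generics::glance
glance.lda_loocv <- function(x, ...) {
  tibble(
    accuracy = x$accuracy,
    n = nrow(x$posteriors),
    positive = x$positive,
    ridge = x$ridge,
    selected = if (is.null(x$selected)) NA_character_
               else paste(x$selected, collapse = ",")
  )
}

#' Tidy per-variant t statistics of a max-t permutation test
#'
#' @param x A `maxt_test` object.
#' @param ... Unused.
#' @return Tibble with `algorithm` and `t`.
#' @exportS3Method generics::tidy
tidy.maxt_test <- function(x, ...) {
  tibble(algorithm = names(x$t_obs), t = as.numeric(x$t_obs))
}

#' One-row summary of a max-t permutation test
#'
#' @param x A `maxt_test` object.
#' @param ... Unused.
#' @return Tibble with `max_t`, `p`, `mode`, `n_assignments`.
#' @exportS3Method generics::glance
glance.maxt_test <- function(x, ...) {
  tibble(max_t = x$max_t, p = x$p, mode = x$mode,
         n_assignments = x$n_assignments)
}

#' Tidy the points of a representation space
#'
#' @param x A `rep_space` object.
#' @param ... Unused.
#' @return Long tibble with `subject`, `group` (when known), `coordinate`
#'   (measure.algorithm), `value`.
#' @exportS3Method generics::tidy
tidy.rep_space <- function(x, ...) {
  out <- as_tibble(x$X)
  out$subject <- x$subjects
  if (!is.null(x$labels)) out$group <- x$labels
  tidyr::pivot_longer(out, cols = colnames(x$X),
                      names_to = "coordinate", values_to = "value")
}
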