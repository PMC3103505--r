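#' Canonical measure ordering
#'
#' The listing order C, L, Q, E_glob, E_loc, sigma used for coordinate
#' layout and for tie-breaking in feature selection.
#' @keywords internal
MEASURE_ORDER <- c("C", "L", "Q", "E_glob", "E_loc", "sigma")

#' Build a network-measure representation space
#'
#' In a representation space every subject is a single point whose
#' coordinates are the values of the chosen network measure(s) under each
#' tracking-algorithm variant: one measure with N variants gives an
#' N-dimensional space (e.g. 3-D for three algorithms); M measures jointly
#' give an (M x N)-dimensional space. Coordinates are laid out measures-first
#' (declared order), algorithms within each measure.
#'
#' @param metrics Long tibble from [metrics_table()] (columns `subject_id`,
#'   `algorithm`, `measure`, `value`, optionally `group`).
#' @param measures Character vector of measures to include, in order;
#'   defaults to all of C, L, Q, E_glob, E_loc, sigma present in `metrics`.
#' @param algorithms Algorithm variants to include, in order; defaults to
#'   the sorted unique values present.
#' @return An object of class `rep_space`: list with the point matrix `X`
#'   (subjects x M*N, rownames = subject ids), `subjects`, `measures`,
#'   `algorithms` and `labels` (group factor, when present).
#' @export
build_space <- function(metrics, measures = NULL, algorithms = NULL) {
  stopifnot(all(c("subject_id", "algorithm", "measure", "value") %in% names(metrics)))
  if (is.null(measures)) {
    measures <- intersect(MEASURE_ORDER, unique(metrics$measure))
  }
  if (is.null(algorithms)) algorithms <- sort(unique(metrics$algorithm))
  subjects <- unique(metrics$subject_id)
  X <- matrix(NA_real_, length(subjects), length(measures) * length(algorithms),
              dimnames = list(subjects,
                              paste(rep(measures, each = length(algorithms)),
                                    rep(algorithms, length(measures)), sep = ".")))
  sub_i <- match(metrics$subject_id, subjects)
  col_i <- match(paste(metrics$measure, metrics$algorithm, sep = "."),
                 colnames(X))
  ok <- !is.na(col_i)
  X[cbind(sub_i[ok], col_i[ok])] <- metrics$value[ok]
  if (anyNA(X)) {
    miss <- which(is.na(X), arr.ind = TRUE)[1L, ]
    abort(sprintf("Missing value for subject '%s', coordinate '%s'.",
                  subjects[miss[1L]], colnames(X)[miss[2L]]))
  }
  labels <- NULL
  if ("group" %in% names(metrics)) {
    lab <- metrics$group[!duplicated(metrics$subject_id)]
    labels <- factor(lab, levels = unique(lab))
    names(labels) <- subjects
  }
  structure(list(X = X, subjects = subjects, measures = measures,
                 algorithms = algorithms, labels = labels),
            class = "rep_space")
}

#' @export
print.rep_space <- function(x, ...) {
  cat(sprintf("<rep_space> %d subjects in %d dimensions (%s x %s)\n",
              nrow(x$X), ncol(x$X),
              paste(x$measures, collapse = ","),
              paste(x$algorithms, collapse = ",")))
  invisible(x)
}

# Gaussian LDA with pooled within-class covariance, diagonal ridge loading
# and equal priors; returns discriminant direction and intercept for the
# first class
lda_fit <- function(X, y, ridge) {
  lev <- levels(y)
  mu1 <- colMeans(X[y == lev[1L], , drop = FALSE])
  mu2 <- colMeans(X[y == lev[2L], , drop = FALSE])
  d <- ncol(X)
  cc1 <- scale(X[y == lev[1L], , drop = FALSE], center = mu1, scale = FALSE)
  cc2 <- scale(X[y == lev[2L], , drop = FALSE], center = mu2, scale = FALSE)
  S <- (crossprod(cc1) + crossprod(cc2)) / (nrow(X) - 2L)
  load <- ridge * sum(diag(S)) / d
  if (load <= 0) load <- ridge
  S <- S + diag(load, d)
  Sinv <- tryCatch(solve(S), error = function(e) {
    abort("Pooled covariance is singular even after ridge loading; increase `ridge`.")
  })
  coef <- as.numeric(Sinv %*% (mu1 - mu2))
  intercept <- -0.5 * sum((mu1 + mu2) * coef)
  list(coef = coef, intercept = intercept)
}

#' Leave-one-out LDA over a representation space
#'
#' Classical two-class linear discriminant analysis (shared within-class
#' covariance, equal priors) in a leave-one-out rotation: each subject in
#' turn is held out, the discriminant is fit on the remaining subjects, and
#' the held-out subject receives the posterior probability of belonging to
#' the first class. Because few training subjects may face many coordinates,
#' the pooled covariance receives a diagonal ridge loading
#' `ridge * trace(S)/d` before inversion. The boundary hyperplane of each
#' fold is normalized to a unit normal and averaged into a mean boundary
#' hyperplane.
#'
#' @param space A `rep_space` (or a bare numeric matrix, subjects in rows).
#' @param labels Two-level factor of true classes; taken from the space when
#'   omitted. The first level is the "positive" class whose posterior is
#'   reported (e.g. control).
#' @param ridge Ridge loading factor (default 1e-6).
#' @param threshold Posterior threshold for prediction (default 0.5; a
#'   posterior exactly at the threshold counts as incorrect and is logged).
#' @return An object of class `lda_loocv`: list with `posteriors` (tibble:
#'   subject, truth, posterior, predicted, correct), `accuracy` (percent,
#'   2 decimals), `hyperplane` (mean unit-normal coefficients and
#'   intercept), `positive` (the class the posterior refers to), `ridge`.
#' @export
lda_loocv <- function(space, labels = NULL, ridge = 1e-6, threshold = 0.5) {
  X <- if (inherits(space, "rep_space")) space$X else as.matrix(space)
  if (is.null(labels) && inherits(space, "rep_space")) labels <- space$labels
  if (is.null(labels)) abort("`labels` must be supplied.")
  y <- factor(labels)
  if (nlevels(y) != 2L) abort("Exactly two classes are required.")
  if (any(table(y) < 2L)) abort("Each class needs at least 2 members.")
  n <- nrow(X)
  stopifnot(length(y) == n)
  post <- numeric(n)
  planes <- matrix(0, n, ncol(X) + 1L)
  for (i in seq_len(n)) {
    fit <- lda_fit(X[-i, , drop = FALSE], y[-i], ridge)
    score <- sum(X[i, ] * fit$coef) + fit$intercept
    post[i] <- stats::plogis(score)
    nrm <- sqrt(sum(fit$coef^2))
    planes[i, ] <- c(fit$coef, fit$intercept) / nrm
  }
  lev <- levels(y)
  predicted <- ifelse(post > threshold, lev[1L], lev[2L])
  correct <- predicted == as.character(y) & post != threshold
  if (any(post == threshold)) {
    message(sprintf("%d posterior(s) exactly at the threshold; counted incorrect.",
                    sum(post == threshold)))
  }
  mean_plane <- colMeans(planes)
  subjects <- rownames(X) %||% paste0("s", seq_len(n))
  res <- structure(
    list(
      posteriors = tibble(subject = subjects, truth = as.character(y),
                          posterior = post, predicted = predicted,
                          correct = correct),
      accuracy = round(100 * mean(correct), 2),
      hyperplane = list(coef = mean_plane[seq_len(ncol(X))],
                        intercept = mean_plane[ncol(X) + 1L]),
      positive = lev[1L], ridge = ridge, threshold = threshold,
      selected = NULL
    ),
    class = "lda_loocv"
  )
  res
}

#' @export
print.lda_loocv <- function(x, ...) {
  cat(sprintf("<lda_loocv> %d subjects, %.2f%% correctly predicted (positive class: %s)\n",
              nrow(x$posteriors), x$accuracy, x$positive))
  if (!is.null(x$selected)) {
    cat("  selected measures:", paste(x$selected, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Percent correct from thresholded posteriors
#'
#' Thresholds per-subject posterior probabilities of the positive class and
#' reports the percent of subjects whose thresholded posterior matches the
#' truth, to 2 decimals. A posterior exactly at the threshold is counted
#' incorrect (and logged).
#'
#' @param posteriors Numeric vector in `[0, 1]`: P(positive class) per subject.
#' @param is_positive Logical vector: is each subject truly in the positive
#'   class?
#' @param threshold Decision threshold (default 0.5).
#' @return Percent correct, rounded to 2 decimals.
#' @export
#' @examples
#' accuracy_from_posteriors(c(0.9, 0.8, 0.2), c(TRUE, TRUE, FALSE))  # 100
accuracy_from_posteriors <- function(posteriors, is_positive, threshold = 0.5) {
  if (any(posteriors < 0 | posteriors > 1)) {
    abort("`posteriors` must lie in [0, 1].")
  }
  stopifnot(length(posteriors) == length(is_positive), is.logical(is_positive))
  at <- posteriors == threshold
  if (any(at)) {
    message(sprintf("%d posterior(s) exactly at the threshold; counted incorrect.",
                    sum(at)))
  }
  correct <- ifelse(posteriors > threshold, is_positive, !is_positive) & !at
  round(100 * mean(correct), 2)
}

#' Forward sequential feature selection over network measures
#'
#' Wrapper-style selection: measures are ranked by their single-measure
#' leave-one-out accuracy (ties broken by the canonical order C, L, Q,
#' E_glob, E_loc, sigma); prediction starts from the best single measure and
#' the next-ranked measure's coordinates are appended while the combined
#' leave-one-out accuracy strictly improves. Deterministic for fixed inputs.
#'
#' @param metrics Long metric tibble (see [build_space()]).
#' @param labels Two-level factor of true classes; taken from `metrics`'
#'   `group` column when omitted.
#' @param measures Candidate measures (default: all canonical measures
#'   present).
#' @param algorithms Algorithm variants (default: all present).
#' @inheritParams lda_loocv
#' @return An `lda_loocv` object for the final combined space, with
#'   `selected` (ordered selected measures) and `single_accuracy` (named
#'   vector of per-measure accuracies) filled in.
#' @export
sequential_forward_select <- function(metrics, labels = NULL, measures = NULL,
                                      algorithms = NULL, ridge = 1e-6,
                                      threshold = 0.5) {
  if (is.null(measures)) {
    measures <- intersect(MEASURE_ORDER, unique(metrics$measure))
  }
  if (length(measures) < 1) abort("Need at least one measure.")
  spaces <- lapply(measures, function(m) {
    build_space(metrics, measures = m, algorithms = algorithms)
  })
  names(spaces) <- measures
  if (is.null(labels)) labels <- spaces[[1L]]$labels
  single <- vapply(spaces, function(sp) {
    lda_loocv(sp, labels, ridge = ridge, threshold = threshold)$accuracy
  }, numeric(1))
  ranking <- measures[order(-single, match(measures, MEASURE_ORDER))]
  selected <- ranking[1L]
  best <- lda_loocv(build_space(metrics, measures = selected,
                                algorithms = algorithms),
                    labels, ridge = ridge, threshold = threshold)
  for (m in ranking[-1L]) {
    cand_measures <- c(selected, m)
    cand <- lda_loocv(build_space(metrics, measures = cand_measures,
                                  algorithms = algorithms),
                      labels, ridge = ridge, threshold = threshold)
    if (cand$accuracy > best$accuracy) {
      selected <- cand_measures
      best <- cand
    } else {
      break
    }
  }
  best$selected <- selected
  best$single_accuracy <- single
  best
}
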