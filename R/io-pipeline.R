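#' Write / read a connectivity matrix as CSV
#'
#' Matrices are stored as comma-separated text with a header row of node
#' labels and a square numeric body, at 17 significant digits so a
#' write-read cycle reproduces the doubles exactly. Reading validates that
#' the body is square and symmetric (tolerance 1e-9).
#'
#' @param w Symmetric weight matrix.
#' @param path File path.
#' @return `write_matrix()`: `path` invisibly. `read_matrix()`: the matrix
#'   with node labels as dimnames.
#' @export
write_matrix <- function(w, path) {
  validate_network(w)
  labs <- node_labels(w)
  body <- apply(w, 1L, function(r) {
    paste(formatC(r, digits = 17, format = "g"), collapse = ",")
  })
  writeLines(c(paste(labs, collapse = ","), body), path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("File '%s' does not exist.", path))
  if (file.size(path) == 0) abort(sprintf("File '%s' is empty.", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    abort(sprintf("File '%s' has no matrix body below the header.", path))
  }
  labs <- strsplit(lines[1L], ",")[[1L]]
  rows <- strsplit(lines[-1L], ",")
  if (length(rows) != length(labs) || any(lengths(rows) != length(labs))) {
    abort(sprintf("File '%s' is not a square %d x %d matrix.",
                  path, length(labs), length(labs)))
  }
  w <- do.call(rbind, lapply(rows, as.numeric))
  if (anyNA(w)) abort(sprintf("File '%s' contains non-numeric entries.", path))
  dimnames(w) <- list(labs, labs)
  asym <- abs(w - t(w))
  if (any(asym > 1e-9)) {
    idx <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    abort(sprintf("Matrix in '%s' is asymmetric at [%d, %d] vs [%d, %d] (|diff| = %.3g).",
                  path, idx[1L], idx[2L], idx[2L], idx[1L], max(asym)))
  }
  w
}

#' Pipeline configuration
#'
#' One object holding every knob of the end-to-end synthetic pipeline: the
#' group design, the backbone stopping rule, the metric options, the
#' permutation-test and classifier settings, and the master seed. It
#' round-trips losslessly through JSON via [write_config()] /
#' [read_config()].
#'
#' @param design A [group_design()].
#' @param target_avg_degree Backbone average-degree stopping rule.
#' @param ensemble_size Null-ensemble size for small-worldness.
#' @param scaled Scale clustering weights by the network maximum.
#' @param test_mode,n_perm Permutation-test mode and Monte-Carlo size.
#' @param ridge LDA ridge loading factor.
#' @param seed Master seed for the metric/test stages (the design carries
#'   its own generation seed).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = group_design(), target_avg_degree = 4,
                            ensemble_size = 20, scaled = TRUE,
                            test_mode = "auto", n_perm = 2000,
                            ridge = 1e-6, seed = 1L) {
  structure(
    list(design = design, target_avg_degree = target_avg_degree,
         ensemble_size = ensemble_size, scaled = scaled,
         test_mode = test_mode, n_perm = n_perm, ridge = ridge,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$design <- unclass(x$design)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  design <- do.call(group_design, x$design)
  pipeline_config(design = design,
                  target_avg_degree = x$target_avg_degree,
                  ensemble_size = x$ensemble_size, scaled = x$scaled,
                  test_mode = x$test_mode, n_perm = x$n_perm,
                  ridge = x$ridge, seed = x$seed)
}

#' Run the full synthetic discrimination pipeline
#'
#' Executes the stages in study order: generate two-group connectomes,
#' extract connectivity backbones, compute the six network measures per
#' subject and variant, test each measure for a group difference with the
#' max-t permutation test, classify subjects per measure by leave-one-out
#' LDA in the measure's representation space, and combine measures by
#' forward sequential selection. Identical configs (including seeds) give
#' identical summaries.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, the metric table
#'   (CSV), per-subject networks and a JSON summary are written there.
#' @return A list of class `pipeline_summary`: `metrics` (long tibble),
#'   `tests` (per-measure max-t results), `classification` (per-measure
#'   accuracy tibble), `combined` (the forward-selection `lda_loocv`),
#'   `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
  }
  samples <- with_stage("simulate", generate_group_connectomes(config$design))
  metrics <- with_stage("metrics", metrics_table(
    samples, backbone = TRUE,
    target_avg_degree = config$target_avg_degree,
    ensemble_size = config$ensemble_size,
    seed = config$seed, scaled = config$scaled
  ))
  tests <- with_stage("permtest", maxt_test_table(
    metrics, mode = config$test_mode, n_perm = config$n_perm,
    seed = config$seed
  ))
  measures <- intersect(MEASURE_ORDER, unique(metrics$measure))
  per_measure <- with_stage("classify", purrr::map(measures, function(m) {
    lda_loocv(build_space(metrics, measures = m), ridge = config$ridge)
  }))
  classification <- tibble(
    measure = measures,
    accuracy = vapply(per_measure, `[[`, numeric(1), "accuracy"),
    result = per_measure
  )
  combined <- with_stage("classify",
                         sequential_forward_select(metrics,
                                                   ridge = config$ridge))
  summary <- structure(
    list(metrics = metrics, tests = tests, classification = classification,
         combined = combined, config = config),
    class = "pipeline_summary"
  )
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    write_subject_samples(samples, file.path(output_dir, "networks"),
                          design = config$design)
    utils::write.csv(metrics, file.path(output_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(
        p_values = setNames(as.list(tests$p), tests$measure),
        accuracy = setNames(as.list(classification$accuracy),
                            classification$measure),
        combined_accuracy = combined$accuracy,
        selected_measures = combined$selected,
        seed = config$seed, design_seed = config$design$seed
      ),
      file.path(output_dir, "summary.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  summary
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat("<pipeline_summary>\n")
  cat(sprintf("  %d subjects x %d variants, %d-node networks\n",
              2 * x$config$design$n_per_group, 3, x$config$design$n_nodes))
  cat("  permutation p-values:\n")
  for (i in seq_len(nrow(x$tests))) {
    cat(sprintf("    %-7s p = %.4g\n", x$tests$measure[i], x$tests$p[i]))
  }
  cat("  per-measure LOO accuracy (%):\n")
  for (i in seq_len(nrow(x$classification))) {
    cat(sprintf("    %-7s %.2f\n", x$classification$measure[i],
                x$classification$accuracy[i]))
  }
  cat(sprintf("  combined (selected: %s): %.2f%%\n",
              paste(x$combined$selected, collapse = ", "),
              x$combined$accuracy))
  invisible(x)
}
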