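# build a long metric tibble from a subjects x algorithms value matrix
metrics_from_matrix <- function(X, measure, groups,
                                algorithms = paste0("alg", seq_len(ncol(X)))) {
  tibble::tibble(
    subject_id = rep(rownames(X), each = ncol(X)),
    group = rep(groups, each = ncol(X)),
    algorithm = rep(algorithms, nrow(X)),
    measure = measure,
    value = as.vector(t(X))
  )
}

two_cluster_metrics <- function(gap = 10, seed = 1, measure = "C") {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(18, mean = gap), 6, 3),
               matrix(rnorm(18, mean = 0), 6, 3))
    rownames(X) <- c(paste0("ctl", 1:6), paste0("shi", 1:6))
    metrics_from_matrix(X, measure, rep(c("control", "case"), each = 6))
  })
}

test_that("representation spaces have the declared layout", {
  m <- two_cluster_metrics()
  sp <- build_space(m)
  expect_s3_class(sp, "rep_space")
  expect_equal(dim(sp$X), c(12, 3))
  m6 <- dplyr::bind_rows(lapply(c("C", "L", "Q", "E_glob", "E_loc", "sigma"),
                                function(ms) two_cluster_metrics(measure = ms)))
  sp6 <- build_space(m6)
  expect_equal(dim(sp6$X), c(12, 18))
  expect_equal(colnames(sp6$X)[1:3], c("C.alg1", "C.alg2", "C.alg3"))
  # permuting the input rows permutes the points identically
  perm <- withr::with_seed(3, sample(nrow(m)))
  sp_perm <- build_space(m[perm, ])
  expect_equal(sp_perm$X[rownames(sp$X), ], sp$X)
  # a missing value is reported with subject and coordinate
  expect_error(build_space(m[-1, ]), "Missing value.*ctl1")
})

test_that("LOO-LDA separates well-separated spherical clusters", {
  res <- lda_loocv(build_space(two_cluster_metrics(gap = 10)))
  expect_equal(res$accuracy, 100)
  post <- res$posteriors
  expect_true(all(post$posterior[post$truth == "control"] > 0.99))
  expect_true(all(post$posterior[post$truth == "case"] < 0.01))
  expect_true(all(post$posterior >= 0 & post$posterior <= 1))
})

test_that("a held-out point midway between mirror-symmetric classes gets posterior 0.5", {
  X <- rbind(c(0, 0),
             c(1, 1), c(2, 1.5), c(1.5, 0.5),
             -rbind(c(1, 1), c(2, 1.5), c(1.5, 0.5)))
  rownames(X) <- paste0("s", 1:7)
  labels <- factor(c("control", rep("control", 3), rep("case", 3)),
                   levels = c("control", "case"))
  res <- suppressMessages(lda_loocv(X, labels))
  expect_equal(res$posteriors$posterior[1], 0.5, tolerance = 1e-12)
  expect_false(res$posteriors$correct[1])  # at-threshold counts incorrect
})

test_that("accuracy is invariant under common affine rescaling", {
  m <- two_cluster_metrics(gap = 2, seed = 6)
  sp <- build_space(m)
  r1 <- lda_loocv(sp)
  X2 <- sp$X * 3.7 + 11
  r2 <- lda_loocv(X2, sp$labels)
  expect_equal(r2$accuracy, r1$accuracy)
  expect_equal(r2$posteriors$posterior, r1$posteriors$posterior,
               tolerance = 1e-8)
})

test_that("permuted labels classify at chance level on average", {
  m <- two_cluster_metrics(gap = 3, seed = 8)
  sp <- build_space(m)
  accs <- withr::with_seed(99, {
    replicate(200, {
      lda_loocv(sp$X, sample(sp$labels))$accuracy
    })
  })
  expect_gt(mean(accs), 35)
  expect_lt(mean(accs), 65)
})

test_that("posterior thresholding reproduces accuracy percentages", {
  expect_equal(accuracy_from_posteriors(c(0.9, 0.8, 0.2),
                                        c(TRUE, TRUE, FALSE)), 100)
  expect_equal(accuracy_from_posteriors(c(0.9, 0.2, 0.4, 0.6),
                                        c(TRUE, TRUE, FALSE, FALSE)), 50)
  expect_message(
    at <- accuracy_from_posteriors(c(0.5, 0.9), c(TRUE, TRUE)),
    "threshold"
  )
  expect_equal(at, 50)
  expect_error(accuracy_from_posteriors(c(1.2, 0.1), c(TRUE, FALSE)),
               "0, 1")
})

test_that("forward selection stops at a perfect single measure", {
  m_good <- two_cluster_metrics(gap = 10, seed = 2, measure = "C")
  m_noise <- two_cluster_metrics(gap = 0, seed = 5, measure = "L")
  res <- sequential_forward_select(dplyr::bind_rows(m_good, m_noise))
  expect_equal(res$selected, "C")
  expect_equal(res$accuracy, 100)
})

test_that("a pure-noise measure is never selected alongside a perfect one", {
  for (s in 1:20) {
    m_good <- two_cluster_metrics(gap = 10, seed = 2, measure = "C")
    m_noise <- two_cluster_metrics(gap = 0, seed = 100 + s, measure = "Q")
    res <- sequential_forward_select(dplyr::bind_rows(m_good, m_noise))
    expect_false("Q" %in% res$selected)
  }
})

test_that("forward selection is deterministic and at least as good as single measures", {
  m6 <- dplyr::bind_rows(lapply(seq_along(c("C", "L", "Q", "E_glob", "E_loc",
                                            "sigma")), function(k) {
    ms <- c("C", "L", "Q", "E_glob", "E_loc", "sigma")[k]
    two_cluster_metrics(gap = k / 2, seed = 40 + k, measure = ms)
  }))
  r1 <- sequential_forward_select(m6)
  r2 <- sequential_forward_select(m6)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$posteriors, r2$posteriors)
  expect_gte(r1$accuracy, max(r1$single_accuracy))
})

test_that("tidy and glance methods expose the classification results", {
  res <- lda_loocv(build_space(two_cluster_metrics()))
  td <- generics::tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("subject", "truth", "posterior", "predicted", "correct"))
  gl <- generics::glance(res)
  expect_equal(gl$accuracy, 100)
  expect_equal(gl$n, 12L)
})

test_that("posteriors agree with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  m <- two_cluster_metrics(gap = 1.5, seed = 12)
  sp <- build_space(m)
  ours <- lda_loocv(sp)
  for (i in seq_len(nrow(sp$X))) {
    fit <- MASS::lda(sp$X[-i, ], grouping = sp$labels[-i],
                     prior = c(0.5, 0.5))
    ref <- predict(fit, sp$X[i, , drop = FALSE])$posterior[, "control"]
    expect_equal(ours$posteriors$posterior[i], unname(ref), tolerance = 1e-4)
  }
})
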