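test_that("fitting computes per-tau means and population variances", {
  # two cells with known values at every tau
  f <- rbind(
    data.frame(cell_id = "a", tau = -15:-1, lambda1_norm = 0.6,
               lambda2_norm = 0.2, skewness = 0.1),
    data.frame(cell_id = "b", tau = -15:-1, lambda1_norm = 0.4,
               lambda2_norm = 0.3, skewness = 0.3)
  )
  m <- fit_reference_model(f)
  expect_equal(m$support$mean_lambda1_norm, rep(0.5, 15))
  # population variance of {0.6, 0.4}: mean squared deviation = 0.01
  expect_equal(m$support$var_lambda1_norm, rep(0.01, 15))
  expect_equal(m$support$var_skewness, rep(0.01, 15))
  expect_identical(m$support$n, rep(2L, 15))
})

test_that("fitting rejects sparse and degenerate cohorts", {
  truth <- default_truth()
  co <- sample_cohort(truth, 10, seed = 2)
  # remove all frames at tau = -7 but one
  broken <- co[!(co$tau == -7 & co$cell_id != "cell001"), ]
  expect_error(fit_reference_model(broken), "tau = -7")
  # identical feature values at one tau: zero variance
  dup <- co
  dup[dup$tau == -1, c("lambda1_norm", "lambda2_norm", "skewness")] <-
    list(0.34, 0.33, 0.01)
  expect_error(fit_reference_model(dup), "zero variance")
})

test_that("fitting is deterministic and recovers truth at cohort scale", {
  truth <- default_truth()
  co <- sample_cohort(truth, 39, seed = 1)
  m1 <- fit_reference_model(co)
  m2 <- fit_reference_model(co)
  expect_identical(m1$support, m2$support)
  expect_identical(m1$cohort_hash, m2$cohort_hash)
  merged <- dplyr::inner_join(m1$support, truth$support, by = "tau")
  expect_lt(mean(abs(merged$mean_lambda1_norm - merged$mean_lambda1)),
            2 * 0.02 / sqrt(39))
  expect_lt(mean(abs(merged$mean_skewness.x - merged$mean_skewness.y)),
            2 * 0.02 / sqrt(39))
})

test_that("likelihood is the product of independent Gaussian densities", {
  means <- matrix(rep(c(0.5, 0.25, 0.1), each = 15), 15)
  m <- make_model(means, matrix(1 / (2 * pi), 15, 3))
  # with sigma = 1/sqrt(2*pi), each density peaks at exactly 1
  expect_equal(likelihood(m, c(0.5, 0.25, 0.1), -5), 1)
  # closed form at an off-mode point
  f <- c(0.6, 0.25, 0.1)
  expect_equal(likelihood(m, f, -5),
               prod(stats::dnorm(f, c(0.5, 0.25, 0.1), sqrt(1 / (2 * pi)))))
  # mode beats a 3-sigma displacement; density > 1 is legitimate
  m2 <- make_model(means, matrix(0.001^2, 15, 3))
  expect_gt(likelihood(m2, c(0.5, 0.25, 0.1), -3), 1)
  expect_gt(likelihood(m2, c(0.5, 0.25, 0.1), -3),
            likelihood(m2, c(0.5 + 0.003, 0.25, 0.1), -3))
  expect_error(likelihood(m, c(0.5, 0.25, 0.1), -16), "support")
})

test_that("likelihood integrates to 1 over feature space at a fixed tau", {
  truth <- default_truth()
  m <- fit_reference_model(sample_cohort(truth, 39, seed = 1))
  p <- m$support[m$support$tau == -8, ]
  # quadrature on a +/- 6 sigma grid, feature by feature (independence)
  total <- 1
  for (feat in c("lambda1_norm", "lambda2_norm", "skewness")) {
    mu <- p[[paste0("mean_", feat)]]
    sd <- sqrt(p[[paste0("var_", feat)]])
    x <- seq(mu - 6 * sd, mu + 6 * sd, length.out = 2001)
    total <- total * sum(stats::dnorm(x, mu, sd)) * (x[2] - x[1])
  }
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("k-NN gate separates early from late phases", {
  truth <- default_truth()
  co <- sample_cohort(truth, 39, start_tau_range = c(-25, -20), seed = 3)
  m <- fit_reference_model(co)
  # an exact early reference with k = 1 votes early
  e <- m$early[1, ]
  expect_identical(knn_stage(m, e, k = 1)$label, "early")
  # k = full reference count returns the global majority class
  maj <- names(which.max(table(m$knn_ref$label)))
  expect_identical(knn_stage(m, e, k = nrow(m$knn_ref))$label, maj)
  # well-separated synthetic clusters classify held-out points perfectly
  held <- sample_cohort(truth, 8, start_tau_range = c(-25, -20), seed = 99)
  gates <- vapply(seq_len(nrow(held)), function(i) {
    knn_stage(m, held[i, ], k = 5)$label
  }, character(1))
  truth_lab <- ifelse(held$tau < -15, "early", "late")
  # the very-early frames are far from the late manifold; rounding frames
  # (tau near -1) are far from early; accuracy should be high overall
  expect_gt(mean(gates == truth_lab), 0.85)
  expect_error(knn_stage(m, e, k = 0), "k must be")
})

test_that("k-NN tie votes resolve to late with a warning", {
  ref <- data.frame(
    cell_id = "x", tau = c(-20, -20, -10, -10),
    lambda1_norm = c(0.8, 0.8, 0.4, 0.4),
    lambda2_norm = c(0.1, 0.1, 0.3, 0.3),
    skewness = c(0.2, 0.2, 0.02, 0.02)
  )
  m0 <- fit_reference_model(
    sample_cohort(default_truth(), 10, seed = 5)
  )
  m0$knn_ref <- fit_knn_ref_for_test(ref)
  query <- c(0.6, 0.2, 0.11) # equidistant-ish; k = 4 gives a 2-2 vote
  expect_warning(res <- knn_stage(m0, query, k = 4), "tie")
  expect_identical(res$label, "late")
})

test_that("reference models round-trip through JSON", {
  truth <- default_truth()
  co <- sample_cohort(truth, 12, seed = 6)
  m <- fit_reference_model(co)
  path <- withr::local_tempfile(fileext = ".json")
  write_reference_model(m, path)
  back <- read_reference_model(path)
  expect_equal(back$support, m$support, ignore_attr = TRUE)
  expect_equal(back$frame_interval, m$frame_interval)
  expect_identical(back$cohort_hash, m$cohort_hash)
  expect_equal(likelihood(back, c(0.5, 0.3, 0.05), -4),
               likelihood(m, c(0.5, 0.3, 0.05), -4))
  other <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "something_else"), other, auto_unbox = TRUE)
  expect_error(read_reference_model(other), "not a reference-model")
})

test_that("tidy and glance summarise a reference model", {
  m <- fit_reference_model(sample_cohort(default_truth(), 10, seed = 8))
  td <- tidy(m)
  expect_identical(nrow(td), 45L) # 15 taus x 3 features
  expect_setequal(unique(td$feature),
                  c("lambda1_norm", "lambda2_norm", "skewness"))
  expect_true(all(td$variance > 0))
  g <- glance(m)
  expect_identical(nrow(g), 1L)
  expect_gte(g$n_support_frames, 150L)
})
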