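feature_cols <- c("lambda1_norm", "lambda2_norm", "skewness")

check_feature_frame <- function(features, need_tau = TRUE) {
  stopifnot(is.data.frame(features))
  need <- c(if (need_tau) "tau", feature_cols)
  miss <- setdiff(need, names(features))
  if (length(miss) > 0) {
    stop("feature table is missing columns: ", paste(miss, collapse = ", "))
  }
  invisible(features)
}

#' Fit the per-frame Gaussian reference model
#'
#' From a cohort of division-aligned trajectories (a feature table with one
#' row per cell per frame and a `tau` column counting frames before
#' division, `tau = -1` being the last pre-division frame), fits an
#' independent Gaussian per feature per `tau` over the 15-frame support
#' `tau = -15, ..., -1`: the sample mean and the population variance
#' (denominator `n`) of each of `lambda1_norm`, `lambda2_norm`,
#' `skewness`. Frames with `tau < -15` — where cell shape carries no timing
#' information — are pooled into the early-phase reference set used by the
#' k-NN gate ([knn_stage()]).
#'
#' @param features data frame with columns `cell_id`, `tau`,
#'   `lambda1_norm`, `lambda2_norm`, `skewness`.
#' @param frame_interval minutes between frames (default 2.5).
#' @return An object of class `reference_model`: per-`tau` means/variances
#'   (`support`), early-phase reference rows (`early`), the k-NN reference
#'   table, the frame interval, and a hash of the fitting cohort.
#' @export
fit_reference_model <- function(features, frame_interval = 2.5) {
  check_feature_frame(features)
  late <- dplyr::filter(features, .data$tau >= -15, .data$tau <= -1)
  counts <- table(factor(late$tau, levels = -15:-1))
  short <- names(counts)[counts < 2]
  if (length(short) > 0) {
    stop("fit_reference_model: fewer than 2 frames at tau = ",
         paste(short, collapse = ", "))
  }
  support <- late |>
    dplyr::group_by(tau = .data$tau) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(feature_cols),
                    list(mean = mean,
                         var = ~ mean((.x - mean(.x))^2)),
                    .names = "{.fn}_{.col}"),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$tau)
  vars <- as.matrix(support[, paste0("var_", feature_cols)])
  if (any(vars <= 0)) {
    bad <- support$tau[apply(vars <= 0, 1, any)]
    stop("fit_reference_model: zero variance at tau = ",
         paste(bad, collapse = ", "), " (degenerate cohort)")
  }
  early <- dplyr::filter(features, .data$tau < -15)
  knn_ref <- features |>
    dplyr::transmute(
      lambda1_norm = .data$lambda1_norm,
      lambda2_norm = .data$lambda2_norm,
      lambda3_norm = 1 - .data$lambda1_norm - .data$lambda2_norm,
      skewness = .data$skewness,
      label = ifelse(.data$tau < -15, "early", "late")
    )
  structure(
    list(
      support = support,
      early = tibble::as_tibble(early),
      knn_ref = knn_ref,
      frame_interval = frame_interval,
      cohort_hash = rlang::hash(features[order(features$cell_id, features$tau),
                                         c("cell_id", "tau", feature_cols)])
    ),
    class = "reference_model"
  )
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf(
    "<reference_model> 15 support frames (%d frames total), %d early-phase frames, interval %.1f min\n",
    sum(x$support$n), nrow(x$early), x$frame_interval
  ))
  invisible(x)
}

model_params <- function(model, tau) {
  row <- model$support[model$support$tau == tau, ]
  if (nrow(row) != 1) stop("tau = ", tau, " outside the model support (-15..-1)")
  list(mean = as.numeric(row[, paste0("mean_", feature_cols)]),
       var = as.numeric(row[, paste0("var_", feature_cols)]))
}

as_feature_vec <- function(f) {
  if (is.data.frame(f)) {
    check_feature_frame(f, need_tau = FALSE)
    stopifnot(nrow(f) == 1)
    as.numeric(f[1, feature_cols])
  } else {
    f <- as.numeric(f)
    stopifnot(length(f) == 3, all(is.finite(f)))
    f
  }
}

log_likelihood <- function(model, f, tau) {
  p <- model_params(model, tau)
  sum(stats::dnorm(as_feature_vec(f), mean = p$mean, sd = sqrt(p$var), log = TRUE))
}

#' Class-conditional likelihood of a feature vector
#'
#' The density \eqn{p_0(f \mid \tau)}: a product of three independent
#' univariate Gaussian densities with the model's mean and variance at
#' `tau`. This is a density, not a probability — it can exceed 1.
#'
#' @param model a [fit_reference_model()] fit.
#' @param f a one-row feature tibble or numeric
#'   `(lambda1_norm, lambda2_norm, skewness)`.
#' @param tau integer in -15..-1.
#' @return A strictly positive density value.
#' @export
likelihood <- function(model, f, tau) {
  exp(log_likelihood(model, f, tau))
}

#' k-NN early/late gate
#'
#' Decides whether a newly observed cell is still in the uninformative
#' early phase (`tau < -15`) or within the 15-frame window before division
#' (`tau >= -15`), by majority vote of the `k` nearest reference frames
#' under Euclidean distance on `(lambda1_norm, lambda2_norm, lambda3_norm,
#' skewness)`. Early cells are excluded from inference until they re-enter
#' as late. A tied vote resolves to `"late"` (the cell is kept under
#' observation), with a warning.
#'
#' @param model a [fit_reference_model()] fit whose cohort contained both
#'   early and late frames.
#' @param f a one-row feature tibble or numeric feature vector.
#' @param k number of neighbours (default 5; must be between 1 and the
#'   reference count).
#' @return A one-row tibble with `label` (`"early"` or `"late"`),
#'   `vote_fraction` (fraction of the k votes for the winning label) and `k`.
#' @export
knn_stage <- function(model, f, k = 5L) {
  stopifnot(inherits(model, "reference_model"))
  k <- as.integer(k)
  ref <- model$knn_ref
  if (k < 1 || k > nrow(ref)) {
    stop("knn_stage: k must be between 1 and the reference count (", nrow(ref), ")")
  }
  fv <- as_feature_vec(f)
  q <- c(fv[1], fv[2], 1 - fv[1] - fv[2], fv[3])
  dists <- sqrt((ref$lambda1_norm - q[1])^2 + (ref$lambda2_norm - q[2])^2 +
                  (ref$lambda3_norm - q[3])^2 + (ref$skewness - q[4])^2)
  nb <- ref$label[order(dists)][seq_len(k)]
  n_early <- sum(nb == "early")
  n_late <- k - n_early
  if (n_early == n_late) {
    warning("knn_stage: tied vote; resolving to 'late'")
    label <- "late"
    frac <- 0.5
  } else if (n_late > n_early) {
    label <- "late"; frac <- n_late / k
  } else {
    label <- "early"; frac <- n_early / k
  }
  tibble::tibble(label = label, vote_fraction = frac, k = k)
}

#' Serialize / load a reference model
#'
#' Versioned JSON document holding the support table, early-phase
#' references, k-NN reference table, frame interval and the fitting-cohort
#' hash, so any prediction is traceable to its training set.
#'
#' @param model a `reference_model`.
#' @param path file path.
#' @return `write_reference_model` returns `path` invisibly;
#'   `read_reference_model` returns the `reference_model`.
#' @export
write_reference_model <- function(model, path) {
  stopifnot(inherits(model, "reference_model"))
  doc <- list(
    format = "mitotimer_reference_model",
    version = 1L,
    frame_interval = model$frame_interval,
    cohort_hash = model$cohort_hash,
    support = model$support,
    early = model$early,
    knn_ref = model$knn_ref
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference_model
#' @export
read_reference_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "mitotimer_reference_model")) {
    stop("read_reference_model: not a reference-model file: ", path)
  }
  structure(
    list(
      support = tibble::as_tibble(doc$support),
      early = tibble::as_tibble(doc$early),
      knn_ref = tibble::as_tibble(doc$knn_ref),
      frame_interval = doc$frame_interval,
      cohort_hash = doc$cohort_hash
    ),
    class = "reference_model"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a reference model
#'
#' @param x a `reference_model`.
#' @param ... unused.
#' @return A tibble with one row per `tau` per feature: `tau`, `feature`,
#'   `mean`, `variance`, `sd`, `n`.
#' @method tidy reference_model
#' @export
tidy.reference_model <- function(x, ...) {
  x$support |>
    tidyr::pivot_longer(
      cols = -c("tau", "n"),
      names_to = c(".value", "feature"),
      names_pattern = "(mean|var)_(.*)"
    ) |>
    dplyr::transmute(
      tau = .data$tau, feature = .data$feature,
      mean = .data$mean, variance = .data$var, sd = sqrt(.data$var),
      n = .data$n
    )
}

#' @param x a `reference_model`.
#' @param ... unused.
#' @rdname tidy.reference_model
#' @return For `glance`, a one-row tibble summarising the fit.
#' @method glance reference_model
#' @export
glance.reference_model <- function(x, ...) {
  tibble::tibble(
    n_support_frames = sum(x$support$n),
    n_early_frames = nrow(x$early),
    frame_interval = x$frame_interval,
    cohort_hash = x$cohort_hash
  )
}
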