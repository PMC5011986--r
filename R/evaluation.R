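#' Leave-one-out cross-validation of division-timing prediction
#'
#' For each cell in the cohort: fit the reference model on every other
#' cell, run the sequential Bayesian filter and the single-frame MLE over
#' the held-out cell's frames (truncated to the informative window
#' `tau >= -15`), and record the estimate against the true `tau` at every
#' step. Aggregates per-`tau` means/SDs for both methods, the histogram of
#' integer-rounded frame deviations, and a Mann-Whitney rank-sum comparison
#' of the pooled absolute errors (Bayes vs MLE).
#'
#' @param features cohort feature table (`cell_id`, `tau`, features).
#' @param frame_interval minutes per frame.
#' @return An object of class `loocv_report`: list with `records` (one row
#'   per held-out cell per step), `per_tau`, `histogram`, `rank_sum`,
#'   `n_cells`.
#' @export
loocv <- function(features, frame_interval = 2.5) {
  check_feature_frame(features)
  stopifnot("cell_id" %in% names(features))
  cells <- unique(features$cell_id)
  if (length(cells) < 3) stop("loocv: need at least 3 cells")
  records <- purrr::map_dfr(cells, function(cid) {
    train <- dplyr::filter(features, .data$cell_id != cid)
    model <- tryCatch(
      fit_reference_model(train, frame_interval = frame_interval),
      error = function(e) {
        stop("loocv: fitting failed for fold holding out '", cid, "': ",
             conditionMessage(e), call. = FALSE)
      }
    )
    test <- features |>
      dplyr::filter(.data$cell_id == cid, .data$tau >= -15, .data$tau <= -1) |>
      dplyr::arrange(.data$tau)
    predict_division(test, model)
  })
  records <- records |>
    dplyr::mutate(
      error_bayes = .data$tau_hat_frames - .data$tau,
      error_mle = .data$mle_tau - .data$tau
    )
  new_loocv_report(records, n_cells = length(cells))
}

new_loocv_report <- function(records, n_cells) {
  per_tau <- records |>
    dplyr::group_by(tau = .data$tau) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_bayes = mean(.data$tau_hat_frames),
      sd_bayes = stats::sd(.data$tau_hat_frames),
      mean_mle = mean(.data$mle_tau),
      sd_mle = stats::sd(.data$mle_tau),
      mae_bayes = mean(abs(.data$error_bayes)),
      mae_mle = mean(abs(.data$error_mle)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$tau)
  histogram <- dplyr::bind_rows(
    tibble::tibble(method = "bayes", deviation = round(records$error_bayes)),
    tibble::tibble(method = "mle", deviation = round(records$error_mle))
  ) |>
    dplyr::count(.data$method, .data$deviation, name = "count")
  rs <- rank_sum_test(abs(records$error_bayes), abs(records$error_mle))
  structure(
    list(records = records, per_tau = per_tau, histogram = histogram,
         rank_sum = rs, n_cells = n_cells),
    class = "loocv_report"
  )
}

#' @export
print.loocv_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    paste0("<loocv_report> %d cells, %d (cell, step) records\n",
           "  Bayes MAE %.3f frames | MLE MAE %.3f frames | rank-sum p = %.3g\n"),
    x$n_cells, nrow(x$records), g$mae_bayes, g$mae_mle, g$rank_sum_p
  ))
  invisible(x)
}

#' @param x a `loocv_report`.
#' @param ... unused.
#' @return `tidy()` returns the per-`tau` aggregate table; `glance()` a
#'   one-row summary (MAE per method, fraction of final-frame predictions
#'   within one frame, rank-sum U and p).
#' @rdname loocv
#' @method tidy loocv_report
#' @export
tidy.loocv_report <- function(x, ...) x$per_tau

#' @rdname loocv
#' @method glance loocv_report
#' @export
glance.loocv_report <- function(x, ...) {
  final <- dplyr::filter(x$records, .data$tau == -1)
  tibble::tibble(
    n_cells = x$n_cells,
    n_records = nrow(x$records),
    mae_bayes = mean(abs(x$records$error_bayes)),
    mae_mle = mean(abs(x$records$error_mle)),
    final_within_1_frame = mean(abs(final$error_bayes) <= 1),
    rank_sum_U = x$rank_sum$U,
    rank_sum_p = x$rank_sum$p
  )
}

#' Group predictions by observation start frame
#'
#' Mirrors the analysis of prediction accuracy as a function of when
#' observation began: cells are grouped by the frame number of their first
#' informative frame and per-group, per-step means and SDs of the Bayes
#' estimate are reported. Cells first observed close to division have
#' fewer indistinct early frames, so their first-step estimates spread
#' less.
#'
#' @param features cohort feature table with `cell_id` and `tau` columns;
#'   a `start_tau` column is used if present, otherwise the first observed
#'   `tau >= -15` per cell.
#' @param model a [fit_reference_model()] fit used for all cells.
#' @return A tibble: `start_tau`, `step`, `n_cells`, `mean_tau_hat`,
#'   `sd_tau_hat` (NA for single-cell groups), `mean_abs_error`.
#' @export
start_point_sweep <- function(features, model) {
  check_feature_frame(features)
  stopifnot("cell_id" %in% names(features), inherits(model, "reference_model"))
  preds <- features |>
    dplyr::filter(.data$tau >= -15, .data$tau <= -1) |>
    dplyr::arrange(.data$cell_id, .data$tau) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_map(~ predict_division(.x |>
                                          dplyr::mutate(cell_id = .y$cell_id),
                                        model)) |>
    dplyr::bind_rows()
  starts <- preds |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(start_tau = min(.data$tau), .groups = "drop")
  preds |>
    dplyr::left_join(starts, by = "cell_id") |>
    dplyr::group_by(.data$start_tau, .data$step) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      mean_tau_hat = mean(.data$tau_hat_frames),
      sd_tau_hat = stats::sd(.data$tau_hat_frames),
      mean_abs_error = mean(abs(.data$tau_hat_frames - .data$tau)),
      .groups = "drop"
    )
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney U test used to compare absolute prediction
#' errors between methods. Uses exact enumeration when both samples have
#' at most 8 observations and no ties are present; otherwise the normal
#' approximation with tie correction and continuity correction. If every
#' value across both samples is identical the test is undefined and
#' `U = n1 n2 / 2`, `p = 1` is returned with a warning.
#'
#' @param errors_a,errors_b non-empty numeric vectors.
#' @return A list with `U` (for the first sample) and `p` (two-sided).
#' @export
rank_sum_test <- function(errors_a, errors_b) {
  stopifnot(length(errors_a) > 0, length(errors_b) > 0)
  n1 <- length(errors_a); n2 <- length(errors_b)
  if (length(unique(c(errors_a, errors_b))) == 1) {
    warning("rank_sum_test: all values tied across both samples; p = 1")
    return(list(U = n1 * n2 / 2, p = 1))
  }
  ties <- any(duplicated(c(errors_a, errors_b)))
  wt <- suppressWarnings(stats::wilcox.test(
    errors_a, errors_b,
    exact = (n1 <= 8 && n2 <= 8 && !ties),
    correct = TRUE
  ))
  list(U = unname(wt$statistic), p = wt$p.value)
}
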