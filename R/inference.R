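logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

new_posterior_state <- function(step, taus, probs, clamped_steps = 0L,
                                history = NULL) {
  stopifnot(length(taus) == length(probs))
  structure(
    list(step = step, taus = taus, probs = probs,
         clamped_steps = clamped_steps,
         division_imminent = clamped_steps >= 2L,
         history = history %||%
           tibble::tibble(step = integer(), tau_hat = numeric())),
    class = "posterior_state"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.posterior_state <- function(x, ...) {
  cat(sprintf("<posterior_state> step %d, support %d..%d, tau_hat = %.3f%s\n",
              x$step, min(x$taus), max(x$taus),
              sum(x$taus * x$probs),
              if (x$division_imminent) " [division imminent]" else ""))
  invisible(x)
}

#' Posterior over division timing from the first observed frame
#'
#' Applies Bayes' rule with a uniform prior \eqn{p_0(\tau) = 1/15} over the
#' 15 candidate frame numbers `tau = -15, ..., -1` (the observed cell is
#' assumed to be within 15 frames of division; earlier cells are screened
#' out by [knn_stage()]):
#' \deqn{p_0(\tau \mid f) = \frac{p_0(\tau)\, p_0(f \mid \tau)}
#'   {\sum_{\tau'} p_0(\tau')\, p_0(f \mid \tau')}.}
#' All arithmetic is done in log space; if every likelihood underflows to
#' zero the posterior falls back to uniform with a warning.
#'
#' @param model a [fit_reference_model()] fit.
#' @param f0 feature vector of the first observed frame.
#' @return A `posterior_state` at observation step 0.
#' @export
init_posterior <- function(model, f0) {
  taus <- -15:-1
  ll <- vapply(taus, function(tau) log_likelihood(model, f0, tau), numeric(1))
  lp <- ll + log(1 / 15)
  Z <- logsumexp(lp)
  if (!is.finite(Z)) {
    warning("init_posterior: all likelihoods underflowed; using uniform posterior")
    probs <- rep(1 / 15, 15)
  } else {
    probs <- exp(lp - Z)
  }
  st <- new_posterior_state(0L, taus, probs,
                            clamped_steps = as.integer(probs[15] >= 1 - 1e-6))
  record_history(st)
}

record_history <- function(state) {
  state$history <- dplyr::bind_rows(
    state$history,
    tibble::tibble(step = state$step, tau_hat = sum(state$taus * state$probs))
  )
  state
}

#' Advance the posterior one frame toward division
#'
#' The prior for observation step `s + 1` is the step-`s` posterior shifted
#' one frame toward division: a cell that was at `tau` one frame ago is now
#' at `tau + 1`, so `prior(tau) = posterior(tau - 1)` over the shrunken
#' support `{s - 14, ..., -1}`; the mass that would shift past `tau = -1`
#' (from `posterior(-1)`) is clamped onto `tau = -1` — the cell is about to
#' divide, not past the support — and the vector is renormalized.
#'
#' @param state a `posterior_state` at step `s`.
#' @return A list with `taus` (new support) and `prior` (probabilities).
#' @export
advance_prior <- function(state) {
  stopifnot(inherits(state, "posterior_state"))
  new_taus <- (state$step + 1L - 15L):-1L
  prior <- state$probs[match(new_taus - 1L, state$taus)]
  prior[length(prior)] <- prior[length(prior)] +
    state$probs[match(-1L, state$taus)]
  prior <- prior / sum(prior)
  list(taus = new_taus, prior = prior)
}

#' Sequential Bayesian update with a new frame
#'
#' Multiplies the advanced prior ([advance_prior()]) by the likelihood of
#' the newly observed feature vector and renormalizes (in log space). The
#' support shrinks by one candidate per step; once 15 frames have been
#' observed without division the support would be empty and an
#' observation-overrun error is raised.
#'
#' @param state a `posterior_state` at step `s`.
#' @param f feature vector observed at step `s + 1`.
#' @param model the [fit_reference_model()] fit.
#' @return The `posterior_state` at step `s + 1`.
#' @export
sequential_update <- function(state, f, model) {
  stopifnot(inherits(state, "posterior_state"))
  if (state$step >= 14L) {
    stop("sequential_update: observation overrun - 15 frames observed without ",
         "division; the cell should have divided")
  }
  adv <- advance_prior(state)
  ll <- vapply(adv$taus, function(tau) log_likelihood(model, f, tau), numeric(1))
  lp <- log(adv$prior) + ll
  Z <- logsumexp(lp)
  if (!is.finite(Z)) {
    warning("sequential_update: all likelihoods underflowed; keeping advanced prior")
    probs <- adv$prior
  } else {
    probs <- exp(lp - Z)
  }
  clamped <- probs[length(probs)] >= 1 - 1e-6
  st <- new_posterior_state(
    state$step + 1L, adv$taus, probs,
    clamped_steps = if (clamped) state$clamped_steps + 1L else 0L,
    history = state$history
  )
  record_history(st)
}

#' Posterior-mean estimate of the remaining time to division
#'
#' \eqn{\hat\tau = \sum_\tau \tau\, p_s(\tau \mid f(0..s))}, reported as a
#' real number of frames (negative: frames remaining) and in minutes
#' (`tau_hat * frame_interval`).
#'
#' @param state a `posterior_state`.
#' @param frame_interval minutes per frame (default 2.5).
#' @return A one-row tibble: `step`, `tau_hat_frames`, `tau_hat_minutes`,
#'   `map_tau` (posterior mode), `p_max`, `division_imminent`.
#' @export
tau_hat <- function(state, frame_interval = 2.5) {
  stopifnot(inherits(state, "posterior_state"))
  th <- sum(state$taus * state$probs)
  tibble::tibble(
    step = state$step,
    tau_hat_frames = th,
    tau_hat_minutes = th * frame_interval,
    map_tau = state$taus[which.max(state$probs)],
    p_max = max(state$probs),
    division_imminent = state$division_imminent
  )
}

#' Single-frame maximum-likelihood estimate
#'
#' `argmax` over the model support of the class-conditional likelihood of
#' one observed frame — equivalent to assigning the nearest `tau` in
#' Mahalanobis distance under the per-`tau` diagonal Gaussians. Stateless:
#' it uses no observation history. An exact tie resolves to the latest
#' `tau` (closest to division).
#'
#' @param model a [fit_reference_model()] fit.
#' @param f feature vector.
#' @return An integer `tau` in -15..-1.
#' @export
mle_estimate <- function(model, f) {
  taus <- -15:-1
  ll <- vapply(taus, function(tau) log_likelihood(model, f, tau), numeric(1))
  best <- which(ll == max(ll))
  as.integer(taus[max(best)]) # tie -> latest tau
}

#' Predict division timing over a trajectory
#'
#' Runs the sequential Bayesian filter over a cell's observed frames (in
#' order), together with the stateless MLE baseline, and returns one row
#' per observation step. Input frames are used as given: apply the k-NN
#' gate ([knn_stage()]) beforehand to drop early-phase frames.
#'
#' @param features data frame of one cell's frames in observation order,
#'   with the three feature columns (and optionally `cell_id`, `tau`).
#' @param model a [fit_reference_model()] fit.
#' @return A tibble with one row per step: `cell_id`, `step`, `tau` (true,
#'   if present in the input), `tau_hat_frames`, `tau_hat_minutes`,
#'   `mle_tau`, `division_imminent`.
#' @export
predict_division <- function(features, model) {
  check_feature_frame(features, need_tau = FALSE)
  stopifnot(inherits(model, "reference_model"), nrow(features) >= 1)
  if (nrow(features) > 15) {
    stop("predict_division: more than 15 frames observed without division")
  }
  cell_id <- if ("cell_id" %in% names(features)) features$cell_id[1] else NA_character_
  out <- vector("list", nrow(features))
  state <- NULL
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    state <- if (i == 1) init_posterior(model, f)
             else sequential_update(state, f, model)
    row <- tau_hat(state, frame_interval = model$frame_interval)
    row$cell_id <- cell_id
    row$tau <- if ("tau" %in% names(features)) features$tau[i] else NA_integer_
    row$mle_tau <- mle_estimate(model, f)
    out[[i]] <- row
  }
  dplyr::bind_rows(out) |>
    dplyr::select("cell_id", "step", "tau", "tau_hat_frames",
                  "tau_hat_minutes", "mle_tau", "p_max", "division_imminent")
}
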