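# Shared fixtures and independent oracles.

# voxel_grid from a matrix of 1-based (z, y, x) indices
make_grid <- function(idx, dim = c(10, 10, 10), spacing = c(1, 1, 1)) {
  mask <- array(FALSE, dim = dim)
  mask[as.matrix(idx)] <- TRUE
  voxel_grid(mask, spacing = spacing)
}

# Oracle: naive double-loop central second moments over occupied voxels
naive_moment <- function(grid) {
  idx <- which(grid$mask, arr.ind = TRUE)
  sp <- grid$spacing
  pts <- cbind((idx[, 3] - 0.5) * sp["x"],
               (idx[, 2] - 0.5) * sp["y"],
               (idx[, 1] - 0.5) * sp["z"])
  n <- nrow(pts)
  ctr <- colMeans(pts)
  M <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    for (p in 1:3) for (q in 1:3) {
      M[p, q] <- M[p, q] + (pts[i, p] - ctr[p]) * (pts[i, q] - ctr[q])
    }
  }
  M / n
}

# Hand-built reference model with prescribed per-tau means and variances
# (15 x 3 matrices, rows tau = -15..-1, columns lambda1, lambda2, skewness)
make_model <- function(means, vars, frame_interval = 2.5) {
  stopifnot(all(dim(means) == c(15, 3)), all(dim(vars) == c(15, 3)))
  support <- tibble::tibble(
    tau = -15:-1,
    mean_lambda1_norm = means[, 1], var_lambda1_norm = vars[, 1],
    mean_lambda2_norm = means[, 2], var_lambda2_norm = vars[, 2],
    mean_skewness = means[, 3], var_skewness = vars[, 3],
    n = 2L
  )
  structure(
    list(support = support, early = tibble::tibble(),
         knn_ref = tibble::tibble(), frame_interval = frame_interval,
         cohort_hash = "hand-built"),
    class = "reference_model"
  )
}

# A model whose per-tau means are well separated along lambda1
separated_model <- function(sd = 0.005) {
  means <- cbind(seq(0.9, 0.2, length.out = 15), rep(0.05, 15),
                 seq(0.3, 0.01, length.out = 15))
  make_model(means, matrix(sd^2, 15, 3))
}

# Oracle: posterior by direct summation over all division-timing paths.
# The time evolution is the deterministic one-frame shift clamped at -1,
# so each starting tau0 determines the whole path; weights are
# prior0(tau0) * prod_s p(f_s | min(tau0 + s, -1)), aggregated on the
# final tau and normalized.
enum_posterior <- function(model, fs, prior0 = rep(1 / 15, 15)) {
  taus0 <- -15:-1
  S <- length(fs) - 1
  final_tau <- pmin(taus0 + S, -1)
  w <- vapply(seq_along(taus0), function(i) {
    lw <- log(prior0[i])
    for (s in 0:S) {
      tau_s <- min(taus0[i] + s, -1)
      lw <- lw + log(likelihood(model, fs[[s + 1]], tau_s))
    }
    exp(lw)
  }, numeric(1))
  support <- sort(unique(final_tau))
  probs <- vapply(support, function(tau) sum(w[final_tau == tau]), numeric(1))
  list(taus = support, probs = probs / sum(probs))
}

# The 24 orientation-preserving symmetries of the cube, as signed
# permutation matrices acting on (z, y, x) offsets from the array centre
cubic_rotations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) {
    P0 <- diag(3)[p, ]
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      R <- diag(c(s1, s2, s3)) %*% P0
      if (abs(det(R) - 1) < 1e-9) out[[length(out) + 1]] <- R
    }
  }
  out
}

# Apply a cubic rotation to a cubic mask (indices mapped about the centre)
rotate_mask <- function(mask, R) {
  d <- dim(mask)
  stopifnot(length(unique(d)) == 1)
  ctr <- (d + 1) / 2
  idx <- which(mask, arr.ind = TRUE)
  new_idx <- t(R %*% t(sweep(idx, 2, ctr))) + rep(ctr, each = nrow(idx))
  out <- array(FALSE, dim = d)
  out[round(new_idx)] <- TRUE
  out
}

truth_params_for_test <- function(truth, tau) {
  row <- truth$support[truth$support$tau == tau, ]
  list(mean = c(row$mean_lambda1, row$mean_lambda2, row$mean_skewness),
       sd = c(row$sd_lambda1, row$sd_lambda2, row$sd_skewness))
}

fit_knn_ref_for_test <- function(df) {
  tibble::tibble(
    lambda1_norm = df$lambda1_norm,
    lambda2_norm = df$lambda2_norm,
    lambda3_norm = 1 - df$lambda1_norm - df$lambda2_norm,
    skewness = df$skewness,
    label = ifelse(df$tau < -15, "early", "late")
  )
}
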