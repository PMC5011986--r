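#' Central second-moment tensor of a voxel mask
#'
#' Computes the 3 x 3 matrix of mean-centred second moments over the
#' physical centres of the occupied voxels,
#' \deqn{M_{pq} = \frac{1}{N}\sum_i (p_i - \bar p)(q_i - \bar q), \quad
#'   p, q \in \{x, y, z\},}
#' in squared micrometres. Using physical (anisotropically spaced)
#' coordinates makes the descriptor independent of how the cell happens to
#' be oriented relative to the imaging axes. Central moments are invariant
#' under translation of the mask by construction.
#'
#' @param grid a [voxel_grid()] with at least 2 occupied voxels.
#' @return An object of class `moment_tensor`: a list with `M` (3 x 3
#'   symmetric matrix, um^2), `n_voxels`, and `centroid` (um).
#' @export
moment_tensor <- function(grid) {
  xyz <- voxel_coordinates(grid)
  n <- nrow(xyz)
  if (n == 0) stop("moment_tensor: empty mask")
  if (n == 1) stop("moment_tensor: single-voxel mask has a degenerate (all-zero) tensor")
  ctr <- colMeans(xyz)
  cc <- sweep(xyz, 2, ctr)
  M <- crossprod(cc) / n
  dimnames(M) <- list(c("x", "y", "z"), c("x", "y", "z"))
  structure(list(M = M, n_voxels = n, centroid = ctr), class = "moment_tensor")
}

#' @export
print.moment_tensor <- function(x, ...) {
  cat(sprintf("<moment_tensor> N = %d voxels, centroid (%.2f, %.2f, %.2f) um\n",
              x$n_voxels, x$centroid[1], x$centroid[2], x$centroid[3]))
  print(round(x$M, 4))
  invisible(x)
}

as_moment_matrix <- function(M) {
  if (inherits(M, "moment_tensor")) M <- M$M
  stopifnot(is.matrix(M), all(dim(M) == c(3, 3)))
  M
}

#' Normalized eigenvalues of the moment tensor
#'
#' Eigenvalues of the second-moment tensor sorted in descending order and
#' divided by their sum, so the triple lies on the simplex
#' \eqn{\tilde\lambda_1 + \tilde\lambda_2 + \tilde\lambda_3 = 1} and is
#' invariant under rotation, translation and uniform scaling of the shape.
#' A sphere gives (1/3, 1/3, 1/3); elongation pushes
#' \eqn{\tilde\lambda_1} toward 1.
#'
#' @param M a `moment_tensor` or a symmetric positive semi-definite 3 x 3
#'   matrix with positive trace.
#' @return Named numeric vector `(lambda1_norm, lambda2_norm, lambda3_norm)`.
#' @export
eigen_features <- function(M) {
  M <- as_moment_matrix(M)
  tr <- sum(diag(M))
  if (tr <= 0) stop("eigen_features: zero-trace tensor (degenerate shape)")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values # descending
  ev <- pmax(ev, 0)
  out <- ev / sum(ev)
  names(out) <- c("lambda1_norm", "lambda2_norm", "lambda3_norm")
  out
}

#' Shape skewness
#'
#' Quantifies asymmetric elongation (e.g. the teardrop shape of a cell
#' anchored by a process) as \eqn{A = d / v^{1/3}}, where `v` is the mask
#' volume and `d` the distance between the centre of mass and the geometric
#' centre of the shape — the midpoint of the occupied extent along each
#' principal axis of the moment tensor, mapped back to world coordinates.
#' Normalizing `d` by the cube root of the volume makes `A` dimensionless
#' and scale-invariant; a point-symmetric solid (ellipsoid, sphere) has
#' `A = 0` up to voxelization error.
#'
#' @param grid a [voxel_grid()] with a non-degenerate mask.
#' @return A list with `A` (dimensionless), `d` (um), `v` (um^3),
#'   `center_mass` and `center_geom` (um).
#' @export
skewness <- function(grid) {
  mt <- moment_tensor(grid)
  xyz <- voxel_coordinates(grid)
  v <- mt$n_voxels * prod(grid$spacing)
  E <- eigen(mt$M, symmetric = TRUE)$vectors # columns: principal axes
  q <- xyz %*% E                             # principal-frame coordinates
  mid <- (apply(q, 2, min) + apply(q, 2, max)) / 2
  center_geom <- as.numeric(E %*% mid)
  names(center_geom) <- c("x", "y", "z")
  d <- sqrt(sum((center_geom - mt$centroid)^2))
  list(A = d / v^(1 / 3), d = d, v = v,
       center_mass = mt$centroid, center_geom = center_geom)
}

#' Shape feature vector of a cell mask
#'
#' Assembles the per-frame shape descriptor used for division-timing
#' prediction: the first two normalized moment eigenvalues and the
#' skewness, `(lambda1_norm, lambda2_norm, A)`, with provenance fields
#' (third eigenvalue, raw eigenvalues, volume, centre offset, voxel count)
#' retained for logging.
#'
#' @param grid a [voxel_grid()] with a non-degenerate mask.
#' @return A one-row tibble with columns `lambda1_norm`, `lambda2_norm`,
#'   `skewness`, `lambda3_norm`, `lambda1`, `lambda2`, `lambda3` (um^2),
#'   `volume_um3`, `d_um`, `n_voxels`.
#' @export
feature_vector <- function(grid) {
  mt <- moment_tensor(grid)
  tr <- sum(diag(mt$M))
  if (tr <= 0) stop("feature_vector: degenerate mask (zero-trace moment tensor)")
  raw <- pmax(eigen(mt$M, symmetric = TRUE, only.values = TRUE)$values, 0)
  lam <- raw / sum(raw)
  sk <- skewness(grid)
  tibble::tibble(
    lambda1_norm = lam[1], lambda2_norm = lam[2], skewness = sk$A,
    lambda3_norm = lam[3],
    lambda1 = raw[1], lambda2 = raw[2], lambda3 = raw[3],
    volume_um3 = sk$v, d_um = sk$d, n_voxels = mt$n_voxels
  )
}

feature_triple <- function(f) {
  if (is.data.frame(f)) {
    stopifnot(nrow(f) == 1)
    l1 <- f$lambda1_norm; l2 <- f$lambda2_norm
    l3 <- if ("lambda3_norm" %in% names(f)) f$lambda3_norm else 1 - l1 - l2
  } else {
    f <- as.numeric(f)
    if (length(f) == 2) f <- c(f, 1 - sum(f))
    stopifnot(length(f) >= 3)
    l1 <- f[1]; l2 <- f[2]; l3 <- f[3]
  }
  c(l1, l2, l3)
}

#' Distance between two shape-feature vectors
#'
#' Euclidean distance on the full normalized-eigenvalue triple
#' `(lambda1_norm, lambda2_norm, lambda3_norm)`. Symmetric, non-negative,
#' zero iff the triples are equal. Used by the k-NN early/late gate.
#'
#' @param f,g one-row feature tibbles (see [feature_vector()]) or numeric
#'   vectors `(lambda1_norm, lambda2_norm[, lambda3_norm])`.
#' @return A non-negative number.
#' @export
feature_distance <- function(f, g) {
  sqrt(sum((feature_triple(f) - feature_triple(g))^2))
}
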