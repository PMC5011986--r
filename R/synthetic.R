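# Seed handling: run code under a temporary RNG state so sampling is
# reproducible given `seed` without clobbering the caller's RNG.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Per-cell seed derived from the cohort seed and cell index by a fixed
# multiplicative hash, so cell i's trajectory is stable under changes of
# n_cells. Kept below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(index) * 7919) %% 2147483647)
}

#' Ground-truth per-frame feature distributions for simulation
#'
#' A `trajectory_truth` object holds, for every frame number
#' `tau` in -15..-1 (frames remaining before division; one frame = 2.5 min),
#' the true mean and standard deviation of each shape feature
#' `(lambda1_norm, lambda2_norm, skewness)`, plus a pooled "early" phase
#' (`tau < -15`) distribution in which cell shape is assumed stationary.
#'
#' `default_truth()` returns a fixed, documented table that emulates the
#' stereotyped geometry of mitotic rounding: cells are elongated and
#' asymmetric early (`lambda1_norm` around 0.62, skewness around 0.12) and
#' drift smoothly toward the rounded, symmetric point
#' `(1/3, 1/3, 0)` at `tau = -1`, with the drift accelerating over the last
#' few frames. With `u = (-tau - 1)/14` scaled to `[0, 1]`:
#' \deqn{\mu_{\lambda_1}(\tau) = 0.35 + 0.27 u^{0.8}, \quad
#'   \mu_{\lambda_2}(\tau) = 0.325 - 0.085 u^{0.8}, \quad
#'   \mu_A(\tau) = 0.01 + 0.11 u,}
#' with constant per-feature standard deviations (0.02, 0.015, 0.02) —
#' per-frame mean steps of order one standard deviation, so neighbouring
#' frames overlap but are statistically distinguishable. The stationary
#' early phase sits just beyond the `tau = -15` distribution (means
#' 0.66/0.215/0.16, SDs 0.03/0.02/0.03): cells earlier than 15 frames
#' from division look alike, and are distinguishable from — though
#' overlapping with — the start of the informative window.
#'
#' @param seed integer; accepted for interface symmetry with the samplers —
#'   the default table is fixed and does not depend on it.
#' @return A `trajectory_truth`: list with `support` (tibble: `tau`,
#'   `mean_*`, `sd_*` for the three features), `early` (named means/sds),
#'   and `frame_interval` (minutes, 2.5).
#' @export
default_truth <- function(seed = 0L) {
  tau <- -15:-1
  u <- (-tau - 1) / 14
  support <- tibble::tibble(
    tau = tau,
    mean_lambda1 = 0.35 + 0.27 * u^0.8,
    mean_lambda2 = 0.325 - 0.085 * u^0.8,
    mean_skewness = 0.01 + 0.11 * u,
    sd_lambda1 = 0.02,
    sd_lambda2 = 0.015,
    sd_skewness = 0.02
  )
  truth <- structure(
    list(
      support = support,
      early = c(mean_lambda1 = 0.66, mean_lambda2 = 0.215,
                mean_skewness = 0.16,
                sd_lambda1 = 0.03, sd_lambda2 = 0.02, sd_skewness = 0.03),
      frame_interval = 2.5
    ),
    class = "trajectory_truth"
  )
  validate_truth(truth)
  truth
}

validate_truth <- function(truth) {
  s <- truth$support
  stopifnot(
    identical(as.integer(s$tau), -15:-1),
    all(s$mean_lambda1 >= s$mean_lambda2), all(s$mean_lambda2 >= 0),
    all(s$mean_lambda1 + s$mean_lambda2 <= 1),
    all(s[, c("sd_lambda1", "sd_lambda2", "sd_skewness")] > 0),
    truth$frame_interval > 0
  )
  d_at <- function(row) {
    sqrt((row$mean_lambda1 - 1 / 3)^2 + (row$mean_lambda2 - 1 / 3)^2 +
           row$mean_skewness^2)
  }
  if (d_at(s[s$tau == -1, ]) >= d_at(s[s$tau == -15, ])) {
    stop("trajectory_truth: tau = -1 mean must be closer to the rounded point than tau = -15")
  }
  invisible(truth)
}

#' @export
print.trajectory_truth <- function(x, ...) {
  cat(sprintf("<trajectory_truth> 15 support frames + early phase, interval %.1f min\n",
              x$frame_interval))
  print(x$support, n = 5)
  invisible(x)
}

truth_params <- function(truth, tau) {
  if (tau >= -15) {
    row <- truth$support[truth$support$tau == tau, ]
    list(mean = c(row$mean_lambda1, row$mean_lambda2, row$mean_skewness),
         sd = c(row$sd_lambda1, row$sd_lambda2, row$sd_skewness))
  } else {
    e <- truth$early
    list(mean = e[c("mean_lambda1", "mean_lambda2", "mean_skewness")],
         sd = e[c("sd_lambda1", "sd_lambda2", "sd_skewness")])
  }
}

in_feature_region <- function(f) {
  f[1] >= f[2] && f[2] >= 0 && f[1] + f[2] <= 1 && f[3] >= 0
}

#' Sample one division-aligned cell trajectory
#'
#' Draws per-frame feature vectors independently from the per-`tau`
#' Gaussians of `truth`, for frames `tau = start_tau, ..., -1` (frames
#' before -15 use the pooled early-phase distribution). Draws falling
#' outside the valid feature region (`lambda1 >= lambda2 >= 0`,
#' `lambda1 + lambda2 <= 1`, `skewness >= 0`) are rejected and redrawn, so
#' no probability mass piles up on the boundary.
#'
#' @param truth a `trajectory_truth`.
#' @param start_tau integer <= -1; first observed frame number.
#' @param seed integer RNG seed; identical seeds give identical tables.
#' @param cell_id identifier stored in the `cell_id` column.
#' @return A tibble with one row per frame: `cell_id`, `frame_index`
#'   (1-based observation order), `tau`, `lambda1_norm`, `lambda2_norm`,
#'   `skewness`.
#' @export
sample_trajectory <- function(truth, start_tau, seed = 0L, cell_id = "cell") {
  stopifnot(inherits(truth, "trajectory_truth"))
  start_tau <- as.integer(start_tau)
  if (start_tau >= 0) stop("sample_trajectory: start_tau must be <= -1")
  taus <- start_tau:-1
  with_local_seed(seed, {
    feats <- vapply(taus, function(tau) {
      p <- truth_params(truth, tau)
      for (try in 1:10000) {
        f <- stats::rnorm(3, mean = p$mean, sd = p$sd)
        if (in_feature_region(f)) return(f)
      }
      stop("sample_trajectory: rejection sampling failed at tau = ", tau)
    }, numeric(3))
    tibble::tibble(
      cell_id = cell_id,
      frame_index = seq_along(taus),
      tau = taus,
      lambda1_norm = feats[1, ],
      lambda2_norm = feats[2, ],
      skewness = feats[3, ]
    )
  })
}

#' Sample a cohort of cell trajectories
#'
#' Generates `n_cells` trajectories with starting frames drawn uniformly
#' from `start_tau_range` (inclusive). Per-cell seeds are derived from the
#' cohort seed and the cell index by a fixed hash, so cell `i` is identical
#' across runs regardless of `n_cells`. The default cohort size of 39
#' matches the size of a typical training cohort of tracked cells.
#'
#' @param truth a `trajectory_truth`.
#' @param n_cells number of cells (>= 1).
#' @param start_tau_range integer pair `(lo, hi)`, `lo <= hi <= -1`.
#' @param seed cohort RNG seed.
#' @return A tibble of stacked trajectories (see [sample_trajectory()])
#'   with an additional `start_tau` column.
#' @export
sample_cohort <- function(truth, n_cells = 39L,
                          start_tau_range = c(-20L, -15L), seed = 0L) {
  stopifnot(inherits(truth, "trajectory_truth"))
  n_cells <- as.integer(n_cells)
  if (n_cells < 1) stop("sample_cohort: n_cells must be >= 1")
  lo <- as.integer(start_tau_range[1]); hi <- as.integer(start_tau_range[2])
  if (length(start_tau_range) != 2 || lo > hi || hi > -1) {
    stop("sample_cohort: start_tau_range must be an integer pair lo <= hi <= -1")
  }
  starts <- with_local_seed(seed, sample(lo:hi, n_cells, replace = TRUE))
  purrr::map2_dfr(seq_len(n_cells), starts, function(i, st) {
    tr <- sample_trajectory(truth, start_tau = st,
                            seed = derive_seed(seed, i),
                            cell_id = sprintf("cell%03d", i))
    tr$start_tau <- st
    tr
  })
}

#' Write / read a truth table
#'
#' Serializes a `trajectory_truth` as plain CSV: one row per support frame
#' plus one `phase = "early"` row, columns `phase`, `tau`, `mean_*`, `sd_*`,
#' `frame_interval`. A run is fully reproducible from this file plus seeds.
#'
#' @param truth a `trajectory_truth`.
#' @param path file path.
#' @return `write_truth` returns `path` invisibly; `read_truth` returns a
#'   `trajectory_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "trajectory_truth"))
  sup <- truth$support
  sup$phase <- "support"
  early <- tibble::as_tibble(as.list(truth$early))
  early$phase <- "early"
  early$tau <- NA_integer_
  out <- dplyr::bind_rows(sup, early)
  out$frame_interval <- truth$frame_interval
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path)
  sup <- df[df$phase == "support",
            c("tau", "mean_lambda1", "mean_lambda2", "mean_skewness",
              "sd_lambda1", "sd_lambda2", "sd_skewness")]
  sup <- tibble::as_tibble(sup[order(sup$tau), ])
  er <- df[df$phase == "early", ]
  truth <- structure(
    list(
      support = sup,
      early = c(mean_lambda1 = er$mean_lambda1, mean_lambda2 = er$mean_lambda2,
                mean_skewness = er$mean_skewness, sd_lambda1 = er$sd_lambda1,
                sd_lambda2 = er$sd_lambda2, sd_skewness = er$sd_skewness),
      frame_interval = df$frame_interval[1]
    ),
    class = "trajectory_truth"
  )
  validate_truth(truth)
  truth
}

#' Voxel phantom specification
#'
#' Describes a solid ellipsoid, optionally tapered into a teardrop, to be
#' rendered onto a voxel grid as a stand-in for a binarized cell mask. The
#' taper multiplies the cross-sectional semi-axes `b`, `c` by a factor
#' falling linearly from 1 at one end of the long axis to `1 - skew` at the
#' other, so `skew = 0` is a plain ellipsoid and `skew > 0` shifts the
#' centre of mass toward the wide end (positive shape skewness).
#'
#' @param a,b,c semi-axes in um, `a >= b >= c > 0` (`a` is the long axis).
#' @param skew dimensionless taper fraction in `[0, 1)`.
#' @param angles Euler angles (radians), intrinsic Z-Y-X rotation.
#' @param translation length-3 `(x, y, z)` offset of the phantom centre
#'   from the grid centre, um.
#' @param grid_shape integer length-3 `(nz, ny, nx)` voxel grid size.
#' @param spacing voxel spacing `(dx, dy, dz)` um.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(a, b, c, skew = 0, angles = c(0, 0, 0),
                         translation = c(0, 0, 0),
                         grid_shape = c(64L, 64L, 64L),
                         spacing = c(0.5, 0.5, 0.5)) {
  stopifnot(a > 0, b > 0, c > 0, a >= b, b >= c,
            skew >= 0, skew < 1,
            length(angles) == 3, length(translation) == 3,
            length(grid_shape) == 3, all(grid_shape >= 1))
  structure(
    list(a = a, b = b, c = c, skew = skew, angles = as.numeric(angles),
         translation = as.numeric(translation),
         grid_shape = as.integer(grid_shape),
         spacing = check_spacing(spacing)),
    class = "phantom_spec"
  )
}

euler_rotation <- function(angles) {
  cz <- cos(angles[1]); sz <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cx <- cos(angles[3]); sx <- sin(angles[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Render a phantom onto a voxel grid
#'
#' A voxel is occupied iff its physical centre lies inside the (tapered,
#' rotated, translated) solid. The solid must fit entirely inside the grid:
#' rendering a clipped phantom would silently bias the moment tensor, so it
#' is an error, checked analytically against the bounding ellipsoid's
#' support along each axis.
#'
#' @param spec a [phantom_spec()].
#' @return A [voxel_grid()].
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$spacing
  extent <- c(d[3] * sp["x"], d[2] * sp["y"], d[1] * sp["z"])
  center <- extent / 2 + spec$translation
  R <- euler_rotation(spec$angles)

  # clipping check: support of the bounding ellipsoid along each world axis
  Ax <- R %*% diag(c(spec$a, spec$b, spec$c))
  support <- sqrt(rowSums(Ax^2))
  if (any(center - support < 0) || any(center + support > extent)) {
    stop("render_phantom: phantom clipped by the grid boundary ",
         "(enlarge grid_shape or reduce translation)")
  }

  xs <- (seq_len(d[3]) - 0.5) * sp["x"]
  ys <- (seq_len(d[2]) - 0.5) * sp["y"]
  zs <- (seq_len(d[1]) - 0.5) * sp["z"]
  pts <- cbind(
    x = rep(xs, each = d[1] * d[2]),
    y = rep(rep(ys, each = d[1]), times = d[3]),
    z = rep(zs, times = d[2] * d[3])
  ) # column-major over (z, y, x) array order
  local <- sweep(pts, 2, center) %*% R # rows: (u, v, w) body coordinates
  u <- local[, 1]
  taper <- 1 - spec$skew * (u / spec$a + 1) / 2
  inside <- taper > 0 &
    (u / spec$a)^2 +
    (local[, 2] / (spec$b * taper))^2 +
    (local[, 3] / (spec$c * taper))^2 <= 1
  voxel_grid(array(inside, dim = d), spacing = sp)
}
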