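#' 3D median filter
#'
#' Replaces every voxel by the median intensity within a spherical
#' neighbourhood of the given radius, measured in voxel units (the ImageJ
#' "radius" convention: offsets with squared Euclidean norm at most
#' `radius^2` are included). Edges are handled by nearest-value padding.
#' `radius = 0` is the identity.
#'
#' @param stack an [image_stack()].
#' @param radius non-negative integer radius in voxels (default 2, the value
#'   used for denoising confocal stacks before binarization).
#' @param shape `"ball"` (default) or `"cube"` structuring element.
#' @return A filtered [image_stack()].
#' @export
median_filter_3d <- function(stack, radius = 2L, shape = c("ball", "cube")) {
  stopifnot(inherits(stack, "image_stack"))
  shape <- match.arg(shape)
  radius <- as.integer(radius)
  if (radius < 0) stop("median_filter_3d: radius must be >= 0")
  if (radius == 0) return(stack)

  off <- as.matrix(expand.grid(
    dz = -radius:radius, dy = -radius:radius, dx = -radius:radius
  ))
  if (shape == "ball") {
    off <- off[rowSums(off^2) <= radius^2, , drop = FALSE]
  }
  d <- dim(stack$data)
  zs <- seq_len(d[1]); ys <- seq_len(d[2]); xs <- seq_len(d[3])
  vals <- matrix(0, nrow = prod(d), ncol = nrow(off))
  for (m in seq_len(nrow(off))) {
    iz <- pmin(pmax(zs + off[m, "dz"], 1L), d[1])
    iy <- pmin(pmax(ys + off[m, "dy"], 1L), d[2])
    ix <- pmin(pmax(xs + off[m, "dx"], 1L), d[3])
    vals[, m] <- stack$data[iz, iy, ix]
  }
  med <- apply(vals, 1, stats::median)
  image_stack(array(med, dim = d), spacing = stack$spacing,
              bit_depth = stack$bit_depth)
}

#' Crop a region of interest from a stack
#'
#' Extracts a sub-stack of exactly `size_voxels` centred on `center_voxel`.
#' The ROI must lie entirely inside the stack: no silent padding, an
#' out-of-bounds request is an error. Spacing is preserved.
#'
#' @param stack an [image_stack()].
#' @param center_voxel integer length-3 `(z, y, x)` voxel index of the ROI
#'   centre (1-based).
#' @param size_voxels integer length-3 `(z, y, x)` ROI size; default the
#'   45 x 45 x 45 single-cell ROI.
#' @return An [image_stack()] of the requested size.
#' @export
crop_roi <- function(stack, center_voxel, size_voxels = c(45L, 45L, 45L)) {
  stopifnot(inherits(stack, "image_stack"))
  center_voxel <- as.integer(center_voxel)
  size_voxels <- as.integer(size_voxels)
  if (length(center_voxel) != 3 || length(size_voxels) != 3 ||
      any(size_voxels < 1)) {
    stop("crop_roi: center_voxel and size_voxels must be positive length-3 (z, y, x)")
  }
  d <- dim(stack$data)
  lo <- center_voxel - (size_voxels - 1L) %/% 2L
  hi <- lo + size_voxels - 1L
  if (any(lo < 1L) || any(hi > d)) {
    stop(sprintf(
      "crop_roi: ROI [%s]..[%s] exceeds stack bounds [%s]",
      paste(lo, collapse = ","), paste(hi, collapse = ","),
      paste(d, collapse = ",")
    ))
  }
  image_stack(
    stack$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
    spacing = stack$spacing, bit_depth = stack$bit_depth
  )
}

#' Threshold binarization
#'
#' A voxel is occupied iff its intensity is at least `threshold`. The same
#' threshold chosen on the first frame of a cell's time series is intended
#' to be reused for every subsequent frame of that cell. An empty result is
#' an error, because shape features are undefined for an empty mask.
#'
#' @param stack an [image_stack()].
#' @param threshold numeric threshold on the intensity scale of the stack.
#' @return A [voxel_grid()].
#' @export
binarize <- function(stack, threshold) {
  stopifnot(inherits(stack, "image_stack"), is.numeric(threshold))
  mask <- stack$data >= threshold
  if (!any(mask)) {
    stop("binarize: threshold ", threshold, " yields an empty mask")
  }
  voxel_grid(mask, spacing = stack$spacing)
}

#' Otsu threshold (convenience initializer)
#'
#' Maximizes between-class variance on a 256-bin intensity histogram. This
#' is offered only as a starting point for choosing a per-cell threshold;
#' the reference workflow uses a manually chosen threshold held fixed over
#' the cell's time series.
#'
#' @param stack an [image_stack()].
#' @return A numeric threshold.
#' @export
otsu_threshold <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  v <- as.integer(round(pmin(pmax(stack$data, 0), 255)))
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  which.max(sigma_b) - 1L + 1L # threshold applied as >=, so one above the split
}

#' Keep only the largest connected component
#'
#' Removes background specks and fragments of neighbouring cells from a
#' binarized mask by retaining the connected component with the most voxels
#' (the target cell dominates the ROI by construction). A tie for largest is
#' resolved deterministically toward the component containing the smallest
#' linear voxel index, with a warning.
#'
#' @param grid a non-empty [voxel_grid()].
#' @param connectivity 6 (face) or 26 (face+edge+corner, default)
#'   neighbourhood.
#' @return A [voxel_grid()] containing a single connected component.
#' @export
keep_largest_component <- function(grid, connectivity = 26L) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!any(grid$mask)) stop("keep_largest_component: empty mask")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) {
    stop("keep_largest_component: connectivity must be 6 or 26")
  }
  d <- dim(grid$mask)
  lin <- which(grid$mask)
  n <- length(lin)
  id <- array(0L, dim = d)
  id[lin] <- seq_len(n)
  idx <- which(grid$mask, arr.ind = TRUE) # z, y, x

  if (connectivity == 6L) {
    half <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    half <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    half <- half[rowSums(half != 0) > 0, , drop = FALSE]
    # keep one of each +/- pair
    key <- half[, 1] * 9 + half[, 2] * 3 + half[, 3]
    half <- half[key > 0, , drop = FALSE]
  }

  from <- integer(0); to <- integer(0)
  for (m in seq_len(nrow(half))) {
    nz <- idx[, 1] + half[m, 1]
    ny <- idx[, 2] + half[m, 2]
    nx <- idx[, 3] + half[m, 3]
    ok <- nz >= 1 & nz <= d[1] & ny >= 1 & ny <= d[2] & nx >= 1 & nx <= d[3]
    if (!any(ok)) next
    nb <- id[cbind(nz[ok], ny[ok], nx[ok])]
    hit <- nb > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, nb[hit])
  }

  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # tie: component containing the smallest linear voxel index wins
    first_lin <- vapply(best, function(cid) min(lin[comp$membership == cid]),
                        numeric(1))
    best <- best[which.min(first_lin)]
    warning("keep_largest_component: tie for largest component; ",
            "kept the one containing the smallest voxel index")
  }
  mask <- array(FALSE, dim = d)
  mask[lin[comp$membership == best]] <- TRUE
  voxel_grid(mask, spacing = grid$spacing)
}
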