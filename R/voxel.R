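#' Image stack and voxel grid containers
#'
#' `image_stack()` wraps a 3D scalar intensity array in `(z, y, x)` order
#' together with its physical voxel spacing; `voxel_grid()` wraps a 3D logical
#' occupancy array (the binarized cell mask) with the same spacing convention.
#' Voxel indices are 0-based in physical-coordinate formulas: the centre of
#' voxel `(i, j, k)` (z, y, x) sits at `((k + 0.5) dx, (j + 0.5) dy,
#' (i + 0.5) dz)` micrometres.
#'
#' @param data numeric 3D array, dimensions `(nz, ny, nx)`, non-negative.
#' @param spacing numeric length-3 vector `(dx, dy, dz)` in micrometres,
#'   strictly positive. Defaults to the confocal calibration used throughout:
#'   0.516 um in x/y and 0.775 um optical slice thickness in z.
#' @param bit_depth integer, 8 or 16.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, spacing = default_spacing(), bit_depth = 8L) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- check_spacing(spacing)
  if (any(data < 0)) stop("image_stack: intensities must be non-negative")
  structure(
    list(data = data, spacing = spacing, bit_depth = as.integer(bit_depth)),
    class = "image_stack"
  )
}

#' @param mask logical 3D array, dimensions `(nz, ny, nx)`.
#' @rdname image_stack
#' @export
voxel_grid <- function(mask, spacing = default_spacing()) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  spacing <- check_spacing(spacing)
  mask <- array(as.logical(mask), dim = dim(mask))
  structure(list(mask = mask, spacing = spacing), class = "voxel_grid")
}

#' Default physical voxel spacing (um)
#'
#' The acquisition calibration assumed when none is given: 0.516 um pixels in
#' x and y, 0.775 um optical slices in z.
#' @return Named numeric vector `c(x, y, z)`.
#' @export
default_spacing <- function() c(x = 0.516, y = 0.516, z = 0.775)

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 strictly positive numbers (dx, dy, dz) in um")
  }
  names(spacing) <- c("x", "y", "z")
  spacing
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %d x %d x %d (z,y,x), %d-bit, spacing %.3f/%.3f/%.3f um\n",
    d[1], d[2], d[3], x$bit_depth, x$spacing["x"], x$spacing["y"], x$spacing["z"]
  ))
  invisible(x)
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf(
    "<voxel_grid> %d x %d x %d (z,y,x), %d occupied, spacing %.3f/%.3f/%.3f um\n",
    d[1], d[2], d[3], sum(x$mask), x$spacing["x"], x$spacing["y"], x$spacing["z"]
  ))
  invisible(x)
}

#' Physical centre coordinates of occupied voxels
#'
#' @param grid a `voxel_grid`.
#' @return A numeric matrix with one row per occupied voxel and columns
#'   `x`, `y`, `z` (um), voxel-centre convention.
#' @export
voxel_coordinates <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  idx <- which(grid$mask, arr.ind = TRUE) # columns: z, y, x (1-based)
  if (nrow(idx) == 0) {
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "z"))))
  }
  cbind(
    x = (idx[, 3] - 0.5) * grid$spacing["x"],
    y = (idx[, 2] - 0.5) * grid$spacing["y"],
    z = (idx[, 1] - 0.5) * grid$spacing["z"]
  )
}

#' Read a multi-page TIFF z-stack
#'
#' Reads an 8- or 16-bit grayscale multi-page TIFF into an [image_stack()].
#' 16-bit input is linearly rescaled to 8-bit with the stack maximum mapped
#' to 255, as done when converting 16-bit acquisition output for fast
#' processing.
#'
#' @param path path to a multi-page TIFF file.
#' @param spacing voxel spacing `(dx, dy, dz)` in um.
#' @return An [image_stack()] (always 8-bit after rescaling).
#' @export
read_stack <- function(path, spacing = default_spacing()) {
  if (!file.exists(path)) stop("read_stack: file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2, logical(1)))) {
    stop("read_stack: RGB/multi-channel TIFF not supported (grayscale only)")
  }
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  mx <- max(arr)
  if (mx > 255) { # 16-bit: rescale so stack max -> 255
    arr <- arr / mx * 255
  }
  image_stack(arr, spacing = spacing, bit_depth = 8L)
}

#' Write a stack or mask as a multi-page 8-bit TIFF
#'
#' Masks are written as binary 0/255 images so they round-trip through
#' [read_stack()] and [binarize()].
#'
#' @param x an `image_stack` or `voxel_grid`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path) {
  if (inherits(x, "voxel_grid")) {
    arr <- array(ifelse(x$mask, 255, 0), dim = dim(x$mask))
  } else if (inherits(x, "image_stack")) {
    arr <- x$data
  } else {
    stop("write_stack: expected an image_stack or voxel_grid")
  }
  pages <- lapply(seq_len(dim(arr)[1]), function(i) arr[i, , ] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
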