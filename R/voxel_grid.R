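#' Regular 3D intensity volume
#'
#' A voxel grid with voxel-centre geometry: voxel `(i, j, k)` (0-based)
#' has its centre at `origin + c(i, j, k) * spacing`. Missing voxels are
#' stored as `NA` in `data`; the logical `mask` is `TRUE` where a value is
#' present.
#'
#' @param dim integer length-3 voxel counts `(nx, ny, nz)`, each >= 1.
#' @param spacing per-axis voxel size in mm (> 0); a scalar is recycled.
#' @param origin position (mm) of the centre of voxel (0, 0, 0).
#' @param data optional 3D array of intensities (`NA` = missing); default
#'   all-missing.
#' @return An object of class `voxel_grid`: list with `data`, `spacing`,
#'   `origin`, `dim` and `mask`.
#' @examples
#' g <- voxel_grid(c(4, 4, 2), spacing = 0.5)
#' g$dim
#' @export
voxel_grid <- function(dim, spacing, origin = c(0, 0, 0), data = NULL) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L)) stop("`dim` must be 3 counts >= 1")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` components must be positive")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite 3D position")
  if (is.null(data)) {
    data <- array(NA_real_, dim)
  } else {
    data <- array(as.numeric(data), dim)
    if (any(is.infinite(data))) stop("voxel data must be finite or NA")
  }
  structure(list(data = data, spacing = spacing, origin = origin, dim = dim,
                 mask = !is.na(data)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm, %d missing of %d voxels\n",
              x$origin[1], x$origin[2], x$origin[3],
              sum(!x$mask), prod(x$dim)))
  invisible(x)
}

#' Voxel-centre coordinates along each axis
#'
#' @param grid a [voxel_grid()].
#' @return List with numeric vectors `x`, `y`, `z` of voxel-centre
#'   coordinates (mm).
#' @export
voxel_centers <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  list(x = grid$origin[1] + (seq_len(grid$dim[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(grid$dim[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(grid$dim[3]) - 1) * grid$spacing[3])
}

#' Grid geometry covering a box
#'
#' Convenience constructor: the smallest voxel grid at the given spacing
#' whose voxel centres span `[lower, upper]`.
#'
#' @param lower,upper numeric length-3 box corners (mm).
#' @param spacing voxel size in mm (scalar or per-axis).
#' @return An empty [voxel_grid()].
#' @export
grid_from_box <- function(lower, upper, spacing) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(upper < lower)) stop("`upper` must not be below `lower`")
  dims <- pmax(1L, as.integer(floor((upper - lower) / spacing + 1e-9)) + 1L)
  voxel_grid(dims, spacing, origin = lower)
}

#' Reconstruct a volume from a scattered point cloud
#'
#' The target-volume-reconstruction stage: evaluates the local polynomial
#' kernel-regression estimate at every voxel centre of `grid`. Voxels with
#' no cloud sample within `support_factor * bandwidth` are flagged missing
#' (`NA` plus mask). The computation is deterministic, independent of the
#' cloud's record order (up to floating-point summation, < 1e-10), and
#' may be chunked arbitrarily without changing results since voxels are
#' independent.
#'
#' @param cloud a [point_cloud()].
#' @param grid a [voxel_grid()] supplying the output geometry (its data
#'   are ignored).
#' @param spec a [kernel_spec()]; if `NULL`, a spec with
#'   [default_bandwidth()] and order 1 is used.
#' @return A list of class `kr_reconstruction` with elements `volume`
#'   (the filled [voxel_grid()]) and `report` (class
#'   `reconstruction_report`: `n_points`, `n_voxels`, `n_missing`,
#'   `bandwidth`, `order`, and `neighbors`, the min/median/max neighbour
#'   counts over voxels).
#' @examples
#' pc <- point_cloud(matrix(runif(600, 0, 4), ncol = 3), rep(7, 200))
#' g <- grid_from_box(c(1, 1, 1), c(3, 3, 3), spacing = 1)
#' rec <- reconstruct_volume(pc, g, kernel_spec(1.5, order = 0))
#' range(rec$volume$data)
#' @export
reconstruct_volume <- function(cloud, grid, spec = NULL) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(grid, "voxel_grid"))
  if (is.null(spec)) spec <- kernel_spec(default_bandwidth(cloud))
  stopifnot(inherits(spec, "kernel_spec"))
  if (cloud$n >= 2L) {
    mean_nn <- mean(cpp_nn_dists(cloud$positions))
    if (is.finite(mean_nn) && mean_nn > 0 &&
        spec$bandwidth < 1e-6 * mean_nn)
      stop(sprintf(paste0("bandwidth %.3g mm is below 1e-6 x the mean ",
                          "nearest-neighbour spacing (%.3g mm); ",
                          "every voxel would be missing"),
                   spec$bandwidth, mean_nn))
  }
  res <- cpp_kr_grid(cloud$positions, cloud$values, grid$origin,
                     grid$spacing, grid$dim, spec$bandwidth, spec$order,
                     spec$support_factor, spec$min_neighbors, spec$ridge_eps)
  vol <- voxel_grid(grid$dim, grid$spacing, grid$origin,
                    data = array(res$estimate, grid$dim))
  nb <- res$n_used
  report <- structure(
    list(n_points = cloud$n, n_voxels = prod(grid$dim),
         n_missing = sum(is.na(res$estimate)),
         bandwidth = spec$bandwidth, order = spec$order,
         neighbors = c(min = min(nb), median = stats::median(nb),
                       max = max(nb))),
    class = "reconstruction_report")
  structure(list(volume = vol, report = report), class = "kr_reconstruction")
}

#' @export
print.reconstruction_report <- function(x, ...) {
  cat(sprintf("reconstruction: %d points -> %d voxels (%d missing)\n",
              x$n_points, x$n_voxels, x$n_missing))
  cat(sprintf("  h = %.4g mm, order %d, neighbours min/median/max %d/%g/%d\n",
              x$bandwidth, x$order, x$neighbors[["min"]],
              x$neighbors[["median"]], x$neighbors[["max"]]))
  invisible(x)
}

#' @export
print.kr_reconstruction <- function(x, ...) {
  print(x$report)
  print(x$volume)
  invisible(x)
}

#' Nearest-neighbour interpolation baseline
#'
#' Each voxel takes the value of the nearest cloud sample (ties broken by
#' lowest sample index). Used as the comparison baseline for the
#' kernel-regression reconstruction.
#'
#' @inheritParams reconstruct_volume
#' @return A filled [voxel_grid()], never missing for a non-empty cloud.
#' @export
nearest_neighbor_baseline <- function(cloud, grid) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(grid, "voxel_grid"))
  vals <- cpp_nn_grid(cloud$positions, cloud$values, grid$origin,
                      grid$spacing, grid$dim)
  voxel_grid(grid$dim, grid$spacing, grid$origin,
             data = array(vals, grid$dim))
}

#' Data-driven default bandwidth
#'
#' Heuristic bandwidth for [kernel_spec()]: 1.5 times the median
#' nearest-neighbour distance of the cloud. Scales linearly with the cloud
#' (homogeneous of degree 1 in the positions), so rescaling the geometry
#' rescales the bandwidth.
#'
#' @param cloud a [point_cloud()] with at least 2 samples.
#' @return Bandwidth in mm.
#' @export
default_bandwidth <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (cloud$n < 2L) stop("need at least 2 points to choose a bandwidth")
  1.5 * stats::median(cpp_nn_dists(cloud$positions))
}

#' Peak signal-to-noise ratio between two volumes
#'
#' `10 log10(range^2 / MSE)` over voxels present in both volumes
#' (missing voxels are excluded pairwise). Identical volumes give `Inf`.
#'
#' @param volume_a,volume_b [voxel_grid()]s with identical geometry;
#'   `volume_b` is the reference.
#' @param data_range intensity range of the reference signal; default is
#'   the range of `volume_b`'s present voxels.
#' @return PSNR in dB (`Inf` when the MSE is zero).
#' @export
psnr <- function(volume_a, volume_b, data_range = NULL) {
  stopifnot(inherits(volume_a, "voxel_grid"), inherits(volume_b, "voxel_grid"))
  if (!identical(volume_a$dim, volume_b$dim) ||
      !isTRUE(all.equal(volume_a$spacing, volume_b$spacing)) ||
      !isTRUE(all.equal(volume_a$origin, volume_b$origin)))
    stop("volumes must share geometry (dim, spacing, origin)")
  ok <- volume_a$mask & volume_b$mask
  if (!any(ok)) stop("no voxels present in both volumes")
  if (is.null(data_range))
    data_range <- diff(range(volume_b$data[volume_b$mask]))
  mse <- mean((volume_a$data[ok] - volume_b$data[ok])^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}
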