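#' Scattered ultrasound samples as a point cloud
#'
#' Container for the raw observations of the reconstruction problem: one
#' record per sample, a 3D position (mm) and a scalar intensity. The
#' observed value is modelled as the unknown smooth field at the position
#' plus additive zero-mean noise; the reconstruction estimates the field.
#'
#' @param positions numeric matrix (or coercible) with 3 columns, one row
#'   per sample, coordinates in mm.
#' @param values numeric vector of scalar intensities, one per row of
#'   `positions`.
#' @return An object of class `point_cloud`: list with `positions`
#'   (P x 3 matrix), `values` and `n`.
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), ncol = 3), rnorm(10))
#' pc$n
#' @export
point_cloud <- function(positions, values) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  values <- as.numeric(values)
  if (ncol(positions) != 3L)
    stop("`positions` must have exactly 3 columns (x, y, z in mm)")
  if (nrow(positions) < 1L)
    stop("a point cloud needs at least one sample")
  if (nrow(positions) != length(values))
    stop("`positions` and `values` must have equal length")
  if (!all(is.finite(positions)) || !all(is.finite(values)))
    stop("all coordinates and values must be finite")
  dimnames(positions) <- list(NULL, c("x", "y", "z"))
  structure(list(positions = positions, values = values, n = nrow(positions)),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  rng <- apply(x$positions, 2, range)
  cat(sprintf("point_cloud: %d samples\n", x$n))
  cat(sprintf("  extent x [%.2f, %.2f], y [%.2f, %.2f], z [%.2f, %.2f] mm\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  cat(sprintf("  values  [%.3g, %.3g]\n", min(x$values), max(x$values)))
  invisible(x)
}

basis_size <- function(order) c(1L, 4L, 10L)[order + 1L]

#' Kernel and local-fit configuration
#'
#' Bundles everything the local polynomial estimator needs: kernel family,
#' bandwidth, polynomial order, neighbourhood truncation and the numerical
#' fallback policy.
#'
#' @param bandwidth Gaussian bandwidth h in mm (> 0); the kernel's length
#'   scale. See [default_bandwidth()] for a data-driven choice.
#' @param order polynomial order of the local fit: 0 (locally constant,
#'   the Nadaraya-Watson weighted mean), 1 (locally linear, the default)
#'   or 2 (locally quadratic).
#' @param support_factor neighbourhood cutoff as a multiple of `bandwidth`
#'   (default 3): samples farther than `support_factor * bandwidth` from
#'   the query point are ignored. At the default the discarded Gaussian
#'   weight is below exp(-4.5).
#' @param min_neighbors minimum neighbour count before the fallback policy
#'   triggers; default is the basis size plus two. With fewer neighbours
#'   the order degrades 2 -> 1 -> 0; with zero neighbours the estimate is
#'   the missing marker `NA`.
#' @param ridge_eps relative ridge added to the diagonal of the weighted
#'   normal equations (times their trace) only when the plain solve fails
#'   on a rank-deficient neighbourhood. Default 1e-10.
#' @return An object of class `kernel_spec`. The derived field
#'   `second_moment` is the kernel's second moment (h^2 per axis for the
#'   Gaussian).
#' @examples
#' kernel_spec(bandwidth = 0.5)
#' @export
kernel_spec <- function(bandwidth, order = 1L, support_factor = 3,
                        min_neighbors = NULL, ridge_eps = 1e-10) {
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L ||
      !is.finite(bandwidth) || bandwidth <= 0)
    stop("`bandwidth` must be a single positive number (mm)")
  order <- as.integer(order)
  if (!order %in% 0:2) stop("`order` must be 0, 1 or 2")
  if (!is.numeric(support_factor) || support_factor < 1)
    stop("`support_factor` must be >= 1")
  if (is.null(min_neighbors)) min_neighbors <- basis_size(order) + 2L
  min_neighbors <- as.integer(min_neighbors)
  if (min_neighbors < 1L) stop("`min_neighbors` must be >= 1")
  if (!is.numeric(ridge_eps) || ridge_eps < 0)
    stop("`ridge_eps` must be >= 0")
  structure(list(family = "gaussian", bandwidth = bandwidth, order = order,
                 support_factor = support_factor,
                 min_neighbors = min_neighbors, ridge_eps = ridge_eps,
                 second_moment = bandwidth^2),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf(
    "kernel_spec: %s, h = %.4g mm, order %d, support %.3g h, min_neighbors %d\n",
    x$family, x$bandwidth, x$order, x$support_factor, x$min_neighbors))
  invisible(x)
}

#' Isotropic Gaussian kernel
#'
#' Unnormalized Gaussian weight `exp(-||u||^2 / (2 h^2))` of a 3D offset.
#' The normalizing constant is omitted deliberately: it cancels in the
#' weighted least-squares fit. The kernel is symmetric (K(u) = K(-u)),
#' maximal at the origin, and strictly positive.
#'
#' @param offset numeric length-3 displacement in mm, or a matrix with one
#'   offset per row.
#' @param h bandwidth in mm (> 0).
#' @return Non-negative weight(s), 1 at the origin.
#' @examples
#' gaussian_kernel(c(1, 0, 0), h = 1) # exp(-1/2)
#' @export
gaussian_kernel <- function(offset, h) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("bandwidth `h` must be a single positive number")
  if (is.null(dim(offset))) offset <- matrix(offset, ncol = 3L)
  if (ncol(offset) != 3L) stop("`offset` must be a 3D displacement")
  if (!all(is.finite(offset))) stop("`offset` must be finite")
  drop(exp(-rowSums(offset^2) / (2 * h^2)))
}

#' Kernel weights of a neighbourhood
#'
#' The influence of each neighbour on a query point: the Gaussian kernel
#' evaluated at the neighbour's offset from the centre. Weights decrease
#' monotonically with distance.
#'
#' @param center numeric length-3 query position (mm).
#' @param neighbors matrix of neighbour positions, one per row.
#' @param h bandwidth in mm.
#' @return Numeric weight vector, one entry per neighbour.
#' @examples
#' local_weights(c(0, 0, 0), rbind(c(1, 0, 0), c(0, 2, 0)), h = 1)
#' @export
local_weights <- function(center, neighbors, h) {
  neighbors <- as.matrix(neighbors)
  if (nrow(neighbors) == 0L) stop("empty neighbourhood: no neighbors supplied")
  gaussian_kernel(sweep(neighbors, 2L, center), h)
}

#' Local polynomial design matrix
#'
#' Monomial basis rows of the neighbour offsets from the query point, used
#' as the regression design of the local fit. Column order is fixed:
#' `1, dx, dy, dz` for order 1, extended by
#' `dx^2, dx*dy, dx*dz, dy^2, dy*dz, dz^2` for order 2. The first column
#' is always the intercept, whose coefficient is the field estimate.
#'
#' @param center numeric length-3 query position (mm).
#' @param neighbors matrix of neighbour positions, one per row.
#' @param order polynomial order, 0, 1 or 2.
#' @return Numeric matrix with one row per neighbour and 1, 4 or 10
#'   columns.
#' @examples
#' build_design(c(0, 0, 0), rbind(c(1, 2, 3)), order = 1)
#' @export
build_design <- function(center, neighbors, order = 1L) {
  order <- as.integer(order)
  if (!order %in% 0:2) stop("`order` must be 0, 1 or 2")
  neighbors <- as.matrix(neighbors)
  d <- sweep(neighbors, 2L, center)
  n <- nrow(d)
  out <- matrix(1, nrow = n, ncol = basis_size(order))
  cn <- "1"
  if (order >= 1L) {
    out[, 2:4] <- d
    cn <- c(cn, "dx", "dy", "dz")
  }
  if (order == 2L) {
    out[, 5] <- d[, 1]^2
    out[, 6] <- d[, 1] * d[, 2]
    out[, 7] <- d[, 1] * d[, 3]
    out[, 8] <- d[, 2]^2
    out[, 9] <- d[, 2] * d[, 3]
    out[, 10] <- d[, 3]^2
    cn <- c(cn, "dx2", "dxdy", "dxdz", "dy2", "dydz", "dz2")
  }
  colnames(out) <- cn
  out
}

#' Weighted least-squares local fit
#'
#' Solves the kernel-weighted normal equations
#' `(X' W X) beta = X' W y` for the local polynomial coefficients. The
#' intercept `beta[1]` is the field estimate at the query point. When the
#' plain solve fails (rank-deficient neighbourhood) a ridge of
#' `ridge_eps * trace(X'WX)` is added to the diagonal; this is the only
#' non-deterministic-looking branch and it is itself deterministic.
#'
#' @param design design matrix from [build_design()].
#' @param weights non-negative kernel weights, one per row.
#' @param values observed intensities, one per row.
#' @param ridge_eps relative ridge regularizer (0 disables it and lets a
#'   singular system fail with an error; an internal 1e-10 floor is used
#'   for the retry when a positive value is not supplied explicitly).
#' @return An object of class `local_fit`: list with `design`, `weights`,
#'   `beta`, `estimate` (= beta\[1\]) and `n_used`.
#' @examples
#' X <- build_design(c(0, 0, 0), rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
#'                                     c(-1, -1, -1)), order = 1)
#' fit_local(X, rep(1, 4), c(3, 2, 4, 1), ridge_eps = 0)$estimate
#' @export
fit_local <- function(design, weights, values, ridge_eps = 1e-10) {
  design <- as.matrix(design)
  weights <- as.numeric(weights)
  values <- as.numeric(values)
  if (nrow(design) != length(weights) || nrow(design) != length(values))
    stop("`design`, `weights` and `values` must have matching row counts")
  if (!all(is.finite(design)) || !all(is.finite(weights)) ||
      !all(is.finite(values)))
    stop("non-finite inputs in local fit")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (!any(weights > 0)) stop("empty neighbourhood: all weights are zero")
  M <- crossprod(design, design * weights)
  v <- crossprod(design, weights * values)
  beta <- tryCatch(solve(M, v), error = function(e) NULL)
  if (is.null(beta) || !all(is.finite(beta))) {
    eps <- if (ridge_eps > 0) ridge_eps else 1e-10
    Mr <- M + diag(eps * sum(diag(M)), ncol(M))
    beta <- solve(Mr, v)
  }
  beta <- drop(beta)
  structure(list(design = design, weights = weights, beta = beta,
                 estimate = unname(beta[1]), n_used = nrow(design)),
            class = "local_fit")
}

#' @export
print.local_fit <- function(x, ...) {
  cat(sprintf("local_fit: %d neighbours, %d coefficients, estimate %.6g\n",
              x$n_used, length(x$beta), x$estimate))
  invisible(x)
}

#' Kernel-regression estimate at a single point
#'
#' Reference (pure R) evaluation of the local polynomial estimator:
#' gathers the cloud samples within `support_factor * bandwidth` of the
#' query point, degrades the polynomial order when the neighbourhood is
#' too sparse for a stable fit, and returns the intercept of the weighted
#' least-squares fit. Returns `NA` (the missing marker, not an error) when
#' no sample lies within support. [reconstruct_volume()] applies the same
#' estimator to every voxel centre through a compiled spatial index; the
#' two routes agree to near machine precision.
#'
#' @param point numeric length-3 query position (mm), or a matrix of query
#'   points (one per row).
#' @param cloud a [point_cloud()].
#' @param spec a [kernel_spec()].
#' @param details if `TRUE`, return a list with `estimate`, `n_used` and
#'   `order_used` instead of a bare numeric.
#' @return Numeric estimate(s); `NA` where no neighbour is in support.
#' @export
estimate_point <- function(point, cloud, spec, details = FALSE) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(spec, "kernel_spec"))
  if (is.matrix(point)) {
    res <- apply(point, 1L, estimate_point, cloud = cloud, spec = spec)
    return(res)
  }
  r <- spec$support_factor * spec$bandwidth
  d2 <- colSums((t(cloud$positions) - point)^2)
  sel <- which(d2 <= r^2)
  n <- length(sel)
  if (n == 0L) {
    if (details) return(list(estimate = NA_real_, n_used = 0L,
                             order_used = NA_integer_))
    return(NA_real_)
  }
  eff <- spec$order
  while (eff > 0L && n < max(spec$min_neighbors, basis_size(eff) + 2L))
    eff <- eff - 1L
  nb <- cloud$positions[sel, , drop = FALSE]
  w <- exp(-d2[sel] / (2 * spec$bandwidth^2))
  X <- build_design(point, nb, eff)
  fit <- fit_local(X, w, cloud$values[sel], spec$ridge_eps)
  if (details)
    return(list(estimate = fit$estimate, n_used = n, order_used = eff))
  fit$estimate
}
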