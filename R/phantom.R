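#' Digital phantom of the anal sphincter complex
#'
#' Parameters of an analytic piecewise-constant 3D intensity field that
#' emulates the anal sphincter complex on transperineal ultrasound: a
#' concentric internal-anal-sphincter (IAS) ring running the whole canal,
#' an external-anal-sphincter (EAS) ring abutting the IAS outer wall in
#' the distal third, and a puborectalis (PRM) horseshoe subtending the
#' posterior 180 degrees at mid-canal, separated from the IAS by a thin
#' longitudinal-muscle gap. The canal axis is z (cranial), the anterior
#' direction +y; the three measurement planes sit at fixed z fractions
#' 0.2 (distal), 0.5 (mid) and 0.8 (proximal) of the canal length.
#'
#' Default dimensions follow the magnitudes reported for primiparous
#' women: IAS thickness ~2 mm, EAS ~2 mm, PRM ~7 mm.
#'
#' @param ias_inner_radius IAS inner (luminal) radius, mm.
#' @param ias_thickness IAS wall thickness, mm.
#' @param eas_thickness EAS wall thickness, mm (ring from the IAS outer
#'   wall outwards, distal third only).
#' @param prm_thickness PRM sling thickness, mm (posterior horseshoe at
#'   mid-canal).
#' @param prm_gap radial gap between IAS outer wall and PRM inner edge,
#'   mm (intervening longitudinal muscle).
#' @param canal_length canal extent along z, mm.
#' @param box_margin in-plane margin beyond the outermost structure, mm.
#' @param intensities named levels for `background`, `IAS`, `EAS`, `PRM`
#'   (arbitrary ultrasound units).
#' @param blur_sigma radial edge smoothing in mm (0 = sharp boundaries).
#' @param noise_sd default additive Gaussian noise SD for
#'   [sample_cloud()], intensity units.
#' @param seed default seed for [sample_cloud()].
#' @return An object of class `phantom_spec` with derived radii and plane
#'   positions.
#' @export
phantom_spec <- function(ias_inner_radius = 6, ias_thickness = 2,
                         eas_thickness = 2, prm_thickness = 7,
                         prm_gap = 1.5, canal_length = 30, box_margin = 3,
                         intensities = c(background = 0, IAS = 100,
                                         EAS = 50, PRM = 60),
                         blur_sigma = 0, noise_sd = 10, seed = 1L) {
  num <- c(ias_inner_radius, ias_thickness, eas_thickness, prm_thickness,
           prm_gap, canal_length, box_margin)
  if (any(!is.finite(num)) ||
      any(c(ias_inner_radius, ias_thickness, eas_thickness, prm_thickness,
            canal_length) <= 0) || prm_gap < 0 || box_margin < 0)
    stop("phantom radii, thicknesses and canal length must be positive")
  intensities <- unlist(intensities)
  need <- c("background", "IAS", "EAS", "PRM")
  if (!all(need %in% names(intensities)))
    stop("`intensities` must name background, IAS, EAS and PRM levels")
  if (blur_sigma < 0) stop("`blur_sigma` must be >= 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  ias_outer <- ias_inner_radius + ias_thickness
  prm_inner <- ias_outer + prm_gap
  spec <- list(
    ias_inner_radius = ias_inner_radius, ias_thickness = ias_thickness,
    eas_thickness = eas_thickness, prm_thickness = prm_thickness,
    prm_gap = prm_gap, canal_length = canal_length, box_margin = box_margin,
    intensities = intensities[need], blur_sigma = blur_sigma,
    noise_sd = noise_sd, seed = as.integer(seed),
    ias_outer_radius = ias_outer,
    eas_inner_radius = ias_outer,
    eas_outer_radius = ias_outer + eas_thickness,
    prm_inner_radius = prm_inner,
    prm_outer_radius = prm_inner + prm_thickness,
    # z bands: EAS occupies the distal third, PRM the middle third
    eas_z = c(0, 0.35) * canal_length,
    prm_z = c(0.35, 0.65) * canal_length,
    plane_fractions = c(proximal = 0.8, mid = 0.5, distal = 0.2))
  class(spec) <- "phantom_spec"
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("phantom_spec: IAS [%g, %g] mm, EAS [%g, %g] mm ",
                     "(distal), PRM [%g, %g] mm (mid, posterior)\n"),
              x$ias_inner_radius, x$ias_outer_radius, x$eas_inner_radius,
              x$eas_outer_radius, x$prm_inner_radius, x$prm_outer_radius))
  cat(sprintf("  canal %g mm, blur %g mm, noise SD %g, seed %d\n",
              x$canal_length, x$blur_sigma, x$noise_sd, x$seed))
  invisible(x)
}

# radial band indicator, optionally erf-smoothed at the two edges
radial_band <- function(r, a, b, sigma) {
  if (sigma <= 0) return(as.numeric(r >= a & r < b))
  pnorm((r - a) / sigma) - pnorm((r - b) / sigma)
}

#' Build the analytic ground-truth field
#'
#' Turns a [phantom_spec()] into a callable noiseless intensity field and
#' its exact per-site thickness table. The field is deterministic and
#' vectorized over positions.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `ground_truth`: list with `spec`, `field`
#'   (a function `f(x, y, z)` in mm returning intensities), `thickness`
#'   (data.frame of the 18 measurement sites with exact thickness),
#'   `box` (`lower`, `upper` corners), `plane_z` (named z positions) and
#'   `center` (in-plane canal centre).
#' @examples
#' gt <- make_phantom(phantom_spec())
#' gt$field(0, 0, 15)                       # lumen: background
#' gt$field(gt$spec$ias_inner_radius + 1, 0, 15)  # inside the IAS wall
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  lv <- spec$intensities
  s <- spec
  field <- function(x, y, z) {
    r <- sqrt(x^2 + y^2)
    f <- rep(lv[["background"]], length(r))
    in_canal <- z >= 0 & z <= s$canal_length
    f <- f + (lv[["IAS"]] - lv[["background"]]) * in_canal *
      radial_band(r, s$ias_inner_radius, s$ias_outer_radius, s$blur_sigma)
    in_eas <- z >= s$eas_z[1] & z < s$eas_z[2]
    f <- f + (lv[["EAS"]] - lv[["background"]]) * in_eas *
      radial_band(r, s$eas_inner_radius, s$eas_outer_radius, s$blur_sigma)
    in_prm <- z >= s$prm_z[1] & z < s$prm_z[2] & y < 0
    f <- f + (lv[["PRM"]] - lv[["background"]]) * in_prm *
      radial_band(r, s$prm_inner_radius, s$prm_outer_radius, s$blur_sigma)
    f
  }
  sites <- asc_sites()
  sites$thickness_mm <- ifelse(sites$structure == "IAS", spec$ias_thickness,
                        ifelse(sites$structure == "EAS", spec$eas_thickness,
                               spec$prm_thickness))
  ext <- spec$prm_outer_radius + spec$box_margin
  structure(list(spec = spec, field = field, thickness = sites,
                 box = list(lower = c(-ext, -ext, 0),
                            upper = c(ext, ext, spec$canal_length)),
                 plane_z = spec$plane_fractions * spec$canal_length,
                 center = c(0, 0)),
            class = "ground_truth")
}

#' Sample a noisy scattered point cloud from a phantom
#'
#' Emulates the data-acquisition stage: sample positions in the phantom
#' box and observe the field plus i.i.d. zero-mean Gaussian noise. The
#' global RNG stream is left untouched.
#'
#' @param truth a [make_phantom()] ground truth.
#' @param n number of samples (>= 1).
#' @param noise_sd noise standard deviation (intensity units); defaults
#'   to the phantom spec's `noise_sd`.
#' @param seed integer seed; defaults to the phantom spec's `seed`.
#' @param mode `"uniform"` (default) samples positions uniformly in the
#'   box; `"sweep"` emulates a freehand fan sweep from the anal verge to
#'   the anorectal angle: dense transverse planes at jittered z.
#' @return A [point_cloud()].
#' @export
sample_cloud <- function(truth, n, noise_sd = NULL, seed = NULL,
                         mode = c("uniform", "sweep")) {
  stopifnot(inherits(truth, "ground_truth"))
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1")
  if (is.null(noise_sd)) noise_sd <- truth$spec$noise_sd
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (is.null(seed)) seed <- truth$spec$seed
  lo <- truth$box$lower
  hi <- truth$box$upper
  with_seed(seed, {
    if (mode == "uniform") {
      x <- runif(n, lo[1], hi[1])
      y <- runif(n, lo[2], hi[2])
      z <- runif(n, lo[3], hi[3])
    } else {
      # ~0.5 mm plane pitch with jitter, uniform in-plane positions
      nplanes <- max(2L, as.integer(round((hi[3] - lo[3]) / 0.5)))
      zp <- seq(lo[3], hi[3], length.out = nplanes)
      plane <- sample.int(nplanes, n, replace = TRUE)
      z <- pmin(pmax(zp[plane] + rnorm(n, 0, 0.1), lo[3]), hi[3])
      x <- runif(n, lo[1], hi[1])
      y <- runif(n, lo[2], hi[2])
    }
    vals <- truth$field(x, y, z)
    if (noise_sd > 0) vals <- vals + rnorm(n, 0, noise_sd)
    point_cloud(cbind(x, y, z), vals)
  })
}

#' Rasterize the ground-truth field onto a voxel grid
#'
#' Evaluates the noiseless phantom field at every voxel centre; used as
#' the PSNR reference for reconstructions.
#'
#' @param truth a [make_phantom()] ground truth.
#' @param grid a [voxel_grid()] geometry.
#' @return A filled [voxel_grid()].
#' @export
rasterize_truth <- function(truth, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  cc <- voxel_centers(grid)
  data <- array(NA_real_, grid$dim)
  xy <- cbind(rep(cc$x, times = grid$dim[2]),
              rep(cc$y, each = grid$dim[1]))
  for (k in seq_len(grid$dim[3]))   # slice-wise to bound memory
    data[, , k] <- truth$field(xy[, 1], xy[, 2], cc$z[k])
  voxel_grid(grid$dim, grid$spacing, grid$origin, data = data)
}

#' Default reconstruction grid for a phantom
#'
#' @param truth a [make_phantom()] ground truth.
#' @param spacing isotropic voxel size in mm (default 0.2).
#' @return An empty [voxel_grid()] covering the phantom box.
#' @export
phantom_grid <- function(truth, spacing = 0.2) {
  stopifnot(inherits(truth, "ground_truth"))
  grid_from_box(truth$box$lower, truth$box$upper, spacing)
}
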