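#' Measurement sites of the sphincter-complex protocol
#'
#' The fixed clock-face protocol: IAS thickness at 3, 6, 9 and 12 o'clock
#' on the proximal, mid and distal planes; EAS at 3, 6, 9 and 12 o'clock
#' on the distal plane only; PRM at 4 and 8 o'clock on the mid plane only.
#'
#' @return data.frame with columns `structure`, `plane`, `clock`
#'   (18 rows).
#' @export
asc_sites <- function() {
  rbind(
    expand.grid(structure = "IAS", plane = c("proximal", "mid", "distal"),
                clock = c(3L, 6L, 9L, 12L), stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE),
    expand.grid(structure = "EAS", plane = "distal",
                clock = c(3L, 6L, 9L, 12L), stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE),
    expand.grid(structure = "PRM", plane = "mid", clock = c(4L, 8L),
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  )[, c("structure", "plane", "clock")]
}

#' Clock position to in-plane angle
#'
#' Clock-face convention on an axial slice viewed from caudal: 12 o'clock
#' is anterior (+y), 3 o'clock is patient-left (+x), positions advance
#' clockwise. The angle (degrees, mathematical convention from +x) is
#' `90 - 30 * (clock mod 12)`.
#'
#' @param clock_position integer 1-12 (vectorized).
#' @return Angle in degrees in (-180, 180].
#' @examples
#' clock_to_angle(c(12, 3, 6, 9))  # 90, 0, -90, 180
#' @export
clock_to_angle <- function(clock_position) {
  if (any(!clock_position %in% 1:12))
    stop("`clock_position` must be an integer in 1..12")
  a <- 90 - 30 * (clock_position %% 12)
  ifelse(a <= -180, a + 360, a)
}

#' Extract an axial plane from a volume
#'
#' Selects the slice at a z fraction of the volume extent: 0.8 for the
#' proximal plane (adjacent to the anorectal angle), 0.5 for the mid
#' plane (clearest PRM) and 0.2 for the distal plane (IAS and EAS
#' together). The slice index is `floor(fraction * (nz - 1))` (0-based),
#' i.e. a fractional position resolves to the lower neighbouring slice.
#'
#' @param volume a [voxel_grid()].
#' @param plane `"proximal"`, `"mid"` or `"distal"`; ignored when
#'   `fraction` is given.
#' @param fraction optional explicit z fraction in `[0, 1]`.
#' @return An object of class `axial_slice`: list with `data` (2D
#'   matrix), `spacing`, `origin` (in-plane), `z` (mm), `index`
#'   (0-based slice index) and `plane`.
#' @export
extract_plane <- function(volume, plane = c("proximal", "mid", "distal"),
                          fraction = NULL) {
  stopifnot(inherits(volume, "voxel_grid"))
  if (is.null(fraction)) {
    plane <- match.arg(plane)
    fraction <- c(proximal = 0.8, mid = 0.5, distal = 0.2)[[plane]]
  } else {
    plane <- if (is.character(plane) && length(plane) == 1L &&
                 plane %in% c("proximal", "mid", "distal")) plane
             else NA_character_
    if (fraction < 0 || fraction > 1) stop("`fraction` must be in [0, 1]")
  }
  nz <- volume$dim[3]
  idx <- as.integer(floor(fraction * (nz - 1) + 1e-9))
  structure(list(data = volume$data[, , idx + 1L],
                 spacing = volume$spacing[1:2],
                 origin = volume$origin[1:2],
                 z = volume$origin[3] + idx * volume$spacing[3],
                 index = idx, plane = plane),
            class = "axial_slice")
}

# bilinear interpolation on a slice; NA outside or next to missing voxels
sample_slice <- function(slice, x, y) {
  u <- (x - slice$origin[1]) / slice$spacing[1]
  v <- (y - slice$origin[2]) / slice$spacing[2]
  nx <- nrow(slice$data)
  ny <- ncol(slice$data)
  out <- rep(NA_real_, length(u))
  ok <- u >= 0 & u <= nx - 1 & v >= 0 & v <= ny - 1
  if (!any(ok)) return(out)
  u <- u[ok]; v <- v[ok]
  i0 <- pmin(floor(u), nx - 2); i1 <- i0 + 1
  j0 <- pmin(floor(v), ny - 2); j1 <- j0 + 1
  fu <- u - i0; fv <- v - j0
  d <- slice$data
  val <- d[cbind(i0 + 1, j0 + 1)] * (1 - fu) * (1 - fv) +
         d[cbind(i1 + 1, j0 + 1)] * fu * (1 - fv) +
         d[cbind(i0 + 1, j1 + 1)] * (1 - fu) * fv +
         d[cbind(i1 + 1, j1 + 1)] * fu * fv
  out[ok] <- val
  out
}

# linear interpolation of the crossing of `level` between profile samples
# i and i+1 (assumes a sign change of f - level across the pair)
crossing_t <- function(t, f, i, level) {
  f0 <- f[i]; f1 <- f[i + 1]
  if (f1 == f0) return((t[i] + t[i + 1]) / 2)
  t[i] + (level - f0) / (f1 - f0) * (t[i + 1] - t[i])
}

#' Wall thickness along a clock-face ray
#'
#' Casts a ray from the canal centre at the clock position's angle,
#' samples the slice at quarter-voxel steps with bilinear interpolation,
#' and locates the target structure's wall by a full-width-at-half-
#' maximum rule generalized to abutting structures: the wall core is the
#' longest contiguous run of samples within half the level gap of the
#' structure's nominal intensity, the entry position is the nearest
#' crossing of the half-way level between the structure and its inner
#' neighbour (`inner_ref`, background by default) scanning inward from
#' the core, and the exit position the nearest crossing of the half-way
#' level against the outer neighbour (`outer_ref`) scanning outward. For
#' an isolated wall over background this reduces to the classical FWHM
#' rule. Thickness is `exit - entry`; the result is missing (with a
#' reason) when the ray shows no such wall before leaving the slice.
#'
#' @param slice an [extract_plane()] slice.
#' @param center numeric length-2 canal centre (mm, slice coordinates).
#' @param clock_position integer 1-12.
#' @param structure name of the target structure; must appear in
#'   `levels`.
#' @param levels named numeric intensity model: nominal level of each
#'   structure present on this plane plus `"background"`.
#' @param inner_ref,outer_ref names (in `levels`) of the tissue adjacent
#'   to the wall on its luminal and outer side; both default to
#'   `"background"`.
#' @param step sampling step along the ray in mm; default a quarter of
#'   the smaller in-plane voxel size.
#' @param fan_deg,fan_rays the site's thickness is the mean over
#'   `fan_rays` rays fanned evenly across +-`fan_deg` degrees about the
#'   clock angle. The default +-15 degrees is the site's full clock
#'   sector (the twelve 30-degree sectors tile the face); all fan rays
#'   are radial for a centred ring, so the averaging reduces
#'   edge-localization noise without biasing the thickness.
#'   `fan_rays = 1` measures the single central ray.
#' @return One-row data.frame: `structure`, `plane`, `clock`,
#'   `thickness_mm`, `entry_mm`, `exit_mm` (distances from the centre),
#'   `angle_deg`, `reason` (`NA` on success).
#' @export
measure_thickness <- function(slice, center, clock_position, structure,
                              levels, inner_ref = "background",
                              outer_ref = "background", step = NULL,
                              fan_deg = 15, fan_rays = 13L) {
  stopifnot(inherits(slice, "axial_slice"))
  if (!structure %in% names(levels))
    stop(sprintf("`levels` has no entry for structure '%s'", structure))
  if (!"background" %in% names(levels))
    stop("`levels` must include a 'background' level")
  if (!inner_ref %in% names(levels) || !outer_ref %in% names(levels))
    stop("`inner_ref` and `outer_ref` must name entries of `levels`")
  if (is.null(step)) step <- 0.25 * min(slice$spacing)
  fan_rays <- as.integer(fan_rays)
  if (fan_rays < 1L) stop("`fan_rays` must be >= 1")
  angle0 <- clock_to_angle(clock_position)
  offsets <- if (fan_rays == 1L) 0
             else seq(-fan_deg, fan_deg, length.out = fan_rays)
  rays <- lapply(angle0 + offsets, function(a)
    measure_ray(slice, center, a, structure, levels, inner_ref, outer_ref,
                step))
  ok <- vapply(rays, function(r) is.na(r$reason), logical(1))
  out <- data.frame(
    structure = structure, plane = slice$plane, clock = clock_position,
    thickness_mm = NA_real_, entry_mm = NA_real_, exit_mm = NA_real_,
    angle_deg = angle0, reason = NA_character_, stringsAsFactors = FALSE)
  if (sum(ok) < ceiling(fan_rays / 2)) {
    reasons <- vapply(rays[!ok], function(r) r$reason, character(1))
    out$reason <- names(sort(table(reasons), decreasing = TRUE))[1]
    return(out)
  }
  out$entry_mm <- mean(vapply(rays[ok], function(r) r$entry, numeric(1)))
  out$exit_mm <- mean(vapply(rays[ok], function(r) r$exit, numeric(1)))
  out$thickness_mm <- mean(vapply(rays[ok], function(r) r$exit - r$entry,
                                  numeric(1)))
  out
}

# single-ray wall localization at an arbitrary in-plane angle
measure_ray <- function(slice, center, angle_deg, structure, levels,
                        inner_ref, outer_ref, step) {
  dir <- c(cos(angle_deg * pi / 180), sin(angle_deg * pi / 180))
  ext <- dim(slice$data) - 1L
  tmax <- sqrt(sum((ext * slice$spacing)^2))  # longest possible in-slice ray
  t <- seq(0, tmax, by = step)
  f <- sample_slice(slice, center[1] + t * dir[1], center[2] + t * dir[2])
  nas <- which(is.na(f))
  if (length(nas)) {
    t <- t[seq_len(nas[1] - 1L)]
    f <- f[seq_len(nas[1] - 1L)]
  }
  miss <- function(reason) list(entry = NA_real_, exit = NA_real_,
                                reason = reason)
  if (length(t) < 3L) return(miss("ray left the slice immediately"))
  lv <- unlist(levels)
  Ls <- lv[[structure]]
  # wall core: longest run of samples within half the smallest level gap
  gamma <- min(abs(Ls - lv[names(lv) != structure])) / 2
  runs <- rle(abs(f - Ls) <= gamma)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  if (!length(cand)) return(miss("no wall found on the ray"))
  ri <- cand[which.max(runs$lengths[cand])]
  i0 <- starts[ri]
  i1 <- ends[ri]
  if (i0 < 2L) return(miss("wall core starts at the centre"))
  half_in <- (Ls + lv[[inner_ref]]) / 2
  entry <- NA_real_
  for (i in seq(i0 - 1L, 1L)) {
    if ((f[i] - half_in) * (f[i + 1L] - half_in) <= 0) {
      entry <- crossing_t(t, f, i, half_in)
      break
    }
  }
  half_out <- (Ls + lv[[outer_ref]]) / 2
  exit <- NA_real_
  if (i1 < length(f)) {
    for (i in seq(i1, length(f) - 1L)) {
      if ((f[i] - half_out) * (f[i + 1L] - half_out) <= 0) {
        exit <- crossing_t(t, f, i, half_out)
        break
      }
    }
  }
  if (!is.finite(entry) || !is.finite(exit))
    return(miss("no wall crossing pair found on the ray"))
  list(entry = entry, exit = exit, reason = NA_character_)
}

# canal centre as the intensity-weighted centroid of pixels classified IAS
estimate_center <- function(slice, levels) {
  lv <- unlist(levels)
  d <- slice$data
  cls <- names(lv)[apply(abs(outer(as.vector(d), lv, "-")), 1L, which.min)]
  w <- ifelse(!is.na(d) & cls == "IAS",
              abs(as.vector(d) - lv[["background"]]), 0)
  if (sum(w, na.rm = TRUE) == 0) stop("cannot locate the IAS annulus")
  w[is.na(w)] <- 0
  xs <- slice$origin[1] + (seq_len(nrow(d)) - 1) * slice$spacing[1]
  ys <- slice$origin[2] + (seq_len(ncol(d)) - 1) * slice$spacing[2]
  cx <- sum(w * rep(xs, times = ncol(d))) / sum(w)
  cy <- sum(w * rep(ys, each = nrow(d))) / sum(w)
  c(cx, cy)
}

#' Measure the full sphincter-complex protocol on a volume
#'
#' Runs [measure_thickness()] at every protocol site ([asc_sites()]):
#' IAS at 3/6/9/12 o'clock on the proximal, mid and distal planes, EAS at
#' 3/6/9/12 on the distal plane, PRM at 4/8 on the mid plane. Per plane,
#' only the structures anatomically present there enter the intensity
#' model (proximal: IAS; mid: IAS and PRM; distal: IAS and EAS). The
#' canal centre defaults to the intensity-weighted centroid of the IAS
#' annulus on the mid plane.
#'
#' @param volume a [voxel_grid()] reconstruction.
#' @param config optional list overriding `center` (length-2, mm),
#'   `levels` (named intensities incl. `background`), `plane_fractions`
#'   (named, proximal/mid/distal) and `sites` (data.frame like
#'   [asc_sites()]).
#' @return data.frame with one row per site: `structure`, `plane`,
#'   `clock`, `thickness_mm` (rounded to 2 decimals, the measurement
#'   precision of the clinical tables), `entry_mm`, `exit_mm`,
#'   `angle_deg`, `reason`.
#' @export
measure_complex <- function(volume, config = list()) {
  stopifnot(inherits(volume, "voxel_grid"))
  defaults <- list(
    center = NULL,
    levels = c(background = 0, IAS = 100, EAS = 50, PRM = 60),
    plane_fractions = c(proximal = 0.8, mid = 0.5, distal = 0.2),
    sites = asc_sites())
  cfg <- modifyList(defaults, config)
  plane_levels <- list(
    proximal = cfg$levels[c("background", "IAS")],
    mid = cfg$levels[c("background", "IAS", "PRM")],
    distal = cfg$levels[c("background", "IAS", "EAS")])
  slices <- lapply(names(cfg$plane_fractions), function(p) {
    s <- extract_plane(volume, fraction = cfg$plane_fractions[[p]])
    s$plane <- p
    s
  })
  names(slices) <- names(cfg$plane_fractions)
  center <- cfg$center
  if (is.null(center))
    center <- estimate_center(slices$mid, plane_levels$mid)
  rows <- lapply(seq_len(nrow(cfg$sites)), function(i) {
    site <- cfg$sites[i, ]
    # adjacency of each wall along the ray: the EAS abuts the IAS outer
    # wall on the distal plane; everything else borders background
    inner <- if (site$structure == "EAS") "IAS" else "background"
    outer <- if (site$structure == "IAS" && site$plane == "distal")
      "EAS" else "background"
    measure_thickness(slices[[site$plane]], center, site$clock,
                      site$structure, plane_levels[[site$plane]],
                      inner_ref = inner, outer_ref = outer)
  })
  out <- do.call(rbind, rows)
  out$thickness_mm <- round(out$thickness_mm, 2L)
  out$entry_mm <- round(out$entry_mm, 4L)
  out$exit_mm <- round(out$exit_mm, 4L)
  rownames(out) <- NULL
  out
}
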