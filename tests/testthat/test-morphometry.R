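test_that("clock positions map to the stated anatomical angles", {
  expect_equal(clock_to_angle(12), 90)   # anterior
  expect_equal(clock_to_angle(3), 0)     # patient left
  expect_equal(clock_to_angle(6), -90)   # posterior
  expect_equal(clock_to_angle(9), 180)   # patient right
  expect_equal(clock_to_angle(4), -30)
  expect_error(clock_to_angle(13), "1..12")
  expect_error(clock_to_angle(0), "1..12")
})

test_that("plane extraction selects the documented slice index", {
  vol <- voxel_grid(c(3, 3, 9), 1, data = array(seq_len(81), c(3, 3, 9)))
  mid <- extract_plane(vol, "mid")          # 2k+1 slices -> slice k
  expect_identical(mid$index, 4L)
  expect_identical(mid$data, vol$data[, , 5])
  expect_equal(mid$z, 4)
  vol100 <- voxel_grid(c(2, 2, 100), 1,
                       data = array(rnorm(400), c(2, 2, 100)))
  expect_identical(extract_plane(vol100, fraction = 0.25)$index, 24L)
  expect_identical(extract_plane(vol100, fraction = 1)$index, 99L)
  expect_error(extract_plane(vol100, fraction = 1.2), "fraction")
})

test_that("an ideal annulus measures its construction thickness at every clock position", {
  levels <- c(background = 0, IAS = 100)
  sl <- slice_from_profile(function(r) ifelse(r >= 5 & r < 7, 100, 0))
  for (ck in 1:12) {
    m <- measure_thickness(sl, c(0, 0), ck, "IAS", levels)
    expect_lt(abs(m$thickness_mm - 2), 0.05)
    expect_lt(abs(m$entry_mm - 5), 0.05)
  }
  # a uniform slice yields missing at all positions, not an error
  flat <- slice_from_profile(function(r) rep(0, length(r)))
  for (ck in c(3, 6, 9, 12)) {
    m <- measure_thickness(flat, c(0, 0), ck, "IAS", levels)
    expect_true(is.na(m$thickness_mm))
    expect_false(is.na(m$reason))
  }
})

test_that("blurred annulus measurements match a brute-force 1D FWHM oracle", {
  sigma <- 0.3
  prof <- function(r) 100 * (pnorm((r - 5) / sigma) - pnorm((r - 7) / sigma))
  sl <- slice_from_profile(prof, spacing = 0.2)
  m <- measure_thickness(sl, c(0, 0), 3, "IAS",
                         c(background = 0, IAS = 100), fan_rays = 1)
  # independent oracle: dense 1D profile scan for the half-maximum pair
  r <- seq(0, 10, by = 1e-4)
  above <- which(prof(r) >= 50)
  entry <- r[above[1]]
  exit <- r[above[length(above)]]
  step <- 0.25 * 0.2
  expect_lt(abs(m$entry_mm - entry), step)
  expect_lt(abs(m$exit_mm - exit), step)
  expect_lt(abs(m$thickness_mm - (exit - entry)), step)
})

test_that("walls between abutting structures use the half-level of the shared edge", {
  # IAS [5, 7) abutted by a dimmer outer ring [7, 9): the IAS exit must sit
  # at the shared wall, not at the outer ring's far edge
  levels <- c(background = 0, IAS = 100, EAS = 50)
  prof <- function(r) ifelse(r >= 5 & r < 7, 100, ifelse(r >= 7 & r < 9, 50, 0))
  sl <- slice_from_profile(prof)
  ias <- measure_thickness(sl, c(0, 0), 12, "IAS", levels, outer_ref = "EAS")
  expect_lt(abs(ias$thickness_mm - 2), 0.05)
  eas <- measure_thickness(sl, c(0, 0), 12, "EAS", levels, inner_ref = "IAS")
  expect_lt(abs(eas$thickness_mm - 2), 0.05)
  expect_lt(abs(eas$entry_mm - 7), 0.05)
  expect_lt(abs(eas$exit_mm - 9), 0.05)
})

test_that("the full protocol on an ideal phantom returns all 18 sites accurately", {
  gt <- make_phantom(phantom_spec())
  vol <- rasterize_truth(gt, phantom_grid(gt, spacing = 0.2))
  th <- measure_complex(vol, list(center = gt$center))
  expect_identical(nrow(th), 18L)
  sites <- asc_sites()
  expect_identical(th$structure, sites$structure)
  expect_identical(th$plane, sites$plane)
  expect_identical(th$clock, sites$clock)
  expect_false(any(is.na(th$thickness_mm)))
  expect_true(all(abs(th$thickness_mm - gt$thickness$thickness_mm) <= 0.1))
  # the automatically estimated canal centre matches the supplied one
  th_auto <- measure_complex(vol)
  expect_true(all(abs(th_auto$thickness_mm - th$thickness_mm) <= 0.1))
})

test_that("measurements are invariant under volume translation", {
  gt <- make_phantom(phantom_spec())
  grid <- phantom_grid(gt, spacing = 0.4)
  vol <- rasterize_truth(gt, grid)
  th <- measure_complex(vol, list(center = gt$center))
  moved <- voxel_grid(vol$dim, vol$spacing, vol$origin + c(13, -7, 2),
                      data = vol$data)
  th2 <- measure_complex(moved, list(center = gt$center + c(13, -7)))
  expect_identical(nrow(th2), 18L)
  expect_equal(th2$thickness_mm, th$thickness_mm, tolerance = 1e-12)
})

test_that("rotating the phantom a quarter turn maps 12 o'clock onto 3 o'clock", {
  gt <- make_phantom(phantom_spec())
  rot <- gt
  rot$field <- function(x, y, z) gt$field(y, -x, z)  # +90 deg about z
  grid <- phantom_grid(gt, spacing = 0.25)
  vol <- rasterize_truth(gt, grid)
  volr <- rasterize_truth(rot, grid)
  lv <- gt$spec$intensities[c("background", "IAS")]
  s <- extract_plane(vol, "proximal")
  sr <- extract_plane(volr, "proximal")
  m3 <- measure_thickness(s, gt$center, 3, "IAS", lv)
  m12r <- measure_thickness(sr, gt$center, 12, "IAS", lv)
  expect_lt(abs(m12r$thickness_mm - m3$thickness_mm), 0.25)
})

test_that("measured thickness tracks wall thickness, not ring radius", {
  # doubling the radius alone leaves thickness unchanged
  big <- make_phantom(phantom_spec(ias_inner_radius = 12))
  volb <- rasterize_truth(big, phantom_grid(big, spacing = 0.25))
  thb <- measure_complex(volb, list(center = big$center))
  ias_b <- thb$thickness_mm[thb$structure == "IAS"]
  expect_true(all(abs(ias_b - 2) <= 0.125))
  # doubling the wall doubles the measurement
  thick <- make_phantom(phantom_spec(ias_thickness = 4))
  volt <- rasterize_truth(thick, phantom_grid(thick, spacing = 0.25))
  tht <- measure_complex(volt, list(center = thick$center))
  ias_t <- tht$thickness_mm[tht$structure == "IAS"]
  expect_true(all(abs(ias_t - 4) <= 0.125))
})
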