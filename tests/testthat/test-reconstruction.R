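test_that("a constant field reconstructs to a constant volume with no missing voxels", {
  set.seed(61)
  cloud <- point_cloud(matrix(runif(900, 0, 6), ncol = 3), rep(7, 300))
  grid <- grid_from_box(c(1, 1, 1), c(5, 5, 5), spacing = 1)
  rec <- reconstruct_volume(cloud, grid, kernel_spec(1.5, order = 1))
  expect_identical(rec$report$n_missing, 0L)
  expect_equal(as.vector(rec$volume$data), rep(7, prod(grid$dim)),
               tolerance = 1e-10)
})

test_that("affine fields reconstruct exactly on the grid", {
  set.seed(62)
  f <- function(x, y, z) 2 + 3 * x - y + 0.5 * z
  cloud <- field_cloud(f, n = 800)
  grid <- grid_from_box(c(2, 2, 2), c(8, 8, 8), spacing = 0.75)
  rec <- reconstruct_volume(cloud, grid, kernel_spec(1.5, order = 1))
  cc <- voxel_centers(rec$volume)
  truth <- array(0, grid$dim)
  for (k in seq_along(cc$z))
    truth[, , k] <- outer(cc$x, cc$y, function(x, y) f(x, y, cc$z[k]))
  expect_lt(max(abs(rec$volume$data - truth)), 1e-6)
})

test_that("the compiled grid evaluator matches the reference point estimator", {
  set.seed(63)
  cloud <- point_cloud(matrix(runif(1500, 0, 10), ncol = 3), rnorm(500, 30, 10))
  grid <- grid_from_box(c(1, 1, 1), c(9, 9, 9), spacing = 2)
  for (ord in 0:2) {
    spec <- kernel_spec(1.6, order = ord)
    rec <- reconstruct_volume(cloud, grid, spec)
    cc <- voxel_centers(rec$volume)
    idx <- cbind(sample(grid$dim[1], 8, TRUE), sample(grid$dim[2], 8, TRUE),
                 sample(grid$dim[3], 8, TRUE))
    for (r in seq_len(nrow(idx))) {
      q <- c(cc$x[idx[r, 1]], cc$y[idx[r, 2]], cc$z[idx[r, 3]])
      expect_equal(rec$volume$data[idx[r, 1], idx[r, 2], idx[r, 3]],
                   estimate_point(q, cloud, spec), tolerance = 1e-8)
    }
  }
})

test_that("reconstruction is invariant to the cloud's record order", {
  set.seed(64)
  cloud <- point_cloud(matrix(runif(900, 0, 6), ncol = 3), rnorm(300, 10, 5))
  grid <- grid_from_box(c(1, 1, 1), c(5, 5, 5), spacing = 1)
  spec <- kernel_spec(1.4, order = 1)
  a <- reconstruct_volume(cloud, grid, spec)$volume$data
  perm <- sample(cloud$n)
  shuffled <- point_cloud(cloud$positions[perm, ], cloud$values[perm])
  b <- reconstruct_volume(shuffled, grid, spec)$volume$data
  expect_lt(max(abs(a - b)), 1e-10)
})

test_that("refining the grid leaves coinciding voxel centres unchanged", {
  set.seed(65)
  cloud <- point_cloud(matrix(runif(600, 0, 8), ncol = 3), rnorm(200, 5, 2))
  spec <- kernel_spec(1.8, order = 1)
  coarse <- reconstruct_volume(cloud, voxel_grid(c(4, 4, 4), 2, c(0.5, 0.5, 0.5)),
                               spec)$volume
  fine <- reconstruct_volume(cloud, voxel_grid(c(7, 7, 7), 1, c(0.5, 0.5, 0.5)),
                             spec)$volume
  sub <- fine$data[seq(1, 7, by = 2), seq(1, 7, by = 2), seq(1, 7, by = 2)]
  expect_equal(coarse$data, sub, tolerance = 1e-12)
})

test_that("shrinking the bandwidth never decreases the missing count", {
  set.seed(66)
  cloud <- point_cloud(matrix(runif(90, 0, 10), ncol = 3), rnorm(30))
  grid <- grid_from_box(c(0, 0, 0), c(10, 10, 10), spacing = 2)
  miss <- vapply(c(1.5, 0.8, 0.4, 0.2), function(h)
    reconstruct_volume(cloud, grid, kernel_spec(h))$report$n_missing,
    integer(1))
  expect_true(all(diff(miss) >= 0))
})

test_that("tiny bandwidths are rejected as a configuration error", {
  set.seed(67)
  cloud <- point_cloud(matrix(runif(300, 0, 10), ncol = 3), rnorm(100))
  grid <- grid_from_box(c(0, 0, 0), c(10, 10, 10), spacing = 5)
  expect_error(reconstruct_volume(cloud, grid, kernel_spec(1e-9)),
               "missing")
})

test_that("nearest-neighbour baseline matches the exhaustive search", {
  # single-point cloud paints the whole volume
  one <- point_cloud(rbind(c(5, 5, 5)), 42)
  grid <- grid_from_box(c(0, 0, 0), c(9, 9, 9), spacing = 3)
  vol <- nearest_neighbor_baseline(one, grid)
  expect_true(all(vol$data == 42))
  # voxel coinciding with a cloud point takes that point's value
  set.seed(68)
  pts <- rbind(c(0, 0, 0), c(9, 0, 3), c(3, 6, 9), c(6, 6, 0), c(2, 8, 5))
  cloud <- point_cloud(pts, c(10, 20, 30, 40, 50))
  vol <- nearest_neighbor_baseline(cloud, grid)
  expect_identical(vol$data[1, 1, 1], 10)
  expect_identical(vol$data[2, 3, 4], 30)  # centre (3, 6, 9)
  # full agreement with the O(P * V) double loop
  cc <- voxel_centers(vol)
  query <- as.matrix(expand.grid(cc$x, cc$y, cc$z))
  expect_equal(as.vector(vol$data), cloud$values[brute_nn(pts, query)])
})

test_that("the default bandwidth is 1.5 x the median nearest-neighbour distance", {
  lat <- as.matrix(expand.grid(0:4, 0:4, 0:4))
  cloud <- point_cloud(lat, rnorm(125))
  expect_equal(default_bandwidth(cloud), 1.5)
  # homogeneity: scaling positions scales the bandwidth
  scaled <- point_cloud(lat * 2.5, cloud$values)
  expect_equal(default_bandwidth(scaled), 2.5 * 1.5)
  # against a direct computation on a random cloud
  set.seed(69)
  pos <- matrix(runif(3 * 2000, 0, 10), ncol = 3)
  d <- as.matrix(dist(pos))
  diag(d) <- Inf
  expect_equal(default_bandwidth(point_cloud(pos, rnorm(2000))),
               1.5 * median(apply(d, 1, min)), tolerance = 1e-12)
})

test_that("PSNR matches its closed form and handles the zero-MSE case", {
  a <- voxel_grid(c(2, 2, 2), 1, data = array(0, c(2, 2, 2)))
  expect_identical(psnr(a, a), Inf)
  b <- voxel_grid(c(2, 2, 2), 1, data = array(rep(c(0, 1), 4), c(2, 2, 2)))
  shifted <- voxel_grid(c(2, 2, 2), 1, data = b$data + 1)
  expect_equal(psnr(shifted, b), 0)  # MSE equals the squared range
  # hand-computed 2x2x2 fixture: reference range 2, MSE 2
  ref <- voxel_grid(c(2, 2, 2), 1, data = array(rep(c(0, 2), 4), c(2, 2, 2)))
  noisy <- voxel_grid(c(2, 2, 2), 1,
                      data = ref$data + array(rep(c(2, 0), 4), c(2, 2, 2)) - 1)
  expect_equal(psnr(noisy, ref), 10 * log10(4 / mean((noisy$data - ref$data)^2)))
  # missing voxels are excluded pairwise
  holey <- ref
  holey$data[1, 1, 1] <- NA
  holey <- voxel_grid(c(2, 2, 2), 1, data = holey$data)
  expect_true(is.finite(psnr(holey, ref)) || is.infinite(psnr(holey, ref)))
  expect_error(psnr(ref, voxel_grid(c(2, 2, 3), 1)), "geometry")
})
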