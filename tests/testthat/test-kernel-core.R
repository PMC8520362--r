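test_that("Gaussian kernel is symmetric, maximal at the origin, and matches the closed form", {
  expect_equal(gaussian_kernel(c(0, 0, 0), h = 0.7), 1)
  u <- c(1, 2, 3)
  expect_identical(gaussian_kernel(u, h = 2), gaussian_kernel(-u, h = 2))
  # decay by one bandwidth along any axis
  expect_equal(gaussian_kernel(c(2, 0, 0), h = 2) / gaussian_kernel(c(0, 0, 0), h = 2),
               exp(-1 / 2), tolerance = 1e-12)
  # mode at the origin over random offsets
  set.seed(11)
  offs <- matrix(rnorm(60), ncol = 3)
  expect_true(all(gaussian_kernel(offs, h = 1.3) <= 1))
  expect_error(gaussian_kernel(c(1, 0, 0), h = 0), "positive")
  expect_error(gaussian_kernel(c(1, 0, NA), h = 1), "finite")
})

test_that("local weights decrease with distance and are isotropic", {
  ctr <- c(1, 2, 3)
  nb <- rbind(ctr, ctr + c(2, 0, 0), ctr + c(0, 0, 2), ctr + c(0, 5, 0))
  w <- local_weights(ctr, nb, h = 1.5)
  expect_equal(unname(which.max(w)), 1L)      # coincident neighbour dominates
  expect_equal(w[2], w[3], tolerance = 1e-14) # equal distance, any direction
  w2 <- local_weights(c(0, 0, 0), rbind(c(1, 0, 0), c(0, 2, 0)), h = 1)
  expect_equal(w2[1] / w2[2], exp(1.5), tolerance = 1e-12)
  expect_error(local_weights(ctr, nb[0, , drop = FALSE], h = 1), "empty")
  # strict monotonicity over seeded configurations
  for (s in 1:10) {
    set.seed(s)
    d <- sort(runif(8, 0.1, 4))
    nb <- cbind(d, 0, 0)
    w <- local_weights(c(0, 0, 0), nb, h = runif(1, 0.3, 2))
    expect_true(all(diff(w) < 0))
  }
})

test_that("design matrix has the documented monomial layout", {
  row1 <- build_design(c(1, 1, 1), rbind(c(1 + 0.3, 1 - 0.2, 1 + 0.5)), order = 1)
  expect_equal(unname(row1), matrix(c(1, 0.3, -0.2, 0.5), nrow = 1),
               tolerance = 1e-12)
  X0 <- build_design(c(0, 0, 0), matrix(rnorm(15), ncol = 3), order = 0)
  expect_identical(unname(X0), matrix(1, 5, 1))
  X2 <- build_design(c(0, 0, 0), rbind(c(2, 3, 4)), order = 2)
  expect_identical(ncol(X2), 10L)  # monomials of degree <= 2 in 3 variables
  expect_equal(unname(X2[1, ]), c(1, 2, 3, 4, 4, 6, 8, 9, 12, 16),
               tolerance = 1e-12)
  expect_error(build_design(c(0, 0, 0), rbind(c(1, 1, 1)), order = 3), "order")
})

test_that("local fits reproduce constant and affine fields exactly", {
  set.seed(21)
  nb <- matrix(runif(42, -1, 1), ncol = 3)
  ctr <- c(0.1, -0.2, 0.3)
  w <- local_weights(ctr, nb, h = 1)
  # constant reproduction at any order (14 points keep order 2 full rank)
  for (ord in 0:2) {
    fit <- fit_local(build_design(ctr, nb, ord), w, rep(4.25, 14), 0)
    expect_equal(fit$estimate, 4.25, tolerance = 1e-10)
    expect_equal(unname(fit$beta[-1]), rep(0, length(fit$beta) - 1),
                 tolerance = 1e-9)
  }
  # affine field: estimate is the field at the centre, gradient recovered
  f <- function(p) 2 + 3 * p[, 1] - p[, 2] + 0.5 * p[, 3]
  fit <- fit_local(build_design(ctr, nb, 1), w, f(nb), 0)
  expect_equal(fit$estimate, unname(f(rbind(ctr))[1]), tolerance = 1e-10)
  expect_equal(unname(fit$beta[2:4]), c(3, -1, 0.5), tolerance = 1e-9)
})

test_that("local fits agree with the explicit-loop normal-equation oracle", {
  for (s in 1:100) {
    set.seed(s)
    ord <- s %% 3
    n <- basis_size_for(ord) + sample(2:6, 1)
    nb <- matrix(runif(3 * n, -2, 2), ncol = 3)
    ctr <- runif(3, -0.5, 0.5)
    w <- local_weights(ctr, nb, h = runif(1, 0.8, 2.5))
    y <- rnorm(n, 10, 3)
    X <- build_design(ctr, nb, ord)
    fit <- fit_local(X, w, y, 0)
    expect_equal(unname(fit$beta), brute_wls(X, w, y),
                 tolerance = 1e-10)
    # weighted normal equations are satisfied to near machine precision
    res <- crossprod(X, w * (y - X %*% fit$beta))
    expect_lt(max(abs(res)) / max(abs(crossprod(X, w * y))), 1e-8)
  }
})

test_that("degenerate local-fit inputs raise the documented errors", {
  X <- build_design(c(0, 0, 0), rbind(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_error(fit_local(X, c(0, 0), c(1, 2), 0), "empty neighbourhood")
  expect_error(fit_local(X, c(1, NA), c(1, 2), 0), "finite")
  expect_error(fit_local(X, c(1, 1), c(1, Inf), 0), "finite")
  # rank-deficient design (all points coincident) still solves via the
  # documented deterministic ridge fallback
  Xd <- build_design(c(0, 0, 0), rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1),
                                       c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)), 1)
  fit <- fit_local(Xd, rep(1, 6), rep(3, 6), 1e-10)
  expect_true(is.finite(fit$estimate))
  fit2 <- fit_local(Xd, rep(1, 6), rep(3, 6), 1e-10)
  expect_identical(fit$beta, fit2$beta)
})

test_that("point estimates reduce to the Nadaraya-Watson mean at order 0", {
  set.seed(31)
  cloud <- point_cloud(matrix(runif(300, 0, 5), ncol = 3), rnorm(100, 20, 4))
  spec <- kernel_spec(1.2, order = 0)
  q <- c(2.5, 2.5, 2.5)
  est <- estimate_point(q, cloud, spec)
  d2 <- colSums((t(cloud$positions) - q)^2)
  sel <- d2 <= (3 * 1.2)^2
  w <- exp(-d2[sel] / (2 * 1.2^2))
  expect_equal(est, sum(w * cloud$values[sel]) / sum(w), tolerance = 1e-12)
})

test_that("polynomial fields of degree <= order are reproduced exactly", {
  for (s in 1:50) {
    set.seed(100 + s)
    ord <- s %% 3
    f <- random_poly_field(ord)
    cloud <- field_cloud(f, n = 350)
    spec <- kernel_spec(runif(1, 1.5, 3), order = ord)
    q <- runif(3, 3, 7)
    est <- estimate_point(q, cloud, spec)
    truth <- f(q[1], q[2], q[3])
    expect_equal(est, truth, tolerance = 1e-8)
  }
})

test_that("estimates converge to the global mean for huge bandwidths", {
  set.seed(41)
  cloud <- point_cloud(matrix(runif(600, 0, 10), ncol = 3), rnorm(200, 5, 2))
  spec <- kernel_spec(1e6 * 10, order = 0)
  expect_equal(estimate_point(c(5, 5, 5), cloud, spec), mean(cloud$values),
               tolerance = 1e-9)
})

test_that("sparse neighbourhoods degrade order and empty support is missing", {
  cloud <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                       c(1, 2, 3, 4))
  # 4 neighbours cannot support a quadratic (needs >= 12): order degrades
  det <- estimate_point(c(0.2, 0.2, 0.2), cloud, kernel_spec(2, order = 2),
                        details = TRUE)
  expect_lt(det$order_used, 2L)
  expect_identical(det$n_used, 4L)
  # far query point: no neighbour in support -> missing marker, not an error
  expect_true(is.na(estimate_point(c(100, 100, 100), cloud, kernel_spec(2))))
})

test_that("estimates are equivariant under translation and rotation", {
  set.seed(51)
  f <- random_poly_field(1)
  cloud <- field_cloud(f, n = 250)
  spec <- kernel_spec(2, order = 1)
  q <- c(5, 5, 5)
  base <- estimate_point(q, cloud, spec)
  shift <- c(3.2, -1.7, 8.9)
  shifted <- point_cloud(sweep(cloud$positions, 2, -shift), cloud$values)
  expect_equal(estimate_point(q + shift, shifted, spec), base,
               tolerance = 1e-10)
  Q <- random_rotation()
  rotated <- point_cloud(cloud$positions %*% t(Q), cloud$values)
  expect_equal(estimate_point(drop(Q %*% q), rotated, spec), base,
               tolerance = 1e-10)
})
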