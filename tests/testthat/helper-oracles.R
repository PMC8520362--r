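# Independent oracles used to cross-check the package implementation.
# These are deliberately written the slow, explicit way.

basis_size_for <- function(order) c(1L, 4L, 10L)[order + 1L]

# weighted normal equations built by explicit loops, solved with base solve()
brute_wls <- function(design, weights, values) {
  k <- ncol(design)
  n <- nrow(design)
  M <- matrix(0, k, k)
  v <- numeric(k)
  for (i in seq_len(n)) {
    for (a in seq_len(k)) {
      v[a] <- v[a] + weights[i] * design[i, a] * values[i]
      for (b in seq_len(k)) {
        M[a, b] <- M[a, b] + weights[i] * design[i, a] * design[i, b]
      }
    }
  }
  drop(solve(M, v))
}

# exhaustive nearest-neighbour search with lowest-index tie breaking
brute_nn <- function(positions, query) {
  best <- integer(nrow(query))
  for (j in seq_len(nrow(query))) {
    d2 <- rep(Inf, nrow(positions))
    for (i in seq_len(nrow(positions)))
      d2[i] <- sum((positions[i, ] - query[j, ])^2)
    best[j] <- which.min(d2)  # which.min takes the first (lowest index) tie
  }
  best
}

# random rotation matrix (det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# random polynomial field of total degree <= deg in 3 variables,
# returned as a vectorized function together with its coefficients
random_poly_field <- function(deg) {
  co <- runif(10, -2, 2)
  function(x, y, z) {
    f <- rep(co[1], length(x))
    if (deg >= 1) f <- f + co[2] * x + co[3] * y + co[4] * z
    if (deg >= 2) f <- f + co[5] * x^2 + co[6] * x * y + co[7] * x * z +
        co[8] * y^2 + co[9] * y * z + co[10] * z^2
    f
  }
}

# build an axial slice directly from a radial intensity profile
slice_from_profile <- function(profile_fun, half_extent = 10, spacing = 0.1) {
  xs <- seq(-half_extent, half_extent, by = spacing)
  data <- outer(xs, xs, function(x, y) profile_fun(sqrt(x^2 + y^2)))
  structure(list(data = data, spacing = c(spacing, spacing),
                 origin = c(-half_extent, -half_extent),
                 z = 0, index = 0L, plane = NA_character_),
            class = "axial_slice")
}

# a small dense cloud sampling a given field without noise
field_cloud <- function(field, n = 400, lo = c(0, 0, 0), hi = c(10, 10, 10)) {
  pos <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
  point_cloud(pos, field(pos[, 1], pos[, 2], pos[, 3]))
}
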