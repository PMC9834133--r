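test_that("the Fibonacci sphere is deterministic and quasi-uniform", {
  s1 <- make_sphere_source_space(1, radius = 0.07)
  expect_equal(dim(s1$positions), c(1L, 3L))
  expect_equal(sqrt(sum(s1$positions^2)), 0.07, tolerance = 1e-12)
  expect_equal(s1$orientations[1, ],
               s1$positions[1, ] / sqrt(sum(s1$positions^2)),
               tolerance = 1e-12)

  sp <- make_sphere_source_space(500, radius = 0.08)
  expect_equal(unname(sqrt(rowSums(sp$positions^2))), rep(0.08, 500),
               tolerance = 1e-10)
  expect_equal(unname(sqrt(rowSums(sp$orientations^2))), rep(1, 500),
               tolerance = 1e-10)
  # lattice-uniformity oracle: nearest-neighbor distances concentrate
  d <- as.matrix(dist(sp$positions))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_lt(sd(nn) / mean(nn), 0.5)
  # reproducible
  expect_identical(sp$positions, make_sphere_source_space(500, 0.08)$positions)

  tang <- make_sphere_source_space(100, orientation = "tangential")
  rad <- tang$positions / sqrt(rowSums(tang$positions^2))
  expect_lt(max(abs(rowSums(tang$orientations * rad))), 1e-10)
})

test_that("radial dipoles are magnetically silent in the spherical model", {
  sp <- make_sphere_source_space(80, radius = 0.08, orientation = "radial")
  sens <- make_sensor_array(40, radius = 0.12)
  M <- make_meg_leadfield(sp, sens)
  typical <- sqrt(mean(M^2)) * sqrt(nrow(M))
  for (j in seq_len(sp$n)) {
    idx <- (3 * j - 2):(3 * j)
    f_rad <- sqrt(sum((M[, idx] %*% sp$orientations[j, ])^2))
    expect_lt(f_rad / norm(M, "F"), 1e-6)
  }
  # linearity in the moment is inherited from the matrix form
  q <- c(0.3, -1, 2)
  j <- 17
  idx <- (3 * j - 2):(3 * j)
  expect_equal(as.vector(M[, idx] %*% (2 * q)),
               2 * as.vector(M[, idx] %*% q), tolerance = 1e-14)
})

test_that("the Sarvas radial field equals the primary-current dipole field", {
  # volume currents contribute nothing to the radial component in a sphere,
  # so against radially oriented sensors the closed form must agree with
  # the free-space Biot-Savart field of the primary current dipole alone
  sp <- make_sphere_source_space(25, radius = 0.07, orientation = "tangential")
  sens <- make_sensor_array(30, radius = 0.1)
  M <- make_meg_leadfield(sp, sens)
  mu0_4pi <- 1e-7
  for (j in c(1, 7, 25)) {
    idx <- (3 * j - 2):(3 * j)
    q <- sp$orientations[j, ] * 1e-8   # tangential unit dipole, 10 nAm
    got <- as.vector(M[, idx] %*% q)
    r0 <- sp$positions[j, ]
    for (i in seq_len(sens$m)) {
      r <- sens$positions[i, ]
      a <- r - r0
      B_primary <- mu0_4pi * c(q[2] * a[3] - q[3] * a[2],
                               q[3] * a[1] - q[1] * a[3],
                               q[1] * a[2] - q[2] * a[1]) / sum(a^2)^1.5
      expect_equal(got[i], sum(B_primary * sens$orientations[i, ]),
                   tolerance = 1e-10)
    }
  }
  # sensors inside the conductor are a geometry error
  expect_error(make_meg_leadfield(sp, make_sensor_array(10, radius = 0.05)),
               "inside")
})

test_that("random lead fields are reproducible with concentrated columns", {
  A <- make_random_leadfield(6, 4, seed = 5)
  expect_identical(A, make_random_leadfield(6, 4, seed = 5))
  expect_false(identical(A, make_random_leadfield(6, 4, seed = 6)))
  # chi-distribution oracle: column norms near sqrt(m)
  B <- make_random_leadfield(500, 10, seed = 7)
  expect_lt(max(abs(sqrt(colSums(B^2)) / sqrt(500) - 1)), 0.2)
})

test_that("patch activation matches a brute-force distance filter", {
  sp <- make_sphere_source_space(200, radius = 0.08)
  center <- sp$positions[42, ]
  radius <- 0.02
  patch <- simulate_patch(sp, center, radius, amplitude = 2, timecourse = c(1, 0.5))
  oracle <- which(sqrt(colSums((t(sp$positions) - center)^2)) <= radius)
  expect_identical(patch$support, oracle)
  expect_equal(patch$Q_true[oracle[1], , 1], 2 * sp$orientations[oracle[1], ],
               tolerance = 1e-14)
  expect_equal(patch$Q_true[, , 2], 0.5 * patch$Q_true[, , 1],
               tolerance = 1e-14)
  expect_true(all(patch$Q_true[-oracle, , ] == 0))

  # radius below the nearest-neighbor distance selects only the center vertex
  d <- sort(sqrt(colSums((t(sp$positions) - center)^2)))
  solo <- simulate_patch(sp, center, d[2] * 0.99)
  expect_identical(solo$support, 42L)

  expect_equal(max(abs(simulate_patch(sp, center, radius,
                                      amplitude = 0)$Q_true)), 0)
  expect_error(simulate_patch(sp, c(1, 1, 1), 1e-4), "nearest dipole")
})

test_that("added noise hits the target SNR and has zero mean", {
  set.seed(8)
  clean <- matrix(rnorm(100 * 100), 100)
  noisy <- add_noise(clean, snr_target = 15, seed = 9)
  eps <- noisy - clean
  realized <- mean(colSums(clean^2)) / mean(colSums(eps^2))
  expect_lt(abs(realized / 15 - 1), 0.05)
  expect_lt(abs(mean(eps)), 3 * sd(eps) / sqrt(length(eps)))
  expect_identical(noisy, add_noise(clean, 15, seed = 9))
  expect_identical(add_noise(clean, Inf, seed = 1), clean)
  expect_error(add_noise(clean * 0, 10, seed = 1), "zero")
})

test_that("scenarios wire the pieces together consistently", {
  sc <- make_scenario(n = 150, m = 24, patch_size = 5, snr = 15,
                      timecourse = rep(1, 80), seed = 4)
  expect_length(sc$support, 5)
  expect_equal(sc$clean[, 1],
               as.vector(sc$leadfield %*% as_vec3(sc$Q_true[, , 1])),
               tolerance = 1e-14)
  eps <- sc$noisy - sc$clean
  realized <- mean(colSums(sc$clean^2)) / mean(colSums(eps^2))
  expect_lt(abs(realized / 15 - 1), 0.1)
  # background activity scaled to a stated brain-SNR
  bgy <- add_brain_noise(sc$clean, sc$leadfield, sc$space, brain_snr = 4,
                         seed = 11)
  bg <- bgy - sc$clean
  expect_lt(abs(mean(colSums(sc$clean^2)) / mean(colSums(bg^2)) / 4 - 1), 1e-10)
})
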