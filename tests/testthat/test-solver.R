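test_that("the Gibbs energy matches a term-by-term dense oracle", {
  p <- small_problem(51, n = 4, m = 7, delta = 0.2, eta = 0.7)
  set.seed(52)
  Qm <- matrix(rnorm(12), 4, 3)
  theta <- exp(rnorm(4, sd = 0.5))
  en <- ias_energy(Qm, theta, p$b, p$leadfield, p$prior, p$theta_star,
                   p$eta, p$noise)
  # independent dense evaluation
  r <- p$b - p$leadfield %*% as_vec3(Qm)
  misfit <- 0.5 * sum(r^2) / p$noise$sigma2
  qC <- vapply(1:4, function(j) {
    as.numeric(t(Qm[j, ]) %*% solve(p$prior$blocks[, , j], Qm[j, ]))
  }, 1)
  oracle <- misfit + 0.5 * sum(qC / theta) - p$eta * sum(log(theta)) +
    sum(theta / p$theta_star)
  expect_equal(en, oracle, tolerance = 1e-12)

  # hand-expanded special case: Q = 0, b = 0, theta = theta*, eta = 1
  en0 <- ias_energy(matrix(0, 4, 3), p$theta_star, rep(0, 7), p$leadfield,
                    p$prior, p$theta_star, 1, p$noise)
  expect_equal(en0, sum(1 - log(p$theta_star)), tolerance = 1e-12)

  expect_error(ias_energy(Qm, c(-1, theta[-1]), p$b, p$leadfield, p$prior,
                          p$theta_star, p$eta, p$noise), "positive")
})

test_that("the closed-form theta update is the 1-D minimizer", {
  # fixed-point examples forced by the formula
  ss <- source_space(matrix(0, 1, 3), matrix(c(0, 0, 1), 1))
  pr <- anatomical_prior(ss, delta = 1)
  expect_equal(update_theta(matrix(0, 1, 3), pr, theta_star = 2, eta = 0.01),
               0.02, tolerance = 1e-14)
  # eta = 0 with ||q||^2_C = 2 theta*: the square root collapses to 1
  q <- matrix(c(sqrt(2 * 3), 0, 0), 1)   # ||q||^2 = 2 * theta* with C = I
  expect_equal(update_theta(q, pr, theta_star = 3, eta = 0), 3,
               tolerance = 1e-12)

  # 1-D numerical minimization oracle on part (b) of the energy
  part_b <- function(th, qC, eta, ts) qC / th - 2 * eta * log(th) + 2 * th / ts
  q2 <- matrix(c(sqrt(0.5), 0, 0), 1)
  got <- update_theta(q2, pr, theta_star = 1, eta = 0.1)
  opt <- optimize(part_b, c(1e-8, 50), qC = 0.5, eta = 0.1, ts = 1,
                  tol = 1e-12)$minimum
  expect_equal(got, opt, tolerance = 1e-8)
  expect_equal(got, 0.05 + sqrt(0.0025 + 0.25), tolerance = 1e-12)

  # the update is a strict minimizer: +/- 1% perturbations increase part (b)
  set.seed(53)
  for (r in 1:20) {
    qC <- exp(rnorm(1))
    eta <- runif(1, 1e-4, 0.5)
    ts <- exp(rnorm(1))
    qv <- matrix(c(sqrt(qC), 0, 0), 1)
    th <- update_theta(qv, pr, theta_star = ts, eta = eta)
    f0 <- part_b(th, qC, eta, ts)
    expect_gt(part_b(th * 1.01, qC, eta, ts), f0)
    expect_gt(part_b(th * 0.99, qC, eta, ts), f0)
    expect_gte(th, eta * ts)
  }
})

test_that("replacing theta by its update never increases the energy", {
  for (r in 1:100) {
    p <- small_problem(100 + r, n = 3, m = 5, eta = 0.05)
    set.seed(300 + r)
    Qm <- matrix(rnorm(9), 3, 3)
    theta0 <- exp(rnorm(3))
    e0 <- ias_energy(Qm, theta0, p$b, p$leadfield, p$prior, p$theta_star,
                     p$eta, p$noise)
    theta1 <- update_theta(Qm, p$prior, p$theta_star, p$eta)
    e1 <- ias_energy(Qm, theta1, p$b, p$leadfield, p$prior, p$theta_star,
                     p$eta, p$noise)
    expect_lte(e1, e0 + 1e-12 * abs(e0))
  }
})

test_that("priorconditioned CGLS reproduces dense least-squares solutions", {
  # undamped route, consistent overdetermined system: exact recovery
  p <- small_problem(61, n = 2, m = 8)
  set.seed(62)
  Q_true <- matrix(rnorm(6), 2, 3)
  b <- as.vector(p$leadfield %*% as_vec3(Q_true))
  theta <- rep(1, 2)
  ctrl0 <- ias_control(max_it = 200, inner_stop = "max_it", damp = 0)
  out <- solve_Q(b, p$leadfield, p$prior, theta, p$noise, ctrl0)
  expect_lt(max(abs(out$field$moments - Q_true)), 1e-8)

  # undamped, underdetermined: minimum-norm priorconditioned solution
  p2 <- small_problem(63, n = 5, m = 10)
  set.seed(64)
  theta2 <- exp(rnorm(5, sd = 0.4))
  s_th <- rep(sqrt(theta2), each = 3)
  D_dense <- matrix(0, 15, 15)
  for (j in 1:5) {
    idx <- (3 * j - 2):(3 * j)
    D_dense[idx, idx] <- p2$prior$factor[, , j]
  }
  A <- (p2$leadfield / p2$noise$sigma) %*% t(D_dense) %*% diag(s_th)
  y <- p2$b / p2$noise$sigma
  w_mn <- pinv(A) %*% y
  Q_mn <- as_rows3(t(D_dense) %*% (s_th * w_mn))
  out2 <- solve_Q(p2$b, p2$leadfield, p2$prior, theta2, p2$noise, ctrl0)
  expect_lt(max(abs(out2$field$moments - Q_mn)), 1e-6)
  expect_true(all(diff(out2$resnorms) <= 1e-10 * out2$resnorms[1]))

  # damped route (the quadratic step of the alternation): matches the
  # dense solution of min ||y - Aw||^2 + ||w||^2
  ctrl1 <- ias_control(max_it = 200, inner_stop = "max_it", damp = 1)
  w_damped <- solve(crossprod(A) + diag(15), crossprod(A, y))
  Q_damped <- as_rows3(t(D_dense) %*% (s_th * w_damped))
  out3 <- solve_Q(p2$b, p2$leadfield, p2$prior, theta2, p2$noise, ctrl1)
  expect_lt(max(abs(out3$field$moments - Q_damped)), 1e-8)
  expect_true(all(diff(out3$resnorms) <= 1e-10 * out3$resnorms[1]))

  # zero data: zero solution after zero iterations
  out0 <- solve_Q(rep(0, 10), p2$leadfield, p2$prior, theta2, p2$noise)
  expect_equal(out0$inner, 0L)
  expect_true(all(out0$field$moments == 0))

  expect_error(solve_Q(p2$b, p2$leadfield * NA, p2$prior, theta2, p2$noise),
               "non-finite")
})

test_that("zero data drives IAS to its fixed point in exactly 2 iterations", {
  p <- small_problem(71, n = 6, m = 9, eta = 0.01)
  fit <- ias_solve(rep(0, 9), p$prior, p$model)
  expect_true(all(fit$field$moments == 0))
  expect_equal(fit$theta, 0.01 * p$theta_star, tolerance = 1e-14)
  expect_identical(nrow(fit$diagnostics), 2L)
  expect_true(fit$converged)
  expect_equal(unname(fit$diagnostics[2, "rel_change"]), 0)
})

test_that("the energy is non-increasing along exact outer iterations", {
  ctrl <- ias_control(max_it = 500, inner_stop = "max_it")
  for (r in 1:50) {
    p <- small_problem(400 + r, n = 3, m = 5, eta = 0.05)
    theta <- p$theta_star
    en_prev <- Inf
    for (k in 1:8) {
      out <- solve_Q(p$b, p$leadfield, p$prior, theta, p$noise, ctrl)
      theta <- update_theta(out$field, p$prior, p$theta_star, p$eta)
      en <- ias_energy(out$field, theta, p$b, p$leadfield, p$prior,
                       p$theta_star, p$eta, p$noise)
      expect_lte(en, en_prev + 1e-9 * abs(en))
      en_prev <- en
    }
  }
})

test_that("IAS reaches the global minimum of the energy", {
  ctrl <- ias_control(tau = 1e-10, n_outer = 400, max_it = 500,
                      inner_stop = "max_it")
  for (r in 1:5) {
    p <- small_problem(500 + r, n = 3, m = 5, eta = 0.05)
    fit <- ias_solve(p$b, p$prior, p$model, ctrl)
    en_bf <- brute_force_energy_min(p$b, p$leadfield, p$prior, p$theta_star,
                                    p$eta, p$noise, seed = r)
    expect_equal(fit$energy, en_bf, tolerance = 1e-6)
  }
})

test_that("solver rejects inconsistent dimensions before iterating", {
  p <- small_problem(81, n = 4, m = 6)
  expect_error(ias_solve(rep(0, 5), p$prior, p$model), "does not match")
  bad <- p$model
  bad$theta_star <- bad$theta_star[-1]
  expect_error(ias_solve(p$b, p$prior, bad), "theta_star")
  expect_error(ias_solve(p$b, p$prior, p$model,
                         theta_init = rep(-1, 4)), "theta_init")
})

test_that("warm starting speeds up constant and smooth time series", {
  p <- small_problem(91, n = 8, m = 12, eta = 0.01)
  # constant-in-time data: slice 2 starts near the slice-1 fixed point and
  # needs at most 2 outer iterations to certify convergence
  B <- cbind(p$b, p$b)
  res <- ias_time_series(B, p$prior, p$model, warm_start = TRUE)
  expect_lte(nrow(res$diagnostics[[2]]), 2)
  expect_equal(res$Q_hat[, , 1], res$Q_hat[, , 2], tolerance = 0.05)

  # smooth time course: mean outer iterations warm <= cold
  set.seed(92)
  tc <- sin(seq(0, pi, length.out = 20))
  Bs <- outer(p$b, tc) + matrix(rnorm(12 * 20, sd = 0.01), 12)
  warm <- ias_time_series(Bs, p$prior, p$model, warm_start = TRUE)
  cold <- ias_time_series(Bs, p$prior, p$model, warm_start = FALSE)
  outer_iters <- function(res) vapply(res$diagnostics, nrow, 1L)
  expect_lte(mean(outer_iters(warm)), mean(outer_iters(cold)))
  # t = 1 reduces to a single solve
  one <- ias_time_series(p$b, p$prior, p$model)
  single <- ias_solve(p$b, p$prior, p$model)
  expect_equal(one$Q_hat[, , 1], single$field$moments, tolerance = 1e-14)
})

test_that("a non-finite slice is reported and the rest still processed", {
  p <- small_problem(95, n = 4, m = 6)
  # scale the data well above the unit noise floor so slices produce
  # nonzero reconstructions under the discrepancy stop
  p$b <- 10 * p$b
  B <- cbind(p$b, NA * p$b, p$b)
  res <- ias_time_series(B, p$prior, p$model)
  expect_match(res$errors[2], "slice 2")
  expect_true(is.na(res$errors[1]) && is.na(res$errors[3]))
  expect_true(all(res$Q_hat[, , 2] == 0))
  expect_gt(max(abs(res$Q_hat[, , 3])), 0)
})

test_that("scaling the problem consistently leaves the solution invariant", {
  # multiplying Sigma by c^2 and b, M by c leaves Q unchanged
  p <- small_problem(97, n = 10, m = 8)
  cfac <- 3.7
  m1 <- p$model
  fit1 <- ias_solve(p$b, p$prior, m1)
  m2 <- list(leadfield = p$leadfield * cfac, theta_star = p$theta_star,
             eta = p$eta, noise = noise_model(8, sigma2 = p$noise$sigma2 *
                                                cfac^2))
  fit2 <- ias_solve(p$b * cfac, p$prior, m2)
  expect_equal(fit1$field$moments, fit2$field$moments, tolerance = 1e-10)
})
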