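# Shared fixtures and independent numerical oracles.

# random unit vectors, n x 3
random_unit_rows <- function(n, seed) {
  set.seed(seed)
  v <- matrix(rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

# a small random inverse problem with everything the solver needs
small_problem <- function(seed, n = 5, m = 10, delta = 0.3, eta = 0.01,
                          sigma2 = 1) {
  set.seed(seed)
  space <- source_space(matrix(rnorm(3 * n), n, 3), random_unit_rows(n, seed + 1))
  prior <- anatomical_prior(space, delta)
  leadfield <- make_random_leadfield(m, n, seed + 2)
  set.seed(seed + 3)
  theta_star <- exp(rnorm(n, sd = 0.3))
  noise <- noise_model(m, sigma2 = sigma2)
  set.seed(seed + 4)
  b <- rnorm(m)
  list(space = space, prior = prior, leadfield = leadfield,
       theta_star = theta_star, eta = eta, noise = noise, b = b,
       model = list(leadfield = leadfield, theta_star = theta_star,
                    eta = eta, noise = noise))
}

# Moore-Penrose pseudoinverse via SVD (dense least-squares oracle)
pinv <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# interleave n x 3 rows into a length-3n vector (dipole-major), as the
# lead-field columns are ordered
as_vec3 <- function(V) as.vector(t(V))
as_rows3 <- function(v) matrix(v, ncol = 3, byrow = TRUE)

# dense 3n x 3n inverse of C_theta from the prior's inverse blocks
dense_Ctheta_inv <- function(prior, theta) {
  n <- prior$n
  out <- matrix(0, 3 * n, 3 * n)
  for (j in seq_len(n)) {
    idx <- (3 * j - 2):(3 * j)
    out[idx, idx] <- prior$inv_blocks[, , j] / theta[j]
  }
  out
}

# Independent brute-force minimizer of the Gibbs energy: alternates a dense
# normal-equations solve for Q (no CGLS) with per-coordinate 1-D numerical
# minimization for theta (no closed form), iterated to 1e-10 relative energy
# change, from multiple random starts; returns the best energy found.
brute_force_energy_min <- function(b, leadfield, prior, theta_star, eta,
                                   noise, n_starts = 3, seed = 1,
                                   max_sweeps = 2000) {
  n <- prior$n
  m <- length(b)
  sigma2 <- noise$sigma2
  MtM <- crossprod(leadfield) / sigma2
  Mtb <- crossprod(leadfield, b) / sigma2
  best <- Inf
  set.seed(seed)
  for (st in seq_len(n_starts)) {
    theta <- theta_star * exp(rnorm(n, sd = if (st == 1) 0 else 1))
    en_prev <- Inf
    for (sweep in seq_len(max_sweeps)) {
      H <- MtM + dense_Ctheta_inv(prior, theta)
      Qv <- solve(H, Mtb)
      Qm <- as_rows3(Qv)
      qC <- vapply(seq_len(n), function(j) {
        q <- Qm[j, ]
        as.numeric(t(q) %*% prior$inv_blocks[, , j] %*% q)
      }, 1)
      for (j in seq_len(n)) {
        f <- function(th) qC[j] / th - 2 * eta * log(th) + 2 * th / theta_star[j]
        hi <- max(theta_star[j] * (eta + 2), 2 * sqrt(qC[j] * theta_star[j]), 1)
        theta[j] <- optimize(f, c(1e-14, 10 * hi), tol = 1e-14)$minimum
      }
      en <- ias_energy(Qm, theta, b, leadfield, prior, theta_star, eta, noise)
      if (is.finite(en_prev) && abs(en_prev - en) <= 1e-10 * abs(en)) break
      en_prev <- en
    }
    best <- min(best, en)
  }
  best
}

# cache for the standard recovery scenario shared across tests
.scenario_cache <- new.env(parent = emptyenv())

recovery_fit <- function(seed, eta) {
  key <- sprintf("sc_%d", seed)
  if (is.null(.scenario_cache[[key]])) {
    .scenario_cache[[key]] <- make_scenario(n = 400, m = 60, patch_size = 5,
                                            snr = 15, seed = seed)
  }
  sc <- .scenario_cache[[key]]
  fkey <- sprintf("fit_%d_%g", seed, eta)
  if (is.null(.scenario_cache[[fkey]])) {
    prior <- anatomical_prior(sc$space, 0.05)
    model <- set_parameters(sc$leadfield, sc$noisy, prior, snr = 15, eta = eta)
    fit <- ias_solve(model$data[, 1], prior, model)
    .scenario_cache[[fkey]] <- list(scenario = sc, fit = fit)
  }
  .scenario_cache[[fkey]]
}
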