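#' Dipole moment field
#'
#' @param moments n x 3 matrix of current dipole moments (rows q_j).
#' @return Object of class `dipole_field` with `moments` and `intensities`
#'   a_j = ||q_j||.
#' @export
dipole_field <- function(moments) {
  moments <- as_n_by_3(moments, "moments")
  structure(list(moments = moments,
                 intensities = sqrt(rowSums(moments^2))),
            class = "dipole_field")
}

#' Solver control parameters
#'
#' @param tau Outer-loop tolerance on the relative Euclidean change of the
#'   variance vector Theta; default 0.01.
#' @param n_outer Maximum outer (alternating) iterations; default 30.
#' @param max_it Maximum inner CGLS iterations; default 120.
#' @param inner_stop Inner early-stopping rule: `"discrepancy"` (default)
#'   stops CGLS once the whitened residual reaches the noise level
#'   (Morozov discrepancy, the early stopping that regularizes the
#'   low-rank priorconditioned solve), `"max_it"` disables it and runs to
#'   `max_it` / stagnation (useful for testing against exact
#'   least-squares solutions).
#' @param noise_level Per-component standard deviation of the whitened
#'   noise; 1 after exact whitening. The discrepancy threshold is
#'   m * noise_level^2.
#' @param damp Weight of the prior penalty in the inner solve. The default
#'   1 makes the quadratic step minimize its full objective (data misfit
#'   plus prior penalty) when run to convergence, which is what the outer
#'   alternation needs to descend the Gibbs energy; 0 drops the explicit
#'   penalty and regularizes through early stopping alone (the pure
#'   low-rank priorconditioned Krylov route).
#' @return List of class `ias_control`.
#' @export
ias_control <- function(tau = 0.01, n_outer = 30L, max_it = 120L,
                        inner_stop = c("discrepancy", "max_it"),
                        noise_level = 1, damp = 1) {
  inner_stop <- match.arg(inner_stop)
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (!is.finite(damp) || damp < 0) stop("damp must be >= 0", call. = FALSE)
  n_outer <- as.integer(n_outer)
  max_it <- as.integer(max_it)
  if (n_outer < 1L) stop("n_outer must be >= 1", call. = FALSE)
  if (max_it < 1L) stop("max_it must be >= 1", call. = FALSE)
  structure(list(tau = tau, n_outer = n_outer, max_it = max_it,
                 inner_stop = inner_stop, noise_level = noise_level,
                 damp = damp),
            class = "ias_control")
}

#' Gibbs energy of the hierarchical model
#'
#' The negative log-posterior (up to a constant)
#'
#'   E(Q, Theta) = 1/2 ||b - M Q||^2_Sigma
#'               + 1/2 sum_j ||q_j||^2_Cj / theta_j
#'               - eta sum_j log theta_j + sum_j theta_j / theta*_j
#'
#' with ||v||^2_A = v' A^-1 v and eta = beta - 5/2. The IAS iteration
#' minimizes this jointly in (Q, Theta); the energy is globally convex
#' after the change of variables that underlies the algorithm, so the
#' fixed point is the unique MAP estimate.
#'
#' @param moments n x 3 matrix of dipole moments (or a [dipole_field()]).
#' @param theta Length-n positive variance vector.
#' @param b Length-m data vector (scaled units).
#' @param leadfield m x 3n scaled lead field.
#' @param prior An [anatomical_prior()].
#' @param theta_star Length-n hyperprior scale vector.
#' @param eta Focality parameter (beta - 5/2).
#' @param noise A [noise_model()] for the whitened misfit.
#' @return Scalar energy.
#' @export
ias_energy <- function(moments, theta, b, leadfield, prior, theta_star, eta,
                       noise) {
  if (inherits(moments, "dipole_field")) moments <- moments$moments
  if (any(theta <= 0)) stop("theta must be strictly positive", call. = FALSE)
  r <- b - as.vector(leadfield %*% moments_to_vec(moments))
  misfit <- 0.5 * sum(whiten(noise, r)^2)
  qC <- block_quad_form(prior$inv_blocks, moments)
  misfit + 0.5 * sum(qC / theta) - eta * sum(log(theta)) +
    sum(theta / theta_star)
}

#' Closed-form variance update
#'
#' For fixed dipole moments the energy separates over j and each theta_j
#' has the analytic minimizer
#'
#'   theta_j = theta*_j ( eta/2 + sqrt(eta^2/4 + ||q_j||^2_Cj / (2 theta*_j)) )
#'
#' so theta_j >= eta * theta*_j with equality iff q_j = 0. The update does
#' not depend on the previous Theta.
#'
#' @param moments n x 3 moment matrix or [dipole_field()].
#' @param prior An [anatomical_prior()].
#' @param theta_star Length-n hyperprior scale vector.
#' @param eta Focality parameter, >= 0 (eta = 0 is the minimum-current
#'   limit of the shape parameter).
#' @return Length-n updated variance vector.
#' @export
update_theta <- function(moments, prior, theta_star, eta) {
  if (inherits(moments, "dipole_field")) moments <- moments$moments
  if (any(theta_star <= 0)) stop("theta_star must be positive", call. = FALSE)
  if (eta < 0) stop("eta must be non-negative", call. = FALSE)
  qC <- block_quad_form(prior$inv_blocks, moments)
  theta_star * (eta / 2 + sqrt(eta^2 / 4 + qC / (2 * theta_star)))
}

# Build the whitened, priorconditioned operator G = W M D' (m x 3n); fixed
# across outer iterations, so it is computed once per ias_solve call.
priorcond_operator <- function(leadfield, prior, noise) {
  WM <- whiten(noise, leadfield)
  block_right_tcross(WM, prior$factor)
}

#' Priorconditioned CGLS dipole update
#'
#' Solves the quadratic step of the alternation,
#' min_Q 1/2 ||b - M Q||^2_Sigma + 1/2 Q' C_theta^-1 Q, by CGLS on the
#' transformed system A w ~ y with A = W M D_theta' (left preconditioner:
#' the noise whitener W; right preconditioner: the prior factor
#' D_theta' with D_theta' D_theta = C_theta), y = W b, started from w = 0
#' and mapped back through Q = D_theta' w. In the priorconditioned
#' variables the prior penalty is exactly `damp * ||w||^2`, so the
#' iteration is damped CGLS (conjugate gradients on A'A + damp I); with
#' `damp = 0` the penalty is dropped and the early-stopped low-rank Krylov
#' iterate itself carries the regularization. With the Morozov discrepancy
#' stop (the default) the iteration also terminates as soon as
#' ||y - A w_k||^2 <= m * noise_level^2, i.e. once the whitened residual
#' is at the noise level; a stagnation guard protects rank-deficient
#' undamped systems. The whitened data-residual norm is non-increasing
#' over iterations (CG iterate norms grow monotonically from a zero
#' start while the augmented residual shrinks).
#'
#' @param b Length-m data vector (scaled units).
#' @param leadfield m x 3n scaled lead field.
#' @param prior An [anatomical_prior()].
#' @param theta Length-n positive variance vector.
#' @param noise A [noise_model()].
#' @param control An [ias_control()]; only `max_it`, `inner_stop`,
#'   `noise_level` and `damp` are used here.
#' @param G Optional precomputed operator from the internal factorization
#'   (recomputed when absent).
#' @return List with `field` (a [dipole_field()]), `inner` (iteration
#'   count), `resnorms` (whitened data-residual norms, one per iteration
#'   including the start), and `hit_max` (TRUE when max_it was reached
#'   without meeting the discrepancy).
#' @export
solve_Q <- function(b, leadfield, prior, theta, noise,
                    control = ias_control(), G = NULL) {
  if (!all(is.finite(leadfield))) {
    stop("lead field contains non-finite entries", call. = FALSE)
  }
  if (any(theta <= 0)) stop("theta must be strictly positive", call. = FALSE)
  n <- prior$n
  m <- length(b)
  if (nrow(leadfield) != m) {
    stop("data length ", m, " does not match lead field rows ",
         nrow(leadfield), call. = FALSE)
  }
  if (is.null(G)) G <- priorcond_operator(leadfield, prior, noise)
  s_th <- rep(sqrt(theta), each = 3L)
  y <- as.vector(whiten(noise, b))
  damp <- control$damp

  threshold <- if (control$inner_stop == "discrepancy") {
    m * control$noise_level^2
  } else {
    0
  }

  w <- numeric(3L * n)
  r <- y
  rn2 <- sum(r^2)
  resnorms <- sqrt(rn2)
  hit_max <- FALSE
  it <- 0L
  if (rn2 > threshold) {
    s <- s_th * as.vector(crossprod(G, r)) - damp * w
    p <- s
    gamma <- sum(s^2)
    gamma0 <- gamma
    while (it < control$max_it && gamma > 0) {
      q <- as.vector(G %*% (s_th * p))
      denom <- sum(q^2) + damp * sum(p^2)
      if (denom == 0) break
      alpha <- gamma / denom
      w <- w + alpha * p
      r <- r - alpha * q
      rn2_new <- sum(r^2)
      it <- it + 1L
      resnorms <- c(resnorms, sqrt(rn2_new))
      if (rn2_new <= threshold) { rn2 <- rn2_new; break }
      # undamped rank-deficient systems: residual stagnation means done
      if (damp == 0 && rn2 > 0 && (rn2 - rn2_new) / rn2 < 1e-12) {
        rn2 <- rn2_new
        break
      }
      rn2 <- rn2_new
      s <- s_th * as.vector(crossprod(G, r)) - damp * w
      gamma_new <- sum(s^2)
      if (gamma_new <= 1e-28 * gamma0) { gamma <- gamma_new; break }
      p <- s + (gamma_new / gamma) * p
      gamma <- gamma_new
    }
    if (it >= control$max_it && rn2 > threshold) hit_max <- TRUE
  }
  Qvec <- moments_to_vec(block_rowmult(prior$factor, vec_to_moments(s_th * w),
                                       transpose = TRUE))
  list(field = dipole_field(vec_to_moments(Qvec)), inner = it,
       resnorms = resnorms, hit_max = hit_max)
}

#' IAS alternating minimization for one time slice
#'
#' Alternates the priorconditioned CGLS dipole update ([solve_Q()]) with
#' the closed-form variance update ([update_theta()]) until the relative
#' Euclidean change of Theta falls below `tau` or `n_outer` iterations are
#' reached. Theta is initialized at theta* unless `theta_init` is given
#' (warm starting across time slices).
#'
#' @param b Length-m data vector (scaled units, consistent with `model`).
#' @param prior An [anatomical_prior()].
#' @param model A `hyper_model` from [set_parameters()], or any list with
#'   elements `leadfield`, `theta_star`, `eta`, `noise`.
#' @param control An [ias_control()].
#' @param theta_init Optional initial variance vector (default theta*).
#' @return List of class `ias_fit`: `field` ([dipole_field()]), `theta`,
#'   `diagnostics` (matrix with columns `inner`, `rel_change`, one row per
#'   outer iteration), `converged`, `energy` (final Gibbs energy).
#' @export
ias_solve <- function(b, prior, model, control = ias_control(),
                      theta_init = NULL) {
  leadfield <- model$leadfield
  theta_star <- model$theta_star
  n <- prior$n
  m <- length(b)
  if (ncol(leadfield) != 3L * n) {
    stop("lead field has ", ncol(leadfield), " columns; expected 3n = ", 3L * n,
         call. = FALSE)
  }
  if (nrow(leadfield) != m) {
    stop("data length ", m, " does not match lead field rows ",
         nrow(leadfield), call. = FALSE)
  }
  if (length(theta_star) != n) {
    stop("theta_star length ", length(theta_star), " != n = ", n, call. = FALSE)
  }
  theta <- if (is.null(theta_init)) theta_star else theta_init
  if (length(theta) != n || any(theta <= 0)) {
    stop("theta_init must be a positive length-n vector", call. = FALSE)
  }
  G <- priorcond_operator(leadfield, prior, model$noise)
  diag_rows <- matrix(NA_real_, control$n_outer, 2,
                      dimnames = list(NULL, c("inner", "rel_change")))
  converged <- FALSE
  fit <- NULL
  k_used <- 0L
  for (k in seq_len(control$n_outer)) {
    fit <- solve_Q(b, leadfield, prior, theta, model$noise, control, G = G)
    theta_new <- update_theta(fit$field, prior, theta_star, model$eta)
    rel <- sqrt(sum((theta_new - theta)^2)) / sqrt(sum(theta^2))
    diag_rows[k, ] <- c(fit$inner, rel)
    theta <- theta_new
    k_used <- k
    if (rel < control$tau) { converged <- TRUE; break }
  }
  en <- ias_energy(fit$field, theta, b, leadfield, prior, theta_star,
                   model$eta, model$noise)
  structure(list(field = fit$field, theta = theta,
                 diagnostics = diag_rows[seq_len(k_used), , drop = FALSE],
                 converged = converged, energy = en),
            class = "ias_fit")
}

#' @export
print.ias_fit <- function(x, ...) {
  k <- nrow(x$diagnostics)
  cat(sprintf("IAS fit: %d outer iterations (%s), final energy %.6g\n",
              k, if (x$converged) "converged" else "not converged", x$energy))
  cat(sprintf("  peak intensity %.4g at dipole %d\n",
              max(x$field$intensities), which.max(x$field$intensities)))
  invisible(x)
}

#' IAS over a time series with optional warm starting
#'
#' Applies [ias_solve()] to each column of the data matrix. With
#' `warm_start = TRUE` (default) the variance vector of slice s > 1 is
#' initialized at the final estimate from slice s - 1: successive slices
#' of evoked activity change slowly, so the previous variances are a good
#' starting guess and the outer loop typically needs only a few
#' iterations. Slice 1 always starts from theta*. A slice with non-finite
#' data is recorded as an error entry and skipped; processing continues
#' (and the warm start is reset to theta* after a failed slice).
#'
#' @param B m x t data matrix (scaled units, consistent with `model`).
#' @param prior An [anatomical_prior()].
#' @param model A `hyper_model` from [set_parameters()].
#' @param control An [ias_control()].
#' @param warm_start Logical; default TRUE.
#' @return Object of class `ias_result` with `Q_hat` (n x 3 x t array),
#'   `intensities` (n x t), `theta_hat` (n x t), `diagnostics` (list of
#'   per-slice matrices), `converged` (length-t logical), `errors`
#'   (length-t character, NA where the slice succeeded) and `warm_start`.
#' @export
ias_time_series <- function(B, prior, model, control = ias_control(),
                            warm_start = TRUE) {
  B <- as.matrix(B)
  t_len <- ncol(B)
  if (t_len < 1L) stop("data must contain at least one time slice", call. = FALSE)
  n <- prior$n
  Q_hat <- array(0, c(n, 3L, t_len))
  theta_hat <- matrix(0, n, t_len)
  intens <- matrix(0, n, t_len)
  diags <- vector("list", t_len)
  conv <- logical(t_len)
  errs <- rep(NA_character_, t_len)
  theta_prev <- NULL
  for (s in seq_len(t_len)) {
    b <- B[, s]
    if (!all(is.finite(b))) {
      errs[s] <- paste0("non-finite data in slice ", s)
      theta_prev <- NULL
      next
    }
    init <- if (warm_start) theta_prev else NULL
    fit <- ias_solve(b, prior, model, control, theta_init = init)
    Q_hat[, , s] <- fit$field$moments
    intens[, s] <- fit$field$intensities
    theta_hat[, s] <- fit$theta
    diags[[s]] <- fit$diagnostics
    conv[s] <- fit$converged
    theta_prev <- fit$theta
  }
  structure(list(Q_hat = Q_hat, intensities = intens, theta_hat = theta_hat,
                 diagnostics = diags, converged = conv, errors = errs,
                 warm_start = warm_start),
            class = "ias_result")
}

#' @export
print.ias_result <- function(x, ...) {
  t_len <- dim(x$Q_hat)[3]
  ok <- sum(is.na(x$errors))
  mean_outer <- mean(vapply(x$diagnostics[is.na(x$errors)], nrow, 1L))
  cat(sprintf("IAS result: %d slices (%d ok), warm_start = %s\n",
              t_len, ok, x$warm_start))
  cat(sprintf("  mean outer iterations %.2f, converged in %d/%d slices\n",
              mean_outer, sum(x$converged), ok))
  invisible(x)
}
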