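#' Build the anatomical prior covariance
#'
#' The prior on the dipole moment at source point j is a zero-mean Gaussian
#' with covariance theta_j * C_j, where the local anatomical covariance
#'
#'   C_j = nu_j nu_j' + delta (xi_j xi_j' + zeta_j zeta_j')
#'       = (1 - delta) nu_j nu_j' + delta I
#'
#' concentrates prior variance along the preferred orientation nu_j
#' (eigenvalue 1) and leaves a fraction `delta` in the tangent plane
#' (double eigenvalue delta). The full covariance C = diag(C_1, ..., C_n)
#' is block diagonal and is returned together with its per-block upper
#' triangular Cholesky factor D (D' D = C), used as the priorconditioner of
#' the inner least-squares solver, and the per-block inverse used in the
#' prior quadratic form.
#'
#' @param space A [source_space()].
#' @param delta Relative prior variance of the dipole components orthogonal
#'   to the preferred orientation, in (0, 1]. `delta = 1` gives the
#'   isotropic prior C_j = I (no orientation preference). Default 0.05.
#' @return An object of class `anatomical_prior` with elements `blocks`,
#'   `factor`, `inv_blocks` (each a 3 x 3 x n array), `delta` and `n`.
#' @examples
#' ss <- source_space(matrix(rnorm(9), 3), matrix(rnorm(9), 3))
#' pr <- anatomical_prior(ss, delta = 0.05)
#' eigen(pr$blocks[, , 1])$values # 1, 0.05, 0.05
#' @export
anatomical_prior <- function(space, delta = 0.05) {
  stopifnot(inherits(space, "source_space"))
  delta <- as.numeric(delta)
  if (length(delta) != 1L || !is.finite(delta) || delta <= 0 || delta > 1) {
    stop("delta must be a scalar in (0, 1]; got ", format(delta), call. = FALSE)
  }
  nu <- space$orientations
  n <- space$n
  blocks <- array(0, c(3, 3, n))
  inv_blocks <- array(0, c(3, 3, n))
  for (a in 1:3) {
    for (b in 1:3) {
      nab <- nu[, a] * nu[, b]
      blocks[a, b, ] <- (1 - delta) * nab + delta * (a == b)
      # C_j^{-1} = (1/delta) I + (1 - 1/delta) nu nu'
      inv_blocks[a, b, ] <- (1 - 1 / delta) * nab + (1 / delta) * (a == b)
    }
  }
  fac <- array(0, c(3, 3, n))
  for (j in seq_len(n)) fac[, , j] <- chol(blocks[, , j])
  structure(
    list(blocks = blocks, factor = fac, inv_blocks = inv_blocks,
         delta = delta, n = n),
    class = "anatomical_prior"
  )
}

#' @export
print.anatomical_prior <- function(x, ...) {
  cat("Anatomical prior:", x$n, "3x3 blocks, delta =", x$delta, "\n")
  invisible(x)
}

#' Symmetric square root of the prior blocks
#'
#' Returns C_j^(1/2) (symmetric) for each block. Sensitivity weighting
#' depends only on the Frobenius norm of M_j C_j^(1/2), which is invariant
#' to the choice of factor; this symmetric root is provided for checks
#' against the Cholesky factor.
#'
#' @param prior An [anatomical_prior()].
#' @return A 3 x 3 x n array of symmetric matrices S with S S = C_j.
#' @export
prior_sqrt_blocks <- function(prior) {
  stopifnot(inherits(prior, "anatomical_prior"))
  out <- array(0, c(3, 3, prior$n))
  for (j in seq_len(prior$n)) {
    e <- eigen(prior$blocks[, , j], symmetric = TRUE)
    out[, , j] <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  }
  out
}

# ---- blockwise linear algebra on 3 x 3 x n arrays -------------------------

# rows of V (n x 3) multiplied per-block: out_j = A_j v_j (or A_j' v_j)
block_rowmult <- function(A3, V, transpose = FALSE) {
  out <- matrix(0, nrow(V), 3L)
  for (a in 1:3) {
    acc <- 0
    for (b in 1:3) {
      w <- if (transpose) A3[b, a, ] else A3[a, b, ]
      acc <- acc + w * V[, b]
    }
    out[, a] <- acc
  }
  out
}

# per-block quadratic form v_j' A_j v_j for rows of V (n x 3)
block_quad_form <- function(A3, V) {
  acc <- 0
  for (a in 1:3) {
    for (b in 1:3) acc <- acc + A3[a, b, ] * V[, a] * V[, b]
  }
  acc
}

# right-multiply an m x 3n matrix by blockdiag(A_j)' : out[, idx_j] = M_j A_j'
block_right_tcross <- function(M, A3) {
  n <- dim(A3)[3]
  stopifnot(ncol(M) == 3L * n)
  out <- matrix(0, nrow(M), ncol(M))
  for (a in 1:3) {
    cols_a <- seq(a, 3L * n, by = 3L)
    acc <- 0
    for (b in 1:3) {
      acc <- acc + M[, seq(b, 3L * n, by = 3L), drop = FALSE] *
        rep(A3[a, b, ], each = nrow(M))
    }
    out[, cols_a] <- acc
  }
  out
}

# interleave an n x 3 matrix of dipole rows into a length-3n vector
# (q1x q1y q1z q2x ...) and back
moments_to_vec <- function(V) as.vector(t(V))
vec_to_moments <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

#' Per-dipole lead-field sensitivity
#'
#' Computes s_j = ||M_j C_j^(1/2)||_F^2 = trace(M_j C_j M_j') for each
#' dipole, the lead-field energy that the sensitivity-weighting formula
#' normalizes away. Invariant to the choice of square-root factor of C_j.
#'
#' @param leadfield m x 3n lead field matrix, dipole-major column order
#'   (columns 3j-2, 3j-1, 3j belong to dipole j).
#' @param prior An [anatomical_prior()].
#' @return Length-n numeric vector of sensitivities.
#' @export
leadfield_sensitivity <- function(leadfield, prior) {
  stopifnot(inherits(prior, "anatomical_prior"))
  n <- prior$n
  if (ncol(leadfield) != 3L * n) {
    stop("lead field has ", ncol(leadfield), " columns; expected 3n = ",
         3L * n, call. = FALSE)
  }
  s <- 0
  for (a in 1:3) {
    Ma <- leadfield[, seq(a, 3L * n, by = 3L), drop = FALSE]
    for (b in 1:3) {
      Mb <- leadfield[, seq(b, 3L * n, by = 3L), drop = FALSE]
      s <- s + prior$blocks[a, b, ] * colSums(Ma * Mb)
    }
  }
  s
}
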