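#' Construct a source space
#'
#' A source space is the discretized set of candidate current-dipole
#' locations together with a preferred orientation per dipole (typically the
#' local cortical surface normal). Coordinates follow the right-handed
#' convention x = right, y = front, z = crown, in meters.
#'
#' Orientations are renormalized to unit Euclidean norm on construction;
#' zero or non-finite orientations are rejected rather than silently
#' replaced, since they usually indicate an upstream segmentation error.
#'
#' @param positions Numeric n x 3 matrix of dipole coordinates (meters).
#' @param orientations Numeric n x 3 matrix of preferred dipole directions.
#' @return An object of class `source_space` with elements `positions`
#'   (n x 3), `orientations` (n x 3, unit rows) and `n`.
#' @examples
#' ss <- source_space(matrix(rnorm(15), 5), matrix(rnorm(15), 5))
#' rowSums(ss$orientations^2) # all 1
#' @export
source_space <- function(positions, orientations) {
  positions <- as_n_by_3(positions, "positions")
  orientations <- as_n_by_3(orientations, "orientations")
  if (nrow(positions) != nrow(orientations)) {
    stop("positions and orientations must have the same number of rows (",
         nrow(positions), " vs ", nrow(orientations), ")", call. = FALSE)
  }
  n <- nrow(positions)
  if (n < 1L) stop("source space must contain at least one dipole", call. = FALSE)
  if (!all(is.finite(positions))) {
    stop("positions contain non-finite values", call. = FALSE)
  }
  if (!all(is.finite(orientations))) {
    stop("orientations contain non-finite values", call. = FALSE)
  }
  nrm <- sqrt(rowSums(orientations^2))
  if (any(nrm == 0)) {
    stop("orientation(s) with zero norm at dipole index ",
         paste(which(nrm == 0), collapse = ", "),
         "; refusing to substitute a default direction", call. = FALSE)
  }
  orientations <- orientations / nrm
  structure(
    list(positions = positions, orientations = orientations, n = n),
    class = "source_space"
  )
}

#' @export
print.source_space <- function(x, ...) {
  bb <- apply(x$positions, 2, range)
  cat("Source space:", x$n, "dipoles\n")
  cat(sprintf("  bounding box [m]: x [%.4g, %.4g]  y [%.4g, %.4g]  z [%.4g, %.4g]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# coerce to an n x 3 double matrix with an informative error
as_n_by_3 <- function(x, what) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) {
    stop(what, " must be an n x 3 matrix; found ", nrow(x), " x ", ncol(x),
         call. = FALSE)
  }
  dimnames(x) <- NULL
  x
}

#' Deterministic orthonormal frame completion of a unit vector
#'
#' Completes a unit orientation vector `nu` to a right-handed orthonormal
#' frame (xi, zeta, nu) with xi x zeta = nu. The completion is
#' deterministic: the coordinate axis least parallel to `nu` is
#' orthogonalized against `nu` to give xi, and zeta = nu x xi. Any
#' orthonormal completion yields the same anatomical prior covariance
#' (xi xi' + zeta zeta' = I - nu nu'); fixing one makes the factorization
#' reproducible across runs.
#'
#' @param nu Numeric length-3 unit vector (norm within 1e-6 of 1).
#' @return A list of class `local_frame` with unit vectors `xi`, `zeta`,
#'   `nu`.
#' @examples
#' fr <- local_frame(c(0, 0, 1))
#' crossprod(cbind(fr$xi, fr$zeta, fr$nu)) # identity
#' @export
local_frame <- function(nu) {
  nu <- as.numeric(nu)
  if (length(nu) != 3L || !all(is.finite(nu))) {
    stop("invalid orientation: nu must be a finite length-3 vector", call. = FALSE)
  }
  nn <- sqrt(sum(nu^2))
  if (nn == 0) stop("invalid orientation: zero vector", call. = FALSE)
  if (abs(nn - 1) > 1e-6) {
    stop("invalid orientation: norm ", format(nn), " is not within 1e-6 of 1",
         call. = FALSE)
  }
  nu <- nu / nn
  e <- c(0, 0, 0)
  e[which.min(abs(nu))] <- 1
  xi <- e - sum(e * nu) * nu
  xi <- xi / sqrt(sum(xi^2))
  zeta <- cross3(nu, xi)
  structure(list(xi = xi, zeta = zeta, nu = nu), class = "local_frame")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
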