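#' Estimate signal power from a data window
#'
#' The signal power P entering the sensitivity-weighting formula is taken
#' as the mean squared Euclidean norm of the data columns over a
#' user-designated window (e.g. a segment containing the evoked response).
#'
#' @param data_subset m x k numeric matrix of data columns (time slices).
#' @return Scalar P >= 0.
#' @export
estimate_signal_power <- function(data_subset) {
  data_subset <- as.matrix(data_subset)
  if (ncol(data_subset) < 1L || nrow(data_subset) < 1L) {
    stop("data window is empty", call. = FALSE)
  }
  if (!all(is.finite(data_subset))) {
    stop("data window contains non-finite values", call. = FALSE)
  }
  mean(colSums(data_subset^2))
}

#' Sensitivity-weighted hyperprior scales
#'
#' Computes the gamma-hyperprior scale vector
#'
#'   theta*_j = P (1 - 1/SNR) / (beta ||M_j C_j^(1/2)||_F^2)
#'
#' which makes dipoles a priori exchangeable: any dipole configuration of
#' equal support size explains the same expected signal power, removing the
#' depth bias of unweighted minimum-norm-type estimates. The product
#' theta*_j * ||M_j C_j^(1/2)||_F^2 is constant across j by construction.
#'
#' @param leadfield m x 3n lead field matrix.
#' @param prior An [anatomical_prior()].
#' @param P Scalar signal power (see [estimate_signal_power()]).
#' @param snr Scalar signal-to-noise ratio (power ratio), must exceed 1.
#' @param beta Gamma-hyperprior shape, beta = eta + 5/2.
#' @return Length-n positive vector theta*.
#' @export
compute_theta_star <- function(leadfield, prior, P, snr, beta) {
  if (!is.finite(snr) || snr <= 1) {
    stop("snr must exceed 1 (signal power must exceed noise power); got ",
         format(snr), call. = FALSE)
  }
  if (!is.finite(P) || P < 0) stop("signal power must be non-negative", call. = FALSE)
  if (!is.finite(beta) || beta <= 5 / 2) {
    stop("beta must exceed 5/2; got ", format(beta), call. = FALSE)
  }
  s <- leadfield_sensitivity(leadfield, prior)
  if (any(s <= 0)) {
    stop("zero-sensitivity dipole(s) at index ",
         paste(which(s <= 0), collapse = ", "),
         "; such dipoles are invisible to the sensors and cannot be weighted",
         call. = FALSE)
  }
  P * (1 - 1 / snr) / (beta * s)
}

#' Truncate the hyperprior scale vector at a quantile
#'
#' Deep or poorly seen dipoles get very large theta*_j; optionally the
#' upper tail is clipped at an empirical quantile so a few near-blind
#' dipoles cannot dominate the prior. Clipping (rather than deleting
#' dipoles) preserves the source-space size. Quantiles use linear
#' interpolation between order statistics ([stats::quantile()] type 7), so
#' the cutoff is bit-reproducible.
#'
#' @param theta_star Positive numeric vector.
#' @param cutoff_quantile Quantile level in (0, 1]; 1 (default) disables
#'   truncation and returns `cutoff_value = max(theta_star)`.
#' @return List with `theta_star` (clipped, same length) and `cutoff_value`.
#' @export
truncate_theta_star <- function(theta_star, cutoff_quantile = 1) {
  if (!is.numeric(cutoff_quantile) || length(cutoff_quantile) != 1L ||
      !is.finite(cutoff_quantile) || cutoff_quantile <= 0 || cutoff_quantile > 1) {
    stop("cutoff_quantile must be a scalar in (0, 1]; got ",
         format(cutoff_quantile), call. = FALSE)
  }
  cutoff <- unname(stats::quantile(theta_star, cutoff_quantile, type = 7))
  list(theta_star = pmin(theta_star, cutoff), cutoff_value = cutoff)
}

#' Noise model with whitening transform
#'
#' Wraps the noise covariance Sigma together with a whitener W satisfying
#' W Sigma W' = I (and W'W = Sigma^-1). A scalar variance sigma2 implies
#' homoscedastic Sigma = sigma2 * I and a diagonal whitener.
#'
#' @param m Number of sensors.
#' @param Sigma Optional m x m symmetric positive-definite covariance.
#' @param sigma2 Optional scalar variance (used when `Sigma` is absent).
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(m, Sigma = NULL, sigma2 = NULL) {
  if (is.null(Sigma)) {
    if (is.null(sigma2) || !is.finite(sigma2) || sigma2 <= 0) {
      stop("either Sigma or a positive scalar sigma2 is required", call. = FALSE)
    }
    return(structure(list(type = "scalar", m = m, sigma2 = sigma2,
                          sigma = sqrt(sigma2)),
                     class = "noise_model"))
  }
  Sigma <- as.matrix(Sigma)
  if (nrow(Sigma) != m || ncol(Sigma) != m) {
    stop("Sigma must be ", m, " x ", m, call. = FALSE)
  }
  if (max(abs(Sigma - t(Sigma))) > 1e-10 * max(abs(Sigma))) {
    stop("Sigma is not symmetric", call. = FALSE)
  }
  U <- tryCatch(chol(Sigma),
                error = function(e) stop("Sigma is not positive definite",
                                         call. = FALSE))
  # W = U^-T (lower triangular): W Sigma W' = I
  W <- t(backsolve(U, diag(m)))
  structure(list(type = "full", m = m, Sigma = Sigma, W = W,
                 sigma2 = sum(diag(Sigma)) / m,
                 sigma = sqrt(sum(diag(Sigma)) / m)),
            class = "noise_model")
}

#' Apply the whitening transform
#'
#' @param noise A [noise_model()].
#' @param x Vector of length m or m x k matrix.
#' @return Whitened vector/matrix W x.
#' @export
whiten <- function(noise, x) {
  stopifnot(inherits(noise, "noise_model"))
  if (noise$type == "scalar") x / noise$sigma else noise$W %*% x
}

#' Lead-field/data scaling and noise model from an SNR estimate
#'
#' Brings the inverse problem to a numerically convenient scale and derives
#' the homoscedastic noise level implied by the user's SNR:
#' the lead field is scaled by `scale_M = 1 / max_j ||M_j||_F`, the data by
#' `scale_b` such that the median column norm of the scaled data is
#' sqrt(m), and (unless a full covariance is supplied) the scaled noise is
#' Sigma = sigma^2 I with sigma^2 = P_scaled / (SNR * m), so that
#' trace(Sigma) = P_scaled / SNR matches the SNR power-ratio definition.
#'
#' @param leadfield m x 3n lead field matrix (unscaled).
#' @param data_subset m x k data window (unscaled) used for the power
#'   estimate and the data scale.
#' @param snr Signal-to-noise power ratio, > 1.
#' @param Sigma Optional full noise covariance on the *unscaled* data
#'   scale; it is rescaled by scale_b^2 and overrides the homoscedastic
#'   default.
#' @return List with `noise` (a [noise_model()] on the scaled problem),
#'   `scale_M`, `scale_b`, `sigma_scaled`, `P_scaled`, `leadfield` and
#'   `data` (the scaled inputs).
#' @export
build_noise_and_scaling <- function(leadfield, data_subset, snr, Sigma = NULL) {
  leadfield <- as.matrix(leadfield)
  data_subset <- as.matrix(data_subset)
  m <- nrow(leadfield)
  if (nrow(data_subset) != m) {
    stop("data has ", nrow(data_subset), " rows; lead field has ", m,
         " rows", call. = FALSE)
  }
  if (ncol(leadfield) %% 3L != 0L) {
    stop("lead field must have 3n columns; found ", ncol(leadfield), call. = FALSE)
  }
  n <- ncol(leadfield) %/% 3L
  bnorm <- rep(0, n)
  for (a in 1:3) {
    bnorm <- bnorm + colSums(leadfield[, seq(a, 3L * n, by = 3L), drop = FALSE]^2)
  }
  mx <- sqrt(max(bnorm))
  if (mx == 0) stop("lead field is identically zero", call. = FALSE)
  scale_M <- 1 / mx
  colnorms <- sqrt(colSums(data_subset^2))
  med <- stats::median(colnorms)
  if (med == 0) stop("median data column norm is zero; cannot scale", call. = FALSE)
  scale_b <- sqrt(m) / med
  M_s <- leadfield * scale_M
  B_s <- data_subset * scale_b
  P_scaled <- estimate_signal_power(B_s)
  if (is.null(Sigma)) {
    if (!is.finite(snr) || snr <= 1) {
      stop("snr must exceed 1; got ", format(snr), call. = FALSE)
    }
    sigma2 <- P_scaled / (snr * m)
    noise <- noise_model(m, sigma2 = sigma2)
  } else {
    noise <- noise_model(m, Sigma = as.matrix(Sigma) * scale_b^2)
  }
  list(noise = noise, scale_M = scale_M, scale_b = scale_b,
       sigma_scaled = noise$sigma, P_scaled = P_scaled,
       leadfield = M_s, data = B_s)
}

#' Prepare all solver parameters from an SNR estimate
#'
#' One-shot parameter setup: scales the lead field and data, estimates the
#' signal power, builds the sensitivity-weighted hyperprior scale vector
#' theta* (optionally truncated at a quantile), and derives the noise model
#' used for whitening. This is the single place where the user's SNR
#' estimate enters the model.
#'
#' @param leadfield m x 3n lead field matrix (unscaled).
#' @param data m x t data matrix (unscaled, preprocessed/artifact-free).
#' @param prior An [anatomical_prior()].
#' @param snr Signal-to-noise power ratio, > 1. The only required tuning
#'   input.
#' @param eta Focality parameter eta = beta - 5/2, > 0. Small values
#'   (0.0001-0.001) favor focal reconstructions, larger ones (0.01-0.1)
#'   distributed ones. Default 0.01.
#' @param cutoff_quantile Quantile at which theta* is clipped
#'   ([truncate_theta_star()]); default 1 (no truncation).
#' @param power_window Optional column indices of `data` used for the
#'   signal-power estimate; default all columns.
#' @param Sigma Optional full noise covariance (unscaled data units).
#' @return Object of class `hyper_model` holding the scaled `leadfield` and
#'   `data`, `theta_star`, `cutoff_value`, `eta`, `beta`, `snr`,
#'   `signal_power` (scaled units), `scale_M`, `scale_b`, `sigma_scaled`
#'   and the `noise` model.
#' @export
set_parameters <- function(leadfield, data, prior, snr, eta = 0.01,
                           cutoff_quantile = 1, power_window = NULL,
                           Sigma = NULL) {
  stopifnot(inherits(prior, "anatomical_prior"))
  if (!is.finite(eta) || eta <= 0) {
    stop("eta must be a positive scalar; got ", format(eta), call. = FALSE)
  }
  data <- as.matrix(data)
  if (is.null(power_window)) power_window <- seq_len(ncol(data))
  sc <- build_noise_and_scaling(leadfield,
                                data[, power_window, drop = FALSE],
                                snr, Sigma = Sigma)
  beta <- eta + 5 / 2
  theta_star <- compute_theta_star(sc$leadfield, prior, sc$P_scaled, snr, beta)
  tr <- truncate_theta_star(theta_star, cutoff_quantile)
  structure(
    list(leadfield = sc$leadfield, data = as.matrix(data) * sc$scale_b,
         theta_star = tr$theta_star, cutoff_value = tr$cutoff_value,
         cutoff_quantile = cutoff_quantile,
         eta = eta, beta = beta, snr = snr, signal_power = sc$P_scaled,
         scale_M = sc$scale_M, scale_b = sc$scale_b,
         sigma_scaled = sc$sigma_scaled, noise = sc$noise),
    class = "hyper_model"
  )
}

#' @export
print.hyper_model <- function(x, ...) {
  cat("IAS hyper model\n")
  cat(sprintf("  snr = %g, eta = %g (beta = %g), sigma_scaled = %.4g\n",
              x$snr, x$eta, x$beta, x$sigma_scaled))
  cat(sprintf("  theta*: n = %d, range [%.4g, %.4g], cutoff %.4g (q = %g)\n",
              length(x$theta_star), min(x$theta_star), max(x$theta_star),
              x$cutoff_value, x$cutoff_quantile))
  invisible(x)
}
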