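#' Quasi-uniform spherical source space
#'
#' Places n points on a sphere by the Fibonacci (golden-angle) lattice,
#' which is quasi-uniform and fully deterministic, and assigns each point
#' a preferred orientation: `"radial"` (outward unit radial, emulating
#' e.g. gyral-crown pyramidal orientation) or `"tangential"` (a
#' deterministic unit tangent, the frame completion of the radial
#' direction). Radial dipoles are magnetically silent in a spherical
#' conductor, so MEG test scenarios use tangential orientations.
#'
#' @param n Number of dipoles, >= 1.
#' @param radius Sphere radius in meters; default 0.08 (outer cortex).
#' @param orientation `"radial"` (default) or `"tangential"`.
#' @param seed Optional integer; the lattice itself is deterministic, the
#'   seed is reserved for randomized variants and recorded for provenance.
#' @return A [source_space()].
#' @export
make_sphere_source_space <- function(n, radius = 0.08,
                                     orientation = c("radial", "tangential"),
                                     seed = NULL) {
  orientation <- match.arg(orientation)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0", call. = FALSE)
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  rho <- sqrt(pmax(1 - z^2, 0))
  phi <- pi * (3 - sqrt(5)) * i
  pts <- cbind(rho * cos(phi), rho * sin(phi), z)
  ori <- if (orientation == "radial") {
    pts
  } else {
    t(vapply(seq_len(n), function(j) local_frame(pts[j, ])$xi, numeric(3)))
  }
  source_space(radius * pts, ori)
}

#' Magnetometer array on a sphere
#'
#' Fibonacci-lattice magnetometers at a fixed radius, each measuring the
#' radial field component (orientation = outward radial), emulating a
#' simple whole-head magnetometer helmet.
#'
#' @param m Number of sensors.
#' @param radius Sensor sphere radius in meters; default 0.12.
#' @return List of class `sensor_array` with `positions` and
#'   `orientations` (m x 3 each) and `m`.
#' @export
make_sensor_array <- function(m, radius = 0.12) {
  sp <- make_sphere_source_space(m, radius = radius, orientation = "radial")
  structure(list(positions = sp$positions, orientations = sp$orientations,
                 m = m), class = "sensor_array")
}

#' Spherical-conductor MEG lead field (Sarvas model)
#'
#' Closed-form magnetic field of a current dipole inside a homogeneous
#' spherical conductor, including volume currents. The measured channel is
#' the projection of the field onto the sensor orientation. Radial dipoles
#' produce no external magnetic field in this geometry, so the three
#' columns of each dipole block span (numerically) only the tangential
#' subspace.
#'
#' @param space A [source_space()] strictly inside the sensor sphere.
#' @param sensors A [make_sensor_array()] (or list with m x 3 `positions`
#'   and `orientations`).
#' @return m x 3n lead field matrix (tesla per A*m), dipole-major columns.
#' @export
make_meg_leadfield <- function(space, sensors) {
  stopifnot(inherits(space, "source_space"))
  pos <- space$positions
  n <- space$n
  spos <- as_n_by_3(sensors$positions, "sensor positions")
  sori <- as_n_by_3(sensors$orientations, "sensor orientations")
  m <- nrow(spos)
  src_r <- sqrt(rowSums(pos^2))
  sen_r <- sqrt(rowSums(spos^2))
  if (min(sen_r) <= max(src_r)) {
    stop("sensor(s) inside the source sphere: min sensor radius ",
         format(min(sen_r)), " <= max source radius ", format(max(src_r)),
         call. = FALSE)
  }
  mu0_4pi <- 1e-7
  M <- matrix(0, m, 3L * n)
  for (i in seq_len(m)) {
    r <- spos[i, ]
    o <- sori[i, ]
    R <- sqrt(sum(r^2))
    a_vec <- cbind(r[1] - pos[, 1], r[2] - pos[, 2], r[3] - pos[, 3])
    a <- sqrt(rowSums(a_vec^2))
    r0_dot_r <- pos[, 1] * r[1] + pos[, 2] * r[2] + pos[, 3] * r[3]
    a_dot_r <- a_vec[, 1] * r[1] + a_vec[, 2] * r[2] + a_vec[, 3] * r[3]
    FF <- a * (R * a + R^2 - r0_dot_r)
    cf_r <- a^2 / R + a_dot_r / a + 2 * a + 2 * R   # gradF = cf_r*r - cf_r0*r0
    cf_r0 <- a + 2 * R + a_dot_r / a
    gradF <- cbind(cf_r * r[1] - cf_r0 * pos[, 1],
                   cf_r * r[2] - cf_r0 * pos[, 2],
                   cf_r * r[3] - cf_r0 * pos[, 3])
    gradF_dot_o <- gradF[, 1] * o[1] + gradF[, 2] * o[2] + gradF[, 3] * o[3]
    # e_a x r0 for the three unit dipole components
    ex_cr <- cbind(0, -pos[, 3], pos[, 2])
    ey_cr <- cbind(pos[, 3], 0, -pos[, 1])
    ez_cr <- cbind(-pos[, 2], pos[, 1], 0)
    for (a_idx in 1:3) {
      cr <- switch(a_idx, ex_cr, ey_cr, ez_cr)
      cr_dot_o <- cr[, 1] * o[1] + cr[, 2] * o[2] + cr[, 3] * o[3]
      cr_dot_r <- cr[, 1] * r[1] + cr[, 2] * r[2] + cr[, 3] * r[3]
      M[i, seq(a_idx, 3L * n, by = 3L)] <-
        mu0_4pi / FF^2 * (FF * cr_dot_o - cr_dot_r * gradF_dot_o)
    }
  }
  M
}

#' Random dense lead field (unit-test fixture)
#'
#' i.i.d. standard normal entries; full row rank with probability 1 when
#' 3n >= m. Deterministic given the seed.
#'
#' @param m Sensors. @param n Dipoles. @param seed Integer seed.
#' @return m x 3n matrix.
#' @export
make_random_leadfield <- function(m, n, seed) {
  set.seed(seed)
  matrix(stats::rnorm(m * 3L * n), m, 3L * n)
}

#' Patch activation
#'
#' Activates all dipoles within `radius` of `center` along their preferred
#' orientations: q_j(s) = amplitude * timecourse(s) * nu_j inside the
#' patch, zero elsewhere.
#'
#' @param space A [source_space()].
#' @param center Length-3 patch center (meters).
#' @param radius Patch radius (meters), > 0.
#' @param amplitude Dipole strength in A*m; default 1e-8 (10 nAm, a
#'   typical evoked-response equivalent dipole).
#' @param timecourse Numeric vector of length t; default 1 (single slice).
#' @return List with `Q_true` (n x 3 x t array), `support` (dipole
#'   indices) and `center`.
#' @export
simulate_patch <- function(space, center, radius, amplitude = 1e-8,
                           timecourse = 1) {
  stopifnot(inherits(space, "source_space"))
  center <- as.numeric(center)
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0", call. = FALSE)
  d <- sqrt(colSums((t(space$positions) - center)^2))
  support <- which(d <= radius)
  if (length(support) == 0L) {
    stop("empty patch: nearest dipole is ", format(min(d)),
         " m from the center (radius ", format(radius), " m)", call. = FALSE)
  }
  t_len <- length(timecourse)
  Q <- array(0, c(space$n, 3L, t_len))
  for (s in seq_len(t_len)) {
    Q[support, , s] <- amplitude * timecourse[s] *
      space$orientations[support, , drop = FALSE]
  }
  list(Q_true = Q, support = support, center = center)
}

#' Add sensor noise at a target SNR
#'
#' Draws zero-mean Gaussian noise with total power trace(Sigma) =
#' P / snr_target, where P is the mean squared column norm of the clean
#' data, and adds it to the clean signal. An infinite SNR returns the
#' clean data unchanged.
#'
#' @param clean m x t clean data matrix.
#' @param snr_target Target signal-to-noise power ratio, > 0 or Inf.
#' @param seed Integer seed.
#' @param Sigma Optional m x m covariance shape; rescaled so that
#'   trace(Sigma) = P / snr_target. Default: white (sigma^2 I).
#' @return m x t noisy data matrix.
#' @export
add_noise <- function(clean, snr_target, seed, Sigma = NULL) {
  clean <- as.matrix(clean)
  if (!(snr_target > 0)) stop("snr_target must be > 0", call. = FALSE)
  if (is.infinite(snr_target)) return(clean)
  m <- nrow(clean)
  t_len <- ncol(clean)
  P <- mean(colSums(clean^2))
  if (P == 0) {
    stop("clean data is identically zero: SNR is undefined", call. = FALSE)
  }
  set.seed(seed)
  if (is.null(Sigma)) {
    sigma <- sqrt(P / (snr_target * m))
    noise <- matrix(stats::rnorm(m * t_len, sd = sigma), m, t_len)
  } else {
    Sigma <- as.matrix(Sigma) * (P / snr_target) / sum(diag(Sigma))
    U <- chol(Sigma)
    noise <- t(U) %*% matrix(stats::rnorm(m * t_len), m, t_len)
  }
  clean + noise
}

#' Random background dipole activity ("brain noise")
#'
#' Adds spatially distributed background activity: every dipole receives
#' an i.i.d. Gaussian amplitude along its preferred orientation at each
#' time slice, projected to the sensors through the lead field, and scaled
#' so that the power ratio of the signal of interest to the background
#' equals `brain_snr`. A crude but useful stand-in for correlated
#' physiological background.
#'
#' @param clean m x t signal of interest at the sensors.
#' @param leadfield m x 3n lead field.
#' @param space The [source_space()] behind the lead field.
#' @param brain_snr Target signal-to-background power ratio.
#' @param seed Integer seed.
#' @return m x t data with background added.
#' @export
add_brain_noise <- function(clean, leadfield, space, brain_snr, seed) {
  clean <- as.matrix(clean)
  if (!(brain_snr > 0)) stop("brain_snr must be > 0", call. = FALSE)
  if (is.infinite(brain_snr)) return(clean)
  P <- mean(colSums(clean^2))
  if (P == 0) stop("clean data is identically zero", call. = FALSE)
  set.seed(seed)
  t_len <- ncol(clean)
  bg <- matrix(0, nrow(clean), t_len)
  for (s in seq_len(t_len)) {
    amp <- stats::rnorm(space$n)
    bg[, s] <- leadfield %*% moments_to_vec(amp * space$orientations)
  }
  Pb <- mean(colSums(bg^2))
  clean + bg * sqrt(P / (brain_snr * Pb))
}

#' Mean nearest-neighbor spacing of a source space
#'
#' @param space A [source_space()].
#' @return Scalar mean distance to the nearest other dipole (meters).
#' @export
nn_spacing <- function(space) {
  d <- as.matrix(stats::dist(space$positions))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

#' Intensity-weighted center of mass
#'
#' @param space A [source_space()].
#' @param intensities Non-negative length-n vector (e.g. reconstructed
#'   a_j).
#' @return Length-3 weighted mean position.
#' @export
intensity_center_of_mass <- function(space, intensities) {
  stopifnot(length(intensities) == space$n, all(intensities >= 0))
  if (sum(intensities) == 0) stop("all intensities are zero", call. = FALSE)
  colSums(space$positions * intensities) / sum(intensities)
}

#' Full synthetic MEG scenario
#'
#' Builds a complete, seeded test scenario: a tangential-orientation
#' spherical source space, a magnetometer array, the Sarvas lead field, a
#' compact patch of `patch_size` dipoles around a (seeded) randomly chosen
#' vertex, a time course, and sensor noise calibrated to `snr`. Defaults
#' (n = 400 dipoles, m = 60 magnetometers, 5-dipole patch, SNR = 15)
#' define the package's standard validation conditions.
#'
#' @param n Dipole count; default 400.
#' @param m Magnetometer count; default 60.
#' @param patch_size Number of active dipoles; default 5. The patch radius
#'   is the distance to the `patch_size`-th nearest vertex of the chosen
#'   center.
#' @param snr Target sensor SNR (power ratio); default 15.
#' @param amplitude Dipole strength, A*m; default 1e-8.
#' @param timecourse Activation time course; default 1 (single slice).
#' @param seed Integer seed driving patch placement and the noise draw.
#' @param src_radius,sen_radius Source/sensor sphere radii (m).
#' @return List of class `ias_scenario` with `space`, `sensors`,
#'   `leadfield`, `Q_true`, `support`, `center`, `clean`, `noisy`,
#'   `snr_target`, `seed`, `nn_spacing`.
#' @export
make_scenario <- function(n = 400, m = 60, patch_size = 5, snr = 15,
                          amplitude = 1e-8, timecourse = 1, seed = 1,
                          src_radius = 0.08, sen_radius = 0.12) {
  space <- make_sphere_source_space(n, radius = src_radius,
                                    orientation = "tangential")
  sensors <- make_sensor_array(m, radius = sen_radius)
  leadfield <- make_meg_leadfield(space, sensors)
  set.seed(seed)
  center_idx <- sample.int(n, 1)
  center <- space$positions[center_idx, ]
  d <- sort(sqrt(colSums((t(space$positions) - center)^2)))
  radius <- d[patch_size] * (1 + 1e-9)
  patch <- simulate_patch(space, center, radius, amplitude = amplitude,
                          timecourse = timecourse)
  t_len <- length(timecourse)
  clean <- matrix(0, m, t_len)
  for (s in seq_len(t_len)) {
    clean[, s] <- leadfield %*% moments_to_vec(patch$Q_true[, , s])
  }
  noisy <- add_noise(clean, snr, seed = seed + 1L)
  structure(list(space = space, sensors = sensors, leadfield = leadfield,
                 Q_true = patch$Q_true, support = patch$support,
                 center = center, clean = clean, noisy = noisy,
                 snr_target = snr, seed = seed,
                 nn_spacing = nn_spacing(space)),
            class = "ias_scenario")
}
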