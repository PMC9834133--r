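#' Parcel the source space into slice layers
#'
#' Subdivides the source space along one anatomical direction into
#' `n_layers` equal-width layers between the extremal coordinates: layer
#' boundaries c_l = c_min + l (c_max - c_min) / n_layers, l = 0..n_layers,
#' with half-open layers \[c_(l-1), c_l) and the maximal coordinate closed
#' into the top layer (otherwise the maximum would belong to no layer).
#' Axes follow the x = right, y = front, z = crown convention: axial
#' slices cut along z, coronal along y, sagittal along x.
#'
#' @param space A [source_space()].
#' @param axis `"axial"`, `"coronal"` or `"sagittal"`.
#' @param n_layers Number of layers; default 10.
#' @return Object of class `slice_parcellation` with `axis`, `coord`
#'   (which column was sliced), `boundaries` (length n_layers + 1) and
#'   `assignment` (length-n layer index in 1..n_layers).
#' @export
parcel_slices <- function(space, axis = c("axial", "coronal", "sagittal"),
                          n_layers = 10L) {
  stopifnot(inherits(space, "source_space"))
  axis <- match.arg(axis)
  n_layers <- as.integer(n_layers)
  if (n_layers < 1L) stop("n_layers must be >= 1", call. = FALSE)
  col <- switch(axis, axial = 3L, coronal = 2L, sagittal = 1L)
  v <- space$positions[, col]
  lo <- min(v)
  hi <- max(v)
  if (hi == lo) {
    boundaries <- rep(lo, n_layers + 1L)
    assignment <- rep(1L, space$n)
  } else {
    boundaries <- lo + (0:n_layers) * (hi - lo) / n_layers
    # pin the extremes so rounding cannot push min/max out of layers 1/n
    boundaries[1] <- lo
    boundaries[n_layers + 1L] <- hi
    assignment <- findInterval(v, boundaries, rightmost.closed = TRUE)
  }
  structure(list(axis = axis, coord = col, boundaries = boundaries,
                 assignment = assignment, n_layers = n_layers),
            class = "slice_parcellation")
}

#' @export
print.slice_parcellation <- function(x, ...) {
  cat("Slice parcellation (", x$axis, "): ", x$n_layers, " layers, counts ",
      paste(tabulate(x$assignment, x$n_layers), collapse = " "), "\n", sep = "")
  invisible(x)
}

# in-plane columns for a slicing axis (what is plotted within a layer)
inplane_cols <- function(axis) {
  switch(axis, axial = c(1L, 2L), coronal = c(1L, 3L), sagittal = c(2L, 3L))
}

inplane_labels <- function(axis) {
  switch(axis,
         axial = c("x (right)", "y (front)"),
         coronal = c("x (right)", "z (crown)"),
         sagittal = c("y (front)", "z (crown)"))
}

activity_palette <- function(k = 256L) {
  grDevices::colorRampPalette(
    c("#00004B", "#0040FF", "#00C0FF", "#80FF80", "#FFE000", "#FF4000",
      "#800000"))(k)
}

# map intensities to palette indices on a shared scale
intensity_colors <- function(intensities, pal) {
  rng <- range(intensities)
  if (rng[2] == rng[1]) return(rep(pal[1], length(intensities)))
  idx <- 1L + floor((intensities - rng[1]) / (rng[2] - rng[1]) *
                      (length(pal) - 1L))
  pal[idx]
}

#' Sliced activity-map figures
#'
#' For each requested view renders one raster figure with `n_layers`
#' panels; panel l scatter-plots the in-plane coordinates of the dipoles
#' in layer l colored by intensity on a color scale shared across all
#' panels of all views (per-figure maximum normalization).
#'
#' @param space A [source_space()].
#' @param intensities Non-negative length-n vector a_j = ||q_j||.
#' @param out_prefix Path prefix; files `<prefix>_<axis>.png` are written.
#' @param axes Character vector of views; default all three.
#' @param n_layers Layers per view; default 10.
#' @param width,height Device size in pixels.
#' @return Named character vector of created file paths (invisibly).
#' @export
render_activity_map <- function(space, intensities, out_prefix,
                                axes = c("axial", "coronal", "sagittal"),
                                n_layers = 10L, width = 1400, height = 600) {
  stopifnot(inherits(space, "source_space"))
  if (length(intensities) != space$n) {
    stop("intensities length ", length(intensities), " != n = ", space$n,
         call. = FALSE)
  }
  if (any(intensities < 0)) stop("intensities must be non-negative", call. = FALSE)
  pal <- activity_palette()
  cols <- intensity_colors(intensities, pal)
  paths <- character(0)
  for (axis in axes) {
    pc <- parcel_slices(space, axis, n_layers)
    ip <- inplane_cols(axis)
    labs <- inplane_labels(axis)
    xlim <- range(space$positions[, ip[1]])
    ylim <- range(space$positions[, ip[2]])
    path <- paste0(out_prefix, "_", axis, ".png")
    grDevices::png(path, width = width, height = height)
    op <- graphics::par(mfrow = c(2, ceiling(n_layers / 2)),
                        mar = c(2, 2, 2, 0.5))
    for (l in seq_len(n_layers)) {
      in_l <- pc$assignment == l
      graphics::plot(NA, xlim = xlim, ylim = ylim, asp = 1,
                     xlab = labs[1], ylab = labs[2],
                     main = sprintf("%s layer %d (%d pts)", axis, l,
                                    sum(in_l)),
                     cex.main = 0.9)
      if (any(in_l)) {
        graphics::points(space$positions[in_l, ip[1]],
                         space$positions[in_l, ip[2]],
                         pch = 16, cex = 0.8, col = cols[in_l])
      }
    }
    graphics::par(op)
    grDevices::dev.off()
    paths[axis] <- path
  }
  invisible(paths)
}

#' Single-slice activity view through a point
#'
#' Renders one figure with three panels: the axial, coronal and sagittal
#' layer containing the selected point, with a marker at the point's
#' in-plane projection. Useful for checking how well a focal source is
#' localized. A point outside the source-space bounding box is clamped to
#' the nearest layer with a warning.
#'
#' @param space A [source_space()].
#' @param intensities Non-negative length-n vector.
#' @param point Length-3 coordinates of the intersection point (meters).
#' @param out_file Output PNG path.
#' @param marker Plot character for the intersection marker; default
#'   `"+"`.
#' @param n_layers Layers per axis; default 10.
#' @param width,height Device size in pixels.
#' @return The output path (invisibly).
#' @export
render_single_slice <- function(space, intensities, point, out_file,
                                marker = "+", n_layers = 10L,
                                width = 1200, height = 420) {
  stopifnot(inherits(space, "source_space"))
  point <- as.numeric(point)
  if (length(point) != 3L || !all(is.finite(point))) {
    stop("point must be a finite length-3 vector", call. = FALSE)
  }
  if (length(intensities) != space$n) {
    stop("intensities length ", length(intensities), " != n = ", space$n,
         call. = FALSE)
  }
  pal <- activity_palette()
  cols <- intensity_colors(intensities, pal)
  grDevices::png(out_file, width = width, height = height)
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
  for (axis in c("axial", "coronal", "sagittal")) {
    pc <- parcel_slices(space, axis, n_layers)
    v <- point[pc$coord]
    lo <- pc$boundaries[1]
    hi <- pc$boundaries[n_layers + 1L]
    if (v < lo || v > hi) {
      warning("point coordinate ", format(v), " outside source-space range [",
              format(lo), ", ", format(hi), "] on the ", axis,
              " axis; using the nearest slice", call. = FALSE)
      v <- min(max(v, lo), hi)
    }
    layer <- if (hi == lo) 1L else {
      findInterval(v, pc$boundaries, rightmost.closed = TRUE)
    }
    in_l <- pc$assignment == layer
    ip <- inplane_cols(axis)
    labs <- inplane_labels(axis)
    graphics::plot(NA, xlim = range(space$positions[, ip[1]]),
                   ylim = range(space$positions[, ip[2]]), asp = 1,
                   xlab = labs[1], ylab = labs[2],
                   main = sprintf("%s slice %d", axis, layer))
    if (any(in_l)) {
      graphics::points(space$positions[in_l, ip[1]],
                       space$positions[in_l, ip[2]],
                       pch = 16, cex = 1.1, col = cols[in_l])
    }
    graphics::points(point[ip[1]], point[ip[2]], pch = marker, cex = 2.5,
                     col = "black", lwd = 2)
  }
  graphics::par(op)
  grDevices::dev.off()
  invisible(out_file)
}

#' Strongest dipole time courses
#'
#' Selects the k dipoles with the largest peak intensity over time and
#' returns their intensity traces; the standard way to summarize which
#' sources drive a reconstruction over a time window.
#'
#' @param result An `ias_result` from [ias_time_series()] (or any list
#'   with an `intensities` n x t matrix).
#' @param k Number of dipoles; clipped to n with a warning when larger.
#' @return List with `indices` (length k, by decreasing peak intensity)
#'   and `traces` (k x t matrix).
#' @export
extract_peak_timecourses <- function(result, k) {
  intens <- result$intensities
  n <- nrow(intens)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > n) {
    warning("k = ", k, " exceeds the number of dipoles (", n,
            "); returning all ", n, call. = FALSE)
    k <- n
  }
  peak <- apply(intens, 1, max)
  idx <- order(peak, decreasing = TRUE)[seq_len(k)]
  list(indices = idx, traces = intens[idx, , drop = FALSE])
}
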