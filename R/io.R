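#' Write a numeric matrix as tab-separated text
#'
#' Values are written with 17 significant digits (`%.17g`), enough to
#' round-trip IEEE doubles bit-exactly. No header, one matrix row per
#' line. This plain-text layout is the package's canonical on-disk format
#' for lead fields, source spaces, data and results.
#'
#' @param x Numeric matrix (a vector is written as one column).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("refusing to write non-finite values", call. = FALSE)
  lines <- apply(x, 1, function(row) paste(sprintf("%.17g", row),
                                           collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a tab-separated numeric matrix
#'
#' @param path File written by [write_matrix_tsv()] (or any headerless
#'   whitespace-delimited numeric table).
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- as.matrix(utils::read.table(path, header = FALSE,
                                   colClasses = "numeric"))
  dimnames(x) <- NULL
  x
}

#' Read and shape-check the solver inputs
#'
#' @param paths Named list/vector with elements `leadfield`, `positions`,
#'   `orientations` and `data`, each a delimited-text matrix file.
#' @return List with `space` (a [source_space()]), `leadfield` (m x 3n)
#'   and `data` (m x t), after consistency checks with informative errors.
#' @export
read_inputs <- function(paths) {
  need <- c("leadfield", "positions", "orientations", "data")
  missing_keys <- setdiff(need, names(paths))
  if (length(missing_keys) > 0) {
    stop("missing input path(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  leadfield <- read_matrix_tsv(paths[["leadfield"]])
  positions <- read_matrix_tsv(paths[["positions"]])
  orientations <- read_matrix_tsv(paths[["orientations"]])
  data <- read_matrix_tsv(paths[["data"]])
  space <- source_space(positions, orientations)
  if (ncol(leadfield) != 3L * space$n) {
    hint <- if (nrow(leadfield) == 3L * space$n) {
      " (the matrix appears to be transposed: rows = 3n)"
    } else ""
    stop("lead field has ", ncol(leadfield), " columns; expected 3n = ",
         3L * space$n, " for n = ", space$n, " dipoles", hint, call. = FALSE)
  }
  if (nrow(data) != nrow(leadfield)) {
    stop("data has ", nrow(data), " rows; lead field has ", nrow(leadfield),
         " rows (channels must match)", call. = FALSE)
  }
  list(space = space, leadfield = leadfield, data = data)
}

#' Pipeline run configuration
#'
#' Collects file paths and solver parameters with the package defaults:
#' delta = 0.05, eta = 0.01, tau = 0.01, n_outer = 30, max_it = 120,
#' cutoff_quantile = 1 (no truncation).
#'
#' @param leadfield,positions,orientations,data Input file paths.
#' @param output Output directory.
#' @param snr Signal-to-noise power ratio (required, > 1).
#' @param eta,delta,cutoff_quantile,tau,n_outer,max_it Model/solver
#'   parameters, see [set_parameters()] and [ias_control()].
#' @param warm_start Warm-start the time series; default TRUE.
#' @param figures Render sliced activity maps; default TRUE.
#' @param seed Seed recorded for synthetic subcommands.
#' @param log_level `"info"` prints per-slice diagnostics, `"quiet"`
#'   suppresses them.
#' @return List of class `run_config`.
#' @export
run_config <- function(leadfield, positions, orientations, data, output,
                       snr, eta = 0.01, delta = 0.05, cutoff_quantile = 1,
                       tau = 0.01, n_outer = 30L, max_it = 120L,
                       warm_start = TRUE, figures = TRUE, seed = 1L,
                       log_level = c("info", "quiet")) {
  if (missing(snr)) stop("snr is required", call. = FALSE)
  structure(list(leadfield = leadfield, positions = positions,
                 orientations = orientations, data = data, output = output,
                 snr = snr, eta = eta, delta = delta,
                 cutoff_quantile = cutoff_quantile, tau = tau,
                 n_outer = as.integer(n_outer), max_it = as.integer(max_it),
                 warm_start = isTRUE(warm_start), figures = isTRUE(figures),
                 seed = as.integer(seed),
                 log_level = match.arg(log_level)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys match the arguments of [run_config()]; `overrides` (e.g. parsed
#' command-line flags) take precedence over file values.
#'
#' @param path YAML file.
#' @param overrides Named list of values overriding the file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  do.call(run_config, cfg)
}

#' Run the full reconstruction pipeline
#'
#' Executes the four stages in order: anatomical prior construction,
#' SNR-driven parameter setup, the IAS time-series solve, and sliced
#' visualization; then persists the result container (and figures) under
#' `config$output`. Reconstructed moments are returned on the physical
#' scale of the inputs (the internal lead-field/data scalings are undone).
#'
#' @param config A [run_config()].
#' @param inputs Optional pre-loaded inputs (as returned by
#'   [read_inputs()]); when absent the paths in `config` are read.
#' @return The `ias_result` (invisibly), with `Q_hat` in input units.
#' @export
run_pipeline <- function(config, inputs = NULL) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$log_level == "info") message(...)
  stage <- "read-inputs"
  res <- tryCatch({
    if (is.null(inputs)) {
      inputs <- read_inputs(config[c("leadfield", "positions",
                                     "orientations", "data")])
    }
    stage <- "prior"
    say("[prior] building anatomical prior (delta = ", config$delta, ")")
    prior <- anatomical_prior(inputs$space, delta = config$delta)
    stage <- "hyper"
    say("[hyper] SNR = ", config$snr, ", eta = ", config$eta,
        ", cutoff quantile = ", config$cutoff_quantile)
    model <- set_parameters(inputs$leadfield, inputs$data, prior,
                            snr = config$snr, eta = config$eta,
                            cutoff_quantile = config$cutoff_quantile)
    stage <- "solver"
    control <- ias_control(tau = config$tau, n_outer = config$n_outer,
                           max_it = config$max_it)
    result <- ias_time_series(model$data, prior, model, control,
                              warm_start = config$warm_start)
    if (config$log_level == "info") {
      for (s in seq_along(result$diagnostics)) {
        d <- result$diagnostics[[s]]
        if (is.null(d)) { say("[solver] slice ", s, ": ", result$errors[s]); next }
        for (k in seq_len(nrow(d))) {
          say(sprintf("[solver] slice %d outer %d: inner = %d, dTheta = %.3g",
                      s, k, d[k, "inner"], d[k, "rel_change"]))
        }
      }
    }
    # undo the internal scalings: b' = scale_b b, M' = scale_M M
    # => Q_physical = Q_scaled * scale_M / scale_b
    unscale <- model$scale_M / model$scale_b
    result$Q_hat <- result$Q_hat * unscale
    result$intensities <- result$intensities * unscale
    stage <- "write-result"
    dir.create(config$output, recursive = TRUE, showWarnings = FALSE)
    write_result(result, config$output, config = config)
    if (config$figures) {
      stage <- "viz"
      peak_slice <- which.max(apply(result$intensities, 2, max))
      render_activity_map(inputs$space, result$intensities[, peak_slice],
                          file.path(config$output, "activity"))
    }
    result
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' Persist an IAS result container
#'
#' Writes `Q_hat.tsv` (3n x t, dipole-major rows), `theta_hat.tsv`
#' (n x t), `intensities.tsv` (n x t), `diagnostics.tsv` (long table:
#' slice, outer, inner, rel_change) and `config.yaml` (when a config is
#' supplied) into `dir`.
#'
#' @param result An `ias_result`.
#' @param dir Output directory (created if needed).
#' @param config Optional [run_config()] echoed alongside the result.
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(result$Q_hat)
  Qflat <- matrix(aperm(result$Q_hat, c(2, 1, 3)), d[1] * 3L, d[3])
  write_matrix_tsv(Qflat, file.path(dir, "Q_hat.tsv"))
  write_matrix_tsv(result$theta_hat, file.path(dir, "theta_hat.tsv"))
  write_matrix_tsv(result$intensities, file.path(dir, "intensities.tsv"))
  rows <- list()
  for (s in seq_along(result$diagnostics)) {
    dm <- result$diagnostics[[s]]
    if (is.null(dm)) next
    rows[[s]] <- cbind(slice = s, outer = seq_len(nrow(dm)), dm)
  }
  diag_tab <- do.call(rbind, rows)
  utils::write.table(diag_tab, file.path(dir, "diagnostics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(config)) {
    yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' Read back a persisted IAS result
#'
#' @param dir Directory written by [write_result()].
#' @return List with `Q_hat` (n x 3 x t), `theta_hat`, `intensities` and
#'   `diagnostics` (data frame).
#' @export
read_result <- function(dir) {
  Qflat <- read_matrix_tsv(file.path(dir, "Q_hat.tsv"))
  n <- nrow(Qflat) %/% 3L
  t_len <- ncol(Qflat)
  Q_hat <- aperm(array(Qflat, c(3L, n, t_len)), c(2, 1, 3))
  list(Q_hat = Q_hat,
       theta_hat = read_matrix_tsv(file.path(dir, "theta_hat.tsv")),
       intensities = read_matrix_tsv(file.path(dir, "intensities.tsv")),
       diagnostics = utils::read.table(file.path(dir, "diagnostics.tsv"),
                                       header = TRUE, sep = "\t"))
}

#' Write a ready-to-run synthetic scenario
#'
#' Generates a [make_scenario()] and writes it in the layout
#' [read_inputs()] expects (`leadfield.tsv`, `positions.tsv`,
#' `orientations.tsv`, `data.tsv`), plus ground truth for validation
#' (`Q_true.tsv` 3n x t, `support.tsv`) and a `meta.yaml` with the
#' scenario parameters.
#'
#' @param dir Output directory.
#' @param ... Passed to [make_scenario()].
#' @return The scenario (invisibly).
#' @export
make_synthetic <- function(dir, ...) {
  sc <- make_scenario(...)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(sc$leadfield, file.path(dir, "leadfield.tsv"))
  write_matrix_tsv(sc$space$positions, file.path(dir, "positions.tsv"))
  write_matrix_tsv(sc$space$orientations, file.path(dir, "orientations.tsv"))
  write_matrix_tsv(sc$noisy, file.path(dir, "data.tsv"))
  d <- dim(sc$Q_true)
  write_matrix_tsv(matrix(aperm(sc$Q_true, c(2, 1, 3)), d[1] * 3L, d[3]),
                   file.path(dir, "Q_true.tsv"))
  write_matrix_tsv(matrix(sc$support, ncol = 1), file.path(dir, "support.tsv"))
  yaml::write_yaml(list(n = sc$space$n, m = sc$sensors$m,
                        snr_target = sc$snr_target, seed = sc$seed,
                        patch_center = as.numeric(sc$center),
                        patch_size = length(sc$support),
                        nn_spacing = sc$nn_spacing),
                   file.path(dir, "meta.yaml"))
  invisible(sc)
}
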