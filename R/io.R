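# Delimited-text I/O for rasters, traces, positions, configs and results.
# Rasters/traces: tab-separated, first row = neuron ids, rows = timepoints.
# Positions: tab-separated with columns neuron_id, x_um, y_um.

#' Read a binary activity raster from delimited text
#'
#' @param path file path; tab- or comma-delimited, header row of neuron ids.
#' @return integer binary matrix (time x neuron) with neuron-id column names.
#' @export
read_raster <- function(path) {
  m <- read_matrix_file(path)
  bad <- which(!(m == 0 | m == 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_invalid("non-binary value ", m[bad[1L, 1L], bad[1L, 2L]],
                 " in raster at row ", bad[1L, 1L], ", column ",
                 colnames(m)[bad[1L, 2L]])
  }
  storage.mode(m) <- "integer"
  m
}

#' Read continuous deconvolved traces from delimited text
#' @param path file path; same layout as rasters.
#' @return numeric matrix (time x neuron), nonnegative.
#' @export
read_traces <- function(path) {
  m <- read_matrix_file(path)
  if (any(m < 0)) stop_invalid("traces must be nonnegative")
  m
}

read_matrix_file <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE)
  m <- as.matrix(dt)
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop_invalid("non-finite value at row ", bad[1L], ", column ", bad[2L],
                 " of ", path)
  }
  m
}

#' Write a raster or trace matrix as delimited text
#' @param m matrix, time x neuron; column names are the neuron ids.
#' @param path destination file.
#' @export
write_raster <- function(m, path) {
  if (is.null(colnames(m))) colnames(m) <- seq_len(ncol(m)) - 1L
  data.table::fwrite(data.table::as.data.table(m), path, sep = "\t")
  invisible(path)
}

#' Read neuron positions from delimited text
#'
#' @param path file with columns `neuron_id`, `x_um`, `y_um`.
#' @return data.frame ordered by neuron id.
#' @export
read_positions <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  dt <- as.data.frame(data.table::fread(path, header = TRUE))
  need <- c("neuron_id", "x_um", "y_um")
  if (!all(need %in% names(dt))) {
    stop_invalid("positions file must have columns ",
                 paste(need, collapse = ", "))
  }
  dt <- dt[order(dt$neuron_id), need]
  if (anyDuplicated(dt$neuron_id) ||
      !identical(as.integer(dt$neuron_id), seq_len(nrow(dt)) - 1L)) {
    stop_invalid("neuron ids must be unique and contiguous from 0")
  }
  if (any(!is.finite(dt$x_um)) || any(!is.finite(dt$y_um))) {
    stop_invalid("positions contain non-finite coordinates")
  }
  rownames(dt) <- NULL
  dt
}

#' Write neuron positions as delimited text
#' @param positions positions data.frame.
#' @param path destination file.
#' @export
write_positions <- function(positions, path) {
  data.table::fwrite(positions, path, sep = "\t")
  invisible(path)
}

#' Check raster / positions consistency
#'
#' @param raster binary matrix with neuron-id column names.
#' @param positions positions table.
#' @return invisibly TRUE; errors when ids mismatch.
#' @export
check_consistency <- function(raster, positions) {
  if (ncol(raster) != nrow(positions)) {
    stop_invalid("raster has ", ncol(raster), " neurons but positions has ",
                 nrow(positions))
  }
  if (!is.null(colnames(raster))) {
    rid <- suppressWarnings(as.integer(colnames(raster)))
    if (!any(is.na(rid)) && !identical(rid, as.integer(positions$neuron_id))) {
      stop_invalid("neuron ids of raster and positions do not match")
    }
  }
  invisible(TRUE)
}

#' Read a pipeline configuration (YAML)
#'
#' Unspecified keys fall back to [default_config()].
#'
#' @param path YAML file.
#' @return a config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user)
}

#' Default pipeline configuration
#'
#' Analysis constants default to the values used throughout the package:
#' lag `tau = 1` frame, effective-length window `d0 = 100`, `dmax = 1500`
#' micrometres, long-path threshold 4 hops, `k = 10` neighbours per layer.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    generator = list(n_neurons = 200L, n_timepoints = 20000L,
                     field_size = 3000, lambda_true = 600, c0_true = 0.1,
                     c_inf_true = 0.01, persistence = 0.3,
                     firing_prob = 0.05, xor_triplets = list(),
                     xor_flip_prob = 0.05),
    raster_file = NULL, traces_file = NULL, positions_file = NULL,
    tau = 1L,
    max_pairs = 500000L, min_pair_distance_um = 0,
    n_null = 100L, null_series_length = 10000L, null_finite_sample = FALSE,
    n_bins = 20L, d_min = 10, d_max_bin = NULL, min_pairs_per_bin = 50L,
    d0 = 100, dmax = 1500,
    k = 10L, long_threshold = 4L,
    out_dir = NULL)
}
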