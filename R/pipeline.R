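#' Run the full analysis pipeline
#'
#' Chains the stages behind one configuration: obtain data (synthetic
#' generation or files), binarize continuous traces if needed, compute the
#' pairwise time-delayed PID, Z-score it against TDMI-matched null models,
#' build distance curves and decay fits for Pearson correlation and Z-scored
#' synergy / redundancy, construct the kNN interaction layers and classify
#' union shortest paths. All randomness flows from `config$seed` through
#' fixed per-stage sub-seeds, so reruns with the same config are
#' bit-identical. When `config$out_dir` is set, every stage's table plus a
#' machine-readable `summary.json` (with a provenance block) is written
#' there.
#'
#' @param config a config list (see [default_config()] / [read_config()]).
#' @return object of class `synpid_results`: list with `positions`,
#'   `raster`, `pid`, `profiles` (per-metric curve/fit/lambda/lambda_eff),
#'   `network` (layers, counts, proportions), `summary`, `log`.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- modifyList(default_config(), config)
  log <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  seeds <- derive_seeds(config$seed)

  # --- input --------------------------------------------------------------
  inp <- stage("input", {
    if (!is.null(config$raster_file) || !is.null(config$traces_file)) {
      positions <- read_positions(config$positions_file)
      if (!is.null(config$raster_file)) {
        raster <- read_raster(config$raster_file)
      } else {
        raster <- read_traces(config$traces_file)
      }
      check_consistency(raster, positions)
      list(positions = positions, raster = raster)
    } else {
      g <- config$generator
      params <- generator_params(
        n_neurons = g$n_neurons, n_timepoints = g$n_timepoints,
        field_size = g$field_size, lambda_true = g$lambda_true,
        c0_true = g$c0_true, c_inf_true = g$c_inf_true,
        persistence = g$persistence, firing_prob = g$firing_prob,
        xor_triplets = g$xor_triplets, xor_flip_prob = g$xor_flip_prob,
        seed = seeds["generator"])
      positions <- generate_positions(g$n_neurons, g$field_size,
                                      seed = seeds["positions"])
      list(positions = positions, raster = simulate_raster(positions, params))
    }
  })
  positions <- inp$positions
  raster <- inp$raster

  # --- binarization (skipped for already-binary input) --------------------
  raster <- stage("binarization", {
    if (is_binary_matrix(raster)) {
      storage.mode(raster) <- "integer"
      raster
    } else {
      binarize_dataset(raster)
    }
  })
  log$n_neurons <- ncol(raster)
  log$n_timepoints <- nrow(raster)

  # --- pairwise PID + NuMIT ----------------------------------------------
  pid <- stage("pid", {
    pid_pair_table(raster, positions, tau = config$tau,
                   max_pairs = config$max_pairs,
                   min_pair_distance_um = config$min_pair_distance_um,
                   seed = seeds["pairs"])
  })
  log$n_pairs <- nrow(pid)
  log$n_degenerate_pairs <- sum(pid$degenerate)
  pid <- stage("numit", {
    numit_table(pid, n_null = config$n_null, seed = seeds["numit"],
                series_length = config$null_series_length,
                finite_sample = config$null_finite_sample)
  })

  # --- spatial profiles ---------------------------------------------------
  pearson <- stage("pearson", pairwise_pearson(raster, positions))
  log$n_pairs_excluded_constant <- attr(pearson, "n_excluded")
  profiles <- stage("spatial", {
    prof <- list(pearson = spatial_profile(
      pearson, n_bins = config$n_bins, d_min = config$d_min,
      d_max_bin = config$d_max_bin,
      min_pairs_per_bin = config$min_pairs_per_bin,
      d0 = config$d0, dmax = config$dmax))
    for (metric in c("z_si", "z_ri")) {
      pv <- data.frame(i = pid$i, j = pid$j, value = pid[[metric]],
                       distance_um = pid$distance_um)
      prof[[metric]] <- spatial_profile(
        pv, n_bins = config$n_bins, d_min = config$d_min,
        d_max_bin = config$d_max_bin,
        min_pairs_per_bin = config$min_pairs_per_bin,
        d0 = config$d0, dmax = config$dmax)
    }
    prof
  })

  # --- network decomposition ---------------------------------------------
  network <- stage("network", {
    ok <- is.finite(pid$z_si) & is.finite(pid$z_ri)
    la <- build_knn_layer(
      data.frame(i = pid$i[ok], j = pid$j[ok], value = pid$z_si[ok]),
      node_ids = positions$neuron_id, k = config$k, metric = "z_si")
    lb <- build_knn_layer(
      data.frame(i = pid$i[ok], j = pid$j[ok], value = pid$z_ri[ok]),
      node_ids = positions$neuron_id, k = config$k, metric = "z_ri")
    net <- combined_network(la, lb)
    counts <- classify_paths(net)
    props <- path_proportions(counts, long_threshold = config$long_threshold)
    list(synergy_layer = la, redundancy_layer = lb, net = net,
         counts = counts, proportions = props)
  })
  log$n_synergy_edges <- nrow(network$synergy_layer$edges)
  log$n_redundancy_edges <- nrow(network$redundancy_layer$edges)
  log$nodes_short_of_k <- network$synergy_layer$n_short_of_k

  summary <- list(
    lambda_um = list(pearson = profiles$pearson$lambda,
                     z_si = profiles$z_si$lambda,
                     z_ri = profiles$z_ri$lambda),
    lambda_eff_um = list(pearson = profiles$pearson$lambda_eff,
                         z_si = profiles$z_si$lambda_eff,
                         z_ri = profiles$z_ri$lambda_eff),
    c0 = list(pearson = profiles$pearson$fit$c0,
              z_si = profiles$z_si$fit$c0, z_ri = profiles$z_ri$fit$c0),
    c_inf = list(pearson = profiles$pearson$fit$c_inf,
                 z_si = profiles$z_si$fit$c_inf,
                 z_ri = profiles$z_ri$fit$c_inf),
    long_path_proportions = as.list(network$proportions$long),
    counts = log)

  res <- structure(list(positions = positions, raster = raster, pid = pid,
                        profiles = profiles, network = network,
                        summary = summary, log = log, config = config),
                   class = "synpid_results")
  if (!is.null(config$out_dir)) write_results(res, config$out_dir)
  res
}

derive_seeds <- function(seed) {
  with_seed(seed, {
    s <- sample.int(.Machine$integer.max - 1L, 6L)
    names(s) <- c("generator", "positions", "pairs", "numit", "null", "misc")
    s
  })
}

#' Write a results bundle to an output directory
#'
#' Writes the raster, positions, pair PID/Z table, per-metric curves and
#' fits, per-layer and union edge lists, the per-length path-classification
#' table, and `summary.json` including a provenance block (config hash,
#' seed, package version).
#'
#' @param res a `synpid_results` from [run_pipeline()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the output directory.
#' @export
write_results <- function(res, out_dir) {
  stopifnot(inherits(res, "synpid_results"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_raster(res$raster, fp("raster.tsv"))
  write_positions(res$positions, fp("positions.tsv"))
  data.table::fwrite(res$pid, fp("pair_pid.tsv"), sep = "\t")
  for (metric in names(res$profiles)) {
    p <- res$profiles[[metric]]
    data.table::fwrite(as.data.frame(p$curve),
                       fp(paste0("curve_", metric, ".tsv")), sep = "\t")
    jsonlite::write_json(
      list(c0 = p$fit$c0, c_inf = p$fit$c_inf, lambda_um = p$fit$lam,
           lambda_eff_um = p$lambda_eff, converged = p$fit$converged),
      fp(paste0("fit_", metric, ".json")), auto_unbox = TRUE, digits = NA)
  }
  edges_df <- function(e) data.frame(i = e[, 1L], j = e[, 2L])
  data.table::fwrite(edges_df(res$network$synergy_layer$edges),
                     fp("edges_synergy.tsv"), sep = "\t")
  data.table::fwrite(edges_df(res$network$redundancy_layer$edges),
                     fp("edges_redundancy.tsv"), sep = "\t")
  data.table::fwrite(edges_df(res$network$net$union_edges),
                     fp("edges_union.tsv"), sep = "\t")
  data.table::fwrite(as.data.frame(res$network$counts),
                     fp("path_classes.tsv"), sep = "\t")

  cfg_file <- fp("config.yaml")
  yaml::write_yaml(res$config, cfg_file)
  # hash the analysis-relevant configuration only (output paths excluded)
  hash_file <- tempfile(fileext = ".yaml")
  cfg_for_hash <- res$config
  cfg_for_hash$out_dir <- NULL
  yaml::write_yaml(cfg_for_hash, hash_file)
  provenance <- list(config_hash = unname(tools::md5sum(hash_file)),
                     seed = res$config$seed,
                     package_version = as.character(
                       utils::packageVersion("synpid")))
  jsonlite::write_json(c(res$summary, list(provenance = provenance)),
                       fp("summary.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(out_dir)
}

#' @export
print.synpid_results <- function(x, ...) {
  cat("synpid pipeline results\n")
  cat(sprintf("  %d neurons x %d timepoints, %d pairs analysed\n",
              x$log$n_neurons, x$log$n_timepoints, x$log$n_pairs))
  cat(sprintf("  lambda (pearson): %.4g um; lambda_eff z_si %.4g um, z_ri %.4g um\n",
              x$summary$lambda_um$pearson, x$summary$lambda_eff_um$z_si,
              x$summary$lambda_eff_um$z_ri))
  lp <- x$summary$long_path_proportions
  cat(sprintf("  long-path proportions: complementary %.3f, shared %.3f, unique %.3f / %.3f\n",
              lp$complementary, lp$shared, lp$unique_a, lp$unique_b))
  invisible(x)
}

#' Two-condition synthetic experiment
#'
#' Generates `n_per_condition` independent rasters per condition with
#' condition-specific generator parameters (typically differing in
#' `lambda_true`, emulating spontaneous vs stimulated recordings), fits the
#' Pearson decay per raster, and compares the fitted correlation lengths
#' across conditions with an exhaustive permutation test and Hedge's g.
#'
#' @param params_a,params_b `generator_params` for the two conditions (their
#'   `seed` fields are overridden per replicate).
#' @param n_per_condition recordings per condition.
#' @param seed integer master seed.
#' @param n_bins,d_min,d_max_bin,min_pairs_per_bin binning settings.
#' @return list with `lambda_a`, `lambda_b` (per-recording fitted lambdas)
#'   and `comparison` (a `group_comparison`).
#' @export
run_condition_experiment <- function(params_a, params_b,
                                     n_per_condition = 5L, seed = 1L,
                                     n_bins = 20L, d_min = 10,
                                     d_max_bin = NULL,
                                     min_pairs_per_bin = 50L) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      4L * n_per_condition + 1L))
  fit_one <- function(params, s_pos, s_gen) {
    params$seed <- s_gen
    pos <- generate_positions(params$n_neurons, params$field_size,
                              seed = s_pos)
    r <- simulate_raster(pos, params)
    pv <- pairwise_pearson(r, pos)
    prof <- spatial_profile(pv, n_bins = n_bins, d_min = d_min,
                            d_max_bin = d_max_bin,
                            min_pairs_per_bin = min_pairs_per_bin)
    prof$lambda
  }
  off <- 2L * n_per_condition
  lambda_a <- vapply(seq_len(n_per_condition), function(r)
    fit_one(params_a, seeds[2L * r - 1L], seeds[2L * r]), numeric(1))
  lambda_b <- vapply(seq_len(n_per_condition), function(r)
    fit_one(params_b, seeds[off + 2L * r - 1L], seeds[off + 2L * r]),
    numeric(1))
  list(lambda_a = lambda_a, lambda_b = lambda_b,
       comparison = compare_conditions(lambda_a, lambda_b,
                                       seed = seeds[4L * n_per_condition + 1L]))
}
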