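#' Run configuration for the full workflow
#'
#' Collects the grid specification, simulation settings, feature settings
#' and fit settings used by [run_sweep()] and [run_fit()]. Configurations
#' can also be loaded from YAML with [read_run_config()]. All randomness is
#' routed through explicit seeds; one network seed per g_I level is shared
#' across all g_E at that level, so simulations at a given inhibition level
#' differ only in their excitation scaling.
#'
#' @param g_E_values,g_I_values Grid axes. The default g_E ladder is
#'   irregular (denser at the middle); the default g_I axis has step 4.
#' @param n_cells,p_connect,duration,dt,syn_every,syn_scale,transient
#'   Simulation settings (see [network_config()]).
#' @param n_feat,n_subsets,beta,eps Fit settings (see [fit_dataset()]).
#' @param seed Master seed; the per-g_I network seeds are `seed + 1000 * i`.
#' @param cell Cell model.
#' @return A `run_config` list.
#' @export
run_config <- function(g_E_values = c(15, 25, 32, 40, 50, 62, 75, 90, 110),
                       g_I_values = seq(5, 65, by = 4),
                       n_cells = 2500, p_connect = 0.2,
                       duration = 200, dt = 0.05, syn_every = 1,
                       syn_scale = NULL, transient = 2,
                       n_feat = 7, n_subsets = 30, beta = 3, eps = 1e-7,
                       seed = 1, cell = msn_cell_model()) {
  if (is.null(syn_scale)) syn_scale <- (2500 * 0.2) / (n_cells * p_connect)
  structure(list(g_E_values = g_E_values, g_I_values = g_I_values,
                 n_cells = n_cells, p_connect = p_connect,
                 duration = duration, dt = dt, syn_every = syn_every,
                 syn_scale = syn_scale, transient = transient,
                 n_feat = n_feat, n_subsets = n_subsets, beta = beta,
                 eps = eps, seed = seed, cell = cell),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Scalar fields of [run_config()] plus `g_E_values`/`g_I_values` lists;
#' unknown fields are rejected. The cell model accepts a `cell:` mapping of
#' [msn_cell_model()] arguments.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  if (!is.null(y$cell)) y$cell <- do.call(msn_cell_model, y$cell)
  do.call(run_config, y)
}

#' Simulate the parameter grid and build a model library
#'
#' Simulates every (g_E, g_I) grid point, reduces each simulation to its
#' per-cell feature table (model mode: one 200-s spike train per active
#' cell), and returns the library. With an output directory, each grid point
#' is written as spike TSV plus feature CSV, with a manifest JSON listing
#' the configuration and per-point file names; an existing manifest allows a
#' partial sweep to resume.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param keep_spikes Keep raw spike trains in the returned library.
#' @return A model library: `grid`, `features` (list of data frames),
#'   optionally `spikes`.
#' @export
run_sweep <- function(config, out_dir = NULL, keep_spikes = FALSE) {
  grid <- expand.grid(g_I = config$g_I_values, g_E = config$g_E_values,
                      KEEP.OUT.ATTRS = FALSE)[, c("g_E", "g_I")]
  feats <- vector("list", nrow(grid))
  spikes <- if (keep_spikes) vector("list", nrow(grid)) else NULL
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  manifest_path <- if (!is.null(out_dir)) file.path(out_dir, "manifest.json")
  for (i in seq_len(nrow(grid))) {
    g_I <- grid$g_I[i]; g_E <- grid$g_E[i]
    seed_i <- config$seed + 1000L * match(g_I, config$g_I_values)
    point_csv <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("gE%03d_gI%02d_features.csv", g_E, g_I))
    if (!is.null(out_dir) && file.exists(point_csv)) {
      feats[[i]] <- read_feature_csv(point_csv)
      next
    }
    cfg <- network_config(n_cells = config$n_cells,
                          p_connect = config$p_connect,
                          g_E = g_E, g_I = g_I,
                          duration = config$duration, dt = config$dt,
                          seed = seed_i, transient = config$transient,
                          syn_every = config$syn_every,
                          syn_scale = config$syn_scale, cell = config$cell)
    net <- build_network(cfg)
    res <- simulate_network(net, cfg)
    segs <- lapply(res$spike_times, function(st)
      list(spike_times = st, t_seg = config$duration))
    segs <- filter_segments(segs, mode = "model")$kept
    feats[[i]] <- feature_table(segs)
    if (keep_spikes) spikes[[i]] <- res
    if (!is.null(out_dir)) {
      write_spike_tsv(res, file.path(out_dir,
        sprintf("gE%03d_gI%02d_spikes.tsv", g_E, g_I)))
      write_feature_csv(feats[[i]], point_csv)
    }
  }
  lib <- list(grid = grid, features = feats)
  if (keep_spikes) lib$spikes <- spikes
  if (!is.null(out_dir)) {
    man <- list(grid = grid,
                n_points = nrow(grid),
                settings = config[setdiff(names(config), "cell")])
    jsonlite::write_json(man, manifest_path, auto_unbox = TRUE, digits = NA)
  }
  lib
}

#' Fit a dataset against a model library, with report
#'
#' Wraps [fit_dataset()] with the segment accounting a full analysis needs:
#' input segments are filtered (experimental mode), reduced to features, and
#' the returned object carries the estimate, the log-KL heat map, and a
#' plain-text report of filters and counts.
#'
#' @param segments List of spike-train segments (experimental-style).
#' @param library Model library from [run_sweep()].
#' @param config A [run_config()] (fit settings are taken from it).
#' @param seed Seed for the subset draws (defaults to the config's).
#' @return List with `estimate` (a `param_estimate`), `features`, `report`.
#' @export
run_fit <- function(segments, library, config = run_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  filt <- filter_segments(segments, mode = "experimental")
  feats <- feature_table(filt$kept)
  est <- fit_dataset(feats, library, n_feat = config$n_feat,
                     n_subsets = config$n_subsets, beta = config$beta,
                     eps = config$eps, seed = seed)
  report <- paste(
    sprintf("segments in: %d", length(segments)),
    sprintf("rejected by filters: %d", nrow(filt$log)),
    sprintf("usable feature vectors: %d", nrow(feats)),
    sprintf("library: %d grid points", nrow(library$grid)),
    sprintf("estimate: gE* = %.2f +/- %.2f, gI* = %.2f +/- %.2f",
            est$gE, est$se_gE, est$gI, est$se_gI),
    sep = "\n")
  list(estimate = est, features = feats, report = report,
       rejection_log = filt$log)
}
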