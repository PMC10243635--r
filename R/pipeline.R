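#' Workflow configuration
#'
#' Bundles every knob of the end-to-end analysis. `input` is either a path
#' to an edge-list file, a `ugraph`, or a null-model recipe list (see
#' [generate_null_model()]). `K` is capped at the graph size at run time.
#'
#' @param input Edge-list path, `ugraph`, or null-model recipe list.
#' @param K Truncation order of the spectral decomposition (default 2000).
#' @param k Number of diffusion communities (default 100).
#' @param t_embed Explicit embedding time, or `NULL` to use the floored
#'   relaxation time.
#' @param grid_points Size of the default logarithmic time grid.
#' @param scan Either `NULL` or a list `(residence, speed, edge_length)`;
#'   when present, community ranking is evaluated at
#'   `scan_steps(residence, speed, edge_length)` instead of `floor(tau)`.
#' @param m_extremes Number of extreme communities reported per feature.
#' @param coords_path Optional coordinates CSV companion of a path input.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param seed Integer seed driving community detection (and generation when
#'   `input` is a recipe without its own seed).
#' @param label Display name for the network.
#' @return Object of class `workflow_config`.
#' @export
workflow_config <- function(input, K = 2000L, k = 100L, t_embed = NULL,
                            grid_points = 12L, scan = NULL, m_extremes = 5L,
                            coords_path = NULL, out_dir = NULL, seed = 1L,
                            label = "network") {
  stopifnot(K >= 2L, k >= 1L, m_extremes >= 1L)
  structure(list(input = input, K = as.integer(K), k = as.integer(k),
                 t_embed = t_embed, grid_points = as.integer(grid_points),
                 scan = scan, m_extremes = as.integer(m_extremes),
                 coords_path = coords_path, out_dir = out_dir,
                 seed = as.integer(seed), label = label),
            class = "workflow_config")
}

resolve_input_graph <- function(cfg) {
  inp <- cfg$input
  if (inherits(inp, "ugraph")) return(inp)
  if (is.character(inp)) return(read_edge_list(inp, cfg$coords_path))
  if (is.list(inp)) {
    if (is.null(inp$seed)) inp$seed <- cfg$seed
    return(generate_null_model(inp))
  }
  stop("input must be an edge-list path, a ugraph, or a null-model recipe")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full diffusion-community workflow
#'
#' Executes, in order: input resolution, largest-component restriction,
#' transition matrix, truncated spectral decomposition, relaxation time,
#' community detection at the embedding time, per-community feature table on
#' a logarithmic time grid, heterogeneity statistics, and ranking of extreme
#' communities (lowest `p_in`, lowest `p_out`, lowest and highest Cheeger
#' index) at the feature time (`scan_steps(...)` when scan parameters are
#' configured, else `floor(tau)`).
#'
#' When `cfg$out_dir` is set, writes `partition.csv` (node_id,
#' community_id), `features.csv`, `summary.json` and `provenance.json`.
#' Outputs are deterministic: identical configs give byte-identical files.
#'
#' @param cfg A [workflow_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list (`workflow_result`): `graph`, `model`,
#'   `partition`, `features`, `heterogeneity`, `rankings`, `summary`.
#' @export
run_workflow <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "workflow_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  g0 <- with_stage("input", resolve_input_graph(cfg))
  g <- with_stage("largest_component", largest_component(g0))
  rf <- attr(g, "retained_fraction")
  say("largest component: %d of %d nodes retained (%.1f%%)",
      g$n_nodes, g0$n_nodes, 100 * rf)
  tm <- with_stage("transition_matrix", transition_matrix(g))
  K <- min(cfg$K, g$n_nodes)
  mod <- with_stage("spectral_decomposition", spectral_decomposition(tm, K))
  tau <- with_stage("relaxation_time", relaxation_time(mod))
  say("relaxation time tau = %.2f (|lambda_1| = %.6f)",
      tau, abs(mod$lambdas[2L]))
  t_embed <- if (is.null(cfg$t_embed)) floor(tau) else as.integer(cfg$t_embed)
  part <- with_stage("detect_communities",
                     detect_communities(mod, cfg$k, t = t_embed,
                                        seed = cfg$seed))
  grid <- with_stage("time_grid", time_grid(tau, cfg$grid_points))
  feats <- with_stage("feature_table", feature_table(g, mod, part, grid))
  het <- with_stage("heterogeneity", heterogeneity(mod, part, grid))
  hbar <- if (part$k >= 2L) mean_cheeger(g, part) else NA_real_
  t_rank <- if (!is.null(cfg$scan)) {
    do.call(scan_steps, cfg$scan)
  } else floor(tau)
  m_ext <- min(cfg$m_extremes, part$k)
  cp_rank <- community_probabilities(mod, part, t_rank)
  rankings <- list(
    t_rank = t_rank,
    lowest_pin = rank_communities(cp_rank$pin[, 1L], m_ext, "lowest",
                                  percent = TRUE),
    lowest_pout = rank_communities(cp_rank$pout[, 1L], m_ext, "lowest",
                                   percent = TRUE),
    lowest_cheeger = rank_communities(feats$cheeger, m_ext, "lowest",
                                      percent = TRUE),
    highest_cheeger = rank_communities(feats$cheeger, m_ext, "highest",
                                       percent = TRUE))
  sizes <- community_sizes(part)
  summary <- list(
    label = cfg$label, n_nodes = g$n_nodes, n_edges = nrow(g$edges),
    mean_degree = mean_degree(g), retained_fraction = rf,
    K = K, k = part$k, tau = tau, t_embed = t_embed, t_rank = t_rank,
    size_min = min(sizes), size_mean = mean(sizes), size_max = max(sizes),
    mean_cheeger = hbar,
    max_sd_pin = het$max_sd_pin, max_sd_pout = het$max_sd_pout,
    remote_communities = rankings$lowest_pin$community)
  res <- structure(list(graph = g, model = mod, partition = part,
                        features = feats, heterogeneity = het,
                        rankings = rankings, summary = summary, config = cfg),
                   class = "workflow_result")
  if (!is.null(cfg$out_dir)) write_workflow_outputs(res, cfg$out_dir)
  invisible(res)
}

write_workflow_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  part_df <- data.frame(node_id = seq_len(res$graph$n_nodes) - 1L,
                        community_id = res$partition$labels)
  utils::write.csv(part_df, file.path(out_dir, "partition.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(res$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- res$config
  prov <- list(
    config = cfg[setdiff(names(cfg), "input")],
    input = if (is.character(cfg$input)) cfg$input else
      if (inherits(cfg$input, "ugraph")) "in-memory graph" else cfg$input,
    seeds = list(workflow = cfg$seed, partition = res$partition$seed),
    versions = list(R = as.character(getRversion()),
                    diffcomm = as.character(utils::packageVersion("diffcomm"))))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.workflow_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "workflow_result '%s': N = %d, E = %d, mean degree %.3f\n",
    "  tau = %.2f, k = %d communities at t = %d\n",
    "  mean Cheeger = %.4f, max SD(p_in) = %.3g, max SD(p_out) = %.3g\n"),
    s$label, s$n_nodes, s$n_edges, s$mean_degree, s$tau, s$k, s$t_embed,
    s$mean_cheeger, s$max_sd_pin, s$max_sd_pout))
  invisible(x)
}

#' Compare several networks under the same workflow
#'
#' Runs [run_workflow()] on each configuration and tabulates the headline
#' statistics (one row per network). A failure in one network is reported in
#' its row (`status`/`error` columns) without stopping the others.
#'
#' @param cfgs List of [workflow_config()] objects.
#' @param quiet Suppress progress messages.
#' @return data.frame with columns `network`, `status`, `n_nodes`,
#'   `n_edges`, `mean_degree`, `tau`, `mean_cheeger`, `max_sd_pin`,
#'   `max_sd_pout`, `error`.
#' @export
compare_networks <- function(cfgs, quiet = TRUE) {
  stopifnot(length(cfgs) >= 2L)
  rows <- lapply(cfgs, function(cfg) {
    res <- tryCatch(run_workflow(cfg, quiet = quiet), error = identity)
    if (inherits(res, "error")) {
      data.frame(network = cfg$label, status = "error", n_nodes = NA_integer_,
                 n_edges = NA_integer_, mean_degree = NA_real_,
                 tau = NA_real_, mean_cheeger = NA_real_,
                 max_sd_pin = NA_real_, max_sd_pout = NA_real_,
                 error = conditionMessage(res))
    } else {
      s <- res$summary
      data.frame(network = s$label, status = "ok", n_nodes = s$n_nodes,
                 n_edges = s$n_edges, mean_degree = s$mean_degree,
                 tau = s$tau, mean_cheeger = s$mean_cheeger,
                 max_sd_pin = s$max_sd_pin, max_sd_pout = s$max_sd_pout,
                 error = NA_character_)
    }
  })
  do.call(rbind, rows)
}
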