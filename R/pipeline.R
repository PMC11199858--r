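# End-to-end pipeline: read / generate -> renormalise -> degree & decay
# stats -> map-equation modules (+ Louvain comparison) -> hub roles ->
# top-flow links -> hub tracing; every stage writes a plain CSV/JSON
# artifact so runs are independently inspectable, and a manifest records
# seeds, parameters, input checksums and versions for reproducibility.

#' Run the full mesoscale-connectome analysis
#'
#' @param input one of: a [connectome] (LNe or FLNe weights), a
#'   [synth_config] (a synthetic connectome is generated and censored to
#'   its measured set), or a path to a link-list file
#' @param records injection records (required to rescale an FLNe input)
#' @param out_dir output directory (created if absent)
#' @param tau teleportation probability for the random walk
#' @param n_trials restarts for the map-equation optimiser
#' @param seed master RNG seed, recorded in the manifest
#' @param boundaries role-cartography boundaries ([role_boundaries])
#' @param top_flow_fraction fraction of links kept in the high-traffic table
#' @param trace_top_hubs how many top hubs to seed the trace from
#' @param stages character vector of stages to run, any of `"stats"`,
#'   `"modules"`, `"roles"`, `"flow"`, `"trace"` (earlier stages a later one
#'   needs are run regardless)
#' @return invisibly, a list with all stage results and the manifest
#' @export
run_pipeline <- function(input, records = NULL, out_dir = "cortexflow_out",
                         tau = 0.15, n_trials = 100, seed = 1L,
                         boundaries = role_boundaries(),
                         top_flow_fraction = 0.15, trace_top_hubs = 8,
                         stages = c("stats", "modules", "roles", "flow",
                                    "trace")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, tau = tau, n_trials = n_trials,
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("cortexflow")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  # ---- input ----
  gt <- NULL
  if (inherits(input, "synth_config")) {
    sim <- generate_connectome(input)
    con <- censor(sim$connectome, sim$ground_truth$measured_set)
    gt <- sim$ground_truth
    manifest$input <- c(source = "synthetic", unlist(unclass(input)))
  } else if (inherits(input, "connectome")) {
    con <- input
    manifest$input <- list(source = "connectome object")
  } else if (is.character(input) && length(input) == 1) {
    manifest$input <- list(source = input,
                           md5 = unname(tools::md5sum(input)))
    con <- stage("read", read_link_list(input))
  } else stop("input must be a connectome, synth_config or file path")
  if (con$weight_kind == "FLNe") {
    if (is.null(records))
      stop("FLNe input needs injection records to recover LNe weights")
    con <- stage("renormalise", flne_to_lne(con, records))
  }
  if (is.null(con$D) && all(c("x", "y", "z") %in% names(con$nodes)))
    con <- compute_distances(con)
  write_adjacency(con, file.path(out_dir, "lne_adjacency.tsv"))
  results <- list(connectome = con, ground_truth = gt)

  # ---- stats ----
  if ("stats" %in% stages) {
    deg <- degree_table(con)
    utils::write.csv(deg, file.path(out_dir, "degree_table.csv"),
                     row.names = FALSE)
    fits <- list(
      k_out = as.list(compare_families(deg$k_out[deg$k_out > 0])[1, 1:2]),
      k_in = as.list(compare_families(deg$k_in[deg$k_in > 0])[1, 1:2]))
    if (!is.null(con$D)) {
      fits$decay_exponential <- unclass(weight_distance_fit(con, "exponential"))
      fits$decay_powerlaw <- unclass(weight_distance_fit(con, "powerlaw"))
    }
    jsonlite::write_json(fits, file.path(out_dir, "fit_summaries.json"),
                         auto_unbox = TRUE, digits = NA)
    results$degree <- deg; results$fits <- fits
  }

  # ---- modules ----
  need_modules <- any(c("modules", "roles", "flow", "trace") %in% stages)
  if (need_modules) {
    part <- stage("modules",
                  optimize_partition(con, tau = tau, n_trials = n_trials,
                                     seed = seed))
    part$Q <- modularity_q(con, part)
    louv <- louvain_partition(con, seed = seed)
    agree <- compare_partitions(part, louv)
    summ <- module_summary(part)
    utils::write.csv(data.frame(label = names(part$assignment),
                                module = unname(part$assignment),
                                node_flow = unname(part$flow$node_flow[names(part$assignment)])),
                     file.path(out_dir, "partition.csv"), row.names = FALSE)
    utils::write.csv(summ, file.path(out_dir, "module_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(codelength_bits = part$codelength,
                              n_modules = part$n_modules,
                              modularity_Q = part$Q,
                              orphans = part$orphans,
                              louvain_n_modules = louv$n_modules,
                              louvain_Q = louv$Q,
                              infomap_vs_louvain = agree),
                         file.path(out_dir, "modules.json"),
                         auto_unbox = TRUE, digits = NA)
    results$partition <- part; results$louvain <- louv
    results$agreement <- agree
  }

  # ---- roles ----
  if (any(c("roles", "trace") %in% stages)) {
    roles_in <- role_table(con, results$partition, "in",
                           boundaries = boundaries)
    roles_out <- role_table(con, results$partition, "out",
                            boundaries = boundaries)
    roles <- rbind(roles_in, roles_out)
    utils::write.csv(roles, file.path(out_dir, "roles.csv"),
                     row.names = FALSE)
    hc <- extract_hubs_and_connectors(roles_in, roles_out)
    jsonlite::write_json(lapply(hc, utils::head, 10),
                         file.path(out_dir, "hubs_connectors.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    results$roles_in <- roles_in; results$roles_out <- roles_out
    results$hubs <- hc
  }

  # ---- flow ranking ----
  if ("flow" %in% stages) {
    top <- top_flow_links(results$partition$flow,
                          fraction = top_flow_fraction)
    utils::write.csv(top, file.path(out_dir, "top_flow_links.csv"),
                     row.names = FALSE)
    results$top_links <- top
  }

  # ---- tracing around top hubs ----
  if ("trace" %in% stages && !is.null(con$D)) {
    hubs <- utils::head(results$hubs$hubs$label, trace_top_hubs)
    if (length(hubs)) {
      for (dir in c("out", "in")) {
        tr <- trace_links(con, trace_config(hubs, direction = dir))
        utils::write.csv(tr$events,
                         file.path(out_dir, sprintf("trace_%s.csv", dir)),
                         row.names = FALSE)
        results[[paste0("trace_", dir)]] <- tr
      }
      export_viz(con, results$partition, events = results$trace_out$events,
                 prefix = file.path(out_dir, "viz_hub_trace"))
    }
    results$trace_seeds <- hubs
  }

  manifest$stages <- stages
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
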