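# Time-evolving link tracing around seed areas.
#
# Signals are assumed to propagate at a constant conduction velocity
# (default 1 m/s = 1 mm/ms, typical of unmyelinated local circuits), so link
# length in mm maps directly to latency in ms; each synaptic relay adds a
# fixed delay (default 2 ms, equivalent to 2 mm of extra path). Tracing
# covers the first-neighbour shell of each seed and extends one synapse
# further to second neighbours, which is enough to expose the local cluster
# around a hub and its bridges outward.

#' Trace configuration
#'
#' @param seeds character vector of seed area labels
#' @param direction `"out"` follows links away from the seeds (rows of W);
#'   `"in"` follows links into the seeds, backwards
#' @param velocity_mm_per_ms conduction velocity (default 1: 1 m/s)
#' @param synaptic_delay_ms delay added per synaptic relay (default 2)
#' @param max_order synaptic order to trace to (default 2: first and second
#'   neighbours)
#' @param min_weight drop links weaker than this (default 1, the display
#'   cutoff below which labelled-neuron counts are of unclear meaning)
#' @param max_length_mm drop links longer than this (default 5 mm, the
#'   local-cluster display cutoff; raise it to follow longer pathways)
#' @return a `trace_config` list
#' @export
trace_config <- function(seeds, direction = c("out", "in"),
                         velocity_mm_per_ms = 1, synaptic_delay_ms = 2,
                         max_order = 2, min_weight = 1, max_length_mm = 5) {
  direction <- match.arg(direction)
  stopifnot(velocity_mm_per_ms > 0, max_order >= 1,
            min_weight >= 0, max_length_mm >= 0, synaptic_delay_ms >= 0)
  structure(list(seeds = as.character(seeds), direction = direction,
                 velocity = velocity_mm_per_ms,
                 synaptic_delay_ms = synaptic_delay_ms,
                 max_order = as.integer(max_order),
                 min_weight = min_weight, max_length_mm = max_length_mm),
            class = "trace_config")
}

#' Trace time-evolving link shells around seed areas
#'
#' Emits one event per activated link: order-1 events are qualifying links
#' touching a seed (arrival = length / velocity); order-2 events are
#' qualifying links of each first-neighbour endpoint (arrival = summed path
#' length / velocity + one synaptic delay). When several paths activate the
#' same link, only the earliest arrival is kept; likewise each node's first
#' arrival is recorded. Events are sorted by arrival time, ties by (order,
#' source, target).
#'
#' @param c a [connectome] with distances attached
#' @param cfg a [trace_config]
#' @return list with `events` (data.frame `arrival_ms, order, source,
#'   target, weight, length_mm`), `node_arrival` (named vector of first
#'   arrival per reached node, seeds at 0) and `n_filtered` (links touching
#'   the frontier that failed the weight/length cutoffs)
#' @export
trace_links <- function(c, cfg) {
  stopifnot(inherits(cfg, "trace_config"))
  if (is.null(c$D)) stop("no distance matrix; call compute_distances() first")
  unknown <- setdiff(cfg$seeds, c$nodes$label)
  if (length(unknown)) stop("unknown seed(s): ", paste(unknown, collapse = ", "))
  # for an in-trace, walk the transposed matrix; events are reported with
  # their original (source, target) orientation
  W <- if (cfg$direction == "out") c$W else t(c$W)
  D <- c$D
  n_filtered <- 0L
  events <- list()
  # keep-earliest update of a named numeric vector
  upd <- function(vec, name, val) {
    if (!(name %in% names(vec)) || val < vec[[name]]) vec[[name]] <- val
    vec
  }
  node_arrival <- stats::setNames(rep(0, length(cfg$seeds)), cfg$seeds)
  frontier <- node_arrival
  expanded <- character(0)
  for (ord in seq_len(cfg$max_order)) {
    next_frontier <- numeric(0)
    for (v in names(frontier)) {
      t0 <- frontier[[v]]
      for (u in names(which(W[v, ] > 0))) {
        w <- W[v, u]; len <- D[v, u]
        if (w < cfg$min_weight || len > cfg$max_length_mm) {
          n_filtered <- n_filtered + 1L
          next
        }
        arrival <- t0 + len / cfg$velocity +
          if (ord > 1) cfg$synaptic_delay_ms else 0
        key <- if (cfg$direction == "out") paste(v, u) else paste(u, v)
        if (is.null(events[[key]]) || arrival < events[[key]]$arrival_ms) {
          events[[key]] <- list(
            arrival_ms = arrival, order = ord,
            source = if (cfg$direction == "out") v else u,
            target = if (cfg$direction == "out") u else v,
            weight = w, length_mm = len)
        }
        node_arrival <- upd(node_arrival, u, arrival)
        if (ord < cfg$max_order &&
            !(u %in% c(names(frontier), expanded)))
          next_frontier <- upd(next_frontier, u, arrival)
      }
    }
    expanded <- c(expanded, names(frontier))
    frontier <- next_frontier
    if (!length(frontier)) break
  }
  df <- do.call(rbind, lapply(events, function(e)
    data.frame(e, stringsAsFactors = FALSE)))
  if (is.null(df)) {
    df <- data.frame(arrival_ms = numeric(0), order = integer(0),
                     source = character(0), target = character(0),
                     weight = numeric(0), length_mm = numeric(0))
  } else {
    df <- df[order(df$arrival_ms, df$order, df$source, df$target), ]
    rownames(df) <- NULL
  }
  list(events = df, node_arrival = node_arrival, n_filtered = n_filtered)
}

#' Nodes first reached within a latency radius
#'
#' The local cluster of the trace: every node whose first arrival is within
#' `radius_ms` of the seeds, seeds included (arrival 0).
#'
#' @param trace result of [trace_links]
#' @param radius_ms latency radius in ms
#' @return character vector of node labels, in order of arrival
#' @export
local_cluster <- function(trace, radius_ms) {
  arr <- sort(trace$node_arrival)
  names(arr)[arr <= radius_ms]
}

#' Export node and edge tables for external 3-D viewers
#'
#' Writes flat tables carrying everything a rendering tool needs: node
#' positions, module membership and colour key; edge weights, lengths and
#' either trace arrival times or link flow. Written as CSV and JSON.
#'
#' @param c a [connectome]
#' @param partition a `partition` (module colours follow module id)
#' @param events optional event table from [trace_links]; when absent, all
#'   links are exported
#' @param flow optional `flow_field`; adds a `link_flow` column
#' @param prefix output path prefix; writes `<prefix>_nodes.csv`,
#'   `<prefix>_edges.csv`, `<prefix>.json`
#' @return invisibly, the list of node and edge data.frames
#' @export
export_viz <- function(c, partition, events = NULL, flow = NULL,
                       prefix = "viz") {
  z <- stats::setNames(full_membership(c, partition), c$nodes$label)
  palette <- c("yellow", "lightgreen", "red", "salmon", "green",
               "brown", "lime", "darksalmon", "grey", "blue", "purple",
               "orange")
  nodes <- data.frame(label = c$nodes$label,
                      x = c$nodes$x %||% NA, y = c$nodes$y %||% NA,
                      z_mm = c$nodes$z %||% NA,
                      module = unname(z),
                      colour = palette[(unname(z) - 1) %% length(palette) + 1],
                      stringsAsFactors = FALSE)
  if (is.null(events)) {
    idx <- which(c$W > 0, arr.ind = TRUE)
    edges <- data.frame(source = rownames(c$W)[idx[, 1]],
                        target = colnames(c$W)[idx[, 2]],
                        weight = c$W[idx],
                        length_mm = if (is.null(c$D)) NA else c$D[idx],
                        stringsAsFactors = FALSE)
  } else {
    edges <- events[, c("source", "target", "weight", "length_mm",
                        "arrival_ms", "order")]
  }
  edges$module_source <- unname(z[edges$source])
  edges$module_target <- unname(z[edges$target])
  if (!is.null(flow))
    edges$link_flow <- flow$link_flow[cbind(edges$source, edges$target)]
  utils::write.csv(nodes, paste0(prefix, "_nodes.csv"), row.names = FALSE)
  utils::write.csv(edges, paste0(prefix, "_edges.csv"), row.names = FALSE)
  jsonlite::write_json(list(nodes = nodes, edges = edges),
                       paste0(prefix, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(list(nodes = nodes, edges = edges))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
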