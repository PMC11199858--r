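#!/usr/bin/env Rscript

# Stage 5: high-traffic links and time-evolving tracing around hubs.
#
# Ranks links by random-walk probability flow (top 15% = the cortical
# high-traffic backbone), then traces time-evolving link shells around the
# top hubs at 1 m/s conduction velocity with a 2 ms synaptic delay,
# keeping links of weight > 1 and length < 5 mm to expose local clusters.
# Node/edge tables for external 3-D viewers are exported as CSV/JSON.

suppressMessages(library(cortexflow))

con <- read_adjacency("results/lne_adjacency.tsv",
                      node_meta = "data/node_meta.tsv")
con <- compute_distances(con)
part_df <- read.csv("results/partition.csv")
membership <- setNames(part_df$module, part_df$label)

flow <- stationary_flow(con, tau = 0.15)
top <- top_flow_links(flow, fraction = 0.15)
write.csv(top, "results/top_flow_links.csv", row.names = FALSE)
message(sprintf("top 15%% of links by probability flow: %d links; strongest %s -> %s",
                nrow(top), top$source[1], top$target[1]))

hubs <- jsonlite::read_json("results/hubs_connectors.json",
                            simplifyVector = TRUE)$hubs
seeds <- head(hubs$label, 8)
if (length(seeds) == 0) {
  # fall back to the highest-flow areas when no node clears the hub band
  seeds <- names(sort(flow$node_flow, decreasing = TRUE))[1:8]
  message("no z > 2.5 hubs; seeding trace from the 8 highest-flow areas")
}

for (dir in c("out", "in")) {
  tr <- trace_links(con, trace_config(seeds, direction = dir))
  write.csv(tr$events, sprintf("results/trace_%s.csv", dir),
            row.names = FALSE)
  cl <- local_cluster(tr, radius_ms = 5)
  message(sprintf("%s-trace from %d seeds: %d events (%d weak/long links filtered); %d areas within 5 ms",
                  dir, length(seeds), nrow(tr$events), tr$n_filtered,
                  length(cl)))
}

tr_out <- trace_links(con, trace_config(seeds, direction = "out"))
export_viz(con, membership, events = tr_out$events, flow = flow,
           prefix = "results/viz_hub_trace")
export_viz(con, membership, flow = flow, prefix = "results/viz_full")
message("wrote results/top_flow_links.csv, trace_{out,in}.csv, viz_* tables")
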