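#!/usr/bin/env Rscript

# Stage 1: build the study connectome.
#
# Generates the marmoset-scale synthetic connectome (116 areas in a
# 25 x 15 x 10 mm volume, 8 spatially compact planted modules, exponential
# weight-distance decay with lambda = 4.57 mm, log-normal weight noise),
# censors in-links to the 55 simulated injection sites, and writes the
# link list, node metadata and matched injection records under data/.
#
# To analyse a real link list instead, drop it in data/ and start from
# stage 02 with input_link_list pointed at it.

suppressMessages(library(cortexflow))

seed <- 20260101L
dir.create("data", showWarnings = FALSE)

cfg <- synth_config(seed = seed)
sim <- generate_connectome(cfg)
con <- censor(sim$connectome, sim$ground_truth$measured_set)

message(sprintf("generated %d areas, %d links after censoring to %d injection sites",
                nrow(con$nodes), n_links(con), sum(con$nodes$measured)))
w <- con$W[con$W > 0]
message(sprintf("weights span %.1f decades (%.3g to %.3g)",
                log10(max(w) / min(w)), min(w), max(w)))

write_link_list(con, "data/connectome_lne.tsv")
write_node_meta(con, "data/node_meta.tsv")

# matched FLNe view + injection records, as a tracer resource would ship
f <- to_flne(con)
write_link_list(f$connectome, "data/connectome_flne.tsv")
write_injection_records(f$records, "data/injection_records.tsv")

# ground truth for later recovery checks
writeLines(jsonlite::toJSON(sim$ground_truth, auto_unbox = TRUE, digits = NA),
           "data/ground_truth.json")
message("wrote data/connectome_{lne,flne}.tsv, node_meta.tsv, injection_records.tsv, ground_truth.json")
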