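#!/usr/bin/env Rscript

# Stage 4: hub and connector classification.
#
# Computes weighted participation coefficients and within-module z-scores
# for in- and out-links separately, classifies every area into the R1-R7
# role cartography (hubs require z > 2.5; the 2 < z <= 2.5 band is flagged
# marginal), and extracts ranked hub / connector lists.

suppressMessages(library(cortexflow))

con <- read_adjacency("results/lne_adjacency.tsv",
                      node_meta = "data/node_meta.tsv")
part <- read.csv("results/partition.csv")
membership <- setNames(part$module, part$label)

roles_in <- role_table(con, membership, "in")
roles_out <- role_table(con, membership, "out")
write.csv(rbind(roles_in, roles_out), "results/roles.csv", row.names = FALSE)

hc <- extract_hubs_and_connectors(roles_in, roles_out)
message(sprintf("%d hubs (z > 2.5), %d marginal hubs (2 < z <= 2.5), %d R3/R4 connectors",
                nrow(hc$hubs), nrow(hc$marginal_hubs), nrow(hc$connectors)))
if (nrow(hc$hubs)) {
  message("top hubs: ", paste(sprintf("%s (%s %s, z=%.1f)", head(hc$hubs$label, 8),
                                      head(hc$hubs$role, 8),
                                      head(hc$hubs$direction, 8),
                                      head(hc$hubs$z, 8)), collapse = "; "))
}
if (nrow(hc$connectors)) {
  message("top connectors: ",
          paste(head(hc$connectors$label, 9), collapse = ", "))
}
jsonlite::write_json(lapply(hc, head, 15), "results/hubs_connectors.json",
                     dataframe = "rows", auto_unbox = TRUE, digits = NA)
message("wrote results/roles.csv, hubs_connectors.json")
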