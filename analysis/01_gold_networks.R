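#!/usr/bin/env Rscript
# Build the gold-standard networks for the study.
#
# Two suites are produced: a 13-network benchmark suite whose
# (nodes, edges) profiles match the published summaries of networks
# learned from small real-world categorical datasets, and the 6-network
# recovery suite (5-10 variables, sharpened CPTs) used for the
# structure-recovery experiments.  Networks are written as JSON plus
# plain-text edge lists, with a YAML manifest of seeds and shapes.

suppressPackageStartupMessages(library(bnrecover))

seed <- 1
out_dir <- "results/gold"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

manifest <- list(seed = seed, networks = list())

write_suite <- function(suite, tag) {
  for (name in names(suite)) {
    bn <- suite[[name]]
    write_network_json(bn, file.path(out_dir, paste0(name, ".json")))
    write_edge_list(bn$graph, file.path(out_dir, paste0(name, ".edges")))
    manifest$networks[[name]] <<- list(
      suite = tag, nodes = length(bn$graph$nodes),
      edges = n_edges(bn$graph),
      avg_in_degree = round(n_edges(bn$graph) / length(bn$graph$nodes),
                            2))
  }
}

bench <- benchmark_suite(seed = seed)
write_suite(bench, "benchmark")
recov <- recovery_suite(seed)
write_suite(recov, "recovery")

yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

shapes <- t(vapply(c(bench, recov), function(bn)
  c(nodes = length(bn$graph$nodes), edges = n_edges(bn$graph)),
  integer(2)))
cat("wrote", nrow(shapes), "gold networks to", out_dir, "\n")
print(shapes)
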