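#!/usr/bin/env Rscript

# Step 3: build the two-layer interaction network for the high-tier
# genes.
#
# Core layer: the categorized high-tier genes, one edge per hub element
# (FMRP, MTOR, VITD) their membership mask touches, clustered by mask.
# Secondary layer: residual high-tier genes attached through cross-list
# interactions with combined score > 0.7, edges labelled by their
# strongest qualifying evidence channel, genes placed by the clusters
# they touch. Exports SIF, GraphML and Cytoscape attribute tables under
# results/network/.

suppressPackageStartupMessages(library(mtornet))

fix <- file.path("results", "fixtures")
asg_path <- file.path("results", "assignment_high_tier.tsv")
stopifnot(file.exists(asg_path))  # run steps 01 and 02 first

asg <- readr::read_tsv(asg_path, show_col_types = FALSE,
                       col_types = readr::cols(key = "c", tier = "c"))
asg <- tibble::as_tibble(asg)
class(asg) <- c("category_assignment", class(asg))

categorized <- asg[asg$mask > 0, ]
class(categorized) <- c("category_assignment",
                        setdiff(class(categorized),
                                "category_assignment"))
residual <- gene_set(asg$key[asg$mask == 0], "residual",
                     symbols = asg$symbol[asg$mask == 0])

core <- build_core_layer(categorized)
cat(sprintf("core layer: %d genes, %d gene-hub edges\n",
            sum(core$nodes$type == "gene"), nrow(core$edges)))

interactions <- read_interactions(file.path(fix, "interactions.tsv"))
model <- build_full_network(core, residual, interactions, cutoff = 0.7)
print(model)
rep <- model$report
cat(sprintf("connected: %d out of %d (%d%%)\n", rep$total_connected,
            rep$n_primary + rep$n_residual, rep$percent_connected))
cat("edge types:\n")
for (nm in names(rep$edge_type_counts)) {
  cat(sprintf("  %-25s %4d\n", nm, rep$edge_type_counts[[nm]]))
}

out <- file.path("results", "network")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
write_sif(model, file.path(out, "network.sif"))
write_graphml(model, file.path(out, "network.graphml"))
write_attribute_tables(model, file.path(out, "nodes.tsv"),
                       file.path(out, "edges.tsv"))
write_gene_list(model$unconnected, file.path(out, "unconnected.txt"))
jsonlite::write_json(rep, file.path(out, "report.json"),
                     auto_unbox = TRUE, pretty = TRUE)
cat("network files written to", out, "\n")
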