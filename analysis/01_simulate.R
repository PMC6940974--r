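#!/usr/bin/env Rscript

# Step 1: generate the synthetic study inputs.
#
# Emits, under results/fixtures/: a KEGG-style synonym table, a scored
# candidate table (SFARI dialect), the four category gene lists, and a
# STRING-style interaction table for the high-tier network stage. The
# candidate/category structure follows the reference study conditions
# (1053 candidates; 606 categorized / 447 outside; per-category totals
# 258/42/314/223; PTEN, APC and DOCK1 planted in the quadruple region;
# 281 high-tier genes of which 179 categorized) — see
# ?reference_venn_spec.

suppressPackageStartupMessages(library(mtornet))

seed <- 20190115
out <- file.path("results", "fixtures")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

universe <- generate_gene_universe(1500, seed = seed,
                                   include_symbols = c("PTEN", "APC",
                                                       "DOCK1"))
gen <- generate_categories(
  reference_venn_spec(), universe, seed = seed,
  planted = list("1111" = c("PTEN", "APC", "DOCK1")),
  high_tier_by_region = reference_high_tier_plan(),
  planted_high = "PTEN")

write_synonym_table(universe$table, file.path(out, "synonyms.txt"))
write_candidate_table(gen$candidates, file.path(out, "candidates.csv"))
for (nm in names(gen$categories)) {
  write_gene_list(gen$categories[[nm]]$members$symbol,
                  file.path(out, paste0(nm, ".txt")))
}

# interactions between the categorized and residual high-tier genes
high <- filter_tier(gen$candidates, c("1", "2", "3"))
asg <- assign_categories(high, gen$categories)
primary <- gene_set(asg$key[asg$mask > 0], "categorized")
residual <- gene_set(asg$key[asg$mask == 0], "residual")
gi <- generate_interactions(
  interaction_spec(n_cross = 400, n_within_primary = 40,
                   n_within_secondary = 40, n_weakest = 10),
  primary, residual, seed = seed)
write_interaction_table(gi$interactions,
                        file.path(out, "interactions.tsv"))

cat(sprintf("universe: %d genes; candidates: %d; interactions: %d\n",
            length(universe$symbols), nrow(gen$candidates),
            nrow(gi$interactions)))
cat("fixtures written to", out, "\n")
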