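#!/usr/bin/env Rscript

# Step 2: normalize symbols and assign the four functional categories.
#
# Reads the fixtures from step 1 through the package's file readers,
# resolves symbols against the synonym table, assigns each candidate a
# 4-bit membership mask, and writes the full and high-tier Venn region
# tables plus summary counts under results/.

suppressPackageStartupMessages(library(mtornet))

fix <- file.path("results", "fixtures")
stopifnot(dir.exists(fix))  # run analysis/01_simulate.R first

syn <- load_synonym_table(file.path(fix, "synonyms.txt"))
candidates <- read_candidate_table(file.path(fix, "candidates.csv"),
                                   table = syn)
categories <- lapply(c("FMRP_TARGET", "MTOR_NETWORK", "MTOR_MODULATED",
                       "VITD_SENSITIVE"), function(nm) {
  merge_gene_sets(list(read_gene_list(file.path(fix, paste0(nm, ".txt")))),
                  name = nm, table = syn)
})
names(categories) <- c("FMRP_TARGET", "MTOR_NETWORK", "MTOR_MODULATED",
                       "VITD_SENSITIVE")

assignment <- assign_categories(candidates, categories)
print(summarize_assignment(assignment))
vp <- venn_partition(assignment)
cat("genes in all four categories:",
    paste(vp$region_members[["1111"]], collapse = ", "), "\n")

high <- filter_tier(candidates, c("1", "2", "3"))
assignment_high <- assign_categories(high, categories)
print(summarize_assignment(assignment_high))
vp_high <- venn_partition(assignment_high)
cat("high-tier genes in all four categories:",
    paste(vp_high$region_members[["1111"]], collapse = ", "), "\n")

readr::write_tsv(tibble::as_tibble(assignment),
                 file.path("results", "assignment_full.tsv"))
readr::write_tsv(tibble::as_tibble(assignment_high),
                 file.path("results", "assignment_high_tier.tsv"))
write_venn_table(vp, file.path("results", "venn_full.tsv"))
write_venn_table(vp_high, file.path("results", "venn_high_tier.tsv"))
cat("tables written to results/\n")
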