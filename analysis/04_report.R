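#!/usr/bin/env Rscript

# Step 4: one-shot pipeline run and summary rendering.
#
# Re-runs normalize -> categorize -> Venn -> network as a single
# configured pipeline over the step-1 fixtures (checking that the
# chained steps 02-03 and the one-shot run agree is part of the test
# suite), and renders the generalized summary table in all three
# styles under results/report/.

suppressPackageStartupMessages(library(mtornet))

fix <- file.path("results", "fixtures")
stopifnot(dir.exists(fix))  # run analysis/01_simulate.R first

cats <- c("FMRP_TARGET", "MTOR_NETWORK", "MTOR_MODULATED",
          "VITD_SENSITIVE")
cfg <- pipeline_config(
  candidates = file.path(fix, "candidates.csv"),
  synonyms = file.path(fix, "synonyms.txt"),
  categories = stats::setNames(
    as.list(file.path(fix, paste0(cats, ".txt"))), cats),
  interactions = file.path(fix, "interactions.tsv"),
  tiers = c("1", "2", "3"), cutoff = 0.7,
  out_dir = file.path("results", "pipeline_run"))

summary <- run_pipeline(cfg)

out <- file.path("results", "report")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
writeLines(render_summary(summary, "text"),
           file.path(out, "summary.txt"))
writeLines(render_summary(summary, "tsv"), file.path(out, "summary.tsv"))
writeLines(render_summary(summary, "json"),
           file.path(out, "summary.json"))
cat(render_summary(summary, "text"))
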