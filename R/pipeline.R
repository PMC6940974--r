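# End-to-end orchestration: normalize -> categorize -> Venn -> network,
# with a declarative config, per-stage logging, checksummed provenance
# and a self-consistency check on the written artifacts.

#' Build a pipeline configuration
#'
#' A single declarative object capturing every knob of a run so results
#' are reproducible; a YAML copy is written into the run's output
#' directory.
#'
#' @param candidates Path to the scored candidate table (CSV/TSV,
#'   SFARI-style `gene-symbol`/`gene-score`).
#' @param synonyms Path to the KEGG-style synonym flat file.
#' @param categories Named list over `CATEGORY_NAMES`; each element a
#'   character vector of gene-list file paths merged into that category.
#' @param interactions Optional path to a STRING-style detailed
#'   interaction export; when `NULL`, the network stage is skipped.
#' @param tiers Tier subset treated as high-confidence (default
#'   `c("1","2","3")`).
#' @param cutoff,cutoff_inclusive Combined-score cutoff and boundary
#'   behavior; see [filter_cross_list()].
#' @param ambiguity_policy `"first"` or `"drop"`; see
#'   [normalize_symbols()].
#' @param seed Optional integer seed recorded for provenance.
#' @param out_dir Output directory (created if needed).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(candidates, synonyms, categories,
                            interactions = NULL,
                            tiers = HIGH_TIERS, cutoff = 0.7,
                            cutoff_inclusive = FALSE,
                            ambiguity_policy = "first", seed = NULL,
                            out_dir = tempfile("mtornet_run_")) {
  stopifnot(is.list(categories), setequal(names(categories),
                                          CATEGORY_NAMES))
  cfg <- list(candidates = candidates, synonyms = synonyms,
              categories = lapply(categories[CATEGORY_NAMES],
                                  as.character),
              interactions = interactions, tiers = as.character(tiers),
              cutoff = cutoff, cutoff_inclusive = cutoff_inclusive,
              ambiguity_policy = ambiguity_policy, seed = seed,
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `path` invisibly, or the config.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full pipeline
#'
#' Stages: load the synonym table; normalize the candidate table and the
#' category source lists; assign categories and compute Venn partitions
#' for the whole list and the high-tier subset; if an interaction table
#' is configured, build the two-layer network on the high-tier view;
#' write all artifacts plus a run summary. Any stage failure aborts with
#' the stage name and cause, and no partial outputs are left in
#' `out_dir` (artifacts are staged in a scratch directory and moved on
#' success). Reruns with an identical config give identical summaries
#' apart from the timestamp.
#'
#' @param config A [pipeline_config()].
#' @return A `run_summary` (list of counts plus provenance), invisibly
#'   written to `out_dir/summary.json` along with the artifact tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  staging <- tempfile("mtornet_staging_")
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) abort_stage(stage, e))
  }

  syn <- run_stage("normalize", {
    load_synonym_table(config$synonyms)
  })

  norm <- run_stage("normalize", {
    candidates <- read_candidate_table(config$candidates, table = syn,
                                       policy = config$ambiguity_policy)
    stage_log("normalize", "candidates: %d rows", nrow(candidates))
    candidates
  })

  category_sets <- run_stage("categorize", {
    sets <- lapply(CATEGORY_NAMES, function(nm) {
      paths <- config$categories[[nm]]
      if (length(paths) == 0 || !all(file.exists(paths))) {
        stop("category '", nm, "' source file(s) missing: ",
             paste(paths[!file.exists(paths)], collapse = ", "),
             call. = FALSE)
      }
      sources <- lapply(paths, read_gene_list)
      names(sources) <- basename(paths)
      merged <- merge_gene_sets(sources, name = nm, table = syn,
                                policy = config$ambiguity_policy)
      stage_log("categorize", "category %s: %d members from %d source(s)",
                nm, length(merged), length(paths))
      merged
    })
    names(sets) <- CATEGORY_NAMES
    sets
  })

  full <- run_stage("categorize", {
    assignment <- assign_categories(norm, category_sets)
    stage_log("categorize", "assigned %d candidates; %d categorized",
              nrow(assignment), sum(assignment$mask > 0))
    assignment
  })
  high <- run_stage("categorize", {
    keep <- full$tier %in% config$tiers
    h <- full[keep, , drop = FALSE]
    class(h) <- c("category_assignment",
                  setdiff(class(h), "category_assignment"))
    stage_log("categorize", "high-tier subset {%s}: %d candidates",
              paste(config$tiers, collapse = ","), nrow(h))
    h
  })

  venn_full <- run_stage("venn", venn_partition(full))
  venn_high <- run_stage("venn", {
    if (nrow(high) > 0) venn_partition(high) else NULL
  })
  summary_full <- summarize_assignment(full)
  summary_high <- if (nrow(high) > 0) summarize_assignment(high) else NULL

  network_report <- NULL
  model <- NULL
  if (!is.null(config$interactions)) {
    model <- run_stage("network", {
      categorized <- high[high$mask > 0, , drop = FALSE]
      class(categorized) <- c("category_assignment",
                              setdiff(class(categorized),
                                      "category_assignment"))
      residual <- gene_set(high$key[high$mask == 0], "residual",
                           symbols = high$symbol[high$mask == 0])
      core <- build_core_layer(categorized)
      interactions <- read_interactions(config$interactions)
      m <- build_full_network(core, residual, interactions,
                              cutoff = config$cutoff,
                              inclusive = config$cutoff_inclusive)
      stage_log("network",
                "core: %d genes, %d edges; secondary: %d genes, %d edges; %d unconnected",
                m$report$n_primary, m$report$n_core_edges,
                m$report$n_connected_secondary,
                m$report$n_secondary_edges, m$report$n_unconnected)
      m
    })
    network_report <- model$report
  }

  # artifacts -----------------------------------------------------------
  run_stage("write", {
    report <- normalize_symbols(norm$symbol, syn,
                                policy = config$ambiguity_policy)
    write_normalization_report(report,
                               file.path(staging,
                                         "normalization_report.json"))
    readr::write_tsv(tibble::as_tibble(full)[
      , c("key", "symbol", "tier", "syndromic", "mask")],
      file.path(staging, "assignment.tsv"), progress = FALSE)
    write_venn_table(venn_full, file.path(staging, "venn_full.tsv"))
    if (!is.null(venn_high)) {
      write_venn_table(venn_high, file.path(staging, "venn_tier.tsv"))
    }
    if (!is.null(model)) {
      write_sif(model, file.path(staging, "network.sif"))
      write_graphml(model, file.path(staging, "network.graphml"))
      write_attribute_tables(model,
                             file.path(staging, "network_nodes.tsv"),
                             file.path(staging, "network_edges.tsv"))
    }
  })

  inputs <- c(candidates = config$candidates, synonyms = config$synonyms,
              stats::setNames(unlist(config$categories),
                              paste0("category_",
                                     rep(names(config$categories),
                                         lengths(config$categories)))),
              if (!is.null(config$interactions))
                c(interactions = config$interactions))
  checksums <- as.list(tools::md5sum(inputs))

  cfg_tmp <- file.path(staging, "config.yaml")
  write_pipeline_config(config, cfg_tmp)
  config_hash <- unname(tools::md5sum(cfg_tmp))

  summary <- structure(list(
    counts = list(
      n_candidates = summary_full$n_candidates,
      per_category = as.list(summary_full$per_category),
      n_categorized = summary_full$n_categorized,
      n_uncategorized = summary_full$n_uncategorized,
      pct_categorized = summary_full$pct_categorized,
      tier_subset = list(
        tiers = config$tiers,
        n_candidates = if (is.null(summary_high)) 0L
                       else summary_high$n_candidates,
        n_categorized = if (is.null(summary_high)) 0L
                        else summary_high$n_categorized,
        n_uncategorized = if (is.null(summary_high)) 0L
                          else summary_high$n_uncategorized,
        pct_categorized = if (is.null(summary_high)) 0L
                          else summary_high$pct_categorized),
      venn_full = as.list(venn_full$region_counts),
      venn_tier = if (is.null(venn_high)) NULL
                  else as.list(venn_high$region_counts),
      network = network_report),
    provenance = list(input_checksums = checksums,
                      config_hash = config_hash,
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "run_summary")

  run_stage("write", {
    validate_run_summary(summary, staging)
    out <- list(counts = summary$counts, provenance = summary$provenance)
    jsonlite::write_json(out, file.path(staging, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(staging, full.names = TRUE)) {
    file.copy(f, file.path(config$out_dir, basename(f)), overwrite = TRUE)
  }
  stage_log("done", "artifacts written to %s", config$out_dir)
  invisible(summary)
}

# Every count in the summary must be recomputable from the emitted
# tables; checked before the artifacts leave the staging directory.
validate_run_summary <- function(summary, dir) {
  asg <- readr::read_tsv(file.path(dir, "assignment.tsv"),
                         show_col_types = FALSE, progress = FALSE)
  stopifnot(nrow(asg) == summary$counts$n_candidates,
            sum(asg$mask > 0) == summary$counts$n_categorized)
  venn <- readr::read_tsv(file.path(dir, "venn_full.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  stopifnot(sum(venn$count) == summary$counts$n_candidates,
            identical(as.integer(venn$count),
                      as.integer(unlist(summary$counts$venn_full))))
  if (!is.null(summary$counts$network)) {
    edges <- readr::read_tsv(file.path(dir, "network_edges.tsv"),
                             show_col_types = FALSE, progress = FALSE)
    stopifnot(sum(edges$layer == "secondary") ==
                summary$counts$network$n_secondary_edges)
  }
  invisible(TRUE)
}

#' Render a run summary
#'
#' Produces the run's generalized table in one of three styles: `text`
#' (human-readable, including lines such as
#' `"categorized: 606 out of 1053 (58%)"`), `tsv`, or `json`. All three
#' carry identical numbers.
#'
#' @param summary A `run_summary` from [run_pipeline()].
#' @param style One of `"text"`, `"tsv"`, `"json"`.
#' @return A character scalar (the rendered document).
#' @export
render_summary <- function(summary, style = c("text", "tsv", "json")) {
  style <- match.arg(style)
  stopifnot(inherits(summary, "run_summary"))
  cts <- summary$counts
  rows <- tibble::tibble(
    quantity = c(paste0("total_", names(cts$per_category)),
                 "n_candidates", "n_categorized", "n_uncategorized",
                 "pct_categorized",
                 "tier_n_candidates", "tier_n_categorized",
                 "tier_n_uncategorized", "tier_pct_categorized"),
    value = c(unlist(cts$per_category, use.names = FALSE),
              cts$n_candidates, cts$n_categorized, cts$n_uncategorized,
              cts$pct_categorized,
              cts$tier_subset$n_candidates,
              cts$tier_subset$n_categorized,
              cts$tier_subset$n_uncategorized,
              cts$tier_subset$pct_categorized))
  if (!is.null(cts$network)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      quantity = c("network_total_connected", "network_total_candidates",
                   "network_pct_connected"),
      value = c(cts$network$total_connected,
                cts$network$n_primary + cts$network$n_residual,
                cts$network$percent_connected)))
  }
  if (style == "json") {
    return(as.character(jsonlite::toJSON(
      stats::setNames(as.list(rows$value), rows$quantity),
      auto_unbox = TRUE, pretty = TRUE)))
  }
  if (style == "tsv") {
    return(paste0("quantity\tvalue\n",
                  paste(rows$quantity, rows$value, sep = "\t",
                        collapse = "\n"), "\n"))
  }
  lines <- c(
    "Category assignment",
    sprintf("  %-15s %5d", names(cts$per_category),
            unlist(cts$per_category)),
    sprintf("  categorized: %d out of %d (%d%%)", cts$n_categorized,
            cts$n_candidates, cts$pct_categorized),
    sprintf("  uncategorized: %d", cts$n_uncategorized),
    sprintf("High-confidence tiers {%s}",
            paste(cts$tier_subset$tiers, collapse = ",")),
    sprintf("  categorized: %d out of %d (%d%%)",
            cts$tier_subset$n_categorized, cts$tier_subset$n_candidates,
            cts$tier_subset$pct_categorized),
    sprintf("  uncategorized: %d", cts$tier_subset$n_uncategorized))
  if (!is.null(cts$network)) {
    lines <- c(lines, "Network",
               sprintf("  connected: %d out of %d (%d%%)",
                       cts$network$total_connected,
                       cts$network$n_primary + cts$network$n_residual,
                       cts$network$percent_connected))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
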