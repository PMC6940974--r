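# Category assignment and 4-way Venn partitioning of a scored candidate
# gene table.
#
# The four categories are fixed in CATEGORY_NAMES order (FMRP targets,
# mTOR signaling-network members, mTOR-modulated transcripts,
# vitamin-D-sensitive genes); membership of a candidate is encoded as a
# 4-bit mask whose bit values 1/2/4/8 follow that order.

#' Construct a scored candidate gene table
#'
#' @param key Character gene keys (ids or surrogates).
#' @param symbol Display symbols, parallel to `key`.
#' @param tier Confidence tier per gene, drawn from
#'   `c("1".."7", "S")`. Dual scores like `"2S"` should be split into
#'   `tier = "2"` and `syndromic = TRUE` before construction (the reader
#'   [read_candidate_table()] does this).
#' @param syndromic Logical syndromic flag, orthogonal to the tier.
#' @return A tibble of class `scored_gene_table` with one row per unique
#'   key.
#' @export
scored_gene_table <- function(key, symbol, tier,
                              syndromic = rep(FALSE, length(key))) {
  key <- as.character(key)
  tier <- as.character(tier)
  bad <- setdiff(unique(tier), TIER_VOCABULARY)
  if (length(bad) > 0) {
    stop("tier values outside the vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(key)) {
    stop("duplicate gene keys in candidate table", call. = FALSE)
  }
  out <- tibble::tibble(key = key, symbol = as.character(symbol),
                        tier = tier, syndromic = as.logical(syndromic))
  class(out) <- c("scored_gene_table", class(out))
  out
}

#' Read a scored candidate table (SFARI export dialect)
#'
#' Expects a CSV/TSV with a gene-symbol column and a gene-score column
#' (column names matched case-insensitively against
#' `gene-symbol`/`gene_symbol`/`symbol` and
#' `gene-score`/`gene_score`/`score`). Scores such as `"2S"` are split
#' into tier `"2"` plus a syndromic flag; a bare `"S"` stays tier `"S"`.
#'
#' @param path Path to the table.
#' @param table Optional [synonym_table()]; when given, symbols are
#'   normalized to gene-id keys (unmapped symbols keep surrogate keys).
#' @param policy Ambiguity policy for normalization.
#' @return A [scored_gene_table()].
#' @export
read_candidate_table <- function(path, table = NULL, policy = "first") {
  first <- readr::read_lines(path, n_max = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  nm <- tolower(gsub("[-_. ]", "", names(df)))
  sym_col <- which(nm %in% c("genesymbol", "symbol", "gene"))[1]
  score_col <- which(nm %in% c("genescore", "score", "tier"))[1]
  if (is.na(sym_col) || is.na(score_col)) {
    stop("candidate table needs gene-symbol and gene-score columns; got: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  symbols <- trimws(as.character(df[[sym_col]]))
  score <- toupper(trimws(as.character(df[[score_col]])))
  syndromic <- grepl("S", score, fixed = TRUE)
  tier <- sub("S", "", score, fixed = TRUE)
  tier[!nzchar(tier)] <- "S"

  keys <- toupper(symbols)
  if (!is.null(table)) {
    report <- normalize_symbols(symbols, table, policy = policy)
    map <- c(report$resolved,
             stats::setNames(surrogate_key(report$unmapped),
                             report$unmapped))
    if (report$policy == "drop" && length(report$ambiguous) > 0) {
      amb <- names(report$ambiguous)
      map <- c(map, stats::setNames(surrogate_key(amb), amb))
    }
    keys <- unname(map[match(toupper(symbols), toupper(names(map)))])
  } else {
    keys <- surrogate_key(symbols)
  }
  keep <- !duplicated(keys)
  scored_gene_table(keys[keep], symbols[keep], tier[keep], syndromic[keep])
}

#' Restrict a candidate table to a tier subset
#'
#' @param candidates A [scored_gene_table()].
#' @param tiers Character subset of the tier vocabulary, e.g.
#'   `c("1","2","3")` for the high-confidence tiers.
#' @return A [scored_gene_table()] with original tier labels preserved;
#'   warns if the result is empty.
#' @export
filter_tier <- function(candidates, tiers) {
  stopifnot(inherits(candidates, "scored_gene_table"))
  tiers <- as.character(tiers)
  bad <- setdiff(tiers, TIER_VOCABULARY)
  if (length(bad) > 0) {
    stop("unknown tiers: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- candidates[candidates$tier %in% tiers, ]
  if (nrow(out) == 0) {
    warning("tier filter produced an empty candidate table", call. = FALSE)
  }
  class(out) <- c("scored_gene_table", setdiff(class(out),
                                               "scored_gene_table"))
  out
}

#' Assign candidate genes to the four functional categories
#'
#' Sets membership bit b of each candidate's mask iff its key belongs to
#' category b. The result is deterministic and independent of input
#' order. Surrogate keys inside the *category* sets (entries whose
#' symbols failed normalization, e.g. loci rather than genes) are by
#' default excluded from the membership tests, since candidates are
#' genes; their count is reported via a message.
#'
#' @param candidates A [scored_gene_table()].
#' @param categories A list of exactly 4 [gene_set()]s, in
#'   `CATEGORY_NAMES` order or named by `CATEGORY_NAMES`.
#' @param include_surrogates Logical; if `TRUE`, surrogate keys in the
#'   category sets participate in matching (exact uppercase-symbol
#'   comparison).
#' @return A tibble of class `category_assignment` with columns `key`,
#'   `symbol`, `tier`, `syndromic`, `mask`.
#' @export
assign_categories <- function(candidates, categories,
                              include_surrogates = FALSE) {
  stopifnot(inherits(candidates, "scored_gene_table"))
  if (!is.list(categories) || length(categories) != 4) {
    stop("exactly 4 category gene sets are required", call. = FALSE)
  }
  if (!is.null(names(categories)) && all(nzchar(names(categories)))) {
    if (!setequal(names(categories), CATEGORY_NAMES)) {
      stop("category names must be ", paste(CATEGORY_NAMES, collapse = ", "),
           call. = FALSE)
    }
    categories <- categories[CATEGORY_NAMES]
  }
  stopifnot(all(vapply(categories, inherits, logical(1), "gene_set")))

  mask <- integer(nrow(candidates))
  n_excluded <- 0L
  for (b in seq_len(4)) {
    keys <- categories[[b]]$members$key
    if (!include_surrogates) {
      drop <- is_surrogate_key(keys)
      n_excluded <- n_excluded + sum(drop)
      keys <- keys[!drop]
    }
    mask <- mask + ifelse(candidates$key %in% keys, bitwShiftL(1L, b - 1L),
                          0L)
  }
  if (n_excluded > 0) {
    message(sprintf(
      "assign_categories: %d unresolvable category entries (surrogate keys) excluded from matching",
      n_excluded))
  }
  out <- tibble::tibble(key = candidates$key, symbol = candidates$symbol,
                        tier = candidates$tier,
                        syndromic = candidates$syndromic,
                        mask = as.integer(mask))
  class(out) <- c("category_assignment", class(out))
  out
}

#' Full 16-region Venn partition of a category assignment
#'
#' Enumerates all 2^4 membership combinations over the four categories,
#' including the outside region (mask 0, candidates in no category).
#' Region members are sorted by symbol for reproducibility.
#'
#' @param assignment A `category_assignment` (nonempty).
#' @return An object of class `venn_partition`: list with
#'   `region_counts` (named integer vector over the 16 bitstring masks,
#'   `"0000"` .. `"1111"` in FMRP/mTOR-network/mTOR-modulated/vitamin-D
#'   bit order) and `region_members` (same keys, sorted symbol vectors).
#' @export
venn_partition <- function(assignment) {
  stopifnot(inherits(assignment, "category_assignment"))
  if (nrow(assignment) == 0) {
    stop("venn_partition() requires a nonempty assignment", call. = FALSE)
  }
  masks <- 0:15
  bits <- mask_bits(masks)
  region_members <- lapply(masks, function(m) {
    sort(assignment$symbol[assignment$mask == m])
  })
  names(region_members) <- bits
  region_counts <- stats::setNames(lengths(region_members), bits)
  structure(list(region_counts = region_counts,
                 region_members = region_members,
                 n = nrow(assignment)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("<venn_partition> %d genes over 16 regions\n", x$n))
  pop <- x$region_counts[x$region_counts > 0]
  for (b in names(pop)) {
    cat(sprintf("  %s %-55s %5d\n", b, mask_label(bits_to_mask(b)), pop[[b]]))
  }
  invisible(x)
}

#' Summary table of a category assignment
#'
#' Reports per-category totals, the categorized/uncategorized split and
#' the categorized percentage under half-up integer rounding.
#'
#' @param assignment A `category_assignment`.
#' @return An object of class `category_summary`: list with
#'   `per_category` (named integer vector over `CATEGORY_NAMES`),
#'   `n_candidates`, `n_categorized`, `n_uncategorized`,
#'   `pct_categorized`.
#' @export
summarize_assignment <- function(assignment) {
  stopifnot(inherits(assignment, "category_assignment"))
  per_category <- vapply(seq_len(4), function(b) {
    sum(bitwAnd(assignment$mask, bitwShiftL(1L, b - 1L)) > 0L)
  }, integer(1))
  names(per_category) <- CATEGORY_NAMES
  n <- nrow(assignment)
  n_cat <- sum(assignment$mask > 0L)
  structure(list(
    per_category = per_category,
    n_candidates = n,
    n_categorized = n_cat,
    n_uncategorized = n - n_cat,
    pct_categorized = percent_half_up(n_cat, n)
  ), class = "category_summary")
}

#' @export
print.category_summary <- function(x, ...) {
  cat("<category_summary>\n")
  for (nm in names(x$per_category)) {
    cat(sprintf("  %-15s %5d\n", nm, x$per_category[[nm]]))
  }
  cat(sprintf("  categorized: %d out of %d (%d%%); uncategorized: %d\n",
              x$n_categorized, x$n_candidates, x$pct_categorized,
              x$n_uncategorized))
  invisible(x)
}

#' Write a Venn region table as TSV
#'
#' Columns: `mask` (bitstring), `label`, `count`, `members`
#' (comma-joined sorted symbols).
#'
#' @param partition A [venn_partition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_venn_table <- function(partition, path) {
  stopifnot(inherits(partition, "venn_partition"))
  bits <- names(partition$region_counts)
  df <- tibble::tibble(
    mask = bits,
    label = mask_label(bits_to_mask(bits)),
    count = as.integer(partition$region_counts),
    members = vapply(partition$region_members, paste, character(1),
                     collapse = ",")
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
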