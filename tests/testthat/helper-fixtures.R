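# Fixtures built in code; no stored data beyond the 3-line KEGG-dialect
# sample under inst/extdata.

mini_synonym_path <- function() {
  system.file("extdata", "synonyms_kegg_mini.txt", package = "mtornet")
}

mini_synonym_table <- function() load_synonym_table(mini_synonym_path())

# A hand-built synonym table with one ambiguous alias ("SHARED" maps to
# ids 10 and 20).
ambiguous_table <- function() {
  synonym_table(tibble::tibble(
    gene_id = c("10", "20", "30"),
    primary_symbol = c("ALPHA", "BETA", "GAMMA"),
    aliases = list(c("ALPHA", "SHARED"), c("BETA", "SHARED"), "GAMMA")))
}

# Small assignment built directly from keys and masks.
assignment_from_masks <- function(masks, keys = NULL) {
  keys <- keys %||% as.character(seq_along(masks) + 100)
  out <- tibble::tibble(key = keys, symbol = paste0("G", keys),
                        tier = "1", syndromic = FALSE,
                        mask = as.integer(masks))
  class(out) <- c("category_assignment", class(out))
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# One interaction record with given channel scores (0 elsewhere).
record_with <- function(gene_a = "1", gene_b = "1001", combined = 0.9,
                        ...) {
  sc <- list(...)
  row <- tibble::tibble(gene_a = gene_a, gene_b = gene_b,
                        neighborhood = 0, fusion = 0, cooccurrence = 0,
                        coexpression = 0, experimental = 0, database = 0,
                        textmining = 0, homology = 0, combined = combined)
  for (ch in names(sc)) row[[ch]] <- sc[[ch]]
  interaction_table(row)
}

# Brute-force 4-membership-test oracle for the Venn partition: per gene,
# test membership in each category set independently.
venn_oracle <- function(candidates, categories) {
  counts <- stats::setNames(integer(16),
                            mtornet:::mask_bits(0:15))
  for (i in seq_len(nrow(candidates))) {
    m <- 0L
    for (b in 1:4) {
      keys <- categories[[b]]$members$key
      keys <- keys[!startsWith(keys, "SYM:")]
      if (candidates$key[[i]] %in% keys) m <- m + bitwShiftL(1L, b - 1L)
    }
    bits <- mtornet:::mask_bits(m)
    counts[[bits]] <- counts[[bits]] + 1L
  }
  counts
}
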