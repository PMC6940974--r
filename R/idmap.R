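# Symbol-to-identifier normalization against a KEGG-style synonym table.
#
# All downstream set algebra runs on stable numeric gene ids; symbols the
# table cannot resolve are retained under an uppercase-symbol surrogate
# key ("SYM:<SYMBOL>") so list cardinalities never silently shrink.

#' Construct a synonym table
#'
#' A synonym table maps gene symbols and their aliases to stable numeric
#' gene identifiers and is the comparison key for every set operation in
#' the package. Lookup is case-insensitive and whitespace-trimmed;
#' hyphen/underscore variants are deliberately not folded.
#'
#' @param entries A data frame with columns `gene_id` (character, unique),
#'   `primary_symbol` (character) and `aliases` (list column of character
#'   vectors, each including the primary symbol).
#' @return An object of class `synonym_table`.
#' @export
synonym_table <- function(entries) {
  entries <- tibble::as_tibble(entries)
  stopifnot(all(c("gene_id", "primary_symbol", "aliases") %in%
                  names(entries)))
  entries$gene_id <- as.character(entries$gene_id)
  if (anyDuplicated(entries$gene_id)) {
    dup <- unique(entries$gene_id[duplicated(entries$gene_id)])
    stop("duplicate gene_id in synonym table: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  ok <- mapply(function(p, a) toupper(p) %in% toupper(a),
               entries$primary_symbol, entries$aliases)
  stopifnot(all(ok))
  lookup <- tibble::tibble(
    key = toupper(trimws(unlist(entries$aliases))),
    gene_id = rep(entries$gene_id, lengths(entries$aliases))
  )
  lookup <- dplyr::distinct(lookup)
  structure(list(entries = entries, lookup = lookup),
            class = "synonym_table")
}

#' @export
print.synonym_table <- function(x, ...) {
  n_amb <- sum(table(x$lookup$key) > 1)
  cat(sprintf("<synonym_table> %d genes, %d lookup keys (%d ambiguous)\n",
              nrow(x$entries), length(unique(x$lookup$key)), n_amb))
  invisible(x)
}

#' Read a KEGG-style gene synonym flat file
#'
#' Parses the dialect of the KEGG organism gene list
#' (`rest.kegg.jp/list/hsa`): one gene per line,
#' `ID<TAB>symbol1, symbol2, ...; description`. A leading `"hsa:"` prefix
#' on the identifier is stripped so ids are plain NCBI gene ids. The first
#' listed symbol becomes the primary symbol. Lines with an empty symbol
#' field yield an entry whose primary symbol is the id string itself and
#' are flagged with a warning.
#'
#' @param path Path to the flat file.
#' @return A [synonym_table()].
#' @export
load_synonym_table <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop("empty synonym table source: ", path, call. = FALSE)
  }
  parsed <- lapply(seq_along(lines), function(i) {
    line <- lines[[i]]
    tab <- regexpr("\t", line, fixed = TRUE)
    if (tab < 0) {
      stop(sprintf("malformed synonym table line %d (no tab separator): %s",
                   i, substr(line, 1, 60)), call. = FALSE)
    }
    id <- trimws(substr(line, 1, tab - 1))
    rest <- substr(line, tab + 1, nchar(line))
    id <- sub("^hsa:", "", id)
    if (!nzchar(id)) {
      stop(sprintf("malformed synonym table line %d (empty id)", i),
           call. = FALSE)
    }
    symfield <- strsplit(rest, ";", fixed = TRUE)[[1]][1]
    aliases <- trimws(strsplit(symfield %||% "", ",", fixed = TRUE)[[1]])
    aliases <- aliases[nzchar(aliases)]
    flagged <- length(aliases) == 0
    if (flagged) aliases <- id
    list(gene_id = id, primary_symbol = aliases[[1]], aliases = aliases,
         flagged = flagged)
  })
  flagged <- vapply(parsed, `[[`, logical(1), "flagged")
  if (any(flagged)) {
    warning(sprintf("%d synonym table line(s) had an empty symbol field; %s",
                    sum(flagged),
                    "the id string is used as the primary symbol"),
            call. = FALSE)
  }
  entries <- tibble::tibble(
    gene_id = vapply(parsed, `[[`, character(1), "gene_id"),
    primary_symbol = vapply(parsed, `[[`, character(1), "primary_symbol"),
    aliases = lapply(parsed, `[[`, "aliases")
  )
  synonym_table(entries)
}

# All gene_ids an (uppercased) key resolves to, sorted numerically.
lookup_key <- function(table, key) {
  ids <- table$lookup$gene_id[table$lookup$key == key]
  sort_keys(unique(ids))
}

#' Normalize gene symbols to stable gene ids
#'
#' Resolves each input symbol against a synonym table, reporting — never
#' silently resolving — aliases claimed by more than one gene id. The
#' input is de-duplicated case-insensitively (first spelling wins) before
#' resolution.
#'
#' @param symbols Character vector of gene symbols.
#' @param table A [synonym_table()].
#' @param policy How to treat ambiguous symbols: `"first"` (default)
#'   resolves them to the lowest gene id *and* logs them in the
#'   `ambiguous` slot; `"drop"` leaves them only in `ambiguous`, so
#'   `resolved`/`unmapped`/`ambiguous` partition the input.
#' @return A `normalization_report`: list with `resolved` (named character
#'   vector symbol -> gene_id), `unmapped` (character), `ambiguous` (named
#'   list symbol -> gene ids), `n_input`, `n_unique_ids`, `policy`.
#' @export
normalize_symbols <- function(symbols, table,
                              policy = c("first", "drop")) {
  policy <- match.arg(policy)
  stopifnot(inherits(table, "synonym_table"))
  symbols <- trimws(as.character(symbols))
  symbols <- symbols[nzchar(symbols) & !is.na(symbols)]
  n_input <- length(symbols)
  symbols <- symbols[!duplicated(toupper(symbols))]

  hits <- lapply(toupper(symbols), lookup_key, table = table)
  n_hits <- lengths(hits)

  resolved <- character(0)
  if (any(n_hits == 1)) {
    resolved <- vapply(hits[n_hits == 1], `[[`, character(1), 1)
    names(resolved) <- symbols[n_hits == 1]
  }
  unmapped <- symbols[n_hits == 0]
  ambiguous <- hits[n_hits > 1]
  names(ambiguous) <- symbols[n_hits > 1]

  if (length(ambiguous) > 0) {
    message(sprintf(
      "normalize_symbols: %d ambiguous symbol(s) (%s) map to multiple gene ids; policy = '%s'",
      length(ambiguous),
      paste(utils::head(names(ambiguous), 3), collapse = ", "), policy))
    if (policy == "first") {
      first_ids <- vapply(ambiguous, `[[`, character(1), 1)
      resolved <- c(resolved, stats::setNames(first_ids, names(ambiguous)))
      resolved <- resolved[order(match(names(resolved), symbols))]
    }
  }

  structure(list(
    resolved = resolved,
    unmapped = unmapped,
    ambiguous = ambiguous,
    n_input = n_input,
    n_unique_ids = length(unique(resolved)),
    policy = policy
  ), class = "normalization_report")
}

#' @export
print.normalization_report <- function(x, ...) {
  cat(sprintf(
    "<normalization_report> %d input, %d resolved (%d unique ids), %d unmapped, %d ambiguous [policy=%s]\n",
    x$n_input, length(x$resolved), x$n_unique_ids, length(x$unmapped),
    length(x$ambiguous), x$policy))
  invisible(x)
}

#' Serialize a normalization report to JSON
#'
#' @param report A `normalization_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_normalization_report <- function(report, path) {
  stopifnot(inherits(report, "normalization_report"))
  out <- list(
    n_input = report$n_input,
    n_resolved = length(report$resolved),
    n_unique_ids = report$n_unique_ids,
    n_unmapped = length(report$unmapped),
    n_ambiguous = length(report$ambiguous),
    policy = report$policy,
    resolved = as.list(report$resolved),
    unmapped = report$unmapped,
    ambiguous = report$ambiguous
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Construct a gene set
#'
#' A gene set is a named, provenance-tagged collection of normalized gene
#' keys (numeric gene ids, or `"SYM:<SYMBOL>"` surrogates for unmapped
#' symbols) with a display symbol per member.
#'
#' @param keys Character vector of member keys (de-duplicated, order of
#'   first appearance kept).
#' @param name Set name.
#' @param symbols Optional display symbols, parallel to `keys`; defaults
#'   to the keys themselves.
#' @param provenance Optional list describing the source(s).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(keys, name, symbols = NULL, provenance = NULL) {
  keys <- as.character(keys)
  symbols <- as.character(symbols %||% keys)
  stopifnot(length(symbols) == length(keys), is.character(name),
            length(name) == 1)
  keep <- !duplicated(keys)
  structure(list(
    name = name,
    members = tibble::tibble(key = keys[keep], symbol = symbols[keep]),
    provenance = provenance %||% list()
  ), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> '%s': %d members (%d surrogate keys)\n",
              x$name, nrow(x$members),
              sum(is_surrogate_key(x$members$key))))
  invisible(x)
}

#' @export
length.gene_set <- function(x) nrow(x$members)

#' Normalize a symbol list into a gene set
#'
#' Symbols the table resolves become gene-id keys; unmapped symbols are
#' retained under uppercase-symbol surrogate keys so the set cardinality
#' stays conservative and auditable.
#'
#' @inheritParams normalize_symbols
#' @param name Name for the resulting set.
#' @return A [gene_set()] with the `normalization_report` attached as
#'   attribute `"report"`.
#' @export
normalize_gene_set <- function(symbols, table, name,
                               policy = c("first", "drop")) {
  policy <- match.arg(policy)
  report <- normalize_symbols(symbols, table, policy = policy)
  syms <- c(names(report$resolved), report$unmapped,
            if (policy == "drop") names(report$ambiguous))
  keys <- c(unname(report$resolved), surrogate_key(report$unmapped),
            if (policy == "drop") surrogate_key(names(report$ambiguous)))
  # several symbols can resolve to one id; keep the first
  set <- gene_set(keys, name, symbols = syms,
                  provenance = list(list(source = name,
                                         n_symbols = report$n_input,
                                         n_unmapped = length(report$unmapped))))
  attr(set, "report") <- report
  set
}

#' Merge gene sets into their de-duplicated union
#'
#' The union is taken on normalized keys, so two sources listing the same
#' gene under different aliases contribute a single member. Provenance
#' records each source set and the number of new keys it contributed.
#'
#' @param sets A non-empty list of [gene_set()] objects, or of character
#'   symbol vectors (normalized via `table` first).
#' @param name Name for the merged set.
#' @param table A [synonym_table()]; required when `sets` contains raw
#'   symbol vectors.
#' @param policy Ambiguity policy passed to [normalize_symbols()].
#' @return A [gene_set()].
#' @export
merge_gene_sets <- function(sets, name = "merged", table = NULL,
                            policy = "first") {
  if (!is.list(sets) || length(sets) == 0) {
    stop("merge_gene_sets() needs a non-empty list of sets", call. = FALSE)
  }
  sets <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (inherits(s, "gene_set")) return(s)
    if (is.character(s)) {
      if (is.null(table)) {
        stop("raw symbol vectors require a synonym table", call. = FALSE)
      }
      nm <- names(sets)[i] %||% paste0("set", i)
      if (is.na(nm) || !nzchar(nm)) nm <- paste0("set", i)
      return(normalize_gene_set(s, table, name = nm, policy = policy))
    }
    stop("each element must be a gene_set or a character vector",
         call. = FALSE)
  })
  members <- tibble::tibble(key = character(0), symbol = character(0))
  provenance <- list()
  for (s in sets) {
    new <- !(s$members$key %in% members$key)
    provenance[[length(provenance) + 1]] <- list(
      source = s$name, size = nrow(s$members),
      contributed = sum(new))
    members <- dplyr::bind_rows(members, s$members[new, ])
  }
  gene_set(members$key, name, symbols = members$symbol,
           provenance = provenance)
}

#' Read a plain gene list
#'
#' Accepts either one symbol per line, or a single-column CSV/TSV with a
#' header row (the first column is used).
#'
#' @param path Path to the list file.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(character(0))
  delim <- if (grepl("\t", lines[[1]])) "\t"
           else if (grepl(",", lines[[1]])) ","
           else NULL
  if (is.null(delim)) {
    lines <- trimws(lines)
    # single-column file: a leading line that reads like a column header
    # (not a gene symbol) is dropped
    header_words <- c("gene", "genes", "symbol", "symbols", "gene-symbol",
                      "gene_symbol", "genesymbol", "id", "gene-id",
                      "gene_id")
    if (tolower(lines[[1]]) %in% header_words) lines <- lines[-1]
    return(lines)
  }
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  trimws(as.character(df[[1]]))
}
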