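# Two-layer interaction-network construction.
#
# Layer 1 (core): categorized high-tier genes linked to the three hub
# elements (FMRP, MTOR, VITD), one edge per hub a gene's membership mask
# touches, with a seven-cluster taxonomy over the FMRP-target /
# mTOR-modulated / vitamin-D-sensitive bits (pure mTOR-signaling-network
# genes attach to the MTOR hub as HUB_ATTACHED).
# Layer 2 (secondary): residual genes joined only through cross-list
# interaction records whose combined score clears the high-confidence
# cutoff, each edge labelled by its strongest qualifying evidence
# channel (or as weakest_high_confidence), each gene given a categorical
# placement label from the clusters its edges touch.

HUB_IDS <- c("FMRP", "MTOR", "VITD")

#' Hubs touched by a membership mask
#'
#' FMRP targets attach to the FMRP hub; mTOR-network and mTOR-modulated
#' genes both attach to the MTOR hub; vitamin-D-sensitive genes attach to
#' the VITD hub.
#'
#' @param mask Integer mask in 1..15.
#' @return Character vector, subset of `c("FMRP","MTOR","VITD")`.
#' @export
hubs_for_mask <- function(mask) {
  stopifnot(length(mask) == 1, mask >= 1, mask <= 15)
  hubs <- character(0)
  if (bitwAnd(mask, 1L) > 0L) hubs <- c(hubs, "FMRP")
  if (bitwAnd(mask, 2L) > 0L || bitwAnd(mask, 4L) > 0L) {
    hubs <- c(hubs, "MTOR")
  }
  if (bitwAnd(mask, 8L) > 0L) hubs <- c(hubs, "VITD")
  hubs
}

#' Cluster label of a categorized gene
#'
#' The seven original clusters are the populated combinations of the
#' FMRP-target, mTOR-modulated and vitamin-D-sensitive bits; a gene whose
#' only membership is the mTOR signaling network carries no cluster of
#' its own and is labelled `HUB_ATTACHED` (it sits at the MTOR hub).
#'
#' @param mask Integer mask in 1..15.
#' @return A single cluster label string.
#' @export
cluster_for_mask <- function(mask) {
  stopifnot(length(mask) == 1)
  if (mask == 0) {
    stop("uncategorized gene (mask 0) has no cluster", call. = FALSE)
  }
  parts <- CATEGORY_NAMES[c(1, 3, 4)][c(
    bitwAnd(mask, 1L) > 0L, bitwAnd(mask, 4L) > 0L, bitwAnd(mask, 8L) > 0L)]
  if (length(parts) == 0) return("HUB_ATTACHED")
  paste(parts, collapse = "+")
}

new_network_model <- function(nodes, edges, unconnected = character(0),
                              report = NULL) {
  structure(list(nodes = nodes, edges = edges, unconnected = unconnected,
                 report = report),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf(
    "<network_model> %d nodes (%d primary, %d secondary, %d hubs), %d edges (%d core, %d secondary)\n",
    nrow(x$nodes), sum(x$nodes$list == "primary", na.rm = TRUE),
    sum(x$nodes$list == "secondary", na.rm = TRUE),
    sum(x$nodes$type == "hub"), nrow(x$edges),
    sum(x$edges$layer == "core"), sum(x$edges$layer == "secondary")))
  if (length(x$unconnected) > 0) {
    cat(sprintf("  %d unconnected secondary gene(s)\n",
                length(x$unconnected)))
  }
  invisible(x)
}

#' Build the core network layer
#'
#' Every categorized gene receives one edge per hub its mask touches and
#' a cluster label; the core edge count is therefore the sum over genes
#' of the number of distinct hubs touched.
#'
#' @param assignment A `category_assignment` (typically restricted to the
#'   high-confidence tiers) in which every gene has a nonzero mask.
#' @return A `network_model` containing hubs, primary gene nodes and core
#'   edges only.
#' @export
build_core_layer <- function(assignment) {
  stopifnot(inherits(assignment, "category_assignment"))
  if (any(assignment$mask == 0L)) {
    stop("build_core_layer(): assignment contains uncategorized genes ",
         "(mask 0); filter them out first", call. = FALSE)
  }
  hub_nodes <- tibble::tibble(
    id = HUB_IDS, symbol = HUB_IDS, type = "hub", list = NA_character_,
    mask = NA_integer_, cluster = NA_character_,
    placement = NA_character_)
  gene_nodes <- tibble::tibble(
    id = assignment$key, symbol = assignment$symbol, type = "gene",
    list = "primary", mask = assignment$mask,
    cluster = vapply(assignment$mask, cluster_for_mask, character(1)),
    placement = NA_character_)
  edges <- dplyr::bind_rows(lapply(seq_len(nrow(assignment)), function(i) {
    hubs <- hubs_for_mask(assignment$mask[[i]])
    tibble::tibble(from = assignment$key[[i]], to = hubs)
  }))
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(0), to = character(0))
  }
  edges$layer <- rep("core", nrow(edges))
  edges$label <- rep(NA_character_, nrow(edges))
  edges$label_score <- rep(NA_real_, nrow(edges))
  new_network_model(dplyr::bind_rows(hub_nodes, gene_nodes), edges)
}

# Interaction tables ----------------------------------------------------

# Column-name synonyms of STRING "detailed" exports.
STRING_COLUMN_SYNONYMS <- c(
  protein1 = "gene_a", protein2 = "gene_b",
  node1 = "gene_a", node2 = "gene_b",
  gene_a = "gene_a", gene_b = "gene_b",
  neighborhood = "neighborhood", fusion = "fusion",
  cooccurence = "cooccurrence", cooccurrence = "cooccurrence",
  coexpression = "coexpression",
  experimental = "experimental", experiments = "experimental",
  database = "database", databases = "database",
  textmining = "textmining", homology = "homology",
  combined_score = "combined", combined = "combined")

#' Canonicalize an interaction table
#'
#' Validates and canonicalizes STRING-style interaction records: drops
#' self-pairs, stores each pair in sorted order, rejects duplicate pairs,
#' and auto-detects the score scale (any score above 1 means the 0-1000
#' STRING scale; all scores are then divided by 1000). The `combined`
#' column is taken from the input as authoritative; it is never
#' recomputed here.
#'
#' @param df Data frame with columns `gene_a`, `gene_b`, the seven
#'   evidence channels, optionally `homology`, and `combined`.
#' @return A tibble of class `interaction_table`.
#' @export
interaction_table <- function(df) {
  df <- tibble::as_tibble(df)
  needed <- c("gene_a", "gene_b", EVIDENCE_CHANNELS, "combined")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("interaction table misses columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"homology" %in% names(df)) df$homology <- 0
  df$gene_a <- as.character(df$gene_a)
  df$gene_b <- as.character(df$gene_b)
  df <- df[df$gene_a != df$gene_b, , drop = FALSE]

  score_cols <- c(EVIDENCE_CHANNELS, "homology", "combined")
  mx <- suppressWarnings(max(unlist(df[score_cols]), na.rm = TRUE))
  if (is.finite(mx) && mx > 1) {
    df[score_cols] <- lapply(df[score_cols], function(x) x / 1000)
  }
  df[score_cols] <- lapply(df[score_cols], function(x) {
    x[is.na(x)] <- 0
    pmin(pmax(as.numeric(x), 0), 1)
  })

  swap <- key_order_pairwise(df$gene_a, df$gene_b)
  tmp <- df$gene_a[swap]
  df$gene_a[swap] <- df$gene_b[swap]
  df$gene_b[swap] <- tmp

  pair <- paste(df$gene_a, df$gene_b, sep = "\r")
  if (anyDuplicated(pair)) {
    stop("duplicate interaction pairs after canonicalization: ",
         paste(utils::head(unique(gsub("\r", "--", pair[duplicated(pair)])),
                           3), collapse = ", "), call. = FALSE)
  }
  na <- suppressWarnings(as.numeric(df$gene_a))
  nb <- suppressWarnings(as.numeric(df$gene_b))
  df <- df[order(is.na(na), na, df$gene_a, is.na(nb), nb, df$gene_b), ,
           drop = FALSE]
  df <- df[, c("gene_a", "gene_b", EVIDENCE_CHANNELS, "homology",
               "combined",
               setdiff(names(df), c("gene_a", "gene_b", score_cols)))]
  class(df) <- c("interaction_table", class(df))
  df
}

# TRUE where the pair (a, b) is out of canonical order.
key_order_pairwise <- function(a, b) {
  na <- suppressWarnings(as.numeric(a))
  nb <- suppressWarnings(as.numeric(b))
  both_num <- !is.na(na) & !is.na(nb)
  out <- logical(length(a))
  out[both_num] <- na[both_num] > nb[both_num]
  out[!both_num] <- a[!both_num] > b[!both_num]
  out
}

#' Read a STRING-style detailed interaction export
#'
#' Accepts tab- or whitespace-separated files with the usual STRING
#' column names (`protein1`, `protein2`, per-channel scores,
#' `combined_score`); `col_map` overrides the name mapping
#' (`c(file_column = "standard_name")`).
#'
#' @param path Path to the export.
#' @param col_map Optional named character vector mapping file columns to
#'   the standard names `gene_a`, `gene_b`, the channels, `homology`,
#'   `combined`.
#' @return An [interaction_table()].
#' @export
read_interactions <- function(path, col_map = NULL) {
  first <- readr::read_lines(path, n_max = 1)
  if (grepl("\t", first)) {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    df <- readr::read_table(path, show_col_types = FALSE, progress = FALSE)
  }
  map <- STRING_COLUMN_SYNONYMS
  if (!is.null(col_map)) map <- c(col_map, map)
  hit <- match(tolower(names(df)), names(map))
  names(df)[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
  interaction_table(df)
}

#' Filter interactions to qualifying cross-list pairs
#'
#' Retains exactly the records with one endpoint in each list and a
#' combined score clearing the cutoff; within-list interactions (both
#' endpoints primary, or both secondary) are removed regardless of
#' score. Output is stably sorted by `(gene_a, gene_b)`.
#'
#' @param interactions An [interaction_table()].
#' @param primary,secondary Disjoint [gene_set()]s or character key
#'   vectors.
#' @param cutoff Combined-score cutoff; default 0.7, the conventional
#'   high-confidence threshold.
#' @param inclusive If `FALSE` (default) the comparison is strict
#'   (`combined > cutoff`, the "more than 0.7" reading); if `TRUE`,
#'   boundary equality also qualifies (the STRING >= 700 convention).
#' @return An [interaction_table()] of the retained records.
#' @export
filter_cross_list <- function(interactions, primary, secondary,
                              cutoff = 0.7, inclusive = FALSE) {
  stopifnot(inherits(interactions, "interaction_table"))
  p <- set_keys(primary)
  s <- set_keys(secondary)
  if (length(intersect(p, s)) > 0) {
    stop("primary and secondary gene lists overlap: ",
         paste(utils::head(intersect(p, s), 3), collapse = ", "),
         call. = FALSE)
  }
  a_in_p <- interactions$gene_a %in% p
  b_in_p <- interactions$gene_b %in% p
  a_in_s <- interactions$gene_a %in% s
  b_in_s <- interactions$gene_b %in% s
  cross <- (a_in_p & b_in_s) | (a_in_s & b_in_p)
  qual <- if (inclusive) interactions$combined >= cutoff
          else interactions$combined > cutoff
  out <- interactions[cross & qual, , drop = FALSE]
  class(out) <- c("interaction_table",
                  setdiff(class(out), "interaction_table"))
  out
}

set_keys <- function(x) {
  if (inherits(x, "gene_set")) x$members$key else as.character(x)
}

#' Classify retained edges by their strongest evidence channel
#'
#' For each record, the label is the evidence channel (homology included)
#' with the maximal score among channels clearing the cutoff; ties are
#' broken by a fixed precedence (database > experimental > homology >
#' textmining > coexpression > neighborhood > fusion > cooccurrence). A
#' record in which no single channel clears the cutoff while the combined
#' score does is labelled `"weakest_high_confidence"` with the combined
#' score as its label score. Records whose combined score does not clear
#' the cutoff must not reach classification and raise an error.
#'
#' @inheritParams filter_cross_list
#' @return The input with `label` and `label_score` columns added.
#' @export
classify_edges <- function(interactions, cutoff = 0.7, inclusive = FALSE) {
  stopifnot(inherits(interactions, "interaction_table"))
  qual_comb <- if (inclusive) interactions$combined >= cutoff
               else interactions$combined > cutoff
  if (any(!qual_comb)) {
    stop("classify_edges(): record(s) with combined score not above the ",
         "cutoff reached classification", call. = FALSE)
  }
  chans <- c(EVIDENCE_CHANNELS, "homology")
  scores <- as.matrix(interactions[chans])
  n <- nrow(interactions)
  label <- character(n)
  label_score <- numeric(n)
  prec <- match(chans, CHANNEL_PRECEDENCE)
  for (i in seq_len(n)) {
    s <- scores[i, ]
    qual <- if (inclusive) s >= cutoff else s > cutoff
    if (!any(qual)) {
      label[i] <- WEAKEST_LABEL
      label_score[i] <- interactions$combined[[i]]
    } else {
      cand <- which(qual & s == max(s[qual]))
      pick <- cand[which.min(prec[cand])]
      label[i] <- chans[[pick]]
      label_score[i] <- s[[pick]]
    }
  }
  out <- interactions
  out$label <- label
  out$label_score <- label_score
  out
}

#' Placement label for a secondary gene
#'
#' Derives the set of original clusters a secondary gene's retained edges
#' touch (via the cluster labels of its primary partners) and applies the
#' categorical placement rules: partners confined to the MTOR hub
#' (`HUB_ATTACHED` only) give `NEAR_CORE(MTOR)`; one touched cluster
#' gives `NEAR_CLUSTER(<cluster>)`; two give `BETWEEN(<a>,<b>)`; three or
#' more give `CENTER`. `NETWORK_CENTER` (the unique gene touching at
#' least six of the seven clusters) is assigned at network level by
#' [build_full_network()]. The label depends only on the set of touched
#' clusters, never on edge order.
#'
#' @param gene Secondary gene key (used in error messages).
#' @param edges Retained classified edges of this gene (an
#'   [interaction_table()] subset; must be nonempty).
#' @param cluster_of Named character vector mapping primary gene keys to
#'   cluster labels.
#' @param hub_attached_counts_as Cluster that `HUB_ATTACHED` partners
#'   count as touching when mixed with cluster partners (default
#'   `"MTOR_MODULATED"`).
#' @return A list with `placement` (label string) and `touched`
#'   (character vector of touched clusters after mapping).
#' @export
placement_for_gene <- function(gene, edges, cluster_of,
                               hub_attached_counts_as = "MTOR_MODULATED") {
  if (nrow(edges) == 0) {
    stop("gene ", gene, " has no retained edges; report it as ",
         "unconnected instead of placing it", call. = FALSE)
  }
  partners <- ifelse(edges$gene_a == gene, edges$gene_b, edges$gene_a)
  raw <- unique(unname(cluster_of[partners]))
  if (anyNA(raw)) {
    stop("gene ", gene, " has a partner without a cluster label",
         call. = FALSE)
  }
  if (all(raw == "HUB_ATTACHED")) {
    return(list(placement = "NEAR_CORE(MTOR)", touched = character(0)))
  }
  touched <- sort(unique(ifelse(raw == "HUB_ATTACHED",
                                hub_attached_counts_as, raw)))
  placement <- if (length(touched) == 1) {
    sprintf("NEAR_CLUSTER(%s)", touched)
  } else if (length(touched) == 2) {
    sprintf("BETWEEN(%s,%s)", touched[[1]], touched[[2]])
  } else {
    "CENTER"
  }
  list(placement = placement, touched = touched)
}

#' Build the full two-layer network
#'
#' Adds the residual (secondary) genes to a core layer: interactions are
#' filtered to qualifying cross-list pairs, classified by evidence
#' channel, and each connected secondary gene receives a placement
#' label. If a unique secondary gene touches at least six of the seven
#' original clusters and strictly more than every other secondary gene,
#' it is upgraded to `NETWORK_CENTER`. Secondary genes with no
#' qualifying edge are reported in the `unconnected` slot rather than
#' dropped silently.
#'
#' @param core A core-layer `network_model` from [build_core_layer()].
#' @param residual [gene_set()] (or keys) of uncategorized candidates;
#'   must be disjoint from the core genes.
#' @param interactions An [interaction_table()].
#' @param cutoff,inclusive Combined-score cutoff; see
#'   [filter_cross_list()].
#' @param hub_attached_counts_as See [placement_for_gene()].
#' @return A `network_model` whose `report` slot carries
#'   `n_primary`, `n_residual`, `n_connected_secondary`,
#'   `n_secondary_edges`, `n_unconnected`, `total_connected`,
#'   `percent_connected` and the per-label edge-type counts.
#' @export
build_full_network <- function(core, residual, interactions,
                               cutoff = 0.7, inclusive = FALSE,
                               hub_attached_counts_as = "MTOR_MODULATED") {
  stopifnot(inherits(core, "network_model"))
  primary_nodes <- core$nodes[core$nodes$type == "gene", ]
  res_keys <- set_keys(residual)
  res_syms <- if (inherits(residual, "gene_set")) {
    stats::setNames(residual$members$symbol, residual$members$key)
  } else {
    stats::setNames(res_keys, res_keys)
  }

  retained <- filter_cross_list(interactions, primary_nodes$id, res_keys,
                                cutoff = cutoff, inclusive = inclusive)
  retained <- classify_edges(retained, cutoff = cutoff,
                             inclusive = inclusive)

  cluster_of <- stats::setNames(primary_nodes$cluster, primary_nodes$id)
  sec_of_pair <- as.character(ifelse(retained$gene_a %in% res_keys,
                                     retained$gene_a, retained$gene_b))
  connected <- sort_keys(unique(sec_of_pair))
  placements <- lapply(connected, function(g) {
    placement_for_gene(g, retained[sec_of_pair == g, , drop = FALSE],
                       cluster_of,
                       hub_attached_counts_as = hub_attached_counts_as)
  })
  names(placements) <- connected
  n_touched <- vapply(placements, function(p) length(p$touched), integer(1))
  labels <- vapply(placements, `[[`, character(1), "placement")
  if (length(n_touched) > 0) {
    mx <- max(n_touched)
    if (mx >= 6 && sum(n_touched == mx) == 1) {
      labels[[which.max(n_touched)]] <- "NETWORK_CENTER"
    }
  }

  sec_nodes <- tibble::tibble(
    id = connected,
    symbol = unname(res_syms[connected]),
    type = "gene", list = "secondary", mask = 0L,
    cluster = NA_character_, placement = unname(labels))
  sec_edges <- tibble::tibble(
    from = retained$gene_a, to = retained$gene_b, layer = "secondary",
    label = retained$label, label_score = retained$label_score)

  nodes <- dplyr::bind_rows(core$nodes, sec_nodes)
  edges <- dplyr::bind_rows(core$edges, sec_edges)
  unconnected <- setdiff(res_keys, connected)

  n_primary <- nrow(primary_nodes)
  report <- list(
    n_primary = n_primary,
    n_residual = length(res_keys),
    n_connected_secondary = length(connected),
    n_secondary_edges = nrow(sec_edges),
    n_unconnected = length(unconnected),
    total_connected = n_primary + length(connected),
    percent_connected = percent_half_up(
      n_primary + length(connected), n_primary + length(res_keys)),
    edge_type_counts = as.list(table(retained$label)),
    n_core_edges = sum(core$edges$layer == "core")
  )
  model <- new_network_model(nodes, edges, unconnected, report)
  validate_network_model(model)
  model
}

# Structural invariants asserted on every built/exported model.
validate_network_model <- function(model) {
  nodes <- model$nodes
  edges <- model$edges
  list_of <- stats::setNames(nodes$list, nodes$id)
  sec <- edges[edges$layer == "secondary", , drop = FALSE]
  if (nrow(sec) > 0) {
    lf <- list_of[sec$from]
    lt <- list_of[sec$to]
    if (any(lf == "secondary" & lt == "secondary", na.rm = TRUE)) {
      stop("invariant violated: secondary-layer edge joins two secondary ",
           "genes", call. = FALSE)
    }
    if (any(lf == "primary" & lt == "primary", na.rm = TRUE)) {
      stop("invariant violated: secondary-layer edge joins two primary ",
           "genes", call. = FALSE)
    }
  }
  sec_ids <- nodes$id[!is.na(nodes$list) & nodes$list == "secondary"]
  touched <- unique(c(sec$from, sec$to))
  if (!all(sec_ids %in% touched)) {
    stop("invariant violated: secondary node without an edge to a primary ",
         "gene", call. = FALSE)
  }
  invisible(model)
}

# Exporters --------------------------------------------------------------

#' Export a network as SIF
#'
#' Simple interaction format, `node<TAB>type<TAB>node`; core edges carry
#' the type `core`, secondary edges their evidence-channel label.
#'
#' @param model A `network_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(model, path) {
  validate_network_model(model)
  e <- model$edges
  type <- ifelse(e$layer == "core", "core", e$label)
  readr::write_lines(paste(e$from, type, e$to, sep = "\t"), path)
  invisible(path)
}

#' Convert a network model to an igraph graph
#'
#' @param model A `network_model`.
#' @return An undirected [igraph::graph] with node attributes `symbol`,
#'   `type`, `list`, `mask`, `cluster`, `placement` and edge attributes
#'   `layer`, `label`, `label_score`.
#' @export
as_igraph <- function(model) {
  validate_network_model(model)
  nodes <- model$nodes
  nodes$list[is.na(nodes$list)] <- ""
  nodes$cluster[is.na(nodes$cluster)] <- ""
  nodes$placement[is.na(nodes$placement)] <- ""
  nodes$mask[is.na(nodes$mask)] <- -1L
  edges <- model$edges
  edges$label[is.na(edges$label)] <- ""
  edges$label_score[is.na(edges$label_score)] <- -1
  igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = nodes[, c("id", "symbol", "type", "list", "mask",
                         "cluster", "placement")])
}

#' Export a network as GraphML
#'
#' @inheritParams write_sif
#' @return `path`, invisibly.
#' @export
write_graphml <- function(model, path) {
  g <- as_igraph(model)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export Cytoscape-loadable node and edge attribute tables
#'
#' @inheritParams write_sif
#' @param nodes_path,edges_path Output TSV paths.
#' @return A list of the two paths, invisibly.
#' @export
write_attribute_tables <- function(model, nodes_path, edges_path) {
  validate_network_model(model)
  nodes <- model$nodes
  nodes$mask_bits <- ifelse(is.na(nodes$mask), NA_character_,
                            mask_bits(ifelse(is.na(nodes$mask), 0L,
                                             nodes$mask)))
  readr::write_tsv(nodes, nodes_path, progress = FALSE)
  readr::write_tsv(model$edges, edges_path, progress = FALSE)
  invisible(list(nodes = nodes_path, edges = edges_path))
}
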