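# Synthetic-data generators.
#
# Every pipeline stage gets inputs with known ground truth: alias tables
# with controlled ambiguity, category sets built to prescribed
# Venn-region cardinalities (the generator is the exact inverse of
# venn_partition), tiered candidate tables, and channel-score interaction
# tables whose combined score follows the prior-corrected noisy-OR
# forward model used by STRING. A single integer seed drives a named
# substream per stage, so stages can be regenerated independently and
# identical seeds give byte-identical output files.

#' Prior-corrected noisy-OR combined score
#'
#' The forward model combining independent evidence-channel scores into
#' one confidence score, following the STRING convention: each channel
#' score is corrected for the prior probability `p` of a random pair
#' interacting, `s* = max(0, (s - p) / (1 - p))`; the corrected scores
#' are combined as a noisy OR, `total = 1 - prod(1 - s*)`; and the prior
#' is added back, `combined = total * (1 - p) + p`. With all channels at
#' zero the combined score equals `p`; with a single active channel `s`
#' it equals `s` exactly. The auxiliary homology channel never enters
#' this combination.
#'
#' This model lives in the generator (and may be used as a validator);
#' the filtering path always trusts the `combined` column of its input.
#'
#' @param scores Numeric vector (one pair) or matrix (pairs x channels)
#'   of channel scores in `[0, 1]`.
#' @param prior Baseline interaction probability; default 0.041.
#' @return Combined score(s) in `[p, 1]`.
#' @export
#' @examples
#' string_combine_score(c(0, 0, 0))           # the prior itself
#' string_combine_score(c(0.9, 0, 0))         # a single channel passes through
string_combine_score <- function(scores, prior = 0.041) {
  stopifnot(prior >= 0, prior < 1)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  stopifnot(all(scores >= 0 & scores <= 1))
  corrected <- scores  # pmax() drops dim, so fill in place
  corrected[] <- pmax(0, (scores - prior) / (1 - prior))
  total <- 1 - apply(1 - corrected, 1, prod)
  unname(total * (1 - prior) + prior)
}

#' Generate a synthetic gene universe with a synonym table
#'
#' Creates `n` genes with unique numeric ids and synthetic primary
#' symbols; a fraction `alias_rate` of genes receive 1-3 extra aliases,
#' and each extra alias is independently shared with a second random
#' gene with probability `ambiguity_rate`, producing aliases that
#' resolve to two gene ids (the controlled-ambiguity fixture for the
#' normalization stage).
#'
#' @param n Number of genes (>= 1).
#' @param alias_rate Probability a gene carries extra aliases.
#' @param ambiguity_rate Probability an extra alias is shared with a
#'   second gene.
#' @param seed Integer seed; fully determines the output.
#' @param include_symbols Optional character vector of real symbols to
#'   use as the primary symbols of the first genes (for planting known
#'   genes into synthetic fixtures).
#' @return List with `table` (a [synonym_table()]), `symbols` (primary
#'   symbols), and `extra_aliases` (tibble `alias`, `gene_id`, `shared`).
#' @export
generate_gene_universe <- function(n, alias_rate = 0.3,
                                   ambiguity_rate = 0.02, seed = 1,
                                   include_symbols = character(0)) {
  stopifnot(n >= 1)
  if (alias_rate < 0 || alias_rate > 1 || ambiguity_rate < 0 ||
      ambiguity_rate > 1) {
    stop("alias_rate and ambiguity_rate must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(length(include_symbols) <= n)
  set.seed(substream_seed(seed, "universe"))
  gene_id <- as.character(sort(sample.int(n * 10L, n)) + 1000L)
  primary <- paste0("SYG", formatC(seq_len(n), width = 5, flag = "0"))
  if (length(include_symbols) > 0) {
    primary[seq_along(include_symbols)] <- include_symbols
  }
  aliases <- as.list(primary)
  extra <- tibble::tibble(alias = character(0), gene_id = character(0),
                          shared = logical(0))
  has_alias <- stats::runif(n) < alias_rate
  for (i in which(has_alias)) {
    k <- sample(1:3, 1)
    new <- paste0(primary[[i]], "-A", seq_len(k))
    aliases[[i]] <- c(aliases[[i]], new)
    shared <- stats::runif(k) < ambiguity_rate
    if (any(shared) && n > 1) {
      for (a in new[shared]) {
        j <- sample(setdiff(seq_len(n), i), 1)
        aliases[[j]] <- c(aliases[[j]], a)
      }
    }
    extra <- dplyr::bind_rows(extra, tibble::tibble(
      alias = new, gene_id = gene_id[[i]], shared = shared))
  }
  table <- synonym_table(tibble::tibble(
    gene_id = gene_id, primary_symbol = primary, aliases = aliases))
  list(table = table, symbols = primary, extra_aliases = extra)
}

#' Specify Venn-region cardinalities and tier proportions
#'
#' @param region_sizes Named non-negative integer vector; names are
#'   4-bit mask bitstrings (`"0000"`..`"1111"`, FMRP/mTOR-network/
#'   mTOR-modulated/vitamin-D bit order). Unnamed regions default to 0;
#'   `"0000"` is the outside (uncategorized) count. The sum is the
#'   candidate-universe size.
#' @param tier_fractions Named numeric vector over the tier vocabulary
#'   summing to 1 (tolerance 1e-9); the marginal tier distribution used
#'   when no explicit per-region tier plan is given.
#' @return An object of class `venn_spec`.
#' @export
venn_spec <- function(region_sizes,
                      tier_fractions = c("1" = 0.1, "2" = 0.1, "3" = 0.1,
                                         "4" = 0.25, "5" = 0.25,
                                         "6" = 0.1, "7" = 0.05,
                                         "S" = 0.05)) {
  all_bits <- mask_bits(0:15)
  sizes <- stats::setNames(integer(16), all_bits)
  if (is.null(names(region_sizes))) {
    stop("region_sizes must be named by mask bitstrings", call. = FALSE)
  }
  stopifnot(all(names(region_sizes) %in% all_bits),
            all(region_sizes >= 0))
  sizes[names(region_sizes)] <- as.integer(region_sizes)
  stopifnot(all(names(tier_fractions) %in% TIER_VOCABULARY))
  if (abs(sum(tier_fractions) - 1) > 1e-9) {
    stop("tier_fractions must sum to 1", call. = FALSE)
  }
  structure(list(region_sizes = sizes, tier_fractions = tier_fractions),
            class = "venn_spec")
}

#' Generate category sets with prescribed Venn-region cardinalities
#'
#' The exact inverse of [venn_partition()]: genes are drawn from the
#' universe and dealt into the 16 regions so that
#' `venn_partition(assign_categories(...))` reproduces
#' `spec$region_sizes` by construction. Tiers are sampled from the
#' spec's tier fractions, or per an explicit high-tier plan.
#'
#' @param spec A [venn_spec()].
#' @param universe Output of [generate_gene_universe()] (or a list with
#'   `table` and `symbols`).
#' @param seed Integer seed.
#' @param planted Optional named list, bitstring mask -> character
#'   symbols from the universe to force into that region (counted within
#'   the region's size).
#' @param high_tier_by_region Optional named integer vector, bitstring
#'   mask -> how many of that region's genes get a high tier (sampled
#'   uniformly from `high_tiers`); the rest get tiers `"4"`-`"7"`.
#'   Overrides `spec$tier_fractions`.
#' @param planted_high Symbols that must be among the high-tier draws of
#'   their region (counted within that region's high-tier quota).
#' @param high_tiers Tiers considered high-confidence (default
#'   `c("1","2","3")`).
#' @param syndromic_rate Probability of the orthogonal syndromic flag.
#' @return List with `candidates` (a [scored_gene_table()]),
#'   `categories` (named list of 4 [gene_set()]s), and `truth` (tibble
#'   `key`, `symbol`, `mask`).
#' @export
generate_categories <- function(spec, universe, seed = 1, planted = NULL,
                                high_tier_by_region = NULL,
                                high_tiers = HIGH_TIERS,
                                planted_high = character(0),
                                syndromic_rate = 0.05) {
  stopifnot(inherits(spec, "venn_spec"))
  set.seed(substream_seed(seed, "categories"))
  n_total <- sum(spec$region_sizes)
  syms <- universe$symbols
  ids <- universe$table$entries$gene_id
  if (n_total > length(syms)) {
    stop("venn spec (", n_total, " genes) exceeds the universe (",
         length(syms), ")", call. = FALSE)
  }

  # planted symbols claim their slots first
  planted <- planted %||% list()
  planted_syms <- unlist(planted, use.names = FALSE)
  stopifnot(all(planted_syms %in% syms))
  free <- setdiff(syms, planted_syms)
  picked <- sample(free, n_total - length(planted_syms))

  region_syms <- vector("list", 16)
  names(region_syms) <- names(spec$region_sizes)
  offset <- 0
  for (b in names(spec$region_sizes)) {
    want <- spec$region_sizes[[b]]
    pl <- planted[[b]] %||% character(0)
    if (length(pl) > want) {
      stop("region ", b, " has more planted genes than its size",
           call. = FALSE)
    }
    take <- want - length(pl)
    region_syms[[b]] <- c(pl, picked[seq_len(take) + offset])
    offset <- offset + take
  }

  member_syms <- unlist(region_syms, use.names = FALSE)
  member_mask <- rep(bits_to_mask(names(region_syms)),
                     lengths(region_syms))
  key_of <- stats::setNames(ids, syms)

  # tiers
  if (!is.null(high_tier_by_region)) {
    low_tiers <- setdiff(as.character(1:7), high_tiers)
    tier <- character(length(member_syms))
    for (b in unique(names(region_syms))) {
      idx <- which(rep(names(region_syms), lengths(region_syms)) == b)
      n_high <- as.integer(high_tier_by_region[b] %||% 0L)
      if (is.na(n_high)) n_high <- 0L
      if (n_high > length(idx)) {
        stop("high-tier plan for region ", b, " exceeds its size",
             call. = FALSE)
      }
      forced <- idx[member_syms[idx] %in% planted_high]
      if (length(forced) > n_high) {
        stop("region ", b, " has more planted high-tier genes than its ",
             "high-tier quota", call. = FALSE)
      }
      hi <- c(forced, sample(setdiff(idx, forced), n_high - length(forced)))
      tier[hi] <- sample(high_tiers, n_high, replace = TRUE)
      tier[setdiff(idx, hi)] <- sample(low_tiers, length(idx) - n_high,
                                       replace = TRUE)
    }
  } else {
    tier <- sample(names(spec$tier_fractions), length(member_syms),
                   replace = TRUE, prob = spec$tier_fractions)
  }
  syndromic <- stats::runif(length(member_syms)) < syndromic_rate
  syndromic[tier == "S"] <- TRUE

  ord <- sample(length(member_syms))  # shuffle so region order leaks nowhere
  candidates <- scored_gene_table(
    key = unname(key_of[member_syms[ord]]),
    symbol = member_syms[ord], tier = tier[ord],
    syndromic = syndromic[ord])

  categories <- lapply(seq_len(4), function(b) {
    in_cat <- bitwAnd(member_mask, bitwShiftL(1L, b - 1L)) > 0L
    gene_set(unname(key_of[member_syms[in_cat]]), CATEGORY_NAMES[[b]],
             symbols = member_syms[in_cat],
             provenance = list(list(source = "synthetic",
                                    n_symbols = sum(in_cat))))
  })
  names(categories) <- CATEGORY_NAMES

  list(candidates = candidates, categories = categories,
       truth = tibble::tibble(key = unname(key_of[member_syms]),
                              symbol = member_syms, mask = member_mask))
}

#' Specify a synthetic interaction table
#'
#' @param n_cross Number of cross-list pairs to draw.
#' @param n_within_primary,n_within_secondary Within-list pairs (these
#'   exercise the within-list-removal rule; they are never retained).
#' @param n_weakest Planted weakest-high-confidence pairs: every channel
#'   is drawn at or below the cutoff while the combined score, built by
#'   the noisy-OR forward model from several mid-range channels, exceeds
#'   it.
#' @param zero_inflation Named per-channel probability that a channel is
#'   silent (0) for a pair; textmining is least inflated by default.
#' @param beta_shape1,beta_shape2 Shape parameters of the scaled-beta
#'   score distribution of active channels (support `[0.15, 0.999]`).
#' @param prior Baseline interaction probability of the forward model.
#' @param cutoff Cutoff the ground-truth labels are computed against.
#' @return An object of class `interaction_spec`.
#' @export
interaction_spec <- function(n_cross, n_within_primary = 0,
                             n_within_secondary = 0, n_weakest = 0,
                             zero_inflation = c(
                               neighborhood = 0.95, fusion = 0.98,
                               cooccurrence = 0.95, coexpression = 0.7,
                               experimental = 0.8, database = 0.85,
                               textmining = 0.45, homology = 0.92),
                             beta_shape1 = 1.5, beta_shape2 = 3,
                             prior = 0.041, cutoff = 0.7) {
  stopifnot(all(zero_inflation >= 0 & zero_inflation <= 1),
            setequal(names(zero_inflation),
                     c(EVIDENCE_CHANNELS, "homology")),
            prior >= 0, prior < 1)
  structure(list(n_cross = n_cross, n_within_primary = n_within_primary,
                 n_within_secondary = n_within_secondary,
                 n_weakest = n_weakest, zero_inflation = zero_inflation,
                 beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
                 prior = prior, cutoff = cutoff),
            class = "interaction_spec")
}

# Independent re-derivation of the expected edge label; deliberately a
# plain scalar loop, separate from the vectorized classifier it checks.
truth_label <- function(channel_scores, combined, cutoff) {
  best <- ""
  best_score <- -1
  for (ch in CHANNEL_PRECEDENCE) {
    s <- channel_scores[[ch]]
    if (s > cutoff && s > best_score) {
      best <- ch
      best_score <- s
    }
  }
  if (nzchar(best)) list(label = best, score = best_score)
  else list(label = WEAKEST_LABEL, score = combined)
}

#' Generate a synthetic STRING-style interaction table with ground truth
#'
#' Draws channel scores per pair from zero-inflated scaled-beta
#' distributions, computes the combined score with the prior-corrected
#' noisy-OR forward model ([string_combine_score()]), and emits the
#' ground-truth retention flag and edge-type label alongside each
#' record.
#'
#' @param spec An [interaction_spec()].
#' @param primary,secondary Disjoint [gene_set()]s or key vectors.
#' @param seed Integer seed.
#' @return List with `interactions` (an [interaction_table()]) and
#'   `truth` (tibble `gene_a`, `gene_b`, `cross_list`, `retained`,
#'   `label`, `label_score`).
#' @export
generate_interactions <- function(spec, primary, secondary, seed = 1) {
  stopifnot(inherits(spec, "interaction_spec"))
  p <- sort_keys(set_keys(primary))
  s <- sort_keys(set_keys(secondary))
  if (length(intersect(p, s)) > 0) {
    stop("primary and secondary lists must be disjoint", call. = FALSE)
  }
  set.seed(substream_seed(seed, "interactions"))

  n_cross_possible <- length(p) * length(s)
  if (spec$n_cross + spec$n_weakest > n_cross_possible) {
    stop("requested more cross-list pairs than exist", call. = FALSE)
  }
  pick_pairs <- function(a, b, n, exclude = character(0)) {
    # sample distinct unordered pairs between two disjoint lists
    if (n == 0) return(tibble::tibble(gene_a = character(0),
                                      gene_b = character(0)))
    idx <- sample(length(a) * length(b),
                  min(length(a) * length(b), n * 3 + 10))
    ga <- a[(idx - 1) %% length(a) + 1]
    gb <- b[(idx - 1) %/% length(a) + 1]
    swap <- key_order_pairwise(ga, gb)
    tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
    pair <- paste(ga, gb, sep = "\r")
    keep <- !duplicated(pair) & !(pair %in% exclude) & ga != gb
    if (sum(keep) < n) stop("could not draw enough distinct pairs",
                            call. = FALSE)
    tibble::tibble(gene_a = ga[keep][seq_len(n)],
                   gene_b = gb[keep][seq_len(n)])
  }
  pick_within <- function(a, n) {
    if (n == 0 || length(a) < 2) {
      return(tibble::tibble(gene_a = character(0), gene_b = character(0)))
    }
    combs <- utils::combn(a, 2)
    if (n > ncol(combs)) stop("too many within-list pairs requested",
                              call. = FALSE)
    sel <- sample(ncol(combs), n)
    ga <- combs[1, sel]; gb <- combs[2, sel]
    swap <- key_order_pairwise(ga, gb)
    tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
    tibble::tibble(gene_a = ga, gene_b = gb)
  }

  cross <- pick_pairs(p, s, spec$n_cross)
  weak <- pick_pairs(p, s, spec$n_weakest,
                     exclude = paste(cross$gene_a, cross$gene_b,
                                     sep = "\r"))
  wp <- pick_within(p, spec$n_within_primary)
  ws <- pick_within(s, spec$n_within_secondary)

  chans <- c(EVIDENCE_CHANNELS, "homology")
  draw_scores <- function(n) {
    m <- matrix(0, n, length(chans), dimnames = list(NULL, chans))
    for (ch in chans) {
      active <- stats::runif(n) >= spec$zero_inflation[[ch]]
      m[active, ch] <- 0.15 + 0.849 *
        stats::rbeta(sum(active), spec$beta_shape1, spec$beta_shape2)
    }
    m
  }
  draw_weak_scores <- function(n) {
    # several mid-range channels, none above the cutoff, combined above it
    m <- matrix(0, n, length(chans), dimnames = list(NULL, chans))
    for (i in seq_len(n)) {
      repeat {
        k <- sample(4:6, 1)
        which_ch <- sample(EVIDENCE_CHANNELS, k)
        sc <- stats::runif(k, 0.5, spec$cutoff - 0.02)
        row <- stats::setNames(numeric(length(chans)), chans)
        row[which_ch] <- sc
        comb <- string_combine_score(row[EVIDENCE_CHANNELS],
                                     prior = spec$prior)
        if (comb > spec$cutoff) {
          m[i, ] <- row
          break
        }
      }
    }
    m
  }

  pairs <- dplyr::bind_rows(cross, weak, wp, ws)
  cross_flag <- c(rep(TRUE, nrow(cross) + nrow(weak)),
                  rep(FALSE, nrow(wp) + nrow(ws)))
  scores <- rbind(draw_scores(nrow(cross)), draw_weak_scores(nrow(weak)),
                  draw_scores(nrow(wp)), draw_scores(nrow(ws)))
  combined <- string_combine_score(scores[, EVIDENCE_CHANNELS,
                                          drop = FALSE],
                                   prior = spec$prior)

  df <- dplyr::bind_cols(pairs, tibble::as_tibble(scores),
                         tibble::tibble(combined = combined))
  interactions <- interaction_table(df)

  truth <- lapply(seq_len(nrow(pairs)), function(i) {
    lab <- truth_label(as.list(scores[i, ]), combined[[i]], spec$cutoff)
    tibble::tibble(gene_a = pairs$gene_a[[i]], gene_b = pairs$gene_b[[i]],
                   cross_list = cross_flag[[i]],
                   retained = cross_flag[[i]] &&
                     combined[[i]] > spec$cutoff,
                   label = lab$label, label_score = lab$score)
  })
  truth <- dplyr::bind_rows(truth)

  list(interactions = interactions, truth = truth)
}

#' Reference Venn-region cardinalities of the SFARI categorization
#'
#' Region cardinalities consistent with the published categorization of
#' the SFARI Gene release 01.15.2019 into the four mTOR/vitamin-D
#' functional classes: 1053 candidates of which 606 fall in at least one
#' category and 447 outside; per-category totals 258 (FMRP targets), 42
#' (mTOR network), 314 (mTOR-modulated), 223 (vitamin-D-sensitive); and
#' exactly 3 genes in all four categories. Only those marginal counts
#' are published; the interior region sizes here are one fixed solution
#' consistent with them, used as the package's synthetic study
#' conditions.
#'
#' `high_tier_by_region()` gives the companion per-region plan placing
#' 281 genes in the high tiers, 179 of them categorized and 1 in the
#' quadruple region.
#'
#' @return A [venn_spec()] (`reference_venn_spec`) or a named integer
#'   vector over mask bitstrings (`reference_high_tier_plan`).
#' @export
reference_venn_spec <- function() {
  venn_spec(c(
    "0000" = 447L,
    "1000" = 110L,  # FMRP only
    "0100" = 20L,   # mTOR network only
    "1100" = 5L,
    "0010" = 168L,  # mTOR-modulated only
    "1010" = 70L,
    "0110" = 10L,
    "1110" = 0L,
    "0001" = 113L,  # vitamin D only
    "1001" = 40L,
    "0101" = 4L,
    "1101" = 0L,
    "0011" = 33L,
    "1011" = 30L,
    "0111" = 0L,
    "1111" = 3L))
}

#' @rdname reference_venn_spec
#' @export
reference_high_tier_plan <- function() {
  c("0000" = 102L,
    "1000" = 35L, "0100" = 8L, "1100" = 2L, "0010" = 45L, "1010" = 22L,
    "0110" = 4L, "1110" = 0L, "0001" = 30L, "1001" = 12L, "0101" = 2L,
    "1101" = 0L, "0011" = 10L, "1011" = 8L, "0111" = 0L, "1111" = 1L)
}

# Fixture writers --------------------------------------------------------

#' Write synthetic fixtures in the dialects the readers consume
#'
#' `write_synonym_table()` emits the KEGG-style flat list;
#' `write_gene_list()` one symbol per line; `write_candidate_table()` the
#' SFARI-style CSV (`gene-symbol`, `gene-score`, syndromic flag folded
#' into the score as an `"S"` suffix); `write_interaction_table()` the
#' STRING detailed TSV dialect on the 0-1000 integer scale.
#'
#' @param table,symbols,candidates,interactions The object to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @name fixture_writers
NULL

#' @rdname fixture_writers
#' @export
write_synonym_table <- function(table, path) {
  stopifnot(inherits(table, "synonym_table"))
  lines <- vapply(seq_len(nrow(table$entries)), function(i) {
    sprintf("hsa:%s\t%s; synthetic gene %s",
            table$entries$gene_id[[i]],
            paste(table$entries$aliases[[i]], collapse = ", "),
            table$entries$primary_symbol[[i]])
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname fixture_writers
#' @export
write_gene_list <- function(symbols, path) {
  readr::write_lines(symbols, path)
  invisible(path)
}

#' @rdname fixture_writers
#' @export
write_candidate_table <- function(candidates, path) {
  stopifnot(inherits(candidates, "scored_gene_table"))
  score <- ifelse(candidates$tier == "S", "S",
                  paste0(candidates$tier,
                         ifelse(candidates$syndromic, "S", "")))
  readr::write_csv(tibble::tibble(`gene-symbol` = candidates$symbol,
                                  `gene-score` = score),
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname fixture_writers
#' @export
write_interaction_table <- function(interactions, path) {
  stopifnot(inherits(interactions, "interaction_table"))
  out <- tibble::tibble(protein1 = interactions$gene_a,
                        protein2 = interactions$gene_b)
  for (ch in c(EVIDENCE_CHANNELS, "homology")) {
    out[[ch]] <- as.integer(round(interactions[[ch]] * 1000))
  }
  out$combined_score <- as.integer(round(interactions$combined * 1000))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
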