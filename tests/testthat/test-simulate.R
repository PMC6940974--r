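test_that("the combined-score forward model obeys its algebraic identities", {
  # all channels silent: the prior itself
  expect_equal(string_combine_score(rep(0, 7), prior = 0.041), 0.041)
  # a single active channel passes through exactly
  for (s in c(0.2, 0.5, 0.83, 0.99)) {
    expect_equal(string_combine_score(c(s, 0, 0, 0, 0, 0, 0),
                                      prior = 0.041), s,
                 tolerance = 1e-12)
  }
  # adding evidence never lowers the combined score
  expect_gt(string_combine_score(c(0.6, 0.6, 0, 0, 0, 0, 0)),
            string_combine_score(c(0.6, 0, 0, 0, 0, 0, 0)))
  # matrix input, row-wise
  m <- rbind(c(0.9, rep(0, 6)), rep(0, 7))
  expect_equal(string_combine_score(m), c(0.9, 0.041), tolerance = 1e-12)
})

test_that("gene universes are reproducible and respect their rates", {
  u1 <- generate_gene_universe(100, alias_rate = 0.4,
                               ambiguity_rate = 0.1, seed = 99)
  u2 <- generate_gene_universe(100, alias_rate = 0.4,
                               ambiguity_rate = 0.1, seed = 99)
  expect_identical(u1$table$entries, u2$table$entries)

  # alias_rate = 0: exactly n resolvable symbols, none ambiguous
  u0 <- generate_gene_universe(100, alias_rate = 0, seed = 1)
  r <- normalize_symbols(u0$symbols, u0$table)
  expect_equal(length(r$resolved), 100)
  expect_equal(length(r$ambiguous), 0)

  expect_error(generate_gene_universe(10, alias_rate = 1.2), "\\[0, 1\\]")
})

test_that("ambiguous-alias counts fall within binomial bounds", {
  # each extra alias is shared with probability 0.05; over 50 seeds the
  # observed count must stay within the 99.9% binomial envelope
  for (seed in 1:50) {
    u <- generate_gene_universe(200, alias_rate = 0.8,
                                ambiguity_rate = 0.05, seed = seed)
    n_alias <- nrow(u$extra_aliases)
    suppressMessages(
      r <- normalize_symbols(unlist(u$table$entries$aliases), u$table))
    lo <- qbinom(0.0005, n_alias, 0.05)
    hi <- qbinom(0.9995, n_alias, 0.05)
    expect_gte(length(r$ambiguous), lo)
    expect_lte(length(r$ambiguous), hi)
    expect_equal(length(r$ambiguous), sum(u$extra_aliases$shared))
  }
})

test_that("generated categories invert the Venn partition exactly", {
  withr::local_seed(123)
  for (i in 1:20) {
    n_regions <- sample(3:10, 1)
    bits <- sample(mtornet:::mask_bits(0:15), n_regions)
    sizes <- stats::setNames(sample(0:40, n_regions, replace = TRUE), bits)
    u <- generate_gene_universe(sum(sizes) + 10, seed = i)
    g <- generate_categories(venn_spec(sizes), u, seed = i)
    vp <- venn_partition(assign_categories(g$candidates, g$categories))
    spec_full <- stats::setNames(integer(16), mtornet:::mask_bits(0:15))
    spec_full[bits] <- sizes
    expect_identical(unname(vp$region_counts), unname(spec_full))
  }
})

test_that("degenerate Venn specs generate the expected structure", {
  u <- generate_gene_universe(20, seed = 2)
  # only the quadruple region populated
  g <- generate_categories(venn_spec(c("1111" = 3)), u, seed = 2)
  asg <- assign_categories(g$candidates, g$categories)
  expect_equal(nrow(asg), 3)
  expect_true(all(asg$mask == 15L))
  # empty in-category regions: all genes uncategorized
  g0 <- generate_categories(venn_spec(c("0000" = 5)), u, seed = 2)
  asg0 <- assign_categories(g0$candidates, g0$categories)
  expect_true(all(asg0$mask == 0L))
  # spec exceeding the universe errors
  expect_error(generate_categories(venn_spec(c("1000" = 100)), u),
               "exceeds the universe")
})

test_that("planted genes land in their regions with their planned tiers", {
  u <- generate_gene_universe(60, seed = 4,
                              include_symbols = c("PTEN", "APC"))
  g <- generate_categories(
    venn_spec(c("1111" = 2, "1000" = 5, "0000" = 10)), u, seed = 4,
    planted = list("1111" = c("PTEN", "APC")),
    high_tier_by_region = c("1111" = 1, "1000" = 2, "0000" = 3),
    planted_high = "PTEN")
  asg <- assign_categories(g$candidates, g$categories)
  expect_equal(sort(asg$symbol[asg$mask == 15L]), c("APC", "PTEN"))
  expect_true(asg$tier[asg$symbol == "PTEN"] %in% c("1", "2", "3"))
  hi <- filter_tier(g$candidates, c("1", "2", "3"))
  expect_equal(nrow(hi), 6)
})

test_that("interaction generation is seed-deterministic with faithful truth labels", {
  p <- gene_set(as.character(1:25), "p")
  s <- gene_set(as.character(1001:1025), "s")
  spec <- interaction_spec(n_cross = 100, n_within_primary = 10,
                           n_within_secondary = 10, n_weakest = 5)
  g1 <- generate_interactions(spec, p, s, seed = 8)
  g2 <- generate_interactions(spec, p, s, seed = 8)
  expect_identical(g1$interactions, g2$interactions)
  expect_identical(g1$truth, g2$truth)

  # planted weakest pairs: no channel above the cutoff, combined above
  weak <- g1$truth[g1$truth$label == "weakest_high_confidence" &
                     g1$truth$retained, ]
  expect_gte(nrow(weak), 5)
  chans <- c("neighborhood", "fusion", "cooccurrence", "coexpression",
             "experimental", "database", "textmining", "homology")
  for (i in seq_len(nrow(weak))) {
    rec <- g1$interactions[
      g1$interactions$gene_a == weak$gene_a[i] &
        g1$interactions$gene_b == weak$gene_b[i], ]
    expect_true(all(unlist(rec[chans]) <= 0.7))
    expect_gt(rec$combined, 0.7)
  }

  # the recorded combined score is the forward model of the channels
  chans7 <- c("neighborhood", "fusion", "cooccurrence", "coexpression",
              "experimental", "database", "textmining")
  expect_equal(g1$interactions$combined,
               string_combine_score(as.matrix(g1$interactions[chans7])),
               tolerance = 1e-12)

  expect_error(generate_interactions(interaction_spec(n_cross = 10^6),
                                     p, s), "more cross-list pairs")
})

test_that("fixture writers round-trip through the package readers", {
  u <- generate_gene_universe(40, alias_rate = 0.5, seed = 31)
  syn_path <- withr::local_tempfile()
  write_synonym_table(u$table, syn_path)
  syn_back <- load_synonym_table(syn_path)
  expect_identical(syn_back$entries$gene_id, u$table$entries$gene_id)
  expect_identical(syn_back$entries$aliases, u$table$entries$aliases)

  g <- generate_categories(venn_spec(c("1000" = 10, "0000" = 5)), u,
                           seed = 31)
  cand_path <- withr::local_tempfile(fileext = ".csv")
  write_candidate_table(g$candidates, cand_path)
  back <- read_candidate_table(cand_path, table = u$table)
  expect_setequal(back$key, g$candidates$key)
  expect_identical(back$tier[match(g$candidates$symbol, back$symbol)],
                   g$candidates$tier)

  gi <- generate_interactions(interaction_spec(n_cross = 30),
                              gene_set(as.character(1:10), "p"),
                              gene_set(as.character(101:110), "s"),
                              seed = 31)
  int_path <- withr::local_tempfile(fileext = ".tsv")
  write_interaction_table(gi$interactions, int_path)
  ib <- read_interactions(int_path)
  expect_equal(nrow(ib), nrow(gi$interactions))
  expect_equal(ib$combined, round(gi$interactions$combined, 3),
               tolerance = 1e-9)

  # identical seeds produce byte-identical files
  p2 <- withr::local_tempfile()
  u_again <- generate_gene_universe(40, alias_rate = 0.5, seed = 31)
  write_synonym_table(u_again$table, p2)
  expect_identical(readLines(syn_path), readLines(p2))
})
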