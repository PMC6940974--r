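primary_set <- function(keys) gene_set(as.character(keys), "primary")
secondary_set <- function(keys) gene_set(as.character(keys), "secondary")

test_that("hub mapping and cluster labels follow the membership mask", {
  expect_equal(hubs_for_mask(1L), "FMRP")
  expect_equal(hubs_for_mask(2L), "MTOR")
  expect_equal(hubs_for_mask(4L), "MTOR")
  expect_equal(hubs_for_mask(6L), "MTOR")   # network + modulated: one hub
  expect_equal(hubs_for_mask(9L), c("FMRP", "VITD"))
  expect_equal(hubs_for_mask(15L), c("FMRP", "MTOR", "VITD"))

  expect_equal(cluster_for_mask(1L), "FMRP_TARGET")
  expect_equal(cluster_for_mask(2L), "HUB_ATTACHED")
  expect_equal(cluster_for_mask(9L), "FMRP_TARGET+VITD_SENSITIVE")
  expect_equal(cluster_for_mask(13L),
               "FMRP_TARGET+MTOR_MODULATED+VITD_SENSITIVE")
  expect_error(cluster_for_mask(0L), "mask 0")
})

test_that("core layer gives one edge per touched hub; count matches enumeration", {
  asg <- assignment_from_masks(c(9, 2, 15))
  core <- build_core_layer(asg)
  expect_equal(nrow(core$edges), 2 + 1 + 3)
  g9 <- core$edges[core$edges$from == asg$key[1], ]
  expect_setequal(g9$to, c("FMRP", "VITD"))
  expect_equal(core$nodes$cluster[core$nodes$id == asg$key[2]],
               "HUB_ATTACHED")

  # brute-force enumeration over all 15 nonzero masks
  all_masks <- assignment_from_masks(1:15)
  core_all <- build_core_layer(all_masks)
  expected <- sum(vapply(1:15, function(m) length(hubs_for_mask(m)),
                         integer(1)))
  expect_equal(nrow(core_all$edges), expected)

  expect_error(build_core_layer(assignment_from_masks(c(1, 0))), "mask 0")

  # empty assignment: hubs only, no edges
  empty <- build_core_layer(assignment_from_masks(integer(0)))
  expect_equal(nrow(empty$edges), 0)
  expect_equal(sum(empty$nodes$type == "hub"), 3)
})

test_that("cross-list filtering keeps exactly qualifying between-list pairs", {
  tab <- interaction_table(tibble::tibble(
    gene_a = c("1", "2", "1001", "3"),
    gene_b = c("1001", "1002", "1002", "4"),
    neighborhood = 0, fusion = 0, cooccurrence = 0, coexpression = 0,
    experimental = 0, database = 0, textmining = 0, homology = 0,
    combined = c(0.71, 0.70, 0.99, 0.95)))
  p <- primary_set(1:10)
  s <- secondary_set(1001:1010)
  kept <- filter_cross_list(tab, p, s, cutoff = 0.7)
  # 0.71 above cutoff kept; 0.70 at the boundary removed under the
  # strict "more than" reading; within-secondary 0.99 removed; 3-4 is
  # within-primary and removed
  expect_equal(nrow(kept), 1)
  expect_equal(kept$gene_a, "1")
  # inclusive boundary retains the 0.70 pair as well
  expect_equal(nrow(filter_cross_list(tab, p, s, 0.7, inclusive = TRUE)), 2)
  expect_error(filter_cross_list(tab, primary_set(1:5),
                                 secondary_set(5:8), 0.7), "overlap")
})

test_that("raising the cutoff never increases the retained edge count", {
  p <- primary_set(1:30)
  s <- secondary_set(1001:1030)
  gi <- generate_interactions(interaction_spec(n_cross = 200), p, s,
                              seed = 19)
  ns <- vapply(seq(0.3, 0.95, by = 0.05), function(cut) {
    nrow(filter_cross_list(gi$interactions, p, s, cutoff = cut))
  }, integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("edges are labelled by their strongest qualifying channel", {
  # homology outranks a qualifying experimental score
  e <- classify_edges(record_with(experimental = 0.75, homology = 0.82,
                                  combined = 0.8))
  expect_equal(e$label, "homology")
  expect_equal(e$label_score, 0.82)

  # single qualifying channel
  e2 <- classify_edges(record_with(textmining = 0.9, combined = 0.9))
  expect_equal(e2$label, "textmining")

  # no channel above the cutoff but combined above it
  e3 <- classify_edges(record_with(textmining = 0.6, coexpression = 0.6,
                                   database = 0.55, combined = 0.74))
  expect_equal(e3$label, "weakest_high_confidence")
  expect_equal(e3$label_score, 0.74)

  # a tie at the maximum uses the fixed precedence (database first)
  e4 <- classify_edges(record_with(database = 0.8, textmining = 0.8,
                                   combined = 0.85))
  expect_equal(e4$label, "database")

  # records that failed the combined cutoff must not be classified
  expect_error(classify_edges(record_with(combined = 0.5)), "cutoff")
})

test_that("edge-type partition invariant holds on generated tables", {
  p <- primary_set(1:40)
  s <- secondary_set(1001:1040)
  gi <- generate_interactions(
    interaction_spec(n_cross = 150, n_weakest = 10), p, s, seed = 23)
  kept <- classify_edges(filter_cross_list(gi$interactions, p, s, 0.7))
  chans <- c("neighborhood", "fusion", "cooccurrence", "coexpression",
             "experimental", "database", "textmining", "homology")
  for (i in seq_len(nrow(kept))) {
    if (kept$label[i] == "weakest_high_confidence") {
      expect_true(all(unlist(kept[i, chans]) <= 0.7))
      expect_gt(kept$combined[i], 0.7)
    } else {
      expect_gt(kept$label_score[i], 0.7)
      expect_equal(kept$label_score[i],
                   max(unlist(kept[i, chans])[unlist(kept[i, chans]) > 0.7]))
    }
  }
})

test_that("placement follows the touched-cluster rules, independent of edge order", {
  cluster_of <- c("10" = "FMRP_TARGET", "11" = "VITD_SENSITIVE",
                  "12" = "MTOR_MODULATED", "13" = "HUB_ATTACHED",
                  "14" = "FMRP_TARGET+VITD_SENSITIVE")
  edges_to <- function(partners) {
    interaction_table(tibble::tibble(
      gene_a = "2001", gene_b = partners,
      neighborhood = 0, fusion = 0, cooccurrence = 0, coexpression = 0,
      experimental = 0, database = 0, textmining = 0.9, homology = 0,
      combined = 0.9))
  }
  p1 <- placement_for_gene("2001", edges_to("10"), cluster_of)
  expect_equal(p1$placement, "NEAR_CLUSTER(FMRP_TARGET)")
  p2 <- placement_for_gene("2001", edges_to(c("10", "11")), cluster_of)
  expect_equal(p2$placement, "BETWEEN(FMRP_TARGET,VITD_SENSITIVE)")
  # permuting the edges changes nothing
  p2r <- placement_for_gene("2001", edges_to(c("11", "10")), cluster_of)
  expect_equal(p2, p2r)
  p3 <- placement_for_gene("2001", edges_to(c("10", "11", "12")),
                           cluster_of)
  expect_equal(p3$placement, "CENTER")
  # hub-attached partners only: settled near the MTOR core element
  p4 <- placement_for_gene("2001", edges_to("13"), cluster_of)
  expect_equal(p4$placement, "NEAR_CORE(MTOR)")
  # hub-attached mixed with a cluster counts as touching mTOR-modulated
  p5 <- placement_for_gene("2001", edges_to(c("13", "10")), cluster_of)
  expect_equal(p5$placement, "BETWEEN(FMRP_TARGET,MTOR_MODULATED)")
  expect_error(placement_for_gene("2001", edges_to("10")[0, ], cluster_of),
               "unconnected")
})

test_that("a unique gene touching six clusters becomes the network center", {
  # primary genes covering six distinct clusters plus extras
  masks <- c(1, 4, 8, 5, 9, 12, 13)
  prim <- assignment_from_masks(masks, keys = as.character(101:107))
  core <- build_core_layer(prim)
  mk_edges <- function(sec, partners) {
    tibble::tibble(gene_a = sec, gene_b = partners,
                   neighborhood = 0, fusion = 0, cooccurrence = 0,
                   coexpression = 0, experimental = 0, database = 0,
                   textmining = 0.95, homology = 0, combined = 0.95)
  }
  tab <- interaction_table(dplyr::bind_rows(
    mk_edges("2001", as.character(101:106)),  # six clusters
    mk_edges("2002", as.character(c(101, 102, 103)))))
  m <- build_full_network(core, secondary_set(c(2001, 2002)), tab)
  pl <- m$nodes$placement[m$nodes$id == "2001"]
  expect_equal(pl, "NETWORK_CENTER")
  expect_equal(m$nodes$placement[m$nodes$id == "2002"], "CENTER")

  # two genes tied at six touched clusters: no unique maximum, both CENTER
  tab2 <- interaction_table(dplyr::bind_rows(
    mk_edges("2001", as.character(101:106)),
    mk_edges("2002", as.character(101:106))))
  m2 <- build_full_network(core, secondary_set(c(2001, 2002)), tab2)
  sec2 <- !is.na(m2$nodes$list) & m2$nodes$list == "secondary"
  expect_setequal(m2$nodes$placement[sec2], "CENTER")
})

test_that("the full network separates layers, counts and unconnected genes", {
  prim <- assignment_from_masks(c(1, 8, 5), keys = as.character(101:103))
  core <- build_core_layer(prim)
  mk <- function(a, b, combined) {
    tibble::tibble(gene_a = a, gene_b = b, neighborhood = 0, fusion = 0,
                   cooccurrence = 0, coexpression = 0, experimental = 0,
                   database = 0, textmining = combined, homology = 0,
                   combined = combined)
  }
  tab <- interaction_table(dplyr::bind_rows(
    mk("2001", "101", 0.9),
    mk("2002", "102", 0.75),
    mk("2003", "103", 0.5),     # below cutoff
    mk("2004", "2005", 0.99)))  # within-secondary, removed
  m <- build_full_network(core, secondary_set(2001:2005), tab)
  expect_equal(m$report$n_connected_secondary, 2)
  expect_equal(m$report$n_secondary_edges, 2)
  expect_setequal(m$unconnected, c("2003", "2004", "2005"))
  expect_equal(m$report$total_connected, 3 + 2)
  expect_equal(m$report$percent_connected, percent_half_up(5, 8))

  # no residual genes: report equals core stats
  m0 <- build_full_network(core, secondary_set(integer(0)), tab[0, ])
  expect_equal(m0$report$n_connected_secondary, 0)
  expect_equal(m0$report$total_connected, 3)

  # every residual-residual pair strong, no cross-list pair qualifies
  tab_ss <- interaction_table(dplyr::bind_rows(
    mk("2001", "2002", 0.99), mk("2001", "2003", 0.99)))
  m_ss <- build_full_network(core, secondary_set(2001:2003), tab_ss)
  expect_equal(m_ss$report$n_connected_secondary, 0)
})

test_that("networks export to SIF, GraphML and attribute tables", {
  prim <- assignment_from_masks(c(1, 9), keys = c("101", "102"))
  core <- build_core_layer(prim)
  tab <- record_with(gene_a = "101", gene_b = "2001", textmining = 0.9,
                     combined = 0.9)
  m <- build_full_network(core, secondary_set(2001), tab)

  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(m, sif)
  lines <- readLines(sif)
  expect_length(lines, nrow(m$edges))
  expect_true(any(grepl("^101\ttextmining\t2001$", lines)))

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(m, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(m$nodes))
  expect_equal(igraph::ecount(g), nrow(m$edges))
  expect_true("placement" %in% igraph::vertex_attr_names(g))

  np <- withr::local_tempfile(fileext = ".tsv")
  ep <- withr::local_tempfile(fileext = ".tsv")
  write_attribute_tables(m, np, ep)
  nodes <- readr::read_tsv(np, show_col_types = FALSE)
  expect_true(all(c("cluster", "placement", "mask_bits") %in% names(nodes)))
})

test_that("interaction tables canonicalize pairs and auto-detect the score scale", {
  df <- tibble::tibble(
    gene_a = c("1005", "7"), gene_b = c("3", "7"),
    neighborhood = 0, fusion = 0, cooccurrence = 0, coexpression = 0,
    experimental = c(850, 0), database = 0, textmining = c(0, 900),
    homology = 0, combined = c(851, 901))
  tab <- interaction_table(df)   # self-pair dropped, scale /1000
  expect_equal(nrow(tab), 1)
  expect_equal(tab$gene_a, "3")  # numeric-aware canonical order
  expect_equal(tab$combined, 0.851)
  dup <- dplyr::bind_rows(df[1, ], df[1, ])
  expect_error(interaction_table(dup), "duplicate")
})

test_that("STRING-style exports read through the column-name map", {
  tmp <- withr::local_tempfile()
  writeLines(c(
    "protein1\tprotein2\tneighborhood\tfusion\tcooccurence\tcoexpression\texperiments\tdatabases\ttextmining\thomology\tcombined_score",
    "9\t4\t0\t0\t0\t0\t800\t0\t300\t0\t820"), tmp)
  tab <- read_interactions(tmp)
  expect_equal(tab$gene_a, "4")
  expect_equal(tab$experimental, 0.8)
  expect_equal(tab$cooccurrence, 0)
  expect_equal(tab$combined, 0.82)
})
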