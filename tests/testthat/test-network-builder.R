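toy_tables <- function() {
  de_snc <- tibble::tibble(
    feature_id = c("mir-1", "mir-2", "mir-3", "mir-4"),
    direction = c("up", "down", "up", "ns"),
    p_value = c(0.001, 0.01, 0.02, 0.5),
    fold_change = c(2.5, 0.4, 1.8, 1.0)
  )
  de_mrna <- tibble::tibble(
    feature_id = sprintf("Gene%d", 1:6),
    direction = c("down", "down", "up", "up", "ns", "down"),
    p_value = c(0.001, 0.002, 0.003, 0.004, 0.6, 0.005),
    fold_change = c(0.3, 0.4, 3, 4, 1, 0.2)
  )
  pairs <- tidyr::crossing(
    sncrna_id = de_snc$feature_id, utr_id = de_mrna$feature_id
  ) |>
    dplyr::mutate(best_score = 150, n_sites = 1L)
  list(snc = de_snc, mrna = de_mrna, pairs = pairs)
}

test_that("pair filter keeps exactly the anti-correlated predicted pairs", {
  t <- toy_tables()
  edges <- pair_filter(t$snc, t$mrna, t$pairs)
  want <- oracle_pair_filter(t$snc, t$mrna, as.data.frame(t$pairs))
  expect_equal(nrow(edges), nrow(want))
  expect_setequal(
    paste(edges$regulator, edges$target),
    paste(want$sncrna_id, want$utr_id)
  )
  # up regulator with up target is excluded
  expect_false(any(edges$regulator_direction == edges$target_direction))
  # ns features never appear
  expect_false("mir-4" %in% edges$regulator)
  expect_false("Gene5" %in% edges$target)
  # 3 DE regulators x their anti-correlated targets: up mirs get the 3 down
  # genes, the down mir gets the 2 up genes
  expect_equal(nrow(edges), 2 * 3 + 1 * 2)
  # output is a subset of the predicted pairs (monotonicity)
  expect_true(all(
    paste(edges$regulator, edges$target) %in%
      paste(t$pairs$sncrna_id, t$pairs$utr_id)
  ))
  # ids missing from DE tables are dropped with a warning
  extra <- dplyr::bind_rows(
    t$pairs,
    tibble::tibble(sncrna_id = "ghost", utr_id = "Gene1",
      best_score = 150, n_sites = 1L)
  )
  expect_warning(pair_filter(t$snc, t$mrna, extra), "dropped")
})

test_that("network construction populates attributes and degrees", {
  t <- toy_tables()
  edges <- pair_filter(t$snc, t$mrna, t$pairs)
  g <- build_network(edges, t$snc, t$mrna,
    tf_list = "Gene1", regulator_type = "miRNA"
  )
  nodes <- tidy(g)
  # brute-force incidence count
  for (id in nodes$id) {
    expect_equal(
      nodes$degree[nodes$id == id],
      sum(edges$regulator == id) + sum(edges$target == id)
    )
  }
  expect_equal(sum(nodes$degree), 2 * nrow(edges))
  expect_true(nodes$is_tf[nodes$id == "Gene1"])
  expect_equal(sum(nodes$is_tf), 1)
  expect_equal(nodes$p_value[nodes$id == "mir-1"], 0.001)
  expect_setequal(unique(nodes$node_type), c("miRNA", "mRNA"))
  gl <- glance(g)
  expect_equal(gl$n_edges, nrow(edges))
  expect_equal(gl$n_regulators + gl$n_targets, gl$n_nodes)
  # empty edge set gives an empty graph
  g0 <- build_network(edges[0, ])
  expect_equal(igraph::vcount(g0), 0)
  # bipartite violations are rejected
  bad <- tibble::tibble(
    regulator = c("mir-1", "GeneX"), target = c("GeneX", "Gene2"),
    regulator_direction = "up", target_direction = "down", score = 150
  )
  expect_error(build_network(bad), "bipartite")
  self <- tibble::tibble(
    regulator = "mir-1", target = "mir-1",
    regulator_direction = "up", target_direction = "down", score = 150
  )
  expect_error(build_network(self), "bipartite")
})

test_that("hub ranking orders by degree then p-value then id", {
  # planted hub with degree 10 against others with <= 3
  edges <- tibble::tibble(
    regulator = c(rep("hub", 10), rep("mir-x", 3), rep("mir-y", 3)),
    target = c(sprintf("G%d", 1:10), sprintf("G%d", 1:3), sprintf("G%d", 4:6)),
    regulator_direction = "up", target_direction = "down", score = 150
  )
  de_snc <- tibble::tibble(
    feature_id = c("hub", "mir-x", "mir-y"),
    p_value = c(0.04, 0.001, 0.01), fold_change = 2, direction = "up"
  )
  g <- build_network(edges, de_snc, regulator_type = "miRNA")
  ranked <- hub_ranking(g, k = 3)
  expect_equal(ranked$id[1], "hub")
  # degree tie between mir-x and mir-y: lower p first
  expect_equal(ranked$id[2:3], c("mir-x", "mir-y"))
  # k larger than the regulator count returns everything
  expect_equal(nrow(hub_ranking(g, k = 50)), 3)
  expect_error(hub_ranking(g, k = 0), "positive")
})

test_that("TF overlap between the two networks is an id intersection", {
  tf_a <- c("Mybl1", "Fos", "Giot1", "Arid4b", "Zfp347", "Gabpa")
  tf_b <- c("Mybl1", "Fos", "Nr4a1", "Pbrm1", "Lin28a", "Gabpa")
  # both six-TF sets ship as a fixture
  fixture <- readLines(
    system.file("extdata", "tf_list.txt", package = "trfnet")
  )
  expect_true(all(c(tf_a, tf_b) %in% fixture))
  make_g <- function(tfs) {
    edges <- tibble::tibble(
      regulator = "mir-1", target = tfs,
      regulator_direction = "up", target_direction = "down", score = 150
    )
    build_network(edges, tf_list = tfs)
  }
  expect_equal(
    tf_overlap(make_g(tf_a), make_g(tf_b)),
    c("Fos", "Gabpa", "Mybl1")
  )
  expect_equal(tf_overlap(make_g(c("A1", "B1")), make_g(c("C1", "D1"))),
    character(0))
  expect_equal(tf_overlap(make_g(tf_a), make_g(tf_a)), sort(tf_a))
})

test_that("merging unions nodes and edges and recomputes degree", {
  mk <- function(reg, targets, type) {
    edges <- tibble::tibble(
      regulator = reg, target = targets,
      regulator_direction = "up", target_direction = "down", score = 150
    )
    build_network(edges, regulator_type = type)
  }
  a <- mk("mir-1", c("GeneA", "GeneB"), "miRNA")
  b <- mk("tRF3-Thr-AGT", c("GeneB", "GeneC"), "tRF/tiRNA")
  m <- merge_networks(a, b)
  nodes <- tidy(m)
  # shared mRNA merges by id; its degree is the sum across networks
  expect_equal(sum(nodes$id == "GeneB"), 1)
  expect_equal(nodes$degree[nodes$id == "GeneB"], 2)
  expect_equal(igraph::ecount(m), 4)
  expect_equal(sum(nodes$degree), 2 * igraph::ecount(m))
  # disjoint graphs are additive
  c_g <- mk("mir-9", "GeneZ", "miRNA")
  expect_equal(
    igraph::vcount(merge_networks(a, c_g)),
    igraph::vcount(a) + igraph::vcount(c_g)
  )
  # self-merge is idempotent
  mm <- merge_networks(a, a)
  expect_equal(igraph::vcount(mm), igraph::vcount(a))
  expect_equal(igraph::ecount(mm), igraph::ecount(a))
  # conflicting attributes for a shared node are rejected
  b_conflict <- mk("tRF3-Thr-AGT", c("GeneB", "GeneC"), "tRF/tiRNA")
  igraph::V(b_conflict)$is_tf[igraph::V(b_conflict)$name == "GeneB"] <- TRUE
  expect_error(merge_networks(a, b_conflict), "GeneB")
})

test_that("network exports are readable interchange files", {
  t <- toy_tables()
  edges <- pair_filter(t$snc, t$mrna, t$pairs)
  g <- build_network(edges, t$snc, t$mrna, tf_list = "Gene1",
    regulator_type = "miRNA")
  sif <- tempfile(fileext = ".sif")
  write_sif(g, sif)
  lines <- readLines(sif)
  expect_length(lines, nrow(edges))
  expect_true(all(grepl("\ttargets\t", lines)))
  gml <- tempfile(fileext = ".graphml")
  write_network_graphml(g, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), nrow(edges))
  expect_setequal(igraph::V(back)$name, tidy(g)$id)
})
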