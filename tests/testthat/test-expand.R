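test_that("link communities resolve canonical overlapping structures", {
  # two triangles sharing one vertex: two clusters, shared vertex in both
  g <- igraph::graph_from_edgelist(
    rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(4, 5), c(1, 5)),
    directed = FALSE)
  igraph::V(g)$name <- paste0("P", 1:5)
  cs <- link_communities(g)
  expect_equal(length(cs$edge_sets), 2)
  expect_true(all(vapply(cs$vertex_sets, function(v) "P1" %in% v, TRUE)))

  # a single clique is one cluster holding every edge
  g2 <- igraph::make_full_graph(5)
  igraph::V(g2)$name <- paste0("Q", 1:5)
  cs2 <- link_communities(g2)
  expect_equal(length(cs2$edge_sets), 1)
  expect_equal(length(cs2$edge_sets[[1]]), 10)

  # edge sets always partition the edge set
  set.seed(31)
  for (rep in 1:5) {
    gr <- igraph::sample_gnp(10, 0.35)
    igraph::V(gr)$name <- paste0("R", 1:10)
    csr <- link_communities(gr)
    expect_equal(sum(lengths(csr$edge_sets)), igraph::ecount(gr))
    ids <- sort(unlist(csr$edge_sets))
    expect_equal(ids, seq_len(igraph::ecount(gr)))
  }

  # edgeless graph: empty cluster set
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g0)$name <- c("a", "b", "c")
  expect_equal(length(link_communities(g0)$edge_sets), 0)
})

test_that("the mean-degree rule selects exactly the dense cluster", {
  # 4-clique (mean degree 3) + pendant 4-chain; graph mean degree
  # 2*10/8 = 2.5; the chain part (2*4/5 = 1.6) must be rejected
  clique <- t(combn(1:4, 2))
  chain <- rbind(c(4, 5), c(5, 6), c(6, 7), c(7, 8))
  g <- igraph::graph_from_edgelist(rbind(clique, chain), directed = FALSE)
  igraph::V(g)$name <- paste0("P", 1:8)
  cs <- select_dense_clusters(link_communities(g))
  expect_equal(cs$graph_mean_degree, 2.5)
  sel <- which(cs$selected)
  expect_equal(length(sel), 1)
  expect_equal(sort(cs$vertex_sets[[sel]]), paste0("P", 1:4))
  expect_equal(cs$mean_degree[sel], 3)

  # boundary: a regular graph whose single cluster is the whole graph is
  # never selected (strict inequality)
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- paste0("r", 1:6)
  csr <- select_dense_clusters(link_communities(ring))
  whole <- lengths(csr$edge_sets) == igraph::ecount(ring)
  expect_false(any(csr$selected[whole]))

  # empty cluster set passes through
  g0 <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(g0)$name <- c("x", "y")
  expect_equal(length(select_dense_clusters(link_communities(g0))$selected), 0)
})

test_that("hypergeometric enrichment matches direct combinatorial evaluation", {
  # term held by all 5 cluster proteins and only them among 100
  cluster <- paste0("C", 1:5)
  bg <- c(cluster, paste0("B", 1:95))
  go_map <- c(setNames(lapply(cluster, function(p) "GO:1"), cluster),
              setNames(lapply(paste0("B", 1:95), function(p) "GO:2"),
                       paste0("B", 1:95)))
  enr <- go_enrichment(cluster, go_map, bg)
  row <- enr[enr$term == "GO:1", ]
  expect_equal(row$p, 1 / choose(100, 5), tolerance = 1e-12)
  expect_true(row$enriched)

  # a term with identical prevalence inside and outside is not enriched
  go_map2 <- setNames(lapply(bg, function(p) "GO:3"), bg)
  enr2 <- go_enrichment(cluster, go_map2, bg)
  expect_false(enr2$enriched[enr2$term == "GO:3"])
  expect_equal(enr2$p[enr2$term == "GO:3"], 1)

  # BH adjustment: q >= p, and q non-decreasing after sorting by p
  set.seed(41)
  go_map3 <- setNames(lapply(bg, function(p) {
    sample(paste0("GO:", 1:8), 3)
  }), bg)
  enr3 <- go_enrichment(cluster, go_map3, bg)
  expect_true(all(enr3$q >= enr3$p - 1e-15))
  expect_true(!is.unsorted(enr3$q[order(enr3$p)]))

  expect_error(go_enrichment(cluster, go_map, character()), "empty")
  expect_error(go_enrichment(c(cluster, "ZZ"), go_map, bg), "subset")
})

test_that("label permutation keeps the enrichment false-positive rate in check", {
  set.seed(42)
  bg <- paste0("B", 1:80)
  terms <- paste0("GO:", 1:12)
  go_map <- setNames(lapply(bg, function(p) sample(terms, 4)), bg)
  fp <- 0
  n_perm <- 200
  for (k in seq_len(n_perm)) {
    perm_map <- setNames(go_map[sample(length(go_map))], bg)
    cl <- sample(bg, 8)
    enr <- go_enrichment(cl, perm_map, bg)
    fp <- fp + any(enr$enriched)
  }
  rate <- fp / n_perm
  se <- sqrt(0.05 * 0.95 / n_perm)
  expect_lte(rate, 0.05 + 2 * se)
})

test_that("expansion filters nominate the planted candidate and reject decoys", {
  cluster <- paste0("CL", 1:6)
  fx <- make_expansion_fixture(cluster, high_anomaly_proteins = cluster[1:4],
                               seed = 5)
  ppi_path <- withr::local_tempfile(fileext = ".txt")
  gaf_path <- withr::local_tempfile(fileext = ".gaf")
  write_fixtures(fx, ppi_path, gaf_path)
  ppi <- read_biogrid_tab3(ppi_path)
  go <- read_gaf(gaf_path)
  enr <- go_enrichment(cluster, go, union(names(go), cluster))
  enriched_terms <- enr$term[enr$enriched]
  expect_true(fx$enriched_term %in% enriched_terms)

  cands <- expand_cluster(cluster, cluster[1:4], ppi, enriched_terms, go)
  cand_row <- cands[cands$protein == fx$candidate, ]
  expect_equal(cand_row$anomaly_link_fraction, 0.75)
  expect_true(cand_row$pass)
  expect_false(cands$pass[cands$protein == fx$decoys[1]])  # 0.25 links
  expect_false(cands$pass[cands$protein == fx$decoys[2]])  # no shared term
  # candidate pool excludes the cluster itself
  expect_false(any(cands$protein %in% cluster))

  nom <- nominate_targets(list(`0.86` = cands, `0.92` = cands))
  expect_equal(nom$protein[nom$nominated], fx$candidate)
  expect_equal(nom$rho_support[nom$protein == fx$candidate], 2)

  # a candidate passing at only one penalty is not robust
  cands_fail <- cands
  cands_fail$pass <- FALSE
  nom1 <- nominate_targets(list(`0.86` = cands, `0.92` = cands_fail))
  expect_equal(sum(nom1$nominated), 0)
})

test_that("filter thresholds act monotonically", {
  cluster <- paste0("CL", 1:6)
  fx <- make_expansion_fixture(cluster, high_anomaly_proteins = cluster[1:4],
                               seed = 6)
  g <- igraph::simplify(igraph::graph_from_data_frame(fx$ppi_edges,
                                                      directed = FALSE))
  # raising the high quantile never enlarges the high-anomaly set
  scores <- setNames(seq_along(cluster) / length(cluster), cluster)
  h1 <- high_anomaly_proteins(scores, cluster, 0.5)
  h2 <- high_anomaly_proteins(scores, cluster, 0.9)
  expect_true(all(h2 %in% h1))

  # lowering the link threshold never shrinks the passing set
  c1 <- expand_cluster(cluster, cluster[1:4], g, fx$enriched_term,
                       fx$go_map, link_threshold = 0.5)
  c2 <- expand_cluster(cluster, cluster[1:4], g, fx$enriched_term,
                       fx$go_map, link_threshold = 0.2)
  expect_true(all(c1$protein[c1$pass] %in% c2$protein[c2$pass]))
})

test_that("interaction and annotation parsers enforce their dialects", {
  # duplicate and reciprocal rows collapse to one undirected edge
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(paste("#BioGRID Interaction ID",
                     "Official Symbol Interactor A",
                     "Official Symbol Interactor B", sep = "\t"),
               "1\tAAA\tBBB", "2\tAAA\tBBB", "3\tBBB\tAAA", "4\tAAA\tAAA"),
             p)
  g <- read_biogrid_tab3(p)
  expect_equal(igraph::ecount(g), 1)
  expect_setequal(igraph::V(g)$name, c("AAA", "BBB"))

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Symbol A\tSymbol B", "x\ty"), bad)
  expect_error(read_biogrid_tab3(bad), "Official Symbol Interactor A")

  # GAF: comment pragma skipped, NOT-qualified rows excluded
  gaf <- withr::local_tempfile(fileext = ".gaf")
  row <- function(sym, qual, term) {
    paste(c("DB", paste0("ID:", sym), sym, qual, term, "REF", "IDA", "",
            "P", sym, "", "protein", "taxon:9606", "20260101", "DB", "",
            ""), collapse = "\t")
  }
  writeLines(c("!gaf-version: 2.2", row("AAA", "enables", "GO:1"),
               row("AAA", "NOT|enables", "GO:2"),
               row("BBB", "involved_in", "GO:3")), gaf)
  go <- read_gaf(gaf)
  expect_equal(go$AAA, "GO:1")
  expect_equal(go$BBB, "GO:3")
})
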