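test_that("Spearman edges are rank-based, positive-only and tie-correct", {
  set.seed(20)
  x <- rnorm(30)
  v <- rbind(a = x, b = exp(x), c = x^3,        # monotone transforms
             d = -x,                             # perfect negative
             e = rnorm(30))
  net <- spearman_network(make_abund(v, scale = "log"),
                          fdr_cut = 0.01, rho_cut = 0.38)
  g <- net$graph
  # complete triangle among the monotone transforms, all weights 1
  expect_true(igraph::are_adjacent(g, "a", "b"))
  expect_true(igraph::are_adjacent(g, "a", "c"))
  expect_true(igraph::are_adjacent(g, "b", "c"))
  tri <- net$edges[net$edges$source %in% c("a", "b", "c") &
                     net$edges$target %in% c("a", "b", "c"), ]
  expect_equal(tri$rho, rep(1, 3))
  # the rho = -1 pair is excluded by the positive-only rule
  expect_false(igraph::are_adjacent(g, "a", "d"))
  expect_equal(igraph::degree(g, "d"), c(d = 0))
})

test_that("tie-heavy Spearman matches the brute-force midrank oracle", {
  midrank_rho <- function(x, y) {   # Pearson on midranks, from scratch
    mr <- function(v) {
      sapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2)
    }
    rx <- mr(x); ry <- mr(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  set.seed(21)
  x <- sample(c(0, 0, 0, 1, 1, 2), 20, replace = TRUE)
  y <- sample(c(0, 1, 1, 3), 20, replace = TRUE) + 0.3 * x
  v <- rbind(a = x, b = y, c = rnorm(20))
  net <- spearman_network(make_abund(v), fdr_cut = 1, rho_cut = -1)
  ab <- net$edges[(net$edges$source == "a" & net$edges$target == "b") |
                    (net$edges$source == "b" & net$edges$target == "a"), ]
  expect_equal(ab$rho, midrank_rho(x, y), tolerance = 1e-12)
})

test_that("constant features are excluded with a warning", {
  v <- rbind(a = rnorm(12), flat = rep(2, 12), b = rnorm(12))
  expect_warning(net <- spearman_network(make_abund(v), fdr_cut = 1,
                                         rho_cut = 0),
                 "constant")
  expect_false("flat" %in% igraph::V(net$graph)$name)
  expect_error(spearman_network(make_abund(matrix(rnorm(15), 3))),
               "at least 10")
})

test_that("the G(n, m) null has the exact size and expected clustering", {
  set.seed(22)
  g <- igraph::sample_gnm(100, 500)
  cmp <- er_null_compare(as_test_network(g), n_draws = 200, seed = 3)
  expect_true(all(attr(cmp, "null_ecount") == 500))
  # closed-form ER clustering: edge density 2m / (n (n-1))
  clus <- cmp[cmp$metric == "clustering", ]
  dens <- 2 * 500 / (100 * 99)
  expect_lt(abs(clus$null_mean - dens), 3 * clus$null_sd)
  # an ER graph is typically inside its own null envelope
  expect_lte(sum(cmp$outside_envelope), 1)
})

test_that("a planted-block network is markedly distinct from the ER null", {
  set.seed(23)
  g <- igraph::disjoint_union(
    igraph::make_full_graph(12), igraph::make_full_graph(12),
    igraph::make_full_graph(12))
  g <- igraph::add_edges(g, c(1, 13, 13, 25))   # sparse bridges
  cmp <- er_null_compare(as_test_network(g), n_draws = 100, seed = 2)
  expect_true(cmp$outside_envelope[cmp$metric == "clustering"])
  expect_true(attr(cmp, "markedly_distinct"))
  expect_error(er_null_compare(as_test_network(igraph::make_empty_graph(
    3, directed = FALSE))), "no edges")
})

test_that("Leiden finds canonical partitions and the exhaustive optimum", {
  # two 5-cliques joined by one edge split into the two cliques
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(5))
  g <- igraph::add_edges(g, c(1, 6))
  igraph::V(g)$name <- paste0("n", 1:10)
  part <- detect_communities(as_test_network(g), seed = 1)
  expect_equal(nrow(part$summary), 2)
  mem <- part$membership
  expect_length(unique(mem[1:5]), 1)
  expect_length(unique(mem[6:10]), 1)
  expect_false(mem[["n1"]] == mem[["n6"]])

  # 8-node graph: modularity equals the exhaustive optimum (4140 partitions)
  g8 <- igraph::disjoint_union(igraph::make_full_graph(4),
                               igraph::make_full_graph(4))
  g8 <- igraph::add_edges(g8, c(1, 5))
  igraph::V(g8)$name <- paste0("v", 1:8)
  part8 <- detect_communities(as_test_network(g8), seed = 1)
  best <- max(vapply(all_partitions(8), function(p) {
    igraph::modularity(g8, p)
  }, numeric(1)))
  expect_equal(part8$modularity, best, tolerance = 1e-12)

  # infinite-resolution limit: all singletons
  sing <- detect_communities(as_test_network(g8), resolution = 1e6, seed = 1)
  expect_equal(nrow(sing$summary), 8)
  expect_error(detect_communities(as_test_network(
    igraph::make_empty_graph(0, directed = FALSE))), "empty")
})

test_that("planted-block correlation networks are recovered at high ARI", {
  aris <- vapply(1:10, function(s) {
    set.seed(400 + s)
    n <- 60; sizes <- c(15, 15, 15)
    truth <- rep(1:3, sizes)
    f <- matrix(rnorm(3 * n), 3)
    v <- t(sapply(truth, function(b) {
      sqrt(0.7) * f[b, ] + sqrt(0.3) * rnorm(n)
    }))
    rownames(v) <- paste0("g", seq_len(nrow(v)))
    net <- spearman_network(make_abund(v, scale = "log"),
                            fdr_cut = 1e-4, rho_cut = 0.38)
    part <- detect_communities(net, seed = 1)
    mclust::adjustedRandIndex(part$membership[rownames(v)], truth)
  }, numeric(1))
  expect_true(all(aris >= 0.9))
})

test_that("degree hubs rank correctly with documented tie-breaks", {
  g <- igraph::make_star(10, mode = "undirected")
  igraph::V(g)$name <- paste0("n", 1:10)
  top <- centrality_rank(as_test_network(g), 0.1)
  expect_equal(top$node, "n1")

  # all degrees equal: lexicographic order decides
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- c("f", "b", "d", "a", "e", "c")
  top2 <- centrality_rank(as_test_network(ring), 0.5)
  expect_equal(top2$node, c("a", "b", "c"))

  # hubs are stable under edge-weight rescaling (degree uses counts)
  set.seed(24)
  v <- matrix(rnorm(20 * 25), 20)
  rownames(v) <- paste0("g", 1:20)
  net <- spearman_network(make_abund(v), fdr_cut = 1, rho_cut = 0)
  t1 <- centrality_rank(net, 0.3)$node
  net2 <- net
  igraph::E(net2$graph)$weight <- igraph::E(net2$graph)$weight * 7
  expect_equal(centrality_rank(net2, 0.3)$node, t1)
})

test_that("community scores drive clinical regression as designed", {
  set.seed(25)
  n <- 80
  grp <- factor(rep(c("noMetS", "MetS"), each = n / 2),
                levels = c("noMetS", "MetS"))
  # community members track the group label, plus unrelated features
  sig <- t(sapply(1:5, function(i) ifelse(grp == "MetS", 1, -1) +
                    rnorm(n, sd = 0.1)))
  noise <- matrix(rnorm(10 * n), 10)
  v <- rbind(sig, noise)
  rownames(v) <- paste0("g", 1:15)
  m <- make_abund(v, group = grp, scale = "log")
  net <- spearman_network(m, fdr_cut = 0.01, rho_cut = 0.38)
  part <- detect_communities(net, seed = 1)
  clin <- data.frame(group = grp,
                     vat = ifelse(grp == "MetS", 150, 75) + rnorm(n, sd = 20),
                     flat = 1)
  expect_warning(assoc <- community_clinical_assoc(part, m, clin),
                 "constant")
  hit <- assoc[assoc$variable == "group" & assoc$model == "logistic", ]
  hit <- hit[which.min(hit$q), ]
  expect_lt(hit$q, 0.01)
  expect_gt(hit$estimate, 0)
  expect_false("flat" %in% assoc$variable)
})

test_that("a singleton community's score is the member z-score", {
  set.seed(26)
  v <- matrix(rnorm(2 * 20), 2, dimnames = list(c("a", "b"), NULL))
  colnames(v) <- paste0("s", 1:20)
  m <- make_abund(v, scale = "log")
  part <- structure(list(membership = c(a = 1L, b = 2L),
                         summary = data.frame(community = 1:2, size = 1)),
                    class = "community_partition")
  sc <- lipidmets:::.community_scores(part, m)
  expect_equal(unname(sc[, "c1"]),
               unname((v["a", ] - mean(v["a", ])) / sd(v["a", ])))
})

test_that("feature-clinical association finds generating features only", {
  set.seed(27)
  n <- 100
  v <- matrix(rnorm(20 * n), 20, dimnames = list(paste0("g", 1:20), NULL))
  colnames(v) <- paste0("s", 1:n)
  m <- make_abund(v, scale = "log")
  vat <- 2 * v["g3", ] + rnorm(n, sd = 0.5)
  res <- feature_clinical_assoc(m, vat, q_cut = 0.01)
  expect_true(res$selected[res$unit == "g3"])
  expect_equal(res$model[1], "linear")

  # permuted response: usually nothing selected
  none <- vapply(1:5, function(s) {
    set.seed(500 + s)
    sum(feature_clinical_assoc(m, sample(vat), q_cut = 0.01)$selected)
  }, numeric(1))
  expect_gte(mean(none == 0), 0.8)

  # single feature: BH with m = 1 leaves q = p
  one <- feature_clinical_assoc(make_abund(v[1, , drop = FALSE],
                                           scale = "log"), vat)
  expect_equal(one$q, one$p)
})

test_that("hypergeometric enrichment matches first principles", {
  # fully contained term: p = 1 / choose(100, 10)
  bg <- paste0("x", 1:100)
  term <- bg[1:10]
  res <- ora_enrichment(term, list(t1 = term), bg)
  expect_equal(res$p, 1 / choose(100, 10), tolerance = 1e-12)

  # equal proportions inside and outside: no enrichment signal
  res2 <- ora_enrichment(bg[1:20], list(t1 = bg[seq(1, 100, by = 5)]), bg)
  expect_gte(res2$p, 0.5)

  expect_error(ora_enrichment("a", list(t = "a"), character(0)), "empty")
  expect_error(ora_enrichment("zzz", list(t = "a"), bg), "subset")
})

test_that("network writers emit loadable GraphML and edge lists", {
  set.seed(28)
  x <- rnorm(20)
  v <- rbind(a = x, b = x + rnorm(20, sd = 0.1), c = rnorm(20))
  net <- spearman_network(make_abund(v), fdr_cut = 0.05, rho_cut = 0.38)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), igraph::ecount(net$graph))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, tsv)
  el <- read.delim(tsv)
  expect_equal(names(el), c("source", "target", "weight"))
  expect_equal(nrow(el), igraph::ecount(net$graph))
})
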