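test_that("common network is the node and edge intersection", {
  n1 <- toy_network(a = c("g1", "g1", "g3"), b = c("g2", "g3", "g4"),
                    w = c(0.5, 0.6, 0.7))
  n2 <- toy_network(a = c("g1", "g2", "g3"), b = c("g2", "g5", "g4"),
                    w = c(0.9, 0.8, 0.5))
  com <- common_network(list(n1, n2))
  key <- paste(com$edges$node_a, com$edges$node_b)
  expect_setequal(key, c("g1 g2", "g3 g4"))
  # weight of a common edge is the mean across networks
  expect_equal(com$edges$weight[key == "g1 g2"], mean(c(0.5, 0.9)))
  expect_equal(com$edges$weight[key == "g3 g4"], mean(c(0.7, 0.5)))
  expect_error(common_network(list(n1)), ">= 2")
})

test_that("common-edge supporting miRNAs are the union across networks", {
  n1 <- toy_network("g1", "g2", supp = "miR_001,miR_003")
  n2 <- toy_network("g1", "g2", supp = "miR_002,miR_003")
  com <- common_network(list(n1, n2))
  expect_identical(com$edges$supporting_miRNAs, "miR_001,miR_002,miR_003")
})

test_that("specific network removes common edges and isolated nodes", {
  n1 <- toy_network(a = c("g1", "g1", "g3"), b = c("g2", "g3", "g4"))
  n2 <- toy_network(a = c("g1", "g5"), b = c("g2", "g6"))
  com <- common_network(list(n1, n2))
  spec <- specific_network(n1, com)
  key <- paste(spec$edges$node_a, spec$edges$node_b)
  expect_setequal(key, c("g1 g3", "g3 g4"))
  # g2's only edge was common, so it drops out of the specific node set
  expect_false("g2" %in% spec$nodes$gene)
  expect_identical(attr(spec, "node_difference"),
                   length(setdiff(n1$nodes$gene, com$nodes$gene)))
})

test_that("network set algebra holds on random networks", {
  set.seed(77)
  for (i in 1:25) {
    nets <- list(random_network(), random_network(), random_network())
    com <- common_network(nets)
    ck <- paste(com$edges$node_a, com$edges$node_b)
    for (net in nets) {
      pk <- paste(net$edges$node_a, net$edges$node_b)
      expect_true(all(ck %in% pk))                     # common is a subset
      spec <- specific_network(net, com)
      sk <- paste(spec$edges$node_a, spec$edges$node_b)
      expect_length(intersect(sk, ck), 0L)             # disjoint from common
      expect_identical(length(sk), length(pk) - length(intersect(pk, ck)))
    }
  }
})

test_that("MCL separates two triangles joined by nothing", {
  net <- toy_network(a = c("a1", "a1", "a2", "b1", "b1", "b2"),
                     b = c("a2", "a3", "a3", "b2", "b3", "b3"))
  ms <- mcl_cluster(net)
  expect_true(ms$converged)
  expect_length(ms$modules, 2L)
  expect_setequal(ms$modules[[1L]], c("a1", "a2", "a3"))
  expect_setequal(ms$modules[[2L]], c("b1", "b2", "b3"))
})

test_that("MCL splits two cliques across a weak bridge", {
  cl1 <- t(combn(paste0("a", 1:6), 2))
  cl2 <- t(combn(paste0("b", 1:6), 2))
  net <- toy_network(a = c(cl1[, 1], cl2[, 1], "a1"),
                     b = c(cl1[, 2], cl2[, 2], "b1"),
                     w = c(rep(1, nrow(cl1) + nrow(cl2)), 0.01))
  ms <- mcl_cluster(net)
  expect_length(ms$modules, 2L)
  expect_setequal(ms$modules[[1L]], paste0("a", 1:6))
  expect_setequal(ms$modules[[2L]], paste0("b", 1:6))
})

test_that("modules partition the node set and respect components", {
  set.seed(99)
  for (i in 1:10) {
    net <- random_network(n_nodes = 14, p_edge = 0.2)
    ms <- mcl_cluster(net)
    expect_setequal(unlist(ms$modules), net$nodes$gene)
    expect_identical(anyDuplicated(unlist(ms$modules)), 0L)
    # no module may span two connected components
    g <- igraph::graph_from_data_frame(net$edges[, c("node_a", "node_b")],
                                       directed = FALSE,
                                       vertices = net$nodes$gene)
    comp <- igraph::components(g)$membership
    for (m in ms$modules)
      expect_length(unique(comp[m]), 1L)
  }
})

test_that("MCL agrees with an independent dense reference implementation", {
  set.seed(123)
  for (i in 1:8) {
    net <- random_network(n_nodes = 12, p_edge = 0.3)
    ms <- mcl_cluster(net)
    got <- lapply(ms$modules, sort)
    ref <- reference_mcl(adjacency_of(net))
    norm <- function(mods) mods[order(vapply(mods, `[`, character(1), 1L))]
    expect_identical(unname(norm(got)), norm(ref))
  }
})

test_that("module ordering and naming are deterministic", {
  net <- toy_network(a = c("z1", "z1", "z2", "a1"), b = c("z2", "z3", "z3", "a2"))
  ms <- mcl_cluster(net)
  expect_identical(names(ms$modules), paste0("M", seq_along(ms$modules)))
  expect_true(all(diff(lengths(ms$modules)) <= 0))   # sorted by size, descending
})

test_that("lncRNA/circRNA module filter keeps only mixed modules", {
  net <- toy_network(a = c("a1", "a1", "a2", "b1", "b1", "b2"),
                     b = c("a2", "a3", "a3", "b2", "b3", "b3"),
                     classes = c(a1 = "mRNA", a2 = "lncRNA", a3 = "mRNA",
                                 b1 = "mRNA", b2 = "mRNA", b3 = "mRNA"))
  ms <- mcl_cluster(net)
  kept <- filter_lc_modules(ms)
  expect_length(kept$modules, 1L)
  expect_setequal(kept$modules[[1L]], c("a1", "a2", "a3"))
  expect_setequal(module_gene_union(kept, "mRNA"), c("a1", "a3"))
  expect_setequal(module_gene_union(kept), c("a1", "a2", "a3"))
})

test_that("clustering an empty network fails loudly", {
  nodes <- data.frame(gene = character(), class = character())
  edges <- data.frame(node_a = character(), node_b = character(),
                      class_a = character(), class_b = character(),
                      weight = numeric(), evidence = character(),
                      supporting_miRNAs = character())
  net <- cerna_network(nodes, edges, "empty", allow_isolated = TRUE)
  expect_error(mcl_cluster(net), "empty")
})

test_that("mcl_config validates inflation", {
  expect_error(mcl_config(inflation = 1), "inflation")
})
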