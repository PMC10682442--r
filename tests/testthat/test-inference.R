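# deterministic vectors with known correlation signs for rule-level tests
.trip_rows <- function(n = 30) {
  x <- seq_len(n) / n
  list(x = x,
       up1 = 2 * x + 0.01 * sin(seq_len(n)),
       up2 = 3 * x + 0.01 * cos(seq_len(n)),
       down = 2.2 - 2 * x + 0.01 * sin(2 * seq_len(n)),
       noise = 1 + 0.5 * rep(c(0.1, -0.1), length.out = n) * rep(c(1, 2, 3), length.out = n))
}

test_that("pearson_with_p matches cor.test", {
  set.seed(5)
  x <- rnorm(25); y <- x + rnorm(25)
  got <- pearson_with_p(x, y)
  ref <- cor.test(x, y)
  expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_error(pearson_with_p(x, y[1:10]), "equal length")
  expect_error(pearson_with_p(rep(1, 25), y), "constant")
})

test_that("db route requires validated pairs for both sponges", {
  v <- .trip_rows()
  rows <- list(miR_001 = v$down, mRNA_001 = v$up1, lncRNA_001 = v$up2)
  cls <- c(miR_001 = "miRNA", mRNA_001 = "mRNA", lncRNA_001 = "lncRNA")
  ds <- dataset_from_rows(rows, cls)

  full <- interaction_db(c("miR_001", "miR_001"), c("mRNA_001", "lncRNA_001"))
  e <- infer_db_edges(ds, full)
  expect_identical(nrow(e), 1L)
  expect_setequal(c(e$node_a, e$node_b), c("lncRNA_001", "mRNA_001"))
  expect_identical(e$evidence, "db-validated")
  expect_identical(e$supporting_miRNAs, "miR_001")
  expect_equal(e$weight, cor(v$up1, v$up2), tolerance = 1e-12)

  half <- interaction_db("miR_001", "mRNA_001")
  expect_identical(nrow(infer_db_edges(ds, half)), 0L)
})

test_that("correlation-only route covers circRNA pairs and nothing else", {
  v <- .trip_rows()
  rows <- list(miR_001 = v$down, circ_001 = v$up1, mRNA_001 = v$up2,
               lncRNA_001 = v$up1 + 0.02 * v$noise)
  cls <- c(miR_001 = "miRNA", circ_001 = "circRNA", mRNA_001 = "mRNA",
           lncRNA_001 = "lncRNA")
  ds <- dataset_from_rows(rows, cls)
  e <- infer_corr_only_edges(ds)
  expect_true(all(e$class_a == "circRNA" | e$class_b == "circRNA"))
  key <- paste(e$node_a, e$node_b)
  expect_true("circ_001 mRNA_001" %in% key)
  expect_true("circ_001 lncRNA_001" %in% key)
  expect_false("lncRNA_001 mRNA_001" %in% key)   # no circRNA endpoint
  expect_true(all(e$evidence == "correlation-only"))
})

test_that("a positive sponge pair without a negative mediator yields no edge", {
  v <- .trip_rows()
  # miRNA correlates POSITIVELY with the sponges: mediator screen must fail
  rows <- list(miR_001 = v$up1 + 0.02 * v$noise, circ_001 = v$up1, mRNA_001 = v$up2)
  cls <- c(miR_001 = "miRNA", circ_001 = "circRNA", mRNA_001 = "mRNA")
  expect_identical(nrow(infer_corr_only_edges(dataset_from_rows(rows, cls))), 0L)
})

test_that("anti-correlated sponges never form an edge", {
  v <- .trip_rows()
  rows <- list(miR_001 = v$noise, circ_001 = v$up1, mRNA_001 = v$down)
  cls <- c(miR_001 = "miRNA", circ_001 = "circRNA", mRNA_001 = "mRNA")
  expect_identical(nrow(infer_corr_only_edges(dataset_from_rows(rows, cls))), 0L)
})

test_that("constant genes are excluded with a warning, not an error", {
  v <- .trip_rows()
  rows <- list(miR_001 = v$down, circ_001 = v$up1, mRNA_001 = v$up2,
               mRNA_002 = rep(3, 30))
  cls <- c(miR_001 = "miRNA", circ_001 = "circRNA", mRNA_001 = "mRNA",
           mRNA_002 = "mRNA")
  expect_warning(e <- infer_corr_only_edges(dataset_from_rows(rows, cls)),
                 "constant")
  expect_false("mRNA_002" %in% c(e$node_a, e$node_b))
  expect_gte(nrow(e), 1L)
})

test_that("primary network matches the brute-force enumerator on small instances", {
  for (seed in 1:3) {
    cfg <- small_gen(seed, subtypes = c(A = 40L),
                     n_genes = c(mRNA = 15L, lncRNA = 8L, circRNA = 6L, miRNA = 8L))
    syn <- generate_synthetic(cfg)
    net <- build_primary_network(syn$datasets$A, syn$interactions)
    oracle <- oracle_primary_edges(syn$datasets$A, syn$interactions)
    got <- net$edges[order(net$edges$node_a, net$edges$node_b), ]
    expect_identical(paste(got$node_a, got$node_b),
                     paste(oracle$node_a, oracle$node_b))
    # identical supporting-miRNA sets per edge
    expect_identical(got$supporting_miRNAs, oracle$supp)
  }
})

test_that("primary network recovers every planted in-scope edge", {
  syn <- generate_synthetic(small_gen(21))
  net <- build_primary_network(syn$datasets$B, syn$interactions)
  keys <- paste(net$edges$node_a, net$edges$node_b)
  pe <- planted_edges(syn$truth, "B")
  expect_true(all(paste(pe$node_a, pe$node_b) %in% keys))
})

test_that("edge direction conventions: weight is the sponge-sponge correlation", {
  syn <- generate_synthetic(small_gen(22, subtypes = c(A = 50L)))
  net <- build_primary_network(syn$datasets$A, syn$interactions)
  e <- net$edges[1L, ]
  expect_equal(e$weight,
               cor(syn$datasets$A$values[e$node_a, ], syn$datasets$A$values[e$node_b, ]),
               tolerance = 1e-12)
  expect_true(all(net$edges$weight > 0.4))
})
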