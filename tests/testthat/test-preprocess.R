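make_pair <- function(m1, m2, classes = NULL) {
  rows1 <- lapply(seq_len(nrow(m1)), function(i) m1[i, ])
  names(rows1) <- rownames(m1)
  rows2 <- lapply(seq_len(nrow(m2)), function(i) m2[i, ])
  names(rows2) <- rownames(m2)
  cls <- classes %||% setNames(rep("mRNA", nrow(m1)), rownames(m1))
  list(A = dataset_from_rows(rows1, cls, "A"),
       B = dataset_from_rows(rows2, cls, "B"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("mean filter removes genes by pooled mean, not per-subtype mean", {
  # g_low is below threshold in A but its pooled mean across both is above
  m1 <- rbind(g_hi = rep(10, 4), g_low = rep(0.2, 4), g_gone = rep(0.1, 4))
  m2 <- rbind(g_hi = rep(10, 4), g_low = rep(1.2, 4), g_gone = rep(0.3, 4))
  ds <- make_pair(m1, m2)
  out <- filter_low_mean(ds, threshold = 0.5)
  expect_identical(out$removed, "g_gone")
  expect_setequal(rownames(out$datasets$A$values), c("g_hi", "g_low"))
  expect_setequal(rownames(out$datasets$B$values), c("g_hi", "g_low"))
})

test_that("mean filter boundary is strict: a gene exactly at threshold stays", {
  m <- rbind(g_at = rep(0.5, 4), g_below = rep(0.5 - 1e-9, 4))
  ds <- make_pair(m, m)
  out <- filter_low_mean(ds, threshold = 0.5)
  expect_identical(out$removed, "g_below")
})

test_that("variance filter uses pooled population variance", {
  m1 <- rbind(g_const = rep(2, 4), g_var = c(1, 2, 3, 4), g_shift = rep(1, 4))
  m2 <- rbind(g_const = rep(2, 4), g_var = c(2, 3, 1, 4), g_shift = rep(3, 4))
  ds <- make_pair(m1, m2)
  out <- filter_low_variance(ds, threshold = 1e-8)
  # g_shift is constant within each subtype but varies pooled: kept
  expect_identical(out$removed, "g_const")
  # hand-check the pooled population variance of g_var
  pooled <- c(m1["g_var", ], m2["g_var", ])
  v <- mean((pooled - mean(pooled))^2)
  expect_gt(v, 1e-8)
})

test_that("variance threshold 0 removes only exactly-constant genes", {
  m <- rbind(g_const = rep(5, 4), g_tiny = 5 + c(0, 1e-10, 0, -1e-10))
  ds <- make_pair(m, m)
  out <- filter_low_variance(ds, threshold = 0)
  expect_identical(out$removed, "g_const")
})

test_that("hierarchical outlier detection recovers planted outliers", {
  hits <- 0L; false_pos <- 0L
  for (seed in 1:5) {
    syn <- generate_synthetic(small_gen(seed, subtypes = c(A = 60L), n_outliers = 3L))
    res <- detect_outliers(syn$datasets$A)
    truth <- syn$truth$outliers$A
    hits <- hits + length(intersect(res$removed, truth))
    false_pos <- false_pos + length(setdiff(res$removed, truth))
  }
  expect_identical(hits, 15L)            # all 3 outliers found, all 5 seeds
  expect_lte(false_pos, 15L)             # false removals stay modest (<= 5%)
})

test_that("clean cohorts lose only a small fraction of samples", {
  removed <- integer(10)
  for (seed in 1:10) {
    syn <- generate_synthetic(small_gen(seed + 100, subtypes = c(A = 60L)))
    removed[seed] <- length(detect_outliers(syn$datasets$A)$removed)
  }
  # the height-based cut trims the loosest leaves even without planted
  # outliers; the false-removal rate must stay below 10% of the cohort
  expect_true(all(removed <= 6L))
  expect_lt(mean(removed) / 60, 0.1)
})

test_that("outlier detection validates its inputs", {
  ds <- dataset_from_rows(list(g1 = c(1, 2), g2 = c(3, 4)),
                          c(g1 = "mRNA", g2 = "mRNA"))
  expect_error(detect_outliers(ds), ">= 3 samples")
  flat <- dataset_from_rows(list(g1 = c(2, 1, 1), g2 = c(2, 1, 5)),
                            c(g1 = "mRNA", g2 = "mRNA"))
  # sample 1 has identical values for all genes -> zero variance on log scale
  expect_error(detect_outliers(flat), "zero-variance")
})

test_that("dendrograms serialise to parseable newick", {
  syn <- generate_synthetic(small_gen(9, subtypes = c(A = 20L)))
  res <- detect_outliers(syn$datasets$A)
  nwk <- dendrogram_newick(res$tree)
  expect_match(nwk, "^\\(")
  tr <- ape::read.tree(text = nwk)
  expect_identical(sort(tr$tip.label), sort(colnames(syn$datasets$A$values)))
})

test_that("the combined preprocessing report is consistent", {
  syn <- generate_synthetic(small_gen(10, n_outliers = 2L))
  out <- preprocess_datasets(syn$datasets)
  rep <- out$report
  for (st in names(syn$datasets)) {
    expect_identical(
      ncol(out$datasets[[st]]$values),
      ncol(syn$datasets[[st]]$values) - length(rep$samples_removed[[st]]))
    expect_identical(
      nrow(out$datasets[[st]]$values),
      nrow(syn$datasets[[st]]$values) - length(rep$genes_removed_mean) -
        length(rep$genes_removed_variance))
  }
  # gene filtering keeps the shared gene list identical across subtypes
  expect_identical(rownames(out$datasets$A$values), rownames(out$datasets$B$values))
})

test_that("datasets with mismatched gene lists are rejected", {
  d1 <- dataset_from_rows(list(g1 = 1:3, g2 = 4:6), c(g1 = "mRNA", g2 = "mRNA"), "A")
  d2 <- dataset_from_rows(list(g1 = 1:3, g3 = 4:6), c(g1 = "mRNA", g3 = "mRNA"), "B")
  expect_error(filter_low_mean(list(d1, d2)), "identical gene list")
})
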