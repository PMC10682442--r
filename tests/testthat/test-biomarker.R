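# balanced count pair: background genes identical across samples plus two
# antisymmetric test genes, so library sizes are equal and TMM factors are 1
.balanced_counts <- function(x, y, n_bg = 50) {
  bg <- matrix(rep(10L, n_bg * 2), n_bg, 2)
  m <- rbind(bg, g_test = c(x, y), g_anti = c(y, x))
  rownames(m)[seq_len(n_bg)] <- sprintf("bg%02d", seq_len(n_bg))
  colnames(m) <- c("a1", "b1")
  list(a = m[, 1, drop = FALSE], b = m[, 2, drop = FALSE])
}

test_that("TMM factors are 1 for identical libraries and error on empty ones", {
  m <- matrix(rpois(200, 20), 50, 4,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:4)))
  m2 <- cbind(m, m)
  colnames(m2) <- sprintf("s%d", 1:8)
  f <- normalize_counts(m2)
  expect_equal(f[1:4], f[5:8], tolerance = 1e-12)
  bad <- m; bad[, 2] <- 0L
  expect_error(normalize_counts(bad), "all-zero sample: s2")
})

test_that("dispersion-zero exact test equals binomial enumeration", {
  for (pair in list(c(10L, 0L), c(7L, 3L), c(5L, 5L), c(0L, 12L))) {
    cc <- .balanced_counts(pair[1L], pair[2L])
    res <- nb_exact_test(cc$a, cc$b, dispersion = 0, genes = "g_test")
    n <- sum(pair)
    expect_equal(res$p, binom_two_sided(pair[1L], n, 0.5), tolerance = 1e-12)
  }
})

test_that("the exact NB test is symmetric and labels direction as A vs B", {
  cc <- .balanced_counts(40L, 5L)
  up <- nb_exact_test(cc$a, cc$b, dispersion = 0.1, genes = c("g_test", "g_anti"))
  dn <- nb_exact_test(cc$b, cc$a, dispersion = 0.1, genes = c("g_test", "g_anti"))
  gt <- up$gene == "g_test"
  expect_gt(up$log2fc[gt], 0)           # higher in group A
  expect_lt(dn$log2fc[gt], 0)
  expect_equal(up$p, dn$p, tolerance = 1e-12)
  expect_equal(up$log2fc[gt], -dn$log2fc[gt], tolerance = 1e-12)
})

test_that("log2 fold changes follow the prior-count convention", {
  cc <- .balanced_counts(30L, 10L)
  res <- nb_exact_test(cc$a, cc$b, dispersion = 0.2)
  gt <- res$gene == "g_test"
  # equal library sizes: normalised counts equal raw counts
  expect_equal(res$log2fc[gt], log2((30 + 0.5) / (10 + 0.5)), tolerance = 1e-6)
})

test_that("genes with zero counts in both groups are reported as null", {
  a <- matrix(c(10L, 0L, 8L), 3, 2, dimnames = list(c("g1", "g0", "g2"), c("a1", "a2")))
  b <- matrix(c(12L, 0L, 9L), 3, 2, dimnames = list(c("g1", "g0", "g2"), c("b1", "b2")))
  res <- nb_exact_test(a, b, dispersion = 0.2)
  g0 <- res$gene == "g0"
  expect_identical(res$p[g0], 1)
  expect_identical(res$log2fc[g0], 0)
})

test_that("gene subsetting tests fewer genes but keeps full-library normalisation", {
  set.seed(61)
  genes <- sprintf("g%03d", 1:100)
  a <- matrix(rnbinom(400, mu = 50, size = 5), 100, 4, dimnames = list(genes, sprintf("a%d", 1:4)))
  b <- matrix(rnbinom(400, mu = 50, size = 5), 100, 4, dimnames = list(genes, sprintf("b%d", 1:4)))
  full <- nb_exact_test(a, b, dispersion = 0.2)
  sub <- nb_exact_test(a, b, dispersion = 0.2, genes = genes[1:10])
  expect_identical(sub$gene, genes[1:10])
  expect_equal(sub$p, full$p[1:10], tolerance = 1e-12)
  expect_equal(sub$log2fc, full$log2fc[1:10], tolerance = 1e-12)
  expect_error(nb_exact_test(a, b, genes = "nope"), "unknown gene")
})

test_that("pairwise DE applies both thresholds strictly and per comparison", {
  syn <- generate_synthetic(small_gen(62))
  genes <- rownames(syn$counts$A)[1:30]
  deg <- pairwise_deg(syn$counts, "A", genes)
  expect_named(deg, c("B", "C"))
  for (d in deg) {
    expect_identical(d$pass, d$fdr < 0.05 & abs(d$log2fc) > 0.5)
    expect_equal(d$fdr, naive_bh(d$p), tolerance = 1e-12)
  }
  empty <- pairwise_deg(syn$counts, "A", character())
  expect_true(all(vapply(empty, nrow, integer(1)) == 0L))
  expect_error(pairwise_deg(syn$counts, "Z", genes), "unknown subtype")
})

test_that("biomarker intersection requires passing every comparison", {
  d1 <- data.frame(gene = c("g1", "g2", "g3"), log2fc = c(2, 2, 2),
                   p = c(0.001, 0.001, 0.2), fdr = c(0.003, 0.003, 0.3),
                   pass = c(TRUE, TRUE, FALSE))
  d2 <- data.frame(gene = c("g1", "g2", "g3"), log2fc = c(-3, 1.4, 2),
                   p = c(0.002, 0.3, 0.001), fdr = c(0.004, 0.4, 0.003),
                   pass = c(TRUE, FALSE, TRUE))
  deg <- structure(list(B = d1, C = d2), subtype = "A", class = "de_result_list")
  bio <- intersect_biomarkers(deg)
  expect_identical(bio$gene, "g1")
  expect_equal(bio$avg_abs_log2fc, mean(c(2, 3)))
  expect_equal(bio$avg_fdr, mean(c(0.003, 0.004)))
  expect_identical(attr(bio, "subtype"), "A")
})

test_that("planted biomarkers survive the full DE + intersection path", {
  syn <- generate_synthetic(small_gen(63))
  planted <- syn$truth$biomarkers$A
  deg <- pairwise_deg(syn$counts, "A", rownames(syn$counts$A))
  bio <- intersect_biomarkers(deg)
  expect_true(all(planted %in% bio$gene))
})

test_that("SVM cross-validation separates a cleanly separable panel", {
  set.seed(71)
  n_case <- 30L; n_rest <- 40L
  genes <- c("g1", "g2")
  mk <- function(center, n, st) {
    v <- matrix(rnorm(2 * n, center, 0.1), 2, n,
                dimnames = list(genes, sprintf("%s%03d", st, 1:n)))
    expression_dataset(abs(v), c(g1 = "mRNA", g2 = "mRNA"), st)
  }
  datasets <- list(A = mk(10, n_case, "A"), B = mk(1, n_rest, "B"))
  cv <- svm_cv_evaluate(datasets, "A", genes, folds = 5L, seed = 1L)
  expect_identical(cv$fold_auc, rep(1, 5L))
  expect_identical(cv$mean_auc, 1)
})

test_that("SVM evaluation is deterministic given the seed", {
  syn <- generate_synthetic(small_gen(72))
  genes <- rownames(syn$datasets$A$values)[1:5]
  c1 <- svm_cv_evaluate(syn$datasets, "A", genes, seed = 3L)
  c2 <- svm_cv_evaluate(syn$datasets, "A", genes, seed = 3L)
  expect_identical(c1$fold_auc, c2$fold_auc)
  expect_error(svm_cv_evaluate(syn$datasets, "A", character()), "empty")
})
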