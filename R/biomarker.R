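# Between-subtype differential expression on module genes, biomarker
# intersection across all pairwise comparisons, and cross-validated SVM
# evaluation of the resulting gene panel.  Normalisation and the exact
# negative-binomial test run through edgeR (TMM + exact conditional
# test); the log2 fold change follows the prior-count convention below.

#' TMM library-size factors
#'
#' Trimmed mean of M-values (30% M-trim, 5% A-trim) against a reference
#' sample; factors multiply raw library sizes and are scaled so their
#' geometric mean is 1.
#'
#' @param counts non-negative integer matrix (genes x samples).
#' @return numeric vector of normalisation factors, one per sample.
#' @export
normalize_counts <- function(counts) {
  if (any(counts < 0)) .stopf("counts must be non-negative")
  zero <- colSums(counts) == 0
  if (any(zero)) .stopf("all-zero sample: %s",
                        colnames(counts)[zero][1L] %||% which(zero)[1L])
  unname(edgeR::calcNormFactors(counts, method = "TMM"))
}

#' Exact negative-binomial test between two groups
#'
#' Two-sided exact conditional test on each gene's total count with the
#' group counts adjusted to equal effective (TMM-normalised) library
#' sizes, at a single common dispersion.  Dispersion 0 reduces to the
#' exact binomial conditional test.  The reported log2 fold change is
#' log2((mean normalised count in A + prior) / (mean in B + prior)) with
#' prior 0.5, positive = up in group A.
#'
#' Library sizes and normalisation factors come from the full matrices;
#' `genes` restricts which genes are tested (so a module-gene screen
#' still normalises against the whole library composition).
#'
#' @param counts_a,counts_b integer matrices (same genes x group samples).
#' @param dispersion common NB dispersion (>= 0), or NULL to estimate a
#'   pooled common dispersion from the data.
#' @param genes optional gene subset to test (default: all genes).
#' @return data.frame with columns gene, log2fc, p.
#' @export
nb_exact_test <- function(counts_a, counts_b, dispersion = 0.2, genes = NULL) {
  if (!identical(rownames(counts_a), rownames(counts_b)))
    .stopf("count matrices must share the same gene list")
  counts <- cbind(counts_a, counts_b)
  grp <- factor(rep(c("A", "B"), c(ncol(counts_a), ncol(counts_b))), levels = c("B", "A"))
  f <- normalize_counts(counts)
  lib <- colSums(counts) * f
  d <- edgeR::DGEList(counts = counts, group = grp)
  d$samples$norm.factors <- f
  if (is.null(dispersion)) {
    d <- edgeR::estimateCommonDisp(d)
    dispersion <- d$common.dispersion
  }
  if (dispersion < 0) .stopf("'dispersion' must be >= 0")
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(counts))
    if (length(miss)) .stopf("unknown gene(s): %s", paste(utils::head(miss, 5L), collapse = ", "))
    d <- d[genes, , keep.lib.sizes = TRUE]
    counts <- counts[genes, , drop = FALSE]
  }
  # pair = c("B","A") so edgeR's comparison direction is A vs B
  et <- edgeR::exactTest(d, pair = c("B", "A"), dispersion = dispersion)
  norm <- sweep(counts, 2L, lib / mean(lib), "/")
  ia <- seq_len(ncol(counts_a)); ib <- ncol(counts_a) + seq_len(ncol(counts_b))
  ma <- rowMeans(norm[, ia, drop = FALSE]); mb <- rowMeans(norm[, ib, drop = FALSE])
  res <- data.frame(gene = rownames(counts),
                    log2fc = log2((ma + 0.5) / (mb + 0.5)),
                    p = et$table$PValue, stringsAsFactors = FALSE)
  both_zero <- rowSums(counts) == 0
  res$p[both_zero] <- 1; res$log2fc[both_zero] <- 0
  rownames(res) <- NULL
  attr(res, "dispersion") <- dispersion
  res
}

#' Between-subtype differential expression of module genes
#'
#' For one subtype C, tests the module-gene union G against every other
#' subtype C' separately; within each comparison, p-values are
#' BH-adjusted and a gene passes iff fdr < fdr_threshold and
#' |log2fc| > lfc_threshold (both strict).
#'
#' @param counts named list of count matrices (genes x samples), one per
#'   subtype, sharing the gene list.
#' @param subtype the reference subtype C.
#' @param genes module-gene union G^C to test.
#' @param lfc_threshold absolute log2 fold-change cutoff (default 0.5).
#' @param fdr_threshold BH FDR cutoff (default 0.05).
#' @param dispersion common NB dispersion; NULL estimates it per
#'   comparison.
#' @return named list (one element per C') of data.frames with columns
#'   gene, log2fc, p, fdr, pass; class `de_result_list`.
#' @export
pairwise_deg <- function(counts, subtype, genes, lfc_threshold = 0.5,
                         fdr_threshold = 0.05, dispersion = 0.2) {
  if (!subtype %in% names(counts)) .stopf("unknown subtype '%s'", subtype)
  others <- setdiff(names(counts), subtype)
  res <- list()
  for (st in others) {
    if (!length(genes)) {
      res[[st]] <- data.frame(gene = character(), log2fc = numeric(),
                              p = numeric(), fdr = numeric(), pass = logical(),
                              stringsAsFactors = FALSE)
      next
    }
    de <- nb_exact_test(counts[[subtype]], counts[[st]],
                        dispersion = dispersion, genes = genes)
    de$fdr <- bh_adjust(de$p)
    de$pass <- de$fdr < fdr_threshold & abs(de$log2fc) > lfc_threshold
    res[[st]] <- de
  }
  structure(res, subtype = subtype, class = "de_result_list")
}

#' Intersect pairwise DE sets into a biomarker panel
#'
#' A gene is a biomarker for subtype C iff it passes the thresholds in
#' every pairwise comparison.  Mean and sd of |log2fc| and FDR across
#' the comparisons summarise each biomarker.
#'
#' @param deg a `de_result_list` from [pairwise_deg()].
#' @return data.frame of class `biomarker_set` with columns gene,
#'   avg_abs_log2fc, sd_abs_log2fc, avg_fdr, sd_fdr; attribute
#'   `"subtype"`.
#' @export
intersect_biomarkers <- function(deg) {
  passing <- lapply(deg, function(d) d$gene[d$pass])
  genes <- Reduce(intersect, passing)
  if (is.null(genes)) genes <- character()
  rows <- lapply(genes, function(g) {
    lfc <- vapply(deg, function(d) abs(d$log2fc[d$gene == g]), numeric(1))
    fdr <- vapply(deg, function(d) d$fdr[d$gene == g], numeric(1))
    data.frame(gene = g, avg_abs_log2fc = mean(lfc), sd_abs_log2fc = stats::sd(lfc),
               avg_fdr = mean(fdr), sd_fdr = stats::sd(fdr), stringsAsFactors = FALSE)
  })
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), avg_abs_log2fc = numeric(),
               sd_abs_log2fc = numeric(), avg_fdr = numeric(), sd_fdr = numeric(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "subtype") <- attr(deg, "subtype")
  class(res) <- c("biomarker_set", "data.frame")
  res
}

.stratified_folds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validated SVM evaluation of a biomarker panel
#'
#' One-vs-rest classification of the target subtype from the continuous
#' expression of the biomarker genes: radial-kernel SVM (cost 1 by
#' default), stratified k-fold with a fixed seed, features z-scored with
#' training-fold statistics only, per-fold ROC from the decision values
#' and trapezoidal AUC.
#'
#' @param datasets named list of [expression_dataset] (all subtypes).
#' @param subtype the positive class C.
#' @param genes biomarker gene ids (or a [intersect_biomarkers()] result).
#' @param folds number of CV folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param kernel,cost SVM kernel and cost passed to e1071.
#' @return list of class `cv_report`: `subtype`, `fold_auc`, `mean_auc`,
#'   `roc` (per-fold data.frames with fpr/tpr).
#' @export
svm_cv_evaluate <- function(datasets, subtype, genes, folds = 5L, seed = 1L,
                            kernel = "radial", cost = 1) {
  if (inherits(genes, "biomarker_set")) genes <- genes$gene
  if (!length(genes)) .stopf("empty biomarker panel")
  X <- do.call(cbind, lapply(datasets, function(d) d$values[genes, , drop = FALSE]))
  X <- t(X)
  y <- factor(rep(ifelse(names(datasets) == subtype, "case", "rest"),
                  vapply(datasets, function(d) ncol(d$values), integer(1))),
              levels = c("case", "rest"))
  if (min(table(y)) < folds)
    .stopf("need >= %d samples in each class for %d-fold stratification", folds, folds)
  set.seed(seed)
  fold <- .stratified_folds(as.character(y), folds)
  fold_auc <- numeric(folds); rocs <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    sdv[sdv == 0] <- 1
    Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2L, mu), 2L, sdv, "/")
    Zte <- sweep(sweep(X[te, , drop = FALSE], 2L, mu), 2L, sdv, "/")
    fit <- e1071::svm(Ztr, y[tr], kernel = kernel, cost = cost, scale = FALSE)
    dvm <- attr(stats::predict(fit, Zte, decision.values = TRUE), "decision.values")
    dv <- dvm[, 1L]
    if (!startsWith(colnames(dvm)[1L], "case/")) dv <- -dv
    roc <- pROC::roc(response = y[te], predictor = dv,
                     levels = c("rest", "case"), direction = "<", quiet = TRUE)
    fold_auc[f] <- as.numeric(pROC::auc(roc))
    rocs[[f]] <- data.frame(fpr = 1 - roc$specificities, tpr = roc$sensitivities)
  }
  structure(list(subtype = subtype, fold_auc = fold_auc,
                 mean_auc = mean(fold_auc), roc = rocs, genes = genes),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report [%s]: %d genes, fold AUC %s, mean %.3f\n",
              x$subtype, length(x$genes),
              paste(sprintf("%.3f", x$fold_auc), collapse = "/"), x$mean_auc))
  invisible(x)
}
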