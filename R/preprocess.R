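# Three-stage preprocessing: pooled mean filter, pooled variance filter,
# hierarchical-clustering outlier removal per subtype.

#' Preprocessing configuration
#'
#' @param mean_threshold genes with pooled mean expression below this are
#'   removed (default 0.5).
#' @param variance_threshold genes with pooled population variance below
#'   this are removed; the default removes only near-constant genes.
#' @param linkage agglomeration method for outlier clustering.
#' @param distance sample-distance: `1 - Pearson` on log1p expression, or
#'   Euclidean on log1p.
#' @param k tree-cut multiplier: cut height = mean(merge heights) +
#'   k * sd(merge heights).
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(mean_threshold = 0.5,
                              variance_threshold = 1e-8,
                              linkage = c("average", "complete", "ward"),
                              distance = c("one-minus-pearson", "euclidean-on-log"),
                              k = 2) {
  if (mean_threshold < 0) .stopf("'mean_threshold' must be >= 0")
  if (variance_threshold < 0) .stopf("'variance_threshold' must be >= 0")
  structure(list(mean_threshold = mean_threshold,
                 variance_threshold = variance_threshold,
                 linkage = match.arg(linkage),
                 distance = match.arg(distance), k = k),
            class = "preprocess_config")
}

.check_shared_genes <- function(datasets) {
  if (!length(datasets)) .stopf("no datasets supplied")
  ref <- rownames(datasets[[1L]]$values)
  for (ds in datasets)
    if (!identical(rownames(ds$values), ref))
      .stopf("datasets must share an identical gene list")
  ref
}

.pooled_stat <- function(datasets, fn) {
  pooled <- do.call(cbind, lapply(datasets, function(d) d$values))
  apply(pooled, 1L, fn)
}

.drop_genes <- function(datasets, removed) {
  lapply(datasets, function(ds) {
    keep <- setdiff(rownames(ds$values), removed)
    expression_dataset(ds$values[keep, , drop = FALSE], ds$classes, ds$subtype)
  })
}

#' Remove genes with low pooled mean expression
#'
#' A gene is removed from all subtypes iff its mean over the pooled
#' samples of every subtype falls below the threshold; the statistic is
#' pooled because filtering operates on the shared gene space.
#'
#' @param datasets named list of [expression_dataset] sharing one gene list.
#' @param threshold mean-expression cutoff (default 0.5).
#' @return list with elements `datasets` (filtered) and `removed`
#'   (gene ids, in input order).
#' @export
filter_low_mean <- function(datasets, threshold = 0.5) {
  genes <- .check_shared_genes(datasets)
  m <- .pooled_stat(datasets, mean)
  removed <- genes[m < threshold]
  list(datasets = .drop_genes(datasets, removed), removed = removed)
}

#' Remove genes with low pooled variance
#'
#' Population variance (divisor n) over the pooled samples; genes with
#' near-uniform expression across all subtypes carry no signal for
#' correlation or differential analysis.
#'
#' @inheritParams filter_low_mean
#' @param threshold variance cutoff; genes with pooled variance strictly
#'   below it are removed (0 removes only exactly-constant genes... a
#'   constant gene has variance 0 which is not < 0, so use a tiny
#'   positive threshold to catch constants).
#' @return list(datasets, removed).
#' @export
filter_low_variance <- function(datasets, threshold = 1e-8) {
  genes <- .check_shared_genes(datasets)
  v <- .pooled_stat(datasets, function(x) mean((x - mean(x))^2))
  removed <- if (threshold > 0) genes[v < threshold] else genes[v == 0]
  list(datasets = .drop_genes(datasets, removed), removed = removed)
}

#' Detect outlier samples by hierarchical clustering
#'
#' Samples are clustered agglomeratively on log1p expression profiles;
#' the tree is cut at `mean(merge heights) + k * sd(merge heights)` and
#' every sample outside the largest resulting cluster is removed.  The
#' fitted tree is returned for audit/plotting and can be serialised with
#' [dendrogram_newick()].
#'
#' @param dataset an [expression_dataset] with >= 3 samples.
#' @param config a [preprocess_config].
#' @return list with `dataset` (retained samples), `removed` (sample
#'   ids) and `tree` (the `hclust` object).
#' @export
detect_outliers <- function(dataset, config = preprocess_config()) {
  stopifnot(inherits(dataset, "expression_dataset"))
  n <- ncol(dataset$values)
  if (n < 3L) .stopf("outlier detection needs >= 3 samples, got %d", n)
  lv <- log1p(dataset$values)
  if (config$distance == "one-minus-pearson") {
    sds <- apply(lv, 2L, stats::sd)
    if (any(sds == 0))
      .stopf("zero-variance sample under pearson distance: %s",
             colnames(lv)[sds == 0][1L])
    d <- stats::as.dist(1 - stats::cor(lv))
  } else {
    d <- stats::dist(t(lv))
  }
  method <- switch(config$linkage, average = "average",
                   complete = "complete", ward = "ward.D2")
  hc <- stats::hclust(d, method = method)
  h <- hc$height
  cut_h <- mean(h) + config$k * stats::sd(h)
  removed <- character()
  if (is.finite(cut_h) && cut_h < max(h)) {
    cl <- stats::cutree(hc, h = cut_h)
    sizes <- table(cl)
    main <- as.integer(names(sizes)[which.max(sizes)])
    removed <- colnames(dataset$values)[cl != main]
  }
  keep <- setdiff(colnames(dataset$values), removed)
  list(dataset = subset_dataset(dataset, samples = keep),
       removed = removed, tree = hc)
}

#' Serialise an hclust merge tree as a newick string
#'
#' @param tree an `hclust` object (e.g. from [detect_outliers()]).
#' @return single newick string with branch lengths.
#' @export
dendrogram_newick <- function(tree) {
  ape::write.tree(ape::as.phylo(tree))
}

#' Run all three preprocessing stages
#'
#' Mean filter and variance filter act on the pooled gene space; outlier
#' removal runs per subtype.
#'
#' @param datasets named list of [expression_dataset] sharing a gene list.
#' @param config a [preprocess_config].
#' @return list with `datasets` (filtered), and `report`: a list holding
#'   `genes_removed_mean`, `genes_removed_variance`, `samples_removed`
#'   (named list per subtype) and `retained` dimensions per subtype.
#' @export
preprocess_datasets <- function(datasets, config = preprocess_config()) {
  s1 <- filter_low_mean(datasets, config$mean_threshold)
  s2 <- filter_low_variance(s1$datasets, config$variance_threshold)
  out <- lapply(s2$datasets, detect_outliers, config = config)
  datasets <- lapply(out, `[[`, "dataset")
  report <- list(
    genes_removed_mean = s1$removed,
    genes_removed_variance = s2$removed,
    samples_removed = lapply(out, `[[`, "removed"),
    retained = lapply(datasets, dim),
    trees = lapply(out, `[[`, "tree"))
  list(datasets = datasets, report = report)
}
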