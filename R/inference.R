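# Primary ceRNA network inference: Pearson triplet rules with a shared
# miRNA mediator.  Two routes: database-validated (mRNA/lncRNA pairs with
# validated miRNA-target support) and correlation-only (pairs involving a
# circRNA, for which no validated interaction data exists).

#' Inference configuration
#'
#' Threshold comparisons are strict: an edge needs r strictly above
#' `corr_threshold` (sponge-sponge), strictly below `-corr_threshold`
#' (miRNA-sponge), and p strictly below `p_threshold`; p-values are raw
#' (no multiple-testing correction at this screen).
#'
#' @param corr_threshold Pearson magnitude cutoff (default 0.4).
#' @param p_threshold two-sided p-value cutoff (default 0.05).
#' @return list of class `inference_config`.
#' @export
inference_config <- function(corr_threshold = 0.4, p_threshold = 0.05) {
  if (corr_threshold <= 0 || corr_threshold >= 1)
    .stopf("'corr_threshold' must be in (0, 1)")
  structure(list(corr_threshold = corr_threshold, p_threshold = p_threshold),
            class = "inference_config")
}

#' Pearson correlation with two-sided p-value
#'
#' p is computed from t = r * sqrt((n - 2) / (1 - r^2)) against a
#' Student-t distribution with n - 2 degrees of freedom; |r| = 1 gives
#' p = 0 exactly.
#'
#' @param x,y numeric vectors of equal length n >= 3, non-constant.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) .stopf("'x' and 'y' must have equal length")
  if (n < 3L) .stopf("need n >= 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    .stopf("degenerate input: constant vector")
  r <- stats::cor(x, y)
  p <- .cor_pvalue(r, n)
  list(r = r, p = p, n = n)
}

.cor_pvalue <- function(r, n) {
  p <- numeric(length(r))
  one <- abs(r) >= 1 - 1e-15
  p[one] <- 0
  tt <- r[!one] * sqrt((n - 2) / (1 - r[!one]^2))
  p[!one] <- 2 * stats::pt(-abs(tt), df = n - 2)
  p
}

# correlation screen matrices among the given genes; constant genes are
# excluded with a warning (they cannot carry a Pearson signal)
.screen_matrices <- function(dataset, genes) {
  v <- dataset$values[genes, , drop = FALSE]
  const <- apply(v, 1L, function(x) stats::var(x) == 0)
  if (any(const)) {
    .warnf("excluding %d constant gene(s) from inference in subtype '%s'",
           sum(const), dataset$subtype)
    v <- v[!const, , drop = FALSE]
  }
  n <- ncol(v)
  R <- stats::cor(t(v))
  P <- matrix(.cor_pvalue(as.numeric(R), n), nrow(R), nrow(R), dimnames = dimnames(R))
  list(R = R, P = P, genes = rownames(v), n = n)
}

.genes_of <- function(dataset, cls) names(dataset$classes)[dataset$classes %in% cls]

# shared edge assembly: given logical mediator matrix A (miRNA x sponge,
# TRUE = miRNA passes the negative screen [and db support where required]),
# the sponge-sponge positive screen, and a pair-eligibility mask.
.assemble_edges <- function(A, R, pos_ok, eligible, classes, evidence) {
  counts <- crossprod(A)                      # common supporting miRNAs per pair
  cand <- which(counts > 0 & pos_ok & eligible & upper.tri(counts), arr.ind = TRUE)
  if (!nrow(cand)) return(.empty_edges())
  sponges <- colnames(A); mirnas <- rownames(A)
  a <- sponges[cand[, 1L]]; b <- sponges[cand[, 2L]]
  supp <- vapply(seq_len(nrow(cand)), function(i) {
    paste(mirnas[A[, cand[i, 1L]] & A[, cand[i, 2L]]], collapse = ",")
  }, character(1))
  data.frame(node_a = a, node_b = b,
             class_a = unname(classes[a]), class_b = unname(classes[b]),
             weight = R[cbind(a, b)], evidence = evidence,
             supporting_miRNAs = supp, stringsAsFactors = FALSE)
}

.empty_edges <- function() {
  data.frame(node_a = character(), node_b = character(), class_a = character(),
             class_b = character(), weight = numeric(), evidence = character(),
             supporting_miRNAs = character(), stringsAsFactors = FALSE)
}

#' Database-validated ceRNA edges
#'
#' For each unordered mRNA/lncRNA pair (u, v): an edge is emitted iff
#' some miRNA t has validated interactions with both u and v, r(t, u)
#' and r(t, v) are below `-corr_threshold`, r(u, v) is above
#' `corr_threshold`, and all three p-values are below `p_threshold`.
#' Every qualifying t is listed in `supporting_miRNAs`.
#'
#' @param dataset an [expression_dataset] (one subtype).
#' @param db an [interaction_db]; empty db returns no edges with a warning.
#' @param config an [inference_config].
#' @return edge data.frame (see [cerna_network()]).
#' @export
infer_db_edges <- function(dataset, db, config = inference_config()) {
  if (!nrow(db)) {
    .warnf("empty interaction database: no db-validated edges")
    return(.empty_edges())
  }
  mirnas <- .genes_of(dataset, "miRNA")
  sponges <- .genes_of(dataset, c("mRNA", "lncRNA"))
  if (!length(mirnas) || length(sponges) < 2L) return(.empty_edges())
  sm <- .screen_matrices(dataset, c(mirnas, sponges))
  mirnas <- intersect(mirnas, sm$genes); sponges <- intersect(sponges, sm$genes)
  if (!length(mirnas) || length(sponges) < 2L) return(.empty_edges())

  neg <- sm$R[mirnas, sponges, drop = FALSE] < -config$corr_threshold &
         sm$P[mirnas, sponges, drop = FALSE] < config$p_threshold
  dbm <- matrix(FALSE, length(mirnas), length(sponges),
                dimnames = list(mirnas, sponges))
  hit <- db$miRNA %in% mirnas & db$target %in% sponges
  dbm[cbind(db$miRNA[hit], db$target[hit])] <- TRUE
  A <- neg & dbm
  Rss <- sm$R[sponges, sponges, drop = FALSE]
  pos_ok <- Rss > config$corr_threshold &
            sm$P[sponges, sponges, drop = FALSE] < config$p_threshold
  eligible <- matrix(TRUE, length(sponges), length(sponges))
  .assemble_edges(A, Rss, pos_ok, eligible, dataset$classes, "db-validated")
}

#' Correlation-only ceRNA edges (circRNA routes)
#'
#' For each unordered pair with at least one circRNA endpoint (partner
#' any of circRNA, mRNA, lncRNA): an edge is emitted iff some miRNA t is
#' negatively correlated with both endpoints and the endpoints are
#' positively correlated, at the same strict thresholds; no database
#' support is required because validated circRNA-miRNA interaction data
#' does not exist.
#'
#' @inheritParams infer_db_edges
#' @return edge data.frame.
#' @export
infer_corr_only_edges <- function(dataset, config = inference_config()) {
  mirnas <- .genes_of(dataset, "miRNA")
  circ <- .genes_of(dataset, "circRNA")
  sponges <- .genes_of(dataset, SPONGE_CLASSES)
  if (!length(mirnas) || !length(circ) || length(sponges) < 2L) return(.empty_edges())
  sm <- .screen_matrices(dataset, c(mirnas, sponges))
  mirnas <- intersect(mirnas, sm$genes); sponges <- intersect(sponges, sm$genes)
  if (!length(mirnas) || length(sponges) < 2L) return(.empty_edges())

  A <- sm$R[mirnas, sponges, drop = FALSE] < -config$corr_threshold &
       sm$P[mirnas, sponges, drop = FALSE] < config$p_threshold
  Rss <- sm$R[sponges, sponges, drop = FALSE]
  pos_ok <- Rss > config$corr_threshold &
            sm$P[sponges, sponges, drop = FALSE] < config$p_threshold
  is_circ <- dataset$classes[sponges] == "circRNA"
  eligible <- outer(is_circ, is_circ, `|`)
  .assemble_edges(A, Rss, pos_ok, eligible, dataset$classes, "correlation-only")
}

#' Build one subtype's primary ceRNA network
#'
#' Union of the database-validated and correlation-only edge sets over
#' all mRNA/lncRNA/circRNA genes; nodes without any edge are dropped.
#'
#' @inheritParams infer_db_edges
#' @return a [cerna_network] tagged with the dataset's subtype.
#' @export
build_primary_network <- function(dataset, db, config = inference_config()) {
  e1 <- infer_db_edges(dataset, db, config)
  e2 <- infer_corr_only_edges(dataset, config)
  edges <- rbind(e1, e2)
  nodes <- data.frame(gene = .genes_of(dataset, SPONGE_CLASSES),
                      class = unname(dataset$classes[.genes_of(dataset, SPONGE_CLASSES)]),
                      stringsAsFactors = FALSE)
  cerna_network(nodes, edges, dataset$subtype)
}
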