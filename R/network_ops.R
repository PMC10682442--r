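# Common/specific network set algebra and module filtering.

#' Common ceRNA network across subtypes
#'
#' Nodes are the intersection of the node sets; edges the intersection
#' of the edge sets (edge identity = unordered endpoint pair), with the
#' weight recomputed as the mean of the per-subtype weights and the
#' supporting miRNAs pooled across subtypes.  The result may contain
#' isolated nodes: a node can be present in every primary network while
#' none of its edges is.
#'
#' @param primaries named list of >= 2 [cerna_network] objects.
#' @return a [cerna_network] tagged "common".
#' @export
common_network <- function(primaries) {
  if (length(primaries) < 2L) .stopf("need >= 2 primary networks")
  node_genes <- Reduce(intersect, lapply(primaries, function(p) p$nodes$gene))
  nodes <- primaries[[1L]]$nodes
  nodes <- nodes[nodes$gene %in% node_genes, , drop = FALSE]
  keys <- lapply(primaries, function(p) edge_keys(p$edges))
  common_keys <- Reduce(intersect, keys)
  if (length(common_keys)) {
    base <- primaries[[1L]]$edges
    base <- base[match(common_keys, keys[[1L]]), , drop = FALSE]
    wsum <- numeric(length(common_keys))
    supp <- vector("list", length(common_keys))
    for (p in primaries) {
      idx <- match(common_keys, edge_keys(p$edges))
      wsum <- wsum + p$edges$weight[idx]
      supp <- Map(c, supp, strsplit(p$edges$supporting_miRNAs[idx], ",", fixed = TRUE))
    }
    base$weight <- wsum / length(primaries)
    base$supporting_miRNAs <- vapply(supp, function(s) paste(sort(unique(s)), collapse = ","),
                                     character(1))
    edges <- base
  } else {
    edges <- .empty_edges()
  }
  cerna_network(nodes, edges, "common", allow_isolated = TRUE)
}

#' Subtype-specific ceRNA network
#'
#' Edges are the primary network's edges minus the common network's
#' edges; nodes are the endpoints of the remaining edges, so no specific
#' edge is orphaned (the strict node-set difference would remove shared
#' hub nodes that still carry specific edges).  The strict node-set
#' difference count is reported in the `"node_difference"` attribute.
#'
#' @param primary a subtype's [cerna_network].
#' @param common the [common_network()] of all subtypes.
#' @return a [cerna_network] tagged with the primary's subtype;
#'   attribute `"node_difference"` holds |N_primary \ N_common|.
#' @export
specific_network <- function(primary, common) {
  drop <- edge_keys(primary$edges) %in% edge_keys(common$edges)
  edges <- primary$edges[!drop, , drop = FALSE]
  net <- cerna_network(primary$nodes, edges, primary$subtype)
  attr(net, "node_difference") <- length(setdiff(primary$nodes$gene, common$nodes$gene))
  net
}

#' Markov-cluster configuration
#'
#' @param inflation entry-wise power applied each iteration (> 1).
#' @param expansion matrix power applied each iteration (>= 2).
#' @param self_loop "max-weight" adds each node's maximum incident edge
#'   weight on the diagonal (standard regularisation), "unit" adds 1.
#' @param prune_threshold entries below this are zeroed each iteration.
#' @param max_iterations iteration cap; hitting it flags non-convergence.
#' @param convergence_tol maximum absolute entry change declaring
#'   convergence.
#' @return list of class `mcl_config`.
#' @export
mcl_config <- function(inflation = 2.0, expansion = 2L,
                       self_loop = c("max-weight", "unit"),
                       prune_threshold = 1e-5, max_iterations = 100L,
                       convergence_tol = 1e-8) {
  if (inflation <= 1) .stopf("'inflation' must be > 1")
  if (expansion < 2) .stopf("'expansion' must be >= 2")
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 self_loop = match.arg(self_loop),
                 prune_threshold = prune_threshold,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol),
            class = "mcl_config")
}

.mcl_matrix <- function(network, self_loop) {
  genes <- network$nodes$gene
  A <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  e <- network$edges
  if (nrow(e)) {
    A[cbind(e$node_a, e$node_b)] <- e$weight
    A[cbind(e$node_b, e$node_a)] <- e$weight
  }
  diag(A) <- if (self_loop == "max-weight") pmax(apply(A, 1L, max), .Machine$double.eps)
             else 1
  A
}

#' Markov clustering of a ceRNA network
#'
#' Column-normalised random-walk matrix alternating expansion (matrix
#' power) and inflation (entry-wise power + renormalisation) with
#' pruning, until the maximum entry change falls below the tolerance.
#' Each node is assigned to the attractor with the highest attraction
#' value (ties broken lexicographically), so modules partition the node
#' set.
#'
#' @param network a non-empty [cerna_network].
#' @param config an [mcl_config].
#' @return a [module_set]; `converged = FALSE` (with a warning) when the
#'   iteration cap is hit.
#' @export
mcl_cluster <- function(network, config = mcl_config()) {
  if (!nrow(network$nodes)) .stopf("cannot cluster an empty network")
  A <- .mcl_matrix(network, config$self_loop)
  M <- sweep(A, 2L, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(config$max_iterations)) {
    prev <- M
    for (e in seq_len(config$expansion - 1L)) M <- M %*% prev   # expansion: M^e
    M <- M^config$inflation                                     # inflation

    M[M < config$prune_threshold] <- 0
    cs <- colSums(M)
    dead <- cs == 0
    if (any(dead)) { diag(M)[dead] <- 1; cs[dead] <- 1 }
    M <- sweep(M, 2L, cs, "/")
    if (max(abs(M - prev)) < config$convergence_tol) { converged <- TRUE; break }
  }
  if (!converged) .warnf("MCL did not converge within %d iterations", config$max_iterations)
  modules <- .mcl_read_clusters(M)
  ms <- module_set(network$subtype, modules, network, converged = converged)
  ms$network <- network
  ms
}

# read clusters from the converged matrix: assign each column to its
# strongest attractor row, then follow attractor assignments to a fixed
# point so attractor systems collapse into one module.
.mcl_read_clusters <- function(M) {
  genes <- colnames(M)
  owner <- apply(M, 2L, which.max)      # ties: which.max takes the first (lexicographic row order is fixed)
  for (i in seq_len(ncol(M))) {         # path-compress owner chains
    seen <- integer()
    j <- i
    while (!(owner[j] == j || j %in% seen)) { seen <- c(seen, j); j <- owner[j] }
    owner[c(i, seen)] <- owner[j]
  }
  split_idx <- split(seq_along(genes), owner)
  modules <- lapply(split_idx, function(ix) genes[ix])
  modules <- modules[order(-lengths(modules), vapply(modules, `[`, character(1), 1L))]
  names(modules) <- paste0("M", seq_along(modules))
  modules
}

#' Keep modules containing at least one lncRNA or circRNA
#'
#' The downstream biomarker stages analyse only modules where a
#' non-coding sponge is present.
#'
#' @param modules a [module_set].
#' @return the filtered [module_set] (flags recomputed).
#' @export
filter_lc_modules <- function(modules) {
  keep <- modules$summary$contains_lncRNA | modules$summary$contains_circRNA
  ms <- module_set(modules$subtype, modules$modules[keep],
                   list(nodes = data.frame(gene = names(modules$classes),
                                           class = unname(modules$classes),
                                           stringsAsFactors = FALSE)),
                   converged = modules$converged)
  ms$network <- modules$network
  ms
}

#' Union of genes of given classes across a module set
#'
#' @param modules a [module_set].
#' @param classes RNA classes to keep (default all).
#' @return character vector of gene ids.
#' @export
module_gene_union <- function(modules, classes = SPONGE_CLASSES) {
  g <- unique(unlist(modules$modules, use.names = FALSE))
  g[modules$classes[g] %in% classes]
}
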