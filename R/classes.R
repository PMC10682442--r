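#' RNA classes recognised by the pipeline
#'
#' Every gene carries exactly one of these classes.  miRNAs act only as
#' edge mediators; network nodes are restricted to the sponge classes.
#' @export
RNA_CLASSES <- c("mRNA", "lncRNA", "circRNA", "miRNA")

#' Sponge (node-eligible) RNA classes
#' @export
SPONGE_CLASSES <- c("mRNA", "lncRNA", "circRNA")

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Expression dataset for one subtype
#'
#' A genes-by-samples matrix of non-negative expression values, each gene
#' typed by RNA class.  This is the per-subtype container every pipeline
#' stage consumes.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); finite, non-negative.
#' @param classes named character vector mapping every gene id in
#'   `rownames(values)` to one of [RNA_CLASSES].
#' @param subtype subtype label (single non-empty string).
#' @return an object of class `expression_dataset` with fields
#'   `values`, `classes` (aligned to the row order) and `subtype`.
#' @export
expression_dataset <- function(values, classes, subtype) {
  if (!is.matrix(values) || !is.numeric(values))
    .stopf("'values' must be a numeric matrix")
  gn <- rownames(values); sn <- colnames(values)
  if (is.null(gn) || is.null(sn))
    .stopf("'values' must carry gene rownames and sample colnames")
  if (anyDuplicated(gn)) .stopf("duplicate gene id: %s", gn[duplicated(gn)][1L])
  if (anyDuplicated(sn)) .stopf("duplicate sample id: %s", sn[duplicated(sn)][1L])
  if (any(!is.finite(values))) .stopf("expression values must be finite")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    .stopf("negative expression at gene '%s', sample '%s'", gn[bad[1L]], sn[bad[2L]])
  }
  if (is.null(names(classes))) .stopf("'classes' must be a named character vector")
  miss <- setdiff(gn, names(classes))
  if (length(miss)) .stopf("no RNA class for gene(s): %s", paste(utils::head(miss, 5L), collapse = ", "))
  cls <- unname(classes[gn])
  bad <- !cls %in% RNA_CLASSES
  if (any(bad)) .stopf("unknown RNA class '%s' for gene '%s'", cls[bad][1L], gn[bad][1L])
  if (!is.character(subtype) || length(subtype) != 1L || !nzchar(subtype))
    .stopf("'subtype' must be a single non-empty string")
  structure(list(values = values, classes = stats::setNames(cls, gn), subtype = subtype),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(factor(x$classes, levels = RNA_CLASSES))
  cat(sprintf("expression_dataset '%s': %d genes x %d samples\n",
              x$subtype, nrow(x$values), ncol(x$values)))
  cat("  ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Subset an expression dataset by genes and/or samples
#' @param ds an [expression_dataset].
#' @param genes,samples character vectors of ids to keep (NULL keeps all).
#' @return the subset `expression_dataset`.
#' @export
subset_dataset <- function(ds, genes = NULL, samples = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  g <- genes %||% rownames(ds$values)
  s <- samples %||% colnames(ds$values)
  miss <- setdiff(g, rownames(ds$values))
  if (length(miss)) .stopf("unknown gene(s): %s", paste(utils::head(miss, 5L), collapse = ", "))
  expression_dataset(ds$values[g, s, drop = FALSE], ds$classes, ds$subtype)
}

#' Validated miRNA-target interaction database
#'
#' Deduplicated (miRNA, target) pairs with a provenance tag, emulating a
#' merged miRTarBase/TarBase extract.
#'
#' @param miRNA,target character vectors of equal length.
#' @param source provenance tag(s), recycled.
#' @return data.frame of class `interaction_db` with columns
#'   `miRNA`, `target`, `source`.
#' @export
interaction_db <- function(miRNA = character(), target = character(),
                           source = "user") {
  if (length(miRNA) != length(target)) .stopf("'miRNA' and 'target' lengths differ")
  if (any(miRNA == target)) {
    .stopf("self-interaction not allowed: %s", miRNA[miRNA == target][1L])
  }
  df <- data.frame(miRNA = as.character(miRNA), target = as.character(target),
                   source = rep_len(as.character(source), length(miRNA)),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df[c("miRNA", "target")]), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("interaction_db", "data.frame")
  df
}

#' @export
print.interaction_db <- function(x, ...) {
  cat(sprintf("interaction_db: %d validated miRNA-target pairs (%d miRNAs, %d targets)\n",
              nrow(x), length(unique(x$miRNA)), length(unique(x$target))))
  invisible(x)
}

#' Clinical survival table
#'
#' @param sample sample ids (unique).
#' @param time overall survival / follow-up time, non-negative.
#' @param event 1 = death observed, 0 = censored.
#' @param subtype subtype label per sample.
#' @return data.frame of class `clinical_table`.
#' @export
clinical_table <- function(sample, time, event, subtype) {
  if (anyDuplicated(sample)) .stopf("duplicate sample id: %s", sample[duplicated(sample)][1L])
  if (any(!is.finite(time)) || any(time < 0)) .stopf("survival times must be finite and >= 0")
  if (!all(event %in% c(0, 1))) .stopf("event indicator must be 0 (censored) or 1 (death)")
  df <- data.frame(sample = as.character(sample), time = as.numeric(time),
                   event = as.integer(event), subtype = as.character(subtype),
                   stringsAsFactors = FALSE)
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Gene-set collection (GMT-style)
#'
#' @param sets named list; each element a list with `description` (string)
#'   and `genes` (non-empty character vector, deduplicated on construction).
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    .stopf("every gene set needs a non-empty name")
  if (anyDuplicated(names(sets))) .stopf("duplicate set name: %s", names(sets)[duplicated(names(sets))][1L])
  sets <- lapply(sets, function(s) {
    g <- unique(as.character(s$genes))
    if (!length(g)) .stopf("empty gene set not allowed")
    list(description = as.character(s$description %||% ""), genes = g)
  })
  structure(list(sets = sets), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, median size %d\n",
              length(x$sets), as.integer(stats::median(lengths(lapply(x$sets, `[[`, "genes"))))))
  invisible(x)
}

#' ceRNA network container
#'
#' Typed nodes plus weighted undirected edges carrying their supporting
#' miRNA evidence.  Edge endpoints are stored in canonical (sorted) order
#' so edge identity is the unordered pair.
#'
#' @param nodes data.frame with columns `gene`, `class`
#'   (class in [SPONGE_CLASSES]).
#' @param edges data.frame with columns `node_a`, `node_b`, `class_a`,
#'   `class_b`, `weight`, `evidence` ("db-validated" or
#'   "correlation-only") and `supporting_miRNAs` (comma-joined ids).
#' @param subtype subtype label, or a tag such as "common".
#' @param allow_isolated keep nodes without incident edges (used for the
#'   common network, whose node set is an intersection).
#' @return object of class `cerna_network`.
#' @export
cerna_network <- function(nodes, edges, subtype, allow_isolated = FALSE) {
  edge_cols <- c("node_a", "node_b", "class_a", "class_b", "weight",
                 "evidence", "supporting_miRNAs")
  if (nrow(edges)) {
    miss <- setdiff(edge_cols, names(edges))
    if (length(miss)) .stopf("edges missing column(s): %s", paste(miss, collapse = ", "))
    flip <- edges$node_a > edges$node_b
    if (any(flip)) {
      tmp <- edges$node_a[flip]; edges$node_a[flip] <- edges$node_b[flip]; edges$node_b[flip] <- tmp
      tmp <- edges$class_a[flip]; edges$class_a[flip] <- edges$class_b[flip]; edges$class_b[flip] <- tmp
    }
    if (anyDuplicated(edges[c("node_a", "node_b")])) .stopf("duplicate edge")
    bad <- !c(edges$class_a, edges$class_b) %in% SPONGE_CLASSES
    if (any(bad)) .stopf("edge endpoint with non-sponge RNA class")
    edges <- edges[order(edges$node_a, edges$node_b), edge_cols, drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(node_a = character(), node_b = character(),
                        class_a = character(), class_b = character(),
                        weight = numeric(), evidence = character(),
                        supporting_miRNAs = character(), stringsAsFactors = FALSE)
  }
  if (!allow_isolated) {
    keep <- nodes$gene %in% c(edges$node_a, edges$node_b)
    nodes <- nodes[keep, , drop = FALSE]
  }
  ep <- unique(c(edges$node_a, edges$node_b))
  if (length(setdiff(ep, nodes$gene))) .stopf("edge endpoint not in node set")
  nodes <- nodes[order(nodes$gene), c("gene", "class"), drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(subtype = subtype, nodes = nodes, edges = edges),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("cerna_network [%s]: %d nodes, %d edges\n",
              x$subtype, nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes)) {
    tab <- table(factor(x$nodes$class, levels = SPONGE_CLASSES))
    cat("  nodes: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$edges)) {
    tab <- table(x$edges$evidence)
    cat("  edges: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

edge_keys <- function(edges) paste(edges$node_a, edges$node_b, sep = "\r")

#' Module set from network clustering
#'
#' @param subtype subtype tag of the source network.
#' @param modules named list of character vectors (module id -> member
#'   genes); modules must be disjoint.
#' @param network the source [cerna_network] (class lookup + induced edges).
#' @param converged logical; FALSE flags a clustering run that hit the
#'   iteration cap.
#' @return object of class `module_set`; `$summary` tabulates size and
#'   lncRNA/circRNA content per module.
#' @export
module_set <- function(subtype, modules, network, converged = TRUE) {
  all_genes <- unlist(modules, use.names = FALSE)
  if (anyDuplicated(all_genes)) .stopf("modules must be disjoint")
  if (length(setdiff(all_genes, network$nodes$gene))) .stopf("module gene not in source network")
  cls <- stats::setNames(network$nodes$class, network$nodes$gene)
  summ <- data.frame(
    module = names(modules) %||% paste0("M", seq_along(modules)),
    size = lengths(modules),
    contains_lncRNA = vapply(modules, function(g) any(cls[g] == "lncRNA"), logical(1)),
    contains_circRNA = vapply(modules, function(g) any(cls[g] == "circRNA"), logical(1)),
    stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  names(modules) <- summ$module
  structure(list(subtype = subtype, modules = modules, summary = summ,
                 classes = cls, converged = converged),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set [%s]: %d modules covering %d nodes%s\n",
              x$subtype, length(x$modules), sum(lengths(x$modules)),
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}
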