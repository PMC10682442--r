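# shared fixture builders: small generator configs and hand-made networks

small_gen <- function(seed, subtypes = c(A = 100L, B = 100L, C = 100L),
                      n_outliers = 0L,
                      n_genes = c(mRNA = 40L, lncRNA = 18L, circRNA = 12L, miRNA = 18L),
                      ...) {
  generator_config(seed = seed, subtypes = subtypes, n_genes = n_genes,
                   n_outliers = n_outliers, ...)
}

# build a cerna_network from a bare edge list (equal classes default mRNA)
toy_network <- function(a, b, w = 1, classes = NULL, subtype = "toy",
                        evidence = "correlation-only", supp = "m1",
                        allow_isolated = FALSE, extra_nodes = NULL) {
  genes <- unique(c(a, b, extra_nodes))
  cls <- stats::setNames(rep("mRNA", length(genes)), genes)
  if (!is.null(classes)) cls[names(classes)] <- classes
  nodes <- data.frame(gene = genes, class = unname(cls[genes]),
                      stringsAsFactors = FALSE)
  edges <- data.frame(node_a = a, node_b = b,
                      class_a = unname(cls[a]), class_b = unname(cls[b]),
                      weight = rep_len(w, length(a)),
                      evidence = rep_len(evidence, length(a)),
                      supporting_miRNAs = rep_len(supp, length(a)),
                      stringsAsFactors = FALSE)
  cerna_network(nodes, edges, subtype, allow_isolated = allow_isolated)
}

# random small network over a fixed gene universe (for set-algebra checks)
random_network <- function(n_nodes = 12, p_edge = 0.3, subtype = "r") {
  genes <- sprintf("g%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(genes, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[1] <- TRUE
  toy_network(pairs[keep, 1], pairs[keep, 2], w = round(stats::runif(sum(keep), 0.4, 1), 3),
              subtype = subtype)
}

# dataset with explicitly planted correlation structure, for edge-rule tests
dataset_from_rows <- function(rows, classes, subtype = "T") {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  expression_dataset(m, classes, subtype)
}
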