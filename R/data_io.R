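# Readers/writers for the plain-text formats the pipeline touches.
# All files are tab-separated; lines starting with '#' are provenance
# comments and are skipped on read.

.read_tsv <- function(path, header = TRUE, ...) {
  utils::read.delim(path, header = header, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = NA, ...)
}

.provenance_line <- function(provenance) {
  if (is.null(provenance)) return(NULL)
  sprintf("# cernapipe seed=%s config=%s", provenance$seed, provenance$hash)
}

.write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  pl <- .provenance_line(provenance)
  if (!is.null(pl)) writeLines(pl, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column gene-to-RNA-class map
#'
#' Expression matrices do not encode RNA class, so the map is supplied
#' separately as a headerless two-column file: gene id, class.
#'
#' @param path file path.
#' @return named character vector gene -> class.
#' @export
read_class_map <- function(path) {
  df <- .read_tsv(path, header = FALSE)
  if (ncol(df) < 2L) .stopf("class map '%s' needs two tab-separated columns", path)
  if (anyDuplicated(df[[1L]])) .stopf("duplicate gene in class map: %s", df[[1L]][duplicated(df[[1L]])][1L])
  bad <- !df[[2L]] %in% RNA_CLASSES
  if (any(bad)) .stopf("unknown RNA class '%s' in class map (line %d)", df[[2L]][bad][1L], which(bad)[1L])
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' @rdname read_class_map
#' @param class_map named character vector gene -> class.
#' @export
write_class_map <- function(class_map, path) {
  .write_tsv(data.frame(V1 = names(class_map), V2 = unname(class_map)),
             path)
  # headerless layout: rewrite without the header row
  lines <- readLines(path)
  writeLines(lines[-1L], path)
  invisible(path)
}

#' Read a genes-by-samples expression matrix
#'
#' First column gene ids, header row sample ids, numeric body.  Every
#' gene must be present in `class_map`; under `strict = FALSE` unmapped
#' genes are dropped with a warning and reported in the `"rejected"`
#' attribute so no row disappears silently.
#'
#' @param path tab-separated file path.
#' @param class_map named character vector gene -> class (or path to a
#'   two-column map file).
#' @param subtype subtype label for the dataset.
#' @param strict if TRUE (default), genes missing from the class map are
#'   an error; if FALSE they are dropped and reported.
#' @return an [expression_dataset]; attribute `"rejected"` lists dropped
#'   genes (lenient mode only).
#' @export
read_expression <- function(path, class_map, subtype, strict = TRUE) {
  if (is.character(class_map) && is.null(names(class_map)) && length(class_map) == 1L)
    class_map <- read_class_map(class_map)
  df <- .read_tsv(path, header = TRUE)
  if (ncol(df) < 2L) .stopf("expression file '%s' has no sample columns", path)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) .stopf("duplicated gene row: %s", genes[duplicated(genes)][1L])
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num) & !anyNA(v)) {
        i <- which(is.na(num))[1L]
        .stopf("non-numeric value '%s' at gene '%s', sample '%s'",
               v[i], genes[i], names(body)[j])
      }
      body[[j]] <- num
    }
  }
  mat <- as.matrix(body)
  rownames(mat) <- genes
  if (anyNA(mat)) {
    i <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    .stopf("missing value at gene '%s', sample '%s'", genes[i[1L]], colnames(mat)[i[2L]])
  }
  if (any(mat < 0)) {
    i <- which(mat < 0, arr.ind = TRUE)[1L, ]
    .stopf("negative value at gene '%s', sample '%s'", genes[i[1L]], colnames(mat)[i[2L]])
  }
  unmapped <- setdiff(genes, names(class_map))
  rejected <- character()
  if (length(unmapped)) {
    if (strict) .stopf("gene(s) missing from class map: %s",
                       paste(utils::head(unmapped, 5L), collapse = ", "))
    .warnf("dropping %d gene(s) missing from class map", length(unmapped))
    rejected <- unmapped
    mat <- mat[setdiff(genes, unmapped), , drop = FALSE]
  }
  ds <- expression_dataset(mat, class_map, subtype)
  attr(ds, "rejected") <- rejected
  ds
}

#' @rdname read_expression
#' @param ds an [expression_dataset].
#' @param provenance optional list(seed, hash) embedded as a comment line.
#' @export
write_expression <- function(ds, path, provenance = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  df <- data.frame(gene = rownames(ds$values), ds$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path, provenance)
}

#' Read a validated miRNA-target interaction table
#'
#' Two or more tab-separated columns: miRNA id, target id, optional
#' source database.  Duplicate pairs are collapsed; a self-pair is an
#' error; an empty file yields an empty database with a warning.
#'
#' @param path file path.
#' @return an [interaction_db].
#' @export
read_interactions <- function(path) {
  n_lines <- length(readLines(path))
  if (n_lines == 0L) {
    .warnf("interaction file '%s' is empty", path)
    return(interaction_db())
  }
  df <- .read_tsv(path, header = FALSE)
  if (ncol(df) < 2L) .stopf("interaction file '%s' needs >= 2 columns", path)
  src <- if (ncol(df) >= 3L) as.character(df[[3L]]) else "unspecified"
  interaction_db(as.character(df[[1L]]), as.character(df[[2L]]), src)
}

#' @rdname read_interactions
#' @param db an [interaction_db].
#' @param provenance optional list(seed, hash).
#' @export
write_interactions <- function(db, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  pl <- .provenance_line(provenance)
  if (!is.null(pl)) writeLines(pl, con)
  utils::write.table(as.data.frame(db), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write a clinical survival table
#'
#' Columns: sample, time, event (0/1), subtype; with header.
#' @param path file path.
#' @return a [clinical_table].
#' @export
read_clinical <- function(path) {
  df <- .read_tsv(path, header = TRUE)
  need <- c("sample", "time", "event", "subtype")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("clinical table missing column(s): %s", paste(miss, collapse = ", "))
  clinical_table(df$sample, df$time, df$event, df$subtype)
}

#' @rdname read_clinical
#' @param clin a [clinical_table].
#' @param provenance optional list(seed, hash).
#' @export
write_clinical <- function(clin, path, provenance = NULL) {
  .write_tsv(as.data.frame(clin), path, provenance)
}

#' Read a GMT gene-set file
#'
#' Standard layout: set name, description, then member genes, all
#' tab-separated, one set per line.
#'
#' @param path file path.
#' @return a [gene_set_collection].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) .stopf("malformed GMT line %d: need name, description, >= 1 gene", i)
    sets[[f[1L]]] <- list(description = f[2L], genes = f[-(1:2)])
  }
  gene_set_collection(sets)
}

#' @rdname read_gmt
#' @param gsc a [gene_set_collection].
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm) {
    s <- gsc$sets[[nm]]
    paste(c(nm, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a ceRNA network as SIF or GraphML
#'
#' SIF rows are `nodeA<TAB>cerna<TAB>nodeB`; isolated nodes are written
#' as single-token lines (standard SIF convention).  GraphML (via
#' igraph) carries node `class` and edge `weight`, `evidence` and
#' `supporting_miRNAs` attributes and can be read back with
#' [read_network_graphml()].
#'
#' @param network a [cerna_network].
#' @param path output file path.
#' @param format "sif" or "graphml".
#' @export
write_network <- function(network, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "cerna_network"))
  if (format == "sif") {
    e <- network$edges
    lines <- if (nrow(e)) paste(e$node_a, "cerna", e$node_b, sep = "\t") else character()
    iso <- setdiff(network$nodes$gene, c(e$node_a, e$node_b))
    writeLines(c(lines, iso), path)
    return(invisible(path))
  }
  g <- .as_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

.as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    d = network$edges[, c("node_a", "node_b", "weight", "evidence", "supporting_miRNAs"), drop = FALSE],
    directed = FALSE,
    vertices = network$nodes)
  g
}

#' @rdname write_network
#' @param subtype tag to attach to the re-imported network.
#' @export
read_network_graphml <- function(path, subtype = "imported") {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(gene = igraph::vertex_attr(g, "name"),
                      class = igraph::vertex_attr(g, "class"),
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  cls <- stats::setNames(nodes$class, nodes$gene)
  edges <- data.frame(node_a = el[, 1L], node_b = el[, 2L],
                      class_a = unname(cls[el[, 1L]]), class_b = unname(cls[el[, 2L]]),
                      weight = igraph::edge_attr(g, "weight") %||% numeric(nrow(el)),
                      evidence = igraph::edge_attr(g, "evidence") %||% rep("correlation-only", nrow(el)),
                      supporting_miRNAs = igraph::edge_attr(g, "supporting_miRNAs") %||% rep("", nrow(el)),
                      stringsAsFactors = FALSE)
  cerna_network(nodes, edges, subtype, allow_isolated = TRUE)
}

#' Write a network edge table as TSV
#'
#' Columns: node_a, node_b, class_a, class_b, weight, evidence,
#' supporting_miRNAs (comma-joined).
#' @param network a [cerna_network].
#' @param path output path.
#' @param provenance optional list(seed, hash).
#' @export
write_edge_table <- function(network, path, provenance = NULL) {
  .write_tsv(network$edges, path, provenance)
}
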