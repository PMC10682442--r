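# Pipeline orchestration: staged execution over plain-text artifacts.
# Every stage reads only the artifacts of earlier stages, so a
# monolithic run is literally the sequence of staged runs and produces
# bit-identical files.

PIPELINE_STAGES <- c("generate", "preprocess", "infer-network",
                     "network-algebra", "cluster", "enrich", "survival",
                     "biomarkers", "evaluate")

#' Pipeline configuration
#'
#' Exactly one of `generator` (synthetic mode) and `input_paths` (file
#' mode) must be supplied.  In file mode, `input_paths` is a list with
#' `expression` (named character vector: subtype label -> TSV path),
#' `class_map`, `interactions` and `clinical` paths; counts for the
#' differential-expression stage are the rounded expression values.
#'
#' @param generator a [generator_config], or NULL.
#' @param input_paths list of input file paths, or NULL.
#' @param gene_sets optional GMT path or [gene_set_collection] enabling
#'   the enrichment stage.
#' @param preprocess a [preprocess_config].
#' @param inference an [inference_config].
#' @param mcl an [mcl_config].
#' @param survival_alpha raw log-rank significance level.
#' @param lfc_threshold,fdr_threshold DE inclusion thresholds (strict).
#' @param dispersion common NB dispersion for the DE stage (NULL =
#'   estimate per comparison).
#' @param folds CV folds for the evaluation stage.
#' @param seed integer seed governing every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL, input_paths = NULL,
                            gene_sets = NULL,
                            preprocess = preprocess_config(),
                            inference = inference_config(),
                            mcl = mcl_config(),
                            survival_alpha = 0.05,
                            lfc_threshold = 0.5, fdr_threshold = 0.05,
                            dispersion = 0.2, folds = 5L, seed = 1L) {
  if (is.null(generator) == is.null(input_paths))
    .stopf("supply exactly one of 'generator' and 'input_paths'")
  if (!is.null(generator)) stopifnot(inherits(generator, "generator_config"))
  cfg <- list(generator = generator, input_paths = input_paths,
              gene_sets = gene_sets, preprocess = preprocess,
              inference = inference, mcl = mcl,
              survival_alpha = survival_alpha,
              lfc_threshold = lfc_threshold, fdr_threshold = fdr_threshold,
              dispersion = dispersion, folds = as.integer(folds),
              seed = as.integer(seed))
  cfg$hash <- .config_hash(cfg)
  structure(cfg, class = "pipeline_config")
}

.config_hash <- function(cfg) {
  s <- paste(deparse(cfg[setdiff(names(cfg), "hash")]), collapse = "")
  h <- 0
  for (x in utf8ToInt(s)) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}

.prov <- function(config) list(seed = config$seed, hash = config$hash)

.need <- function(path, producing_stage) {
  if (!file.exists(path))
    .stopf("missing artifact '%s': run stage '%s' first", path, producing_stage)
  path
}

.stage_error <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

.subtype_manifest <- function(outdir) {
  df <- .read_tsv(.need(file.path(outdir, "data", "subtypes.tsv"), "generate"))
  df$tag <- as.character(df$tag); df$subtype <- as.character(df$subtype)
  df
}

.report_path <- function(outdir, stage) {
  dir.create(file.path(outdir, "reports"), showWarnings = FALSE, recursive = TRUE)
  file.path(outdir, "reports", paste0(stage, ".tsv"))
}

.write_report <- function(outdir, stage, rows, config) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(stage = stage, subtype = r[[1L]], metric = r[[2L]],
               value = as.character(r[[3L]]), stringsAsFactors = FALSE)))
  if (is.null(df)) df <- data.frame(stage = character(), subtype = character(),
                                    metric = character(), value = character())
  .write_tsv(df, .report_path(outdir, stage), .prov(config))
}

.read_counts <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

.read_edges <- function(path) {
  df <- .read_tsv(path)
  df$supporting_miRNAs <- as.character(df$supporting_miRNAs)
  df$node_a <- as.character(df$node_a); df$node_b <- as.character(df$node_b)
  df
}

.read_network_artifacts <- function(edges_path, nodes_path, tag, stage) {
  edges <- .read_edges(.need(edges_path, stage))
  nodes <- .read_tsv(.need(nodes_path, stage))
  cerna_network(data.frame(gene = as.character(nodes$gene),
                           class = as.character(nodes$class),
                           stringsAsFactors = FALSE),
                edges, tag, allow_isolated = TRUE)
}

.read_modules <- function(path, tag, class_map, stage) {
  df <- .read_tsv(.need(path, stage))
  mods <- split(as.character(df$gene), as.character(df$module))
  mods <- mods[order(names(mods))]
  net <- list(nodes = data.frame(gene = names(class_map), class = unname(class_map),
                                 stringsAsFactors = FALSE))
  module_set(tag, mods, net)
}

#' Run one pipeline stage against an artifact directory
#'
#' Stages (in order): generate, preprocess, infer-network,
#' network-algebra, cluster, enrich, survival, biomarkers, evaluate.
#' Each stage reads the artifacts of earlier stages from `outdir`,
#' writes its own artifacts plus a `reports/<stage>.tsv` count summary,
#' and fails with a stage-tagged error naming the producing stage if an
#' upstream artifact is missing.
#'
#' @param config a [pipeline_config].
#' @param stage stage name.
#' @param outdir artifact directory (created if needed).
#' @return invisibly, the stage's report rows.
#' @export
run_stage <- function(config, stage, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- match.arg(stage, PIPELINE_STAGES)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + match(stage, PIPELINE_STAGES))
  fn <- switch(stage,
               "generate" = .stage_generate, "preprocess" = .stage_preprocess,
               "infer-network" = .stage_infer, "network-algebra" = .stage_algebra,
               "cluster" = .stage_cluster, "enrich" = .stage_enrich,
               "survival" = .stage_survival, "biomarkers" = .stage_biomarkers,
               "evaluate" = .stage_evaluate)
  .stage_error(stage, fn(config, outdir))
}

.stage_generate <- function(config, outdir) {
  dd <- file.path(outdir, "data")
  dir.create(dd, showWarnings = FALSE, recursive = TRUE)
  prov <- .prov(config)
  if (!is.null(config$generator)) {
    syn <- generate_synthetic(config$generator)
    datasets <- syn$datasets; counts <- syn$counts
    interactions <- syn$interactions; clinical <- syn$clinical
    class_map <- syn$truth$classes
    tr <- syn$truth
    .write_tsv(tr$triplets, file.path(dd, "truth_triplets.tsv"), prov)
    bm <- data.frame(subtype = rep(names(tr$biomarkers), lengths(tr$biomarkers)),
                     gene = unlist(tr$biomarkers, use.names = FALSE))
    .write_tsv(bm, file.path(dd, "truth_biomarkers.tsv"), prov)
    .write_tsv(data.frame(subtype = names(tr$survival_genes),
                          gene = unname(tr$survival_genes)),
               file.path(dd, "truth_survival_genes.tsv"), prov)
    ol <- data.frame(subtype = rep(names(tr$outliers), lengths(tr$outliers)),
                     sample = unlist(tr$outliers, use.names = FALSE))
    .write_tsv(ol, file.path(dd, "truth_outliers.tsv"), prov)
  } else {
    ip <- config$input_paths
    class_map <- read_class_map(.need(ip$class_map, "external input"))
    datasets <- lapply(names(ip$expression), function(st)
      read_expression(ip$expression[[st]], class_map, st))
    names(datasets) <- names(ip$expression)
    counts <- lapply(datasets, function(d) round(d$values))
    interactions <- read_interactions(.need(ip$interactions, "external input"))
    clinical <- read_clinical(.need(ip$clinical, "external input"))
  }
  manifest <- data.frame(subtype = names(datasets),
                         tag = .sanitize(names(datasets)),
                         n_samples = vapply(datasets, function(d) ncol(d$values), integer(1)),
                         stringsAsFactors = FALSE)
  .write_tsv(manifest, file.path(dd, "subtypes.tsv"), prov)
  write_class_map(class_map, file.path(dd, "class_map.tsv"))
  write_interactions(interactions, file.path(dd, "interactions.tsv"), prov)
  write_clinical(clinical, file.path(dd, "clinical.tsv"), prov)
  for (i in seq_len(nrow(manifest))) {
    st <- manifest$subtype[i]; tag <- manifest$tag[i]
    write_expression(datasets[[st]], file.path(dd, sprintf("expression_%s.tsv", tag)), prov)
    cdf <- data.frame(gene = rownames(counts[[st]]), counts[[st]], check.names = FALSE)
    .write_tsv(cdf, file.path(dd, sprintf("counts_%s.tsv", tag)), prov)
  }
  rows <- lapply(seq_len(nrow(manifest)), function(i)
    list(manifest$subtype[i], "n_samples", manifest$n_samples[i]))
  rows <- c(rows, list(list("all", "n_genes", nrow(datasets[[1L]]$values)),
                       list("all", "n_interactions", nrow(interactions))))
  .write_report(outdir, "generate", rows, config)
  invisible(rows)
}

.load_datasets <- function(outdir, dir, stage) {
  man <- .subtype_manifest(outdir)
  class_map <- read_class_map(.need(file.path(outdir, "data", "class_map.tsv"), "generate"))
  datasets <- lapply(seq_len(nrow(man)), function(i)
    read_expression(.need(file.path(outdir, dir, sprintf("expression_%s.tsv", man$tag[i])), stage),
                    class_map, man$subtype[i]))
  names(datasets) <- man$subtype
  list(man = man, class_map = class_map, datasets = datasets)
}

.stage_preprocess <- function(config, outdir) {
  x <- .load_datasets(outdir, "data", "generate")
  pd <- file.path(outdir, "preprocess")
  dir.create(pd, showWarnings = FALSE, recursive = TRUE)
  prov <- .prov(config)
  res <- preprocess_datasets(x$datasets, config$preprocess)
  rows <- list(list("all", "genes_removed_mean", length(res$report$genes_removed_mean)),
               list("all", "genes_removed_variance", length(res$report$genes_removed_variance)))
  for (i in seq_len(nrow(x$man))) {
    st <- x$man$subtype[i]; tag <- x$man$tag[i]
    ds <- res$datasets[[st]]
    write_expression(ds, file.path(pd, sprintf("expression_%s.tsv", tag)), prov)
    cnt <- .read_counts(.need(file.path(outdir, "data", sprintf("counts_%s.tsv", tag)), "generate"))
    cnt <- cnt[rownames(ds$values), colnames(ds$values), drop = FALSE]
    .write_tsv(data.frame(gene = rownames(cnt), cnt, check.names = FALSE),
               file.path(pd, sprintf("counts_%s.tsv", tag)), prov)
    writeLines(dendrogram_newick(res$report$trees[[st]]),
               file.path(pd, sprintf("dendrogram_%s.nwk", tag)))
    rows <- c(rows, list(list(st, "samples_removed", length(res$report$samples_removed[[st]])),
                         list(st, "samples_retained", ncol(ds$values))))
  }
  rem <- res$report$samples_removed
  .write_tsv(data.frame(subtype = rep(names(rem), lengths(rem)),
                        sample = unlist(rem, use.names = FALSE)),
             file.path(pd, "samples_removed.tsv"), prov)
  .write_tsv(data.frame(filter = rep(c("mean", "variance"),
                                     c(length(res$report$genes_removed_mean),
                                       length(res$report$genes_removed_variance))),
                        gene = c(res$report$genes_removed_mean,
                                 res$report$genes_removed_variance)),
             file.path(pd, "genes_removed.tsv"), prov)
  .write_report(outdir, "preprocess", rows, config)
  invisible(rows)
}

.stage_infer <- function(config, outdir) {
  x <- .load_datasets(outdir, "preprocess", "preprocess")
  db <- read_interactions(.need(file.path(outdir, "data", "interactions.tsv"), "generate"))
  nd <- file.path(outdir, "networks")
  dir.create(nd, showWarnings = FALSE, recursive = TRUE)
  prov <- .prov(config)
  rows <- list()
  for (i in seq_len(nrow(x$man))) {
    st <- x$man$subtype[i]; tag <- x$man$tag[i]
    net <- build_primary_network(x$datasets[[st]], db, config$inference)
    write_edge_table(net, file.path(nd, sprintf("primary_%s_edges.tsv", tag)), prov)
    .write_tsv(net$nodes, file.path(nd, sprintf("primary_%s_nodes.tsv", tag)), prov)
    write_network(net, file.path(nd, sprintf("primary_%s.sif", tag)), "sif")
    rows <- c(rows, list(list(st, "n_nodes", nrow(net$nodes)),
                         list(st, "n_edges", nrow(net$edges))))
  }
  .write_report(outdir, "infer-network", rows, config)
  invisible(rows)
}

.stage_algebra <- function(config, outdir) {
  man <- .subtype_manifest(outdir)
  nd <- file.path(outdir, "networks")
  ad <- file.path(outdir, "algebra")
  dir.create(ad, showWarnings = FALSE, recursive = TRUE)
  prov <- .prov(config)
  primaries <- lapply(seq_len(nrow(man)), function(i)
    .read_network_artifacts(file.path(nd, sprintf("primary_%s_edges.tsv", man$tag[i])),
                            file.path(nd, sprintf("primary_%s_nodes.tsv", man$tag[i])),
                            man$subtype[i], "infer-network"))
  names(primaries) <- man$subtype
  common <- common_network(primaries)
  write_edge_table(common, file.path(ad, "common_edges.tsv"), prov)
  .write_tsv(common$nodes, file.path(ad, "common_nodes.tsv"), prov)
  rows <- list(list("common", "n_nodes", nrow(common$nodes)),
               list("common", "n_edges", nrow(common$edges)))
  ndiff <- list()
  for (i in seq_len(nrow(man))) {
    st <- man$subtype[i]; tag <- man$tag[i]
    sp <- specific_network(primaries[[st]], common)
    write_edge_table(sp, file.path(ad, sprintf("specific_%s_edges.tsv", tag)), prov)
    .write_tsv(sp$nodes, file.path(ad, sprintf("specific_%s_nodes.tsv", tag)), prov)
    ndiff[[st]] <- attr(sp, "node_difference")
    rows <- c(rows, list(list(st, "n_specific_edges", nrow(sp$edges)),
                         list(st, "n_specific_nodes", nrow(sp$nodes)),
                         list(st, "node_set_difference", ndiff[[st]])))
  }
  .write_tsv(data.frame(subtype = names(ndiff), node_set_difference = unlist(ndiff)),
             file.path(ad, "node_difference.tsv"), prov)
  .write_report(outdir, "network-algebra", rows, config)
  invisible(rows)
}

.stage_cluster <- function(config, outdir) {
  man <- .subtype_manifest(outdir)
  class_map <- read_class_map(.need(file.path(outdir, "data", "class_map.tsv"), "generate"))
  md <- file.path(outdir, "modules")
  dir.create(md, showWarnings = FALSE, recursive = TRUE)
  prov <- .prov(config)
  rows <- list()
  for (i in seq_len(nrow(man))) {
    st <- man$subtype[i]; tag <- man$tag[i]
    sp <- .read_network_artifacts(
      file.path(outdir, "algebra", sprintf("specific_%s_edges.tsv", tag)),
      file.path(outdir, "algebra", sprintf("specific_%s_nodes.tsv", tag)),
      st, "network-algebra")
    if (!nrow(sp$nodes)) {
      .write_tsv(data.frame(module = character(), gene = character(),
                            class = character(), in_lc = logical()),
                 file.path(md, sprintf("modules_%s.tsv", tag)), prov)
      rows <- c(rows, list(list(st, "n_modules", 0L), list(st, "n_lc_modules", 0L)))
      next
    }
    ms <- mcl_cluster(sp, config$mcl)
    lc <- filter_lc_modules(ms)
    df <- do.call(rbind, lapply(names(ms$modules), function(m)
      data.frame(module = m, gene = ms$modules[[m]],
                 class = unname(ms$classes[ms$modules[[m]]]),
                 in_lc = m %in% names(lc$modules), stringsAsFactors = FALSE)))
    .write_tsv(df, file.path(md, sprintf("modules_%s.tsv", tag)), prov)
    rows <- c(rows, list(list(st, "n_modules", length(ms$modules)),
                         list(st, "n_lc_modules", length(lc$modules))))
  }
  .write_report(outdir, "cluster", rows, config)
  invisible(rows)
}

.load_lc_modules <- function(outdir, man, class_map, i) {
  path <- file.path(outdir, "modules", sprintf("modules_%s.tsv", man$tag[i]))
  df <- .read_tsv(.need(path, "cluster"))
  df <- df[df$in_lc %in% c(TRUE, "TRUE"), , drop = FALSE]
  mods <- split(as.character(df$gene), as.character(df$module))
  net <- list(nodes = data.frame(gene = names(class_map), class = unname(class_map),
                                 stringsAsFactors = FALSE))
  module_set(man$subtype[i], mods, net)
}

.stage_enrich <- function(config, outdir) {
  man <- .subtype_manifest(outdir)
  ed <- file.path(outdir, "enrich")
  dir.create(ed, showWarnings = FALSE, recursive = TRUE)
  prov <- .prov(config)
  rows <- list()
  if (is.null(config$gene_sets)) {
    rows <- list(list("all", "skipped_no_gene_sets", 1L))
    .write_report(outdir, "enrich", rows, config)
    return(invisible(rows))
  }
  sets <- if (inherits(config$gene_sets, "gene_set_collection")) config$gene_sets
          else read_gmt(config$gene_sets)
  x <- .load_datasets(outdir, "preprocess", "preprocess")
  for (i in seq_len(nrow(man))) {
    st <- man$subtype[i]; tag <- man$tag[i]
    lc <- .load_lc_modules(outdir, man, x$class_map, i)
    universe <- rownames(x$datasets[[st]]$values)
    res <- hypergeom_enrich(lc, sets, universe)
    .write_tsv(res, file.path(ed, sprintf("enrichment_%s.tsv", tag)), prov)
    rows <- c(rows, list(list(st, "n_significant_sets", sum(res$fdr < 0.05))))
  }
  .write_report(outdir, "enrich", rows, config)
  invisible(rows)
}

.stage_survival <- function(config, outdir) {
  x <- .load_datasets(outdir, "preprocess", "preprocess")
  clinical <- read_clinical(.need(file.path(outdir, "data", "clinical.tsv"), "generate"))
  sd_ <- file.path(outdir, "survival")
  dir.create(sd_, showWarnings = FALSE, recursive = TRUE)
  prov <- .prov(config)
  rows <- list()
  for (i in seq_len(nrow(x$man))) {
    st <- x$man$subtype[i]; tag <- x$man$tag[i]
    lc <- .load_lc_modules(outdir, x$man, x$class_map, i)
    res <- screen_module_mrnas(lc, x$datasets[[st]], clinical,
                               alpha = config$survival_alpha)
    .write_tsv(res, file.path(sd_, sprintf("survival_%s.tsv", tag)), prov)
    rows <- c(rows, list(list(st, "n_screened", nrow(res)),
                         list(st, "n_significant", sum(res$significant))))
  }
  .write_report(outdir, "survival", rows, config)
  invisible(rows)
}

.stage_biomarkers <- function(config, outdir) {
  man <- .subtype_manifest(outdir)
  class_map <- read_class_map(.need(file.path(outdir, "data", "class_map.tsv"), "generate"))
  counts <- lapply(seq_len(nrow(man)), function(i)
    .read_counts(.need(file.path(outdir, "preprocess", sprintf("counts_%s.tsv", man$tag[i])),
                       "preprocess")))
  names(counts) <- man$subtype
  bd <- file.path(outdir, "biomarkers")
  dir.create(bd, showWarnings = FALSE, recursive = TRUE)
  prov <- .prov(config)
  rows <- list()
  for (i in seq_len(nrow(man))) {
    st <- man$subtype[i]; tag <- man$tag[i]
    lc <- .load_lc_modules(outdir, man, class_map, i)
    genes <- module_gene_union(lc)
    genes <- intersect(genes, rownames(counts[[st]]))
    deg <- pairwise_deg(counts, st, genes, config$lfc_threshold,
                        config$fdr_threshold, config$dispersion)
    for (st2 in names(deg))
      .write_tsv(deg[[st2]],
                 file.path(bd, sprintf("de_%s_vs_%s.tsv", tag, .sanitize(st2))), prov)
    bio <- intersect_biomarkers(deg)
    .write_tsv(as.data.frame(bio), file.path(bd, sprintf("biomarkers_%s.tsv", tag)), prov)
    rows <- c(rows, list(list(st, "n_tested", length(genes)),
                         list(st, "n_biomarkers", nrow(bio))))
  }
  .write_report(outdir, "biomarkers", rows, config)
  invisible(rows)
}

.stage_evaluate <- function(config, outdir) {
  x <- .load_datasets(outdir, "preprocess", "preprocess")
  vd <- file.path(outdir, "evaluate")
  dir.create(vd, showWarnings = FALSE, recursive = TRUE)
  prov <- .prov(config)
  rows <- list()
  for (i in seq_len(nrow(x$man))) {
    st <- x$man$subtype[i]; tag <- x$man$tag[i]
    bio <- .read_tsv(.need(file.path(outdir, "biomarkers", sprintf("biomarkers_%s.tsv", tag)),
                           "biomarkers"))
    if (!nrow(bio)) {
      rows <- c(rows, list(list(st, "mean_auc", NA)))
      next
    }
    cv <- svm_cv_evaluate(x$datasets, st, as.character(bio$gene),
                          folds = config$folds, seed = config$seed)
    .write_tsv(data.frame(fold = seq_along(cv$fold_auc), auc = cv$fold_auc),
               file.path(vd, sprintf("cv_%s.tsv", tag)), prov)
    roc <- do.call(rbind, lapply(seq_along(cv$roc), function(f)
      cbind(fold = f, cv$roc[[f]])))
    .write_tsv(roc, file.path(vd, sprintf("roc_%s.tsv", tag)), prov)
    rows <- c(rows, list(list(st, "mean_auc", sprintf("%.6f", cv$mean_auc))))
  }
  .write_report(outdir, "evaluate", rows, config)
  invisible(rows)
}

#' Run the whole pipeline
#'
#' Executes every stage in order against `outdir` (fails fast with
#' stage-tagged errors; artifacts from completed stages are retained),
#' then assembles the run report.  By construction this is identical,
#' artifact for artifact, to chaining [run_stage()] calls with the same
#' config.
#'
#' @param config a [pipeline_config].
#' @param outdir artifact directory.
#' @return a `run_report` (see [collect_run_report()]), invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  timing <- numeric()
  for (stage in PIPELINE_STAGES) {
    t0 <- proc.time()[["elapsed"]]
    run_stage(config, stage, outdir)
    timing[stage] <- proc.time()[["elapsed"]] - t0
  }
  rep <- collect_run_report(outdir)
  attr(rep, "timing") <- timing
  invisible(rep)
}

#' Assemble the run report from per-stage report artifacts
#'
#' Concatenates `reports/<stage>.tsv` in stage order into
#' `run_report.tsv` and returns it; callable after a staged run to
#' obtain the same report file a monolithic run writes.
#'
#' @param outdir artifact directory.
#' @return data.frame of class `run_report` (stage, subtype, metric,
#'   value).
#' @export
collect_run_report <- function(outdir) {
  parts <- list()
  for (stage in PIPELINE_STAGES) {
    p <- .report_path(outdir, stage)
    if (file.exists(p)) parts[[stage]] <- .read_tsv(p)
  }
  df <- do.call(rbind, parts)
  rownames(df) <- NULL
  utils::write.table(df, file.path(outdir, "run_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  structure(df, class = c("run_report", "data.frame"))
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run report\n")
  print.data.frame(x)
  invisible(x)
}
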