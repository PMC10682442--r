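# Gene-set over-representation for the lncRNA/circRNA modules:
# hypergeometric upper tail + Benjamini-Hochberg across all
# (module, set) tests.

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment, order-preserving with the input, capped
#' at 1 and monotone in rank.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Hypergeometric over-representation of modules in gene sets
#'
#' For a module of size n drawn from a universe of size N containing K
#' members of a set, the enrichment p-value is the upper tail
#' P[X >= k] of Hypergeometric(N, K, n) at the observed overlap k.
#' Gene sets are intersected with the universe before testing; BH
#' adjustment runs across all (module, set) tests and results are
#' sorted by FDR.
#'
#' @param modules a [module_set], or a named list of gene-id vectors.
#' @param sets a [gene_set_collection].
#' @param universe character vector of background gene ids (every module
#'   gene must be in it).
#' @return data.frame with columns module, set, k, n, K, N, p, fdr.
#' @export
hypergeom_enrich <- function(modules, sets, universe) {
  if (!length(universe)) .stopf("empty universe")
  universe <- unique(universe)
  mods <- if (inherits(modules, "module_set")) modules$modules else modules
  offenders <- unlist(lapply(mods, setdiff, y = universe), use.names = FALSE)
  if (length(offenders))
    .stopf("module gene(s) outside the universe: %s",
           paste(utils::head(unique(offenders), 5L), collapse = ", "))
  N <- length(universe)
  rows <- list()
  for (mi in seq_along(mods)) {
    mg <- unique(mods[[mi]])
    n <- length(mg)
    for (si in seq_along(sets$sets)) {
      sg <- intersect(sets$sets[[si]]$genes, universe)
      K <- length(sg)
      k <- length(intersect(mg, sg))
      p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        module = names(mods)[mi] %||% paste0("M", mi),
        set = names(sets$sets)[si], k = k, n = n, K = K, N = N, p = p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) return(data.frame(module = character(), set = character(),
                                      k = integer(), n = integer(), K = integer(),
                                      N = integer(), p = numeric(), fdr = numeric()))
  res$fdr <- bh_adjust(res$p)
  res <- res[order(res$fdr, res$p, res$module, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}
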