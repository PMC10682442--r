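# Synthetic multi-subtype data with planted ground truth: ceRNA triplets
# (shared latent factor), subtype biomarkers (fold-change), survival
# effects (exponential hazards), and distortion outliers.

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror a five-subtype breast-cancer-style design with
#' unequal cohort sizes and four RNA classes of class-specific
#' abundance (circRNA lowest).
#'
#' @param seed integer RNG seed; the whole synthesis is a pure function
#'   of the config including this seed.
#' @param subtypes named integer vector: subtype label -> sample count.
#' @param n_genes named integer vector: genes per RNA class.
#' @param n_triplets_common number of miRNA-sponge triplets planted in
#'   every subtype.
#' @param n_triplets_specific triplets planted per subtype, active only
#'   there.
#' @param triplet_strength target |Pearson r| of the planted pairwise
#'   correlations (0 < strength < 1).
#' @param triplet_cv marginal coefficient of variation of planted-gene
#'   expression on the linear scale.
#' @param n_biomarkers per-subtype count of planted differential genes,
#'   drawn from that subtype's specific-triplet sponges so they reach
#'   the module stage.
#' @param biomarker_log2fc planted log2 fold change (subtype vs rest).
#' @param nb_dispersion negative-binomial dispersion used when sampling
#'   the count matrices from the continuous expression means.
#' @param survival_effect log-hazard per unit z-score of the designated
#'   survival gene's expression.
#' @param baseline_hazard exponential baseline event rate (per time unit).
#' @param censor_rate target fraction of censored samples (uniform
#'   censoring horizon solved numerically).
#' @param n_outliers per-subtype count of distorted samples
#'   (scale-multiplied, gene-shuffled).
#' @param outlier_scale multiplicative distortion applied to outliers.
#' @param baseline_log_mean named numeric: class-level mean of per-gene
#'   baseline log-expression.
#' @param baseline_log_sd named numeric: within-gene log-normal noise sd
#'   (between samples).
#' @param gene_log_sd sd of per-gene baseline offsets around the class
#'   mean; baselines are drawn once and shared across subtypes so the
#'   between-subtype null holds for unplanted genes.
#' @param n_decoy_interactions validated-database decoy pairs per miRNA
#'   (random targets, no planted correlation).
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             subtypes = c("basal-like" = 88L, "luminal B" = 100L,
                                          "normal-like" = 76L, "luminal A" = 252L,
                                          "HER2+" = 42L),
                             n_genes = c(mRNA = 150L, lncRNA = 60L,
                                         circRNA = 40L, miRNA = 50L),
                             n_triplets_common = 2L,
                             n_triplets_specific = 2L,
                             triplet_strength = 0.7,
                             triplet_cv = 0.3,
                             n_biomarkers = 2L,
                             biomarker_log2fc = 2.0,
                             nb_dispersion = 0.2,
                             survival_effect = 0.8,
                             baseline_hazard = 0.1,
                             censor_rate = 0.3,
                             n_outliers = 3L,
                             outlier_scale = 5.0,
                             baseline_log_mean = c(mRNA = 3.0, lncRNA = 1.5,
                                                   circRNA = 0.5, miRNA = 2.5),
                             baseline_log_sd = c(mRNA = 0.5, lncRNA = 0.5,
                                                 circRNA = 0.5, miRNA = 0.5),
                             gene_log_sd = 1.5,
                             n_decoy_interactions = 3L) {
  cfg <- list(seed = as.integer(seed), subtypes = subtypes, n_genes = n_genes,
              n_triplets_common = n_triplets_common,
              n_triplets_specific = n_triplets_specific,
              triplet_strength = triplet_strength, triplet_cv = triplet_cv,
              n_biomarkers = n_biomarkers, biomarker_log2fc = biomarker_log2fc,
              nb_dispersion = nb_dispersion, survival_effect = survival_effect,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              n_outliers = n_outliers, outlier_scale = outlier_scale,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              gene_log_sd = gene_log_sd,
              n_decoy_interactions = n_decoy_interactions)
  if (is.null(names(cfg$subtypes)) || any(!nzchar(names(cfg$subtypes))))
    .stopf("'subtypes' must be a named vector: label -> sample count")
  if (anyDuplicated(names(cfg$subtypes))) .stopf("subtype labels must be unique")
  if (any(cfg$subtypes < 1)) .stopf("every subtype needs >= 1 sample")
  miss <- setdiff(RNA_CLASSES, names(cfg$n_genes))
  if (length(miss)) .stopf("'n_genes' missing class(es): %s", paste(miss, collapse = ", "))
  for (nm in c("n_triplets_common", "n_triplets_specific", "n_biomarkers", "n_outliers"))
    if (cfg[[nm]] < 0) .stopf("'%s' must be >= 0", nm)
  if (cfg$triplet_strength <= 0 || cfg$triplet_strength >= 1)
    .stopf("'triplet_strength' must be in (0, 1)")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    .stopf("'censor_rate' must be in [0, 1)")
  if (any(cfg$n_outliers >= cfg$subtypes))
    .stopf("'n_outliers' must be smaller than every cohort size")
  structure(cfg, class = "generator_config")
}

# sponge-pair compositions cycled over when planting triplets; pairs with
# both sponges in {mRNA, lncRNA} get their miRNA-target pairs inserted in
# the validated database, circRNA-containing pairs never do.
.TRIPLET_COMPS <- list(c("mRNA", "lncRNA"), c("mRNA", "circRNA"),
                       c("circRNA", "circRNA"), c("mRNA", "mRNA"),
                       c("lncRNA", "circRNA"))

.sanitize <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

#' Generate a synthetic multi-subtype ceRNA study
#'
#' Produces one expression dataset per subtype over a shared gene list
#' (all four RNA classes), matched count matrices for the
#' differential-expression stage, a validated miRNA-target interaction
#' database, a clinical survival table, and the planted ground truth.
#'
#' Background genes are log-normal with per-gene baselines shared across
#' subtypes.  Each planted triplet (miRNA, sponge_a, sponge_b) draws a
#' latent activity factor per sample; the miRNA loads negatively and
#' both sponges positively with loading sqrt(strength), so every
#' pairwise |r| targets `triplet_strength` within the scoped subtype(s)
#' only.  Planted baselines are clamped upwards so the default
#' mean-expression filter cannot remove a planted signal.
#'
#' @param config a [generator_config].
#' @return list of class `cerna_synthesis` with elements `datasets`
#'   (named list of [expression_dataset]), `counts` (named list of
#'   integer matrices), `interactions` ([interaction_db]), `clinical`
#'   ([clinical_table]), `truth` (ground-truth list: `triplets` data
#'   frame, `biomarkers`, `survival_genes`, `outliers`) and `config`.
#' @export
generate_synthetic <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  subtypes <- names(config$subtypes)

  # gene universe and shared per-gene baselines
  ids <- lapply(RNA_CLASSES, function(cl)
    sprintf("%s_%03d", sub("miRNA", "miR", cl), seq_len(config$n_genes[[cl]])))
  names(ids) <- RNA_CLASSES
  genes <- unlist(ids, use.names = FALSE)
  classes <- stats::setNames(rep(RNA_CLASSES, times = lengths(ids)), genes)
  mu <- stats::setNames(
    config$baseline_log_mean[classes] + stats::rnorm(length(genes), 0, config$gene_log_sd),
    genes)
  lsd <- stats::setNames(unname(config$baseline_log_sd[classes]), genes)

  # reserve planted genes class by class
  ptr <- stats::setNames(rep(1L, length(RNA_CLASSES)), RNA_CLASSES)
  take <- function(cl) {
    i <- ptr[[cl]]
    if (i > config$n_genes[[cl]])
      .stopf("planted-triplet demand exceeds available %s genes", cl)
    ptr[[cl]] <<- i + 1L
    ids[[cl]][i]
  }
  make_triplets <- function(n, scope, comp_offset) {
    if (n == 0L) return(NULL)
    do.call(rbind, lapply(seq_len(n), function(k) {
      comp <- .TRIPLET_COMPS[[((k - 1L + comp_offset) %% length(.TRIPLET_COMPS)) + 1L]]
      data.frame(miRNA = take("miRNA"), sponge_a = take(comp[1L]),
                 sponge_b = take(comp[2L]), class_a = comp[1L], class_b = comp[2L],
                 scope = scope, db = all(comp %in% c("mRNA", "lncRNA")),
                 stringsAsFactors = FALSE)
    }))
  }
  trip <- make_triplets(config$n_triplets_common, "common", 0L)
  for (i in seq_along(subtypes))
    trip <- rbind(trip, make_triplets(config$n_triplets_specific, subtypes[i], i - 1L))
  if (is.null(trip))
    trip <- data.frame(miRNA = character(), sponge_a = character(),
                       sponge_b = character(), class_a = character(),
                       class_b = character(), scope = character(), db = logical(),
                       stringsAsFactors = FALSE)
  planted <- unique(c(trip$miRNA, trip$sponge_a, trip$sponge_b))
  mu[planted] <- pmax(mu[planted], log(4))

  # biomarkers: sponges of the subtype's specific triplets, restricted to
  # triplets whose sponge pair contains a lncRNA or circRNA -- an
  # mRNA-only pair forms a module the lncRNA/circRNA filter discards, so
  # a biomarker planted there could never reach the screening stages
  lc_eligible <- !(trip$class_a == "mRNA" & trip$class_b == "mRNA")
  biomarkers <- lapply(subtypes, function(st) {
    sel <- trip$scope == st & lc_eligible
    pool <- unique(unlist(trip[sel, c("sponge_a", "sponge_b")], use.names = FALSE))
    if (config$n_biomarkers > length(pool))
      .stopf("n_biomarkers (%d) exceeds specific-triplet sponge genes (%d) for '%s'",
             config$n_biomarkers, length(pool), st)
    pool[seq_len(config$n_biomarkers)]
  })
  names(biomarkers) <- subtypes

  # survival gene: an mRNA sponge of the subtype's specific triplets,
  # falling back to the first background mRNA (clamped upwards)
  survival_genes <- vapply(subtypes, function(st) {
    sp <- unlist(trip[trip$scope == st & lc_eligible, c("sponge_a", "sponge_b")],
                 use.names = FALSE)
    sp <- sp[classes[sp] == "mRNA"]
    if (length(sp)) sp[1L] else ids$mRNA[config$n_genes[["mRNA"]]]
  }, character(1))
  mu[survival_genes] <- pmax(mu[survival_genes], log(4))

  # interaction database: planted pairs (both-sponge mRNA/lncRNA triplets
  # only) plus random decoys
  db_mi <- character(); db_tg <- character()
  dbt <- trip[trip$db, , drop = FALSE]
  if (nrow(dbt)) {
    db_mi <- c(rbind(dbt$miRNA, dbt$miRNA))
    db_tg <- c(rbind(dbt$sponge_a, dbt$sponge_b))
  }
  if (config$n_decoy_interactions > 0L) {
    targets <- c(ids$mRNA, ids$lncRNA)
    for (m in ids$miRNA) {
      db_mi <- c(db_mi, rep(m, config$n_decoy_interactions))
      db_tg <- c(db_tg, sample(targets, config$n_decoy_interactions))
    }
  }
  interactions <- interaction_db(db_mi, db_tg, "synthetic")

  lam <- sqrt(config$triplet_strength)
  datasets <- list(); counts <- list(); clin <- list(); outliers <- list()
  for (st in subtypes) {
    n <- config$subtypes[[st]]
    samples <- sprintf("%s_s%03d", .sanitize(st), seq_len(n))
    vals <- exp(matrix(stats::rnorm(length(genes) * n), length(genes), n) * lsd + mu)
    dimnames(vals) <- list(genes, samples)

    active <- trip[trip$scope %in% c("common", st), , drop = FALSE]
    for (k in seq_len(nrow(active))) {
      m <- stats::rnorm(n)
      zm <- -(lam * m + sqrt(1 - lam^2) * stats::rnorm(n))
      za <- lam * m + sqrt(1 - lam^2) * stats::rnorm(n)
      zb <- lam * m + sqrt(1 - lam^2) * stats::rnorm(n)
      for (pair in list(list(active$miRNA[k], zm), list(active$sponge_a[k], za),
                        list(active$sponge_b[k], zb))) {
        g <- pair[[1L]]
        gm <- exp(mu[[g]] + lsd[[g]]^2 / 2)
        vals[g, ] <- pmax(gm * (1 + config$triplet_cv * pair[[2L]]), gm * 1e-3)
      }
    }
    if (length(biomarkers[[st]]))
      vals[biomarkers[[st]], ] <- vals[biomarkers[[st]], , drop = FALSE] * 2^config$biomarker_log2fc

    # survival before outlier distortion: hazards follow the clean signal
    z <- as.numeric(scale(vals[survival_genes[[st]], ]))
    if (any(!is.finite(z))) z <- rep(0, n)
    rate <- config$baseline_hazard * exp(config$survival_effect * z)
    tt <- stats::rexp(n, rate)
    if (config$censor_rate > 0) {
      f <- function(tau) mean(pmin(tt / tau, 1)) - config$censor_rate
      tau <- stats::uniroot(f, c(min(tt) * 1e-3, max(tt) * 1e3))$root
      cc <- stats::runif(n, 0, tau)
      time <- pmin(tt, cc); event <- as.integer(tt <= cc)
    } else {
      time <- tt; event <- rep(1L, n)
    }
    clin[[st]] <- data.frame(sample = samples, time = time, event = event,
                             subtype = st, stringsAsFactors = FALSE)

    out_idx <- if (config$n_outliers > 0L) seq(n - config$n_outliers + 1L, n) else integer()
    for (j in out_idx)
      vals[, j] <- vals[sample(length(genes)), j] * config$outlier_scale
    outliers[[st]] <- samples[out_idx]

    cnt <- if (config$nb_dispersion > 0) {
      matrix(stats::rnbinom(length(vals), mu = vals, size = 1 / config$nb_dispersion),
             nrow(vals), ncol(vals), dimnames = dimnames(vals))
    } else {
      matrix(stats::rpois(length(vals), lambda = vals),
             nrow(vals), ncol(vals), dimnames = dimnames(vals))
    }

    datasets[[st]] <- expression_dataset(vals, classes, st)
    counts[[st]] <- cnt
  }

  clinical <- do.call(rbind, clin)
  clinical <- clinical_table(clinical$sample, clinical$time, clinical$event, clinical$subtype)
  truth <- list(triplets = trip, biomarkers = biomarkers,
                survival_genes = survival_genes, outliers = outliers,
                classes = classes)
  structure(list(datasets = datasets, counts = counts,
                 interactions = interactions, clinical = clinical,
                 truth = truth, config = config),
            class = "cerna_synthesis")
}

#' @export
print.cerna_synthesis <- function(x, ...) {
  cat(sprintf("cerna_synthesis: %d subtypes, %d genes, %d planted triplets, seed %d\n",
              length(x$datasets), length(x$truth$classes), nrow(x$truth$triplets),
              x$config$seed))
  invisible(x)
}

#' Planted ceRNA edges expected in one subtype's primary network
#'
#' The sponge pair of every triplet scoped to the subtype (its own
#' specific triplets plus the common ones).
#'
#' @param truth the `truth` element of a [generate_synthetic()] result.
#' @param subtype subtype label.
#' @param scope_only if TRUE, only the subtype-specific triplets.
#' @return data.frame with canonical `node_a`/`node_b` columns.
#' @export
planted_edges <- function(truth, subtype, scope_only = FALSE) {
  sel <- if (scope_only) truth$triplets$scope == subtype
         else truth$triplets$scope %in% c("common", subtype)
  t2 <- truth$triplets[sel, , drop = FALSE]
  a <- pmin(t2$sponge_a, t2$sponge_b); b <- pmax(t2$sponge_a, t2$sponge_b)
  unique(data.frame(node_a = a, node_b = b, stringsAsFactors = FALSE))
}
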