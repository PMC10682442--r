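# Kaplan-Meier estimation and log-rank screening of module mRNAs with
# mean-expression grouping.  The estimators are computed through the
# survival package; this file owns the grouping rule and the screen.

#' Kaplan-Meier product-limit estimate
#'
#' @param times non-negative follow-up times.
#' @param events 1 = event observed, 0 = censored.
#' @return data.frame of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `survival` at the distinct event/censoring times;
#'   survival starts at 1 and is non-increasing.  With only censored
#'   records the curve is identically 1.
#' @export
km_estimate <- function(times, events) {
  if (any(times < 0) || any(!is.finite(times))) .stopf("times must be finite and >= 0")
  if (!all(events %in% c(0, 1))) .stopf("events must be 0/1")
  if (!length(times)) .stopf("need >= 1 record")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, survival = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a KM curve at arbitrary times
#'
#' @param curve a `km_curve` from [km_estimate()].
#' @param t times at which to read the step function.
#' @return survival probabilities (right-continuous step function,
#'   S(t) = 1 before the first recorded time).
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(tt) {
    i <- which(curve$time <= tt)
    if (!length(i)) 1 else curve$survival[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard log-rank with hypergeometric variance (tie-corrected):
#' chi-square = (sum O - sum E)^2 / sum V against chi-square(1).
#'
#' @param times_a,events_a,times_b,events_b per-group follow-up data.
#' @return list with `chi_square`, `p`, `n` (total records).  If neither
#'   group has any event, `chi_square = 0`, `p = 1` with a warning.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b)) .stopf("both groups must be non-empty")
  if (sum(events_a) + sum(events_b) == 0) {
    .warnf("no events in either group: log-rank undefined, returning p = 1")
    return(list(chi_square = 0, p = 1, n = length(times_a) + length(times_b)))
  }
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  grp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chi <- unname(sd$chisq)
  list(chi_square = chi, p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       n = length(time))
}

#' Survival screen of module mRNAs
#'
#' For every mRNA in the union of module genes, samples are split at the
#' gene's mean expression (strictly greater = high group) and the two
#' groups compared by log-rank.  Genes for which one group is empty
#' (e.g. constant expression) are skipped with a warning.
#'
#' @param modules a [module_set] (same subtype as the dataset).
#' @param dataset an [expression_dataset]; its samples must appear in
#'   the clinical table.
#' @param clinical a [clinical_table].
#' @param alpha significance level used to flag genes (raw log-rank p).
#' @param keep_curves if TRUE, per-gene high/low [km_estimate()] curves
#'   are attached as the `"curves"` attribute.
#' @return data.frame with columns gene, subtype, n_high, n_low,
#'   chi_square, p, significant.
#' @export
screen_module_mrnas <- function(modules, dataset, clinical, alpha = 0.05,
                                keep_curves = FALSE) {
  samples <- colnames(dataset$values)
  idx <- match(samples, clinical$sample)
  if (anyNA(idx)) .stopf("clinical table missing sample(s): %s",
                         paste(utils::head(samples[is.na(idx)], 5L), collapse = ", "))
  time <- clinical$time[idx]; event <- clinical$event[idx]
  genes <- module_gene_union(modules, "mRNA")
  genes <- intersect(genes, rownames(dataset$values))
  rows <- list(); curves <- list()
  for (g in genes) {
    x <- dataset$values[g, ]
    high <- x > mean(x)
    if (!any(high) || all(high)) {
      .warnf("skipping gene '%s': empty expression group at the mean split", g)
      next
    }
    lr <- logrank_test(time[high], event[high], time[!high], event[!high])
    rows[[g]] <- data.frame(gene = g, subtype = dataset$subtype,
                            n_high = sum(high), n_low = sum(!high),
                            chi_square = lr$chi_square, p = lr$p,
                            significant = lr$p < alpha,
                            stringsAsFactors = FALSE)
    if (keep_curves)
      curves[[g]] <- list(high = km_estimate(time[high], event[high]),
                          low = km_estimate(time[!high], event[!high]))
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), subtype = character(), n_high = integer(),
               n_low = integer(), chi_square = numeric(), p = numeric(),
               significant = logical(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  if (keep_curves) attr(res, "curves") <- curves
  res
}
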