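# independent reference implementations used as oracles; these
# deliberately share no code with the package internals

# literal enumeration of every (pair, mediator) triplet rule
oracle_primary_edges <- function(dataset, db, corr = 0.4, pthr = 0.05) {
  v <- dataset$values
  cls <- dataset$classes
  n <- ncol(v)
  genes <- rownames(v)
  mir <- genes[cls[genes] == "miRNA"]
  sp <- genes[cls[genes] %in% c("mRNA", "lncRNA", "circRNA")]
  dbp <- paste(db$miRNA, db$target)
  rp <- function(a, b) {
    r <- stats::cor(v[a, ], v[b, ])
    p <- if (abs(r) >= 1) 0 else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tt), n - 2)
    }
    c(r = r, p = p)
  }
  out <- list()
  if (length(sp) >= 2) for (i in 2:length(sp)) for (j in 1:(i - 1)) {
    u <- sp[i]; w <- sp[j]
    pc <- cls[c(u, w)]
    both_ml <- all(pc %in% c("mRNA", "lncRNA"))
    has_circ <- any(pc == "circRNA")
    uw <- rp(u, w)
    if (!(uw["r"] > corr && uw["p"] < pthr)) next
    supp <- character()
    for (t in mir) {
      tu <- rp(t, u); tw <- rp(t, w)
      if (!(tu["r"] < -corr && tu["p"] < pthr && tw["r"] < -corr && tw["p"] < pthr)) next
      if (both_ml) {
        if (paste(t, u) %in% dbp && paste(t, w) %in% dbp) supp <- c(supp, t)
      } else if (has_circ) {
        supp <- c(supp, t)
      }
    }
    if (length(supp))
      out[[length(out) + 1L]] <- data.frame(node_a = min(u, w), node_b = max(u, w),
                                            supp = paste(sort(supp), collapse = ","),
                                            stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(node_a = character(), node_b = character(),
                                      supp = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$node_a, res$node_b), , drop = FALSE]
}

# plain dense-matrix Markov clustering on a given adjacency matrix
reference_mcl <- function(A, inflation = 2, expansion = 2, prune = 1e-5,
                          tol = 1e-8, maxit = 100) {
  M <- A %*% diag(1 / colSums(A))
  dimnames(M) <- dimnames(A)
  for (it in seq_len(maxit)) {
    start <- M
    X <- start
    if (expansion >= 2) for (k in 2:expansion) X <- X %*% start
    X <- X^inflation
    X[X < prune] <- 0
    cs <- colSums(X)
    zero <- cs == 0
    if (any(zero)) { for (j in which(zero)) X[j, j] <- 1; cs[zero] <- 1 }
    X <- X %*% diag(1 / cs)
    dimnames(X) <- dimnames(A)
    M <- X
    if (max(abs(M - start)) < tol) break
  }
  owner <- apply(M, 2, which.max)
  repeat {
    nxt <- owner[owner]
    if (all(nxt == owner)) break
    owner <- nxt
  }
  lab <- colnames(A)
  unname(lapply(split(seq_along(lab), owner), function(ix) sort(lab[ix])))
}

# adjacency with max-incident-weight self-loops, built from first principles
adjacency_of <- function(network) {
  g <- network$nodes$gene
  A <- matrix(0, length(g), length(g), dimnames = list(g, g))
  e <- network$edges
  for (i in seq_len(nrow(e))) {
    A[e$node_a[i], e$node_b[i]] <- e$weight[i]
    A[e$node_b[i], e$node_a[i]] <- e$weight[i]
  }
  for (j in seq_along(g)) A[j, j] <- max(max(A[, j]), .Machine$double.eps)
  A
}

# literal step-up definition: adj_i = min over {j : p_j >= p_i} of m p_j / r_j
naive_bh <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi]
    min(1, min(m * cand / vapply(cand, function(x) sum(p <= x), numeric(1))))
  }, numeric(1))
}

# exact two-sided binomial p: total probability of outcomes no more likely
# than the observed one
binom_two_sided <- function(x, n, prob = 0.5) {
  d <- stats::dbinom(0:n, n, prob)
  sum(d[d <= d[x + 1L]])
}

# upper-tail hypergeometric by full enumeration of overlap outcomes
hyper_upper_enum <- function(k, N, K, n) {
  ks <- max(0, n - (N - K)):min(n, K)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= k])
}

# hand product-limit estimator
oracle_km <- function(times, events) {
  tt <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(tt))
  for (i in seq_along(tt)) {
    ni <- sum(times >= tt[i])
    di <- sum(times == tt[i] & events == 1)
    s <- s * (1 - di / ni)
    out[i] <- s
  }
  data.frame(time = tt, survival = out)
}

# hand log-rank: observed vs hypergeometric-expected events per event time
oracle_logrank <- function(t1, e1, t2, e2) {
  tt <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  O <- 0; E <- 0; V <- 0
  for (s in tt) {
    n1 <- sum(t1 >= s); n2 <- sum(t2 >= s)
    d1 <- sum(t1 == s & e1 == 1); d2 <- sum(t2 == s & e2 == 1)
    n <- n1 + n2; d <- d1 + d2
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chi <- (O - E)^2 / V
  list(chi_square = chi, p = stats::pchisq(chi, 1, lower.tail = FALSE))
}

# trapezoidal AUC from scores, computed from the ROC definition
oracle_auc <- function(scores, positive) {
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(ths, function(t) mean(scores[positive] >= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(scores[!positive] >= t), numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
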