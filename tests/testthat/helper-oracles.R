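# Independent brute-force oracles, written directly from the mathematical
# definitions with plain loops. They never call into the package's scoring
# path; the tests compare the two routes.

# `parents` is a named list: every term id has an entry, possibly
# character(0) for roots.

oracle_ancestors <- function(parents, t) {
  acc <- character(0)
  frontier <- t
  repeat {
    new <- setdiff(frontier, acc)
    if (!length(new)) break
    acc <- c(acc, new)
    frontier <- unlist(parents[new], use.names = FALSE)
  }
  sort(unique(acc))
}

oracle_ic <- function(parents, corpus) {
  ids <- names(parents)
  n <- length(corpus)
  counts <- stats::setNames(rep(0L, length(ids)), ids)
  for (ts in corpus) {
    hit <- unique(unlist(lapply(unique(ts), function(t) {
      oracle_ancestors(parents, t)
    })))
    counts[hit] <- counts[hit] + 1L
  }
  ic <- ifelse(counts == 0L, log(n), -log(counts / n))
  ic[lengths(parents) == 0L] <- 0
  ic
}

oracle_mica_ic <- function(parents, ic, t1, t2) {
  common <- intersect(oracle_ancestors(parents, t1),
                      oracle_ancestors(parents, t2))
  if (!length(common)) 0 else max(ic[common])
}

oracle_term_sim <- function(parents, ic, q, h) {
  a <- oracle_ancestors(parents, q)
  b <- oracle_ancestors(parents, h)
  common <- intersect(a, b)
  if (!length(common)) return(0)
  j <- length(common) / length(union(a, b))
  sqrt(j * max(ic[common]))
}

# Full scalar re-derivation of the percentage score: all pairwise
# similarities, per-query best, max/mean, self-optimum, equal-weight
# normalisation, clamp.
oracle_phenodigm <- function(parents, ic, query_terms, hit_terms) {
  best <- numeric(length(query_terms))
  for (i in seq_along(query_terms)) {
    sims <- numeric(length(hit_terms))
    for (j in seq_along(hit_terms)) {
      sims[j] <- oracle_term_sim(parents, ic, query_terms[i], hit_terms[j])
    }
    best[i] <- max(sims)
  }
  self <- sqrt(ic[query_terms])
  opt_max <- max(self)
  opt_mean <- mean(self)
  if (opt_max <= 0) {
    return(list(raw_max = max(best), raw_mean = mean(best),
                percentage = 0))
  }
  pct <- 100 * (max(best) / opt_max + mean(best) / opt_mean) / 2
  list(raw_max = max(best), raw_mean = mean(best),
       percentage = min(max(pct, 0), 100))
}

# Random DAG as a parent map: term i > 1 gets one uniformly chosen earlier
# parent plus extra earlier parents with probability p_extra each (capped
# at 2 extras). Uses the ambient RNG state.
random_dag <- function(n_terms, p_extra = 0.25) {
  ids <- sprintf("T%03d", seq_len(n_terms))
  parents <- stats::setNames(vector("list", n_terms), ids)
  parents[[1L]] <- character(0)
  for (i in seq_len(n_terms)[-1L]) {
    ps <- ids[sample.int(i - 1L, 1L)]
    n_extra <- stats::rbinom(1L, min(2L, i - 1L), p_extra)
    if (n_extra > 0L) {
      ps <- unique(c(ps, ids[sample.int(i - 1L, n_extra)]))
    }
    parents[[i]] <- ps
  }
  parents
}

random_corpus <- function(ids, n_entities = 8L, max_terms = 3L) {
  lapply(seq_len(n_entities), function(i) {
    ids[sample.int(length(ids), sample.int(max_terms, 1L))]
  })
}

obo_from_parents <- function(parents) {
  unlist(lapply(names(parents), function(id) {
    c("[Term]", paste0("id: ", id),
      paste0("is_a: ", parents[[id]]), "")
  }))
}

# Exact two-sided Fisher p by hypergeometric enumeration: sum the
# probabilities of all tables (same margins) no more probable than the
# observed one.
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  lo <- max(0L, k - m2)
  hi <- min(k, m1)
  probs <- stats::dhyper(lo:hi, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up: q(i) = min_{j >= i} p(j) * m / j over the
# sorted p-values, mapped back to the input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exact two-sided Wilcoxon rank-sum p by exhaustive enumeration of all
# group assignments (small n, no ties).
oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(pooled), n)
  w_all <- apply(combos, 2L, function(idx) {
    sum(r[idx]) - n * (n + 1) / 2
  })
  mu <- n * length(y) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
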