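# Naive brute-force reimplementations used as independent oracles.
# Deliberately slow and literal; never call package internals.

oracle_shannon <- function(x) {
  p <- x[x > 0] / sum(x)
  h <- 0
  for (pi in p) h <- h - pi * log(pi)
  h
}

oracle_bray <- function(x, y) {
  sum(abs(x - y)) / sum(x + y)
}

# beta-MNTD by double loops over taxa of each community.
oracle_bmntd <- function(ca, cb, d, weighted = TRUE) {
  ta <- which(ca > 0)
  tb <- which(cb > 0)
  wa <- if (weighted) ca[ta] / sum(ca[ta]) else rep(1 / length(ta), length(ta))
  wb <- if (weighted) cb[tb] / sum(cb[tb]) else rep(1 / length(tb), length(tb))
  s1 <- 0
  for (k in seq_along(ta)) {
    mind <- Inf
    for (l in tb) mind <- min(mind, d[ta[k], l])
    s1 <- s1 + wa[k] * mind
  }
  s2 <- 0
  for (k in seq_along(tb)) {
    mind <- Inf
    for (l in ta) mind <- min(mind, d[tb[k], l])
    s2 <- s2 + wb[k] * mind
  }
  unname((s1 + s2) / 2)
}

oracle_levins <- function(counts_taxon) {
  P <- counts_taxon / sum(counts_taxon)
  1 / sum(P^2)
}

oracle_simper_pair <- function(p, q) {
  abs(p - q) / sum(p + q)
}

# Zi / Pi from an adjacency matrix and module membership, by loops.
oracle_zipi <- function(adj, memb) {
  n <- nrow(adj)
  mods <- sort(unique(memb))
  kis <- numeric(n)
  for (i in seq_len(n))
    kis[i] <- sum(adj[i, memb == memb[i]])
  zi <- numeric(n)
  for (i in seq_len(n)) {
    members <- which(memb == memb[i])
    mu <- mean(kis[members])
    s <- stats::sd(kis[members])
    zi[i] <- if (is.na(s) || s == 0) 0 else (kis[i] - mu) / s
  }
  pi <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(adj[i, ])
    if (k == 0) { pi[i] <- 0; next }
    acc <- 0
    for (m in mods) acc <- acc + (sum(adj[i, memb == m]) / k)^2
    pi[i] <- 1 - acc
  }
  list(Zi = zi, Pi = pi)
}

# Newman modularity Q = sum_m (e_mm - a_m^2) from adjacency + membership.
oracle_modularity <- function(adj, memb) {
  E2 <- sum(adj)                       # 2 * edge count for 0/1 symmetric adj
  if (E2 == 0) return(0)
  q <- 0
  for (m in unique(memb)) {
    idx <- memb == m
    e_mm <- sum(adj[idx, idx]) / E2
    a_m <- sum(adj[idx, ]) / E2
    q <- q + e_mm - a_m^2
  }
  q
}

# helper: co-assignment agreement between two partitions
co_assignment_accuracy <- function(a, b) {
  pr <- utils::combn(length(a), 2)
  same_a <- a[pr[1, ]] == a[pr[2, ]]
  same_b <- b[pr[1, ]] == b[pr[2, ]]
  mean(same_a == same_b)
}
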