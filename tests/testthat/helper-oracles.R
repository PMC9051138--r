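# Independent oracles used across tests; deliberately written without
# reference to the package internals they check.

# Two-level map equation (in bits) of a node partition of a weighted
# undirected graph given as an edge data.frame (i, j, w) over nodes 1..n.
# membership: integer vector of module labels per node.
map_equation_bits <- function(edges, n, membership) {
  plogp <- function(x) ifelse(x > 0, x * log2(x), 0)
  strength <- numeric(n)
  for (r in seq_len(nrow(edges))) {
    strength[edges$i[r]] <- strength[edges$i[r]] + edges$w[r]
    strength[edges$j[r]] <- strength[edges$j[r]] + edges$w[r]
  }
  W2 <- sum(strength)                      # = 2 * total weight
  p <- strength / W2
  mods <- sort(unique(membership))
  q <- numeric(length(mods))
  for (r in seq_len(nrow(edges))) {
    mi <- membership[edges$i[r]]
    mj <- membership[edges$j[r]]
    if (mi != mj) {
      q[match(mi, mods)] <- q[match(mi, mods)] + edges$w[r] / W2
      q[match(mj, mods)] <- q[match(mj, mods)] + edges$w[r] / W2
    }
  }
  p_mod <- vapply(mods, function(m) sum(p[membership == m]), 1)
  plogp(sum(q)) - 2 * sum(plogp(q)) + sum(plogp(q + p_mod)) - sum(plogp(p))
}

# Brute-force per-node top-k edge nomination (the sparse-graph rule):
# returns a data.frame (i, j, w) with i < j, union of per-node picks,
# ties broken by lexicographic neighbor id.
brute_force_topk <- function(sim, ids, k) {
  n <- nrow(sim)
  picked <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(-sim[i, others], ids[others])]
    take <- head(ord, k)
    take <- take[sim[i, take] > 0]
    picked[i, take] <- TRUE
  }
  keep <- picked | t(picked)
  out <- data.frame(i = integer(0), j = integer(0), w = numeric(0))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (keep[i, j]) out <- rbind(out, data.frame(i = i, j = j, w = sim[i, j]))
  }
  out
}

# Numerical-integration KL divergence between two univariate normals.
kl_numeric <- function(m1, v1, m2, v2) {
  f <- function(x) {
    p <- stats::dnorm(x, m1, sqrt(v1))
    q <- stats::dnorm(x, m2, sqrt(v2))
    ifelse(p > 0, p * (stats::dnorm(x, m1, sqrt(v1), log = TRUE) -
                         stats::dnorm(x, m2, sqrt(v2), log = TRUE)), 0)
  }
  stats::integrate(f, m1 - 12 * sqrt(v1), m1 + 12 * sqrt(v1),
                   rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# Convert an igraph produced by the package into the (i, j, w) edge frame
# used by the oracles, with nodes indexed by sorted name order.
graph_to_edges <- function(g) {
  ids <- sort(igraph::V(g)$name)
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0L) {
    return(list(edges = data.frame(i = integer(0), j = integer(0),
                                   w = numeric(0)), ids = ids))
  }
  i <- match(el[, 1], ids)
  j <- match(el[, 2], ids)
  list(edges = data.frame(i = pmin(i, j), j = pmax(i, j),
                          w = igraph::E(g)$weight), ids = ids)
}
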