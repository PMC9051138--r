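test_that("closed-form normal KL matches numerical integration", {
  expect_equal(kl_normal(0, 1, 0, 1), 0)
  expect_equal(kl_normal(0, 1, 1, 1), 0.5)   # symmetrized KL of N(0,1), N(1,1)
  withr::local_seed(101)
  for (rep in 1:100) {
    m1 <- runif(1, -5, 5); m2 <- runif(1, -5, 5)
    v1 <- runif(1, 0.2, 4); v2 <- runif(1, 0.2, 4)
    oracle <- 0.5 * (kl_numeric(m1, v1, m2, v2) + kl_numeric(m2, v2, m1, v1))
    expect_equal(kl_normal(m1, v1, m2, v2), oracle, tolerance = 1e-6)
    expect_equal(kl_normal(m1, v1, m2, v2), kl_normal(m2, v2, m1, v1))
  }
  # multi-sample argument averages over samples
  expect_equal(kl_normal(c(0, 0), c(1, 1), c(1, 0), c(1, 1)),
               (kl_normal(0, 1, 1, 1) + 0) / 2)
  expect_error(kl_normal(NA, 1, 0, 1), "non-finite")
})

test_that("pair similarity follows the two-regime formula", {
  expect_equal(pair_similarity(0, 0.5, n_samples = 1), 1)
  expect_equal(pair_similarity(0, n_samples = 5), 1)
  expect_equal(pair_similarity(2, n_samples = 5), 0)
  expect_equal(pair_similarity(0.5, 0.8, n_samples = 1), 0.6)
  expect_equal(pair_similarity(0.5, n_samples = 6), 0.5)
  # clamping of the abundance multiplier
  expect_equal(pair_similarity(0.5, 0, n_samples = 1), 1 - 0.5 * 1e-6)
  expect_error(pair_similarity(0.5, NULL, n_samples = 2), "abundance")
})

test_that("sparse graph equals the brute-force top-k oracle", {
  withr::local_seed(55)
  for (rep in 1:50) {
    n <- sample(5:30, 1)
    k <- sample(1:6, 1)
    ids <- sprintf("n%02d", sample.int(99, n))
    vec <- matrix(rnorm(n * 3, sd = 0.3), n, dimnames = list(ids, NULL))
    dm <- matrix(runif(n, 1, 40), n, 1, dimnames = list(ids, "S1"))
    dv <- dm + 0.05 * dm^2
    g <- build_sparse_graph(vec, max_edges = k, n_samples = 1,
                            depth_means = dm, depth_vars = dv)
    got <- graph_to_edges(g)

    ord <- order(ids)
    d <- as.matrix(dist(vec[ord, , drop = FALSE]))
    sim <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j) {
        a <- kl_normal(dm[ord[i]], dv[ord[i]], dm[ord[j]], dv[ord[j]])
        sim[i, j] <- pair_similarity(d[i, j], a, n_samples = 1)
      }
    }
    want <- brute_force_topk(sim, ids[ord], k)
    got_key <- sort(paste(got$edges$i, got$edges$j))
    want_key <- sort(paste(want$i, want$j))
    expect_equal(got_key, want_key)
    # weights equal independently recomputed similarities
    m <- merge(got$edges, want, by = c("i", "j"))
    expect_equal(m$w.x, m$w.y, tolerance = 1e-12)
  }
})

test_that("graph intersection equals the set-intersection oracle", {
  mk <- function(edges, ids) {
    g <- igraph::make_empty_graph(length(ids), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = ids)
    if (nrow(edges)) {
      g <- igraph::add_edges(g, rbind(ids[edges$i], ids[edges$j]),
                             weight = edges$w)
    }
    g
  }
  ids <- sprintf("n%d", 1:8)
  withr::local_seed(77)
  for (rep in 1:20) {
    all_pairs <- t(combn(8, 2))
    pick <- function() {
      sel <- sample(nrow(all_pairs), sample(3:12, 1))
      data.frame(i = all_pairs[sel, 1], j = all_pairs[sel, 2],
                 w = round(runif(length(sel)), 3))
    }
    e1 <- pick(); e2 <- pick()
    gi <- intersect_with_raw_graph(mk(e1, ids), mk(e2, ids))
    got <- graph_to_edges(gi)$edges
    want_key <- intersect(paste(e1$i, e1$j), paste(e2$i, e2$j))
    expect_setequal(paste(got$i, got$j), want_key)
    # weights come from the first (embedding) graph
    if (nrow(got)) {
      w1 <- e1$w[match(paste(got$i, got$j), paste(e1$i, e1$j))]
      expect_equal(got$w, w1)
    }
  }
  expect_error(intersect_with_raw_graph(mk(e1, ids), mk(e2, sprintf("m%d", 1:8))),
               "node sets")
  # identity and disjoint extremes
  g1 <- mk(data.frame(i = 1, j = 2, w = 0.5), ids)
  expect_equal(igraph::ecount(intersect_with_raw_graph(g1, g1)), 1)
  g2 <- mk(data.frame(i = 3, j = 4, w = 0.5), ids)
  expect_equal(igraph::ecount(intersect_with_raw_graph(g1, g2)), 0)
})

test_that("partitioning recovers planted module structure", {
  clique_graph <- function(sizes, bridge_weight = NULL) {
    n <- sum(sizes)
    ids <- sprintf("v%02d", seq_len(n))
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = ids)
    start <- 0
    for (s in sizes) {
      for (i in seq_len(s - 1)) for (j in (i + 1):s) {
        g <- igraph::add_edges(g, c(start + i, start + j), weight = 1)
      }
      start <- start + s
    }
    if (!is.null(bridge_weight)) {
      g <- igraph::add_edges(g, c(1, sizes[1] + 1), weight = bridge_weight)
    }
    g
  }
  # two disconnected 5-cliques
  g <- clique_graph(c(5, 5))
  comms <- partition_graph(g, rng_seed = 1)
  expect_equal(length(comms), 2L)
  expect_setequal(comms[[1]], sprintf("v%02d", 1:5))
  expect_setequal(comms[[2]], sprintf("v%02d", 6:10))

  # two 6-cliques with one weak bridge
  g2 <- clique_graph(c(6, 6), bridge_weight = 0.01)
  comms2 <- partition_graph(g2, rng_seed = 1)
  expect_equal(length(comms2), 2L)
  expect_setequal(comms2[[1]], sprintf("v%02d", 1:6))
  expect_setequal(comms2[[2]], sprintf("v%02d", 7:12))

  # exhaustive map-equation check: the returned split is the best 2-partition
  ge <- graph_to_edges(g2)
  best <- Inf; best_m <- NULL
  for (mask in 1:(2^11 - 1)) {
    memb <- c(1L, as.integer(intToBits(mask))[1:11]) + 1L
    L <- map_equation_bits(ge$edges, 12, memb)
    if (L < best) { best <- L; best_m <- memb }
  }
  expect_setequal(ge$ids[best_m == best_m[1]], comms2[[1]])
  got_memb <- ifelse(ge$ids %in% comms2[[1]], 1L, 2L)
  expect_equal(map_equation_bits(ge$edges, 12, got_memb), best)

  # empty edge set: all singletons
  g3 <- igraph::set_vertex_attr(igraph::make_empty_graph(4, directed = FALSE),
                                "name", value = sprintf("v%d", 1:4))
  expect_equal(lengths(partition_graph(g3, 1)), rep(1L, 4))
})

test_that("returned partition scores no worse than the one-module partition", {
  withr::local_seed(33)
  for (rep in 1:5) {
    n <- 14
    ids <- sprintf("v%02d", 1:n)
    vec <- matrix(rnorm(n * 2), n, dimnames = list(ids, NULL))
    dm <- matrix(runif(n, 5, 20), n, 1, dimnames = list(ids, "S1"))
    g <- build_sparse_graph(vec, max_edges = 4, n_samples = 1,
                            depth_means = dm, depth_vars = dm)
    comms <- partition_graph(g, rng_seed = rep)
    ge <- graph_to_edges(g)
    memb <- integer(n)
    for (ci in seq_along(comms)) memb[match(comms[[ci]], ge$ids)] <- ci
    expect_lte(map_equation_bits(ge$edges, n, memb),
               map_equation_bits(ge$edges, n, rep(1L, n)) + 1e-12)
  }
})

test_that("reclustering splits a two-genome bin and respects the gate", {
  withr::local_seed(90)
  n_per <- 8
  ids <- c(sprintf("a%d", 1:n_per), sprintf("b%d", 1:n_per))
  emb <- rbind(matrix(rnorm(n_per * 4, 0, 0.05), n_per),
               matrix(rnorm(n_per * 4, 1, 0.05), n_per))
  rownames(emb) <- ids
  ab <- matrix(c(rep(0.1, n_per), rep(0.4, n_per)), ncol = 1,
               dimnames = list(ids, "S1"))
  lens <- setNames(rep(5000, 2 * n_per), ids)
  mk <- data.frame(contig_id = c("a1", "b1", "a2", "b2"),
                   marker_id = c("m1", "m1", "m2", "m2"),
                   stringsAsFactors = FALSE)
  out <- recluster_bin(ids, mk, emb, ab, lens)
  expect_equal(length(out), 2L)
  expect_setequal(out[[which(vapply(out, function(x) "a1" %in% x, TRUE))]],
                  sprintf("a%d", 1:n_per))
  # gate: mean copy number <= 1 passes through untouched
  mk1 <- mk[c(1, 3), ]
  expect_equal(recluster_bin(ids, mk1, emb, ab, lens), list(sort(ids)))
})

test_that("length weights pull k-means centers as hand-computed", {
  # three points on a line; one cluster; duplicating a point's weight moves
  # the weighted centroid exactly to the closed-form position
  x <- matrix(c(0, 1, 4), ncol = 1)
  w1 <- c(1, 1, 1)
  w2 <- c(1, 1, 2)
  c1 <- magbin:::weighted_kmeans(x, matrix(2, 1, 1), w1, max_iter = 1)
  expect_equal(c1, rep(1L, 3))
  # directly check the weighted centroid update
  expect_equal(sum(x * w2) / sum(w2), 9 / 4)
  expect_equal(sum(x * w1) / sum(w1), 5 / 3)
})

test_that("small bins are dropped at the exact boundary", {
  lens <- c(a = 100000, b = 99999, c = 100000, d = 100000)
  bins <- list(c("a", "b"), c("c", "d"))
  out <- filter_small_bins(bins, lens, min_bp = 200000)
  expect_equal(out, list(c("c", "d")))
  expect_equal(filter_small_bins(list(), lens), list())
})
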