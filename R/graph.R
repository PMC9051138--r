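#' Symmetrized KL divergence between per-contig depth distributions
#'
#' Per-base read depth of a contig in one sample is modeled as a normal
#' distribution with the recorded mean and variance. The divergence between
#' two contigs is the symmetrized Kullback-Leibler divergence
#' \eqn{\frac12[KL(N_1 \| N_2) + KL(N_2 \| N_1)]} in closed form; with
#' several samples the mean over samples is returned. Variances are floored
#' at \code{1e-4 * mean + 1e-6} so constant-depth contigs do not degenerate
#' the closed form.
#'
#' @param mean1,var1,mean2,var2 Numeric vectors (one entry per sample) of
#'   depth means and variances for the two contigs.
#' @return Scalar divergence (>= 0).
#' @export
kl_normal <- function(mean1, var1, mean2, var2) {
  if (any(!is.finite(c(mean1, var1, mean2, var2)))) {
    stop("non-finite depth parameters")
  }
  stopifnot(length(mean1) == length(mean2), length(var1) == length(mean1),
            length(var2) == length(mean1))
  v1 <- pmax(var1, 1e-4 * mean1 + 1e-6)
  v2 <- pmax(var2, 1e-4 * mean2 + 1e-6)
  kl12 <- 0.5 * (log(v2 / v1) + (v1 + (mean1 - mean2)^2) / v2 - 1)
  kl21 <- 0.5 * (log(v1 / v2) + (v2 + (mean2 - mean1)^2) / v1 - 1)
  mean(0.5 * (kl12 + kl21))
}

#' Similarity between two contigs
#'
#' With five or more samples (abundance already inside the embedding) the
#' similarity is \eqn{S = 1 - \min(d, 1)} where d is the Euclidean embedding
#' distance. With fewer samples the depth-distribution divergence a acts as
#' a multiplier: \eqn{S = 1 - \min(d \cdot a, 1)}; a is clamped to
#' \[1e-6, 1 - 1e-6\] so coinciding coverages cannot collapse every
#' similarity to 1.
#'
#' @param embed_dist Euclidean distance(s) between embeddings (>= 0).
#' @param abundance_term Divergence(s) from [kl_normal()]; ignored when
#'   \code{n_samples >= 5}.
#' @param n_samples Number of samples N.
#' @return Similarity in \[0, 1\] (vectorized).
#' @export
pair_similarity <- function(embed_dist, abundance_term = NULL, n_samples = 1L) {
  if (n_samples >= 5) return(1 - pmin(embed_dist, 1))
  if (is.null(abundance_term)) stop("abundance term required when N < 5")
  a <- pmin(pmax(abundance_term, 1e-6), 1 - 1e-6)
  1 - pmin(embed_dist * a, 1)
}

# Dense pairwise similarity matrix for a set of contigs. `vectors` rows are
# embedding (or raw Z) vectors; depth_means/depth_vars are n x N matrices
# used only in the N < 5 regime.
similarity_matrix <- function(vectors, n_samples, depth_means = NULL,
                              depth_vars = NULL) {
  d <- as.matrix(stats::dist(vectors))
  if (n_samples >= 5) return(1 - pmin(d, 1))
  if (is.null(depth_means) || is.null(depth_vars)) {
    stop("depth summaries required when N < 5")
  }
  n <- nrow(vectors)
  a <- matrix(0, n, n)
  m <- as.matrix(depth_means)
  v <- as.matrix(depth_vars)
  v <- pmax(v, 1e-4 * m + 1e-6)
  for (s in seq_len(ncol(m))) {
    ms <- m[, s]; vs <- v[, s]
    dm2 <- outer(ms, ms, "-")^2
    lr <- outer(log(vs), log(vs), "-")      # log(v_i) - log(v_j)
    r12 <- outer(vs, 1 / vs)                # v_i / v_j
    kl_ij <- 0.5 * (-lr + sweep(dm2, 2L, vs, "/") + r12 - 1)
    a <- a + 0.5 * (kl_ij + t(kl_ij))
  }
  a <- a / ncol(m)
  a <- pmin(pmax(a, 1e-6), 1 - 1e-6)
  s <- 1 - pmin(d * a, 1)
  diag(s) <- 1
  s
}

#' Build the pruned similarity graph
#'
#' Starting from the implicit complete graph with [pair_similarity()] edge
#' weights, every node nominates its \code{max_edges} incident edges of
#' highest weight (ties broken by lexicographically smaller neighbor id);
#' the kept edge set is the union of all nominations. Zero-weight edges are
#' dropped. A node's degree can exceed \code{max_edges}: beyond its own
#' nominations it keeps every edge through which other nodes nominated it.
#'
#' @param vectors Matrix of embedding (or raw feature) vectors, rownames =
#'   contig ids.
#' @param max_edges Per-node nomination budget (default 200).
#' @param n_samples Number of samples N (selects the similarity regime).
#' @param depth_means,depth_vars Per-contig per-sample depth summaries
#'   (required when \code{n_samples < 5}).
#' @return An \pkg{igraph} undirected graph with a \code{weight} edge
#'   attribute in (0, 1\].
#' @export
build_sparse_graph <- function(vectors, max_edges = 200, n_samples = 1L,
                               depth_means = NULL, depth_vars = NULL) {
  n <- nrow(vectors)
  if (n < 2L) stop("need at least 2 contigs to build a graph")
  ids <- rownames(vectors)
  if (is.null(ids)) stop("vectors must have contig ids as rownames")
  s <- similarity_matrix(vectors, n_samples, depth_means, depth_vars)
  diag(s) <- -Inf
  ord_ids <- order(ids)          # rank by id for deterministic tie-breaks
  id_rank <- integer(n); id_rank[ord_ids] <- seq_len(n)
  keep <- matrix(FALSE, n, n)
  k <- min(max_edges, n - 1L)
  for (i in seq_len(n)) {
    o <- order(-s[i, ], id_rank)[seq_len(k)]
    o <- o[is.finite(s[i, o]) & s[i, o] > 0]
    keep[i, o] <- TRUE
  }
  keep <- keep | t(keep)
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(idx)) {
    g <- igraph::add_edges(g, rbind(idx[, 1L], idx[, 2L]),
                           weight = s[idx])
  }
  g
}

#' Intersect the embedding graph with the raw-feature graph
#'
#' Removes potentially artefactual edges introduced by the embedding: only
#' edges present in both the embedding-space graph and the graph built by
#' the same procedure from the original feature vectors are kept, with
#' weights taken from the embedding graph.
#'
#' @param embed_graph,raw_graph Graphs from [build_sparse_graph()] over the
#'   same node set.
#' @return The intersected \pkg{igraph} graph.
#' @export
intersect_with_raw_graph <- function(embed_graph, raw_graph) {
  n1 <- sort(igraph::V(embed_graph)$name)
  n2 <- sort(igraph::V(raw_graph)$name)
  if (!identical(n1, n2)) stop("graphs have different node sets")
  out <- igraph::intersection(embed_graph, raw_graph, byname = TRUE,
                              keep.all.vertices = TRUE)
  ea <- igraph::edge_attr_names(out)
  if ("weight_1" %in% ea) {
    out <- igraph::set_edge_attr(out, "weight",
                                 value = igraph::edge_attr(out, "weight_1"))
    out <- igraph::delete_edge_attr(out, "weight_1")
    out <- igraph::delete_edge_attr(out, "weight_2")
  }
  out
}

#' Partition a similarity graph into communities
#'
#' Two-level map-equation (Infomap) community detection on the weighted
#' undirected graph; isolated nodes become singleton communities. The run
#' is seeded through R's RNG, so results are reproducible.
#'
#' @param graph Weighted \pkg{igraph} graph.
#' @param rng_seed Integer seed.
#' @param trials Number of Infomap attempts (best taken).
#' @return List of character vectors of contig ids, one per community,
#'   ordered by decreasing size then by smallest member id.
#' @export
partition_graph <- function(graph, rng_seed = 0L, trials = 10L) {
  if (igraph::vcount(graph) == 0L) return(list())
  memb <- if (igraph::ecount(graph) == 0L) {
    seq_len(igraph::vcount(graph))
  } else {
    local_seed_eval(rng_seed, {
      cl <- igraph::cluster_infomap(graph,
                                    e.weights = igraph::E(graph)$weight,
                                    nb.trials = trials)
      igraph::membership(cl)
    })
  }
  ids <- igraph::V(graph)$name
  comms <- split(ids, memb)
  comms <- lapply(comms, sort)
  first <- vapply(comms, `[`, "", 1L)
  comms <- comms[order(-lengths(comms), first)]
  names(comms) <- NULL
  comms
}

# Mean single-copy marker copy number of a contig set: total hits divided by
# the number of distinct marker families present (0 when no hits).
mean_scg_count <- function(contig_ids, marker_hits) {
  hits <- marker_hits[marker_hits$contig_id %in% contig_ids, , drop = FALSE]
  if (nrow(hits) == 0L) return(0)
  nrow(hits) / length(unique(hits$marker_id))
}

# Weighted Lloyd k-means with fixed initial centers. Rows of x are points,
# w are per-point weights. Ties in assignment go to the lowest center index.
weighted_kmeans <- function(x, centers, w, tol = 1e-4, max_iter = 300L) {
  k <- nrow(centers)
  for (iter in seq_len(max_iter)) {
    d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
      outer(rep(1, nrow(x)), rowSums(centers^2))
    assign <- max.col(-d2, ties.method = "first")
    new_centers <- centers
    for (j in seq_len(k)) {
      sel <- assign == j
      if (any(sel)) {
        new_centers[j, ] <- colSums(x[sel, , drop = FALSE] * w[sel]) / sum(w[sel])
      }
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
  max.col(-d2, ties.method = "first")
}

#' Recluster a contaminated bin with single-copy-gene guidance
#'
#' A bin whose mean single-copy marker copy number exceeds one likely mixes
#' several genomes. The bin is split by weighted k-means on the
#' concatenation of embedding and scaled abundance features, with contig
#' lengths (bp) as sample weights: k is the maximum copy number of any one
#' marker in the bin, and the initial centers are the k contigs carrying the
#' most-duplicated marker (ties broken by descending length, then id).
#' Bins at mean copy number <= 1 are returned unchanged.
#'
#' @param contig_ids Member contig ids of the bin.
#' @param marker_hits Marker hit \code{data.frame}.
#' @param embedded Embedding matrix covering the members (rownames = ids).
#' @param abundances Scaled abundance matrix (rownames = ids); may have 0
#'   columns.
#' @param contig_lengths Named vector of contig lengths (bp).
#' @return List of character vectors of contig ids (one per resulting bin).
#' @export
recluster_bin <- function(contig_ids, marker_hits, embedded, abundances,
                          contig_lengths) {
  if (mean_scg_count(contig_ids, marker_hits) <= 1) return(list(sort(contig_ids)))
  hits <- marker_hits[marker_hits$contig_id %in% contig_ids, , drop = FALSE]
  copy <- table(hits$marker_id)
  k <- max(copy)
  if (k < 2) stop("mean copy number > 1 but no marker has 2 copies")
  best_marker <- sort(names(copy)[copy == max(copy)])[1L]
  carriers <- unique(hits$contig_id[hits$marker_id == best_marker])
  carriers <- carriers[order(-contig_lengths[carriers], carriers)]
  seeds <- carriers[seq_len(k)]

  ids <- sort(contig_ids)
  x <- cbind(embedded[ids, , drop = FALSE],
             if (!is.null(abundances)) abundances[ids, , drop = FALSE])
  assign <- weighted_kmeans(x, x[match(seeds, ids), , drop = FALSE],
                            w = as.numeric(contig_lengths[ids]))
  out <- split(ids, assign)
  out <- lapply(out, sort)
  names(out) <- NULL
  out
}

#' Drop bins below the minimum size
#'
#' @param bins List of character vectors of contig ids.
#' @param contig_lengths Named vector of contig lengths (bp).
#' @param min_bp Minimum total basepairs to keep a bin (default 200 kbp).
#' @return The surviving bins.
#' @export
filter_small_bins <- function(bins, contig_lengths, min_bp = 200000) {
  keep <- vapply(bins, function(b) sum(as.numeric(contig_lengths[b])) >= min_bp,
                 logical(1))
  bins[keep]
}
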