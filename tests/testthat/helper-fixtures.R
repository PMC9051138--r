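# Shared fixtures: tiny communities and network configs sized for fast
# unit tests (hidden sizes are deliberately small; nothing in the tests
# depends on the default architecture).

tiny_community <- function(seed = 11, n_genomes = 4, genome_length_bp = 60000,
                           ...) {
  simulate_community(community_config(
    n_genomes = n_genomes, genome_length_bp = genome_length_bp,
    contig_meanlog = log(6000), contig_sdlog = 0.3,
    marker_panel_size = 10, rng_seed = seed, ...))
}

tiny_net_config <- function(input_dim, seed = 5, epochs = 8, ...) {
  network_config(input_dim = input_dim, hidden_dims = c(32, 24),
                 embedding_dim = 8, epochs = epochs, batch_pairs = 64,
                 pairs_per_epoch = 256, rng_seed = seed, ...)
}

tiny_pipeline_config <- function(seed = 5, ...) {
  pipeline_config(hidden_dims = c(32, 24), epochs = 8,
                  pairs_per_epoch = 1024, min_bin_bp = 20000,
                  rng_seed = seed, ...)
}

# Two well-separated point clouds with profiles, constraints and ids; used
# for embedding-separation tests without a full simulation.
two_cluster_profiles <- function(n_per = 30, dim = 20, seed = 3) {
  set.seed(seed)
  center <- rep(0, dim)
  a <- matrix(rnorm(n_per * dim, 0, 0.05), n_per) +
    matrix(rep(c(rep(0.5, dim %/% 2), rep(0, dim - dim %/% 2)), each = n_per), n_per)
  b <- matrix(rnorm(n_per * dim, 0, 0.05), n_per) +
    matrix(rep(c(rep(0, dim %/% 2), rep(0.5, dim - dim %/% 2)), each = n_per), n_per)
  z <- rbind(a, b)
  ids <- c(sprintf("a%02d", seq_len(n_per)), sprintf("b%02d", seq_len(n_per)))
  rownames(z) <- ids
  ml <- data.frame(
    c1 = c(sprintf("a%02d", seq_len(n_per - 1)), sprintf("b%02d", seq_len(n_per - 1))),
    c2 = c(sprintf("a%02d", 2:n_per), sprintf("b%02d", 2:n_per)))
  set.seed(seed + 1)
  cl <- data.frame(c1 = sample(ids[seq_len(n_per)], 60, replace = TRUE),
                   c2 = sample(ids[n_per + seq_len(n_per)], 60, replace = TRUE))
  cl <- cl[!duplicated(paste(cl$c1, cl$c2)), ]
  list(z = z, constraints = list(must_link = ml, cannot_link = cl),
       group = rep(c("a", "b"), each = n_per))
}
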