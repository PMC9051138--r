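#' Pipeline configuration
#'
#' Bundles the tunable parameters of the binning pipeline. \code{NULL}
#' means "decide from the data" where a heuristic exists.
#'
#' @param min_contig_len Minimum contig length for binning; \code{NULL} =
#'   choose 1000/2500 bp via [select_min_length()].
#' @param small_fraction Basepair fraction driving [select_min_length()].
#' @param bp_fraction Basepair fraction driving [must_link_threshold()].
#' @param max_edges Per-node edge budget of the sparse graph.
#' @param min_bin_bp Minimum bin size in bp (default 200 kbp).
#' @param recluster Run single-copy-gene guided reclustering.
#' @param max_cannot Cannot-link constraint cap.
#' @param hidden_dims,epochs,batch_pairs,pairs_per_epoch,learning_rate,dropout_rate
#'   Network training parameters (see [network_config()]).
#' @param infomap_trials Infomap attempts per partition.
#' @param rng_seed Master seed for constraint subsampling, training and
#'   partitioning.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(min_contig_len = NULL, small_fraction = 0.05,
                            bp_fraction = 0.98, max_edges = 200,
                            min_bin_bp = 200000, recluster = TRUE,
                            max_cannot = 4e6, hidden_dims = c(512, 512),
                            epochs = 20, batch_pairs = 1024,
                            pairs_per_epoch = 4096, learning_rate = 1e-3,
                            dropout_rate = 0.2, infomap_trials = 10L,
                            rng_seed = 0L) {
  structure(as.list(environment()), class = "pipeline_config")
}

# Assemble per-catalog features: filter by length, build k-mer and depth
# matrices, scales and Z, split long contigs for must-link pairs and build
# the training matrix (originals + fragments) and the constraint set.
prepare_catalog <- function(contigs, coverage, taxonomy, markers, config) {
  min_len <- if (is.null(config$min_contig_len)) {
    select_min_length(contigs$length, config$small_fraction)
  } else config$min_contig_len
  keep <- contigs[contigs$length >= min_len, , drop = FALSE]
  if (nrow(keep) < 2L) {
    return(list(min_len = min_len, filtered = keep, enough = FALSE))
  }
  keep <- keep[order(keep$contig_id), , drop = FALSE]
  samples <- sort(unique(coverage$sample_id))
  n_samples <- length(samples)

  cov_key <- paste(coverage$contig_id, coverage$sample_id, sep = "\r")
  get_cov <- function(ids, col) {
    m <- matrix(NA_real_, length(ids), n_samples,
                dimnames = list(ids, samples))
    for (s in seq_along(samples)) {
      idx <- match(paste(ids, samples[s], sep = "\r"), cov_key)
      m[, s] <- coverage[[col]][idx]
    }
    if (anyNA(m)) {
      miss <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop("missing coverage record for contig '", ids[miss[1L]],
           "' in sample '", samples[miss[2L]], "'")
    }
    m
  }
  depth_means <- get_cov(keep$contig_id, "mean_depth")
  depth_vars <- get_cov(keep$contig_id, "depth_variance")
  scales <- scale_constant(colMeans(depth_means))

  kf <- kmer_frequencies(stats::setNames(keep$sequence, keep$contig_id))
  z <- assemble_z(kf, depth_means, scales, n_samples)
  regime <- if (n_samples >= 5) "kmer_plus_abundance" else "kmer_only"

  threshold <- must_link_threshold(keep$length, config$bp_fraction)
  sp <- split_for_must_link(keep, threshold)
  frags <- sp$fragments
  z_train <- z
  if (nrow(frags)) {
    fkf <- kmer_frequencies(stats::setNames(frags$sequence, frags$contig_id))
    fmeans <- depth_means[frags$parent_id, , drop = FALSE]
    rownames(fmeans) <- frags$contig_id
    fz <- assemble_z(fkf, fmeans, scales, n_samples)
    z_train <- rbind(z, fz)
  }
  fragment_parents <- stats::setNames(frags$parent_id, frags$contig_id)
  constraints <- build_constraints(
    sp$must_link, taxonomy, markers,
    eligible_contig_ids = c(keep$contig_id, frags$contig_id),
    fragment_parents = fragment_parents,
    max_cannot = config$max_cannot, rng_seed = config$rng_seed)

  list(min_len = min_len, filtered = keep, enough = TRUE,
       samples = samples, n_samples = n_samples,
       depth_means = depth_means, depth_vars = depth_vars, scales = scales,
       kmer = kf, z = z, z_train = z_train, regime = regime,
       threshold = threshold, constraints = constraints)
}

# Apply the m/c/mc graph variants: add weight-1 edges for must-link pairs
# whose endpoints are graph nodes, delete edges between cannot-link pairs.
apply_constraint_edges <- function(graph, constraints, variant) {
  nodes <- igraph::V(graph)$name
  if (variant %in% c("m", "mc")) {
    ml <- constraints$must_link
    sel <- ml$c1 %in% nodes & ml$c2 %in% nodes
    if (any(sel)) {
      pres <- igraph::get_edge_ids(graph, rbind(ml$c1[sel], ml$c2[sel]))
      add <- which(pres == 0)
      if (length(add)) {
        graph <- igraph::add_edges(graph,
                                   rbind(ml$c1[sel][add], ml$c2[sel][add]),
                                   weight = 1)
      }
      bump <- pres[pres > 0]
      if (length(bump)) {
        graph <- igraph::set_edge_attr(graph, "weight", index = bump, value = 1)
      }
    }
  }
  if (variant %in% c("c", "mc")) {
    cl <- constraints$cannot_link
    sel <- cl$c1 %in% nodes & cl$c2 %in% nodes
    if (any(sel)) {
      eids <- igraph::get_edge_ids(graph, rbind(cl$c1[sel], cl$c2[sel]))
      eids <- eids[eids > 0]
      if (length(eids)) graph <- igraph::delete_edges(graph, eids)
    }
  }
  graph
}

# Bin one contig catalog (single-sample or co-assembly semantics).
bin_catalog <- function(contigs, coverage, taxonomy, markers,
                        variant, config, model = NULL) {
  prep <- prepare_catalog(contigs, coverage, taxonomy, markers, config)
  unbinned_all <- data.frame(contig_id = contigs$contig_id,
                             bin_id = "unbinned", stringsAsFactors = FALSE)
  if (!prep$enough) return(unbinned_all)

  if (variant == "full") {
    if (is.null(model)) {
      net_cfg <- network_config(
        input_dim = ncol(prep$z_train), hidden_dims = config$hidden_dims,
        dropout_rate = config$dropout_rate,
        learning_rate = config$learning_rate, epochs = config$epochs,
        batch_pairs = config$batch_pairs,
        pairs_per_epoch = config$pairs_per_epoch,
        rng_seed = config$rng_seed)
      model <- train_embedder(prep$z_train, prep$constraints, net_cfg,
                              feature_regime = prep$regime,
                              n_samples = prep$n_samples)
    }
    vectors <- embed_contigs(model, prep$z, feature_regime = prep$regime)
  } else {
    vectors <- prep$z
  }

  g_embed <- build_sparse_graph(vectors, config$max_edges, prep$n_samples,
                                prep$depth_means, prep$depth_vars)
  g_raw <- if (variant == "full") {
    build_sparse_graph(prep$z, config$max_edges, prep$n_samples,
                       prep$depth_means, prep$depth_vars)
  } else g_embed
  g <- intersect_with_raw_graph(g_embed, g_raw)
  if (variant %in% c("m", "c", "mc")) {
    g <- apply_constraint_edges(g, prep$constraints, variant)
  }

  comms <- partition_graph(g, rng_seed = config$rng_seed,
                           trials = config$infomap_trials)
  clen <- stats::setNames(prep$filtered$length, prep$filtered$contig_id)
  if (config$recluster) {
    scaled_ab <- sweep(prep$depth_means, 2L, prep$scales, "/")
    comms <- do.call(c, lapply(comms, function(b) {
      recluster_bin(b, markers, vectors, scaled_ab, clen)
    }))
  }
  bins <- filter_small_bins(comms, clen, config$min_bin_bp)

  if (length(bins) == 0L) return(unbinned_all)
  bp <- vapply(bins, function(b) sum(as.numeric(clen[b])), 1)
  first <- vapply(bins, `[`, "", 1L)
  bins <- bins[order(-bp, first)]
  assign <- stats::setNames(
    rep(sprintf("bin_%03d", seq_along(bins) - 1L), lengths(bins)),
    unlist(bins))
  out <- unbinned_all
  hit <- match(out$contig_id, names(assign))
  out$bin_id[!is.na(hit)] <- assign[hit[!is.na(hit)]]
  out
}

#' Run the full binning pipeline
#'
#' Orchestrates length filtering, feature assembly, constraint generation,
#' siamese training (or application of a pretrained model), embedding,
#' sparse-graph construction and intersection, Infomap partitioning,
#' optional single-copy-gene reclustering and bin-size filtering.
#'
#' Variants mirror the semi-supervision ablation: \code{"full"} is the
#' complete method; \code{"nosemi"} skips training and clusters on the raw
#' feature vectors Z; \code{"m"}, \code{"c"} and \code{"mc"} also skip
#' training but instead inject the constraints directly into the sparse
#' graph (must-link pairs as weight-1 edges, cannot-link pairs as edge
#' deletions).
#'
#' @param contigs Contig \code{data.frame} (see [read_fasta()]); in
#'   \code{"multi"} mode the \code{sample_id} column assigns contigs to
#'   samples.
#' @param coverage Coverage \code{data.frame}; in \code{"multi"} mode it
#'   holds records for every contig in every sample.
#' @param taxonomy Taxonomy \code{data.frame}.
#' @param markers Marker-hit \code{data.frame}.
#' @param mode \code{"single"}, \code{"coassembly"} or \code{"multi"}.
#'   Single and co-assembly bin the catalog as one unit (they differ only in
#'   how the input was assembled); multi bins each sample's contigs
#'   separately while using abundance across all samples.
#' @param variant \code{"full"}, \code{"nosemi"}, \code{"m"}, \code{"c"} or
#'   \code{"mc"}.
#' @param config A [pipeline_config()].
#' @param model Optional pretrained \code{trained_embedder} (or path to a
#'   saved one) applied instead of per-run training.
#' @return Assignment \code{data.frame} with \code{contig_id},
#'   \code{sample_id}, \code{bin_id} (\code{"unbinned"} for contigs not
#'   placed in any bin). In multi mode bin ids are prefixed with the sample
#'   id, so no bin spans samples.
#' @export
run_pipeline <- function(contigs, coverage, taxonomy, markers,
                         mode = c("single", "coassembly", "multi"),
                         variant = c("full", "nosemi", "m", "c", "mc"),
                         config = pipeline_config(), model = NULL) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  if (is.character(model)) model <- load_embedder(model)
  if (mode %in% c("single", "coassembly")) {
    out <- bin_catalog(contigs, coverage, taxonomy, markers,
                       variant, config, model)
    out$sample_id <- contigs$sample_id[match(out$contig_id, contigs$contig_id)]
    return(out[, c("contig_id", "sample_id", "bin_id")])
  }
  samples <- sort(unique(contigs$sample_id))
  if (any(!nzchar(samples))) {
    stop("multi mode requires a sample_id for every contig")
  }
  res <- lapply(samples, function(s) {
    sub <- contigs[contigs$sample_id == s, , drop = FALSE]
    cov <- coverage[coverage$contig_id %in% sub$contig_id, , drop = FALSE]
    tax <- taxonomy[taxonomy$contig_id %in% sub$contig_id, , drop = FALSE]
    mk <- markers[markers$contig_id %in% sub$contig_id, , drop = FALSE]
    a <- bin_catalog(sub, cov, tax, mk, variant, config, model)
    a$sample_id <- s
    a$bin_id <- ifelse(a$bin_id == "unbinned", "unbinned",
                       paste0(s, "_", a$bin_id))
    a[, c("contig_id", "sample_id", "bin_id")]
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pretrain an embedder on one or more samples
#'
#' Builds features and constraints for each dataset independently
#' (constraints never cross samples), concatenates the training profiles and
#' trains a single model that can be saved with [save_embedder()] and
#' applied to other samples of the same feature regime via
#' \code{run_pipeline(..., model = )}.
#'
#' @param datasets List of lists, each with elements \code{contigs},
#'   \code{coverage}, \code{taxonomy}, \code{markers}.
#' @param config A [pipeline_config()].
#' @return A \code{trained_embedder}.
#' @export
pretrain_embedder <- function(datasets, config = pipeline_config()) {
  preps <- lapply(datasets, function(d) {
    prepare_catalog(d$contigs, d$coverage, d$taxonomy, d$markers, config)
  })
  if (any(!vapply(preps, `[[`, TRUE, "enough"))) {
    stop("a dataset has fewer than 2 contigs after length filtering")
  }
  regimes <- unique(vapply(preps, `[[`, "", "regime"))
  dims <- unique(vapply(preps, function(p) ncol(p$z_train), 1L))
  if (length(regimes) != 1L || length(dims) != 1L) {
    stop("datasets disagree on feature regime or dimension")
  }
  tag <- function(i, x) paste0("d", i, "|", x)
  z_all <- do.call(rbind, lapply(seq_along(preps), function(i) {
    z <- preps[[i]]$z_train
    rownames(z) <- tag(i, rownames(z))
    z
  }))
  ml <- do.call(rbind, lapply(seq_along(preps), function(i) {
    p <- preps[[i]]$constraints$must_link
    data.frame(c1 = tag(i, p$c1), c2 = tag(i, p$c2), stringsAsFactors = FALSE)
  }))
  cl <- do.call(rbind, lapply(seq_along(preps), function(i) {
    p <- preps[[i]]$constraints$cannot_link
    data.frame(c1 = tag(i, p$c1), c2 = tag(i, p$c2), stringsAsFactors = FALSE)
  }))
  net_cfg <- network_config(
    input_dim = dims, hidden_dims = config$hidden_dims,
    dropout_rate = config$dropout_rate, learning_rate = config$learning_rate,
    epochs = config$epochs, batch_pairs = config$batch_pairs,
    pairs_per_epoch = config$pairs_per_epoch, rng_seed = config$rng_seed)
  train_embedder(z_all, list(must_link = ml, cannot_link = cl), net_cfg,
                 feature_regime = regimes,
                 n_samples = preps[[1L]]$n_samples)
}
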