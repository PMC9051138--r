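#' Configuration of the siamese embedding network
#'
#' The encoder maps the input vector Z (dimension F) through two hidden
#' layers to a 100-dimensional embedding; a mirror-image decoder reconstructs
#' Z from the embedding. The first two layers of encoder and decoder are each
#' followed by batch normalization, a leaky rectified linear unit and dropout
#' (rate 0.2); the encoder output layer is linear. Both siamese branches
#' share all weights, so the network is stored once.
#'
#' @param input_dim Input dimension F (136, or 136 + N with >= 5 samples).
#' @param hidden_dims Sizes of the two hidden layers.
#' @param embedding_dim Embedding dimension (100).
#' @param dropout_rate Dropout probability in \[0, 1).
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_pairs Constraint pairs per minibatch.
#' @param pairs_per_epoch Upper bound on constraint pairs visited per epoch;
#'   every must-link pair is always included and cannot-link pairs are
#'   resampled each epoch up to this budget (see the methods vignette).
#' @param rng_seed Integer seed controlling initialization, dropout and batch
#'   order.
#' @return A \code{network_config} list.
#' @export
network_config <- function(input_dim, hidden_dims = c(512, 512),
                           embedding_dim = 100, dropout_rate = 0.2,
                           learning_rate = 1e-3, epochs = 20,
                           batch_pairs = 1024, pairs_per_epoch = 4096,
                           rng_seed = 0L) {
  stopifnot(input_dim >= 1, length(hidden_dims) == 2, all(hidden_dims >= 1),
            embedding_dim >= 1, dropout_rate >= 0, dropout_rate < 1,
            learning_rate > 0, epochs >= 1, batch_pairs >= 1,
            pairs_per_epoch >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 embedding_dim = as.integer(embedding_dim),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_pairs = as.integer(batch_pairs),
                 pairs_per_epoch = as.integer(pairs_per_epoch),
                 rng_seed = as.integer(rng_seed)),
            class = "network_config")
}

#' Build an untrained siamese encoder/decoder
#'
#' Weight initialization is drawn from the R RNG seeded with
#' \code{config$rng_seed}, so the same config always yields identical
#' initial weights.
#'
#' @param config A [network_config()].
#' @return A \code{siamese_network} list with \code{enc} and \code{dec}
#'   layer stacks.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  local_seed_eval(config$rng_seed, {
    structure(c(list(config = config), make_siamese_stacks(config)),
              class = "siamese_network")
  })
}

# Encoder/decoder layer stacks; draws initialization from the current RNG
# stream (callers seed it).
make_siamese_stacks <- function(config) {
  F <- config$input_dim
  h1 <- config$hidden_dims[1L]
  h2 <- config$hidden_dims[2L]
  E <- config$embedding_dim
  p <- config$dropout_rate
  list(enc = list(nn_linear(F, h1), nn_bn(h1), nn_lrelu(), nn_dropout(p),
                  nn_linear(h1, h2), nn_bn(h2), nn_lrelu(), nn_dropout(p),
                  nn_linear(h2, E)),
       dec = list(nn_linear(E, h2), nn_bn(h2), nn_lrelu(), nn_dropout(p),
                  nn_linear(h2, h1), nn_bn(h1), nn_lrelu(), nn_dropout(p),
                  nn_linear(h1, F)))
}

#' Number of trainable parameters of a network
#'
#' Counts weights, biases and batch-norm scale/shift (not running
#' statistics).
#'
#' @param network A \code{siamese_network}.
#' @return Integer parameter count.
#' @export
n_parameters <- function(network) {
  n_stack_parameters(network$enc) + n_stack_parameters(network$dec)
}

#' Contrastive loss over embedding pairs
#'
#' For each pair with Euclidean embedding distance d and label y (1 =
#' must-link, 0 = cannot-link), the loss is
#' \eqn{y d^2 + (1 - y) \max(1 - d, 0)^2}, averaged over pairs: must-link
#' pairs are pulled together, cannot-link pairs pushed beyond unit margin.
#'
#' @param e1,e2 Embedding matrices (one row per pair member).
#' @param y Labels in \{0, 1\}, one per pair.
#' @return Scalar loss.
#' @export
contrastive_loss <- function(e1, e2, y) {
  if (NROW(e1) == 0L) stop("empty pair set")
  stopifnot(identical(dim(e1), dim(e2)), length(y) == nrow(e1),
            all(y %in% c(0, 1)))
  d <- sqrt(rowSums((e1 - e2)^2))
  mean(y * d^2 + (1 - y) * pmax(1 - d, 0)^2)
}

# Gradient of the contrastive loss w.r.t. e1 (the e2 gradient is its
# negative). d is floored to avoid 0/0 at coincident embeddings; for
# must-link pairs the d*(e1-e2)/d form cancels exactly.
contrastive_grad_e1 <- function(e1, e2, y) {
  diff <- e1 - e2
  d <- sqrt(rowSums(diff^2))
  d_safe <- pmax(d, 1e-12)
  coef <- ifelse(y == 1, 2, ifelse(d < 1, -2 * (1 - d) / d_safe, 0))
  diff * (coef / length(y))
}

#' Mean-squared reconstruction loss
#'
#' Mean over contigs (and input dimensions) of the squared elementwise
#' difference between the input and its autoencoder reconstruction.
#'
#' @param inputs,reconstructions Matrices of identical shape.
#' @return Scalar loss (>= 0).
#' @export
reconstruction_loss <- function(inputs, reconstructions) {
  if (!identical(dim(inputs), dim(reconstructions))) {
    stop("inputs and reconstructions differ in shape")
  }
  mean((inputs - reconstructions)^2)
}

#' Train the semi-supervised siamese embedder
#'
#' Minimizes the sum of the contrastive loss over constraint pairs and the
#' reconstruction loss over all profiled contigs (equal weights) with Adam.
#' Each epoch visits every must-link pair and a fresh uniform sample of
#' cannot-link pairs up to \code{config$pairs_per_epoch}, in shuffled
#' minibatches of \code{config$batch_pairs} pairs; alongside each minibatch
#' one chunk of the (shuffled) full contig set is passed through the
#' autoencoder, so the reconstruction term sees every contig once per epoch.
#' Training is deterministic under \code{config$rng_seed} on one device.
#'
#' @param z Input matrix Z, one row per training contig, rownames = contig
#'   ids (original contigs plus split fragments).
#' @param constraints List with \code{must_link} and \code{cannot_link} pair
#'   \code{data.frame}s (columns \code{c1}, \code{c2}) referencing rownames
#'   of \code{z}.
#' @param config A [network_config()]; \code{input_dim} must equal
#'   \code{ncol(z)}.
#' @param feature_regime \code{"kmer_only"} or \code{"kmer_plus_abundance"};
#'   recorded in the model and checked again at apply time.
#' @param n_samples Number of samples backing the feature regime.
#' @return A \code{trained_embedder} with the network, config, feature
#'   regime and per-epoch loss history.
#' @export
train_embedder <- function(z, constraints, config,
                           feature_regime = c("kmer_only", "kmer_plus_abundance"),
                           n_samples = 1L) {
  feature_regime <- match.arg(feature_regime)
  stopifnot(inherits(config, "network_config"))
  if (config$input_dim != ncol(z)) {
    stop("config input_dim (", config$input_dim, ") != ncol(z) (", ncol(z), ")")
  }
  ml <- constraints$must_link
  cl <- constraints$cannot_link
  if (is.null(ml) || nrow(ml) == 0L) stop("need at least one must-link pair")
  if (is.null(cl) || nrow(cl) == 0L) stop("need at least one cannot-link pair")
  ids <- rownames(z)
  if (is.null(ids)) stop("z must have contig ids as rownames")
  ref <- unique(c(ml$c1, ml$c2, cl$c1, cl$c2))
  unknown <- setdiff(ref, ids)
  if (length(unknown)) {
    stop("constraint references unknown contig '", unknown[1L], "'")
  }
  ml_i <- cbind(match(ml$c1, ids), match(ml$c2, ids))
  cl_i <- cbind(match(cl$c1, ids), match(cl$c2, ids))
  n <- nrow(z)

  local_seed_eval(config$rng_seed, {
    # built under the already-seeded stream so that initialization, dropout
    # and batch order share one deterministic RNG sequence
    net <- make_siamese_stacks(config)
    opt_enc <- adam_init(net$enc)
    opt_dec <- adam_init(net$dec)
    t_step <- 0L
    history <- numeric(config$epochs)

    for (epoch in seq_len(config$epochs)) {
      n_cl_take <- min(nrow(cl_i), max(0L, config$pairs_per_epoch - nrow(ml_i)))
      cl_take <- if (n_cl_take < nrow(cl_i)) {
        cl_i[sample.int(nrow(cl_i), n_cl_take), , drop = FALSE]
      } else cl_i
      pairs <- rbind(ml_i, cl_take)
      y <- c(rep(1, nrow(ml_i)), rep(0, nrow(cl_take)))
      ord <- sample.int(nrow(pairs))
      pairs <- pairs[ord, , drop = FALSE]
      y <- y[ord]
      n_batches <- ceiling(nrow(pairs) / config$batch_pairs)
      batch_of <- rep(seq_len(n_batches), each = config$batch_pairs,
                      length.out = nrow(pairs))
      recon_ord <- sample.int(n)
      recon_of <- rep(seq_len(n_batches), length.out = n)

      epoch_loss <- 0
      for (b in seq_len(n_batches)) {
        sel <- batch_of == b
        bi <- pairs[sel, , drop = FALSE]
        by <- y[sel]
        xb <- z[c(bi[, 1L], bi[, 2L]), , drop = FALSE]
        fw <- stack_forward(net$enc, xb, train = TRUE)
        net$enc <- fw$stack
        m <- nrow(bi)
        e1 <- fw$out[seq_len(m), , drop = FALSE]
        e2 <- fw$out[m + seq_len(m), , drop = FALSE]
        l_con <- contrastive_loss(e1, e2, by)
        g1 <- contrastive_grad_e1(e1, e2, by)
        bw_con <- stack_backward(net$enc, fw$caches, rbind(g1, -g1))
        g_enc <- bw_con$grads

        rsel <- recon_ord[recon_of == b]
        xr <- z[rsel, , drop = FALSE]
        fe <- stack_forward(net$enc, xr, train = TRUE)
        net$enc <- fe$stack
        fd <- stack_forward(net$dec, fe$out, train = TRUE)
        net$dec <- fd$stack
        l_mse <- reconstruction_loss(xr, fd$out)
        d_rec <- 2 * (fd$out - xr) / length(xr)
        bw_dec <- stack_backward(net$dec, fd$caches, d_rec)
        bw_enc2 <- stack_backward(net$enc, fe$caches, bw_dec$dX)
        g_enc <- add_grads(g_enc, bw_enc2$grads)

        t_step <- t_step + 1L
        up <- adam_step(net$enc, g_enc, opt_enc, config$learning_rate, t_step)
        net$enc <- up$stack; opt_enc <- up$state
        up <- adam_step(net$dec, bw_dec$grads, opt_dec, config$learning_rate, t_step)
        net$dec <- up$stack; opt_dec <- up$state
        epoch_loss <- epoch_loss + l_con + l_mse
      }
      history[epoch] <- epoch_loss / n_batches
    }
    structure(list(version = 1L, config = config,
                   feature_regime = feature_regime,
                   n_samples = as.integer(n_samples),
                   net = net, history = history),
              class = "trained_embedder")
  })
}

#' Embed contigs with a trained model
#'
#' Evaluation-mode forward pass through the encoder: batch normalization
#' uses running statistics and dropout is disabled, so embedding is
#' deterministic.
#'
#' @param embedder A \code{trained_embedder}.
#' @param z Input matrix with \code{ncol(z) == config$input_dim}.
#' @param feature_regime The regime of \code{z}; must match the model's.
#' @return Embedding matrix (rows = contigs, 100 columns by default).
#' @export
embed_contigs <- function(embedder, z, feature_regime = embedder$feature_regime) {
  stopifnot(inherits(embedder, "trained_embedder"))
  if (!identical(feature_regime, embedder$feature_regime)) {
    stop("feature regime mismatch: model is '", embedder$feature_regime,
         "', query is '", feature_regime, "'")
  }
  if (ncol(z) != embedder$config$input_dim) {
    stop("input dimension mismatch: model expects F = ",
         embedder$config$input_dim, ", got ", ncol(z))
  }
  out <- stack_forward(embedder$net$enc, z, train = FALSE)$out
  rownames(out) <- rownames(z)
  out
}

#' Save / load a trained embedder
#'
#' The model file is a self-describing RDS container holding a format
#' version, the network config, the feature regime and all weights;
#' \code{load_embedder(save_embedder(m))} reproduces identical embeddings.
#'
#' @param embedder A \code{trained_embedder}.
#' @param path File path.
#' @return \code{path} (save) or the \code{trained_embedder} (load).
#' @export
save_embedder <- function(embedder, path) {
  stopifnot(inherits(embedder, "trained_embedder"))
  saveRDS(unclass(embedder), path)
  invisible(path)
}

#' @rdname save_embedder
#' @export
load_embedder <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$version) || is.null(obj$net) ||
      is.null(obj$feature_regime)) {
    stop("not an embedder model file: ", path)
  }
  if (obj$version != 1L) stop("unsupported model file version: ", obj$version)
  structure(obj, class = "trained_embedder")
}
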