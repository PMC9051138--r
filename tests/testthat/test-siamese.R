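test_that("losses match hand-computed values on small fixtures", {
  e0 <- matrix(0, 1, 4)
  # must-link at distance 0
  expect_equal(contrastive_loss(e0, e0, 1), 0)
  # cannot-link beyond the unit margin
  e2 <- matrix(c(2, 0, 0, 0), 1, 4)
  expect_equal(contrastive_loss(e0, e2, 0), 0)
  # one must-link and one cannot-link both at distance 0.5
  e1a <- matrix(0, 2, 4)
  e1b <- rbind(c(0.5, 0, 0, 0), c(0.5, 0, 0, 0))
  expect_equal(contrastive_loss(e1a, e1b, c(1, 0)), (0.25 + 0.25) / 2)
  # three-pair fixture: distances 0.3 (must), 0.4 (cannot), 1.2 (cannot)
  a <- matrix(0, 3, 2)
  b <- rbind(c(0.3, 0), c(0.4, 0), c(1.2, 0))
  expect_equal(contrastive_loss(a, b, c(1, 0, 0)),
               (0.3^2 + (1 - 0.4)^2 + 0) / 3)
  expect_error(contrastive_loss(matrix(0, 0, 4), matrix(0, 0, 4), numeric(0)),
               "empty")

  expect_equal(reconstruction_loss(matrix(1:4, 2), matrix(1:4, 2)), 0)
  expect_equal(reconstruction_loss(matrix(0, 1, 2), matrix(1, 1, 2)), 1)
  withr::local_seed(1)
  x <- matrix(rnorm(20), 4)
  y <- matrix(rnorm(20), 4)
  expect_gte(reconstruction_loss(x, y), 0)
  expect_equal(reconstruction_loss(x, y), mean((x - y)^2))
  expect_error(reconstruction_loss(x, y[, 1:3]), "shape")
})

test_that("loss is invariant to swapping the members of any pair", {
  withr::local_seed(8)
  e1 <- matrix(rnorm(40), 8)
  e2 <- matrix(rnorm(40), 8)
  y <- rep(c(1, 0), 4)
  expect_equal(contrastive_loss(e1, e2, y), contrastive_loss(e2, e1, y))
})

test_that("analytic loss gradients match central finite differences", {
  withr::local_seed(15)
  h <- 1e-5
  for (rep in 1:5) {
    e1 <- matrix(rnorm(12, sd = 0.6), 3)
    e2 <- matrix(rnorm(12, sd = 0.6), 3)
    y <- sample(c(0, 1), 3, replace = TRUE)
    g <- magbin:::contrastive_grad_e1(e1, e2, y)
    num <- matrix(0, 3, 4)
    for (i in seq_len(12)) {
      ep <- e1; em <- e1
      ep[i] <- ep[i] + h; em[i] <- em[i] - h
      num[i] <- (contrastive_loss(ep, e2, y) - contrastive_loss(em, e2, y)) / (2 * h)
    }
    expect_lt(max(abs(g - num)) / max(abs(num), 1e-8), 1e-4)

    x <- matrix(rnorm(10), 2)
    xh <- matrix(rnorm(10), 2)
    g_mse <- 2 * (xh - x) / length(x)
    num <- matrix(0, 2, 5)
    for (i in seq_len(10)) {
      xp <- xh; xm <- xh
      xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
      num[i] <- (reconstruction_loss(x, xp) - reconstruction_loss(x, xm)) / (2 * h)
    }
    expect_lt(max(abs(g_mse - num)) / max(abs(num)), 1e-4)
  }
})

test_that("full network backprop matches finite differences on a tiny net", {
  # dropout off so the loss is a deterministic function of the parameters;
  # batch-norm runs in training mode (batch statistics)
  cfg <- network_config(input_dim = 6, hidden_dims = c(5, 4),
                        embedding_dim = 3, dropout_rate = 0, rng_seed = 2)
  net <- build_network(cfg)
  withr::local_seed(3)
  X <- matrix(rnorm(8 * 6), 8)
  target <- matrix(rnorm(8 * 3), 8)

  loss_of <- function(enc) {
    out <- magbin:::stack_forward(enc, X, train = TRUE)$out
    mean((out - target)^2)
  }
  fw <- magbin:::stack_forward(net$enc, X, train = TRUE)
  dOut <- 2 * (fw$out - target) / length(target)
  an <- magbin:::stack_backward(fw$stack, fw$caches, dOut)$grads

  h <- 1e-5
  for (li in c(1, 2, 5, 9)) {           # linear and batch-norm layers
    for (nm in names(net$enc[[li]]$params)) {
      p <- net$enc[[li]]$params[[nm]]
      ii <- seq_len(min(6, length(p)))  # spot-check a few coordinates
      for (i in ii) {
        ep <- net$enc; em <- net$enc
        ep[[li]]$params[[nm]][i] <- p[i] + h
        em[[li]]$params[[nm]][i] <- p[i] - h
        num <- (loss_of(ep) - loss_of(em)) / (2 * h)
        expect_lt(abs(an[[li]][[nm]][i] - num) / max(abs(num), 1e-6), 1e-3)
      }
    }
  }
})

test_that("network construction is seed-deterministic with the right shape", {
  cfg <- network_config(input_dim = 136)
  n1 <- build_network(cfg)
  n2 <- build_network(cfg)
  expect_identical(n1, n2)
  # closed-form parameter count: linear W+b, batch-norm gamma+beta
  F <- 136; h1 <- 512; h2 <- 512; E <- 100
  expected <- (F * h1 + h1) + 2 * h1 + (h1 * h2 + h2) + 2 * h2 + (h2 * E + E) +
    (E * h2 + h2) + 2 * h2 + (h2 * h1 + h1) + 2 * h1 + (h1 * F + F)
  expect_equal(n_parameters(n1), expected)
})

test_that("training requires both constraint types and known ids", {
  fix <- two_cluster_profiles()
  cfg <- tiny_net_config(ncol(fix$z))
  expect_error(train_embedder(fix$z, list(must_link = fix$constraints$must_link,
                                          cannot_link = fix$constraints$cannot_link[0, ]),
                              cfg), "cannot-link")
  bad <- fix$constraints
  bad$must_link$c1[1] <- "nonexistent"
  expect_error(train_embedder(fix$z, bad, cfg), "unknown contig")
})

test_that("training separates two planted clusters and descends the loss", {
  fix <- two_cluster_profiles()
  cfg <- tiny_net_config(ncol(fix$z), epochs = 30)
  emb <- train_embedder(fix$z, fix$constraints, cfg)
  expect_lte(emb$history[length(emb$history)], emb$history[1])
  e <- embed_contigs(emb, fix$z)
  expect_equal(ncol(e), 8L)
  d <- as.matrix(dist(e))
  same <- outer(fix$group, fix$group, "==")
  diag(same) <- NA
  intra <- mean(d[which(same)])
  inter <- mean(d[which(!same)])
  expect_gt(inter, intra)
})

test_that("embedding is deterministic and training reproducible under a seed", {
  fix <- two_cluster_profiles()
  cfg <- tiny_net_config(ncol(fix$z))
  e1 <- train_embedder(fix$z, fix$constraints, cfg)
  e2 <- train_embedder(fix$z, fix$constraints, cfg)
  expect_identical(e1, e2)
  expect_identical(embed_contigs(e1, fix$z), embed_contigs(e1, fix$z))
})

test_that("save/load round-trips embeddings and validates inputs", {
  fix <- two_cluster_profiles()
  cfg <- tiny_net_config(ncol(fix$z), epochs = 2)
  emb <- train_embedder(fix$z, fix$constraints, cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_embedder(emb, path)
  back <- load_embedder(path)
  expect_identical(embed_contigs(back, fix$z), embed_contigs(emb, fix$z))
  expect_error(embed_contigs(back, fix$z[, 1:10]), "dimension mismatch")
  expect_error(embed_contigs(back, fix$z, feature_regime = "kmer_plus_abundance"),
               "regime mismatch")
  saveRDS(list(foo = 1), path)
  expect_error(load_embedder(path), "not an embedder")
})

test_that("split-contig fragments embed near each other after training", {
  com <- tiny_community(seed = 31)
  thr <- must_link_threshold(com$contigs$length)
  sp <- split_for_must_link(com$contigs, thr)
  kf_all <- kmer_frequencies(setNames(c(com$contigs$sequence, sp$fragments$sequence),
                                      c(com$contigs$contig_id, sp$fragments$contig_id)))
  cs <- build_constraints(
    sp$must_link, com$taxonomy, com$markers,
    eligible_contig_ids = rownames(kf_all),
    fragment_parents = setNames(sp$fragments$parent_id, sp$fragments$contig_id),
    rng_seed = 4)
  cfg <- tiny_net_config(136, epochs = 15)
  emb <- train_embedder(kf_all, cs, cfg)
  e <- embed_contigs(emb, kf_all)
  frag_d <- sqrt(rowSums((e[cs$must_link$c1, , drop = FALSE] -
                            e[cs$must_link$c2, , drop = FALSE])^2))
  all_pairs_d <- as.vector(dist(e))
  expect_lt(median(frag_d), median(all_pairs_d))
})
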