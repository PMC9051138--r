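test_that("genome generation is seed-deterministic with exact lengths", {
  cfg <- community_config(n_genomes = 3, genome_length_bp = 20000, rng_seed = 5)
  g1 <- generate_genomes(cfg)
  g2 <- generate_genomes(cfg)
  expect_identical(g1, g2)
  expect_equal(unname(nchar(g1)), rep(20000L, 3))
  expect_true(all(strsplit(paste(g1, collapse = ""), "")[[1]] %in%
                    c("A", "C", "G", "T")))
})

test_that("planted genomes have separable tetranucleotide signatures", {
  cfg <- community_config(n_genomes = 2, genome_length_bp = 100000, rng_seed = 8)
  g <- generate_genomes(cfg)
  # cut each genome into 10 kb windows and compare signature distances
  windows <- function(s) {
    starts <- seq(1, nchar(s) - 9999, by = 10000)
    substring(s, starts, starts + 9999)
  }
  f1 <- kmer_frequencies(windows(g[[1]]))
  f2 <- kmer_frequencies(windows(g[[2]]))
  d_all <- as.matrix(dist(rbind(f1, f2)))
  n1 <- nrow(f1)
  intra <- c(d_all[seq_len(n1), seq_len(n1)][upper.tri(diag(n1))],
             d_all[-seq_len(n1), -seq_len(n1)][upper.tri(diag(nrow(f2)))])
  inter <- d_all[seq_len(n1), -seq_len(n1)]
  expect_gt(mean(inter), mean(intra))
})

test_that("fragmentation conserves genome length and coverage is complete", {
  cfg <- community_config(n_genomes = 4, genome_length_bp = 80000,
                          n_samples = 3, rng_seed = 12)
  com <- simulate_community(cfg)
  expect_equal(unname(com$genome_bp), rep(80000, 4))
  # contigs reassemble each genome exactly
  genomes <- generate_genomes(cfg)
  for (g in names(genomes)) {
    ids <- com$truth$contig_id[com$truth$genome_id == g]
    expect_equal(paste(com$contigs$sequence[match(ids, com$contigs$contig_id)],
                       collapse = ""), genomes[[g]])
  }
  expect_equal(nrow(com$coverage), 3 * nrow(com$contigs))
  expect_true(all(com$contigs$length >= cfg$contig_min))
  # every contig is covered by the ground truth
  expect_setequal(com$truth$contig_id, com$contigs$contig_id)
})

test_that("mean contig depth tracks the planted genome abundance", {
  cfg <- community_config(n_genomes = 5, genome_length_bp = 200000,
                          contig_meanlog = log(4000), rng_seed = 19)
  com <- simulate_community(cfg)
  genome_of <- setNames(com$truth$genome_id, com$truth$contig_id)
  for (s in unique(com$coverage$sample_id)) {
    cov <- com$coverage[com$coverage$sample_id == s, ]
    got <- tapply(cov$mean_depth, genome_of[cov$contig_id], mean)
    planted <- com$abundances[names(got), s]
    # lognormal jitter with sdlog 0.15 has mean exp(0.15^2/2) ~ 1.011
    expect_true(all(abs(got / planted - 1) < 0.10))
  }
})

test_that("annotation noise hits the configured rate and markers are single-copy", {
  cfg <- community_config(n_genomes = 6, genome_length_bp = 150000,
                          contig_meanlog = log(3500), contig_sdlog = 0.2,
                          taxonomy_error_rate = 0.5, marker_panel_size = 15,
                          rng_seed = 23)
  com <- simulate_community(cfg)
  wrong <- attr(com$taxonomy, "mislabeled")
  n <- nrow(com$taxonomy)
  # binomial 99% CI around 0.5
  ci <- qbinom(c(0.005, 0.995), n, 0.5) / n
  expect_gte(length(wrong) / n, ci[1])
  expect_lte(length(wrong) / n, ci[2])
  # with no noise, downstream cannot-links are all inter-genome (see
  # constraint tests); here check marker single-copy structure instead
  counts <- table(com$markers$marker_id,
                  setNames(com$truth$genome_id,
                           com$truth$contig_id)[com$markers$contig_id])
  expect_true(all(counts == 1))
  expect_equal(nrow(com$markers), 6 * 15)
  # markers sit on contigs of at least 2500 bp
  lens <- setNames(com$contigs$length, com$contigs$contig_id)
  expect_true(all(lens[com$markers$contig_id] >= 2500))
})

test_that("error-free annotations yield only inter-genome label disagreements", {
  com <- tiny_community(seed = 27, taxonomy_error_rate = 0)
  genome_of <- setNames(com$truth$genome_id, com$truth$contig_id)
  sp_of <- tapply(com$taxonomy$species_label, genome_of[com$taxonomy$contig_id],
                  function(x) length(unique(x)))
  expect_true(all(sp_of == 1))
})

test_that("the hard preset adds strain pairs sharing species labels", {
  cfg <- community_config_hard(n_genomes = 4, genome_length_bp = 60000,
                               rng_seed = 3)
  com <- simulate_community(cfg)
  expect_setequal(unique(com$truth$genome_id),
                  c("G01", "G02", "G03", "G04", "G01s", "G02s"))
  tax_of <- function(g) {
    unique(com$taxonomy$species_label[
      com$taxonomy$contig_id %in%
        com$truth$contig_id[com$truth$genome_id == g] &
        !(com$taxonomy$contig_id %in% attr(com$taxonomy, "mislabeled"))])
  }
  expect_equal(tax_of("G01s"), tax_of("G01"))
  # strains diverge by about 1% of bases
  g <- generate_genomes(cfg)
  diff <- mapply(function(a, b) sum(a != b),
                 strsplit(g[["G01"]], ""), strsplit(g[["G01s"]], ""))
  expect_equal(unname(diff / 60000), 0.01, tolerance = 0.15)
})

test_that("emitted files validate against the package readers", {
  dir <- withr::local_tempdir()
  com <- simulate_community(community_config(n_genomes = 3,
                                             genome_length_bp = 40000,
                                             rng_seed = 2), out_dir = dir)
  contigs <- read_fasta(file.path(dir, "contigs.fa"))
  expect_equal(contigs$contig_id, com$contigs$contig_id)
  expect_equal(contigs$sequence, com$contigs$sequence)
  cov <- read_coverage_table(file.path(dir, "coverage.tsv"))
  expect_equal(cov$mean_depth, com$coverage$mean_depth, tolerance = 1e-9)
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_equal(tax$species_label, com$taxonomy$species_label)
  mk <- read_markers(file.path(dir, "markers.tsv"))
  expect_equal(mk, com$markers)
})
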