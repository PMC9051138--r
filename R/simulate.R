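#' Configuration of the synthetic community generator
#'
#' The generator plants a small microbial community with known ground truth
#' and emulates every input the binner consumes: genomes with distinct
#' tetranucleotide signatures (order-2 Markov chains with genome-specific,
#' Dirichlet-perturbed transition matrices), contigs cut from the genomes,
#' per-sample coverage summaries (log-normal genome abundances with
#' Poisson-like per-contig depth noise), noisy taxonomy annotations and
#' single-copy marker-gene hits.
#'
#' @param n_genomes Number of base genomes.
#' @param genome_length_bp Length of each genome (bp).
#' @param n_samples Number of samples with independent abundance profiles.
#' @param contig_meanlog,contig_sdlog Log-normal contig length parameters.
#' @param contig_min,contig_max Clipping bounds on contig length (bp).
#' @param abundance_meanlog,abundance_sdlog Log-normal per-genome per-sample
#'   mean depth (reads per base).
#' @param depth_jitter_sdlog Log-normal per-contig depth jitter around the
#'   genome abundance.
#' @param overdispersion Extra-Poisson noise: depth variance is
#'   \code{mean + (overdispersion * mean)^2}.
#' @param taxonomy_error_rate Probability a contig is annotated with another
#'   genome's labels.
#' @param score_range Range of the uniform annotation confidence scores.
#' @param marker_panel_size Number of single-copy marker families; each
#'   genome carries each marker on exactly one contig.
#' @param genus_group_size Consecutive genomes sharing one genus label.
#' @param dirichlet_conc Dirichlet concentration of the transition-matrix
#'   perturbation (smaller = more distinct compositions).
#' @param strain_pairs Number of genomes duplicated as 1%-divergent strains
#'   (the "hard" preset uses 2); strains share the parent's species and
#'   genus but have independent abundance profiles.
#' @param strain_divergence Per-base substitution rate for strain copies.
#' @param rng_seed Integer seed; the whole community is a pure function of
#'   this config.
#' @return A \code{community_config} list.
#' @export
community_config <- function(n_genomes = 20, genome_length_bp = 300000,
                             n_samples = 3,
                             contig_meanlog = log(15000), contig_sdlog = 0.45,
                             contig_min = 2500, contig_max = 60000,
                             abundance_meanlog = log(20), abundance_sdlog = 1,
                             depth_jitter_sdlog = 0.15, overdispersion = 0.1,
                             taxonomy_error_rate = 0.05,
                             score_range = c(0.85, 1),
                             marker_panel_size = 40, genus_group_size = 2,
                             dirichlet_conc = 6, strain_pairs = 0,
                             strain_divergence = 0.01, rng_seed = 0L) {
  stopifnot(n_genomes >= 1, genome_length_bp >= 1000, n_samples >= 1,
            contig_min >= 8, contig_max >= contig_min,
            taxonomy_error_rate >= 0, taxonomy_error_rate <= 1,
            marker_panel_size >= 1, genus_group_size >= 1,
            strain_pairs >= 0, strain_pairs <= n_genomes)
  structure(as.list(environment()), class = "community_config")
}

#' The "hard" community preset
#'
#' The default community plus two strain pairs (genomes copied with 1%
#' substitutions), which the composition-based embedding cannot separate;
#' resolving them exercises the single-copy-gene reclustering path.
#'
#' @param ... Overrides passed to [community_config()].
#' @return A \code{community_config}.
#' @export
community_config_hard <- function(...) {
  community_config(strain_pairs = 2, ...)
}

base_codes <- c("A", "C", "G", "T")

# One genome sequence from an order-2 Markov chain with the given 16 x 4
# transition matrix (rows sum to 1).
markov_genome <- function(trans, len) {
  cum <- t(apply(trans, 1L, cumsum))
  s0 <- sample.int(4L, 1L) - 1L
  s1 <- sample.int(4L, 1L) - 1L
  codes <- cpp_markov_order2(cum, as.integer(len), s0, s1)
  paste(base_codes[codes + 1L], collapse = "")
}

#' Generate planted genome sequences
#'
#' Each genome is sampled from its own order-2 Markov chain whose transition
#' rows are Dirichlet perturbations of the uniform distribution, giving each
#' genome a distinct tetranucleotide signature. With \code{strain_pairs > 0}
#' the first genomes are additionally copied with random substitutions.
#'
#' @param config A [community_config()].
#' @return Named character vector of genome sequences; strain copies are
#'   named \code{"<genome>s"}. Carries an attribute \code{strain_parent}
#'   (named vector mapping strain id to parent id).
#' @export
generate_genomes <- function(config) {
  local_seed_eval(config$rng_seed, {
    n <- config$n_genomes
    ids <- sprintf("G%02d", seq_len(n))
    seqs <- vapply(seq_len(n), function(i) {
      raw <- matrix(stats::rgamma(64, shape = config$dirichlet_conc), 16, 4)
      trans <- raw / rowSums(raw)
      markov_genome(trans, config$genome_length_bp)
    }, character(1))
    names(seqs) <- ids
    strain_parent <- character(0)
    if (config$strain_pairs > 0) {
      for (i in seq_len(config$strain_pairs)) {
        parent <- ids[i]
        sid <- paste0(parent, "s")
        s <- strsplit(seqs[[parent]], "")[[1]]
        nsub <- round(config$strain_divergence * length(s))
        pos <- sample.int(length(s), nsub)
        repl <- vapply(s[pos], function(b) {
          sample(setdiff(base_codes, b), 1L)
        }, character(1))
        s[pos] <- repl
        seqs[sid] <- paste(s, collapse = "")
        strain_parent[sid] <- parent
      }
    }
    attr(seqs, "strain_parent") <- strain_parent
    seqs
  })
}

#' Cut genomes into contigs and simulate per-sample coverage
#'
#' Contig lengths are drawn from a clipped log-normal; each genome is cut
#' sequentially so member contig lengths sum exactly to the genome length
#' (a short terminal remainder is absorbed into the last contig). Per
#' (genome, sample) mean depth is log-normal; per-contig depth adds
#' log-normal jitter, and the depth variance follows the Poisson-like model
#' \code{mean + (overdispersion * mean)^2}.
#'
#' @param genomes Output of [generate_genomes()].
#' @param config The same [community_config()].
#' @return List with \code{contigs} (contig \code{data.frame}),
#'   \code{coverage} (coverage \code{data.frame}) and \code{truth}
#'   (\code{data.frame} contig_id, genome_id).
#' @export
fragment_and_cover <- function(genomes, config) {
  local_seed_eval(config$rng_seed + 1L, {
    contig_rows <- list()
    truth_rows <- list()
    for (g in names(genomes)) {
      glen <- nchar(genomes[[g]])
      cuts <- integer(0)
      pos <- 0L
      while (pos < glen) {
        len <- round(stats::rlnorm(1, config$contig_meanlog, config$contig_sdlog))
        len <- min(max(len, config$contig_min), config$contig_max)
        if (glen - (pos + len) < config$contig_min) len <- glen - pos
        cuts <- c(cuts, len)
        pos <- pos + len
      }
      ends <- cumsum(cuts)
      starts <- c(1L, utils::head(ends, -1L) + 1L)
      ids <- sprintf("%s_c%03d", g, seq_along(cuts))
      contig_rows[[g]] <- data.frame(
        contig_id = ids, sample_id = "",
        sequence = substring(genomes[[g]], starts, ends),
        length = cuts, stringsAsFactors = FALSE)
      truth_rows[[g]] <- data.frame(contig_id = ids, genome_id = g,
                                    stringsAsFactors = FALSE)
    }
    contigs <- do.call(rbind, contig_rows)
    truth <- do.call(rbind, truth_rows)
    rownames(contigs) <- rownames(truth) <- NULL

    samples <- sprintf("S%d", seq_len(config$n_samples))
    abund <- matrix(stats::rlnorm(length(genomes) * config$n_samples,
                                  config$abundance_meanlog,
                                  config$abundance_sdlog),
                    length(genomes), config$n_samples,
                    dimnames = list(names(genomes), samples))
    cov_rows <- vector("list", config$n_samples)
    for (s in seq_along(samples)) {
      base <- abund[truth$genome_id, s]
      m <- base * stats::rlnorm(nrow(contigs), 0, config$depth_jitter_sdlog)
      v <- m + (config$overdispersion * m)^2
      cov_rows[[s]] <- data.frame(contig_id = contigs$contig_id,
                                  sample_id = samples[s],
                                  mean_depth = m, depth_variance = v,
                                  stringsAsFactors = FALSE)
    }
    coverage <- do.call(rbind, cov_rows)
    rownames(coverage) <- NULL
    list(contigs = contigs, coverage = coverage, truth = truth,
         abundances = abund)
  })
}

#' Simulate taxonomy annotations and marker-gene hits
#'
#' Each base genome gets a distinct species label; consecutive genomes share
#' genus labels in groups of \code{genus_group_size}; strain copies reuse the
#' parent's labels. Contigs inherit their genome's labels with confidence
#' scores drawn uniformly from \code{score_range}, except that with
#' probability \code{taxonomy_error_rate} a contig is mislabeled with
#' another genome's species and genus. Every genome carries each of the
#' single-copy markers on exactly one uniformly chosen contig of >= 2500 bp.
#'
#' @param truth Truth \code{data.frame} from [fragment_and_cover()].
#' @param contig_lengths Named vector of contig lengths.
#' @param config The [community_config()].
#' @param strain_parent Named vector mapping strain genome ids to parents.
#' @return List with \code{taxonomy} and \code{markers} \code{data.frame}s.
#' @export
annotate_community <- function(truth, contig_lengths, config,
                               strain_parent = character(0)) {
  local_seed_eval(config$rng_seed + 2L, {
    genome_ids <- unique(truth$genome_id)
    base_ids <- setdiff(genome_ids, names(strain_parent))
    sp <- stats::setNames(paste0("sp_", base_ids), base_ids)
    genus_idx <- ceiling(seq_along(base_ids) / config$genus_group_size)
    ge <- stats::setNames(sprintf("gen_%02d", genus_idx), base_ids)
    label_of <- function(g) {
      if (g %in% names(strain_parent)) g <- strain_parent[[g]]
      c(sp[[g]], ge[[g]])
    }

    n <- nrow(truth)
    lab <- t(vapply(truth$genome_id, label_of, character(2)))
    wrong <- stats::runif(n) < config$taxonomy_error_rate
    if (any(wrong) && length(base_ids) > 1L) {
      for (i in which(wrong)) {
        own <- truth$genome_id[i]
        if (own %in% names(strain_parent)) own <- strain_parent[[own]]
        other <- sample(setdiff(base_ids, own), 1L)
        lab[i, ] <- c(sp[[other]], ge[[other]])
      }
    }
    sc <- matrix(stats::runif(2 * n, config$score_range[1], config$score_range[2]),
                 n, 2)
    taxonomy <- data.frame(contig_id = truth$contig_id,
                           species_label = lab[, 1], species_score = sc[, 1],
                           genus_label = lab[, 2], genus_score = sc[, 2],
                           stringsAsFactors = FALSE)
    attr(taxonomy, "mislabeled") <- truth$contig_id[wrong]

    marker_ids <- sprintf("SCG%03d", seq_len(config$marker_panel_size))
    mk <- list()
    for (g in genome_ids) {
      cands <- truth$contig_id[truth$genome_id == g]
      cands <- cands[contig_lengths[cands] >= 2500]
      if (length(cands) == 0L) next
      host <- if (length(cands) == 1L) {
        rep(cands, length(marker_ids))
      } else {
        cands[sample.int(length(cands), length(marker_ids), replace = TRUE)]
      }
      mk[[g]] <- data.frame(contig_id = host, marker_id = marker_ids,
                            stringsAsFactors = FALSE)
    }
    markers <- do.call(rbind, mk)
    rownames(markers) <- NULL
    list(taxonomy = taxonomy, markers = markers)
  })
}

#' Generate a full synthetic community
#'
#' Runs [generate_genomes()], [fragment_and_cover()] and
#' [annotate_community()] and (optionally) writes every pipeline input plus
#' the ground truth to a directory: \code{contigs.fa}, \code{coverage.tsv},
#' \code{taxonomy.tsv}, \code{markers.tsv}, \code{truth.tsv}.
#'
#' @param config A [community_config()].
#' @param out_dir Optional output directory.
#' @return List with \code{contigs}, \code{coverage}, \code{taxonomy},
#'   \code{markers}, \code{truth}, \code{genome_bp} (named vector) and
#'   \code{abundances} (genome x sample matrix).
#' @export
simulate_community <- function(config = community_config(), out_dir = NULL) {
  genomes <- generate_genomes(config)
  fc <- fragment_and_cover(genomes, config)
  clen <- stats::setNames(fc$contigs$length, fc$contigs$contig_id)
  ann <- annotate_community(fc$truth, clen, config,
                            attr(genomes, "strain_parent"))
  genome_bp <- vapply(split(as.numeric(fc$contigs$length), fc$truth$genome_id),
                      sum, 1)
  out <- list(contigs = fc$contigs, coverage = fc$coverage,
              taxonomy = ann$taxonomy, markers = ann$markers,
              truth = fc$truth, genome_bp = genome_bp,
              abundances = fc$abundances)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_fasta(out$contigs, file.path(out_dir, "contigs.fa"))
    write_coverage_table(out$coverage, file.path(out_dir, "coverage.tsv"))
    write_taxonomy(out$taxonomy, file.path(out_dir, "taxonomy.tsv"))
    write_markers(out$markers, file.path(out_dir, "markers.tsv"))
    utils::write.table(out$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
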