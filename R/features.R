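#' Canonical k-mer index
#'
#' A k-mer and its reverse complement are counted as one feature. The
#' canonical representative of a k-mer is the lexicographic minimum of the
#' pair; features are ordered lexicographically by canonical form. For k = 4
#' this yields the 136-dimensional tetranucleotide space
#' ((4^k + 4^(k/2)) / 2 features for even k, 4^k / 2 for odd k).
#'
#' @param k Word size (k >= 1).
#' @return Named integer vector mapping each canonical k-mer to its column
#'   index (1-based, lexicographic order).
#' @export
canonical_kmer_index <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), width = as.integer(k))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  canon <- ifelse(kmers <= rc, kmers, rc)
  lev <- sort(unique(canon))
  stats::setNames(seq_along(lev), lev)
}

# Map from all 4^k lexicographic k-mers (the column order of
# Biostrings::oligonucleotideFrequency) to canonical column indices.
kmer_collapse_map <- function(k) {
  idx <- canonical_kmer_index(k)
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), width = as.integer(k))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  canon <- ifelse(kmers <= rc, kmers, rc)
  unname(idx[canon])
}

#' Canonical k-mer relative frequencies
#'
#' Counts all overlapping k-mer windows of each sequence (windows containing
#' any non-ACGT letter, e.g. N, are skipped), pools reverse-complement pairs,
#' adds a pseudo-count of 1e-5 to every canonical count and normalizes so
#' each row sums to 1:
#' \deqn{k'_i = (k_i + 10^{-5}) / \sum_j (k_j + 10^{-5}).}
#' The pseudo-count keeps every entry strictly positive; canonicalization
#' makes the result strand-invariant.
#'
#' @param sequences Character vector of DNA sequences (or a
#'   \code{DNAStringSet}).
#' @param k Word size; the default 4 gives the 136 canonical tetranucleotides.
#' @return Numeric matrix, one row per sequence, columns ordered as in
#'   [canonical_kmer_index()]; every row sums to 1.
#' @export
kmer_frequencies <- function(sequences, k = 4) {
  if (is.character(sequences)) {
    names <- names(sequences)
    sequences <- Biostrings::DNAStringSet(sequences)
    names(sequences) <- names
  }
  counts <- Biostrings::oligonucleotideFrequency(sequences, width = as.integer(k))
  none <- rowSums(counts) == 0
  if (any(none)) {
    lab <- if (!is.null(names(sequences))) names(sequences)[none][1L] else which(none)[1L]
    stop("sequence '", lab, "' too short for k-mer features (no valid ",
         k, "-mer window)")
  }
  map <- kmer_collapse_map(k)
  ncanon <- max(map)
  collapse <- matrix(0, ncol(counts), ncanon)
  collapse[cbind(seq_len(ncol(counts)), map)] <- 1
  pooled <- counts %*% collapse + 1e-5
  freq <- pooled / rowSums(pooled)
  colnames(freq) <- names(canonical_kmer_index(k))
  rownames(freq) <- names(sequences)
  freq
}

#' Abundance scaling constant
#'
#' Abundance features are divided by \eqn{s = 100 \lceil a_{mean} / 100
#' \rceil} (per sample), bringing them to the same order of magnitude as the
#' k-mer frequencies. A zero mean abundance maps to s = 100 so unmapped
#' samples never divide by zero.
#'
#' @param mean_abundance Mean per-base read depth across contigs of one
#'   sample (>= 0).
#' @return The scale s (a positive multiple of 100).
#' @export
scale_constant <- function(mean_abundance) {
  if (any(!is.finite(mean_abundance)) || any(mean_abundance < 0)) {
    stop("mean_abundance must be finite and non-negative")
  }
  100 * pmax(1, ceiling(mean_abundance / 100))
}

#' Assemble the model input vector Z
#'
#' With five or more samples the input concatenates the k-mer frequencies and
#' the scaled per-sample abundances (dimension 136 + N); with fewer samples
#' the input is the k-mer vector alone (dimension 136) and abundance instead
#' enters the pipeline through the depth-distribution divergence term of the
#' similarity.
#'
#' @param kmer_freq Matrix of canonical k-mer frequencies (rows = contigs).
#' @param abundances Matrix of per-sample mean depths (rows = contigs,
#'   columns = samples), or \code{NULL} when unused.
#' @param per_sample_scales Positive scale per sample (see
#'   [scale_constant()]).
#' @param n_samples Number of samples N.
#' @return The input matrix Z.
#' @export
assemble_z <- function(kmer_freq, abundances, per_sample_scales, n_samples) {
  if (n_samples < 5) return(kmer_freq)
  if (is.null(abundances) || ncol(abundances) != n_samples) {
    stop("abundance matrix must have one column per sample")
  }
  if (nrow(abundances) != nrow(kmer_freq)) {
    stop("kmer_freq and abundances disagree on the number of contigs")
  }
  if (length(per_sample_scales) != n_samples || any(per_sample_scales <= 0)) {
    stop("need one positive scale per sample")
  }
  cbind(kmer_freq, sweep(abundances, 2L, per_sample_scales, "/"))
}

#' Choose the minimum contig length for binning
#'
#' Contigs shorter than the returned threshold are excluded from binning.
#' The default cutoff is 2500 bp, relaxed to 1000 bp when contigs in the
#' 1000-2500 bp range make up less than \code{small_fraction} (default 5%)
#' of the basepairs among contigs of at least 1000 bp.
#'
#' @param contig_lengths Non-empty integer vector of contig lengths (bp).
#' @param small_fraction Fraction below which the 1000 bp cutoff is used.
#' @return 1000 or 2500.
#' @export
select_min_length <- function(contig_lengths, small_fraction = 0.05) {
  stopifnot(length(contig_lengths) > 0)
  eligible <- contig_lengths[contig_lengths >= 1000]
  total <- sum(as.numeric(eligible))
  short_bp <- sum(as.numeric(eligible[eligible < 2500]))
  if (total == 0 || short_bp < small_fraction * total) 1000L else 2500L
}

#' Minimum length of contigs to split for must-link constraints
#'
#' Must-link constraints come from splitting long contigs in half. The split
#' threshold is chosen so that the contigs at or above it still contain most
#' (by default 98%) of the input basepairs: the largest observed length L*
#' with \code{sum(lengths >= L*) >= bp_fraction * sum(lengths)} is selected,
#' then floored at 4000 bp so that split halves stay usefully long.
#'
#' @param contig_lengths Non-empty integer vector of contig lengths (bp).
#' @param bp_fraction Fraction of basepairs the retained contigs must hold.
#' @return Threshold in bp (>= 4000).
#' @export
must_link_threshold <- function(contig_lengths, bp_fraction = 0.98) {
  stopifnot(length(contig_lengths) > 0)
  total <- sum(as.numeric(contig_lengths))
  cands <- sort(unique(contig_lengths))
  ok <- vapply(cands, function(L) {
    sum(as.numeric(contig_lengths[contig_lengths >= L])) >= bp_fraction * total
  }, logical(1))
  max(4000, max(cands[ok]))
}
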