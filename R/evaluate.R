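#' Score bins against a planted ground truth
#'
#' Basepair-weighted scoring: each bin is mapped to the genome with the
#' largest basepair overlap (ties broken lexicographically by genome id).
#' Completeness (recall) is overlap over the genome's total basepairs;
#' purity (precision) is overlap over the bin's basepairs; contamination is
#' 1 - purity; F1 is the harmonic mean of completeness and purity. Quality
#' tiers: \emph{high} = completeness > 0.90 and contamination < 0.05;
#' \emph{medium} = completeness >= 0.50 and contamination < 0.10 (and not
#' high); \emph{low} = completeness < 0.50 and contamination < 0.10;
#' \emph{none} otherwise. Unbinned contigs never penalize purity.
#'
#' @param assignments Assignment \code{data.frame} (\code{contig_id},
#'   \code{bin_id}; \code{"unbinned"} rows are ignored).
#' @param truth \code{data.frame} with \code{contig_id}, \code{genome_id}
#'   covering every binned contig.
#' @param contig_lengths Named vector of contig lengths (bp).
#' @return \code{data.frame} with one row per bin: \code{bin_id},
#'   \code{mapped_genome}, \code{completeness}, \code{purity},
#'   \code{contamination}, \code{f1}, \code{tier}.
#' @export
score_bins <- function(assignments, truth, contig_lengths) {
  binned <- assignments[assignments$bin_id != "unbinned", , drop = FALSE]
  empty <- data.frame(bin_id = character(0), mapped_genome = character(0),
                      completeness = numeric(0), purity = numeric(0),
                      contamination = numeric(0), f1 = numeric(0),
                      tier = character(0), stringsAsFactors = FALSE)
  if (nrow(binned) == 0L) return(empty)
  unknown <- setdiff(binned$contig_id, truth$contig_id)
  if (length(unknown)) stop("binned contig without truth label: '", unknown[1L], "'")
  unknown <- setdiff(binned$contig_id, names(contig_lengths))
  if (length(unknown)) stop("binned contig without length: '", unknown[1L], "'")

  genome_of <- stats::setNames(truth$genome_id, truth$contig_id)
  genome_bp <- tapply(as.numeric(contig_lengths[truth$contig_id]),
                      truth$genome_id, sum)

  rows <- lapply(sort(unique(binned$bin_id)), function(b) {
    ids <- binned$contig_id[binned$bin_id == b]
    bp <- as.numeric(contig_lengths[ids])
    by_genome <- tapply(bp, genome_of[ids], sum)
    best <- sort(names(by_genome)[by_genome == max(by_genome)])[1L]
    overlap <- by_genome[[best]]
    completeness <- overlap / genome_bp[[best]]
    purity <- overlap / sum(bp)
    contamination <- 1 - purity
    f1 <- if (completeness + purity == 0) 0 else
      2 * completeness * purity / (completeness + purity)
    tier <- if (completeness > 0.90 && contamination < 0.05) "high"
    else if (completeness >= 0.50 && contamination < 0.10) "medium"
    else if (completeness < 0.50 && contamination < 0.10) "low"
    else "none"
    data.frame(bin_id = b, mapped_genome = best, completeness = completeness,
               purity = purity, contamination = contamination, f1 = f1,
               tier = tier, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count distinct genomes recovered at a quality tier or better
#'
#' @param scores Output of [score_bins()].
#' @param tier Requested tier (\code{"high"}, \code{"medium"} or
#'   \code{"low"}); bins at this tier or better count.
#' @return Number of distinct mapped genomes.
#' @export
count_distinct_recovered <- function(scores, tier = c("high", "medium", "low")) {
  tier <- match.arg(tier)
  rank <- c(high = 3L, medium = 2L, low = 1L, none = 0L)
  sel <- rank[scores$tier] >= rank[[tier]]
  length(unique(scores$mapped_genome[sel]))
}

#' Per-tier summary of a scored binning
#'
#' @param scores Output of [score_bins()].
#' @return Named integer vector of bin counts per tier plus distinct
#'   genomes recovered at high quality.
#' @export
summarize_scores <- function(scores) {
  c(high = sum(scores$tier == "high"),
    medium = sum(scores$tier == "medium"),
    low = sum(scores$tier == "low"),
    none = sum(scores$tier == "none"),
    genomes_high = count_distinct_recovered(scores, "high"))
}
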