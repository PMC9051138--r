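#' Split long contigs to create must-link constraints
#'
#' Every contig at least \code{threshold} bp long is broken into two halves
#' (the first \code{ceiling(L/2)} bp and the last \code{floor(L/2)} bp),
#' named \code{"<id>_1"} and \code{"<id>_2"}, and the two halves form one
#' must-link pair: by construction they belong to the same genome. The
#' original contig is kept for binning; the fragments are used only to train
#' the embedding. Fragments inherit the parent's coverage records (read
#' depth is locally homogeneous at half-contig scale) and, downstream, its
#' taxonomy annotation.
#'
#' @param contigs Contig \code{data.frame} (see [read_fasta()]).
#' @param threshold Minimum length to split, from [must_link_threshold()].
#' @return A list with \code{fragments} (contig \code{data.frame} of the new
#'   halves, with \code{parent_id}) and \code{must_link} (\code{data.frame}
#'   with columns \code{c1}, \code{c2}).
#' @export
split_for_must_link <- function(contigs, threshold) {
  if (threshold < 8) stop("threshold < 8 bp: fragments could not support 4-mers")
  long <- contigs[contigs$length >= threshold, , drop = FALSE]
  if (nrow(long) == 0L) {
    return(list(
      fragments = data.frame(contig_id = character(0), sample_id = character(0),
                             sequence = character(0), length = integer(0),
                             parent_id = character(0), stringsAsFactors = FALSE),
      must_link = data.frame(c1 = character(0), c2 = character(0),
                             stringsAsFactors = FALSE)))
  }
  cut <- ceiling(long$length / 2)
  first <- substr(long$sequence, 1L, cut)
  second <- substr(long$sequence, cut + 1L, long$length)
  fragments <- data.frame(
    contig_id = c(paste0(long$contig_id, "_1"), paste0(long$contig_id, "_2")),
    sample_id = rep(long$sample_id, 2L),
    sequence = c(first, second),
    length = nchar(c(first, second)),
    parent_id = rep(long$contig_id, 2L),
    stringsAsFactors = FALSE)
  must_link <- data.frame(c1 = paste0(long$contig_id, "_1"),
                          c2 = paste0(long$contig_id, "_2"),
                          stringsAsFactors = FALSE)
  list(fragments = fragments, must_link = must_link)
}

# Canonicalize an unordered pair table: c1 < c2, no self-pairs, unique.
canonical_pairs <- function(c1, c2, type = NULL) {
  lo <- pmin(c1, c2)
  hi <- pmax(c1, c2)
  keep <- lo != hi
  df <- data.frame(c1 = lo[keep], c2 = hi[keep], stringsAsFactors = FALSE)
  if (!is.null(type)) df$type <- type[keep]
  df[!duplicated(paste(df$c1, df$c2, sep = "\r")), , drop = FALSE]
}

#' Cannot-link constraints from taxonomy disagreements
#'
#' Two contigs receive a cannot-link constraint when their annotations
#' disagree at species level with both species scores above 0.95, or at
#' genus level with both genus scores above 0.80 (strict inequalities;
#' labels compared as exact strings). Contigs lacking the relevant label or
#' score never trigger the corresponding rule.
#'
#' @param annotations Taxonomy \code{data.frame} (see [read_taxonomy()]).
#' @param eligible_contig_ids Contig ids eligible for constraints (e.g. the
#'   length-filtered training set).
#' @param species_min,genus_min Score thresholds for the two rules.
#' @return \code{data.frame} with columns \code{c1}, \code{c2}, \code{type}
#'   (\code{"taxonomy_species"} or \code{"taxonomy_genus"}).
#' @export
cannot_link_from_taxonomy <- function(annotations, eligible_contig_ids,
                                      species_min = 0.95, genus_min = 0.80) {
  ann <- annotations[annotations$contig_id %in% eligible_contig_ids, , drop = FALSE]
  out <- list()

  pair_rule <- function(ids, labels, type) {
    if (length(ids) < 2L) return(NULL)
    ord <- order(ids)
    ids <- ids[ord]; labels <- labels[ord]
    idx <- utils::combn(length(ids), 2L)
    diff <- labels[idx[1L, ]] != labels[idx[2L, ]]
    if (!any(diff)) return(NULL)
    canonical_pairs(ids[idx[1L, diff]], ids[idx[2L, diff]],
                    rep(type, sum(diff)))
  }

  sp <- !is.na(ann$species_label) & !is.na(ann$species_score) &
    ann$species_score > species_min
  out$species <- pair_rule(ann$contig_id[sp], ann$species_label[sp],
                           "taxonomy_species")
  ge <- !is.na(ann$genus_label) & !is.na(ann$genus_score) &
    ann$genus_score > genus_min
  out$genus <- pair_rule(ann$contig_id[ge], ann$genus_label[ge],
                         "taxonomy_genus")
  df <- do.call(rbind, out)
  if (is.null(df)) {
    return(data.frame(c1 = character(0), c2 = character(0),
                      type = character(0), stringsAsFactors = FALSE))
  }
  rownames(df) <- NULL
  # species provenance wins when both rules fire on a pair
  df[!duplicated(paste(df$c1, df$c2, sep = "\r")), , drop = FALSE]
}

#' Cannot-link constraints between single-copy marker-gene seed contigs
#'
#' Single-copy marker genes occur once per genome, so distinct contigs
#' carrying the same marker must come from distinct genomes. The marker
#' observed on the largest number of distinct eligible contigs (ties broken
#' lexicographically by marker id) defines the seed set; every unordered
#' pair of seeds becomes a cannot-link constraint.
#'
#' @param marker_hits Marker \code{data.frame} (see [read_markers()]).
#' @param eligible_contig_ids Contig ids eligible for constraints.
#' @return \code{data.frame} with columns \code{c1}, \code{c2}, \code{type}
#'   (\code{"scg_seed"}).
#' @export
scg_seed_cannot_link <- function(marker_hits, eligible_contig_ids) {
  empty <- data.frame(c1 = character(0), c2 = character(0),
                      type = character(0), stringsAsFactors = FALSE)
  hits <- marker_hits[marker_hits$contig_id %in% eligible_contig_ids, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[!duplicated(paste(hits$contig_id, hits$marker_id, sep = "\r")), ]
  counts <- table(hits$marker_id)
  best <- sort(names(counts)[counts == max(counts)])[1L]
  seeds <- sort(unique(hits$contig_id[hits$marker_id == best]))
  if (length(seeds) < 2L) return(empty)
  idx <- utils::combn(length(seeds), 2L)
  canonical_pairs(seeds[idx[1L, ]], seeds[idx[2L, ]],
                  rep("scg_seed", ncol(idx)))
}

#' Subsample cannot-link constraints
#'
#' Caps the number of cannot-link pairs (default four million) by uniform
#' sampling without replacement, to bound training cost; reproducible under
#' \code{rng_seed}.
#'
#' @param pairs Cannot-link pair \code{data.frame}.
#' @param max_cannot Maximum number of pairs to keep.
#' @param rng_seed Integer seed.
#' @return The (possibly subsampled) pair \code{data.frame}.
#' @export
subsample_cannot_link <- function(pairs, max_cannot = 4e6, rng_seed = 0L) {
  stopifnot(max_cannot > 0)
  if (nrow(pairs) <= max_cannot) return(pairs)
  keep <- local_seed_eval(rng_seed, sample.int(nrow(pairs), max_cannot))
  out <- pairs[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
local_seed_eval <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build the full constraint set
#'
#' Combines must-link pairs from contig splitting with cannot-link pairs
#' from taxonomy disagreements and single-copy marker seeds, pools the
#' cannot-link sources before subsampling to \code{max_cannot}, and checks
#' that the two sets are disjoint. Split fragments inherit their parent's
#' annotation and therefore participate in taxonomy cannot-links; marker
#' seeds are drawn from original contigs only (a fragment pair from one
#' parent would otherwise be declared cannot-link).
#'
#' @param must_link Must-link pair \code{data.frame} (from
#'   [split_for_must_link()]).
#' @param annotations Taxonomy annotations covering original contigs;
#'   fragments are matched through \code{fragment_parents}.
#' @param marker_hits Marker hits on original contigs.
#' @param eligible_contig_ids Ids in the training set (originals and
#'   fragments).
#' @param fragment_parents Named character vector mapping fragment id to
#'   parent id (may be empty).
#' @param max_cannot Cannot-link cap (default four million).
#' @param rng_seed Integer seed for the subsampling step.
#' @return A list with \code{must_link} and \code{cannot_link} pair
#'   \code{data.frame}s (\code{c1}, \code{c2}, \code{type}).
#' @export
build_constraints <- function(must_link, annotations, marker_hits,
                              eligible_contig_ids,
                              fragment_parents = character(0),
                              max_cannot = 4e6, rng_seed = 0L) {
  ann <- annotations
  if (length(fragment_parents)) {
    idx <- match(fragment_parents, annotations$contig_id)
    ok <- !is.na(idx)
    frag_ann <- annotations[idx[ok], , drop = FALSE]
    frag_ann$contig_id <- names(fragment_parents)[ok]
    ann <- rbind(annotations, frag_ann)
  }
  tax <- cannot_link_from_taxonomy(ann, eligible_contig_ids)
  scg <- scg_seed_cannot_link(marker_hits,
                              setdiff(eligible_contig_ids, names(fragment_parents)))
  cannot <- rbind(tax, scg)
  cannot <- cannot[!duplicated(paste(cannot$c1, cannot$c2, sep = "\r")), , drop = FALSE]
  ml_key <- paste(pmin(must_link$c1, must_link$c2),
                  pmax(must_link$c1, must_link$c2), sep = "\r")
  cannot <- cannot[!(paste(cannot$c1, cannot$c2, sep = "\r") %in% ml_key), , drop = FALSE]
  cannot <- subsample_cannot_link(cannot, max_cannot, rng_seed)
  rownames(cannot) <- NULL
  ml <- canonical_pairs(must_link$c1, must_link$c2)
  ml$type <- rep("split", nrow(ml))
  list(must_link = ml, cannot_link = cannot)
}

#' Write a constraint set to a TSV for inspection
#'
#' @param constraints List with \code{must_link} and \code{cannot_link}.
#' @param path Output TSV path (columns c1, c2, link, type).
#' @export
write_constraints <- function(constraints, path) {
  ml <- constraints$must_link
  cl <- constraints$cannot_link
  df <- rbind(
    if (nrow(ml)) data.frame(c1 = ml$c1, c2 = ml$c2, link = "must",
                             type = ml$type, stringsAsFactors = FALSE),
    if (nrow(cl)) data.frame(c1 = cl$c1, c2 = cl$c2, link = "cannot",
                             type = cl$type, stringsAsFactors = FALSE))
  if (is.null(df)) df <- data.frame(c1 = character(0), c2 = character(0),
                                    link = character(0), type = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
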