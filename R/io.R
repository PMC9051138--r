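#' Read contigs from a FASTA file
#'
#' Parses a (multi-)FASTA file of assembled contigs. Headers are truncated at
#' the first whitespace to obtain the contig id. In multi-sample mode, ids of
#' the form \code{"<sample_id><sep><name>"} are split on the first occurrence
#' of the separator, recovering the per-sample contig catalogs from a
#' concatenated database.
#'
#' @param path Path to a FASTA file.
#' @param multi_sample Logical; if \code{TRUE}, split ids into sample id and
#'   contig name on the first \code{sep}.
#' @param sep Separator between sample id and contig name (default ":").
#' @return A \code{data.frame} with columns \code{contig_id},
#'   \code{sample_id} (empty string outside multi-sample mode),
#'   \code{sequence} and \code{length}.
#' @export
read_fasta <- function(path, multi_sample = FALSE, sep = ":") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  if (any(Biostrings::width(seqs) == 0L)) {
    stop("empty sequence for contig '", ids[Biostrings::width(seqs) == 0L][1L], "'")
  }
  sample_id <- rep("", length(ids))
  if (multi_sample) {
    has_sep <- grepl(sep, ids, fixed = TRUE)
    if (any(!has_sep)) {
      stop("multi-sample mode: id '", ids[!has_sep][1L],
           "' lacks separator '", sep, "'")
    }
    pos <- regexpr(sep, ids, fixed = TRUE)
    sample_id <- substr(ids, 1L, pos - 1L)
    ids <- substr(ids, pos + nchar(sep), nchar(ids))
  }
  key <- paste(sample_id, ids, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate contig id '", ids[duplicated(key)][1L], "'")
  }
  data.frame(contig_id = ids, sample_id = sample_id,
             sequence = as.character(seqs),
             length = Biostrings::width(seqs),
             stringsAsFactors = FALSE)
}

#' Write contigs to a FASTA file
#'
#' Inverse of [read_fasta()]. In multi-sample mode the header is
#' \code{"<sample_id><sep><contig_id>"}; sample ids containing the separator
#' are rejected so that the id concatenation is invertible.
#'
#' @param contigs A contig \code{data.frame} as returned by [read_fasta()].
#' @param path Output path.
#' @param multi_sample Logical; prefix headers with the sample id.
#' @param sep Separator used in multi-sample headers.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(contigs, path, multi_sample = FALSE, sep = ":") {
  ids <- contigs$contig_id
  if (multi_sample) {
    bad <- grepl(sep, contigs$sample_id, fixed = TRUE)
    if (any(bad)) {
      stop("sample_id '", contigs$sample_id[bad][1L],
           "' contains the separator '", sep, "'")
    }
    ids <- paste0(contigs$sample_id, sep, ids)
  }
  x <- Biostrings::DNAStringSet(contigs$sequence)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Read a TSV with a required header, reporting 1-based file line numbers
# (header = line 1) for malformed rows.
read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE, quote = "")
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  df
}

# Convert a character column to numeric; "" becomes NA if allow_na, otherwise
# an error; non-numeric text is an error with the offending file line.
num_col <- function(x, name, path, allow_na = FALSE) {
  blank <- !nzchar(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !blank
  if (any(bad)) {
    stop("malformed value in column '", name, "' of ", path,
         " at line ", which(bad)[1L] + 1L, ": '", x[bad][1L], "'")
  }
  if (any(blank) && !allow_na) {
    stop("empty value in column '", name, "' of ", path,
         " at line ", which(blank)[1L] + 1L)
  }
  out
}

#' Read a per-contig per-sample coverage table
#'
#' The coverage table summarises read mapping as, per (contig, sample), the
#' mean and the population variance of per-base read depth. This is the only
#' mapping-derived input the binner needs, so any aligner/depth tool can feed
#' it through this TSV contract.
#'
#' @param path TSV with header columns \code{contig_id}, \code{sample_id},
#'   \code{mean_depth}, \code{depth_variance}.
#' @return A \code{data.frame} with those columns, depths numeric.
#' @export
read_coverage_table <- function(path) {
  df <- read_tsv_checked(path, c("contig_id", "sample_id",
                                 "mean_depth", "depth_variance"))
  mean_depth <- num_col(df$mean_depth, "mean_depth", path)
  depth_variance <- num_col(df$depth_variance, "depth_variance", path)
  if (any(mean_depth < 0)) {
    stop("negative mean_depth in ", path,
         " at line ", which(mean_depth < 0)[1L] + 1L)
  }
  if (any(depth_variance < 0)) {
    stop("negative depth_variance in ", path,
         " at line ", which(depth_variance < 0)[1L] + 1L)
  }
  out <- data.frame(contig_id = df$contig_id, sample_id = df$sample_id,
                    mean_depth = mean_depth, depth_variance = depth_variance,
                    stringsAsFactors = FALSE)
  key <- paste(out$contig_id, out$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (contig_id, sample_id) pair in ", path,
         " at line ", which(duplicated(key))[1L] + 1L)
  }
  out
}

#' @rdname read_coverage_table
#' @param coverage A coverage \code{data.frame}.
#' @export
write_coverage_table <- function(coverage, path) {
  stopifnot(all(c("contig_id", "sample_id", "mean_depth", "depth_variance")
                %in% names(coverage)))
  utils::write.table(
    coverage[, c("contig_id", "sample_id", "mean_depth", "depth_variance")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarise a per-base depth array into a coverage record
#'
#' Models read depth along a contig: the record keeps the arithmetic mean and
#' the population variance (divide by n) of per-base depth, the two parameters
#' of the per-contig normal depth model used downstream.
#'
#' @param contig_id,sample_id Identifiers for the record.
#' @param per_base_depths Non-empty numeric vector of non-negative per-base
#'   read depths (one entry per base, 0-based half-open positions).
#' @return A one-row coverage \code{data.frame}.
#' @export
depth_array_to_record <- function(contig_id, sample_id, per_base_depths) {
  if (length(per_base_depths) == 0L) stop("empty per-base depth array")
  if (any(!is.finite(per_base_depths)) || any(per_base_depths < 0)) {
    stop("per-base depths must be finite and non-negative")
  }
  m <- mean(per_base_depths)
  v <- mean((per_base_depths - m)^2)
  data.frame(contig_id = contig_id, sample_id = sample_id,
             mean_depth = m, depth_variance = v, stringsAsFactors = FALSE)
}

#' Read per-contig taxonomy annotations
#'
#' Adapter for the output of a reference-based contig annotator. Species- and
#' genus-level labels come with confidence scores in \[0, 1\]; absent
#' annotations are encoded as empty fields. These feed the cannot-link
#' constraint rules.
#'
#' @param path TSV with header columns \code{contig_id}, \code{species_label},
#'   \code{species_score}, \code{genus_label}, \code{genus_score}.
#' @return A \code{data.frame} with labels as character (\code{NA} when
#'   absent) and scores numeric (\code{NA} when absent).
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv_checked(path, c("contig_id", "species_label", "species_score",
                                 "genus_label", "genus_score"))
  species_score <- num_col(df$species_score, "species_score", path, allow_na = TRUE)
  genus_score <- num_col(df$genus_score, "genus_score", path, allow_na = TRUE)
  for (nm in c("species_score", "genus_score")) {
    sc <- if (nm == "species_score") species_score else genus_score
    bad <- !is.na(sc) & (sc < 0 | sc > 1)
    if (any(bad)) {
      stop(nm, " outside [0,1] in ", path, " at line ", which(bad)[1L] + 1L)
    }
  }
  species_label <- ifelse(nzchar(df$species_label), df$species_label, NA_character_)
  genus_label <- ifelse(nzchar(df$genus_label), df$genus_label, NA_character_)
  orphan <- !is.na(species_label) & is.na(genus_label)
  if (any(orphan)) {
    stop("species_label without genus_label in ", path,
         " at line ", which(orphan)[1L] + 1L)
  }
  data.frame(contig_id = df$contig_id,
             species_label = species_label, species_score = species_score,
             genus_label = genus_label, genus_score = genus_score,
             stringsAsFactors = FALSE)
}

#' @rdname read_taxonomy
#' @param taxonomy A taxonomy \code{data.frame}.
#' @export
write_taxonomy <- function(taxonomy, path) {
  df <- taxonomy[, c("contig_id", "species_label", "species_score",
                     "genus_label", "genus_score")]
  df[] <- lapply(df, function(x) ifelse(is.na(x), "", as.character(x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read single-copy marker-gene hits
#'
#' Adapter for the output of a marker-gene caller: one row per (contig,
#' marker family) hit. A (contig, marker) pair appearing twice means the
#' contig genuinely carries two copies.
#'
#' @param path TSV with header columns \code{contig_id}, \code{marker_id}.
#' @return A \code{data.frame} with those columns.
#' @export
read_markers <- function(path) {
  df <- read_tsv_checked(path, c("contig_id", "marker_id"))
  blank <- !nzchar(df$contig_id) | !nzchar(df$marker_id)
  if (any(blank)) {
    stop("empty field in ", path, " at line ", which(blank)[1L] + 1L)
  }
  data.frame(contig_id = df$contig_id, marker_id = df$marker_id,
             stringsAsFactors = FALSE)
}

#' @rdname read_markers
#' @param markers A marker \code{data.frame}.
#' @export
write_markers <- function(markers, path) {
  utils::write.table(markers[, c("contig_id", "marker_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write contig-to-bin assignments
#'
#' @param path TSV with header columns \code{contig_id}, \code{bin_id};
#'   unbinned contigs carry the literal bin id \code{"unbinned"}.
#' @return A \code{data.frame} with those columns.
#' @export
read_assignments <- function(path) {
  df <- read_tsv_checked(path, c("contig_id", "bin_id"))
  if (anyDuplicated(df$contig_id)) {
    stop("duplicate contig_id in ", path, " at line ",
         which(duplicated(df$contig_id))[1L] + 1L)
  }
  data.frame(contig_id = df$contig_id, bin_id = df$bin_id,
             stringsAsFactors = FALSE)
}

#' @rdname read_assignments
#' @param assignments An assignment \code{data.frame}.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(assignments[, c("contig_id", "bin_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write bins as per-bin FASTA files plus an assignment table
#'
#' Bins are renamed deterministically \code{bin_000, bin_001, ...} in order of
#' descending total basepairs (ties broken by the lexicographically smallest
#' member contig id). Unbinned contigs appear in the TSV only.
#'
#' @param assignments \code{data.frame} with \code{contig_id}, \code{bin_id}.
#' @param contigs Contig \code{data.frame} covering every assigned contig.
#' @param out_dir Output directory (created if absent).
#' @param overwrite Logical; overwrite existing output files.
#' @return Invisibly, the renamed assignment \code{data.frame}.
#' @export
write_bins <- function(assignments, contigs, out_dir, overwrite = FALSE) {
  unknown <- setdiff(assignments$contig_id, contigs$contig_id)
  if (length(unknown)) {
    stop("assignment references unknown contig '", unknown[1L], "'")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  binned <- assignments[assignments$bin_id != "unbinned", , drop = FALSE]
  clen <- stats::setNames(contigs$length, contigs$contig_id)

  new_ids <- character(0)
  if (nrow(binned)) {
    bp <- tapply(clen[binned$contig_id], binned$bin_id, sum)
    first <- tapply(binned$contig_id, binned$bin_id, min)
    ord <- order(-bp, first[names(bp)])
    old_ids <- names(bp)[ord]
    new_ids <- sprintf("bin_%03d", seq_along(old_ids) - 1L)
    names(new_ids) <- old_ids
    binned$bin_id <- unname(new_ids[binned$bin_id])
  }
  out <- assignments
  out$bin_id <- ifelse(out$bin_id == "unbinned", "unbinned",
                       unname(new_ids[out$bin_id]))

  tsv <- file.path(out_dir, "bins.tsv")
  fas <- if (length(new_ids)) file.path(out_dir, paste0(sort(unname(new_ids)), ".fa")) else character(0)
  clash <- c(tsv, fas)[file.exists(c(tsv, fas))]
  if (length(clash) && !overwrite) {
    stop("output file exists (use overwrite = TRUE): ", clash[1L])
  }
  write_assignments(out, tsv)
  seqs <- stats::setNames(contigs$sequence, contigs$contig_id)
  for (b in sort(unique(binned$bin_id))) {
    ids <- sort(binned$contig_id[binned$bin_id == b])
    x <- Biostrings::DNAStringSet(seqs[ids])
    names(x) <- ids
    Biostrings::writeXStringSet(x, file.path(out_dir, paste0(b, ".fa")))
  }
  invisible(out)
}
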