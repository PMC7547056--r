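#' Taxonomic profile container
#'
#' The central object of the pipeline: a samples x genera matrix of
#' non-negative integer counts, a lineage table mapping every genus to its
#' superkingdom and phylum, and per-sample metadata (growing location,
#' total unmapped reads).
#'
#' @param counts samples x genera integer matrix with dimnames.
#' @param lineage data.frame with columns genus, superkingdom, phylum.
#' @param metadata data.frame with columns sample, location, total_reads.
#' @return an object of class \code{taxonomic_profile}.
#' @export
taxonomic_profile <- function(counts, lineage, metadata) {
  stop_if_not(is.matrix(counts), "counts must be a matrix")
  stop_if_not(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              "counts needs sample rownames and genus colnames")
  stop_if_not(all(counts >= 0), "negative counts are not allowed")
  stop_if_not(!anyDuplicated(rownames(counts)), "sample ids must be unique")
  stop_if_not(all(colnames(counts) %in% lineage$genus),
              "every genus needs a lineage entry")
  stop_if_not(all(rownames(counts) %in% metadata$sample),
              "every sample needs a metadata entry")
  lineage <- lineage[match(colnames(counts), lineage$genus), , drop = FALSE]
  metadata <- metadata[match(rownames(counts), metadata$sample), , drop = FALSE]
  rownames(lineage) <- NULL; rownames(metadata) <- NULL
  structure(list(counts = counts, lineage = lineage, metadata = metadata),
            class = "taxonomic_profile")
}

#' @export
print.taxonomic_profile <- function(x, ...) {
  cat(sprintf("taxonomic profile: %d samples x %d genera\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  superkingdoms: %s\n",
              paste(unique(x$lineage$superkingdom), collapse = ", ")))
  cat(sprintf("  locations: %s\n",
              paste(unique(x$metadata$location), collapse = ", ")))
  invisible(x)
}

#' Assemble a profile from per-sample genus-count mappings
#'
#' Takes the per-sample named count vectors produced by
#' [read_classification_report()], fills zeros over the union of genera,
#' restricts to Bacteria and Archaea by lineage, and reports the fraction
#' of reads dropped per sample (genera with unknown lineage are dropped,
#' not guessed).
#'
#' @param sample_counts named list: sample id -> named numeric vector
#'   (genus -> count).
#' @param lineage data.frame(genus, superkingdom, phylum).
#' @param metadata data.frame(sample, location, ...).
#' @return a [taxonomic_profile()]; attribute \code{dropped_fraction} holds
#'   the per-sample fraction of counts removed by the restriction.
#' @export
build_profile <- function(sample_counts, lineage, metadata) {
  stop_if_not(length(sample_counts) > 0, "no samples supplied")
  stop_if_not(!anyDuplicated(names(sample_counts)), "sample id collision")
  genera <- sort(unique(unlist(lapply(sample_counts, names))))
  stop_if_not(length(genera) > 0, "no genus counts in any sample")

  known <- genera[genera %in% lineage$genus]
  unknown <- setdiff(genera, known)
  if (length(unknown)) {
    warning(sprintf("%d genera without lineage dropped: %s", length(unknown),
                    paste(utils::head(unknown, 5), collapse = ", ")))
  }
  keep_lin <- lineage[lineage$genus %in% known &
                        lineage$superkingdom %in% c("Bacteria", "Archaea"), ,
                      drop = FALSE]
  kept <- keep_lin$genus
  stop_if_not(length(kept) > 0, "no Bacteria/Archaea genera retained")

  counts <- matrix(0L, nrow = length(sample_counts), ncol = length(kept),
                   dimnames = list(names(sample_counts), kept))
  dropped <- numeric(length(sample_counts))
  for (i in seq_along(sample_counts)) {
    v <- sample_counts[[i]]
    tot <- sum(v)
    hit <- intersect(names(v), kept)
    counts[i, hit] <- as.integer(v[hit])
    dropped[i] <- if (tot > 0) 1 - sum(v[hit]) / tot else 0
  }
  if (!"total_reads" %in% names(metadata)) {
    metadata$total_reads <- rowSums(counts)[metadata$sample]
  }
  prof <- taxonomic_profile(counts, keep_lin, metadata)
  attr(prof, "dropped_fraction") <- stats::setNames(dropped,
                                                    names(sample_counts))
  prof
}

#' Relative abundance at a taxonomic rank
#'
#' Aggregates counts to the requested rank and row-normalizes. All-zero
#' samples yield an all-zero row with a warning rather than NaN.
#'
#' @param profile a [taxonomic_profile()].
#' @param rank "genus" or "phylum".
#' @return samples x taxa matrix of proportions (rows sum to 1 or 0).
#' @export
relative_abundance <- function(profile, rank = c("genus", "phylum")) {
  rank <- match.arg(rank)
  m <- profile$counts
  if (rank == "phylum") {
    grp <- profile$lineage$phylum[match(colnames(m), profile$lineage$genus)]
    m <- t(rowsum(t(m), group = grp))
  }
  tot <- rowSums(m)
  if (any(tot == 0)) warning("all-zero sample(s): returning all-zero rows")
  out <- m / ifelse(tot == 0, 1, tot)
  out
}

#' Keep genera present in at least a fraction of samples
#'
#' A genus survives iff it is nonzero in at least
#' \code{ceiling(min_prevalence * n_samples)} samples.
#'
#' @param profile a [taxonomic_profile()].
#' @param min_prevalence proportion in (0, 1].
#' @return the filtered [taxonomic_profile()].
#' @export
prevalence_filter <- function(profile, min_prevalence = 0.5) {
  stop_if_not(min_prevalence > 0 && min_prevalence <= 1,
              "min_prevalence must lie in (0, 1]")
  need <- ceiling(min_prevalence * nrow(profile$counts))
  keep <- colSums(profile$counts > 0) >= need
  stop_if_not(any(keep), "no genus passes the prevalence filter")
  taxonomic_profile(profile$counts[, keep, drop = FALSE],
                    profile$lineage, profile$metadata)
}

#' Taxa with mean relative abundance above a threshold
#'
#' Strictly-greater comparison, matching the ">1 percent" convention used
#' for both genera and pathways.
#'
#' @param rel samples x taxa proportion matrix.
#' @param min_mean mean-abundance threshold (default 0.01).
#' @return character vector of retained taxa names.
#' @export
abundance_filter <- function(rel, min_mean = 0.01) {
  colnames(rel)[colMeans(rel) > min_mean]
}

#' Write / read a taxonomic profile as TSV
#'
#' Three plain tab-separated files under \code{dir}: counts.tsv (samples x
#' genera), lineage.tsv and metadata.tsv. The pair of functions round-trips
#' exactly.
#'
#' @param profile a [taxonomic_profile()].
#' @param dir output directory (created if needed).
#' @return \code{write_profile}: the directory, invisibly;
#'   \code{read_profile}: the profile.
#' @export
write_profile <- function(profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- data.frame(sample = rownames(profile$counts), profile$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cm, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(profile$lineage, file.path(dir, "lineage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(profile$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_profile
#' @export
read_profile <- function(dir) {
  cm <- utils::read.delim(file.path(dir, "counts.tsv"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(cm[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- cm$sample
  lineage <- utils::read.delim(file.path(dir, "lineage.tsv"),
                               stringsAsFactors = FALSE)
  metadata <- utils::read.delim(file.path(dir, "metadata.tsv"),
                                stringsAsFactors = FALSE)
  taxonomic_profile(counts, lineage, metadata)
}
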