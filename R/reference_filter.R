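## Reference filtering: remove contigs that look like collapsed homologs /
## low-complexity assemblies (excess gDNA read depth) or duplicated genome
## regions (multimapped gDNA reads), before SNP discovery.

#' Per-contig alignment depth and multimap profiles
#'
#' Counts, for every contig of the reference, the number of primary gDNA
#' alignments (each read counted once), the mean fold-coverage from
#' reference-consuming CIGAR ops, and the number of multimap reads touching
#' the contig. A read is a multimap read if any of its alignment records is
#' secondary (FLAG 0x100); it counts towards every contig on which it has a
#' record, including the contig of its primary alignment.
#'
#' @param alignments G2T alignment table (see [read_sam()]).
#' @param contigs Named character vector of contig sequences (or named
#'   integer lengths).
#' @return A data.frame (`contig_depth_profile`) with columns `contig_id`,
#'   `length`, `aligned_read_count`, `mean_depth`, `multimap_read_count`.
#' @export
profile_contigs <- function(alignments, contigs) {
  lens <- if (is.character(contigs)) nchar(contigs) else as.integer(contigs)
  ids <- names(contigs)
  missing_ctg <- setdiff(unique(alignments$rname), ids)
  if (length(missing_ctg))
    stop("alignment references contig absent from the reference: ",
         missing_ctg[1])
  prim <- alignments[!alignments$secondary, , drop = FALSE]
  cnt <- table(factor(prim$rname, levels = ids))
  span <- if (nrow(prim))
    vapply(prim$cigar, cigar_ref_span, integer(1), USE.NAMES = FALSE) else integer(0)
  depth_bp <- tapply(span, factor(prim$rname, levels = ids), sum, default = 0L)
  multi_reads <- unique(alignments$qname[alignments$secondary])
  mm <- alignments[alignments$qname %in% multi_reads, , drop = FALSE]
  mm_cnt <- if (nrow(mm)) {
    tapply(mm$qname, factor(mm$rname, levels = ids),
           function(x) length(unique(x)), default = 0L)
  } else rep.int(0L, length(ids))
  out <- data.frame(
    contig_id = ids, length = as.integer(lens),
    aligned_read_count = as.integer(cnt),
    mean_depth = as.numeric(depth_bp) / lens,
    multimap_read_count = as.integer(mm_cnt), row.names = NULL)
  class(out) <- c("contig_depth_profile", "data.frame")
  out
}

#' Flag contigs with disproportionately many aligned reads
#'
#' Contigs whose length-normalized primary read count exceeds
#' `median + k * MAD` are flagged as excess-depth (collapsed homologous genes
#' or low-complexity assemblies). When the MAD is zero (near-constant
#' counts), a fold-over-median rule is used instead: flag contigs above
#' `fold x median`.
#'
#' @param profiles Output of [profile_contigs()].
#' @param k MAD multiplier (default 5).
#' @param fold Fallback fold-over-median threshold when MAD is 0 (default 5).
#' @return Character vector of contig ids to remove.
#' @export
excess_depth_filter <- function(profiles, k = 5, fold = 5) {
  stopifnot(nrow(profiles) >= 2)
  rate <- profiles$aligned_read_count / profiles$length
  med <- median(rate)
  dev <- mad(rate)
  if (dev > 0) {
    profiles$contig_id[rate > med + k * dev]
  } else if (med > 0) {
    profiles$contig_id[rate > fold * med]
  } else character(0)
}

#' Flag contigs containing multimap reads
#'
#' Every contig touched by at least one multimap read (a read with a
#' secondary alignment anywhere, including within the same contig) is
#' returned as a potentially duplicated genome region.
#'
#' @param profiles Output of [profile_contigs()].
#' @return Character vector of contig ids to remove.
#' @export
multimap_filter <- function(profiles) {
  profiles$contig_id[profiles$multimap_read_count >= 1L]
}

#' Filter a transcriptome reference with both devices
#'
#' Applies [excess_depth_filter()] first, then [multimap_filter()] among the
#' remaining contigs, so that the report's three sets are disjoint and
#' together cover the input.
#'
#' @param alignments G2T alignment table.
#' @param contigs Named character vector of contig sequences.
#' @param k,fold Passed to [excess_depth_filter()].
#' @param annotate_only If `TRUE`, multimap contigs are reported but kept in
#'   the retained set.
#' @return A `filter_report` list with `removed_excess_depth`,
#'   `removed_multimap`, `retained` (character vectors of contig ids) and the
#'   computed `profiles`.
#' @export
filter_reference <- function(alignments, contigs, k = 5, fold = 5,
                             annotate_only = FALSE) {
  profiles <- profile_contigs(alignments, contigs)
  excess <- if (nrow(profiles) >= 2) excess_depth_filter(profiles, k, fold)
            else character(0)
  rest <- profiles[!profiles$contig_id %in% excess, , drop = FALSE]
  multi <- multimap_filter(rest)
  retained <- setdiff(profiles$contig_id, c(excess, if (!annotate_only) multi))
  structure(list(removed_excess_depth = excess,
                 removed_multimap = multi,
                 retained = retained,
                 annotate_only = annotate_only,
                 profiles = profiles),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Reference filter report\n")
  cat("  contigs in:            ", nrow(x$profiles), "\n")
  cat("  removed excess depth:  ", length(x$removed_excess_depth), "\n")
  cat("  removed multimap:      ", length(x$removed_multimap),
      if (x$annotate_only) " (annotate-only: kept)" else "", "\n", sep = "")
  cat("  retained:              ", length(x$retained), "\n")
  invisible(x)
}

#' Write a filter report as TSV
#' @param report A `filter_report`.
#' @param path Output path.
#' @export
write_filter_report <- function(report, path) {
  status <- ifelse(report$profiles$contig_id %in% report$removed_excess_depth,
                   "excess_depth",
            ifelse(report$profiles$contig_id %in% report$removed_multimap,
                   "multimap", "retained"))
  out <- cbind(report$profiles, status = status)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
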