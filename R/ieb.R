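## Intron-exon boundary (IEB) prediction. A genome read that crosses an exon
## boundary cannot align contiguously to the spliced contig: a local aligner
## clips the intronic remainder, so its alignment starts or ends at an
## internal contig position with soft-clipped sequence left over. Positions
## where unexpectedly many reads do this are change points; significant
## change points are predicted IEBs.

#' Collect change points from local alignments on one contig
#'
#' For every internal contig position, counts the reads whose local alignment
#' terminates there with clipped sequence remaining (soft-clipped termini).
#' Natural read ends -- alignments that simply exhaust the read -- do not
#' count as support; they occur everywhere and carry no boundary signal.
#' Depth at a position counts reads whose reference footprint covers or abuts
#' it, so a clipping read always contributes to the depth of its own change
#' point.
#'
#' @param alignments Alignment table for one contig (secondary records are
#'   ignored).
#' @param contig_length Length of the contig (bp).
#' @param contig_id Contig name (for the output table).
#' @param p0 Background terminus rate used for the p-value (see
#'   [estimate_background()]).
#' @return A data.frame (`change_point`) with columns `contig_id`, `pos`,
#'   `side` ("start"/"end"), `support`, `depth`, `p_value`, one row per
#'   (position, side) with support > 0, strictly internal positions only.
#' @export
collect_change_points <- function(alignments, contig_length, contig_id = NULL,
                                  p0 = 1e-3) {
  aln <- alignments[!alignments$secondary, , drop = FALSE]
  if (is.null(contig_id))
    contig_id <- if (nrow(aln)) aln$rname[1] else NA_character_
  if (nrow(aln) == 0)
    return(data.frame(contig_id = character(), pos = integer(),
                      side = character(), support = integer(),
                      depth = integer(), p_value = numeric()))
  span <- vapply(aln$cigar, cigar_ref_span, integer(1), USE.NAMES = FALSE)
  starts <- aln$pos
  ends <- aln$pos + span
  lead_clip <- grepl("^[0-9]+S", aln$cigar)
  trail_clip <- grepl("[0-9]+S$", aln$cigar)
  # depth with inclusive ends: read covering [s, e) counts at positions s..e
  cov <- integer(contig_length + 1L)
  inc <- tabulate(starts + 1L, nbins = contig_length + 1L)
  dec <- tabulate(pmin(ends, contig_length) + 2L, nbins = contig_length + 2L)
  cov <- cumsum(inc - dec[seq_len(contig_length + 1L)])
  cps <- list()
  st <- starts[lead_clip & starts > 0L & starts < contig_length]
  if (length(st)) {
    tb <- table(st)
    cps$start <- data.frame(pos = as.integer(names(tb)), side = "start",
                            support = as.integer(tb))
  }
  en <- ends[trail_clip & ends > 0L & ends < contig_length]
  if (length(en)) {
    tb <- table(en)
    cps$end <- data.frame(pos = as.integer(names(tb)), side = "end",
                          support = as.integer(tb))
  }
  if (!length(cps))
    return(data.frame(contig_id = character(), pos = integer(),
                      side = character(), support = integer(),
                      depth = integer(), p_value = numeric()))
  out <- do.call(rbind, cps)
  out$depth <- cov[out$pos + 1L]
  out$p_value <- change_point_pvalue(out$support, out$depth, p0)
  out <- data.frame(contig_id = contig_id, out, row.names = NULL)
  out[order(out$pos, out$side), ]
}

#' Upper-tail binomial p-value for a change point
#'
#' Probability of observing at least `support` clipped termini among `depth`
#' overlapping reads if termini occurred independently at the background rate
#' `p0`: `P(X >= support)` with `X ~ Binomial(depth, p0)`. A low value marks
#' an unexpectedly large number of reads terminating their local alignment at
#' the position.
#'
#' @param support Number of clipped termini at the position (vectorized).
#' @param depth Number of reads overlapping the position.
#' @param p0 Background terminus rate, in (0, 1).
#' @return p-value(s) in `[0, 1]`; depth 0 gives 1 by convention.
#' @export
change_point_pvalue <- function(support, depth, p0) {
  stopifnot(all(support >= 0), all(support <= depth), p0 > 0, p0 < 1)
  p <- pbinom(support - 1L, depth, p0, lower.tail = FALSE)
  p[depth == 0L] <- 1
  p
}

#' Estimate the background clipped-terminus rate
#'
#' The null model for change-point testing assumes clipped alignment termini
#' appear at a constant ambient rate along the reference. That rate is
#' estimated dataset-wide as total clipped termini / total aligned bases,
#' floored at 1e-6. When contig lengths are supplied, clips touching a
#' contig bound are excluded: a local alignment truncated at the end of the
#' reference is structural, not ambient noise, and can never support an
#' (internal) change point.
#'
#' @param alignments Alignment table (all contigs; secondary records ignored).
#' @param contigs Optional named character (or integer length) vector used to
#'   drop bound-touching clips from the terminus count.
#' @return Background rate `p0`.
#' @export
estimate_background <- function(alignments, contigs = NULL) {
  aln <- alignments[!alignments$secondary, , drop = FALSE]
  if (!is.null(contigs))
    aln <- aln[aln$rname %in% names(contigs), , drop = FALSE]
  if (nrow(aln) == 0) stop("no aligned reads: cannot estimate background rate")
  ops <- cigar_op_table(aln$cigar)
  aligned <- sum(ops$len[ops$op %in% c("M", "=", "X")])
  if (aligned == 0) stop("zero aligned bases: cannot estimate background rate")
  lead <- grepl("^[0-9]+S", aln$cigar)
  trail <- grepl("[0-9]+S$", aln$cigar)
  if (!is.null(contigs)) {
    lens <- if (is.character(contigs)) nchar(contigs) else as.integer(contigs)
    clen <- setNames(lens, names(contigs))[aln$rname]
    span <- vapply(aln$cigar, cigar_ref_span, integer(1), USE.NAMES = FALSE)
    lead <- lead & aln$pos > 0L
    trail <- trail & (aln$pos + span) < clen
  }
  max((sum(lead) + sum(trail)) / aligned, 1e-6)
}

#' Predict IEB positions from change points
#'
#' Keeps change points with `p_value < alpha` and `support >= min_support`,
#' then merges start-side and end-side evidence lying within
#' `collapse_window` bases (alignment ambiguity at boundary-adjacent
#' microhomology shifts termini by a few bases) into a single breakpoint at
#' the maximum-support position.
#'
#' @param change_points Output of [collect_change_points()].
#' @param alpha Significance threshold (default 1e-4).
#' @param min_support Minimum clipped-terminus support (default 3).
#' @param collapse_window Merge window in bp (default 3).
#' @return Sorted integer vector of predicted IEB positions (0-based).
#' @export
detect_iebs <- function(change_points, alpha = 1e-4, min_support = 3L,
                        collapse_window = 3L) {
  cp <- change_points[change_points$p_value < alpha &
                        change_points$support >= min_support, , drop = FALSE]
  if (nrow(cp) == 0) return(integer(0))
  cp <- cp[order(cp$pos, -cp$support), ]
  # chain-merge: points within collapse_window of the previous point join it
  grp <- cumsum(c(1L, diff(cp$pos) > collapse_window))
  out <- vapply(split(cp, grp), function(d) {
    d$pos[which.max(d$support)]
  }, integer(1))
  sort(unname(out))
}

#' Segment a contig into putative exons
#'
#' Divides `[0, contig_length)` at each predicted IEB, producing the
#' half-open putative-exon intervals used downstream for flank truncation.
#' Duplicate breakpoints are collapsed.
#'
#' @param contig_length Contig length (bp).
#' @param iebs Integer vector of predicted IEB positions (0-based, strictly
#'   internal).
#' @param contig_id Optional contig name carried into the output.
#' @return An `exon_segmentation` list with `contig_id`, `breakpoints` and
#'   `segments` (data.frame with `start`, `end`).
#' @export
segment_exons <- function(contig_length, iebs, contig_id = NA_character_) {
  bp <- sort(unique(as.integer(iebs)))
  stopifnot(all(bp > 0), all(bp < contig_length))
  bounds <- c(0L, bp, as.integer(contig_length))
  structure(list(contig_id = contig_id, breakpoints = bp,
                 segments = data.frame(start = bounds[-length(bounds)],
                                       end = bounds[-1])),
            class = "exon_segmentation")
}

#' Predict IEBs for every contig of a dataset
#'
#' Convenience wrapper: estimates the background terminus rate once from the
#' whole alignment set, then collects change points and predicts IEBs per
#' contig.
#'
#' @param alignments G2T alignment table (all contigs).
#' @param contigs Named character (or integer length) vector; only contigs
#'   listed here are processed.
#' @param alpha,min_support,collapse_window See [detect_iebs()].
#' @return A list with `p0` and `iebs`, a data.frame of `contig_id`, `pos`.
#' @export
predict_iebs <- function(alignments, contigs, alpha = 1e-4, min_support = 3L,
                         collapse_window = 3L) {
  lens <- if (is.character(contigs)) nchar(contigs) else as.integer(contigs)
  p0 <- estimate_background(alignments, contigs)
  by_ctg <- split(seq_len(nrow(alignments)), alignments$rname)
  res <- list()
  for (cid in names(contigs)) {
    idx <- by_ctg[[cid]]
    if (is.null(idx)) next
    cp <- collect_change_points(alignments[idx, , drop = FALSE],
                                lens[[cid]], cid, p0)
    pos <- detect_iebs(cp, alpha, min_support, collapse_window)
    if (length(pos))
      res[[cid]] <- data.frame(contig_id = cid, pos = pos)
  }
  iebs <- if (length(res)) do.call(rbind, res) else
    data.frame(contig_id = character(), pos = integer())
  rownames(iebs) <- NULL
  list(p0 = p0, iebs = iebs)
}

#' Write predicted IEBs as BED
#'
#' Single-base, 0-based half-open intervals.
#' @param iebs Data.frame with `contig_id`, `pos`.
#' @param path Output path.
#' @export
write_ieb_bed <- function(iebs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(iebs))
    writeLines(paste(iebs$contig_id, iebs$pos, iebs$pos + 1L, sep = "\t"), con)
  invisible(path)
}
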