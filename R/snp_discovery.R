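## Dual-evidence SNP discovery: variants are called independently from the
## T2T (transcriptome reads) and G2T (genome reads) alignments under a
## high-quality base count/depth filter cascade, and only sites discovered by
## both approaches are kept.

BASES <- c("A", "C", "G", "T")

#' SNP filter policy
#'
#' The dual-evidence filter cascade. A site passes a side's filter iff it is
#' biallelic, its HQ depth is at most `max_depth`, and either the alternate
#' HQ count reaches the waiving count (no depth requirement) or it reaches
#' the minimum count with the side's minimum HQ depth. Defaults: T2T needs
#' alt >= 2 at depth >= 8, waived at alt >= 3; G2T needs alt >= 2 at depth
#' >= 20, waived at alt >= 3; both sides are capped at depth 200 to dodge
#' collapsed duplicated regions (PSVs/MSVs).
#'
#' @param t2t_min_count,t2t_min_depth,t2t_waive_count T2T thresholds.
#' @param g2t_min_count,g2t_min_depth,g2t_waive_count G2T thresholds.
#' @param max_depth Maximum HQ site depth, applied to both sides.
#' @param hq An [hq_policy()].
#' @return A `snp_filter_policy` list.
#' @export
snp_filter_policy <- function(t2t_min_count = 2L, t2t_min_depth = 8L,
                              t2t_waive_count = 3L,
                              g2t_min_count = 2L, g2t_min_depth = 20L,
                              g2t_waive_count = 3L,
                              max_depth = 200L, hq = hq_policy()) {
  stopifnot(t2t_waive_count > t2t_min_count, g2t_waive_count > g2t_min_count,
            max_depth > t2t_min_depth, max_depth > g2t_min_depth)
  structure(list(t2t_min_count = t2t_min_count, t2t_min_depth = t2t_min_depth,
                 t2t_waive_count = t2t_waive_count,
                 g2t_min_count = g2t_min_count, g2t_min_depth = g2t_min_depth,
                 g2t_waive_count = g2t_waive_count,
                 max_depth = max_depth, hq = hq),
            class = "snp_filter_policy")
}

#' Remove PCR-duplicate reads
#'
#' Among primary alignments sharing contig, unclipped start position and
#' orientation, only the read with the highest total base quality is kept
#' (ties broken by read name for determinism). The unclipped start -- the
#' alignment start minus any leading soft clip -- identifies the template's
#' origin, so local alignments that merely clip at the same internal
#' position (e.g. reads entering an exon from different intron offsets) are
#' not mistaken for duplicates. Secondary records of removed reads are
#' dropped too.
#'
#' @param alignments Alignment table.
#' @return Alignment table with duplicates removed.
#' @export
dedup_reads <- function(alignments) {
  if (nrow(alignments) == 0) return(alignments)
  prim <- alignments[!alignments$secondary, , drop = FALSE]
  if (nrow(prim) == 0) return(alignments)
  totq <- vapply(prim$qual, function(q) sum(utf8ToInt(q)), numeric(1),
                 USE.NAMES = FALSE)
  lead_clip <- rep.int(0L, nrow(prim))
  has_clip <- grepl("^[0-9]+S", prim$cigar)
  lead_clip[has_clip] <- as.integer(sub("S.*", "", prim$cigar[has_clip]))
  ustart <- prim$pos - lead_clip
  ord <- order(prim$rname, ustart, prim$reverse, -totq, prim$qname)
  prim <- prim[ord, , drop = FALSE]
  key <- paste(prim$rname, ustart[ord], prim$reverse)
  keep_names <- prim$qname[!duplicated(key)]
  out <- alignments[alignments$qname %in% keep_names, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tally high-quality bases per site
#'
#' Builds per-contig pileups restricted to HQ bases: at every covered
#' position, counts of A/C/G/T among bases whose Phred quality meets the
#' policy. Columns touched by an insertion or deletion in any read are
#' flagged non-biallelic (`indel = TRUE`); only primary alignments
#' contribute.
#'
#' @param alignments Alignment table.
#' @param contigs Named character vector of contig sequences.
#' @param hq An [hq_policy()].
#' @return A list, one element per contig with any coverage: a list with
#'   `counts` (4 x L integer matrix, rows A,C,G,T, HQ bases only) and
#'   `indel` (logical vector of length L).
#' @export
pileup_sites <- function(alignments, contigs, hq = hq_policy()) {
  prim <- alignments[!alignments$secondary, , drop = FALSE]
  out <- list()
  if (nrow(prim) == 0) return(out)
  missing_ctg <- setdiff(unique(prim$rname), names(contigs))
  if (length(missing_ctg))
    stop("alignment references contig absent from the reference: ",
         missing_ctg[1])
  ops <- cigar_op_table(prim$cigar)
  for (cid in intersect(names(contigs), unique(prim$rname))) {
    rows <- which(prim$rname == cid)
    L <- nchar(contigs[[cid]])
    po <- ops[ops$row %in% rows, , drop = FALSE]
    mo <- po[po$op %in% c("M", "=", "X"), , drop = FALSE]
    counts <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(BASES, NULL))
    indel <- logical(L)
    if (nrow(mo)) {
      # expand every M segment into (refpos, base, qual) triples, vectorized
      refpos <- rep.int(prim$pos[mo$row] + mo$roff, mo$len) +
        sequence(mo$len) - 1L
      frag_seq <- substring(prim$seq[mo$row], mo$qoff + 1L, mo$qoff + mo$len)
      frag_qual <- substring(prim$qual[mo$row], mo$qoff + 1L, mo$qoff + mo$len)
      base <- strsplit(paste(frag_seq, collapse = ""), "")[[1]]
      qual <- utf8ToInt(paste(frag_qual, collapse = "")) - 33L
      ok <- qual >= hq$min_phred
      bidx <- match(base, BASES)
      ok <- ok & !is.na(bidx)
      if (any(ok)) {
        idx <- (refpos[ok]) * 4L + bidx[ok]    # 1..4L encoding
        tb <- tabulate(idx, nbins = 4L * L)
        counts[] <- tb
      }
    }
    io <- po[po$op %in% c("I", "D"), , drop = FALSE]
    if (nrow(io)) {
      for (i in seq_len(nrow(io))) {
        rp <- prim$pos[io$row[i]] + io$roff[i]
        if (io$op[i] == "D") {
          span <- rp + seq_len(io$len[i]) - 1L
        } else {
          span <- c(rp - 1L, rp)  # insertion between rp-1 and rp
        }
        span <- span[span >= 0L & span < L]
        indel[span + 1L] <- TRUE
      }
    }
    out[[cid]] <- list(counts = counts, indel = indel)
  }
  out
}

#' Call putative SNPs from pileups under the filter cascade
#'
#' A site is a candidate when the observed HQ bases form exactly the
#' reference base plus one alternate (sites with three or more observed
#' alleles, an unobserved reference plus two alternates, or an indel flag are
#' dropped as non-biallelic). A candidate passes iff
#' `hq_depth <= max_depth` and (`alt_hq_count >= waive_count` or
#' (`alt_hq_count >= min_count` and `hq_depth >= min_depth`)) for the given
#' side.
#'
#' @param pileups Output of [pileup_sites()].
#' @param contigs Named character vector of contig sequences.
#' @param policy A [snp_filter_policy()].
#' @param side `"T2T"` or `"G2T"` (selects the side's thresholds).
#' @return Variant table: `contig`, `pos` (0-based), `ref`, `alt`,
#'   `hq_depth`, `alt_hq_count`, `source`.
#' @export
call_variants <- function(pileups, contigs, policy = snp_filter_policy(),
                          side = c("T2T", "G2T")) {
  side <- match.arg(side)
  min_count <- if (side == "T2T") policy$t2t_min_count else policy$g2t_min_count
  min_depth <- if (side == "T2T") policy$t2t_min_depth else policy$g2t_min_depth
  waive <- if (side == "T2T") policy$t2t_waive_count else policy$g2t_waive_count
  res <- list()
  for (cid in names(pileups)) {
    pu <- pileups[[cid]]
    counts <- pu$counts
    depth <- colSums(counts)
    n_alleles <- colSums(counts > 0L)
    refb <- strsplit(contigs[[cid]], "")[[1]]
    ref_idx <- match(refb, BASES)
    cand <- which(n_alleles == 2L & !pu$indel & !is.na(ref_idx))
    if (!length(cand)) next
    keep <- logical(length(cand)); alt_b <- character(length(cand))
    alt_n <- integer(length(cand))
    for (j in seq_along(cand)) {
      p <- cand[j]
      present <- which(counts[, p] > 0L)
      if (!(ref_idx[p] %in% present)) next   # reference allele unobserved
      altp <- setdiff(present, ref_idx[p])
      keep[j] <- TRUE
      alt_b[j] <- BASES[altp]
      alt_n[j] <- counts[altp, p]
    }
    cand <- cand[keep]; alt_b <- alt_b[keep]; alt_n <- alt_n[keep]
    if (!length(cand)) next
    dp <- depth[cand]
    pass <- dp <= policy$max_depth &
      (alt_n >= waive | (alt_n >= min_count & dp >= min_depth))
    if (!any(pass)) next
    res[[cid]] <- data.frame(
      contig = cid, pos = cand[pass] - 1L, ref = refb[cand[pass]],
      alt = alt_b[pass], hq_depth = as.integer(dp[pass]),
      alt_hq_count = alt_n[pass], source = side, stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(contig = character(), pos = integer(), ref = character(),
               alt = character(), hq_depth = integer(),
               alt_hq_count = integer(), source = character())
  rownames(out) <- NULL
  out[order(out$contig, out$pos), , drop = FALSE]
}

#' Intersect T2T and G2T variant sets
#'
#' A common SNP requires identical contig, position, and unordered allele
#' pair in both sets. Same-position sites with mismatching allele pairs are
#' excluded and returned in the `"mismatch"` attribute.
#'
#' @param t2t,g2t Variant tables from [call_variants()].
#' @return Variant table with `source = "both"`, carrying both sides' depths
#'   (`hq_depth`/`alt_hq_count` from T2T, `g2t_hq_depth`/`g2t_alt_hq_count`).
#' @export
intersect_variant_sets <- function(t2t, g2t) {
  pair <- function(v) {
    a <- pmin(v$ref, v$alt); b <- pmax(v$ref, v$alt)
    paste(v$contig, v$pos, a, b)
  }
  key_t <- paste(t2t$contig, t2t$pos)
  key_g <- paste(g2t$contig, g2t$pos)
  common_pos <- intersect(key_t, key_g)
  ti <- match(common_pos, key_t)
  gi <- match(common_pos, key_g)
  same <- pair(t2t[ti, , drop = FALSE]) == pair(g2t[gi, , drop = FALSE])
  out <- t2t[ti[same], , drop = FALSE]
  if (nrow(out)) {
    out$source <- "both"
    out$g2t_hq_depth <- g2t$hq_depth[gi[same]]
    out$g2t_alt_hq_count <- g2t$alt_hq_count[gi[same]]
  } else {
    out$g2t_hq_depth <- integer(0)
    out$g2t_alt_hq_count <- integer(0)
    out$source <- character(0)
  }
  rownames(out) <- NULL
  mism <- data.frame(contig = t2t$contig[ti[!same]], pos = t2t$pos[ti[!same]])
  attr(out, "mismatch") <- mism
  if (nrow(mism))
    message(nrow(mism), " same-position site(s) excluded for allele mismatch")
  out
}

#' Classify substitutions as transitions or transversions
#' @param ref,alt Single-base allele vectors.
#' @return Character vector `"transition"`/`"transversion"`.
#' @export
classify_tstv <- function(ref, alt) {
  stopifnot(length(ref) == length(alt), all(ref != alt))
  purine <- c("A", "G")
  ts <- (ref %in% purine) == (alt %in% purine)
  ifelse(ts, "transition", "transversion")
}

#' Transition/transversion ratio
#' @param n_ts,n_tv Transition and transversion counts.
#' @param digits Rounding for the reported ratio.
#' @return ts/tv ratio.
#' @export
tstv_ratio <- function(n_ts, n_tv, digits = 2L) {
  round(n_ts / n_tv, digits)
}

#' Call common SNPs from both alignment sets
#'
#' Full discovery wrapper: de-duplicates reads, builds HQ pileups, calls
#' variants on each side, restricts to retained contigs and intersects.
#'
#' @param t2t_alignments,g2t_alignments Alignment tables.
#' @param contigs Named character vector of contig sequences.
#' @param policy A [snp_filter_policy()].
#' @param retained Character vector of contig ids kept by
#'   [filter_reference()]; defaults to all contigs.
#' @return A list with `t2t`, `g2t` (per-side variant tables) and `common`.
#' @export
call_common_snps <- function(t2t_alignments, g2t_alignments, contigs,
                             policy = snp_filter_policy(),
                             retained = names(contigs)) {
  keep <- contigs[names(contigs) %in% retained]
  sel_t <- t2t_alignments[t2t_alignments$rname %in% retained, , drop = FALSE]
  sel_g <- g2t_alignments[g2t_alignments$rname %in% retained, , drop = FALSE]
  pu_t <- pileup_sites(dedup_reads(sel_t), keep, policy$hq)
  pu_g <- pileup_sites(dedup_reads(sel_g), keep, policy$hq)
  t2t <- call_variants(pu_t, keep, policy, "T2T")
  g2t <- call_variants(pu_g, keep, policy, "G2T")
  list(t2t = t2t, g2t = g2t, common = intersect_variant_sets(t2t, g2t))
}
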