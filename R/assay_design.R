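## Genotyping-assay design: build flanking sequences around candidate SNPs
## (masking every other variant as N, truncating at contig ends and predicted
## IEBs), screen them for similarity to other contigs, categorize SNPs by
## coding-region homology, compute preliminary per-marker Fst, and assemble
## the selection panel.

#' Build a genotyping flank for one target SNP
#'
#' The flank is the putative-exon segment containing the target (truncation
#' at contig ends and predicted IEB breakpoints), with every non-target
#' variant position -- from either evidence source -- masked as `N` and the
#' target written as `[ref/alt]`. A candidate is rejected when fewer than
#' `min_flank` bases remain on either side (`short_flank`) or when any
#' variant or `N` falls within `core_halfwidth` bases of the target
#' (`nonconserved_core`).
#'
#' @param contig_seq Contig sequence (single string).
#' @param target_pos 0-based target position.
#' @param target_ref,target_alt Target alleles.
#' @param mask_pos Integer vector of 0-based positions of all other variants
#'   on the contig (any source; the target itself is ignored if present).
#' @param iebs Integer vector of predicted IEB positions on the contig.
#' @param contig_id Contig name.
#' @param min_flank Minimum available bases on each side (default 30).
#' @param core_halfwidth Conservation window half-width (default 5).
#' @return A one-row data.frame (`assay_candidate`): `contig`, `pos`, `ref`,
#'   `alt`, `flank_seq`, `upstream_len`, `downstream_len`, `accepted`,
#'   `rejection_reason` (`"none"`, `"short_flank"`, `"nonconserved_core"`).
#' @export
build_flank <- function(contig_seq, target_pos, target_ref, target_alt,
                        mask_pos = integer(0), iebs = integer(0),
                        contig_id = NA_character_, min_flank = 30L,
                        core_halfwidth = 5L) {
  L <- nchar(contig_seq)
  stopifnot(target_pos >= 0, target_pos < L)
  seg <- segment_exons(L, iebs)$segments
  si <- which(seg$start <= target_pos & target_pos < seg$end)
  s <- seg$start[si]; e <- seg$end[si]
  upstream <- target_pos - s
  downstream <- e - target_pos - 1L
  ch <- strsplit(substr(contig_seq, s + 1L, e), "")[[1]]
  rel_mask <- setdiff(mask_pos[mask_pos >= s & mask_pos < e], target_pos) - s
  if (length(rel_mask)) ch[rel_mask + 1L] <- "N"
  rel_t <- target_pos - s
  core <- setdiff(seq.int(max(0L, rel_t - core_halfwidth),
                          min(length(ch) - 1L, rel_t + core_halfwidth)), rel_t)
  core_dirty <- any(ch[core + 1L] != "A" & ch[core + 1L] != "C" &
                      ch[core + 1L] != "G" & ch[core + 1L] != "T")
  ch[rel_t + 1L] <- sprintf("[%s/%s]", target_ref, target_alt)
  reason <- if (upstream < min_flank || downstream < min_flank) "short_flank"
            else if (core_dirty) "nonconserved_core"
            else "none"
  out <- data.frame(
    contig = contig_id, pos = target_pos, ref = target_ref, alt = target_alt,
    flank_seq = paste(ch, collapse = ""), upstream_len = upstream,
    downstream_len = downstream, accepted = reason == "none",
    rejection_reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("assay_candidate", "data.frame")
  out
}

#' Build flanks for every common SNP
#'
#' @param variants Common-SNP table (from [intersect_variant_sets()]).
#' @param contigs Named character vector of contig sequences (retained set).
#' @param all_variants Variant table pooling T2T-only, G2T-only and common
#'   sites; every position is masked in flanks (the target excepted).
#' @param iebs Data.frame `contig_id`, `pos` of predicted IEBs.
#' @param min_flank,core_halfwidth See [build_flank()].
#' @return `assay_candidate` data.frame, one row per input variant.
#' @export
build_flanks <- function(variants, contigs, all_variants, iebs,
                         min_flank = 30L, core_halfwidth = 5L) {
  mask_by_ctg <- split(all_variants$pos, all_variants$contig)
  ieb_by_ctg <- split(iebs$pos, iebs$contig_id)
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    cid <- variants$contig[i]
    if (!cid %in% names(contigs))
      stop("target SNP on a contig absent from the retained reference: ", cid)
    build_flank(contigs[[cid]], variants$pos[i], variants$ref[i],
                variants$alt[i],
                mask_pos = mask_by_ctg[[cid]] %||% integer(0),
                iebs = ieb_by_ctg[[cid]] %||% integer(0),
                contig_id = cid, min_flank = min_flank,
                core_halfwidth = core_halfwidth)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(contig = character(), pos = integer(), ref = character(),
                      alt = character(), flank_seq = character(),
                      upstream_len = integer(), downstream_len = integer(),
                      accepted = logical(), rejection_reason = character())
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- similarity screen ------------------------------------------------------

# Ungapped Karlin-Altschul lambda for match score `ma`, mismatch `mi` under
# uniform base composition: the unique positive root of
# (1/4) e^{lambda*ma} + (3/4) e^{lambda*mi} = 1.
ka_lambda <- function(ma = 1, mi = -2) {
  f <- function(l) 0.25 * exp(l * ma) + 0.75 * exp(l * mi) - 1
  uniroot(f, c(1e-6, 10), tol = 1e-12)$root
}

#' Screen a flank for similarity to other contigs
#'
#' A built-in seeded local-similarity search: exact `word`-length seed
#' matches between the flank and every other contig are extended without
#' gaps (match +1, mismatch -2) under an X-drop rule, and the best local
#' score is converted to an E-value with the ungapped Karlin-Altschul
#' approximation. The candidate fails if any other contig reaches an E-value
#' below `evalue_threshold`. An external search's tabular hits can be
#' supplied instead via `external_hits`.
#'
#' @param flank_seq Flank sequence; the `[ref/alt]` target is evaluated as
#'   the reference allele, masked `N`s never match.
#' @param contig_id The candidate's own contig (self-hits are ignored).
#' @param contig_db Named character vector of contigs to screen against,
#'   including contigs removed from SNP calling.
#' @param evalue_threshold Failing E-value (default 1e-25).
#' @param word Seed length (default 11).
#' @param xdrop Score drop-off terminating extension (default 20).
#' @param external_hits Optional data.frame `query`, `subject`, `evalue`; if
#'   given, the built-in search is skipped and the candidate fails iff a
#'   non-self hit is below threshold.
#' @param query_id Query name used to match `external_hits$query` (defaults
#'   to `contig_id:pos` not being available here, use `contig_id`).
#' @return `TRUE` (pass) or `FALSE` (similarity hit).
#' @export
similarity_screen <- function(flank_seq, contig_id, contig_db,
                              evalue_threshold = 1e-25, word = 11L,
                              xdrop = 20, external_hits = NULL,
                              query_id = contig_id) {
  if (!is.null(external_hits)) {
    hit <- external_hits$query == query_id &
      external_hits$subject != contig_id &
      external_hits$evalue < evalue_threshold
    return(!any(hit))
  }
  q <- toupper(gsub("\\[([ACGT])/[ACGT]\\]", "\\1", flank_seq))
  subjects <- contig_db[setdiff(names(contig_db), contig_id)]
  if (!length(subjects) || nchar(q) < word) return(TRUE)
  lam <- ka_lambda()
  K <- 0.35
  n_db <- sum(nchar(subjects))
  qv <- strsplit(q, "")[[1]]
  nq <- length(qv)
  # query seed index: word -> start positions (words containing N skipped)
  q_words <- substring(q, seq_len(nq - word + 1L), seq.int(word, nq))
  q_words_ok <- !grepl("N", q_words, fixed = TRUE)
  for (sid in names(subjects)) {
    sseq <- subjects[[sid]]
    ns <- nchar(sseq)
    if (ns < word) next
    sv <- strsplit(sseq, "")[[1]]
    s_words <- substring(sseq, seq_len(ns - word + 1L), seq.int(word, ns))
    hits <- which(q_words_ok & q_words %in% s_words)
    if (!length(hits)) next
    best <- 0
    s_index <- split(seq_along(s_words), s_words)
    for (qi in hits) {
      for (si in s_index[[q_words[qi]]]) {
        sc <- extend_ungapped(qv, sv, qi, si, word, xdrop)
        if (sc > best) best <- sc
      }
      if (best >= nq) break   # cannot improve on a full-length match
    }
    if (best > 0) {
      evalue <- K * nq * n_db * exp(-lam * best)
      if (evalue < evalue_threshold) return(FALSE)
    }
  }
  TRUE
}

# Ungapped X-drop extension of a word hit at query pos qi / subject pos si
# (1-based starts). Match +1, mismatch -2, N never matches.
extend_ungapped <- function(qv, sv, qi, si, word, xdrop,
                            match = 1, mismatch = -2) {
  score <- word * match
  best <- score
  i <- qi + word; j <- si + word
  while (i <= length(qv) && j <= length(sv)) {
    score <- score + if (qv[i] == sv[j] && qv[i] != "N") match else mismatch
    if (score > best) best <- score
    if (best - score > xdrop) break
    i <- i + 1L; j <- j + 1L
  }
  score <- best
  i <- qi - 1L; j <- si - 1L
  cur <- best
  while (i >= 1L && j >= 1L) {
    cur <- cur + if (qv[i] == sv[j] && qv[i] != "N") match else mismatch
    if (cur > best) best <- cur
    if (best - cur > xdrop) break
    i <- i - 1L; j <- j - 1L
  }
  best
}

## ---- homology categories ----------------------------------------------------

#' Categorize a SNP by coding-region homology
#'
#' Uses protein-level hit intervals supplied per contig (a pluggable input;
#' any external search's intervals can be fed in). Categories: no intervals
#' on the contig gives `no_homology`; a contig carrying both coding and
#' non-coding assignments gives the ambiguous `tSNP`; otherwise `cSNP` if
#' the SNP lies inside a coding interval and `ncSNP` if outside all of them.
#'
#' @param contig_id,pos The SNP (0-based position).
#' @param hits Data.frame with columns `contig`, `start`, `end` (half-open,
#'   0-based) and `coding` (logical).
#' @return One of `"cSNP"`, `"ncSNP"`, `"tSNP"`, `"no_homology"`.
#' @export
categorize_homology <- function(contig_id, pos, hits) {
  stopifnot(all(c("contig", "start", "end", "coding") %in% names(hits)))
  if (nrow(hits) && any(hits$end < hits$start)) stop("malformed interval: end < start")
  h <- hits[hits$contig == contig_id, , drop = FALSE]
  if (nrow(h) == 0) return("no_homology")
  if (any(h$coding) && any(!h$coding)) return("tSNP")
  inside_cds <- any(h$coding & h$start <= pos & pos < h$end)
  if (inside_cds) "cSNP" else "ncSNP"
}

## ---- Weir-Cockerham Fst -----------------------------------------------------

#' Weir-Cockerham Fst (theta) for one biallelic marker
#'
#' Variance-components estimator for diploid genotype calls grouped into
#' populations: theta = a / (a + b + c), where a, b, c are the
#' among-population, between-individual-within-population and
#' within-individual components. Returns `NA` when the denominator is zero
#' (no variation) or fewer than two populations have genotyped individuals.
#'
#' @param calls Character vector of genotype calls (`AA`/`AB`/`BB`, `NA`
#'   missing), one per individual.
#' @param pops Population label per individual.
#' @return Estimated theta (can be slightly negative at low differentiation).
#' @export
wc_fst <- function(calls, pops) {
  stopifnot(length(calls) == length(pops))
  if (length(unique(pops)) < 2) stop("Fst requires at least two populations")
  ok <- !is.na(calls)
  calls <- calls[ok]; pops <- factor(pops[ok])
  pops <- droplevels(pops)
  n_i <- as.numeric(table(pops))
  if (sum(n_i > 0) < 2) return(NA_real_)
  alt_count <- c(AA = 0, AB = 1, BB = 2)[calls]
  p_i <- tapply(alt_count, pops, mean) / 2
  h_i <- tapply(calls == "AB", pops, mean)
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  if (nbar <= 1 || nc == 0) return(NA_real_)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  if (denom == 0) return(NA_real_)
  a / denom
}

#' Per-individual genotypes from G2T allele depths
#'
#' Determines individual genotypes at called SNP sites from each
#' individual's HQ allele depths in the G2T alignment: homozygous when at
#' least 90 percent of HQ bases show one allele at depth >= `min_depth`,
#' heterozygous otherwise at depth >= `min_depth`, missing below it.
#'
#' @param g2t_alignments G2T alignment table.
#' @param read_individuals Named integer vector mapping read name (`qname`)
#'   to individual index.
#' @param variants Common-SNP table.
#' @param contigs Named character vector of contig sequences.
#' @param hq An [hq_policy()].
#' @param min_depth Minimum per-individual HQ depth for a call (default 4).
#' @param hom_frac Allele fraction at or above which a site is called
#'   homozygous (default 0.9).
#' @return Character matrix (markers x individuals) of `AA`/`AB`/`BB`/`NA`
#'   with rownames `contig:pos`.
#' @export
genotypes_from_g2t <- function(g2t_alignments, read_individuals, variants,
                               contigs, hq = hq_policy(), min_depth = 4L,
                               hom_frac = 0.9) {
  inds <- sort(unique(read_individuals))
  gm <- matrix(NA_character_, nrow = nrow(variants), ncol = length(inds),
               dimnames = list(paste0(variants$contig, ":", variants$pos),
                               paste0("ind", inds)))
  aln_ind <- read_individuals[g2t_alignments$qname]
  for (k in seq_along(inds)) {
    sel <- g2t_alignments[!is.na(aln_ind) & aln_ind == inds[k], , drop = FALSE]
    if (nrow(sel) == 0) next
    pu <- pileup_sites(sel, contigs, hq)
    for (i in seq_len(nrow(variants))) {
      cid <- variants$contig[i]
      if (is.null(pu[[cid]])) next
      cnt <- pu[[cid]]$counts[, variants$pos[i] + 1L]
      nr <- cnt[[variants$ref[i]]]; na <- cnt[[variants$alt[i]]]
      dp <- nr + na
      if (dp < min_depth) next
      gm[i, k] <- if (nr / dp >= hom_frac) "AA"
                  else if (na / dp >= hom_frac) "BB" else "AB"
    }
  }
  gm
}

## ---- panel selection --------------------------------------------------------

#' Assemble the genotyping panel
#'
#' Two subsets: (1) the homology subset -- every accepted `cSNP`, completed
#' with randomly drawn accepted `tSNP`s up to `homology_target`; (2) the
#' differentiation subset -- the highest-Fst accepted candidates not already
#' chosen, filling the panel to `panel_size`. Deterministic for a fixed
#' `seed`.
#'
#' @param candidates `assay_candidate` table with an added `marker_id`
#'   column; only rows with `accepted == TRUE` are eligible.
#' @param categories Character vector (parallel to `candidates`) of homology
#'   categories from [categorize_homology()].
#' @param fst_values Numeric vector (parallel) of preliminary Fst values
#'   (`NA` allowed; sorted last).
#' @param panel_size Total markers wanted.
#' @param homology_target Size cap for subset 1 (default `ceiling(panel_size
#'   / 2)`); all cSNPs are always kept even beyond the cap.
#' @param seed Seed for the random tSNP draw.
#' @return The selected subset of `candidates`, with columns `subset`
#'   (`"homology"`/`"fst"`) and `category` added.
#' @export
select_panel <- function(candidates, categories, fst_values, panel_size,
                         homology_target = NULL, seed = 1L) {
  stopifnot(nrow(candidates) == length(categories),
            nrow(candidates) == length(fst_values))
  if (is.null(homology_target)) homology_target <- ceiling(panel_size / 2)
  elig <- which(candidates$accepted)
  if (length(elig) <= panel_size) {
    if (length(elig) < panel_size)
      warning("panel_size exceeds available candidates: returning all ",
              length(elig))
    out <- candidates[elig, , drop = FALSE]
    out$category <- categories[elig]
    out$subset <- ifelse(out$category == "cSNP", "homology", "fst")
    rownames(out) <- NULL
    return(out)
  }
  csnp <- elig[categories[elig] == "cSNP"]
  tsnp <- elig[categories[elig] == "tSNP"]
  n_t <- max(0L, min(length(tsnp), homology_target - length(csnp),
                     panel_size - length(csnp)))
  t_pick <- with_seed(seed, if (n_t > 0) sort(sample(tsnp, n_t)) else integer(0))
  subset1 <- c(csnp, t_pick)
  subset1 <- subset1[seq_len(min(length(subset1), panel_size))]
  rest <- setdiff(elig, subset1)
  n_fst <- panel_size - length(subset1)
  fst_rest <- fst_values[rest]
  ord <- rest[order(-ifelse(is.na(fst_rest), -Inf, fst_rest), rest)]
  subset2 <- head(ord, n_fst)
  sel <- c(subset1, subset2)
  out <- candidates[sel, , drop = FALSE]
  out$category <- categories[sel]
  out$subset <- rep(c("homology", "fst"),
                    c(length(subset1), length(subset2)))
  rownames(out) <- NULL
  out
}
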