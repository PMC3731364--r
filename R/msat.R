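## Perfect microsatellite (SSR) discovery: maximal uninterrupted runs of a
## primitive 2-6 bp motif with at least five repetitions, with a flank-purity
## filter standing in for primer-design compatibility.

#' Canonical form of a repeat motif
#'
#' Lexicographic minimum over all rotations of the motif and of its reverse
#' complement, so that strand and phase variants (AC, CA, GT, TG) collapse
#' to one class.
#'
#' @param motif Motif string (A/C/G/T).
#' @return Canonical motif string.
#' @export
canonical_motif <- function(motif) {
  rots <- function(x) {
    n <- nchar(x)
    vapply(seq_len(n), function(i)
      paste0(substr(x, i, n), substr(x, 1, i - 1)), character(1))
  }
  rc <- revcomp(motif)
  min(c(rots(motif), rots(rc)))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

is_primitive_motif <- function(motif) {
  n <- nchar(motif)
  for (d in seq_len(n - 1)) {
    if (n %% d == 0 &&
        motif == strrep(substr(motif, 1, d), n / d)) return(FALSE)
  }
  TRUE
}

#' Find perfect microsatellite repeats in a contig
#'
#' Reports maximal uninterrupted runs of a primitive motif of length 2-6
#' with at least `min_units` repetitions, each motif in canonical form.
#' Runs reported by a non-primitive motif (e.g. ACAC as a 4-mer) are
#' suppressed, and when runs of different motif lengths overlap on the same
#' stretch, the longest span (ties: most units) wins, so reported hits never
#' overlap.
#'
#' @param seq Contig sequence (uppercase).
#' @param min_units Minimum repetitions (default 5).
#' @param motif_lens Motif lengths to scan (default 2:6).
#' @param contig_id Contig name for the output.
#' @return Data.frame (`repeat_hit`): `contig_id`, `start`, `end` (0-based
#'   half-open), `motif` (canonical), `motif_len`, `unit_count`.
#' @export
find_repeats <- function(seq, min_units = 5L, motif_lens = 2:6,
                         contig_id = NA_character_) {
  L <- nchar(seq)
  hits <- list(); k <- 0L
  x <- utf8ToInt(seq)
  acgt <- utf8ToInt("ACGT")
  for (m in motif_lens) {
    if (L < m * min_units) next
    eq <- x[seq_len(L - m)] == x[(m + 1L):L]
    r <- rle(eq)
    ends_at <- cumsum(r$lengths)
    starts_at <- ends_at - r$lengths + 1L
    runs <- which(r$values & r$lengths >= m * (min_units - 1L))
    for (ri in runs) {
      i <- starts_at[ri]                  # 1-based position in eq
      q <- r$lengths[ri]
      units <- (q + m) %/% m
      span <- units * m
      start0 <- i - 1L                    # 0-based start in seq
      motif <- substr(seq, i, i + m - 1L)
      if (!all(utf8ToInt(motif) %in% acgt)) next
      if (!is_primitive_motif(motif)) next
      k <- k + 1L
      hits[[k]] <- data.frame(
        contig_id = contig_id, start = start0, end = start0 + span,
        motif = canonical_motif(motif), motif_len = m,
        unit_count = units, stringsAsFactors = FALSE)
    }
  }
  if (!k)
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      motif_len = integer(), unit_count = integer()))
  out <- do.call(rbind, hits)
  # resolve overlaps: longest span first, then most units
  out <- out[order(-(out$end - out$start), -out$unit_count, out$start), ]
  keep <- logical(nrow(out))
  taken_s <- integer(0); taken_e <- integer(0)
  for (i in seq_len(nrow(out))) {
    if (!any(out$start[i] < taken_e & out$end[i] > taken_s)) {
      keep[i] <- TRUE
      taken_s <- c(taken_s, out$start[i]); taken_e <- c(taken_e, out$end[i])
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Check repeat flanks for homopolymers and nanosatellites
#'
#' A flank is dirty when, within `flank_len` bases on either side of the
#' repeat, there is a homopolymer run of at least `max_homopolymer` bases or
#' a secondary repeat (2-6 bp motif) of at least `nanosat_units` units.
#' Flanks truncated by the contig end are evaluated on the available bases
#' and flagged short.
#'
#' @param hit One row of [find_repeats()] output.
#' @param seq The contig sequence.
#' @param flank_len Flank window (default 50 bp).
#' @param max_homopolymer Homopolymer run length considered dirty (default 5).
#' @param nanosat_units Secondary-repeat unit count considered dirty
#'   (default 3).
#' @return List with `flank_clean` (logical) and `short_flank` (logical).
#' @export
flank_purity_filter <- function(hit, seq, flank_len = 50L,
                                max_homopolymer = 5L, nanosat_units = 3L) {
  L <- nchar(seq)
  up_s <- max(0L, hit$start - flank_len); up_e <- hit$start
  dn_s <- hit$end; dn_e <- min(L, hit$end + flank_len)
  short <- (hit$start - up_s) < flank_len || (dn_e - dn_s) < flank_len
  dirty <- FALSE
  for (w in list(c(up_s, up_e), c(dn_s, dn_e))) {
    if (w[2] - w[1] <= 0) next
    win <- substr(seq, w[1] + 1L, w[2])
    r <- rle(strsplit(win, "")[[1]])
    if (any(r$lengths >= max_homopolymer)) { dirty <- TRUE; break }
    nano <- find_repeats(win, min_units = nanosat_units)
    if (nrow(nano) > 0) { dirty <- TRUE; break }
  }
  list(flank_clean = !dirty, short_flank = short)
}

#' Scan contigs for acceptable microsatellites
#'
#' Runs [find_repeats()] on every contig and applies
#' [flank_purity_filter()].
#'
#' @param contigs Named character vector of sequences.
#' @param min_units,motif_lens See [find_repeats()].
#' @param flank_len,max_homopolymer,nanosat_units See
#'   [flank_purity_filter()].
#' @return Data.frame of hits with `flank_clean` and `short_flank` columns.
#' @export
scan_microsatellites <- function(contigs, min_units = 5L, motif_lens = 2:6,
                                 flank_len = 50L, max_homopolymer = 5L,
                                 nanosat_units = 3L) {
  res <- list()
  for (cid in names(contigs)) {
    h <- find_repeats(contigs[[cid]], min_units, motif_lens, cid)
    if (nrow(h) == 0) next
    fl <- lapply(seq_len(nrow(h)), function(i)
      flank_purity_filter(h[i, ], contigs[[cid]], flank_len,
                          max_homopolymer, nanosat_units))
    h$flank_clean <- vapply(fl, `[[`, logical(1), "flank_clean")
    h$short_flank <- vapply(fl, `[[`, logical(1), "short_flank")
    res[[cid]] <- h
  }
  out <- if (length(res)) do.call(rbind, res) else
    cbind(find_repeats(""), flank_clean = logical(0), short_flank = logical(0))
  rownames(out) <- NULL
  out
}

#' Motif-size by unit-count summary of repeat hits
#'
#' The classic repeat-survey table: rows are motif lengths (di- to
#' hexanucleotide), columns unit counts (capped at `max_units`, larger runs
#' pooled into the last column), plus a row/column total.
#'
#' @param hits Output of [find_repeats()]/[scan_microsatellites()].
#' @param max_units Largest unit-count column (default 10).
#' @return Integer matrix with dimnames.
#' @export
summarize_repeats <- function(hits, max_units = 10L) {
  lens <- 2:6
  units <- 5:max_units
  mat <- matrix(0L, nrow = length(lens), ncol = length(units) + 1L,
                dimnames = list(paste0(lens, "-mer"),
                                c(units, "total")))
  for (i in seq_along(lens)) {
    sel <- hits$motif_len == lens[i]
    u <- pmin(hits$unit_count[sel], max_units)
    tb <- table(factor(u, levels = units))
    mat[i, seq_along(units)] <- as.integer(tb)
    mat[i, length(units) + 1L] <- sum(sel)
  }
  mat
}
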