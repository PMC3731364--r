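# Shared fixtures: hand-built alignment rows and tiny simulated studies.

aln_row <- function(qname, rname, pos, cigar, seq = NULL, qual = NULL,
                    flag = 0L, mapq = 60L) {
  if (is.null(seq)) {
    n <- dualsnp::cigar_query_length(cigar)
    seq <- strrep("A", n)
  }
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  data.frame(qname = qname, flag = flag, rname = rname, pos = as.integer(pos),
             mapq = mapq, cigar = cigar, seq = seq, qual = qual,
             secondary = bitwAnd(flag, 256L) > 0L,
             reverse = bitwAnd(flag, 16L) > 0L,
             stringsAsFactors = FALSE)
}

aln_table <- function(...) {
  do.call(rbind, list(...))
}

empty_aln <- function() {
  aln_row("x", "c1", 0L, "10M")[0, ]
}

# A small standard simulation reused by several suites (computed once).
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42, n_genes = 6, n_duplicated_genes = 1,
                        snps_per_contig = c(2L, 3L))
      ref <- simulate_reference(cfg)
      reads <- simulate_reads(cfg, ref)
      sams <- emit_truth_sam(reads, ref)
      cache <<- list(cfg = cfg, ref = ref, reads = reads, sams = sams)
    }
    cache
  }
})

# Independent brute-force binomial upper tail: direct pmf summation with
# choose(), no pbinom.
brute_binom_tail <- function(support, depth, p0) {
  if (depth == 0) return(1)
  k <- support:depth
  sum(choose(depth, k) * p0^k * (1 - p0)^(depth - k))
}

# Independent HWE enumeration oracle: direct log-factorial probability for
# every admissible heterozygote count (no recurrence).
brute_hwe_exact <- function(nAA, nAB, nBB) {
  nA <- 2 * nAA + nAB; nB <- 2 * nBB + nAB; n <- nAA + nAB + nBB
  if (nA == 0 || nB == 0) return(1)
  hets <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (nA - h) / 2; nbb <- (nB - h) / 2
    lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
      h * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp)
  obs <- p[match(nAB, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# Independent Weir-Cockerham theta via the general multiallelic per-allele
# variance-component sums (summing a, b, c over both alleles), rather than
# the biallelic closed form used by the implementation.
brute_wc_theta <- function(calls, pops) {
  ok <- !is.na(calls)
  calls <- calls[ok]; pops <- factor(pops[ok]); pops <- droplevels(pops)
  n_i <- as.numeric(table(pops))
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  if (nbar <= 1 || nc == 0) return(NA_real_)
  num <- 0; den <- 0
  for (allele in c("A", "B")) {
    dose <- switch(allele,
                   A = c(AA = 2, AB = 1, BB = 0)[calls],
                   B = c(AA = 0, AB = 1, BB = 2)[calls])
    p_i <- tapply(dose, pops, mean) / 2
    h_i <- tapply(calls == "AB", pops, mean)   # heterozygous for this allele
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Independent validator for accepted assay candidates (fresh logic, not the
# builder's): >= 30 clean-length flanks, spotless +/-5 core, no IEB inside
# the reported flank span.
validate_candidate <- function(cand, contig_seq, mask_pos, iebs,
                               min_flank = 30L, core_halfwidth = 5L) {
  if (!cand$accepted) return(TRUE)
  if (cand$upstream_len < min_flank || cand$downstream_len < min_flank)
    return(FALSE)
  p <- cand$pos
  core <- setdiff(seq(p - core_halfwidth, p + core_halfwidth), p)
  core <- core[core >= 0 & core < nchar(contig_seq)]
  if (any(core %in% setdiff(mask_pos, p))) return(FALSE)
  ch <- strsplit(contig_seq, "")[[1]][core + 1]
  if (any(!ch %in% c("A", "C", "G", "T"))) return(FALSE)
  span <- c(p - cand$upstream_len, p + cand$downstream_len)
  if (any(iebs > span[1] & iebs <= span[2])) return(FALSE)
  TRUE
}
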