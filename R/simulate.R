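## Synthetic study generator: toy genomes with gene models, planted SNPs,
## duplicated contigs, and reads with truth-placement alignments. Everything
## downstream of assembly can be exercised hermetically, with known truth.

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic-data generator. Defaults
#' emulate the sampling and sequencing design the pipeline targets: ten
#' diploid individuals split across three populations, pooled cDNA reads at
#' roughly 15-fold coverage of each contig (long-read transcriptome
#' sequencing), and per-individual 100 bp gDNA reads summing to roughly
#' 78-fold coverage of the exome (short-read genome sequencing).
#'
#' @param seed Integer seed; identical configs (same seed) give byte-identical
#'   outputs.
#' @param n_genes Number of genes (one transcriptome contig each).
#' @param exons_per_gene Integer range `c(min, max)` of exons per gene.
#' @param exon_len,intron_len Length ranges (bp).
#' @param n_individuals Total diploid individuals, split as evenly as possible
#'   across `n_populations`.
#' @param n_populations Number of populations.
#' @param snps_per_contig Range of planted biallelic SNPs per contig.
#' @param maf_range Range from which each planted SNP's population alternate
#'   allele frequency is drawn (uniform).
#' @param pop_freq_sd Standard deviation of per-population perturbation around
#'   the drawn frequency (0 = identical frequencies in all populations).
#' @param gdna_depth Total gDNA fold-coverage of the exome summed over
#'   individuals.
#' @param cdna_depth cDNA fold-coverage per contig (pooled over individuals).
#' @param read_len_gdna gDNA read length (bp).
#' @param read_len_cdna Range of cDNA read lengths (bp).
#' @param error_rate Per-base sequencing error probability.
#' @param n_duplicated_genes Number of genes given a near-identical paralog
#'   (extra contig + intron-less genomic copy).
#' @param duplicate_divergence Per-base substitution probability between
#'   paralog copies.
#' @param min_anchor Minimum exon overlap (bp) for a gDNA read to be placed as
#'   a local alignment on the contig.
#' @param gene_flank Intergenic sequence added on each side of a gene's
#'   genomic scaffold, so gDNA coverage is uniform across terminal exons.
#' @param cdna_min_len Minimum cDNA fragment length kept after truncation at
#'   contig ends.
#' @param cdna_end_jitter Mean 5'/3' end heterogeneity of cDNA molecules
#'   (bp, exponential); spreads fragment starts near contig ends the way
#'   variable transcript ends and degradation do, so position-based
#'   duplicate removal does not collapse genuinely distinct molecules.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 20L,
                       exons_per_gene = c(2L, 4L),
                       exon_len = c(150L, 350L),
                       intron_len = c(200L, 400L),
                       n_individuals = 10L,
                       n_populations = 3L,
                       snps_per_contig = c(1L, 4L),
                       maf_range = c(0.05, 0.5),
                       pop_freq_sd = 0.1,
                       gdna_depth = 78,
                       cdna_depth = 15,
                       read_len_gdna = 100L,
                       read_len_cdna = c(250L, 350L),
                       error_rate = 0.001,
                       n_duplicated_genes = 0L,
                       duplicate_divergence = 0.02,
                       min_anchor = 20L,
                       gene_flank = 150L,
                       cdna_min_len = 50L,
                       cdna_end_jitter = 75) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_len = as.integer(exon_len), intron_len = as.integer(intron_len),
              n_individuals = as.integer(n_individuals),
              n_populations = as.integer(n_populations),
              snps_per_contig = as.integer(snps_per_contig),
              maf_range = maf_range, pop_freq_sd = pop_freq_sd,
              gdna_depth = gdna_depth, cdna_depth = cdna_depth,
              read_len_gdna = as.integer(read_len_gdna),
              read_len_cdna = as.integer(read_len_cdna),
              error_rate = error_rate,
              n_duplicated_genes = as.integer(n_duplicated_genes),
              duplicate_divergence = duplicate_divergence,
              min_anchor = as.integer(min_anchor),
              gene_flank = as.integer(gene_flank),
              cdna_min_len = as.integer(cdna_min_len),
              cdna_end_jitter = cdna_end_jitter)
  for (nm in c("exons_per_gene", "exon_len", "intron_len", "snps_per_contig",
               "read_len_cdna", "maf_range")) {
    if (cfg[[nm]][2] < cfg[[nm]][1])
      stop("infeasible range for ", nm, ": max < min")
  }
  stopifnot(cfg$n_genes >= 0, cfg$n_individuals >= 1, cfg$n_populations >= 1,
            cfg$error_rate >= 0, cfg$error_rate < 1,
            cfg$n_duplicated_genes <= cfg$n_genes,
            all(cfg$maf_range >= 0), all(cfg$maf_range <= 1))
  structure(cfg, class = "sim_config")
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

sample_range <- function(rng, n = 1L) {
  if (rng[1] == rng[2]) rep.int(rng[1], n) else
    sample(seq.int(rng[1], rng[2]), n, replace = TRUE)
}

mutate_bases <- function(seq, idx) {
  # substitute positions idx (1-based) with a uniformly random *different* base
  if (!length(idx)) return(seq)
  ch <- strsplit(seq, "")[[1]]
  alt <- vapply(ch[idx], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                character(1))
  ch[idx] <- alt
  paste(ch, collapse = "")
}

#' Simulate a toy genome and transcriptome with known truth
#'
#' Builds `n_genes` genes, each a chain of exons separated by introns. The
#' gene's transcriptome contig is the exact concatenation of its exons, so
#' each internal exon junction is a true intron-exon boundary (IEB) at a known
#' contig position. Planted biallelic SNPs are placed in exons with
#' per-population alternate allele frequencies; diploid genotypes are drawn
#' per individual under Hardy-Weinberg equilibrium within its population.
#' Optionally, the first `n_duplicated_genes` genes get a diverged paralog:
#' an extra near-identical contig plus an intron-less genomic copy, emulating
#' a duplicated genome region.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (named character vector, one scaffold per gene
#'   copy), `transcriptome` (named character vector of contigs) and `truth`, a
#'   `sim_truth` list recording exon structure, true IEB positions, planted
#'   SNPs with per-population frequencies, per-individual haplotypes, and
#'   duplication flags.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    npop <- config$n_populations
    pop_of <- rep(seq_len(npop), length.out = config$n_individuals)
    pop_of <- sort(pop_of)
    genes <- list(); exons <- list(); iebs <- list(); snps <- list()
    pgenes <- list(); pexons <- list()  # paralog entries, appended after the loop
    genome <- character(0); transcriptome <- character(0)
    dup <- data.frame(contig_id = character(), partner_id = character())
    hap_rows <- list(); freq_rows <- list()
    snp_counter <- 0L
    for (g in seq_len(config$n_genes)) {
      gid <- sprintf("gene%03d", g)
      cid <- sprintf("contig%03d", g)
      n_ex <- sample_range(config$exons_per_gene)
      ex_len <- sample_range(config$exon_len, n_ex)
      in_len <- if (n_ex > 1) sample_range(config$intron_len, n_ex - 1L) else integer(0)
      ex_seq <- vapply(ex_len, rand_seq, character(1))
      in_seq <- vapply(in_len, rand_seq, character(1))
      flank5 <- rand_seq(config$gene_flank)
      flank3 <- rand_seq(config$gene_flank)
      parts <- flank5
      g_off <- config$gene_flank
      ex_tab <- data.frame(gene_id = gid, contig_id = cid,
                           exon_index = seq_len(n_ex),
                           g_start = NA_integer_, g_end = NA_integer_,
                           c_start = NA_integer_, c_end = NA_integer_)
      c_off <- 0L
      for (e in seq_len(n_ex)) {
        ex_tab$g_start[e] <- g_off
        ex_tab$g_end[e] <- g_off + ex_len[e]
        ex_tab$c_start[e] <- c_off
        ex_tab$c_end[e] <- c_off + ex_len[e]
        parts <- c(parts, ex_seq[e])
        g_off <- g_off + ex_len[e]
        c_off <- c_off + ex_len[e]
        if (e < n_ex) {
          parts <- c(parts, in_seq[e])
          g_off <- g_off + in_len[e]
        }
      }
      gseq <- paste(c(parts, flank3), collapse = "")
      cseq <- paste(ex_seq, collapse = "")
      genome[gid] <- gseq
      transcriptome[cid] <- cseq
      genes[[g]] <- data.frame(gene_id = gid, contig_id = cid, n_exons = n_ex,
                               gene_len = nchar(gseq), contig_len = nchar(cseq))
      exons[[g]] <- ex_tab
      if (n_ex > 1)
        iebs[[g]] <- data.frame(contig_id = cid, pos = cumsum(ex_len)[-n_ex])
      # planted SNPs (skipped for genes that will receive a paralog: their
      # divergence, not polymorphism, is the signal under test)
      is_dup <- g <= config$n_duplicated_genes
      n_snp <- if (is_dup) 0L else sample_range(config$snps_per_contig)
      n_snp <- min(n_snp, nchar(cseq))
      if (n_snp > 0) {
        pos <- sort(sample.int(nchar(cseq), n_snp)) - 1L  # 0-based contig pos
        for (p in pos) {
          snp_counter <- snp_counter + 1L
          refb <- substr(cseq, p + 1L, p + 1L)
          altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
          p0 <- runif(1, config$maf_range[1], config$maf_range[2])
          fr <- pmin(pmax(p0 + rnorm(npop, 0, config$pop_freq_sd), 0.01), 0.99)
          e_idx <- which(ex_tab$c_start <= p & p < ex_tab$c_end)
          gpos <- ex_tab$g_start[e_idx] + (p - ex_tab$c_start[e_idx])
          snps[[snp_counter]] <- data.frame(
            site_id = sprintf("snp%05d", snp_counter), gene_id = gid,
            contig_id = cid, pos = p, g_pos = gpos, ref = refb, alt = altb,
            freq = mean(fr), stringsAsFactors = FALSE)
          # two haplotype alleles per individual, HWE within population
          hap <- rbinom(2L * config$n_individuals, 1L, fr[rep(pop_of, each = 2L)])
          hap_rows[[snp_counter]] <- hap
          freq_rows[[snp_counter]] <- fr
        }
      }
      if (is_dup) {
        did <- paste0(cid, "d")
        dgid <- paste0(gid, "d")
        n_mut <- rbinom(1L, nchar(cseq), config$duplicate_divergence)
        idx <- if (n_mut > 0) sample.int(nchar(cseq), n_mut) else integer(0)
        dseq <- mutate_bases(cseq, idx)
        transcriptome[did] <- dseq
        # intron-less paralog copy in the genome, with its own flanks
        genome[dgid] <- paste0(rand_seq(config$gene_flank), dseq,
                               rand_seq(config$gene_flank))
        genes[[g]]$has_paralog <- TRUE
        dup <- rbind(dup,
                     data.frame(contig_id = c(cid, did), partner_id = c(did, cid)))
        pexons[[length(pexons) + 1L]] <- data.frame(
          gene_id = dgid, contig_id = did, exon_index = 1L,
          g_start = config$gene_flank, g_end = config$gene_flank + nchar(dseq),
          c_start = 0L, c_end = nchar(dseq))
        pgenes[[length(pgenes) + 1L]] <- data.frame(
          gene_id = dgid, contig_id = did, n_exons = 1L,
          gene_len = nchar(genome[[dgid]]), contig_len = nchar(dseq),
          has_paralog = TRUE)
      } else {
        genes[[g]]$has_paralog <- FALSE
      }
    }
    gene_tab <- do.call(rbind, c(genes, pgenes))
    exons <- c(exons, pexons)
    snp_tab <- if (snp_counter > 0) do.call(rbind, snps) else
      data.frame(site_id = character(), gene_id = character(),
                 contig_id = character(), pos = integer(), g_pos = integer(),
                 ref = character(), alt = character(), freq = numeric())
    haplotypes <- if (snp_counter > 0)
      matrix(unlist(hap_rows), nrow = snp_counter, byrow = TRUE,
             dimnames = list(snp_tab$site_id, NULL)) else
      matrix(0L, 0L, 2L * config$n_individuals)
    # per-population frequencies (recomputed deterministically is messy; store)
    truth <- structure(list(
      genes = gene_tab,
      exons = do.call(rbind, exons),
      iebs = if (length(iebs)) do.call(rbind, iebs) else
        data.frame(contig_id = character(), pos = integer()),
      snps = snp_tab,
      pop_freqs = if (snp_counter > 0)
        matrix(unlist(freq_rows), nrow = snp_counter, byrow = TRUE,
               dimnames = list(snp_tab$site_id, NULL)) else
        matrix(numeric(), 0L, npop),
      haplotypes = haplotypes,
      pop_of = pop_of,
      duplicated = dup,
      config = config), class = "sim_truth")
    list(genome = genome, transcriptome = transcriptome, truth = truth)
  })
}

# alleles (0 = ref, 1 = alt) carried by haplotype h (1..2n) at each snp row
hap_allele <- function(truth, snp_rows, hap_idx) {
  truth$haplotypes[cbind(snp_rows, hap_idx)]
}

#' Simulate sequencing reads from a synthetic reference
#'
#' Draws per-individual gDNA reads uniformly from each genomic scaffold (read
#' starts Poisson in number, uniform in position) carrying that individual's
#' diploid alleles at the planted SNP positions, and a pooled cDNA read set
#' from the transcriptome contigs (each read from a random individual and
#' haplotype). Sequencing errors are injected per base at `error_rate`; base
#' qualities are constant Q40.
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()].
#' @return A list with `gdna` and `cdna` read tables (columns `id`,
#'   `individual`, `source_id`, `start`, `len`, `seq`, `qual`) ready for
#'   [write_fastq()] and [emit_truth_sam()].
#' @export
simulate_reads <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"))
  truth <- reference$truth
  with_seed(config$seed + 1L, {
    n_ind <- config$n_individuals
    rl <- config$read_len_gdna
    per_ind_depth <- config$gdna_depth / n_ind
    gdna <- list(); k <- 0L
    for (gi in seq_len(nrow(truth$genes))) {
      gid <- truth$genes$gene_id[gi]
      gseq <- reference$genome[[gid]]
      L <- nchar(gseq)
      if (L < rl) next
      gene_snps <- which(truth$snps$gene_id == gid)
      for (ind in seq_len(n_ind)) {
        n_reads <- rpois(1L, per_ind_depth * L / rl)
        if (n_reads == 0L) next
        starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE) - 1L
        seqs <- substring(gseq, starts + 1L, starts + rl)
        hap_pick <- sample.int(2L, n_reads, replace = TRUE)
        if (length(gene_snps)) {
          for (s in gene_snps) {
            gp <- truth$snps$g_pos[s]
            off <- gp - starts           # 0-based offset within read
            cover <- off >= 0L & off < rl
            if (!any(cover)) next
            hap_idx <- 2L * (ind - 1L) + hap_pick
            carry <- cover & hap_allele(truth, rep(s, n_reads), hap_idx) == 1L
            if (any(carry))
              substr(seqs[carry], off[carry] + 1L, off[carry] + 1L) <-
                truth$snps$alt[s]
          }
        }
        seqs <- inject_errors(seqs, config$error_rate)
        k <- k + 1L
        gdna[[k]] <- data.frame(
          id = sprintf("g_%s_i%02d_%05d", gid, ind, seq_len(n_reads)),
          individual = ind, source_id = gid, start = starts,
          len = rl, seq = seqs, stringsAsFactors = FALSE)
      }
    }
    gdna <- if (length(gdna)) do.call(rbind, gdna) else
      data.frame(id = character(), individual = integer(),
                 source_id = character(), start = integer(), len = integer(),
                 seq = character())
    gdna$qual <- strrep("I", gdna$len)

    cdna <- list(); k <- 0L
    mean_crl <- mean(config$read_len_cdna)
    for (ci in seq_along(reference$transcriptome)) {
      cid <- names(reference$transcriptome)[ci]
      cseq <- reference$transcriptome[[cid]]
      Lc <- nchar(cseq)
      # fragments may overhang the molecule's ends (truncated on placement);
      # each fragment's parent molecule has exponentially jittered 5'/3' ends,
      # and fragments are drawn until the target base yield (depth x length)
      # is reached, so interior coverage sits at the stated depth
      target_bases <- rpois(1L, config$cdna_depth * Lc)
      n_draw <- max(16L, ceiling(3 * target_bases / mean_crl))
      flen <- sample_range(config$read_len_cdna, n_draw)
      fstart <- vapply(flen, function(l)
        sample.int(Lc + l - 1L, 1L) - l, integer(1))  # in [-(l-1), Lc-1]
      jit <- config$cdna_end_jitter
      m5 <- if (jit > 0) pmin(floor(stats::rexp(n_draw, 1 / jit)), Lc - 1L)
            else rep.int(0L, n_draw)
      m3 <- if (jit > 0) floor(stats::rexp(n_draw, 1 / jit)) else rep.int(0L, n_draw)
      span_e <- pmax(Lc - m3, m5 + 1L)
      starts <- as.integer(pmax(fstart, m5))
      ends <- as.integer(pmin(fstart + flen, span_e))
      lens <- ends - starts
      ok <- lens >= config$cdna_min_len
      starts <- starts[ok]; lens <- lens[ok]
      n_reads <- which(cumsum(lens) >= target_bases)[1]
      if (is.na(n_reads)) n_reads <- length(starts)
      starts <- starts[seq_len(n_reads)]; lens <- lens[seq_len(n_reads)]
      if (n_reads == 0L) next
      seqs <- substring(cseq, starts + 1L, starts + lens)
      inds <- sample.int(config$n_individuals, n_reads, replace = TRUE)
      haps <- sample.int(2L, n_reads, replace = TRUE)
      contig_snps <- which(truth$snps$contig_id == cid)
      for (s in contig_snps) {
        cp <- truth$snps$pos[s]
        off <- cp - starts
        cover <- off >= 0L & off < lens
        if (!any(cover)) next
        hap_idx <- 2L * (inds - 1L) + haps
        carry <- cover & hap_allele(truth, rep(s, n_reads), hap_idx) == 1L
        if (any(carry))
          substr(seqs[carry], off[carry] + 1L, off[carry] + 1L) <-
            truth$snps$alt[s]
      }
      seqs <- inject_errors(seqs, config$error_rate)
      k <- k + 1L
      cdna[[k]] <- data.frame(
        id = sprintf("c_%s_%05d", cid, seq_len(n_reads)),
        individual = inds, source_id = cid, start = starts, len = lens,
        seq = seqs, stringsAsFactors = FALSE)
    }
    cdna <- if (length(cdna)) do.call(rbind, cdna) else
      data.frame(id = character(), individual = integer(),
                 source_id = character(), start = integer(), len = integer(),
                 seq = character())
    cdna$qual <- strrep("I", cdna$len)
    rownames(gdna) <- rownames(cdna) <- NULL
    list(gdna = gdna, cdna = cdna)
  })
}

inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || !length(seqs)) return(seqs)
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[i])
    idx <- which(runif(n) < error_rate)
    if (length(idx)) seqs[i] <- mutate_bases(seqs[i], idx)
  }
  seqs
}

#' Emit truth-placement SAM alignments
#'
#' Writes local alignments directly from the simulator's known read
#' placements, without invoking an aligner. gDNA reads are assigned to the
#' exon they overlap most; the portions extending beyond that exon's
#' boundaries are soft-clipped, reproducing the change-point pattern a local
#' aligner produces at intron-exon boundaries. Reads overlapping no exon by at
#' least `min_anchor` bases are omitted. Reads from a gene with a paralog get
#' an additional secondary (FLAG 0x100) record on the partner contig. cDNA
#' reads align end-to-end.
#'
#' @param reads Output of [simulate_reads()].
#' @param reference Output of [simulate_reference()].
#' @return A list with `g2t` and `t2t` alignment tables (see [read_sam()]) and
#'   `contigs`, the transcriptome lengths for SAM headers.
#' @export
emit_truth_sam <- function(reads, reference) {
  truth <- reference$truth
  cfg <- truth$config
  partner <- setNames(truth$duplicated$partner_id, truth$duplicated$contig_id)
  contig_of_gene <- setNames(truth$genes$contig_id, truth$genes$gene_id)

  g2t <- list(); k <- 0L
  gd <- reads$gdna
  if (nrow(gd)) {
    ex <- truth$exons
    for (gid in unique(gd$source_id)) {
      rows <- which(gd$source_id == gid)
      exg <- ex[ex$gene_id == gid, , drop = FALSE]
      cid <- contig_of_gene[[gid]]
      s <- gd$start[rows]; e <- s + gd$len[rows]
      # overlap of each read with each exon; pick the best exon
      best_ov <- rep.int(0L, length(rows)); best_e <- rep.int(NA_integer_, length(rows))
      for (j in seq_len(nrow(exg))) {
        ov <- pmin(e, exg$g_end[j]) - pmax(s, exg$g_start[j])
        better <- ov > best_ov
        best_ov[better] <- ov[better]
        best_e[better] <- j
      }
      keep <- best_ov >= cfg$min_anchor
      if (!any(keep)) next
      ki <- which(keep)
      j <- best_e[ki]
      ov_start <- pmax(s[ki], exg$g_start[j])
      ov_end <- pmin(e[ki], exg$g_end[j])
      lead <- ov_start - s[ki]
      trail <- e[ki] - ov_end
      mlen <- ov_end - ov_start
      cpos <- exg$c_start[j] + (ov_start - exg$g_start[j])
      cigar <- paste0(ifelse(lead > 0, paste0(lead, "S"), ""),
                      mlen, "M",
                      ifelse(trail > 0, paste0(trail, "S"), ""))
      k <- k + 1L
      g2t[[k]] <- data.frame(
        qname = gd$id[rows][ki], flag = 0L, rname = cid, pos = cpos,
        mapq = 60L, cigar = cigar, seq = gd$seq[rows][ki],
        qual = gd$qual[rows][ki], secondary = FALSE, reverse = FALSE,
        stringsAsFactors = FALSE)
      if (cid %in% names(partner)) {
        k <- k + 1L
        sec <- g2t[[k - 1L]]
        sec$flag <- 256L
        sec$rname <- partner[[cid]]
        sec$secondary <- TRUE
        g2t[[k]] <- sec
      }
    }
  }
  g2t <- if (length(g2t)) do.call(rbind, g2t) else empty_alignments()

  t2t <- reads$cdna
  if (nrow(t2t)) {
    t2t <- data.frame(
      qname = t2t$id, flag = 0L, rname = t2t$source_id, pos = t2t$start,
      mapq = 60L, cigar = paste0(t2t$len, "M"), seq = t2t$seq,
      qual = t2t$qual, secondary = FALSE, reverse = FALSE,
      stringsAsFactors = FALSE)
  } else t2t <- empty_alignments()
  rownames(g2t) <- rownames(t2t) <- NULL
  list(g2t = g2t, t2t = t2t,
       contigs = setNames(nchar(reference$transcriptome),
                          names(reference$transcriptome)))
}

#' Simulate a genotyping run over a marker panel
#'
#' Draws fresh diploid individuals per population at the planted
#' per-population allele frequencies (HWE within population) and genotypes
#' the given markers. Markers that are not planted SNPs (sequencing-error
#' artifacts that slipped through discovery) genotype as monomorphic
#' reference calls. A per-call missing rate emulates assay dropout.
#'
#' @param truth A `sim_truth` from [simulate_reference()].
#' @param markers Data.frame with `contig`, `pos` columns (0-based) naming the
#'   panel; defaults to all planted SNPs.
#' @param n_per_pop Individuals genotyped per population.
#' @param miss_rate Per-call missing probability.
#' @param seed Integer seed.
#' @return List with `genotypes` (markers x individuals call matrix with
#'   rownames `contig:pos`) and `pops` (population label per individual).
#' @export
simulate_genotypes <- function(truth, markers = NULL, n_per_pop = 30L,
                               miss_rate = 0.02, seed = 1L) {
  cfg <- truth$config
  npop <- cfg$n_populations
  if (is.null(markers))
    markers <- data.frame(contig = truth$snps$contig_id, pos = truth$snps$pos)
  with_seed(seed, {
    n <- npop * n_per_pop
    pops <- rep(paste0("pop", seq_len(npop)), each = n_per_pop)
    ids <- sprintf("%s_i%03d", pops, sequence(rep(n_per_pop, npop)))
    gm <- matrix(NA_character_, nrow = nrow(markers), ncol = n,
                 dimnames = list(paste0(markers$contig, ":", markers$pos), ids))
    key <- paste0(truth$snps$contig_id, ":", truth$snps$pos)
    for (i in seq_len(nrow(markers))) {
      mk <- paste0(markers$contig[i], ":", markers$pos[i])
      s <- match(mk, key)
      if (is.na(s)) {
        calls <- rep("AA", n)  # artifact marker: monomorphic reference
      } else {
        fr <- truth$pop_freqs[s, ]
        gcount <- rbinom(n, 2L, fr[rep(seq_len(npop), each = n_per_pop)])
        calls <- c("AA", "AB", "BB")[gcount + 1L]
      }
      calls[runif(n) < miss_rate] <- NA_character_
      gm[i, ] <- calls
    }
    list(genotypes = gm, pops = pops)
  })
}

#' Write a simulated study to disk
#'
#' Convenience wrapper: generates reference, reads and truth alignments and
#' writes FASTA/FASTQ/SAM plus truth tables (TSV) under `dir`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(config)
  reads <- simulate_reads(config, ref)
  sams <- emit_truth_sam(reads, ref)
  write_fasta(ref$genome, file.path(dir, "genome.fasta"))
  write_fasta(ref$transcriptome, file.path(dir, "transcriptome.fasta"))
  for (ind in sort(unique(reads$gdna$individual))) {
    sel <- reads$gdna$individual == ind
    write_fastq(reads$gdna[sel, ], file.path(dir, sprintf("gdna_i%02d.fastq", ind)))
  }
  write_fastq(reads$cdna, file.path(dir, "cdna.fastq"))
  write_sam(sams$g2t, sams$contigs, file.path(dir, "g2t.sam"))
  write_sam(sams$t2t, sams$contigs, file.path(dir, "t2t.sam"))
  write.table(ref$truth$iebs, file.path(dir, "truth_iebs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ref$truth$snps, file.path(dir, "truth_snps.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(reference = ref, reads = reads, sams = sams))
}
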