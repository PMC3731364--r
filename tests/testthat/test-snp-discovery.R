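test_that("duplicate removal keys on template origin and orientation", {
  a <- aln_row("r1", "c", 10L, "50M", qual = strrep("I", 50))
  b <- aln_row("r2", "c", 10L, "50M", qual = strrep("5", 50))  # lower quality
  out <- dedup_reads(rbind(a, b))
  expect_equal(out$qname, "r1")
  # same start, opposite strands: both kept
  c_rev <- aln_row("r3", "c", 10L, "50M", flag = 16L)
  expect_equal(nrow(dedup_reads(rbind(a, c_rev))), 2L)
  # same unclipped start through different clipping: duplicates
  d <- aln_row("r4", "c", 30L, "20S30M")   # unclipped start 10
  expect_equal(nrow(dedup_reads(rbind(a, d))), 1L)
  # different unclipped starts clipping at the same position: both kept
  e <- aln_row("r5", "c", 30L, "5S45M")    # unclipped start 25
  f <- aln_row("r6", "c", 30L, "12S38M")   # unclipped start 18
  expect_equal(nrow(dedup_reads(rbind(e, f))), 2L)
  # idempotence and empty input
  once <- dedup_reads(rbind(a, b, c_rev, d, e, f))
  expect_equal(dedup_reads(once), once)
  expect_equal(nrow(dedup_reads(empty_aln())), 0L)
})

test_that("pileups are restricted to HQ bases and flag indel columns", {
  contigs <- c(c = paste0(strrep("A", 50), "G", strrep("A", 49)))
  ten_ref <- do.call(rbind, lapply(1:10, function(i)
    aln_row(paste0("r", i), "c", 40L, "30M", seq = strrep("A", 30))))
  pu <- pileup_sites(ten_ref, contigs)
  expect_equal(unname(pu$c$counts["A", 41]), 10L)
  expect_false(any(pu$c$indel))
  # low-quality bases are excluded from tallies
  mixed <- rbind(
    do.call(rbind, lapply(1:8, function(i)
      aln_row(paste0("h", i), "c", 50L, "1M", seq = "G", qual = "I"))),
    do.call(rbind, lapply(1:2, function(i)
      aln_row(paste0("l", i), "c", 50L, "1M", seq = "T", qual = "0"))))  # Q15
  pu <- pileup_sites(mixed, contigs)
  expect_equal(sum(pu$c$counts[, 51]), 8L)
  expect_equal(unname(pu$c$counts["T", 51]), 0L)
  # insertions and deletions mark their columns non-biallelic
  ins <- aln_row("i1", "c", 10L, "5M2I5M", seq = strrep("A", 12))
  del <- aln_row("d1", "c", 70L, "4M3D4M", seq = strrep("A", 8))
  pu <- pileup_sites(rbind(ten_ref, ins, del), contigs)
  expect_true(pu$c$indel[15] || pu$c$indel[16])   # around the insertion point
  expect_true(all(pu$c$indel[75:77]))             # deleted reference bases
  expect_false(pu$c$indel[41])
})

test_that("the filter cascade passes and fails sites exactly as stated", {
  mk_pileup <- function(ref_n, alt_n, L = 20L) {
    counts <- matrix(0L, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    counts["A", 10] <- ref_n
    counts["G", 10] <- alt_n
    list(c = list(counts = counts, indel = logical(L)))
  }
  contigs <- c(c = strrep("A", 20))
  call1 <- function(ref_n, alt_n, side) {
    nrow(call_variants(mk_pileup(ref_n, alt_n), contigs, side = side))
  }
  expect_equal(call1(6L, 2L, "T2T"), 1L)    # alt 2, depth 8: pass
  expect_equal(call1(5L, 2L, "T2T"), 0L)    # alt 2, depth 7: fail
  expect_equal(call1(4L, 3L, "T2T"), 1L)    # alt 3 waives the depth rule
  expect_equal(call1(18L, 2L, "G2T"), 1L)   # alt 2 at depth exactly 20: pass
  expect_equal(call1(17L, 2L, "G2T"), 0L)   # depth 19: fail
  expect_equal(call1(16L, 3L, "G2T"), 1L)   # alt 3 waives depth on G2T too
  expect_equal(call1(199L, 2L, "G2T"), 0L)  # depth 201 > 200: fail
  expect_equal(call1(198L, 2L, "G2T"), 1L)  # depth 200: pass
  expect_equal(call1(197L, 4L, "T2T"), 0L)  # max depth applies to T2T as well
})

test_that("non-biallelic and reference-free columns are never called", {
  contigs <- c(c = strrep("A", 20))
  counts <- matrix(0L, 4, 20, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts["A", 10] <- 10L; counts["G", 10] <- 5L; counts["T", 10] <- 3L
  counts["C", 15] <- 10L; counts["G", 15] <- 10L   # reference A unobserved
  pu <- list(c = list(counts = counts, indel = logical(20)))
  expect_equal(nrow(call_variants(pu, contigs, side = "G2T")), 0L)
  # indel flag suppresses an otherwise passing site
  counts2 <- matrix(0L, 4, 20, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts2["A", 10] <- 20L; counts2["G", 10] <- 10L
  ind <- logical(20); ind[10] <- TRUE
  expect_equal(nrow(call_variants(list(c = list(counts = counts2, indel = ind)),
                                  contigs, side = "G2T")), 0L)
})

test_that("set intersection demands position and allele-pair identity", {
  t2t <- data.frame(contig = c("c1", "c1", "c2"), pos = c(5L, 9L, 3L),
                    ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                    hq_depth = 10L, alt_hq_count = 3L, source = "T2T")
  g2t_disjoint <- transform(t2t, pos = pos + 100L, source = "G2T")
  expect_equal(nrow(intersect_variant_sets(t2t, g2t_disjoint)), 0L)
  g2t_same <- transform(t2t, source = "G2T")
  both <- intersect_variant_sets(t2t, g2t_same)
  expect_equal(nrow(both), 3L)
  expect_true(all(both$source == "both"))
  # allele mismatch at the same position is excluded (and reported)
  g2t_mm <- g2t_same; g2t_mm$alt[2] <- "G"
  expect_message(both2 <- intersect_variant_sets(t2t, g2t_mm), "mismatch")
  expect_equal(nrow(both2), 2L)
  expect_equal(nrow(attr(both2, "mismatch")), 1L)
  # subset property
  expect_true(all(paste(both2$contig, both2$pos) %in% paste(t2t$contig, t2t$pos)))
})

test_that("transitions and transversions are classified and summed", {
  expect_equal(classify_tstv("A", "G"), "transition")
  expect_equal(classify_tstv("C", "T"), "transition")
  expect_equal(classify_tstv("A", "C"), "transversion")
  expect_equal(classify_tstv(c("G", "T"), c("A", "C")),
               c("transition", "transition"))
  expect_equal(classify_tstv("G", "T"), "transversion")
  expect_error(classify_tstv("A", "A"))
  expect_equal(tstv_ratio(13255, 5739), 2.31)
})

test_that("every emitted call satisfies the policy predicate (oracle re-check)", {
  sim <- tiny_sim()
  pol <- snp_filter_policy()
  res <- call_common_snps(sim$sams$t2t, sim$sams$g2t, sim$ref$transcriptome)
  # independent re-check straight from the predicate text
  check <- function(v, min_count, min_depth, waive) {
    all(v$hq_depth <= pol$max_depth &
          (v$alt_hq_count >= waive |
             (v$alt_hq_count >= min_count & v$hq_depth >= min_depth)))
  }
  expect_gt(nrow(res$t2t), 0L)
  expect_gt(nrow(res$g2t), 0L)
  expect_true(check(res$t2t, pol$t2t_min_count, pol$t2t_min_depth,
                    pol$t2t_waive_count))
  expect_true(check(res$g2t, pol$g2t_min_count, pol$g2t_min_depth,
                    pol$g2t_waive_count))
  # common set is a subset of each side
  kc <- paste(res$common$contig, res$common$pos)
  expect_true(all(kc %in% paste(res$t2t$contig, res$t2t$pos)))
  expect_true(all(kc %in% paste(res$g2t$contig, res$g2t$pos)))
  # transitions + transversions = total
  cls <- classify_tstv(res$common$ref, res$common$alt)
  expect_equal(sum(cls == "transition") + sum(cls == "transversion"),
               nrow(res$common))
})

test_that("no SNPs are called on SNP-free error-free simulations", {
  cfg <- sim_config(seed = 29, n_genes = 5, snps_per_contig = c(0L, 0L),
                    error_rate = 0)
  ref <- simulate_reference(cfg)
  reads <- simulate_reads(cfg, ref)
  sams <- emit_truth_sam(reads, ref)
  res <- call_common_snps(sams$t2t, sams$g2t, ref$transcriptome)
  expect_equal(nrow(res$t2t), 0L)
  expect_equal(nrow(res$g2t), 0L)
  expect_equal(nrow(res$common), 0L)
})

test_that("planted SNPs with adequate depth on both sides are all called", {
  cfg <- sim_config(seed = 37, n_genes = 8, error_rate = 0,
                    maf_range = c(0.4, 0.5), pop_freq_sd = 0)
  ref <- simulate_reference(cfg)
  reads <- simulate_reads(cfg, ref)
  sams <- emit_truth_sam(reads, ref)
  pol <- snp_filter_policy()
  res <- call_common_snps(sams$t2t, sams$g2t, ref$transcriptome, policy = pol)
  # which planted sites meet both sides' conditions, from raw pileups
  pu_t <- pileup_sites(dedup_reads(sams$t2t), ref$transcriptome)
  pu_g <- pileup_sites(dedup_reads(sams$g2t), ref$transcriptome)
  tr <- ref$truth$snps
  meets <- vapply(seq_len(nrow(tr)), function(i) {
    ct <- pu_t[[tr$contig_id[i]]]$counts[, tr$pos[i] + 1L]
    cg <- pu_g[[tr$contig_id[i]]]$counts[, tr$pos[i] + 1L]
    at <- ct[[tr$alt[i]]]; dt <- sum(ct)
    ag <- cg[[tr$alt[i]]]; dg <- sum(cg)
    sum(ct > 0) == 2 && sum(cg > 0) == 2 &&
      dt <= 200 && dg <= 200 &&
      (at >= 3 || (at >= 2 && dt >= 8)) &&
      (ag >= 3 || (ag >= 2 && dg >= 20))
  }, logical(1))
  key_called <- paste(res$common$contig, res$common$pos)
  key_meets <- paste(tr$contig_id, tr$pos)[meets]
  expect_true(all(key_meets %in% key_called))
})
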