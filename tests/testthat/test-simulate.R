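test_that("contigs are exact exon concatenations with known boundaries", {
  cfg <- sim_config(seed = 5, n_genes = 1, exons_per_gene = c(3L, 3L),
                    exon_len = c(200L, 200L), intron_len = c(300L, 300L))
  ref <- simulate_reference(cfg)
  expect_length(ref$transcriptome, 1L)
  expect_equal(nchar(ref$transcriptome[[1]]), 600L)
  expect_equal(ref$truth$iebs$pos, c(200L, 400L))
  ex <- ref$truth$exons
  rebuilt <- paste(substring(ref$genome[[ex$gene_id[1]]],
                             ex$g_start + 1L, ex$g_end), collapse = "")
  expect_equal(rebuilt, ref$transcriptome[[1]])
  # planted SNP invariants: inside the contig, ref allele matches the contig
  tr <- ref$truth$snps
  expect_true(all(tr$pos >= 0 & tr$pos < 600))
  expect_equal(unname(substring(ref$transcriptome[tr$contig_id],
                                tr$pos + 1, tr$pos + 1)),
               tr$ref)
})

test_that("identical seeds give byte-identical outputs", {
  cfg <- sim_config(seed = 7, n_genes = 3, n_duplicated_genes = 1)
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(cfg, d1)
  write_simulation(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("no duplicated genes means no near-identical contig pair", {
  ref <- simulate_reference(sim_config(seed = 9, n_genes = 4,
                                       n_duplicated_genes = 0L))
  expect_equal(nrow(ref$truth$duplicated), 0L)
  expect_length(ref$transcriptome, 4L)
})

test_that("read yield follows the configured depth and error-free reads match truth", {
  cfg <- sim_config(seed = 21, n_genes = 1, exons_per_gene = c(1L, 1L),
                    exon_len = c(1000L, 1000L), gene_flank = 0L,
                    gdna_depth = 50, error_rate = 0, snps_per_contig = c(0L, 0L))
  ref <- simulate_reference(cfg)
  reads <- simulate_reads(cfg, ref)
  # ~ depth * L / read_len gDNA reads (Poisson)
  expect_gt(nrow(reads$gdna), 500 - 4 * sqrt(500))
  expect_lt(nrow(reads$gdna), 500 + 4 * sqrt(500))
  # with no SNPs and no errors every read is a verbatim genome substring
  idx <- sample.int(nrow(reads$gdna), 50)
  expect_true(all(
    reads$gdna$seq[idx] ==
      substring(ref$genome[reads$gdna$source_id[idx]],
                reads$gdna$start[idx] + 1L,
                reads$gdna$start[idx] + reads$gdna$len[idx])))
})

test_that("zero gDNA depth yields an empty gDNA read set", {
  cfg <- sim_config(seed = 3, n_genes = 2, gdna_depth = 0)
  ref <- simulate_reference(cfg)
  reads <- simulate_reads(cfg, ref)
  expect_equal(nrow(reads$gdna), 0L)
  expect_gt(nrow(reads$cdna), 0L)
})

test_that("planted allele frequency is recovered in read pileups", {
  # one SNP at frequency 0.5, error-free: alt read fraction within binomial CI
  cfg <- sim_config(seed = 13, n_genes = 1, exons_per_gene = c(1L, 1L),
                    exon_len = c(800L, 800L), snps_per_contig = c(1L, 1L),
                    maf_range = c(0.5, 0.5), pop_freq_sd = 0, error_rate = 0,
                    n_individuals = 40L, gdna_depth = 200)
  ref <- simulate_reference(cfg)
  reads <- simulate_reads(cfg, ref)
  sams <- emit_truth_sam(reads, ref)
  tr <- ref$truth$snps
  hap_frac <- mean(ref$truth$haplotypes[1, ])
  pu <- pileup_sites(sams$g2t, ref$transcriptome)
  cnt <- pu[[tr$contig_id]]$counts[, tr$pos + 1L]
  alt_frac <- cnt[[tr$alt]] / (cnt[[tr$ref]] + cnt[[tr$alt]])
  n <- cnt[[tr$ref]] + cnt[[tr$alt]]
  expect_lt(abs(alt_frac - hap_frac), 4 * sqrt(0.25 / n) + 0.02)
})

test_that("planted frequencies converge across many individuals", {
  cfg <- sim_config(seed = 31, n_genes = 8, n_individuals = 200L,
                    pop_freq_sd = 0, snps_per_contig = c(2L, 2L))
  ref <- simulate_reference(cfg)
  obs <- rowMeans(ref$truth$haplotypes)
  expect_lt(max(abs(obs - ref$truth$snps$freq)), 0.12)
  expect_lt(mean(abs(obs - ref$truth$snps$freq)), 0.04)
})

test_that("truth SAM reproduces the boundary soft-clip pattern", {
  sim <- tiny_sim()
  g2t <- sim$sams$g2t
  truth <- sim$ref$truth
  # every SAM record's sequence appears verbatim in the read set
  expect_true(all(g2t$seq %in% sim$reads$gdna$seq))
  expect_true(all(sim$sams$t2t$seq %in% sim$reads$cdna$seq))
  # a read straddling an exon boundary is soft-clipped at the boundary
  prim <- g2t[!g2t$secondary, ]
  spans <- vapply(prim$cigar, cigar_ref_span, integer(1), USE.NAMES = FALSE)
  trail <- grepl("S$", prim$cigar)
  clipped_ends <- (prim$pos + spans)[trail]
  boundary_like <- paste(prim$rname[trail], clipped_ends) %in%
    paste(truth$iebs$contig_id, truth$iebs$pos)
  contig_len <- nchar(sim$ref$transcriptome)[prim$rname[trail]]
  at_contig_end <- clipped_ends == contig_len
  expect_true(all(boundary_like | at_contig_end))
  # duplicated genes carry a secondary record on the paralog
  dup <- truth$duplicated
  expect_gt(nrow(dup), 0L)
  sec <- g2t[g2t$secondary, ]
  expect_true(all(sec$rname %in% dup$contig_id))
  expect_setequal(unique(sec$rname), dup$contig_id)
})

test_that("wholly intronic reads are absent from the truth G2T SAM", {
  sim <- tiny_sim()
  ex <- sim$ref$truth$exons
  g2t_names <- unique(sim$sams$g2t$qname)
  gd <- sim$reads$gdna
  in_sam <- gd$id %in% g2t_names
  for (i in sample(which(!in_sam), min(50, sum(!in_sam)))) {
    exg <- ex[ex$gene_id == gd$source_id[i], ]
    ov <- pmin(gd$start[i] + gd$len[i], exg$g_end) - pmax(gd$start[i], exg$g_start)
    expect_lt(max(ov), sim$cfg$min_anchor)
  }
})

test_that("genotyping simulation produces plausible panels", {
  sim <- tiny_sim()
  gt <- simulate_genotypes(sim$ref$truth, n_per_pop = 30, seed = 4)
  expect_equal(ncol(gt$genotypes), 90L)
  expect_equal(nrow(gt$genotypes), nrow(sim$ref$truth$snps))
  expect_true(all(gt$genotypes %in% c("AA", "AB", "BB", NA)))
  # an artifact marker (not planted) genotypes monomorphic reference
  fake <- data.frame(contig = sim$ref$truth$snps$contig_id[1], pos = -99L)
  gt2 <- simulate_genotypes(sim$ref$truth, markers = fake, n_per_pop = 10,
                            miss_rate = 0, seed = 4)
  expect_true(all(gt2$genotypes == "AA"))
})
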