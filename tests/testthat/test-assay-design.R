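test_that("flank construction enforces length, conservation and IEB truncation", {
  seq500 <- local({set.seed(2); paste(sample(c("A","C","G","T"), 500, TRUE),
                                      collapse = "")})
  ref <- substr(seq500, 11, 11); alt <- setdiff(c("A","C","G","T"), ref)[1]
  # target 10 bases from the contig start: upstream too short
  cand <- build_flank(seq500, 10L, ref, alt, contig_id = "c")
  expect_false(cand$accepted)
  expect_equal(cand$rejection_reason, "short_flank")
  expect_equal(cand$upstream_len, 10L)
  # another variant 3 bp away: nonconserved core
  r2 <- substr(seq500, 251, 251); a2 <- setdiff(c("A","C","G","T"), r2)[1]
  cand <- build_flank(seq500, 250L, r2, a2, mask_pos = 253L, contig_id = "c")
  expect_false(cand$accepted)
  expect_equal(cand$rejection_reason, "nonconserved_core")
  # variant 6 bp away is outside the +/-5 core but still masked
  cand <- build_flank(seq500, 250L, r2, a2, mask_pos = 256L, contig_id = "c")
  expect_true(cand$accepted)
  expect_equal(substr(cand$flank_seq, 250 + 6 + nchar("[X/Y]") - 1 + 1, 257 + 4),
               "N")
  expect_match(cand$flank_seq, sprintf("\\[%s/%s\\]", r2, a2), fixed = FALSE)
  # an IEB 40 bp upstream caps the flank at the breakpoint
  cand <- build_flank(seq500, 250L, r2, a2, iebs = 210L, contig_id = "c")
  expect_true(cand$accepted)
  expect_equal(cand$upstream_len, 40L)
  expect_equal(cand$downstream_len, 500L - 250L - 1L)
  expect_equal(nchar(cand$flank_seq), (500L - 210L) - 1L + nchar("[X/Y]"))
  # IEB 20 bp upstream: too little room left
  cand <- build_flank(seq500, 250L, r2, a2, iebs = 230L, contig_id = "c")
  expect_equal(cand$rejection_reason, "short_flank")
})

test_that("accepted flanks survive an independent validator (seeded candidates)", {
  set.seed(99)
  n_ok <- 0L; n_total <- 1000L
  for (i in seq_len(n_total)) {
    L <- sample(120:900, 1)
    seqc <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    pos <- sample(0:(L - 1), 1)
    refb <- substr(seqc, pos + 1, pos + 1)
    altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
    mask <- sort(sample(0:(L - 1), sample(0:8, 1)))
    iebs <- sort(sample(seq_len(L - 1), sample(0:3, 1)))
    cand <- build_flank(seqc, pos, refb, altb, mask_pos = mask, iebs = iebs,
                        contig_id = "c")
    expect_true(validate_candidate(cand, seqc, mask, iebs), info = i)
    n_ok <- n_ok + cand$accepted
  }
  expect_gt(n_ok, 0L)  # the validator exercised real acceptances
})

test_that("similarity screen fails identical stretches and passes unique flanks", {
  set.seed(5)
  uniq <- paste(sample(c("A","C","G","T"), 120, TRUE), collapse = "")
  other <- paste(sample(c("A","C","G","T"), 400, TRUE), collapse = "")
  db <- c(self = uniq, other = other)
  expect_true(similarity_screen(uniq, "self", db))
  # flank identical to a 100 bp stretch of another contig: E-value << 1e-25
  shared <- substr(other, 101, 200)
  expect_false(similarity_screen(shared, "self", db))
  # matching only its own contig passes (self-hit exclusion)
  expect_true(similarity_screen(substr(uniq, 1, 100), "self", db))
  expect_true(similarity_screen(uniq, "self", db[1]))  # empty effective db
  # external tabular hits override the built-in search
  hits <- data.frame(query = "self", subject = "other", evalue = 1e-30)
  expect_false(similarity_screen(uniq, "self", db, external_hits = hits,
                                 query_id = "self"))
  hits$evalue <- 1e-10
  expect_true(similarity_screen(uniq, "self", db, external_hits = hits,
                                query_id = "self"))
})

test_that("homology categories follow the interval rules", {
  hits <- data.frame(contig = c("c1", "c2", "c2", "c3"),
                     start = c(100L, 100L, 400L, 0L),
                     end = c(300L, 300L, 600L, 50L),
                     coding = c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(categorize_homology("cX", 10L, hits), "no_homology")
  expect_equal(categorize_homology("c1", 150L, hits), "cSNP")
  expect_equal(categorize_homology("c1", 50L, hits), "ncSNP")
  # contig with both coding and non-coding assignments is ambiguous
  expect_equal(categorize_homology("c2", 150L, hits), "tSNP")
  expect_equal(categorize_homology("c2", 500L, hits), "tSNP")
  expect_error(categorize_homology("c1", 1L, transform(hits, end = start - 5L)),
               "malformed")
})

test_that("Weir-Cockerham theta matches its variance-component definition", {
  # maximal differentiation: two populations fixed for alternate alleles
  calls <- c(rep("AA", 10), rep("BB", 10))
  pops <- rep(c("p1", "p2"), each = 10)
  expect_equal(wc_fst(calls, pops), 1.0)
  # identical HWE-ish populations: theta near zero (30 individuals per pop)
  arr <- rep(c(rep("AA", 4), rep("AB", 4), rep("BB", 2)), 3)
  g <- rep(arr, 3)
  p <- rep(c("p1", "p2", "p3"), each = 30)
  expect_lt(abs(wc_fst(g, p)), 0.05)
  expect_error(wc_fst(calls, rep("p1", 20)), "two populations")
  # hand-worked toy table against the independent multiallelic-sum oracle
  toy <- c("AA", "AB", "AB", "BB", "AA", "AA", "AB", "BB", "BB", "BB")
  toyp <- rep(c("x", "y"), each = 5)
  expect_equal(wc_fst(toy, toyp), brute_wc_theta(toy, toyp), tolerance = 1e-12)
})

test_that("theta equals the small-case oracle over exhaustive toy tables", {
  gts <- c("AA", "AB", "BB")
  comp_tables <- function(n) {
    # all genotype-count compositions (nAA, nAB, nBB) summing to n
    out <- list()
    for (a in 0:n) for (b in 0:(n - a)) out[[length(out) + 1L]] <- c(a, b, n - a - b)
    out
  }
  expand_calls <- function(cnt) rep(gts, cnt)
  # exhaustive: 2 populations x up to 4 individuals each
  for (n1 in 1:4) for (n2 in 1:4) {
    for (t1 in comp_tables(n1)) for (t2 in comp_tables(n2)) {
      calls <- c(expand_calls(t1), expand_calls(t2))
      pops <- rep(c("p1", "p2"), c(n1, n2))
      got <- wc_fst(calls, pops)
      want <- brute_wc_theta(calls, pops)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
  # 3 populations x up to 3 individuals each: seeded random subsample of the
  # composition space plus edge cases
  set.seed(11)
  for (rep_i in 1:300) {
    ns <- sample(1:3, 3, replace = TRUE)
    calls <- unlist(lapply(ns, function(n) sample(gts, n, replace = TRUE)))
    pops <- rep(c("p1", "p2", "p3"), ns)
    expect_equal(wc_fst(calls, pops), brute_wc_theta(calls, pops),
                 tolerance = 1e-10)
  }
})

test_that("panel selection is deterministic and honors the two-subset rule", {
  cand <- data.frame(marker_id = paste0("m", 1:10), accepted = TRUE)
  cats <- c("cSNP", "cSNP", "tSNP", "tSNP", "tSNP", "ncSNP", "ncSNP",
            "no_homology", "no_homology", "no_homology")
  fst <- c(0.2, 0.1, 0.05, 0.3, 0.15, 0.1, 0.5, 0.3, 0.01, NA)
  # all cSNPs fit exactly
  sel <- select_panel(cand[1:5, ], cats[1:5], fst[1:5], panel_size = 2)
  expect_equal(sel$marker_id, c("m1", "m2"))
  # one fst slot: the highest-Fst remaining marker wins
  sel <- select_panel(cand, cats, fst, panel_size = 3, homology_target = 2,
                      seed = 1)
  expect_equal(sel$marker_id[1:2], c("m1", "m2"))
  expect_equal(sel$marker_id[3], "m7")  # fst 0.5
  expect_equal(sel$subset, c("homology", "homology", "fst"))
  # determinism under a fixed seed
  s1 <- select_panel(cand, cats, fst, panel_size = 6, seed = 42)
  s2 <- select_panel(cand, cats, fst, panel_size = 6, seed = 42)
  expect_identical(s1, s2)
  # overflow: returns everything with a warning
  expect_warning(all10 <- select_panel(cand, cats, fst, panel_size = 50),
                 "exceeds")
  expect_equal(nrow(all10), 10L)
})

test_that("per-individual G2T genotypes recover planted genotypes", {
  cfg <- sim_config(seed = 51, n_genes = 4, error_rate = 0,
                    maf_range = c(0.3, 0.5), pop_freq_sd = 0)
  ref <- simulate_reference(cfg)
  reads <- simulate_reads(cfg, ref)
  sams <- emit_truth_sam(reads, ref)
  tr <- ref$truth$snps
  variants <- data.frame(contig = tr$contig_id, pos = tr$pos,
                         ref = tr$ref, alt = tr$alt)
  read_ind <- setNames(reads$gdna$individual, reads$gdna$id)
  gm <- genotypes_from_g2t(dedup_reads(sams$g2t), read_ind, variants,
                           ref$transcriptome)
  # compare with truth (alt-allele dose per individual)
  hap <- ref$truth$haplotypes
  n_ind <- cfg$n_individuals
  dose <- sapply(seq_len(n_ind), function(i) hap[, 2 * i - 1] + hap[, 2 * i])
  truth_calls <- matrix(c("AA", "AB", "BB")[dose + 1L], nrow = nrow(tr))
  # ~7.8x per individual before dedup: most sites callable at min_depth 4,
  # with occasional het-as-hom miscalls at depth 4-6 reads
  called <- !is.na(gm)
  expect_gt(mean(called), 0.7)
  expect_gt(mean(gm[called] == truth_calls[called]), 0.9)
})
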