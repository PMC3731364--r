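## End-to-end orchestration: simulate -> filter reference -> predict IEBs ->
## call SNPs -> design assays -> genotype & validate, plus the planted-truth
## benchmark used to calibrate and regression-test the whole pipeline.

#' Run the discovery pipeline on simulated data
#'
#' Generates a synthetic study from `config` and runs every discovery stage:
#' reference filtering (excess depth + multimap), IEB prediction, dual
#' evidence SNP calling, flank construction with similarity screening, and
#' per-marker preliminary Fst from per-individual G2T genotypes.
#'
#' @param config A [sim_config()].
#' @param alpha,min_support,collapse_window IEB detection parameters (see
#'   [detect_iebs()]).
#' @param policy A [snp_filter_policy()].
#' @param min_flank,core_halfwidth Flank rules (see [build_flank()]).
#' @param evalue_threshold Similarity-screen threshold.
#' @return A list with the simulation objects (`reference`, `reads`, `sams`),
#'   the `filter` report, `ieb` predictions, `snps` (per-side and common),
#'   `candidates` (assay table with screen results) and `genotypes_g2t`.
#' @export
run_pipeline <- function(config,
                         alpha = 1e-4, min_support = 3L, collapse_window = 3L,
                         policy = snp_filter_policy(),
                         min_flank = 30L, core_halfwidth = 5L,
                         evalue_threshold = 1e-25) {
  ref <- simulate_reference(config)
  reads <- simulate_reads(config, ref)
  sams <- emit_truth_sam(reads, ref)
  contigs <- ref$transcriptome

  filt <- filter_reference(sams$g2t, contigs)
  retained <- filt$retained
  g2t_kept <- sams$g2t[sams$g2t$rname %in% retained, , drop = FALSE]

  ieb <- predict_iebs(g2t_kept, contigs[retained], alpha = alpha,
                      min_support = min_support,
                      collapse_window = collapse_window)

  snps <- call_common_snps(sams$t2t, sams$g2t, contigs, policy = policy,
                           retained = retained)

  all_pos <- unique(rbind(snps$t2t[c("contig", "pos")],
                          snps$g2t[c("contig", "pos")]))
  candidates <- build_flanks(snps$common, contigs[retained], all_pos,
                             ieb$iebs, min_flank = min_flank,
                             core_halfwidth = core_halfwidth)
  if (nrow(candidates)) {
    sim_ok <- vapply(seq_len(nrow(candidates)), function(i)
      similarity_screen(candidates$flank_seq[i], candidates$contig[i],
                        contigs, evalue_threshold = evalue_threshold),
      logical(1))
    candidates$rejection_reason[candidates$accepted & !sim_ok] <- "similarity_hit"
    candidates$accepted <- candidates$accepted & sim_ok
    candidates$marker_id <- paste0(candidates$contig, ":", candidates$pos)
  }

  gm <- NULL
  if (nrow(snps$common)) {
    read_ind <- setNames(reads$gdna$individual, reads$gdna$id)
    gm <- genotypes_from_g2t(dedup_reads(sams$g2t), read_ind, snps$common,
                             contigs, hq = policy$hq)
  }

  list(config = config, reference = ref, reads = reads, sams = sams,
       filter = filt, ieb = ieb, snps = snps, candidates = candidates,
       genotypes_g2t = gm)
}

#' Benchmark the pipeline against planted truth
#'
#' Runs [run_pipeline()] and scores IEB prediction and SNP calling against
#' the simulator's truth table. An IEB prediction matches a true boundary
#' when within `tol` bases; sensitivity and precision are computed over
#' retained contigs only (contigs removed by the reference filter are out of
#' play by design). SNP sensitivity is the fraction of planted SNPs on
#' retained contigs recovered as common SNPs; FDR is the fraction of common
#' calls not matching a planted site. Multimap recall is the fraction of
#' truly duplicated contigs removed by the multimap filter.
#'
#' @param config A [sim_config()].
#' @param tol IEB position-match tolerance in bp (default 3, the collapse
#'   window).
#' @param ... Passed to [run_pipeline()].
#' @return A list of metrics plus the underlying pipeline result (`run`).
#' @export
run_planted_truth_benchmark <- function(config, tol = 3L, ...) {
  run <- run_pipeline(config, ...)
  truth <- run$reference$truth
  retained <- run$filter$retained

  true_iebs <- truth$iebs[truth$iebs$contig_id %in% retained, , drop = FALSE]
  pred_iebs <- run$ieb$iebs
  match_true <- logical(nrow(true_iebs))
  match_pred <- logical(nrow(pred_iebs))
  if (nrow(true_iebs) && nrow(pred_iebs)) {
    for (i in seq_len(nrow(true_iebs))) {
      same <- pred_iebs$contig_id == true_iebs$contig_id[i] &
        abs(pred_iebs$pos - true_iebs$pos[i]) <= tol
      if (any(same)) {
        match_true[i] <- TRUE
        match_pred[which(same)[1]] <- TRUE
      }
    }
    # predictions matching any true boundary count as correct
    for (j in seq_len(nrow(pred_iebs))) {
      if (!match_pred[j]) {
        match_pred[j] <- any(true_iebs$contig_id == pred_iebs$contig_id[j] &
                               abs(true_iebs$pos - pred_iebs$pos[j]) <= tol)
      }
    }
  }
  ieb_sens <- if (nrow(true_iebs)) mean(match_true) else NA_real_
  ieb_prec <- if (nrow(pred_iebs)) mean(match_pred) else NA_real_

  planted <- truth$snps[truth$snps$contig_id %in% retained, , drop = FALSE]
  # only planted sites that are actually polymorphic among the sequenced
  # individuals can be discovered
  if (nrow(planted)) {
    seen <- rowSums(truth$haplotypes) > 0
    planted <- planted[seen[match(planted$site_id, rownames(truth$haplotypes))], ,
                       drop = FALSE]
  }
  common <- run$snps$common
  key_p <- paste(planted$contig_id, planted$pos)
  key_c <- paste(common$contig, common$pos)
  snp_sens <- if (nrow(planted)) mean(key_p %in% key_c) else NA_real_
  snp_fdr <- if (nrow(common)) mean(!(key_c %in% key_p)) else NA_real_

  dup_contigs <- unique(truth$duplicated$contig_id)
  mm_recall <- if (length(dup_contigs))
    mean(dup_contigs %in% run$filter$removed_multimap) else NA_real_

  list(ieb_sensitivity = ieb_sens, ieb_precision = ieb_prec,
       n_true_iebs = nrow(true_iebs), n_pred_iebs = nrow(pred_iebs),
       snp_sensitivity = snp_sens, snp_fdr = snp_fdr,
       n_planted = nrow(planted), n_common = nrow(common),
       multimap_recall = mm_recall, run = run)
}
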