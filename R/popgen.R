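## Post-genotyping marker validation: class labels, conversion/validation
## rates, descriptive statistics, exact Hardy-Weinberg testing, linkage
## grouping and the independent-marker count.

MARKER_CLASSES <- c("no_signal", "disperse", "psv_msv", "monomorphic",
                    "polymorphic")

#' Classify a genotyped marker
#'
#' Precedence: no amplification at all gives `no_signal`; assigned fraction
#' below 0.80 gives `disperse`; heterozygote fraction among assigned at or
#' above 0.99 gives `psv_msv` (paralogous/multisite sequence variants
#' masquerading as SNPs); minor allele frequency below 0.01 gives
#' `monomorphic`; anything else is `polymorphic`. PSV/MSV is checked before
#' the MAF rule because an all-heterozygote column has MAF 0.5.
#'
#' @param calls Character vector of calls (`AA`/`AB`/`BB`, `NA` missing).
#' @return One class label.
#' @export
classify_marker <- function(calls) {
  stopifnot(length(calls) >= 1)
  assigned <- !is.na(calls)
  if (!any(assigned)) return("no_signal")
  if (mean(assigned) < 0.80) return("disperse")
  obs <- calls[assigned]
  if (mean(obs == "AB") >= 0.99) return("psv_msv")
  if (marker_stats(calls)$maf < 0.01) return("monomorphic")
  "polymorphic"
}

#' Panel conversion and validation rates
#'
#' Conversion rate: fraction of assayed markers that amplified and clustered
#' (everything but `no_signal` and `disperse`). Validation rate: fraction
#' that proved polymorphic. False-positive share: monomorphic plus PSV/MSV
#' markers (sequence artifacts that looked like SNPs).
#'
#' @param class_counts Named integer vector (or table) of class counts; any
#'   of the five class labels may be present.
#' @return List with `conversion_rate` and `validation_rate` (percentages,
#'   one decimal) and `false_positive_share` (percentage, two decimals).
#' @export
panel_rates <- function(class_counts) {
  cc <- setNames(rep(0L, length(MARKER_CLASSES)), MARKER_CLASSES)
  cc[names(class_counts)] <- as.integer(class_counts)
  n <- sum(cc)
  if (n == 0) stop("empty panel: no class counts")
  list(conversion_rate = round(100 * (n - cc["no_signal"] - cc["disperse"]) / n, 1)[[1]],
       validation_rate = round(100 * cc["polymorphic"] / n, 1)[[1]],
       false_positive_share =
         round(100 * (cc["monomorphic"] + cc["psv_msv"]) / n, 2)[[1]])
}

#' Descriptive statistics for one marker
#'
#' @param calls Genotype calls (`AA`/`AB`/`BB`, `NA` missing); at least one
#'   assigned call required.
#' @return List with `maf` (minor allele frequency), `he` (expected
#'   heterozygosity, `2p(1-p)`), `ho` (observed heterozygote fraction) and
#'   `call_rate`.
#' @export
marker_stats <- function(calls) {
  assigned <- !is.na(calls)
  if (!any(assigned)) stop("all calls missing: no statistics")
  obs <- calls[assigned]
  p_alt <- (2 * sum(obs == "BB") + sum(obs == "AB")) / (2 * length(obs))
  maf <- min(p_alt, 1 - p_alt)
  list(maf = maf, he = 2 * p_alt * (1 - p_alt), ho = mean(obs == "AB"),
       call_rate = mean(assigned))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' The exact conditional test on genotype counts: conditioning on the
#' observed allele counts, the probability of `nAB` heterozygotes is
#' \deqn{P(n_{AB}) = \frac{n!}{n_{AA}! n_{AB}! n_{BB}!} \cdot
#'   \frac{2^{n_{AB}} \, n_A! \, n_B!}{(2n)!}}{
#'   P(nAB) = n! / (nAA! nAB! nBB!) * 2^nAB * nA! nB! / (2n)!}
#' and the two-sided p-value sums the probabilities of all heterozygote
#' counts with the same allele counts whose probability does not exceed the
#' observed configuration's. Computed by the stable ratio recurrence from
#' the distribution's mode.
#'
#' @param n_AA,n_AB,n_BB Genotype counts.
#' @return Exact p-value in `[0, 1]` (1 for monomorphic columns).
#' @export
hwe_exact_test <- function(n_AA, n_AB, n_BB) {
  stopifnot(n_AA >= 0, n_AB >= 0, n_BB >= 0, n_AA + n_AB + n_BB > 0)
  nA <- 2L * n_AA + n_AB
  nB <- 2L * n_BB + n_AB
  if (nA == 0L || nB == 0L) return(1)
  rare <- min(nA, nB)
  # possible heterozygote counts share the parity of the rare allele count
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # unnormalized weights by ratio recurrence:
  # w(h+2)/w(h) = 4 * nAA(h) * nBB(h) / ((h+2)(h+1))
  w <- numeric(length(hets))
  w[1] <- 1
  if (length(hets) > 1) {
    for (k in seq_len(length(hets) - 1L)) {
      h <- hets[k]
      naa <- (nA - h) / 2; nbb <- (nB - h) / 2
      w[k + 1L] <- w[k] * 4 * naa * nbb / ((h + 2) * (h + 1))
    }
  }
  prob <- w / sum(w)
  obs <- match(n_AB, hets)
  if (is.na(obs)) stop("inconsistent genotype counts: impossible nAB parity")
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-12)]))
}

#' Group markers in linkage disequilibrium
#'
#' Tests every pair of polymorphic markers for genotypic association with
#' Fisher's exact test on the genotype contingency table (no phasing), joins
#' significant pairs by transitive closure, and reports group membership.
#' Significance is `alpha` Bonferroni-corrected over the number of tested
#' pairs by default.
#'
#' @param genotypes Character matrix (markers x individuals) of calls.
#' @param alpha Per-family significance level (default 0.05).
#' @param bonferroni Correct `alpha` over the number of pairs (default TRUE).
#' @return List with `groups` (data.frame `marker`, `group`),
#'   `n_linked` (markers in groups of size >= 2), `n_groups` (number of such
#'   groups) and `independent_count` = markers - (linked - groups).
#' @export
ld_groups <- function(genotypes, alpha = 0.05, bonferroni = TRUE) {
  m <- nrow(genotypes)
  stopifnot(m >= 1)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  pairs <- if (m >= 2) utils::combn(m, 2) else matrix(integer(0), 2, 0)
  testable <- logical(ncol(pairs))
  pvals <- rep(NA_real_, ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ok <- !is.na(genotypes[i, ]) & !is.na(genotypes[j, ])
    if (sum(ok) < 2) next
    gi <- factor(genotypes[i, ok], levels = c("AA", "AB", "BB"))
    gj <- factor(genotypes[j, ok], levels = c("AA", "AB", "BB"))
    tab <- table(droplevels(gi), droplevels(gj))
    if (nrow(tab) < 2 || ncol(tab) < 2) next
    testable[k] <- TRUE
    pvals[k] <- fisher.test(tab, workspace = 2e7)$p.value
  }
  thr <- if (bonferroni && any(testable)) alpha / sum(testable) else alpha
  sig <- which(testable & pvals < thr)
  for (k in sig) {
    ri <- find(pairs[1, k]); rj <- find(pairs[2, k])
    if (ri != rj) parent[rj] <- ri
  }
  root <- vapply(seq_len(m), find, integer(1))
  grp <- match(root, unique(root))
  sizes <- table(grp)
  linked_groups <- as.integer(names(sizes)[sizes >= 2])
  n_linked <- sum(grp %in% linked_groups)
  n_groups <- length(linked_groups)
  list(groups = data.frame(marker = rownames(genotypes) %||% seq_len(m),
                           group = grp),
       n_linked = n_linked, n_groups = n_groups,
       independent_count = m - (n_linked - n_groups))
}

#' Independent-marker arithmetic
#'
#' Starting from the polymorphic markers, removes those deviating from HWE
#' and collapses linked markers to one representative per LD group:
#' `n_polymorphic - n_hwe_fail - (n_linked - n_groups)`.
#'
#' @param n_polymorphic Polymorphic marker count.
#' @param n_hwe_fail Markers failing HWE.
#' @param n_linked Markers (HWE-passing) found in LD.
#' @param n_groups LD groups (haplotypes) they collapse into.
#' @return Independent marker count.
#' @export
independent_marker_count <- function(n_polymorphic, n_hwe_fail, n_linked,
                                     n_groups) {
  n_polymorphic - n_hwe_fail - (n_linked - n_groups)
}

#' Full validation summary for a genotyped panel
#'
#' Classifies every marker, computes per-marker statistics, tests HWE per
#' population (exact test; a marker fails when its smallest per-population
#' p-value is below `hwe_alpha`), groups HWE-passing polymorphic markers by
#' linkage, computes Weir-Cockerham Fst, and reports panel rates and the
#' independent-marker count.
#'
#' @param genotypes Character matrix (markers x individuals).
#' @param pops Population label per individual (column).
#' @param hwe_alpha HWE significance threshold (default 0.001).
#' @param ld_alpha Passed to [ld_groups()].
#' @return List with `markers` (per-marker data.frame: class, call_rate,
#'   maf, he, ho, hwe_p, hwe_fail, ld_group, fst), `rates` (from
#'   [panel_rates()]), `class_counts`, `n_hwe_fail`, `ld` and
#'   `independent_count`.
#' @export
popgen_summary <- function(genotypes, pops, hwe_alpha = 0.001,
                           ld_alpha = 0.05) {
  stopifnot(ncol(genotypes) == length(pops))
  m <- nrow(genotypes)
  cls <- character(m); maf <- he <- ho <- cr <- hwe_p <- fst <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    calls <- genotypes[i, ]
    cls[i] <- classify_marker(calls)
    if (all(is.na(calls))) next
    st <- marker_stats(calls)
    maf[i] <- st$maf; he[i] <- st$he; ho[i] <- st$ho; cr[i] <- st$call_rate
    if (cls[i] == "polymorphic") {
      pp <- vapply(unique(pops), function(p) {
        cc <- calls[pops == p]
        hwe_exact_test(sum(cc == "AA", na.rm = TRUE),
                       sum(cc == "AB", na.rm = TRUE),
                       sum(cc == "BB", na.rm = TRUE))
      }, numeric(1))
      hwe_p[i] <- min(pp)
      fst[i] <- tryCatch(wc_fst(calls, pops), error = function(e) NA_real_)
    }
  }
  hwe_fail <- !is.na(hwe_p) & hwe_p < hwe_alpha
  poly_ok <- which(cls == "polymorphic" & !hwe_fail)
  ld <- if (length(poly_ok) >= 2)
    ld_groups(genotypes[poly_ok, , drop = FALSE], alpha = ld_alpha)
  else list(groups = NULL, n_linked = 0L, n_groups = 0L,
            independent_count = length(poly_ok))
  ld_group <- rep(NA_integer_, m)
  if (!is.null(ld$groups)) ld_group[poly_ok] <- ld$groups$group
  markers <- data.frame(
    marker_id = rownames(genotypes) %||% seq_len(m), class = cls,
    call_rate = cr, maf = maf, he = he, ho = ho, hwe_p = hwe_p,
    hwe_fail = hwe_fail, ld_group = ld_group, fst = fst, row.names = NULL)
  class_counts <- table(factor(cls, levels = MARKER_CLASSES))
  list(markers = markers, rates = panel_rates(class_counts),
       class_counts = class_counts,
       n_hwe_fail = sum(hwe_fail),
       ld = ld,
       independent_count = independent_marker_count(
         sum(cls == "polymorphic"), sum(hwe_fail), ld$n_linked, ld$n_groups))
}
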