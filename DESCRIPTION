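Package: dualsnp
Title: Dual-Evidence Exome SNP Discovery and Validation for Non-Model Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and in-silico validation of genotypable exonic SNPs in
    species without a reference genome, by combining transcriptome-to-transcriptome
    (T2T) and genome-to-transcriptome (G2T) read alignment evidence. Implements
    intron-exon boundary (IEB) prediction from change points in local alignments,
    duplicated-region filtering via multimapped reads, a dual-evidence SNP filter
    cascade with high-quality base depth/count thresholds, genotyping-assay flank
    construction with variant masking and a built-in similarity screen,
    post-genotyping marker validation statistics (exact Hardy-Weinberg test,
    Weir-Cockerham Fst, linkage-disequilibrium grouping), and a perfect
    microsatellite scanner. A deterministic simulator generates toy genomes with
    gene models, planted SNPs, duplicated contigs and reads with truth-placement
    alignments so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
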