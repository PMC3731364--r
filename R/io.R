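#' @importFrom stats median mad pbinom dbinom rbinom rpois rnorm runif setNames
#'   fisher.test uniroot
#' @importFrom utils write.table head tail
NULL

# Internal: evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

## ---- high-quality base policy -----------------------------------------------

#' High-quality base policy
#'
#' Defines the Phred threshold above which a base call counts as high quality
#' (HQ). The default, `min_phred = 21`, keeps bases with Phred score strictly
#' greater than 20, the conventional Q20 cutoff for "HQ bases" in
#' transcriptome SNP discovery.
#'
#' @param min_phred Minimum Phred score (inclusive) for a base to count as HQ.
#' @return An object of class `hq_policy`.
#' @export
#' @examples
#' hq_base_count(c(20L, 21L, 30L), hq_policy())  # 2
hq_policy <- function(min_phred = 21L) {
  min_phred <- as.integer(min_phred)
  stopifnot(min_phred >= 0L, min_phred <= 93L)
  structure(list(min_phred = min_phred), class = "hq_policy")
}

#' Count high-quality bases
#'
#' @param base_quals Integer vector of Phred qualities (0-93).
#' @param policy An [hq_policy()].
#' @return Number of bases meeting the policy.
#' @export
hq_base_count <- function(base_quals, policy = hq_policy()) {
  if (length(base_quals) == 0) return(0L)
  stopifnot(all(base_quals >= 0 & base_quals <= 93))
  sum(base_quals >= policy$min_phred)
}

#' Convert a Phred+33 quality string to integer scores
#' @param qual Character vector of quality strings.
#' @return For length-1 input an integer vector; otherwise a list of them.
#' @export
phred_scores <- function(qual) {
  out <- lapply(qual, function(q) utf8ToInt(q) - 33L)
  if (length(out) == 1L) out[[1]] else out
}

## ---- CIGAR ------------------------------------------------------------------

CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
CIGAR_QUERY <- c("M", "I", "S", "=", "X")   # ops consuming query bases
CIGAR_REF   <- c("M", "D", "N", "=", "X")   # ops consuming reference bases

#' Parse a SAM CIGAR string
#'
#' @param cigar A single CIGAR string; `"*"` denotes an unmapped record.
#' @return A data.frame with columns `op` (character) and `len` (integer),
#'   one row per CIGAR segment, in order. `"*"` yields zero rows.
#' @export
#' @examples
#' parse_cigar("5S60M35S")
parse_cigar <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1L)
  if (cigar == "*") return(data.frame(op = character(), len = integer()))
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1]]
  if (nchar(paste(toks, collapse = "")) != nchar(cigar))
    stop("malformed CIGAR string: '", cigar, "'")
  op <- substr(toks, nchar(toks), nchar(toks))
  bad <- setdiff(op, CIGAR_OPS)
  if (length(bad))
    stop("malformed CIGAR token: unknown op '", bad[1], "' in '", cigar, "'")
  data.frame(op = op, len = as.integer(substr(toks, 1L, nchar(toks) - 1L)))
}

#' Query length implied by a CIGAR string (soft clips included, hard clips not)
#' @param cigar CIGAR string.
#' @return Integer number of query bases.
#' @export
cigar_query_length <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% CIGAR_QUERY])
}

#' Reference span of a CIGAR string
#' @param cigar CIGAR string.
#' @return Integer number of reference bases consumed.
#' @export
cigar_ref_span <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% CIGAR_REF])
}

# Vectorized CIGAR op table across many alignments. Returns a data.frame with
# one row per op: row (alignment index), op, len, qstart, rstart (0-based
# offsets of the op within query and reference).
cigar_op_table <- function(cigar) {
  m <- gregexpr("[0-9]+[A-Z=]", cigar)
  toks <- regmatches(cigar, m)
  toks[cigar == "*"] <- list(character())
  n_ops <- lengths(toks)
  row <- rep.int(seq_along(cigar), n_ops)
  tk <- unlist(toks, use.names = FALSE)
  if (!length(tk))
    return(data.frame(row = integer(), op = character(), len = integer(),
                      qoff = integer(), roff = integer()))
  op <- substr(tk, nchar(tk), nchar(tk))
  len <- as.integer(substr(tk, 1L, nchar(tk) - 1L))
  qlen <- ifelse(op %in% CIGAR_QUERY, len, 0L)
  rlen <- ifelse(op %in% CIGAR_REF, len, 0L)
  # per-row cumulative offsets via global cumsum minus each row's base
  per_row_offset <- function(x) {
    cx <- cumsum(x) - x
    first <- !duplicated(row)
    cx - rep.int(cx[first], n_ops[n_ops > 0L])
  }
  data.frame(row = row, op = op, len = len,
             qoff = per_row_offset(qlen), roff = per_row_offset(rlen))
}

## ---- FASTA / FASTQ ----------------------------------------------------------

#' Read a FASTA file into a named character vector
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = width)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#' @param path Path to FASTQ.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"))
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             row.names = NULL)
}

#' Write reads to FASTQ (Phred+33)
#' @param reads data.frame with `id`, `seq`, `qual` columns.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)),
            all(nchar(reads$seq) == nchar(reads$qual)))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

## ---- SAM --------------------------------------------------------------------

#' Read a SAM file
#'
#' Parses a headerful SAM text file into an alignment table. Coordinates are
#' converted to 0-based at this boundary. Soft clips retain their bases and
#' qualities; the secondary-alignment bit (0x100) is exposed as a column.
#'
#' @param path Path to a SAM file.
#' @return A list with `contigs` (named integer vector of `@SQ` lengths) and
#'   `alignments`, a data.frame with columns `qname`, `flag`, `rname`, `pos`
#'   (0-based leftmost reference position), `mapq`, `cigar`, `seq`, `qual`,
#'   and the derived logicals `secondary` and `reverse`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  contigs <- integer(0)
  if (length(sq)) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    contigs <- setNames(ln, sn)
  }
  if (!length(body))
    return(list(contigs = contigs, alignments = empty_alignments()))
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L))
    stop("malformed SAM record at line ", which(nf < 11L)[1] + length(hdr))
  g <- function(i) vapply(f, `[[`, character(1), i)
  aln <- data.frame(
    qname = g(1), flag = as.integer(g(2)), rname = g(3),
    pos = as.integer(g(4)) - 1L, mapq = as.integer(g(5)), cigar = g(6),
    seq = g(10), qual = g(11), row.names = NULL)
  aln$secondary <- bitwAnd(aln$flag, 256L) > 0L
  aln$reverse <- bitwAnd(aln$flag, 16L) > 0L
  list(contigs = contigs, alignments = aln)
}

empty_alignments <- function() {
  data.frame(qname = character(), flag = integer(), rname = character(),
             pos = integer(), mapq = integer(), cigar = character(),
             seq = character(), qual = character(),
             secondary = logical(), reverse = logical())
}

#' Write alignments to SAM
#' @param alignments Alignment data.frame as produced by [read_sam()] (0-based
#'   `pos`; converted to 1-based on output).
#' @param contigs Named character vector of reference sequences, or a named
#'   integer vector of lengths, for the `@SQ` header.
#' @param path Output path.
#' @export
write_sam <- function(alignments, contigs, path) {
  lens <- if (is.character(contigs)) nchar(contigs) else as.integer(contigs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  if (length(contigs))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), lens), con)
  if (nrow(alignments)) {
    writeLines(paste(alignments$qname, alignments$flag, alignments$rname,
                     alignments$pos + 1L, alignments$mapq, alignments$cigar,
                     "*", 0L, 0L, alignments$seq, alignments$qual,
                     sep = "\t"), con)
  }
  invisible(path)
}

## ---- VCF --------------------------------------------------------------------

#' Write biallelic SNV calls to VCF 4.2
#'
#' One record per variant; 0-based positions are converted to 1-based. INFO
#' carries `DP` (HQ site depth), `AD` (ref,alt HQ counts) and `SRC`
#' (evidence source: T2T, G2T or both).
#'
#' @param variants Variant table with columns `contig`, `pos` (0-based),
#'   `ref`, `alt`, `hq_depth`, `alt_hq_count`, `source`.
#' @param contigs Named character (or integer length) vector for `##contig`
#'   header lines.
#' @param path Output path.
#' @export
write_vcf_snps <- function(variants, contigs, path) {
  lens <- if (is.character(contigs)) nchar(contigs) else as.integer(contigs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=dualsnp",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), lens),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"HQ site depth\">",
    "##INFO=<ID=AD,Number=R,Type=Integer,Description=\"HQ allelic depths (ref,alt)\">",
    "##INFO=<ID=SRC,Number=1,Type=String,Description=\"Evidence source (T2T/G2T/both)\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    info <- sprintf("DP=%d;AD=%d,%d;SRC=%s", variants$hq_depth,
                    variants$hq_depth - variants$alt_hq_count,
                    variants$alt_hq_count, variants$source)
    writeLines(paste(variants$contig, variants$pos + 1L, ".", variants$ref,
                     variants$alt, ".", "PASS", info, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a dualsnp VCF back into a variant table
#' @param path Path to a VCF written by [write_vcf_snps()].
#' @return Variant data.frame with 0-based `pos`.
#' @export
read_vcf_snps <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(data.frame(contig = character(), pos = integer(), ref = character(),
                      alt = character(), hq_depth = integer(),
                      alt_hq_count = integer(), source = character()))
  f <- strsplit(body, "\t", fixed = TRUE)
  g <- function(i) vapply(f, `[[`, character(1), i)
  info <- g(8)
  pick <- function(key) sub(paste0(".*", key, "=([^;]*).*"), "\\1", info)
  ad <- strsplit(pick("AD"), ",", fixed = TRUE)
  data.frame(
    contig = g(1), pos = as.integer(g(2)) - 1L, ref = g(4), alt = g(5),
    hq_depth = as.integer(pick("DP")),
    alt_hq_count = as.integer(vapply(ad, `[[`, character(1), 2)),
    source = pick("SRC"), row.names = NULL)
}

## ---- genotype matrices ------------------------------------------------------

MISSING_TOKENS <- c("NA", "", "--", "-", "NN", "./.", ".", "00", "?")

#' Read a genotype-call matrix
#'
#' Reads a rectangular delimited file with a header row of individual ids and
#' marker ids in the first column. Every cell is normalized to one of the
#' call states `AA`, `AB`, `BB` or `NA` (missing). Accepted spellings:
#'
#' * the canonical tokens `AA`, `AB` (or `BA`), `BB`;
#' * missing aliases `NA`, `""`, `--`, `-`, `NN`, `./.`, `.`, `00`, `?`;
#' * allele-letter pairs such as `AG` for an A/G marker, when the marker's
#'   two alleles are supplied via `alleles` (a data.frame with columns
#'   `marker`, `a`, `b`).
#'
#' @param path Path to a TSV file.
#' @param alleles Optional per-marker allele letters for normalizing
#'   allele-letter genotype spellings.
#' @param sep Field separator.
#' @return Character matrix (markers x individuals) of normalized calls with
#'   `NA` for missing.
#' @export
read_genotype_matrix <- function(path, alleles = NULL, sep = "\t") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(f)
  if (length(unique(nf)) != 1L)
    stop("ragged genotype matrix: row ", which(nf != nf[1])[1], " has ",
         nf[which(nf != nf[1])[1]], " fields, expected ", nf[1])
  header <- f[[1]][-1]
  markers <- vapply(f[-1], `[[`, character(1), 1)
  cells <- do.call(rbind, lapply(f[-1], function(x) x[-1]))
  out <- matrix(NA_character_, nrow = length(markers), ncol = length(header),
                dimnames = list(markers, header))
  for (i in seq_along(markers)) {
    ab <- NULL
    if (!is.null(alleles)) {
      j <- match(markers[i], alleles$marker)
      if (!is.na(j)) ab <- c(alleles$a[j], alleles$b[j])
    }
    out[i, ] <- vapply(cells[i, ], normalize_call, character(1), ab = ab)
  }
  out
}

normalize_call <- function(token, ab = NULL) {
  tok <- toupper(trimws(token))
  if (tok %in% MISSING_TOKENS) return(NA_character_)
  if (!is.null(ab) && nchar(tok) == 2L) {
    a <- toupper(ab[1]); b <- toupper(ab[2])
    x <- strsplit(tok, "")[[1]]
    if (all(x == a)) return("AA")
    if (all(x == b)) return("BB")
    if (setequal(x, c(a, b)) && x[1] != x[2]) return("AB")
  }
  if (tok %in% c("AA", "AB", "BA", "BB"))
    return(if (tok == "BA") "AB" else tok)
  stop("unknown genotype token '", token, "'")
}

#' Write a genotype matrix to TSV
#' @param genotypes Character matrix of calls (markers x individuals).
#' @param path Output path.
#' @export
write_genotype_matrix <- function(genotypes, path) {
  df <- data.frame(marker = rownames(genotypes), genotypes,
                   check.names = FALSE, row.names = NULL)
  df[is.na(df)] <- "NA"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
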