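#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences (or a `ref_sample_pair`,
#'   whose reference and both chromosomes are written).
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
write_fasta <- function(seqs, file) {
  if (inherits(seqs, "ref_sample_pair"))
    seqs <- c(reference = seqs$reference, chromosome1 = seqs$chromosome1,
              chromosome2 = seqs$chromosome2)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = file, width = 60L)
  invisible(file)
}

#' Read sequences from FASTA
#'
#' @param file FASTA path.
#' @return Named character vector.
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  setNames(as.character(x), names(x))
}

#' Write a read pool to FASTQ
#'
#' Read IDs encode the source chromosome, 0-based footprint start and strand
#' (`read<i>:chr<c>:<start>:<strand>`) so downstream diagnostics can recover
#' each read's origin. Base qualities are constant.
#'
#' @param pool A `read_pool` data.frame.
#' @param file Output path.
#' @param base_qual Constant Phred quality (default 35).
#' @return Invisibly, the file path.
#' @export
write_fastq <- function(pool, file, base_qual = 35L) {
  qc <- rawToChar(as.raw(33L + base_qual))
  ids <- sprintf("@read%d:chr%d:%d:%s", seq_len(nrow(pool)), pool$chrom,
                 pool$start, pool$strand)
  qual <- vapply(pool$len, function(l) strrep(qc, l), character(1))
  writeLines(as.vector(rbind(ids, pool$seq, "+", qual)), file)
  invisible(file)
}

#' Write mapped reads as SAM
#'
#' Minimal single-contig SAM: header plus one alignment line per mapped
#' read; unmapped reads get flag 4. Reverse-strand reads are written
#' reverse-complemented, as sequenced data would be.
#'
#' @param mapped Mapping table from [map_reads()] (with `seq`).
#' @param ref_name Contig name (default "ref").
#' @param ref_len Contig length.
#' @param file Output path.
#' @param base_qual Constant Phred quality for the QUAL field.
#' @return Invisibly, the file path.
#' @export
write_sam <- function(mapped, ref_name = "ref", ref_len, file,
                      base_qual = 35L) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", ref_name, as.integer(ref_len))),
             con)
  qc <- rawToChar(as.raw(33L + base_qual))
  revcomp <- function(s) {
    chartr("ACGT", "TGCA",
           vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]),
                                       collapse = ""), character(1),
                  USE.NAMES = FALSE))
  }
  seq_out <- mapped$seq
  minus <- !is.na(mapped$strand) & mapped$strand == "-"
  if (any(minus)) seq_out[minus] <- revcomp(mapped$seq[minus])
  flag <- ifelse(!mapped$mapped, 4L, ifelse(minus, 16L, 0L))
  lines <- sprintf("read%d\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                   seq_len(nrow(mapped)), flag,
                   ifelse(mapped$mapped, ref_name, "*"),
                   ifelse(mapped$mapped, mapped$pos + 1L, 0L),
                   ifelse(mapped$mapped, mapped$mapq, 0L),
                   ifelse(mapped$mapped, mapped$cigar, "*"),
                   seq_out,
                   vapply(nchar(mapped$seq), function(l) strrep(qc, l),
                          character(1)))
  writeLines(lines, con)
  invisible(file)
}

vcf_header <- function(ref_name, ref_len) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", ref_name, as.integer(ref_len)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "sample", sep = "\t"))
}

#' Write variant records to VCF v4.2
#'
#' Works for both truth catalogs and call tables: any data.frame with
#' `ref_pos` (0-based; indels anchored at the base before the event),
#' `kind`, `ref_allele`, `alt_allele` and `genotype`. Heterozygous records
#' get GT 0/1, homozygous 1/1.
#'
#' @param records Variant data.frame.
#' @param ref_name Contig name.
#' @param ref_len Contig length.
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
write_vcf <- function(records, ref_name = "ref", ref_len, file) {
  qual <- if ("qual" %in% names(records)) sprintf("%.2f", records$qual)
          else rep(".", nrow(records))
  info <- if ("depth" %in% names(records)) sprintf("DP=%d", records$depth)
          else rep(".", nrow(records))
  lines <- sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\t%s\tGT\t%s", ref_name,
                   records$ref_pos + 1L, records$ref_allele,
                   records$alt_allele, qual, info,
                   ifelse(records$genotype == "hom", "1/1", "0/1"))
  writeLines(c(vcf_header(ref_name, ref_len), lines), file)
  invisible(file)
}

#' Export the truth catalog as a VCF restricted to the evaluation window
#'
#' @param pair A `ref_sample_pair`.
#' @param edge_margin Flank exclusion in bp; only variants with 1-based
#'   position in `[edge_margin, length - edge_margin]` are written.
#' @param file Output path.
#' @param ref_name Contig name.
#' @return Invisibly, the file path.
#' @export
export_truth <- function(pair, edge_margin = 500L, file, ref_name = "ref") {
  L <- nchar(pair$reference)
  truth <- truth_in_window(pair$truth, L, edge_margin)
  write_vcf(truth, ref_name = ref_name, ref_len = L, file = file)
}

#' Write a read pool's damage ledger as a JSON sidecar
#'
#' Records the injected-damage bookkeeping of a pool for downstream
#' validation: per-offset misincorporation opportunity and event counts
#' for both read ends, and, when the pool was generated with
#' `keep_edits = TRUE`, the 1-based flipped positions of every read.
#'
#' @param pool A `read_pool` with a `damage_ledger` attribute.
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
write_damage_ledger <- function(pool, file) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("the 'jsonlite' package is required")
  ledger <- attr(pool, "damage_ledger")
  if (is.null(ledger)) stop("pool carries no damage ledger")
  payload <- list(n_reads = nrow(pool), opp5 = ledger$opp5,
                  flip5 = ledger$flip5, opp3 = ledger$opp3,
                  flip3 = ledger$flip3)
  edits <- attr(pool, "damage_edits")
  if (!is.null(edits)) payload$edits <- edits
  jsonlite::write_json(payload, file, auto_unbox = TRUE)
  invisible(file)
}

#' Read a VCF written by this package
#'
#' Lightweight parser for single-sample VCFs with GT: returns the variant
#' table in the package's internal convention (0-based `ref_pos`, `kind`
#' inferred from allele lengths).
#'
#' @param file VCF path.
#' @return Variant data.frame.
#' @export
read_vcf <- function(file) {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(ref_pos = integer(0), kind = character(0),
                      ref_allele = character(0), alt_allele = character(0),
                      genotype = character(0), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  pos <- vapply(f, function(x) as.integer(x[2]), integer(1))
  ref <- vapply(f, `[`, character(1), 4)
  alt <- vapply(f, `[`, character(1), 5)
  gt <- vapply(f, function(x) x[10], character(1))
  qual <- suppressWarnings(vapply(f, function(x) as.numeric(x[6]),
                                  numeric(1)))
  kind <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "snp",
                 ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
  out <- data.frame(ref_pos = pos - 1L, kind = kind, ref_allele = ref,
                    alt_allele = alt,
                    genotype = ifelse(startsWith(gt, "1/1"), "hom", "het"),
                    stringsAsFactors = FALSE)
  if (!all(is.na(qual))) out$qual <- qual
  out
}
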