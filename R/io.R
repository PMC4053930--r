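#' Read and write FASTA
#'
#' Thin tibble wrappers around Biostrings. Gzip is handled transparently.
#'
#' @param path File path.
#' @return `read_fasta()` returns a tibble with columns `name` and `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(name = names(x), seq = unname(as.character(x)))
}

#' @rdname read_fasta
#' @param x Tibble with `name` and `seq` columns, or a named character
#'   vector.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- tibble(name = names(x), seq = unname(x))
  dss <- Biostrings::DNAStringSet(setNames(x$seq, x$name))
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read and write FASTQ (Phred+33)
#'
#' @param path File path (`.gz` supported).
#' @return `read_fastq()` returns a tibble with `name`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # structural pre-scan of the 4-line dialect: truncated files and
  # sequence/quality length mismatches fail with the offending record
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4 != 0)
    abort(sprintf("truncated FASTQ: %d lines is not a multiple of 4",
                  length(lines)))
  sq <- lines[seq(2, length(lines), by = 4)]
  ql <- lines[seq(4, length(lines), by = 4)]
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad) > 0)
    abort(sprintf("FASTQ record %d: quality length %d != sequence length %d",
                  bad[1], nchar(ql[bad[1]]), nchar(sq[bad[1]])))
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble(name = names(x), seq = unname(as.character(x)),
         qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' @rdname read_fastq
#' @param x Tibble with `name`, `seq` and `qual` columns.
#' @export
write_fastq <- function(x, path) {
  dss <- Biostrings::DNAStringSet(setNames(x$seq, x$name))
  Biostrings::writeXStringSet(dss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(x$qual))
  invisible(path)
}

#' Write simulated read pairs as a FASTQ file pair
#'
#' @param pairs A [simulate_reads()] tibble.
#' @param prefix Output prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @param gz Compress with gzip.
#' @return The two paths, invisibly.
#' @export
write_read_pairs <- function(pairs, prefix, gz = FALSE) {
  ext <- if (gz) ".fastq.gz" else ".fastq"
  p1 <- paste0(prefix, "_1", ext)
  p2 <- paste0(prefix, "_2", ext)
  write_fastq(tibble(name = paste0(pairs$name, "/1"), seq = pairs$read1,
                     qual = pairs$qual1), p1)
  write_fastq(tibble(name = paste0(pairs$name, "/2"), seq = pairs$read2,
                     qual = pairs$qual2), p2)
  invisible(c(p1, p2))
}

#' Minimal SAM reader and writer
#'
#' Supports the dialect this package emits: `@HD`/`@SQ` header lines, the 11
#' mandatory columns, and ungapped or M/I/D CIGARs. Positions are 1-based in
#' the file (SAM convention) and in the returned tibble.
#'
#' @param path File path.
#' @return `read_sam()` returns a list with `header` (tibble: name, length)
#'   and `alignments` (tibble of the 11 mandatory columns).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  aln <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  header <- tibble(
    name = stringr::str_match(sq, "SN:([^\t]+)")[, 2],
    length = as.integer(stringr::str_match(sq, "LN:([^\t]+)")[, 2]))
  if (length(aln) == 0) {
    alignments <- tibble(qname = character(), flag = integer(),
                         rname = character(), pos = integer(),
                         mapq = integer(), cigar = character(),
                         rnext = character(), pnext = integer(),
                         tlen = integer(), seq = character(),
                         qual = character())
    return(list(header = header, alignments = alignments))
  }
  f <- strsplit(aln, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11))
    abort(paste0("malformed SAM record at line ",
                 which(nf < 11)[1] + length(hdr)))
  g <- function(i) vapply(f, `[[`, character(1), i)
  list(header = header,
       alignments = tibble(
         qname = g(1), flag = as.integer(g(2)), rname = g(3),
         pos = as.integer(g(4)), mapq = as.integer(g(5)), cigar = g(6),
         rnext = g(7), pnext = as.integer(g(8)), tlen = as.integer(g(9)),
         seq = g(10), qual = g(11)))
}

#' @rdname read_sam
#' @param alignments Tibble with the 11 mandatory SAM columns (as returned
#'   in `read_sam()$alignments`).
#' @param header Tibble with `name` and `length` for `@SQ` lines.
#' @export
write_sam <- function(alignments, header, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", header$name, header$length), con)
  if (nrow(alignments) > 0) {
    writeLines(do.call(paste, c(lapply(alignments, as.character),
                                sep = "\t")), con)
  }
  invisible(path)
}

#' Write SNV/SNP calls as minimal VCF 4.2
#'
#' Emits CHROM, POS (1-based), REF, ALT (comma-separated for multi-allelic
#' records) and INFO `DP`/`AD`.
#'
#' @param sites Tibble with `scaffold`, `pos`, `ref`, and either `alt` plus
#'   `depth`/`ad` columns or an `alleles` list-column of tibbles
#'   (base, count).
#' @param header Tibble with `name` and `length` of the reference sequences.
#' @param path Output path.
#' @export
write_vcf <- function(sites, header, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", header$name,
                       header$length),
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
               "##INFO=<ID=AD,Number=.,Type=Integer,Description=\"Allele depths (ref first)\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(sites) > 0) {
    if ("alleles" %in% names(sites)) {
      alt <- purrr::map2_chr(sites$alleles, sites$ref, function(a, r)
        paste(setdiff(a$base, r), collapse = ","))
      ad <- purrr::map2_chr(sites$alleles, sites$ref, function(a, r) {
        a <- a[order(a$base != r, a$base), ]
        paste(a$count, collapse = ",")
      })
    } else {
      alt <- sites$alt
      ad <- sites$ad
    }
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AD=%s",
                       sites$scaffold, sites$pos, sites$ref, alt,
                       sites$depth, ad), con)
  }
  invisible(path)
}

#' Read GFF3 gene models
#'
#' Parses GFF3 via rtracklayer and returns the features as a tibble with
#' 1-based inclusive coordinates (converted internally to half-open where
#' interval arithmetic needs it).
#'
#' @param path GFF3 file path.
#' @return Tibble with `seqid`, `source`, `type`, `start`, `end`, `strand`,
#'   `ID`, `Parent`.
#' @export
read_gff3 <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  parent <- S4Vectors::mcols(g)$Parent
  tibble(seqid = as.character(GenomicRanges::seqnames(g)),
         source = as.character(S4Vectors::mcols(g)$source),
         type = as.character(S4Vectors::mcols(g)$type),
         start = GenomicRanges::start(g), end = GenomicRanges::end(g),
         strand = as.character(GenomicRanges::strand(g)),
         ID = as.character(S4Vectors::mcols(g)$ID %||% NA_character_),
         Parent = if (is.null(parent)) NA_character_ else
           vapply(as.list(parent), function(p)
             if (length(p)) p[[1]] else NA_character_, character(1)))
}
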