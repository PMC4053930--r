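#' Map reads to an assembly
#'
#' Deliberately minimal seed-and-extend mapper: exact seed index on the
#' assembly, ungapped extension over the full read, best hit by match
#' count, ties mapped nowhere. Alignments must pass the similarity and
#' aligned-length-fraction filters (the conventional 0.9 / 0.5 mapping
#' filters) to be reported. Real-data users can supply external SAM
#' instead; mapping here is plumbing, not the method.
#'
#' @param reads Character vector of read sequences, or a tibble with `seq`
#'   (and optionally `name`, `qual`) columns.
#' @param assembly Tibble with `id`/`name` and `sequence`/`seq` columns, or
#'   a named character vector of scaffold sequences.
#' @param seed_length Exact seed length for the index (default 21).
#' @param min_similarity Minimum matches / aligned-length (default 0.9).
#' @param min_length_fraction Minimum aligned-length / read-length
#'   (default 0.5).
#' @param max_seed_hits Seeds occurring more often than this in the
#'   assembly are skipped as repeats.
#' @return Tibble: `name`, `mapped`, `scaffold`, `pos` (1-based leftmost
#'   aligned base), `strand`, `matches`, `aligned_len`, `nm`, and `seq`/
#'   `qual` oriented to the reference strand.
#' @export
map_reads <- function(reads, assembly, seed_length = 21,
                      min_similarity = 0.9, min_length_fraction = 0.5,
                      max_seed_hits = 100) {
  asm <- as_assembly(assembly)
  if (nrow(asm) == 0 || sum(nchar(asm$sequence)) == 0)
    abort("empty assembly")
  if (is.character(reads)) reads <- tibble(seq = reads)
  if (!"name" %in% names(reads))
    reads$name <- sprintf("read%06d", seq_len(nrow(reads)))
  if (!"qual" %in% names(reads)) reads$qual <- NA_character_
  hit <- cpp_map_reads(reads$seq, asm$sequence, as.integer(seed_length),
                       min_similarity, min_length_fraction,
                       as.integer(max_seed_hits))
  minus <- !is.na(hit$strand) & hit$strand == "-"
  oseq <- reads$seq
  oseq[minus] <- revcomp(oseq[minus])
  oqual <- reads$qual
  oqual[minus & !is.na(oqual)] <- stringi_rev(oqual[minus & !is.na(oqual)])
  tibble(name = reads$name, mapped = hit$mapped,
         scaffold = asm$id[hit$ref], pos = hit$pos + 1L,
         read_start0 = hit$start,
         strand = hit$strand, matches = hit$matches,
         aligned_len = hit$aligned_len, nm = hit$nm,
         seq = ifelse(hit$mapped, oseq, NA_character_),
         qual = ifelse(hit$mapped, oqual, NA_character_))
}

stringi_rev <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# normalise assembly input to tibble(id, sequence); FASTA convention: the
# id is the first whitespace-delimited token of the header
as_assembly <- function(assembly) {
  if (is.character(assembly)) {
    ids <- names(assembly) %||% sprintf("seq%04d", seq_along(assembly))
    return(tibble(id = sub("\\s.*$", "", ids), sequence = unname(assembly)))
  }
  nm <- names(assembly)
  id <- if ("id" %in% nm) assembly$id else assembly$name
  sq <- if ("sequence" %in% nm) assembly$sequence else assembly$seq
  tibble(id = sub("\\s.*$", "", id), sequence = sq)
}

#' Map simulated read pairs and classify pair orientation
#'
#' Maps both mates with [map_reads()] and derives the implied pair
#' orientation deterministically from the strand/position configuration:
#' for mates on one scaffold, `forward_reverse` when the leftmost mate is
#' on the plus strand and the other on minus, `reverse_forward` for the
#' converse, `other` for same-strand configurations; mates on two different
#' scaffolds are `cross_contig` (their FR/RF status is undefined without
#' knowing the scaffolds' relative layout -- these pairs carry the
#' scaffolding evidence); pairs with an unmapped mate are `unaligned`.
#'
#' @param pairs Read-pair tibble from [simulate_reads()] (or any tibble
#'   with `name`, `read1`, `read2`, optional `qual1`/`qual2`).
#' @param assembly As in [map_reads()].
#' @param library Library id recorded with each pair.
#' @inheritParams map_reads
#' @return Tibble: `name`, `library`, per-mate mapping columns (suffix
#'   `1`/`2`), and `orientation`.
#' @export
map_read_pairs <- function(pairs, assembly, library = "lib1",
                           seed_length = 21, min_similarity = 0.9,
                           min_length_fraction = 0.5, max_seed_hits = 100) {
  m1 <- map_reads(tibble(name = pairs$name, seq = pairs$read1,
                         qual = pairs$qual1 %||% NA_character_),
                  assembly, seed_length, min_similarity,
                  min_length_fraction, max_seed_hits)
  m2 <- map_reads(tibble(name = pairs$name, seq = pairs$read2,
                         qual = pairs$qual2 %||% NA_character_),
                  assembly, seed_length, min_similarity,
                  min_length_fraction, max_seed_hits)
  out <- tibble(name = pairs$name, library = library,
                mapped1 = m1$mapped, scaffold1 = m1$scaffold,
                pos1 = m1$pos, strand1 = m1$strand,
                alen1 = m1$aligned_len,
                mapped2 = m2$mapped, scaffold2 = m2$scaffold,
                pos2 = m2$pos, strand2 = m2$strand,
                alen2 = m2$aligned_len)
  out$orientation <- classify_pair_orientation(out)
  out
}

#' @rdname map_read_pairs
#' @param aln A pair-alignment tibble (both mates' scaffold, pos, strand).
#' @export
classify_pair_orientation <- function(aln) {
  ori <- rep("unaligned", nrow(aln))
  both <- aln$mapped1 & aln$mapped2
  cross <- both & aln$scaffold1 != aln$scaffold2
  ori[cross] <- "cross_contig"
  same <- both & !cross
  # leftmost mate's strand decides FR vs RF
  first1 <- aln$pos1 <= aln$pos2
  lead_strand <- ifelse(first1, aln$strand1, aln$strand2)
  trail_strand <- ifelse(first1, aln$strand2, aln$strand1)
  fr <- same & lead_strand == "+" & trail_strand == "-"
  rf <- same & lead_strand == "-" & trail_strand == "+"
  ori[same] <- "other"
  ori[fr] <- "forward_reverse"
  ori[rf] <- "reverse_forward"
  ori
}

#' Convert mapped reads to minimal SAM records
#'
#' @param aln A [map_reads()] tibble.
#' @param assembly As in [map_reads()] (for `@SQ` header lines).
#' @return List with `header` and `alignments` tibbles suitable for
#'   [write_sam()].
#' @export
alignments_to_sam <- function(aln, assembly) {
  asm <- as_assembly(assembly)
  header <- tibble(name = asm$id, length = nchar(asm$sequence))
  mapped <- aln[aln$mapped, ]
  alignments <- tibble(
    qname = mapped$name,
    flag = ifelse(mapped$strand == "-", 16L, 0L),
    rname = mapped$scaffold, pos = mapped$pos, mapq = 60L,
    cigar = paste0(mapped$aligned_len, "M"),
    rnext = "*", pnext = 0L, tlen = 0L,
    seq = mapped$seq,
    qual = ifelse(is.na(mapped$qual), "*", mapped$qual))
  list(header = header, alignments = alignments)
}
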