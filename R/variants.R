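# Individual SNV calling and per-scaffold density: scaffolds from the
# single-copy (hemizygous) part of a male genome carry no allelic
# variation, so their SNV density is theoretically zero (bar sequencing
# error), far below the diploid background set by the heterozygosity rate.

#' Call SNVs from read alignments by pileup
#'
#' A site is an SNV when its depth reaches `min_coverage` (default 10-fold)
#' and at least two alleles each pass the evidence rule: at least
#' `min_alt_reads` reads and at least `min_alt_fraction` of the site depth.
#' The evidence rule stands in for genotype-likelihood internals; it is
#' deliberately simple and configurable.
#'
#' @param alignments A [map_reads()] tibble (oriented `seq` per mapped
#'   read), or a list with `header`/`alignments` from [read_sam()].
#' @param assembly Assembly the reads were mapped to (tibble or named
#'   character vector).
#' @param min_coverage Minimum site depth to consider a call (default 10).
#' @param min_alt_reads Minimum reads supporting each allele (default 2).
#' @param min_alt_fraction Minimum fraction of depth per allele
#'   (default 0.2).
#' @param all_sites Return every covered site rather than only SNVs.
#' @return Site-call tibble: `scaffold`, `pos` (1-based), `ref`, `depth`,
#'   `A`, `C`, `G`, `T`, `alt`, `is_snv`.
#' @export
call_snvs <- function(alignments, assembly, min_coverage = 10,
                      min_alt_reads = 2, min_alt_fraction = 0.2,
                      all_sites = FALSE) {
  asm <- as_assembly(assembly)
  counts <- pileup_counts(alignments, asm, min_qual = 0, window = 0)
  sites <- purrr::imap(counts, function(M, scf) {
    depth <- colSums(M)
    cand <- which(depth >= min_coverage)
    if (length(cand) == 0) return(NULL)
    sub <- M[, cand, drop = FALSE]
    d <- depth[cand]
    thr <- pmax(min_alt_reads, ceiling(min_alt_fraction * d))
    n_pass <- colSums(sub >= rep(thr, each = 4))
    is_snv <- n_pass >= 2
    if (!all_sites && !any(is_snv)) return(NULL)
    keep <- if (all_sites) seq_along(cand) else which(is_snv)
    ref <- substring(asm$sequence[asm$id == scf], cand[keep], cand[keep])
    top2 <- apply(sub[, keep, drop = FALSE], 2, function(x)
      rownames(M)[order(-x)][1:2])
    alt <- ifelse(top2[1, ] == ref, top2[2, ], top2[1, ])
    tibble(scaffold = scf, pos = as.integer(cand[keep]), ref = ref,
           depth = as.integer(d[keep]),
           A = sub[1, keep], C = sub[2, keep], G = sub[3, keep],
           T = sub[4, keep], alt = alt, is_snv = is_snv[keep])
  })
  out <- bind_rows(sites)
  if (nrow(out) == 0)
    out <- tibble(scaffold = character(), pos = integer(), ref = character(),
                  depth = integer(), A = integer(), C = integer(),
                  G = integer(), T = integer(), alt = character(),
                  is_snv = logical())
  out
}

# run the C++ pileup over mapped reads; returns a named list of 4 x len
# matrices (rows A,C,G,T)
pileup_counts <- function(alignments, asm, min_qual, window,
                          qual_offset = 33L) {
  if (is.list(alignments) && !is.data.frame(alignments) &&
      "alignments" %in% names(alignments))
    alignments <- sam_to_alignments(alignments)
  aln <- alignments[alignments$mapped, ]
  ref_idx <- match(aln$scaffold, asm$id)
  if (anyNA(ref_idx)) abort("alignment names scaffold absent from assembly")
  pos0 <- if ("read_start0" %in% names(aln)) aln$read_start0 else aln$pos - 1L
  mats <- cpp_pileup(nchar(asm$sequence), ref_idx, pos0, aln$seq,
                     aln$qual, as.integer(min_qual), as.integer(window),
                     as.integer(qual_offset))
  mats <- purrr::map(mats, function(M) {
    rownames(M) <- c("A", "C", "G", "T")
    M
  })
  names(mats) <- asm$id
  mats
}

# adapt read_sam() output to the mapped-alignment tibble shape
sam_to_alignments <- function(sam) {
  a <- sam$alignments
  tibble(name = a$qname, mapped = !bitwAnd(a$flag, 4L),
         scaffold = a$rname, pos = a$pos, read_start0 = a$pos - 1L,
         strand = ifelse(bitwAnd(a$flag, 16L) > 0, "-", "+"),
         seq = a$seq, qual = ifelse(a$qual == "*", NA_character_, a$qual))
}

#' Per-scaffold SNV density
#'
#' Density is SNVs per kbp of non-N scaffold sequence; the assembly-wide
#' density is attached as attribute `overall_density`.
#'
#' @param calls A [call_snvs()] tibble (only rows with `is_snv` count).
#' @param assembly The assembly the calls were made against.
#' @return Summary tibble: `scaffold`, `length` (non-N), `snv_count`,
#'   `density`.
#' @export
scaffold_snv_density <- function(calls, assembly) {
  asm <- as_assembly(assembly)
  lens <- non_n_length(asm$sequence)
  if (any(lens == 0)) abort("zero-length scaffold in assembly")
  snv <- calls[calls$is_snv, ]
  cnt <- snv |> count(.data$scaffold)
  out <- tibble(scaffold = asm$id, length = lens) |>
    left_join(cnt, by = "scaffold") |>
    mutate(snv_count = dplyr::coalesce(.data$n, 0L),
           density = .data$snv_count / (.data$length / 1000)) |>
    select("scaffold", "length", "snv_count", "density")
  attr(out, "overall_density") <- sum(out$snv_count) / (sum(out$length) / 1000)
  out
}

#' Classify hemizygous-candidate (sex-linked) scaffolds by SNV density
#'
#' Hemizygous scaffolds (single-copy in the sequenced individual, like the
#' ancestral-X portion of a male neo-X) are expected to show near-zero SNV
#' density. A scaffold is a `hemizygous_candidate` when it is at least
#' `min_classify_length` long and its density is at most
#' `threshold_fraction` of the median density of scaffolds that long;
#' long scaffolds above the threshold are `diploid`; shorter scaffolds are
#' `unclassified_short`.
#'
#' @param summaries A [scaffold_snv_density()] tibble.
#' @param min_classify_length Minimum scaffold length to classify
#'   (default 50 kbp; scale down for desk-scale simulations).
#' @param threshold_fraction Fraction of the median long-scaffold density
#'   at or below which a scaffold is flagged (default 0.1).
#' @return The summary tibble with a `classification` column.
#' @export
classify_sex_linked <- function(summaries, min_classify_length = 50000,
                                threshold_fraction = 0.1) {
  long <- summaries$length >= min_classify_length
  if (!any(long)) {
    warn("no scaffold reaches min_classify_length; all unclassified_short")
    summaries$classification <- "unclassified_short"
    return(summaries)
  }
  med <- median(summaries$density[long])
  summaries$classification <- dplyr::case_when(
    !long ~ "unclassified_short",
    summaries$density <= threshold_fraction * med ~ "hemizygous_candidate",
    TRUE ~ "diploid")
  attr(summaries, "median_long_density") <- med
  summaries
}

#' Scan an assembly for hemizygous scaffolds
#'
#' Convenience pipeline: map reads, call SNVs at `min_coverage`, compute
#' per-scaffold density, classify.
#'
#' @param reads Read-pair tibble or character vector of reads.
#' @param assembly Assembly tibble or named character vector.
#' @inheritParams call_snvs
#' @inheritParams classify_sex_linked
#' @return List with `calls`, `summaries` (classified) and `alignments`.
#' @export
sexscan <- function(reads, assembly, min_coverage = 10,
                    min_classify_length = 50000, threshold_fraction = 0.1) {
  if (is.data.frame(reads) && all(c("read1", "read2") %in% names(reads))) {
    reads <- tibble(name = rep(reads$name %||%
                                 sprintf("p%06d", seq_len(nrow(reads))), 2),
                    seq = c(reads$read1, reads$read2),
                    qual = c(reads$qual1, reads$qual2))
  }
  aln <- map_reads(reads, assembly)
  calls <- call_snvs(aln, assembly, min_coverage = min_coverage)
  summaries <- scaffold_snv_density(calls, assembly) |>
    classify_sex_linked(min_classify_length = min_classify_length,
                        threshold_fraction = threshold_fraction)
  list(calls = calls, summaries = summaries, alignments = aln)
}
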