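#' Build a de Bruijn k-mer graph from reads
#'
#' Nodes are canonical k-mers (a k-mer and its reverse complement are one
#' node, represented by the lexicographic minimum) with multiplicity counts;
#' edges are the (k-1)-base overlaps supported by observed (k+1)-mers.
#' k-mers spanning an N are skipped; non-ACGTN characters raise an error.
#' Nodes with multiplicity below `min_multiplicity` are pruned (along with
#' edges touching them), the minimal choice that removes isolated
#' sequencing-error k-mers.
#'
#' @param reads Character vector of reads, a tibble with a `seq` column, or
#'   a read-pair tibble from [simulate_reads()] (both mates are used).
#' @param k K-mer size in bases (>= 3, at most the shortest read length).
#'   The desk-scale default is 25; large short-read assemblies conventionally
#'   use larger k (e.g. 64 on 76-150 bp reads).
#' @param min_multiplicity Minimum k-mer multiplicity to keep a node.
#' @return A `kmer_graph`: list with `k`, `nodes` (tibble: kmer, count) and
#'   `edges` (tibble: kmer1 -- the observed canonical (k+1)-mers whose two
#'   constituent k-mers both survive pruning).
#' @export
build_kmer_graph <- function(reads, k = 25, min_multiplicity = 2) {
  reads <- as_read_vector(reads)
  if (k < 3) abort("k must be >= 3")
  if (min_multiplicity < 1) abort("min_multiplicity must be >= 1")
  if (k > min(nchar(reads)))
    abort(sprintf("shortest read (%d bases) is shorter than k = %d",
                  min(nchar(reads)), k))
  res <- cpp_count_kmers(reads, as.integer(k), as.integer(min_multiplicity))
  structure(list(k = as.integer(k),
                 nodes = tibble(kmer = res$kmer, count = res$count),
                 edges = tibble(kmer1 = res$edge)),
            class = "kmer_graph")
}

as_read_vector <- function(reads) {
  if (is.character(reads)) return(reads)
  if (is.data.frame(reads)) {
    if (all(c("read1", "read2") %in% names(reads)))
      return(c(reads$read1, reads$read2))
    if ("seq" %in% names(reads)) return(reads$seq)
  }
  abort("`reads` must be a character vector or a tibble with seq/read1+read2")
}

#' @export
print.kmer_graph <- function(x, ...) {
  cat("<kmer_graph> k=", x$k, ": ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Compact a k-mer graph into unitigs
#'
#' Unitigs are maximal non-branching paths of the strand-symmetric graph;
#' every surviving k-mer lands in exactly one unitig. Output is oriented to
#' the lexicographic minimum of each unitig and its reverse complement and
#' sorted by sequence, so the result is independent of read order.
#'
#' @param graph A [build_kmer_graph()] result.
#' @return A contig tibble (`id`, `sequence`, `length`,
#'   `mean_kmer_coverage`) with attributes `k` and `adjacency` (tibble of
#'   signed unitig indices `from`/`to`: positive = forward orientation,
#'   negative = reverse complement).
#' @export
assemble_unitigs <- function(graph) {
  stopifnot(inherits(graph, "kmer_graph"))
  if (nrow(graph$nodes) == 0) abort("empty k-mer graph")
  res <- cpp_assemble_unitigs(graph$nodes$kmer, graph$nodes$count,
                              graph$edges$kmer1, graph$k)
  out <- tibble(id = sprintf("u%06d", seq_along(res$seq)),
                sequence = res$seq,
                length = nchar(res$seq),
                mean_kmer_coverage = res$cov)
  attr(out, "k") <- graph$k
  attr(out, "adjacency") <- tibble(from = res$edge_from, to = res$edge_to)
  class(out) <- c("hetasm_contigs", class(out))
  out
}
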