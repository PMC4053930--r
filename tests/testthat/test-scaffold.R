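# Mate-pair filtering, s/n link thresholds, chaining, and transcript merges.

make_pairs <- function(...) {
  rows <- list(...)
  tibble::tibble(
    name = paste0("p", seq_along(rows)),
    library = "lib1",
    mapped1 = vapply(rows, function(r) r$m1 %||% TRUE, logical(1)),
    scaffold1 = vapply(rows, function(r) r$c1 %||% "A", character(1)),
    pos1 = vapply(rows, function(r) r$p1 %||% 1L, numeric(1)),
    strand1 = vapply(rows, function(r) r$s1 %||% "+", character(1)),
    alen1 = 100L,
    mapped2 = vapply(rows, function(r) r$m2 %||% TRUE, logical(1)),
    scaffold2 = vapply(rows, function(r) r$c2 %||% "A", character(1)),
    pos2 = vapply(rows, function(r) r$p2 %||% 500L, numeric(1)),
    strand2 = vapply(rows, function(r) r$s2 %||% "-", character(1)),
    alen2 = 100L)
}

test_that("pair orientation is derived from strand/position geometry", {
  p <- make_pairs(
    list(p1 = 100, s1 = "+", p2 = 6000, s2 = "-"),   # FR
    list(p1 = 100, s1 = "-", p2 = 6000, s2 = "+"),   # RF
    list(p1 = 6000, s1 = "+", p2 = 100, s2 = "-"),   # RF (mate order flipped)
    list(p1 = 100, s1 = "+", p2 = 6000, s2 = "+"),   # other
    list(c2 = "B"),                                   # cross contig
    list(m2 = FALSE))                                 # unaligned
  ori <- classify_pair_orientation(p)
  expect_equal(ori, c("forward_reverse", "reverse_forward",
                      "reverse_forward", "other", "cross_contig",
                      "unaligned"))
})

test_that("filter_matepairs keeps RF, removes FR/other/unaligned, partitions", {
  p <- make_pairs(
    list(p1 = 100, s1 = "+", p2 = 6000, s2 = "-"),
    list(p1 = 100, s1 = "-", p2 = 6000, s2 = "+"),
    list(p1 = 100, s1 = "-", p2 = 6000, s2 = "-"),
    list(c2 = "B"),
    list(m2 = FALSE))
  p$orientation <- classify_pair_orientation(p)
  fl <- filter_matepairs(p)
  expect_setequal(fl$kept$name, c("p2", "p4"))
  expect_setequal(fl$removed$name, c("p1", "p3", "p5"))
  expect_equal(fl$removed$reason[fl$removed$name == "p5"], "unaligned")
  expect_equal(fl$removed$reason[fl$removed$name == "p1"], "fr_orientation")
  expect_equal(nrow(fl$kept) + nrow(fl$removed), nrow(p))
  expect_length(intersect(fl$kept$name, fl$removed$name), 0)
  # cross-contig pairs can be dropped on request
  fl2 <- filter_matepairs(p, keep_cross_contig = FALSE)
  expect_setequal(fl2$kept$name, "p2")
})

test_that("chimeric mate-pair filtering is exact against truth labels", {
  tr <- simulate_diploid_genome(sim_config(genome_length = 40000,
                                           heterozygosity = 0, seed = 51))
  mp <- simulate_reads(tr, library_spec("mate_pair", fragment_mean = 4000,
                                        fragment_sd = 300, coverage = 10,
                                        chimera_fraction = 0.3), seed = 52)
  ref <- tibble::tibble(id = "chr1", sequence = tr$haplotype_A[[1]])
  aln <- map_read_pairs(mp, ref, library = "mp")
  fl <- filter_matepairs(aln)
  truth_chimera <- mp$name[mp$is_chimera]
  expect_setequal(fl$removed$name, truth_chimera)
  expect_equal(mean(mp$is_chimera), 0.3, tolerance = 0.06)
})

test_that("s and n thresholds gate scaffold links exactly", {
  set.seed(53)
  ctg <- tibble::tibble(id = c("A", "B", "C"),
                        sequence = c(random_dna(2000), random_dna(400),
                                     random_dna(2000)))
  # hand-made RF cross-contig pairs A -> C (forward/forward layout)
  mk <- function(n, c1, c2, l1, l2) {
    tibble::tibble(name = paste0(c1, c2, seq_len(n)), library = "mp",
                   mapped1 = TRUE, scaffold1 = c1,
                   pos1 = l1 - 300, strand1 = "-", alen1 = 100L,
                   mapped2 = TRUE, scaffold2 = c2, pos2 = 200,
                   strand2 = "+", alen2 = 100L,
                   orientation = "cross_contig")
  }
  pairs10 <- mk(10, "A", "C", 2000, 2000)
  sg <- build_scaffold_graph(ctg, pairs10, s = 500, n = 10,
                             fragment_mean = 1000, kind = "mate_pair")
  expect_equal(nrow(sg$links), 1)
  expect_equal(sg$links$n_pairs, 10)
  # 9 supporting pairs at n = 10: discarded
  sg9 <- build_scaffold_graph(ctg, pairs10[1:9, ], s = 500, n = 10,
                              fragment_mean = 1000, kind = "mate_pair")
  expect_equal(nrow(sg9$links), 0)
  # n = 3 large-insert setting keeps a 3-pair link
  sg3 <- build_scaffold_graph(ctg, pairs10[1:3, ], s = 500, n = 3,
                              fragment_mean = 1000, kind = "mate_pair")
  expect_equal(nrow(sg3$links), 1)
  # a 400 bp contig is never placed: links touching B are dropped at s=500
  pairsB <- mk(12, "A", "B", 2000, 400)
  sgB <- build_scaffold_graph(ctg, pairsB, s = 500, n = 10,
                              fragment_mean = 1000, kind = "mate_pair")
  expect_equal(nrow(sgB$links), 0)
  scB <- scaffold_contigs(sgB)
  expect_equal(nrow(scB), 3)  # all singletons, B included once
  expect_setequal(unlist(purrr::map(scB$members, "contig")), c("A", "B", "C"))
})

test_that("chains assemble in order with estimated gaps and stay idempotent", {
  set.seed(54)
  genome <- random_dna(30000)
  cuts <- c(0, 9000, 21000, 30000)
  ctg <- tibble::tibble(id = c("A", "B", "C"),
                        sequence = substring(genome, head(cuts, -1) + 1,
                                             cuts[-1]))
  tr <- structure(list(haplotype_A = c(chr1 = genome),
                       haplotype_B = c(chr1 = genome),
                       het_sites = tibble::tibble(),
                       hemizygous_intervals = tibble::tibble(),
                       config = sim_config(genome_length = 30000, seed = 1)),
                  class = "diploid_truth")
  mp <- simulate_reads(tr, library_spec("mate_pair", fragment_mean = 4000,
                                        fragment_sd = 300, coverage = 8),
                       seed = 55)
  aln <- map_read_pairs(mp, ctg)
  fl <- filter_matepairs(aln)
  sg <- build_scaffold_graph(ctg, fl$kept, s = 500, n = 5,
                             fragment_mean = 4000, kind = "mate_pair")
  sc <- scaffold_contigs(sg)
  expect_equal(nrow(sc), 1)
  m <- sc$members[[1]]
  expect_equal(m$contig, c("A", "B", "C"))
  expect_equal(m$orientation, c("+", "+", "+"))
  # conservation: non-N scaffold bases equal the contig bases
  expect_equal(gsub("N", "", sc$sequence), paste0(ctg$sequence, collapse = ""))
  # idempotence: re-mapping the same evidence onto the output and
  # rescaffolding changes nothing
  aln2 <- map_read_pairs(mp, sc)
  fl2 <- filter_matepairs(aln2)
  sg2 <- build_scaffold_graph(sc, fl2$kept, s = 500, n = 5,
                              fragment_mean = 4000, kind = "mate_pair")
  sc2 <- scaffold_contigs(sg2)
  expect_equal(sc2$sequence, sc$sequence)
})

test_that("ambiguous forks terminate chains conservatively", {
  ctg <- tibble::tibble(id = c("A", "B", "C"),
                        sequence = c(random_dna(1500), random_dna(1500),
                                     random_dna(1500)))
  mk <- function(n, c2) {
    tibble::tibble(name = paste0(c2, seq_len(n)), library = "mp",
                   mapped1 = TRUE, scaffold1 = "A", pos1 = 1300,
                   strand1 = "-", alen1 = 100L,
                   mapped2 = TRUE, scaffold2 = c2, pos2 = 200,
                   strand2 = "+", alen2 = 100L, orientation = "cross_contig")
  }
  sg <- build_scaffold_graph(ctg, dplyr::bind_rows(mk(8, "B"), mk(8, "C")),
                             s = 500, n = 5, fragment_mean = 1000,
                             kind = "mate_pair")
  sc <- scaffold_contigs(sg)
  expect_equal(nrow(sc), 3)  # A alone: equal-support fork is ambiguous
})

test_that("transcript evidence merges scaffolds per the two-library rule", {
  set.seed(56)
  scf <- tibble::tibble(id = c("s1", "s2"),
                        sequence = c(random_dna(5000), random_dna(4000)))
  span <- function(tr, lib) {
    tibble::tibble(transcript = tr, library = lib, scaffold = c("s1", "s2"),
                   t_start = c(1, 201), t_end = c(200, 400),
                   s_start = c(4801, 1), s_end = c(5000, 200), strand = "+")
  }
  # two transcripts from two libraries: merged with exactly 100 Ns
  m <- merge_by_transcripts(scf, dplyr::bind_rows(span("t1", "L1"),
                                                  span("t2", "L2")))
  expect_equal(nrow(m), 1)
  expect_equal(m$length, 9100)
  expect_equal(stringr::str_count(m$sequence, "N"), 100)
  expect_equal(gsub("N", "", m$sequence),
               paste0(scf$sequence, collapse = ""))
  # two transcripts, one library: not merged
  m2 <- merge_by_transcripts(scf, dplyr::bind_rows(span("t1", "L1"),
                                                   span("t2", "L1")))
  expect_equal(nrow(m2), 2)
  # a single transcript: not merged
  m3 <- merge_by_transcripts(scf, span("t1", "L1"))
  expect_equal(nrow(m3), 2)
})

test_that("a transcript spanning three scaffolds merges each adjacent pair", {
  set.seed(57)
  scf <- tibble::tibble(id = c("s1", "s2", "s3"),
                        sequence = c(random_dna(3000), random_dna(2000),
                                     random_dna(3000)))
  span3 <- function(tr, lib) {
    tibble::tibble(transcript = tr, library = lib,
                   scaffold = c("s1", "s2", "s3"),
                   t_start = c(1, 201, 401), t_end = c(200, 400, 600),
                   s_start = c(2801, 1, 1), s_end = c(3000, 2000, 200),
                   strand = c("+", "+", "+"))
  }
  m <- merge_by_transcripts(scf, dplyr::bind_rows(span3("t1", "L1"),
                                                  span3("t2", "L2")))
  expect_equal(nrow(m), 1)
  expect_equal(m$length, 3000 + 100 + 2000 + 100 + 3000)
})
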