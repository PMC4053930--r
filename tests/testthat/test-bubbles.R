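# Bubble detection against the exhaustive oracle, and the popping rules at
# their decision boundaries.

test_that("hand-built simple and complex bubbles are recognised", {
  # u -> {b1, b2} -> v
  b <- make_simple_bubble("AAA", "CCC", "GGG", "TTT")
  expect_equal(b$kind, "simple")
  expect_equal(nrow(b$branches), 2)

  # diamond of diamonds: u -> a,b -> m -> c,d -> v
  g <- asm_graph(rep("ACGT", 7),
                 tibble::tibble(from = c(1, 1, 2, 3, 4, 4, 5, 6),
                                to = c(2, 3, 4, 4, 5, 6, 7, 7)),
                 ov = 0)
  bs <- find_bubbles(g)
  kinds <- vapply(bs, function(b) b$kind, character(1))
  expect_true("complex" %in% kinds)
  big <- bs[[which(vapply(bs, function(b) length(b$interior), integer(1)) == 5)]]
  expect_equal(big$kind, "complex")
  expect_equal(sort(abs(big$interior)), 2:6)
})

test_that("find_bubbles equals the brute-force oracle on random graphs", {
  set.seed(41)
  n_graphs <- 60  # the full 500-graph battery runs in the acceptance suite
  for (i in seq_len(n_graphs)) {
    n <- sample(4:12, 1)
    edges <- random_digraph(n)
    g <- asm_graph(vapply(seq_len(n), function(j) random_dna(sample(3:9, 1)),
                          character(1)), edges, ov = 0)
    got <- find_bubbles(g)
    want <- oracle_bubbles(n, edges)
    expect_setequal(vapply(got, bubble_key, character(1)),
                    vapply(want, bubble_key, character(1)))
    for (b in got) {
      w <- want[[match(bubble_key(b), vapply(want, bubble_key,
                                             character(1)))]]
      expect_equal(b$kind, w$kind)
    }
  }
})

test_that("short bubble popping follows the two-SNV-within-k rule", {
  k <- 25
  base <- random_dna(60)  # 60 < 3k = 75
  mutate_at <- function(s, pos) {
    v <- strsplit(s, "")[[1]]
    v[pos] <- chartr("ACGT", "CGTA", v[pos])
    paste(v, collapse = "")
  }
  # one SNV, higher coverage retained
  b1 <- make_simple_bubble("AAACCC", base, mutate_at(base, 30), "GGGTTT",
                           cov = c(10, 4))
  rec <- pop_simple_bubble(b1, k)
  expect_equal(rec$rule, "short_two_snv")
  expect_equal(rec$retained_cov, 10)
  expect_equal(rec$retained_seq, base)
  expect_equal(rec$discarded_seqs[[1]], mutate_at(base, 30))

  # two SNVs within k: popped; exactly k apart: still popped
  b2 <- make_simple_bubble("AAACCC", base, mutate_at(base, c(20, 40)),
                           "GGGTTT")
  expect_equal(pop_simple_bubble(b2, k)$rule, "short_two_snv")
  b2b <- make_simple_bubble("AAACCC", base, mutate_at(base, c(10, 35)),
                            "GGGTTT")
  expect_equal(pop_simple_bubble(b2b, k)$rule, "short_two_snv")

  # three SNVs within k: not popped
  b3 <- make_simple_bubble("AAACCC", base, mutate_at(base, c(20, 30, 40)),
                           "GGGTTT")
  expect_null(pop_simple_bubble(b3, k))

  # two SNVs more than k apart: not popped by this rule
  b4 <- make_simple_bubble("AAACCC", base, mutate_at(base, c(10, 50)),
                           "GGGTTT")
  expect_null(pop_simple_bubble(b4, k))

  # branch length >= 3k: out of scope for the short rule
  long <- random_dna(80)
  b5 <- make_simple_bubble("AAACCC", long, mutate_at(long, 40), "GGGTTT")
  expect_null(pop_simple_bubble(b5, k))

  # coverage tie retains the lexicographically smaller branch
  b6 <- make_simple_bubble("AAACCC", base, mutate_at(base, 30), "GGGTTT",
                           cov = c(7, 7))
  rec6 <- pop_simple_bubble(b6, k)
  expect_equal(rec6$retained_seq, min(base, mutate_at(base, 30)))

  expect_error(pop_simple_bubble(structure(list(kind = "complex"),
                                           class = "bubble"), k),
               "simple")
})

test_that("long bubble popping applies the 90% identity rule", {
  k <- 25
  base <- random_dna(100)
  mutate_at <- function(s, pos) {
    v <- strsplit(s, "")[[1]]
    v[pos] <- chartr("ACGT", "CGTA", v[pos])
    paste(v, collapse = "")
  }
  # 5 mismatches in 100 -> 95% identity -> popped
  b <- make_simple_bubble("AAACCC", base,
                          mutate_at(base, c(10, 30, 50, 70, 90)), "GGGTTT",
                          cov = c(12, 5))
  rec <- pop_long_bubble(b, k)
  expect_equal(rec$rule, "long_identity")
  expect_equal(rec$identity, 95)
  expect_equal(rec$retained_seq, base)

  # 11 mismatches -> 89% -> kept
  b2 <- make_simple_bubble("AAACCC", base,
                           mutate_at(base, seq(5, 95, length.out = 11)),
                           "GGGTTT")
  expect_null(pop_long_bubble(b2, k))

  # 10 mismatches -> exactly 90% -> popped (minimum identity is inclusive)
  b3 <- make_simple_bubble("AAACCC", base,
                           mutate_at(base, seq(5, 95, length.out = 10)),
                           "GGGTTT")
  expect_equal(pop_long_bubble(b3, k)$identity, 90)

  # 3-base deletion, no mismatches: 97 matches / 100 columns -> popped
  del <- paste0(substring(base, 1, 40), substring(base, 44, 100))
  b4 <- make_simple_bubble("AAACCC", base, del, "GGGTTT")
  rec4 <- pop_long_bubble(b4, k)
  expect_equal(rec4$identity, 97)
})

test_that("global alignment identity matches an independent reference DP", {
  ref_align <- function(a, b) {
    # plain-R Needleman-Wunsch on unit costs with full traceback
    a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
    n <- length(a); m <- length(b)
    D <- matrix(0, n + 1, m + 1)
    D[, 1] <- 0:n; D[1, ] <- 0:m
    for (i in seq_len(n)) for (j in seq_len(m))
      D[i + 1, j + 1] <- min(D[i, j] + (a[i] != b[j]), D[i, j + 1] + 1,
                             D[i + 1, j] + 1)
    D[n + 1, m + 1]
  }
  set.seed(42)
  for (rep in 1:25) {
    a <- random_dna(sample(3:40, 1))
    b <- random_dna(sample(3:40, 1))
    al <- hetasm:::cpp_global_align(a, b)
    expect_equal(al$distance, ref_align(a, b))
    expect_lte(al$columns, nchar(a) + nchar(b))
    expect_gte(al$columns, max(nchar(a), nchar(b)))
    # identity consistency: matches <= min length; columns >= max length
    expect_lte(al$matches, min(nchar(a), nchar(b)))
  }
})

test_that("complex bubbles resolve to the longest-path N span", {
  # two interior paths of total lengths 12 and 17 -> span 17
  g <- asm_graph(c("AAAA", random_dna(12), random_dna(9), random_dna(8),
                   "TTTT"),
                 tibble::tibble(from = c(1, 1, 3, 2, 4), to = c(2, 3, 4, 5, 5)),
                 ov = 0)
  bs <- find_bubbles(g)
  b <- bs[[which.max(vapply(bs, function(x) length(x$interior), integer(1)))]]
  expect_equal(b$kind, "complex")
  res <- resolve_complex_bubble(b, g)
  expect_equal(res$nspan, 17)
  expect_equal(res$record$rule, "complex_span")

  # degenerate single interior path: N span equals its length
  deg <- structure(list(source = 1L, sink = 3L, interior = 2L,
                        kind = "complex", branches = NULL),
                   class = "bubble")
  g2 <- asm_graph(c("AAAA", random_dna(9), "TTTT"),
                  tibble::tibble(from = c(1, 2), to = c(2, 3)), ov = 0)
  expect_equal(resolve_complex_bubble(deg, g2)$nspan, 9)
})

test_that("longest-path spans equal exhaustive enumeration on random DAGs", {
  set.seed(43)
  done <- 0
  for (rep in 1:60) {
    n <- sample(6:12, 1)
    edges <- random_bubble_dag(n)
    lens <- sample(3:9, n, replace = TRUE)
    g <- asm_graph(vapply(lens, random_dna, character(1)), edges, ov = 0)
    bs <- find_bubbles(g)
    for (b in bs) {
      if (b$kind != "complex") next
      res <- resolve_complex_bubble(b, g)
      want <- oracle_longest_path(edges, b$source, b$sink, lens)
      expect_equal(res$nspan, max(as.integer(want), 1L))
      done <- done + 1
    }
  }
  expect_gte(done, 25)  # enough complex instances actually exercised
})

test_that("popping conserves every branch and resolves a diploid genome", {
  tr <- simulate_diploid_genome(sim_config(genome_length = 30000,
                                           heterozygosity = 0.005,
                                           seed = 44))
  pe <- simulate_reads(tr, library_spec("paired_end", coverage = 40),
                       seed = 45)
  un <- assemble_unitigs(build_kmer_graph(pe, 25, 2))
  pb <- pop_bubbles(un)
  expect_gt(nrow(pb$popped), 0.7 * nrow(tr$het_sites))
  # conservation: retained and discarded branches partition each bubble
  for (i in seq_len(nrow(pb$popped))) {
    rec <- pb$popped[i, ]
    if (rec$rule == "complex_span") next
    expect_false(rec$retained_seq %in% rec$discarded_seqs[[1]])
    expect_equal(length(rec$discarded_seqs[[1]]), 1)
  }
  # every discarded branch is genuine haplotype sequence (error-free reads)
  hap <- c(tr$haplotype_A[[1]], tr$haplotype_B[[1]])
  disc <- unlist(pb$popped$discarded_seqs[pb$popped$rule != "complex_span"])
  hits <- vapply(disc, function(s)
    any(grepl(s, hap, fixed = TRUE)) ||
      any(grepl(revcomp(s), hap, fixed = TRUE)), logical(1))
  expect_gte(mean(hits), 0.95)
  # popping increased contig N50 over the raw unitigs
  expect_gt(n50(pb$contigs$length), n50(un$length))
})
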