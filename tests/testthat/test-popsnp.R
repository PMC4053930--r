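# Pooled SNP filters, morphism classes, and genomic-region partitioning.

pool_stack <- function(ref_seq, pos, alleles, counts, width = 60,
                       qual = "I") {
  start <- max(1, pos - width %/% 2)
  template <- substring(ref_seq, start, start + width - 1)
  dplyr::bind_rows(purrr::map2(alleles, counts, function(a, n) {
    v <- strsplit(template, "")[[1]]
    v[pos - start + 1] <- a
    tibble::tibble(name = paste0("r", a, seq_len(n)), mapped = TRUE,
                   scaffold = "c1", pos = start, read_start0 = start - 1L,
                   strand = "+", seq = paste(v, collapse = ""),
                   qual = strrep(qual, width))
  }))
}

test_that("the coverage, count and frequency filters gate reporting", {
  set.seed(81)
  asm <- tibble::tibble(id = "c1", sequence = random_dna(400))
  refb <- substring(asm$sequence, 200, 200)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  # depth 20, variant count 2: not reported
  s1 <- call_pooled_snps(pool_stack(asm$sequence, 200, c(refb, alt),
                                    c(18, 2)), asm)
  expect_equal(nrow(s1), 0)
  # depth 48, count 3 = 6.25% exactly: reported
  s2 <- call_pooled_snps(pool_stack(asm$sequence, 200, c(refb, alt),
                                    c(45, 3)), asm)
  expect_equal(nrow(s2), 1)
  expect_equal(s2$alleles[[1]]$count[s2$alleles[[1]]$base == alt], 3)
  # depth 19, count 5: below min coverage
  s3 <- call_pooled_snps(pool_stack(asm$sequence, 200, c(refb, alt),
                                    c(14, 5)), asm)
  expect_equal(nrow(s3), 0)
  # count 3 but depth 60 -> 5% < 6.25%: not reported
  s4 <- call_pooled_snps(pool_stack(asm$sequence, 200, c(refb, alt),
                                    c(57, 3)), asm)
  expect_equal(nrow(s4), 0)
  # even windows cannot centre on a site
  expect_error(call_pooled_snps(s2, asm, window_length = 50), "odd")
})

test_that("lowering the frequency threshold only adds sites", {
  set.seed(82)
  asm <- tibble::tibble(id = "c1", sequence = random_dna(400))
  refb <- substring(asm$sequence, 200, 200)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  aln <- pool_stack(asm$sequence, 200, c(refb, alt), c(57, 3))
  hi <- call_pooled_snps(aln, asm, min_variant_frequency = 0.0625)
  lo <- call_pooled_snps(aln, asm, min_variant_frequency = 0.03)
  expect_true(all(paste(hi$scaffold, hi$pos) %in% paste(lo$scaffold, lo$pos)))
  expect_gte(nrow(lo), nrow(hi))
})

test_that("the neighbourhood quality window vetoes low-quality support", {
  set.seed(83)
  asm <- tibble::tibble(id = "c1", sequence = random_dna(400))
  refb <- substring(asm$sequence, 200, 200)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  # low-quality bases ('#' = Phred 2) anywhere in the 51-window kill the
  # read's support under "window" mode but not under "central"
  good <- pool_stack(asm$sequence, 200, c(refb, alt), c(20, 5))
  bad <- good
  # corrupt one base 10 positions away from the site in every read
  bad$qual <- vapply(bad$qual, function(q) {
    v <- strsplit(q, "")[[1]]; v[200 - (200 - 30) + 1 - 10] <- "#"
    paste(v, collapse = "")
  }, character(1))
  s_win <- call_pooled_snps(bad, asm, quality_mode = "window")
  s_cen <- call_pooled_snps(bad, asm, quality_mode = "central")
  expect_equal(nrow(s_win), 0)
  expect_equal(nrow(s_cen), 1)
  s_good <- call_pooled_snps(good, asm, quality_mode = "window")
  expect_equal(nrow(s_good), 1)
})

test_that("morphism classes count passing alleles against the consensus", {
  set.seed(84)
  asm <- tibble::tibble(id = "c1", sequence = random_dna(400))
  refb <- substring(asm$sequence, 200, 200)
  others <- setdiff(c("A", "C", "G", "T"), refb)
  # all 30 reads a non-consensus base: monomorphic
  s1 <- call_pooled_snps(pool_stack(asm$sequence, 200, others[1], 30), asm)
  expect_equal(s1$morphism, "monomorphic")
  # consensus + one alternative: dimorphic
  s2 <- call_pooled_snps(pool_stack(asm$sequence, 200, c(refb, others[1]),
                                    c(20, 10)), asm)
  expect_equal(s2$morphism, "dimorphic")
  # three passing alleles: trimorphic; four: tetramorphic
  s3 <- call_pooled_snps(pool_stack(asm$sequence, 200,
                                    c(refb, others[1], others[2]),
                                    c(20, 10, 10)), asm)
  expect_equal(s3$morphism, "trimorphic")
  s4 <- call_pooled_snps(pool_stack(asm$sequence, 200,
                                    c(refb, others[1], others[2], others[3]),
                                    c(20, 10, 10, 10)), asm)
  expect_equal(s4$morphism, "tetramorphic")
})

test_that("pooled frequencies track truth on a simulated pool", {
  cfg <- sim_config(genome_length = 20000, seed = 85)
  pop <- simulate_population(cfg, n_individuals = 8, snp_rate = 0.002,
                             triallelic_fraction = 0.1)
  pool <- simulate_pool(pop$individuals,
                        library_spec("paired_end", coverage = 120),
                        seed = 86, reference = pop$reference)
  ref <- tibble::tibble(id = names(pop$reference),
                        sequence = unname(pop$reference))
  rd <- tibble::tibble(name = rep(pool$pairs$name, 2),
                       seq = c(pool$pairs$read1, pool$pairs$read2),
                       qual = c(pool$pairs$qual1, pool$pairs$qual2))
  snps <- call_pooled_snps(map_reads(rd, ref), ref)
  # audit: every reported allele satisfies the filters
  al <- tidyr::unnest(snps, "alleles")
  expect_true(all(al$count >= 3))
  expect_true(all(al$freq >= 0.0625))
  expect_true(all(snps$depth >= 20))
  # frequencies match truth within binomial error (3 sigma)
  tt <- pool$truth_sites
  j <- dplyr::inner_join(al, tt,
                         by = c("scaffold" = "chrom", "pos",
                                "base" = "allele"))
  sigma <- sqrt(j$freq.y * (1 - j$freq.y) / j$depth)
  expect_gte(mean(abs(j$freq.x - j$freq.y) <= 3 * pmax(sigma, 1e-6) +
                    0.5 / j$depth), 0.95)
  # a planted tri-allelic site recovered as trimorphic at depth
  tri_pos <- tt |> dplyr::count(.data$chrom, .data$pos) |>
    dplyr::filter(n >= 3)
  if (nrow(tri_pos) > 0) {
    hit <- snps[snps$pos %in% tri_pos$pos, ]
    expect_true(any(hit$morphism %in% c("trimorphic", "tetramorphic")))
  }
})

test_that("region annotation partitions SNPs and bases exactly", {
  set.seed(87)
  asm <- tibble::tibble(id = "scf1",
                        sequence = paste0(random_dna(6000), strrep("N", 50),
                                          random_dna(3950)))
  gm <- tibble::tibble(seqid = "scf1",
                       type = c("gene", "exon", "exon", "gene", "exon"),
                       start = c(1001, 1001, 2501, 7001, 7201),
                       end = c(3000, 1500, 3000, 8000, 7800))
  sites <- tibble::tibble(scaffold = "scf1",
                          pos = c(1200L, 2000L, 2700L, 7100L, 5000L, 9000L),
                          ref = "A", depth = 40L,
                          alleles = purrr::map(1:6, ~ tibble::tibble(
                            base = c("A", "G"), count = c(30, 10),
                            freq = c(0.75, 0.25))),
                          n_alleles = 2L, morphism = "dimorphic")
  ar <- annotate_regions(sites, gm, asm)
  expect_equal(ar$sites$region,
               c("exonic", "intronic", "exonic", "intronic", "intergenic",
                 "intergenic"))
  rep <- ar$report
  expect_equal(sum(rep$snp_count), nrow(sites))
  expect_equal(sum(rep$bases), 10000 - 50)  # Ns in no region
  expect_equal(rep$bases[rep$region == "exonic"], 500 + 500 + 600)
  # gene bases minus exon bases
  expect_equal(rep$bases[rep$region == "intronic"],
               (2000 - 1000) + (1000 - 600))
  # coordinates beyond the scaffold raise with the feature named
  bad <- dplyr::bind_rows(gm, tibble::tibble(seqid = "scf1", type = "exon",
                                             start = 9900, end = 10050))
  expect_error(annotate_regions(sites, bad, asm), "exceeds")
})
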