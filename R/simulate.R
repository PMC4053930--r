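#' Simulation configuration for a synthetic diploid genome
#'
#' Describes the genome the simulator emulates: a diploid with i.i.d. uniform
#' ACGT base composition, substitution-only heterozygous variants, an
#' optional hemizygous region present on one haplotype only (the
#' ancestral-X analogue of a male neo-XY system), and optional exact repeat
#' copies of a 500 bp motif to stress the assembler.
#'
#' @param genome_length Total haploid genome length in bases (>= 1000).
#' @param heterozygosity Per-base probability of a heterozygous SNV
#'   (0 to 0.1).
#' @param hemizygous_fraction Fraction of the genome present in one copy
#'   only, placed as a single contiguous interval centred on the first
#'   chromosome -- an ancestral-X block embedded in a fused chromosome, so
#'   haplotype B carries a clean deletion junction (0 to < 1).
#' @param n_chromosomes Number of chromosomes; the genome length is split
#'   evenly.
#' @param repeat_fraction Fraction of the genome composed of inserted exact
#'   copies of a single sampled 500 bp motif.
#' @param seed RNG seed; identical configurations (including seed)
#'   reproduce byte-identical output.
#' @return A `sim_config` object (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 50000, heterozygosity = 0.005, seed = 1)
sim_config <- function(genome_length = 100000, heterozygosity = 0.005,
                       hemizygous_fraction = 0, n_chromosomes = 1,
                       repeat_fraction = 0, seed = 1) {
  if (!is.numeric(genome_length) || genome_length < 1000)
    abort("`genome_length` must be >= 1000")
  if (heterozygosity < 0 || heterozygosity > 0.1)
    abort("`heterozygosity` must be in [0, 0.1]")
  if (hemizygous_fraction < 0 || hemizygous_fraction >= 1)
    abort("`hemizygous_fraction` must be in [0, 1)")
  if (repeat_fraction < 0 || repeat_fraction >= 1)
    abort("`repeat_fraction` must be in [0, 1)")
  if (n_chromosomes < 1) abort("`n_chromosomes` must be >= 1")
  if (hemizygous_fraction * n_chromosomes >= 1)
    abort("`hemizygous_fraction` too large for the first chromosome to hold")
  structure(list(genome_length = as.integer(genome_length),
                 heterozygosity = heterozygosity,
                 hemizygous_fraction = hemizygous_fraction,
                 n_chromosomes = as.integer(n_chromosomes),
                 repeat_fraction = repeat_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a diploid genome with truth tables
#'
#' Generates two haplotypes that are identical except at heterozygous SNV
#' sites, plus a hemizygous interval present only on haplotype A. Every
#' heterozygous site lies outside the hemizygous interval. Truth tables
#' (het sites and hemizygous intervals) are returned for downstream oracle
#' checks.
#'
#' @param config A [sim_config()] object.
#' @return A `diploid_truth` object: list with `haplotype_A` and
#'   `haplotype_B` (named character vectors of chromosome sequences),
#'   `het_sites` (tibble: chrom, pos, allele_A, allele_B; 1-based positions
#'   on haplotype A), `hemizygous_intervals` (tibble: chrom, start, end;
#'   1-based inclusive) and the config.
#' @export
simulate_diploid_genome <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  nchr <- config$n_chromosomes
  lens <- rep(config$genome_length %/% nchr, nchr)
  lens[1] <- lens[1] + config$genome_length - sum(lens)
  chroms <- paste0("chr", seq_len(nchr))

  motif <- if (config$repeat_fraction > 0) random_dna(500) else NULL
  hapA <- vapply(seq_len(nchr), function(i) {
    L <- lens[i]
    if (is.null(motif)) return(random_dna(L))
    n_rep <- floor(config$repeat_fraction * L / 500)
    base_len <- L - n_rep * 500
    base <- random_dna(base_len)
    if (n_rep == 0) return(base)
    cuts <- sort(sample.int(base_len, n_rep, replace = FALSE))
    pieces <- substring(base, c(1, cuts + 1), c(cuts, base_len))
    paste0(paste0(pieces[-length(pieces)], motif, collapse = ""),
           pieces[length(pieces)])
  }, character(1))
  names(hapA) <- chroms
  lens <- nchar(hapA)

  hemi_len <- round(config$hemizygous_fraction * config$genome_length)
  hemi <- tibble(chrom = character(), start = integer(), end = integer())
  if (hemi_len > 0) {
    if (hemi_len > lens[1])
      abort("hemizygous interval exceeds the first chromosome")
    h0 <- as.integer((lens[1] - hemi_len) %/% 2)
    hemi <- tibble(chrom = chroms[1], start = h0 + 1L,
                   end = as.integer(h0 + hemi_len))
  }

  # heterozygous sites: per-base Bernoulli outside hemizygous intervals
  bases <- c("A", "C", "G", "T")
  het <- purrr::map(seq_len(nchr), function(i) {
    L <- lens[i]
    elig <- seq_len(L)
    if (nrow(hemi) > 0 && hemi$chrom[1] == chroms[i])
      elig <- elig[elig < hemi$start[1] | elig > hemi$end[1]]
    n_elig <- length(elig)
    if (n_elig <= 0 || config$heterozygosity == 0) return(NULL)
    k <- rbinom(1, n_elig, config$heterozygosity)
    if (k == 0) return(NULL)
    pos <- sort(sample(elig, k))
    a <- substring(hapA[i], pos, pos)
    b <- vapply(a, function(x) sample(setdiff(bases, x), 1), character(1),
                USE.NAMES = FALSE)
    tibble(chrom = chroms[i], pos = as.integer(pos), allele_A = a, allele_B = b)
  })
  het <- bind_rows(het)
  if (nrow(het) == 0)
    het <- tibble(chrom = character(), pos = integer(),
                  allele_A = character(), allele_B = character())

  hapB <- hapA
  if (nrow(het) > 0) {
    for (cc in unique(het$chrom)) {
      h <- het[het$chrom == cc, ]
      s <- strsplit(hapB[[cc]], "", fixed = TRUE)[[1]]
      s[h$pos] <- h$allele_B
      hapB[[cc]] <- paste(s, collapse = "")
    }
  }
  if (nrow(hemi) > 0) {
    cc <- hemi$chrom[1]
    hapB[[cc]] <- paste0(substring(hapB[[cc]], 1, hemi$start[1] - 1),
                         substring(hapB[[cc]], hemi$end[1] + 1, lens[[cc]]))
  }

  structure(list(haplotype_A = hapA, haplotype_B = hapB, het_sites = het,
                 hemizygous_intervals = hemi, config = config),
            class = "diploid_truth")
}

#' @export
print.diploid_truth <- function(x, ...) {
  cat("<diploid_truth> ", length(x$haplotype_A), " chromosome(s), ",
      sum(nchar(x$haplotype_A)), " bp haploid; ",
      nrow(x$het_sites), " het sites; ",
      nrow(x$hemizygous_intervals), " hemizygous interval(s)\n", sep = "")
  invisible(x)
}

#' Sequencing library specification
#'
#' Paired-end libraries emit forward-reverse (FR) pairs; mate-pair
#' libraries emit reverse-forward (RF) pairs except for a chimera fraction,
#' which behaves like short-fragment FR contamination (the unlabelled
#' short-fragment reads that co-purify in mate-pair protocols).
#'
#' @param kind `"paired_end"` or `"mate_pair"`.
#' @param fragment_mean,fragment_sd Fragment length distribution in bases.
#' @param read_length Read length in bases.
#' @param coverage Fold sequence coverage of the haploid genome.
#' @param error_rate Per-base substitution error probability.
#' @param chimera_fraction Fraction of mate-pair pairs emitted as
#'   forward-reverse short-fragment chimeras (mate-pair only; must be 0 for
#'   paired-end).
#' @param base_quality Constant Phred score assigned to simulated bases.
#' @param chimera_fragment_mean,chimera_fragment_sd Fragment length
#'   distribution of chimeric pairs.
#' @return A `library_spec` object.
#' @export
library_spec <- function(kind = c("paired_end", "mate_pair"),
                         fragment_mean = 600, fragment_sd = 50,
                         read_length = 100, coverage = 40,
                         error_rate = 0, chimera_fraction = 0,
                         base_quality = 40,
                         chimera_fragment_mean = 400,
                         chimera_fragment_sd = 40) {
  kind <- match.arg(kind)
  if (kind == "paired_end" && chimera_fraction != 0)
    abort("`chimera_fraction` must be 0 for paired_end libraries")
  if (chimera_fraction < 0 || chimera_fraction >= 1)
    abort("`chimera_fraction` must be in [0, 1)")
  if (read_length > fragment_mean)
    abort("`read_length` must not exceed `fragment_mean`")
  if (kind == "mate_pair" && fragment_mean <= 2 * read_length)
    abort("mate_pair libraries require `fragment_mean` > 2 * `read_length`")
  structure(list(kind = kind, fragment_mean = fragment_mean,
                 fragment_sd = fragment_sd, read_length = read_length,
                 coverage = coverage, error_rate = error_rate,
                 chimera_fraction = chimera_fraction,
                 base_quality = base_quality,
                 chimera_fragment_mean = chimera_fragment_mean,
                 chimera_fragment_sd = chimera_fragment_sd),
            class = "library_spec")
}

# sample read pairs from a set of haplotypes (internal engine shared by
# simulate_reads and simulate_pool). haps: list of named chromosome vectors;
# each pair draws its haplotype by cycling (alternation) over `haps`.
sample_read_pairs <- function(haps, hap_names, spec, n_pairs) {
  L <- spec$read_length
  hap_idx <- rep_len(seq_along(haps), n_pairs)
  chimera <- if (spec$kind == "mate_pair" && spec$chimera_fraction > 0)
    runif(n_pairs) < spec$chimera_fraction else rep(FALSE, n_pairs)
  frag <- round(rnorm(n_pairs, spec$fragment_mean, spec$fragment_sd))
  frag[chimera] <- round(rnorm(sum(chimera), spec$chimera_fragment_mean,
                               spec$chimera_fragment_sd))
  frag <- pmax(frag, L)

  # chromosome choice weighted by length within the drawn haplotype
  chrom <- character(n_pairs)
  start <- integer(n_pairs)
  for (h in seq_along(haps)) {
    sel <- which(hap_idx == h)
    if (length(sel) == 0) next
    lens <- nchar(haps[[h]])
    cs <- sample(names(haps[[h]]), length(sel), replace = TRUE,
                 prob = lens / sum(lens))
    chrom[sel] <- cs
    maxs <- pmax(1L, lens[cs] - frag[sel] + 1L)
    frag[sel] <- pmin(frag[sel], lens[cs])
    start[sel] <- 1L + floor(runif(length(sel)) * maxs)
  }
  end <- start + frag - 1L

  src <- vapply(seq_len(n_pairs),
                function(i) substring(haps[[hap_idx[i]]][[chrom[i]]],
                                      start[i], end[i]),
                character(1))
  left <- substring(src, 1L, L)
  right <- revcomp(substring(src, frag - L + 1L, frag))
  # PE (and chimeras): read1 = left (+), read2 = rc(right block) (-)
  # MP RF: read1 = rc(left) (-), read2 = right block forward (+)
  rf <- spec$kind == "mate_pair" & !chimera
  read1 <- ifelse(rf, revcomp(left), left)
  read2 <- ifelse(rf, revcomp(right), right)
  strand1 <- ifelse(rf, "-", "+")
  strand2 <- ifelse(rf, "+", "-")

  if (spec$error_rate > 0) {
    read1 <- add_seq_errors(read1, spec$error_rate)
    read2 <- add_seq_errors(read2, spec$error_rate)
  }
  qual <- strrep(rawToChar(as.raw(33L + spec$base_quality)), L)
  tibble(pair = seq_len(n_pairs),
         hap = hap_names[hap_idx], chrom = chrom,
         frag_start = start, frag_end = end,
         is_chimera = chimera,
         read1 = read1, qual1 = qual, strand1 = strand1,
         read2 = read2, qual2 = qual, strand2 = strand2)
}

add_seq_errors <- function(reads, rate) {
  L <- nchar(reads[1])
  ne <- rbinom(length(reads), L, rate)
  hit <- which(ne > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    s <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(L, ne[i])
    s[pos] <- vapply(s[pos], function(x) sample(setdiff(bases, x), 1),
                     character(1), USE.NAMES = FALSE)
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

#' Simulate read pairs from a diploid genome
#'
#' Pairs are drawn alternately from the two haplotypes (the hemizygous
#' interval exists only on haplotype A, so only haplotype A emits reads
#' there). Read names encode the truth in a colon-delimited scheme:
#' `sim:<pair>:<hap>:<chrom>:<frag_start>:<frag_end>:<kind>:<chimera>`,
#' enabling oracle checks without a truth-alignment file.
#'
#' @param truth A [simulate_diploid_genome()] result.
#' @param spec A [library_spec()].
#' @param seed RNG seed.
#' @return A tibble of read pairs with truth columns (`hap`, `chrom`,
#'   `frag_start`, `frag_end`, `is_chimera`, per-mate strands) and reads
#'   `read1`/`read2` with constant quality strings; the library spec is
#'   attached as attribute `library_spec`.
#' @export
simulate_reads <- function(truth, spec, seed = 1) {
  stopifnot(inherits(truth, "diploid_truth"), inherits(spec, "library_spec"))
  set.seed(seed)
  haploid_len <- sum(nchar(truth$haplotype_A))
  n_pairs <- round(spec$coverage * haploid_len / (2 * spec$read_length))
  pairs <- sample_read_pairs(list(truth$haplotype_A, truth$haplotype_B),
                             c("A", "B"), spec, n_pairs)
  pairs$name <- sprintf("sim:%d:%s:%s:%d:%d:%s:%s", pairs$pair, pairs$hap,
                        pairs$chrom, pairs$frag_start, pairs$frag_end,
                        spec$kind, pairs$is_chimera)
  attr(pairs, "library_spec") <- spec
  pairs
}

#' Simulate pooled-population sequencing with an allele-frequency truth table
#'
#' Draws read pairs uniformly from all chromosomes of all individuals in the
#' pool and returns, alongside the reads, a truth table of per-site allele
#' frequencies among the `2 * n` chromosomes (sites where at least one
#' chromosome differs from the shared reference; tri- and tetra-allelic
#' sites are supported).
#'
#' @param truth_population List of `diploid_truth` objects sharing reference
#'   coordinates (same chromosome names and lengths), e.g. from
#'   [simulate_population()].
#' @param spec A [library_spec()]; `coverage` is the total pooled coverage.
#' @param seed RNG seed.
#' @param reference Named character vector of reference chromosome
#'   sequences. Defaults to haplotype A of the first individual.
#' @return List with `pairs` (read-pair tibble as in [simulate_reads()],
#'   `hap` recording individual:haplotype) and `truth_sites` (tibble:
#'   chrom, pos, ref, allele, count, freq).
#' @export
simulate_pool <- function(truth_population, spec, seed = 1,
                          reference = NULL) {
  if (length(truth_population) < 2)
    abort("a pool needs at least 2 individuals")
  ref <- reference %||% truth_population[[1]]$haplotype_A
  for (ind in truth_population) {
    for (hp in list(ind$haplotype_A, ind$haplotype_B)) {
      if (!identical(names(hp), names(ref)) ||
          !identical(nchar(hp), nchar(ref)))
        abort("individuals do not share reference coordinates")
    }
  }
  set.seed(seed)
  haps <- list()
  hap_names <- character()
  for (i in seq_along(truth_population)) {
    haps <- c(haps, list(truth_population[[i]]$haplotype_A),
              list(truth_population[[i]]$haplotype_B))
    hap_names <- c(hap_names, paste0("ind", i, ":A"), paste0("ind", i, ":B"))
  }
  haploid_len <- sum(nchar(ref))
  n_pairs <- round(spec$coverage * haploid_len / (2 * spec$read_length))
  # uniform draw over the 2n chromosomes: shuffle the cycling order
  ord <- sample(length(haps))
  pairs <- sample_read_pairs(haps[ord], hap_names[ord], spec, n_pairs)
  pairs$name <- sprintf("sim:%d:%s:%s:%d:%d:pool:FALSE", pairs$pair,
                        pairs$hap, pairs$chrom, pairs$frag_start,
                        pairs$frag_end)

  truth_sites <- pool_truth_sites(haps, ref)
  list(pairs = pairs, truth_sites = truth_sites)
}

# per-site allele frequencies among a set of haplotypes, relative to ref;
# only sites where some haplotype differs from ref are listed
pool_truth_sites <- function(haps, ref) {
  out <- list()
  for (cc in names(ref)) {
    refv <- strsplit(ref[[cc]], "", fixed = TRUE)[[1]]
    mat <- vapply(haps, function(h) strsplit(h[[cc]], "", fixed = TRUE)[[1]],
                  character(length(refv)))
    diff_any <- rowSums(mat != refv) > 0
    for (p in which(diff_any)) {
      tab <- table(mat[p, ])
      out[[length(out) + 1]] <- tibble(
        chrom = cc, pos = as.integer(p), ref = refv[p],
        allele = names(tab), count = as.integer(tab),
        freq = as.numeric(tab) / length(haps))
    }
  }
  if (length(out) == 0)
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  allele = character(), count = integer(), freq = double()))
  bind_rows(out)
}

#' Simulate a population of diploid individuals sharing coordinates
#'
#' Builds a reference genome, plants polymorphic sites with known population
#' allele frequencies (optionally tri-allelic), and samples `n_individuals`
#' diploid genotypes from those frequencies. The result feeds
#' [simulate_pool()].
#'
#' @param config A [sim_config()]; `heterozygosity` and
#'   `hemizygous_fraction` are ignored (population variation is planted
#'   separately, and pools have no hemizygous analogue here).
#' @param n_individuals Number of diploid individuals.
#' @param snp_rate Per-base probability of a polymorphic site.
#' @param triallelic_fraction Fraction of polymorphic sites planted with a
#'   second alternative allele.
#' @return List with `individuals` (list of `diploid_truth`), `reference`
#'   (named character vector) and `planted_sites` (tibble: chrom, pos, ref,
#'   alleles and their planted chromosome counts).
#' @export
simulate_population <- function(config, n_individuals = 8, snp_rate = 0.002,
                                triallelic_fraction = 0) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  base_cfg <- sim_config(genome_length = config$genome_length,
                         heterozygosity = 0, hemizygous_fraction = 0,
                         n_chromosomes = config$n_chromosomes,
                         repeat_fraction = config$repeat_fraction,
                         seed = config$seed)
  ref_truth <- simulate_diploid_genome(base_cfg)
  ref <- ref_truth$haplotype_A
  set.seed(config$seed + 1L)
  n_chrom_copies <- 2L * n_individuals
  bases <- c("A", "C", "G", "T")

  planted <- list()
  hap_mats <- list()  # per chromosome: site x 2n matrix of alleles
  for (cc in names(ref)) {
    L <- nchar(ref[[cc]])
    k <- rbinom(1, L, snp_rate)
    if (k == 0) next
    pos <- sort(sample.int(L, k))
    refb <- substring(ref[[cc]], pos, pos)
    site_alleles <- matrix("", nrow = k, ncol = n_chrom_copies)
    rows <- list()
    for (j in seq_len(k)) {
      alt1 <- sample(setdiff(bases, refb[j]), 1)
      # alt count uniform over 1..2n-1 so every frequency multiple of
      # 1/(2n) is reachable, including fixed differences (count = 2n)
      c1 <- sample.int(n_chrom_copies, 1)
      alleles <- rep(refb[j], n_chrom_copies)
      alleles[sample.int(n_chrom_copies, c1)] <- alt1
      if (runif(1) < triallelic_fraction) {
        alt2 <- sample(setdiff(bases, c(refb[j], alt1)), 1)
        ref_left <- which(alleles == refb[j])
        take <- min(length(ref_left), max(2L, round(n_chrom_copies / 8)))
        if (take > 0) alleles[sample(ref_left, take)] <- alt2
      }
      site_alleles[j, ] <- alleles
      tab <- table(alleles)
      rows[[j]] <- tibble(chrom = cc, pos = as.integer(pos[j]), ref = refb[j],
                          allele = names(tab), count = as.integer(tab))
    }
    planted[[cc]] <- bind_rows(rows)
    hap_mats[[cc]] <- list(pos = pos, alleles = site_alleles)
  }

  individuals <- purrr::map(seq_len(n_individuals), function(i) {
    hapA <- ref; hapB <- ref
    het <- list()
    for (cc in names(hap_mats)) {
      pos <- hap_mats[[cc]]$pos
      aA <- hap_mats[[cc]]$alleles[, 2L * i - 1L]
      aB <- hap_mats[[cc]]$alleles[, 2L * i]
      sA <- strsplit(hapA[[cc]], "", fixed = TRUE)[[1]]
      sB <- strsplit(hapB[[cc]], "", fixed = TRUE)[[1]]
      sA[pos] <- aA; sB[pos] <- aB
      hapA[[cc]] <- paste(sA, collapse = "")
      hapB[[cc]] <- paste(sB, collapse = "")
      hetsel <- aA != aB
      if (any(hetsel))
        het[[cc]] <- tibble(chrom = cc, pos = as.integer(pos[hetsel]),
                            allele_A = aA[hetsel], allele_B = aB[hetsel])
    }
    structure(list(haplotype_A = hapA, haplotype_B = hapB,
                   het_sites = bind_rows(het),
                   hemizygous_intervals = tibble(chrom = character(),
                                                 start = integer(),
                                                 end = integer()),
                   config = base_cfg),
              class = "diploid_truth")
  })
  list(individuals = individuals, reference = ref,
       planted_sites = bind_rows(planted))
}
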