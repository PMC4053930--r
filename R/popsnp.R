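# Pooled-population SNP calling. A pool of nine to fourteen diploid
# individuals sequenced as one library exposes population variation as
# allele fractions; with sixteen chromosomes in a pool, one chromosome is
# 1/16 = 6.25%, which motivates the minimum variant frequency default.

#' Call SNPs from pooled alignments
#'
#' A site is reported when: its central base quality meets `min_quality`;
#' its depth reaches `min_coverage`; and at least one non-consensus allele
#' has count >= `required_variant_count` and frequency >=
#' `min_variant_frequency` (frequency denominator = total site depth). The
#' neighbourhood filter drops a read's support for a site unless all its
#' bases inside the centred `window_length` window meet `min_quality`
#' (`quality_mode = "window"`); `"central"` checks only the site base and
#' `"off"` disables quality checking.
#'
#' @param alignments A [map_reads()] tibble or [read_sam()] output; reads
#'   should already have passed the mapping filters (similarity 0.9,
#'   length fraction 0.5 by [map_reads()] defaults).
#' @param assembly The assembly mapped against; its base at each site is
#'   the consensus the morphism classes are relative to.
#' @param window_length Neighbourhood window in bases; must be odd
#'   (default 51).
#' @param min_quality Minimum Phred base quality (default 20).
#' @param min_coverage Minimum site depth (default 20).
#' @param required_variant_count Minimum reads per reported allele
#'   (default 3).
#' @param min_variant_frequency Minimum allele frequency (default 0.0625,
#'   i.e. one chromosome in a 16-chromosome pool).
#' @param quality_mode `"window"`, `"central"` or `"off"`.
#' @return `pooled_snp_sites` tibble: `scaffold`, `pos`, `ref` (consensus
#'   base), `depth`, `alleles` (list-column of tibbles base/count/freq,
#'   passing alleles only), `n_alleles`, `morphism`.
#' @export
call_pooled_snps <- function(alignments, assembly, window_length = 51,
                             min_quality = 20, min_coverage = 20,
                             required_variant_count = 3,
                             min_variant_frequency = 0.0625,
                             quality_mode = c("window", "central", "off")) {
  quality_mode <- match.arg(quality_mode)
  if (window_length %% 2 == 0)
    abort("window_length must be odd so the window centres on the site")
  asm <- as_assembly(assembly)
  window <- switch(quality_mode, window = as.integer(window_length),
                   central = 1L, off = 0L)
  counts <- pileup_counts(alignments, asm, min_qual = min_quality,
                          window = window)
  bases <- c("A", "C", "G", "T")
  sites <- purrr::imap(counts, function(M, scf) {
    depth <- colSums(M)
    cand <- which(depth >= min_coverage)
    if (length(cand) == 0) return(NULL)
    refv <- substring(asm$sequence[asm$id == scf], cand, cand)
    sub <- M[, cand, drop = FALSE]
    d <- depth[cand]
    pass <- sub >= required_variant_count &
      sub >= min_variant_frequency * rep(d, each = 4)
    # reported iff some passing allele differs from the consensus
    ref_row <- match(refv, bases)
    nonref_pass <- pass
    ok_ref <- !is.na(ref_row)
    nonref_pass[cbind(ref_row[ok_ref], which(ok_ref))] <- FALSE
    keep <- which(colSums(nonref_pass) >= 1)
    if (length(keep) == 0) return(NULL)
    alleles <- purrr::map(keep, function(j) {
      sel <- which(pass[, j])
      tibble(base = bases[sel], count = unname(sub[sel, j]),
             freq = unname(sub[sel, j] / d[j]))
    })
    tibble(scaffold = scf, pos = as.integer(cand[keep]), ref = refv[keep],
           depth = as.integer(d[keep]), alleles = alleles,
           n_alleles = purrr::map_int(alleles, nrow))
  })
  out <- bind_rows(sites)
  if (nrow(out) == 0)
    out <- tibble(scaffold = character(), pos = integer(), ref = character(),
                  depth = integer(), alleles = list(), n_alleles = integer())
  out$morphism <- classify_morphism(out)
  class(out) <- c("pooled_snp_sites", class(out))
  out
}

#' Classify SNP sites by allele morphism
#'
#' The morphism class is the number of distinct passing alleles:
#' monomorphic (a single passing allele that differs from the consensus --
#' the pool is fixed for a non-reference base), dimorphic, trimorphic or
#' tetramorphic.
#'
#' @param sites A [call_pooled_snps()] tibble (or one row of it).
#' @return Character vector of morphism classes.
#' @export
classify_morphism <- function(sites) {
  if (nrow(sites) == 0) return(character(0))
  n <- sites$n_alleles
  if (any(n < 1)) abort("site with zero passing alleles should not be called")
  mono <- n == 1
  # a single passing allele equal to the consensus would mean the site was
  # never reportable; guard against inconsistent input
  single_ref <- mono & purrr::map2_lgl(sites$alleles, sites$ref,
                                       ~ all(.x$base == .y))
  if (any(single_ref))
    abort("monomorphic site whose only allele is the consensus base")
  c("monomorphic", "dimorphic", "trimorphic", "tetramorphic")[pmin(n, 4)]
}

#' Partition SNPs and SNP density by genomic region
#'
#' Classifies each SNP as exonic, intronic (inside a gene but not an exon)
#' or intergenic, with precedence exon > intron > intergenic, and reports
#' per-region SNP counts, non-N base counts and densities (SNPs/kbp).
#' Region base counts partition the non-N assembly length exactly, and
#' region SNP counts partition the total.
#'
#' @param sites A [call_pooled_snps()] tibble.
#' @param gene_models GFF3 path, or a tibble with `seqid`, `type`,
#'   `start`, `end` (1-based inclusive) containing `exon` features and
#'   gene-extent features (`gene` or `mRNA`).
#' @param assembly The assembly (for scaffold lengths and N masking).
#' @return List with `sites` (annotated with a `region` column) and
#'   `report` (tibble: region, snp_count, bases, density), with overall
#'   density as attribute `overall_density`.
#' @export
annotate_regions <- function(sites, gene_models, assembly) {
  asm <- as_assembly(assembly)
  gm <- if (is.character(gene_models)) read_gff3(gene_models) else gene_models
  bad <- gm$end > nchar(asm$sequence)[match(gm$seqid, asm$id)]
  if (any(bad, na.rm = TRUE)) {
    b <- gm[which(bad)[1], ]
    abort(sprintf("feature %s %s:%d-%d exceeds scaffold length",
                  b$type, b$seqid, b$start, b$end))
  }
  exon_counts <- 0; intron_counts <- 0; intergenic_counts <- 0
  region_rows <- list()
  sites$region <- NA_character_
  for (i in seq_len(nrow(asm))) {
    scf <- asm$id[i]
    L <- nchar(asm$sequence[i])
    ex <- gm[gm$seqid == scf & gm$type == "exon", ]
    gn <- gm[gm$seqid == scf & gm$type %in% c("gene", "mRNA"), ]
    ex_r <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
    gn_r <- IRanges::reduce(IRanges::IRanges(gn$start, gn$end))
    gn_r <- IRanges::union(gn_r, ex_r)  # exons imply gene extent
    intron_r <- IRanges::setdiff(gn_r, ex_r)
    all_r <- IRanges::IRanges(1L, L)
    intergenic_r <- IRanges::setdiff(all_r, gn_r)
    # N positions count in no region
    n_pos <- stringr::str_locate_all(asm$sequence[i], "N+")[[1]]
    n_r <- if (nrow(n_pos) > 0) IRanges::IRanges(n_pos[, 1], n_pos[, 2])
           else IRanges::IRanges()
    w <- function(r) sum(IRanges::width(IRanges::setdiff(r, n_r)))
    region_rows[[i]] <- tibble(
      region = c("exonic", "intronic", "intergenic"),
      bases = c(w(ex_r), w(intron_r), w(intergenic_r)))
    sel <- which(sites$scaffold == scf)
    if (length(sel) > 0) {
      p <- IRanges::IRanges(sites$pos[sel], sites$pos[sel])
      in_ex <- IRanges::overlapsAny(p, ex_r)
      in_gn <- IRanges::overlapsAny(p, gn_r)
      sites$region[sel] <- dplyr::case_when(in_ex ~ "exonic",
                                            in_gn ~ "intronic",
                                            TRUE ~ "intergenic")
    }
  }
  report <- bind_rows(region_rows) |>
    group_by(.data$region) |>
    summarise(bases = sum(.data$bases), .groups = "drop") |>
    left_join(count(tibble(region = sites$region), .data$region,
                    name = "snp_count"),
              by = "region") |>
    mutate(snp_count = dplyr::coalesce(.data$snp_count, 0L),
           density = .data$snp_count / (.data$bases / 1000)) |>
    arrange(factor(.data$region, c("exonic", "intronic", "intergenic"))) |>
    select("region", "snp_count", "bases", "density")
  attr(report, "overall_density") <-
    sum(report$snp_count) / (sum(report$bases) / 1000)
  list(sites = sites, report = report)
}
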