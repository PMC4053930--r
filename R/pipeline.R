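#' Pipeline configuration
#'
#' One nested configuration drives the whole pipeline; unknown keys are
#' rejected so typos fail loudly. Round-trips losslessly through YAML
#' ([read_pipeline_config()] / [write_pipeline_config()]).
#'
#' @param simulate Simulation section (see [sim_config()]).
#' @param pe_library,mp_library Library sections (see [library_spec()]);
#'   set `mp_library$enabled = FALSE` to skip mate-pair scaffolding.
#' @param assembly `k`, `min_multiplicity`, `min_identity`.
#' @param scaffolding Per-library-class `s`/`n` thresholds. Defaults are
#'   desk-scale; the published large-genome settings are `pe = list(s =
#'   500, n = 10)`, `mp = list(s = 1100, n = 25)` (6 kbp inserts) and
#'   `list(s = 3400, n = 3)` (10-12 kbp inserts).
#' @param sexscan `min_coverage`, `min_classify_length`,
#'   `threshold_fraction`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = list(), pe_library = list(),
                            mp_library = list(), assembly = list(),
                            scaffolding = list(), sexscan = list()) {
  defaults <- list(
    simulate = list(genome_length = 50000, heterozygosity = 0.005,
                    hemizygous_fraction = 0, n_chromosomes = 1,
                    repeat_fraction = 0, seed = 1),
    pe_library = list(fragment_mean = 600, fragment_sd = 50,
                      read_length = 100, coverage = 40, error_rate = 0,
                      base_quality = 40),
    mp_library = list(enabled = FALSE, fragment_mean = 6000,
                      fragment_sd = 500, read_length = 100, coverage = 20,
                      error_rate = 0, chimera_fraction = 0.3,
                      base_quality = 40),
    assembly = list(k = 25, min_multiplicity = 2, min_identity = 90),
    scaffolding = list(pe = list(s = 200, n = 5), mp = list(s = 300, n = 5)),
    sexscan = list(min_coverage = 10, min_classify_length = 10000,
                   threshold_fraction = 0.1))
  user <- list(simulate = simulate, pe_library = pe_library,
               mp_library = mp_library, assembly = assembly,
               scaffolding = scaffolding, sexscan = sexscan)
  cfg <- defaults
  for (sec in names(user)) {
    extra <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(extra) > 0)
      abort(sprintf("unknown key in %s: %s", sec,
                    paste(extra, collapse = ", ")))
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  extra <- setdiff(names(raw), c("simulate", "pe_library", "mp_library",
                                 "assembly", "scaffolding", "sexscan"))
  if (length(extra) > 0)
    abort(sprintf("unknown config section: %s", paste(extra, collapse = ", ")))
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full assembly pipeline on a simulated genome
#'
#' Stages, in order: simulate the diploid genome and libraries; de Bruijn
#' assembly with bubble popping; paired-end scaffolding; mate-pair
#' orientation filtering and scaffolding (when enabled); transcript-
#' evidence merging (when alignments are supplied); SNV density scan and
#' hemizygous-scaffold classification. All randomness flows from the
#' config seed. With an `out_dir`, per-stage artifacts (FASTA, TSV, VCF,
#' popped-branch auxiliary FASTA, AGP-like placement table) and a JSON
#' summary are written to disk.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param transcript_alignments Optional transcript evidence for
#'   [merge_by_transcripts()].
#' @param quiet Suppress per-stage messages.
#' @return List with `truth`, `assembly`, `scaffolds`, `sexscan`,
#'   `summary` (also serialised to `summary.json` under `out_dir`).
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         transcript_alignments = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))
  seed <- config$simulate$seed

  say("[simulate] genome %d bp", config$simulate$genome_length)
  truth <- simulate_diploid_genome(do.call(sim_config, config$simulate))
  pe_spec <- do.call(library_spec,
                     c(list(kind = "paired_end"), config$pe_library))
  pe <- simulate_reads(truth, pe_spec, seed = seed + 1L)

  k <- config$assembly$k
  if (k > pe_spec$read_length)
    abort(sprintf("assemble: k = %d exceeds the read length (%d)", k,
                  pe_spec$read_length))
  say("[assemble] %d read pairs, k=%d", nrow(pe), k)
  asm <- assemble_genome(pe, k = k,
                         min_multiplicity = config$assembly$min_multiplicity,
                         min_identity = config$assembly$min_identity)
  say("[assemble] %d contigs, N50 %d", nrow(asm$contigs),
      n50(asm$contigs$length))

  say("[scaffold:pe] s=%d n=%d", config$scaffolding$pe$s,
      config$scaffolding$pe$n)
  pe_aln <- map_read_pairs(pe, asm$contigs, library = "pe")
  pe_graph <- build_scaffold_graph(asm$contigs, pe_aln,
                                   s = config$scaffolding$pe$s,
                                   n = config$scaffolding$pe$n,
                                   fragment_mean = pe_spec$fragment_mean,
                                   kind = "paired_end")
  scaffolds <- scaffold_contigs(pe_graph)

  mp_filter <- NULL
  if (isTRUE(config$mp_library$enabled)) {
    mp_cfg <- config$mp_library
    mp_cfg$enabled <- NULL
    mp_spec <- do.call(library_spec, c(list(kind = "mate_pair"), mp_cfg))
    mp <- simulate_reads(truth, mp_spec, seed = seed + 2L)
    mp_aln <- map_read_pairs(mp, scaffolds, library = "mp")
    mp_filter <- filter_matepairs(mp_aln)
    say("[scaffold:mp] kept %d / removed %d pairs", nrow(mp_filter$kept),
        nrow(mp_filter$removed))
    mp_graph <- build_scaffold_graph(scaffolds, mp_filter$kept,
                                     s = config$scaffolding$mp$s,
                                     n = config$scaffolding$mp$n,
                                     fragment_mean = mp_spec$fragment_mean,
                                     kind = "mate_pair")
    scaffolds <- scaffold_contigs(mp_graph)
  }

  if (!is.null(transcript_alignments)) {
    say("[merge] transcript evidence: %d alignments",
        nrow(transcript_alignments))
    scaffolds <- merge_by_transcripts(scaffolds, transcript_alignments)
  }

  say("[sexscan] min_coverage=%d", config$sexscan$min_coverage)
  scan <- sexscan(pe, scaffolds,
                  min_coverage = config$sexscan$min_coverage,
                  min_classify_length = config$sexscan$min_classify_length,
                  threshold_fraction = config$sexscan$threshold_fraction)

  summary <- list(
    genome_length = config$simulate$genome_length,
    n_het_sites = nrow(truth$het_sites),
    n_contigs = nrow(asm$contigs),
    contig_n50 = n50(asm$contigs$length),
    n_scaffolds = nrow(scaffolds),
    scaffold_n50 = n50(scaffolds$length),
    popped = as.list(table(asm$popped$rule)),
    matepairs_removed = if (!is.null(mp_filter)) nrow(mp_filter$removed)
                        else NA_integer_,
    overall_snv_density = attr(scan$summaries, "overall_density") %||%
      (sum(scan$summaries$snv_count) / (sum(scan$summaries$length) / 1000)),
    classification = as.list(table(scan$summaries$classification)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(tibble(name = names(truth$haplotype_A),
                       seq = unname(truth$haplotype_A)),
                file.path(out_dir, "haplotype_A.fasta"))
    write_fasta(tibble(name = sprintf("%s cov=%.1f", asm$contigs$id,
                                      asm$contigs$mean_kmer_coverage),
                       seq = asm$contigs$sequence),
                file.path(out_dir, "contigs.fasta"))
    write_fasta(tibble(name = scaffolds$id, seq = scaffolds$sequence),
                file.path(out_dir, "scaffolds.fasta"))
    write_popped(asm$popped, file.path(out_dir, "popped"))
    utils::write.table(agp_table(scaffolds),
                       file.path(out_dir, "scaffolds.agp.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(scan$summaries,
                       file.path(out_dir, "snv_density.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    snvs <- scan$calls[scan$calls$is_snv, ]
    write_vcf(tibble(scaffold = snvs$scaffold, pos = snvs$pos,
                     ref = snvs$ref, alt = snvs$alt, depth = snvs$depth,
                     ad = paste(pmax(snvs$A, 0), pmax(snvs$C, 0),
                                pmax(snvs$G, 0), pmax(snvs$T, 0),
                                sep = ",")),
              tibble(name = scaffolds$id, length = scaffolds$length),
              file.path(out_dir, "snvs.vcf"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(truth = truth, assembly = asm, scaffolds = scaffolds,
                 sexscan = scan, summary = summary))
}

# auxiliary popped-branch FASTA (bubbleID|rule|identity|coverage headers)
# plus a TSV of all records
write_popped <- function(popped, prefix) {
  rows <- popped |>
    mutate(bubble = sprintf("bubble%05d", row_number()))
  if (nrow(rows) > 0) {
    aux <- rows |>
      tidyr::unnest(c("discarded_seqs", "discarded_cov",
                      "discarded_vertices")) |>
      filter(!is.na(.data$discarded_seqs))
    write_fasta(tibble(
      name = sprintf("%s|%s|%s|%s", aux$bubble, aux$rule,
                     ifelse(is.na(aux$identity), ".",
                            sprintf("%.1f", aux$identity)),
                     ifelse(is.na(aux$discarded_cov), ".",
                            sprintf("%.1f", aux$discarded_cov))),
      seq = aux$discarded_seqs), paste0(prefix, "_branches.fasta"))
  } else {
    write_fasta(tibble(name = character(), seq = character()),
                paste0(prefix, "_branches.fasta"))
  }
  flat <- rows |>
    select("bubble", "rule", "identity", "retained_seq", "nspan") |>
    mutate(identity = round(.data$identity, 2))
  utils::write.table(flat, paste0(prefix, "_records.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' AGP-like placement table for scaffolds
#'
#' One row per component (contig or gap): object, object coordinates,
#' component id or gap length, orientation.
#'
#' @param scaffolds A [scaffold_contigs()] tibble with `members`.
#' @return A plain data frame.
#' @export
agp_table <- function(scaffolds) {
  rows <- list()
  for (i in seq_len(nrow(scaffolds))) {
    m <- scaffolds$members[[i]]
    for (j in seq_len(nrow(m))) {
      rows[[length(rows) + 1]] <- data.frame(
        object = scaffolds$id[i], part = j * 2L - 1L,
        component = m$contig[j], orientation = m$orientation[j],
        gap_after = m$gap_after[j])
    }
  }
  do.call(rbind, rows)
}
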