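# Mate-pair filtering and s/n scaffolding. `s` is the minimum contig size
# to consider placing in a scaffold; `n` is the minimum number of read-pair
# links required to merge two contigs. The published settings for the
# corresponding library classes are s=500/n=10 (paired-end), s=1100/n=25
# (6 kbp mate-pair) and s=3400/n=3 (10-12 kbp mate-pair).

#' Filter mate-pair libraries by orientation
#'
#' Mate-pair protocols contaminate the library with short-fragment chimeras
#' that align forward-reverse instead of the expected reverse-forward. This
#' routes every pair either to `kept` or `removed` (a disjoint partition):
#' reverse-forward pairs are kept; forward-reverse and other same-scaffold
#' configurations are removed; unaligned pairs are removed with reason
#' `"unaligned"`. Pairs whose mates align to two different scaffolds cannot
#' be orientation-classified and are kept by default (they carry the
#' linking evidence scaffolding needs); set `keep_cross_contig = FALSE` to
#' remove them too.
#'
#' @param pairs Pair-alignment tibble from [map_read_pairs()] (must carry
#'   an `orientation` column, recomputed if absent).
#' @param keep_cross_contig Keep pairs spanning two scaffolds.
#' @return List with `kept` and `removed` tibbles; `removed` gains a
#'   `reason` column. `kept` and `removed` partition the input.
#' @export
filter_matepairs <- function(pairs, keep_cross_contig = TRUE) {
  if (!"orientation" %in% names(pairs))
    pairs$orientation <- classify_pair_orientation(pairs)
  keep_classes <- c("reverse_forward",
                    if (keep_cross_contig) "cross_contig")
  kept <- pairs[pairs$orientation %in% keep_classes, ]
  removed <- pairs[!pairs$orientation %in% keep_classes, ]
  removed$reason <- dplyr::case_when(
    removed$orientation == "unaligned" ~ "unaligned",
    removed$orientation == "forward_reverse" ~ "fr_orientation",
    removed$orientation == "cross_contig" ~ "cross_contig",
    TRUE ~ "other_orientation")
  list(kept = kept, removed = removed)
}

#' Build a scaffold graph from contigs and filtered pair alignments
#'
#' Pairs spanning two contigs imply an ordered, oriented link; links are
#' aggregated per oriented contig pair, links supported by fewer than `n`
#' pairs are discarded, and contigs shorter than `s` never enter the graph.
#' The gap estimate for a link is the mean over its supporting pairs of
#' (library fragment mean - the two flank spans); negative estimates are
#' later clipped to a single N.
#'
#' @param contigs Contig tibble (`id`, `sequence`) or named character
#'   vector.
#' @param pairs Kept pair alignments ([filter_matepairs()] output
#'   `$kept`), from a single library.
#' @param s Minimum contig size to place in a scaffold.
#' @param n Minimum number of supporting pairs per link.
#' @param fragment_mean Library fragment mean in bases (for gap
#'   estimation).
#' @param kind Library kind: `"mate_pair"` (reverse-forward) or
#'   `"paired_end"` (forward-reverse).
#' @return A `scaffold_graph`: list with `contigs`, `links` (tibble:
#'   from, to, n_pairs, gap -- signed contig indices), `s`, `n`.
#' @export
build_scaffold_graph <- function(contigs, pairs, s, n, fragment_mean,
                                 kind = c("mate_pair", "paired_end")) {
  kind <- match.arg(kind)
  if (s < 0 || n < 1) abort("need s >= 0 and n >= 1")
  asm <- as_assembly(contigs)
  asm$length <- nchar(asm$sequence)
  cross <- pairs[pairs$mapped1 & pairs$mapped2 &
                   pairs$scaffold1 != pairs$scaffold2, ]
  links <- tibble(from = integer(), to = integer(), n_pairs = integer(),
                  gap = double())
  if (nrow(cross) > 0) {
    # mate roles come from read order: mate 1 reads the fragment start
    # (strand '-' for reverse-forward mate-pairs, '+' for forward-reverse
    # paired-end), mate 2 the fragment end. A contig is genome-forward
    # when the observed mate strand equals the expected one.
    start_strand <- if (kind == "mate_pair") "-" else "+"
    end_strand <- if (kind == "mate_pair") "+" else "-"
    cr <- cross[asm$length[match(cross$scaffold1, asm$id)] >= s &
                  asm$length[match(cross$scaffold2, asm$id)] >= s, ]
    if (nrow(cr) > 0) {
      c_l <- match(cr$scaffold1, asm$id)
      c_r <- match(cr$scaffold2, asm$id)
      len_l <- asm$length[c_l]; len_r <- asm$length[c_r]
      fwd_l <- cr$strand1 == start_strand
      fwd_r <- cr$strand2 == end_strand
      span_l <- ifelse(fwd_l, len_l - cr$pos1 + 1L, cr$pos1 + cr$alen1 - 1L)
      span_r <- ifelse(fwd_r, cr$pos2 + cr$alen2 - 1L, len_r - cr$pos2 + 1L)
      gap <- fragment_mean - span_l - span_r
      from <- ifelse(fwd_l, c_l, -c_l)
      to <- ifelse(fwd_r, c_r, -c_r)
      # canonical representative of the link and its mirror
      flip <- abs(from) > abs(to)
      tmp <- from
      from[flip] <- -to[flip]
      to[flip] <- -tmp[flip]
      links <- tibble(from = from, to = to, gap = gap) |>
        group_by(.data$from, .data$to) |>
        summarise(n_pairs = n(), gap = mean(.data$gap), .groups = "drop") |>
        filter(.data$n_pairs >= n)
      # chimeric contamination can fabricate a weak alternative link
      # between two contigs; a link is kept only if it dominates every
      # other link on the same contig pair by a factor of two
      links <- links |>
        mutate(pair = paste(pmin(abs(.data$from), abs(.data$to)),
                            pmax(abs(.data$from), abs(.data$to)))) |>
        arrange(desc(.data$n_pairs)) |>
        group_by(.data$pair) |>
        summarise(from = first(.data$from), to = first(.data$to),
                  runner_up = if (n() > 1) dplyr::nth(.data$n_pairs, 2) else 0L,
                  n_pairs = first(.data$n_pairs),
                  gap = first(.data$gap), .groups = "drop") |>
        filter(.data$n_pairs >= 2 * .data$runner_up) |>
        arrange(abs(.data$from), abs(.data$to)) |>
        select("from", "to", "n_pairs", "gap")
    }
  }
  structure(list(contigs = asm, links = links, s = s, n = n),
            class = "scaffold_graph")
}

#' @export
print.scaffold_graph <- function(x, ...) {
  cat("<scaffold_graph> ", nrow(x$contigs), " contigs, ", nrow(x$links),
      " links (s=", x$s, ", n=", x$n, ")\n", sep = "")
  invisible(x)
}

#' Chain contigs into scaffolds
#'
#' Emits maximal unambiguous chains: a contig side with more than one
#' outgoing link terminates the chain (conservative fork handling), as does
#' a link whose target side has competing incoming links. Link cycles are
#' broken at the weakest link (lowest pair count). Gap Ns are
#' `max(round(gap), 1)`. Every contig -- including those shorter than `s`,
#' which never join a chain -- appears in exactly one scaffold.
#'
#' @param sgraph A [build_scaffold_graph()] result.
#' @return Scaffold tibble: `id`, `sequence`, `length`, and a `members`
#'   list-column of tibbles (contig, orientation, gap_after).
#' @export
scaffold_contigs <- function(sgraph) {
  asm <- sgraph$contigs
  links <- sgraph$links
  nclink <- nrow(links)
  # out-map over signed sides: link (f,t) gives out[f] = t and out[-t] = -f
  out_from <- c(links$from, -links$to)
  out_to <- c(links$to, -links$from)
  out_np <- c(links$n_pairs, links$n_pairs)
  out_gap <- c(links$gap, links$gap)
  get_out <- function(x) {
    hit <- which(out_from == x)
    if (length(hit) != 1) return(NULL)  # none or ambiguous fork
    list(to = out_to[hit], np = out_np[hit], gap = out_gap[hit])
  }
  visited <- rep(FALSE, nrow(asm))
  scaffolds <- list()
  for (cid in seq_len(nrow(asm))) {
    if (visited[cid]) next
    visited[cid] <- TRUE
    chain <- cid  # signed
    gaps <- numeric(0)
    nps <- numeric(0)
    extend <- function(chain, gaps, nps, dir) {
      repeat {
        cur <- chain[length(chain)]
        nx <- get_out(cur)
        if (is.null(nx)) break
        # target's in-side must be unambiguous too
        back <- which(out_from == -nx$to)
        if (length(back) != 1) break
        if (visited[abs(nx$to)]) break
        visited[abs(nx$to)] <<- TRUE
        chain <- c(chain, nx$to)
        gaps <- c(gaps, nx$gap)
        nps <- c(nps, nx$np)
      }
      list(chain = chain, gaps = gaps, nps = nps)
    }
    r <- extend(chain, gaps, nps)
    # leftward: extend from the reversed orientation, then flip back
    l <- extend(-cid, numeric(0), numeric(0))
    chain <- c(rev(-l$chain[-1]), r$chain)
    gaps <- c(rev(l$gaps), r$gaps)
    nps <- c(rev(l$nps), r$nps)
    # cycle check: does the last side link back to the first?
    closing <- get_out(chain[length(chain)])
    if (!is.null(closing) && closing$to == chain[1] && length(chain) > 1) {
      # break the cycle at its weakest link; w == m breaks the closing link
      m <- length(chain)
      all_np <- c(nps, closing$np)
      w <- which.min(all_np)
      if (w < m) {
        chain <- c(chain[(w + 1):m], chain[seq_len(w)])
        gaps <- c(if (w <= m - 2) gaps[(w + 1):(m - 1)], closing$gap,
                  if (w >= 2) gaps[seq_len(w - 1)])
      }
      inform(sprintf("link cycle broken at weakest link (%d pairs)",
                     as.integer(min(all_np))))
    }
    scaffolds[[length(scaffolds) + 1]] <- list(chain = chain, gaps = gaps)
  }
  build_scaffold_tibble(asm, scaffolds)
}

build_scaffold_tibble <- function(asm, scaffolds) {
  rows <- purrr::imap(scaffolds, function(sc, i) {
    chain <- sc$chain
    gap_n <- if (length(sc$gaps) > 0) pmax(round(sc$gaps), 1) else integer(0)
    seqs <- ifelse(chain > 0, asm$sequence[abs(chain)],
                   revcomp(asm$sequence[abs(chain)]))
    seq <- seqs[1]
    if (length(seqs) > 1)
      seq <- paste0(seq, paste0(strrep("N", gap_n), seqs[-1], collapse = ""))
    tibble(id = sprintf("scf%05d", i), sequence = seq, length = nchar(seq),
           members = list(tibble(
             contig = asm$id[abs(chain)],
             orientation = ifelse(chain > 0, "+", "-"),
             gap_after = c(as.integer(gap_n), NA_integer_))))
  })
  out <- bind_rows(rows)
  class(out) <- c("hetasm_scaffolds", class(out))
  out
}

#' Merge scaffolds spanned by transcript evidence
#'
#' Expressed sequences (ESTs / RNA-seq contigs) aligning across two
#' scaffolds are merge evidence. A merge needs at least `min_support`
#' spanning transcripts from at least `min_libraries` distinct libraries;
#' merged scaffolds are joined with exactly `gap` Ns (default 100).
#' A transcript spanning more than two scaffolds contributes pairwise
#' evidence for each adjacent pair along the transcript. Conflicting
#' merges on one scaffold end are resolved by support count, then scaffold
#' id. A spanning alignment must cover at least `min_aligned` bases on its
#' scaffold and sit within `edge_dist` of the scaffold end it exits from.
#'
#' @param scaffolds Scaffold tibble ([scaffold_contigs()] output or any
#'   tibble with `id`, `sequence`).
#' @param transcript_alignments Tibble with one row per
#'   transcript-to-scaffold alignment block: `transcript`, `library`,
#'   `scaffold`, `t_start`, `t_end` (transcript coordinates), `s_start`,
#'   `s_end` (scaffold coordinates, 1-based inclusive), `strand`.
#' @param min_support Minimum spanning transcripts per merge (default 2).
#' @param min_libraries Minimum distinct libraries among them (default 2).
#' @param gap N gap inserted between merged scaffolds (default 100).
#' @param min_aligned Minimum aligned bases per scaffold (default 50).
#' @param edge_dist Maximum distance from the scaffold edge (default
#'   10000).
#' @return A scaffold tibble; merged rows carry a `merged_from`
#'   list-column.
#' @export
merge_by_transcripts <- function(scaffolds, transcript_alignments,
                                 min_support = 2, min_libraries = 2,
                                 gap = 100, min_aligned = 50,
                                 edge_dist = 10000) {
  asm <- as_assembly(scaffolds)
  asm$length <- nchar(asm$sequence)
  ta <- transcript_alignments
  ta$idx <- match(ta$scaffold, asm$id)
  if (anyNA(ta$idx)) abort("transcript alignment names unknown scaffold")
  ta$alen <- ta$s_end - ta$s_start + 1L

  ev <- list()
  for (tr in unique(ta$transcript)) {
    rows <- ta[ta$transcript == tr, ]
    rows <- rows[order(rows$t_start), ]
    if (nrow(rows) < 2) next
    for (j in seq_len(nrow(rows) - 1)) {
      a <- rows[j, ]; b <- rows[j + 1, ]
      if (a$idx == b$idx) next
      if (a$alen < min_aligned || b$alen < min_aligned) next
      # exit end of the first scaffold, entry end of the second
      a_ok <- if (a$strand == "+") a$s_end >= asm$length[a$idx] - edge_dist
              else a$s_start <= edge_dist
      b_ok <- if (b$strand == "+") b$s_start <= edge_dist
              else b$s_end >= asm$length[b$idx] - edge_dist
      if (!a_ok || !b_ok) next
      from <- if (a$strand == "+") a$idx else -a$idx
      to <- if (b$strand == "+") b$idx else -b$idx
      if (abs(from) > abs(to)) { tmp <- from; from <- -to; to <- -tmp }
      ev[[length(ev) + 1]] <- tibble(from = from, to = to, transcript = tr,
                                     library = a$library)
    }
  }
  if (length(ev) == 0) return(scaffolds)
  ev <- bind_rows(ev) |>
    group_by(.data$from, .data$to) |>
    summarise(support = n_distinct(.data$transcript),
              libraries = n_distinct(.data$library), .groups = "drop") |>
    filter(.data$support >= min_support, .data$libraries >= min_libraries)
  if (nrow(ev) == 0) return(scaffolds)

  # resolve conflicts per scaffold side: best support, then scaffold id
  ev <- ev |> arrange(desc(.data$support), abs(.data$from), abs(.data$to))
  used_side <- character(0)
  keep <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    sides <- c(ev$from[i], -ev$to[i])
    if (any(as.character(sides) %in% used_side)) next
    keep[i] <- TRUE
    used_side <- c(used_side, as.character(sides))
  }
  ev <- ev[keep, ]

  links <- tibble(from = ev$from, to = ev$to, n_pairs = ev$support,
                  gap = gap)
  sg <- structure(list(contigs = asm, links = links, s = 0, n = 1),
                  class = "scaffold_graph")
  merged <- scaffold_contigs(sg)
  merged$merged_from <- purrr::map(merged$members, ~ .x$contig)
  # unmerged scaffolds keep their ids; merges get fresh ids
  nm <- lengths(merged$merged_from)
  merged$id[nm == 1] <- purrr::map_chr(merged$merged_from[nm == 1], 1)
  merged$id[nm > 1] <- sprintf("mrg%05d", seq_len(sum(nm > 1)))
  class(merged) <- c("hetasm_scaffolds", class(merged))
  merged
}
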