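# Bubble detection and resolution. A bubble is a source/sink pair (u, v)
# such that every walk leaving u re-converges at v through a non-empty,
# acyclic interior. Simple bubbles are the two-branch pattern in which the
# out-neighbourhood of u equals the in-neighbourhood of v; anything with
# more paths or internal branching is complex.

#' Find simple and complex bubbles in an assembly graph
#'
#' A pair (u, v) is reported when: u has at least two out-neighbours and
#' every one lies in the interior (the set of vertices on u-to-v paths);
#' at least two interior vertices converge directly at v; the interior's
#' edges stay inside the bubble (interior vertices only reach interior
#' vertices or v, and are only reached from interior vertices or u); no
#' interior vertex is a dead end; the interior is acyclic; and at least
#' two distinct u-to-v paths exist. Cyclic interiors are simply not
#' reported. Overlapping bubbles are reported outermost-first (largest
#' interior first).
#'
#' @param graph An [asm_graph()] (or unitig tibble / [build_kmer_graph()]
#'   result, converted via [as_asm_graph()]).
#' @param max_interior Abandon a candidate source once this many interior
#'   vertices have been seen (keeps scanning linear on large graphs).
#' @return List of `bubble` objects: `source`, `sink` (signed vertex ids),
#'   `interior`, `kind` ("simple"/"complex"), and for simple bubbles a
#'   `branches` tibble (vertex, seq, cov, len).
#' @export
find_bubbles <- function(graph, max_interior = 64) {
  if (inherits(graph, "kmer_graph")) graph <- as_asm_graph(assemble_unitigs(graph))
  if (inherits(graph, "hetasm_contigs")) graph <- as_asm_graph(graph)
  stopifnot(inherits(graph, "asm_graph"))
  g <- graph
  adj <- build_adj(g)
  adjin <- build_adj_in(g)
  n <- nrow(g$vertices)
  sources <- integer(0)
  for (x in c(seq_len(n), -seq_len(n))) {
    if (!g$vertices$alive[abs(x)]) next
    if (length(adj_succ(adj, x)) >= 2) sources <- c(sources, x)
  }
  bubbles <- list()
  for (u in sources) {
    # candidate sinks in BFS discovery order from u; cheap necessary
    # conditions first: a sink needs >= 2 converging in-edges, all from
    # vertices reachable from u, and a direct u->v edge disqualifies
    reach <- bfs_from(adj, u, max_interior + 2L)
    u_out <- adj_succ(adj, u)
    for (v in setdiff(reach, u)) {
      if (v %in% u_out) next
      inn <- adj_in(adjin, v)
      if (length(inn) < 2) next
      if (u %in% inn || !all(inn %in% reach)) next
      b <- check_bubble(g, adj, adjin, u, v, max_interior)
      if (!is.null(b)) bubbles[[length(bubbles) + 1]] <- b
    }
  }
  # outermost-first; deterministic tie-break on endpoints
  if (length(bubbles) > 0) {
    ord <- order(-vapply(bubbles, function(b) length(b$interior), integer(1)),
                 vapply(bubbles, function(b) abs(b$source), integer(1)),
                 vapply(bubbles, function(b) b$source, integer(1)),
                 vapply(bubbles, function(b) b$sink, integer(1)))
    bubbles <- bubbles[ord]
  }
  bubbles
}

bfs_from <- function(adj, u, cap) {
  seen <- u
  frontier <- u
  while (length(frontier) > 0 && length(seen) <= cap) {
    nxt <- unique(unlist(lapply(frontier, function(x) adj_succ(adj, x))))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# predicate: is (u, v) a bubble? Returns a bubble object or NULL.
check_bubble <- function(g, adj, adjin, u, v, max_interior) {
  if (u == v || abs(u) == abs(v)) return(NULL)
  if (length(adj_succ(adj, u)) < 2) return(NULL)
  if (length(adj_in(adjin, v)) < 2) return(NULL)
  # forward reach from u without expanding v
  seen <- u
  frontier <- u
  reached_v <- FALSE
  ok <- TRUE
  while (length(frontier) > 0) {
    nxt <- unique(unlist(lapply(frontier, function(x) adj_succ(adj, x))))
    if (v %in% nxt) reached_v <- TRUE
    nxt <- setdiff(nxt, c(seen, v))
    if (u %in% nxt) { ok <- FALSE; break }  # cycle back through u
    seen <- c(seen, nxt)
    if (length(seen) > max_interior + 2L) { ok <- FALSE; break }
    frontier <- nxt
  }
  if (!ok || !reached_v) return(NULL)
  interior <- setdiff(seen, u)
  if (length(interior) == 0) return(NULL)
  if (any(abs(interior) %in% c(abs(u), abs(v)))) return(NULL)
  if (anyDuplicated(abs(interior)) > 0) return(NULL)  # strand-fold: skip
  # all of u's out-neighbours must enter the interior (v not among them)
  if (!all(adj_succ(adj, u) %in% interior)) return(NULL)
  # interior closure and no dead ends
  for (w in interior) {
    sw <- adj_succ(adj, w)
    if (length(sw) == 0) return(NULL)
    if (!all(sw %in% c(interior, v))) return(NULL)
    if (!all(adj_in(adjin, w) %in% c(interior, u))) return(NULL)
  }
  if (!all(adj_in(adjin, v) %in% interior)) return(NULL)
  # acyclic interior (two or more distinct u->v paths then follow from the
  # >= 2 out-branches of u, closure, and dead-end freedom)
  topo <- topo_sort(adj, interior)
  if (is.null(topo)) return(NULL)

  simple <- length(interior) == 2 &&
    setequal(adj_succ(adj, u), interior) &&
    setequal(adj_in(adjin, v), interior) &&
    all(vapply(interior, function(w)
      identical(adj_succ(adj, w), v) &&
        identical(adj_in(adjin, w), u), logical(1)))
  branches <- NULL
  if (simple) {
    bs <- sort(interior)
    branches <- tibble(vertex = bs, seq = seq_or(g, bs),
                       cov = g$vertices$cov[abs(bs)],
                       len = nchar(g$vertices$seq[abs(bs)]))
  }
  structure(list(source = u, sink = v, interior = sort(interior),
                 kind = if (simple) "simple" else "complex",
                 branches = branches),
            class = "bubble")
}

# Kahn topological sort restricted to `verts`; NULL if cyclic
topo_sort <- function(adj, verts) {
  if (length(verts) == 0) return(integer(0))
  # in-degree within the induced subgraph
  indeg <- setNames(rep(0L, length(verts)), verts)
  for (x in verts) {
    sx <- intersect(adj_succ(adj, x), verts)
    for (y in sx) indeg[match(y, verts)] <- indeg[match(y, verts)] + 1L
  }
  queue <- verts[indeg == 0]
  out <- integer(0)
  while (length(queue) > 0) {
    x <- queue[1]; queue <- queue[-1]
    out <- c(out, x)
    for (y in intersect(adj_succ(adj, x), verts)) {
      i <- match(y, verts)
      indeg[i] <- indeg[i] - 1L
      if (indeg[i] == 0) queue <- c(queue, y)
    }
  }
  if (length(out) != length(verts)) return(NULL)
  out
}

#' Pop a simple bubble by the short two-SNV rule
#'
#' A simple bubble whose branches are shorter than `3 * k` is popped when
#' the two branches are substitution-only variants of one another: equal
#' length, at most two mismatching positions, and all mismatches within one
#' k-base window (mismatches further apart belong to separate bubbles and
#' are not popped here). The branch with the most coverage is retained;
#' coverage ties retain the lexicographically smaller sequence. The
#' discarded branch is preserved in the returned record.
#'
#' @param bubble A simple `bubble` from [find_bubbles()].
#' @param k The k-mer size the graph was built with.
#' @return A one-row popped-record tibble, or `NULL` when the rule does not
#'   apply (no-op).
#' @export
pop_simple_bubble <- function(bubble, k) {
  if (bubble$kind != "simple") abort("pop_simple_bubble() needs a simple bubble")
  br <- bubble$branches
  if (max(br$len) >= 3 * k) return(NULL)
  if (br$len[1] != br$len[2]) return(NULL)
  s1 <- strsplit(br$seq[1], "", fixed = TRUE)[[1]]
  s2 <- strsplit(br$seq[2], "", fixed = TRUE)[[1]]
  diffs <- which(s1 != s2)
  if (length(diffs) == 0 || length(diffs) > 2) return(NULL)
  if (length(diffs) == 2 && (diffs[2] - diffs[1]) > k) return(NULL)
  popped_record(bubble, rule = "short_two_snv", identity = NA_real_)
}

#' Pop a long simple bubble by the identity rule
#'
#' Simple bubbles with branch length at least `3 * k` are popped when a
#' global alignment of the two branches (unit match/mismatch/gap costs)
#' shows at least `min_identity` percent identity, computed as matches over
#' alignment columns. The higher-coverage branch is retained.
#'
#' @param bubble A simple `bubble`.
#' @param k K-mer size (for the 3k length threshold).
#' @param min_identity Minimum percent identity to pop (default 90).
#' @return A one-row popped-record tibble, or `NULL` (no-op).
#' @export
pop_long_bubble <- function(bubble, k, min_identity = 90) {
  if (bubble$kind != "simple") abort("pop_long_bubble() needs a simple bubble")
  br <- bubble$branches
  if (max(br$len) < 3 * k) return(NULL)
  # identity can never exceed min(len)/max(len): skip hopeless alignments
  if (100 * min(br$len) / max(br$len) < min_identity) return(NULL)
  if (prod(as.numeric(br$len)) > 4e7) {
    warn(sprintf("branches too long to align (%d x %d bases); bubble kept",
                 br$len[1], br$len[2]))
    return(NULL)
  }
  al <- cpp_global_align(br$seq[1], br$seq[2])
  if (al$identity < min_identity) return(NULL)
  popped_record(bubble, rule = "long_identity", identity = al$identity)
}

# build the popped record: retain most coverage, ties -> lexicographically
# smaller sequence; the discarded branch is archived, never lost
popped_record <- function(bubble, rule, identity) {
  br <- bubble$branches
  keep <- if (br$cov[1] > br$cov[2]) 1L
          else if (br$cov[2] > br$cov[1]) 2L
          else if (br$seq[1] <= br$seq[2]) 1L else 2L
  drop <- 3L - keep
  tibble(source = bubble$source, sink = bubble$sink, rule = rule,
         identity = identity,
         retained_vertex = br$vertex[keep], retained_seq = br$seq[keep],
         retained_cov = br$cov[keep],
         discarded_vertices = list(br$vertex[drop]),
         discarded_seqs = list(br$seq[drop]),
         discarded_cov = list(br$cov[drop]),
         nspan = NA_integer_)
}

#' Resolve a complex bubble by scaffolding across it with Ns
#'
#' Rather than pick a representative branch, the whole interior is replaced
#' by a span of Ns whose length is the longest path through the bubble:
#' the maximum over u-to-v paths of the interior bases contributed beyond
#' the source and sink sequences (each graph junction absorbs `ov` overlap
#' bases). Computed by dynamic programming over a topological order of the
#' interior; a cyclic interior is an error.
#'
#' @param bubble A complex (or degenerate single-path) `bubble`.
#' @param graph The [asm_graph()] the bubble was found in.
#' @return List with `nspan` (N count), and `record` (popped-record row
#'   archiving all interior sequences).
#' @export
resolve_complex_bubble <- function(bubble, graph) {
  g <- graph
  adj <- build_adj(g)
  interior <- bubble$interior
  topo <- topo_sort(adj, interior)
  if (is.null(topo)) abort("complex bubble has a cyclic interior")
  u <- bubble$source; v <- bubble$sink
  ov <- g$ov
  lens <- setNames(nchar(g$vertices$seq[abs(topo)]), topo)
  dist <- setNames(rep(-Inf, length(topo) + 2), c(u, topo, v))
  dist[as.character(u)] <- 0
  for (x in c(u, topo)) {
    dx <- dist[as.character(x)]
    if (!is.finite(dx)) next
    for (y in adj_succ(adj, x)) {
      key <- as.character(y)
      if (!key %in% names(dist)) next
      gain <- if (y == v) -ov else lens[key] - ov
      dist[key] <- max(dist[key], dx + gain)
    }
  }
  L <- dist[as.character(v)]
  if (!is.finite(L)) abort("sink not reachable through the bubble interior")
  nspan <- max(as.integer(L), 1L)
  rec <- tibble(source = u, sink = v, rule = "complex_span",
                identity = NA_real_,
                retained_vertex = NA_integer_, retained_seq = NA_character_,
                retained_cov = NA_real_,
                discarded_vertices = list(interior),
                discarded_seqs = list(seq_or(g, interior)),
                discarded_cov = list(g$vertices$cov[abs(interior)]),
                nspan = nspan)
  list(nspan = nspan, record = rec)
}

#' Pop all bubbles in an assembly graph
#'
#' Iterates bubble detection and resolution to a fixed point: simple
#' bubbles are popped by the short two-SNV rule or the long identity rule
#' (retaining the higher-coverage branch and archiving the other); complex
#' bubbles are scaffolded over with an N span sized by the longest interior
#' path. Nested bubbles resolve innermost-first, with a compaction and
#' re-scan between rounds. Bubbles matching neither rule are left intact.
#'
#' @param x An [asm_graph()], unitig tibble, or [build_kmer_graph()] result.
#' @param k K-mer size (taken from the contig attributes when present).
#' @param min_identity Identity threshold for the long-bubble rule.
#' @param max_rounds Safety cap on detect/pop/compact rounds.
#' @param max_interior Interior-size cap passed to [find_bubbles()];
#'   popping targets local structures, so a modest cap keeps each round
#'   linear in graph size.
#' @param max_span Complex bubbles whose interior contains a vertex of at
#'   least this many bases are left intact rather than N-spanned (default
#'   `10 * k`). Bubble scaffolding targets short tangles from near-repeats
#'   and clustered variation; a large interior vertex is genuine unique
#'   sequence (for example a hemizygous block forming a deletion bubble
#'   against the other haplotype) that must stay in the assembly.
#' @return List with `contigs` (tibble of surviving contigs), `popped`
#'   (tibble of popped records), and `graph` (the final `asm_graph`).
#' @export
pop_bubbles <- function(x, k = NULL, min_identity = 90, max_rounds = 20,
                        max_interior = 16, max_span = NULL) {
  if (inherits(x, "kmer_graph")) x <- assemble_unitigs(x)
  if (inherits(x, "hetasm_contigs")) {
    k <- k %||% attr(x, "k")
    g <- as_asm_graph(x)
  } else {
    g <- x
  }
  stopifnot(inherits(g, "asm_graph"))
  if (is.null(k)) k <- g$ov + 1L
  if (is.null(max_span)) max_span <- 10L * k
  records <- list()
  for (round in seq_len(max_rounds)) {
    g <- compact_graph(g)
    bubbles <- find_bubbles(g, max_interior = max_interior)
    bubbles <- dedupe_mirror_bubbles(bubbles)
    if (length(bubbles) == 0) break
    # innermost-first within a round
    ord <- order(vapply(bubbles, function(b) length(b$interior), integer(1)),
                 vapply(bubbles, function(b) abs(b$source), integer(1)))
    bubbles <- bubbles[ord]
    # vertices deleted or rewired this round; a bubble referencing one is
    # stale and re-examined next round. A simple pop deletes only the
    # discarded branch, so bubbles merely sharing its endpoints stay valid.
    blocked <- integer(0)
    popped_any <- FALSE
    for (b in bubbles) {
      verts <- c(abs(b$source), abs(b$sink), abs(b$interior))
      if (any(verts %in% blocked)) next
      if (b$kind == "simple") {
        rec <- pop_simple_bubble(b, k)
        if (is.null(rec)) rec <- pop_long_bubble(b, k, min_identity)
        if (is.null(rec)) next
        g <- drop_vertices(g, abs(rec$discarded_vertices[[1]]))
        records[[length(records) + 1]] <- rec
        blocked <- c(blocked, abs(rec$discarded_vertices[[1]]))
      } else {
        if (max(nchar(g$vertices$seq[abs(b$interior)])) >= max_span) next
        res <- resolve_complex_bubble(b, g)
        g <- splice_nspan(g, b, res$nspan)
        records[[length(records) + 1]] <- res$record
        blocked <- c(blocked, verts)
      }
      popped_any <- TRUE
    }
    if (!popped_any) break
  }
  g <- compact_graph(g)
  popped <- if (length(records) > 0) bind_rows(records) else
    tibble(source = integer(), sink = integer(), rule = character(),
           identity = double(), retained_vertex = integer(),
           retained_seq = character(), retained_cov = double(),
           discarded_vertices = list(), discarded_seqs = list(),
           discarded_cov = list(), nspan = integer())
  list(contigs = contigs_from_graph(g, k), popped = popped, graph = g)
}

# mirrored copies of one bubble (u,v) vs (-v,-u) describe the same event
dedupe_mirror_bubbles <- function(bubbles) {
  if (length(bubbles) == 0) return(bubbles)
  keys <- vapply(bubbles, function(b)
    paste(sort(c(abs(b$source), abs(b$sink), abs(b$interior))),
          collapse = ","), character(1))
  bubbles[!duplicated(keys)]
}

# replace u + interior + v by one vertex: seq(u) + N*nspan + seq(v)
splice_nspan <- function(g, bubble, nspan) {
  u <- bubble$source; v <- bubble$sink
  adj <- build_adj(g)
  adjin <- build_adj_in(g)
  preds <- setdiff(adj_in(adjin, u), c(bubble$interior, u, v))
  succs <- setdiff(adj_succ(adj, v), c(bubble$interior, u, v))
  newseq <- paste0(seq_or(g, u), strrep("N", nspan), seq_or(g, v))
  lu <- nchar(g$vertices$seq[abs(u)]); lv <- nchar(g$vertices$seq[abs(v)])
  covs <- g$vertices$cov[c(abs(u), abs(v))]
  w <- !is.na(covs)
  cov <- if (any(w)) sum(covs[w] * c(lu, lv)[w]) / sum(c(lu, lv)[w]) else NA_real_
  res <- add_vertex(g, newseq, cov)
  g <- res$g; nid <- res$id
  g <- drop_vertices(g, unique(c(abs(u), abs(v), abs(bubble$interior))))
  g <- add_edges_mirrored(g, c(preds, rep(nid, length(succs))),
                          c(rep(nid, length(preds)), succs))
  g
}

#' Assemble reads into bubble-popped contigs
#'
#' Convenience pipeline: [build_kmer_graph()], [assemble_unitigs()],
#' [pop_bubbles()].
#'
#' @inheritParams build_kmer_graph
#' @inheritParams pop_bubbles
#' @return A `hetasm_assembly` object: list with `contigs`, `popped`,
#'   `graph`, `k`.
#' @export
assemble_genome <- function(reads, k = 25, min_multiplicity = 2,
                            min_identity = 90) {
  kg <- build_kmer_graph(reads, k = k, min_multiplicity = min_multiplicity)
  un <- assemble_unitigs(kg)
  pb <- pop_bubbles(un, k = k, min_identity = min_identity)
  structure(list(contigs = pb$contigs, popped = pb$popped, graph = pb$graph,
                 k = k), class = "hetasm_assembly")
}

#' @export
print.hetasm_assembly <- function(x, ...) {
  cat("<hetasm_assembly> ", nrow(x$contigs), " contigs, N50 ",
      n50(x$contigs$length), " bp, ", nrow(x$popped),
      " popped bubbles\n", sep = "")
  invisible(x)
}
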