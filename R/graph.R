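# Contig adjacency graph with signed-vertex orientation semantics:
# vertex +i is contig i in its stored orientation, -i its reverse
# complement. An edge (a -> b) means b's oriented sequence follows a's with
# `ov` overlapping bases (ov = k-1 for unitig graphs, 0 for abstract
# graphs). Every edge implies the mirror edge (-b -> -a); assembly graphs
# are kept mirror-closed, abstract test graphs need not be.

#' Construct a contig adjacency graph
#'
#' @param seqs Character vector of vertex sequences.
#' @param edges Tibble or data.frame with signed integer columns
#'   `from`/`to`.
#' @param cov Optional numeric coverage per vertex.
#' @param ov Overlap in bases implied by an edge (k-1 for de Bruijn unitig
#'   graphs; 0 for abstract graphs).
#' @param mirror Add the reverse-complement mirror of every edge and treat
#'   the graph as strand-symmetric.
#' @return An `asm_graph` object.
#' @export
asm_graph <- function(seqs, edges, cov = NULL, ov = 0, mirror = FALSE) {
  n <- length(seqs)
  vertices <- tibble(id = seq_len(n), seq = unname(seqs),
                     cov = cov %||% rep(NA_real_, n),
                     alive = TRUE)
  edges <- tibble(from = as.integer(edges$from), to = as.integer(edges$to))
  if (mirror)
    edges <- distinct(bind_rows(edges,
                                tibble(from = -edges$to, to = -edges$from)))
  structure(list(vertices = vertices, edges = distinct(edges),
                 ov = as.integer(ov), mirrored = mirror),
            class = "asm_graph")
}

#' Convert unitigs to an assembly graph
#'
#' @param contigs A [assemble_unitigs()] result (tibble with `adjacency`
#'   and `k` attributes).
#' @return An `asm_graph` with overlap k-1.
#' @export
as_asm_graph <- function(contigs) {
  k <- attr(contigs, "k")
  adj <- attr(contigs, "adjacency")
  asm_graph(contigs$sequence, adj, cov = contigs$mean_kmer_coverage,
            ov = k - 1L, mirror = TRUE)
}

#' @export
print.asm_graph <- function(x, ...) {
  cat("<asm_graph> ", sum(x$vertices$alive), " vertices, ",
      nrow(x$edges), " oriented edges, overlap ", x$ov, "\n", sep = "")
  invisible(x)
}

# oriented sequence of signed vertex x
seq_or <- function(g, x) {
  s <- g$vertices$seq[abs(x)]
  ifelse(x > 0, s, revcomp(s))
}

# adjacency list keyed by signed vertex: index = x + n + 1
build_adj <- function(g) {
  n <- nrow(g$vertices)
  out <- vector("list", 2 * n + 1)
  alive <- g$vertices$alive
  e <- g$edges
  keep <- alive[abs(e$from)] & alive[abs(e$to)]
  e <- e[keep, ]
  if (nrow(e) > 0) {
    sp <- split(e$to, e$from)
    idx <- as.integer(names(sp)) + n + 1L
    out[idx] <- sp
  }
  list(out = out, n = n)
}

adj_succ <- function(adj, x) {
  r <- adj$out[[x + adj$n + 1L]]
  if (is.null(r)) integer(0) else r
}
adj_pred <- function(adj, x) {
  r <- adj$out[[-x + adj$n + 1L]]
  if (is.null(r)) integer(0) else -r
}

# in a non-mirrored (abstract) graph the predecessor lookup above is wrong;
# build an explicit in-adjacency instead
build_adj_in <- function(g) {
  n <- nrow(g$vertices)
  inn <- vector("list", 2 * n + 1)
  alive <- g$vertices$alive
  e <- g$edges
  keep <- alive[abs(e$from)] & alive[abs(e$to)]
  e <- e[keep, ]
  if (nrow(e) > 0) {
    sp <- split(e$from, e$to)
    idx <- as.integer(names(sp)) + n + 1L
    inn[idx] <- sp
  }
  list(inn = inn, n = n)
}

adj_in <- function(adjin, x) {
  r <- adjin$inn[[x + adjin$n + 1L]]
  if (is.null(r)) integer(0) else r
}

# drop vertices (by absolute id); edges touching dead vertices are
# filtered lazily by the adjacency builders and compaction
drop_vertices <- function(g, ids) {
  g$vertices$alive[ids] <- FALSE
  g
}

# add a vertex; returns list(graph, id)
add_vertex <- function(g, seq, cov = NA_real_) {
  g$vertices <- bind_rows(g$vertices,
                          tibble(id = nrow(g$vertices) + 1L, seq = seq,
                                 cov = cov, alive = TRUE))
  list(g = g, id = nrow(g$vertices))
}

add_edges_mirrored <- function(g, from, to) {
  if (length(from) == 0) return(g)
  e <- tibble(from = as.integer(from), to = as.integer(to))
  g$edges <- distinct(bind_rows(g$edges, e, tibble(from = -e$to, to = -e$from)))
  g
}

# merge the oriented sequences of a chain, dropping `ov` overlap bases at
# each junction; length-weighted mean coverage (N-span vertices carry NA
# coverage and are excluded from the mean)
chain_seq_cov <- function(g, path) {
  seqs <- seq_or(g, path)
  merged <- seqs[1]
  if (length(seqs) > 1)
    merged <- paste0(merged,
                     paste(substring(seqs[-1], g$ov + 1), collapse = ""))
  covs <- g$vertices$cov[abs(path)]
  lens <- nchar(seqs)
  w <- !is.na(covs)
  cov <- if (any(w)) sum(covs[w] * lens[w]) / sum(lens[w]) else NA_real_
  list(seq = merged, cov = cov)
}

# compact all maximal non-branching chains (assembly graphs: mirror-closed).
# All chains of one pass are vertex-disjoint and merged in a single batch;
# a second pass catches chains formed by the first.
compact_graph <- function(g) {
  repeat {
    adj <- build_adj(g)
    alive <- which(g$vertices$alive)
    visited <- rep(FALSE, nrow(g$vertices))
    chains <- list()
    for (a in alive) {
      if (visited[a]) next
      path <- a
      visited[a] <- TRUE
      repeat {  # forward
        s <- adj_succ(adj, path[length(path)])
        if (length(s) != 1) break
        nx <- s
        if (visited[abs(nx)] || abs(nx) %in% abs(path)) break
        if (length(adj_pred(adj, nx)) != 1) break
        path <- c(path, nx)
        visited[abs(nx)] <- TRUE
      }
      repeat {  # backward
        p <- adj_pred(adj, path[1])
        if (length(p) != 1) break
        pv <- p
        if (visited[abs(pv)] || abs(pv) %in% abs(path)) break
        if (length(adj_succ(adj, pv)) != 1) break
        path <- c(pv, path)
        visited[abs(pv)] <- TRUE
      }
      if (length(path) > 1) chains[[length(chains) + 1]] <- path
    }
    if (length(chains) == 0) break

    n0 <- nrow(g$vertices)
    # chain membership and boundary maps over absolute ids
    chain_of <- integer(n0)
    head_v <- integer(length(chains)); tail_v <- integer(length(chains))
    new_rows <- vector("list", length(chains))
    for (ci in seq_along(chains)) {
      p <- chains[[ci]]
      chain_of[abs(p)] <- ci
      head_v[ci] <- p[1]; tail_v[ci] <- p[length(p)]
      sc <- chain_seq_cov(g, p)
      new_rows[[ci]] <- tibble(id = n0 + ci, seq = sc$seq, cov = sc$cov,
                               alive = TRUE)
    }
    g$vertices <- bind_rows(g$vertices, bind_rows(new_rows))
    new_id <- n0 + seq_along(chains)

    map_from <- function(x) {  # vectorised endpoint mapping, NA = drop
      ci <- chain_of[abs(x)]
      out <- x
      inchain <- ci > 0
      out[inchain] <- NA_integer_
      hit <- inchain & x == tail_v[pmax(ci, 1L)]
      out[hit] <- new_id[ci[hit]]
      hit <- inchain & x == -head_v[pmax(ci, 1L)]
      out[hit] <- -new_id[ci[hit]]
      out
    }
    map_to <- function(x) {
      ci <- chain_of[abs(x)]
      out <- x
      inchain <- ci > 0
      out[inchain] <- NA_integer_
      hit <- inchain & x == head_v[pmax(ci, 1L)]
      out[hit] <- new_id[ci[hit]]
      hit <- inchain & x == -tail_v[pmax(ci, 1L)]
      out[hit] <- -new_id[ci[hit]]
      out
    }
    e <- g$edges
    keep <- g$vertices$alive[abs(e$from)] & g$vertices$alive[abs(e$to)]
    e <- e[keep, ]
    f2 <- map_from(e$from); t2 <- map_to(e$to)
    ok <- !is.na(f2) & !is.na(t2)
    g$edges <- distinct(tibble(from = f2[ok], to = t2[ok]))
    g$vertices$alive[which(chain_of > 0)] <- FALSE
  }
  g
}

# extract the surviving contigs as a tibble
contigs_from_graph <- function(g, k = NULL) {
  v <- g$vertices[g$vertices$alive, ]
  seqs <- v$seq
  canon <- pmin(seqs, revcomp(seqs))
  ord <- order(canon)
  out <- tibble(id = sprintf("ctg%05d", seq_along(ord)),
                sequence = canon[ord],
                length = nchar(canon[ord]),
                mean_kmer_coverage = v$cov[ord])
  if (!is.null(k)) attr(out, "k") <- k
  class(out) <- c("hetasm_contigs", class(out))
  out
}
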