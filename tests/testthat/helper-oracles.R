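# Test-side oracles, independent of the package's graph machinery: bubble
# detection by exhaustive path enumeration, longest paths by enumerating
# every path, and plain-R k-mer bookkeeping.

# all simple paths u -> v in a digraph given as an edge data frame
enumerate_paths <- function(edges, u, v, cap = 1e5) {
  out_of <- split(edges$to, edges$from)
  res <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == v) {
      res[[length(res) + 1]] <<- path
      return(invisible())
    }
    for (nx in out_of[[as.character(last)]]) {
      if (nx %in% path) next
      walk(c(path, nx))
      if (length(res) > cap) stop("path cap exceeded")
    }
  }
  walk(u)
  res
}

# does the subgraph induced on `verts` contain a directed cycle?
has_cycle <- function(edges, verts) {
  e <- edges[edges$from %in% verts & edges$to %in% verts, ]
  # exhaustive: repeatedly strip vertices with no outgoing edge
  vs <- verts
  repeat {
    sink_like <- vs[!vs %in% e$from[e$to %in% vs & e$from %in% vs]]
    # strip vertices with no incoming edge instead (either works)
    have_in <- unique(e$to[e$from %in% vs & e$to %in% vs])
    removable <- setdiff(vs, have_in)
    if (length(removable) == 0) return(length(vs) > 0)
    vs <- setdiff(vs, removable)
    if (length(vs) == 0) return(FALSE)
  }
}

# brute-force bubble finder over all ordered vertex pairs, by literal
# condition checking on enumerated paths
oracle_bubbles <- function(n, edges) {
  out_of <- function(x) edges$to[edges$from == x]
  in_of <- function(x) edges$from[edges$to == x]
  found <- list()
  for (u in seq_len(n)) {
    if (length(out_of(u)) < 2) next
    for (v in seq_len(n)) {
      if (u == v) next
      ps <- tryCatch(enumerate_paths(edges, u, v),
                     error = function(e) NULL)
      if (is.null(ps) || length(ps) < 2) next
      interior <- setdiff(unique(unlist(ps)), c(u, v))
      if (length(interior) == 0) next
      if (!all(out_of(u) %in% interior)) next
      if (length(in_of(v)) < 2 || !all(in_of(v) %in% interior)) next
      ok <- TRUE
      for (w in interior) {
        sw <- out_of(w)
        if (length(sw) == 0 || !all(sw %in% c(interior, v)) ||
            !all(in_of(w) %in% c(interior, u))) { ok <- FALSE; break }
      }
      if (!ok) next
      if (has_cycle(edges, interior)) next
      simple <- length(interior) == 2 &&
        setequal(out_of(u), interior) && setequal(in_of(v), interior) &&
        all(vapply(interior, function(w)
          identical(out_of(w), v) && identical(in_of(w), u), logical(1)))
      found[[length(found) + 1]] <-
        list(source = u, sink = v, interior = sort(interior),
             kind = if (simple) "simple" else "complex")
    }
  }
  found
}

# longest u -> v path by exhaustive enumeration; length = sum of interior
# vertex weights
oracle_longest_path <- function(edges, u, v, weights) {
  ps <- enumerate_paths(edges, u, v)
  if (length(ps) == 0) return(NA_real_)
  max(vapply(ps, function(p) {
    int <- p[-c(1, length(p))]
    if (length(int) == 0) 0 else sum(weights[int])
  }, numeric(1)))
}

# a DAG between vertex 1 (source) and n (sink) built to contain bubbles:
# interior vertices ordered 2..n-1 with forward edges, every interior
# vertex given at least one in- and one out-edge
random_bubble_dag <- function(n) {
  stopifnot(n >= 4)
  interior <- 2:(n - 1)
  e <- list()
  for (j in interior) {
    froms <- c(1, interior[interior < j])
    pick <- froms[runif(length(froms)) < 0.5]
    if (length(pick) == 0) pick <- sample(froms, 1)
    e[[length(e) + 1]] <- tibble::tibble(from = pick, to = j)
  }
  edges <- dplyr::bind_rows(e)
  # ensure u branches at least twice
  if (sum(edges$from == 1) < 2) {
    extra <- setdiff(interior, edges$to[edges$from == 1])[1]
    edges <- dplyr::bind_rows(edges, tibble::tibble(from = 1, to = extra))
  }
  # every interior vertex reaches onward; dead ends go to the sink
  for (j in interior) {
    if (!j %in% edges$from) {
      tos <- c(interior[interior > j], n)
      pick <- tos[runif(length(tos)) < 0.4]
      if (length(pick) == 0) pick <- n
      edges <- dplyr::bind_rows(edges, tibble::tibble(from = j, to = pick))
    }
  }
  if (!n %in% edges$to)
    edges <- dplyr::bind_rows(edges,
                              tibble::tibble(from = max(interior), to = n))
  dplyr::distinct(tibble::tibble(from = as.integer(edges$from),
                                 to = as.integer(edges$to)))
}

random_digraph <- function(n, p = NULL) {
  p <- p %||% (2 / n)
  e <- expand.grid(from = seq_len(n), to = seq_len(n))
  e <- e[e$from != e$to, ]
  e <- e[runif(nrow(e)) < p, ]
  tibble::tibble(from = as.integer(e$from), to = as.integer(e$to))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

bubble_key <- function(b) paste(b$source, b$sink, paste(b$interior,
                                                        collapse = ","))

# canonical k-mer set of a sequence collection (plain R bookkeeping; the
# reverse complement itself is trivial plumbing and reuses revcomp())
kmer_set <- function(seqs, k) {
  km <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, seq_len(L - k + 1), k:L)
  }))
  km <- km[!grepl("N", km, fixed = TRUE)]
  rc <- revcomp(km)
  unique(ifelse(km <= rc, km, rc))
}

# fraction of positions of `truth_seq` covered by truth k-mers present in
# the assembly k-mer set
kmer_coverage_frac <- function(contig_seqs, truth_seq, k = 25) {
  asm <- kmer_set(contig_seqs, k)
  L <- nchar(truth_seq)
  starts <- substring(truth_seq, seq_len(L - k + 1), k:L)
  rc <- revcomp(starts)
  hit <- ifelse(starts <= rc, starts, rc) %in% asm
  idx <- which(hit)
  delta <- tabulate(idx, nbins = L + 1) -
    tabulate(pmin(idx + k, L + 1), nbins = L + 1)
  mean(cumsum(delta)[seq_len(L)] > 0)
}

# build a tiny two-branch bubble graph and return the bubble object
make_simple_bubble <- function(u_seq, b1, b2, v_seq, cov = c(10, 4),
                               ov = 0) {
  g <- asm_graph(c(u_seq, b1, b2, v_seq),
                 tibble::tibble(from = c(1L, 1L, 2L, 3L),
                                to = c(2L, 3L, 4L, 4L)),
                 cov = c(20, cov[1], cov[2], 20), ov = ov)
  bs <- find_bubbles(g)
  stopifnot(length(bs) == 1)
  bs[[1]]
}
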