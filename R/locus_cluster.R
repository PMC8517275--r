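#' Hypergeometric p-value for the similarity of two binary rows
#'
#' Two loci with `n` and `N` accessible cell types out of `C` share accessible
#' calls in `s` cell types. Under the null that one row's columns are randomly
#' permuted, `s` is hypergeometric (population `C`, `N` successes, `n` draws);
#' the reported value is the upper tail `P(S >= s)`, so small values indicate
#' unusually similar accessibility patterns. Symmetric in `n` and `N`.
#'
#' @param n,N numbers of 1s in the two rows.
#' @param s number of columns where both rows are 1.
#' @param C total number of columns (cell types).
#' @return Upper-tail probability in (0, 1].
#' @export
pair_pvalue <- function(n, N, s, C) {
  if (any(n < 0 | N < 0 | n > C | N > C)) stop("counts must lie in [0, C]")
  if (any(s > pmin(n, N) | s < pmax(0, n + N - C))) {
    stop("s outside the hypergeometric support for (n, N, C)")
  }
  stats::phyper(s - 1, N, C - N, n, lower.tail = FALSE)
}

# Chunked upper-triangle scan over all row pairs. For every pair, the triple
# (n_a, n_b, s) fully determines the p-value, so pairs are tabulated by an
# integer key n_a*(C+1)^2 + n_b*(C+1) + s (n_a <= n_b). BLAS does the
# intersection counts: S_block = M_chunk %*% t(M), chunked to bound memory.
# `emit` (if given) is called with (i, j) index pairs whose s >= smin[n_i, n_j].
pair_scan <- function(M, chunk = 1024L, emit_smin = NULL) {
  L <- nrow(M)
  C <- ncol(M)
  rs <- as.integer(rowSums(M))
  base <- C + 1L
  tab <- numeric(base^3)   # dense tally over (n_a <= n_b, s); base^3 <= ~5e5 for C=78
  edges <- vector("list", 0)
  storage.mode(M) <- "double"
  tM <- t(M)
  for (a in seq(1L, L - 1L, by = chunk)) {
    b <- min(a + chunk - 1L, L - 1L)
    rows <- a:b
    m <- length(rows)
    Sb <- M[rows, , drop = FALSE] %*% tM        # m x L intersection counts
    I <- rep.int(rows, L)                        # row index, column-major
    J <- rep(seq_len(L), each = m)
    upper <- J > I                               # each unordered pair once
    i <- I[upper]; j <- J[upper]
    svec <- as.integer(Sb)[upper]
    ni <- rs[i]; nj <- rs[j]
    lo <- pmin(ni, nj); hi <- pmax(ni, nj)
    key <- (lo * base + hi) * base + svec + 1L
    tab <- tab + tabulate(key, nbins = length(tab))
    if (!is.null(emit_smin)) {
      pass <- svec >= emit_smin[cbind(lo + 1L, hi + 1L)]
      if (any(pass)) {
        edges[[length(edges) + 1L]] <- cbind(i[pass], j[pass])
      }
    }
  }
  keys <- which(tab > 0)
  k0 <- keys - 1L
  s <- k0 %% base
  nh <- (k0 %/% base) %% base
  nl <- k0 %/% (base * base)
  list(n = nl, N = nh, s = s, count = tab[keys],
       edges = if (length(edges)) do.call(rbind, edges) else matrix(0L, 0, 2))
}

#' Benjamini-Hochberg p-value cutoff over all row pairs
#'
#' Computes the similarity p-value for every unordered pair of rows and applies
#' the BH step-up rule at rate `fdr` over all `T = L(L-1)/2` tests: the cutoff
#' is the largest ascending-sorted p-value `p_(i)` with `p_(i) <= i * fdr / T`
#' (0 when no pair passes). Pairs are tabulated by their (n, N, s) signature,
#' so the scan is a handful of BLAS products rather than an explicit pair loop.
#'
#' @param M binary matrix of non-cell-specific rows.
#' @param fdr target false discovery rate in (0, 1).
#' @return The p-value cutoff (a probability, possibly 0).
#' @export
edge_threshold <- function(M, fdr) {
  if (inherits(M, "access_matrix")) M <- M$M
  stopifnot(fdr > 0, fdr < 1)
  if (nrow(M) < 2) stop("need at least 2 rows to test pairs")
  scan <- pair_scan(M)
  bh_cutoff_weighted(pair_pvalue(scan$n, scan$N, scan$s, ncol(M)),
                     scan$count, fdr)
}

# BH step-up on a weighted p-value tally (count[i] tests share p-value p[i]).
bh_cutoff_weighted <- function(p, count, fdr) {
  o <- order(p)
  p <- p[o]
  count <- count[o]
  total <- sum(count)
  cum <- cumsum(count)                 # rank of the largest test at this p
  ok <- p <= cum * fdr / total
  if (!any(ok)) 0 else p[max(which(ok))]
}

#' Build the locus similarity graph at an edge FDR
#'
#' Places an edge between two loci whose pairwise similarity p-value is at or
#' below the BH cutoff for the requested FDR. Because the p-value is monotone
#' decreasing in the shared count `s` for fixed row sums, edges are extracted
#' with a minimal-shared-count lookup rather than storing all pairwise
#' p-values.
#'
#' @param M binary matrix of non-cell-specific rows (rownames = locus names).
#' @param fdr edge false discovery rate.
#' @return list of class `similarity_graph`: `graph` (igraph, one vertex per
#'   row), `p_cutoff`, `connected_fraction` (fraction of rows with degree >=
#'   1), and `n_edges`.
#' @export
build_graph <- function(M, fdr) {
  if (inherits(M, "access_matrix")) M <- M$M
  C <- ncol(M)
  cutoff <- edge_threshold(M, fdr)
  base <- C + 1L
  # smallest s with P(S >= s) <= cutoff, per (n, N); Inf when unreachable
  smin <- matrix(Inf, base, base)
  if (cutoff > 0) {
    for (n in 0:C) for (N in n:C) {
      smax <- min(n, N)
      slo <- max(0, n + N - C)
      sv <- slo:smax
      pv <- stats::phyper(sv - 1, N, C - N, n, lower.tail = FALSE)
      hit <- which(pv <= cutoff)
      if (length(hit)) smin[n + 1, N + 1] <- sv[hit[1]]
    }
  }
  scan <- pair_scan(M, emit_smin = smin)
  g <- igraph::make_empty_graph(n = nrow(M), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = rownames(M) %||%
                                 as.character(seq_len(nrow(M))))
  if (nrow(scan$edges) > 0) {
    g <- igraph::add_edges(g, t(scan$edges))
  }
  connected <- if (nrow(M)) mean(igraph::degree(g) > 0) else 0
  structure(list(graph = g, p_cutoff = cutoff, connected_fraction = connected,
                 n_edges = nrow(scan$edges)),
            class = "similarity_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Choose the edge FDR operating point by graph connectivity
#'
#' The similarity test's resolution depends on the number of cell types, so a
#' fixed edge FDR does not transfer between panels. Mirroring the way the
#' operating point is chosen on real data — sweep the FDR and take a
#' conservative value at which most loci still connect — this walks `grid`
#' from its smallest value and returns the first FDR whose similarity graph
#' connects at least `min_connected` of the loci (the largest grid value if
#' none does).
#'
#' @param M binary matrix of non-cell-specific rows.
#' @param grid increasing candidate FDRs.
#' @param min_connected target fraction of loci with degree >= 1.
#' @return list with `fdr` (the chosen value) and `graph` (its
#'   `similarity_graph`).
#' @export
choose_edge_fdr <- function(M, grid = c(1e-4, 2e-4, 5e-4, 1e-3, 2e-3, 5e-3,
                                        1e-2, 2e-2, 5e-2),
                            min_connected = 0.7) {
  grid <- sort(grid)
  g <- NULL
  for (fdr in grid) {
    g <- build_graph(M, fdr)
    if (g$connected_fraction >= min_connected) {
      return(list(fdr = fdr, graph = g))
    }
  }
  list(fdr = grid[length(grid)], graph = g)
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("similarity_graph:", igraph::vcount(x$graph), "loci,", x$n_edges,
      "edges (p cutoff ", signif(x$p_cutoff, 3), ");",
      round(100 * x$connected_fraction, 1), "% connected\n")
  invisible(x)
}

#' Louvain community detection on the locus similarity graph
#'
#' Modularity-maximising Louvain communities; isolated loci come out as
#' singleton clusters. Deterministic for a fixed seed.
#'
#' @param graph a `similarity_graph` (or bare igraph).
#' @param resolution Louvain resolution parameter.
#' @param seed RNG seed.
#' @return `locus_clustering`: list with `labels` (named integer cluster id
#'   per locus) and `sizes` (named vector, decreasing).
#' @export
louvain_partition <- function(graph, resolution = 1, seed = 0L) {
  g <- if (inherits(graph, "similarity_graph")) graph$graph else graph
  if (igraph::vcount(g) == 0) stop("empty graph")
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- igraph::membership(comm)
  labels <- stats::setNames(as.integer(labels), igraph::V(g)$name)
  sizes <- sort(table(labels), decreasing = TRUE)
  structure(list(labels = labels,
                 sizes = stats::setNames(as.integer(sizes), names(sizes))),
            class = "locus_clustering")
}

#' @export
print.locus_clustering <- function(x, ...) {
  cat("locus_clustering:", length(x$labels), "loci in", length(x$sizes),
      "clusters; largest", x$sizes[1], "\n")
  invisible(x)
}

#' Large locus clusters
#'
#' Cluster ids with at least `min_size` loci, ordered by decreasing size and
#' then by first row index. Downstream co-clustering uses only loci in these.
#'
#' @param clustering a `locus_clustering`.
#' @param min_size minimum cluster size (30 by default).
#' @return Integer vector of cluster ids.
#' @export
large_clusters <- function(clustering, min_size = 30L) {
  sz <- table(clustering$labels)
  ids <- as.integer(names(sz))
  first <- vapply(ids, function(id) which(clustering$labels == id)[1], 1L)
  o <- order(-as.integer(sz), first)
  ids <- ids[o]
  ids[as.integer(sz)[o] >= min_size]
}

#' Restrict a matrix to loci in large clusters, with relabelled row clusters
#'
#' Convenience for the co-clustering stage: drops loci outside the large
#' clusters and renumbers cluster labels 1, 2, ... in decreasing-size order.
#'
#' @param M binary matrix (rownames matching the clustering's loci).
#' @param clustering `locus_clustering`.
#' @param min_size passed to [large_clusters()].
#' @return list `M` (restricted matrix) and `row_labels` (integer vector).
#' @export
restrict_to_large <- function(M, clustering, min_size = 30L) {
  if (inherits(M, "access_matrix")) M <- M$M
  ids <- large_clusters(clustering, min_size)
  keep <- names(clustering$labels)[clustering$labels %in% ids]
  keep <- intersect(rownames(M), keep)
  lab <- match(clustering$labels[keep], ids)
  list(M = M[keep, , drop = FALSE], row_labels = stats::setNames(lab, keep))
}

#' Write the similarity graph / locus clustering to TSV
#' @param graph `similarity_graph`.
#' @param clustering `locus_clustering`.
#' @param path output path.
#' @export
write_graph_tsv <- function(graph, path) {
  el <- igraph::as_edgelist(graph$graph)
  utils::write.table(data.frame(from = el[, 1], to = el[, 2]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
write_clusters_tsv <- function(clustering, path) {
  df <- data.frame(locus = names(clustering$labels),
                   cluster = unname(clustering$labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
read_clusters_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "")
  structure(list(labels = stats::setNames(as.integer(df$cluster), df$locus),
                 sizes = sort(table(df$cluster), decreasing = TRUE)),
            class = "locus_clustering")
}
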