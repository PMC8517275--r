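#' Sufficient statistics for fast co-cluster sum-of-squares evaluation
#'
#' For a binary matrix the squared Frobenius residual to the co-cluster-mean
#' approximation collapses to
#' \deqn{\|M - \tilde M\|_F^2 = \sum_{j,i} (S_{ji} - S_{ji}^2 / m_{ji})
#'   = \mathrm{ones}(M) - \sum_{j,i} S_{ji}^2 / m_{ji},}
#' where `S_ji` sums the entries of co-cluster (j, i) and `m_ji` counts them.
#' Only per-(row cluster, column) sums are needed to evaluate any column
#' partition, so the cache stores `T[j, c]` and the row-cluster sizes once and
#' every candidate move costs a small matrix product.
#'
#' @param M binary matrix restricted to the clustered loci.
#' @param row_labels integer vector of row-cluster labels (length `nrow(M)`).
#' @return A `fit_cache` list: `Tjc` (J x C), `nj`, `total_ones`, `C`,
#'   `cell_types`, `row_cluster_ids`.
#' @export
fit_cache <- function(M, row_labels) {
  if (inherits(M, "access_matrix")) M <- M$M
  stopifnot(length(row_labels) == nrow(M))
  f <- factor(row_labels)
  Tjc <- rowsum(M, f)                   # J x C column sums per row cluster
  storage.mode(Tjc) <- "double"
  structure(list(Tjc = Tjc, nj = as.numeric(table(f)),
                 total_ones = sum(M), C = ncol(M),
                 cell_types = colnames(M),
                 row_cluster_ids = levels(f)),
            class = "fit_cache")
}

# SSE given a column-cluster assignment vector (values 1..k) aligned with
# cache$cell_types order.
sse_from_assignment <- function(cache, a, k = max(a)) {
  Sk <- t(rowsum(t(cache$Tjc), a))                 # J x k co-cluster sums
  mk <- outer(cache$nj, tabulate(a, nbins = k))    # J x k co-cluster sizes
  cache$total_ones - sum(Sk * Sk / mk)
}

#' Co-cluster sum-of-squares fit
#'
#' `||M - M~||_F^2` where each co-cluster entry of `M~` is replaced by the
#' co-cluster mean; the objective the tree-constrained column clustering
#' minimises.
#'
#' @param M binary matrix (or `access_matrix`), or a prebuilt [fit_cache()].
#' @param row_labels row-cluster labels; ignored when `M` is a cache.
#' @param partition a `tree_partition` (or any object with an `assignment`
#'   named by the matrix's column names).
#' @return Non-negative scalar.
#' @export
cocluster_sse <- function(M, row_labels = NULL, partition) {
  cache <- if (inherits(M, "fit_cache")) M else fit_cache(M, row_labels)
  a <- partition$assignment[cache$cell_types]
  if (anyNA(a)) stop("partition does not cover all matrix columns")
  sse_from_assignment(cache, as.integer(a), k = length(partition$clusters))
}

#' Random initial cut specification
#'
#' Draws `k - 1` distinct non-leaf cut vertices; each receives a single cut
#' group holding all of its children not already claimed by an earlier group.
#' A vertex whose children are exhausted is redrawn from the unused non-leaf
#' vertices.
#'
#' @param tree a [diff_tree].
#' @param k target cluster count.
#' @param seed optional RNG seed (uses the current RNG stream when `NULL`).
#' @return A valid [cut_spec] with `k - 1` groups.
#' @export
random_init <- function(tree, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(k >= 1)
  if (k == 1) return(cut_spec())
  nonleaf <- tree_nonleaves(tree)
  if (length(nonleaf) < k - 1) {
    stop("tree has only ", length(nonleaf), " non-leaf vertices; cannot seed k = ", k)
  }
  for (attempt in 1:100) {
    pool <- sample(nonleaf)
    groups <- list()
    claimed <- character(0)
    used <- character(0)
    ptr <- 1L
    ok <- TRUE
    while (length(groups) < k - 1) {
      if (ptr > length(pool)) { ok <- FALSE; break }
      v <- pool[ptr]; ptr <- ptr + 1L
      members <- setdiff(tree$children[[v]], claimed)
      if (length(members) == 0) next                 # redraw: children exhausted
      groups[[length(groups) + 1L]] <- list(vertex = v, members = members)
      claimed <- c(claimed, members)
      used <- c(used, v)
    }
    if (ok) return(cut_spec(groups, tree))
  }
  stop("could not draw ", k - 1, " feasible cut vertices")
}

#' Enumerate cut-group modifications at a cut vertex
#'
#' All specifications reachable from `spec` by (a) adding one unclaimed child
#' of `v` to one of `v`'s cut groups, (b) removing one member from a group of
#' `v` that keeps the group nonempty, or (c) transferring a member between two
#' groups of `v`. Group count (hence k) is conserved.
#'
#' @param spec a [cut_spec].
#' @param v a cut vertex of `spec`.
#' @param tree the [diff_tree].
#' @return list of candidate `cut_spec`s.
#' @export
cut_group_moves <- function(spec, v, tree) {
  gidx <- which(vapply(spec$groups, function(g) g$vertex == v, TRUE))
  if (length(gidx) == 0) stop(v, " is not a cut vertex of the spec")
  claimed <- unlist(lapply(spec$groups, `[[`, "members"))
  unclaimed <- setdiff(tree$children[[v]], claimed)
  cands <- list()
  for (gi in gidx) {
    for (child in unclaimed) {                      # (a) additions
      s2 <- spec
      s2$groups[[gi]]$members <- c(s2$groups[[gi]]$members, child)
      cands[[length(cands) + 1L]] <- s2
    }
    if (length(spec$groups[[gi]]$members) > 1) {    # (b) removals
      for (m in spec$groups[[gi]]$members) {
        s2 <- spec
        s2$groups[[gi]]$members <- setdiff(s2$groups[[gi]]$members, m)
        cands[[length(cands) + 1L]] <- s2
      }
    }
  }
  if (length(gidx) > 1) {                           # (c) transfers
    for (g1 in gidx) {
      if (length(spec$groups[[g1]]$members) < 2) next   # source must stay nonempty
      for (g2 in setdiff(gidx, g1)) {
        for (m in spec$groups[[g1]]$members) {
          s2 <- spec
          s2$groups[[g1]]$members <- setdiff(s2$groups[[g1]]$members, m)
          s2$groups[[g2]]$members <- c(s2$groups[[g2]]$members, m)
          cands[[length(cands) + 1L]] <- s2
        }
      }
    }
  }
  cands
}

#' Enumerate cut-vertex modifications between two vertices
#'
#' For each cut group `g` of `v` and each child `c` of `v_prime` unclaimed
#' after `g` is deleted, yields the specification with `g` replaced by the
#' singleton group `(v_prime, {c})`. Deleting `g` frees its members, so a
#' freed member that is a child of `v_prime` becomes addable.
#'
#' @param spec a [cut_spec].
#' @param v a cut vertex of `spec`.
#' @param v_prime any other node; leaves yield no candidates.
#' @param tree the [diff_tree].
#' @return list of candidate `cut_spec`s.
#' @export
cut_vertex_moves <- function(spec, v, v_prime, tree) {
  if (v_prime == v) stop("v_prime must differ from v")
  gidx <- which(vapply(spec$groups, function(g) g$vertex == v, TRUE))
  if (length(gidx) == 0) stop(v, " is not a cut vertex of the spec")
  kids <- tree$children[[v_prime]]
  if (length(kids) == 0) return(list())
  cands <- list()
  for (gi in gidx) {
    rest <- spec$groups[-gi]
    claimed_after <- unlist(lapply(rest, `[[`, "members"))
    for (child in setdiff(kids, claimed_after)) {
      s2 <- spec
      s2$groups[[gi]] <- list(vertex = v_prime, members = child)
      cands[[length(cands) + 1L]] <- s2
    }
  }
  cands
}

# One full improvement pass; returns updated state and whether anything moved.
# Both cycles follow tree preorder, accepting the best strictly improving
# candidate per cut vertex (or per vertex pair).
local_search_cycle <- function(state, cache, tree, eps = 1e-9) {
  improved <- FALSE
  moves <- 0L
  k <- length(state$spec$groups) + 1L
  eval_spec <- function(sp) {
    sse_from_assignment(cache, cutspec_assignment(tree, sp), k)
  }
  # cut-group cycle
  for (v in tree$nodes) {
    if (!any(vapply(state$spec$groups, function(g) g$vertex == v, TRUE))) next
    cands <- cut_group_moves(state$spec, v, tree)
    if (length(cands) == 0) next
    sses <- vapply(cands, eval_spec, 1)
    best <- which.min(sses)
    if (sses[best] < state$sse - eps) {
      state$spec <- cands[[best]]
      state$sse <- sses[best]
      improved <- TRUE
      moves <- moves + 1L
    }
  }
  # cut-vertex cycle over ordered pairs (v, v')
  for (v in tree$nodes) {
    if (!any(vapply(state$spec$groups, function(g) g$vertex == v, TRUE))) next
    for (vp in tree$nodes) {
      if (vp == v || length(tree$children[[vp]]) == 0) next
      if (!any(vapply(state$spec$groups, function(g) g$vertex == v, TRUE))) break
      cands <- cut_vertex_moves(state$spec, v, vp, tree)
      if (length(cands) == 0) next
      sses <- vapply(cands, eval_spec, 1)
      best <- which.min(sses)
      if (sses[best] < state$sse - eps) {
        state$spec <- cands[[best]]
        state$sse <- sses[best]
        improved <- TRUE
        moves <- moves + 1L
      }
    }
  }
  list(state = state, improved = improved, moves = moves)
}

#' Tree-constrained column clustering by local search with restarts
#'
#' Minimises the co-cluster sum-of-squares over column partitions that respect
#' the differentiation tree. Each restart starts from a random cut
#' specification and alternates a cycle of cut-group modifications over all
#' cut vertices with a cycle of cut-vertex modifications over all vertex
#' pairs, accepting the best strictly improving candidate at each step, until
#' a full double cycle makes no improvement. Restart r uses seed
#' `seed + r - 1`.
#'
#' @param M binary matrix restricted to large locus clusters (or a
#'   [fit_cache()]).
#' @param row_labels row-cluster labels (ignored when `M` is a cache).
#' @param tree a [diff_tree]; its nodes must equal the matrix column names.
#' @param k number of column clusters.
#' @param restarts number of random restarts (20 by default).
#' @param seed base RNG seed.
#' @return An `optimizer_run`: `best_spec`, `best_partition`, `best_sse`,
#'   `restarts` (data.frame with per-restart seed, sse, cycles, moves), `k`.
#' @export
optimize_tree_partition <- function(M, row_labels = NULL, tree, k,
                                    restarts = 20L, seed = 0L) {
  cache <- if (inherits(M, "fit_cache")) M else fit_cache(M, row_labels)
  if (!setequal(cache$cell_types, tree$nodes)) {
    stop("matrix columns and tree nodes differ")
  }
  # align cache columns to tree preorder so assignments index consistently
  o <- match(tree$nodes, cache$cell_types)
  cache$Tjc <- cache$Tjc[, o, drop = FALSE]
  cache$cell_types <- tree$nodes
  stopifnot(k >= 1)
  best <- NULL
  log <- data.frame(seed = integer(), sse = numeric(), cycles = integer(),
                    moves = integer())
  for (r in seq_len(restarts)) {
    rs <- seed + r - 1L
    spec <- random_init(tree, k, seed = rs)
    state <- list(spec = spec,
                  sse = sse_from_assignment(cache,
                                            cutspec_assignment(tree, spec), k))
    cycles <- 0L
    moves <- 0L
    repeat {
      res <- local_search_cycle(state, cache, tree)
      state <- res$state
      cycles <- cycles + 1L
      moves <- moves + res$moves
      if (!res$improved) break
    }
    log <- rbind(log, data.frame(seed = rs, sse = state$sse, cycles = cycles,
                                 moves = moves))
    if (is.null(best) || state$sse < best$sse) best <- state
  }
  structure(list(best_spec = best$spec,
                 best_partition = partition_from_cutspec(tree, best$spec),
                 best_sse = best$sse, restarts = log, k = k),
            class = "optimizer_run")
}

#' @export
print.optimizer_run <- function(x, ...) {
  cat("optimizer_run: k =", x$k, "; best SSE", format(x$best_sse),
      "over", nrow(x$restarts), "restarts\n")
  invisible(x)
}

#' Unconstrained column-clustering baselines
#'
#' Clusters the cell types (columns) of `M` without the tree constraint:
#' Ward-linkage hierarchical clustering on Euclidean distance, or k-means with
#' k-means++ seeding. Used as the reference against which the tree-constrained
#' fit is compared.
#'
#' @param M binary matrix (rows restricted to large locus clusters).
#' @param k number of clusters.
#' @param method `"hierarchical"` or `"kmeans"`.
#' @param seed RNG seed (k-means only).
#' @return A `tree_partition`-classed column partition (its clusters need not
#'   respect any tree).
#' @export
baseline_partition <- function(M, k, method = c("hierarchical", "kmeans"),
                               seed = 0L) {
  if (inherits(M, "access_matrix")) M <- M$M
  method <- match.arg(method)
  stopifnot(k <= ncol(M))
  X <- t(M)
  if (method == "hierarchical") {
    hc <- stats::hclust(stats::dist(X), method = "ward.D2")
    a <- stats::cutree(hc, k = k)
  } else {
    set.seed(seed)
    centers <- kmeanspp_centers(X, k)
    a <- if (k == 1) stats::setNames(rep(1L, nrow(X)), rownames(X)) else
      stats::kmeans(X, centers = centers, iter.max = 100)$cluster
  }
  as_tree_partition(stats::setNames(as.integer(a), rownames(X)))
}

# k-means++ seeding: iteratively sample points with probability proportional
# to squared distance from the nearest chosen center.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  idx <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rep(Inf, n)
    for (i in 2:k) {
      d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[i - 1], ])^2))
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- c(idx, sample.int(n, 1, prob = prob))
    }
  }
  X[idx, , drop = FALSE] + stats::runif(length(idx) * ncol(X), 0, 1e-8)
}
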