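#' Rooted differentiation tree over cell types
#'
#' Construct a rooted tree whose nodes are the cell types (the columns of the
#' accessibility matrix). Edges point from a parent cell type to the cell types
#' it differentiates into.
#'
#' @param child character vector of child node names.
#' @param parent character vector of the same length; `parent[i]` is the parent
#'   of `child[i]`. Exactly one node must not appear as a child: the root.
#'   Alternatively the root may be listed with parent `NA` or `"-"`.
#' @return An object of class `diff_tree` with components `nodes` (preorder),
#'   `parent` (named character, `NA` at the root), `children` (named list),
#'   `root`, and `depth` (named integer, 0 at the root).
#' @examples
#' tr <- diff_tree(child = c("MPP", "T", "B"), parent = c("HSC", "MPP", "MPP"))
#' tr$root
#' @export
diff_tree <- function(child, parent) {
  child <- as.character(child)
  parent <- as.character(parent)
  if (length(child) != length(parent)) {
    stop("child and parent must have equal length")
  }
  parent[parent %in% c("-", "")] <- NA_character_
  keep <- !is.na(parent)
  edges_child <- child[keep]
  edges_parent <- parent[keep]
  nodes <- unique(c(child, parent[keep]))
  if (anyDuplicated(edges_child)) {
    stop("node listed with two parents: ", edges_child[duplicated(edges_child)][1])
  }
  roots <- setdiff(nodes, edges_child)
  if (length(roots) != 1) {
    stop("tree must have exactly one root, found: ", paste(roots, collapse = ", "))
  }
  root <- roots
  pmap <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  pmap[edges_child] <- edges_parent
  children <- split(edges_child, factor(edges_parent, levels = nodes))
  # preorder traversal; also detects cycles/disconnected nodes
  ord <- character(length(nodes))
  depth <- stats::setNames(integer(length(nodes)), nodes)
  i <- 0L
  stack <- list(list(node = root, d = 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- i + 1L
    ord[i] <- top$node
    depth[top$node] <- top$d
    kids <- children[[top$node]]
    if (length(kids)) {
      for (k in rev(kids)) stack[[length(stack) + 1L]] <- list(node = k, d = top$d + 1L)
    }
  }
  if (i != length(nodes)) {
    stop("tree is not connected (cycle or orphan edges present)")
  }
  structure(
    list(nodes = ord, parent = pmap[ord], children = children[ord],
         root = root, depth = depth[ord]),
    class = "diff_tree"
  )
}

#' @export
print.diff_tree <- function(x, ...) {
  cat("diff_tree with", length(x$nodes), "cell types, root:", x$root, "\n")
  nl <- sum(lengths(x$children) == 0)
  cat("  leaves:", nl, " max depth:", max(x$depth), "\n")
  invisible(x)
}

#' Read/write a differentiation tree as a child-parent TSV
#'
#' Two tab-separated columns, `child` and `parent`; the root row carries
#' parent `-`. Node names must match the accessibility-matrix column names.
#'
#' @param path file path.
#' @return `read_tree_tsv` returns a [diff_tree]; `write_tree_tsv` returns
#'   `path` invisibly.
#' @export
read_tree_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (!all(c("child", "parent") %in% names(df))) {
    stop("tree TSV must have columns 'child' and 'parent'")
  }
  diff_tree(df$child, df$parent)
}

#' @rdname read_tree_tsv
#' @param tree a [diff_tree].
#' @export
write_tree_tsv <- function(tree, path) {
  df <- data.frame(child = tree$nodes,
                   parent = ifelse(is.na(tree$parent), "-", tree$parent))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

tree_leaves <- function(tree) tree$nodes[lengths(tree$children) == 0]
tree_nonleaves <- function(tree) tree$nodes[lengths(tree$children) > 0]

#' Does a set of cell types respect the differentiation tree?
#'
#' A node set respects the tree when its induced subgraph is connected, or when
#' the roots of its connected components are all children of one common parent
#' node. The root of a component is its unique shallowest node; in a
#' tree-induced subgraph it is the one member whose parent lies outside the set.
#'
#' @param node_set nonempty character vector of cell-type names.
#' @param tree a [diff_tree].
#' @return `TRUE` or `FALSE`.
#' @seealso [decompose_connected()], [decompose_respecting()]
#' @export
respects_tree <- function(node_set, tree) {
  node_set <- unique(as.character(node_set))
  if (length(node_set) == 0) stop("node_set must be nonempty")
  if (!all(node_set %in% tree$nodes)) {
    stop("unknown nodes: ", paste(setdiff(node_set, tree$nodes), collapse = ", "))
  }
  par <- tree$parent[node_set]
  root_par <- par[!(par %in% node_set)]   # parents of component roots (NA for tree root)
  if (length(root_par) == 1) return(TRUE)
  if (anyNA(root_par)) return(FALSE)      # tree root's component cannot share a parent
  length(unique(root_par)) == 1
}

#' Count connected components of a cell-type set on the tree
#'
#' @inheritParams respects_tree
#' @return Integer component count.
#' @export
decompose_connected <- function(node_set, tree) {
  node_set <- unique(as.character(node_set))
  if (length(node_set) == 0) stop("node_set must be nonempty")
  par <- tree$parent[node_set]
  sum(!(par %in% node_set))
}

#' Count tree-respecting components of a cell-type set
#'
#' Connected components are grouped by the parent of their roots; each group of
#' components sharing one parent forms a single tree-respecting component, and
#' the component containing the tree root always forms its own. The count is
#' the minimal number of tree-respecting pieces the set decomposes into.
#'
#' @inheritParams respects_tree
#' @return Integer count; equals 1 exactly when `respects_tree(node_set, tree)`.
#' @export
decompose_respecting <- function(node_set, tree) {
  node_set <- unique(as.character(node_set))
  if (length(node_set) == 0) stop("node_set must be nonempty")
  par <- tree$parent[node_set]
  root_par <- par[!(par %in% node_set)]
  length(unique(root_par))  # NA (tree root) counts as its own group
}

#' Cut specifications: tree-respecting k-partitions as severed edges
#'
#' A `cut_spec` encodes a k-way partition of the tree's nodes as `k - 1` cut
#' groups. Each group names a cut vertex `p` and a nonempty set of `p`'s
#' children; severing the edges from each cut vertex to its group members
#' carves the tree into components, and the union of the components rooted at
#' one group's members forms one cluster. The component holding the tree root
#' becomes the final, k-th cluster. Cut vertices may repeat across groups;
#' members must be globally unique.
#'
#' @param groups list of `list(vertex = <node>, members = <character vector>)`.
#' @param tree a [diff_tree] used for validation.
#' @return An object of class `cut_spec`.
#' @export
cut_spec <- function(groups = list(), tree = NULL) {
  stopifnot(is.list(groups))
  groups <- lapply(groups, function(g) {
    list(vertex = as.character(g$vertex), members = as.character(g$members))
  })
  spec <- structure(list(groups = groups), class = "cut_spec")
  if (!is.null(tree)) validate_cut_spec(spec, tree)
  spec
}

validate_cut_spec <- function(spec, tree) {
  all_members <- unlist(lapply(spec$groups, `[[`, "members"))
  if (anyDuplicated(all_members)) {
    stop("cut-group member appears twice: ", all_members[duplicated(all_members)][1])
  }
  for (g in spec$groups) {
    if (length(g$members) == 0) stop("empty cut group at vertex ", g$vertex)
    kids <- tree$children[[g$vertex]]
    bad <- setdiff(g$members, kids)
    if (length(bad)) {
      stop("member ", bad[1], " is not a child of cut vertex ", g$vertex)
    }
  }
  invisible(spec)
}

#' @export
print.cut_spec <- function(x, ...) {
  k <- length(x$groups) + 1L
  cat("cut_spec inducing", k, "clusters\n")
  for (g in x$groups) {
    cat("  cut", g$vertex, "->", paste(g$members, collapse = ","), "\n")
  }
  invisible(x)
}

# Fast internal: cluster assignment (1..k) per node, in tree$nodes order.
# Group i claims the components rooted at its members; the root component is k.
cutspec_assignment <- function(tree, spec) {
  k <- length(spec$groups) + 1L
  member_group <- integer(0)
  if (k > 1L) {
    member_group <- stats::setNames(
      rep(seq_along(spec$groups), vapply(spec$groups, function(g) length(g$members), 1L)),
      unlist(lapply(spec$groups, `[[`, "members"))
    )
  }
  nodes <- tree$nodes
  a <- stats::setNames(integer(length(nodes)), nodes)
  for (v in nodes) {              # preorder: parent precedes child
    g <- member_group[v]
    if (!is.na(g)) {
      a[v] <- g
    } else if (v == tree$root) {
      a[v] <- k
    } else {
      a[v] <- a[tree$parent[v]]
    }
  }
  a
}

#' Build the tree partition induced by a cut specification
#'
#' Severs the edge above each cut-group member and returns the induced k-way
#' partition. Every cluster of the result respects the tree by construction.
#'
#' @param tree a [diff_tree].
#' @param spec a [cut_spec]; the empty spec yields the single-cluster partition.
#' @return An object of class `tree_partition` with `clusters` (list of
#'   character vectors, the final entry holding the tree root), `assignment`
#'   (named integer over `tree$nodes`), and `origin` (the spec).
#' @examples
#' tr <- diff_tree(c("b", "c"), c("a", "b"))
#' partition_from_cutspec(tr, cut_spec(list(list(vertex = "a", members = "b"))))
#' @export
partition_from_cutspec <- function(tree, spec) {
  validate_cut_spec(spec, tree)
  a <- cutspec_assignment(tree, spec)
  k <- length(spec$groups) + 1L
  clusters <- split(names(a), factor(a, levels = seq_len(k)))
  names(clusters) <- NULL
  structure(list(clusters = clusters, assignment = a, origin = spec),
            class = "tree_partition")
}

#' Wrap an arbitrary column partition (baselines, hand-made clusterings)
#'
#' @param assignment named integer vector (names = cell types, values in
#'   `1..k`).
#' @return A `tree_partition`-classed object without an originating cut spec;
#'   its clusters need not respect any tree.
#' @export
as_tree_partition <- function(assignment) {
  stopifnot(!is.null(names(assignment)))
  a <- as.integer(assignment)
  names(a) <- names(assignment)
  ids <- sort(unique(a))
  a <- match(a, ids)                      # relabel to 1..k
  names(a) <- names(assignment)
  clusters <- split(names(a), a)
  names(clusters) <- NULL
  structure(list(clusters = clusters, assignment = a, origin = NULL),
            class = "tree_partition")
}

#' @export
print.tree_partition <- function(x, ...) {
  cat("tree_partition with", length(x$clusters), "clusters over",
      length(x$assignment), "cell types\n")
  invisible(x)
}

#' Read/write a cell-type partition as a two-column TSV
#'
#' Columns `cell_type` and `cluster`.
#' @param partition a `tree_partition`.
#' @param path file path.
#' @export
write_partition_tsv <- function(partition, path) {
  df <- data.frame(cell_type = names(partition$assignment),
                   cluster = unname(partition$assignment))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition_tsv
#' @export
read_partition_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = c("character", "integer"))
  as_tree_partition(stats::setNames(df$cluster, df$cell_type))
}

#' Enumerate every tree-respecting k-partition of a small tree
#'
#' Exhaustive, pruned enumeration used as an exact reference for the local
#' search on small trees. Nodes are assigned in preorder with canonical block
#' labels; a prefix is pruned as soon as any block acquires component roots
#' whose parents differ (such a violation can never be repaired later, because
#' in preorder all subsequently assigned nodes are deeper than existing roots).
#'
#' @param tree a [diff_tree]; intended for trees of at most a dozen nodes.
#' @param k number of clusters.
#' @return List of assignment vectors (named integers over `tree$nodes`), one
#'   per distinct partition whose every block respects the tree.
#' @export
enumerate_tree_partitions <- function(tree, k) {
  nodes <- tree$nodes
  n <- length(nodes)
  stopifnot(k >= 1, k <= n)
  parent_idx <- match(tree$parent, nodes)   # NA at root
  out <- vector("list", 0)
  assign <- integer(n)
  # per-block incremental state: number of component roots, their common parent
  # index (NA allowed only while the block has a single root)
  nroots <- integer(k)
  rootpar <- rep(-1L, k)    # -1 unset; 0 encodes the tree root's NA parent
  recurse <- function(i, used) {
    if (i > n) {
      if (used == k) out[[length(out) + 1L]] <<- stats::setNames(assign, nodes)
      return(invisible(NULL))
    }
    p <- parent_idx[i]
    maxb <- min(used + 1L, k)
    for (b in seq_len(maxb)) {
      is_root <- is.na(p) || assign[p] != b || (b > used)
      ok <- TRUE
      old_n <- nroots[b]; old_p <- rootpar[b]
      if (is_root) {
        pcode <- if (is.na(p)) 0L else p
        if (old_n == 0L) {
          nroots[b] <<- 1L; rootpar[b] <<- pcode
        } else if (pcode == 0L || old_p == 0L || pcode != old_p) {
          ok <- FALSE
        } else {
          nroots[b] <<- old_n + 1L
        }
      }
      if (ok) {
        assign[i] <<- b
        recurse(i + 1L, max(used, b))
      }
      nroots[b] <<- old_n; rootpar[b] <<- old_p
    }
    invisible(NULL)
  }
  recurse(1L, 0L)
  out
}
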