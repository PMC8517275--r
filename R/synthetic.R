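# Named substreams: every stage of the generator draws from its own seed
# derived from the master seed, so trees, states, entries and motifs are
# independently reproducible. Offsets keep derived seeds inside 32-bit range.
substream_seed <- function(seed, name) {
  offset <- c(tree = 1L, cutspec = 2L, states = 3L, entries = 4L,
              specific = 5L, motifs = 6L)[[name]]
  (as.integer(seed) %% 1000000L) * 1009L + offset
}

#' Random differentiation tree
#'
#' Random recursive tree: node i (i >= 2) attaches to a uniformly chosen
#' earlier node, which concentrates branching near the root the way
#' hematopoietic trees do. Caterpillar (path) and balanced-binary shapes are
#' available for stress tests.
#'
#' @param n_cells number of cell types (>= 2).
#' @param seed RNG seed.
#' @param shape `"recursive"`, `"caterpillar"` or `"balanced"`.
#' @return A [diff_tree] with nodes `C01, C02, ...`.
#' @export
random_tree <- function(n_cells, seed = 0L, shape = c("recursive",
                                                      "caterpillar",
                                                      "balanced")) {
  stopifnot(n_cells >= 2)
  shape <- match.arg(shape)
  set.seed(substream_seed(seed, "tree"))
  nm <- sprintf("C%0*d", nchar(n_cells), seq_len(n_cells))
  parent_idx <- switch(shape,
    recursive = vapply(2:n_cells, function(i) sample.int(i - 1L, 1), 1L),
    caterpillar = 1:(n_cells - 1L),
    balanced = (2:n_cells) %/% 2L
  )
  diff_tree(child = nm[2:n_cells], parent = nm[parent_idx])
}

#' Random cut specification on a tree
#'
#' Delegates to [random_init()]; exposed from the generator so planted truths
#' and optimizer starts share one code path.
#' @inheritParams random_init
#' @export
random_cutspec <- function(tree, k, seed = NULL) {
  if (!is.null(seed)) seed <- substream_seed(seed, "cutspec")
  random_init(tree, k, seed = seed)
}

#' Draw a planted tree-respecting partition with an identifiability floor
#'
#' Repeatedly draws random cut specifications (see [random_cutspec()]) until
#' every induced cluster holds at least `min_cluster_size` cell types. Planted
#' clusters of one or two cell types carry almost no block signal and make
#' recovery studies ill-posed; the floor guarantees each planted cluster is a
#' genuine phenotype block.
#'
#' @inheritParams random_cutspec
#' @param min_cluster_size smallest admissible cluster (1 disables rejection).
#' @param max_tries rejection budget.
#' @return A `tree_partition` whose `origin` holds the drawn [cut_spec].
#' @export
planted_partition <- function(tree, k, min_cluster_size = 1L, seed = NULL,
                              max_tries = 1000L) {
  if (!is.null(seed)) set.seed(substream_seed(seed, "cutspec"))
  for (i in seq_len(max_tries)) {
    spec <- random_init(tree, k)
    part <- partition_from_cutspec(tree, spec)
    if (min(lengths(part$clusters)) >= min_cluster_size) return(part)
  }
  stop("no partition with clusters of >= ", min_cluster_size,
       " cell types found in ", max_tries, " draws")
}

#' Simulate a binary accessibility matrix with planted co-cluster structure
#'
#' Emulates the two-state block structure of real accessibility matrices: a
#' planted tree-respecting column partition into `k` clusters and `n_locus_clusters`
#' locus clusters, each locus cluster carrying a two-state vector over the
#' column clusters (at least one accessible and one inaccessible state when
#' `k > 1`). Entries are Bernoulli(`theta_high`) in accessible blocks and
#' Bernoulli(`theta_low`) elsewhere; all-zero rows are redrawn (master loci
#' are accessible somewhere by construction). State vectors are drawn
#' *distinct* across locus clusters so that every planted locus cluster is
#' identifiable. Optional cell-specific loci with 1 or 2 random 1s are
#' appended.
#'
#' @param n_cells tree size.
#' @param k planted column clusters.
#' @param n_locus_clusters planted locus clusters.
#' @param rows_per_cluster loci per planted locus cluster.
#' @param theta_low,theta_high Bernoulli rates for inaccessible/accessible
#'   blocks (`0 <= theta_low < theta_high <= 1`).
#' @param frac_cell_specific fraction of additional cell-specific loci,
#'   relative to the clustered rows.
#' @param seed master seed; all stages derive named substreams from it.
#' @param tree optionally a prebuilt [diff_tree] (otherwise random).
#' @param partition optionally a planted `tree_partition` (otherwise drawn
#'   via [random_cutspec()]).
#' @return A `synthetic_dataset`: `M`, `tree`, `cutspec`, `partition`,
#'   `row_labels` (planted labels for the clustered rows), `states` (planted
#'   J x k logical table), `params`.
#' @export
simulate_accessibility <- function(n_cells = 30L, k = 5L,
                                   n_locus_clusters = 8L,
                                   rows_per_cluster = 250L,
                                   theta_low = 0.05, theta_high = 0.8,
                                   frac_cell_specific = 0,
                                   seed = 0L, tree = NULL, partition = NULL) {
  stopifnot(theta_low >= 0, theta_high <= 1, theta_low < theta_high,
            k >= 1, k <= n_cells, n_locus_clusters >= 1, rows_per_cluster >= 1)
  if (is.null(tree)) tree <- random_tree(n_cells, seed = seed)
  spec <- NULL
  if (is.null(partition)) {
    spec <- random_cutspec(tree, k, seed = seed)
    partition <- partition_from_cutspec(tree, spec)
  } else {
    spec <- partition$origin
  }
  a <- partition$assignment[tree$nodes]
  J <- n_locus_clusters
  set.seed(substream_seed(seed, "states"))
  draw_state <- function() {
    if (k == 1) return(TRUE)
    repeat {
      s <- stats::runif(k) < 0.5
      if (any(s) && !all(s)) return(s)
    }
  }
  states <- matrix(FALSE, J, k)
  seen <- character(0)
  for (j in seq_len(J)) {
    repeat {
      s <- draw_state()
      key <- paste(as.integer(s), collapse = "")
      if (!(key %in% seen) || k == 1 || 2^k - 2 < J) break
    }
    seen <- c(seen, key)
    states[j, ] <- s
  }
  set.seed(substream_seed(seed, "entries"))
  n_rows <- J * rows_per_cluster
  row_labels <- rep(seq_len(J), each = rows_per_cluster)
  theta_row <- ifelse(states[row_labels, a, drop = FALSE], theta_high, theta_low)
  M <- matrix(as.integer(stats::runif(n_rows * n_cells) < theta_row),
              n_rows, n_cells)
  zero <- which(rowSums(M) == 0)
  while (length(zero)) {                           # master loci are never all-zero
    th <- theta_row[zero, , drop = FALSE]
    M[zero, ] <- as.integer(stats::runif(length(zero) * n_cells) < th)
    zero <- zero[rowSums(M[zero, , drop = FALSE]) == 0]
  }
  colnames(M) <- tree$nodes
  rownames(M) <- sprintf("locus_%05d", seq_len(n_rows))
  names(row_labels) <- rownames(M)
  n_spec <- round(frac_cell_specific * n_rows)
  if (n_spec > 0) {
    set.seed(substream_seed(seed, "specific"))
    S <- matrix(0L, n_spec, n_cells,
                dimnames = list(sprintf("specific_%05d", seq_len(n_spec)),
                                tree$nodes))
    for (i in seq_len(n_spec)) {
      S[i, sample.int(n_cells, sample(1:2, 1))] <- 1L
    }
    M <- rbind(M, S)
  }
  structure(list(M = M, tree = tree, cutspec = spec, partition = partition,
                 row_labels = row_labels, states = states,
                 params = list(n_cells = n_cells, k = k,
                               n_locus_clusters = J,
                               rows_per_cluster = rows_per_cluster,
                               theta_low = theta_low, theta_high = theta_high,
                               frac_cell_specific = frac_cell_specific,
                               seed = seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  p <- x$params
  cat("synthetic_dataset:", nrow(x$M), "loci x", p$n_cells, "cell types;",
      p$n_locus_clusters, "locus clusters, k =", p$k, "\n")
  invisible(x)
}

#' Simulate a binary motif-hit matrix with one planted enrichment
#'
#' The planted motif is present with probability `q_in` at the loci of the
#' target locus cluster and `q_out` elsewhere; `n_null` additional motifs are
#' independent Bernoulli(`background`) everywhere.
#'
#' @param dataset a `synthetic_dataset`.
#' @param q_in,q_out planted presence rates (`q_out < q_in`).
#' @param target_cocluster planted locus-cluster id (1-based).
#' @param n_null number of null motifs.
#' @param background null presence rate.
#' @param seed RNG seed (motif substream of the dataset seed when `NULL`).
#' @return Binary matrix, loci x motifs; planted column named
#'   `motif_planted`.
#' @export
simulate_motifs <- function(dataset, q_in = 0.6, q_out = 0.1,
                            target_cocluster = 1L, n_null = 20L,
                            background = 0.1, seed = NULL) {
  stopifnot(q_out >= 0, q_in <= 1, q_out < q_in)
  if (is.null(seed)) seed <- dataset$params$seed
  set.seed(substream_seed(seed, "motifs"))
  loci <- rownames(dataset$M)
  in_target <- loci %in% names(dataset$row_labels)[dataset$row_labels ==
                                                     target_cocluster]
  q <- ifelse(in_target, q_in, q_out)
  planted <- as.integer(stats::runif(length(loci)) < q)
  nulls <- matrix(as.integer(stats::runif(length(loci) * n_null) < background),
                  length(loci), n_null)
  A <- cbind(planted, nulls)
  dimnames(A) <- list(loci, c("motif_planted",
                              sprintf("null_%02d", seq_len(n_null))))
  A
}
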