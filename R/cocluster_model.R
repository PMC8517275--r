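#' Fit co-cluster means
#'
#' The co-cluster approximation replaces every entry of `M` by the mean of its
#' co-cluster, the intersection of one locus (row) cluster and one cell-type
#' (column) cluster.
#'
#' @param M binary matrix (or `access_matrix`).
#' @param row_labels row-cluster labels, length `nrow(M)`.
#' @param partition a `tree_partition` over the columns.
#' @return A `cocluster_model`: `means` (J x k), `counts` (entry counts),
#'   `sums`, `row_cluster_ids`, `col_assignment`, `Tjc`, `nj`.
#' @export
fit_means <- function(M, row_labels, partition) {
  cache <- if (inherits(M, "fit_cache")) M else fit_cache(M, row_labels)
  a <- as.integer(partition$assignment[cache$cell_types])
  if (anyNA(a)) stop("partition does not cover all matrix columns")
  k <- length(partition$clusters)
  Sk <- t(rowsum(t(cache$Tjc), a))
  mk <- outer(cache$nj, tabulate(a, nbins = k))
  means <- Sk / mk
  dimnames(means) <- list(cache$row_cluster_ids, seq_len(k))
  structure(list(means = means, sums = Sk, counts = mk,
                 row_cluster_ids = cache$row_cluster_ids,
                 col_assignment = stats::setNames(a, cache$cell_types),
                 Tjc = cache$Tjc, nj = cache$nj,
                 total_ones = cache$total_ones),
            class = "cocluster_model")
}

#' @export
print.cocluster_model <- function(x, ...) {
  cat("cocluster_model:", nrow(x$means), "locus clusters x", ncol(x$means),
      "cell clusters\n")
  invisible(x)
}

#' Expand a co-cluster model to the full matrix approximation
#'
#' @param model a `cocluster_model` or `two_state_model`.
#' @param row_labels the row-cluster labels used at fit time.
#' @return Numeric matrix with one row per locus and one column per cell type.
#' @export
expand_model <- function(model, row_labels) {
  vals <- if (inherits(model, "two_state_model")) model$value_grid else model$means
  j <- match(as.character(row_labels), rownames(vals))
  out <- vals[j, model$col_assignment, drop = FALSE]
  dimnames(out) <- list(names(row_labels), names(model$col_assignment))
  out
}

#' Optimal split of weighted means into two states
#'
#' Exact 1-D weighted 2-means: sorts the means and scans the `k - 1`
#' contiguous split points; each side's fitted value is its entry-weighted
#' mean. Ties prefer fewer clusters in the high state. With all means equal
#' the fit is degenerate (`a0 == a1`, everything in the low state).
#'
#' @param means numeric vector of co-cluster means.
#' @param weights positive entry counts.
#' @return list `low_value`, `high_value`, `high` (logical per input),
#'   `sse` (weighted SSE of means to their state value), `degenerate`.
#' @export
two_state_split <- function(means, weights) {
  k <- length(means)
  stopifnot(length(weights) == k, all(weights > 0))
  if (max(means) - min(means) < 1e-12) {
    return(list(low_value = means[1], high_value = means[1],
                high = rep(FALSE, k), sse = 0, degenerate = TRUE))
  }
  o <- order(means, seq_len(k))
  mu <- means[o]; w <- weights[o]
  cw <- cumsum(w); cs <- cumsum(w * mu)
  tw <- cw[k]; ts <- cs[k]
  t_idx <- seq_len(k - 1)
  # weighted SSE about the two side means; constant part dropped
  fit <- cs[t_idx]^2 / cw[t_idx] + (ts - cs[t_idx])^2 / (tw - cw[t_idx])
  best_fit <- max(fit)
  # ties -> fewer clusters in the high state = larger low side
  t_star <- max(t_idx[fit >= best_fit - 1e-12])
  high <- rep(FALSE, k)
  high[o[(t_star + 1):k]] <- TRUE
  low_value <- cs[t_star] / cw[t_star]
  high_value <- (ts - cs[t_star]) / (tw - cw[t_star])
  sse <- sum(w * mu^2) - best_fit
  list(low_value = low_value, high_value = high_value, high = high,
       sse = max(sse, 0), degenerate = FALSE)
}

#' Restrict a co-cluster model to two accessibility states per locus cluster
#'
#' Within each locus cluster the co-clusters are forced to one of two values,
#' an inaccessible and an accessible state, chosen to minimise the squared
#' Frobenius residual to `M` (see [two_state_split()]).
#'
#' @param model a fitted [fit_means()] model.
#' @return A `two_state_model`: `low_value`/`high_value` per locus cluster,
#'   `states` (logical J x k, `TRUE` = accessible), `value_grid` (J x k fitted
#'   values), `degenerate` flags, plus the model's column assignment.
#' @export
fit_two_state <- function(model) {
  stopifnot(inherits(model, "cocluster_model"))
  J <- nrow(model$means); k <- ncol(model$means)
  states <- matrix(FALSE, J, k, dimnames = dimnames(model$means))
  value_grid <- model$means
  low <- high <- numeric(J)
  degenerate <- logical(J)
  for (j in seq_len(J)) {
    sp <- two_state_split(model$means[j, ], model$counts[j, ])
    states[j, ] <- sp$high
    low[j] <- sp$low_value; high[j] <- sp$high_value
    degenerate[j] <- sp$degenerate
    value_grid[j, ] <- ifelse(sp$high, sp$high_value, sp$low_value)
  }
  structure(list(low_value = low, high_value = high, states = states,
                 value_grid = value_grid, degenerate = degenerate,
                 means = model$means, counts = model$counts,
                 row_cluster_ids = model$row_cluster_ids,
                 col_assignment = model$col_assignment,
                 Tjc = model$Tjc, nj = model$nj,
                 total_ones = model$total_ones),
            class = "two_state_model")
}

#' @export
print.two_state_model <- function(x, ...) {
  cat("two_state_model:", nrow(x$states), "locus clusters;",
      sum(x$states), "accessible co-clusters",
      if (any(x$degenerate)) paste0(" (", sum(x$degenerate), " degenerate)"),
      "\n")
  invisible(x)
}

#' Accessibility co-clusters
#'
#' One per locus cluster: the cluster's loci paired with the union of cell
#' types belonging to column clusters in the accessible state.
#'
#' @param two_state a `two_state_model`.
#' @param partition the column `tree_partition` used at fit time.
#' @param row_labels row-cluster labels; when supplied, each record also
#'   carries the locus names of its cluster.
#' @return list of records `list(locus_cluster, cell_types, loci, empty)`.
#' @export
accessibility_coclusters <- function(two_state, partition, row_labels = NULL) {
  stopifnot(inherits(two_state, "two_state_model"))
  lapply(seq_len(nrow(two_state$states)), function(j) {
    acc <- which(two_state$states[j, ])
    cells <- names(two_state$col_assignment)[two_state$col_assignment %in% acc]
    jid <- two_state$row_cluster_ids[j]
    loci <- if (!is.null(row_labels)) {
      names(row_labels)[as.character(row_labels) == jid]
    }
    if (length(cells) == 0) {
      warning("locus cluster ", jid, " has no accessible state (degenerate)")
    }
    list(locus_cluster = jid, cell_types = cells, loci = loci,
         empty = length(cells) == 0)
  })
}

#' ANOVA R-squared decomposition of the co-cluster fit
#'
#' Per locus cluster j, with `mu_j` the mean of the restricted matrix:
#' * `r2_total  = 1 - SSE(M_j, M~_j) / sum((M_j - mu_j)^2)` -- the fraction of
#'   all variation captured by the co-cluster approximation;
#' * `r2_celltype = 1 - sum_c (colmean_j(c) - m[j, cl(c)])^2 /
#'   sum_c (colmean_j(c) - mu_j)^2` -- the fraction of the cell-type
#'   (column-mean) variation captured by the column clustering. It equals 1
#'   under singleton column clusters and 0 under the single-cluster partition.
#'
#' Overall values average the per-cluster R-squared without size weighting.
#' A constant locus cluster (zero denominator) reports R-squared 1, flagged.
#'
#' @param model a `cocluster_model` or `two_state_model`.
#' @return A `cocluster_anova`: `per_cluster` data.frame (`locus_cluster`,
#'   `mu`, `r2_total`, `r2_celltype`, `flagged`) and `overall` list with the
#'   unweighted means.
#' @export
cocluster_anova <- function(model) {
  stopifnot(inherits(model, c("cocluster_model", "two_state_model")))
  vals <- if (inherits(model, "two_state_model")) model$value_grid else model$means
  a <- model$col_assignment
  J <- nrow(vals)
  C <- length(a)
  nj <- model$nj
  Sj <- rowSums(model$Tjc)
  mu <- Sj / (nj * C)
  colmeans <- model$Tjc / nj                       # J x C within-cluster column means
  vfull <- vals[, a, drop = FALSE]                 # J x C fitted value per column
  # binary M: sum over cluster j of (x - v)^2 = S - 2 v S + v^2 m per cell-column
  sse_fit <- rowSums(model$Tjc - 2 * vfull * model$Tjc +
                       vfull^2 * matrix(nj, J, C))
  sst <- Sj - Sj^2 / (nj * C)
  num_ct <- rowSums((colmeans - vfull)^2)
  den_ct <- rowSums((colmeans - mu)^2)
  flagged <- sst <= 0 | den_ct <= 0
  r2_total <- ifelse(sst > 0, 1 - sse_fit / sst, 1)
  r2_celltype <- ifelse(den_ct > 0, 1 - num_ct / den_ct, 1)
  per <- data.frame(locus_cluster = model$row_cluster_ids, mu = mu,
                    r2_total = r2_total, r2_celltype = r2_celltype,
                    flagged = flagged, row.names = NULL)
  structure(list(per_cluster = per,
                 overall = list(r2_total = mean(r2_total),
                                r2_celltype = mean(r2_celltype))),
            class = "cocluster_anova")
}

#' @export
print.cocluster_anova <- function(x, ...) {
  cat("cocluster_anova over", nrow(x$per_cluster), "locus clusters:\n")
  cat("  overall R2 total    ", round(x$overall$r2_total, 4), "\n")
  cat("  overall R2 cell type", round(x$overall$r2_celltype, 4), "\n")
  invisible(x)
}

#' Serialize co-cluster model grids as TSV
#' @param model `cocluster_model` or `two_state_model`.
#' @param path output path; means (or two-state values) as a locus-cluster by
#'   cell-cluster grid.
#' @export
write_model_tsv <- function(model, path) {
  vals <- if (inherits(model, "two_state_model")) model$value_grid else model$means
  df <- data.frame(locus_cluster = rownames(vals), vals, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
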