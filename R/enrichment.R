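#' Restrict loci to those distal to transcription start sites
#'
#' Motif enrichment operates on putative enhancers only: loci more than
#' 3,000 bp from the nearest TSS (see [classify_tss()]).
#'
#' @param loci character vector of locus names.
#' @param tss_annotation data.frame from [classify_tss()].
#' @return The distal subset of `loci`.
#' @export
filter_distal <- function(loci, tss_annotation) {
  distal <- tss_annotation$locus[tss_annotation$class == "distal"]
  out <- intersect(loci, distal)
  if (length(out) == 0) warning("no distal loci remain after filtering")
  out
}

# Per-cell-type motif fractions for a (loci, cells) block: for cell c, among
# the block's loci accessible in c, the fraction carrying each motif. Cells
# with zero accessible loci in the block are skipped (NA columns).
motif_fractions <- function(M, A, loci, cells) {
  Mb <- M[loci, cells, drop = FALSE]
  acc <- colSums(Mb)
  hits <- t(A[loci, , drop = FALSE]) %*% Mb       # motifs x cells
  frac <- sweep(hits, 2, acc, "/")
  frac[, acc == 0] <- NA_real_
  frac
}

#' Raw co-cluster motif score
#'
#' For each cell type in the accessibility co-cluster, the fraction of the
#' co-cluster's loci accessible in that cell type which carry the motif,
#' averaged over cell types (cell types with no accessible co-cluster loci are
#' skipped).
#'
#' @param cocluster a record from [accessibility_coclusters()] (fields `loci`,
#'   `cell_types`), or any list with those fields.
#' @param M binary accessibility matrix.
#' @param A binary locus x motif hit matrix (rownames subset of `M`'s).
#' @param motif motif name (column of `A`); `NULL` returns all motifs.
#' @return Named numeric rate(s); `NA` when every cell type is skipped.
#' @export
raw_score <- function(cocluster, M, A, motif = NULL) {
  loci <- intersect(cocluster$loci, rownames(A))
  frac <- motif_fractions(M, A, loci, cocluster$cell_types)
  r <- rowMeans(frac, na.rm = TRUE)
  r[is.nan(r)] <- NA_real_
  if (is.null(motif)) r else r[[motif]]
}

#' Raw null motif score
#'
#' The same computation as [raw_score()] on the complement block: loci not in
#' the co-cluster crossed with cell types not in the co-cluster.
#'
#' @inheritParams raw_score
#' @param all_loci universe of loci (defaults to rownames of `A`).
#' @export
null_score <- function(cocluster, M, A, motif = NULL,
                       all_loci = rownames(A)) {
  loci <- setdiff(all_loci, cocluster$loci)
  cells <- setdiff(colnames(M), cocluster$cell_types)
  frac <- motif_fractions(M, A, loci, cells)
  n <- rowMeans(frac, na.rm = TRUE)
  n[is.nan(n)] <- NA_real_
  if (is.null(motif)) n else n[[motif]]
}

#' Normalised enrichment score
#'
#' `(r - n) / (r + n)`: +1 when the motif appears only inside the co-cluster,
#' -1 only outside, 0 at parity (and, by convention, when both rates vanish).
#'
#' @param r raw co-cluster score.
#' @param n_null raw null score.
#' @return Score in `[-1, 1]`.
#' @export
enrichment_score <- function(r, n_null) {
  out <- (r - n_null) / (r + n_null)
  out[!is.na(r) & !is.na(n_null) & (r + n_null) == 0] <- 0
  out
}

# Score matrix (motifs x co-clusters) for a list of accessibility co-clusters.
score_matrix <- function(M, A, coclusters, all_loci = rownames(A)) {
  out <- vapply(coclusters, function(cc) {
    enrichment_score(raw_score(cc, M, A), null_score(cc, M, A, all_loci = all_loci))
  }, numeric(ncol(A)))
  if (is.null(dim(out))) out <- matrix(out, ncol = length(coclusters))
  dimnames(out) <- list(colnames(A),
                        vapply(coclusters, function(cc) as.character(cc$locus_cluster), ""))
  out
}

#' Permutation FDR cutoff for motif enrichment scores
#'
#' Estimates a global score cutoff controlling the FDR over all
#' (motif, co-cluster) pairs. Each permutation replicate shuffles the locus
#' labels of `A` (one global row permutation), which breaks the locus-motif
#' association while preserving per-motif frequencies and `M`; all scores are
#' recomputed. For each candidate cutoff c (the observed score values), the
#' estimated FDR is the mean permuted count of scores >= c divided by the
#' observed count; the cutoff is the smallest c with estimated FDR at or
#' below `fdr`.
#'
#' @param M binary accessibility matrix.
#' @param A binary locus x motif matrix.
#' @param coclusters list from [accessibility_coclusters()] (with loci).
#' @param fdr target FDR (0.05).
#' @param n_perm number of permutations (>= 20).
#' @param seed RNG seed.
#' @return An `enrichment_result`: `scores` (motif x co-cluster), `cutoff`
#'   (`Inf` when nothing can be called), `calls` (logical matrix), `fdr_hat`
#'   (data.frame of candidate cutoffs and estimated FDR), `n_perm`.
#' @export
permutation_cutoff <- function(M, A, coclusters, fdr = 0.05, n_perm = 100L,
                               seed = 0L) {
  stopifnot(n_perm >= 20)
  obs <- score_matrix(M, A, coclusters)
  set.seed(seed)
  null_scores <- numeric(0)
  for (b in seq_len(n_perm)) {
    Ab <- A[sample.int(nrow(A)), , drop = FALSE]
    rownames(Ab) <- rownames(A)
    null_scores <- c(null_scores, as.numeric(score_matrix(M, Ab, coclusters)))
  }
  obs_v <- as.numeric(obs)
  obs_v <- obs_v[!is.na(obs_v)]
  null_v <- sort(null_scores[!is.na(null_scores)])
  cand <- sort(unique(obs_v))
  n_obs_ge <- length(obs_v) - findInterval(cand - 1e-12, sort(obs_v))
  n_null_ge <- (length(null_v) - findInterval(cand - 1e-12, null_v)) / n_perm
  fdr_hat <- ifelse(n_obs_ge > 0, n_null_ge / n_obs_ge, Inf)
  ok <- which(fdr_hat <= fdr)
  cutoff <- if (length(ok)) cand[min(ok)] else Inf
  calls <- !is.na(obs) & obs >= cutoff
  structure(list(scores = obs, cutoff = cutoff, calls = calls,
                 fdr_hat = data.frame(cutoff = cand, n_obs = n_obs_ge,
                                      mean_null = n_null_ge, fdr_hat = fdr_hat),
                 n_perm = n_perm),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result:", nrow(x$scores), "motifs x", ncol(x$scores),
      "co-clusters;", sum(x$calls), "calls at cutoff",
      format(signif(x$cutoff, 3)), "\n")
  invisible(x)
}

#' Flag loci containing a ChIP-seq peak summit
#'
#' A locus is flagged when at least one peak summit position falls inside its
#' half-open window.
#'
#' @param master master-locus data.frame.
#' @param chip_peaks a `peak_set` of ChIP-seq peaks (summit offsets used).
#' @return Named binary integer vector over the master loci.
#' @export
chip_overlap <- function(master, chip_peaks) {
  hits <- stats::setNames(integer(nrow(master)), master$name)
  p <- chip_peaks$peaks
  if (nrow(p) == 0) return(hits)
  summit <- p$start + p$summit_offset
  for (chr in unique(master$chrom)) {
    rows <- which(master$chrom == chr)
    sm <- sort(summit[p$chrom == chr])
    if (length(sm) == 0) next
    # summits in [start, end): count <= end-1 minus count <= start-1
    cnt <- findInterval(master$end[rows] - 0.5, sm) -
      findInterval(master$start[rows] - 0.5, sm)
    hits[rows] <- as.integer(cnt > 0)
  }
  hits
}

#' Scaled ChIP-seq hit counts per locus cluster
#'
#' The raw per-cluster hit count divided by its expectation under uniform
#' placement of hits across the clustered loci
#' (`expected = total_hits * cluster_size / total_loci`). Clusters with scaled
#' count above 1 are enriched.
#'
#' @param hits binary vector aligned with `row_labels` (names matched when
#'   both are named).
#' @param row_labels locus-cluster labels.
#' @return A `scaled_counts` data.frame: `cluster`, `size`, `raw`, `expected`,
#'   `scaled`, `enriched`.
#' @export
scaled_counts <- function(hits, row_labels) {
  if (!is.null(names(hits)) && !is.null(names(row_labels))) {
    hits <- hits[names(row_labels)]
  }
  stopifnot(length(hits) == length(row_labels))
  f <- factor(row_labels)
  raw <- as.numeric(rowsum(as.numeric(hits), f))
  size <- as.numeric(table(f))
  total <- sum(raw)
  expected <- total * size / length(row_labels)
  if (total == 0) {
    warning("zero total hits; scaled counts undefined")
    scaled <- rep(NA_real_, length(raw))
  } else {
    scaled <- raw / expected
  }
  structure(data.frame(cluster = levels(f), size = size, raw = raw,
                       expected = expected, scaled = scaled,
                       enriched = !is.na(scaled) & scaled > 1),
            class = c("scaled_counts", "data.frame"))
}

#' Hypergeometric association between enriched and accessible clusters
#'
#' Tests whether the locus clusters with enriched ChIP-seq counts overlap the
#' clusters whose accessible state contains a given cell type more than chance
#' allows: upper-tail hypergeometric p-value with population
#' `total_clusters`, successes `|accessible|`, draws `|enriched|`.
#'
#' @param enriched_clusters,accessible_clusters vectors of cluster ids.
#' @param total_clusters total number of locus clusters.
#' @return Upper-tail p-value of the observed overlap.
#' @export
association_test <- function(enriched_clusters, accessible_clusters,
                             total_clusters) {
  enriched_clusters <- unique(enriched_clusters)
  accessible_clusters <- unique(accessible_clusters)
  overlap <- length(intersect(enriched_clusters, accessible_clusters))
  stats::phyper(overlap - 1, length(accessible_clusters),
                total_clusters - length(accessible_clusters),
                length(enriched_clusters), lower.tail = FALSE)
}

#' Read a binary locus x motif matrix from TSV
#'
#' Header row of motif names, first column `locus`.
#' @param path file path.
#' @return Binary integer matrix.
#' @export
read_motif_tsv <- function(path) read_matrix_tsv(path)

#' Write an enrichment result as TSV
#'
#' One row per (motif, co-cluster): raw scores, enrichment score and call.
#' @param result an `enrichment_result`.
#' @param path output path.
#' @export
write_enrichment_tsv <- function(result, path) {
  df <- data.frame(motif = rep(rownames(result$scores), ncol(result$scores)),
                   cocluster = rep(colnames(result$scores),
                                   each = nrow(result$scores)),
                   score = as.numeric(result$scores),
                   call = as.logical(result$calls))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
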