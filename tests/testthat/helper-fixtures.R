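# Shared fixtures built in code.

# Small hematopoiesis-like tree:
#        HSC
#       /   \
#     MPP    GN
#    / | \
#   T  B  NK
#   |  |
#  T4  PB
toy_tree <- function() {
  diff_tree(child = c("MPP", "GN", "T", "B", "NK", "T4", "PB"),
            parent = c("HSC", "HSC", "MPP", "MPP", "MPP", "T", "B"))
}

# Three-generation fan: root R; A,B,C under R; two leaves under each.
fan_tree <- function() {
  diff_tree(child = c("A", "B", "C", "a1", "a2", "b1", "b2", "c1", "c2"),
            parent = c("R", "R", "R", "A", "A", "B", "B", "C", "C"))
}

# Windows data.frame constructor for master-list tests.
win <- function(start, end, score, chrom = "chr1", cell = "x") {
  data.frame(chrom = chrom, start = start, end = end, score = score,
             source_cell = cell, stringsAsFactors = FALSE)
}

# Write narrowPeak lines to a temp file; rows = list of field vectors.
write_np <- function(rows) {
  path <- tempfile(fileext = ".narrowPeak")
  writeLines(vapply(rows, paste, "", collapse = "\t"), path)
  path
}

np_row <- function(chrom, start, end, qval, summit,
                   name = ".", score = 0, strand = ".",
                   signal = 1, pval = 1) {
  c(chrom, start, end, name, score, strand, signal, pval, qval, summit)
}

# Independent naive SSE oracle: direct scan over co-cluster blocks.
naive_sse <- function(M, row_labels, assignment) {
  total <- 0
  for (j in unique(row_labels)) {
    for (i in unique(assignment)) {
      blk <- M[row_labels == j, assignment[colnames(M)] == i, drop = FALSE]
      if (length(blk)) total <- total + sum((blk - mean(blk))^2)
    }
  }
  total
}

# Independent hypergeometric upper tail from binomial coefficients.
naive_hyper_tail <- function(n, N, s, C) {
  smax <- min(n, N)
  if (s > smax) return(0)
  sum(vapply(s:smax, function(j) {
    choose(N, j) * choose(C - N, n - j)
  }, 1)) / choose(C, n)
}

# Canonical label-free form of a column partition.
canon_partition <- function(p) {
  sort(vapply(lapply(p$clusters, sort), paste, "", collapse = ","))
}

# Brute-force two-state fit: all 2^k state assignments, each side fitted with
# its weight-weighted mean; the accessible state must sit above the
# inaccessible one; ties prefer fewer accessible clusters.
brute_two_state <- function(means, weights) {
  k <- length(means)
  best <- Inf; best_high <- NULL
  for (mask in 0:(2^k - 1)) {
    high <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    a0 <- if (any(!high)) sum(weights[!high] * means[!high]) / sum(weights[!high]) else 0
    a1 <- if (any(high)) sum(weights[high] * means[high]) / sum(weights[high]) else 0
    if (any(high) && any(!high) && a1 < a0) next
    v <- ifelse(high, a1, a0)
    sse <- sum(weights * (means - v)^2)
    if (sse < best - 1e-12 ||
        (sse < best + 1e-12 && !is.null(best_high) && sum(high) < sum(best_high))) {
      best <- sse; best_high <- high
    }
  }
  list(sse = best, high = best_high)
}

# Adjusted Rand index (closed form) for comparing clusterings.
ari <- function(x, y) {
  tab <- table(x, y)
  if (sum(tab) < 2) return(NA_real_)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_a <- b * cc / n2
  max_a <- (b + cc) / 2
  if (max_a == exp_a) return(1)
  (a - exp_a) / (max_a - exp_a)
}
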