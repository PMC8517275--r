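#' Read a narrowPeak file of ATAC-seq or ChIP-seq peak calls
#'
#' narrowPeak is BED6+4: chrom, start, end, name, score, strand, signalValue,
#' pValue, qValue, summit offset (relative to start; -1 when absent).
#' Coordinates are 0-based half-open throughout the package.
#'
#' The per-peak quality score used for master-list selection is taken from the
#' qValue column; when qValue is -1 (not reported) the BED score column is used
#' instead. A summit offset of -1 is replaced by the peak midpoint.
#'
#' @param path narrowPeak file path.
#' @param cell_type name attached to the peak set; defaults to the file name
#'   without extension.
#' @return An object of class `peak_set`: a list with `cell_type` and `peaks`,
#'   a data.frame with columns `chrom`, `start`, `end`, `summit_offset`,
#'   `score`, sorted by (chrom, start).
#' @export
read_narrowpeak <- function(path, cell_type = NULL) {
  if (is.null(cell_type)) {
    cell_type <- sub("\\.(narrowPeak|bed|txt)(\\.gz)?$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(peak_set(cell_type, data.frame(chrom = character(), start = integer(),
                                          end = integer(), summit_offset = integer(),
                                          score = numeric())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 10)) {
    stop("malformed narrowPeak line ", which(nf < 10)[1], " in ", path,
         ": expected 10 tab-separated fields, found ", nf[which(nf < 10)[1]])
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  qval <- suppressWarnings(as.numeric(m[, 9]))
  score <- suppressWarnings(as.numeric(m[, 5]))
  summit <- suppressWarnings(as.integer(m[, 10]))
  bad <- which(is.na(start) | is.na(end) | is.na(qval) | is.na(summit))
  if (length(bad)) {
    stop("malformed narrowPeak line ", bad[1], " in ", path,
         ": non-numeric coordinate, qValue or summit field")
  }
  if (any(start >= end)) {
    stop("malformed narrowPeak line ", which(start >= end)[1], " in ", path,
         ": start >= end")
  }
  width <- end - start
  use_mid <- summit == -1L
  summit[use_mid] <- (width[use_mid]) %/% 2L
  out_of_peak <- summit < 0L | summit >= width
  if (any(out_of_peak)) {
    stop("narrowPeak line ", which(out_of_peak)[1], " in ", path,
         ": summit offset ", summit[which(out_of_peak)[1]],
         " outside peak of width ", width[which(out_of_peak)[1]])
  }
  quality <- ifelse(qval >= 0, qval, score)
  peaks <- data.frame(chrom = m[, 1], start = start, end = end,
                      summit_offset = summit, score = quality,
                      stringsAsFactors = FALSE)
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  peak_set(cell_type, peaks)
}

peak_set <- function(cell_type, peaks) {
  structure(list(cell_type = cell_type, peaks = peaks), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set '", x$cell_type, "': ", nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

#' Summit-centred candidate windows from a peak set
#'
#' Each peak contributes the window `[summit - halfwidth, summit + halfwidth)`,
#' i.e. 500 bp at the default halfwidth, carrying the peak's quality score.
#' Windows are clipped at position 0 on the left; no right clipping is applied
#' (chromosome sizes are not required).
#'
#' @param peaks a `peak_set`.
#' @param halfwidth extension on each side of the summit, in bp.
#' @return data.frame of scored windows: `chrom`, `start`, `end`, `score`,
#'   `source_cell`.
#' @export
peaks_to_windows <- function(peaks, halfwidth = 250L) {
  stopifnot(inherits(peaks, "peak_set"), halfwidth > 0)
  p <- peaks$peaks
  summit <- p$start + p$summit_offset
  data.frame(chrom = p$chrom,
             start = pmax(0L, summit - as.integer(halfwidth)),
             end = summit + as.integer(halfwidth),
             score = p$score,
             source_cell = rep(peaks$cell_type, nrow(p)),
             stringsAsFactors = FALSE)
}

#' Greedy master list of non-overlapping loci
#'
#' Pools summit windows from all cell types and scans each chromosome 5' to 3'.
#' At the first window not overlapping the last-added master locus, all
#' subsequent windows overlapping *that* window are gathered, the gathered
#' window with the highest quality score is added to the master list, and the
#' scan resumes at the next window clear of the *added* locus. Ties on score
#' break by leftmost start, then lexicographic cell-type name.
#'
#' @param windows data.frame of scored windows as returned by
#'   [peaks_to_windows()], possibly row-bound across cell types, or a list of
#'   such data.frames.
#' @return data.frame of master loci (same columns), sorted and pairwise
#'   non-overlapping, with a `name` column `chrom:start-end`.
#' @export
build_master_loci <- function(windows) {
  if (is.list(windows) && !is.data.frame(windows)) {
    windows <- do.call(rbind, windows)
  }
  if (is.null(windows) || nrow(windows) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      score = numeric(), source_cell = character(),
                      name = character(), stringsAsFactors = FALSE))
  }
  if (is.null(windows$source_cell)) windows$source_cell <- NA_character_
  keep <- lapply(split(seq_len(nrow(windows)), windows$chrom), function(idx) {
    w <- windows[idx, , drop = FALSE]
    o <- order(w$start, w$end)
    w <- w[o, , drop = FALSE]
    idx <- idx[o]
    chosen <- integer(0)
    i <- 1L
    n <- nrow(w)
    last_end <- -Inf
    while (i <= n) {
      if (w$start[i] < last_end) { i <- i + 1L; next }   # overlaps added locus
      cur_end <- w$end[i]
      j <- i
      while (j < n && w$start[j + 1L] < cur_end) j <- j + 1L  # gather vs current
      grp <- i:j
      ord <- order(-w$score[grp], w$start[grp],
                   as.character(w$source_cell[grp]))
      best <- grp[ord[1L]]
      chosen <- c(chosen, idx[best])
      last_end <- w$end[best]
      i <- j + 1L
    }
    chosen
  })
  out <- windows[unlist(keep, use.names = FALSE), , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$name <- paste0(out$chrom, ":", out$start, "-", out$end)
  out
}

locus_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Assemble the binary accessibility matrix M
#'
#' Entry (locus, cell type) is 1 when any *original* peak interval of the cell
#' type (not its summit window) overlaps the master locus by at least one base.
#'
#' @param master master-locus data.frame from [build_master_loci()].
#' @param peak_sets list of `peak_set` objects, one per cell type.
#' @return An `access_matrix`: list with `M` (binary integer matrix, rownames =
#'   locus names, colnames = cell types) and `loci` (the master data.frame).
#' @export
build_matrix <- function(master, peak_sets) {
  stopifnot(nrow(master) > 0, length(peak_sets) > 0)
  cell_types <- vapply(peak_sets, function(p) p$cell_type, "")
  if (anyDuplicated(cell_types)) stop("duplicate cell-type names in peak_sets")
  gr_master <- locus_granges(master)
  M <- matrix(0L, nrow = nrow(master), ncol = length(peak_sets),
              dimnames = list(master$name, cell_types))
  for (s in seq_along(peak_sets)) {
    p <- peak_sets[[s]]$peaks
    if (nrow(p) == 0) {
      warning("cell type ", cell_types[s], " has zero peaks; all-zero column")
      next
    }
    gr_p <- locus_granges(p)
    hit <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(gr_master, gr_p, minoverlap = 1L)))
    M[hit, s] <- 1L
  }
  structure(list(M = M, loci = master), class = "access_matrix")
}

#' @export
print.access_matrix <- function(x, ...) {
  cat("access_matrix:", nrow(x$M), "loci x", ncol(x$M), "cell types;",
      "density", round(mean(x$M), 3), "\n")
  invisible(x)
}

#' Split cell-specific loci from the matrix
#'
#' A cell-specific locus is accessible in at most `max_cells` cell types
#' (2 by default); only the non-specific loci enter locus clustering.
#'
#' @param M binary matrix (or `access_matrix`).
#' @param max_cells row-sum threshold for cell specificity.
#' @return list with binary matrices `cell_specific` and `non_specific`.
#' @export
split_cell_specific <- function(M, max_cells = 2L) {
  if (inherits(M, "access_matrix")) M <- M$M
  rs <- rowSums(M)
  list(cell_specific = M[rs <= max_cells, , drop = FALSE],
       non_specific = M[rs > max_cells, , drop = FALSE])
}

#' Classify loci by distance to the nearest TSS
#'
#' Distance is measured from the locus midpoint to the nearest TSS, and is 0
#' when a TSS falls inside the locus. Loci within 500 bp of a TSS are proximal;
#' loci more than 3,000 bp away are distal; the rest are intermediate.
#' Chromosomes with no TSS yield infinite distance (distal).
#'
#' @param master master-locus data.frame.
#' @param tss data.frame with columns `chrom` and `pos` (0-based TSS
#'   positions), or a named list of position vectors per chromosome.
#' @param proximal_max,distal_min class boundaries in bp.
#' @return data.frame `locus`, `distance`, `class`.
#' @export
classify_tss <- function(master, tss, proximal_max = 500, distal_min = 3000) {
  if (is.data.frame(tss)) tss <- split(tss$pos, tss$chrom)
  mid <- (master$start + master$end) / 2
  dist <- rep(Inf, nrow(master))
  for (chr in unique(master$chrom)) {
    rows <- which(master$chrom == chr)
    tp <- sort(as.numeric(tss[[chr]]))
    if (length(tp) == 0) next
    i <- findInterval(mid[rows], tp)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, length(tp))
    d <- pmin(abs(mid[rows] - tp[lo]), abs(tp[hi] - mid[rows]))
    # TSS anywhere inside the locus counts as distance 0
    inside <- findInterval(master$end[rows] - 1L + 0.5, tp) -
      findInterval(master$start[rows] - 0.5, tp) > 0
    d[inside] <- 0
    dist[rows] <- d
  }
  cls <- ifelse(dist <= proximal_max, "proximal",
                ifelse(dist > distal_min, "distal", "intermediate"))
  data.frame(locus = master$name, distance = dist, class = cls,
             stringsAsFactors = FALSE)
}

#' Write the master loci as a BED4 file
#'
#' Name column is `chrom:start-end`; the score column carries the selected
#' peak's quality score.
#' @param master master-locus data.frame.
#' @param path output path.
#' @export
write_master_bed <- function(master, path) {
  df <- data.frame(master$chrom, master$start, master$end, master$name,
                   master$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write the accessibility matrix as TSV
#'
#' Dense format: header row of cell types, first column `locus`. Sparse
#' format: three columns `row`, `col`, `value` of 1-based indices preceded by
#' two header lines naming loci and cell types.
#'
#' @param M binary matrix with dimnames (or `access_matrix`).
#' @param path file path.
#' @param format `"dense"` or `"sparse"`.
#' @export
write_matrix_tsv <- function(M, path, format = c("dense", "sparse")) {
  if (inherits(M, "access_matrix")) M <- M$M
  format <- match.arg(format)
  if (format == "dense") {
    df <- data.frame(locus = rownames(M), M, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("#loci\t", paste(rownames(M), collapse = "\t")),
                 paste0("#cells\t", paste(colnames(M), collapse = "\t")),
                 "row\tcol\tvalue"), con)
    idx <- which(M != 0, arr.ind = TRUE)
    utils::write.table(data.frame(idx[, 1], idx[, 2], 1L), con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#loci")) {
    hdr <- readLines(path, n = 2L)
    loci <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]][-1]
    cells <- strsplit(hdr[2], "\t", fixed = TRUE)[[1]][-1]
    df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 2)
    M <- matrix(0L, length(loci), length(cells), dimnames = list(loci, cells))
    M[cbind(df$row, df$col)] <- as.integer(df$value)
    return(M)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "")
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "integer"
  rownames(M) <- df[[1]]
  M
}
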