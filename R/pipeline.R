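#' Read a flat key = value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values are
#' type-converted (logical, numeric) when unambiguous. Returns a plain list
#' that [run_pipeline()] accepts; round-trips through [write_config()].
#'
#' @param path config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("malformed config line: ", ln)
    val <- trimws(kv[3])
    val <- gsub('^"|"$', "", val)
    conv <- suppressWarnings(as.numeric(val))
    out[[kv[2]]] <- if (val %in% c("true", "TRUE", "false", "FALSE")) {
      as.logical(toupper(val))
    } else if (!is.na(conv)) conv else val
  }
  out
}

#' @rdname read_config
#' @param config named list of scalar parameters.
#' @export
write_config <- function(config, path) {
  fmt <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, " = ", if (is.character(v)) v else format(v, scientific = FALSE))
  }, "")
  writeLines(fmt, path)
  invisible(path)
}

default_config <- function() {
  list(halfwidth = 250, max_specific = 2, edge_fdr = 0.001, min_size = 30,
       k = 12, restarts = 20, motif_fdr = 0.05, n_perm = 100, seed = 0,
       resolution = 1, baseline = "")
}

pipeline_paths <- function(out_dir) {
  file <- function(...) file.path(out_dir, paste0(...))
  list(matrix = file("matrix.tsv"), master = file("master.bed"),
       tree = file("tree.tsv"), row_clusters = file("row_clusters.tsv"),
       graph = file("graph.tsv"), partition = file("partition.tsv"),
       run_report = file("celltype_run.json"), model = file("model.tsv"),
       anova = file("anova.json"), enrichment = file("enrichment.tsv"),
       chip = file("chip_counts.tsv"), truth = file("truth.json"),
       motifs = file("motifs.tsv"))
}

manifest_path <- function(out_dir, stage) {
  file.path(out_dir, paste0(".manifest_", stage, ".json"))
}

stage_manifest <- function(inputs, params) {
  files <- inputs[file.exists(inputs)]
  list(inputs = as.list(tools::md5sum(files)),
       params = params,
       version = as.character(utils::packageVersion("treecoclust")))
}

stage_current <- function(out_dir, stage, manifest, outputs) {
  mp <- manifest_path(out_dir, stage)
  if (!file.exists(mp) || !all(file.exists(outputs))) return(FALSE)
  old <- tryCatch(jsonlite::read_json(mp, simplifyVector = TRUE),
                  error = function(e) NULL)
  identical(jsonlite::toJSON(old, auto_unbox = TRUE, digits = NA),
            jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA))
}

write_manifest <- function(out_dir, stage, manifest) {
  jsonlite::write_json(manifest, manifest_path(out_dir, stage),
                       auto_unbox = TRUE, digits = NA)
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message("[treecoclust] ", ...)
}

#' Run the end-to-end co-clustering pipeline
#'
#' Executes the requested stages in dependency order inside `out_dir`:
#' `simulate` (synthetic matrix + tree), `build_matrix` (narrowPeak inputs),
#' `cluster_loci`, `cluster_celltypes`, `anova`, `motif_enrich`,
#' `chip_assoc`. Each stage writes its outputs plus a JSON manifest recording
#' input checksums, parameters and package version; a stage whose manifest
#' already matches is skipped, and rerunning an identical configuration
#' reproduces identical outputs.
#'
#' @param config named list (see [read_config()]) or a config file path. Keys
#'   of note: `stages` (comma-separated), `out_dir`, `peaks_dir` (narrowPeak
#'   files, one per cell type), `tree_file`, `motifs_file`, `chip_file`,
#'   `tss_file`, simulation and algorithm parameters (`k`, `edge_fdr`,
#'   `min_size`, `restarts`, `n_perm`, `seed`, ...).
#' @param verbose log stage progress to stderr.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- pipeline_paths(cfg$out_dir)
  stages <- strsplit(cfg$stages %||% "", ",")[[1]]
  stages <- trimws(stages)
  known <- c("simulate", "build_matrix", "cluster_loci", "cluster_celltypes",
             "anova", "motif_enrich", "chip_assoc")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- known[known %in% stages]

  require_upstream <- function(path, producer) {
    if (!file.exists(path)) {
      stop("missing upstream output ", basename(path),
           "; run stage '", producer, "' first")
    }
  }

  if ("simulate" %in% stages) {
    params <- cfg[c("n_cells", "k", "n_locus_clusters", "rows_per_cluster",
                    "theta_low", "theta_high", "frac_cell_specific", "seed")]
    params <- params[!vapply(params, is.null, TRUE)]
    man <- stage_manifest(character(0), params)
    outs <- c(paths$matrix, paths$tree, paths$truth)
    if (stage_current(cfg$out_dir, "simulate", man, outs)) {
      pipeline_log(verbose, "simulate: up to date, skipping")
    } else {
      pipeline_log(verbose, "simulate: generating synthetic dataset")
      ds <- do.call(simulate_accessibility, params)
      write_matrix_tsv(ds$M, paths$matrix)
      write_tree_tsv(ds$tree, paths$tree)
      jsonlite::write_json(
        list(row_labels = as.list(ds$row_labels),
             partition = as.list(ds$partition$assignment),
             states = ds$states, params = ds$params),
        paths$truth, auto_unbox = TRUE, digits = NA)
      if (!is.null(cfg$simulate_motifs) && isTRUE(cfg$simulate_motifs != 0)) {
        A <- simulate_motifs(ds)
        write_matrix_tsv(A, paths$motifs)
      }
      write_manifest(cfg$out_dir, "simulate", man)
    }
  }

  if ("build_matrix" %in% stages) {
    if (is.null(cfg$peaks_dir)) stop("build_matrix requires peaks_dir")
    files <- sort(list.files(cfg$peaks_dir, pattern = "\\.narrowPeak$",
                             full.names = TRUE))
    if (length(files) == 0) stop("no .narrowPeak files in ", cfg$peaks_dir)
    params <- cfg[c("halfwidth", "max_specific")]
    man <- stage_manifest(files, params)
    outs <- c(paths$matrix, paths$master)
    if (stage_current(cfg$out_dir, "build_matrix", man, outs)) {
      pipeline_log(verbose, "build_matrix: up to date, skipping")
    } else {
      pipeline_log(verbose, "build_matrix: ", length(files), " peak files")
      sets <- lapply(files, read_narrowpeak)
      windows <- lapply(sets, peaks_to_windows, halfwidth = cfg$halfwidth)
      master <- build_master_loci(windows)
      am <- build_matrix(master, sets)
      write_master_bed(master, paths$master)
      write_matrix_tsv(am, paths$matrix)
      write_manifest(cfg$out_dir, "build_matrix", man)
    }
  }

  if ("cluster_loci" %in% stages) {
    require_upstream(paths$matrix, "build_matrix/simulate")
    params <- cfg[c("edge_fdr", "min_size", "resolution", "seed",
                    "max_specific")]
    man <- stage_manifest(paths$matrix, params)
    if (stage_current(cfg$out_dir, "cluster_loci", man,
                      c(paths$row_clusters, paths$graph))) {
      pipeline_log(verbose, "cluster_loci: up to date, skipping")
    } else {
      M <- read_matrix_tsv(paths$matrix)
      ns <- split_cell_specific(M, cfg$max_specific)$non_specific
      pipeline_log(verbose, "cluster_loci: ", nrow(ns),
                   " non-specific loci at edge FDR ", cfg$edge_fdr)
      g <- build_graph(ns, fdr = cfg$edge_fdr)
      cl <- louvain_partition(g, resolution = cfg$resolution, seed = cfg$seed)
      write_graph_tsv(g, paths$graph)
      write_clusters_tsv(cl, paths$row_clusters)
      write_manifest(cfg$out_dir, "cluster_loci", man)
    }
  }

  if ("cluster_celltypes" %in% stages) {
    require_upstream(paths$matrix, "build_matrix/simulate")
    require_upstream(paths$row_clusters, "cluster_loci")
    if (is.null(cfg$tree_file) && !file.exists(paths$tree)) {
      stop("cluster_celltypes requires tree_file (or a simulated tree)")
    }
    tree_file <- cfg$tree_file %||% paths$tree
    params <- cfg[c("k", "restarts", "min_size", "seed", "baseline")]
    man <- stage_manifest(c(paths$matrix, paths$row_clusters, tree_file),
                          params)
    if (stage_current(cfg$out_dir, "cluster_celltypes", man,
                      c(paths$partition, paths$run_report))) {
      pipeline_log(verbose, "cluster_celltypes: up to date, skipping")
    } else {
      M <- read_matrix_tsv(paths$matrix)
      cl <- read_clusters_tsv(paths$row_clusters)
      tree <- read_tree_tsv(tree_file)
      big <- restrict_to_large(M, cl, min_size = cfg$min_size)
      if (nrow(big$M) == 0) {
        stop("no loci fall in clusters of size >= ", cfg$min_size,
             "; lower min_size or raise edge_fdr")
      }
      pipeline_log(verbose, "cluster_celltypes: k = ", cfg$k, ", ",
                   nrow(big$M), " loci in large clusters")
      run <- optimize_tree_partition(big$M, big$row_labels, tree, k = cfg$k,
                                     restarts = cfg$restarts, seed = cfg$seed)
      part <- run$best_partition
      report <- list(k = run$k, best_sse = run$best_sse,
                     restarts = run$restarts)
      if (nzchar(cfg$baseline)) {
        bp <- baseline_partition(big$M, k = cfg$k, method = cfg$baseline,
                                 seed = cfg$seed)
        report$baseline <- list(method = cfg$baseline,
                                sse = cocluster_sse(big$M, big$row_labels, bp))
      }
      write_partition_tsv(part, paths$partition)
      jsonlite::write_json(report, paths$run_report, auto_unbox = TRUE,
                           digits = NA)
      write_manifest(cfg$out_dir, "cluster_celltypes", man)
    }
  }

  if ("anova" %in% stages) {
    require_upstream(paths$matrix, "build_matrix/simulate")
    require_upstream(paths$row_clusters, "cluster_loci")
    require_upstream(paths$partition, "cluster_celltypes")
    params <- cfg[c("min_size", "two_state")]
    params <- params[!vapply(params, is.null, TRUE)]
    man <- stage_manifest(c(paths$matrix, paths$row_clusters,
                            paths$partition), params)
    if (stage_current(cfg$out_dir, "anova", man,
                      c(paths$anova, paths$model))) {
      pipeline_log(verbose, "anova: up to date, skipping")
    } else {
      M <- read_matrix_tsv(paths$matrix)
      cl <- read_clusters_tsv(paths$row_clusters)
      part <- read_partition_tsv(paths$partition)
      big <- restrict_to_large(M, cl, min_size = cfg$min_size)
      model <- fit_means(big$M, big$row_labels, part)
      if (isTRUE(cfg$two_state != 0)) model <- fit_two_state(model)
      an <- cocluster_anova(model)
      pipeline_log(verbose, "anova: overall R2 cell type ",
                   round(an$overall$r2_celltype, 3))
      write_model_tsv(model, paths$model)
      jsonlite::write_json(list(per_cluster = an$per_cluster,
                                overall = an$overall),
                           paths$anova, auto_unbox = TRUE, digits = NA)
      write_manifest(cfg$out_dir, "anova", man)
    }
  }

  if ("motif_enrich" %in% stages) {
    require_upstream(paths$matrix, "build_matrix/simulate")
    require_upstream(paths$row_clusters, "cluster_loci")
    require_upstream(paths$partition, "cluster_celltypes")
    motifs_file <- cfg$motifs_file %||% paths$motifs
    require_upstream(motifs_file, "simulate (motifs) or provide motifs_file")
    params <- cfg[c("motif_fdr", "n_perm", "seed", "min_size")]
    man <- stage_manifest(c(paths$matrix, paths$row_clusters,
                            paths$partition, motifs_file), params)
    if (stage_current(cfg$out_dir, "motif_enrich", man, paths$enrichment)) {
      pipeline_log(verbose, "motif_enrich: up to date, skipping")
    } else {
      M <- read_matrix_tsv(paths$matrix)
      cl <- read_clusters_tsv(paths$row_clusters)
      part <- read_partition_tsv(paths$partition)
      A <- read_motif_tsv(motifs_file)
      big <- restrict_to_large(M, cl, min_size = cfg$min_size)
      model <- fit_two_state(fit_means(big$M, big$row_labels, part))
      ccs <- accessibility_coclusters(model, part, big$row_labels)
      ccs <- Filter(function(cc) !cc$empty, ccs)
      if (!is.null(cfg$tss_file) && file.exists(paths$master)) {
        master <- utils::read.table(paths$master, sep = "\t",
                                    col.names = c("chrom", "start", "end",
                                                  "name", "score"))
        tss <- utils::read.table(cfg$tss_file, sep = "\t",
                                 col.names = c("chrom", "pos"))
        ann <- classify_tss(master, tss)
        ccs <- lapply(ccs, function(cc) {
          cc$loci <- filter_distal(cc$loci, ann)
          cc
        })
        ccs <- Filter(function(cc) length(cc$loci) > 0, ccs)
      }
      pipeline_log(verbose, "motif_enrich: ", ncol(A), " motifs x ",
                   length(ccs), " co-clusters, ", cfg$n_perm, " permutations")
      res <- permutation_cutoff(M, A, ccs, fdr = cfg$motif_fdr,
                                n_perm = cfg$n_perm, seed = cfg$seed)
      write_enrichment_tsv(res, paths$enrichment)
      write_manifest(cfg$out_dir, "motif_enrich", man)
    }
  }

  if ("chip_assoc" %in% stages) {
    require_upstream(paths$master, "build_matrix")
    require_upstream(paths$row_clusters, "cluster_loci")
    if (is.null(cfg$chip_file)) stop("chip_assoc requires chip_file")
    man <- stage_manifest(c(paths$master, paths$row_clusters, cfg$chip_file),
                          list())
    if (stage_current(cfg$out_dir, "chip_assoc", man, paths$chip)) {
      pipeline_log(verbose, "chip_assoc: up to date, skipping")
    } else {
      master <- utils::read.table(paths$master, sep = "\t",
                                  col.names = c("chrom", "start", "end",
                                                "name", "score"))
      cl <- read_clusters_tsv(paths$row_clusters)
      chip <- read_narrowpeak(cfg$chip_file)
      hits <- chip_overlap(master, chip)
      labs <- cl$labels[intersect(names(cl$labels), master$name)]
      sc <- scaled_counts(hits[names(labs)], labs)
      pipeline_log(verbose, "chip_assoc: ", sum(sc$raw), " hits, ",
                   sum(sc$enriched), " enriched clusters")
      utils::write.table(sc, paths$chip, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      write_manifest(cfg$out_dir, "chip_assoc", man)
    }
  }

  invisible(cfg$out_dir)
}
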