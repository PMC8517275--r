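test_that("cocluster_sse matches the definition on canonical cases", {
  ct <- paste0("c", 1:2)
  one_cluster <- as_tree_partition(stats::setNames(c(1L, 1L), ct))
  singletons <- as_tree_partition(stats::setNames(1:2, ct))

  M1 <- matrix(1L, 3, 2, dimnames = list(paste0("l", 1:3), ct))
  expect_equal(cocluster_sse(M1, rep(1, 3), one_cluster), 0)

  Mi <- matrix(c(1L, 0L, 0L, 1L), 2, 2, dimnames = list(paste0("l", 1:2), ct))
  expect_equal(cocluster_sse(Mi, rep(1, 2), one_cluster), 1)  # four 0.25 residuals

  expect_equal(cocluster_sse(Mi, 1:2, singletons), 0)          # cell-level model
})

test_that("cache-based SSE equals the naive direct scan on random instances", {
  set.seed(12)
  for (rep in 1:10) {
    M <- matrix(rbinom(60 * 7, 1, runif(1, 0.2, 0.8)), 60, 7,
                dimnames = list(paste0("l", 1:60), paste0("c", 1:7)))
    rl <- sample(1:4, 60, replace = TRUE)
    a <- stats::setNames(sample(1:3, 7, replace = TRUE), colnames(M))
    part <- as_tree_partition(a)
    expect_equal(cocluster_sse(M, rl, part),
                 naive_sse(M, rl, part$assignment), tolerance = 1e-9)
  }
})

test_that("random_init draws valid specs and degenerates properly", {
  star <- diff_tree(paste0("leaf", 1:5), rep("root", 5))
  expect_length(random_init(star, 1, seed = 0)$groups, 0)
  sp <- random_init(star, 2, seed = 0)
  expect_equal(sp$groups[[1]]$vertex, "root")
  expect_setequal(sp$groups[[1]]$members, paste0("leaf", 1:5))
  expect_error(random_init(star, 3, seed = 0), "non-leaf|feasible")

  sp1 <- random_init(toy_tree(), 3, seed = 42)
  sp2 <- random_init(toy_tree(), 3, seed = 42)
  expect_identical(sp1, sp2)
})

test_that("cut_group_moves enumerates additions, removals and transfers", {
  tr <- diff_tree(c("a", "b", "c"), c("v", "v", "v"))
  # one group {a}: two additions, no removal (would empty), no transfer
  sp <- cut_spec(list(list(vertex = "v", members = "a")), tr)
  cands <- cut_group_moves(sp, "v", tr)
  expect_length(cands, 2)
  mem <- lapply(cands, function(s) sort(s$groups[[1]]$members))
  expect_setequal(vapply(mem, paste, "", collapse = ","), c("a,b", "a,c"))

  # groups {a},{b}, child c unclaimed: 2 additions only (transfers empty source)
  sp2 <- cut_spec(list(list(vertex = "v", members = "a"),
                       list(vertex = "v", members = "b")), tr)
  expect_length(cut_group_moves(sp2, "v", tr), 2)

  # one group with all children: removals only, one per member
  sp3 <- cut_spec(list(list(vertex = "v", members = c("a", "b", "c"))), tr)
  cands3 <- cut_group_moves(sp3, "v", tr)
  expect_length(cands3, 3)
  expect_true(all(vapply(cands3, function(s) length(s$groups[[1]]$members), 1L) == 2))
})

test_that("cut_vertex_moves respects post-deletion availability", {
  tr <- fan_tree()
  # v=A has one group; v'=B has two unclaimed children
  sp <- cut_spec(list(list(vertex = "A", members = "a1")), tr)
  expect_length(cut_vertex_moves(sp, "A", "B", tr), 2)
  # leaves contribute nothing
  expect_length(cut_vertex_moves(sp, "A", "a2", tr), 0)
  # deleting the group frees a member that is a child of v'
  sp2 <- cut_spec(list(list(vertex = "R", members = c("A", "B"))), tr)
  cands <- cut_vertex_moves(sp2, "R", "A", tr)
  expect_length(cands, 2)   # a1, a2 both addable once the R-group is deleted
  expect_true(all(vapply(cands, function(s) s$groups[[1]]$vertex, "") == "A"))
})

test_that("moves preserve group count and cut-spec invariants", {
  for (seed in 1:10) {
    tree <- random_tree(10, seed = seed)
    nonleaf <- tree$nodes[lengths(tree$children) > 0]
    k <- min(3, length(nonleaf) + 1)
    if (k < 2) next
    sp <- random_init(tree, k, seed = seed)
    v <- sp$groups[[1]]$vertex
    cands <- cut_group_moves(sp, v, tree)
    for (vp in setdiff(tree$nodes, v)) {
      cands <- c(cands, cut_vertex_moves(sp, v, vp, tree))
    }
    for (cand in cands) {
      expect_length(cand$groups, length(sp$groups))
      expect_silent(treecoclust:::validate_cut_spec(cand, tree))
      part <- partition_from_cutspec(tree, cand)
      for (cl in part$clusters) expect_true(respects_tree(cl, tree))
    }
  }
})

test_that("optimizer attains the exhaustively enumerated optimum on small trees", {
  matched <- 0L
  total <- 0L
  for (inst in 1:8) {
    set.seed(inst * 17)
    n <- sample(6:9, 1)
    k <- sample(2:4, 1)
    tree <- random_tree(n, seed = inst * 17)
    if (length(tree$nodes[lengths(tree$children) > 0]) < k - 1) next
    ds <- simulate_accessibility(n_cells = n, k = min(k, n), n_locus_clusters = 4,
                                 rows_per_cluster = 40, seed = inst, tree = tree)
    M <- ds$M[names(ds$row_labels), ]
    cache <- fit_cache(M, ds$row_labels)
    opt <- min(vapply(enumerate_tree_partitions(tree, k), function(a) {
      treecoclust:::sse_from_assignment(cache, a[colnames(M)], k)
    }, 1))
    run <- optimize_tree_partition(M, ds$row_labels, tree, k = k,
                                   restarts = 20, seed = 0)
    total <- total + 1L
    if (run$best_sse <= opt + 1e-9) matched <- matched + 1L
    expect_gte(run$best_sse, opt - 1e-9)   # never better than the true optimum
  }
  expect_gte(matched / total, 0.9)
})

test_that("optimizer run is deterministic, monotone and k = 1 is trivial", {
  tree <- random_tree(12, seed = 5)
  ds <- simulate_accessibility(n_cells = 12, k = 3, n_locus_clusters = 3,
                               rows_per_cluster = 40, seed = 5, tree = tree)
  M <- ds$M[names(ds$row_labels), ]
  r1 <- optimize_tree_partition(M, ds$row_labels, tree, k = 3, restarts = 5, seed = 2)
  r2 <- optimize_tree_partition(M, ds$row_labels, tree, k = 3, restarts = 5, seed = 2)
  expect_identical(r1$best_spec, r2$best_spec)
  expect_equal(r1$best_sse, min(r1$restarts$sse))
  # each restart's final SSE is no worse than its own starting point
  cache <- fit_cache(M, ds$row_labels)
  for (i in seq_len(nrow(r1$restarts))) {
    init <- random_init(tree, 3, seed = r1$restarts$seed[i])
    init_sse <- cocluster_sse(cache, partition = partition_from_cutspec(tree, init))
    expect_lte(r1$restarts$sse[i], init_sse + 1e-9)
  }

  rk1 <- optimize_tree_partition(M, ds$row_labels, tree, k = 1, restarts = 3, seed = 0)
  expect_length(rk1$best_partition$clusters, 1)
  expect_equal(rk1$restarts$moves, rep(0L, 3))
  expect_equal(rk1$best_sse,
               cocluster_sse(M, ds$row_labels,
                             as_tree_partition(stats::setNames(rep(1L, 12), tree$nodes))))
})

test_that("baselines recover duplicated column groups and singletons fit exactly", {
  set.seed(9)
  base <- matrix(rbinom(80 * 2, 1, 0.5), 80, 2)
  M <- cbind(base[, c(1, 1, 1)], base[, c(2, 2, 2)])
  colnames(M) <- paste0("c", 1:6)
  rownames(M) <- paste0("l", 1:80)
  truth <- rep(1:2, each = 3)
  for (method in c("hierarchical", "kmeans")) {
    part <- baseline_partition(M, k = 2, method = method, seed = 1)
    expect_equal(ari(part$assignment[colnames(M)], truth), 1, info = method)
  }
  part6 <- baseline_partition(M, k = 6, method = "hierarchical")
  expect_equal(cocluster_sse(M, seq_len(nrow(M)), part6), 0)
})
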