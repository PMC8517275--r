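test_that("fit_means computes and reproduces co-cluster means", {
  ct <- paste0("c", 1:5)
  M <- rbind(matrix(1L, 2, 5), matrix(c(1L, 1L, 1L, 0L, 0L,
                                        0L, 0L, 0L, 0L, 0L), 2, 5, byrow = TRUE))
  dimnames(M) <- list(paste0("l", 1:4), ct)
  rl <- c(1, 1, 2, 2)
  part <- as_tree_partition(stats::setNames(rep(1L, 5), ct))
  mod <- fit_means(M, rl, part)
  expect_equal(unname(mod$means[, 1]), c(1, 0.3))   # all ones; 3 of 10

  # re-averaging the expansion reproduces the grid exactly
  full <- expand_model(mod, stats::setNames(rl, rownames(M)))
  for (j in 1:2) for (i in 1) {
    blk <- full[rl == j, mod$col_assignment == i, drop = FALSE]
    expect_equal(mean(blk), mod$means[j, i])
  }
})

test_that("two_state_split solves the hand-checked splits", {
  sp <- two_state_split(c(0, 1), c(5, 5))
  expect_equal(sp$low_value, 0); expect_equal(sp$high_value, 1)
  expect_equal(sp$high, c(FALSE, TRUE))

  sp <- two_state_split(c(0.1, 0.2, 0.8), c(10, 10, 10))
  expect_equal(sp$high, c(FALSE, FALSE, TRUE))
  expect_equal(sp$low_value, 0.15)
  expect_equal(sp$high_value, 0.8)

  sp <- two_state_split(c(0.4, 0.4, 0.4), c(1, 2, 3))
  expect_true(sp$degenerate)
  expect_equal(sp$low_value, sp$high_value)
  expect_false(any(sp$high))
})

test_that("sorted-scan two-state split equals brute force over assignments", {
  set.seed(14)
  for (rep in 1:30) {
    k <- sample(2:8, 1)
    means <- round(runif(k), 3)
    weights <- sample(1:50, k, replace = TRUE)
    sp <- two_state_split(means, weights)
    bf <- brute_two_state(means, weights)
    expect_equal(sum(weights * (means - ifelse(sp$high, sp$high_value,
                                               sp$low_value))^2),
                 bf$sse, tolerance = 1e-9)
    expect_lte(sp$low_value, sp$high_value)
    expect_equal(sum(sp$high), sum(bf$high))   # tie policy: minimal high side
  }
})

test_that("two-state restriction fits no better than free co-cluster means", {
  set.seed(15)
  for (rep in 1:5) {
    tree <- random_tree(8, seed = rep)
    ds <- simulate_accessibility(n_cells = 8, k = 3, n_locus_clusters = 3,
                                 rows_per_cluster = 30, seed = rep, tree = tree)
    M <- ds$M[names(ds$row_labels), ]
    mod <- fit_means(M, ds$row_labels, ds$partition)
    ts <- fit_two_state(mod)
    rl <- ds$row_labels
    sse_free <- sum((M - expand_model(mod, rl))^2)
    sse_two <- sum((M - expand_model(ts, rl))^2)
    expect_gte(sse_two, sse_free - 1e-9)
    # at most two distinct fitted values per locus cluster
    expect_true(all(apply(ts$value_grid, 1, function(x) length(unique(x))) <= 2))
  }
})

test_that("accessibility co-clusters union the accessible cell clusters", {
  ct <- paste0("c", 1:6)
  # cluster 1: accessible in cell clusters 1-2; cluster 2: accessible in 2-3
  M <- rbind(matrix(rep(c(1L, 1L, 1L, 1L, 0L, 0L), 20), 20, 6, byrow = TRUE),
             matrix(rep(c(0L, 0L, 1L, 1L, 1L, 1L), 20), 20, 6, byrow = TRUE))
  dimnames(M) <- list(paste0("l", 1:40), ct)
  rl <- stats::setNames(rep(1:2, each = 20), rownames(M))
  part <- as_tree_partition(stats::setNames(c(1L, 1L, 2L, 2L, 3L, 3L), ct))
  ts <- fit_two_state(fit_means(M, rl, part))
  ccs <- accessibility_coclusters(ts, part, rl)
  expect_length(ccs, 2)
  expect_setequal(ccs[[1]]$cell_types, c("c1", "c2", "c3", "c4"))
  expect_setequal(ccs[[2]]$cell_types, c("c3", "c4", "c5", "c6"))
  expect_length(ccs[[1]]$loci, 20)

  # constant cluster -> degenerate fit, no accessible state, flagged
  Mc <- matrix(1L, 10, 6, dimnames = list(paste0("x", 1:10), ct))
  tsc <- fit_two_state(fit_means(Mc, rep(1, 10), part))
  expect_true(all(tsc$degenerate))
  expect_warning(ccsc <- accessibility_coclusters(tsc, part), "no accessible")
  expect_true(ccsc[[1]]$empty)
})

# Direct spreadsheet-style ANOVA on a small matrix.
naive_anova <- function(M, rl, assignment) {
  out <- list()
  for (j in unique(rl)) {
    Mj <- M[rl == j, , drop = FALSE]
    mu <- mean(Mj)
    m <- sapply(sort(unique(assignment)), function(i) {
      mean(Mj[, assignment == i, drop = FALSE])
    })
    fit <- m[assignment]
    pred <- matrix(fit, nrow(Mj), ncol(Mj), byrow = TRUE)
    r2_tot <- 1 - sum((Mj - pred)^2) / sum((Mj - mu)^2)
    cm <- colMeans(Mj)
    r2_ct <- 1 - sum((cm - fit)^2) / sum((cm - mu)^2)
    out[[as.character(j)]] <- c(r2_tot, r2_ct)
  }
  out
}

test_that("anova R-squared matches direct computation on a hand-sized matrix", {
  set.seed(16)
  ct <- paste0("c", 1:4)
  M <- matrix(rbinom(16, 1, 0.5), 4, 4, dimnames = list(paste0("l", 1:4), ct))
  M[1, ] <- c(1L, 0L, 1L, 0L)  # guarantee column variation
  rl <- c(1, 1, 2, 2)
  a <- stats::setNames(c(1L, 1L, 2L, 2L), ct)
  an <- cocluster_anova(fit_means(M, rl, as_tree_partition(a)))
  ref <- naive_anova(M, rl, a)
  for (j in 1:2) {
    expect_equal(an$per_cluster$r2_total[j], ref[[as.character(j)]][1])
    expect_equal(an$per_cluster$r2_celltype[j], ref[[as.character(j)]][2])
  }
  expect_equal(an$overall$r2_celltype,
               mean(an$per_cluster$r2_celltype))  # unweighted average
})

test_that("cell-type R-squared hits its analytic endpoints", {
  set.seed(17)
  ct <- paste0("c", 1:10)
  M <- matrix(rbinom(500, 1, 0.5), 50, 10, dimnames = list(paste0("l", 1:50), ct))
  rl <- rep(1, 50)
  singletons <- as_tree_partition(stats::setNames(1:10, ct))
  onecluster <- as_tree_partition(stats::setNames(rep(1L, 10), ct))
  expect_equal(cocluster_anova(fit_means(M, rl, singletons))$overall$r2_celltype, 1)
  expect_equal(cocluster_anova(fit_means(M, rl, onecluster))$overall$r2_celltype, 0)
})

test_that("refining the column partition never lowers cell-type R-squared", {
  set.seed(18)
  ct <- paste0("c", 1:8)
  for (rep in 1:5) {
    M <- matrix(rbinom(40 * 8, 1, 0.5), 40, 8, dimnames = list(paste0("l", 1:40), ct))
    rl <- sample(1:2, 40, replace = TRUE)
    # refinement chain: 1 cluster -> 2 -> 4 -> 8, each refining the last
    a1 <- rep(1L, 8)
    a2 <- rep(1:2, each = 4)
    a4 <- rep(1:4, each = 2)
    a8 <- 1:8
    r2 <- vapply(list(a1, a2, a4, a8), function(a) {
      cocluster_anova(fit_means(M, rl,
        as_tree_partition(stats::setNames(a, ct))))$overall$r2_celltype
    }, 1)
    expect_true(all(diff(r2) >= -1e-12))
  }
})

test_that("constant locus clusters are flagged with R-squared 1", {
  ct <- paste0("c", 1:4)
  M <- matrix(1L, 6, 4, dimnames = list(paste0("l", 1:6), ct))
  an <- cocluster_anova(fit_means(M, rep(1, 6),
    as_tree_partition(stats::setNames(c(1L, 1L, 2L, 2L), ct))))
  expect_true(an$per_cluster$flagged[1])
  expect_equal(an$per_cluster$r2_total[1], 1)
  expect_equal(an$per_cluster$r2_celltype[1], 1)
})

test_that("binary SSE identity holds numerically", {
  set.seed(19)
  M <- matrix(rbinom(300, 1, 0.4), 30, 10,
              dimnames = list(paste0("l", 1:30), paste0("c", 1:10)))
  rl <- sample(1:3, 30, replace = TRUE)
  a <- stats::setNames(sample(1:4, 10, replace = TRUE), colnames(M))
  part <- as_tree_partition(a)
  mod <- fit_means(M, rl, part)
  # SSE = total ones - sum_ji m_ji^2 * count_ji for binary M
  expect_equal(sum(M) - sum(mod$means^2 * mod$counts),
               sum((M - expand_model(mod, stats::setNames(rl, rownames(M))))^2),
               tolerance = 1e-9)
})
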