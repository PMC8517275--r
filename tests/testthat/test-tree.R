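test_that("diff_tree validates structure and computes preorder", {
  tr <- toy_tree()
  expect_s3_class(tr, "diff_tree")
  expect_equal(tr$root, "HSC")
  expect_equal(tr$nodes[1], "HSC")
  expect_true(all(match(tr$parent[-1], tr$nodes) <
                    match(tr$nodes[-1], tr$nodes)))  # preorder: parent first
  expect_equal(unname(tr$depth[c("HSC", "MPP", "T4")]), c(0L, 1L, 3L))

  expect_error(diff_tree(c("b", "b"), c("a", "c")), "two parents")
  expect_error(diff_tree(c("b", "d"), c("a", "c")), "exactly one root")
  expect_error(diff_tree(c("a", "b"), c("b", "a")), "root|connected")
})

test_that("tree TSV round-trips", {
  tr <- fan_tree()
  path <- tempfile(fileext = ".tsv")
  write_tree_tsv(tr, path)
  tr2 <- read_tree_tsv(path)
  expect_equal(tr2$nodes, tr$nodes)
  expect_equal(tr2$parent, tr$parent)
})

# Literal implementation of the respects definition: connected, or there is a
# single candidate parent p such that all component roots are children of p.
naive_respects <- function(node_set, tree) {
  comp_roots <- node_set[!(tree$parent[node_set] %in% node_set)]
  if (length(comp_roots) == 1) return(TRUE)
  for (p in tree$nodes) {
    if (all(comp_roots %in% tree$children[[p]])) return(TRUE)
  }
  FALSE
}

test_that("respects_tree matches the definition on every subset of a small tree", {
  tr <- toy_tree()
  n <- length(tr$nodes)
  for (mask in 1:(2^n - 1)) {
    ss <- tr$nodes[as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))]
    expect_equal(respects_tree(ss, tr), naive_respects(ss, tr), info = paste(ss, collapse = ","))
  }
})

test_that("respects_tree handles the canonical cases", {
  tr <- fan_tree()
  expect_true(respects_tree(c("a1", "a2"), tr))        # two leaves under one parent
  expect_true(respects_tree(c("A", "a1", "b1", "B"), tr))  # connected through R? no:
  # {A,a1} and {B,b1} are two components with roots A and B, children of R
  expect_true(respects_tree(c("R", "A", "a1"), tr))    # connected
  expect_false(respects_tree(c("a1", "b1"), tr))       # roots under different parents
  expect_false(respects_tree(c("R", "a1"), tr))        # root component cannot pair
  expect_error(respects_tree(character(0), tr), "nonempty")
})

test_that("component decompositions count connected and respecting pieces", {
  tr <- fan_tree()
  expect_equal(decompose_connected(c("A", "a1", "a2"), tr), 1L)
  expect_equal(decompose_connected(c("a1", "b1", "c1"), tr), 3L)
  # six singleton leaves under three parents: 6 connected, 3 respecting
  blue <- c("a1", "a2", "b1", "b2", "c1", "c2")
  expect_equal(decompose_connected(blue, tr), 6L)
  expect_equal(decompose_respecting(blue, tr), 3L)
  expect_equal(decompose_respecting(c("a1", "a2", "b1"), tr), 2L)
})

test_that("decompose_respecting is 1 exactly on respecting sets", {
  tr <- toy_tree()
  n <- length(tr$nodes)
  for (mask in 1:(2^n - 1)) {
    ss <- tr$nodes[as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))]
    expect_equal(decompose_respecting(ss, tr) == 1L, respects_tree(ss, tr))
  }
})

test_that("partition_from_cutspec executes the edge-removal construction", {
  path <- diff_tree(c("b", "c"), c("a", "b"))
  part <- partition_from_cutspec(path, cut_spec(list(list(vertex = "a", members = "b"))))
  expect_equal(lapply(part$clusters, sort), list(c("b", "c"), "a"))

  # root with three children; carving two yields a disconnected, respecting cluster
  star <- diff_tree(c("c1", "c2", "c3"), c("r", "r", "r"))
  part <- partition_from_cutspec(star, cut_spec(list(list(vertex = "r",
                                                          members = c("c1", "c2")))))
  expect_equal(lapply(part$clusters, sort), list(c("c1", "c2"), c("c3", "r")))
  expect_true(all(vapply(part$clusters, respects_tree, TRUE, tree = star)))

  # empty spec: one cluster holding everything
  part <- partition_from_cutspec(star, cut_spec())
  expect_length(part$clusters, 1)
  expect_setequal(part$clusters[[1]], star$nodes)
})

test_that("cut_spec invariants are enforced", {
  tr <- fan_tree()
  expect_error(partition_from_cutspec(tr, cut_spec(list(
    list(vertex = "A", members = "b1")))), "not a child")
  expect_error(partition_from_cutspec(tr, cut_spec(list(
    list(vertex = "A", members = "a1"),
    list(vertex = "A", members = "a1")))), "twice")
  # repeated cut vertex with distinct members is legal
  part <- partition_from_cutspec(tr, cut_spec(list(
    list(vertex = "R", members = "A"),
    list(vertex = "R", members = "B"))))
  expect_length(part$clusters, 3)
})

test_that("cutspec-induced clusters always respect the tree (random specs)", {
  for (seed in 1:20) {
    tree <- random_tree(sample(5:15, 1), seed = seed)
    k <- sample(2:4, 1)
    nonleaf <- tree$nodes[lengths(tree$children) > 0]
    if (length(nonleaf) < k - 1) next
    spec <- random_init(tree, k, seed = seed)
    part <- partition_from_cutspec(tree, spec)
    expect_length(part$clusters, k)
    expect_setequal(unlist(part$clusters), tree$nodes)
    for (cl in part$clusters) expect_true(respects_tree(cl, tree))
  }
})

# Brute-force all valid cut specs of a small tree (groups = (vertex, nonempty
# child subset); choose k-1 groups with globally distinct members).
all_cutspec_partitions <- function(tree, k) {
  groups <- list()
  for (v in tree$nodes) {
    kids <- tree$children[[v]]
    if (length(kids) == 0) next
    for (mask in 1:(2^length(kids) - 1)) {
      groups[[length(groups) + 1]] <-
        list(vertex = v, members = kids[as.logical(bitwAnd(mask, 2^(seq_along(kids) - 1)))])
    }
  }
  if (k == 1) return("single")
  combos <- utils::combn(length(groups), k - 1, simplify = FALSE)
  out <- character(0)
  for (cmb in combos) {
    members <- unlist(lapply(groups[cmb], `[[`, "members"))
    if (anyDuplicated(members)) next
    part <- partition_from_cutspec(tree, cut_spec(groups[cmb]))
    out <- c(out, paste(canon_partition(part), collapse = "|"))
  }
  unique(out)
}

test_that("cutspec-reachable partitions equal all-blocks-respecting partitions", {
  # surjectivity of the cut encoding, checked exhaustively on small trees
  for (seed in c(3, 9)) {
    tree <- random_tree(6, seed = seed)
    for (k in 2:3) {
      via_spec <- sort(all_cutspec_partitions(tree, k))
      via_enum <- sort(unique(vapply(enumerate_tree_partitions(tree, k), function(a) {
        paste(canon_partition(list(clusters = split(names(a), a))), collapse = "|")
      }, "")))
      expect_equal(via_spec, via_enum, info = paste("seed", seed, "k", k))
    }
  }
})

test_that("partition TSV round-trips", {
  tr <- fan_tree()
  part <- partition_from_cutspec(tr, cut_spec(list(list(vertex = "R", members = c("A", "B")))))
  path <- tempfile(fileext = ".tsv")
  write_partition_tsv(part, path)
  part2 <- read_partition_tsv(path)
  expect_equal(canon_partition(part2), canon_partition(part))
})
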