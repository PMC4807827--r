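test_that("branch sums reproduce trivial cases", {
  tr <- ape::read.tree(text = "((A:1,B:1):2,C:3);")
  expect_equal(subtree_branch_sum(tr, "A"), 0)            # singleton
  expect_equal(subtree_branch_sum(tr, c("A", "B", "C")), 7)  # whole tree
  expect_equal(subtree_branch_sum(tr, c("A", "B")), 2)    # cherry
  expect_error(subtree_branch_sum(tr, character(0)), "empty")
  expect_error(subtree_branch_sum(tr, "Z"), "not a tip")
})

test_that("FD and PD kernels equal the brute-force path-union oracle", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(5:15, 1)
    tr <- ape::rtree(n)
    k <- sample(1:n, 1)
    tips <- sample(tr$tip.label, k)
    expect_equal(subtree_branch_sum(tr, tips),
                 oracle_subtree_sum(tr, tips), tolerance = 1e-12)
    expect_equal(subtree_branch_sum(tr, tips, include_root = TRUE),
                 oracle_subtree_sum(tr, tips, include_root = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("include-root PD agrees with an independent reference implementation", {
  skip_if_not_installed("picante")
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(6:14, 1)
    tr <- ape::rtree(n)
    k <- sample(2:n, 1)
    tips <- sample(tr$tip.label, k)
    comm <- matrix(0, 1, n, dimnames = list("s", tr$tip.label))
    comm[1, tips] <- 1
    expect_equal(subtree_branch_sum(tr, tips, include_root = TRUE),
                 suppressWarnings(picante::pd(comm, tr)$PD),
                 tolerance = 1e-10)
  }
})

test_that("diversity is monotone under species addition", {
  set.seed(13)
  for (rep in 1:15) {
    tr <- ape::rtree(10)
    sub <- sample(tr$tip.label, 4)
    extra <- sample(setdiff(tr$tip.label, sub), 1)
    expect_lte(subtree_branch_sum(tr, sub),
               subtree_branch_sum(tr, c(sub, extra)))
  }
})

test_that("FD of a tip pair equals its cophenetic distance", {
  set.seed(14)
  tt <- rand_trait_table(8)
  dend <- upgma(gower_distance(tt))
  cp <- ape::cophenetic.phylo(dend)
  for (rep in 1:10) {
    pair <- sample(rownames(tt), 2)
    expect_equal(dendrogram_fd(dend, pair), cp[pair[1], pair[2]],
                 tolerance = 1e-10)
  }
  # full pool uses every edge
  expect_equal(dendrogram_fd(dend, rownames(tt)), total_branch_length(dend))
})

test_that("pruning preserves patristic distances and is PD-neutral", {
  tr <- ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):6);")
  p <- prune_tree(tr, c("A", "C"))
  expect_setequal(p$tip.label, c("A", "C"))
  expect_equal(ape::cophenetic.phylo(p)["A", "C"], 14)
  expect_error(prune_tree(tr, c("A", "Z")), "unknown tip")
  expect_equal(sum(prune_tree(tr, tr$tip.label)$edge.length),
               sum(tr$edge.length))
  # single-tip pruning is legal and yields no pairwise distances
  p1 <- prune_tree(tr, "A")
  expect_equal(ape::Ntip(p1), 1)

  set.seed(15)
  for (rep in 1:15) {
    tr2 <- ape::rtree(sample(6:14, 1))
    k <- sample(2:ape::Ntip(tr2), 1)
    tips <- sample(tr2$tip.label, k)
    pr <- prune_tree(tr2, tips)
    expect_equal(ape::cophenetic.phylo(pr)[tips, tips],
                 ape::cophenetic.phylo(tr2)[tips, tips], tolerance = 1e-10)
    expect_equal(faith_pd(pr, tips), faith_pd(tr2, tips), tolerance = 1e-10)
  }
})

test_that("PD of all tips of an ultrametric tree equals its total length", {
  set.seed(16)
  tr <- simulate_tree(12)
  expect_equal(faith_pd(tr, tr$tip.label), total_branch_length(tr))
})

test_that("vectorised branch sums match the single-set kernel", {
  set.seed(17)
  tr <- ape::rtree(12)
  ctx <- diversity_context(tr)
  S <- matrix(rbinom(20 * 12, 1, 0.4), 20, 12,
              dimnames = list(NULL, tr$tip.label))
  got <- branch_sums_matrix(ctx, S)
  want <- apply(S, 1, function(row) {
    tips <- colnames(S)[row == 1]
    if (length(tips) == 0) 0 else subtree_branch_sum(tr, tips)
  })
  expect_equal(got, want, tolerance = 1e-12)
  got_root <- branch_sums_matrix(ctx, S, include_root = TRUE)
  want_root <- apply(S, 1, function(row) {
    tips <- colnames(S)[row == 1]
    if (length(tips) == 0) 0
    else subtree_branch_sum(tr, tips, include_root = TRUE)
  })
  expect_equal(got_root, want_root, tolerance = 1e-12)
})

test_that("re-clustered FD equals the subcluster dendrogram total", {
  set.seed(18)
  tt <- rand_trait_table(9)
  gd <- gower_distance(tt)
  expect_equal(fd_recluster(gd, rownames(tt)[1]), 0)
  sub <- rownames(tt)[1:5]
  expect_equal(fd_recluster(gd, sub),
               total_branch_length(upgma(unclass(gd)[sub, sub])))
})
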