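test_that("simulated trees are ultrametric with unit height and reproducible", {
  tr2 <- simulate_tree(2, seed = 1)
  expect_equal(sort(tr2$edge.length), c(1, 1))
  for (s in 1:3) {
    tr <- simulate_tree(sample(5:40, 1), seed = 40 + s)
    depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
    expect_true(all(abs(depths - 1) < 1e-10))
  }
  expect_identical(ape::write.tree(simulate_tree(12, seed = 7)),
                   ape::write.tree(simulate_tree(12, seed = 7)))
  expect_false(identical(ape::write.tree(simulate_tree(12, seed = 7)),
                         ape::write.tree(simulate_tree(12, seed = 8))))
  expect_error(simulate_tree(1), "at least 2")
})

test_that("trait phylogenetic signal controls sister-tip correlation", {
  # sister pair with tiny divergence: under full signal the standardised
  # Brownian values of A and B are almost identical; with no signal they
  # are (nearly) independent.  A 12-tip tree keeps the compositional
  # dependence induced by per-replicate standardisation negligible.
  others <- paste(sprintf("t%d:1", 1:10), collapse = ",")
  tr <- ape::read.tree(text = sprintf("((A:0.02,B:0.02):0.98,%s);", others))
  pull <- function(w, seed) {
    tt <- simulate_traits(tr, n_continuous = 1, n_categorical = 0,
                          signal_weight = w, seed = seed)
    unlist(tt[c("A", "B"), "cont1"])
  }
  full <- vapply(1:200, function(i) pull(1, i), numeric(2))
  none <- vapply(1:200, function(i) pull(0, 1000 + i), numeric(2))
  expect_gt(cor(full[1, ], full[2, ]), 0.85)
  expect_lt(abs(cor(none[1, ], none[2, ])), 0.25)
})

test_that("simulated traits pass trait-table validation", {
  for (s in 1:3) {
    tr <- simulate_tree(20, seed = 50 + s)
    tt <- simulate_traits(tr, seed = 60 + s)
    ty <- attr(tt, "trait_types")
    expect_s3_class(tt, "trait_table")
    for (k in names(tt)[ty == "categorical"])
      expect_gte(length(unique(tt[[k]])), 2)
  }
  expect_error(simulate_traits(simulate_tree(5, seed = 1),
                               signal_weight = 2), "\\[0, 1\\]")
})

test_that("default communities respect the study-design constraints", {
  for (s in 1:5) {
    ds <- simulate_dataset(scenario_config("A"), seed = 80 + s)
    occ <- ds$occ
    expect_length(occ$sites, 12)
    expect_length(occ$species, 31)
    wet_sr <- rowSums(occ$wet); dry_sr <- rowSums(occ$dry)
    expect_true(all(wet_sr >= 5 & wet_sr <= 15))
    expect_true(all(dry_sr >= 2 & dry_sr <= 12))
    expect_true(all(dry_sr <= wet_sr))
    # no dry-exclusive species pool-wide
    dry_seen <- occ$species[colSums(occ$dry) > 0]
    wet_seen <- occ$species[colSums(occ$wet) > 0]
    expect_true(all(dry_seen %in% wet_seen))
    # generated data pass the core validators
    expect_s3_class(reconcile(occ, ds$traits, ds$tree), "analysis_bundle")
    expect_s3_class(ds$coords, "site_coords")
  }
})

test_that("turnover inserts dry-season species absent from the site's wet assemblage", {
  hits <- vapply(1:6, function(s) {
    occ <- simulate_dataset(scenario_config("A"), seed = 90 + s)$occ
    sum(vapply(occ$sites, function(site)
      sum(occ$dry[site, ] == 1L & occ$wet[site, ] == 0L), 0L))
  }, 0)
  # mean ~1 insertion per site: some turnover must appear in 12 sites
  expect_true(all(hits > 0))
})

test_that("generation is a pure function of configuration and seed", {
  cfg <- scenario_config("C+D")
  d1 <- simulate_dataset(cfg, seed = 123)
  d2 <- simulate_dataset(cfg, seed = 123)
  expect_identical(d1$occ, d2$occ)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  expect_identical(d1$coords, d2$coords)
  # the caller's RNG stream is untouched
  set.seed(99); before <- .Random.seed
  invisible(simulate_dataset(cfg, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("limiting similarity raises wet-season FD relative to neutral assembly", {
  per_species_fd <- function(sc, seed) {
    ds <- simulate_dataset(scenario_config(sc), seed = seed)
    dend <- upgma(gower_distance(ds$traits))
    ad <- assemblage_diversity(ds$occ, dend, ds$tree)
    w <- ad[ad$season == "wet", ]
    mean(w$FD / w$SR)
  }
  a <- vapply(1:25, function(i) per_species_fd("A", 200 + i), 0)
  c_ <- vapply(1:25, function(i) per_species_fd("C", 200 + i), 0)
  expect_lt(t.test(c_, a, alternative = "greater")$p.value, 0.01)
})

test_that("clade-concentrated loss lowers dry-season PD relative to neutral assembly", {
  per_species_pd <- function(sc, seed) {
    ds <- simulate_dataset(scenario_config(sc), seed = seed)
    ad <- assemblage_diversity(ds$occ, upgma(gower_distance(ds$traits)),
                               ds$tree)
    d <- ad[ad$season == "dry" & ad$SR > 1, ]
    mean(d$PD / d$SR)
  }
  a <- vapply(1:25, function(i) per_species_pd("A", 300 + i), 0)
  d_ <- vapply(1:25, function(i) per_species_pd("D", 300 + i), 0)
  expect_lt(t.test(d_, a, alternative = "less")$p.value, 0.01)
})

test_that("scenario fields are validated", {
  expect_error(scenario_config("E"), "arg")
  expect_error(scenario_config("A", wet_sr_range = c(5, 40)),
               "exceed pool size")
  expect_error(scenario_config("A", turnover = 1.5), "turnover")
  # C+D defaults to signal-free traits; others to moderate signal
  expect_equal(scenario_config("C+D")$signal_weight, 0)
  expect_equal(scenario_config("A")$signal_weight, 0.5)
})

test_that("dataset artifacts are written as plain-text files", {
  ds <- simulate_dataset(scenario_config("A", n_sites = 4, pool_size = 10,
                                         wet_sr_range = c(3, 6),
                                         dry_sr_range = c(2, 5)),
                         seed = 17)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_setequal(list.files(dir),
                  c("occurrences.csv", "traits.csv", "tree.nwk",
                    "coordinates.csv"))
  occ <- read_occurrences(file.path(dir, "occurrences.csv"))
  expect_equal(rowSums(occ$wet)[occ$sites], rowSums(ds$occ$wet)[occ$sites])
})
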