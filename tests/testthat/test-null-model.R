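test_that("the site pool is the union of the two seasonal assemblages", {
  occ <- worked_example_occ()
  expect_length(build_pool(occ, "s1"), 11)
  expect_error(build_pool(occ, "nope"), "unknown site")

  occ2 <- occ_from_lists(wet = list(s1 = c("A", "B")),
                         dry = list(s1 = c("A", "B")))
  expect_setequal(build_pool(occ2, "s1"), c("A", "B"))
  occ3 <- occ_from_lists(wet = list(s1 = "A"), dry = list(s1 = "B"))
  expect_setequal(build_pool(occ3, "s1"), c("A", "B"))
})

test_that("a null draw preserves richness and turnover bookkeeping", {
  set.seed(21)
  pool <- paste0("sp", 1:11)
  pair <- draw_null_pair(pool, wet_sr = 9, dry_sr = 6, dry_only_count = 2)
  expect_length(pair$wet, 9)
  expect_length(pair$dry, 6)
  forced <- setdiff(pool, pair$wet)
  expect_length(forced, 2)                       # dry-only slots
  expect_true(all(forced %in% pair$dry))         # forced into dry
  restock <- setdiff(pair$dry, forced)
  expect_length(restock, 4)                      # restocked from wet
  expect_true(all(restock %in% pair$wet))

  expect_error(draw_null_pair(pool, 8, 6, 2), "pool size")
  expect_error(draw_null_pair(pool, 9, 1, 2), "dry_only_count <= dry_sr")
})

test_that("with no turnover and equal richness the dry null equals the wet null", {
  set.seed(22)
  pool <- paste0("sp", 1:7)
  pair <- draw_null_pair(pool, wet_sr = 7, dry_sr = 7, dry_only_count = 0)
  expect_setequal(pair$dry, pair$wet)
})

test_that("ensemble replicates satisfy all set invariants", {
  set.seed(23)
  ds <- simulate_dataset(scenario_config("A", n_sites = 6, pool_size = 15,
                                         wet_sr_range = c(3, 8),
                                         dry_sr_range = c(1, 6)),
                         seed = 23)
  ens <- build_null_ensemble(ds$occ, replicates = 50, seed = 99)
  for (st in ens$sites) {
    expect_equal(rowSums(st$wet), rep(st$wet_sr, 50))       # |wet| = x
    expect_equal(rowSums(st$dry), rep(st$dry_sr, 50))       # |dry| = SR_dry
    for (r in c(1, 25, 50)) {
      wet <- st$pool[st$wet[r, ]]
      dry <- st$pool[st$dry[r, ]]
      forced <- setdiff(st$pool, wet)
      expect_true(all(forced %in% dry))              # (pool \ wet) subset dry
      expect_true(all(setdiff(dry, forced) %in% wet))  # restock from wet
      expect_setequal(union(wet, dry), st$pool)
    }
  }
})

test_that("uniform shuffling gives each species the expected wet-null frequency", {
  pool <- paste0("sp", 1:5)
  x <- 3; n_draws <- 10000
  counts <- setNames(numeric(5), pool)
  withr::with_seed(24, {
    for (i in seq_len(n_draws)) {
      pair <- draw_null_pair(pool, x, 3, 2)
      counts[pair$wet] <- counts[pair$wet] + 1
    }
  })
  p <- x / length(pool)
  se <- sqrt(p * (1 - p) / n_draws)
  expect_true(all(abs(counts / n_draws - p) < 3 * se + 1e-9))
})

test_that("ensembles are reproducible and per-site draws are stable under site addition", {
  occ3 <- occ_from_lists(
    wet = list(s1 = c("A", "B", "C"), s2 = c("B", "C", "D")),
    dry = list(s1 = c("A", "B"), s2 = c("D", "E")))
  e1 <- build_null_ensemble(occ3, replicates = 20, seed = 5)
  e2 <- build_null_ensemble(occ3, replicates = 20, seed = 5)
  expect_identical(e1, e2)
  # adding a site leaves the existing sites' draws untouched
  occ4 <- occ_from_lists(
    wet = list(s1 = c("A", "B", "C"), s2 = c("B", "C", "D"),
               s3 = c("A", "D", "E")),
    dry = list(s1 = c("A", "B"), s2 = c("D", "E"), s3 = c("A", "E")))
  e3 <- build_null_ensemble(occ4, replicates = 20, seed = 5)
  expect_identical(e3$sites$s1$dry, e1$sites$s1$dry)
  expect_identical(e3$sites$s2$wet, e1$sites$s2$wet)
})

test_that("ensemble evaluation has degenerate SR and responds to contexts", {
  set.seed(26)
  tt <- rand_trait_table(6)
  occ <- occ_from_lists(
    wet = list(s1 = rownames(tt)[1:4], s2 = rownames(tt)[2:6]),
    dry = list(s1 = rownames(tt)[c(1, 5)], s2 = rownames(tt)[2:3]))
  dend <- upgma(gower_distance(tt))
  tr <- simulate_tree(6, seed = 26)
  tr$tip.label <- rownames(tt)
  ens <- build_null_ensemble(occ, replicates = 30, seed = 1)
  es <- evaluate_ensemble(ens, dend = dend, tree = tr)
  for (s in c("s1", "s2")) {
    # null SR is degenerate at observed SR by construction
    expect_equal(unique(es$per_site[[s]]$SR_wet), sum(occ$wet[s, ]))
    expect_equal(unique(es$per_site[[s]]$SR_dry), sum(occ$dry[s, ]))
    expect_true(all(es$per_site[[s]]$FD_wet >= 0))
  }
  # R = 1: the null mean equals the single replicate value
  es1 <- evaluate_ensemble(build_null_ensemble(occ, replicates = 1, seed = 2),
                           dend = dend, tree = tr)
  sm <- ensemble_summary(es1)
  expect_equal(sm$null_mean[sm$site == "s1" & sm$statistic == "FD_dry"],
               es1$per_site$s1$FD_dry)
})

test_that("functionally identical pools give zero null FD", {
  # a dendrogram with all-zero heights: every assemblage connects at cost 0
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dend <- upgma(d)
  occ <- occ_from_lists(wet = list(s1 = letters[1:3]),
                        dry = list(s1 = letters[1:2]))
  es <- evaluate_ensemble(build_null_ensemble(occ, 20, seed = 3), dend = dend)
  expect_true(all(es$per_site$s1$FD_wet == 0))
  expect_true(all(es$per_site$s1$FD_dry == 0))
})

test_that("the long export matches the incidence matrices", {
  occ <- occ_from_lists(wet = list(s1 = c("A", "B")), dry = list(s1 = "A"))
  ens <- build_null_ensemble(occ, replicates = 5, seed = 8)
  long <- ensemble_long(ens)
  expect_setequal(names(long), c("site", "replicate", "season", "species"))
  expect_equal(sum(long$season == "wet"), 5 * 2)
  expect_equal(sum(long$season == "dry"), 5 * 1)
})
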