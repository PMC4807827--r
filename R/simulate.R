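#' Simulate a unit-height pure-birth (Yule) phylogeny
#'
#' Stand-in for a time-calibrated species-pool phylogeny: a constant
#' speciation rate, no extinction, rescaled so the root-to-tip height is
#' exactly 1 (relative time units).
#'
#' @param n_tips number of tips (>= 2).
#' @param seed optional integer seed; if given the call is a pure
#'   function of its arguments and leaves the caller's RNG untouched.
#' @return An ultrametric `phylo` with tip labels `sp01`, `sp02`, ...
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 2) stop("need at least 2 tips")
  gen <- function() {
    tr <- ape::rphylo(n_tips, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth
    tr$tip.label <- sprintf("sp%02d", seq_len(n_tips))
    tr
  }
  if (is.null(seed)) gen() else with_local_seed(seed, gen())
}

#' Simulate species traits with tunable phylogenetic signal
#'
#' Each continuous trait is a standardised mixture
#' `w * BM + (1 - w) * noise` of a Brownian-motion character evolved
#' along the tree and independent Gaussian noise, where `w` is
#' `signal_weight` (1 = fully heritable, 0 = signal-free).  Each
#' categorical trait thresholds an analogous latent variable into
#' `n_levels` classes at its empirical quantiles, which guarantees at
#' least two observed levels.
#'
#' @param tree a `phylo` over the species pool.
#' @param n_continuous,n_categorical numbers of traits of each kind.
#' @param signal_weight mixing weight in \[0, 1\].
#' @param n_levels levels per categorical trait.
#' @param seed optional integer seed.
#' @return A [trait_table()] over the tree's tips.
#' @export
simulate_traits <- function(tree, n_continuous = 4, n_categorical = 2,
                            signal_weight = 0.5, n_levels = 3, seed = NULL) {
  if (signal_weight < 0 || signal_weight > 1)
    stop("signal_weight must be in [0, 1]")
  if (n_continuous + n_categorical < 1) stop("need at least one trait")
  n <- length(tree$tip.label)
  gen <- function() {
    latent <- function() {
      bm <- ape::rTraitCont(tree, model = "BM", sigma = 1)
      z <- signal_weight * as.vector(scale(bm)) +
        (1 - signal_weight) * rnorm(n)
      as.vector(scale(z))
    }
    df <- list()
    for (i in seq_len(n_continuous)) df[[sprintf("cont%d", i)]] <- latent()
    for (i in seq_len(n_categorical)) {
      z <- latent()
      br <- unique(quantile(z, seq(0, 1, length.out = n_levels + 1)))
      df[[sprintf("cat%d", i)]] <-
        letters[cut(z, br, labels = FALSE, include.lowest = TRUE)]
    }
    df <- as.data.frame(df, row.names = tree$tip.label)
    trait_table(df, setNames(
      rep(c("continuous", "categorical"), c(n_continuous, n_categorical)),
      names(df)))
  }
  if (is.null(seed)) gen() else with_local_seed(seed, gen())
}

#' Configuration for the synthetic community generator
#'
#' Defaults emulate the study design the package targets: 12 stream
#' sites over a pool of 31 species, wet-season richness 5-15,
#' dry-season richness 2-12 (never above the site's wet richness),
#' partial turnover (some dry-season species absent from the same
#' site's wet assemblage, but none absent from every wet assemblage
#' unless `dry_exclusive = TRUE`), and site coordinates uniform on a
#' 1-km square.
#'
#' Scenarios: `"A"` neutral assembly; `"B"` environmental filtering of
#' the wet assemblage toward a site-specific trait optimum; `"C"`
#' limiting similarity (wet assemblage by sequential furthest-trait
#' selection, dry-season loss sparing functionally distinct species);
#' `"D"` phylogenetically clustered dry-season loss (survival
#' concentrated around a focal clade); `"C+D"` both dry-season
#' mechanisms jointly (uniform wet assembly).
#'
#' @param n_sites number of sites.
#' @param pool_size species-pool size.
#' @param wet_sr_range,dry_sr_range inclusive richness ranges.
#' @param scenario one of `"A"`, `"B"`, `"C"`, `"D"`, `"C+D"`.
#' @param signal_weight trait phylogenetic-signal weight (see
#'   [simulate_traits()]).  Defaults to 0.5; for scenario `"C+D"` the
#'   default is 0, because the joint dry-season signature (high FD with
#'   low PD) is attainable only when functional traits are decoupled
#'   from phylogeny.
#' @param turnover per-dry-slot probability of being filled by a
#'   species not in the site's wet assemblage.
#' @param dry_exclusive allow turnover insertions of species absent
#'   from every site's wet assemblage.
#' @param filter_strength scenario-B selection strength.
#' @param similarity_strength scenario-C removal-weight strength.
#' @param clade_strength scenario-D removal-weight strength.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("A", "B", "C", "D", "C+D"),
                            n_sites = 12, pool_size = 31,
                            wet_sr_range = c(5, 15), dry_sr_range = c(2, 12),
                            signal_weight = NULL, turnover = 0.15,
                            dry_exclusive = FALSE, filter_strength = 6,
                            similarity_strength = 120, clade_strength = 40) {
  scenario <- match.arg(scenario)
  if (is.null(signal_weight))
    signal_weight <- if (scenario == "C+D") 0 else 0.5
  if (wet_sr_range[2] > pool_size || dry_sr_range[2] > pool_size)
    stop("richness ranges exceed pool size")
  if (wet_sr_range[1] < 1 || dry_sr_range[1] < 0)
    stop("infeasible richness ranges")
  if (turnover < 0 || turnover > 1) stop("turnover must be in [0, 1]")
  structure(list(n_sites = n_sites, pool_size = pool_size,
                 wet_sr_range = wet_sr_range, dry_sr_range = dry_sr_range,
                 scenario = scenario, signal_weight = signal_weight,
                 turnover = turnover, dry_exclusive = dry_exclusive,
                 filter_strength = filter_strength,
                 similarity_strength = similarity_strength,
                 clade_strength = clade_strength),
            class = "scenario_config")
}

# Uniform draw from an inclusive integer range (safe when lo == hi,
# unlike sample(lo:hi, 1)).
sample_int_range <- function(lo, hi) lo + sample.int(hi - lo + 1, 1) - 1

# Greedy maximin ("furthest trait") selection: start from a random
# species, then repeatedly add the species maximising its minimum Gower
# distance to the current members.
maximin_select <- function(gd, size) {
  pool <- rownames(gd)
  sel <- sample(pool, 1)
  while (length(sel) < size) {
    rest <- setdiff(pool, sel)
    mind <- apply(gd[rest, sel, drop = FALSE], 1, min)
    best <- rest[mind == max(mind)]
    sel <- c(sel, if (length(best) > 1) sample(best, 1) else best)
  }
  sel
}

# Sequentially remove species from `wet` until `n_keep` remain, with
# per-step removal weights defined by the scenario: functionally
# redundant species (small minimum Gower distance to the others) are
# removed preferentially under C, species far from the focal clade
# under D, and both weights multiply under C+D.  Because removal is
# sequential, a strong clade weight acts first (while between-clade
# distances dominate) and the similarity weight then differentiates
# among the remaining clade members.
seasonal_removal <- function(wet, n_keep, scenario, gd, pdist, cfg, focal) {
  current <- wet
  while (length(current) > n_keep) {
    w <- rep(1, length(current))
    if (scenario %in% c("C", "C+D") && length(current) > 1) {
      mind <- apply(gd[current, current, drop = FALSE] +
                      diag(Inf, length(current)), 1, min)
      w <- w * exp(-cfg$similarity_strength * mind)
    }
    if (scenario %in% c("D", "C+D"))
      w <- w * exp(cfg$clade_strength * pdist[current, focal] / max(pdist))
    drop <- sample(seq_along(current), 1, prob = w)
    current <- current[-drop]
  }
  current
}

# Turnover insertions follow the same dry-season mechanism as survival:
# under C arrivals are functionally distinct from the residents, under
# D they come from the focal clade; neutral scenarios insert uniformly.
seasonal_insertions <- function(candidates, n_ins, survivors, scenario,
                                gd, pdist, cfg, focal) {
  if (n_ins == 0) return(character())
  w <- rep(1, length(candidates))
  if (scenario %in% c("C", "C+D")) {
    mind <- apply(gd[candidates, survivors, drop = FALSE], 1, min)
    w <- w * exp(cfg$similarity_strength * mind)
  }
  if (scenario %in% c("D", "C+D"))
    w <- w * exp(-cfg$clade_strength * pdist[candidates, focal] / max(pdist))
  candidates[sample.int(length(candidates), n_ins, prob = w)]
}

#' Simulate two-season community occurrence data under an assembly
#' scenario
#'
#' Wet-season assemblages are drawn from the pool per scenario; each
#' site's dry-season assemblage is derived from its wet assemblage by
#' scenario-specific removal, plus turnover insertions of species drawn
#' from outside that site's wet assemblage (restricted, unless
#' `dry_exclusive`, to species present in some other site's wet
#' assemblage, so no species is exclusive to the dry season pool-wide).
#'
#' @param tree pool phylogeny from [simulate_tree()].
#' @param traits pool traits from [simulate_traits()].
#' @param cfg a [scenario_config()].
#' @param seed optional integer seed.
#' @return List with `occ` (an [occ_table()]) and `coords` (a
#'   [site_coords()]).
#' @export
simulate_communities <- function(tree, traits, cfg = scenario_config(),
                                 seed = NULL) {
  pool <- rownames(traits)
  if (length(pool) != cfg$pool_size)
    stop("trait table has ", length(pool), " species but pool_size is ",
         cfg$pool_size)
  gen <- function() {
    gd <- gower_distance(traits)
    pdist <- ape::cophenetic.phylo(tree)[pool, pool]
    sites <- sprintf("site%02d", seq_len(cfg$n_sites))
    wet_list <- vector("list", cfg$n_sites)
    for (i in seq_len(cfg$n_sites)) {
      wet_sr <- sample_int_range(cfg$wet_sr_range[1], cfg$wet_sr_range[2])
      wet_list[[i]] <- switch(cfg$scenario,
        "B" = {
          opt <- sample(pool, 1)  # site optimum anchored at a random species
          w <- exp(-cfg$filter_strength * gd[, opt])
          sample(pool, wet_sr, prob = w)
        },
        "C" = maximin_select(gd, wet_sr),
        sample(pool, wet_sr))  # A, D, C+D: uniform
    }
    wet_union <- unique(unlist(wet_list))
    dry_list <- vector("list", cfg$n_sites)
    for (i in seq_len(cfg$n_sites)) {
      wet <- wet_list[[i]]
      dry_max <- min(cfg$dry_sr_range[2], length(wet))
      dry_sr <- sample_int_range(min(cfg$dry_sr_range[1], dry_max), dry_max)
      candidates <- setdiff(if (cfg$dry_exclusive) pool else wet_union, wet)
      n_ins <- min(rbinom(1, dry_sr, cfg$turnover), length(candidates),
                   dry_sr - 1)
      focal <- if (cfg$scenario %in% c("D", "C+D")) sample(wet, 1)
      survivors <- seasonal_removal(wet, dry_sr - n_ins, cfg$scenario,
                                    gd, pdist, cfg, focal)
      insertions <- seasonal_insertions(candidates, n_ins, survivors,
                                        cfg$scenario, gd, pdist, cfg, focal)
      dry_list[[i]] <- c(survivors, insertions)
    }
    mk <- function(lst) {
      m <- matrix(0L, cfg$n_sites, length(pool),
                  dimnames = list(sites, pool))
      for (i in seq_len(cfg$n_sites)) m[i, lst[[i]]] <- 1L
      m
    }
    coords <- data.frame(site = sites,
                         x = runif(cfg$n_sites, 0, 1000),
                         y = runif(cfg$n_sites, 0, 1000))
    list(occ = occ_table(mk(wet_list), mk(dry_list)),
         coords = site_coords(coords, "m"))
  }
  if (is.null(seed)) gen() else with_local_seed(seed, gen())
}

#' Simulate a complete synthetic study dataset
#'
#' Tree, traits, two-season occurrences and site coordinates in one
#' call; a pure function of (configuration, seed).
#'
#' @param cfg a [scenario_config()].
#' @param seed integer seed.
#' @param n_continuous,n_categorical trait counts passed to
#'   [simulate_traits()].
#' @return List with `tree`, `traits`, `occ`, `coords`, `cfg`, `seed`.
#' @export
simulate_dataset <- function(cfg = scenario_config(), seed = 1,
                             n_continuous = 4, n_categorical = 2) {
  with_local_seed(seed, {
    tree <- simulate_tree(cfg$pool_size)
    traits <- simulate_traits(tree, n_continuous, n_categorical,
                              signal_weight = cfg$signal_weight)
    comm <- simulate_communities(tree, traits, cfg)
    list(tree = tree, traits = traits, occ = comm$occ,
         coords = comm$coords, cfg = cfg, seed = seed)
  })
}

#' Write a simulated dataset's four artifacts to a directory
#'
#' @param ds a [simulate_dataset()] result.
#' @param dir output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_occurrences(ds$occ, file.path(dir, "occurrences.csv"))
  write_traits(ds$traits, file.path(dir, "traits.csv"))
  ape::write.tree(ds$tree, file.path(dir, "tree.nwk"))
  write.csv(as.data.frame(ds$coords), file.path(dir, "coordinates.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(dir)
}
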