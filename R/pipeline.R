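#' Aggregate observed and null results into the full seasonal report
#'
#' Builds the per-site table (observed SR/FD/PD per season and their
#' relative changes, with null means, SDs, standardised effect sizes and
#' rank quantiles) and the global inferential tables: the paired
#' wet-vs-dry SR test, the observed-vs-null paired tests for relative FD
#' and PD change and for per-season FD and PD, per-season redundancy
#' regressions of observed and null-mean FD/PD on SR, and Moran's I of
#' every measure and change (when coordinates are supplied).
#'
#' Observed-vs-null pairing uses the per-site null mean across
#' replicates; the SES and rank quantile of the observed value within
#' the full null distribution are reported alongside.
#'
#' @param observed data frame from [assemblage_diversity()].
#' @param es an [evaluate_ensemble()] result over the same sites.
#' @param coords optional [site_coords()].
#' @param row_standardise Moran weight option, see [morans_i()].
#' @return Object of class `seasonal_report` with elements `per_site`,
#'   `global_tests`, `regressions`, `morans`.
#' @export
season_summary <- function(observed, es, coords = NULL,
                           row_standardise = FALSE) {
  sites <- names(es$per_site)
  obs_wide <- list()
  for (metric in c("SR", "FD", "PD")) {
    w <- observed[observed$season == "wet", ]
    d <- observed[observed$season == "dry", ]
    obs_wide[[paste0(metric, "_wet")]] <- w[[metric]][match(sites, w$site)]
    obs_wide[[paste0(metric, "_dry")]] <- d[[metric]][match(sites, d$site)]
    obs_wide[[paste0("d", metric)]] <-
      safe_change(obs_wide[[paste0(metric, "_wet")]],
                  obs_wide[[paste0(metric, "_dry")]])
  }
  stats_names <- names(es$per_site[[1]])

  per_site <- do.call(rbind, lapply(stats_names, function(v) {
    obs <- obs_wide[[v]]
    nul <- lapply(sites, function(s) es$per_site[[s]][[v]])
    ses <- ses_values(obs, nul)
    data.frame(site = sites,
               statistic = sub("^d", "change_", sub("_", "_", v)),
               observed = obs,
               null_mean = vapply(nul, function(x) mean(x, na.rm = TRUE), 0),
               null_sd = vapply(nul, function(x) sd(x, na.rm = TRUE), 0),
               deviation = obs - vapply(nul, function(x) mean(x, na.rm = TRUE), 0),
               ses = ses$ses, rank_q = ses$rank_q,
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  null_mean_of <- function(v)
    vapply(sites, function(s) mean(es$per_site[[s]][[v]], na.rm = TRUE), 0)

  tests <- list(SR_wet_vs_dry = paired_test(obs_wide$SR_wet, obs_wide$SR_dry))
  for (v in c("dFD", "dPD", "FD_wet", "FD_dry", "PD_wet", "PD_dry")) {
    if (!v %in% stats_names) next
    nm <- if (startsWith(v, "d"))
      paste0("change_", sub("^d", "", v), "_obs_vs_null")
      else paste0(v, "_obs_vs_null")
    tests[[nm]] <- paired_test(obs_wide[[v]], null_mean_of(v))
  }
  global_tests <- do.call(rbind, lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    data.frame(test = nm, n = t$n, mean_diff = t$mean_diff, t = t$statistic,
               df = t$df, p = t$p.value, stringsAsFactors = FALSE)
  }))

  regr <- list()
  for (season in c("wet", "dry")) for (metric in c("FD", "PD")) {
    v <- paste0(metric, "_", season)
    if (!v %in% stats_names) next
    sr <- obs_wide[[paste0("SR_", season)]]
    for (src in c("observed", "null_mean")) {
      y <- if (src == "observed") obs_wide[[v]] else null_mean_of(v)
      fit <- tryCatch(redundancy_regression(sr, y), error = function(e) NULL)
      if (is.null(fit)) next
      regr[[paste(season, metric, src, sep = "_")]] <-
        data.frame(season = season, response = metric, source = src,
                   selected = fit$selected, linear_coef = fit$linear_coef,
                   quadratic_coef = fit$quadratic_coef,
                   aic_linear = fit$aic_linear, aic_full = fit$aic_full,
                   r_squared = fit$r_squared, redundancy = fit$redundancy,
                   stringsAsFactors = FALSE)
    }
  }
  regressions <- if (length(regr)) do.call(rbind, c(regr, make.row.names = FALSE))

  morans <- NULL
  if (!is.null(coords)) {
    co <- coords[match(sites, coords$site), ]
    vars <- intersect(c("SR_wet", "SR_dry", "FD_wet", "FD_dry", "PD_wet",
                        "PD_dry", "dSR", "dFD", "dPD"),
                      names(obs_wide))
    morans <- do.call(rbind, lapply(vars, function(v) {
      m <- tryCatch(morans_i(obs_wide[[v]], co, row_standardise),
                    error = function(e) NULL)
      if (is.null(m)) return(NULL)
      data.frame(variable = sub("^d", "change_", v), moran_i = m$observed,
                 expected = m$expected, sd = m$sd, p = m$p.value,
                 stringsAsFactors = FALSE)
    }))
  }

  structure(list(per_site = per_site, global_tests = global_tests,
                 regressions = regressions, morans = morans,
                 replicates = es$replicates, seed = es$seed),
            class = "seasonal_report")
}

#' @export
print.seasonal_report <- function(x, ...) {
  cat("Seasonal diversity report (", length(unique(x$per_site$site)),
      " sites, ", x$replicates, " null replicates, seed ", x$seed, ")\n\n",
      sep = "")
  cat("Global tests:\n")
  print(format(x$global_tests, digits = 4), row.names = FALSE)
  if (!is.null(x$regressions)) {
    cat("\nRedundancy regressions:\n")
    print(format(x$regressions[, c("season", "response", "source", "selected",
                                   "r_squared", "redundancy")], digits = 3),
          row.names = FALSE)
  }
  if (!is.null(x$morans)) {
    cat("\nMoran's I p-value range: ",
        paste(signif(range(x$morans$p), 3), collapse = " - "), "\n", sep = "")
  }
  invisible(x)
}

#' Run the full seasonal diversity analysis
#'
#' End-to-end orchestration: reconcile the inputs, build the Gower/UPGMA
#' trait dendrogram, compute observed SR/FD/PD, draw and evaluate the
#' turnover-preserving null ensemble, and assemble the [season_summary()]
#' report.  With `out_dir` the result tables are written as CSV together
#' with a JSON run manifest (inputs, seed, package version), and rerunning
#' with the same inputs and seed reproduces the files byte for byte.
#'
#' @param occ an [occ_table()].
#' @param traits a [trait_table()].
#' @param tree a `phylo`.
#' @param replacements optional [replacement_map()].
#' @param coords optional [site_coords()].
#' @param replicates null replicates per site.
#' @param seed master seed.
#' @param include_root root convention flag for FD and PD.
#' @param fd_method `"prune"` (default: one pool-level dendrogram,
#'   assemblage FD by subtree extraction) or `"recluster"` (rebuild the
#'   dendrogram per assemblage; sensitivity analysis only, not monotone).
#' @param row_standardise Moran's I weight option.
#' @param out_dir optional output directory.
#' @return A `seasonal_report`, with the intermediate objects attached
#'   as attributes `bundle`, `dendrogram`, `distances`, `ensemble_stats`.
#' @export
run_seasonal_analysis <- function(occ, traits, tree, replacements = NULL,
                                  coords = NULL, replicates = 1000, seed = 1,
                                  include_root = FALSE,
                                  fd_method = c("prune", "recluster"),
                                  row_standardise = FALSE, out_dir = NULL) {
  fd_method <- match.arg(fd_method)
  bundle <- reconcile(occ, traits, tree, replacements)
  gd <- gower_distance(traits)
  dend <- upgma(gd)
  observed <- assemblage_diversity(occ, dend, tree, tip_map = bundle$tip_map,
                                   include_root = include_root)
  if (fd_method == "recluster")
    observed$FD <- mapply(function(s, sea) {
      sp <- occ$species[occ[[sea]][s, ] == 1L]
      fd_recluster(gd, sp)
    }, observed$site, observed$season)
  ens <- build_null_ensemble(occ, replicates = replicates, seed = seed)
  es <- evaluate_ensemble(ens, dend = dend, tree = tree,
                          tip_map = bundle$tip_map,
                          include_root = include_root)
  if (fd_method == "recluster")
    for (s in names(es$per_site)) {
      st <- ens$sites[[s]]
      recl <- function(M) apply(M, 1, function(row)
        fd_recluster(gd, st$pool[row]))
      es$per_site[[s]]$FD_wet <- recl(st$wet)
      es$per_site[[s]]$FD_dry <- recl(st$dry)
      es$per_site[[s]]$dFD <- safe_change(es$per_site[[s]]$FD_wet,
                                          es$per_site[[s]]$FD_dry)
    }
  rep_out <- season_summary(observed, es, coords = coords,
                            row_standardise = row_standardise)
  attr(rep_out, "bundle") <- bundle
  attr(rep_out, "dendrogram") <- dend
  attr(rep_out, "distances") <- gd
  attr(rep_out, "ensemble_stats") <- es
  if (!is.null(out_dir))
    write_report(rep_out, out_dir,
                 config = list(replicates = replicates, seed = seed,
                               include_root = include_root,
                               fd_method = fd_method,
                               row_standardise = row_standardise,
                               n_sites = length(occ$sites),
                               n_species = length(occ$species),
                               substitutions = nrow(bundle$substitutions)))
  rep_out
}

#' Write a seasonal report's tables and run manifest to a directory
#'
#' @param report a `seasonal_report`.
#' @param dir output directory (created if absent).
#' @param config list echoed into the JSON manifest.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir, config = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) if (!is.null(df))
    write.csv(df, file.path(dir, f), row.names = FALSE, quote = FALSE)
  wr(report$per_site, "per_site_diversity.csv")
  wr(report$global_tests, "global_tests.csv")
  wr(report$regressions, "regressions.csv")
  wr(report$morans, "morans_i.csv")
  manifest <- list(package = "seasondiv",
                   version = as.character(packageVersion("seasondiv")),
                   seed = report$seed, replicates = report$replicates,
                   config = config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

# One synthetic dataset through the pipeline, reduced to the quantities
# the operating-characteristics studies need.
dataset_outcomes <- function(ds, replicates, seed) {
  rep_out <- run_seasonal_analysis(ds$occ, ds$traits, ds$tree,
                                   coords = ds$coords,
                                   replicates = replicates, seed = seed)
  gt <- rep_out$global_tests
  row <- function(nm) gt[gt$test == nm, ]
  ps <- rep_out$per_site
  ses_of <- function(stat) mean(ps$ses[ps$statistic == stat], na.rm = TRUE)
  regr <- rep_out$regressions
  red <- if (is.null(regr)) NULL
         else regr[regr$season == "dry" & regr$response == "FD" &
                     regr$source == "observed", ]
  list(p_dFD = row("change_FD_obs_vs_null")$p,
       diff_dFD = row("change_FD_obs_vs_null")$mean_diff,
       p_dPD = row("change_PD_obs_vs_null")$p,
       diff_dPD = row("change_PD_obs_vs_null")$mean_diff,
       p_FD_dry = row("FD_dry_obs_vs_null")$p,
       diff_FD_dry = row("FD_dry_obs_vs_null")$mean_diff,
       p_PD_dry = row("PD_dry_obs_vs_null")$p,
       diff_PD_dry = row("PD_dry_obs_vs_null")$mean_diff,
       ses_FD_dry = ses_of("FD_dry"), ses_PD_dry = ses_of("PD_dry"),
       dry_fd_redundant = !is.null(red) && nrow(red) == 1 && red$redundancy)
}

#' Operating characteristics of the inferential layer under known truth
#'
#' Simulates `n_datasets` complete datasets per scenario, runs each
#' through the full pipeline, and tabulates rejection rates of the
#' observed-vs-null paired tests, the rate of the joint dry-season
#' signature (observed FD above the null mean AND observed PD below it,
#' both p < 0.05), redundancy-detection rates, and mean dry-season SES
#' of FD and PD.
#'
#' @param scenarios character vector of scenario labels (see
#'   [scenario_config()]).
#' @param n_datasets simulated datasets per scenario.
#' @param replicates null replicates per site within each dataset.
#' @param seed master seed.
#' @param alpha test level for the rejection rates.
#' @param cfg_args named list of [scenario_config()] overrides.
#' @return Data frame, one row per scenario.
#' @export
power_study <- function(scenarios = c("A", "C+D"), n_datasets = 100,
                        replicates = 200, seed = 1, alpha = 0.05,
                        cfg_args = list()) {
  do.call(rbind, lapply(scenarios, function(sc) {
    cfg <- do.call(scenario_config, c(list(scenario = sc), cfg_args))
    res <- lapply(seq_len(n_datasets), function(i) {
      ds_seed <- (seed * 100003 + hash_string(sc) + i * 7919) %% 2147483647
      ds <- simulate_dataset(cfg, seed = ds_seed)
      dataset_outcomes(ds, replicates, seed = ds_seed + 1)
    })
    g <- function(f) vapply(res, function(r) as.numeric(r[[f]]), 0)
    data.frame(
      scenario = sc, n_datasets = n_datasets, replicates = replicates,
      fd_change_reject = mean(g("p_dFD") < alpha, na.rm = TRUE),
      pd_change_reject = mean(g("p_dPD") < alpha, na.rm = TRUE),
      fd_dry_reject = mean(g("p_FD_dry") < alpha, na.rm = TRUE),
      pd_dry_reject = mean(g("p_PD_dry") < alpha, na.rm = TRUE),
      fd_dry_high_rate = mean(g("p_FD_dry") < alpha & g("diff_FD_dry") > 0,
                              na.rm = TRUE),
      pd_dry_low_rate = mean(g("p_PD_dry") < alpha & g("diff_PD_dry") < 0,
                             na.rm = TRUE),
      joint_signature_rate = mean(g("p_FD_dry") < alpha &
                                    g("diff_FD_dry") > 0 &
                                    g("p_PD_dry") < alpha &
                                    g("diff_PD_dry") < 0, na.rm = TRUE),
      redundancy_rate = mean(g("dry_fd_redundant") == 1, na.rm = TRUE),
      mean_ses_fd_dry = mean(g("ses_FD_dry"), na.rm = TRUE),
      mean_ses_pd_dry = mean(g("ses_PD_dry"), na.rm = TRUE),
      stringsAsFactors = FALSE)
  }))
}
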