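#' Site-level species pool
#'
#' All species found at a site in the wet and/or the dry season; the
#' pool from which that site's null assemblages are drawn.
#'
#' @param occ an [occ_table()].
#' @param site site identifier.
#' @return Character vector of species.
#' @export
build_pool <- function(occ, site) {
  if (!site %in% occ$sites) stop("unknown site: ", site)
  occ$species[occ$wet[site, ] == 1L | occ$dry[site, ] == 1L]
}

#' Draw one turnover-preserving null wet/dry assemblage pair
#'
#' The pool is shuffled uniformly; the first `wet_sr` species form the
#' wet-season null assemblage; the remaining `dry_only_count` species
#' (those slots that represent the observed dry-only turnover) are
#' forced into the dry-season null assemblage, which is then restocked
#' with `dry_sr - dry_only_count` species sampled without replacement
#' from the replicate's own wet null assemblage.  Null richness thus
#' equals observed richness in both seasons and observed turnover counts
#' are preserved exactly.
#'
#' @param pool vector of species (the site pool, wet union dry).
#' @param wet_sr observed wet-season richness (`x`).
#' @param dry_sr observed dry-season richness.
#' @param dry_only_count number of observed dry-only species (`y`);
#'   `length(pool)` must equal `wet_sr + dry_only_count`.
#' @return List with elements `wet` and `dry` (species vectors).
#' @export
draw_null_pair <- function(pool, wet_sr, dry_sr, dry_only_count) {
  np <- length(pool)
  if (np != wet_sr + dry_only_count)
    stop("pool size (", np, ") must equal wet_sr + dry_only_count (",
         wet_sr + dry_only_count, ")")
  if (dry_only_count > dry_sr || dry_sr > np)
    stop("need dry_only_count <= dry_sr <= pool size")
  perm <- pool[sample.int(np)]
  wet <- perm[seq_len(wet_sr)]
  forced <- if (dry_only_count > 0) perm[wet_sr + seq_len(dry_only_count)]
            else pool[0]
  restock_n <- dry_sr - dry_only_count
  restock <- if (restock_n > 0) wet[sample.int(wet_sr, restock_n)] else pool[0]
  list(wet = wet, dry = c(forced, restock))
}

#' Build the null-assemblage ensemble for every site
#'
#' Each site gets its own RNG substream derived from the master seed by
#' a stable hash of the site identifier, so adding or removing a site
#' never perturbs the draws of the others; identical seed and inputs
#' give a bit-identical ensemble.
#'
#' @param occ an [occ_table()].
#' @param replicates number of null wet/dry pairs per site (default
#'   1000).
#' @param seed master integer seed.
#' @return An object of class `null_ensemble`: per site, the pool, the
#'   richness bookkeeping (`wet_sr`, `dry_sr`, `dry_only`), and
#'   replicate-by-pool-species incidence matrices `wet` and `dry`.
#' @export
build_null_ensemble <- function(occ, replicates = 1000, seed = 1) {
  if (replicates < 1) stop("replicates must be >= 1")
  sites <- lapply(occ$sites, function(s) {
    pool <- build_pool(occ, s)
    np <- length(pool)
    x <- sum(occ$wet[s, ])
    dry_sr <- sum(occ$dry[s, ])
    y <- np - x
    W <- matrix(FALSE, replicates, np, dimnames = list(NULL, pool))
    D <- matrix(FALSE, replicates, np, dimnames = list(NULL, pool))
    with_local_seed(site_stream_seed(seed, s), {
      idx <- seq_len(np)
      for (r in seq_len(replicates)) {
        pair <- draw_null_pair(idx, x, dry_sr, y)
        W[r, pair$wet] <- TRUE
        D[r, pair$dry] <- TRUE
      }
    })
    list(site = s, pool = pool, wet_sr = x, dry_sr = dry_sr, dry_only = y,
         wet = W, dry = D)
  })
  names(sites) <- occ$sites
  structure(list(sites = sites, replicates = replicates, seed = seed,
                 species = occ$species),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("Null-assemblage ensemble: ", length(x$sites), " sites x ",
      x$replicates, " replicates (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Export a null ensemble as a long data frame
#' @param ens a [build_null_ensemble()] result.
#' @return Data frame with columns site, replicate, season, species.
#' @export
ensemble_long <- function(ens) {
  do.call(rbind, lapply(ens$sites, function(st) {
    do.call(rbind, lapply(c("wet", "dry"), function(sea) {
      idx <- which(st[[sea]], arr.ind = TRUE)
      if (!nrow(idx)) return(NULL)
      data.frame(site = st$site, replicate = idx[, 1], season = sea,
                 species = st$pool[idx[, 2]], row.names = NULL,
                 stringsAsFactors = FALSE)
    }))
  }))
}

# Expand a replicate-by-pool incidence matrix to replicate-by-context-tip,
# collapsing species that share a proxy tip with a logical OR.
expand_to_tips <- function(M, pool, ctx, tip_map = NULL) {
  tips <- if (is.null(tip_map)) pool else unname(tip_map[pool])
  cols <- match(tips, ctx$tip.label)
  if (anyNA(cols))
    stop("pool species missing from diversity context: ",
         paste(pool[is.na(cols)], collapse = ", "))
  S <- matrix(0, nrow(M), length(ctx$tip.label))
  for (k in seq_along(cols)) S[, cols[k]] <- pmax(S[, cols[k]], M[, k])
  S
}

safe_change <- function(wet, dry) ifelse(wet > 0, -1 * (1 - dry / wet), NA_real_)

#' Evaluate SR, FD and PD over a null ensemble
#'
#' Computes, for every replicate of every site, the wet- and dry-season
#' SR, FD and PD and the relative seasonal change of each, using the
#' vectorised branch-sum kernel.
#'
#' @param ens a [build_null_ensemble()] result.
#' @param dend pool-level trait dendrogram from [upgma()] (or `NULL` to
#'   skip FD).
#' @param tree phylogeny (or `NULL` to skip PD).
#' @param tip_map species -> tip mapping for PD (see [reconcile()]).
#' @param include_root root convention flag for both measures.
#' @return Object of class `ensemble_stats`: per site a data frame of
#'   per-replicate values (`SR_wet`, `SR_dry`, `FD_wet`, `FD_dry`,
#'   `PD_wet`, `PD_dry`, `dSR`, `dFD`, `dPD`).
#' @export
evaluate_ensemble <- function(ens, dend = NULL, tree = NULL, tip_map = NULL,
                              include_root = FALSE) {
  fd_ctx <- if (!is.null(dend)) diversity_context(dend)
  pd_ctx <- if (!is.null(tree)) diversity_context(tree)
  per_site <- lapply(ens$sites, function(st) {
    out <- data.frame(SR_wet = rep(st$wet_sr, nrow(st$wet)),
                      SR_dry = st$dry_sr)
    if (!is.null(fd_ctx)) {
      out$FD_wet <- branch_sums_matrix(fd_ctx,
        expand_to_tips(st$wet, st$pool, fd_ctx), include_root)
      out$FD_dry <- branch_sums_matrix(fd_ctx,
        expand_to_tips(st$dry, st$pool, fd_ctx), include_root)
    }
    if (!is.null(pd_ctx)) {
      out$PD_wet <- branch_sums_matrix(pd_ctx,
        expand_to_tips(st$wet, st$pool, pd_ctx, tip_map), include_root)
      out$PD_dry <- branch_sums_matrix(pd_ctx,
        expand_to_tips(st$dry, st$pool, pd_ctx, tip_map), include_root)
    }
    out$dSR <- safe_change(out$SR_wet, out$SR_dry)
    if (!is.null(fd_ctx)) out$dFD <- safe_change(out$FD_wet, out$FD_dry)
    if (!is.null(pd_ctx)) out$dPD <- safe_change(out$PD_wet, out$PD_dry)
    out
  })
  structure(list(per_site = per_site, replicates = ens$replicates,
                 seed = ens$seed),
            class = "ensemble_stats")
}

#' Per-site null-distribution summaries
#'
#' @param es an [evaluate_ensemble()] result.
#' @param probs quantiles to report.
#' @return Data frame: site, statistic, null mean/SD/quantiles.
#' @export
ensemble_summary <- function(es, probs = c(0.025, 0.975)) {
  do.call(rbind, lapply(names(es$per_site), function(s) {
    df <- es$per_site[[s]]
    do.call(rbind, lapply(names(df), function(v) {
      x <- df[[v]]
      qs <- quantile(x, probs, na.rm = TRUE, names = FALSE)
      data.frame(site = s, statistic = v,
                 null_mean = mean(x, na.rm = TRUE),
                 null_sd = sd(x, na.rm = TRUE),
                 null_lo = qs[1], null_hi = qs[2],
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }))
}
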