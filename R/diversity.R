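#' Branch-length sum connecting a set of tips
#'
#' The shared kernel behind both diversity measures: the sum of edge
#' lengths of the subtree induced by a set of tips.  By default the
#' subtree is rooted at the tips' most recent common ancestor (MRCA)
#' and the path above it is excluded — the branch length "needed to
#' connect" the tips; `include_root = TRUE` adds the path from the MRCA
#' up to the tree root.  A singleton set needs no branches, so it scores
#' 0 under the default convention.
#'
#' Implementation: one postorder pass counting, for each edge, how many
#' of the selected tips descend through it; an edge is part of the
#' connecting subtree iff that count is positive and (under the MRCA
#' convention) less than the set size.
#'
#' @param phy a rooted `phylo` with branch lengths.
#' @param tips character vector of tip labels (or integer tip indices).
#' @param include_root include the MRCA-to-root path.
#' @return A single nonnegative number in the tree's branch-length units.
#' @export
subtree_branch_sum <- function(phy, tips, include_root = FALSE) {
  if (length(tips) == 0) stop("empty assemblage")
  if (is.character(tips)) {
    idx <- match(unique(tips), phy$tip.label)
    if (anyNA(idx))
      stop("species not a tip of the tree/dendrogram: ",
           paste(unique(tips)[is.na(idx)], collapse = ", "))
  } else idx <- unique(as.integer(tips))
  n_sel <- length(idx)
  po <- ape::reorder.phylo(phy, "postorder")
  nnode <- length(phy$tip.label) + phy$Nnode
  cnt <- integer(nnode)
  cnt[idx] <- 1L
  e <- po$edge
  for (r in seq_len(nrow(e))) cnt[e[r, 1]] <- cnt[e[r, 1]] + cnt[e[r, 2]]
  child_cnt <- cnt[e[, 2]]
  keep <- if (include_root) child_cnt > 0 else child_cnt > 0 & child_cnt < n_sel
  sum(po$edge.length[keep])
}

#' Precompute a reusable diversity context for fast repeated evaluation
#'
#' Builds the tip-by-edge incidence matrix of a tree so that the branch
#' sums of many assemblages (e.g. thousands of null replicates) can be
#' evaluated with a single matrix product in [branch_sums_matrix()].
#'
#' @param phy a rooted `phylo` with branch lengths.
#' @return An object of class `diversity_context`.
#' @export
diversity_context <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(po$tip.label)
  nnode <- ntip + po$Nnode
  e <- po$edge
  desc <- matrix(FALSE, nnode, ntip)
  desc[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (r in seq_len(nrow(e)))
    desc[e[r, 1], ] <- desc[e[r, 1], ] | desc[e[r, 2], ]
  structure(list(tip.label = po$tip.label,
                 incidence = t(desc[e[, 2], , drop = FALSE]) * 1,  # tips x edges
                 edge.length = po$edge.length),
            class = "diversity_context")
}

#' Branch sums of many assemblages at once
#'
#' @param ctx a [diversity_context()].
#' @param S assemblage-by-tip 0/1 matrix; columns must be named by (or
#'   ordered as) the context's tip labels.
#' @param include_root include the MRCA-to-root path.
#' @return Numeric vector, one branch sum per row of `S`.
#' @export
branch_sums_matrix <- function(ctx, S, include_root = FALSE) {
  S <- as.matrix(S)
  if (!is.null(colnames(S))) {
    idx <- match(ctx$tip.label, colnames(S))
    if (anyNA(idx)) stop("S lacks columns for some context tips")
    S <- S[, idx, drop = FALSE]
  } else if (ncol(S) != length(ctx$tip.label))
    stop("S has ", ncol(S), " columns; context has ",
         length(ctx$tip.label), " tips")
  counts <- S %*% ctx$incidence
  n_sel <- rowSums(S)
  keep <- if (include_root) counts > 0 else counts > 0 & counts < n_sel
  as.vector(keep %*% ctx$edge.length)
}

#' Functional diversity of an assemblage from a trait dendrogram
#'
#' Dendrogram-based FD: the total branch length of the UPGMA trait
#' dendrogram needed to connect the assemblage's species.  The
#' dendrogram is built ONCE from the full species pool and assemblage FD
#' is obtained by pruning, so FD is monotone under species addition by
#' construction; see [fd_recluster()] for the re-clustering alternative.
#'
#' @param dend pool-level dendrogram from [upgma()].
#' @param assemblage character vector of species.
#' @param include_root include the MRCA-to-root path of the dendrogram.
#' @return FD in Gower-distance units; 0 for a singleton.
#' @export
dendrogram_fd <- function(dend, assemblage, include_root = FALSE)
  subtree_branch_sum(dend, assemblage, include_root = include_root)

#' Functional diversity by per-assemblage re-clustering
#'
#' Sensitivity-analysis variant: rebuild the UPGMA dendrogram from the
#' assemblage's own distance submatrix and sum all its branch lengths.
#' Unlike [dendrogram_fd()] this is not monotone under species addition.
#'
#' @param d pool-level distance matrix from [gower_distance()].
#' @param assemblage character vector of species.
#' @return FD in Gower-distance units; 0 for a singleton.
#' @export
fd_recluster <- function(d, assemblage) {
  assemblage <- unique(assemblage)
  if (length(assemblage) < 2) {
    if (length(assemblage) == 0) stop("empty assemblage")
    return(0)
  }
  total_branch_length(upgma(as.matrix(d)[assemblage, assemblage]))
}

#' Prune a phylogeny to a tip subset, retaining branch lengths
#'
#' Drops all other tips and collapses the resulting unbranched internal
#' nodes, summing their incident edge lengths, so that patristic
#' distances among the kept tips are preserved exactly.
#'
#' @param tree a `phylo`.
#' @param keep character vector of tip labels to retain.
#' @return The pruned `phylo`.
#' @export
prune_tree <- function(tree, keep) {
  keep <- unique(keep)
  bad <- setdiff(keep, tree$tip.label)
  if (length(bad)) stop("unknown tip(s): ", paste(bad, collapse = ", "))
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Faith-style phylogenetic diversity of an assemblage
#'
#' The sum of branch lengths of the phylogeny's subtree needed to
#' connect the assemblage's species — same MRCA-rooted convention as
#' [dendrogram_fd()], so FD and PD are directly comparable statistics.
#' Species absent from the tree are mapped through `tip_map` (from
#' [reconcile()]); species sharing a proxy tip collapse to a single tip,
#' never double-counting branch length.
#'
#' @param tree a rooted `phylo` with branch lengths (full or pruned —
#'   pruning is PD-neutral).
#' @param assemblage character vector of species.
#' @param tip_map optional named character vector mapping species to tip
#'   labels; defaults to the identity.
#' @param include_root include the MRCA-to-root path.
#' @return PD in the tree's branch-length (time) units; 0 for a single
#'   tip.
#' @export
faith_pd <- function(tree, assemblage, tip_map = NULL, include_root = FALSE) {
  if (length(assemblage) == 0) stop("empty assemblage")
  tips <- if (is.null(tip_map)) assemblage else {
    mapped <- tip_map[assemblage]
    if (anyNA(mapped))
      stop("species without tip mapping: ",
           paste(assemblage[is.na(mapped)], collapse = ", "))
    unname(mapped)
  }
  subtree_branch_sum(tree, unique(tips), include_root = include_root)
}

#' Observed per-site, per-season diversity
#'
#' @param occ an [occ_table()].
#' @param dend pool dendrogram from [upgma()].
#' @param tree a `phylo`.
#' @param tip_map species -> tip mapping (see [reconcile()]).
#' @param include_root root convention flag passed to both measures.
#' @return Data frame with columns site, season, SR, FD, PD.
#' @export
assemblage_diversity <- function(occ, dend, tree, tip_map = NULL,
                                 include_root = FALSE) {
  res <- expand.grid(site = occ$sites, season = c("wet", "dry"),
                     stringsAsFactors = FALSE)
  vals <- t(apply(res, 1, function(row) {
    m <- occ[[row[["season"]]]]
    sp <- occ$species[m[row[["site"]], ] == 1L]
    if (length(sp) == 0) return(c(0, 0, 0))
    c(length(sp),
      dendrogram_fd(dend, sp, include_root = include_root),
      faith_pd(tree, sp, tip_map = tip_map, include_root = include_root))
  }))
  res$SR <- vals[, 1]; res$FD <- vals[, 2]; res$PD <- vals[, 3]
  res
}
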