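#' UPGMA clustering of a species distance matrix into an ultrametric
#' dendrogram
#'
#' Standard unweighted pair-group average agglomeration.  Merge heights
#' are half the average inter-cluster distance, so the tip-to-root
#' height equals half the cophenetic distance and the patristic distance
#' between two tips of the returned tree equals their cophenetic
#' distance.  When two candidate merges are exactly tied, the pair whose
#' lexicographically smallest member label is smallest (then the smaller
#' partner) is merged, making the output deterministic across platforms.
#'
#' @param d symmetric distance matrix (e.g. from [gower_distance()]) or
#'   a `dist` object with labels.
#' @return An ultrametric `phylo` dendrogram over the species pool, with
#'   a `heights` attribute giving the merge heights in distance units.
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- unclass(as.matrix(d))
  n <- nrow(d)
  if (n < 2) stop("need at least 2 species to cluster")
  labels <- rownames(d)
  if (is.null(labels)) stop("distance matrix needs species labels")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix is not symmetric")

  # active clusters: id = tip index (1..n) or n + merge index
  members <- c(as.list(seq_len(n)), vector("list", n - 1))
  sizes <- c(rep(1L, n), integer(n - 1))
  min_label <- c(labels, character(n - 1))
  heights <- numeric(n - 1)
  children <- matrix(0L, n - 1, 2)
  active <- seq_len(n)
  D <- d

  for (m in seq_len(n - 1)) {
    k <- length(active)
    sub <- D[active, active, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    dmin <- min(sub)
    cand <- which(sub <= dmin + 0, arr.ind = TRUE)  # exact ties only
    if (nrow(cand) > 1) {
      key <- apply(cand, 1, function(rc) {
        labs <- sort(c(min_label[active[rc[1]]], min_label[active[rc[2]]]))
        paste(labs, collapse = "\r")
      })
      cand <- cand[order(key)[1], , drop = FALSE]
    }
    i <- active[cand[1, 1]]; j <- active[cand[1, 2]]
    heights[m] <- dmin / 2
    children[m, ] <- c(i, j)
    new_id <- n + m
    members[[new_id]] <- c(members[[i]], members[[j]])
    sizes[new_id] <- sizes[i] + sizes[j]
    min_label[new_id] <- min(min_label[i], min_label[j])
    # UPGMA update: size-weighted average of the two merged clusters
    rest <- setdiff(active, c(i, j))
    newD <- rbind(cbind(D, 0), 0)
    for (r in rest)
      newD[r, new_id] <- newD[new_id, r] <-
        (sizes[i] * D[r, i] + sizes[j] * D[r, j]) / sizes[new_id]
    D <- newD
    active <- c(rest, new_id)
  }

  phy <- merge_tree_to_phylo(children, heights, labels, n)
  attr(phy, "heights") <- heights
  phy
}

# Convert an agglomeration history (children ids per merge, merge
# heights = half average distance) into a rooted ultrametric phylo.
merge_tree_to_phylo <- function(children, heights, labels, n) {
  n_merge <- n - 1
  # ape convention: root must be node n+1; merge order is increasing in
  # height, so reverse it when assigning internal node numbers
  node_of_merge <- function(m) n + (n_merge - m + 1)
  height_of <- function(id) if (id <= n) 0 else heights[id - n]
  edges <- matrix(0L, 2 * n_merge, 2)
  elen <- numeric(2 * n_merge)
  r <- 0
  for (m in seq_len(n_merge)) {
    parent <- node_of_merge(m)
    for (child_id in children[m, ]) {
      child <- if (child_id <= n) child_id else node_of_merge(child_id - n)
      r <- r + 1
      edges[r, ] <- c(parent, child)
      elen[r] <- heights[m] - height_of(child_id)
    }
  }
  if (any(elen < -1e-12))
    stop("non-monotone merge heights (not a valid UPGMA agglomeration)")
  elen[elen < 0] <- 0
  phy <- structure(list(edge = edges, edge.length = elen,
                        tip.label = labels, Nnode = n_merge),
                   class = "phylo")
  ape::reorder.phylo(phy, "postorder")
}

#' Total branch length of a tree or dendrogram
#' @param phy a `phylo`.
#' @return Sum of all edge lengths.
#' @export
total_branch_length <- function(phy) sum(phy$edge.length)
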