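# Independent brute-force oracles; deliberately naive implementations
# that share no code with the package internals.

# Branch sum of the subtree connecting `tips`: union of each tip's
# root-path edge set; edges common to every path lie above the MRCA and
# are dropped unless include_root.
oracle_subtree_sum <- function(phy, tips, include_root = FALSE) {
  idx <- match(unique(tips), phy$tip.label)
  e <- phy$edge
  path_edges <- lapply(idx, function(tip) {
    rows <- integer(0)
    node <- tip
    repeat {
      r <- which(e[, 2] == node)
      if (!length(r)) break
      rows <- c(rows, r)
      node <- e[r, 1]
    }
    rows
  })
  edges <- unique(unlist(path_edges))
  if (!include_root)
    edges <- setdiff(edges, Reduce(intersect, path_edges))
  sum(phy$edge.length[edges])
}

# Pairwise Gower dissimilarity by an explicit per-pair, per-trait loop.
oracle_gower <- function(df, types) {
  n <- nrow(df)
  rng <- lapply(names(df), function(tr)
    if (types[[tr]] == "continuous") diff(range(df[[tr]], na.rm = TRUE)))
  names(rng) <- names(df)
  out <- matrix(0, n, n, dimnames = list(rownames(df), rownames(df)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0; m <- 0
    for (tr in names(df)) {
      xi <- df[i, tr]; xj <- df[j, tr]
      if (is.na(xi) || is.na(xj)) next
      s <- s + if (types[[tr]] == "categorical") as.numeric(xi != xj)
               else abs(xi - xj) / rng[[tr]]
      m <- m + 1
    }
    out[i, j] <- s / m
  }
  out
}
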