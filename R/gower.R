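#' Gower dissimilarity on mixed categorical/continuous traits
#'
#' For each species pair the dissimilarity is the mean, over traits
#' observed in both species, of the per-trait term: 0/1 mismatch for a
#' categorical trait, and |xi - xj| / range for a continuous trait, the
#' range being taken over the FULL species pool so that assemblage FD
#' values are comparable across sites and seasons.  Missing values are
#' dropped pairwise with reweighting; a pair with no jointly observed
#' trait is an error, not a silent zero.
#'
#' @param traits a [trait_table()] with at least 2 species.
#' @return A symmetric species-by-species matrix of class `gower_dist`,
#'   values in \[0, 1\], zero diagonal.
#' @export
gower_distance <- function(traits) {
  if (nrow(traits) < 2) stop("need at least 2 species")
  ty <- attr(traits, "trait_types")
  n <- nrow(traits)
  sp <- rownames(traits)
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (tr in names(traits)) {
    v <- traits[[tr]]
    obs <- !is.na(v)
    both <- outer(obs, obs, "&")
    if (ty[[tr]] == "categorical") {
      s <- outer(v, v, "!=") * 1
    } else {
      rng <- diff(range(v, na.rm = TRUE))
      if (rng == 0) stop("continuous trait '", tr, "' has zero range")
      s <- abs(outer(v, v, "-")) / rng
    }
    s[!both] <- 0
    num <- num + s
    den <- den + both
  }
  diag(den)[diag(den) == 0] <- 1  # all-NA rows are caught by trait_table()
  if (any(den == 0)) {
    bad <- which(den == 0, arr.ind = TRUE)[1, ]
    stop("species pair with no jointly observed traits: ",
         sp[bad[1]], " / ", sp[bad[2]])
  }
  d <- num / den
  dimnames(d) <- list(sp, sp)
  diag(d) <- 0
  structure(d, class = c("gower_dist", "matrix", "array"))
}

#' @export
print.gower_dist <- function(x, ...) {
  cat("Gower distance matrix: ", nrow(x), " species, range ",
      signif(min(x[upper.tri(x)]), 3), "-", signif(max(x), 3), "\n", sep = "")
  invisible(x)
}

#' Write a pairwise distance matrix as CSV
#' @param d symmetric distance matrix with species dimnames.
#' @param path output path.
#' @export
write_distances <- function(d, path) {
  write.csv(as.data.frame(unclass(d)), path, quote = FALSE)
  invisible(path)
}
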