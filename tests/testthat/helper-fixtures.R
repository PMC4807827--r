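# Programmatic fixtures; all randomness is seeded by the calling test.

rand_trait_table <- function(n, n_cont = 2, n_cat = 2) {
  df <- list()
  for (i in seq_len(n_cont)) df[[paste0("x", i)]] <- rnorm(n)
  for (i in seq_len(n_cat)) df[[paste0("k", i)]] <- {
    repeat {
      v <- sample(letters[1:3], n, replace = TRUE)
      if (length(unique(v)) >= 2) break
    }
    v
  }
  df <- as.data.frame(df, row.names = sprintf("sp%02d", seq_len(n)))
  trait_table(df, setNames(rep(c("continuous", "categorical"),
                               c(n_cont, n_cat)), names(df)))
}

# Build an occ_table from named lists of wet/dry species vectors.
occ_from_lists <- function(wet, dry,
                           species = sort(unique(c(unlist(wet), unlist(dry))))) {
  sites <- names(wet)
  mk <- function(l) {
    m <- matrix(0L, length(sites), length(species),
                dimnames = list(sites, species))
    for (s in sites) if (length(l[[s]])) m[s, l[[s]]] <- 1L
    m
  }
  occ_table(mk(wet), mk(dry))
}

# The worked stream: 9 wet species, 6 dry of which 2 are dry-only.
worked_example_occ <- function() {
  wet <- paste0("sp", 1:9)
  dry <- c(paste0("sp", 1:4), "sp10", "sp11")
  occ_from_lists(wet = list(s1 = wet), dry = list(s1 = dry))
}
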