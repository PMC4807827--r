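#' Construct a two-season occurrence table
#'
#' The central data container: presence/absence of each species at each
#' site in the wet and the dry season, stored as two site-by-species 0/1
#' matrices with identical dimnames.
#'
#' @param wet,dry site-by-species 0/1 matrices with matching dimnames
#'   (sites as rows, species as columns).
#' @return An object of class `occ_table` with elements `wet`, `dry`,
#'   `sites`, `species`.
#' @export
occ_table <- function(wet, dry) {
  wet <- as.matrix(wet); dry <- as.matrix(dry)
  if (!identical(dim(wet), dim(dry)))
    stop("wet and dry matrices must have identical dimensions")
  if (is.null(rownames(wet)) || is.null(colnames(wet)))
    stop("occurrence matrices need site rownames and species colnames")
  if (!identical(dimnames(wet), dimnames(dry)))
    stop("wet and dry matrices must have identical dimnames")
  if (anyDuplicated(rownames(wet))) stop("duplicated site identifiers")
  if (anyDuplicated(colnames(wet))) stop("duplicated species identifiers")
  if (!all(c(wet, dry) %in% c(0, 1)))
    stop("presence indicators must be 0 or 1")
  storage.mode(wet) <- "integer"; storage.mode(dry) <- "integer"
  empty_wet <- rownames(wet)[rowSums(wet) == 0]
  if (length(empty_wet))
    stop("site(s) with zero wet-season species: ",
         paste(empty_wet, collapse = ", "),
         " (the relative-change statistic divides by wet-season values)")
  structure(list(wet = wet, dry = dry,
                 sites = rownames(wet), species = colnames(wet)),
            class = "occ_table")
}

#' @export
print.occ_table <- function(x, ...) {
  cat("Two-season occurrence table: ", length(x$sites), " sites x ",
      length(x$species), " species\n", sep = "")
  cat("  wet-season SR: ", paste(range(rowSums(x$wet)), collapse = "-"),
      "; dry-season SR: ", paste(range(rowSums(x$dry)), collapse = "-"),
      "\n", sep = "")
  invisible(x)
}

normalise_season <- function(x, season_levels) {
  key <- tolower(trimws(x))
  out <- season_levels[key]
  bad <- unique(x[is.na(out)])
  if (length(bad))
    stop("unknown season label(s): ", paste(bad, collapse = ", "),
         " (expected one of: ", paste(names(season_levels), collapse = ", "),
         ", or supply a dialect mapping)")
  unname(out)
}

default_dialect <- function() {
  list(site = "site", season = "season", species = "species",
       season_levels = c(wet = "wet", dry = "dry"))
}

#' Read a two-season occurrence table from CSV
#'
#' Accepts either the canonical long format (columns `site`, `season`,
#' `species`; presence implied by the row) or a wide format (columns
#' `site`, `season`, then one 0/1 column per species).  Season labels are
#' matched case-insensitively and canonicalised to `"wet"`/`"dry"`;
#' additional labels can be mapped via `dialect$season_levels` (a named
#' vector, names = labels in the file, values = `"wet"` or `"dry"`).
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param dialect list overriding column names (`site`, `season`,
#'   `species`) and/or `season_levels`.
#' @return An [occ_table()].
#' @export
read_occurrences <- function(path, dialect = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  dia <- utils::modifyList(default_dialect(), dialect)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  long <- all(c(dia$site, dia$season, dia$species) %in% names(df))
  if (long) {
    df <- df[, c(dia$site, dia$season, dia$species)]
    names(df) <- c("site", "season", "species")
  } else if (all(c(dia$site, dia$season) %in% names(df))) {
    sp_cols <- setdiff(names(df), c(dia$site, dia$season))
    if (!length(sp_cols)) stop("wide occurrence file has no species columns")
    df <- do.call(rbind, lapply(sp_cols, function(sp) {
      keep <- df[[sp]] == 1
      data.frame(site = df[[dia$site]][keep], season = df[[dia$season]][keep],
                 species = sp, stringsAsFactors = FALSE)
    }))
  } else {
    stop("occurrence file must have columns ", dia$site, "/", dia$season,
         "/", dia$species, " (long) or ", dia$site, "/", dia$season,
         " plus species columns (wide)")
  }
  df$season <- normalise_season(df$season, dia$season_levels)
  if (anyDuplicated(df[c("site", "season", "species")]))
    stop("duplicate (site, season, species) rows in ", path)
  sites <- sort(unique(df$site)); species <- sort(unique(df$species))
  mk <- function(sea) {
    m <- matrix(0L, length(sites), length(species),
                dimnames = list(sites, species))
    sub <- df[df$season == sea, , drop = FALSE]
    m[cbind(match(sub$site, sites), match(sub$species, species))] <- 1L
    m
  }
  occ_table(mk("wet"), mk("dry"))
}

#' Write an occurrence table as canonical long CSV
#'
#' @param occ an [occ_table()].
#' @param path output path.
#' @export
write_occurrences <- function(occ, path) {
  rows <- lapply(c("wet", "dry"), function(sea) {
    m <- occ[[sea]]
    idx <- which(m == 1L, arr.ind = TRUE)
    data.frame(site = rownames(m)[idx[, 1]], season = sea,
               species = colnames(m)[idx[, 2]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$site, out$season, out$species), ]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a species-by-trait table with declared trait types
#'
#' Trait typing (categorical vs continuous) is always declared, never
#' inferred, because the two enter the Gower dissimilarity differently.
#'
#' @param df data frame of trait values, rownames = species identifiers.
#' @param types named character vector, one element per trait column,
#'   each `"continuous"` or `"categorical"`.
#' @return An object of class `trait_table` (a data frame with a
#'   `trait_types` attribute).
#' @export
trait_table <- function(df, types) {
  df <- as.data.frame(df)
  if (is.null(rownames(df)) || anyDuplicated(rownames(df)))
    stop("trait table needs unique species rownames")
  if (!setequal(names(types), names(df)) || anyDuplicated(names(types)))
    stop("`types` must name every trait column exactly once")
  types <- types[names(df)]
  if (!all(types %in% c("continuous", "categorical")))
    stop("trait types must be 'continuous' or 'categorical'")
  for (tr in names(df)) {
    v <- df[[tr]]
    if (all(is.na(v))) stop("trait '", tr, "' has no observed values")
    if (types[[tr]] == "continuous") {
      if (!is.numeric(v)) stop("continuous trait '", tr, "' is not numeric")
      rng <- range(v, na.rm = TRUE)
      if (diff(rng) == 0)
        stop("continuous trait '", tr, "' has zero range")
    } else {
      df[[tr]] <- as.character(v)
      if (length(unique(v[!is.na(v)])) < 2)
        stop("categorical trait '", tr, "' has fewer than 2 observed levels")
    }
  }
  structure(df, trait_types = types, class = c("trait_table", "data.frame"))
}

#' @export
print.trait_table <- function(x, ...) {
  ty <- attr(x, "trait_types")
  cat("Trait table: ", nrow(x), " species x ", ncol(x), " traits (",
      sum(ty == "continuous"), " continuous, ",
      sum(ty == "categorical"), " categorical)\n", sep = "")
  invisible(x)
}

#' Read a species-by-trait table from CSV
#'
#' The CSV must have a `species` column; the remaining columns are
#' traits.  Types are declared either by a reserved row whose `species`
#' field is `_type_` (each cell `continuous` or `categorical`) or by the
#' `types` argument; the argument wins if both are present.
#'
#' @param path path to CSV.
#' @param types optional named character vector of trait types.
#' @return A [trait_table()].
#' @export
read_traits <- function(path, types = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"species" %in% names(df)) stop("traits file needs a 'species' column")
  type_row <- df$species == "_type_"
  if (is.null(types)) {
    if (!any(type_row))
      stop("no trait types: add a '_type_' row or pass `types`")
    types <- unlist(df[which(type_row)[1], setdiff(names(df), "species")])
  }
  df <- df[!type_row, , drop = FALSE]
  sp <- df$species
  if (anyDuplicated(sp)) stop("duplicated species in traits file")
  df$species <- NULL
  rownames(df) <- sp
  for (tr in names(df))
    if (types[[tr]] == "continuous") df[[tr]] <- as.numeric(df[[tr]])
  trait_table(df, types)
}

#' Write a trait table (with its `_type_` declaration row) as CSV
#' @param traits a [trait_table()].
#' @param path output path.
#' @export
write_traits <- function(traits, path) {
  ty <- attr(traits, "trait_types")
  head_row <- data.frame(species = "_type_", as.list(ty),
                         check.names = FALSE, stringsAsFactors = FALSE)
  body <- data.frame(species = rownames(traits), traits,
                     check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(rbind(head_row, body), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rooted, branch-length-bearing phylogeny from a Newick file
#'
#' @param path path to a Newick file.
#' @return An [ape::read.tree()] `phylo` object, validated: unique tip
#'   labels, branch lengths present and nonnegative, rooted.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) stop("malformed Newick in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick in ", path)
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (anyDuplicated(tr$tip.label)) stop("duplicated tip labels in tree")
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch lengths in tree")
  if (!ape::is.rooted(tr)) stop("tree must be rooted")
  tr
}

#' Read a species-to-proxy-tip replacement map from CSV
#'
#' For species too poorly known to be placed in the phylogeny, a
#' congeneric or confamilial proxy tip stands in for PD computation.
#'
#' @param path CSV with columns `species`, `proxy`.
#' @param tree optional `phylo`; if given, proxy labels are checked
#'   against its tips.
#' @return A data frame of class `replacement_map`.
#' @export
read_replacements <- function(path, tree = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "proxy") %in% names(df)))
    stop("replacement file needs columns 'species' and 'proxy'")
  replacement_map(df, tree)
}

#' @rdname read_replacements
#' @param df data frame with columns `species`, `proxy`.
#' @export
replacement_map <- function(df, tree = NULL) {
  if (anyDuplicated(df$species))
    stop("each unplaced species may map to only one proxy tip")
  if (!is.null(tree)) {
    bad <- setdiff(df$proxy, tree$tip.label)
    if (length(bad))
      stop("proxy label(s) not in tree: ", paste(bad, collapse = ", "))
  }
  structure(df[c("species", "proxy")], class = c("replacement_map", "data.frame"))
}

#' Read site coordinates from CSV
#'
#' @param path CSV with columns `site`, `x`, `y`.
#' @param units declared coordinate units (`"m"` for projected metres or
#'   `"deg"` for decimal degrees); stored as an attribute.
#' @return A data frame of class `site_coords`.
#' @export
read_coordinates <- function(path, units = c("m", "deg")) {
  if (!file.exists(path)) stop("file not found: ", path)
  units <- match.arg(units)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("site", "x", "y") %in% names(df)))
    stop("coordinates file needs columns 'site', 'x', 'y'")
  site_coords(df, units)
}

#' @rdname read_coordinates
#' @param df data frame with columns `site`, `x`, `y`.
#' @export
site_coords <- function(df, units = c("m", "deg")) {
  units <- match.arg(units)
  if (anyDuplicated(df$site)) stop("duplicated site in coordinates")
  if (anyDuplicated(df[c("x", "y")]))
    stop("duplicated coordinate pairs (degenerate distance weights)")
  structure(df[c("site", "x", "y")], units = units,
            class = c("site_coords", "data.frame"))
}

#' Reconcile occurrences, traits, tree and replacement map
#'
#' Checks that every analysed species has a trait record and maps to
#' exactly one tree tip, either directly or via the replacement map, and
#' reports all proxy substitutions.  Species sharing a proxy tip are
#' flagged: they collapse to a single tip for PD (branch length cannot
#' be attributed twice).
#'
#' @param occ an [occ_table()].
#' @param traits a [trait_table()].
#' @param tree a `phylo`.
#' @param replacements optional [replacement_map()].
#' @return An object of class `analysis_bundle`: the validated inputs
#'   plus `tip_map` (named character, species -> tip label) and a
#'   `substitutions` data frame (`species`, `proxy`, `shared` flag).
#' @export
reconcile <- function(occ, traits, tree, replacements = NULL) {
  sp <- occ$species
  miss_tr <- setdiff(sp, rownames(traits))
  if (length(miss_tr))
    stop("species missing from trait table: ", paste(miss_tr, collapse = ", "))
  tip_map <- setNames(sp, sp)
  off_tree <- setdiff(sp, tree$tip.label)
  subs <- data.frame(species = character(), proxy = character(),
                     shared = logical(), stringsAsFactors = FALSE)
  if (length(off_tree)) {
    if (is.null(replacements))
      stop("species absent from tree with no replacement map: ",
           paste(off_tree, collapse = ", "))
    replacements <- replacement_map(as.data.frame(replacements), tree)
    unresolved <- setdiff(off_tree, replacements$species)
    if (length(unresolved))
      stop("unresolvable species (absent from tree and replacement map): ",
           paste(unresolved, collapse = ", "))
    idx <- match(off_tree, replacements$species)
    tip_map[off_tree] <- replacements$proxy[idx]
    shared_tips <- names(which(table(tip_map) > 1))
    subs <- data.frame(species = off_tree,
                       proxy = replacements$proxy[idx],
                       shared = tip_map[off_tree] %in% shared_tips,
                       stringsAsFactors = FALSE)
  }
  structure(list(occ = occ, traits = traits, tree = tree,
                 tip_map = tip_map, substitutions = subs),
            class = "analysis_bundle")
}

#' @export
print.analysis_bundle <- function(x, ...) {
  print(x$occ)
  cat("  tree tips used: ", length(unique(x$tip_map)), "; proxy substitutions: ",
      nrow(x$substitutions), "\n", sep = "")
  invisible(x)
}
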