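#' Read one or more Newick phylogenies
#'
#' Reads a file containing one or more Newick strings (one per line or
#' concatenated) and validates each tree: branch lengths must be present and
#' non-negative, and tip labels unique. Replicate order is preserved.
#'
#' @param path Path to a Newick file.
#' @return A list of `phylo` objects (length 1 for a single tree).
#' @export
read_newick <- function(path) {
  trees <- ape::read.tree(path)
  if (is.null(trees)) stop("No parseable Newick tree in '", path, "'")
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  for (i in seq_along(trees)) {
    ok <- try(validate_phylogeny(trees[[i]]), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("Tree ", i, " in '", path, "': ", attr(ok, "condition")$message)
  }
  trees
}

#' Write phylogenies to a Newick file
#'
#' @param trees A `phylo` object or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file = path)
  invisible(path)
}

#' Validate the structural invariants of a phylogeny
#'
#' Checks that the tree is rooted-compatible, has branch lengths, that all
#' branch lengths are non-negative and all tip labels unique.
#'
#' @param tree A `phylo` object.
#' @param ultrametric If `TRUE`, additionally require all root-to-tip path
#'   lengths to agree within `tol` (in the tree's length units, MY).
#' @param tol Absolute tolerance for the ultrametricity check, in MY.
#' @return `tree`, invisibly.
#' @export
validate_phylogeny <- function(tree, ultrametric = FALSE, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (anyNA(tree$edge.length))
    stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0))
    stop("tree has negative branch lengths")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "))
  if (ultrametric && length(tree$tip.label) > 1) {
    d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
    if (diff(range(d)) > tol)
      stop("tree is not ultrametric within tolerance ", tol, " MY")
  }
  invisible(tree)
}

.RL_CATEGORIES <- c("LC", "NT", "VU", "EN", "CR", "EW", "EX", "DD", "NE")
.DS_CATEGORIES <- c("LC", "NT", "VU", "EN", "CR", "EW")
.THREATENED_CATEGORIES <- c("VU", "EN", "CR", "EW")
.TREND_LEVELS <- c("decreasing", "stable", "increasing", "unknown")

#' Red List category vocabulary helpers
#'
#' `rl_categories()` returns the closed vocabulary of accepted Red List
#' category codes; `is_data_sufficient()` maps categories to the
#' data-sufficient flag (LC, NT, VU, EN, CR and EW are data sufficient; DD,
#' NE and EX are not); `is_threatened()` flags the threatened categories
#' (VU, EN, CR, plus EW which is treated as threatened throughout).
#'
#' @param category Character vector of category codes.
#' @return Character vector (categories) or logical vector (flags).
#' @export
rl_categories <- function() .RL_CATEGORIES

#' @rdname rl_categories
#' @export
is_data_sufficient <- function(category) category %in% .DS_CATEGORIES

#' @rdname rl_categories
#' @export
is_threatened <- function(category) category %in% .THREATENED_CATEGORIES

#' Read and validate a species table
#'
#' Reads a comma-delimited species table with columns `species`, `genus`,
#' `family`, `clade`, `category`, `trend` and `possibly_extinct`, validates
#' the closed vocabularies, and derives the `data_sufficient` flag from the
#' category.
#'
#' @param path Path to a CSV file with a header row.
#' @return A data.frame of species records.
#' @export
read_species_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_species_records(df)
}

#' Validate species records
#'
#' Checks required columns and closed vocabularies; (re)derives the
#' `data_sufficient` column from the category. Row numbers in error messages
#' refer to data rows (header excluded).
#'
#' @param df A data.frame of species records.
#' @return The validated data.frame with a `data_sufficient` column.
#' @export
validate_species_records <- function(df) {
  required <- c("species", "genus", "family", "clade", "category", "trend",
                "possibly_extinct")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("species table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!df$category %in% .RL_CATEGORIES)
  if (length(bad))
    stop("unknown Red List category '", df$category[bad[1]],
         "' at row ", bad[1])
  bad <- which(!df$trend %in% .TREND_LEVELS)
  if (length(bad))
    stop("unknown population trend '", df$trend[bad[1]], "' at row ", bad[1])
  dup <- df$species[duplicated(df$species)]
  if (length(dup))
    stop("duplicate species: ", paste(unique(dup), collapse = ", "))
  df$possibly_extinct <- as.logical(df$possibly_extinct)
  df$data_sufficient <- is_data_sufficient(df$category)
  df
}

#' Write a species or results table as CSV
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Normalize a taxon name for matching
#'
#' Lowercases, converts spaces to underscores and strips quote characters,
#' so that tip labels and table names written under different conventions
#' reconcile.
#'
#' @param x Character vector of names.
#' @return Normalized character vector.
#' @export
normalize_name <- function(x) {
  x <- gsub("['\"]", "", x)
  x <- gsub("[ ]+", "_", trimws(x))
  tolower(x)
}

#' Reconcile tree tips against a species table
#'
#' Applies the same name normalization to both sides and reports which
#' species match, which occur only in the tree(s), and which occur only in
#' the table (the imputation queue).
#'
#' @param trees A `phylo` or list of `phylo` objects.
#' @param records A species record data.frame.
#' @return A list with character vectors `matched`, `tree_only` and
#'   `table_only` (original table/tree spellings, sorted).
#' @export
match_tips <- function(trees, records) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  tips <- unique(unlist(lapply(trees, function(t) t$tip.label)))
  tab <- records$species
  ntip <- normalize_name(tips)
  ntab <- normalize_name(tab)
  list(
    matched    = sort(tab[ntab %in% ntip]),
    tree_only  = sort(tips[!ntip %in% ntab]),
    table_only = sort(tab[!ntab %in% ntip])
  )
}
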