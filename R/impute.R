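# Congeneric imputation: each missing species is grafted onto an edge of its
# genus (a congener's pendant edge, an internal edge of the genus crown, or
# the genus stem edge), at a height drawn uniformly along that edge. On an
# ultrametric tree the new pendant reaches the tip level, so its length
# equals the attachment height.

# node heights above the tip level (ultrametric), indexed by node id
.node_heights <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_along(tree$tip.label)]) - depth
}

# Candidate attachment edges (rows of tree$edge) for a genus given its tip
# indices. Monophyletic genera offer their crown edges plus the stem edge;
# non-monophyletic genera offer only their tips' pendant edges.
.genus_edges <- function(tree, tip_idx) {
  ntip <- length(tree$tip.label)
  if (length(tip_idx) == 1L)
    return(which(tree$edge[, 2] == tip_idx))
  mrca <- ape::getMRCA(tree, tip_idx)
  desc_tips <- .clade_tips(tree, mrca)
  if (length(desc_tips) == length(tip_idx)) {
    keep <- .clade_nodes(tree, mrca)
    which(tree$edge[, 2] %in% c(keep, mrca))
  } else {
    which(tree$edge[, 2] %in% tip_idx)
  }
}

# tip indices descending from node
.clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  e <- ape::reorder.phylo(tree, "postorder")$edge
  below <- logical(ntip + tree$Nnode)
  below[node] <- TRUE
  for (k in rev(seq_len(nrow(e))))
    if (below[e[k, 1]]) below[e[k, 2]] <- TRUE
  which(below[seq_len(ntip)])
}

# all nodes (tips + internals) strictly below node
.clade_nodes <- function(tree, node) {
  e <- ape::reorder.phylo(tree, "postorder")$edge
  below <- logical(length(tree$tip.label) + tree$Nnode)
  below[node] <- TRUE
  for (k in rev(seq_len(nrow(e))))
    if (below[e[k, 1]]) below[e[k, 2]] <- TRUE
  setdiff(which(below), node)
}

#' Impute species missing from a phylogeny into their genus
#'
#' Inserts each missing species as a new tip along an existing branch of its
#' genus, preserving ultrametricity. Insertion order is randomised, so
#' earlier imputations can host later ones. Each insertion picks uniformly
#' among the genus' eligible edges (congeners' pendant edges, internal crown
#' edges, and the genus stem edge when the genus is monophyletic; pendant
#' edges only otherwise) and then a height uniformly along the chosen edge.
#' Species whose genus has no tip in the tree are skipped and reported.
#'
#' @param tree An ultrametric `phylo` object.
#' @param records Species record data.frame with `species` and `genus`
#'   covering both present and missing species.
#' @param missing Character vector of species names to insert.
#' @param tol Ultrametricity tolerance (MY).
#' @return A list with `tree` (augmented `phylo`), `plan` (a data.frame with
#'   one row per insertion: species, genus, attachment height, pendant
#'   length) and `skipped` (character vector).
#' @export
impute_missing <- function(tree, records, missing, tol = 1e-6) {
  validate_phylogeny(tree, ultrametric = TRUE, tol = tol)
  if (!length(missing))
    return(list(tree = tree, plan = .empty_plan(), skipped = character(0)))
  genus_of <- stats::setNames(records$genus, records$species)
  if (anyNA(genus_of[missing]))
    stop("missing species absent from records: ",
         missing[is.na(genus_of[missing])][1])
  order_in <- sample(missing)
  plan <- vector("list", length(order_in))
  skipped <- character(0)
  for (i in seq_along(order_in)) {
    sp <- order_in[i]
    gen <- genus_of[[sp]]
    # congeners currently in the tree (including earlier imputations)
    present <- tree$tip.label[tree$tip.label %in%
                                names(genus_of)[genus_of == gen]]
    tip_idx <- match(present, tree$tip.label)
    if (!length(tip_idx)) {
      skipped <- c(skipped, sp)
      next
    }
    heights <- .node_heights(tree)
    cand <- .genus_edges(tree, tip_idx)
    edge_row <- if (length(cand) == 1L) cand else
      cand[sample.int(length(cand), 1L)]
    child <- tree$edge[edge_row, 2]
    len <- tree$edge.length[edge_row]
    pos <- stats::runif(1, 0, len)          # distance rootward of child
    height <- heights[child] + pos
    tree <- phytools::bind.tip(tree, sp, edge.length = height,
                               where = child, position = pos)
    plan[[i]] <- data.frame(species = sp, genus = gen,
                            attachment_height = height,
                            pendant_length = height,
                            stringsAsFactors = FALSE)
  }
  plan <- do.call(rbind, plan)
  if (is.null(plan)) plan <- .empty_plan()
  validate_phylogeny(tree, ultrametric = TRUE, tol = tol)
  list(tree = tree, plan = plan, skipped = skipped)
}

.empty_plan <- function() {
  data.frame(species = character(0), genus = character(0),
             attachment_height = numeric(0), pendant_length = numeric(0),
             stringsAsFactors = FALSE)
}
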