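# Per-branch survival products are accumulated in log space by a single
# postorder pass so that products over thousands of descendants cannot
# underflow. q = 0 is allowed as a limit (log 0 = -Inf, product 0).

# Postorder accumulation of sum(log q) over each edge's descendant tips.
# Returns a list with the postorder-reordered tree and, aligned to its edge
# rows, the log product logS and the edge lengths.
.branch_log_products <- function(tree, q) {
  ntip <- length(tree$tip.label)
  acc <- numeric(ntip + tree$Nnode)
  acc[seq_len(ntip)] <- log(q)
  po <- ape::reorder.phylo(tree, "postorder")
  e <- po$edge
  for (k in seq_len(nrow(e)))
    acc[e[k, 1]] <- acc[e[k, 1]] + acc[e[k, 2]]
  list(tree = po, logS = acc[e[, 2]], len = po$edge.length,
       node_acc = acc, ntip = ntip)
}

# Align a named or record-style assignment to the tree's tip order.
.tip_q <- function(tree, assignments) {
  if (is.data.frame(assignments)) {
    q <- assignments$q
    names(q) <- assignments$species
  } else q <- assignments
  if (is.null(names(q))) {
    if (length(q) != length(tree$tip.label))
      stop("unnamed q must have one value per tip")
    return(q)
  }
  miss <- setdiff(tree$tip.label, names(q))
  if (length(miss))
    stop("no extinction probability for tip(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  unname(q[tree$tip.label])
}

#' Total phylogenetic diversity of a tree
#'
#' Sum of all branch lengths, terminal branches included; a root edge, if
#' present, is included (it is a branch of the tree).
#'
#' @param tree A `phylo` object with branch lengths (MY).
#' @return PD in MY.
#' @export
total_pd <- function(tree) {
  validate_phylogeny(tree)
  sum(tree$edge.length) + if (is.null(tree$root.edge)) 0 else tree$root.edge
}

#' Expected loss of phylogenetic diversity
#'
#' For each branch, the expected loss is its length times the probability
#' that every descendant species goes extinct (the product of their
#' extinction probabilities); summing over all branches gives the expected
#' PD loss of the tree. A root edge is lost only if every tip goes extinct.
#'
#' @param tree A `phylo` object (lengths in MY).
#' @param assignments Extinction probabilities in [0, 1]: a data.frame with
#'   columns `species` and `q` (e.g. from [assign_weights()]), a named
#'   numeric vector, or an unnamed vector in tip order.
#' @return Expected PD loss in MY.
#' @export
expected_pd_loss <- function(tree, assignments) {
  q <- .tip_q(tree, assignments)
  if (any(q < 0 | q > 1)) stop("extinction probabilities must lie in [0, 1]")
  bp <- .branch_log_products(tree, q)
  loss <- sum(bp$len * exp(bp$logS))
  if (!is.null(tree$root.edge))
    loss <- loss + tree$root.edge * exp(sum(log(q)))
  loss
}

#' Proportion of evolutionary history threatened
#'
#' Expected PD loss as a percentage of total PD.
#'
#' @inheritParams expected_pd_loss
#' @return Percentage in [0, 100].
#' @export
proportion_threatened <- function(tree, assignments) {
  pd <- total_pd(tree)
  if (pd <= 0) stop("tree has zero total PD")
  100 * expected_pd_loss(tree, assignments) / pd
}

#' Per-clade, per-replicate summaries of threatened evolutionary history
#'
#' Computes PD, expected PD loss, the threatened percentage, and
#' per-species history for each clade and replicate, then aggregates across
#' replicates (median, quartiles, and 1.5 x IQR whisker bounds).
#'
#' @param trees_by_clade Named list (clade -> list of replicate `phylo`
#'   trees).
#' @param assignments_by_replicate List over replicates of assignment
#'   data.frames covering all clades' tips (see [assign_weights()]).
#' @param records Species record data.frame with a `clade` column.
#' @return A list with `per_replicate` (one row per clade x replicate) and
#'   `aggregate` (one row per clade) data.frames.
#' @export
clade_summaries <- function(trees_by_clade, assignments_by_replicate,
                            records) {
  rows <- list()
  for (clade in names(trees_by_clade)) {
    trees <- trees_by_clade[[clade]]
    if (!length(trees)) {
      warning("clade '", clade, "' has no trees; skipped")
      next
    }
    if (length(trees) != length(assignments_by_replicate))
      stop("replicate counts differ between trees and assignments for ",
           clade)
    for (r in seq_along(trees)) {
      tree <- trees[[r]]
      pd <- total_pd(tree)
      n <- length(tree$tip.label)
      el <- expected_pd_loss(tree, assignments_by_replicate[[r]])
      rows[[length(rows) + 1L]] <- data.frame(
        clade = clade, replicate = r, n = n, PD = pd,
        expected_PD_loss = el, proportion_threatened = 100 * el / pd,
        PD_per_species = pd / n, threatened_per_species = el / n,
        stringsAsFactors = FALSE)
    }
  }
  per_rep <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_rep, per_rep$clade), function(d) {
    qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    p <- qs(d$proportion_threatened)
    e <- qs(d$expected_PD_loss)
    iqr <- p[3] - p[1]
    data.frame(
      clade = d$clade[1], n = d$n[1], replicates = nrow(d),
      PD_median = stats::median(d$PD),
      expected_PD_loss_q1 = e[1], expected_PD_loss_median = e[2],
      expected_PD_loss_q3 = e[3],
      proportion_q1 = p[1], proportion_median = p[2], proportion_q3 = p[3],
      whisker_low = max(min(d$proportion_threatened), p[1] - 1.5 * iqr),
      whisker_high = min(max(d$proportion_threatened), p[3] + 1.5 * iqr),
      PD_per_species_median = stats::median(d$PD_per_species),
      threatened_per_species_median = stats::median(d$threatened_per_species),
      stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  list(per_replicate = per_rep, aggregate = agg)
}

#' Convert millions of years to billions of years
#'
#' @param my Value(s) in MY.
#' @return Value(s) in GY.
#' @export
my_to_gy <- function(my) my / 1000
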