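#' Terminal branch lengths
#'
#' The pendant edge subtending each tip, a minimum measure of evolutionary
#' distinctiveness that does not depend on any extinction-risk weighting.
#'
#' @param tree A `phylo` object (lengths in MY).
#' @return Named numeric vector, one TBL (MY) per tip.
#' @export
terminal_branch_lengths <- function(tree) {
  ntip <- length(tree$tip.label)
  idx <- match(seq_len(ntip), tree$edge[, 2])
  stats::setNames(tree$edge.length[idx], tree$tip.label)
}

# Shared engine for ED2/EDGE2: a postorder pass gives each branch's
# log-product of descendant q; a preorder pass accumulates, for every tip i,
# W_i = sum over internal ancestral branches j of L_j * prod_{h in C_j} q_h.
# Then EDGE2_i = q_i * TBL_i + W_i and ED2_i = TBL_i + W_i / q_i.
.edge_engine <- function(tree, assignments) {
  q <- .tip_q(tree, assignments)
  if (any(q < 0 | q > 1)) stop("extinction probabilities must lie in [0, 1]")
  bp <- .branch_log_products(tree, q)
  po <- bp$tree
  ntip <- bp$ntip
  contrib <- bp$len * exp(bp$logS)   # L_j * prod q over C_j, per edge
  nnode <- ntip + po$Nnode
  W <- numeric(nnode)
  root <- ntip + 1L
  if (!is.null(tree$root.edge))
    W[root] <- tree$root.edge * exp(sum(log(q)))
  e <- po$edge
  for (k in rev(seq_len(nrow(e)))) {      # preorder (root -> tips)
    child <- e[k, 2]
    W[child] <- W[e[k, 1]] + if (child > ntip) contrib[k] else 0
  }
  # for a tip, ancestral internal contribution lives at its parent
  parent <- e[match(seq_len(ntip), e[, 2]), 1]
  tbl <- terminal_branch_lengths(tree)[po$tip.label]
  list(tip = po$tip.label, q = q[match(po$tip.label, tree$tip.label)],
       tbl = unname(tbl), W = W[parent])
}

#' ED2 scores: expected future terminal branch length
#'
#' A species' terminal branch length plus, for every ancestral branch, that
#' branch's length times the probability that all of the branch's other
#' descendants go extinct — the expected share of shared history the
#' species will come to represent alone.
#'
#' @inheritParams expected_pd_loss
#' @return Named numeric vector of ED2 scores (MY) per tip.
#' @export
ed2_scores <- function(tree, assignments) {
  en <- .edge_engine(tree, assignments)
  ed2 <- en$tbl + ifelse(en$W == 0, 0, en$W / en$q)
  out <- stats::setNames(ed2, en$tip)
  out[tree$tip.label]
}

#' EDGE2 scores: avertable expected loss of evolutionary history
#'
#' EDGE2 = ED2 x GE2: the expected evolutionary history whose loss is
#' averted by securing the species (its own extinction probability times
#' its expected future terminal branch length). Equivalently, the drop in
#' the tree's expected PD loss when the species' extinction probability is
#' set to zero.
#'
#' @inheritParams expected_pd_loss
#' @return Named numeric vector of EDGE2 scores (MY) per tip.
#' @export
edge2_scores <- function(tree, assignments) {
  en <- .edge_engine(tree, assignments)
  out <- stats::setNames(en$q * en$tbl + en$W, en$tip)
  out[tree$tip.label]
}

#' Per-replicate species score table
#'
#' Computes TBL, ED2, EDGE2 and the sampled GE2 for every tip of one
#' replicate tree.
#'
#' @inheritParams expected_pd_loss
#' @param replicate Replicate index to record.
#' @return A data.frame with one row per species.
#' @export
species_scores <- function(tree, assignments, replicate = 1L) {
  en <- .edge_engine(tree, assignments)
  ed2 <- en$tbl + ifelse(en$W == 0, 0, en$W / en$q)
  data.frame(species = en$tip, replicate = replicate, TBL = en$tbl,
             ED2 = ed2, GE2 = en$q, EDGE2 = en$q * en$tbl + en$W,
             stringsAsFactors = FALSE)
}

#' Aggregate per-replicate scores into medians, ranks and flags
#'
#' Medians of TBL, ED2 and EDGE2 across replicates; a descending EDGE2 rank
#' (ties broken by species name for determinism); the fraction of
#' replicates in which the species' EDGE2 is strictly above its clade's
#' median for that replicate; the EDGE-species flag (above the clade median
#' in at least 95% of replicates AND in a threatened category); and a
#' top-1% flag (global rank within ceiling(n/100)).
#'
#' @param scores Data.frame of per-replicate scores, rows from
#'   [species_scores()] over all replicates (and clades).
#' @param records Species record data.frame with `clade` and `category`.
#' @param above_median_threshold Fraction of replicates required above the
#'   clade median (default 0.95).
#' @return A data.frame with one row per species.
#' @export
aggregate_and_rank <- function(scores, records,
                               above_median_threshold = 0.95) {
  clade <- records$clade[match(scores$species, records$species)]
  if (anyNA(clade))
    stop("species in scores but not in records: ",
         scores$species[which(is.na(clade))[1]])
  scores$clade <- clade
  # per replicate x clade median EDGE2, then strict comparison
  key <- interaction(scores$clade, scores$replicate, drop = TRUE)
  med <- stats::ave(scores$EDGE2, key, FUN = stats::median)
  scores$above <- scores$EDGE2 > med

  sp <- split(scores, scores$species)
  agg <- do.call(rbind, lapply(sp, function(d) data.frame(
    species = d$species[1], clade = d$clade[1], replicates = nrow(d),
    TBL_median = stats::median(d$TBL), ED2_median = stats::median(d$ED2),
    EDGE2_median = stats::median(d$EDGE2),
    above_clade_median_frac = mean(d$above), stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg$category <- records$category[match(agg$species, records$species)]
  ord <- order(-agg$EDGE2_median, agg$species)
  agg <- agg[ord, , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  agg$edge_species <-
    agg$above_clade_median_frac >= above_median_threshold &
    is_threatened(agg$category)
  agg$top1pct <- agg$rank <= ceiling(0.01 * nrow(agg))
  rownames(agg) <- NULL
  agg
}

#' Cumulative capture curve of ranked EDGE2 scores
#'
#' For each top fraction of species (by descending median EDGE2), the
#' percentage of the summed median EDGE2 captured. The curve is monotone
#' non-decreasing from 0 to 100%.
#'
#' @param aggregates Output of [aggregate_and_rank()].
#' @return A data.frame with `top_fraction` (in %) and `captured` (in %).
#' @export
capture_curve <- function(aggregates) {
  x <- aggregates$EDGE2_median[order(aggregates$rank)]
  n <- length(x)
  data.frame(top_fraction = 100 * seq_len(n) / n,
             captured = 100 * cumsum(x) / sum(x))
}

#' Evolutionary history already lost or likely lost
#'
#' The conservative accounting of the paper's lost-history estimate: the
#' sum of median terminal branch lengths over species flagged Possibly
#' Extinct or categorised EX.
#'
#' @param records Species record data.frame.
#' @param aggregates Output of [aggregate_and_rank()] (for median TBL), or
#'   any data.frame with `species` and `TBL_median`.
#' @return Lost history in MY.
#' @export
lost_history <- function(records, aggregates) {
  lost <- records$possibly_extinct | records$category == "EX"
  sp <- records$species[lost]
  sum(aggregates$TBL_median[aggregates$species %in% sp])
}
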