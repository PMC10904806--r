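# Synthetic clades with the statistical structure the analysis assumes:
# ultrametric birth-death trees, monophyletic genera and families obtained by
# cutting the tree at two nested depths, configurable Red List category
# frequencies (optionally phylogenetically clumped), a DD/NE fraction,
# population trends and Possibly Extinct flags.

#' Default simulation configuration
#'
#' Eight clades in miniature, mirroring the structure of a comprehensive
#' vertebrate assessment: one species-poor reptile-like clade, a very
#' LC-dominated bird-like clade (77% LC, 4% EN, 2% CR), and an overall
#' Data Deficient fraction of 0.08. Tip counts (60-350) and 100 replicates
#' keep a full pipeline run fast while leaving every stage non-trivial.
#'
#' @param replicates Number of replicate trees per clade.
#' @return A config list understood by [simulate_clade()] and [run_all()].
#' @export
default_sim_config <- function(replicates = 100) {
  base_freq <- c(LC = 0.55, NT = 0.10, VU = 0.15, EN = 0.12, CR = 0.08)
  bird_freq <- c(LC = 0.77, NT = 0.07, VU = 0.10, EN = 0.04, CR = 0.02)
  clades <- list(
    list(name = "cladeA_turtles",    n = 60,  category_freq = base_freq),
    list(name = "cladeB_crocs",      n = 25,  category_freq = base_freq),
    list(name = "cladeC_amphibians", n = 300, category_freq = base_freq),
    list(name = "cladeD_sharks",     n = 120, category_freq = base_freq),
    list(name = "cladeE_lizards",    n = 250, category_freq = base_freq),
    list(name = "cladeF_fish",       n = 350, category_freq = base_freq),
    list(name = "cladeG_mammals",    n = 150, category_freq = base_freq),
    list(name = "cladeH_birds",      n = 280, category_freq = bird_freq)
  )
  list(
    clades = clades,
    crown_age = 300,        # MY
    birth = 0.1, death = 0, # per-lineage rates for tree shape
    genus_depth = 80,       # MY cut defining genera (~3 spp per genus)
    family_depth = 140,     # MY cut defining families (~8 spp per family)
    dd_fraction = 0.08, ne_fraction = 0.02,
    lambda = 0,             # phylogenetic clumping of categories
    trend_freq = c(decreasing = 0.45, stable = 0.35, increasing = 0.05,
                   unknown = 0.15),
    pe_fraction = 0.1,      # Possibly Extinct fraction among CR
    missing_fraction = 0.05,
    replicates = replicates,
    jitter_noise = 0.05,    # sd of log-normal node-age jitter
    scheme = "EDGE2"
  )
}

# group tips by the edge crossing height `depth`; returns integer group ids
.cut_groups <- function(tree, depth) {
  ntip <- length(tree$tip.label)
  heights <- .node_heights(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  e <- po$edge
  grp <- integer(ntip + tree$Nnode)
  root <- ntip + 1L
  grp[root] <- root
  for (k in rev(seq_len(nrow(e)))) {   # preorder
    p <- e[k, 1]; c <- e[k, 2]
    grp[c] <- if (heights[c] < depth && depth <= heights[p]) c else grp[p]
  }
  match(grp[seq_len(ntip)], unique(grp[seq_len(ntip)]))
}

# clumped category assignment: visit tips in random order; with prob lambda
# copy the nearest already-assigned tip's category, else draw from freq
.assign_categories <- function(tree, freq, lambda) {
  ntip <- length(tree$tip.label)
  draw <- function(k) sample(names(freq), k, replace = TRUE, prob = freq)
  if (lambda <= 0 || ntip == 1L) return(draw(ntip))
  D <- stats::cophenetic(tree)
  cat <- character(ntip)
  ord <- sample.int(ntip)
  cat[ord[1]] <- draw(1)
  for (i in ord[-1]) {
    done <- which(nzchar(cat))
    if (stats::runif(1) < lambda) {
      nn <- done[which.min(D[i, done])]
      cat[i] <- cat[nn]
    } else cat[i] <- draw(1)
  }
  cat
}

#' Simulate one clade: ultrametric tree plus species table
#'
#' Simulates a birth-death tree conditioned on the tip count, rescales it to
#' the configured crown age, delineates monophyletic genera and families by
#' cutting the tree at two nested depths, and assigns Red List categories
#' (i.i.d. from the clade's frequency vector, or clumped on the tree with
#' strength `lambda`), a DD/NE fraction, population trends and Possibly
#' Extinct flags. Uses the current RNG state.
#'
#' @param clade A clade entry from the config (`name`, `n`, and optionally
#'   `category_freq`).
#' @param config A config list as from [default_sim_config()].
#' @return A list with `tree` (ultrametric `phylo`) and `records` (species
#'   data.frame).
#' @export
simulate_clade <- function(clade, config) {
  n <- clade$n
  stopifnot(n >= 1)
  if (config$genus_depth >= config$family_depth ||
      config$family_depth >= config$crown_age)
    stop("cut depths must satisfy genus_depth < family_depth < crown_age; ",
         "adjust the depths")
  if (n == 1L) {
    tree <- ape::read.tree(text = sprintf("(%s_g1_sp1:%g);", clade$name,
                                          config$crown_age))
    genus <- 1L; family <- 1L
  } else {
    tree <- ape::rphylo(n, config$birth, config$death)
    heights <- .node_heights(tree)
    tree$edge.length <- tree$edge.length * config$crown_age / max(heights)
    genus <- .cut_groups(tree, config$genus_depth)
    family <- .cut_groups(tree, config$family_depth)
  }
  genus_name <- sprintf("%s_g%d", clade$name, genus)
  species <- stats::ave(seq_len(n), genus_name, FUN = seq_along)
  labels <- sprintf("%s_sp%d", genus_name, species)
  tree$tip.label <- labels
  freq <- clade$category_freq
  freq <- freq / sum(freq)
  cat <- .assign_categories(tree, freq, config$lambda)
  u <- stats::runif(n)
  cat[u < config$dd_fraction] <- "DD"
  cat[u >= config$dd_fraction &
      u < config$dd_fraction + config$ne_fraction] <- "NE"
  trend <- sample(names(config$trend_freq), n, replace = TRUE,
                  prob = config$trend_freq)
  pe <- cat == "CR" & stats::runif(n) < config$pe_fraction
  records <- data.frame(
    species = labels, genus = genus_name,
    family = sprintf("%s_f%d", clade$name, family),
    clade = clade$name, category = cat, trend = trend,
    possibly_extinct = pe, stringsAsFactors = FALSE)
  records$data_sufficient <- is_data_sufficient(records$category)
  list(tree = tree, records = records)
}

#' Prune tips to create an imputation queue
#'
#' Removes approximately `fraction` of the tips uniformly at random while
#' guaranteeing, whenever possible, that every removed species keeps at
#' least one congener in the tree (so congeneric imputation can place it
#' back). Tips of monotypic genera are therefore not removed.
#'
#' @param tree A `phylo` object.
#' @param records Species record data.frame with `genus`.
#' @param fraction Fraction of tips to remove, in [0, 1).
#' @return A list with `tree` (pruned) and `missing` (character vector).
#' @export
prune_for_imputation <- function(tree, records, fraction) {
  stopifnot(fraction >= 0, fraction < 1)
  ntip <- length(tree$tip.label)
  k <- round(fraction * ntip)
  if (k == 0) return(list(tree = tree, missing = character(0)))
  genus <- records$genus[match(tree$tip.label, records$species)]
  remaining <- table(genus)
  removed <- character(0)
  for (tip in sample(tree$tip.label)) {
    if (length(removed) >= k) break
    g <- genus[match(tip, tree$tip.label)]
    if (remaining[[g]] >= 2L) {
      removed <- c(removed, tip)
      remaining[[g]] <- remaining[[g]] - 1L
    }
  }
  pruned <- ape::drop.tip(tree, removed)
  list(tree = pruned, missing = removed)
}

#' Jittered replicate trees
#'
#' Emulates a posterior distribution of time-calibrated trees: each
#' replicate multiplies every internal node age by an independent
#' log-normal factor (median 1, sd of log = `noise`), then restores
#' parent-older-than-child ordering by clamping on a root-to-tip pass, so
#' every replicate is ultrametric with the original topology.
#'
#' @param tree An ultrametric `phylo` object.
#' @param n_reps Number of replicates.
#' @param noise Standard deviation of the log-normal age perturbation
#'   (0 returns identical copies).
#' @return A list of `n_reps` `phylo` trees.
#' @export
jitter_replicates <- function(tree, n_reps, noise) {
  stopifnot(noise >= 0)
  if (noise == 0) return(replicate(n_reps, tree, simplify = FALSE))
  ntip <- length(tree$tip.label)
  heights <- .node_heights(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  e <- po$edge
  lapply(seq_len(n_reps), function(r) {
    h <- heights
    internal <- (ntip + 1L):(ntip + tree$Nnode)
    h[internal] <- h[internal] * exp(stats::rnorm(length(internal), 0, noise))
    h[seq_len(ntip)] <- 0
    for (k in rev(seq_len(nrow(e)))) {    # preorder: clamp child below parent
      p <- e[k, 1]; c <- e[k, 2]
      if (c > ntip && h[c] > h[p]) h[c] <- h[p]
    }
    out <- tree
    out$edge.length <- h[tree$edge[, 1]] - h[tree$edge[, 2]]
    out
  })
}

#' Simulate every clade of a config
#'
#' @param config A config list as from [default_sim_config()].
#' @return A list with `trees` (named list of `phylo` by clade) and
#'   `records` (row-bound species table).
#' @export
simulate_dataset <- function(config) {
  sims <- lapply(config$clades, simulate_clade, config = config)
  names(sims) <- vapply(config$clades, `[[`, "", "name")
  list(trees = lapply(sims, `[[`, "tree"),
       records = do.call(rbind, lapply(sims, `[[`, "records")))
}
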