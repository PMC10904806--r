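# Shared fixtures and independent oracles.

# The worked cherry: two tips (TBL 1, 1) under an internal branch of 10 MY.
cherry <- function() ape::read.tree(text = "((A:1,B:1):10);")

# Random non-ultrametric tree with uniform branch lengths (ape::rtree).
random_tree <- function(n) ape::rtree(n)

# Brute-force oracle for expected PD loss: enumerate all 2^n extinction
# outcomes, weight each by its probability, and sum the branch lengths whose
# descendant tips are all extinct. Descendant sets come from phangorn,
# independently of the package's postorder accumulation.
enum_expected_loss <- function(tree, q) {
  ntip <- length(tree$tip.label)
  stopifnot(ntip <= 14)
  outcomes <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), ntip)))
  pr <- apply(outcomes, 1, function(ext) prod(ifelse(ext, q, 1 - q)))
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  lost <- vapply(seq_along(desc), function(k) {
    d <- desc[[k]]
    rowSums(outcomes[, d, drop = FALSE]) == length(d)
  }, logical(nrow(outcomes)))
  loss <- as.vector(lost %*% tree$edge.length)
  if (!is.null(tree$root.edge))
    loss <- loss + tree$root.edge * (rowSums(outcomes) == ntip)
  sum(pr * loss)
}

# Independent ED2/EDGE2 evaluation straight from the definitions, using
# phangorn descendant sets and explicit products (no log-space tricks).
naive_species_scores <- function(tree, q) {
  ntip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  tbl_edge <- match(seq_len(ntip), tree$edge[, 2])
  vapply(seq_len(ntip), function(i) {
    tbl <- tree$edge.length[tbl_edge[i]]
    anc <- which(vapply(desc, function(d) i %in% d, logical(1)))
    anc <- setdiff(anc, tbl_edge[i])
    ed2 <- tbl + sum(vapply(anc, function(k)
      tree$edge.length[k] * prod(q[setdiff(desc[[k]], i)]), numeric(1)))
    if (!is.null(tree$root.edge))
      ed2 <- ed2 + tree$root.edge * prod(q[-i])
    c(ED2 = ed2, EDGE2 = ed2 * q[i])
  }, numeric(2))
}

# Minimal species-record table around a set of tip labels.
make_records <- function(species, genus = species, family = genus,
                         clade = "cladeX", category = "LC",
                         trend = "unknown", possibly_extinct = FALSE) {
  df <- data.frame(species = species, genus = genus, family = family,
                   clade = clade, category = category, trend = trend,
                   possibly_extinct = possibly_extinct,
                   stringsAsFactors = FALSE)
  df$data_sufficient <- is_data_sufficient(df$category)
  df
}

# A small simulated clade for structural tests.
small_sim <- function(n = 200, seed = 11, lambda = 0, dd = 0.08) {
  set.seed(seed)
  cfg <- default_sim_config()
  cfg$lambda <- lambda
  cfg$dd_fraction <- dd
  simulate_clade(list(name = "cladeX", n = n,
                      category_freq = cfg$clades[[1]]$category_freq), cfg)
}
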