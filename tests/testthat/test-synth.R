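test_that("a single-species clade is one branch of crown-age length", {
  cfg <- default_sim_config()
  set.seed(1)
  s <- simulate_clade(list(name = "solo", n = 1,
                           category_freq = c(LC = 1)), cfg)
  expect_equal(length(s$tree$tip.label), 1)
  expect_equal(total_pd(s$tree), cfg$crown_age)
  expect_equal(nrow(s$records), 1)
  expect_equal(length(unique(s$records$genus)), 1)
  expect_equal(length(unique(s$records$family)), 1)
})

test_that("simulated clades satisfy the tree and record invariants", {
  set.seed(2)
  cfg <- default_sim_config()
  s <- simulate_clade(list(name = "cladeX", n = 150,
                           category_freq = cfg$clades[[1]]$category_freq), cfg)
  expect_silent(validate_phylogeny(s$tree, ultrametric = TRUE, tol = 1e-6))
  expect_equal(max(ape::node.depth.edgelength(s$tree)), cfg$crown_age,
               tolerance = 1e-9)
  expect_silent(validate_species_records(s$records))
  expect_setequal(s$tree$tip.label, s$records$species)
  # genera are monophyletic by construction
  for (g in unique(s$records$genus)) {
    tips <- match(s$records$species[s$records$genus == g], s$tree$tip.label)
    if (length(tips) > 1) {
      clade <- phangorn::Descendants(s$tree, ape::getMRCA(s$tree, tips),
                                     "tips")[[1]]
      expect_equal(sort(clade), sort(tips))
    }
  }
  # genera nest within families
  nest <- tapply(s$records$family, s$records$genus,
                 function(x) length(unique(x)))
  expect_true(all(nest == 1))
})

test_that("an all-LC clade yields small but positive expected loss", {
  set.seed(3)
  cfg <- default_sim_config()
  cfg$dd_fraction <- 0; cfg$ne_fraction <- 0
  s <- simulate_clade(list(name = "lc", n = 80, category_freq = c(LC = 1)),
                      cfg)
  expect_true(all(s$records$category == "LC"))
  a <- assign_weights(s$records, "EDGE2", replicate_seed = 4)
  p <- proportion_threatened(s$tree, a)
  expect_gt(p, 0)
  expect_lt(p, 15)  # LC band tops out at ~8.6% per species
})

test_that("category frequencies converge to the configured vector", {
  set.seed(4)
  cfg <- default_sim_config()
  cfg$dd_fraction <- 0; cfg$ne_fraction <- 0
  freq <- c(LC = 0.5, NT = 0.1, VU = 0.2, EN = 0.1, CR = 0.1)
  s <- simulate_clade(list(name = "freq", n = 1000, category_freq = freq),
                      cfg)
  obs <- table(factor(s$records$category, levels = names(freq))) / 1000
  for (cat in names(freq))
    expect_lt(abs(obs[[cat]] - freq[[cat]]),
              4 * sqrt(freq[[cat]] * (1 - freq[[cat]]) / 1000) + 0.01)
})

test_that("phylogenetic clumping raises between-family threat variance", {
  cfg <- default_sim_config()
  cfg$dd_fraction <- 0; cfg$ne_fraction <- 0
  freq <- c(LC = 0.6, NT = 0, VU = 0, EN = 0, CR = 0.4)
  fam_var <- function(lambda, seed) {
    set.seed(seed)
    cfg$lambda <- lambda
    fr <- unlist(replicate(40, {
      s <- simulate_clade(list(name = "cl", n = 80, category_freq = freq),
                          cfg)
      tapply(is_threatened(s$records$category), s$records$family, mean)
    }, simplify = FALSE))
    var(fr)
  }
  # clumping makes whole families pure, widening the pooled distribution of
  # per-family threatened fractions
  expect_gt(fam_var(0.9, 10), 1.5 * fam_var(0, 10))
})

test_that("pruning hits the requested count and keeps congeners", {
  set.seed(6)
  sim <- small_sim(n = 200)
  p0 <- prune_for_imputation(sim$tree, sim$records, 0)
  expect_identical(ape::write.tree(p0$tree), ape::write.tree(sim$tree))
  p <- prune_for_imputation(sim$tree, sim$records, 0.2)
  expect_equal(length(p$missing), 40)
  expect_equal(length(p$tree$tip.label), 160)
  genus_of <- stats::setNames(sim$records$genus, sim$records$species)
  for (sp in p$missing)
    expect_true(any(genus_of[p$tree$tip.label] == genus_of[[sp]]),
                info = sp)
})

test_that("jittered replicates keep topology and recover the median TBL", {
  set.seed(7)
  sim <- small_sim(n = 50)
  same <- jitter_replicates(sim$tree, 3, 0)
  expect_identical(ape::write.tree(same[[1]]), ape::write.tree(sim$tree))

  reps <- jitter_replicates(sim$tree, 400, 0.05)
  for (t in reps[c(1, 200, 400)]) {
    expect_identical(t$edge, sim$tree$edge)
    d <- ape::node.depth.edgelength(t)[1:50]
    expect_lt(diff(range(d)), 1e-6)
    expect_true(all(t$edge.length >= 0))
  }
  tbl <- sapply(reps, function(t) terminal_branch_lengths(t))
  med <- apply(tbl, 1, median)
  gen <- terminal_branch_lengths(sim$tree)[rownames(tbl)]
  expect_lt(max(abs(med - gen) / gen), 0.02)
})

test_that("with fixed medians the pipeline matches the closed form exactly", {
  set.seed(8)
  cfg <- default_sim_config()
  cfg$dd_fraction <- 0; cfg$ne_fraction <- 0
  s <- simulate_clade(list(name = "det", n = 60,
                           category_freq = cfg$clades[[1]]$category_freq),
                      cfg)
  q <- stats::setNames(median_weight(s$records$category, "EDGE2"),
                       s$records$species)
  reps <- jitter_replicates(s$tree, 5, 0)
  p <- vapply(reps, proportion_threatened, numeric(1), assignments = q)
  expect_equal(p, rep(proportion_threatened(s$tree, q), 5), tolerance = 1e-12)
})
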