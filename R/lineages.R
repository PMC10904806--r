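#' Family stem ages across replicate trees
#'
#' The stem age of a family is the height (distance from the tip level) of
#' the most recent internal node shared by the family and its sister — the
#' parent of the family's MRCA; for a family represented by a single tip it
#' is the height of the tip's parent node. Stem, rather than crown, age is
#' used so monotypic families are measured consistently. Returns the median
#' across replicate trees.
#'
#' @param trees List of replicate ultrametric `phylo` trees.
#' @param records Species record data.frame with `species` and `family`.
#' @return Named numeric vector of median stem ages (MY) per family; NA for
#'   families absent from every tree.
#' @export
family_stem_ages <- function(trees, records) {
  fams <- sort(unique(records$family))
  per_tree <- sapply(trees, function(tree) {
    heights <- .node_heights(tree)
    fam_of <- records$family[match(tree$tip.label, records$species)]
    vapply(fams, function(f) {
      tips <- which(fam_of == f)
      if (!length(tips)) return(NA_real_)
      node <- if (length(tips) == 1L) tips else ape::getMRCA(tree, tips)
      parent <- tree$edge[match(node, tree$edge[, 2]), 1]
      if (is.na(parent)) return(heights[node])  # family MRCA is the root
      heights[parent]
    }, numeric(1))
  })
  if (is.null(dim(per_tree))) per_tree <- matrix(per_tree, nrow = length(fams))
  stats::setNames(apply(per_tree, 1, stats::median, na.rm = TRUE), fams)
}

#' Family-level summaries
#'
#' For each family: richness, data-sufficient and threatened counts, the
#' monotypic and fully-threatened flags, the family-level EDGE score (the
#' MEAN of its species' median EDGE2 — the expected history safeguarded by
#' acting on a random species of the family), the fraction of species with
#' a data sufficient assessment, and the median stem age. Families with no
#' species in any tree keep their threat accounting but get NA score and
#' stem-age fields (with a warning).
#'
#' @param records Species record data.frame.
#' @param aggregates Output of [aggregate_and_rank()].
#' @param trees Optional list of replicate trees for stem ages.
#' @return A data.frame with one row per family.
#' @export
family_summaries <- function(records, aggregates, trees = NULL) {
  stem <- if (!is.null(trees)) family_stem_ages(trees, records) else NULL
  out <- do.call(rbind, lapply(split(records, records$family), function(d) {
    ds <- d$data_sufficient
    thr <- is_threatened(d$category)
    sc <- aggregates$EDGE2_median[match(d$species, aggregates$species)]
    data.frame(
      family = d$family[1], clade = d$clade[1], richness = nrow(d),
      n_data_sufficient = sum(ds), n_threatened = sum(thr),
      monotypic = nrow(d) == 1L,
      fully_threatened_all = all(thr),
      fully_threatened_ds = any(ds) && all(thr[ds]),
      mean_EDGE2 = if (all(is.na(sc))) NA_real_ else mean(sc, na.rm = TRUE),
      frac_assessed = mean(ds),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(stem)) out$stem_age_median <- unname(stem[out$family])
  if (anyNA(out$mean_EDGE2))
    warning(sum(is.na(out$mean_EDGE2)),
            " family(ies) have no scored species; EDGE fields are NA")
  edge_lineage_flags(out)
}

#' Flag EDGE Lineages among family summaries
#'
#' A family is an EDGE Lineage when (1) all its data sufficient species are
#' threatened (and it has at least one), (2) its family-level EDGE score is
#' strictly above the median over all scored families, and (3) more than
#' half of its species are assessed in a data sufficient category. Also adds
#' the family rank by descending mean EDGE2.
#'
#' @param summaries Data.frame from [family_summaries()].
#' @return `summaries` with `edge_lineage` and `rank` columns.
#' @export
edge_lineage_flags <- function(summaries) {
  med <- stats::median(summaries$mean_EDGE2, na.rm = TRUE)
  summaries$edge_lineage <- summaries$fully_threatened_ds &
    !is.na(summaries$mean_EDGE2) & summaries$mean_EDGE2 > med &
    summaries$frac_assessed > 0.5
  ord <- order(-summaries$mean_EDGE2, summaries$family, na.last = TRUE)
  summaries$rank <- NA_integer_
  summaries$rank[ord] <- seq_len(nrow(summaries))
  summaries
}

#' Matched resampling null for monotypic-family population trends
#'
#' Counts the population-trend classes among species of monotypic families
#' and compares them with a null built by repeatedly drawing, without
#' replacement, random species matched to the monotypic set stratum by
#' stratum on (clade, Red List category) from the pool of species with trend
#' data. Each trend class is tested with a two-sided one-sample t-test of
#' the null counts against the observed count (no multiple-testing
#' correction, matching the original analysis); classes whose null is
#' degenerate (zero variance) are reported with NA p-values.
#'
#' @param records Species record data.frame; species with trend
#'   `"unknown"` still count as a trend class, but only species present in
#'   `records` are poolable.
#' @param n_reps Number of resampled sets (default 1000).
#' @param seed Integer seed.
#' @return A list with `observed` (named counts), `null` (matrix n_reps x
#'   classes), `tests` (data.frame with class, observed, null mean, p), and
#'   `strata` (the matched composition).
#' @export
trend_null <- function(records, n_reps = 1000, seed = 1L) {
  mono_fams <- names(which(table(records$family) == 1L))
  mono <- records[records$family %in% mono_fams, , drop = FALSE]
  if (!nrow(mono)) stop("no monotypic families in records")
  trend_null_for_set(records, mono$species, n_reps = n_reps, seed = seed)
}

#' @rdname trend_null
#' @param target_species Species names forming the observed set (for
#'   [trend_null()] these are the monotypic-family species).
#' @param pool Species records to resample from (defaults to `records`;
#'   pass a subset to restrict the pool, e.g. to species with known trends).
#' @export
trend_null_for_set <- function(records, target_species, n_reps = 1000,
                               seed = 1L, pool = records) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  target <- records[records$species %in% target_species, , drop = FALSE]
  if (!nrow(target)) stop("no target species found in records")
  observed <- table(factor(target$trend, levels = .TREND_LEVELS))
  strata <- stats::aggregate(list(n = target$species),
                             by = list(clade = target$clade,
                                       category = target$category),
                             FUN = length)
  strata <- strata[order(strata$clade, strata$category), , drop = FALSE]
  pool_by <- split(seq_len(nrow(pool)),
                   interaction(pool$clade, pool$category, drop = TRUE,
                               sep = "\r"))
  null <- matrix(0L, n_reps, length(.TREND_LEVELS),
                 dimnames = list(NULL, .TREND_LEVELS))
  for (rep in seq_len(n_reps)) {
    idx <- integer(0)
    for (s in seq_len(nrow(strata))) {
      key <- paste(strata$clade[s], strata$category[s], sep = "\r")
      avail <- pool_by[[key]]
      if (is.null(avail) || length(avail) < strata$n[s])
        stop("pool has too few species for stratum (clade=",
             strata$clade[s], ", category=", strata$category[s], ")")
      idx <- c(idx, avail[sample.int(length(avail), strata$n[s])])
    }
    null[rep, ] <- table(factor(pool$trend[idx], levels = .TREND_LEVELS))
  }
  tests <- do.call(rbind, lapply(.TREND_LEVELS, function(cl) {
    x <- null[, cl]
    p <- if (stats::var(x) == 0) NA_real_ else
      stats::t.test(x, mu = observed[[cl]])$p.value
    data.frame(class = cl, observed = observed[[cl]], null_mean = mean(x),
               null_lo = unname(stats::quantile(x, 0.025)),
               null_hi = unname(stats::quantile(x, 0.975)),
               p_value = p, stringsAsFactors = FALSE)
  }))
  list(observed = observed, null = null, tests = tests, strata = strata)
}

#' Candidate EDGE species proportions from taxonomy alone
#'
#' For each clade, among species that are threatened AND belong to a
#' monotypic or fully-threatened (data sufficient) family, the fraction
#' that also meet the phylogeny-based EDGE-species criteria — i.e. how well
#' taxonomy plus Red List status alone predicts EDGE priority.
#'
#' @param records Species record data.frame.
#' @param aggregates Output of [aggregate_and_rank()] (needs
#'   `edge_species`).
#' @param summaries Output of [family_summaries()].
#' @return A data.frame per clade with candidate counts and the proportion
#'   flagged (NA when the denominator is zero).
#' @export
candidate_edge_species <- function(records, aggregates, summaries) {
  fam_flag <- summaries$monotypic | summaries$fully_threatened_ds
  flagged_fams <- summaries$family[fam_flag]
  cand <- is_threatened(records$category) &
    records$family %in% flagged_fams
  edge_flag <- aggregates$edge_species[match(records$species,
                                             aggregates$species)]
  out <- do.call(rbind, lapply(split(seq_len(nrow(records)), records$clade),
    function(i) {
      ci <- i[cand[i]]
      data.frame(clade = records$clade[i[1]], n_candidates = length(ci),
                 n_edge = sum(edge_flag[ci], na.rm = TRUE),
                 proportion = if (length(ci)) mean(edge_flag[ci], na.rm = TRUE)
                              else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}
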