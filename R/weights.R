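#' Extinction-risk weighting schemes
#'
#' Median extinction probabilities per Red List category for the three
#' quantifications of extinction risk: `IUCN50` and `IUCN500` (Criterion-E
#' extrapolations of extinction probability 50 and 500 years ahead) and
#' `EDGE2` (the weighting used to build EDGE prioritisation lists and the
#' GBF phylogenetic-diversity indicator). The EDGE2 medians double from one
#' category to the next (0.060625, 0.12125, 0.2425, 0.485, 0.97).
#'
#' @param scheme One of `"EDGE2"`, `"IUCN50"`, `"IUCN500"` (case-insensitive).
#' @return A named numeric vector of medians for LC, NT, VU, EN, CR.
#' @export
scheme_medians <- function(scheme = c("EDGE2", "IUCN50", "IUCN500")) {
  scheme <- match.arg(toupper(scheme), c("EDGE2", "IUCN50", "IUCN500"))
  m <- switch(scheme,
    IUCN50  = c(LC = 0.00005, NT = 0.004, VU = 0.05,   EN = 0.42,  CR = 0.97),
    IUCN500 = c(LC = 0.0005,  NT = 0.02,  VU = 0.39,   EN = 0.996, CR = 1),
    EDGE2   = c(LC = 0.060625, NT = 0.12125, VU = 0.2425, EN = 0.485,
                CR = 0.97))
  m
}

.ASSESSED <- c("LC", "NT", "VU", "EN", "CR")
.Q_CAP <- 1 - 1e-9

#' Median extinction-risk weight for an assessed category
#'
#' Returns the tabulated median probability for one of the five assessed,
#' extant categories. DD/NE carry no fixed median (they are sampled across
#' the whole distribution; see [sample_weight()]); EW is mapped to the CR
#' band by the sampler; EX carries no forward risk.
#'
#' @param category A Red List category in LC, NT, VU, EN, CR.
#' @inheritParams scheme_medians
#' @return The median probability.
#' @export
median_weight <- function(category, scheme = "EDGE2") {
  m <- scheme_medians(scheme)
  bad <- setdiff(category, .ASSESSED)
  if (length(bad))
    stop("no fixed median weight for category '", bad[1],
         "'; DD/NE/EW are handled by sample_weight(), EX is excluded")
  unname(m[category])
}

#' Evaluate the category-rank-to-probability curve
#'
#' The uncertainty model places the five assessed categories at integer
#' ranks 0 (LC) to 4 (CR) and interpolates extinction probability
#' log-linearly between consecutive category medians, extending the first
#' and last segment's slope to the half-open band ends at -0.5 and 4.5.
#' Under the EDGE2 scheme the medians are exactly geometric (ratio 2), so
#' the curve is a single exponential and doubling per rank is exact.
#' Probabilities are capped at 1 - 1e-9 so log-space branch products stay
#' finite (IUCN500 prints a CR median of 1).
#'
#' @param r Numeric vector of category ranks in [-0.5, 4.5].
#' @inheritParams scheme_medians
#' @return Probabilities in (0, 1).
#' @export
risk_curve <- function(r, scheme = "EDGE2") {
  if (any(r < -0.5 | r > 4.5)) stop("rank out of [-0.5, 4.5]")
  m <- unname(scheme_medians(scheme))
  k <- pmin(pmax(floor(r), 0), 3)
  q <- m[k + 1] * (m[k + 2] / m[k + 1])^(r - k)
  pmin(q, .Q_CAP)
}

.rank_of <- c(LC = 0, NT = 1, VU = 2, EN = 3, CR = 4, EW = 4)

#' Band bounds of a category on the probability scale
#'
#' Each assessed category owns the rank interval [rank - 0.5, rank + 0.5];
#' this returns the probability values of the two band edges.
#'
#' @param category An assessed category (LC, NT, VU, EN, CR; EW maps to CR).
#' @inheritParams scheme_medians
#' @return Numeric vector `c(lower, upper)`.
#' @export
band_bounds <- function(category, scheme = "EDGE2") {
  rk <- .rank_of[[category]]
  risk_curve(c(rk - 0.5, rk + 0.5), scheme)
}

#' Sample extinction-risk weights for one category
#'
#' Implements the two-part uncertainty model. Assessed categories draw a
#' rank uniformly within their own unit band, so the median of the draws
#' equals the category's tabulated median. DD and NE species draw the rank
#' uniformly over the whole range [-0.5, 4.5]: the median draw then equals
#' the Vulnerable median and 60% of draws (3 of the 5 unit bands) fall in
#' the threatened region. EW draws from the CR band. Consumes `n` uniforms
#' from the current RNG state.
#'
#' @param category One of LC, NT, VU, EN, CR, DD, NE, EW.
#' @inheritParams scheme_medians
#' @param n Number of draws.
#' @return A data.frame with columns `r` (rank drawn) and `q` (probability).
#' @export
sample_weight <- function(category, scheme = "EDGE2", n = 1) {
  if (length(category) != 1) stop("one category at a time")
  if (category == "EX")
    stop("EX species carry no forward extinction risk; exclude them")
  if (category %in% c("DD", "NE")) {
    r <- stats::runif(n, -0.5, 4.5)
  } else if (category %in% names(.rank_of)) {
    rk <- .rank_of[[category]]
    r <- stats::runif(n, rk - 0.5, rk + 0.5)
  } else stop("unknown Red List category '", category, "'")
  data.frame(r = r, q = risk_curve(r, scheme))
}

#' Assign sampled extinction probabilities to a species table
#'
#' One independent draw per species for one replicate. Draws are consumed
#' in sorted species-name order so assignments are reproducible regardless
#' of input row order; the RNG is seeded with `replicate_seed`. EX species
#' are excluded (with a message) — their loss is accounted by
#' [lost_history()] instead.
#'
#' @param records Species record data.frame (see [read_species_table()]).
#' @inheritParams scheme_medians
#' @param replicate_seed Integer seed for this replicate.
#' @return A data.frame with `species`, `category`, `r`, `q`, `scheme`.
#' @export
assign_weights <- function(records, scheme = "EDGE2", replicate_seed) {
  ex <- records$category == "EX"
  if (any(ex))
    message(sum(ex), " EX species excluded from risk assignment")
  records <- records[!ex, , drop = FALSE]
  ord <- order(records$species)
  sp <- records$species[ord]
  cat <- records$category[ord]
  set.seed(as.integer(replicate_seed %% .Machine$integer.max))
  lo <- ifelse(cat %in% c("DD", "NE"), -0.5, .rank_of[cat] - 0.5)
  hi <- ifelse(cat %in% c("DD", "NE"), 4.5, .rank_of[cat] + 0.5)
  if (anyNA(lo)) stop("unknown Red List category in records")
  r <- stats::runif(length(sp), lo, hi)
  data.frame(species = sp, category = cat, r = r,
             q = risk_curve(r, scheme), scheme = scheme,
             stringsAsFactors = FALSE)
}
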