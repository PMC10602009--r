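# Estimators and classifiers on progeny score tables -------------------------

#' Decision thresholds for score-table classification
#'
#' `single_insert_max_fraction`: a transgene distribution of 60% or less
#' among progeny of a hemizygote x wild-type cross is interpreted as a
#' single insertion (one unlinked insert transmits to 50%, two to 75%).
#' `viability_min_fraction`: the midpoint of the theoretical marker-positive
#' expectations for homozygous viability (75%) and homozygous lethality
#' (66.7%, i.e. 2/3 of survivors), computed as (0.75 + 0.667)/2 = 0.7085 and
#' conventionally displayed as 70.8%; marker presence above it is
#' interpreted as homozygous viable.
#'
#' @export
lx_thresholds <- list(single_insert_max_fraction = 0.60,
                      viability_min_fraction = (0.75 + 0.667) / 2)

#' Minimum recombinant gametes compatible with a progeny class
#'
#' For a two-locus linked cross, scores how many of the two gametes that
#' formed a progeny individual must have been meiotic recombinants. All
#' parental gamete pairs compatible with the observed progeny class are
#' enumerated (brute force over the two parents' origin-labelled gametes)
#' and the minimum recombinant count is returned -- the maximum-parsimony
#' rule. When compatible pairs imply different counts (the classical
#' double-parental vs double-recombinant ambiguity of the trans-heterozygote
#' class), the ambiguity flag is set and the parsimonious count is used.
#'
#' @param progeny A [lx_genotype()], or a flavor label as produced by the
#'   `flavor` column of [progeny_distribution()].
#' @param cross A [lx_cross()] whose parents' haplotype arrangements are
#'   known.
#' @return List with `count` (0, 1 or 2), `ambiguous` (logical) and
#'   `counts` (all compatible recombinant counts).
#' @export
count_recombinant_gametes <- function(progeny, cross) {
  stopifnot(inherits(cross, "lx_cross"))
  genome <- cross$genome
  flav <- if (inherits(progeny, "lx_genotype"))
    flavor_label(genome, progeny) else as.character(progeny)
  gm <- enumerate_gametes(genome, cross$mother, cross$params)
  gf <- enumerate_gametes(genome, cross$father, cross$params)
  counts <- integer(0)
  for (a in gm) for (b in gf) {
    if (a$prob == 0 || b$prob == 0) next
    z <- fuse_gametes(genome, a$chrs, b$chrs)
    if (flavor_label(genome, z) == flav)
      counts <- c(counts, a$recomb + b$recomb)
  }
  if (!length(counts))
    stop("progeny class '", flav, "' is impossible under cross '",
         cross$id, "'")
  u <- sort(unique(counts))
  list(count = u[1], ambiguous = length(u) > 1L, counts = u)
}

#' Score recombinant gametes in a progeny score table
#'
#' Resolves every phenotype row of a score table to its genotype class under
#' the cross, applies [count_recombinant_gametes()] and accumulates. Every
#' scored progeny contributes two gametes to the total.
#'
#' @param score_table A score table for one two-locus linked cross (columns
#'   `phenotype`, `count`).
#' @param cross The [lx_cross()] that produced the table.
#' @return Named numeric vector with `recombinant` and `total` gamete counts.
#' @export
score_recombination <- function(score_table, cross) {
  stopifnot(is.data.frame(score_table),
            all(c("phenotype", "count") %in% names(score_table)))
  rec <- 0L
  tot <- 0L
  for (i in seq_len(nrow(score_table))) {
    n <- score_table$count[i]
    if (n == 0) next
    res <- resolve_genotypes(score_table$phenotype[i], cross)
    if (!res$unique)
      stop("phenotype '", score_table$phenotype[i],
           "' does not resolve to a unique genotype class under cross '",
           cross$id, "'")
    cr <- count_recombinant_gametes(res$flavors[1], cross)
    rec <- rec + n * cr$count
    tot <- tot + 2L * n
  }
  c(recombinant = rec, total = tot)
}

#' Two-point linkage estimate in centimorgan
#'
#' Per repetition, the recombination fraction is the number of scored
#' recombinant gametes divided by the total gametes; the genetic linkage in
#' cM is 100 times the arithmetic mean of the per-repetition fractions, with
#' the sample standard deviation (n - 1 denominator) on the same scale.
#'
#' @param repetitions A data frame (or matrix, or list of length-2 vectors)
#'   with columns `recombinant` and `total`, one row per independent
#'   repetition; every total must be positive and at least the recombinant
#'   count.
#' @return A `lx_linkage_estimate`: list with `table` (per-repetition
#'   counts and fractions), `mean_cM` and `sd_cM` (`NA` with a single
#'   repetition).
#' @examples
#' estimate_linkage(data.frame(recombinant = c(98, 96, 147),
#'                             total = c(1248, 1171, 1651)))
#' @export
estimate_linkage <- function(repetitions) {
  if (is.list(repetitions) && !is.data.frame(repetitions))
    repetitions <- do.call(rbind, lapply(repetitions, function(x)
      data.frame(recombinant = x[[1]], total = x[[2]])))
  if (is.matrix(repetitions)) repetitions <- as.data.frame(repetitions)
  if (!all(c("recombinant", "total") %in% names(repetitions)))
    repetitions <- stats::setNames(repetitions[, 1:2],
                                   c("recombinant", "total"))
  if (!nrow(repetitions)) stop("at least one repetition is required")
  with(repetitions, {
    if (any(total <= 0)) stop("every gamete total must be > 0")
    if (any(recombinant < 0 | recombinant > total))
      stop("recombinant counts must lie in [0, total]")
  })
  frac <- repetitions$recombinant / repetitions$total
  out <- list(table = data.frame(recombinant = repetitions$recombinant,
                                 total = repetitions$total,
                                 fraction = frac),
              mean_cM = 100 * mean(frac),
              sd_cM = if (length(frac) > 1L) 100 * stats::sd(frac) else NA_real_)
  class(out) <- "lx_linkage_estimate"
  out
}

#' @export
print.lx_linkage_estimate <- function(x, ...) {
  cat(sprintf("<linkage estimate> %.2f cM", x$mean_cM))
  if (!is.na(x$sd_cM)) cat(sprintf(" ± %.2f cM", x$sd_cM))
  cat(sprintf("  (%d repetition%s)\n", nrow(x$table),
              if (nrow(x$table) == 1) "" else "s"))
  invisible(x)
}

#' Cre excision bias from flavor counts
#'
#' From the counts of post-recombination progeny retaining the first-slot
#' versus the second-slot marker, estimates the excision bias: `ratio` is
#' first:second (how many times more often the second-slot marker was
#' excised than the first) and `beta_hat` is the estimated probability that
#' excision leaves the first-slot marker.
#'
#' @param first_only Count of progeny with only the first-slot marker.
#' @param second_only Count of progeny with only the second-slot marker.
#' @return List with `ratio` (`Inf` when `second_only` is 0) and `beta_hat`.
#' @examples
#' estimate_cre_bias(500, 100)  # ratio 5, beta_hat 5/6
#' @export
estimate_cre_bias <- function(first_only, second_only) {
  stopifnot(first_only >= 0, second_only >= 0)
  if (first_only + second_only == 0)
    stop("at least one post-recombination progeny count must be positive")
  list(ratio = if (second_only == 0) Inf else first_only / second_only,
       beta_hat = first_only / (first_only + second_only))
}

#' Expected marker-positive fraction for k independent inserts
#'
#' A hemizygote for k unlinked single inserts transmits at least one insert
#' to `1 - (1/2)^k` of its progeny in a cross with wild type.
#'
#' @param k Number of independent (unlinked) inserts.
#' @return Expected marker-positive fraction.
#' @export
expected_marker_fraction <- function(k) {
  stopifnot(k >= 1)
  1 - 0.5^k
}

#' Classify insert number from a hemizygote x wild-type cross
#'
#' A transgene distribution of 60% or less among the progeny is interpreted
#' as a single insertion (theoretical 50% for one insert, 75% for two).
#'
#' @param marker_positive Number of marker-positive progeny.
#' @param total Total scored progeny (> 0).
#' @return List with `fraction`, `classification` (`"single"` or
#'   `"multiple"`) and `threshold`.
#' @export
classify_insert_number <- function(marker_positive, total) {
  if (total <= 0) stop("total must be > 0")
  if (marker_positive < 0 || marker_positive > total)
    stop("marker_positive must lie in [0, total]")
  f <- marker_positive / total
  list(fraction = f,
       classification = if (f <= lx_thresholds$single_insert_max_fraction)
         "single" else "multiple",
       threshold = lx_thresholds$single_insert_max_fraction)
}

#' Classify homozygous viability from a hemizygous sibling cross
#'
#' Marker presence in more than 70.85% of the scored descendants -- the
#' midpoint of the theoretical expectations for homozygous viability (75%)
#' and homozygous lethality (66.7% of survivors) -- is interpreted as
#' homozygous viable.
#'
#' @param marker_positive Number of marker-positive progeny.
#' @param total Total scored progeny (> 0).
#' @return List with `fraction`, `classification` (`"viable"` or
#'   `"lethal"`) and the derived `threshold` (0.7085).
#' @export
classify_viability <- function(marker_positive, total) {
  if (total <= 0) stop("total must be > 0")
  if (marker_positive < 0 || marker_positive > total)
    stop("marker_positive must lie in [0, total]")
  f <- marker_positive / total
  thr <- lx_thresholds$viability_min_fraction
  list(fraction = f,
       classification = if (f > thr) "viable" else "lethal",
       threshold = thr)
}

#' One-sample two-tailed t-test of observed ratios against a theoretical ratio
#'
#' Tests whether the arithmetic mean of observed progeny ratios differs
#' significantly from the theoretical Mendelian ratio:
#' t = (mean - theoretical) / (sd / sqrt(n)) on n - 1 degrees of freedom,
#' two-tailed.
#'
#' @param observed Numeric vector of observed per-repetition fractions
#'   (length >= 2, nonzero variance).
#' @param theoretical The theoretical ratio to test against.
#' @return A `lx_ratio_test`: list with `mean`, `theoretical`, `t`, `df`,
#'   `p` and `stars` (`"*"` for P<0.05 up to `"****"` for P<0.0001).
#' @export
t_test_vs_theoretical <- function(observed, theoretical) {
  if (length(observed) < 2L)
    stop("at least 2 observations are required (df = n - 1 >= 1)")
  if (stats::var(observed) == 0)
    stop("observations have zero variance; the t statistic is undefined")
  ht <- stats::t.test(observed, mu = theoretical, alternative = "two.sided")
  out <- list(mean = mean(observed), theoretical = theoretical,
              t = unname(ht$statistic), df = unname(ht$parameter),
              p = ht$p.value, stars = significance_stars(ht$p.value))
  class(out) <- "lx_ratio_test"
  out
}

significance_stars <- function(p) {
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

#' @export
print.lx_ratio_test <- function(x, ...) {
  cat(sprintf(
    "<ratio test> mean %.4f vs theoretical %.4f: t = %.3f, df = %d, p = %.3g %s\n",
    x$mean, x$theoretical, x$t, x$df, x$p, x$stars))
  invisible(x)
}
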